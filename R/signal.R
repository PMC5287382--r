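#' MRI acquisition parameters
#'
#' Scanner settings of the dynamic T1-weighted 3D MPRAGE protocol plus the
#' relaxometric constants needed to map Gd-DTPA concentration to signal.
#' Defaults follow a 3 T protocol: TR 1500 ms, TE 3.7 ms, TI 900 ms, flip 12
#' degrees, 0.5 mm isotropic voxels, acquisitions at 0.5, 1, 1.5, 2, 3, 4, 5,
#' 6, 7 and 8 h post-injection.
#'
#' @param TR Repetition time, ms.
#' @param TE Echo time, ms (carried for provenance; the signal laws used here
#'   model T1 enhancement only).
#' @param TI Inversion time, ms (used by the inversion-prepared law).
#' @param flip_angle Excitation flip angle, degrees, in (0, 90).
#' @param r1 Longitudinal relaxivity of the tracer, 1/(mM s). Default 3.7,
#'   typical for Gd-DTPA at 3 T.
#' @param T1_baseline Tissue T1 without tracer, ms. Default 1400 (deep grey
#'   matter at 3 T).
#' @param S0 Equilibrium signal scale, arbitrary units.
#' @param time_points Acquisition times, h post-injection, strictly increasing.
#' @param law Signal law: `"satrec"` (saturation recovery,
#'   S = S0 (1 - exp(-TR R1)), default) or `"inversion"` (inversion-prepared,
#'   S = S0 (1 - 2 exp(-TI R1) + exp(-TR R1))). Both are strictly increasing
#'   in concentration.
#' @return Object of class `acquisition_params`.
#' @export
acquisition_params <- function(TR = 1500, TE = 3.7, TI = 900, flip_angle = 12,
                               r1 = 3.7, T1_baseline = 1400, S0 = 1000,
                               time_points = c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8),
                               law = c("satrec", "inversion")) {
  law <- match.arg(law)
  if (any(c(TR, TI, T1_baseline, r1, S0) <= 0)) {
    stop("TR, TI, T1_baseline, r1 and S0 must all be > 0")
  }
  if (flip_angle <= 0 || flip_angle >= 90) stop("flip_angle must be in (0, 90)")
  if (length(time_points) && (any(time_points < 0) ||
                              is.unsorted(time_points, strictly = TRUE))) {
    stop("time_points must be strictly increasing and non-negative")
  }
  structure(list(TR = TR, TE = TE, TI = TI, flip_angle = flip_angle, r1 = r1,
                 T1_baseline = T1_baseline, S0 = S0,
                 time_points = as.numeric(time_points), law = law),
            class = "acquisition_params")
}

# Longitudinal relaxation rate, 1/s, as a function of concentration (mM).
relaxation_rate <- function(C, acq) 1000 / acq$T1_baseline + acq$r1 * C

#' Signal as a function of tracer concentration
#'
#' Applies the configured signal law. R1(C) = 1/T1_baseline + r1 C; the law
#' maps R1 to magnitude signal. Strictly increasing in C, so invertible.
#'
#' @param C Concentration, mM (any numeric array); must be non-negative.
#' @param acq An [acquisition_params()].
#' @return Signal, same shape as `C`.
#' @export
signal_model <- function(C, acq) {
  if (any(C < 0)) stop("negative concentration")
  R1 <- relaxation_rate(C, acq) / 1000  # 1/ms
  if (acq$law == "satrec") {
    acq$S0 * (1 - exp(-acq$TR * R1))
  } else {
    acq$S0 * (1 - 2 * exp(-acq$TI * R1) + exp(-acq$TR * R1))
  }
}

# Inverse of signal_model: concentration from absolute signal. Analytic for
# the saturation-recovery law; monotone interpolation + Newton polish for the
# inversion-prepared law. S must lie within the law's range.
invert_signal <- function(S, acq) {
  if (acq$law == "satrec") {
    R1 <- -log(pmax(1 - S / acq$S0, .Machine$double.xmin)) / acq$TR * 1000
    (R1 - 1000 / acq$T1_baseline) / acq$r1
  } else {
    cgrid <- seq(0, 50, length.out = 2001L)
    sgrid <- signal_model(cgrid, acq)
    keep <- c(TRUE, diff(sgrid) > 0)  # drop the numerically saturated flat top
    C <- stats::approx(sgrid[keep], cgrid[keep], xout = S, rule = 2)$y
    for (i in 1:4) {  # Newton steps; law is smooth and monotone
      f <- signal_model(C, acq) - S
      h <- 1e-4
      df <- (signal_model(C + h, acq) - signal_model(pmax(C - h, 0), acq)) /
        (C + h - pmax(C - h, 0))
      C <- pmax(C - f / df, 0)
    }
    C
  }
}

#' Convert a concentration series to MRI frames
#'
#' Forward signal model: builds the pre-injection baseline volume (C = 0) and
#' one post-injection frame per time point. Noise is added separately with
#' [add_rician_noise()].
#'
#' @param conc A `concentration_series`.
#' @param acq An [acquisition_params()] whose `time_points` (h) correspond to
#'   `conc$times` (s); if lengths differ, times are taken from `conc`.
#' @param subject_id,group Labels carried into the series.
#' @return An `image_series`: `grid`, `baseline` (3D), `frames` (4D),
#'   `times` (h post-injection), `subject_id`, `group`.
#' @export
concentration_to_signal <- function(conc, acq, subject_id = "sub-01",
                                    group = "custom") {
  stopifnot(inherits(conc, "concentration_series"),
            inherits(acq, "acquisition_params"))
  if (any(!is.finite(conc$values))) stop("concentration values must be finite")
  frames <- signal_model(conc$values, acq)
  baseline <- array(signal_model(0, acq), dim = conc$grid$shape)
  image_series(conc$grid, baseline, frames, times = conc$times / 3600,
               subject_id = subject_id, group = group)
}

#' Construct an image series
#'
#' A baseline (pre-injection) volume plus timestamped post-injection frames.
#'
#' @param grid A [voxel_grid()].
#' @param baseline 3D array matching `grid$shape`.
#' @param frames 4D array, dims `c(grid$shape, length(times))`.
#' @param times Hours post-injection.
#' @param subject_id,group Labels.
#' @return Object of class `image_series`.
#' @export
image_series <- function(grid, baseline, frames, times,
                         subject_id = "sub-01", group = "custom") {
  stopifnot(inherits(grid, "voxel_grid"))
  baseline <- as.array(baseline)
  frames <- as.array(frames)
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  if (!identical(dim(baseline), grid$shape)) {
    stop("baseline shape must equal grid shape")
  }
  if (!identical(dim(frames), as.integer(c(grid$shape, length(times))))) {
    stop("frames dims must be c(grid$shape, length(times))")
  }
  structure(list(grid = grid, baseline = baseline, frames = frames,
                 times = as.numeric(times), subject_id = subject_id,
                 group = group),
            class = "image_series")
}

#' Add Rician noise to magnitude images
#'
#' Magnitude MRI noise: each voxel value A is replaced by
#' sqrt((A + sigma Z1)^2 + (sigma Z2)^2) with independent standard normal Z.
#' `noise_sigma = 0` is the identity; a given `seed` makes the call
#' reproducible without disturbing the caller's RNG stream.
#'
#' @param x Numeric array of magnitude signal.
#' @param noise_sigma Noise standard deviation per channel, signal units.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(x, noise_sigma, seed = NULL) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma == 0) return(x)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(x)
  out <- sqrt((x + stats::rnorm(n, sd = noise_sigma))^2 +
              stats::rnorm(n, sd = noise_sigma)^2)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Noise level corresponding to a baseline signal-to-noise ratio
#'
#' Returns the `noise_sigma` (as a fraction of S0, the unit used by
#' [group_scenario()]) at which the pre-injection tissue signal has the given
#' SNR.
#'
#' @param acq An [acquisition_params()].
#' @param snr Target baseline SNR (> 0).
#' @return Fraction of S0.
#' @export
snr_to_noise_sigma <- function(acq, snr) {
  stopifnot(snr > 0)
  (signal_model(0, acq) / snr) / acq$S0
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %s (%s): baseline + %d frames at %s h\n",
              x$subject_id, x$group, length(x$times),
              paste(x$times, collapse = ", ")))
  invisible(x)
}
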