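#' Rigid integer-voxel registration to the pre-injection baseline
#'
#' Each post-injection frame is aligned to the baseline by the integer-voxel
#' translation (within `+/- max_shift` per axis) maximising normalised
#' cross-correlation over the overlapping region. Head-fixed small-animal
#' acquisitions drift by at most a voxel or two, so integer translation is
#' sufficient and keeps the operation exactly invertible. The baseline must
#' carry spatial structure (anatomy) for the correlation to lock onto;
#' structure-free volumes give noise-driven estimates.
#'
#' @param series An `image_series`.
#' @param max_shift Non-negative integer search radius, voxels. 0 is the
#'   identity transform.
#' @return The registered `image_series`, with an attribute `shifts`
#'   (frames x 3 matrix of applied corrections, voxels).
#' @export
register_series <- function(series, max_shift = 2L) {
  stopifnot(inherits(series, "image_series"))
  max_shift <- as.integer(max_shift)
  if (max_shift < 0) stop("max_shift must be >= 0")
  nt <- length(series$times)
  shifts <- matrix(0L, nt, 3, dimnames = list(NULL, c("dx", "dy", "dz")))
  if (max_shift > 0) {
    for (i in seq_len(nt)) {
      fr <- series$frames[, , , i]
      if (stats::sd(fr) == 0) {
        warning(sprintf("frame %d is constant; leaving it unshifted", i))
        next
      }
      s <- best_shift(series$baseline, fr, max_shift)
      shifts[i, ] <- s
      if (any(s != 0L)) series$frames[, , , i] <- shift_volume(fr, s)
    }
  }
  attr(series, "shifts") <- shifts
  series
}

# Translate a 3D volume by integer voxels, zero-filling exposed edges.
shift_volume <- function(vol, s) {
  d <- dim(vol)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (abs(s[a]) >= d[a]) return(out)
    if (s[a] >= 0) {
      dst[[a]] <- (1 + s[a]):d[a]; src[[a]] <- 1:(d[a] - s[a])
    } else {
      dst[[a]] <- 1:(d[a] + s[a]); src[[a]] <- (1 - s[a]):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# Exhaustive integer-shift search maximising correlation with the baseline
# over the overlap region. Returns the shift to APPLY to the frame.
best_shift <- function(baseline, frame, max_shift) {
  d <- dim(baseline)
  rng <- -max_shift:max_shift
  best <- c(0L, 0L, 0L); best_cc <- -Inf
  for (sx in rng) for (sy in rng) for (sz in rng) {
    s <- c(sx, sy, sz)
    ix <- overlap_idx(d[1], s[1]); iy <- overlap_idx(d[2], s[2])
    iz <- overlap_idx(d[3], s[3])
    b <- baseline[ix$dst, iy$dst, iz$dst]
    f <- frame[ix$src, iy$src, iz$src]
    cc <- suppressWarnings(stats::cor(as.vector(b), as.vector(f)))
    if (is.na(cc)) cc <- -Inf
    if (cc > best_cc) { best_cc <- cc; best <- s }
  }
  best
}

overlap_idx <- function(n, s) {
  if (s >= 0) list(dst = (1 + s):n, src = 1:(n - s))
  else list(dst = 1:(n + s), src = (1 - s):n)
}

#' Subtract the baseline from every frame
#'
#' The signal increment over the pre-injection baseline, voxel by voxel.
#' Negative increments (noise) are preserved so that the background noise
#' scale can be estimated honestly; clipping to zero happens only at the
#' concentration-conversion step. The background noise scale
#' `noise_sigma_est` is the standard deviation of increments pooled over the
#' eight 5x5x5-voxel corner blocks, which the tracer never reaches.
#'
#' @param series A registered `image_series`.
#' @return An `increment_series`: `grid`, `times` (h), `values` (4D, signal
#'   units), `noise_sigma_est`.
#' @export
subtract_baseline <- function(series) {
  stopifnot(inherits(series, "image_series"))
  values <- series$frames - as.vector(series$baseline)
  structure(list(grid = series$grid, times = series$times, values = values,
                 noise_sigma_est = corner_noise_sd(values),
                 subject_id = series$subject_id, group = series$group),
            class = "increment_series")
}

# SD of increments over the eight corner blocks (block edge b, capped at the
# volume size). Returns 0 for noiseless data.
corner_noise_sd <- function(values, b = 5L) {
  d <- dim(values)[1:3]
  b <- pmin(b, d)
  idx <- function(n, k) list(head = 1:k, tail = (n - k + 1):n)
  vals <- c()
  for (cx in idx(d[1], b[1])) for (cy in idx(d[2], b[2]))
    for (cz in idx(d[3], b[3])) {
      vals <- c(vals, as.vector(values[cx, cy, cz, ]))
    }
  stats::sd(vals)
}

#' Convert signal increments to tracer concentration
#'
#' Numerically inverts the configured signal law: for each voxel the absolute
#' signal `baseline + increment` is mapped back to the Gd-DTPA concentration
#' that produces it. Negative increments map to 0. Increments at or beyond
#' the signal produced by `C_max` (where the T1 law has saturated and the
#' inverse is ill-conditioned) are clipped to `C_max` and flagged; the
#' fraction clipped is reported and clipped voxels are recorded so the model
#' fit can exclude them.
#'
#' @param inc An `increment_series`.
#' @param acq The [acquisition_params()] that produced the series.
#' @param C_max Largest invertible concentration, mM. Default 10.
#' @param t_offset Model-clock shift, s, carried to the concentration series
#'   (infusion-midpoint convention; default 300 s for a 600 s infusion).
#' @param headroom_snr On noisy data, a sample is also flagged as saturated
#'   when the remaining signal headroom to the law's supremum is below
#'   `headroom_snr x noise_sigma_est` - there the inverse map amplifies noise
#'   without bound. Default 3.
#' @return A `concentration_series` (times in s post-injection) with
#'   attributes `clip_fraction`, `clipped` (logical 4D array, present only if
#'   any voxel clipped), `noise_sigma_est` (signal units) and
#'   `noise_sigma_conc` (first-order concentration-scale noise),
#'   `max_increment` (3D array of per-voxel maxima over time, for masking).
#' @export
signal_to_concentration <- function(inc, acq, C_max = 10, t_offset = 300,
                                    headroom_snr = 3) {
  stopifnot(inherits(inc, "increment_series"),
            inherits(acq, "acquisition_params"))
  s_base <- signal_model(0, acq)
  sup_inc <- signal_model(C_max, acq) - s_base
  # signal supremum of the law as C -> Inf (both laws tend to S0)
  s_sup <- acq$S0
  sigma <- inc$noise_sigma_est
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 1e-6 * acq$S0) sigma <- 0
  cap_inc <- sup_inc
  if (sigma > 0) {
    cap_inc <- min(sup_inc, (s_sup - headroom_snr * sigma) - s_base)
  }
  v <- inc$values
  clipped <- v >= cap_inc
  v[v < 0] <- 0
  v[clipped] <- cap_inc
  C <- invert_signal(s_base + v, acq)
  C[C < 0] <- 0
  C <- pmin(C, C_max)
  # slope of the law at C = 0, signal units per mM
  eps <- 1e-6
  slope0 <- (signal_model(eps, acq) - s_base) / eps
  out <- concentration_series(inc$grid, inc$times * 3600, C,
                              t_offset = t_offset)
  attr(out, "clip_fraction") <- mean(clipped)
  if (any(clipped)) attr(out, "clipped") <- clipped
  attr(out, "noise_sigma_est") <- inc$noise_sigma_est
  attr(out, "noise_sigma_conc") <- inc$noise_sigma_est / slope0
  nt <- length(inc$times)
  max_inc <- inc$values[, , , 1]
  if (nt > 1) for (i in 2:nt) max_inc <- pmax(max_inc, inc$values[, , , i])
  attr(out, "max_increment") <- max_inc
  # raw increments + acquisition let the model fit work in signal space,
  # where the noise is homoscedastic and symmetric
  attr(out, "increments") <- inc$values
  attr(out, "acq") <- acq
  out$subject_id <- inc$subject_id
  out$group <- inc$group
  out
}
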