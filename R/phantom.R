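#' Group scenario for phantom studies
#'
#' Describes one experimental group to emulate: central ground-truth
#' parameters, between-subject variability, image noise and group size. The
#' three groups of the motivating experiment (sham, rotenone, madopar-treated
#' rotenone; n = 10 each) are available via [reference_scenarios()].
#'
#' @param name Group label.
#' @param true_params A [diffusion_clearance_model()] holding central values.
#' @param between_subject_cv Fractional coefficient of variation applied
#'   (log-normally) to D_star and k_prime across subjects; 0 disables.
#' @param noise_sigma Rician noise scale as a fraction of S0 (see
#'   [snr_to_noise_sigma()]); 0 disables.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed for the scenario's randomness.
#' @return Object of class `group_scenario`.
#' @export
group_scenario <- function(name, true_params, between_subject_cv = 0,
                           noise_sigma = 0, n_subjects = 10L, seed = 1L) {
  stopifnot(inherits(true_params, "diffusion_clearance_model"))
  if (between_subject_cv < 0) stop("between_subject_cv must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(name = name, true_params = true_params,
                 between_subject_cv = between_subject_cv,
                 noise_sigma = noise_sigma,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "group_scenario")
}

#' Central parameter values of the three experimental groups
#'
#' Effective diffusion coefficient D* and clearance rate constant k' central
#' values for the sham, rotenone-lesioned and madopar-treated groups, as used
#' throughout the recovery tests.
#'
#' @return Named list of [diffusion_clearance_model()] objects.
#' @export
reference_scenarios <- function() {
  list(
    sham     = diffusion_clearance_model(D_star = 2.770e-4, k_prime = 0.648e-4),
    rotenone = diffusion_clearance_model(D_star = 5.828e-4, k_prime = 0.333e-4),
    madopar  = diffusion_clearance_model(D_star = 3.645e-4, k_prime = 0.500e-4)
  )
}

# Log-normal draw with mean `m` and coefficient of variation `cv`.
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a phantom study for one group
#'
#' Draws per-subject ground-truth parameters (log-normal around the scenario's
#' central values), simulates each subject's concentration field on the grid
#' at the acquisition schedule, converts to MRI signal, and adds Rician noise.
#' The per-subject truth is returned alongside the images so downstream
#' recovery can be scored.
#'
#' @param scenario A [group_scenario()].
#' @param grid A [voxel_grid()]. Default 64^3 at 0.5 mm, source at centre.
#' @param acq An [acquisition_params()]; its `time_points` (h) define the
#'   schedule.
#' @param source_mode Passed to [simulate_concentration_field()].
#' @return List with `subjects` (list of `image_series`) and `truth`
#'   (data.frame of subject_id, group, D_star, k_prime, Q, alpha).
#' @export
generate_phantom_study <- function(scenario, grid = voxel_grid(),
                                   acq = acquisition_params(),
                                   source_mode = "instantaneous") {
  stopifnot(inherits(scenario, "group_scenario"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  p0 <- scenario$true_params
  n <- scenario$n_subjects
  D <- rlnorm_cv(n, p0$D_star, scenario$between_subject_cv)
  k <- rlnorm_cv(n, p0$k_prime, scenario$between_subject_cv)
  sigma <- scenario$noise_sigma * acq$S0
  times_s <- acq$time_points * 3600
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    m_i <- diffusion_clearance_model(
      D_star = D[i], k_prime = k[i], Q = p0$Q, alpha = p0$alpha,
      source_position = p0$source_position,
      infusion_duration = p0$infusion_duration)
    conc <- simulate_concentration_field(m_i, grid, times_s,
                                         source_mode = source_mode)
    ser <- concentration_to_signal(conc, acq,
                                   subject_id = sprintf("%s-%02d",
                                                        scenario$name, i),
                                   group = scenario$name)
    if (sigma > 0) {
      ser$baseline <- add_rician_noise(ser$baseline, sigma)
      ser$frames <- add_rician_noise(ser$frames, sigma)
    }
    subjects[[i]] <- ser
  }
  truth <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = scenario$name, D_star = D, k_prime = k,
    Q = p0$Q, alpha = p0$alpha, stringsAsFactors = FALSE)
  list(subjects = subjects, truth = truth)
}

#' Write a phantom study to disk as NIfTI-1 volumes
#'
#' One directory per study: per subject either a baseline file plus one file
#' per time point, or a single 4D file (baseline first), controlled by
#' `nifti_4d`; plus a `manifest.csv` sidecar with subject, group, time points
#' and ground-truth parameters.
#'
#' @param study Result of [generate_phantom_study()].
#' @param dir Output directory (created if missing).
#' @param nifti_4d Write one 4D file per subject instead of per-frame files.
#' @return Invisibly, the manifest data.frame.
#' @export
write_phantom_study <- function(study, dir, nifti_4d = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ser in study$subjects) {
    pix <- ser$grid$voxel_size
    if (nifti_4d) {
      vol <- array(c(ser$baseline, ser$frames),
                   dim = c(ser$grid$shape, length(ser$times) + 1L))
      f <- file.path(dir, paste0(ser$subject_id, ".nii"))
      RNifti::writeNifti(RNifti::asNifti(vol, pixdim = pix), f)
      files <- basename(f)
    } else {
      fb <- file.path(dir, paste0(ser$subject_id, "_baseline.nii"))
      RNifti::writeNifti(RNifti::asNifti(ser$baseline, pixdim = pix), fb)
      files <- basename(fb)
      for (i in seq_along(ser$times)) {
        fi <- file.path(dir, sprintf("%s_frame%02d.nii", ser$subject_id, i))
        RNifti::writeNifti(RNifti::asNifti(ser$frames[, , , i], pixdim = pix), fi)
        files <- c(files, basename(fi))
      }
    }
    rows[[ser$subject_id]] <- data.frame(
      subject_id = ser$subject_id, group = ser$group,
      times_h = paste(ser$times, collapse = ";"),
      files = paste(files, collapse = ";"),
      nifti_4d = nifti_4d, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  truth <- study$truth[, setdiff(names(study$truth), "group"), drop = FALSE]
  manifest <- merge(manifest, truth, by = "subject_id", sort = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Plain numeric array from a niftiImage (drops image metadata attributes).
strip_nifti <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim = dim(a))
}

#' Read a phantom study written by [write_phantom_study()]
#'
#' @param dir Study directory containing `manifest.csv`.
#' @return List with `subjects` (list of `image_series`) and `truth`.
#' @export
read_phantom_study <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  subjects <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    times <- as.numeric(strsplit(row$times_h, ";")[[1]])
    files <- file.path(dir, strsplit(row$files, ";")[[1]])
    if (isTRUE(row$nifti_4d)) {
      img <- RNifti::readNifti(files[1])
      vol <- strip_nifti(img)
      baseline <- vol[, , , 1]
      frames <- vol[, , , -1, drop = FALSE]
      pix <- RNifti::pixdim(img)[1:3]
      shp <- dim(baseline)
    } else {
      img <- RNifti::readNifti(files[1])
      baseline <- strip_nifti(img)
      pix <- RNifti::pixdim(img)[1:3]
      shp <- dim(baseline)
      frames <- array(0, dim = c(shp, length(times)))
      for (i in seq_along(times)) {
        frames[, , , i] <- as.array(RNifti::readNifti(files[i + 1]))
      }
    }
    grid <- voxel_grid(shp, pix)
    subjects[[r]] <- image_series(grid, baseline, frames, times,
                                  subject_id = row$subject_id,
                                  group = row$group)
  }
  truth_cols <- intersect(c("subject_id", "group", "D_star", "k_prime",
                            "Q", "alpha"), names(manifest))
  list(subjects = subjects, truth = manifest[, truth_cols])
}
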