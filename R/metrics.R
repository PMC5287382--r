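#' Spreading-region volume time course
#'
#' The "lightened" region at each time point is the set of voxels whose
#' signal increment exceeds a threshold; its volume is the voxel count times
#' the voxel volume (0.125 mm^3 at 0.5 mm isotropic). The threshold defaults
#' to `k_sigma` times the background noise estimate and is always reported
#' with the curve.
#'
#' @param inc An `increment_series`.
#' @param k_sigma Threshold multiplier over `noise_sigma_est`. Default 3.
#' @param threshold Absolute threshold (signal units) overriding `k_sigma`.
#' @return Object of class `spread_curve`: `times` (h), `volumes` (mm^3),
#'   `v_max`, `t_max` (h, time of the maximum), `threshold_used`.
#' @export
spread_volume_timecourse <- function(inc, k_sigma = 3, threshold = NULL) {
  stopifnot(inherits(inc, "increment_series"))
  if (is.null(threshold)) {
    if (is.null(inc$noise_sigma_est) || inc$noise_sigma_est <= 0) {
      stop("noise_sigma_est is not positive; supply an absolute threshold")
    }
    threshold <- k_sigma * inc$noise_sigma_est
  }
  ord <- order(inc$times)
  vv <- voxel_volume(inc$grid)
  volumes <- vapply(ord, function(i) sum(inc$values[, , , i] > threshold) * vv,
                    0)
  times <- inc$times[ord]
  if (all(volumes == 0)) {
    warning("no voxel exceeds the enhancement threshold at any time")
  }
  imax <- which.max(volumes)
  structure(list(times = times, volumes = volumes,
                 v_max = volumes[imax], t_max = times[imax],
                 threshold_used = threshold),
            class = "spread_curve")
}

#' Clearance half-life of the tracer
#'
#' t1/2 is the time for the total in-brain tracer amount to fall to half its
#' peak. The default log-linear method regresses log A(t) on t over the
#' post-peak window (peak point onward) and returns ln(2) / decay rate; the
#' interpolation method returns the time, measured from the peak, at which
#' A(t) first crosses A(peak)/2 (log-linear interpolation between samples).
#' For a perfect exponential the two agree exactly. Scale-invariant in A.
#'
#' @param times Sampling times. Interpreted in the unit given by `time_unit`
#'   and converted so that the result is in minutes.
#' @param amounts Total tracer amounts A(t), any consistent unit; must be
#'   positive over the fit window.
#' @param method `"loglinear"` (default) or `"interpolation"`.
#' @param time_unit Unit of `times`: `"min"`, `"h"` or `"s"`.
#' @return Object of class `half_life_result`: `t_half` (min), `method`,
#'   `fit_window` (indices into the sorted curve), `decay_rate` (1/min).
#' @export
estimate_half_life <- function(times, amounts,
                               method = c("loglinear", "interpolation"),
                               time_unit = c("min", "h", "s")) {
  method <- match.arg(method)
  time_unit <- match.arg(time_unit)
  stopifnot(length(times) == length(amounts))
  fac <- switch(time_unit, min = 1, h = 60, s = 1 / 60)
  ord <- order(times)
  t_min <- times[ord] * fac
  A <- amounts[ord]
  ipk <- which.max(A)
  win <- ipk:length(A)
  if (sum(A[win] > 0) < 3L) {
    stop("no measurable clearance: need at least 3 post-peak time points ",
         "with positive amounts")
  }
  tw <- t_min[win][A[win] > 0]
  Aw <- A[win][A[win] > 0]
  if (method == "loglinear") {
    co <- stats::coef(stats::lm(log(Aw) ~ tw))
    rate <- -co[[2]]
    if (rate <= 0) stop("no measurable clearance: post-peak amounts do not decline")
    t_half <- log(2) / rate
  } else {
    half <- Aw[1] / 2
    below <- which(Aw <= half)
    if (!length(below)) stop("no measurable clearance: amounts never fall to half the peak")
    j <- below[1]
    if (j == 1L) {
      t_half <- 0
    } else {
      # log-linear interpolation between the bracketing samples
      lw <- log(Aw[j - 1]); lb <- log(Aw[j])
      frac <- (log(half) - lw) / (lb - lw)
      t_half <- (tw[j - 1] + frac * (tw[j] - tw[j - 1])) - tw[1]
    }
    rate <- log(2) / t_half
  }
  structure(list(t_half = t_half, method = method,
                 fit_window = win, decay_rate = rate),
            class = "half_life_result")
}
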