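# Independent oracles used across the suite. These deliberately do not call
# the package's kernels: each is a direct transcription of the mathematics.

# Point-source diffusion-clearance field (instantaneous source at origin of
# strength Q/alpha), evaluated at scalar radius r (mm) and time t (s).
oracle_point_source <- function(r, t, Q = 20, alpha = 0.2, D, k) {
  (Q / alpha) * (4 * pi * D * t)^(-3 / 2) * exp(-r^2 / (4 * D * t) - k * t)
}

# Explicit finite-difference (FTCS) solver for dC/dt = D lap(C) - k C on a
# cubic grid with spacing h (mm) and zero-gradient boundaries. C0 is the
# initial 3D field at t0; returns the field after `steps` steps of size dt.
oracle_fd_evolve <- function(C0, D, k, h, dt, steps) {
  C <- C0
  d <- dim(C)
  ip <- function(n) c(2:n, n); im <- function(n) c(1, 1:(n - 1))
  for (s in seq_len(steps)) {
    lap <- (C[ip(d[1]), , ] + C[im(d[1]), , ] +
            C[, ip(d[2]), ] + C[, im(d[2]), ] +
            C[, , ip(d[3])] + C[, , im(d[3])] - 6 * C) / h^2
    C <- C + dt * (D * lap - k * C)
  }
  C
}

# Brute-force one-way ANOVA from explicit sums of squares.
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Small helper fixtures -------------------------------------------------

# A compact noiseless sham-like study on a reduced grid (fast fits).
small_grid <- function(n = 33L, vs = 1) voxel_grid(rep(n, 3), rep(vs, 3))

sham_model <- function(...) {
  diffusion_clearance_model(D_star = 2.770e-4, k_prime = 0.648e-4, ...)
}

standard_schedule_s <- function() c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8) * 3600
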