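test_that("voxel grid validates its geometry", {
  g <- voxel_grid(c(4, 4, 4), c(0.5, 0.5, 0.5))
  expect_equal(voxel_volume(g), 0.125)
  expect_error(voxel_grid(c(0, 4, 4)), "shape")
  expect_error(voxel_grid(c(4, 4, 4), c(0.5, 0, 0.5)), "voxel_size")
  # default grid is centred on the origin
  expect_equal(axis_coords(voxel_grid(c(5, 5, 5), c(1, 1, 1)), 1),
               c(-2, -1, 0, 1, 2))
})

test_that("closed-form field matches the independently computed value", {
  # frozen value computed with a separate script before implementation
  m <- sham_model(infusion_duration = 0)
  g <- voxel_grid(c(3, 1, 1), c(1, 1, 1), origin = c(-1, 0, 0))
  cs <- simulate_concentration_field(m, g, 3600)
  expect_equal(cs$values[3, 1, 1, 1], 1.389380189733131, tolerance = 1e-6)
  # and the transcribed oracle agrees
  expect_equal(cs$values[3, 1, 1, 1],
               oracle_point_source(1, 3600, D = 2.770e-4, k = 0.648e-4),
               tolerance = 1e-12)
})

test_that("mass is conserved without clearance and decays at exp(-k't) with it", {
  g <- voxel_grid(c(48, 48, 48), c(1, 1, 1))
  m0 <- diffusion_clearance_model(2.770e-4, 0, infusion_duration = 0)
  cs <- simulate_concentration_field(m0, g, c(1800, 3600, 14400, 28800))
  amt <- total_amount(cs, alpha = m0$alpha)
  expect_equal(amt, rep(m0$Q, 4), tolerance = 0.01)

  mk <- sham_model(infusion_duration = 0)
  csk <- simulate_concentration_field(mk, g, c(3600, 7200))
  amtk <- total_amount(csk, alpha = mk$alpha)
  # frozen decay factor exp(-0.648e-4 * 3600)
  expect_equal(amtk[2] / amtk[1], 0.7919318015732493, tolerance = 0.01)
})

test_that("spatial profile is radially non-increasing from the source", {
  m <- sham_model()
  g <- voxel_grid(c(33, 33, 33), c(1, 1, 1))
  cs <- simulate_concentration_field(m, g, c(1800, 14400))
  mid <- 17
  for (i in 1:2) {
    line <- cs$values[mid:33, mid, mid, i]
    expect_true(all(diff(line) <= 1e-12))
  }
})

test_that("peak time at fixed radius matches r^2/(6D) for k' = 0", {
  D <- 2.770e-4
  m <- diffusion_clearance_model(D, 0, infusion_duration = 0)
  g <- voxel_grid(c(9, 1, 1), c(1, 1, 1), origin = c(-4, 0, 0))
  times <- seq(600, 7200, by = 60)
  cs <- simulate_concentration_field(m, g, times)
  curve <- cs$values[7, 1, 1, ]  # r = 2 mm
  t_peak <- times[which.max(curve)]
  expect_equal(t_peak, 4 / (6 * D), tolerance = 0.05)
})

test_that("invalid inputs to the simulator are rejected", {
  m <- sham_model()
  g <- small_grid()
  expect_error(simulate_concentration_field(m, g, c(-10, 3600)), "times")
  expect_error(simulate_concentration_field(m, g, 0), "times")
  m_out <- diffusion_clearance_model(2.77e-4, 0, source_position = c(99, 0, 0))
  expect_error(simulate_concentration_field(m_out, g, 3600), "outside")
  expect_error(diffusion_clearance_model(-1e-4, 0), "D_star")
  expect_error(diffusion_clearance_model(1e-4, -1), "k_prime")
  expect_error(diffusion_clearance_model(1e-4, 0, alpha = 1.5), "alpha")
})

test_that("extended-source mode agrees with the midpoint approximation", {
  m <- sham_model()  # 600 s infusion
  g <- voxel_grid(c(17, 17, 17), c(1, 1, 1))
  t <- standard_schedule_s()[c(1, 5, 10)]
  inst <- simulate_concentration_field(m, g, t, source_mode = "instantaneous")
  ext <- simulate_concentration_field(m, g, t, source_mode = "extended")
  # 10 min infusion vs first scan at 30 min: sub-percent agreement in L2
  # (pointwise error is larger only in the exponential far tail)
  for (i in seq_along(t)) {
    a <- inst$values[, , , i]; b <- ext$values[, , , i]
    expect_lt(sqrt(sum((a - b)^2) / sum(b^2)), if (i == 1) 0.02 else 0.005)
  }
})

test_that("signal law is monotone, anchored at baseline, and linear at small C", {
  acq <- acquisition_params()
  C <- seq(0, 5, by = 0.05)
  S <- signal_model(C, acq)
  expect_true(all(diff(S) > 0))
  expect_equal(S[1], signal_model(0, acq))
  # first-order linearity: doubling a small dose doubles the increment
  d1 <- signal_model(0.002, acq) - signal_model(0, acq)
  d2 <- signal_model(0.004, acq) - signal_model(0, acq)
  expect_equal(d2 / d1, 2, tolerance = 0.05)
  expect_error(signal_model(-0.1, acq), "negative")
  # inversion-prepared law is also monotone
  acq_ir <- acquisition_params(law = "inversion")
  expect_true(all(diff(signal_model(C, acq_ir)) > 0))
})

test_that("zero dose reproduces the baseline frame exactly", {
  acq <- acquisition_params()
  g <- voxel_grid(c(8, 8, 8), c(1, 1, 1))
  cs <- concentration_series(g, c(1800, 3600, 5400),
                             array(0, c(8, 8, 8, 3)))
  ser <- concentration_to_signal(cs, acq)
  for (i in 1:3) expect_equal(ser$frames[, , , i], ser$baseline)
})

test_that("Rician noise is seeded, reproducible, and unbiased at high SNR", {
  x <- array(100, c(40, 50, 50))
  expect_identical(add_rician_noise(x, 0), x)
  a <- add_rician_noise(x, 2, seed = 11)
  b <- add_rician_noise(x, 2, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, add_rician_noise(x, 2, seed = 12)))
  # A/sigma = 50: mean over 1e5 voxels within 0.5% of A
  expect_equal(mean(a), 100, tolerance = 0.005)
  expect_error(add_rician_noise(x, -1), "noise_sigma")
})

test_that("phantom studies are reproducible and degenerate correctly", {
  acq <- acquisition_params(time_points = c(0.5, 1, 2))
  g <- voxel_grid(c(12, 12, 12), c(2, 2, 2))
  m <- sham_model()
  scen0 <- group_scenario("g0", m, between_subject_cv = 0, noise_sigma = 0,
                          n_subjects = 3, seed = 5)
  st0 <- generate_phantom_study(scen0, g, acq)
  expect_identical(st0$subjects[[1]]$frames, st0$subjects[[2]]$frames)
  expect_identical(st0$subjects[[2]]$frames, st0$subjects[[3]]$frames)

  scen1 <- group_scenario("g1", m, between_subject_cv = 0.2,
                          noise_sigma = 0.01, n_subjects = 2, seed = 9)
  a <- generate_phantom_study(scen1, g, acq)
  b <- generate_phantom_study(scen1, g, acq)
  expect_identical(a$subjects[[1]]$frames, b$subjects[[1]]$frames)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$subjects[[1]]$frames, a$subjects[[2]]$frames))
  # log-normal draws stay positive and carry the requested spread
  expect_true(all(a$truth$D_star > 0))
})

test_that("phantom studies round-trip through NIfTI on disk", {
  acq <- acquisition_params(time_points = c(0.5, 1))
  g <- voxel_grid(c(10, 10, 10), c(0.5, 0.5, 0.5))
  scen <- group_scenario("rt", sham_model(), 0, 0.01, 2, 3)
  st <- generate_phantom_study(scen, g, acq)
  for (use4d in c(FALSE, TRUE)) {
    dir <- withr::local_tempdir()
    write_phantom_study(st, dir, nifti_4d = use4d)
    back <- read_phantom_study(dir)
    expect_equal(length(back$subjects), 2)
    expect_equal(back$subjects[[1]]$frames, st$subjects[[1]]$frames,
                 tolerance = 1e-6)
    expect_equal(back$subjects[[2]]$baseline, st$subjects[[2]]$baseline,
                 tolerance = 1e-6)
    expect_equal(back$truth$D_star, st$truth$D_star, tolerance = 1e-8)
  }
})
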