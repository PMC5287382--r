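make_small_study <- function(noise_sigma = 0, seed = 3, n = 24L, vs = 1) {
  acq <- acquisition_params(time_points = c(0.5, 1, 2, 4))
  g <- voxel_grid(rep(n, 3), rep(vs, 3))
  scen <- group_scenario("s", sham_model(), 0, noise_sigma, 1, seed)
  list(ser = generate_phantom_study(scen, g, acq)$subjects[[1]], acq = acq,
       grid = g)
}

# Registration needs spatial structure to lock onto; build a series whose
# baseline carries smooth "anatomy" shared by every frame, plus tracer
# enhancement and Rician noise at the requested SNR.
make_anatomy_study <- function(snr = 15, seed = 3, n = 24L) {
  set.seed(seed)
  g <- voxel_grid(rep(n, 3), rep(1, 3))
  co <- lapply(1:3, function(a) axis_coords(g, a))
  anat <- 600 +
    150 * outer(outer(sin(co[[1]] / 3), cos(co[[2]] / 4), `+`),
                sin(co[[3]] / 5), `+`)
  dim(anat) <- g$shape
  cs <- simulate_concentration_field(sham_model(), g, c(0.5, 1, 2) * 3600)
  enh <- 400 * cs$values / max(cs$values)
  sigma <- mean(anat) / snr
  baseline <- add_rician_noise(anat, sigma)
  frames <- array(0, c(g$shape, 3))
  for (i in 1:3) frames[, , , i] <- add_rician_noise(anat + enh[, , , i], sigma)
  image_series(g, baseline, frames, c(0.5, 1, 2))
}

test_that("registration recovers synthetically injected shifts", {
  ser <- make_anatomy_study()
  s_inj <- c(2L, -1L, 0L)
  shifted <- ser
  for (i in seq_along(ser$times)) {
    shifted$frames[, , , i] <- issmri:::shift_volume(ser$frames[, , , i], s_inj)
  }
  reg <- register_series(shifted, max_shift = 3)
  sh <- attr(reg, "shifts")
  for (i in seq_along(ser$times)) {
    expect_equal(unname(sh[i, ]), -s_inj)
  }
  # interior voxels restored exactly (integer shifts are lossless)
  expect_equal(reg$frames[5:20, 5:20, 5:20, 2], ser$frames[5:20, 5:20, 5:20, 2])
})

test_that("registration is the identity on aligned series and max_shift 0", {
  ser <- make_anatomy_study(seed = 4)
  reg <- register_series(ser, max_shift = 2)
  expect_true(all(attr(reg, "shifts") == 0))
  expect_identical(reg$frames, ser$frames)
  reg0 <- register_series(ser, max_shift = 0)
  expect_identical(reg0$frames, ser$frames)
  expect_error(register_series(ser, max_shift = -1), "max_shift")
})

test_that("constant frames trigger a warning and zero shift", {
  st <- make_small_study()
  ser <- st$ser
  ser$frames[, , , 1] <- 7
  expect_warning(reg <- register_series(ser, max_shift = 1), "constant")
  expect_true(all(attr(reg, "shifts")[1, ] == 0))
})

test_that("baseline subtraction is exact, linear, and preserves sign", {
  st <- make_small_study()
  inc <- subtract_baseline(st$ser)
  # noiseless phantom: increment = S(C) - S(0) exactly
  expect_equal(inc$values[, , , 1],
               st$ser$frames[, , , 1] - st$ser$baseline)
  # identical frame -> all-zero increments
  ser0 <- st$ser
  for (i in seq_along(ser0$times)) ser0$frames[, , , i] <- ser0$baseline
  expect_true(all(subtract_baseline(ser0)$values == 0))
  # linearity under global scaling
  ser2 <- st$ser
  ser2$baseline <- 2 * ser2$baseline
  ser2$frames <- 2 * ser2$frames
  expect_equal(subtract_baseline(ser2)$values, 2 * inc$values)
})

test_that("pure-noise increments have zero mean within 3 SEM", {
  set.seed(21)
  g <- voxel_grid(c(30, 30, 30), c(1, 1, 1))
  base <- add_rician_noise(array(500, c(30, 30, 30)), 20)
  fr <- array(add_rician_noise(array(500, c(30, 30, 30, 2)), 20),
              c(30, 30, 30, 2))
  ser <- image_series(g, base, fr, c(1, 2))
  inc <- subtract_baseline(ser)
  n <- length(inc$values)
  expect_lt(abs(mean(inc$values)), 3 * stats::sd(inc$values) / sqrt(n))
  # corner-block estimate close to the true increment noise (sigma*sqrt(2))
  expect_equal(inc$noise_sigma_est, 20 * sqrt(2), tolerance = 0.15)
})

test_that("signal-to-concentration round trip is exact on noiseless data", {
  for (law in c("satrec", "inversion")) {
    acq <- acquisition_params(time_points = c(0.5, 1, 2, 4), law = law)
    g <- voxel_grid(c(24, 24, 24), c(1, 1, 1))
    cs <- simulate_concentration_field(sham_model(), g,
                                       acq$time_points * 3600)
    ser <- concentration_to_signal(cs, acq)
    inc <- subtract_baseline(ser)
    back <- signal_to_concentration(inc, acq)
    rel <- abs(back$values - cs$values) / pmax(cs$values, 1e-9)
    expect_lt(max(rel[cs$values > 1e-4]), 1e-3)
    expect_equal(attr(back, "clip_fraction"), 0)
  }
})

test_that("zero increment maps to zero concentration; small increments are linear", {
  acq <- acquisition_params()
  g <- voxel_grid(c(6, 6, 6), c(1, 1, 1))
  vals <- array(0, c(6, 6, 6, 3))
  inc <- structure(list(grid = g, times = c(1, 2, 3), values = vals,
                        noise_sigma_est = 0), class = "increment_series")
  conc <- signal_to_concentration(inc, acq)
  expect_true(all(conc$values == 0))
  # small increment: C ~ increment / slope at C = 0 within 5%
  slope0 <- (signal_model(1e-6, acq) - signal_model(0, acq)) / 1e-6
  vals2 <- vals; vals2[] <- 0.02 * slope0  # C ~ 0.02 mM
  inc2 <- structure(list(grid = g, times = c(1, 2, 3), values = vals2,
                         noise_sigma_est = 0), class = "increment_series")
  conc2 <- signal_to_concentration(inc2, acq)
  expect_equal(mean(conc2$values), 0.02, tolerance = 0.05)
  # negative increments are clipped to zero concentration only here
  vals3 <- vals; vals3[] <- -5
  inc3 <- structure(list(grid = g, times = c(1, 2, 3), values = vals3,
                         noise_sigma_est = 0), class = "increment_series")
  expect_true(all(signal_to_concentration(inc3, acq)$values == 0))
})

test_that("saturated increments are clipped, flagged, and reported", {
  acq <- acquisition_params()
  g <- voxel_grid(c(6, 6, 6), c(1, 1, 1))
  sup_inc <- acq$S0 - signal_model(0, acq)
  vals <- array(0, c(6, 6, 6, 2))
  vals[1:3, 1, 1, 1] <- sup_inc  # increment at the law's supremum
  inc <- structure(list(grid = g, times = c(1, 2), values = vals,
                        noise_sigma_est = 0), class = "increment_series")
  conc <- signal_to_concentration(inc, acq, C_max = 10)
  expect_equal(attr(conc, "clip_fraction"), 3 / length(vals))
  expect_true(all(conc$values[1:3, 1, 1, 1] == 10))
  expect_true(all(conc$values <= 10))
})
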