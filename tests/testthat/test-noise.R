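test_that("bump amplitude is the mean of the ten highest rates", {
  r <- c(rep(12, 10), rep(0, 350))
  expect_equal(memory_amplitude_estimate(r), 12)
  expect_equal(memory_amplitude_estimate(rep(7, 360)), 7)
  expect_equal(memory_amplitude_estimate(c(rep(20, 5), rep(10, 5),
                                           rep(0, 350))), 15)
  expect_error(memory_amplitude_estimate(1:5), "at least 10")
})

test_that("bump location is the circular center of mass in index units", {
  r <- numeric(360); r[180] <- 5
  expect_equal(bump_location(r), 180)
  r <- numeric(360); r[360] <- 5
  expect_equal(bump_location(r), 360)
  # symmetric bump about 180
  r <- gaussian_stimulus(360, 10, 180, 7)
  expect_equal(bump_location(r), 180, tolerance = 1e-9)
  # rotating the rates rotates the location
  k <- 23
  r2 <- r[((seq_len(360) - 1 - k) %% 360) + 1]
  expect_equal(bump_location(r2), 180 + k, tolerance = 1e-9)
  expect_error(bump_location(rep(0, 360)), "undefined")
  expect_error(bump_location(rep(-1, 360)), "undefined")
})

test_that("location unwrapping accumulates circular steps across the seam", {
  # a drift across the 360 -> 1 seam unwraps to a continuous displacement
  loc <- c(358, 359, 360, 1, 2, 3)
  expect_equal(unwrap_ring(loc, 360), c(0, 1, 2, 3, 4, 5))
  loc <- c(2, 1, 360, 359)
  expect_equal(unwrap_ring(loc, 360), c(0, -1, -2, -3))
  # more than one lap
  loc <- seq(10, 10 + 540, by = 90) %% 360
  expect_equal(unwrap_ring(loc, 360), seq(0, 540, by = 90))
})

test_that("noisy trials are seed-deterministic and sigma = 0 recovers the noiseless run", {
  m <- ring_model()
  a <- amplitude_drift_experiment(m, sigma_list = 4, IA_list = 15,
                                  n_trials = 2, t_memory = 500, seed = 5)
  b <- amplitude_drift_experiment(m, sigma_list = 4, IA_list = 15,
                                  n_trials = 2, t_memory = 500, seed = 5)
  expect_identical(a$timeseries, b$timeseries)
  # distinct trials differ
  t1 <- a$timeseries[a$timeseries$trial == 1, "amplitude"]
  t2 <- a$timeseries[a$timeseries$trial == 2, "amplitude"]
  expect_false(identical(t1, t2))

  z <- amplitude_drift_experiment(m, sigma_list = 0, IA_list = 15,
                                  n_trials = 1, t_memory = 3000, seed = 5)
  ref <- run_encode_memory_ring(m, IA = 15, t_memory = 3000,
                                summarize_every = 10)
  zz <- z$timeseries
  # amplitude exactly constant once the post-offset relaxation has decayed
  late <- zz$amplitude[zz$time >= 2000]
  expect_lt(max(late) - min(late), 1e-6)
  expect_equal(late[length(late)], ref$amplitude, tolerance = 1e-6)
})

test_that("location diffusion is reported on the stated grid and is reproducible", {
  ld1 <- location_diffusion_experiment(s_values = c(0, 8), n_trials = 4,
                                       T = 1500, seed = 3)
  ld2 <- location_diffusion_experiment(s_values = c(0, 8), n_trials = 4,
                                       T = 1500, seed = 3)
  expect_identical(ld1$variance, ld2$variance)
  expect_true(all(ld1$variance$var_location >= 0))
  expect_true(all(ld1$variance$time >= 300))   # transient discarded
  expect_equal(ld1$final$s, c(0, 8))
})
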