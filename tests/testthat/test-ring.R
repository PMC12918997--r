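test_that("ring distance is the shortest periodic path", {
  expect_equal(ring_distance(0, 359, 360), 1)
  expect_equal(ring_distance(0, 180, 360), 180)
  expect_equal(ring_distance(5, 20, 24), 9)
  i <- sample(0:359, 50, replace = TRUE)
  j <- sample(0:359, 50, replace = TRUE)
  expect_equal(ring_distance(i, j, 360), ring_distance(j, i, 360))
  expect_error(ring_distance(-3, 0, 360), "out of range")
})

test_that("ring weights follow the power-law profile with optional directed asymmetry", {
  W <- build_ring_weights(N = 360)
  expect_equal(W[1, 1], 18 / 4)            # d = 0 -> 18/(0+2)^2 = 4.5
  expect_equal(W[10, 14], 18 / 36)         # d = 4
  expect_identical(W, t(W))
  Wa <- build_ring_weights(N = 360, asymmetry_fraction = 0.05)
  # clockwise-directed weight over counter-clockwise for every nearby pair
  expect_equal(Wa[11, 10] / Wa[10, 11], 1.05 / 0.95)
  expect_equal(Wa[2, 360] / Wa[360, 2], 1.05 / 0.95)   # across the seam
  expect_equal(diag(Wa), diag(W))
})

test_that("rate dynamics obey the stated derivative with inert latches", {
  # uniform rates low enough that no latch can activate (w(0) r < Tu),
  # winh = 1/360: dr/dt = -2 r / tau
  m <- ring_model()
  m$r <- rep(1.5, 360)
  sim <- simulate_ring(m, list(list(stimulus = 0, duration = 1)), dt = 1)
  expect_equal(sim$model$r, rep(1.5 * (1 - 2 / 50), 360), tolerance = 1e-12)

  m0 <- ring_model()
  sim0 <- simulate_ring(m0, list(list(stimulus = 0, duration = 50)), dt = 1)
  expect_true(all(sim0$model$r == 0))
  expect_equal(nrow(sim0$model$up), 0)
})

test_that("zero noise leaves the trajectory and the RNG stream untouched", {
  m <- ring_model(N = 24, winh = 1 / 24)
  sched <- list(list(stimulus = gaussian_stimulus(24, 12, 12, 2),
                     duration = 200))
  a <- simulate_ring(m, sched, sigma = 0, thin = 1)
  set.seed(99)
  b <- simulate_ring(m, sched, sigma = 0, thin = 1)
  probe1 <- runif(1)
  set.seed(99)
  probe2 <- runif(1)
  expect_identical(a$rates, b$rates)
  expect_identical(probe1, probe2)        # no random numbers consumed
})

test_that("the solution is rotation-equivariant for symmetric weights", {
  # equivariance is exact in exact arithmetic; numerically the global
  # inhibition sum is accumulated in a different neuron order, so agreement
  # is to floating-point roundoff
  m <- ring_model()
  k <- 37
  a <- run_encode_memory_ring(m, IA = 16, center = 180, t_encode = 400,
                              t_memory = 400, thin = 0)
  b <- run_encode_memory_ring(m, IA = 16, center = 180 + k, t_encode = 400,
                              t_memory = 400, thin = 0)
  expect_equal(b$memory_rates,
               a$memory_rates[((seq_len(360) - 1 - k) %% 360) + 1],
               tolerance = 1e-10)
  expect_equal(bump_location(b$memory_rates),
               ((bump_location(a$memory_rates) + k - 1) %% 360) + 1)
})

test_that("stimulus amplitudes are encoded as distinct ordered memory amplitudes", {
  m <- ring_model()
  ma <- vapply(c(8, 16, 24, 32), function(ia)
    run_encode_memory_ring(m, IA = ia, thin = 0)$amplitude, numeric(1))
  expect_true(all(diff(ma) > 0))
  expect_equal(length(unique(ma)), 4)
  # no stimulus, no memory
  z <- run_encode_memory_ring(m, IA = 0, thin = 0)
  expect_true(all(z$memory_rates == 0))
})

test_that("noiseless memory profiles are steady once transients equilibrate", {
  m <- ring_model()
  mem <- run_encode_memory_ring(m, IA = 24, t_memory = 3000, thin = 1)
  expect_lt(mem$steady_change, 1e-6 * mem$amplitude)
})

test_that("a stored small stimulus barely perturbs the encoding of a later large one", {
  m <- ring_model()
  single <- run_encode_memory_ring(m, IA = 80, thin = 0)
  m2 <- ring_model()
  two <- simulate_ring(m2, list(
    list(stimulus = gaussian_stimulus(360, 20), duration = 1000),
    list(stimulus = gaussian_stimulus(360, 80), duration = 1000),
    list(stimulus = 0, duration = 1000)), thin = 0)
  ma_two <- memory_amplitude_estimate(two$model$r)
  # within one recruitment quantum (a symmetric dendrite pair, 2*beta)
  expect_lt(abs(ma_two - single$amplitude), 2)
})

test_that("effective dendrite counts start at zero and grow with the stimulus", {
  m <- ring_model()
  z <- run_encode_memory_ring(m, IA = 0, thin = 0)
  expect_true(all(effective_dendrite_count(z) == 0))
  counts <- vapply(c(20, 40, 80), function(ia)
    effective_dendrite_count(
      run_encode_memory_ring(m, IA = ia, thin = 0), 180), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("band tracing covers both edges and rejects an empty memory state", {
  m <- ring_model(N = 90, winh = 1 / 90)
  expect_error(trace_band_simulated(m, "down"), "memory state")
  up <- trace_band_simulated(m, "up", IA = 40, center = 45, duration = 800,
                             dt = 0.1)
  expect_equal(up$trace$rate[1], 0)
  # the up-mode trace terminates at the encoding steady state
  n <- nrow(up$trace)
  expect_lt(abs(up$trace$rate[n] - up$trace$rate[n - 100]), 1e-4)
  dn <- trace_band_simulated(up$model, "down", duration = 500, dt = 0.1)
  expect_lt(max(dn$model$r), 1e-6)         # activity driven back to zero
  expect_equal(nrow(dn$model$up), 0)
})

test_that("latch state survives a threshold change across chained simulations", {
  # the Tu = Td initialization state seeds runs with a widened bistable range
  m <- ring_model(Tu = 3, Td = 3)
  init <- run_encode_memory_ring(m, IA = 15, thin = 0)
  m2 <- ring_model(Tu = 4.6, Td = 1.4)
  m2$r <- init$sim$model$r
  m2$up <- init$sim$model$up
  sim <- simulate_ring(m2, list(list(stimulus = 0, duration = 500)), thin = 0)
  expect_gt(memory_amplitude_estimate(sim$model$r), 1)
})
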