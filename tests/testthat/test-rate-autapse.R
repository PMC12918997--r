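test_that("hysteretic units latch with the stated threshold semantics", {
  u <- hysteretic_unit(w = 3, Tu = 9, Td = 2)
  expect_equal(u$ru, 3)
  expect_equal(u$rd, 2 / 3)

  # below the up threshold a down unit stays silent
  res <- hysteretic_response(u, 2.9)
  expect_equal(res$output, 0)
  expect_equal(res$unit$state, "down")

  # activates at 10, persists at 3, releases at 1 (w=1, Tu=9, Td=2)
  u <- hysteretic_unit(w = 1, Tu = 9, Td = 2)
  out <- numeric(4)
  for (k in seq_along(c(0, 10, 3, 1))) {
    res <- hysteretic_response(u, c(0, 10, 3, 1)[k])
    out[k] <- res$output
    u <- res$unit
  }
  expect_equal(out, c(0, 1, 1, 0))

  expect_error(hysteretic_unit(w = -1), "w > 0")
  expect_error(hysteretic_unit(w = 1, Tu = 1, Td = 2))
})

test_that("the autapse integrates to its closed-form linear solutions without latches", {
  # weights too small ever to activate: pure leaky integrator
  m <- autapse_model(rep(1e-6, 3), Tu = 9, Td = 2, tau = 50)
  sim <- integrate_autapse(m, stimulus = 5, dt = 0.1, T = 500)
  tt <- sim$trajectory$time
  expect_equal(sim$trajectory$r, 5 * (1 - exp(-tt / 50)), tolerance = 2e-3)

  m$r <- 4
  sim <- integrate_autapse(m, stimulus = 0, dt = 0.1, T = 300)
  expect_equal(sim$trajectory$r, 4 * exp(-sim$trajectory$time / 50),
               tolerance = 2e-3)
})

test_that("after stimulus offset the rate settles on the latched fixed point", {
  m <- make_fixture("tiny-autapse")
  enc <- integrate_autapse(m, stimulus = 6, dt = 0.5, T = 1000)
  mem <- integrate_autapse(enc$model, stimulus = 0, dt = 0.5, T = 2000)
  r_final <- mem$model$r
  fps <- autapse_fixed_points(m)
  expect_lt(min(abs(fps - r_final)), 1e-6)
  # and it is indeed steady: a further 10 tau of integration does not move it
  more <- integrate_autapse(mem$model, stimulus = 0, dt = 0.5, T = 500)
  expect_lt(abs(more$model$r - r_final), 1e-9)
})

test_that("latch trajectories match the event-driven brute-force oracle", {
  set.seed(7)
  for (rep in 1:20) {
    nd <- sample(2:6, 1)
    w <- sort(runif(nd, 0.2, 5), decreasing = TRUE)
    r_seq <- runif(60, 0, 12)
    m <- autapse_model(w, Tu = 9, Td = 2)
    up <- m$states
    path <- matrix(NA, length(r_seq), nd)
    for (s in seq_along(r_seq)) {
      up <- dendband:::latch_rule(up, w * r_seq[s], 9, 2)
      path[s, ] <- up
    }
    expect_identical(path, oracle_latch_path(w, 9, 2, r_seq))
  }
})

test_that("path dependence reduces to running extrema between threshold crossings", {
  w <- c(2, 1)
  m <- autapse_model(w, Tu = 9, Td = 2)
  # two input sequences sharing extrema produce the same final latch state
  seq_a <- c(0, 5, 3, 6, 2)
  seq_b <- c(0, 2, 5, 6, 3, 2)
  final_a <- oracle_latch_path(w, 9, 2, seq_a)[length(seq_a), ]
  final_b <- oracle_latch_path(w, 9, 2, seq_b)[length(seq_b), ]
  expect_identical(final_a, final_b)
})

test_that("autapse fixed points agree with exhaustive latch-configuration enumeration", {
  fx <- make_fixture("two-unit-latch")
  expect_equal(autapse_fixed_points(fx), c(0, 1, 2))
  expect_equal(enumerate_stable_rates(fx$weights, fx$Tu, fx$Td), c(0, 1, 2))

  set.seed(11)
  for (rep in 1:15) {
    nd <- sample(2:6, 1)
    w <- sort(runif(nd, 0.3, 6), decreasing = TRUE)
    Tu <- runif(1, 4, 12)
    Td <- runif(1, 0.5, Tu)
    m <- autapse_model(w, Tu = Tu, Td = Td)
    expect_equal(autapse_fixed_points(m),
                 enumerate_stable_rates(w, Tu, Td),
                 info = paste("weights:", paste(round(w, 3), collapse = " ")))
  }

  # no units that can activate: only the quiescent state
  m0 <- autapse_model(rep(1e-6, 4))
  expect_equal(autapse_fixed_points(m0), 0)
})

test_that("the stimulus-to-memory map is thresholded, monotone and linear for p = 1 weights", {
  prof <- weight_profile("power_law", a = 18, b = 2, p = 1, domain = 200)
  m <- autapse_model(weight_at(prof, 0:199), Tu = 9, Td = 2)
  map <- stimulus_memory_map(m, IA_grid = seq(0, 40, by = 2), dt = 1)
  expect_true(all(map$MA[map$IA < 1] == 0))
  expect_true(all(diff(map$MA) >= -1e-9))
  nz <- map$MA > 0.5
  fit <- lsfit(map$IA[nz], map$MA[nz])
  # discrete steps of height beta around a straight line
  expect_lt(max(abs(fit$residuals)), 1)
})

test_that("memory states depend on threshold crossings, not the stimulus time course", {
  m <- make_fixture("tiny-autapse")
  ramp <- function(t) ifelse(t < 500, 6 * t / 500, 6)
  a <- integrate_autapse(m, stimulus = 6, dt = 0.5, T = 1000)
  b <- integrate_autapse(m, stimulus = ramp, dt = 0.5, T = 1000)
  ma <- integrate_autapse(a$model, 0, dt = 0.5, T = 2000)$model$r
  mb <- integrate_autapse(b$model, 0, dt = 0.5, T = 2000)$model$r
  expect_equal(ma, mb, tolerance = 1e-9)
})
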