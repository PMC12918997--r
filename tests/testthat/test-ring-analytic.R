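test_that("with no inhibition the analytic ring band reduces to the autapse continuum band", {
  wfn <- function(d) 18 / (d + 2)^2
  width <- 10
  ab <- analytic_band_ring(wfn, winh = 0, stim_width = width)
  # matched continuum band over the doubled index u = 2x with effective
  # weight w(u/2) R(u/2)
  eff <- weight_profile("custom",
                        fn = function(u) wfn(u / 2) * exp(-(u / 2)^2 / 200),
                        domain = 360)
  cb <- continuum_band(eff, Tu = 9, Td = 2, Nd = 360)
  A <- c(3, 5, 10, 20, 40)
  expect_equal(ring_band_u(ab, A), band_u(cb, A), tolerance = 0.05)
  expect_equal(ring_band_d(ab, A), band_d(cb, A), tolerance = 0.05)
})

test_that("recurrent inhibition tilts every band step with slope -winh*kappa", {
  ab <- analytic_band_ring(function(d) 18 / (d + 2)^2)
  # at amplitudes where the activation measure does not change, the band
  # edge falls with exactly the inhibition slope
  A <- seq(10, 40, by = 0.05)
  nu <- ab$n_up(A)
  flat <- which(diff(nu) == 0)
  expect_gt(length(flat), 0)
  i <- flat[1]
  slope <- (ring_band_u(ab, A[i + 1]) - ring_band_u(ab, A[i])) /
    (A[i + 1] - A[i])
  expect_equal(slope, -ab$winh * ab$kappa, tolerance = 1e-8)
})

test_that("the analytic amplitude map tracks full ring simulations within step resolution", {
  wfn <- function(d) 18 / (d + 2)^2
  ab <- analytic_band_ring(wfn)
  IA <- c(8, 16, 24)                       # below the saturating regime
  an <- analytic_ma_map(ab, IA)
  m <- ring_model()
  sim <- vapply(IA, function(ia)
    run_encode_memory_ring(m, IA = ia, thin = 0)$amplitude, numeric(1))
  # one recruitment quantum: a symmetric dendrite pair (2 beta)
  expect_lt(max(abs(an$MA - sim)), 2)
})

test_that("the linear-design inversion has the autapse power-law closed form in the flat limit", {
  # winh = 0 and a flat bump profile: w(x) = Tu / A_act(x) with A_act
  # linear in x, i.e. a power law a/(x+b) with p = 1
  prof <- design_linear_weights(c = 0.5, IA_th = 1.2, winh = 0,
                                stim_profile = function(x) rep(1, length(x)),
                                kappa = 25, calibrate = FALSE,
                                dgrid = seq(0, 40, by = 0.5))
  x <- seq(0, 30, by = 0.5)
  w <- weight_at(prof, x)
  fit <- lsfit(x, 1 / w)                   # 1/w must be linear in x
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # and the slope encodes the design constants: A_act(x) = (2x(1+c)/c + IA_th)
  expect_equal(unname(fit$coefficients[2]), 2 * (1 + 0.5) / 0.5 / 9,
               tolerance = 1e-8)
})

test_that("infeasible design targets are rejected", {
  expect_error(design_linear_weights(c = -1, calibrate = FALSE),
               "design failure")
  expect_error(design_linear_weights(IA_th = -2, calibrate = FALSE),
               "design failure")
})
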