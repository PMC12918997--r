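test_that("synaptic gates follow the decay-and-saturating-jump rule and stay in [0,1]", {
  # jump from zero reaches half saturation; decay over one tau is e^-1;
  # a saturated gate cannot be incremented further
  expect_equal(synaptic_gate_update(0, dt = 1e-9, tau = 2, spike = TRUE), 0.5,
               tolerance = 1e-6)
  expect_equal(synaptic_gate_update(0.5, dt = 2, tau = 2, spike = FALSE),
               0.5 * exp(-1))
  expect_equal(synaptic_gate_update(1, dt = 1e-9, tau = 100, spike = TRUE), 1,
               tolerance = 1e-6)
  expect_error(synaptic_gate_update(0.5, dt = -1, tau = 2), "positive")

  set.seed(4)
  for (rep in 1:5) {
    s <- runif(1)
    spikes <- runif(500) < 0.3
    for (k in 1:500) {
      s <- synaptic_gate_update(s, dt = 0.5, tau = sample(c(2, 100), 1),
                                spike = spikes[k])
      expect_true(s >= 0 && s <= 1)
    }
  }
})

test_that("dendritic currents match hand-evaluated closed forms", {
  p <- spiking_params()
  expect_equal(nmda_gating(0), 1 / 1.15)
  expect_equal(kir_gating(-100), 0.5)

  # at Vd = Vs = EL with zero gates, only the Kir current contributes
  dv <- dendrite_dvdt(-80, -80, 0, 0, p, 1)
  ikir_hand <- 8.6 * (-80 - (-90)) / (1 + exp(0.1 * (-80 + 100)))
  expect_equal(dv, -ikir_hand / 10)

  # independent term-by-term evaluation at a different operating point
  vd <- -60; vs <- -52; sa <- 0.3; sn <- 0.6; i <- 4
  g_n <- 48 * (i + 4.5)^-0.54
  hand <- -(0.5 * (vd + 80) +
            8.6 * (vd + 90) / (1 + exp(0.1 * (vd + 100))) +
            2 * 0.007 * (vd - vs) +
            0.38 * sa * vd +
            g_n * sn * vd / (1 + 0.15 * exp(-0.08 * vd))) / 10
  expect_equal(dendrite_dvdt(vd, vs, sa, sn, p, i), hand)

  # somatic balance: tonic current of -17.2 enters depolarizing
  hand_s <- (-0.5 * (vs + 80) - sum(0.007 * (vs - rep(vd, 10))) -
             5.2 * 0.2 * vs + 17.2) / 10
  expect_equal(soma_dvdt(vs, rep(vd, 10), 0.2, p), hand_s)
})

test_that("the quiescent state located by root-finding is a fixed point of the simulator", {
  p <- spiking_params()
  vd_fix <- function(vs) vapply(1:10, function(i)
    uniroot(function(v) dendrite_dvdt(v, vs, 0, 0, p, i),
            c(-120, -60), tol = 1e-12)$root, numeric(1))
  vs <- -70
  for (k in 1:100) {
    vd <- vd_fix(vs)
    vs_new <- uniroot(function(v) soma_dvdt(v, vd, 0, p),
                      c(-80, -45), tol = 1e-12)$root
    if (abs(vs_new - vs) < 1e-12) break
    vs <- vs_new
  }
  expect_lt(vs, p$spike_threshold)   # rests below threshold
  sim <- simulate_spiking_autapse(p, data.frame(freq = 0, duration = 100),
                                  record_tail = 100, v_init = c(vs, vd))
  expect_length(sim$spike_times, 0)
  expect_lt(abs(sim$state$vs - vs), 1e-4)
  expect_lt(max(abs(sim$state$vd - vd)), 1e-4)
})

test_that("somatic spikes are clamped at 30 mV for 3 ms then reset to -80 mV", {
  p <- spiking_params()
  sim <- simulate_spiking_autapse(p, data.frame(freq = 50, duration = 300),
                                  recurrent = TRUE, record_tail = 100,
                                  thin = 1)
  expect_gt(length(sim$spike_times), 0)
  t1 <- sim$spike_times[1]
  tr <- sim$trace
  during <- tr$time > t1 + 0.05 & tr$time < t1 + 2.95
  expect_true(all(tr$vs[during] == p$spike_peak))
  after <- which(tr$time > t1 + 3.05)[1]
  expect_lt(tr$vs[after], -70)
  # gates stay within bounds along the whole trajectory
  expect_true(all(tr$s_stim >= 0 & tr$s_stim <= 1))
  expect_true(all(tr$s_nmda >= 0 & tr$s_nmda <= 1))
})

test_that("Euler trajectories converge as the step is refined and are reproducible", {
  endpoint <- function(dt) {
    p <- spiking_params(dt = dt)
    simulate_spiking_autapse(p, data.frame(freq = 30, duration = 100),
                             recurrent = FALSE, record_tail = 10)$state$vd[1]
  }
  v1 <- endpoint(0.01)
  v2 <- endpoint(0.005)
  expect_lt(abs(v1 - v2), 0.01)

  p <- spiking_params()
  a <- simulate_spiking_autapse(p, data.frame(freq = 40, duration = 200))
  b <- simulate_spiking_autapse(p, data.frame(freq = 40, duration = 200))
  expect_identical(a$state, b$state)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("dendritic state classification separates plateau from rest", {
  expect_equal(classify_dendrite_state(rep(-80, 20000)), "down")
  expect_equal(classify_dendrite_state(rep(-10, 20000)), "up")
  expect_error(classify_dendrite_state(numeric(0)), "empty")
  expect_error(classify_dendrite_state(rep(-80, 100)), "100 ms")
})

test_that("a coarse hysteresis sweep shows bistable dendrites with ordered thresholds", {
  p <- spiking_params()
  hs <- run_hysteresis_sweep(p, freq_step = 5, dwell = 700,
                             record_window = 500)
  thr <- hs$thresholds
  expect_true(all(thr$up_freq > thr$down_freq))
  # gNMDA decreases with index, so up thresholds must not decrease
  expect_true(all(diff(thr$up_freq) >= 0))
  expect_gt(thr$up_freq[10], thr$up_freq[1])
  # at 0 Hz on the ascending branch every dendrite sits near the
  # leak/Kir resting level
  rest <- hs$table[hs$table$freq == 0 & hs$table$direction == "ascending", ]
  expect_true(all(rest$mean_v < -80))
  # the mean-voltage distribution is bimodal; its valley separates the
  # state clusters and is consistent with the default separatrix
  v <- hs$table$mean_v
  d <- density(v, n = 512)
  inner <- d$x > -80 & d$x < -10
  valley <- d$x[inner][which.min(d$y[inner])]
  expect_true(all(v[v < valley] < -45) || all(v[v > valley] > -45))
  expect_error(run_hysteresis_sweep(p, freq_step = -1), "monotone")
})

test_that("graded storage stores nothing without input", {
  p <- spiking_params()
  gs <- run_graded_storage(p, settle = 300, stim_freqs = c(0, 0),
                           stim_dur = 200, memory_dur = 300,
                           rate_window = 200)
  expect_equal(gs$staircase$up_count, c(0, 0))
  expect_equal(gs$staircase$memory_rate, c(0, 0))
})
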