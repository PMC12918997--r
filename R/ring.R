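#' Distance between two neurons on a ring
#'
#' Shortest path between neuron labels `i` and `j` on a periodic
#' one-dimensional lattice of `N` neurons.  Labels are taken modulo `N`, so
#' 0-based and 1-based labelings both work.
#'
#' @param i,j neuron labels (integer vectors, recycled).
#' @param N ring size.
#' @return integer distances in `[0, floor(N/2)]`.
#' @export
ring_distance <- function(i, j, N) {
  stopifnot(N >= 1, all(is.finite(i)), all(is.finite(j)))
  if (any(i < 0 | i > N) || any(j < 0 | j > N))
    stop("neuron indices out of range")
  m <- abs(i - j) %% N
  pmin(m, N - m)
}

#' Build the ring weight matrix
#'
#' Local excitatory weights `w_ij = profile(d(i, j))`, with `d` the ring
#' distance.  A directed asymmetry perturbation scales clockwise-directed
#' connections (from `j` to the neuron `i` ahead of it within half a ring)
#' by `1 + f` and counter-clockwise ones by `1 - f`; self-connections and
#' antipodal pairs are left unscaled.
#'
#' @param profile a [weight_profile()], a function of distance, or `NULL`
#'   for the default power law `18 / (d + 2)^2`.
#' @param N number of neurons.
#' @param asymmetry_fraction directed asymmetry `f`, `|f| < 1`.
#' @return an `N x N` numeric weight matrix (entry `[i, j]` is the weight of
#'   the connection from neuron `j` onto a dendrite of neuron `i`).
#' @export
build_ring_weights <- function(profile = NULL, N = 360,
                               asymmetry_fraction = 0) {
  stopifnot(abs(asymmetry_fraction) < 1)
  fn <- if (is.null(profile)) {
    function(d) 18 / (d + 2)^2
  } else if (inherits(profile, "weight_profile")) {
    profile$fn
  } else if (is.function(profile)) {
    profile
  } else stop("profile must be a weight_profile, a function, or NULL")
  idx <- seq_len(N)
  diffm <- outer(idx, idx, "-")          # i - j
  d <- abs(diffm) %% N
  d <- pmin(d, N - d)
  W <- matrix(fn(d), N, N)
  if (asymmetry_fraction != 0) {
    fwd <- (diffm %% N)                  # steps from j to i, clockwise
    cw <- fwd > 0 & fwd < N / 2
    ccw <- fwd > N / 2
    W[cw] <- W[cw] * (1 + asymmetry_fraction)
    W[ccw] <- W[ccw] * (1 - asymmetry_fraction)
  }
  W
}

#' Gaussian stimulus profile on the ring
#'
#' External input vector `IA * exp(-(i - center)^2 / (2 width^2))` over
#' neuron indices `i = 1..N` (no wrap-around; with the default center 180
#' and width 10 the tails are negligible at the ring edges).
#'
#' @param N number of neurons.
#' @param amplitude peak amplitude `IA` (rate units).
#' @param center,width center index and width (neurons).
#' @return numeric vector of length `N`.
#' @export
gaussian_stimulus <- function(N = 360, amplitude, center = 180, width = 10) {
  stopifnot(width > 0)
  amplitude * exp(-((seq_len(N) - center)^2) / (2 * width^2))
}

#' Ring network of neurons with bistable dendrites
#'
#' `N` rate neurons on a ring; each excitatory connection from neuron `j`
#' to neuron `i` terminates on its own hysteretic dendrite with weight
#' `w_ij` and latch thresholds `Tu`/`Td`; inhibition is global with strength
#' `winh`.  Rate dynamics:
#' `tau dr_i/dt = -r_i + beta * (up-dendrite count of i) - winh * sum_j r_j
#'  + Istim_i`.
#'
#' @param N number of neurons.
#' @param profile excitatory weight profile (see [build_ring_weights()]).
#' @param winh global inhibition strength.
#' @param tau rate time constant (ms).
#' @param beta per-dendrite rate contribution.
#' @param Tu,Td latch thresholds.
#' @param asymmetry_fraction directed weight asymmetry.
#' @param r_bound rate bound used to prune latches that can never activate;
#'   simulations abort (rather than silently err) if any rate exceeds it.
#' @return an object of class `ring_model` with the weight matrix `W`, the
#'   parameters, and the network state (`r`, `up` latch pairs).
#' @export
ring_model <- function(N = 360, profile = NULL, winh = 1 / 360, tau = 50,
                       beta = 1, Tu = 9, Td = 2, asymmetry_fraction = 0,
                       r_bound = 1000) {
  stopifnot(N >= 1, tau > 0, Tu >= Td, Tu > 0, Td >= 0, r_bound > 0)
  W <- build_ring_weights(profile, N, asymmetry_fraction)
  m <- list(N = N, W = W, winh = winh, tau = tau, beta = beta,
            Tu = Tu, Td = Td, asymmetry_fraction = asymmetry_fraction,
            r_bound = r_bound,
            r = numeric(N),
            up = matrix(integer(0), 0, 2))
  class(m) <- "ring_model"
  m
}

#' Simulate the ring network over a schedule of stimulus epochs
#'
#' Forward-Euler integration.  Each step synchronously updates every latch
#' from the current presynaptic rates (up at `w_ij r_j >= Tu`, down at
#' `w_ij r_j <= Td`), then advances all rates.  Gaussian white noise of
#' standard deviation `sigma` (per 1 ms reference step; rescaled by
#' `sqrt(1/dt)` for other `dt` so the accumulated variance per millisecond is
#' preserved) can be injected into the stimulus term of each neuron.
#'
#' @param model a [ring_model()]; its current state (`r`, `up`) is the
#'   initial condition.
#' @param schedule list of epochs, each a list with elements `stimulus`
#'   (numeric vector of length `N`, or a scalar applied uniformly),
#'   `duration` (ms) and optionally `sigma` (overrides the global `sigma`
#'   for that epoch).
#' @param dt Euler step (ms).
#' @param sigma noise standard deviation at the 1 ms reference step.
#' @param thin record the rate vector every `thin` steps (0 = none).
#' @param track neuron index whose per-step rate and total recurrent
#'   feedback (`beta * up-count - winh * sum(r)`) are recorded (NULL = none).
#' @param summarize_every record bump amplitude (mean of the 10 highest
#'   rates) and circular-center-of-mass location every this many steps
#'   (0 = none).
#' @return list of class `ring_sim`: `rates` (thinned matrix), `times`,
#'   `track`, `summary` (data frame time/amplitude/location), `ever_up_count`
#'   (per-neuron count of distinct dendrites ever up), and `model` with the
#'   final state.
#' @export
simulate_ring <- function(model, schedule, dt = 1, sigma = 0, thin = 0,
                          track = NULL, summarize_every = 0) {
  stopifnot(inherits(model, "ring_model"), dt > 0, sigma >= 0)
  E <- length(schedule)
  stopifnot(E >= 1)
  stim <- matrix(0, model$N, E)
  steps <- integer(E)
  sig <- numeric(E)
  for (e in seq_len(E)) {
    ep <- schedule[[e]]
    s <- ep$stimulus
    if (is.null(s)) s <- 0
    if (length(s) == 1) s <- rep(s, model$N)
    stopifnot(length(s) == model$N, ep$duration > 0)
    stim[, e] <- s
    steps[e] <- round(ep$duration / dt)
    sg <- if (!is.null(ep$sigma)) ep$sigma else sigma
    sig[e] <- sg * sqrt(1 / dt)   # preserve per-1-ms noise variance
  }
  res <- cpp_ring_sim(model$W, model$winh, model$tau, model$beta,
                      model$Tu, model$Td, model$r, model$up,
                      stim, steps, sig, dt,
                      as.integer(thin),
                      if (is.null(track)) 0L else as.integer(track),
                      as.integer(summarize_every), model$r_bound)
  model$r <- res$r
  model$up <- res$up
  summ <- NULL
  if (summarize_every > 0) {
    loc <- ring_location_from_sums(res$summary$cos_sum, res$summary$sin_sum,
                                   res$summary$total, model$N)
    summ <- data.frame(time = res$summary$time,
                       amplitude = res$summary$amplitude,
                       location = loc)
  }
  trk <- NULL
  if (!is.null(track))
    trk <- data.frame(time = res$track$time, rate = res$track$rate,
                      feedback = res$track$feedback)
  out <- list(rates = res$rates, times = res$rate_times, track = trk,
              summary = summ, ever_up_count = res$ever_up_count,
              model = model, dt = dt)
  class(out) <- "ring_sim"
  out
}

# location (index units) from accumulated cos/sin sums; NA where the total
# activity is non-positive (undefined center of mass)
ring_location_from_sums <- function(cx, cy, total, N) {
  loc <- (atan2(cy, cx) / (2 * pi)) * N
  loc <- ((loc - 1) %% N) + 1
  loc[total <= 0] <- NA_real_
  loc
}

#' Encode/memory protocol for the ring network
#'
#' From the all-down quiescent state (or the model's current state if
#' `reset = FALSE`), applies a Gaussian stimulus for `t_encode` ms and then
#' simulates a stimulus-free memory period of `t_memory` ms.
#'
#' @param model a [ring_model()].
#' @param IA stimulus peak amplitude.
#' @param center,width Gaussian stimulus center and width (neurons).
#' @param t_encode,t_memory durations (ms).
#' @param dt Euler step (ms).
#' @param sigma noise level (per 1 ms step).
#' @param reset start from zero rates and all-down latches?
#' @param ... passed to [simulate_ring()] (`thin`, `summarize_every`, ...).
#' @return list of class `ring_memory`: the `ring_sim`, plus `memory_rates`
#'   (final rate vector), `amplitude`, `location` and `steady_change`
#'   (largest absolute per-step rate change over the final 500 ms, from the
#'   thinned record when available).
#' @export
run_encode_memory_ring <- function(model, IA, center = 180, width = 10,
                                   t_encode = 1000, t_memory = 1000,
                                   dt = 1, sigma = 0, reset = TRUE, ...) {
  stopifnot(inherits(model, "ring_model"), IA >= 0)
  if (reset) {
    model$r <- numeric(model$N)
    model$up <- matrix(integer(0), 0, 2)
  }
  sched <- list(
    list(stimulus = gaussian_stimulus(model$N, IA, center, width),
         duration = t_encode),
    list(stimulus = 0, duration = t_memory))
  args <- list(...)
  if (is.null(args$thin)) args$thin <- max(1, round(10 / dt))
  sim <- do.call(simulate_ring,
                 c(list(model = model, schedule = sched, dt = dt,
                        sigma = sigma), args))
  r_mem <- sim$model$r
  amp <- memory_amplitude_estimate(r_mem)
  loc <- if (any(r_mem > 0)) bump_location(r_mem) else NA_real_
  steady <- NA_real_
  if (!is.null(sim$rates) && nrow(sim$rates) > 1) {
    tt <- sim$times
    keep <- tt >= (t_encode + t_memory - 500)
    if (sum(keep) > 1) {
      rr <- sim$rates[keep, , drop = FALSE]
      steady <- max(abs(diff(rr)))
    }
  }
  out <- list(sim = sim, memory_rates = r_mem, amplitude = amp,
              location = loc, steady_change = steady, IA = IA)
  class(out) <- "ring_memory"
  out
}

#' Trace the simulated multistable band of the ring
#'
#' Parametric trace of the peak neuron's total recurrent feedback
#' `beta * (up-dendrite count) - winh * sum(r)` against its firing rate.
#' In `"up"` mode the trace follows the encoding transient from rest under a
#' strong stimulus (default amplitude 80), sweeping out the up-threshold
#' edge `Bu`; in `"down"` mode it starts from a stored memory state and
#' applies a uniform inhibitory input (-10) until activity returns to zero,
#' sweeping out the down-threshold edge `Bd`.
#'
#' @param model a [ring_model()]; for `"down"` mode its state must hold a
#'   memory (some latches up).
#' @param mode `"up"` or `"down"`.
#' @param IA stimulus amplitude for `"up"` mode.
#' @param center,width stimulus geometry; `center` is also the traced neuron.
#' @param duration trace duration (ms).
#' @param dt Euler step (ms); the band figures use 0.01 ms.
#' @param inhibition uniform input applied in `"down"` mode.
#' @return list of class `band_trace`: `trace` (data frame time, rate,
#'   feedback), `mode`, and `model` with the final state.
#' @export
trace_band_simulated <- function(model, mode = c("up", "down"), IA = 80,
                                 center = 180, width = 10, duration = 1000,
                                 dt = 0.01, inhibition = -10) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ring_model"))
  if (mode == "up") {
    model$r <- numeric(model$N)
    model$up <- matrix(integer(0), 0, 2)
    sched <- list(list(stimulus = gaussian_stimulus(model$N, IA, center,
                                                    width),
                       duration = duration))
  } else {
    if (nrow(model$up) == 0)
      stop("down-mode band tracing requires a stored memory state")
    sched <- list(list(stimulus = inhibition, duration = duration))
  }
  sim <- simulate_ring(model, sched, dt = dt, track = center)
  out <- list(trace = sim$track, mode = mode, model = sim$model, dt = dt)
  class(out) <- "band_trace"
  out
}

#' Effective number of dendritic compartments
#'
#' Number of distinct dendrites of each neuron (or of one `neuron`) that
#' entered the up state at any time during a completed simulation.
#' Dendrites whose weights are too weak ever to activate do not contribute,
#' so this measures the effective dendritic complement a neuron needs.
#'
#' @param sim a `ring_sim` (from [simulate_ring()] or the `$sim` element of
#'   [run_encode_memory_ring()]).
#' @param neuron optional neuron index.
#' @return integer vector (or scalar if `neuron` is given).
#' @export
effective_dendrite_count <- function(sim, neuron = NULL) {
  if (inherits(sim, "ring_memory")) sim <- sim$sim
  stopifnot(inherits(sim, "ring_sim"))
  cnt <- sim$ever_up_count
  if (is.null(neuron)) cnt else cnt[neuron]
}
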