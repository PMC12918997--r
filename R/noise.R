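#' Bump amplitude estimate
#'
#' Memory amplitude of a rate pattern, estimated as the mean firing rate of
#' the 10 highest-firing neurons (ties broken by lowest neuron index).
#'
#' @param rates numeric vector of firing rates (length >= 10).
#' @return scalar amplitude.
#' @export
memory_amplitude_estimate <- function(rates) {
  if (length(rates) < 10) stop("need at least 10 neurons")
  ord <- order(-rates, seq_along(rates))
  mean(rates[ord[1:10]])
}

#' Bump location estimate
#'
#' Circular center of mass of a rate pattern: the angle of
#' `sum_i r_i exp(2 pi i sqrt(-1) / N)`, mapped back to neuron-index units
#' in `(0, N]`.
#'
#' @param rates numeric vector of firing rates.
#' @return location in index units.
#' @export
bump_location <- function(rates) {
  N <- length(rates)
  if (all(rates <= 0)) stop("undefined location: no positive rates")
  th <- 2 * pi * seq_len(N) / N
  ang <- atan2(sum(rates * sin(th)), sum(rates * cos(th)))
  ((ang / (2 * pi) * N - 1) %% N) + 1
}

#' Unwrap a circular location series
#'
#' Removes ring wrap-arounds from a time series of bump locations by
#' accumulating minimal-magnitude circular steps, returning continuous
#' displacements relative to `ref` (the first location by default).  Handles
#' drifts of any total extent as long as successive samples move by less
#' than half the ring.
#'
#' @param loc numeric vector of locations in index units.
#' @param N ring size.
#' @param ref reference location subtracted from the series.
#' @return numeric vector of signed displacements (neuron units).
#' @export
unwrap_ring <- function(loc, N, ref = loc[1]) {
  wrap <- function(d) ((d + N / 2) %% N) - N / 2
  steps <- wrap(diff(c(ref, loc)))
  cumsum(steps)
}

#' Amplitude drift under noise
#'
#' For each combination of noise level and stimulus amplitude, runs
#' `n_trials` independent encode/memory simulations with Gaussian noise
#' injected into every neuron (during encoding too, unless
#' `noise_during_encoding = FALSE`) and records the bump-amplitude time
#' course over the memory period.  Because the amplitude estimator (mean of
#' the 10 highest rates) has a positive noise-driven floor even when no
#' memory is stored, classification is baseline-corrected: one zero-stimulus
#' reference run per noise level measures that floor, and a trial's memory
#' counts as retained if its final baseline-subtracted amplitude is at least
#' `degraded_frac` of its baseline-subtracted amplitude 300 ms after
#' stimulus offset (the first 300 ms are discarded to let stimulus
#' transients decay).
#'
#' @param model a [ring_model()].
#' @param sigma_list noise standard deviations (per 1 ms step).
#' @param IA_list stimulus amplitudes.
#' @param n_trials trials per condition.
#' @param t_encode,t_memory durations (ms).
#' @param dt Euler step (ms).
#' @param seed base seed; per-trial seeds are drawn deterministically.
#' @param center,width stimulus geometry.
#' @param noise_during_encoding apply noise during the encoding period too?
#' @param summarize_every amplitude sampling stride (steps).
#' @param degraded_frac retention threshold as a fraction of the initial
#'   post-offset amplitude (analysis convention, not a model parameter).
#' @return list of class `amplitude_drift`: `timeseries` (data frame sigma,
#'   IA, trial, time, amplitude over the memory period) and `survival`
#'   (per-trial classification with initial and final amplitudes).
#' @export
amplitude_drift_experiment <- function(model, sigma_list = c(3, 6, 9),
                                       IA_list = c(10, 15, 20),
                                       n_trials = 10,
                                       t_encode = 1000, t_memory = 10000,
                                       dt = 1, seed = 1,
                                       center = 180, width = 10,
                                       noise_during_encoding = TRUE,
                                       summarize_every = 10,
                                       degraded_frac = 0.25) {
  stopifnot(inherits(model, "ring_model"), n_trials >= 1)
  set.seed(seed)
  conds <- expand.grid(sigma = sigma_list, IA = IA_list,
                       trial = seq_len(n_trials))
  conds$seed <- sample.int(.Machine$integer.max, nrow(conds))
  base_seeds <- sample.int(.Machine$integer.max, length(sigma_list))
  # noise floor of the amplitude estimator: zero-stimulus reference runs
  baseline <- vapply(seq_along(sigma_list), function(k) {
    set.seed(base_seeds[k])
    m <- model
    m$r <- numeric(m$N)
    m$up <- matrix(integer(0), 0, 2)
    sim <- simulate_ring(m, list(list(stimulus = 0, duration = t_memory,
                                      sigma = sigma_list[k])),
                         dt = dt, summarize_every = summarize_every)
    ss <- sim$summary
    mean(ss$amplitude[ss$time >= t_memory / 2])
  }, numeric(1))
  names(baseline) <- as.character(sigma_list)
  ts_list <- vector("list", nrow(conds))
  surv <- conds[c("sigma", "IA", "trial")]
  surv$initial <- surv$final <- NA_real_
  for (k in seq_len(nrow(conds))) {
    set.seed(conds$seed[k])
    m <- model
    m$r <- numeric(m$N)
    m$up <- matrix(integer(0), 0, 2)
    sched <- list(
      list(stimulus = gaussian_stimulus(m$N, conds$IA[k], center, width),
           duration = t_encode,
           sigma = if (noise_during_encoding) conds$sigma[k] else 0),
      list(stimulus = 0, duration = t_memory, sigma = conds$sigma[k]))
    sim <- simulate_ring(m, sched, dt = dt, summarize_every = summarize_every)
    ss <- sim$summary[sim$summary$time > t_encode, , drop = FALSE]
    ss$time <- ss$time - t_encode
    ts_list[[k]] <- data.frame(sigma = conds$sigma[k], IA = conds$IA[k],
                               trial = conds$trial[k], time = ss$time,
                               amplitude = ss$amplitude)
    post <- ss[ss$time >= 300, , drop = FALSE]
    surv$initial[k] <- post$amplitude[1]
    surv$final[k] <- post$amplitude[nrow(post)]
  }
  surv$baseline <- baseline[as.character(surv$sigma)]
  surv$survived <- (surv$final - surv$baseline) >=
    degraded_frac * pmax(surv$initial - surv$baseline, 0)
  out <- list(timeseries = do.call(rbind, ts_list), survival = surv,
              baseline = baseline, degraded_frac = degraded_frac)
  class(out) <- "amplitude_drift"
  out
}

#' Bump-location diffusion under noise
#'
#' Measures how the variance of the memorized bump location grows with time
#' for different dendritic bistable ranges `Tu - Td` (with `Tu = 3 + 0.2 s`,
#' `Td = 3 - 0.2 s`).  To keep the memory amplitude comparable across
#' conditions, all conditions start from one shared state: the network is
#' first initialized with the step-function case `Tu = Td = 3` by a
#' noiseless encode/memory run (`IA = 15`), and the resulting rates and
#' latch states seed every noisy trial.  Noise of standard deviation `sigma`
#' is then applied for `T` ms with no stimulus.  Per-trial location series
#' are unwrapped relative to the initial bump center; the first 300 ms are
#' discarded before variances are computed.
#'
#' @param s_values integer bistable-range settings (`Tu - Td = 0.4 s`).
#' @param sigma noise standard deviation (per 1 ms step).
#' @param n_trials trials per condition.
#' @param T noisy simulation length (ms).
#' @param dt Euler step (ms).
#' @param seed base seed.
#' @param profile excitatory weight profile (default base power law).
#' @param N,winh,tau,beta network parameters.
#' @param asymmetry_fraction directed weight asymmetry applied to the noisy
#'   runs (and to the initialization network).
#' @param init_Tu,init_Td,init_IA initialization protocol parameters.
#' @param center,width stimulus geometry for the initialization.
#' @param summarize_every location sampling stride (steps).
#' @param discard initial transient discarded from the variance curves (ms).
#' @return list of class `location_diffusion`: `variance` (data frame s,
#'   bistable_range, time, var_location, mean_drift), `final` (variance and
#'   mean drift at the last sample per condition), and the shared `init`
#'   state summary.
#' @export
location_diffusion_experiment <- function(s_values = 0:10, sigma = 10,
                                          n_trials = 400, T = 10000,
                                          dt = 1, seed = 1,
                                          profile = NULL, N = 360,
                                          winh = 1 / 360, tau = 50, beta = 1,
                                          asymmetry_fraction = 0,
                                          init_Tu = 3, init_Td = 3,
                                          init_IA = 15,
                                          center = 180, width = 10,
                                          summarize_every = 50,
                                          discard = 300) {
  set.seed(seed)
  init_model <- ring_model(N = N, profile = profile, winh = winh, tau = tau,
                           beta = beta, Tu = init_Tu, Td = init_Td,
                           asymmetry_fraction = asymmetry_fraction)
  init <- run_encode_memory_ring(init_model, IA = init_IA, center = center,
                                 width = width, dt = dt, thin = 0)
  r0 <- init$sim$model$r
  up0 <- init$sim$model$up
  loc0 <- bump_location(r0)

  trial_seeds <- matrix(sample.int(.Machine$integer.max,
                                   length(s_values) * n_trials),
                        nrow = n_trials)
  var_list <- vector("list", length(s_values))
  for (si in seq_along(s_values)) {
    s <- s_values[si]
    m <- ring_model(N = N, profile = profile, winh = winh, tau = tau,
                    beta = beta, Tu = 3 + 0.2 * s, Td = 3 - 0.2 * s,
                    asymmetry_fraction = asymmetry_fraction)
    disp <- NULL
    for (tr in seq_len(n_trials)) {
      set.seed(trial_seeds[tr, si])
      m$r <- r0
      m$up <- up0
      sim <- simulate_ring(m, list(list(stimulus = 0, duration = T)),
                           dt = dt, sigma = sigma,
                           summarize_every = summarize_every)
      loc <- sim$summary$location
      loc[is.na(loc)] <- loc0        # bump lost: hold last defined reference
      d <- unwrap_ring(loc, N, ref = loc0)
      if (is.null(disp)) disp <- matrix(NA_real_, n_trials, length(d))
      disp[tr, ] <- d
    }
    tt <- sim$summary$time
    keep <- tt >= discard
    var_list[[si]] <- data.frame(
      s = s, bistable_range = 0.4 * s, time = tt[keep],
      var_location = apply(disp[, keep, drop = FALSE], 2, var),
      mean_drift = colMeans(disp[, keep, drop = FALSE]))
  }
  variance <- do.call(rbind, var_list)
  final <- do.call(rbind, lapply(var_list, function(d) d[nrow(d), ]))
  out <- list(variance = variance, final = final,
              init = list(location = loc0, amplitude = init$amplitude),
              sigma = sigma, n_trials = n_trials)
  class(out) <- "location_diffusion"
  out
}
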