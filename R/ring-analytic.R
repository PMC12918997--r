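#' Analytic multistable band of the ring network
#'
#' Reduced, whole-network approximation of the ring's multistable feedback
#' band.  Assuming the activity bump keeps the (peak-normalized) shape of
#' the stimulus profile `R(x)`, a bump of peak amplitude `A` drives the
#' dendrite of the peak neuron receiving input from distance `x` with
#' `w(x) * A * R(x)`.  The activated-dendrite measure is
#' `n_u(A) = |\{x : w(x) A R(x) >= Tu\}|` (counting both sides of the ring),
#' and the peak neuron's total recurrent feedback on the up edge is
#' `Bu(A) = beta * n_u(A) - winh * kappa * A`, with `kappa = int R(x) dx`
#' the integrated bump area; the down edge `Bd` uses `Td`.  The inhibition
#' term gives every step of the band its slope `-winh * kappa`.  With
#' `winh = 0` the construction reduces to the autapse continuum band with
#' effective weight `w(x) R(x)`.
#'
#' @param profile a [weight_profile()] (or plain function) for the
#'   excitatory weights as a function of ring distance.
#' @param Tu,Td latch thresholds.
#' @param beta per-dendrite contribution.
#' @param winh global inhibition strength.
#' @param N number of neurons (distance domain is `[0, N/2]`).
#' @param stim_width width of the Gaussian stimulus/bump profile (neurons);
#'   ignored when `stim_profile` is supplied.
#' @param stim_profile optional peak-normalized bump shape `R(x)` as a
#'   function of distance; must satisfy `R(0) = 1`.
#' @param kappa integrated bump area; computed numerically when `NULL`
#'   (for the default Gaussian it is `stim_width * sqrt(2 * pi)`).
#' @param dx grid resolution (distance units) for the threshold tables.
#' @return object of class `ring_band` with edge functions accessible via
#'   [ring_band_u()] / [ring_band_d()] and the activation measures via
#'   `$n_up(A)` / `$n_keep(A)`.
#' @export
analytic_band_ring <- function(profile, Tu = 9, Td = 2, beta = 1,
                               winh = 1 / 360, N = 360, stim_width = 10,
                               stim_profile = NULL, kappa = NULL,
                               dx = 0.02) {
  wfn <- if (inherits(profile, "weight_profile")) profile$fn
         else if (is.function(profile)) profile
         else stop("profile must be a weight_profile or a function")
  R <- if (is.null(stim_profile)) {
    function(x) exp(-x^2 / (2 * stim_width^2))
  } else stim_profile
  if (abs(R(0) - 1) > 1e-8)
    stop("stimulus profile must be peak-normalized (R(0) = 1)")
  xg <- seq(0, N / 2, by = dx)
  Rg <- R(xg)
  if (any(Rg < 0) || any(!is.finite(Rg)))
    stop("non-normalizable stimulus profile")
  if (is.null(kappa)) kappa <- dx * (2 * sum(Rg) - Rg[1])
  g <- wfn(xg) * Rg                      # effective drive per unit amplitude
  act <- sort(Tu / g)                    # amplitude at which x activates
  keep <- if (Td > 0) sort(Td / g) else NULL
  n_up <- function(A) {
    2 * dx * findInterval(A, act)
  }
  n_keep <- if (is.null(keep)) {
    function(A) ifelse(A > 0, N, 0)
  } else {
    function(A) 2 * dx * findInterval(A, keep)
  }
  b <- list(n_up = n_up, n_keep = n_keep, kappa = kappa, beta = beta,
            winh = winh, Tu = Tu, Td = Td, N = N, R = R, weight_fn = wfn)
  class(b) <- "ring_band"
  b
}

#' Analytic ring band edges
#'
#' Up (`ring_band_u`) and down (`ring_band_d`) edges of the analytic band as
#' functions of the bump peak amplitude.
#'
#' @param band a `ring_band` from [analytic_band_ring()].
#' @param A bump peak amplitudes (vectorized).
#' @return total recurrent feedback at the peak neuron.
#' @export
ring_band_u <- function(band, A) {
  stopifnot(inherits(band, "ring_band"))
  band$beta * band$n_up(A) - band$winh * band$kappa * A
}

#' @rdname ring_band_u
#' @export
ring_band_d <- function(band, A) {
  stopifnot(inherits(band, "ring_band"))
  band$beta * band$n_keep(A) - band$winh * band$kappa * A
}

#' Analytic stimulus-to-memory mapping of the ring
#'
#' Integrates the reduced one-dimensional amplitude dynamics
#' `tau dA/dt = -A + beta * n - winh * kappa * A + Istim`
#' with the latched measure `n` ratcheting up along the activation edge
#' during encoding and relaxing along the deactivation edge, exactly as in
#' the autapse: `n <- min(max(n, n_up(A)), n_keep(A))` each step.  This is
#' the encode/memory fixed-point logic of the autapse modified by the
#' inhibition factor.
#'
#' @param band a `ring_band` from [analytic_band_ring()].
#' @param IA_grid stimulus amplitudes.
#' @param t_encode,t_memory durations (ms).
#' @param dt Euler step (ms).
#' @param tau rate time constant (ms).
#' @return data frame with columns `IA` and `MA`.
#' @export
analytic_ma_map <- function(band, IA_grid, t_encode = 1000, t_memory = 1000,
                            dt = 1, tau = 50) {
  stopifnot(inherits(band, "ring_band"))
  wk <- band$winh * band$kappa
  one <- function(ia) {
    A <- 0; n <- 0
    for (s in seq_len(round(t_encode / dt))) {
      n <- min(max(n, band$n_up(A)), max(band$n_keep(A), band$n_up(A)))
      A <- A + dt / tau * (-A + band$beta * n - wk * A + ia)
    }
    for (s in seq_len(round(t_memory / dt))) {
      n <- min(max(n, band$n_up(A)), max(band$n_keep(A), band$n_up(A)))
      A <- A + dt / tau * (-A + band$beta * n - wk * A)
    }
    A
  }
  data.frame(IA = IA_grid, MA = vapply(IA_grid, one, numeric(1)))
}

#' Design ring weights for a linear stimulus-to-memory mapping
#'
#' Inverts the analytic band relation (including the recurrent-inhibition
#' correction) to construct the weight profile whose memory amplitude obeys
#' `MA = c * (IA - IA_th)` above threshold.  Writing `nu = 1 + winh * kappa`,
#' the encode/memory fixed-point logic requires the activated measure on the
#' up edge to be linear in the bump amplitude,
#' `beta * n_u(A) = c * nu * (nu * A - IA_th) / (1 + c * nu)`,
#' which pins down the amplitude `A_act(x)` at which the dendrite at
#' distance `x` must activate and hence the weight
#' `w(x) = Tu / (A_act(x) * R(x))`.  Because the Gaussian bump profile
#' shrinks faster than the linear activation schedule grows, the raw
#' inversion eventually turns upward with distance; weights beyond that
#' turning point can never activate at the design's operating amplitudes and
#' are clamped to keep the profile monotone non-increasing.
#'
#' Because the closed form rests on the bump-shape approximation, the
#' discrete recruitment thresholds it implies land slightly off their
#' intended stimulus amplitudes.  With `calibrate = TRUE` the inversion is
#' therefore refined numerically: noiseless encode/memory simulations of the
#' full ring measure, for each dendrite distance, the drive available at the
#' stimulus amplitude where the target line crosses the midpoint of the
#' corresponding memory plateaus, and the weights are updated multiplicatively
#' (anchored at the observed recruitment thresholds, with damping) until the
#' realized mapping matches the target; the best profile over the fixed
#' number of passes is returned.  The procedure is deterministic (no noise is
#' involved).
#'
#' @param c target slope of the memory-vs-stimulus mapping (> 0).
#' @param IA_th target stimulus-axis intercept (>= 0).
#' @param Tu up threshold of the latches.
#' @param beta per-dendrite contribution.
#' @param winh global inhibition strength.
#' @param N number of neurons.
#' @param stim_width Gaussian stimulus width (neurons).
#' @param stim_profile optional peak-normalized bump shape `R(x)`.
#' @param kappa integrated bump area (`stim_width * sqrt(2*pi)` by default).
#' @param dgrid distance grid on which the designed profile is tabulated.
#' @param calibrate refine the closed-form inversion against noiseless
#'   simulations of the full ring (see Details)?
#' @param IA_max top of the stimulus range the design is calibrated over.
#' @param passes number of calibration passes.
#' @return a tabulated [weight_profile()] carrying the design constants in
#'   `$pars$design`.
#' @export
design_linear_weights <- function(c = 0.5, IA_th = 1.2, Tu = 9, beta = 1,
                                  winh = 1 / 360, N = 360, stim_width = 10,
                                  stim_profile = NULL, kappa = NULL,
                                  dgrid = seq(0, 180, by = 0.5),
                                  calibrate = TRUE, IA_max = 35,
                                  passes = 12) {
  if (c <= 0) stop("design failure: target slope must be positive")
  if (IA_th < 0) stop("design failure: target threshold must be non-negative")
  R <- if (is.null(stim_profile)) {
    function(x) exp(-x^2 / (2 * stim_width^2))
  } else stim_profile
  if (is.null(kappa)) {
    if (is.null(stim_profile)) {
      kappa <- stim_width * sqrt(2 * pi)
    } else {
      xs <- seq(0, N / 2, by = 0.01)
      kappa <- 0.01 * (2 * sum(R(xs)) - R(0))
    }
  }
  nu <- 1 + winh * kappa
  # amplitude at which the dendrite at distance x must activate:
  # n_u(A) = 2x  =>  A_act(x) = ((1 + c*nu) * beta * 2x / (c*nu) + IA_th) / nu
  A_act <- (((1 + c * nu) * beta * 2 * dgrid) / (c * nu) + IA_th) / nu
  if (any(A_act <= 0)) stop("design failure: non-positive activation amplitude")
  w <- Tu / (A_act * R(dgrid))
  # Past the turning point the raw inversion rises with distance, which is
  # infeasible for a monotone profile; those dendrites lie outside the
  # design's operating range, so continue the tail with the bump profile's
  # own decay (the drive w * A * R then falls off as R^2, which keeps tail
  # dendrites silent at all operating amplitudes).
  turn <- which(diff(w) > 0)
  if (length(turn)) {
    k <- turn[1]
    tail_idx <- (k + 1):length(w)
    w[tail_idx] <- w[k] * R(dgrid[tail_idx]) / R(dgrid[k])
  }
  w <- cummin(w)                         # numeric guard; no-op in practice
  if (any(w <= 0) || any(!is.finite(w)))
    stop("design failure: inverted weights are not positive and finite")
  if (calibrate)
    w <- calibrate_design_weights(dgrid, w, c, IA_th, Tu, beta, winh, N,
                                  stim_width, R, IA_max, passes)
  prof <- weight_profile("tabulated", x = dgrid, w = w, domain = max(dgrid))
  prof$pars$design <- list(c = c, IA_th = IA_th, Tu = Tu, beta = beta,
                           winh = winh, kappa = kappa, stim_width = stim_width,
                           calibrated = calibrate)
  prof
}

# Simulation-anchored refinement of the design inversion.  Each pass runs
# noiseless encode/memory simulations over the integer stimulus grid,
# measures the per-distance drive curves and the memory plateaus, and moves
# each pair's recruitment threshold to the stimulus amplitude at which the
# target line crosses the midpoint of the adjacent plateaus.
calibrate_design_weights <- function(dgrid, w0, c, IA_th, Tu, beta, winh, N,
                                     stim_width, R, IA_max, passes) {
  IAg <- 0:IA_max
  kmax <- 14
  center <- floor(N / 2)
  evaluate <- function(wfun) {
    m <- ring_model(N = N, profile = wfun, winh = winh, Tu = Tu,
                    Td = min(2, Tu), beta = beta)
    MAs <- numeric(length(IAg))
    counts <- integer(length(IAg))
    Mk <- matrix(0, length(IAg), kmax + 1)
    for (ii in seq_along(IAg)) {
      mm <- m
      s1 <- simulate_ring(mm, list(list(
        stimulus = gaussian_stimulus(N, IAg[ii], center, stim_width),
        duration = 1000)), thin = 5)
      rmax <- apply(s1$rates, 2, max)
      for (k in 0:kmax)
        Mk[ii, k + 1] <- max(rmax[center + k], rmax[center - k])
      s2 <- simulate_ring(s1$model, list(list(stimulus = 0,
                                              duration = 2000)), thin = 0)
      MAs[ii] <- memory_amplitude_estimate(s2$model$r)
      counts[ii] <- sum(s2$model$up[, 1] == center)
    }
    list(MA = MAs, counts = counts, Mk = Mk)
  }
  w <- stats::approx(dgrid, w0, xout = 0:ceiling(max(dgrid)), rule = 2)$y
  xg <- 0:(length(w) - 1)
  best <- NULL
  for (pass in seq_len(passes)) {
    ev <- evaluate(stats::approxfun(xg, w, rule = 2))
    ks <- (ev$counts - 1) / 2
    mk <- tapply(ev$MA, ks, mean)
    kv <- as.numeric(names(mk))
    pos <- mk[kv >= 0]
    step <- if (length(pos) > 2) mean(diff(pos[-1])) else 2 * beta
    getm <- function(k) {
      if (as.character(k) %in% names(mk)) mk[[as.character(k)]]
      else max(mk) + step * (k - max(kv))
    }
    wnew <- w
    for (k in 0:12) {
      mprev <- if (k == 0) 0 else getm(k - 1)
      IAstar <- IA_th + (mprev + getm(k)) / (2 * c)
      if (IAstar > IA_max + 5) break
      Mfun <- stats::approxfun(IAg, ev$Mk[, k + 1], rule = 2)
      hit <- which(ks >= k)
      if (length(hit)) {
        Tobs <- IAg[hit[1]] - 0.5
        wnew[k + 1] <- w[k + 1] * Mfun(Tobs) / Mfun(IAstar)
      } else {
        drive <- Mfun(IAstar)
        if (drive > 0.5) wnew[k + 1] <- Tu / drive
      }
    }
    turn <- which(diff(wnew) > 0)
    if (length(turn)) {
      j <- turn[1]
      ti <- (j + 1):length(wnew)
      wnew[ti] <- wnew[j] * R(xg[ti]) / R(xg[j])
    }
    wnew <- cummin(wnew)
    nz <- ev$MA > 1e-9
    if (sum(nz) >= 3) {
      fit <- lsfit(IAg[nz], ev$MA[nz])
      co <- fit$coefficients
      err <- abs(co[2] / c - 1) +
        abs((-co[1] / co[2]) / max(IA_th, 0.1) - 1)
      if (is.null(best) || err < best$err) best <- list(w = w, err = err)
    }
    w <- exp(0.5 * log(w) + 0.5 * log(wnew))
  }
  wbest <- if (is.null(best)) w else best$w
  stats::approx(xg, wbest, xout = dgrid, rule = 2)$y
}
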