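#' Hysteretic (latch) dendritic unit
#'
#' A binary latch abstracting the bistable dendrite of the conductance-based
#' model.  Driven by the presynaptic firing rate `r`, the unit flips to its
#' up state when the synaptic drive `w * r` reaches the up threshold `Tu`,
#' flips down when the drive falls to the down threshold `Td`, and otherwise
#' retains its state.  Equivalently, in terms of firing rate the thresholds
#' are `ru = Tu / w` and `rd = Td / w`.
#'
#' Equality convention: activation fires at `w * r >= Tu`, deactivation at
#' `w * r <= Td` (activation wins when `Tu == Td` and the drive equals both).
#'
#' @param w synaptic weight (> 0).
#' @param Tu,Td up and down thresholds (input units), `Tu >= Td`.
#' @param state `"up"` or `"down"`.
#' @return an object of class `hysteretic_unit`.
#' @export
hysteretic_unit <- function(w, Tu = 9, Td = 2, state = "down") {
  stopifnot(w > 0, Tu >= Td, state %in% c("up", "down"))
  u <- list(w = w, Tu = Tu, Td = Td, state = state,
            ru = Tu / w, rd = Td / w)
  class(u) <- "hysteretic_unit"
  u
}

# Vectorized latch rule shared by every rate-based model in the package.
# `up` logical vector of latch states, `h` the matching synaptic drives.
latch_rule <- function(up, h, Tu, Td) {
  ifelse(h >= Tu, TRUE, ifelse(h <= Td, FALSE, up))
}

#' Response of a hysteretic unit to a firing rate
#'
#' Applies the latch rule once and returns the unit's output contribution
#' (`beta` if up, 0 if down) along with the updated unit.
#'
#' @param unit a [hysteretic_unit()].
#' @param r presynaptic firing rate.
#' @param beta contribution of an up-state unit to the postsynaptic rate.
#' @return list with elements `output` and `unit`.
#' @export
hysteretic_response <- function(unit, r, beta = 1) {
  stopifnot(inherits(unit, "hysteretic_unit"), is.finite(r))
  up <- latch_rule(unit$state == "up", unit$w * r, unit$Tu, unit$Td)
  unit$state <- if (up) "up" else "down"
  list(output = if (up) beta else 0, unit = unit)
}

#' Rate-based autapse with hysteretic dendrites
#'
#' A single neuron whose firing rate `r` decays with time constant `tau` and
#' is driven by the summed output of `Nd` hysteretic dendritic units plus an
#' external stimulus:
#' `tau dr/dt = -r + sum_i D_i(r) + Istim`.
#' Weights must be ordered monotone non-increasing (dendrite 1 has the
#' largest weight, hence the lowest activation threshold).
#'
#' @param weights numeric vector of dendritic weights, monotone non-increasing.
#' @param Tu,Td latch thresholds (input units).
#' @param beta per-dendrite rate contribution.
#' @param tau rate time constant (ms).
#' @param r0 initial rate.
#' @param states optional logical vector of initial latch states (TRUE = up).
#' @return an object of class `autapse_model`.
#' @export
autapse_model <- function(weights, Tu = 9, Td = 2, beta = 1, tau = 50,
                          r0 = 0, states = NULL) {
  stopifnot(length(weights) >= 1, all(weights > 0), Tu >= Td, tau > 0)
  if (any(diff(weights) > 1e-12))
    stop("weights must be ordered monotone non-increasing")
  if (is.null(states)) states <- rep(FALSE, length(weights))
  stopifnot(length(states) == length(weights), is.logical(states))
  m <- list(weights = weights, Tu = Tu, Td = Td, beta = beta, tau = tau,
            r = r0, states = states, Nd = length(weights))
  class(m) <- "autapse_model"
  m
}

#' Integrate the rate-based autapse
#'
#' Forward-Euler integration of the autapse.  Each step first updates every
#' latch from the current rate, then advances the rate using the updated
#' latch outputs (so threshold crossings act without a one-step lag; set
#' `latch_first = FALSE` for the alternative ordering).  Rates are not
#' rectified at zero.
#'
#' @param model an [autapse_model()].
#' @param stimulus external input: a single number (constant), a function of
#'   time (ms), or a vector with one value per step.
#' @param dt Euler step (ms).
#' @param T total duration (ms).
#' @param record_latches logical; keep the per-step latch matrix?
#' @param latch_first update latches before the rate step (default) or after.
#' @return list of class `autapse_sim`: `trajectory` (data frame time, r,
#'   n_up), `latches` (steps x Nd logical matrix or NULL), `model` (final
#'   state).
#' @export
integrate_autapse <- function(model, stimulus, dt = 1, T,
                              record_latches = FALSE, latch_first = TRUE) {
  stopifnot(inherits(model, "autapse_model"), dt > 0, T > 0)
  nstep <- round(T / dt)
  stim <- if (is.function(stimulus)) {
    vapply((seq_len(nstep) - 1) * dt, stimulus, numeric(1))
  } else if (length(stimulus) == 1) {
    rep(stimulus, nstep)
  } else {
    stopifnot(length(stimulus) == nstep)
    as.numeric(stimulus)
  }
  w <- model$weights
  up <- model$states
  r <- model$r
  traj_r <- numeric(nstep)
  traj_n <- integer(nstep)
  lat <- if (record_latches) matrix(FALSE, nstep, model$Nd) else NULL
  for (s in seq_len(nstep)) {
    if (latch_first) up <- latch_rule(up, w * r, model$Tu, model$Td)
    r <- r + dt / model$tau * (-r + model$beta * sum(up) + stim[s])
    if (!latch_first) up <- latch_rule(up, w * r, model$Tu, model$Td)
    traj_r[s] <- r
    traj_n[s] <- sum(up)
    if (record_latches) lat[s, ] <- up
  }
  model$r <- r
  model$states <- up
  out <- list(trajectory = data.frame(time = seq_len(nstep) * dt,
                                      r = traj_r, n_up = traj_n),
              latches = lat, model = model)
  class(out) <- "autapse_sim"
  out
}

#' Stable memory rates of the autapse
#'
#' Enumerates the candidate persistent states `r = beta * n` in which the `n`
#' largest-weight dendrites are up, and keeps those that are self-consistent:
#' every up dendrite's drive stays strictly above `Td` and every down
#' dendrite's drive stays strictly below `Tu` (the weak interior of step
#' `n`'s persistence interval, matching the latch equality convention).
#'
#' @param model an [autapse_model()].
#' @return numeric vector of stable memory rates (always includes 0 when the
#'   quiescent state is stable).
#' @export
autapse_fixed_points <- function(model) {
  stopifnot(inherits(model, "autapse_model"))
  w <- model$weights
  nd <- model$Nd
  ok <- vapply(0:nd, function(n) {
    r <- model$beta * n
    up_ok <- n == 0 || all(w[seq_len(n)] * r > model$Td)
    down_ok <- n == nd || all(w[(n + 1):nd] * r < model$Tu)
    up_ok && down_ok
  }, logical(1))
  model$beta * (0:nd)[ok]
}

#' Stimulus-to-memory mapping of the autapse
#'
#' For each stimulus amplitude in `IA_grid`, runs an independent
#' encode/memory protocol from the all-down quiescent state (constant
#' stimulus `IA` for `t_encode` ms, then 0 for `t_memory` ms) and records the
#' final memory rate.
#'
#' @param model an [autapse_model()] (its state is reset per grid point).
#' @param IA_grid stimulus amplitudes.
#' @param t_encode,t_memory durations of the encoding and memory periods (ms).
#' @param dt Euler step (ms).
#' @return data frame with columns `IA` and `MA` (memory amplitude).
#' @export
stimulus_memory_map <- function(model, IA_grid, t_encode = 1000,
                                t_memory = 1000, dt = 1) {
  stopifnot(inherits(model, "autapse_model"))
  MA <- vapply(IA_grid, function(ia) {
    m <- model
    m$r <- 0
    m$states <- rep(FALSE, m$Nd)
    enc <- integrate_autapse(m, ia, dt = dt, T = t_encode)
    mem <- integrate_autapse(enc$model, 0, dt = dt, T = t_memory)
    mem$model$r
  }, numeric(1))
  data.frame(IA = IA_grid, MA = MA)
}
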