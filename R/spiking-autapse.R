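#' Parameters of the spiking autapse neuron
#'
#' Builds the parameter set for a conductance-based integrate-and-fire soma
#' coupled to `n_dendrites` bistable dendritic compartments.  Each dendrite
#' carries a leak current, an inward-rectifier potassium (Kir) current that is
#' activated by hyperpolarization, an electrical coupling current to the soma,
#' and AMPA- and NMDA-receptor synaptic currents.  The voltage-dependent NMDA
#' conductance together with the Kir conductance makes each compartment
#' bistable: a hyperpolarized "down" state and a depolarized plateau ("up")
#' state, each self-sustaining over a range of synaptic drive.
#'
#' The maximal NMDA conductance of dendrite `i` is
#' `nmda_scale * (i + nmda_offset)^nmda_exponent`; with the default negative
#' exponent it decreases with the dendrite index, so dendrite 1 has the lowest
#' activation threshold and dendrites are recruited in index order as the
#' input rate grows.
#'
#' Units: mV, ms, uS/mm^2 (conductances), nA/mm^2 (currents), nF/mm^2
#' (capacitance).
#'
#' @param n_dendrites number of dendritic compartments.
#' @param capacitance membrane capacitance per area.
#' @param leak_conductance,leak_reversal leak conductance and reversal.
#' @param stim_conductance maximal conductance of the somatic stimulus synapse.
#' @param ampa_reversal AMPA (and stimulus) reversal potential.
#' @param tonic_current tonic background current; the printed value -17.2
#'   enters the voltage equation with a leading minus sign and is therefore
#'   net depolarizing.
#' @param dendrite_soma_conductance electrical coupling conductance.
#' @param spike_threshold,spike_peak,spike_duration,reset_voltage spike rule:
#'   crossing `spike_threshold` from below clamps the soma at `spike_peak`
#'   for `spike_duration` ms, after which it resets to `reset_voltage`.
#' @param eta ratio of somatic to dendritic area (scales the coupling current
#'   on the dendritic side).
#' @param kir_conductance,kir_reversal Kir maximal conductance and reversal.
#'   The Kir gating factor is `1 / (1 + exp(0.1 (V + 100)))` (half-activated
#'   at -100 mV, i.e. hyperpolarization-activated).
#' @param ampa_conductance dendritic AMPA maximal conductance.
#' @param nmda_reversal NMDA reversal potential.  The NMDA magnesium-block
#'   factor is `1 / (1 + 0.15 exp(-0.08 V))`.
#' @param nmda_scale,nmda_offset,nmda_exponent NMDA conductance profile across
#'   dendrites (see Details).
#' @param tau_ampa,tau_nmda synaptic gate decay time constants.
#' @param jump_fraction each presynaptic spike increments a gate by
#'   `jump_fraction * (1 - s)`.
#' @param dt integration step (forward Euler).
#' @param v_init initial somatic/dendritic voltage.
#' @return an object of class `spiking_params`.
#' @export
spiking_params <- function(n_dendrites = 10,
                           capacitance = 10,
                           leak_conductance = 0.5,
                           leak_reversal = -80,
                           stim_conductance = 5.2,
                           ampa_reversal = 0,
                           tonic_current = -17.2,
                           dendrite_soma_conductance = 0.007,
                           spike_threshold = -50,
                           spike_peak = 30,
                           spike_duration = 3,
                           reset_voltage = -80,
                           eta = 2,
                           kir_conductance = 8.6,
                           kir_reversal = -90,
                           ampa_conductance = 0.38,
                           nmda_reversal = 0,
                           nmda_scale = 48,
                           nmda_offset = 4.5,
                           nmda_exponent = -0.54,
                           tau_ampa = 2,
                           tau_nmda = 100,
                           jump_fraction = 0.5,
                           dt = 0.01,
                           v_init = -70) {
  stopifnot(capacitance > 0, spike_threshold < spike_peak, spike_duration > 0,
            n_dendrites >= 1, dt > 0, tau_ampa > 0, tau_nmda > 0,
            leak_conductance >= 0, stim_conductance >= 0,
            kir_conductance >= 0, ampa_conductance >= 0,
            dendrite_soma_conductance >= 0,
            jump_fraction >= 0, jump_fraction <= 1)
  gN <- nmda_scale * (seq_len(n_dendrites) + nmda_offset)^nmda_exponent
  if (any(gN < 0)) stop("NMDA conductances must be non-negative")
  d <- diff(gN)
  if (n_dendrites > 1 && !(all(d > 0) || all(d < 0)))
    stop("NMDA conductances must be strictly monotone across dendrites")
  p <- list(n_dendrites = n_dendrites, capacitance = capacitance,
            leak_conductance = leak_conductance, leak_reversal = leak_reversal,
            stim_conductance = stim_conductance, ampa_reversal = ampa_reversal,
            tonic_current = tonic_current,
            dendrite_soma_conductance = dendrite_soma_conductance,
            spike_threshold = spike_threshold, spike_peak = spike_peak,
            spike_duration = spike_duration, reset_voltage = reset_voltage,
            eta = eta, kir_conductance = kir_conductance,
            kir_reversal = kir_reversal, ampa_conductance = ampa_conductance,
            nmda_reversal = nmda_reversal, nmda_conductance = gN,
            tau_ampa = tau_ampa, tau_nmda = tau_nmda,
            jump_fraction = jump_fraction, dt = dt, v_init = v_init)
  class(p) <- "spiking_params"
  p
}

#' Synaptic gate update
#'
#' One Euler-step update of a first-order synaptic activation variable:
#' exponential decay by `exp(-dt/tau)`, followed, if a spike arrived during
#' the step, by the saturating jump `s + jump_fraction * (1 - s)`.
#'
#' @param s gate value in \[0, 1\].
#' @param dt step (ms); must be positive.
#' @param tau decay time constant (ms).
#' @param spike logical; did a presynaptic spike arrive?
#' @param jump_fraction saturating increment fraction.
#' @return updated gate value.
#' @export
synaptic_gate_update <- function(s, dt, tau, spike = FALSE,
                                 jump_fraction = 0.5) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(all(s >= 0), all(s <= 1))
  s <- s * exp(-dt / tau)
  if (spike) s <- s + jump_fraction * (1 - s)
  s
}

#' Kir and NMDA voltage-dependent gating factors
#'
#' `kir_gating()` is the fraction of the inward-rectifier potassium
#' conductance open at voltage `v`; `nmda_gating()` is the fraction of NMDA
#' conductance unblocked by magnesium.
#'
#' @param v membrane voltage (mV).
#' @return gating factor in (0, 1).
#' @export
kir_gating <- function(v) 1 / (1 + exp(0.1 * (v + 100)))

#' @rdname kir_gating
#' @export
nmda_gating <- function(v) 1 / (1 + 0.15 * exp(-0.08 * v))

#' Dendritic voltage derivative
#'
#' Right-hand side of the dendritic compartment voltage equation:
#' `dV/dt = -(IL + IKir + Is + IAMPA + INMDA) / C`, with the Kir current
#' gated by [kir_gating()] and the NMDA current by [nmda_gating()].
#'
#' @param vd dendritic voltage (mV).
#' @param vs somatic voltage (mV).
#' @param s_ampa,s_nmda synaptic gate values.
#' @param params a [spiking_params()] object.
#' @param dendrite dendrite index (selects the NMDA conductance).
#' @return dV/dt in mV/ms.
#' @export
dendrite_dvdt <- function(vd, vs, s_ampa, s_nmda, params, dendrite = 1) {
  stopifnot(is.finite(vd), is.finite(vs))
  p <- params
  il <- p$leak_conductance * (vd - p$leak_reversal)
  ikir <- p$kir_conductance * (vd - p$kir_reversal) * kir_gating(vd)
  is <- p$eta * p$dendrite_soma_conductance * (vd - vs)
  iampa <- p$ampa_conductance * s_ampa * (vd - p$ampa_reversal)
  inmda <- p$nmda_conductance[dendrite] * s_nmda *
    (vd - p$nmda_reversal) * nmda_gating(vd)
  -(il + ikir + is + iampa + inmda) / p$capacitance
}

#' Somatic voltage derivative (sub-threshold)
#'
#' Right-hand side of the somatic voltage equation between spikes:
#' leak, summed dendro-somatic coupling currents, stimulus synapse, and the
#' tonic background current.
#'
#' @param vs somatic voltage (mV).
#' @param vd vector of dendritic voltages (mV).
#' @param s_stim stimulus gate value.
#' @param params a [spiking_params()] object.
#' @return dV/dt in mV/ms.
#' @export
soma_dvdt <- function(vs, vd, s_stim, params) {
  p <- params
  il <- p$leak_conductance * (vs - p$leak_reversal)
  id <- sum(p$dendrite_soma_conductance * (vs - vd))
  istim <- p$stim_conductance * s_stim * (vs - p$ampa_reversal)
  (-il - id - istim - p$tonic_current) / p$capacitance
}

#' Simulate the spiking autapse circuit
#'
#' Integrates the full circuit with forward Euler at `params$dt` over a
#' sequence of epochs, each delivering a periodic spike train of the given
#' frequency.  With `recurrent = TRUE` (the full autapse) external spikes
#' gate the somatic stimulus synapse and every somatic spike jumps the
#' dendritic AMPA and NMDA gates; with `recurrent = FALSE` (open loop, used
#' to characterize single-dendrite hysteresis) external spikes drive the
#' dendritic gates directly and somatic spikes have no synaptic effect.
#'
#' @param params a [spiking_params()] object.
#' @param epochs data frame with columns `freq` (Hz) and `duration` (ms).
#' @param recurrent logical; autaptic feedback on?
#' @param record_tail length (ms) of the window at the end of each epoch over
#'   which mean dendritic voltages and spike counts are accumulated.
#' @param thin if positive, store every `thin`-th step of the voltage/gate
#'   trace (0 = no trace).
#' @param v_init optional initial voltages: a scalar, or a vector
#'   `c(vs, vd_1, ..., vd_Nd)`.
#' @return a list of class `spiking_sim` with elements `epochs` (data frame
#'   of per-epoch frequency, mean dendritic voltages `mean_vd`, tail spike
#'   count and firing rate), `spike_times`, `trace` and `state`.
#' @export
simulate_spiking_autapse <- function(params, epochs, recurrent = TRUE,
                                     record_tail = 400, thin = 0,
                                     v_init = NULL) {
  stopifnot(inherits(params, "spiking_params"),
            is.data.frame(epochs), all(c("freq", "duration") %in% names(epochs)))
  if (any(epochs$freq < 0)) stop("stimulus frequencies must be non-negative")
  if (any(epochs$duration <= 0)) stop("epoch durations must be positive")
  if (is.null(v_init)) v_init <- params$v_init
  res <- cpp_spiking_sim(params, as.numeric(epochs$freq),
                         as.numeric(epochs$duration), recurrent,
                         params$dt, record_tail, as.integer(thin),
                         as.numeric(v_init))
  rate <- res$tail_spikes / (pmin(record_tail, epochs$duration) / 1000)
  out <- list(epochs = data.frame(epoch = seq_len(nrow(epochs)),
                                  freq = epochs$freq,
                                  duration = epochs$duration,
                                  tail_spikes = res$tail_spikes,
                                  rate = rate),
              mean_vd = res$mean_vd,
              spike_times = res$spike_times,
              trace = res$trace,
              state = res$state,
              params = params,
              recurrent = recurrent)
  class(out) <- "spiking_sim"
  out
}

#' Classify a dendritic voltage trace as up or down
#'
#' A trace is classified "up" if its time-averaged voltage exceeds the
#' separatrix voltage, a fixed level between the hyperpolarized resting state
#' (near -88 mV under the default parameters) and the depolarized NMDA
#' plateau.  The default separatrix of -45 mV sits near the valley of the
#' bimodal distribution of mean dendritic voltages observed in the hysteresis
#' sweep.
#'
#' @param vd_trace numeric vector of dendritic voltages sampled at `dt` ms.
#' @param dt sampling interval of the trace (ms).
#' @param separatrix classification voltage (mV).
#' @return `"up"` or `"down"`.
#' @export
classify_dendrite_state <- function(vd_trace, dt = 0.01, separatrix = -45) {
  if (length(vd_trace) == 0) stop("empty voltage trace")
  if (length(vd_trace) * dt < 100)
    stop("voltage trace must cover at least 100 ms")
  if (mean(vd_trace) > separatrix) "up" else "down"
}

#' Hysteresis sweep of the dendritic input-output relations
#'
#' Characterizes each dendrite's bistable response by driving the open-loop
#' circuit with a periodic spike train whose frequency steps from 0 Hz up to
#' `freq_max` and back down to 0 Hz in `freq_step` increments, dwelling
#' `dwell` ms at each frequency and averaging each dendritic voltage over the
#' final `record_window` ms.  Up/down threshold frequencies are the
#' frequencies at which each dendrite's mean voltage crosses the separatrix
#' on the ascending and descending branches.
#'
#' @param params a [spiking_params()] object.
#' @param freq_max top frequency of the sweep (Hz).
#' @param freq_step frequency increment (Hz); must be positive.
#' @param dwell time spent at each frequency (ms).
#' @param record_window averaging window at the end of each dwell (ms).
#' @param separatrix voltage separating up from down states (mV).
#' @return a list of class `hysteresis_sweep` with `table` (long data frame:
#'   direction, freq, dendrite, mean_v, state) and `thresholds` (per-dendrite
#'   up/down threshold frequencies).
#' @export
run_hysteresis_sweep <- function(params, freq_max = 70, freq_step = 1,
                                 dwell = 1400, record_window = 1000,
                                 separatrix = -45) {
  if (freq_step <= 0 || freq_max <= 0)
    stop("invalid protocol: frequency schedule must be monotone (freq_step > 0)")
  up_f <- seq(0, freq_max, by = freq_step)
  down_f <- rev(up_f)[-1]
  freqs <- c(up_f, down_f)
  dir <- c(rep("ascending", length(up_f)), rep("descending", length(down_f)))
  sim <- simulate_spiking_autapse(
    params, data.frame(freq = freqs, duration = dwell),
    recurrent = FALSE, record_tail = record_window)
  nd <- params$n_dendrites
  tab <- data.frame(
    direction = rep(dir, nd),
    freq = rep(freqs, nd),
    dendrite = rep(seq_len(nd), each = length(freqs)),
    mean_v = as.vector(sim$mean_vd))
  tab$state <- ifelse(tab$mean_v > separatrix, "up", "down")
  thr <- do.call(rbind, lapply(seq_len(nd), function(i) {
    asc <- tab[tab$dendrite == i & tab$direction == "ascending", ]
    des <- tab[tab$dendrite == i & tab$direction == "descending", ]
    up_thr <- if (any(asc$state == "up")) min(asc$freq[asc$state == "up"]) else NA
    dn_thr <- if (any(des$state == "up")) min(des$freq[des$state == "up"]) else NA
    data.frame(dendrite = i, up_freq = up_thr, down_freq = dn_thr)
  }))
  out <- list(table = tab, thresholds = thr, sim = sim,
              separatrix = separatrix)
  class(out) <- "hysteresis_sweep"
  out
}

#' Graded-storage protocol for the spiking autapse
#'
#' Runs the full recurrent circuit through the staircase protocol: after a
#' settling period, a sequence of periodic-spike stimuli of increasing
#' frequency is applied, each for `stim_dur` ms followed by a `memory_dur` ms
#' stimulus-free memory period.  Under the default parameters each frequency
#' step recruits exactly one additional dendrite, and the somatic firing rate
#' during each memory period reports the number of recruited (up-state)
#' dendrites.
#'
#' @param params a [spiking_params()] object.
#' @param settle initial stimulus-free settling time (ms).
#' @param stim_freqs stimulus frequencies (Hz), one per storage epoch.
#' @param stim_dur stimulus-on duration (ms).
#' @param memory_dur memory-period duration (ms).
#' @param rate_window window at the end of each memory period over which the
#'   somatic rate and dendritic up-state counts are measured (ms).
#' @param separatrix up/down classification voltage (mV).
#' @return a list of class `graded_storage` with `staircase` (data frame:
#'   step, freq, up_count, memory_rate) and the underlying simulation.
#' @export
run_graded_storage <- function(params, settle = 1200,
                               stim_freqs = seq(20, 65, by = 5),
                               stim_dur = 400, memory_dur = 800,
                               rate_window = 400, separatrix = -45) {
  ep <- data.frame(
    freq = c(0, as.vector(rbind(stim_freqs, 0))),
    duration = c(settle, rep(c(stim_dur, memory_dur), length(stim_freqs))))
  sim <- simulate_spiking_autapse(params, ep, recurrent = TRUE,
                                  record_tail = rate_window)
  mem_rows <- 1 + 2 * seq_along(stim_freqs)   # memory epochs
  up_count <- apply(sim$mean_vd[mem_rows, , drop = FALSE] > separatrix, 1, sum)
  # interspike-interval rate over the same window (finer than count/window)
  epoch_end <- cumsum(ep$duration)
  isi_rate <- vapply(mem_rows, function(row) {
    s <- sim$spike_times
    s <- s[s > epoch_end[row] - rate_window & s <= epoch_end[row]]
    if (length(s) > 1) 1000 * (length(s) - 1) / (max(s) - min(s)) else 0
  }, numeric(1))
  staircase <- data.frame(step = seq_along(stim_freqs),
                          freq = stim_freqs,
                          up_count = up_count,
                          memory_rate = sim$epochs$rate[mem_rows],
                          memory_rate_isi = isi_rate)
  out <- list(staircase = staircase, sim = sim, separatrix = separatrix)
  class(out) <- "graded_storage"
  out
}
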