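#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the conductance-based autapse neuron:
// an integrate-and-fire soma electrically coupled to Nd dendritic
// compartments whose NMDA/Kir conductances make each dendrite bistable.
//
// Two wiring modes:
//   recurrent = true  : full autapse.  External spikes gate the somatic
//                       stimulus conductance; every somatic spike jumps the
//                       shared dendritic AMPA and NMDA gates.
//   recurrent = false : open loop (hysteresis characterisation).  External
//                       spikes jump the dendritic AMPA/NMDA gates directly;
//                       somatic spikes have no synaptic effect (the
//                       soma-dendrite electrical coupling remains).
//
// The stimulus is a periodic spike train whose frequency is piecewise
// constant over the supplied epochs.  Voltages in mV, time in ms,
// conductances in uS/mm^2, currents in nA/mm^2, capacitance in nF/mm^2.

// [[Rcpp::export]]
List cpp_spiking_sim(List par,
                     NumericVector epoch_freq,
                     NumericVector epoch_dur,
                     bool recurrent,
                     double dt,
                     double record_tail,
                     int thin,
                     NumericVector v_init) {
  const double C      = par["capacitance"];
  const double gL     = par["leak_conductance"];
  const double EL     = par["leak_reversal"];
  const double gstim  = par["stim_conductance"];
  const double Eampa  = par["ampa_reversal"];
  const double Iton   = par["tonic_current"];
  const double gds    = par["dendrite_soma_conductance"];
  const double Vth    = par["spike_threshold"];
  const double Vpeak  = par["spike_peak"];
  const double spike_dur = par["spike_duration"];
  const double Vreset = par["reset_voltage"];
  const double eta    = par["eta"];
  const double gKir   = par["kir_conductance"];
  const double EKir   = par["kir_reversal"];
  const double gA     = par["ampa_conductance"];
  const double Enmda  = par["nmda_reversal"];
  const NumericVector gN = par["nmda_conductance"];
  const double tauA   = par["tau_ampa"];
  const double tauN   = par["tau_nmda"];
  const double jump   = par["jump_fraction"];

  const int nd = gN.size();
  const int ne = epoch_freq.size();
  if (epoch_dur.size() != ne) stop("epoch_freq and epoch_dur lengths differ");
  if (dt <= 0) stop("dt must be positive");

  // state
  double Vs;
  std::vector<double> Vd(nd);
  if (v_init.size() == 1) {
    Vs = v_init[0];
    std::fill(Vd.begin(), Vd.end(), v_init[0]);
  } else if (v_init.size() == nd + 1) {
    Vs = v_init[0];
    for (int i = 0; i < nd; ++i) Vd[i] = v_init[i + 1];
  } else {
    stop("v_init must have length 1 or nd + 1");
  }
  double sstim = 0.0, sampa = 0.0, snmda = 0.0;
  double plateau = 0.0;           // ms remaining in the spike plateau

  const double decA = std::exp(-dt / tauA);
  const double decN = std::exp(-dt / tauN);

  NumericMatrix mean_vd(ne, nd);
  IntegerVector tail_spikes(ne);
  std::vector<double> spike_times;

  // thinned trace
  std::vector<double> tr_t, tr_vs, tr_ss, tr_sa, tr_sn;
  std::vector< std::vector<double> > tr_vd(nd);

  double t_abs = 0.0;
  long step_abs = 0;

  for (int e = 0; e < ne; ++e) {
    const double freq = epoch_freq[e];
    const double dur = epoch_dur[e];
    const long nstep = (long) std::floor(dur / dt + 0.5);
    const double period = freq > 0 ? 1000.0 / freq : 0.0;
    const double tail_start = dur - record_tail;
    double next_spike = 0.0;      // relative to epoch start
    double acc_w = 0.0;           // # steps accumulated in tail window
    std::vector<double> acc_vd(nd, 0.0);

    for (long s = 0; s < nstep; ++s) {
      const double t_rel = s * dt;
      bool ext = false;
      if (freq > 0 && t_rel >= next_spike - 1e-9) {
        ext = true;
        next_spike += period;
      }

      // synaptic gates: exact exponential decay, then spike-triggered jumps
      sstim *= decA;
      sampa *= decA;
      snmda *= decN;
      if (ext) {
        if (recurrent) {
          sstim += jump * (1.0 - sstim);
        } else {
          sampa += jump * (1.0 - sampa);
          snmda += jump * (1.0 - snmda);
        }
      }

      // dendritic derivatives from the current (pre-update) state
      double sum_ds = 0.0;        // sum over dendrites of (Vd_i - Vs)
      for (int i = 0; i < nd; ++i) {
        const double v = Vd[i];
        const double IL = gL * (v - EL);
        const double IK = gKir * (v - EKir) / (1.0 + std::exp(0.1 * (v + 100.0)));
        const double Is = eta * gds * (v - Vs);
        const double IA = gA * sampa * (v - Eampa);
        const double IN = gN[i] * snmda * (v - Enmda) /
          (1.0 + 0.15 * std::exp(-0.08 * v));
        sum_ds += v - Vs;
        Vd[i] = v + dt * (-(IL + IK + Is + IA + IN) / C);
      }

      // soma: clamped during the plateau, Euler otherwise
      if (plateau > 0.0) {
        plateau -= dt;
        if (plateau <= 1e-12) {
          Vs = Vreset;
          plateau = 0.0;
        }
      } else {
        const double IL = gL * (Vs - EL);
        const double Ist = gstim * sstim * (Vs - Eampa);
        const double Id = gds * sum_ds;   // current INTO soma from dendrites
        double vnew = Vs + dt * ((-IL + Id - Ist - Iton) / C);
        if (vnew >= Vth) {
          spike_times.push_back(t_abs + dt);
          vnew = Vpeak;
          plateau = spike_dur;
          if (recurrent) {
            sampa += jump * (1.0 - sampa);
            snmda += jump * (1.0 - snmda);
          }
          if (t_rel >= tail_start) tail_spikes[e]++;
        }
        Vs = vnew;
      }

      if (t_rel >= tail_start) {
        acc_w += 1.0;
        for (int i = 0; i < nd; ++i) acc_vd[i] += Vd[i];
      }
      if (thin > 0 && step_abs % thin == 0) {
        tr_t.push_back(t_abs);
        tr_vs.push_back(Vs);
        tr_ss.push_back(sstim);
        tr_sa.push_back(sampa);
        tr_sn.push_back(snmda);
        for (int i = 0; i < nd; ++i) tr_vd[i].push_back(Vd[i]);
      }
      t_abs += dt;
      ++step_abs;
    }
    for (int i = 0; i < nd; ++i)
      mean_vd(e, i) = acc_w > 0 ? acc_vd[i] / acc_w : NA_REAL;
  }

  NumericVector vd_out(nd);
  for (int i = 0; i < nd; ++i) vd_out[i] = Vd[i];

  List trace = R_NilValue;
  if (thin > 0) {
    NumericMatrix vd_tr(tr_t.size(), nd);
    for (int i = 0; i < nd; ++i)
      for (size_t k = 0; k < tr_t.size(); ++k) vd_tr(k, i) = tr_vd[i][k];
    trace = List::create(_["time"] = wrap(tr_t), _["vs"] = wrap(tr_vs),
                         _["vd"] = vd_tr, _["s_stim"] = wrap(tr_ss),
                         _["s_ampa"] = wrap(tr_sa), _["s_nmda"] = wrap(tr_sn));
  }

  return List::create(
    _["mean_vd"] = mean_vd,
    _["tail_spikes"] = tail_spikes,
    _["spike_times"] = wrap(spike_times),
    _["state"] = List::create(_["vs"] = Vs, _["vd"] = vd_out,
                              _["s_stim"] = sstim, _["s_ampa"] = sampa,
                              _["s_nmda"] = snmda, _["plateau"] = plateau),
    _["trace"] = trace);
}
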