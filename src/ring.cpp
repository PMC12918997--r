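#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the bistable-dendrite ring network
//
//   tau dr_i/dt = -r_i + beta * sum_j D_ij(r_j) - winh * sum_j r_j + I_i + noise
//
// where D_ij is a hysteretic latch: it flips up when w_ij * r_j >= Tu and
// down when w_ij * r_j <= Td (latch update precedes the rate update each
// step, synchronously across neurons).
//
// Latch bookkeeping exploits a monotonicity invariant: for a fixed
// presynaptic neuron j, every latch sees the same rate history, so the set
// of up latches in column j is always a prefix of the column's dendrites
// sorted by decreasing weight.  Dendrites whose weight is too small ever to
// matter at rates below r_bound are pruned; a guard aborts if any |rate|
// exceeds r_bound, so pruning can never silently change the dynamics.

struct ColCands {
  std::vector<int> idx;      // postsynaptic index (0-based), sorted by w desc
  std::vector<double> w;     // matching weights, descending (ties: idx asc)
};

// number of leading entries of the descending array with w >= c
static inline int count_ge(const std::vector<double> &w, double c) {
  int lo = 0, hi = (int) w.size();
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (w[mid] >= c) lo = mid + 1; else hi = mid;
  }
  return lo;
}
// number of leading entries with w > c
static inline int count_gt(const std::vector<double> &w, double c) {
  int lo = 0, hi = (int) w.size();
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (w[mid] > c) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export]]
List cpp_ring_sim(NumericMatrix W,
                  double winh, double tau, double beta,
                  double Tu, double Td,
                  NumericVector r0,
                  IntegerMatrix up0,          // k x 2 (i, j) 1-based up latches
                  NumericMatrix stim,         // N x E stimulus per epoch
                  IntegerVector epoch_steps,  // E
                  NumericVector sigma_step,   // E, per-step noise s.d.
                  double dt,
                  int thin,                   // record rates every thin steps
                  int track,                  // 1-based neuron; 0 = none
                  int summarize_every,        // amp/location every k steps
                  double r_bound) {
  const int N = W.nrow();
  if (W.ncol() != N) stop("weight matrix must be square");
  if (r0.size() != N) stop("r0 has wrong length");
  const int E = epoch_steps.size();
  if (stim.nrow() != N || stim.ncol() != E) stop("stim must be N x n_epochs");
  if (sigma_step.size() != E) stop("sigma_step must have one entry per epoch");
  if (Tu < Td) stop("Tu must be >= Td");
  if (Tu <= 0) stop("Tu must be positive");
  if (Td < 0) stop("Td must be non-negative");
  if (tau <= 0 || dt <= 0) stop("tau and dt must be positive");
  if (r_bound <= 0) stop("r_bound must be positive");

  const double cut = std::max(1e-12, std::min(Tu, Td > 0 ? Td : Tu) / r_bound);

  // candidate lists per presynaptic column
  std::vector<ColCands> cols(N);
  for (int j = 0; j < N; ++j) {
    std::vector< std::pair<double, int> > v;
    for (int i = 0; i < N; ++i) {
      const double wij = W(i, j);
      if (wij < 0) stop("weights must be non-negative");
      if (wij >= cut) v.push_back(std::make_pair(-wij, i));
    }
    std::sort(v.begin(), v.end());
    cols[j].idx.resize(v.size());
    cols[j].w.resize(v.size());
    for (size_t k = 0; k < v.size(); ++k) {
      cols[j].w[k] = -v[k].first;
      cols[j].idx[k] = v[k].second;
    }
  }

  // import latch state: per column the up set must be a weight-prefix
  std::vector<int> m(N, 0), evermax(N, 0);
  {
    std::vector< std::vector<int> > per_col(N);
    for (int k = 0; k < up0.nrow(); ++k) {
      int i = up0(k, 0) - 1, j = up0(k, 1) - 1;
      if (i < 0 || i >= N || j < 0 || j >= N) stop("up-state index out of range");
      if (W(i, j) < cut) continue;   // would deactivate on first update anyway
      per_col[j].push_back(i);
    }
    for (int j = 0; j < N; ++j) {
      const int mj = (int) per_col[j].size();
      if (mj == 0) continue;
      std::vector<int> want(cols[j].idx.begin(), cols[j].idx.begin() + mj);
      std::sort(want.begin(), want.end());
      std::sort(per_col[j].begin(), per_col[j].end());
      if (want != per_col[j])
        stop("initial latch state is not a weight-prefix for presynaptic neuron %d",
             j + 1);
      m[j] = mj;
      evermax[j] = mj;
    }
  }

  std::vector<int> upcount(N, 0);
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < m[j]; ++k) upcount[cols[j].idx[k]]++;

  std::vector<double> r(r0.begin(), r0.end());

  long total_steps = 0;
  for (int e = 0; e < E; ++e) total_steps += epoch_steps[e];
  const long n_rec = thin > 0 ? (total_steps + thin - 1) / thin : 0;
  NumericMatrix rates(thin > 0 ? n_rec : 0, thin > 0 ? N : 0);
  std::vector<double> rec_t;
  std::vector<double> trk_t, trk_r, trk_fb;
  std::vector<double> sum_t, sum_amp, sum_cx, sum_cy, sum_tot;

  const double ang = 2.0 * M_PI / N;
  long step_abs = 0;
  long rec_row = 0;
  double t_abs = 0.0;

  std::vector<double> top(N);

  for (int e = 0; e < E; ++e) {
    const long nstep = epoch_steps[e];
    const double sig = sigma_step[e];
    for (long s = 0; s < nstep; ++s) {
      // 1. latch update from current rates
      for (int j = 0; j < N; ++j) {
        const size_t nc = cols[j].w.size();
        if (nc == 0 && m[j] == 0) continue;
        int mnew;
        const double rj = r[j];
        if (rj <= 0.0) {
          mnew = 0;   // w*r <= 0 <= Td: every up latch deactivates
        } else {
          const int a = count_ge(cols[j].w, Tu / rj);
          const int keep = count_gt(cols[j].w, Td / rj);
          mnew = std::min(std::max(m[j], a), std::max(keep, a));
        }
        if (mnew != m[j]) {
          if (mnew > m[j]) {
            for (int k = m[j]; k < mnew; ++k) upcount[cols[j].idx[k]]++;
            if (mnew > evermax[j]) evermax[j] = mnew;
          } else {
            for (int k = mnew; k < m[j]; ++k) upcount[cols[j].idx[k]]--;
          }
          m[j] = mnew;
        }
      }

      // 2. rate update
      double S = 0.0;
      for (int i = 0; i < N; ++i) S += r[i];

      if (track > 0) {
        trk_t.push_back(t_abs);
        trk_r.push_back(r[track - 1]);
        trk_fb.push_back(beta * upcount[track - 1] - winh * S);
      }

      double maxabs = 0.0;
      for (int i = 0; i < N; ++i) {
        double input = beta * upcount[i] - winh * S + stim(i, e);
        if (sig > 0.0) input += sig * norm_rand();
        r[i] += dt / tau * (-r[i] + input);
        const double a = std::fabs(r[i]);
        if (a > maxabs) maxabs = a;
      }
      if (maxabs > r_bound)
        stop("firing rate exceeded r_bound (%g); increase r_bound", r_bound);

      ++step_abs;
      t_abs += dt;

      if (thin > 0 && (step_abs % thin == 0 || step_abs == total_steps)) {
        if (rec_row < rates.nrow()) {
          for (int i = 0; i < N; ++i) rates(rec_row, i) = r[i];
          rec_t.push_back(t_abs);
          ++rec_row;
        }
      }
      if (summarize_every > 0 && step_abs % summarize_every == 0) {
        std::copy(r.begin(), r.end(), top.begin());
        std::nth_element(top.begin(), top.begin() + 9, top.end(),
                         std::greater<double>());
        double amp = 0.0;
        for (int k = 0; k < 10; ++k) amp += top[k];
        amp /= 10.0;
        double cx = 0.0, cy = 0.0, tot = 0.0;
        for (int i = 0; i < N; ++i) {
          cx += r[i] * std::cos(ang * (i + 1));
          cy += r[i] * std::sin(ang * (i + 1));
          tot += r[i];
        }
        sum_t.push_back(t_abs);
        sum_amp.push_back(amp);
        sum_cx.push_back(cx);
        sum_cy.push_back(cy);
        sum_tot.push_back(tot);
      }
    }
  }

  // export latch state as sparse (i, j) pairs
  long n_up = 0;
  for (int j = 0; j < N; ++j) n_up += m[j];
  IntegerMatrix up(n_up, 2);
  {
    long row = 0;
    for (int j = 0; j < N; ++j)
      for (int k = 0; k < m[j]; ++k) {
        up(row, 0) = cols[j].idx[k] + 1;
        up(row, 1) = j + 1;
        ++row;
      }
  }

  // distinct dendrites of each postsynaptic neuron ever in the up state
  IntegerVector ever(N);
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < evermax[j]; ++k) ever[cols[j].idx[k]]++;

  List trackL = R_NilValue;
  if (track > 0)
    trackL = List::create(_["time"] = wrap(trk_t), _["rate"] = wrap(trk_r),
                          _["feedback"] = wrap(trk_fb));
  List summ = R_NilValue;
  if (summarize_every > 0)
    summ = List::create(_["time"] = wrap(sum_t), _["amplitude"] = wrap(sum_amp),
                        _["cos_sum"] = wrap(sum_cx), _["sin_sum"] = wrap(sum_cy),
                        _["total"] = wrap(sum_tot));

  NumericVector r_out(r.begin(), r.end());
  return List::create(
    _["r"] = r_out,
    _["up"] = up,
    _["ever_up_count"] = ever,
    _["rates"] = rates,
    _["rate_times"] = wrap(rec_t),
    _["track"] = trackL,
    _["summary"] = summ);
}
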