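// Tick-driven simulation core for the working-memory circuit.
//
// Semantics per tick (length dt, time t = start of tick):
//   1. deliver spike arrivals scheduled for this tick (PSP onset; STDP
//      pre-arrival pairing on plastic synapses),
//   2. compute per-neuron input current: kernel-summed synaptic arrivals
//      within the truncation horizon, plus per-tick Gaussian noise and any
//      active mean-current offset window,
//   3. force any scheduled spike injections (membrane pushed over threshold),
//   4. advance every neuron one explicit-Euler step; threshold crossings
//      spike, reset, and are stamped with the tick-start time,
//   5. spiking neurons run short-term-plasticity updates on their efferent
//      synapses (arrival queued at t + delay) and STDP post-spike pairing on
//      their plastic afferents.
//
// The noise current is piecewise constant: each neuron redraws one normal
// deviate every hold_ticks ticks (redraw ticks are staggered across neurons
// and anchored to the absolute tick index). Draws are consumed in neuron
// order within a tick, so runs are reproducible and a run of length A
// followed by one of length B consumes the same RNG stream as a single run
// of length A + B.

#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <vector>

using namespace Rcpp;

static inline double psp_val(double t, double tau) {
  if (t < 0.0) return 0.0;
  return (t / tau) * std::exp(1.0 - t / tau);
}

struct PendingArrival {
  int neuron;   // 0-based postsynaptic index
  double amp;   // signed w * u * x captured at emission
  int syn;      // 0-based synapse index, -1 if not tied to a synapse
};

// [[Rcpp::export]]
List engine_run(List neuron_state, List syn_state, List par, List sched,
                double t0, double duration, double dt) {
  NumericVector v = clone(as<NumericVector>(neuron_state["v"]));
  NumericVector u = clone(as<NumericVector>(neuron_state["u"]));
  NumericVector pa = neuron_state["a"], pb = neuron_state["b"];
  NumericVector pc = neuron_state["c"], pd = neuron_state["d"];
  NumericVector nmean = neuron_state["noise_mean"];
  NumericVector nsd = neuron_state["noise_sd"];
  LogicalVector elig = neuron_state["offset_eligible"];
  NumericVector nhold = clone(as<NumericVector>(neuron_state["noise_hold"]));
  const int nN = v.size();

  IntegerVector pre = syn_state["pre"], post = syn_state["post"];
  NumericVector w = clone(as<NumericVector>(syn_state["w"]));
  NumericVector delay = syn_state["delay"];
  IntegerVector sgn = syn_state["sign"];
  LogicalVector plastic = syn_state["plastic"];
  NumericVector x = clone(as<NumericVector>(syn_state["x"]));
  NumericVector uu = clone(as<NumericVector>(syn_state["uu"]));
  NumericVector tlast = clone(as<NumericVector>(syn_state["t_last"]));
  NumericVector lpre = clone(as<NumericVector>(syn_state["last_pre"]));
  NumericVector lpost = clone(as<NumericVector>(syn_state["last_post"]));
  const int nS = pre.size();

  const double U = par["U"], tau_f = par["tau_f"], tau_d = par["tau_d"];
  const double tau_psp = par["psp_tau"], horizon = par["psp_horizon"];
  const double eta = par["eta"], a_plus = par["a_plus"];
  const double a_minus = par["a_minus"];  // magnitude of the depression bound
  const double tau_plus = par["tau_plus"], tau_minus = par["tau_minus"];
  const double w_min = par["w_min"], w_max = par["w_max"];
  const int hold_ticks = as<int>(par["hold_ticks"]);  // noise redraw interval

  IntegerVector forced_neuron = sched["forced_neuron"];
  NumericVector forced_time = sched["forced_time"];
  NumericVector off_start = sched["off_start"], off_end = sched["off_end"];
  NumericVector off_amt = sched["off_amount"];
  NumericVector arr_t = sched["arr_time"];
  IntegerVector arr_neuron = sched["arr_neuron"];
  NumericVector arr_amp = sched["arr_amp"];
  IntegerVector arr_syn = sched["arr_syn"];

  const int n_ticks = (int)std::lround(duration / dt);
  const double t_end = t0 + n_ticks * dt;

  // delays in ticks (>= 1); ring buffer sized to the longest delay
  std::vector<int> dticks(nS);
  int maxd = 1;
  for (int s = 0; s < nS; ++s) {
    int ds = (int)std::lround(delay[s] / dt);
    if (ds < 1) ds = 1;
    dticks[s] = ds;
    if (ds > maxd) maxd = ds;
  }
  const int ring_n = maxd + 1;
  std::vector<std::vector<PendingArrival>> ring(ring_n);

  // efferent adjacency (CSR over presynaptic neuron)
  std::vector<int> eff_ptr(nN + 1, 0), eff_idx(nS);
  for (int s = 0; s < nS; ++s) eff_ptr[pre[s] - 1 + 1]++;
  for (int n = 0; n < nN; ++n) eff_ptr[n + 1] += eff_ptr[n];
  {
    std::vector<int> fill(eff_ptr.begin(), eff_ptr.end() - 1);
    for (int s = 0; s < nS; ++s) eff_idx[fill[pre[s] - 1]++] = s;
  }
  // plastic afferent adjacency (CSR over postsynaptic neuron)
  std::vector<int> aff_ptr(nN + 1, 0);
  int nPl = 0;
  for (int s = 0; s < nS; ++s)
    if (plastic[s]) { aff_ptr[post[s] - 1 + 1]++; nPl++; }
  for (int n = 0; n < nN; ++n) aff_ptr[n + 1] += aff_ptr[n];
  std::vector<int> aff_idx(nPl);
  {
    std::vector<int> fill(aff_ptr.begin(), aff_ptr.end() - 1);
    for (int s = 0; s < nS; ++s)
      if (plastic[s]) aff_idx[fill[post[s] - 1]++] = s;
  }

  // active (already delivered) arrivals per neuron, time-ordered
  std::vector<std::deque<std::pair<double, double>>> act(nN);
  // log of delivered arrivals still relevant for carry-over
  std::vector<double> log_t;
  std::vector<int> log_n;
  std::vector<double> log_a;
  std::vector<int> log_s;
  // future arrivals that land beyond this run
  std::vector<double> car_t;
  std::vector<int> car_n;
  std::vector<double> car_a;
  std::vector<int> car_s;

  // classify incoming arrivals: history (PSP trace) vs future (to deliver)
  for (int i = 0; i < arr_t.size(); ++i) {
    int ti = (int)std::lround((arr_t[i] - t0) / dt);
    int nrn = arr_neuron[i] - 1;
    int sid = arr_syn[i] - 1;  // 0 in R means "none" -> -1
    if (ti < 0) {
      act[nrn].push_back(std::make_pair(arr_t[i], arr_amp[i]));
      log_t.push_back(arr_t[i]);
      log_n.push_back(nrn);
      log_a.push_back(arr_amp[i]);
      log_s.push_back(sid);
    } else if (ti >= n_ticks) {
      car_t.push_back(arr_t[i]);
      car_n.push_back(nrn);
      car_a.push_back(arr_amp[i]);
      car_s.push_back(sid);
    } else {
      PendingArrival pa2;
      pa2.neuron = nrn;
      pa2.amp = arr_amp[i];
      pa2.syn = sid;
      ring[ti % ring_n].push_back(pa2);
    }
  }

  // forced injections mapped to tick indices
  std::vector<std::vector<int>> forced(n_ticks > 0 ? n_ticks : 1);
  for (int i = 0; i < forced_time.size(); ++i) {
    int ti = (int)std::lround((forced_time[i] - t0) / dt);
    if (ti >= 0 && ti < n_ticks) forced[ti].push_back(forced_neuron[i] - 1);
  }

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  std::vector<double> I(nN);
  std::vector<int> spiked;
  spiked.reserve(nN);

  GetRNGstate();
  for (int it = 0; it < n_ticks; ++it) {
    const double t = t0 + it * dt;
    const int slot = it % ring_n;

    // 1. deliver arrivals
    for (size_t q = 0; q < ring[slot].size(); ++q) {
      const PendingArrival &ar = ring[slot][q];
      act[ar.neuron].push_back(std::make_pair(t, ar.amp));
      log_t.push_back(t);
      log_n.push_back(ar.neuron);
      log_a.push_back(ar.amp);
      log_s.push_back(ar.syn);
      if (ar.syn >= 0 && plastic[ar.syn]) {
        if (R_finite(lpost[ar.syn])) {
          double dw = eta * (-a_minus * std::exp(-(t - lpost[ar.syn]) / tau_minus));
          double wn = w[ar.syn] + dw;
          w[ar.syn] = wn < w_min ? w_min : (wn > w_max ? w_max : wn);
          lpost[ar.syn] = NA_REAL;  // each post spike pairs once per direction
        }
        lpre[ar.syn] = t;
      }
    }
    ring[slot].clear();

    // 2. input currents
    double off = 0.0;
    for (int i = 0; i < off_start.size(); ++i)
      if (t >= off_start[i] && t < off_end[i]) off += off_amt[i];
    for (int n = 0; n < nN; ++n) {
      std::deque<std::pair<double, double>> &buf = act[n];
      while (!buf.empty() && t - buf.front().first > horizon) buf.pop_front();
      double isyn = 0.0;
      for (size_t q = 0; q < buf.size(); ++q)
        isyn += buf[q].second * psp_val(t - buf[q].first, tau_psp);
      // piecewise-constant noise: each neuron redraws its standard-normal
      // deviate every hold_ticks ticks, phase-staggered across neurons and
      // anchored to the absolute tick index so chained runs agree
      const long abs_tick = (long)std::lround(t / dt);
      if (((abs_tick + n) % hold_ticks) == 0) nhold[n] = norm_rand();
      I[n] = isyn + nmean[n] + (elig[n] ? off : 0.0) + nsd[n] * nhold[n];
    }

    // 3. forced injections
    for (size_t q = 0; q < forced[it].size(); ++q) v[forced[it][q]] = 40.0;

    // 4. neuron step
    spiked.clear();
    for (int n = 0; n < nN; ++n) {
      bool spk = false;
      if (v[n] > 30.0) {
        spk = true;  // forced (or carried-over) suprathreshold state
      } else {
        const double vo = v[n], uo = u[n];
        v[n] = vo + dt * (0.04 * vo * vo + 5.0 * vo + 140.0 - uo + I[n]);
        u[n] = uo + dt * pa[n] * (pb[n] * vo - uo);
        if (!R_finite(v[n]) || !R_finite(u[n])) {
          PutRNGstate();
          stop("numerical instability: non-finite state for neuron %d at t = %.2f ms",
               n + 1, t);
        }
        if (v[n] > 30.0) spk = true;
      }
      if (spk) {
        v[n] = pc[n];
        u[n] += pd[n];
        spiked.push_back(n);
        sp_neuron.push_back(n + 1);
        sp_time.push_back(t);
      }
    }

    // 5. propagate spikes (STP + delay queue) and STDP post pairing
    for (size_t q = 0; q < spiked.size(); ++q) {
      const int n = spiked[q];
      for (int p = eff_ptr[n]; p < eff_ptr[n + 1]; ++p) {
        const int s = eff_idx[p];
        const double dte = t - tlast[s];
        x[s] = 1.0 - (1.0 - x[s]) * std::exp(-dte / tau_d);
        uu[s] = U + (uu[s] - U) * std::exp(-dte / tau_f);
        uu[s] = uu[s] + U * (1.0 - uu[s]);   // facilitation jump first
        const double eff = uu[s] * x[s];     // transmitted efficacy
        x[s] = x[s] - uu[s] * x[s];          // then depression jump
        tlast[s] = t;
        PendingArrival pa2;
        pa2.neuron = post[s] - 1;
        pa2.amp = sgn[s] * w[s] * eff;
        pa2.syn = s;
        const int ta = it + dticks[s];
        if (ta < n_ticks) {
          ring[ta % ring_n].push_back(pa2);
        } else {
          car_t.push_back(t0 + ta * dt);
          car_n.push_back(pa2.neuron);
          car_a.push_back(pa2.amp);
          car_s.push_back(s);
        }
      }
      for (int p = aff_ptr[n]; p < aff_ptr[n + 1]; ++p) {
        const int s = aff_idx[p];
        if (R_finite(lpre[s])) {
          const double dtt = lpre[s] - t;
          double dw = eta * (dtt < 0 ? a_plus * std::exp(dtt / tau_plus)
                                     : -a_minus * std::exp(-dtt / tau_minus));
          double wn = w[s] + dw;
          w[s] = wn < w_min ? w_min : (wn > w_max ? w_max : wn);
          lpre[s] = NA_REAL;
        }
        lpost[s] = t;
      }
    }
  }
  PutRNGstate();

  // carry-over: delivered arrivals still inside the horizon, plus futures
  std::vector<double> out_t;
  std::vector<int> out_n;
  std::vector<double> out_a;
  std::vector<int> out_s;
  for (size_t i = 0; i < log_t.size(); ++i) {
    if (t_end - log_t[i] <= horizon) {
      out_t.push_back(log_t[i]);
      out_n.push_back(log_n[i] + 1);
      out_a.push_back(log_a[i]);
      out_s.push_back(log_s[i] + 1);
    }
  }
  for (size_t i = 0; i < car_t.size(); ++i) {
    out_t.push_back(car_t[i]);
    out_n.push_back(car_n[i] + 1);
    out_a.push_back(car_a[i]);
    out_s.push_back(car_s[i] + 1);
  }

  return List::create(
      _["spike_neuron"] = wrap(sp_neuron), _["spike_time"] = wrap(sp_time),
      _["v"] = v, _["u"] = u, _["noise_hold"] = nhold,
      _["w"] = w, _["x"] = x, _["uu"] = uu,
      _["t_last"] = tlast, _["last_pre"] = lpre, _["last_post"] = lpost,
      _["arr_time"] = wrap(out_t), _["arr_neuron"] = wrap(out_n),
      _["arr_amp"] = wrap(out_a), _["arr_syn"] = wrap(out_s),
      _["t_end"] = t_end);
}
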