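// Millisecond-resolution spiking network engine.
//
// Dynamics (Izhikevich model): v' = 0.04 v^2 + 5 v + 140 - u + I,
// u' = a (b v - u), spike cutoff at v >= 30 mV. Integration uses two 0.5 ms
// forward-Euler substeps for v (cutoff checked and clamped after each) and a
// single 1 ms step for u, with the synaptic + external input applied at tick
// start; the spike reset (v <- c, u <- u + d) is applied within the tick.
//
// STDP uses unit-amplitude exponential traces with trace reset on each event
// (nearest-event semantics): the LTD trace is indexed by the post-synaptic
// neuron's last firing time, the LTP trace by each synapse's last
// pre-synaptic *arrival* time (spike time + conduction delay). Derivatives
// accumulate between once-per-interval weight updates:
//   w <- clip(w + drift + sd, 0, w_max);  sd <- decay * sd.
//
// Metaplasticity recomputes the per-neuron modification threshold
// theta = tanh(inertia * mean_i f(sd_i, w_i)) over plastic afferents
// immediately before each weight update, and the modulated amplitudes
// A_ltp = A+(0) (1 - theta), A_ltd = A-(0) (1 + theta) then hold for the
// next interval.
//
// The engine draws no random numbers: all stochastic inputs are generated on
// the R side, so determinism is inherited from R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEVER = -1e18;

static inline double resistance_fn(double d, double w, double r, double p,
                                   double soft_min, double soft_max) {
  double m = 0.5 * (d + 10.0);
  if (m < 0.0) m = 0.0;
  if (m > 10.0) m = 10.0;
  return r * std::exp(p * m) * (w - soft_min) -
         r * std::exp(p * (10.0 - m)) * (soft_max - w);
}

// [[Rcpp::export]]
List run_network_cpp(IntegerVector pre, IntegerVector post, IntegerVector delay,
                     NumericVector weight0, NumericVector deriv0,
                     LogicalVector plastic,
                     NumericVector pa, NumericVector pb, NumericVector pc,
                     NumericVector pd, LogicalVector excitatory,
                     NumericVector v0, NumericVector u0,
                     NumericVector last_fire0, NumericVector last_arrival0,
                     NumericVector theta0,
                     IntegerVector pend_syn, IntegerVector pend_time,
                     IntegerVector cur_time, IntegerVector cur_neuron,
                     NumericVector cur_amp,
                     IntegerVector force_time, IntegerVector force_neuron,
                     int t_start, int duration,
                     bool plasticity_on, bool meta_on,
                     double A_plus, double A_minus,
                     double tau_plus, double tau_minus,
                     double drift, double decay, int update_interval,
                     double w_max,
                     double meta_r, double meta_p, double inertia,
                     double soft_min, double soft_max,
                     double guard_hz, bool record_raster, bool record_series) {
  const int n_syn = pre.size();
  const int n_neu = pa.size();

  // raw views of the immutable inputs keep the tick loop free of Rcpp
  // accessor overhead
  const int* p_pre = INTEGER(pre);
  const int* p_post = INTEGER(post);
  const int* p_delay = INTEGER(delay);
  const int* p_plastic = LOGICAL(plastic);
  const int* p_exc = LOGICAL(excitatory);
  const double* p_a = REAL(pa);
  const double* p_b = REAL(pb);
  const double* p_c = REAL(pc);
  const double* p_d = REAL(pd);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> w(weight0.begin(), weight0.end());
  std::vector<double> sd(deriv0.begin(), deriv0.end());
  std::vector<double> last_fire(last_fire0.begin(), last_fire0.end());
  std::vector<double> last_arr(last_arrival0.begin(), last_arrival0.end());
  std::vector<double> theta(theta0.begin(), theta0.end());

  // current amplitudes per post-synaptic neuron; baseline unless metaplastic
  std::vector<double> a_ltp(n_neu), a_ltd(n_neu);
  for (int j = 0; j < n_neu; ++j) {
    a_ltp[j] = A_plus * (1.0 - theta[j]);
    a_ltd[j] = A_minus * (1.0 + theta[j]);
  }

  // outgoing and plastic-afferent adjacency (CSR over synapse indices)
  std::vector<int> out_count(n_neu, 0), in_count(n_neu, 0);
  for (int s = 0; s < n_syn; ++s) {
    out_count[p_pre[s] - 1]++;
    if (p_plastic[s]) in_count[p_post[s] - 1]++;
  }
  std::vector<int> out_start(n_neu + 1, 0), in_start(n_neu + 1, 0);
  for (int j = 0; j < n_neu; ++j) {
    out_start[j + 1] = out_start[j] + out_count[j];
    in_start[j + 1] = in_start[j] + in_count[j];
  }
  std::vector<int> out_idx(n_syn), in_idx(in_start[n_neu]);
  {
    std::vector<int> oc(out_start.begin(), out_start.end() - 1);
    std::vector<int> ic(in_start.begin(), in_start.end() - 1);
    for (int s = 0; s < n_syn; ++s) {
      out_idx[oc[p_pre[s] - 1]++] = s;
      if (p_plastic[s]) in_idx[ic[p_post[s] - 1]++] = s;
    }
  }

  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s)
    if (p_delay[s] > max_delay) max_delay = p_delay[s];
  const int ring_n = max_delay + 1;
  std::vector<std::vector<int>> ring(ring_n);

  // in-flight arrivals from a previous run segment
  for (int k = 0; k < pend_syn.size(); ++k) {
    int at = pend_time[k];
    if (at < t_start || at >= t_start + ring_n)
      stop("pending arrival at t=%d outside the delay horizon of the resumed run", at);
    ring[((at % ring_n) + ring_n) % ring_n].push_back(pend_syn[k] - 1);
  }

  std::vector<double> I(n_neu);
  std::vector<char> fired(n_neu);
  std::vector<int> raster_t, raster_n;
  raster_t.reserve(4096);
  raster_n.reserve(4096);

  // diagnostics per completed update interval
  std::vector<double> diag_sec, diag_exc, diag_inh, diag_theta;
  int sec_exc = 0, sec_inh = 0;
  int n_exc_neu = 0;
  for (int j = 0; j < n_neu; ++j)
    if (p_exc[j]) n_exc_neu++;

  // optional per-interval series for toy circuits
  std::vector<double> ser_w, ser_sd, ser_theta;

  int ci = 0, fi = 0;  // cursors into sorted event streams
  const int n_cur = cur_time.size(), n_force = force_time.size();

  for (int step = 0; step < duration; ++step) {
    const int t = t_start + step;
    const int slot = ((t % ring_n) + ring_n) % ring_n;

    std::fill(I.begin(), I.end(), 0.0);

    // synaptic arrivals scheduled for this tick
    std::vector<int>& arr = ring[slot];
    for (size_t k = 0; k < arr.size(); ++k) {
      const int s = arr[k];
      const int j = p_post[s] - 1;
      I[j] += w[s];
      last_arr[s] = t;
      if (plasticity_on && p_plastic[s] && last_fire[j] > NEVER) {
        // post fired before this pre arrival: depression
        sd[s] -= a_ltd[j] * std::exp(-(t - last_fire[j]) / tau_minus);
      }
    }
    arr.clear();

    // external current pulses
    while (ci < n_cur && cur_time[ci] == t) {
      I[cur_neuron[ci] - 1] += cur_amp[ci];
      ci++;
    }
    if (ci < n_cur && cur_time[ci] < t)
      stop("external current events must be sorted by time");

    std::fill(fired.begin(), fired.end(), 0);

    // forced spikes: exact emission at this tick
    while (fi < n_force && force_time[fi] == t) {
      fired[force_neuron[fi] - 1] = 2;  // 2 = forced, skip integration
      fi++;
    }
    if (fi < n_force && force_time[fi] < t)
      stop("forced spike events must be sorted by time");

    for (int j = 0; j < n_neu; ++j) {
      if (fired[j] == 2) {
        v[j] = p_c[j];
        u[j] += p_d[j];
        continue;
      }
      double vj = v[j], uj = u[j];
      bool f = false;
      for (int sub = 0; sub < 2; ++sub) {
        vj += 0.5 * (0.04 * vj * vj + 5.0 * vj + 140.0 - uj + I[j]);
        if (vj >= 30.0) {
          vj = 30.0;
          f = true;
          break;
        }
      }
      uj += p_a[j] * (p_b[j] * vj - uj);
      if (f) {
        vj = p_c[j];
        uj += p_d[j];
        fired[j] = 1;
      }
      if (!std::isfinite(vj) || !std::isfinite(uj))
        stop("non-finite membrane state for neuron %d at t = %d ms", j + 1, t);
      v[j] = vj;
      u[j] = uj;
    }

    for (int j = 0; j < n_neu; ++j) {
      if (!fired[j]) continue;
      if (record_raster) {
        raster_t.push_back(t);
        raster_n.push_back(j + 1);
      }
      if (p_exc[j]) sec_exc++; else sec_inh++;
      last_fire[j] = t;
      if (plasticity_on) {
        // potentiation of plastic afferents whose arrival preceded this spike
        for (int k = in_start[j]; k < in_start[j + 1]; ++k) {
          const int s = in_idx[k];
          if (last_arr[s] > NEVER)
            sd[s] += a_ltp[j] * std::exp(-(t - last_arr[s]) / tau_plus);
        }
      }
      // schedule outgoing arrivals
      for (int k = out_start[j]; k < out_start[j + 1]; ++k) {
        const int s = out_idx[k];
        ring[((t + p_delay[s]) % ring_n)].push_back(s);
      }
    }

    // end-of-interval bookkeeping (aligned to absolute time)
    if ((t + 1) % update_interval == 0) {
      double mean_theta = 0.0;
      if (plasticity_on && meta_on) {
        for (int j = 0; j < n_neu; ++j) {
          if (!p_exc[j]) continue;
          const int nin = in_start[j + 1] - in_start[j];
          if (nin == 0) continue;
          double acc = 0.0;
          for (int k = in_start[j]; k < in_start[j + 1]; ++k) {
            const int s = in_idx[k];
            acc += resistance_fn(sd[s], w[s], meta_r, meta_p, soft_min, soft_max);
          }
          theta[j] = std::tanh(inertia * acc / nin);
          a_ltp[j] = A_plus * (1.0 - theta[j]);
          a_ltd[j] = A_minus * (1.0 + theta[j]);
        }
      }
      {
        int nth = 0;
        for (int j = 0; j < n_neu; ++j)
          if (p_exc[j]) { mean_theta += theta[j]; nth++; }
        if (nth > 0) mean_theta /= nth;
      }
      if (plasticity_on) {
        for (int s = 0; s < n_syn; ++s) {
          if (!p_plastic[s]) continue;
          double ws = w[s] + drift + sd[s];
          if (ws < 0.0) ws = 0.0;
          if (ws > w_max) ws = w_max;
          w[s] = ws;
          sd[s] *= decay;
        }
      }
      const double secs = update_interval / 1000.0;
      const double exc_rate = n_exc_neu > 0 ? sec_exc / (secs * n_exc_neu) : 0.0;
      const double inh_rate = (n_neu - n_exc_neu) > 0
        ? sec_inh / (secs * (n_neu - n_exc_neu)) : 0.0;
      diag_sec.push_back((t + 1) / 1000.0);
      diag_exc.push_back(exc_rate);
      diag_inh.push_back(inh_rate);
      diag_theta.push_back(mean_theta);
      if (guard_hz > 0 && exc_rate > guard_hz)
        stop("runaway firing: mean excitatory rate %.1f Hz > guard %.1f Hz in the interval ending at t = %d ms",
             exc_rate, guard_hz, t + 1);
      sec_exc = 0;
      sec_inh = 0;
      if (record_series) {
        for (int s = 0; s < n_syn; ++s) { ser_w.push_back(w[s]); ser_sd.push_back(sd[s]); }
        for (int j = 0; j < n_neu; ++j) ser_theta.push_back(theta[j]);
      }
    }
  }

  // collect in-flight arrivals for exact resume
  std::vector<int> out_pend_s, out_pend_t;
  const int t_end = t_start + duration;
  for (int d = 0; d < ring_n; ++d) {
    // slot for absolute time t_end + k is (t_end + k) % ring_n
    const int at = t_end + d;
    const std::vector<int>& b = ring[((at % ring_n) + ring_n) % ring_n];
    for (size_t k = 0; k < b.size(); ++k) {
      out_pend_s.push_back(b[k] + 1);
      out_pend_t.push_back(at);
    }
  }

  List series = R_NilValue;
  if (record_series) {
    const int K = ser_theta.size() / std::max(n_neu, 1);
    series = List::create(
      _["n_intervals"] = K,
      _["weight"] = NumericVector(ser_w.begin(), ser_w.end()),
      _["derivative"] = NumericVector(ser_sd.begin(), ser_sd.end()),
      _["theta"] = NumericVector(ser_theta.begin(), ser_theta.end()));
  }

  return List::create(
    _["spike_time"] = IntegerVector(raster_t.begin(), raster_t.end()),
    _["spike_neuron"] = IntegerVector(raster_n.begin(), raster_n.end()),
    _["weight"] = NumericVector(w.begin(), w.end()),
    _["derivative"] = NumericVector(sd.begin(), sd.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["last_fire"] = NumericVector(last_fire.begin(), last_fire.end()),
    _["last_arrival"] = NumericVector(last_arr.begin(), last_arr.end()),
    _["theta"] = NumericVector(theta.begin(), theta.end()),
    _["pending_synapse"] = IntegerVector(out_pend_s.begin(), out_pend_s.end()),
    _["pending_time"] = IntegerVector(out_pend_t.begin(), out_pend_t.end()),
    _["time_end"] = t_end,
    _["diagnostics"] = List::create(
      _["second"] = NumericVector(diag_sec.begin(), diag_sec.end()),
      _["rate_excitatory"] = NumericVector(diag_exc.begin(), diag_exc.end()),
      _["rate_inhibitory"] = NumericVector(diag_inh.begin(), diag_inh.end()),
      _["mean_theta"] = NumericVector(diag_theta.begin(), diag_theta.end())),
    _["series"] = series);
}

// Repeated independent test frames on a small circuit with plasticity off.
// Each trial starts from the resting state; forced spikes and current pulses
// are given as offsets within the frame, with optional per-trial extra
// current events (e.g. background noise). Returns the target neuron's first
// spike time within each frame (-1 if it never fired).
// [[Rcpp::export]]
IntegerVector run_frames_cpp(IntegerVector pre, IntegerVector post,
                             IntegerVector delay, NumericVector weight,
                             NumericVector pa, NumericVector pb,
                             NumericVector pc, NumericVector pd,
                             IntegerVector force_off, IntegerVector force_neuron,
                             IntegerVector cur_off, IntegerVector cur_neuron,
                             NumericVector cur_amp,
                             IntegerVector trial_idx, IntegerVector trial_off,
                             IntegerVector trial_neuron, NumericVector trial_amp,
                             int frame_ms, int n_trials, int target) {
  const int n_syn = pre.size();
  const int n_neu = pa.size();
  const int* p_pre = INTEGER(pre);
  const int* p_post = INTEGER(post);
  const int* p_delay = INTEGER(delay);
  const double* p_w = REAL(weight);
  const double* p_a = REAL(pa);
  const double* p_b = REAL(pb);
  const double* p_c = REAL(pc);
  const double* p_d = REAL(pd);
  if (n_trials < 1) stop("n_trials must be at least 1");
  if (target < 1 || target > n_neu) stop("unknown target neuron id %d", target);

  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s)
    if (p_delay[s] > max_delay) max_delay = p_delay[s];
  const int ring_n = max_delay + 1;

  // per-tick event index for the shared frame schedule
  std::vector<std::vector<int>> force_at(frame_ms), cur_at(frame_ms);
  for (int k = 0; k < force_off.size(); ++k) {
    if (force_off[k] < 0 || force_off[k] >= frame_ms)
      stop("forced-spike offset outside the frame");
    force_at[force_off[k]].push_back(k);
  }
  for (int k = 0; k < cur_off.size(); ++k) {
    if (cur_off[k] < 0 || cur_off[k] >= frame_ms)
      stop("current-pulse offset outside the frame");
    cur_at[cur_off[k]].push_back(k);
  }
  // per-trial extras, grouped
  std::vector<std::vector<int>> extras(n_trials);
  for (int k = 0; k < trial_idx.size(); ++k) {
    const int tr = trial_idx[k] - 1;
    if (tr < 0 || tr >= n_trials) stop("trial index out of range");
    extras[tr].push_back(k);
  }

  std::vector<int> out_count(n_neu, 0);
  for (int s = 0; s < n_syn; ++s) out_count[p_pre[s] - 1]++;
  std::vector<int> out_start(n_neu + 1, 0);
  for (int j = 0; j < n_neu; ++j) out_start[j + 1] = out_start[j] + out_count[j];
  std::vector<int> out_idx(n_syn);
  {
    std::vector<int> oc(out_start.begin(), out_start.end() - 1);
    for (int s = 0; s < n_syn; ++s) out_idx[oc[p_pre[s] - 1]++] = s;
  }

  IntegerVector first_spike(n_trials, -1);
  std::vector<double> v(n_neu), u(n_neu), I(n_neu);
  std::vector<std::vector<int>> ring(ring_n);

  for (int tr = 0; tr < n_trials; ++tr) {
    for (int j = 0; j < n_neu; ++j) {
      // exact resting fixed point of the dynamics (0.04 v^2 + (5-b) v + 140 = 0)
      v[j] = -70.0;
      u[j] = p_b[j] * v[j];
    }
    for (int d = 0; d < ring_n; ++d) ring[d].clear();
    // per-tick extra events for this trial
    std::vector<std::vector<int>> extra_at(frame_ms);
    for (size_t k = 0; k < extras[tr].size(); ++k) {
      const int e = extras[tr][k];
      if (trial_off[e] < 0 || trial_off[e] >= frame_ms)
        stop("per-trial event offset outside the frame");
      extra_at[trial_off[e]].push_back(e);
    }

    for (int t = 0; t < frame_ms; ++t) {
      const int slot = t % ring_n;
      std::fill(I.begin(), I.end(), 0.0);
      std::vector<int>& arrv = ring[slot];
      for (size_t k = 0; k < arrv.size(); ++k) I[post[arrv[k]] - 1] += p_w[arrv[k]];
      arrv.clear();
      for (size_t k = 0; k < cur_at[t].size(); ++k)
        I[cur_neuron[cur_at[t][k]] - 1] += cur_amp[cur_at[t][k]];
      for (size_t k = 0; k < extra_at[t].size(); ++k)
        I[trial_neuron[extra_at[t][k]] - 1] += trial_amp[extra_at[t][k]];

      std::vector<char> fired(n_neu, 0);
      for (size_t k = 0; k < force_at[t].size(); ++k)
        fired[force_neuron[force_at[t][k]] - 1] = 2;

      for (int j = 0; j < n_neu; ++j) {
        if (fired[j] == 2) {
          v[j] = p_c[j];
          u[j] += p_d[j];
          continue;
        }
        double vj = v[j], uj = u[j];
        bool f = false;
        for (int sub = 0; sub < 2; ++sub) {
          vj += 0.5 * (0.04 * vj * vj + 5.0 * vj + 140.0 - uj + I[j]);
          if (vj >= 30.0) { vj = 30.0; f = true; break; }
        }
        uj += p_a[j] * (p_b[j] * vj - uj);
        if (f) { vj = p_c[j]; uj += p_d[j]; fired[j] = 1; }
        if (!std::isfinite(vj) || !std::isfinite(uj))
          stop("non-finite membrane state for neuron %d at frame offset %d ms", j + 1, t);
        v[j] = vj;
        u[j] = uj;
      }

      for (int j = 0; j < n_neu; ++j) {
        if (!fired[j]) continue;
        if (j + 1 == target && first_spike[tr] < 0) first_spike[tr] = t;
        for (int k = out_start[j]; k < out_start[j + 1]; ++k) {
          const int s = out_idx[k];
          ring[(t + p_delay[s]) % ring_n].push_back(s);
        }
      }
    }
  }
  return first_spike;
}

// Connection-activation partition: a connection is active iff some pre-spike
// at t1 and post-spike at t2 satisfy delay <= t2 - t1 <= delay + jitter.
// spikes_by_neuron is a list of sorted integer spike-time vectors, one per
// neuron id.
// [[Rcpp::export]]
LogicalVector partition_connections_cpp(IntegerVector pre, IntegerVector post,
                                        IntegerVector delay, List spikes_by_neuron,
                                        int jitter) {
  const int n_syn = pre.size();
  const int* p_pre = INTEGER(pre);
  const int* p_post = INTEGER(post);
  const int* p_delay = INTEGER(delay);
  LogicalVector active(n_syn);
  const int n_neu = spikes_by_neuron.size();
  std::vector<IntegerVector> sp(n_neu);
  for (int j = 0; j < n_neu; ++j) sp[j] = as<IntegerVector>(spikes_by_neuron[j]);
  for (int s = 0; s < n_syn; ++s) {
    const IntegerVector& a = sp[p_pre[s] - 1];
    const IntegerVector& b = sp[p_post[s] - 1];
    const int d = p_delay[s];
    bool act = false;
    int bi = 0;
    for (int ai = 0; ai < a.size() && !act; ++ai) {
      const int lo = a[ai] + d, hi = a[ai] + d + jitter;
      while (bi < b.size() && b[bi] < lo) bi++;
      if (bi < b.size() && b[bi] <= hi) act = true;
    }
    active[s] = act;
  }
  return active;
}
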