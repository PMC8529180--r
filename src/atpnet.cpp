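// Core numerical routines: connectivity sampling, link rewiring, the RK2
// network integrator, the deterministic mean-field integrator, and windowed
// firing-rate counting. All randomness flows through a self-contained
// xoshiro256++ generator so that a run is bit-reproducible from its seed
// alone, independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  double spare;
  bool has_spare;

  explicit Xoshiro(uint64_t seed) : has_spare(false) {
    // splitmix64 expansion of the seed into the full state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double runif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in {0, ..., n-1}
  inline int runif_int(int n) {
    int k = (int)(runif() * n);
    return k >= n ? n - 1 : k;
  }

  // standard normal, Box-Muller with cached spare
  inline double rnorm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1;
    do {
      u1 = runif();
    } while (u1 <= 0.0);
    const double u2 = runif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

}  // namespace

// Sample directed links j -> i with probability p0 * exp(-d^2 / (2 sigma^2)),
// independently for every ordered pair, no self-links. Returns 1-based
// (target, source) index vectors.
// [[Rcpp::export]]
List cpp_sample_connectivity(NumericVector x, NumericVector y, double sigma_mm,
                             double peak_prob, double seed) {
  const int n = x.size();
  Xoshiro rng((uint64_t)seed);
  const double inv2s2 = 1.0 / (2.0 * sigma_mm * sigma_mm);
  std::vector<int> tgt, src;
  tgt.reserve((size_t)n * 12);
  src.reserve((size_t)n * 12);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double u = rng.runif();
      if (u >= peak_prob) continue;  // cannot link whatever the distance
      const double dx = xi - x[j], dy = yi - y[j];
      const double p = peak_prob * std::exp(-(dx * dx + dy * dy) * inv2s2);
      if (u < p) {
        tgt.push_back(i + 1);
        src.push_back(j + 1);
      }
    }
  }
  return List::create(_["target"] = wrap(tgt), _["source"] = wrap(src));
}

// Watts-Strogatz style rewiring: each link is selected independently with
// probability beta; a selected link keeps its target and receives a new
// source drawn uniformly among neurons, resampling on self-links and on
// collisions with existing links. Link count is preserved.
// [[Rcpp::export]]
List cpp_rewire_links(IntegerVector target, IntegerVector source, int n,
                      double beta, double seed) {
  const R_xlen_t m = target.size();
  Xoshiro rng((uint64_t)seed);
  std::unordered_set<int64_t> links;
  links.reserve((size_t)(m * 1.4) + 8);
  for (R_xlen_t k = 0; k < m; ++k) {
    links.insert((int64_t)(target[k] - 1) * n + (source[k] - 1));
  }
  IntegerVector new_source = clone(source);
  LogicalVector rewired(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    if (rng.runif() >= beta) continue;
    const int t = target[k] - 1;
    const int old_s = new_source[k] - 1;
    if (n <= 1) continue;
    int s;
    int guard = 0;
    do {
      s = rng.runif_int(n);
      if (++guard > 1000000)
        stop("rewiring could not find a free source for target %d", t + 1);
    } while (s == t ||
             (s != old_s && links.count((int64_t)t * n + s) > 0));
    links.erase((int64_t)t * n + old_s);
    links.insert((int64_t)t * n + s);
    new_source[k] = s + 1;
    rewired[k] = (s != old_s);
  }
  return List::create(_["source"] = new_source, _["rewired"] = rewired);
}

// Heun (explicit trapezoid) integration of the coupled voltage / ATP /
// synaptic cascade system. The synaptic cascade (a, s) has unit-impulse
// response s(t) = (t/lambda) exp(-t/lambda), so one spike through a weight-w
// link contributes an EPSC with time integral lambda * w (= 2w at the 2-ms
// default).
//
// Spike bookkeeping: a neuron whose voltage reaches 1 at the end of a step is
// reset to 0, its ATP is decremented by epsilon (then floored), the spike
// time is the end of the step, and its outgoing impulses reach the target
// cascades at the start of the next step. No refractory period.
//
// Connectivity arrives in compressed-sparse-column form with columns indexed
// by SOURCE neuron and row indices giving the TARGETS, i.e. exactly the
// dgCMatrix slots of the weight matrix C (C[i, j] = strength of j -> i):
// column j of C lists neuron j's outgoing links.
// [[Rcpp::export]]
List cpp_simulate_network(IntegerVector colptr, IntegerVector rowind,
                          NumericVector weight, int n, List params,
                          double duration_ms, double seed, int trace_every,
                          IntegerVector trace_neurons, bool record_pop) {
  const double iapp0 = as<double>(params["iApp0"]);
  const double sigma_i = as<double>(params["sigmaI"]);
  const double tau_leak = as<double>(params["tauLeak"]);
  const double alpha = as<double>(params["alpha"]);
  const double eps = as<double>(params["epsilon"]);
  const double atp_max = as<double>(params["atpMax"]);
  const double tau_atp = as<double>(params["tauATP"]);
  const double lambda = as<double>(params["lambdaSyn"]);
  const double dt = as<double>(params["dt"]);
  const double atp_floor = as<double>(params["atpFloor"]);

  const int steps = (int)std::lround(duration_ms / dt);
  Xoshiro rng((uint64_t)seed);

  std::vector<double> v(n), atp(n, atp_max), a(n, 0.0), s(n, 0.0),
      pend(n, 0.0), noise(n);
  for (int i = 0; i < n; ++i) v[i] = rng.runif();  // v0 ~ U(0,1)

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 20);
  spike_t.reserve(1 << 20);

  const int n_trace = trace_neurons.size();
  const int n_rec = trace_every > 0 ? steps / trace_every + 1 : 0;
  NumericVector rec_t(n_rec);
  NumericVector pop_v(record_pop ? n_rec : 0), pop_atp(record_pop ? n_rec : 0),
      pop_s(record_pop ? n_rec : 0);
  NumericMatrix tr_v(n_rec, n_trace), tr_atp(n_rec, n_trace),
      tr_s(n_rec, n_trace);
  int rec = 0;

  auto record = [&](double t_now) {
    if (trace_every <= 0 || rec >= n_rec) return;
    rec_t[rec] = t_now;
    if (record_pop) {
      double sv = 0, sa = 0, ss = 0;
      for (int i = 0; i < n; ++i) {
        sv += v[i];
        sa += atp[i];
        ss += s[i];
      }
      pop_v[rec] = sv / n;
      pop_atp[rec] = sa / n;
      pop_s[rec] = ss / n;
    }
    for (int k = 0; k < n_trace; ++k) {
      const int i = trace_neurons[k] - 1;
      tr_v(rec, k) = v[i];
      tr_atp(rec, k) = atp[i];
      tr_s(rec, k) = s[i];
    }
    ++rec;
  };

  record(0.0);

  const double inv_leak = 1.0 / tau_leak;
  const double inv_lam = 1.0 / lambda;
  const double inv_tatp = 1.0 / tau_atp;

  for (int k = 0; k < steps; ++k) {
    const double t_next = (k + 1) * dt;

    // deliver impulses from spikes of the previous step
    for (int i = 0; i < n; ++i) {
      a[i] += pend[i];
      pend[i] = 0.0;
    }
    // one applied-current draw per neuron, frozen across both stages
    for (int i = 0; i < n; ++i) noise[i] = iapp0 + sigma_i * rng.rnorm();

    for (int i = 0; i < n; ++i) {
      const double vi = v[i], ai = a[i], si = s[i], pi = atp[i];
      // stage 1
      const double dv1 = noise[i] - vi * inv_leak - alpha * vi * atp_max / pi + si;
      const double dp1 = (atp_max - pi) * inv_tatp;
      const double da1 = -ai * inv_lam;
      const double ds1 = (ai - si) * inv_lam;
      // Euler predictor
      const double vP = vi + dt * dv1;
      const double pP = pi + dt * dp1;
      const double aP = ai + dt * da1;
      const double sP = si + dt * ds1;
      // stage 2
      const double dv2 = noise[i] - vP * inv_leak - alpha * vP * atp_max / pP + sP;
      const double dp2 = (atp_max - pP) * inv_tatp;
      const double da2 = -aP * inv_lam;
      const double ds2 = (aP - sP) * inv_lam;

      double vn = vi + 0.5 * dt * (dv1 + dv2);
      double pn = pi + 0.5 * dt * (dp1 + dp2);
      a[i] = ai + 0.5 * dt * (da1 + da2);
      s[i] = si + 0.5 * dt * (ds1 + ds2);

      if (vn >= 1.0) {
        vn = 0.0;
        pn -= eps;
        spike_id.push_back(i + 1);
        spike_t.push_back(t_next);
        // queue outgoing impulses for the next step
        for (int q = colptr[i]; q < colptr[i + 1]; ++q)
          pend[rowind[q]] += weight[q];
      }
      if (pn < atp_floor) pn = atp_floor;
      if (pn > atp_max) pn = atp_max;
      v[i] = vn;
      atp[i] = pn;
    }

    if ((k & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(v[i]) || !std::isfinite(atp[i]))
          stop("non-finite state for neuron %d at t = %.1f ms", i + 1, t_next);
      }
      if ((k & 262143) == 0) Rcpp::checkUserInterrupt();
    }

    if (trace_every > 0 && ((k + 1) % trace_every == 0)) record(t_next);
  }

  return List::create(
      _["spikeNeuron"] = wrap(spike_id), _["spikeTimeMs"] = wrap(spike_t),
      _["traceTimeMs"] = rec_t, _["popV"] = pop_v, _["popAtp"] = pop_atp,
      _["popSyn"] = pop_s, _["traceV"] = tr_v, _["traceAtp"] = tr_atp,
      _["traceSyn"] = tr_s);
}

// Deterministic single-neuron mean-field model: the synaptic drive is the
// neuron's own Hann-windowed firing rate (spikes/ms) times 2*C_feedback —
// the per-spike voltage integral a unit-strength synapse delivers. No noise.
//
// Post-spike convention: the voltage is held at the reset value for exactly
// one integration step after a spike before integration resumes (the ATP
// production equation keeps running). This single dead step is what
// reproduces the steady-state discharge of the reference trajectory at
// dt = 0.5 ms; see the methods vignette for the analysis.
// [[Rcpp::export]]
List cpp_simulate_meanfield(List params, double c_feedback, double window_ms,
                            double duration_ms) {
  const double iapp0 = as<double>(params["iApp0"]);
  const double tau_leak = as<double>(params["tauLeak"]);
  const double alpha = as<double>(params["alpha"]);
  const double eps = as<double>(params["epsilon"]);
  const double atp_max = as<double>(params["atpMax"]);
  const double tau_atp = as<double>(params["tauATP"]);
  const double dt = as<double>(params["dt"]);
  const double atp_floor = as<double>(params["atpFloor"]);

  const int steps = (int)std::lround(duration_ms / dt);
  const double L = window_ms;
  const double two_pi = 6.283185307179586476925286766559;
  const double denom = L / 2.0;  // integral of the Hann window over [0, L]

  double v = 0.0, atp = atp_max;
  bool hold = false;
  std::vector<double> spikes;  // spike times, ms
  size_t win_lo = 0;           // oldest spike still inside the window

  NumericVector out_t(steps + 1), out_v(steps + 1), out_atp(steps + 1),
      out_ifr(steps + 1);
  out_t[0] = 0.0;
  out_v[0] = v;
  out_atp[0] = atp;
  out_ifr[0] = 0.0;

  const double inv_leak = 1.0 / tau_leak;
  const double inv_tatp = 1.0 / tau_atp;

  auto hann_rate = [&](double t) -> double {
    while (win_lo < spikes.size() && spikes[win_lo] <= t - L) ++win_lo;
    double acc = 0.0;
    for (size_t q = win_lo; q < spikes.size(); ++q) {
      const double u = spikes[q] - t + L;  // position in (0, L]
      if (u > 0.0 && u <= L) acc += 0.5 * (1.0 - std::cos(two_pi * u / L));
    }
    return acc / denom;
  };

  for (int k = 0; k < steps; ++k) {
    const double t_now = k * dt;
    const double t_next = t_now + dt;
    const double ifr = hann_rate(t_now);  // frozen across both stages
    const double drive = iapp0 + 2.0 * c_feedback * ifr;

    double vn, pn;
    if (hold) {
      // dead step: voltage pinned at reset, ATP keeps relaxing
      const double dp1 = (atp_max - atp) * inv_tatp;
      const double pP = atp + dt * dp1;
      const double dp2 = (atp_max - pP) * inv_tatp;
      pn = atp + 0.5 * dt * (dp1 + dp2);
      vn = 0.0;
      hold = false;
    } else {
      const double dv1 = drive - v * inv_leak - alpha * v * atp_max / atp;
      const double dp1 = (atp_max - atp) * inv_tatp;
      const double vP = v + dt * dv1;
      const double pP = atp + dt * dp1;
      const double dv2 = drive - vP * inv_leak - alpha * vP * atp_max / pP;
      const double dp2 = (atp_max - pP) * inv_tatp;
      vn = v + 0.5 * dt * (dv1 + dv2);
      pn = atp + 0.5 * dt * (dp1 + dp2);
      if (vn >= 1.0) {
        vn = 0.0;
        pn -= eps;
        spikes.push_back(t_next);
        hold = true;
      }
    }
    if (pn < atp_floor) pn = atp_floor;
    if (pn > atp_max) pn = atp_max;
    v = vn;
    atp = pn;
    if (!std::isfinite(v) || !std::isfinite(atp))
      stop("non-finite mean-field state at t = %.1f ms", t_next);

    out_t[k + 1] = t_next;
    out_v[k + 1] = v;
    out_atp[k + 1] = atp;
    out_ifr[k + 1] = hann_rate(t_next);
  }

  return List::create(_["timeMs"] = out_t, _["v"] = out_v, _["atp"] = out_atp,
                      _["ifrPerMs"] = out_ifr,
                      _["spikeTimesMs"] = wrap(spikes));
}

// Centered rectangular-window spike counts on a regular grid, per neuron,
// returned in Hz. Grid centers are t0 + window/2 + g*stride for all g with
// the window fully inside [t0, t1]. A spike on the left window edge counts,
// on the right edge it does not: [c - w/2, c + w/2).
// [[Rcpp::export]]
List cpp_ifr_matrix(IntegerVector neuron, NumericVector time_ms, int n,
                    double t0, double t1, double window_ms, double stride_ms) {
  const double c0 = t0 + window_ms / 2.0;
  const int g_max =
      (int)std::floor((t1 - window_ms / 2.0 - c0) / stride_ms + 1e-9);
  if (g_max < 0) stop("analysis epoch shorter than one window");
  const int ng = g_max + 1;
  NumericMatrix rates(ng, n);
  NumericVector centers(ng);
  for (int g = 0; g < ng; ++g) centers[g] = c0 + g * stride_ms;
  const double hz_per_spike = 1000.0 / window_ms;
  const R_xlen_t m = neuron.size();
  for (R_xlen_t k = 0; k < m; ++k) {
    const double ts = time_ms[k];
    // centers c with c - w/2 <= ts < c + w/2
    int g_lo =
        (int)std::floor((ts - window_ms / 2.0 - c0) / stride_ms + 1e-9) + 1;
    int g_hi = (int)std::floor((ts + window_ms / 2.0 - c0) / stride_ms + 1e-9);
    if (g_lo < 0) g_lo = 0;
    if (g_hi > g_max) g_hi = g_max;
    const int col = neuron[k] - 1;
    for (int g = g_lo; g <= g_hi; ++g) rates(g, col) += hz_per_spike;
  }
  return List::create(_["centersMs"] = centers, _["rates"] = rates);
}
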