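// Clock-driven simulation core: forward-Euler integration of the two hybrid
// point-neuron families, per-connection ring-buffer delay queues, exponential
// conductance channels with optional NMDA magnesium block, per-edge
// Tsodyks-Markram resource dynamics (lazy closed-form updates at event times)
// and piecewise-rate Poisson drives generated on the fly.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: deterministic, cheap, stream-splittable
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // inversion method; fine for the small means of a dt-sized window
  int pois(double lambda, double p0) {
    double u = unif();
    if (u <= p0) return 0;
    int k = 0;
    double p = p0, f = p0;
    while (u > f && k < 64) {
      ++k;
      p *= lambda / k;
      f += p;
    }
    return k;
  }
};

inline uint64_t substream(uint64_t seed, uint64_t idx) {
  Rng r(seed * 0x2545F4914F6CDD1DULL + idx + 1);
  return r.next();
}

struct Channel {
  int off, n, delay_steps;
  bool nmda;
  double E, decay;
  std::vector<double> g, buf;
};

struct Conn {
  int chan, pre_off, n_pre;
  double g0;
  bool plastic;
  double U, tau_rec, tau_fac, tau_syn;
  std::vector<int> ptr, post;
  std::vector<double> eu, ex, ey, ez, elast;  // per-edge Tsodyks state
};

struct Drive {
  std::vector<int> tgt;      // global 0-based
  int chan_a, chan_n;        // channel ids (-1 = none)
  double g0a, g0n, base, amp, fmod, phase;  // phase: modulation lag in ms
  NumericMatrix fac;         // (start, end, factor)
  NumericMatrix add;         // (start, end, added rate Hz)
  Rng rng;
  double last_rate = -1.0, lambda = 0.0, p0 = 1.0;
  Drive() : rng(0) {}
};

struct Inj {
  int i0, i1;
  double t0, t1, amp;
};

void neuron_step(int fam, const double* p, double& V, double& u, double I,
                 double dt, bool& spiked, bool stn_min) {
  double dV, du;
  if (fam <= 1) {  // quadratic family: C,k,v_r,v_th,v_peak,c,a,b,d,v_b
    dV = (p[1] * (V - p[2]) * (V - p[3]) - u + I) / p[0];
    if (fam == 1)
      du = (V <= p[9]) ? p[6] * (p[7] * (V - p[9]) * (V - p[9]) * (V - p[9]) - u)
                       : -p[6] * u;
    else
      du = p[6] * (p[7] * (V - p[2]) - u);
  } else {  // adex: C,g_L,E_L,V_T,t_f,V_r,tau_w,a_sub,b_spike,gate,I_e,Delta_T
    double ex = (V - p[3]) / p[11];
    if (ex > 30.0) ex = 30.0;
    dV = (-p[1] * (V - p[2]) + p[1] * p[11] * std::exp(ex) - u + I) / p[0];
    double a_eff = (V < p[9]) ? p[7] : 0.0;
    du = (a_eff * (V - p[2]) - u) / p[6];
  }
  V += dt * dV;
  u += dt * du;
  double cutoff = p[4];
  if (V >= cutoff || !std::isfinite(V)) {
    spiked = true;
    if (fam <= 1) {
      V = p[5];
      u += p[8];
    } else if (fam == 3 && u < 0.0) {
      double off = u - 15.0;
      V = p[5] + (stn_min ? std::min(off, 20.0) : std::max(off, 20.0));
      u += p[8];
    } else {
      V = p[5];
      u += p[8];
    }
  } else {
    spiked = false;
  }
}

// closed-form Tsodyks relaxation over an interval
inline void ts_evolve(double dtm, double U, double tr, double tf, double ts,
                      double& u, double& x, double& y, double& z) {
  if (dtm <= 0) return;
  u = (tf > 0) ? u * std::exp(-dtm / tf) : 0.0;
  double es = std::exp(-dtm / ts), er = std::exp(-dtm / tr);
  double A = y * tr / (ts - tr);
  double z1 = (z - A) * er + A * es;
  double y1 = y * es;
  y = y1;
  z = z1;
  x = 1.0 - y - z;
  if (x < 0) x = 0;
}

}  // namespace

// [[Rcpp::export]]
List engine_run(List rneurons, List rchannels, List rconns, List rdrives,
                List rinj, double duration, double dt, double seed_in,
                double mg_mM, bool stn_min, double init_jitter,
                IntegerVector probe_ids) {
  const uint64_t seed = (uint64_t)seed_in;
  IntegerVector fam = rneurons["fam"];
  NumericMatrix par = rneurons["par"];
  const int n = fam.size();
  const int nsteps = (int)std::lround(duration / dt);
  IntegerVector pop_of = rneurons["pop_of"];  // 0-based population index
  const int npop = Rcpp::max(pop_of) + 1;

  std::vector<Channel> ch(rchannels.size());
  for (int c = 0; c < (int)ch.size(); ++c) {
    List rc = rchannels[c];
    ch[c].off = as<int>(rc["off"]);
    ch[c].n = as<int>(rc["n"]);
    ch[c].delay_steps = std::max(1, as<int>(rc["delay_steps"]));
    ch[c].nmda = as<bool>(rc["nmda"]);
    ch[c].E = as<double>(rc["E"]);
    ch[c].decay = std::exp(-dt / as<double>(rc["tau"]));
    ch[c].g.assign(ch[c].n, 0.0);
    ch[c].buf.assign((size_t)ch[c].delay_steps * ch[c].n, 0.0);
  }

  std::vector<Conn> cn(rconns.size());
  std::vector<std::vector<int>> conns_of_pop(npop);
  for (int k = 0; k < (int)cn.size(); ++k) {
    List rc = rconns[k];
    Conn& co = cn[k];
    co.chan = as<int>(rc["chan"]);
    co.pre_off = as<int>(rc["pre_off"]);
    co.n_pre = as<int>(rc["n_pre"]);
    co.g0 = as<double>(rc["g0"]);
    co.plastic = as<bool>(rc["plastic"]);
    IntegerVector ptr = rc["ptr"], post = rc["post"];
    co.ptr.assign(ptr.begin(), ptr.end());
    co.post.assign(post.begin(), post.end());
    if (co.plastic) {
      co.U = as<double>(rc["U"]);
      co.tau_rec = as<double>(rc["tau_rec"]);
      co.tau_fac = as<double>(rc["tau_fac"]);
      co.tau_syn = as<double>(rc["tau_syn"]);
      size_t ne = co.post.size();
      co.eu.assign(ne, 0.0);
      co.ex.assign(ne, 1.0);
      co.ey.assign(ne, 0.0);
      co.ez.assign(ne, 0.0);
      co.elast.assign(ne, 0.0);
    }
    conns_of_pop[as<int>(rc["pre_pop"])].push_back(k);
  }

  std::vector<Drive> dr(rdrives.size());
  for (int d = 0; d < (int)dr.size(); ++d) {
    List rd = rdrives[d];
    IntegerVector tg = rd["tgt"];
    dr[d].tgt.assign(tg.begin(), tg.end());
    dr[d].chan_a = as<int>(rd["chan_a"]);
    dr[d].chan_n = as<int>(rd["chan_n"]);
    dr[d].g0a = as<double>(rd["g0a"]);
    dr[d].g0n = as<double>(rd["g0n"]);
    dr[d].base = as<double>(rd["base"]);
    dr[d].amp = as<double>(rd["amp"]);
    dr[d].fmod = as<double>(rd["fmod"]);
    dr[d].phase = as<double>(rd["phase"]);
    dr[d].fac = as<NumericMatrix>(rd["fac"]);
    dr[d].add = as<NumericMatrix>(rd["add"]);
    dr[d].rng = Rng(substream(seed, 1000 + d));
  }

  std::vector<Inj> inj(rinj.size());
  for (int k = 0; k < (int)inj.size(); ++k) {
    List ri = rinj[k];
    inj[k].i0 = as<int>(ri["i0"]);
    inj[k].i1 = as<int>(ri["i1"]);
    inj[k].t0 = as<double>(ri["t0"]);
    inj[k].t1 = as<double>(ri["t1"]);
    inj[k].amp = as<double>(ri["amp"]);
  }

  // row-major copy of the parameter matrix for cache-friendly access
  std::vector<double> P((size_t)n * 12);
  for (int i = 0; i < n; ++i)
    for (int c2 = 0; c2 < 12; ++c2) P[(size_t)i * 12 + c2] = par(i, c2);

  std::vector<double> V(n), W(n, 0.0), Icur(n);
  Rng init_rng(substream(seed, 7));
  for (int i = 0; i < n; ++i)
    V[i] = par(i, 2) + init_jitter * (2.0 * init_rng.unif() - 1.0);

  const double mgfac = mg_mM / 3.57;
  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve(1 << 16);
  spk_t.reserve(1 << 16);
  std::vector<int> now;
  now.reserve(1024);
  long long emitted = 0, delivered = 0;

  const int nprobe = probe_ids.size();
  NumericMatrix probeV(nprobe > 0 ? nsteps : 0, nprobe),
      probeU(nprobe > 0 ? nsteps : 0, nprobe);

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    // conductance decay + delivery of delayed events
    for (auto& c : ch) {
      const int slot = step % c.delay_steps;
      double* buf = &c.buf[(size_t)slot * c.n];
      for (int j = 0; j < c.n; ++j) {
        c.g[j] = c.g[j] * c.decay + buf[j];
        buf[j] = 0.0;
      }
    }
    // extrinsic Poisson drives
    for (auto& d : dr) {
      double rate = d.base;
      if (d.fmod > 0 && d.amp > 0) {
        const double half = 500.0 / d.fmod;  // half cycle in ms
        const long cyc = (long)std::floor((t - d.phase) / half);
        const bool high = ((cyc % 2) + 2) % 2 == 0;
        rate *= high ? (1.0 + d.amp) : (1.0 - d.amp);
      }
      for (int r = 0; r < d.fac.nrow(); ++r)
        if (t >= d.fac(r, 0) && t < d.fac(r, 1)) rate *= d.fac(r, 2);
      for (int r = 0; r < d.add.nrow(); ++r)
        if (t >= d.add(r, 0) && t < d.add(r, 1)) rate += d.add(r, 2);
      if (rate <= 0) continue;
      if (rate != d.last_rate) {
        d.last_rate = rate;
        d.lambda = rate * dt * 1e-3;
        d.p0 = std::exp(-d.lambda);
      }
      Channel& ca = ch[d.chan_a];
      Channel* cnn = d.chan_n >= 0 ? &ch[d.chan_n] : nullptr;
      for (int j : d.tgt) {
        const int k = d.rng.pois(d.lambda, d.p0);
        if (k > 0) {
          ca.g[j - ca.off] += k * d.g0a;
          if (cnn) cnn->g[j - cnn->off] += k * d.g0n;
        }
      }
    }
    // synaptic + injected currents
    std::fill(Icur.begin(), Icur.end(), 0.0);
    for (auto& c : ch) {
      if (c.nmda) {
        for (int j = 0; j < c.n; ++j) {
          const double v = V[c.off + j];
          const double B = 1.0 / (1.0 + mgfac * std::exp(-0.062 * v));
          Icur[c.off + j] += c.g[j] * B * (c.E - v);
        }
      } else {
        for (int j = 0; j < c.n; ++j)
          Icur[c.off + j] += c.g[j] * (c.E - V[c.off + j]);
      }
    }
    for (auto& q : inj)
      if (t >= q.t0 && t < q.t1)
        for (int i = q.i0; i < q.i1; ++i) Icur[i] += q.amp;
    // probes sample the state at the beginning of the step
    for (int pj = 0; pj < nprobe; ++pj) {
      probeV(step, pj) = V[probe_ids[pj]];
      probeU(step, pj) = W[probe_ids[pj]];
    }
    // neuron update
    now.clear();
    const double tsp = (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      bool spiked = false;
      const double* prow = &P[(size_t)i * 12];
      neuron_step(fam[i], prow, V[i], W[i], Icur[i] + prow[10], dt, spiked,
                  stn_min);
      if (spiked) {
        now.push_back(i);
        spk_id.push_back(i);
        spk_t.push_back(tsp);
      }
    }
    emitted += now.size();
    // delivery with per-connection delays
    for (int i : now) {
      for (int k : conns_of_pop[pop_of[i]]) {
        Conn& co = cn[k];
        const int lp = i - co.pre_off;
        if (lp < 0 || lp >= co.n_pre) continue;
        Channel& c = ch[co.chan];
        const int slot = step % c.delay_steps;
        double* buf = &c.buf[(size_t)slot * c.n];
        if (co.plastic) {
          for (int e = co.ptr[lp]; e < co.ptr[lp + 1]; ++e) {
            ts_evolve(tsp - co.elast[e], co.U, co.tau_rec, co.tau_fac,
                      co.tau_syn, co.eu[e], co.ex[e], co.ey[e], co.ez[e]);
            co.elast[e] = tsp;
            co.eu[e] += co.U * (1.0 - co.eu[e]);
            const double r = co.eu[e] * co.ex[e];
            co.ex[e] -= r;
            co.ey[e] += r;
            buf[co.post[e]] += co.g0 * r;
            ++delivered;
          }
        } else {
          for (int e = co.ptr[lp]; e < co.ptr[lp + 1]; ++e) {
            buf[co.post[e]] += co.g0;
            ++delivered;
          }
        }
      }
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  for (int i = 0; i < n; ++i)
    if (!std::isfinite(V[i]))
      stop("non-finite membrane potential in neuron %d", i + 1);

  List out = List::create(
      _["id"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["t"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["emitted"] = (double)emitted, _["delivered"] = (double)delivered);
  if (nprobe > 0) {
    out["probe_V"] = probeV;
    out["probe_u"] = probeU;
  }
  return out;
}

// [[Rcpp::export]]
List single_neuron_run(int fam, NumericVector prow, NumericMatrix Iseg,
                       double duration, double dt, double V0, double u0,
                       bool record, bool stn_min) {
  const int nsteps = (int)std::lround(duration / dt);
  double V = V0, u = u0;
  std::vector<double> spikes;
  NumericMatrix trace(record ? nsteps : 0, record ? 3 : 0);
  double p[12];
  for (int c = 0; c < 12; ++c) p[c] = prow[c];
  int seg = 0;
  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    while (seg + 1 < Iseg.nrow() && t >= Iseg(seg + 1, 0)) ++seg;
    const double I = Iseg(seg, 1);
    if (record) {
      trace(step, 0) = t;
      trace(step, 1) = V;
      trace(step, 2) = u;
    }
    bool spiked = false;
    neuron_step(fam, p, V, u, I, dt, spiked, stn_min);
    if (spiked) spikes.push_back((step + 1) * dt);
  }
  List out = List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                          _["V"] = V, _["u"] = u);
  if (record) out["trace"] = trace;
  return out;
}
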