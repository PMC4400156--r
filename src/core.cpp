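// Core numerical kernels: fused read simulation + pileup + dosage-genotype
// likelihood evaluation, and an observation-level aggregator used by the
// alignment (BAM) path. All marginalisation over the latent true allele T
// and error indicator E is collapsed analytically per read into
//   P(obs | g, M) = f * P(obs | T = allele1) + (1 - f) * P(obs | T = allele2)
// with f = g / M, so position log-likelihoods only ever need to be evaluated
// on the grid of distinct dosage fractions g / M across the candidate
// ploidy range.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const double LOG_FLOOR = 1e-300;

// Fast counter-free PRNG for the per-base hot path (quality, error and
// substitution draws). Seeded from R's RNG, so runs remain fully
// reproducible via set.seed() while avoiding per-call overhead.
struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    for (int i = 0; i < 16; ++i) next();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() { return (next() >> 11) * 0x1.0p-53; }
};

// ---------------------------------------------------------------------------
// observation-level aggregation for externally supplied pileups
// ---------------------------------------------------------------------------

// posidx: 0-based position index per observation; p1/p2: per-observation
// probabilities of the observed base under T = allele1 / allele2.
// Returns an npos x F matrix of position log-likelihoods at each fraction.
// [[Rcpp::export]]
NumericMatrix cpp_obs_logliks(IntegerVector posidx, NumericVector p1,
                              NumericVector p2, NumericVector fractions,
                              int npos) {
  const int n = posidx.size(), F = fractions.size();
  NumericMatrix out(npos, F);
  for (int i = 0; i < n; ++i) {
    const int p = posidx[i];
    const double a = p1[i], b = p2[i];
    for (int f = 0; f < F; ++f) {
      double v = b + fractions[f] * (a - b);
      if (v < LOG_FLOOR) v = LOG_FLOOR;
      out(p, f) += std::log(v);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// fused simulator + analysis
// ---------------------------------------------------------------------------

struct SimConfig {
  int M, L, n_frags, read_len, Q, B;
  double frag_mean, frag_sd;
  int max_frag;
  const int *haps;          // M x L column-major (t = haps[m + M*pos])
  const int *qvals;         // Q quality values
  const double *qcum;       // Q x read_len cumulative per-cycle weights
  // generative error model, convention P(E=1) = 1/(1+exp(eta)),
  // eta = alpha[t][gg][q2] + beta*log(qs) (q2=0 only) + gamma[q2]*log(nqs)
  const double *gen_alpha;  // 4*2*2, idx t + 4*gg + 8*q2
  double gen_beta, gen_gamma0, gen_gamma1;
  const double *gen_subcum; // 4*2*4 cumulative, idx t + 4*gg + 8*o
  // analysis lookups
  const double *etab;       // 4*2*Q*B, idx t + 4*(gg + 2*(q + Q*nb))
  const double *psub;       // 4*2*4, idx t + 4*(gg + 2*o)
  double nqs_bin;
  // generative error probabilities pre-evaluated on a 0.1-binned nqs grid
  std::vector<double> gentab; // 4*2*Q*Bg
  int Bg;
  double gen_bin;
};

static inline int draw_qlevel(Xoshiro256pp &rng, const double *qcum, int Q,
                              int cycle) {
  const double u = rng.runif();
  const double *col = qcum + (size_t)Q * cycle;
  for (int q = 0; q < Q - 1; ++q)
    if (u <= col[q]) return q;
  return Q - 1;
}

static inline double obs_prob(const SimConfig &cfg, int a_gen, int o_gen,
                              int strand, int gg, int q, int nb) {
  const int t_rd = strand ? 3 - a_gen : a_gen;
  const double e =
      cfg.etab[t_rd + 4 * (gg + 2 * (q + (size_t)cfg.Q * nb))];
  if (o_gen == a_gen) return 1.0 - e;
  const int o_rd = strand ? 3 - o_gen : o_gen;
  return e * cfg.psub[t_rd + 4 * (gg + 2 * o_rd)];
}

struct ReadOut {
  std::vector<int> start, strand, hap, frag;
  std::vector<std::string> seq, qual;
};

// Accumulator shared across modes. For mode 1 (estimate) per-M totals are
// collected; mode 2 (call) emits per-position genotype summaries; mode 3
// (training) only tallies error/total counts; mode 4 materialises reads;
// mode 5 is mode 1 plus the full position x fraction log-likelihood matrix
// (so ploidy selection and genotype posteriors come from a single pass).
struct Analyzer {
  const SimConfig &cfg;
  int mode;
  // fractions and per-candidate-M structure
  NumericVector fractions;
  std::vector<std::vector<int>> gidx;
  std::vector<std::vector<double>> glp;
  // mode 2
  int call_i; // index into gidx/glp for the ploidy being called
  // ring buffer
  int W, lo;
  std::vector<std::vector<int>> ringkeys;
  std::vector<std::array<int, 4>> ringcnt;
  // grouping scratch
  int KS;
  int tick;
  // cached log rows; rows are shared across feature keys whose (p1, p2)
  // pair quantises to the same point (quant = steps per log unit; 0 = no
  // sharing, one exact row per (allele pair, feature key))
  double quant;
  std::vector<int> rowidx;
  std::vector<double> rowstore;
  std::unordered_map<uint64_t, int> pairmap;
  std::vector<int> stamp_r, gcnt_r, glist_r;
  std::vector<double> acc;
  // outputs
  std::vector<double> loglik;
  double total_bases;
  int n_pos_used;
  IntegerVector out_g, out_a1, out_a2, out_np;
  NumericVector out_score, out_post;
  NumericMatrix out_mat;
  std::vector<double> err_n, tot_n, sub_n;

  Analyzer(const SimConfig &cfg_, int mode_, NumericVector fr, List gidx_,
           List glp_, int call_i_, double quant_)
      : cfg(cfg_), mode(mode_), fractions(fr), call_i(call_i_),
        quant(quant_) {
    for (int i = 0; i < gidx_.size(); ++i) {
      IntegerVector gi = gidx_[i];
      NumericVector lp = glp_[i];
      gidx.push_back(std::vector<int>(gi.begin(), gi.end()));
      glp.push_back(std::vector<double>(lp.begin(), lp.end()));
    }
    W = cfg.max_frag + cfg.read_len + 2;
    if (W > cfg.L) W = cfg.L;
    lo = 0;
    ringkeys.resize(W);
    ringcnt.assign(W, {0, 0, 0, 0});
    KS = 4 * 2 * 2 * cfg.Q * cfg.B;
    tick = 0;
    rowidx.assign((size_t)16 * KS, -1);
    acc.assign(fractions.size(), 0.0);
    loglik.assign(gidx.size(), 0.0);
    total_bases = 0.0;
    n_pos_used = 0;
    if (mode == 2 || mode == 5) {
      out_g = IntegerVector(cfg.L, -1);
      out_a1 = IntegerVector(cfg.L, -1);
      out_a2 = IntegerVector(cfg.L, -1);
      out_np = IntegerVector(cfg.L, 0);
      out_score = NumericVector(cfg.L, NA_REAL);
      out_post = NumericVector(cfg.L, NA_REAL);
      if (mode == 5) out_mat = NumericMatrix(cfg.L, fractions.size());
    }
    if (mode == 3) {
      err_n.assign((size_t)4 * 2 * cfg.Q * cfg.B, 0.0);
      tot_n.assign((size_t)4 * 2 * cfg.Q * cfg.B, 0.0);
      sub_n.assign(4 * 2 * 4, 0.0);
    }
  }

  void push(int pos, int o_gen, int strand, int gg, int q, int nb) {
    const int slot = pos % W;
    const int key = (((o_gen * 2 + strand) * 2 + gg) * cfg.Q + q) * cfg.B + nb;
    ringkeys[slot].push_back(key);
    ringcnt[slot][o_gen]++;
  }

  int make_row(double p1, double p2) {
    const int F = fractions.size();
    const int ridx = (int)(rowstore.size() / F);
    for (int f = 0; f < F; ++f) {
      double v = p2 + fractions[f] * (p1 - p2);
      if (v < LOG_FLOOR) v = LOG_FLOOR;
      rowstore.push_back(std::log(v));
    }
    stamp_r.push_back(-1);
    gcnt_r.push_back(0);
    return ridx;
  }

  int row_for(int pairidx, int key) {
    const size_t rk = (size_t)pairidx * KS + key;
    int ridx = rowidx[rk];
    if (ridx < 0) {
      const int a1 = pairidx >> 2, a2 = pairidx & 3;
      const int o = key / (2 * 2 * cfg.Q * cfg.B);
      int rem = key % (2 * 2 * cfg.Q * cfg.B);
      const int strand = rem / (2 * cfg.Q * cfg.B);
      rem %= 2 * cfg.Q * cfg.B;
      const int gg = rem / (cfg.Q * cfg.B);
      rem %= cfg.Q * cfg.B;
      const int q = rem / cfg.B, nb = rem % cfg.B;
      double p1 = obs_prob(cfg, a1, o, strand, gg, q, nb);
      double p2 = obs_prob(cfg, a2, o, strand, gg, q, nb);
      if (quant > 0) {
        const double l1 = std::round(std::log(std::max(p1, LOG_FLOOR)) * quant);
        const double l2 = std::round(std::log(std::max(p2, LOG_FLOOR)) * quant);
        const uint64_t pk = ((uint64_t)(uint32_t)(int32_t)l1 << 32) |
                            (uint32_t)(int32_t)l2;
        auto it = pairmap.find(pk);
        if (it != pairmap.end()) {
          ridx = it->second;
        } else {
          ridx = make_row(std::exp(l1 / quant), std::exp(l2 / quant));
          pairmap.emplace(pk, ridx);
        }
      } else {
        ridx = make_row(p1, p2);
      }
      rowidx[rk] = ridx;
    }
    return ridx;
  }

  void finalize(int pos) {
    const int slot = pos % W;
    std::vector<int> &keys = ringkeys[slot];
    std::array<int, 4> &cnt = ringcnt[slot];
    const int np = (int)keys.size();
    if (np == 0) return;
    n_pos_used++;
    total_bases += np;
    // candidate alleles: most frequent, then second most frequent observed
    int a1 = 0;
    for (int k = 1; k < 4; ++k)
      if (cnt[k] > cnt[a1]) a1 = k;
    int a2 = -1, best2 = 0;
    for (int k = 0; k < 4; ++k) {
      if (k == a1) continue;
      if (cnt[k] > best2) { best2 = cnt[k]; a2 = k; }
    }
    const bool mono = (a2 < 0);
    const int a2res = mono ? (a1 == 0 ? 1 : 0) : a2;
    const int pairidx = a1 * 4 + a2res;
    // group observations by their (shared) likelihood row
    ++tick;
    glist_r.clear();
    for (int i = 0; i < np; ++i) {
      const int rid = row_for(pairidx, keys[i]);
      if (stamp_r[rid] != tick) {
        stamp_r[rid] = tick;
        gcnt_r[rid] = 0;
        glist_r.push_back(rid);
      }
      gcnt_r[rid]++;
    }
    const int F = fractions.size();
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int rid : glist_r) {
      const double *row = rowstore.data() + (size_t)rid * F;
      const double c = (double)gcnt_r[rid];
      for (int f = 0; f < F; ++f) acc[f] += c * row[f];
    }
    if (mode == 5) {
      for (int f = 0; f < F; ++f) out_mat(pos, f) = acc[f];
      out_a1[pos] = a1;
      out_a2[pos] = mono ? -1 : a2;
      out_np[pos] = np;
    }
    if (mode == 1 || mode == 5) {
      for (size_t m = 0; m < gidx.size(); ++m) {
        const std::vector<int> &gi = gidx[m];
        const std::vector<double> &lp = glp[m];
        double mx = -HUGE_VAL;
        for (size_t j = 0; j < gi.size(); ++j) {
          const double v = lp[j] + acc[gi[j]];
          if (v > mx) mx = v;
        }
        double s = 0.0;
        for (size_t j = 0; j < gi.size(); ++j) {
          const double v = lp[j] + acc[gi[j]];
          if (v > mx - 45.0) s += std::exp(v - mx);
        }
        loglik[m] += mx + std::log(s);
      }
    } else if (mode == 2) {
      const std::vector<int> &gi = gidx[call_i];
      const std::vector<double> &lp = glp[call_i];
      const int ng = (int)gi.size();
      double mx = -HUGE_VAL;
      std::vector<double> val(ng);
      for (int j = 0; j < ng; ++j) {
        val[j] = lp[j] + acc[gi[j]];
        if (val[j] > mx) mx = val[j];
      }
      double s = 0.0;
      int ghat = 0;
      for (int j = 0; j < ng; ++j) {
        s += std::exp(val[j] - mx);
        if (val[j] > val[ghat]) ghat = j; // ties keep smaller g
      }
      const double lse_all = mx + std::log(s);
      const double mnv = std::max(val[0], val[ng - 1]);
      const double lse_nonvar =
          mnv + std::log(std::exp(val[0] - mnv) + std::exp(val[ng - 1] - mnv));
      out_g[pos] = ghat;
      out_post[pos] = std::exp(val[ghat] - lse_all);
      out_score[pos] = -10.0 / M_LN10 * (lse_nonvar - lse_all);
      out_a1[pos] = a1;
      out_a2[pos] = mono ? -1 : a2;
      out_np[pos] = np;
    }
    keys.clear();
    cnt = {0, 0, 0, 0};
  }

  void finalize_up_to(int pos_excl) {
    if (pos_excl > cfg.L) pos_excl = cfg.L;
    while (lo < pos_excl) finalize(lo++);
  }
};

// [[Rcpp::export]]
List cpp_sim_run(IntegerMatrix haps, int n_frags, int read_len,
                 double frag_mean, double frag_sd, IntegerVector qvals,
                 NumericMatrix qcum, NumericVector gen_alpha, double gen_beta,
                 NumericVector gen_gamma, NumericVector gen_subcum,
                 NumericVector etab, NumericVector psub, double nqs_bin,
                 int B, NumericVector fractions, List g_idx, List g_logprior,
                 int mode, int call_i, double quant) {
  SimConfig cfg;
  cfg.M = haps.nrow();
  cfg.L = haps.ncol();
  cfg.n_frags = n_frags;
  cfg.read_len = read_len;
  cfg.Q = qvals.size();
  cfg.B = B;
  cfg.frag_mean = frag_mean;
  cfg.frag_sd = frag_sd;
  cfg.max_frag = std::min((int)std::ceil(frag_mean + 6.0 * frag_sd), cfg.L);
  if (cfg.max_frag < read_len) cfg.max_frag = std::min(read_len, cfg.L);
  cfg.haps = INTEGER(haps);
  cfg.qvals = INTEGER(qvals);
  cfg.qcum = REAL(qcum);
  cfg.gen_alpha = REAL(gen_alpha);
  cfg.gen_beta = gen_beta;
  cfg.gen_gamma0 = gen_gamma[0];
  cfg.gen_gamma1 = gen_gamma[1];
  cfg.gen_subcum = REAL(gen_subcum);
  cfg.etab = REAL(etab);
  cfg.psub = REAL(psub);
  cfg.nqs_bin = nqs_bin;
  cfg.gen_bin = 0.1;
  cfg.Bg = (int)std::ceil(45.0 / cfg.gen_bin) + 2;
  cfg.gentab.assign((size_t)4 * 2 * cfg.Q * cfg.Bg, 0.0);
  for (int t = 0; t < 4; ++t)
    for (int gg = 0; gg < 2; ++gg)
      for (int q = 0; q < cfg.Q; ++q) {
        const int q2 = (cfg.qvals[q] == 2) ? 1 : 0;
        for (int nb = 0; nb < cfg.Bg; ++nb) {
          const double nqs = std::max(nb, 1) * cfg.gen_bin;
          double eta = cfg.gen_alpha[t + 4 * (gg + 2 * q2)];
          if (!q2) eta += cfg.gen_beta * std::log((double)cfg.qvals[q]);
          eta += (q2 ? cfg.gen_gamma1 : cfg.gen_gamma0) * std::log(nqs);
          cfg.gentab[t + 4 * (gg + 2 * (q + (size_t)cfg.Q * nb))] =
              1.0 / (1.0 + std::exp(eta));
        }
      }

  RNGScope rng;

  // fragment placements, then process in coordinate order
  std::vector<int> fstart(n_frags), flen(n_frags), fhap(n_frags);
  for (int i = 0; i < n_frags; ++i) {
    double fl = frag_mean + frag_sd * norm_rand();
    int len = (int)std::lround(fl);
    if (len < read_len) len = read_len;
    if (len > cfg.max_frag) len = cfg.max_frag;
    if (len > cfg.L) len = cfg.L;
    flen[i] = len;
    fstart[i] = (int)std::floor(unif_rand() * (cfg.L - len + 1));
    if (fstart[i] > cfg.L - len) fstart[i] = cfg.L - len;
    fhap[i] = (int)std::floor(unif_rand() * cfg.M);
    if (fhap[i] >= cfg.M) fhap[i] = cfg.M - 1;
  }
  std::vector<int> ord(n_frags);
  for (int i = 0; i < n_frags; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return fstart[a] < fstart[b]; });

  Analyzer an(cfg, mode, fractions, g_idx, g_logprior, call_i, quant);
  Xoshiro256pp fast_rng;
  ReadOut reads;

  std::vector<int> q(read_len), obs(read_len), tru(read_len);
  std::vector<double> nqs(read_len), qsd(read_len);
  std::vector<double> csum(read_len + 1);

  for (int oi = 0; oi < n_frags; ++oi) {
    const int i = ord[oi];
    const int start = fstart[i], len = flen[i], hap = fhap[i];
    if (mode <= 2 || mode == 5) an.finalize_up_to(start);
    for (int mate = 0; mate < 2; ++mate) {
      const int strand = mate; // mate 1 forward, mate 2 reverse
      // per-cycle qualities
      for (int j = 0; j < read_len; ++j) {
        const int ql = draw_qlevel(fast_rng, cfg.qcum, cfg.Q, j);
        q[j] = ql;
        qsd[j] = (double)cfg.qvals[ql];
      }
      // neighboring quality score (mean of <=5 each side, self excluded)
      csum[0] = 0.0;
      for (int j = 0; j < read_len; ++j) csum[j + 1] = csum[j] + qsd[j];
      for (int j = 0; j < read_len; ++j) {
        const int a = std::max(0, j - 5), b = std::min(read_len - 1, j + 5);
        nqs[j] = (csum[b + 1] - csum[a] - qsd[j]) / (double)(b - a);
      }
      // sequencing pass in read orientation
      int gprev1 = -1, gprev2 = -1; // previous two observed bases
      for (int j = 0; j < read_len; ++j) {
        const int gpos = strand ? (start + len - 1 - j) : (start + j);
        const int t_gen = cfg.haps[hap + (size_t)cfg.M * gpos];
        const int t_rd = strand ? 3 - t_gen : t_gen;
        const int gg = (gprev1 == 2 && gprev2 == 2) ? 1 : 0;
        int nbg = (int)std::lround(nqs[j] / cfg.gen_bin);
        if (nbg < 1) nbg = 1;
        if (nbg >= cfg.Bg) nbg = cfg.Bg - 1;
        const double e =
            cfg.gentab[t_rd + 4 * (gg + 2 * (q[j] + (size_t)cfg.Q * nbg))];
        int o_rd = t_rd;
        if (fast_rng.runif() < e) {
          const double u = fast_rng.runif();
          const double *sc = cfg.gen_subcum + t_rd + 0; // stride 4 over o
          for (int o = 0; o < 4; ++o) {
            if (u <= sc[4 * (gg + 2 * o)]) { o_rd = o; break; }
            o_rd = 3;
          }
        }
        obs[j] = o_rd;
        tru[j] = t_rd;
        gprev2 = gprev1;
        gprev1 = o_rd;
        int nb = (int)std::lround(nqs[j] / nqs_bin);
        if (nb < 1) nb = 1;
        if (nb >= B) nb = B - 1;
        if (mode <= 2 || mode == 5) {
          const int o_gen = strand ? 3 - o_rd : o_rd;
          an.push(gpos, o_gen, strand, gg, q[j], nb);
        } else if (mode == 3) {
          const size_t idx = t_rd + 4 * (gg + 2 * (q[j] + (size_t)cfg.Q * nb));
          an.tot_n[idx] += 1.0;
          if (o_rd != t_rd) {
            an.err_n[idx] += 1.0;
            an.sub_n[t_rd + 4 * (gg + 2 * o_rd)] += 1.0;
          }
        }
      }
      if (mode == 4) {
        std::string s(read_len, 'N'), qu(read_len, '!');
        static const char NT[] = "ACGT";
        for (int j = 0; j < read_len; ++j) {
          s[j] = NT[obs[j]];
          qu[j] = (char)(cfg.qvals[q[j]] + 33);
        }
        reads.start.push_back(strand ? (start + len - read_len) : start);
        reads.strand.push_back(strand);
        reads.hap.push_back(hap);
        reads.frag.push_back(i);
        reads.seq.push_back(s);
        reads.qual.push_back(qu);
      }
    }
  }
  if (mode <= 2 || mode == 5) an.finalize_up_to(cfg.L);

  if (mode == 1) {
    return List::create(
        _["loglik"] = NumericVector(an.loglik.begin(), an.loglik.end()),
        _["n_pos_used"] = an.n_pos_used,
        _["total_bases"] = an.total_bases);
  } else if (mode == 5) {
    return List::create(
        _["loglik"] = NumericVector(an.loglik.begin(), an.loglik.end()),
        _["n_pos_used"] = an.n_pos_used,
        _["total_bases"] = an.total_bases, _["mat"] = an.out_mat,
        _["a1"] = an.out_a1, _["a2"] = an.out_a2, _["n_p"] = an.out_np);
  } else if (mode == 2) {
    return List::create(
        _["g"] = an.out_g, _["post"] = an.out_post, _["score"] = an.out_score,
        _["a1"] = an.out_a1, _["a2"] = an.out_a2, _["n_p"] = an.out_np,
        _["n_pos_used"] = an.n_pos_used, _["total_bases"] = an.total_bases);
  } else if (mode == 3) {
    return List::create(
        _["err_n"] = NumericVector(an.err_n.begin(), an.err_n.end()),
        _["tot_n"] = NumericVector(an.tot_n.begin(), an.tot_n.end()),
        _["sub_n"] = NumericVector(an.sub_n.begin(), an.sub_n.end()));
  }
  return List::create(
      _["start"] = IntegerVector(reads.start.begin(), reads.start.end()),
      _["strand"] = IntegerVector(reads.strand.begin(), reads.strand.end()),
      _["hap"] = IntegerVector(reads.hap.begin(), reads.hap.end()),
      _["frag"] = IntegerVector(reads.frag.begin(), reads.frag.end()),
      _["seq"] = CharacterVector(reads.seq.begin(), reads.seq.end()),
      _["qual"] = CharacterVector(reads.qual.begin(), reads.qual.end()));
}
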