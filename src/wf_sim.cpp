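#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Forward Wright-Fisher simulation of a subdivided diploid population with
// symmetric island-model migration, infinite-sites mutation on integer bp,
// single-crossover recombination per gamete, and hard selective sweeps
// (fitness 1 + s * dosage at a sweep locus, acting in the sweep's deme only).
// Uses R's RNG throughout so set.seed() gives reproducible output.

namespace {

struct SweepState {
  int deme;       // 0-based
  int pos;        // 1-based bp
  double s;
  int start_gen;  // 1-based
  int site;       // column index in the current site table, -1 if absent
  bool established; // reached fixation within its deme
  bool injected;
  int retries;
  std::vector<double> freq; // per-generation frequency in its deme
};

inline int sample_weighted(const std::vector<double>& cumw) {
  double u = unif_rand() * cumw.back();
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

} // namespace

// [[Rcpp::export]]
List wf_simulate_cpp(IntegerVector deme_sizes, int n_generations,
                     double migration_rate, double seq_length,
                     double mut_rate, double rec_rate,
                     IntegerVector sweep_deme, IntegerVector sweep_pos,
                     NumericVector sweep_s, IntegerVector sweep_start,
                     int retry_cap) {
  const int D = deme_sizes.size();
  int N = 0;
  std::vector<int> deme_off(D + 1, 0);
  for (int d = 0; d < D; ++d) {
    N += deme_sizes[d];
    deme_off[d + 1] = N;
  }
  const int H = 2 * N;
  const int L = (int)seq_length;

  // site-major flat storage: alleles[s * H + h]
  std::vector<unsigned char> cur, nxt;
  std::vector<int> pos;
  std::unordered_set<int> occupied;

  const int n_sw = sweep_deme.size();
  std::vector<SweepState> sw(n_sw);
  for (int k = 0; k < n_sw; ++k) {
    sw[k] = SweepState{sweep_deme[k], sweep_pos[k], sweep_s[k], sweep_start[k],
                       -1, false, false, 0, {}};
  }

  std::vector<double> fit(N), cumw;
  std::vector<int> par1(H), par2(H);       // the two parent haplotype rows per gamete
  std::vector<int> bp(H);                  // crossover breakpoint (bp); sites <= bp from par1
  const double p_co = std::min(1.0, rec_rate * (double)L);
  const double mut_lambda = (double)H * (double)L * mut_rate;

  RNGScope rng;

  auto inject = [&](SweepState& s_state) {
    // put one copy of the sweep allele on a random haplotype of its deme
    int i = deme_off[s_state.deme] +
            (int)(unif_rand() * (deme_off[s_state.deme + 1] - deme_off[s_state.deme]));
    int h = 2 * i + (unif_rand() < 0.5 ? 0 : 1);
    if (s_state.site < 0) {
      if (occupied.count(s_state.pos)) {
        // a mutation already took this bp; reuse its column if still present
        for (size_t sc = 0; sc < pos.size(); ++sc)
          if (pos[sc] == s_state.pos) { s_state.site = (int)sc; break; }
      }
      if (s_state.site < 0) {
        occupied.insert(s_state.pos);
        pos.push_back(s_state.pos);
        cur.resize(cur.size() + H, 0);
        s_state.site = (int)pos.size() - 1;
      } else {
        std::fill(cur.begin() + (size_t)s_state.site * H,
                  cur.begin() + (size_t)(s_state.site + 1) * H, 0);
      }
    } else {
      std::fill(cur.begin() + (size_t)s_state.site * H,
                cur.begin() + (size_t)(s_state.site + 1) * H, 0);
    }
    cur[(size_t)s_state.site * H + h] = 1;
    s_state.injected = true;
  };

  for (int gen = 1; gen <= n_generations; ++gen) {
    for (int k = 0; k < n_sw; ++k)
      if (!sw[k].injected && gen >= sw[k].start_gen) inject(sw[k]);

    // fitness (within the sweep's deme only)
    std::fill(fit.begin(), fit.end(), 1.0);
    for (int k = 0; k < n_sw; ++k) {
      if (sw[k].site < 0) continue;
      const unsigned char* col = &cur[(size_t)sw[k].site * H];
      for (int i = deme_off[sw[k].deme]; i < deme_off[sw[k].deme + 1]; ++i)
        fit[i] *= 1.0 + sw[k].s * (col[2 * i] + col[2 * i + 1]);
    }

    // choose parents for every gamete
    for (int d = 0; d < D; ++d) {
      for (int i = deme_off[d]; i < deme_off[d + 1]; ++i) {
        for (int g = 0; g < 2; ++g) {
          int src = d;
          if (D > 1 && migration_rate > 0 && unif_rand() < migration_rate) {
            int o = (int)(unif_rand() * (D - 1));
            src = (o >= d) ? o + 1 : o;
          }
          cumw.assign(deme_off[src + 1] - deme_off[src], 0.0);
          double acc = 0.0;
          for (int j = deme_off[src]; j < deme_off[src + 1]; ++j) {
            acc += fit[j];
            cumw[j - deme_off[src]] = acc;
          }
          int p = deme_off[src] + sample_weighted(cumw);
          int h = 2 * i + g;
          int first = (unif_rand() < 0.5) ? 0 : 1;
          par1[h] = 2 * p + first;
          par2[h] = 2 * p + 1 - first;
          bp[h] = (unif_rand() < p_co) ? (1 + (int)(unif_rand() * L)) : L;
        }
      }
    }

    // reproduce
    const int S = (int)pos.size();
    nxt.resize((size_t)S * H);
    for (int s = 0; s < S; ++s) {
      const unsigned char* a = &cur[(size_t)s * H];
      unsigned char* b = &nxt[(size_t)s * H];
      const int ps = pos[s];
      for (int h = 0; h < H; ++h) b[h] = a[ps <= bp[h] ? par1[h] : par2[h]];
    }
    std::swap(cur, nxt);

    // mutation (infinite sites on integer bp)
    int n_mut = (int)R::rpois(mut_lambda);
    for (int m = 0; m < n_mut; ++m) {
      int p = 1 + (int)(unif_rand() * L);
      int tries = 0;
      while (occupied.count(p) && tries < 1000) { p = 1 + (int)(unif_rand() * L); ++tries; }
      if (occupied.count(p)) continue; // saturated; skip
      occupied.insert(p);
      pos.push_back(p);
      cur.resize(cur.size() + H, 0);
      cur[(cur.size() - H) + (size_t)(unif_rand() * H)] = 1;
    }

    // compact: drop monomorphic columns; keep sweep bookkeeping
    const int S2 = (int)pos.size();
    std::vector<int> counts(S2, 0);
    for (int s = 0; s < S2; ++s) {
      const unsigned char* a = &cur[(size_t)s * H];
      int c = 0;
      for (int h = 0; h < H; ++h) c += a[h];
      counts[s] = c;
    }
    // sweep bookkeeping first (column data still at pre-compaction indices)
    std::vector<bool> reinject(n_sw, false);
    for (int k = 0; k < n_sw; ++k) {
      if (sw[k].site < 0) {
        sw[k].freq.push_back(sw[k].injected ? (sw[k].established ? 1.0 : 0.0)
                                            : NA_REAL);
        continue;
      }
      int c = counts[sw[k].site];
      int lo = deme_off[sw[k].deme], hi = deme_off[sw[k].deme + 1];
      double fdeme;
      if (c == 0) {
        fdeme = 0.0;
      } else if (c == H) {
        fdeme = 1.0;
      } else {
        const unsigned char* col = &cur[(size_t)sw[k].site * H];
        int cd = 0;
        for (int i = lo; i < hi; ++i) cd += col[2 * i] + col[2 * i + 1];
        fdeme = (double)cd / (2.0 * (hi - lo));
      }
      if (fdeme >= 1.0) sw[k].established = true;
      sw[k].freq.push_back(fdeme);
      if (c == 0 && !sw[k].established) {
        if (++sw[k].retries > retry_cap) stop("sweep not establishable");
        reinject[k] = true;
        sw[k].freq.back() = 1.0 / (2.0 * (hi - lo));
      }
    }
    std::vector<int> newidx(S2, -1);
    int w = 0;
    for (int s = 0; s < S2; ++s) {
      if (counts[s] > 0 && counts[s] < H) {
        if (w != s) {
          std::copy(cur.begin() + (size_t)s * H, cur.begin() + (size_t)(s + 1) * H,
                    cur.begin() + (size_t)w * H);
          pos[w] = pos[s];
        }
        newidx[s] = w;
        ++w;
      }
    }
    pos.resize(w);
    cur.resize((size_t)w * H);
    for (int k = 0; k < n_sw; ++k) {
      if (sw[k].site >= 0) sw[k].site = newidx[sw[k].site];
      if (reinject[k]) inject(sw[k]);
    }
  }

  // order sites by position
  const int S = (int)pos.size();
  std::vector<int> ord(S);
  for (int s = 0; s < S; ++s) ord[s] = s;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return pos[a] < pos[b]; });

  IntegerMatrix hap(H, S);
  IntegerVector outpos(S);
  for (int s = 0; s < S; ++s) {
    outpos[s] = pos[ord[s]];
    const unsigned char* a = &cur[(size_t)ord[s] * H];
    for (int h = 0; h < H; ++h) hap(h, s) = a[h];
  }

  List traj(n_sw);
  IntegerVector retries(n_sw);
  LogicalVector established(n_sw);
  NumericVector final_freq(n_sw);
  for (int k = 0; k < n_sw; ++k) {
    traj[k] = wrap(sw[k].freq);
    retries[k] = sw[k].retries;
    established[k] = sw[k].established;
    final_freq[k] = sw[k].freq.empty() ? NA_REAL : sw[k].freq.back();
  }

  return List::create(_["haplotypes"] = hap, _["positions"] = outpos,
                      _["sweep_trajectory"] = traj, _["sweep_retries"] = retries,
                      _["sweep_established"] = established,
                      _["sweep_final_freq"] = final_freq);
}

// Site-frequency-spectrum transform for the composite-likelihood sweep scan
// (Nielsen-style hitchhiking model).  Background spectrum q over derived
// counts 1..n-1; a lineage at scaled distance x from the sweep escapes with
// probability p_e = 1 - exp(-x).  The e escaped lineages plus one extra
// lineage (the sweeping haplotype every non-escaped lineage coalesces into)
// are a hypergeometric draw from the background configuration; the extra
// lineage's allele is copied to all n - e non-escaped lineages.  At p_e = 1
// the background spectrum is recovered exactly.  The result is conditioned
// on the site remaining polymorphic.
// Returns a list: `cond`, the (n-1) x length(pe) matrix of
// P(derived count = k | p_e, polymorphic), and `mass`, the probability that
// a background-polymorphic site remains polymorphic under the transform
// (the invariant-site factor of the composite likelihood).
// [[Rcpp::export]]
List clr_prob_table_cpp(NumericVector q, NumericVector pe) {
  const int n = q.size() + 1;
  const int npe = pe.size();
  std::vector<double> lg(n + 2);
  for (int i = 0; i <= n + 1; ++i) lg[i] = R::lgammafn((double)i + 1.0);
  auto lchoose_ = [&](int a, int b) -> double {
    if (b < 0 || b > a) return R_NegInf;
    return lg[a] - lg[b] - lg[a - b];
  };
  NumericMatrix out(n - 1, npe);
  NumericVector mass(npe);
  for (int ip = 0; ip < npe; ++ip) {
    double p = pe[ip];
    std::vector<double> acc(n + 1, 0.0); // index by k = 0..n
    for (int e = 0; e <= n; ++e) {
      double wbin = R::dbinom((double)e, (double)n, p, 0);
      if (wbin < 1e-14) continue;
      for (int j = 1; j <= n - 1; ++j) {
        double qj = q[j - 1];
        if (qj <= 0) continue;
        if (e == n) {
          // everything escapes: background configuration unchanged
          acc[j] += qj * wbin;
          continue;
        }
        // draw e + 1 of the n background lineages; m = derived among them
        int d = e + 1;
        int mlo = std::max(0, d - (n - j)), mhi = std::min(j, d);
        for (int m = mlo; m <= mhi; ++m) {
          double hg = std::exp(lchoose_(j, m) + lchoose_(n - j, d - m) -
                               lchoose_(n, d));
          double w = qj * wbin * hg;
          double pder = (double)m / d; // the extra lineage is derived
          // extra derived: escaped derived = m - 1, plus n - e copies
          acc[(m - 1) + (n - e)] += w * pder;
          // extra ancestral: escaped derived = m
          acc[m] += w * (1.0 - pder);
        }
      }
    }
    double tot = 0.0;
    for (int k = 1; k <= n - 1; ++k) tot += acc[k];
    for (int k = 1; k <= n - 1; ++k) out(k - 1, ip) = (tot > 0) ? acc[k] / tot : NA_REAL;
    mass[ip] = tot;
  }
  return List::create(_["cond"] = out, _["mass"] = mass);
}
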