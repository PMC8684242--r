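// Two-locus LD engine: EM haplotype frequencies from unphased genotypes,
// D'/r2, likelihood-based D' confidence intervals, and the confidence-interval
// haplotype-block span scan. Genotypes are coded 0/1/2 (alt-allele dosage),
// NA = missing.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct PairTab {
  double n[3][3];
  double ntot;   // animals non-missing at both loci
  double pA;     // sample alt-allele frequency, locus A
  double pB;
};

PairTab tabulate_pair(const int* ga, const int* gb, int nind) {
  PairTab t;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) t.n[i][j] = 0.0;
  t.ntot = 0.0;
  double ca = 0.0, cb = 0.0;
  for (int k = 0; k < nind; ++k) {
    int a = ga[k], b = gb[k];
    if (a == NA_INTEGER || b == NA_INTEGER) continue;
    t.n[a][b] += 1.0;
    ca += a;
    cb += b;
    t.ntot += 1.0;
  }
  t.pA = t.ntot > 0 ? ca / (2.0 * t.ntot) : NA_REAL;
  t.pB = t.ntot > 0 ? cb / (2.0 * t.ntot) : NA_REAL;
  return t;
}

// log-likelihood of the 3x3 genotype table under HWE haplotype frequencies
// p[4] = {p00, p01, p10, p11} (first index locus A allele, ref=0/alt=1)
double loglik(const PairTab& t, const double* p) {
  double P[3][3];
  P[0][0] = p[0] * p[0];
  P[0][1] = 2.0 * p[0] * p[1];
  P[0][2] = p[1] * p[1];
  P[1][0] = 2.0 * p[0] * p[2];
  P[1][1] = 2.0 * (p[0] * p[3] + p[1] * p[2]);
  P[1][2] = 2.0 * p[1] * p[3];
  P[2][0] = p[2] * p[2];
  P[2][1] = 2.0 * p[2] * p[3];
  P[2][2] = p[3] * p[3];
  double ll = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      if (t.n[i][j] > 0.0) {
        if (P[i][j] <= 0.0) return R_NegInf;
        ll += t.n[i][j] * std::log(P[i][j]);
      }
    }
  return ll;
}

// EM from one start (initial cis weight w0 for double heterozygotes)
void em_one(const PairTab& t, double w0, double tol, int max_iter, double* p) {
  const double b00 = 2.0 * t.n[0][0] + t.n[0][1] + t.n[1][0];
  const double b01 = t.n[0][1] + 2.0 * t.n[0][2] + t.n[1][2];
  const double b10 = t.n[1][0] + 2.0 * t.n[2][0] + t.n[2][1];
  const double b11 = t.n[1][2] + t.n[2][1] + 2.0 * t.n[2][2];
  const double ndh = t.n[1][1];
  const double tot = b00 + b01 + b10 + b11 + 2.0 * ndh;
  double w = w0;
  p[0] = (b00 + ndh * w) / tot;
  p[1] = (b01 + ndh * (1.0 - w)) / tot;
  p[2] = (b10 + ndh * (1.0 - w)) / tot;
  p[3] = (b11 + ndh * w) / tot;
  if (ndh == 0.0) return;  // phase unambiguous: counting solution is exact
  for (int it = 0; it < max_iter; ++it) {
    double cis = p[0] * p[3], trans = p[1] * p[2];
    w = (cis + trans > 0.0) ? cis / (cis + trans) : 0.5;
    double q[4];
    q[0] = (b00 + ndh * w) / tot;
    q[1] = (b01 + ndh * (1.0 - w)) / tot;
    q[2] = (b10 + ndh * (1.0 - w)) / tot;
    q[3] = (b11 + ndh * w) / tot;
    double delta = 0.0;
    for (int i = 0; i < 4; ++i) {
      double d = std::fabs(q[i] - p[i]);
      if (d > delta) delta = d;
      p[i] = q[i];
    }
    if (delta < tol) break;
  }
}

void em_freqs(const PairTab& t, double tol, int max_iter, double* best) {
  const double starts[3] = {0.5, 0.05, 0.95};
  double best_ll = R_NegInf;
  for (int s = 0; s < 3; ++s) {
    double p[4];
    em_one(t, starts[s], tol, max_iter, p);
    double ll = loglik(t, p);
    if (ll > best_ll) {
      best_ll = ll;
      for (int i = 0; i < 4; ++i) best[i] = p[i];
    }
  }
}

struct DStats {
  double D, dprime, r2;
};

DStats dstats(const double* p) {
  DStats s;
  double pA = p[2] + p[3], pB = p[1] + p[3];
  s.D = p[3] - pA * pB;
  double dmax = (s.D >= 0.0) ? std::min(pA * (1.0 - pB), (1.0 - pA) * pB)
                             : std::min(pA * pB, (1.0 - pA) * (1.0 - pB));
  s.dprime = (dmax > 0.0) ? std::fabs(s.D) / dmax : 0.0;
  if (s.dprime > 1.0) s.dprime = 1.0;
  double denom = pA * (1.0 - pA) * pB * (1.0 - pB);
  s.r2 = (denom > 0.0) ? s.D * s.D / denom : 0.0;
  if (s.r2 > 1.0) s.r2 = 1.0;
  return s;
}

// Likelihood of |D'| profiled on a fixed grid with allele frequencies held at
// their sample estimates; the normalized likelihood is treated as a
// distribution over |D'| and the 5th/95th percentiles reported.
void dprime_ci_grid(const PairTab& t, double sign, int grid_n, double* ci_low,
                    double* ci_high, std::vector<double>* density) {
  const double pA = t.pA, pB = t.pB;
  double dmax = (sign >= 0.0) ? std::min(pA * (1.0 - pB), (1.0 - pA) * pB)
                              : std::min(pA * pB, (1.0 - pA) * (1.0 - pB));
  std::vector<double> ll(grid_n);
  double llmax = R_NegInf;
  for (int k = 0; k < grid_n; ++k) {
    double d = (double)k / (double)(grid_n - 1);
    double D = sign * d * dmax;
    double p[4];
    p[3] = pA * pB + D;
    p[2] = pA - p[3];
    p[1] = pB - p[3];
    p[0] = 1.0 - pA - pB + p[3];
    for (int i = 0; i < 4; ++i)
      if (p[i] < 0.0) p[i] = 0.0;  // boundary round-off only
    ll[k] = loglik(t, p);
    if (ll[k] > llmax) llmax = ll[k];
  }
  double tot = 0.0;
  for (int k = 0; k < grid_n; ++k) {
    ll[k] = std::exp(ll[k] - llmax);
    tot += ll[k];
  }
  double cum = 0.0;
  *ci_low = 0.0;
  *ci_high = 1.0;
  bool low_set = false, high_set = false;
  for (int k = 0; k < grid_n; ++k) {
    cum += ll[k] / tot;
    double d = (double)k / (double)(grid_n - 1);
    if (!low_set && cum >= 0.05) {
      *ci_low = d;
      low_set = true;
    }
    if (!high_set && cum >= 0.95) {
      *ci_high = d;
      high_set = true;
      break;
    }
  }
  if (density != nullptr) {
    density->resize(grid_n);
    for (int k = 0; k < grid_n; ++k) (*density)[k] = ll[k] / tot;
  }
}

struct PairLD {
  double dprime, r2, ci_low, ci_high;
  double ninf;
  bool defined;
};

PairLD pair_ld(const int* ga, const int* gb, int nind, int grid_n, double tol,
               int max_iter) {
  PairLD out;
  PairTab t = tabulate_pair(ga, gb, nind);
  out.ninf = t.ntot;
  if (t.ntot == 0.0 || t.pA <= 0.0 || t.pA >= 1.0 || t.pB <= 0.0 ||
      t.pB >= 1.0) {
    out.defined = false;
    out.dprime = out.r2 = out.ci_low = out.ci_high = NA_REAL;
    return out;
  }
  double p[4];
  em_freqs(t, tol, max_iter, p);
  DStats s = dstats(p);
  out.dprime = s.dprime;
  out.r2 = s.r2;
  double sign = (s.D >= 0.0) ? 1.0 : -1.0;
  dprime_ci_grid(t, sign, grid_n, &out.ci_low, &out.ci_high, nullptr);
  out.defined = true;
  return out;
}

}  // namespace

// [[Rcpp::export]]
List ld_pair_core(IntegerVector ga, IntegerVector gb, int grid_n = 101,
                  double tol = 1e-8, int max_iter = 1000,
                  bool return_density = false) {
  if (ga.size() != gb.size()) stop("genotype vectors differ in length");
  PairTab t = tabulate_pair(ga.begin(), gb.begin(), ga.size());
  bool defined = !(t.ntot == 0.0 || t.pA <= 0.0 || t.pA >= 1.0 ||
                   t.pB <= 0.0 || t.pB >= 1.0);
  NumericVector freqs(4, NA_REAL);
  double D = NA_REAL, dp = NA_REAL, r2 = NA_REAL, cil = NA_REAL,
         cih = NA_REAL;
  NumericVector dens;
  if (defined) {
    double p[4];
    em_freqs(t, tol, max_iter, p);
    for (int i = 0; i < 4; ++i) freqs[i] = p[i];
    DStats s = dstats(p);
    D = s.D;
    dp = s.dprime;
    r2 = s.r2;
    double sign = (s.D >= 0.0) ? 1.0 : -1.0;
    std::vector<double> dv;
    dprime_ci_grid(t, sign, grid_n, &cil, &cih,
                   return_density ? &dv : nullptr);
    if (return_density) dens = wrap(dv);
  }
  freqs.names() = CharacterVector::create("p00", "p01", "p10", "p11");
  List out = List::create(
      _["freqs"] = freqs, _["D"] = D, _["dprime"] = dp, _["r2"] = r2,
      _["ci_low"] = cil, _["ci_high"] = cih, _["n_informative"] = t.ntot,
      _["pA"] = t.pA, _["pB"] = t.pB, _["defined"] = defined);
  if (return_density) out["density"] = dens;
  return out;
}

// All pairwise LD statistics between variants whose start positions differ by
// at most `window` bp. geno: animals x variants, columns position-sorted.
// [[Rcpp::export]]
DataFrame ld_window_core(IntegerMatrix geno, NumericVector pos, double window,
                         int grid_n = 101, double tol = 1e-8,
                         int max_iter = 1000) {
  const int m = geno.ncol(), nind = geno.nrow();
  if (pos.size() != m) stop("pos length must match number of variants");
  std::vector<int> vi, vj;
  std::vector<double> vdp, vr2, vcil, vcih, vninf;
  std::vector<int> vdef;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m && pos[j] - pos[i] <= window; ++j) {
      PairLD r = pair_ld(&geno[(R_xlen_t)i * nind], &geno[(R_xlen_t)j * nind],
                         nind, grid_n, tol, max_iter);
      vi.push_back(i + 1);
      vj.push_back(j + 1);
      vdp.push_back(r.dprime);
      vr2.push_back(r.r2);
      vcil.push_back(r.ci_low);
      vcih.push_back(r.ci_high);
      vninf.push_back(r.ninf);
      vdef.push_back(r.defined ? 1 : 0);
    }
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["dprime"] = vdp,
                           _["r2"] = vr2, _["ci_low"] = vcil,
                           _["ci_high"] = vcih, _["n_informative"] = vninf,
                           _["defined"] = vdef);
}

// Confidence-interval block scan: classify every pair within the window as
// strong LD (ci_low >= strong_low & ci_high >= strong_high), strong
// recombination (ci_high < recomb_high) or non-informative, then enumerate
// every candidate span whose informative pairs are in strong LD at
// proportion >= strong_frac. Greedy overlap resolution is done in R.
// [[Rcpp::export]]
DataFrame gabriel_spans_core(IntegerMatrix geno, NumericVector pos,
                             double window = 200000.0, int grid_n = 101,
                             double tol = 1e-8, int max_iter = 1000,
                             double strong_low = 0.60,
                             double strong_high = 0.85,
                             double recomb_high = 0.90,
                             double strong_frac = 0.95, int min_inf = 5) {
  const int m = geno.ncol(), nind = geno.nrow();
  if (pos.size() != m) stop("pos length must match number of variants");
  // pair classes: 0 = non-informative, 1 = strong LD, 2 = strong recombination
  std::vector<std::vector<unsigned char> > cls(m);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m && pos[j] - pos[i] <= window; ++j) {
      PairLD r = pair_ld(&geno[(R_xlen_t)i * nind], &geno[(R_xlen_t)j * nind],
                         nind, grid_n, tol, max_iter);
      unsigned char c = 0;
      if (r.defined && r.ninf >= min_inf) {
        if (r.ci_low >= strong_low && r.ci_high >= strong_high)
          c = 1;
        else if (r.ci_high < recomb_high)
          c = 2;
      }
      cls[i].push_back(c);
    }
  }
  std::vector<int> si, sj, sstrong, sinf;
  for (int i = 0; i < m; ++i) {
    long nstrong = 0, ninf = 0;
    int width = (int)cls[i].size();
    for (int j = i + 1; j <= i + width; ++j) {
      // extend span (i..j): add pairs (k, j) for k in i..j-1
      for (int k = i; k < j; ++k) {
        unsigned char c = cls[k][j - k - 1];
        if (c == 1) {
          ++nstrong;
          ++ninf;
        } else if (c == 2) {
          ++ninf;
        }
      }
      if (ninf > 0 &&
          (double)nstrong + 1e-9 >= strong_frac * (double)ninf) {
        si.push_back(i + 1);
        sj.push_back(j + 1);
        sstrong.push_back((int)nstrong);
        sinf.push_back((int)ninf);
      }
    }
  }
  return DataFrame::create(_["i"] = si, _["j"] = sj, _["n_strong"] = sstrong,
                           _["n_informative_pairs"] = sinf);
}
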