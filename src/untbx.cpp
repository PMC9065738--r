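#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// log(exp(a) + exp(b)) without leaving log space
static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a < b) std::swap(a, b);
  double d = a - b;
  return d > 36.0 ? a : a + std::log1p(std::exp(-d));
}

// ---------------------------------------------------------------------------
// Unsigned Stirling numbers of the first kind, in log space.
// Rows are cached up to STIRLING_CACHE_MAX; larger rows are rolled on demand.
// Recurrence: s(n+1, a) = n * s(n, a) + s(n, a-1).
// ---------------------------------------------------------------------------

static const int STIRLING_CACHE_MAX = 4096;
static std::vector< std::vector<double> > stirling_cache; // [n-1] -> log s(n, 1..n)

static void stirling_extend_cache(int n) {
  if (stirling_cache.empty()) {
    stirling_cache.push_back(std::vector<double>(1, 0.0)); // s(1,1) = 1
  }
  while ((int)stirling_cache.size() < n) {
    int m = (int)stirling_cache.size(); // have rows 1..m, build row m+1
    const std::vector<double> &prev = stirling_cache[m - 1];
    std::vector<double> row(m + 1, R_NegInf);
    double logm = std::log((double)m);
    row[0] = logm + prev[0];               // s(m+1, 1) = m * s(m, 1)
    for (int a = 1; a < m; ++a)
      row[a] = logadd(logm + prev[a], prev[a - 1]);
    row[m] = 0.0;                          // s(m+1, m+1) = 1
    stirling_cache.push_back(row);
  }
}

// Fill `out` (length n) with log s(n, 1..n)
static void stirling_row(int n, std::vector<double> &out) {
  if (n <= STIRLING_CACHE_MAX) {
    stirling_extend_cache(n);
    out = stirling_cache[n - 1];
    return;
  }
  stirling_extend_cache(STIRLING_CACHE_MAX);
  std::vector<double> cur = stirling_cache[STIRLING_CACHE_MAX - 1];
  cur.resize(n, R_NegInf);
  std::vector<double> nxt(n, R_NegInf);
  for (int m = STIRLING_CACHE_MAX; m < n; ++m) {
    double logm = std::log((double)m);
    nxt[0] = logm + cur[0];
    for (int a = 1; a < m; ++a) nxt[a] = logadd(logm + cur[a], cur[a - 1]);
    nxt[m] = 0.0;
    for (int a = m + 1; a < n; ++a) nxt[a] = R_NegInf;
    std::swap(cur, nxt);
  }
  out = cur;
}

// [[Rcpp::export]]
NumericVector stirling_log_row_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  std::vector<double> row;
  stirling_row(n, row);
  return NumericVector(row.begin(), row.end());
}

// ---------------------------------------------------------------------------
// Etienne sampling-formula machinery.
//
// K(D, A) = sum over {a_i : sum a_i = A, 1 <= a_i <= n_i} of
//           prod_i s(n_i, a_i) (a_i - 1)! / (n_i - 1)!
// computed as a log-space convolution of per-species coefficient vectors.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector etienne_logK_cpp(IntegerVector abund) {
  int S = abund.size();
  if (S < 1) stop("empty abundance vector");
  long J = 0;
  for (int i = 0; i < S; ++i) {
    if (abund[i] < 1) stop("abundances must be positive");
    J += abund[i];
  }
  std::vector<int> n(abund.begin(), abund.end());
  std::sort(n.begin(), n.end(), std::greater<int>()); // big species first: fewer ops
  std::vector<double> cur, lv, row, nxt;
  cur.push_back(0.0); // empty product, A offset handled by index arithmetic
  size_t curlen = 1;
  for (int i = 0; i < S; ++i) {
    int ni = n[i];
    stirling_row(ni, row);
    lv.resize(ni);
    double lg_ni = lgamma((double)ni); // log (n_i - 1)!
    for (int a = 1; a <= ni; ++a)
      lv[a - 1] = row[a - 1] + lgamma((double)a) - lg_ni;
    nxt.assign(curlen + ni - 1, R_NegInf);
    for (size_t j = 0; j < curlen; ++j) {
      double cj = cur[j];
      if (cj == R_NegInf) continue;
      for (int k = 0; k < ni; ++k)
        nxt[j + k] = logadd(nxt[j + k], cj + lv[k]);
    }
    cur.swap(nxt);
    curlen = cur.size();
  }
  // cur[t] corresponds to A = S + t, t = 0 .. J - S
  return NumericVector(cur.begin(), cur.end());
}

// Log-likelihood of an abundance configuration under the Etienne sampling
// formula, given precomputed logK (for A = S..J) and the combinatorial
// constant cnst = log J! - sum log n_i - sum log Phi_j!.
// [[Rcpp::export]]
double etienne_loglik_cpp(NumericVector logK, int S, int J, double cnst,
                          double theta, double I) {
  if (theta <= 0 || I <= 0) stop("theta and I must be positive");
  int len = J - S + 1;
  if (logK.size() != len) stop("logK length mismatch");
  double logI = std::log(I);
  // terms: logK[A-S] + A log I - (lgamma(theta+A) - lgamma(theta))
  std::vector<double> terms(len);
  double lg = lgamma(theta + S) - lgamma(theta);
  double mx = R_NegInf;
  for (int t = 0; t < len; ++t) {
    int A = S + t;
    terms[t] = logK[t] + A * logI - lg;
    if (terms[t] > mx) mx = terms[t];
    lg += std::log(theta + A); // lgamma(theta + A + 1) - lgamma(theta)
  }
  double s = 0.0;
  for (int t = 0; t < len; ++t)
    if (terms[t] != R_NegInf) s += std::exp(terms[t] - mx);
  double lse = mx + std::log(s);
  return cnst + S * std::log(theta) - (lgamma(I + (double)J) - lgamma(I)) + lse;
}

// ---------------------------------------------------------------------------
// Urn-scheme simulators.
// ---------------------------------------------------------------------------

// One local community assembled by the Hubbell urn, generalized so that the
// neutral model, the intrinsic-fitness (IF) model and the density-dependent
// (PC) model share one code path:
//   immigrant step: species k with prob proportional to beta_k * fec_k
//   copy step:      species k with prob proportional to N_k^(1-eps) * fec_k
// With eps = 0 and all fec equal this is exactly the neutral urn, consuming
// the same RNG stream, so effect-0 runs are bit-identical to neutral runs.
// [[Rcpp::export]]
IntegerVector urn_sample_cpp(NumericVector beta, int J, double m,
                             NumericVector fec, double eps) {
  int S = beta.size();
  if (J < 1) stop("J must be >= 1");
  if (m <= 0 || m > 1) stop("m must be in (0, 1]");
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]");
  bool uniform_f = true;
  double fmax = fec[0];
  for (int k = 1; k < S; ++k) {
    if (fec[k] != fec[0]) uniform_f = false;
    if (fec[k] > fmax) fmax = fec[k];
  }
  std::vector<double> cum_imm(S);
  double tot = 0.0;
  for (int k = 0; k < S; ++k) { tot += beta[k] * fec[k]; cum_imm[k] = tot; }
  if (tot <= 0) stop("degenerate immigration weights");
  for (int k = 0; k < S; ++k) cum_imm[k] /= tot;

  bool always_imm = (m >= 1.0);
  double I = always_imm ? 0.0 : m * ((double)J - 1.0) / (1.0 - m);
  IntegerVector counts(S);
  std::vector<int> ind;
  ind.reserve(J);
  std::vector<double> wloc(S, 0.0);
  double W = 0.0;
  RNGScope scope;
  for (int n = 0; n < J; ++n) {
    double pImm = always_imm ? 1.0 : (n == 0 ? 1.0 : I / (I + n));
    bool imm = unif_rand() < pImm;
    int k;
    if (imm) {
      double u = unif_rand();
      k = (int)(std::lower_bound(cum_imm.begin(), cum_imm.end(), u) - cum_imm.begin());
      if (k >= S) k = S - 1;
    } else if (eps == 0.0) {
      for (;;) {
        int idx = (int)(unif_rand() * n);
        if (idx >= n) idx = n - 1;
        k = ind[idx];
        if (uniform_f || unif_rand() < fec[k] / fmax) break;
      }
    } else {
      double u = unif_rand() * W, acc = 0.0;
      k = S - 1;
      for (int j = 0; j < S; ++j) {
        if (wloc[j] == 0.0) continue;
        acc += wloc[j];
        if (u <= acc) { k = j; break; }
      }
    }
    counts[k]++;
    ind.push_back(k);
    if (eps > 0.0) {
      double wnew = std::pow((double)counts[k], 1.0 - eps) * fec[k];
      W += wnew - wloc[k];
      wloc[k] = wnew;
    }
  }
  return counts;
}

// Draw one SAD of size J from the Hubbell model at (theta, I) with the exact
// two-level nested urn (Chinese restaurant franchise): immigrants found new
// ancestral lineages at rate I, lineages pick species by a CRP(theta).
// [[Rcpp::export]]
IntegerVector nested_crp_sad_cpp(double theta, double I, int J) {
  if (theta <= 0 || I <= 0 || J < 1) stop("invalid parameters");
  std::vector<int> ind_dish, table_dish;
  ind_dish.reserve(J);
  int ndish = 0;
  RNGScope scope;
  for (int n = 0; n < J; ++n) {
    bool imm = (n == 0) ? true : (unif_rand() < I / (I + n));
    int dish;
    if (imm) {
      int T = (int)table_dish.size();
      if (T == 0 || unif_rand() < theta / (theta + T)) {
        dish = ndish++;
      } else {
        int j = (int)(unif_rand() * T);
        if (j >= T) j = T - 1;
        dish = table_dish[j];
      }
      table_dish.push_back(dish);
    } else {
      int idx = (int)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
      dish = ind_dish[idx];
    }
    ind_dish.push_back(dish);
  }
  IntegerVector counts(ndish);
  for (size_t i = 0; i < ind_dish.size(); ++i) counts[ind_dish[i]]++;
  return counts;
}

// ---------------------------------------------------------------------------
// Gibbs sampler for the hierarchical Dirichlet process multi-site neutral
// model (Chinese restaurant franchise representation).
// ---------------------------------------------------------------------------

struct SliceTarget {
  double ttot, N;
  double operator()(double u) const {
    double Iv = std::exp(u);
    return ttot * u + lgamma(Iv) - lgamma(Iv + N);
  }
};

// Univariate slice sampler (stepping out + shrinkage) on a bounded interval.
static double slice_sample(const SliceTarget &f, double u0, double lo, double hi,
                           double w) {
  double y = f(u0) - exp_rand();
  double L = u0 - w * unif_rand();
  double R = L + w;
  if (L < lo) L = lo;
  if (R > hi) R = hi;
  int guard = 0;
  while (L > lo && f(L) > y && ++guard < 200) { L -= w; if (L < lo) L = lo; }
  guard = 0;
  while (R < hi && f(R) > y && ++guard < 200) { R += w; if (R > hi) R = hi; }
  for (int it = 0; it < 200; ++it) {
    double u1 = L + unif_rand() * (R - L);
    if (f(u1) > y) return u1;
    if (u1 < u0) L = u1; else R = u1;
  }
  return u0;
}

// [[Rcpp::export]]
List msn_gibbs_cpp(IntegerMatrix counts, int n_gibbs, int burn_in,
                   double prior_shape, double prior_rate,
                   double logI_lo, double logI_hi,
                   double theta0, NumericVector I0) {
  int S = counts.nrow(), M = counts.ncol();
  if (n_gibbs <= burn_in) stop("n_gibbs must exceed burn_in");
  std::vector< std::vector< std::pair<int,int> > > site(M);
  std::vector<double> Nsite(M, 0.0);
  for (int i = 0; i < M; ++i) {
    for (int k = 0; k < S; ++k) {
      int n = counts(k, i);
      if (n < 0) stop("negative count");
      if (n > 0) { site[i].push_back(std::make_pair(k, n)); Nsite[i] += n; }
    }
    if (site[i].empty()) stop("empty site");
  }
  // initial beta: pooled relative abundances
  std::vector<double> beta(S, 0.0);
  double tot = 0.0;
  for (int k = 0; k < S; ++k) {
    for (int i = 0; i < M; ++i) beta[k] += counts(k, i);
    tot += beta[k];
  }
  for (int k = 0; k < S; ++k) beta[k] /= tot;
  double theta = theta0;
  std::vector<double> I(I0.begin(), I0.end());

  int n_keep = n_gibbs - burn_in;
  NumericVector theta_chain(n_keep);
  NumericMatrix I_chain(n_keep, M);
  std::vector<double> beta_sum(S, 0.0);
  std::vector<double> Tk(S);
  std::vector<double> ttot(M);

  RNGScope scope;
  for (int it = 0; it < n_gibbs; ++it) {
    // 1. table counts: t | n, c ~ sum of Bernoulli(c / (c + j)), j = 0..n-1
    std::fill(Tk.begin(), Tk.end(), 0.0);
    double Ttot = 0.0;
    for (int i = 0; i < M; ++i) {
      double ti = 0.0;
      for (size_t r = 0; r < site[i].size(); ++r) {
        int k = site[i][r].first, n = site[i][r].second;
        double c = I[i] * beta[k];
        if (c <= 1e-300) c = 1e-300;
        double t = 1.0; // j = 0 succeeds with probability 1
        for (int j = 1; j < n; ++j)
          if (unif_rand() < c / (c + j)) t += 1.0;
        Tk[k] += t;
        ti += t;
      }
      ttot[i] = ti;
      Ttot += ti;
    }
    // 2. beta | tables ~ Dirichlet(T_1, ..., T_S, theta); keep leftover mass
    double gsum = 0.0;
    std::vector<double> g(S);
    for (int k = 0; k < S; ++k) { g[k] = R::rgamma(Tk[k], 1.0); gsum += g[k]; }
    double grest = R::rgamma(theta, 1.0);
    double denom = gsum + grest;
    for (int k = 0; k < S; ++k) beta[k] = g[k] / denom;
    // 3. theta | #dishes = S, #tables = Ttot (Escobar-West auxiliary draw)
    double eta = R::rbeta(theta + 1.0, Ttot);
    double br = prior_rate - std::log(eta);
    double odds = (prior_shape + S - 1.0) / (Ttot * br);
    double shape = (unif_rand() < odds / (1.0 + odds)) ? prior_shape + S
                                                       : prior_shape + S - 1.0;
    theta = R::rgamma(shape, 1.0 / br);
    if (theta < 1e-8) theta = 1e-8;
    // 4. I_i | tables at site i (slice sampler on log I, log-uniform prior)
    for (int i = 0; i < M; ++i) {
      SliceTarget f;
      f.ttot = ttot[i];
      f.N = Nsite[i];
      double u = slice_sample(f, std::log(I[i]), logI_lo, logI_hi, 1.0);
      I[i] = std::exp(u);
    }
    if (it >= burn_in) {
      int r = it - burn_in;
      theta_chain[r] = theta;
      for (int i = 0; i < M; ++i) I_chain(r, i) = I[i];
      for (int k = 0; k < S; ++k) beta_sum[k] += beta[k];
    }
  }
  NumericVector beta_post(S);
  double bs = 0.0;
  for (int k = 0; k < S; ++k) bs += beta_sum[k];
  for (int k = 0; k < S; ++k) beta_post[k] = beta_sum[k] / bs;
  return List::create(_["theta_chain"] = theta_chain,
                      _["I_chain"] = I_chain,
                      _["beta_post"] = beta_post);
}
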