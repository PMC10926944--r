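// Transfer-matrix kernels for the 1D Ising model of CpG methylation.
//
// A region of N CpG sites carries per-site fields alpha_n and per-adjacent-
// pair couplings beta_n (length N-1).  Patterns x in {0,1}^N have potential
//   V(x) = -sum_n alpha_n * s_n - sum_n beta_n * s_n * s_{n+1},  s = 2x - 1,
// and probability P(x) = exp(-V(x)) / Z.  All routines work with per-step
// rescaling of the 2-state messages so arbitrarily strong fields never
// overflow; only log-scale factors accumulate.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Chain {
  int N;
  // normalized forward/backward messages and cumulative log scale factors
  std::vector<double> fp, fm, lsf; // F_n(s): sum over s_1..s_{n-1}, incl. field at n
  std::vector<double> bp, bm, lsb; // B_n(s): sum over s_{n+1}..s_N, excl. field at n
  double logZ;
};

Chain build_chain(const std::vector<double>& alpha,
                  const std::vector<double>& beta) {
  const int N = static_cast<int>(alpha.size());
  Chain ch;
  ch.N = N;
  ch.fp.resize(N); ch.fm.resize(N); ch.lsf.resize(N);
  ch.bp.resize(N); ch.bm.resize(N); ch.lsb.resize(N);

  double fp = std::exp(alpha[0]), fm = std::exp(-alpha[0]);
  double sc = fp + fm, ls = std::log(sc);
  fp /= sc; fm /= sc;
  ch.fp[0] = fp; ch.fm[0] = fm; ch.lsf[0] = ls;
  for (int n = 1; n < N; ++n) {
    const double eb = std::exp(beta[n - 1]), ebm = std::exp(-beta[n - 1]);
    const double ea = std::exp(alpha[n]), eam = std::exp(-alpha[n]);
    double np = (fp * eb + fm * ebm) * ea;
    double nm = (fp * ebm + fm * eb) * eam;
    sc = np + nm; ls += std::log(sc);
    fp = np / sc; fm = nm / sc;
    ch.fp[n] = fp; ch.fm[n] = fm; ch.lsf[n] = ls;
  }
  ch.logZ = ch.lsf[N - 1]; // messages are normalized, so Z folds into the scale

  double bp = 1.0, bm = 1.0, lb = 0.0;
  ch.bp[N - 1] = bp; ch.bm[N - 1] = bm; ch.lsb[N - 1] = lb;
  for (int n = N - 2; n >= 0; --n) {
    const double eb = std::exp(beta[n]), ebm = std::exp(-beta[n]);
    const double ea = std::exp(alpha[n + 1]), eam = std::exp(-alpha[n + 1]);
    double np = eb * ea * bp + ebm * eam * bm;
    double nm = ebm * ea * bp + eb * eam * bm;
    sc = np + nm; lb += std::log(sc);
    bp = np / sc; bm = nm / sc;
    ch.bp[n] = bp; ch.bm[n] = bm; ch.lsb[n] = lb;
  }
  return ch;
}

std::vector<double> as_std(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

// Log marginal probability of one read's calls over sites [start, start+len).
// Codes: 1 = methylated, 0 = unmethylated, -1 = unobserved (summed out).
double read_logprob(const Chain& ch, const int* calls, int start, int len,
                    const std::vector<double>& alpha,
                    const std::vector<double>& beta) {
  double gp = ch.fp[start], gm = ch.fm[start];
  if (calls[0] == 1) gm = 0.0;
  else if (calls[0] == 0) gp = 0.0;
  double lg = 0.0;
  for (int k = 1; k < len; ++k) {
    const int n = start + k;
    const double eb = std::exp(beta[n - 1]), ebm = std::exp(-beta[n - 1]);
    const double ea = std::exp(alpha[n]), eam = std::exp(-alpha[n]);
    double np = (gp * eb + gm * ebm) * ea;
    double nm = (gp * ebm + gm * eb) * eam;
    if (calls[k] == 1) nm = 0.0;
    else if (calls[k] == 0) np = 0.0;
    const double sc = np + nm;
    if (sc <= 0.0) return R_NegInf;
    lg += std::log(sc);
    gp = np / sc; gm = nm / sc;
  }
  const int j = start + len - 1;
  const double tail = gp * ch.bp[j] + gm * ch.bm[j];
  if (tail <= 0.0) return R_NegInf;
  return ch.lsf[start] + lg + std::log(tail) + ch.lsb[j] - ch.logZ;
}

double total_loglik(const std::vector<double>& alpha,
                    const std::vector<double>& beta,
                    const IntegerVector& starts, const IntegerVector& lens,
                    const IntegerVector& calls_flat,
                    const NumericVector& counts) {
  const Chain ch = build_chain(alpha, beta);
  double tot = 0.0;
  int off = 0;
  for (int r = 0; r < starts.size(); ++r) {
    tot += counts[r] *
           read_logprob(ch, &calls_flat[off], starts[r], lens[r], alpha, beta);
    off += lens[r];
  }
  return tot;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_log_partition")]]
double cpp_log_partition(NumericVector alpha, NumericVector beta) {
  if (alpha.size() < 1) stop("alpha must have length >= 1");
  if (beta.size() != alpha.size() - 1) stop("beta must have length N - 1");
  return build_chain(as_std(alpha), as_std(beta)).logZ;
}

// Per-read log marginal probabilities (reads as flat code vector).
// [[Rcpp::export(name = "cpp_reads_loglik")]]
NumericVector cpp_reads_loglik(NumericVector alpha, NumericVector beta,
                               IntegerVector starts, IntegerVector lens,
                               IntegerVector calls_flat) {
  const std::vector<double> a = as_std(alpha), b = as_std(beta);
  const Chain ch = build_chain(a, b);
  NumericVector out(starts.size());
  int off = 0;
  for (int r = 0; r < starts.size(); ++r) {
    if (starts[r] < 0 || starts[r] + lens[r] > ch.N)
      stop("read window outside region chain");
    out[r] = read_logprob(ch, &calls_flat[off], starts[r], lens[r], a, b);
    off += lens[r];
  }
  return out;
}

// Exact P(L = k/K) for the methylation level over a subset of sites.
// subset0: 0-based, sorted site indices within the region chain.
// [[Rcpp::export(name = "cpp_level_distribution")]]
NumericVector cpp_level_distribution(NumericVector alpha, NumericVector beta,
                                     IntegerVector subset0) {
  const int N = alpha.size();
  const int K = subset0.size();
  if (K < 1) stop("subset must contain at least one site");
  std::vector<bool> in(N, false);
  for (int i = 0; i < K; ++i) {
    if (subset0[i] < 0 || subset0[i] >= N) stop("subset index out of range");
    in[subset0[i]] = true;
  }
  // f[s][k]: message with s at current site and k methylated subset sites so far
  std::vector<double> fp(K + 1, 0.0), fm(K + 1, 0.0);
  fp[in[0] ? 1 : 0] = std::exp(alpha[0]);
  fm[0] = std::exp(-alpha[0]);
  for (int n = 1; n < N; ++n) {
    const double eb = std::exp(beta[n - 1]), ebm = std::exp(-beta[n - 1]);
    const double ea = std::exp(alpha[n]), eam = std::exp(-alpha[n]);
    std::vector<double> np(K + 1, 0.0), nm(K + 1, 0.0);
    const int shift = in[n] ? 1 : 0;
    for (int k = 0; k <= K; ++k) {
      const double f1 = fp[k], f0 = fm[k];
      if (f1 == 0.0 && f0 == 0.0) continue;
      if (k + shift <= K) np[k + shift] += (f1 * eb + f0 * ebm) * ea;
      nm[k] += (f1 * ebm + f0 * eb) * eam;
    }
    double sc = 0.0;
    for (int k = 0; k <= K; ++k) sc += np[k] + nm[k];
    for (int k = 0; k <= K; ++k) { fp[k] = np[k] / sc; fm[k] = nm[k] / sc; }
  }
  NumericVector p(K + 1);
  double tot = 0.0;
  for (int k = 0; k <= K; ++k) { p[k] = fp[k] + fm[k]; tot += p[k]; }
  for (int k = 0; k <= K; ++k) p[k] /= tot;
  return p;
}

// Exact sampling of methylation patterns over contiguous windows of the
// chain: forward-filter (shared messages) then per-read backward draw of
// the window conditional on the rest of the chain marginalized out.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = "cpp_sample_windows")]]
IntegerVector cpp_sample_windows(NumericVector alpha, NumericVector beta,
                                 IntegerVector starts, IntegerVector lens) {
  const std::vector<double> a = as_std(alpha), b = as_std(beta);
  const Chain ch = build_chain(a, b);
  int total = 0;
  for (int r = 0; r < lens.size(); ++r) total += lens[r];
  IntegerVector out(total);
  int off = 0;
  for (int r = 0; r < starts.size(); ++r) {
    const int i0 = starts[r], L = lens[r];
    if (i0 < 0 || i0 + L > ch.N) stop("sample window outside region chain");
    // first site of the window: P(s=+1) prop. to F(s) * B(s)
    double wp = ch.fp[i0] * ch.bp[i0];
    double wm = ch.fm[i0] * ch.bm[i0];
    int s = (unif_rand() < wp / (wp + wm)) ? 1 : -1;
    out[off] = (s + 1) / 2;
    for (int k = 1; k < L; ++k) {
      const int n = i0 + k;
      const double eb = std::exp(b[n - 1] * s);
      const double pp = eb * std::exp(a[n]) * ch.bp[n];
      const double pm = (1.0 / eb) * std::exp(-a[n]) * ch.bm[n];
      s = (unif_rand() < pp / (pp + pm)) ? 1 : -1;
      out[off + k] = (s + 1) / 2;
    }
    off += L;
  }
  return out;
}

namespace {

struct FitData {
  IntegerVector starts, lens, calls;
  NumericVector counts, rho, dcap;
  NumericVector lower, upper;
  int n_sites;
};

double neg_loglik(const double* par, const FitData& fd) {
  double th[3];
  for (int i = 0; i < 3; ++i) {
    th[i] = par[i];
    if (th[i] < fd.lower[i]) th[i] = fd.lower[i];
    if (th[i] > fd.upper[i]) th[i] = fd.upper[i];
  }
  std::vector<double> alpha(fd.n_sites), beta(fd.n_sites > 1 ? fd.n_sites - 1 : 0);
  for (int n = 0; n < fd.n_sites; ++n) alpha[n] = th[0] + th[1] * fd.rho[n];
  for (int n = 0; n + 1 < fd.n_sites; ++n) beta[n] = th[2] / fd.dcap[n];
  return -total_loglik(alpha, beta, fd.starts, fd.lens, fd.calls, fd.counts);
}

// Deterministic Nelder-Mead in 3 dimensions.
double nelder_mead(double x[3], const FitData& fd, double tol, int maxit,
                   bool* converged) {
  const int n = 3, m = 4;
  double simplex[4][3], fval[4];
  for (int v = 0; v < m; ++v) {
    for (int j = 0; j < n; ++j) simplex[v][j] = x[j];
    if (v > 0) simplex[v][v - 1] += 1.0;
    fval[v] = neg_loglik(simplex[v], fd);
  }
  *converged = false;
  int it = 0;
  int order[4] = {0, 1, 2, 3};
  while (it++ < maxit) {
    // order vertices by value (stable insertion sort: deterministic ties)
    for (int i = 1; i < m; ++i) {
      int key = order[i], j = i - 1;
      while (j >= 0 && fval[order[j]] > fval[key]) { order[j + 1] = order[j]; --j; }
      order[j + 1] = key;
    }
    const int lo = order[0], hi = order[3], nh = order[2];
    if (std::fabs(fval[hi] - fval[lo]) <=
        tol * (std::fabs(fval[lo]) + tol)) {
      *converged = true;
      break;
    }
    double cen[3];
    for (int j = 0; j < n; ++j) {
      cen[j] = 0.0;
      for (int v = 0; v < m; ++v) if (v != hi) cen[j] += simplex[v][j];
      cen[j] /= n;
    }
    double xr[3];
    for (int j = 0; j < n; ++j) xr[j] = cen[j] + (cen[j] - simplex[hi][j]);
    const double fr = neg_loglik(xr, fd);
    if (fr < fval[lo]) {
      double xe[3];
      for (int j = 0; j < n; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - simplex[hi][j]);
      const double fe = neg_loglik(xe, fd);
      if (fe < fr) { for (int j = 0; j < n; ++j) simplex[hi][j] = xe[j]; fval[hi] = fe; }
      else { for (int j = 0; j < n; ++j) simplex[hi][j] = xr[j]; fval[hi] = fr; }
    } else if (fr < fval[nh]) {
      for (int j = 0; j < n; ++j) simplex[hi][j] = xr[j];
      fval[hi] = fr;
    } else {
      double xc[3];
      if (fr < fval[hi]) {
        for (int j = 0; j < n; ++j) xc[j] = cen[j] + 0.5 * (cen[j] - simplex[hi][j]);
      } else {
        for (int j = 0; j < n; ++j) xc[j] = cen[j] - 0.5 * (cen[j] - simplex[hi][j]);
      }
      const double fc = neg_loglik(xc, fd);
      if (fc < std::min(fr, fval[hi])) {
        for (int j = 0; j < n; ++j) simplex[hi][j] = xc[j];
        fval[hi] = fc;
      } else {
        for (int v = 0; v < m; ++v) {
          if (v == lo) continue;
          for (int j = 0; j < n; ++j)
            simplex[v][j] = simplex[lo][j] + 0.5 * (simplex[v][j] - simplex[lo][j]);
          fval[v] = neg_loglik(simplex[v], fd);
        }
      }
    }
  }
  int best = 0;
  for (int v = 1; v < m; ++v) if (fval[v] < fval[best]) best = v;
  for (int j = 0; j < n; ++j) x[j] = simplex[best][j];
  return fval[best];
}

} // namespace

// Maximum-likelihood (a, b, c) by multi-start Nelder-Mead; ties between
// starts resolved by strict improvement (earliest start wins).
// [[Rcpp::export(name = "cpp_fit_ising")]]
List cpp_fit_ising(IntegerVector starts, IntegerVector lens,
                   IntegerVector calls_flat, NumericVector counts,
                   NumericVector rho, NumericVector dcap,
                   NumericMatrix start_grid, NumericVector lower,
                   NumericVector upper, double tol, int maxit) {
  FitData fd;
  fd.starts = starts; fd.lens = lens; fd.calls = calls_flat;
  fd.counts = counts; fd.rho = rho; fd.dcap = dcap;
  fd.lower = lower; fd.upper = upper;
  fd.n_sites = rho.size();
  if (static_cast<int>(dcap.size()) != std::max(fd.n_sites - 1, 0))
    stop("dcap must have length N - 1");

  double best_f = R_PosInf, best_x[3] = {0, 0, 0};
  int best_start = -1;
  bool best_conv = false;
  for (int s = 0; s < start_grid.nrow(); ++s) {
    double x[3] = {start_grid(s, 0), start_grid(s, 1), start_grid(s, 2)};
    bool conv = false;
    const double f = nelder_mead(x, fd, tol, maxit, &conv);
    if (f < best_f) {
      best_f = f;
      for (int j = 0; j < 3; ++j) best_x[j] = x[j];
      best_start = s;
      best_conv = conv;
    }
  }
  NumericVector par(3);
  for (int j = 0; j < 3; ++j) {
    par[j] = best_x[j];
    if (par[j] < lower[j]) par[j] = lower[j];
    if (par[j] > upper[j]) par[j] = upper[j];
  }
  return List::create(_["par"] = par, _["logL"] = -best_f,
                      _["converged"] = best_conv,
                      _["start_index"] = best_start + 1);
}

// Total log-likelihood at fixed parameters (used for diagnostics/oracles).
// [[Rcpp::export(name = "cpp_total_loglik")]]
double cpp_total_loglik(NumericVector alpha, NumericVector beta,
                        IntegerVector starts, IntegerVector lens,
                        IntegerVector calls_flat, NumericVector counts) {
  return total_loglik(as_std(alpha), as_std(beta), starts, lens, calls_flat,
                      counts);
}
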