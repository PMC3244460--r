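#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample k ~ Binomial(n, p) from a flattened cumulative-distribution table by
// binary search: smallest k with F(k; n, p) > u.  Counts above the table
// capacity fall back to the normal approximation round(n p + z sqrt(n p (1-p)))
// clamped to [0, n], with z obtained from the same uniform variate by inverse
// transform, so the variate budget is unchanged.
static inline long long cdf_sample(long long n,
                                   const double* cdf, const int* off,
                                   int n_max, double p,
                                   double u, bool fallback) {
  if (n == 0) return 0;
  if (n <= (long long)n_max) {
    const double* row = cdf + off[n];
    int lo = 0, hi = (int)n;       // row holds n + 1 entries; row[n] = 1 > u
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (row[mid] > u) hi = mid; else lo = mid + 1;
    }
    return lo;
  }
  if (!fallback)
    stop("per-square count %d exceeds lookup-table capacity N_max = %d; "
         "enable the normal-approximation fallback or enlarge the table",
         (int)n, n_max);
  double z = R::qnorm(u, 0.0, 1.0, 1, 0);
  double k = std::round((double)n * p + z * std::sqrt((double)n * p * (1.0 - p)));
  if (k < 0.0) k = 0.0;
  if (k > (double)n) k = (double)n;
  return (long long)k;
}

// One synchronous 2D diffusion step on a periodic lattice.  `occ` holds the
// 0-based linear (column-major) indices of the occupied squares; exactly four
// uniforms from `u` are consumed per occupied square, in `occ` order:
// emigrant count ~ Binom(n, p_move), north/south vs east/west split and the
// two directional splits all ~ Binom(., 1/2).  Emigrants are read from the
// frozen pre-step counts and deposited into a fresh accumulator.
// [[Rcpp::export]]
NumericMatrix cpp_diffusion_step_2d(NumericMatrix counts,
                                    NumericVector cdf_emig, IntegerVector off_emig,
                                    int n_max_emig, double p_move,
                                    NumericVector cdf_half, IntegerVector off_half,
                                    int n_max_half,
                                    IntegerVector occ, NumericVector u,
                                    bool fallback) {
  const int nr = counts.nrow(), nc = counts.ncol();
  if (u.size() < 4 * (R_xlen_t)occ.size())
    stop("uniform variate buffer too short: need %d, got %d",
         4 * (int)occ.size(), (int)u.size());
  NumericMatrix out = clone(counts);
  const double* ce = REAL(cdf_emig);  const int* oe = INTEGER(off_emig);
  const double* ch = REAL(cdf_half);  const int* oh = INTEGER(off_half);
  R_xlen_t q = 0;
  for (R_xlen_t t = 0; t < occ.size(); ++t) {
    const int idx = occ[t];
    const int i = idx % nr, j = idx / nr;
    const long long n = (long long)counts[idx];
    if (n < 0) stop("negative count at square %d", idx + 1);
    const long long nd  = cdf_sample(n,  ce, oe, n_max_emig, p_move, u[q],     fallback);
    const long long nns = cdf_sample(nd, ch, oh, n_max_half, 0.5,    u[q + 1], fallback);
    const long long nn  = cdf_sample(nns,        ch, oh, n_max_half, 0.5, u[q + 2], fallback);
    const long long ne  = cdf_sample(nd - nns,   ch, oh, n_max_half, 0.5, u[q + 3], fallback);
    q += 4;
    const long long ns = nns - nn, nw = (nd - nns) - ne;
    out[idx] -= (double)nd;
    const int i_n = (i + nr - 1) % nr, i_s = (i + 1) % nr;
    const int j_e = (j + 1) % nc,      j_w = (j + nc - 1) % nc;
    out[i_n + j * nr] += (double)nn;
    out[i_s + j * nr] += (double)ns;
    out[i + j_e * nr] += (double)ne;
    out[i + j_w * nr] += (double)nw;
  }
  return out;
}

// One synchronous 3D diffusion step (two-table variant).  Six uniforms per
// occupied voxel: emigrants ~ Binom(n, p_move); axis split into X by
// Binom(n_d, 1/3) then Y vs Z by Binom(., 1/2); one sign split ~ Binom(., 1/2)
// per axis.  Marginal per direction is Binom(n, p_move/6).
// [[Rcpp::export]]
NumericVector cpp_diffusion_step_3d(NumericVector counts, IntegerVector dim,
                                    NumericVector cdf_emig, IntegerVector off_emig,
                                    int n_max_emig, double p_move,
                                    NumericVector cdf_third, IntegerVector off_third,
                                    int n_max_third,
                                    NumericVector cdf_half, IntegerVector off_half,
                                    int n_max_half,
                                    IntegerVector occ, NumericVector u,
                                    bool fallback) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  if (u.size() < 6 * (R_xlen_t)occ.size())
    stop("uniform variate buffer too short: need %d, got %d",
         6 * (int)occ.size(), (int)u.size());
  NumericVector out = clone(counts);
  const double* ce = REAL(cdf_emig);   const int* oe = INTEGER(off_emig);
  const double* c3 = REAL(cdf_third);  const int* o3 = INTEGER(off_third);
  const double* ch = REAL(cdf_half);   const int* oh = INTEGER(off_half);
  R_xlen_t q = 0;
  for (R_xlen_t t = 0; t < occ.size(); ++t) {
    const int idx = occ[t];
    const int i = idx % n1, j = (idx / n1) % n2, k = idx / (n1 * n2);
    const long long n = (long long)counts[idx];
    if (n < 0) stop("negative count at voxel %d", idx + 1);
    const long long nd = cdf_sample(n,  ce, oe, n_max_emig, p_move,    u[q],     fallback);
    const long long nx = cdf_sample(nd, c3, o3, n_max_third, 1.0 / 3.0, u[q + 1], fallback);
    const long long ny = cdf_sample(nd - nx, ch, oh, n_max_half, 0.5,  u[q + 2], fallback);
    const long long nz = nd - nx - ny;
    const long long nxp = cdf_sample(nx, ch, oh, n_max_half, 0.5, u[q + 3], fallback);
    const long long nyp = cdf_sample(ny, ch, oh, n_max_half, 0.5, u[q + 4], fallback);
    const long long nzp = cdf_sample(nz, ch, oh, n_max_half, 0.5, u[q + 5], fallback);
    q += 6;
    out[idx] -= (double)nd;
    const int ip = (i + 1) % n1, im = (i + n1 - 1) % n1;
    const int jp = (j + 1) % n2, jm = (j + n2 - 1) % n2;
    const int kp = (k + 1) % n3, km = (k + n3 - 1) % n3;
    out[ip + j * n1 + k * n1 * n2] += (double)nxp;
    out[im + j * n1 + k * n1 * n2] += (double)(nx - nxp);
    out[i + jp * n1 + k * n1 * n2] += (double)nyp;
    out[i + jm * n1 + k * n1 * n2] += (double)(ny - nyp);
    out[i + j * n1 + kp * n1 * n2] += (double)nzp;
    out[i + j * n1 + km * n1 * n2] += (double)(nz - nzp);
  }
  return out;
}

// Vectorized lookup-table binomial sampling (exposed for the sampler API and
// goodness-of-fit tests).
// [[Rcpp::export]]
NumericVector cpp_sample_binomial(NumericVector n,
                                  NumericVector cdf, IntegerVector off,
                                  int n_max, double p,
                                  NumericVector u, bool fallback) {
  if (n.size() != u.size()) stop("n and u must have equal length");
  NumericVector out(n.size());
  const double* c = REAL(cdf);
  const int* o = INTEGER(off);
  for (R_xlen_t i = 0; i < n.size(); ++i)
    out[i] = (double)cdf_sample((long long)n[i], c, o, n_max, p, u[i], fallback);
  return out;
}
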