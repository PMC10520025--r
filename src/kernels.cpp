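#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hot paths of the Metropolis-within-Gibbs sampler.
//
// Distance data come in two layouts chosen for access pattern:
//  * a CSR neighbor structure by habitat cell (nb_ptr / nb_idx / nb_d2):
//    for each cell, the detectors within the precomputed neighbor radius,
//    sorted by distance, with squared distances stored contiguously;
//  * d2t, the dense J x C matrix of squared distances (detectors in rows),
//    used for the few per-detection lookups.
// Detection probability is p = p0eff[j] * hn, hn = exp(-d2 / (2 sigma^2)),
// truncated to zero beyond radius2 (local evaluation of the state space).
// The half-normal factor hn depends only on sigma and the radius, so it is
// computed once per sigma value (cpp_halfnormal) and reused across the
// baseline-detection and effort proposals. Binomial coefficients are omitted
// throughout: they are constant in every sampled quantity.

static inline double pdet(double d2v, double p0e, double s2) {
  return p0e * std::exp(-d2v / (2.0 * s2));
}

// half-normal factor per CSR entry; entries beyond radius2 are exactly 0,
// and within each cell's (distance-sorted) segment the scan stops early
// [[Rcpp::export]]
NumericVector cpp_halfnormal(IntegerVector nb_ptr, NumericVector nb_d2,
                             double sigma, double radius2) {
  double s2 = sigma * sigma;
  int C = nb_ptr.size() - 1;
  NumericVector hn(nb_d2.size());   // zero-initialized
  for (int c = 0; c < C; ++c)
    for (int k = nb_ptr[c]; k < nb_ptr[c + 1]; ++k) {
      if (nb_d2[k] > radius2) break;
      hn[k] = std::exp(-nb_d2[k] / (2.0 * s2));
    }
  return hn;
}

// log(1-p) detection mass of an all-zero encounter history at one cell;
// hn is distance-sorted within the cell segment, so hn == 0 ends the scan
static inline double zerolik_cell(int c, const IntegerVector& nb_ptr,
                                  const IntegerVector& nb_idx,
                                  const NumericVector& hn,
                                  const NumericVector& p0eff,
                                  const IntegerVector& K) {
  double acc = 0.0;
  for (int k = nb_ptr[c]; k < nb_ptr[c + 1]; ++k) {
    if (hn[k] == 0.0) break;
    double p = p0eff[nb_idx[k]] * hn[k];
    // 8-term series for small p: truncation error p^9/9 < 3e-13 at the
    // branch point, far below the Monte Carlo resolution of the sampler
    double l1p = (p < 0.05)
      ? -p * (1.0 + p * (1.0 / 2 + p * (1.0 / 3 + p * (1.0 / 4 + p * (1.0 / 5
             + p * (1.0 / 6 + p * (1.0 / 7 + p * (1.0 / 8))))))))
      : std::log1p(-p);
    acc += K[nb_idx[k]] * l1p;
  }
  return acc;
}

// sum over an individual's detections of y * (log p - log(1-p)); -Inf if any
// detection lies beyond the truncation radius
static inline double det_extra(int c, const NumericMatrix& d2t,
                               const NumericVector& p0eff, double s2,
                               double radius2, int lo, int hi,
                               const IntegerVector& trip_j,
                               const NumericVector& trip_y) {
  double acc = 0.0;
  for (int k = lo; k < hi; ++k) {
    int j = trip_j[k];
    double dd = d2t(j, c);
    if (dd > radius2) return R_NegInf;
    double p = pdet(dd, p0eff[j], s2);
    acc += trip_y[k] * (std::log(p) - std::log1p(-p));
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_zerolik_all(IntegerVector nb_ptr, IntegerVector nb_idx,
                              NumericVector hn, NumericVector p0eff,
                              IntegerVector K, int C) {
  NumericVector out(C);
  for (int c = 0; c < C; ++c)
    out[c] = zerolik_cell(c, nb_ptr, nb_idx, hn, p0eff, K);
  return out;
}

// Encounter log-likelihood (up to binomial constants) of the detected
// individuals at their current cells: per-individual all-zero mass plus the
// detection terms (CSR det_ptr into trip_j / trip_y).
// [[Rcpp::export]]
double cpp_ll_det(NumericMatrix d2t, IntegerVector nb_ptr, IntegerVector nb_idx,
                  NumericVector hn, NumericVector p0eff, double sigma,
                  double radius2, IntegerVector K, IntegerVector cells,
                  IntegerVector det_ptr, IntegerVector trip_j,
                  NumericVector trip_y) {
  double s2 = sigma * sigma;
  double tot = 0.0;
  for (int i = 0; i < cells.size(); ++i) {
    int c = cells[i] - 1;
    tot += zerolik_cell(c, nb_ptr, nb_idx, hn, p0eff, K);
    double ex = det_extra(c, d2t, p0eff, s2, radius2, det_ptr[i],
                          det_ptr[i + 1], trip_j, trip_y);
    if (!std::isfinite(ex)) return R_NegInf;
    tot += ex;
  }
  return tot;
}

// Per-individual encounter log-likelihood of the detected individuals at
// their current cells, under female (col 0) and male (col 1) parameters,
// with precomputed full-cell zerolik vectors.
// [[Rcpp::export]]
NumericMatrix cpp_ll_det_bysex(NumericMatrix d2t, NumericVector zerolikF,
                               NumericVector zerolikM, NumericVector p0effF,
                               NumericVector p0effM, double sigmaF,
                               double sigmaM, double radius2F, double radius2M,
                               IntegerVector cells, IntegerVector det_ptr,
                               IntegerVector trip_j, NumericVector trip_y) {
  int n = cells.size();
  NumericMatrix out(n, 2);
  double s2F = sigmaF * sigmaF, s2M = sigmaM * sigmaM;
  for (int i = 0; i < n; ++i) {
    int c = cells[i] - 1;
    out(i, 0) = zerolikF[c] + det_extra(c, d2t, p0effF, s2F, radius2F,
                                        det_ptr[i], det_ptr[i + 1], trip_j, trip_y);
    out(i, 1) = zerolikM[c] + det_extra(c, d2t, p0effM, s2M, radius2M,
                                        det_ptr[i], det_ptr[i + 1], trip_j, trip_y);
  }
  return out;
}

// Categorical Gibbs draw of the activity-center cell of each detected
// individual. Candidate lists (CSR, 1-based cell ids) are sorted by distance
// to the individual's detection centroid, with squared distances in cand_d2;
// any feasible cell lies within the truncation radius of the centroid, so
// the scan stops there. u holds one uniform per individual. Returns -1 when
// no candidate has positive posterior mass.
// [[Rcpp::export]]
IntegerVector cpp_sample_s_detected(NumericMatrix d2t, NumericVector zerolikF,
                                    NumericVector zerolikM,
                                    NumericVector logpiF, NumericVector logpiM,
                                    NumericVector p0effF, NumericVector p0effM,
                                    double sigmaF, double sigmaM,
                                    double radius2F, double radius2M,
                                    IntegerVector sex, IntegerVector cand_ptr,
                                    IntegerVector cand_idx, NumericVector cand_d2,
                                    IntegerVector det_ptr,
                                    IntegerVector trip_j, NumericVector trip_y,
                                    NumericVector u) {
  int n = sex.size();
  IntegerVector out(n);
  double s2F = sigmaF * sigmaF, s2M = sigmaM * sigmaM;
  std::vector<double> w;
  for (int i = 0; i < n; ++i) {
    bool male = sex[i] == 1;
    const NumericVector& zl = male ? zerolikM : zerolikF;
    const NumericVector& lp = male ? logpiM : logpiF;
    const NumericVector& p0e = male ? p0effM : p0effF;
    double s2 = male ? s2M : s2F;
    double r2 = male ? radius2M : radius2F;
    int lo = cand_ptr[i], hi = cand_ptr[i + 1];
    int m = 0;
    w.assign(hi - lo, 0.0);
    double mx = R_NegInf;
    for (int k = lo; k < hi; ++k) {
      if (cand_d2[k] > r2) break;      // sorted: no feasible cell further out
      int c = cand_idx[k] - 1;
      double ex = det_extra(c, d2t, p0e, s2, r2, det_ptr[i], det_ptr[i + 1],
                            trip_j, trip_y);
      double v = lp[c] + zl[c] + ex;
      w[m++] = v;
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx)) { out[i] = -1; continue; }
    double tot = 0.0;
    for (int k = 0; k < m; ++k) {
      w[k] = std::isfinite(w[k]) ? std::exp(w[k] - mx) : 0.0;
      tot += w[k];
    }
    double target = u[i] * tot, run = 0.0;
    int pick = -1;
    for (int k = 0; k < m; ++k) {
      run += w[k];
      if (run >= target) { pick = cand_idx[lo + k]; break; }
    }
    if (pick < 0) pick = cand_idx[lo + m - 1];
    out[i] = pick;
  }
  return out;
}
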