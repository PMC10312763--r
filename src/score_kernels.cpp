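// Fast kernels for the six restraint terms. Each has a brute-force R oracle
// in the test suite; the kernels exist because the replica-exchange sampler
// evaluates the full score once per Monte Carlo proposal.
#include <Rcpp.h>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// Excluded volume: sum over precomputed pairs of k * max(0, r_i+r_j - d)^2
// [[Rcpp::export]]
double ev_score_cpp(const NumericMatrix& coords, const NumericVector& radii,
                    const IntegerVector& pi_, const IntegerVector& pj_,
                    double k) {
  double s = 0.0;
  const int n = pi_.size();
  for (int p = 0; p < n; ++p) {
    const int i = pi_[p] - 1, j = pj_[p] - 1;
    const double dx = coords(i, 0) - coords(j, 0);
    const double dy = coords(i, 1) - coords(j, 1);
    const double dz = coords(i, 2) - coords(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double o = radii[i] + radii[j] - d;
    if (o > 0.0) s += k * o * o;
  }
  return s;
}

// Sequence connectivity: harmonic upper bound above per-pair thresholds
// [[Rcpp::export]]
double conn_score_cpp(const NumericMatrix& coords, const IntegerVector& pi_,
                      const IntegerVector& pj_, const NumericVector& thr,
                      double k) {
  double s = 0.0;
  const int n = pi_.size();
  for (int p = 0; p < n; ++p) {
    const int i = pi_[p] - 1, j = pj_[p] - 1;
    const double dx = coords(i, 0) - coords(j, 0);
    const double dy = coords(i, 1) - coords(j, 1);
    const double dz = coords(i, 2) - coords(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double e = d - thr[p];
    if (e > 0.0) s += k * e * e;
  }
  return s;
}

// Cylinder confinement: k * max(0, rho - radius)^2 over listed beads
// [[Rcpp::export]]
double cyl_score_cpp(const NumericMatrix& coords, const IntegerVector& idx,
                     double radius, double k) {
  double s = 0.0;
  for (int p = 0; p < idx.size(); ++p) {
    const int i = idx[p] - 1;
    const double rho = std::sqrt(sq(coords(i, 0)) + sq(coords(i, 1)));
    const double e = rho - radius;
    if (e > 0.0) s += k * e * e;
  }
  return s;
}

// Bayesian EM term for one layer. Model beads (idx, weights bw, sigma=radius)
// against data components (mu K x 3, sigma ds, weights dw). For component k:
//   0.5 * (log(ov_MD,k / ov_DD,k))^2 / sigma_em^2,
// capped at `cap` when ov_MD,k underflows to zero.
// [[Rcpp::export]]
double em_score_cpp(const NumericMatrix& coords, const NumericVector& radii,
                    const IntegerVector& idx, const NumericVector& bw,
                    const NumericMatrix& mu, const NumericVector& ds,
                    const NumericVector& ovdd, double sigma_em, double cap) {
  const double two_pi = 2.0 * M_PI;
  double s = 0.0;
  for (int k = 0; k < mu.nrow(); ++k) {
    double ovmd = 0.0;
    for (int p = 0; p < idx.size(); ++p) {
      const int i = idx[p] - 1;
      const double v = sq(radii[i]) + sq(ds[k]);
      const double dx = coords(i, 0) - mu(k, 0);
      const double dy = coords(i, 1) - mu(k, 1);
      const double dz = coords(i, 2) - mu(k, 2);
      ovmd += bw[p] * std::pow(two_pi * v, -1.5) *
        std::exp(-(dx * dx + dy * dy + dz * dz) / (2.0 * v));
    }
    if (ovmd <= 0.0) { s += cap; continue; }
    const double lr = std::log(ovmd / ovdd[k]);
    double term = 0.5 * lr * lr / sq(sigma_em);
    if (term > cap) term = cap;
    s += term;
  }
  return s;
}

// Minimum surface-to-surface distance between two bead index sets
// [[Rcpp::export]]
double min_surface_dist_cpp(const NumericMatrix& coords,
                            const NumericVector& radii,
                            const IntegerVector& ia, const IntegerVector& ib) {
  double best = R_PosInf;
  for (int a = 0; a < ia.size(); ++a) {
    const int i = ia[a] - 1;
    for (int b = 0; b < ib.size(); ++b) {
      const int j = ib[b] - 1;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) -
        radii[i] - radii[j];
      if (d < best) best = d;
    }
  }
  return best;
}

// Immuno-EM term for one record: per listed copy (rows per copy given as a
// list of index vectors), pick the bead whose z is closest to `mean_d` and add
// 0.5 * ((z - mean_d)/sem)^2.
// [[Rcpp::export]]
double immuno_score_cpp(const NumericMatrix& coords, const List& copy_idx,
                        double mean_d, double sem) {
  double s = 0.0;
  for (int c = 0; c < copy_idx.size(); ++c) {
    IntegerVector ix = copy_idx[c];
    double best = R_PosInf, zbest = 0.0;
    for (int p = 0; p < ix.size(); ++p) {
      const double z = coords(ix[p] - 1, 2);
      const double d = std::fabs(z - mean_d);
      if (d < best) { best = d; zbest = z; }
    }
    s += 0.5 * sq((zbest - mean_d) / sem);
  }
  return s;
}
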