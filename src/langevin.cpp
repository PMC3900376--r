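// Compiled inner loop for the overdamped Langevin sampler. The R force
// engine (system_forces) is the reference implementation; cpp_forces must
// agree with it to numerical precision (tested), and cpp_langevin_run uses
// R's RNG stream so ensembles are an exact function of set.seed().
//
// Supported terms: harmonic bonds/springs, harmonic angles, plain-cutoff
// Coulomb and 12-6 Lennard-Jones over a fixed candidate pair list with
// separate Coulomb and LJ cutoffs. Systems with dihedrals fall back to the
// R integrator.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void add_forces(NumericMatrix &f,
                       const IntegerVector &bi, const IntegerVector &bj,
                       const NumericVector &kb, const NumericVector &r0,
                       const IntegerVector &ai, const IntegerVector &aj,
                       const IntegerVector &ak, const NumericVector &kth,
                       const NumericVector &th0,
                       const IntegerVector &pi_, const IntegerVector &pj_,
                       const NumericVector &qq, const NumericVector &sig,
                       const NumericVector &eps,
                       double cutoff, double lj_cutoff,
                       const NumericMatrix &x) {
  const int nb = bi.size(), na = ai.size(), np = pi_.size();
  std::fill(f.begin(), f.end(), 0.0);
  for (int b = 0; b < nb; ++b) {
    int i = bi[b] - 1, j = bj[b] - 1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double c = -kb[b] * (r - r0[b]) / r;  // force on i along +d
    f(i,0) += c*dx; f(i,1) += c*dy; f(i,2) += c*dz;
    f(j,0) -= c*dx; f(j,1) -= c*dy; f(j,2) -= c*dz;
  }
  for (int a = 0; a < na; ++a) {
    int i = ai[a]-1, j = aj[a]-1, k = ak[a]-1;
    double ux = x(i,0)-x(j,0), uy = x(i,1)-x(j,1), uz = x(i,2)-x(j,2);
    double vx = x(k,0)-x(j,0), vy = x(k,1)-x(j,1), vz = x(k,2)-x(j,2);
    double lu = std::sqrt(ux*ux+uy*uy+uz*uz), lv = std::sqrt(vx*vx+vy*vy+vz*vz);
    ux /= lu; uy /= lu; uz /= lu; vx /= lv; vy /= lv; vz /= lv;
    double ct = ux*vx + uy*vy + uz*vz;
    if (ct > 1) ct = 1; if (ct < -1) ct = -1;
    double st = std::sqrt(std::max(1 - ct*ct, 1e-24));
    double theta = std::acos(ct);
    double coef = -kth[a] * (theta - th0[a]);  // th0 in radians
    double dix = (ct*ux - vx)/(lu*st), diy = (ct*uy - vy)/(lu*st),
           diz = (ct*uz - vz)/(lu*st);
    double dkx = (ct*vx - ux)/(lv*st), dky = (ct*vy - uy)/(lv*st),
           dkz = (ct*vz - uz)/(lv*st);
    f(i,0) += coef*dix; f(i,1) += coef*diy; f(i,2) += coef*diz;
    f(k,0) += coef*dkx; f(k,1) += coef*dky; f(k,2) += coef*dkz;
    f(j,0) -= coef*(dix+dkx); f(j,1) -= coef*(diy+dky); f(j,2) -= coef*(diz+dkz);
  }
  for (int p = 0; p < np; ++p) {
    int i = pi_[p]-1, j = pj_[p]-1;
    double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
    double r2 = dx*dx + dy*dy + dz*dz;
    double r = std::sqrt(r2);
    double dudr = 0.0;
    if (qq[p] != 0 && r <= cutoff) dudr -= qq[p] / r2;  // qq pre-multiplied by ke
    if (eps[p] > 0 && r <= lj_cutoff) {
      double sr2 = sig[p]*sig[p]/r2;
      double sr6 = sr2*sr2*sr2;
      dudr += 4 * eps[p] * (-12*sr6*sr6 + 6*sr6) / r;
    }
    if (dudr != 0) {
      double c = -dudr / r;
      f(i,0) += c*dx; f(i,1) += c*dy; f(i,2) += c*dz;
      f(j,0) -= c*dx; f(j,1) -= c*dy; f(j,2) -= c*dz;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix x, IntegerVector bi, IntegerVector bj,
                         NumericVector kb, NumericVector r0,
                         IntegerVector ai, IntegerVector aj, IntegerVector ak,
                         NumericVector kth, NumericVector th0,
                         IntegerVector pi_, IntegerVector pj_,
                         NumericVector qq, NumericVector sig,
                         NumericVector eps, double cutoff, double lj_cutoff) {
  NumericMatrix f(x.nrow(), 3);
  add_forces(f, bi, bj, kb, r0, ai, aj, ak, kth, th0, pi_, pj_, qq, sig, eps,
             cutoff, lj_cutoff, x);
  return f;
}

// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix x0, IntegerVector bi, IntegerVector bj,
                      NumericVector kb, NumericVector r0,
                      IntegerVector ai, IntegerVector aj, IntegerVector ak,
                      NumericVector kth, NumericVector th0,
                      IntegerVector pi_, IntegerVector pj_,
                      NumericVector qq, NumericVector sig, NumericVector eps,
                      double cutoff, double lj_cutoff,
                      double mobility, double noise_scale,
                      int burn_in, int n_frames, int stride) {
  const int n = x0.nrow();
  NumericMatrix x = clone(x0);
  NumericMatrix f(n, 3);
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * n * 3);
  frames.attr("dim") = IntegerVector::create(n_frames, n, 3);
  int rec = 0;
  bool diverged = false;
  const long total = static_cast<long>(burn_in) +
    static_cast<long>(n_frames) * stride;
  for (long s = 1; s <= total && !diverged; ++s) {
    add_forces(f, bi, bj, kb, r0, ai, aj, ak, kth, th0, pi_, pj_, qq, sig,
               eps, cutoff, lj_cutoff, x);
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        double nz = (noise_scale > 0) ? noise_scale * R::norm_rand() : 0.0;
        x(i,d) += f(i,d) * mobility + nz;
        if (!std::isfinite(x(i,d)) || std::fabs(x(i,d)) > 1e4) diverged = true;
      }
    }
    if (s > burn_in && (s - burn_in) % stride == 0 && rec < n_frames) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[rec + n_frames * (i + static_cast<R_xlen_t>(n) * d)] = x(i,d);
      ++rec;
    }
  }
  return List::create(_["frames"] = frames, _["diverged"] = diverged);
}
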