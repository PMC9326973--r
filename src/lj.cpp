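#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 12-6 Lennard-Jones pair kernels in reduced units.  All routines take an
// optional orthorhombic box (length-d vector, empty = free boundaries) and
// apply the minimum-image convention.  cutoff <= 0 means no cutoff.

namespace {

struct LJ {
  double eps, sig, cutoff, eshift;
  bool shifted;
  LJ(double eps_, double sig_, double cutoff_, bool shift_)
      : eps(eps_), sig(sig_), cutoff(cutoff_), eshift(0.0), shifted(false) {
    if (cutoff > 0.0 && shift_) {
      double sr6 = std::pow(sig / cutoff, 6.0);
      eshift = 4.0 * eps * sr6 * (sr6 - 1.0);
      shifted = true;
    }
  }
  inline double energy(double r2) const {
    if (cutoff > 0.0 && r2 >= cutoff * cutoff) return 0.0;
    double sr2 = sig * sig / r2;
    double sr6 = sr2 * sr2 * sr2;
    double e = 4.0 * eps * sr6 * (sr6 - 1.0);
    if (shifted) e -= eshift;
    return e;
  }
  // -phi'(r)/r: force on i is fpair * (ri - rj)
  inline double fpair(double r2) const {
    if (cutoff > 0.0 && r2 >= cutoff * cutoff) return 0.0;
    double sr2 = sig * sig / r2;
    double sr6 = sr2 * sr2 * sr2;
    return 24.0 * eps * sr6 * (2.0 * sr6 - 1.0) / r2;
  }
  // phi''(r)
  inline double d2phi(double r2) const {
    if (cutoff > 0.0 && r2 >= cutoff * cutoff) return 0.0;
    double sr2 = sig * sig / r2;
    double sr6 = sr2 * sr2 * sr2;
    return (624.0 * sr6 * sr6 - 168.0 * sr6) * eps / r2;
  }
};

inline void min_image(double* d, int dim, const double* box) {
  if (box == nullptr) return;
  for (int k = 0; k < dim; ++k) d[k] -= box[k] * std::nearbyint(d[k] / box[k]);
}

inline const double* box_ptr(const NumericVector& box) {
  return box.size() > 0 ? &box[0] : nullptr;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_lj_energy")]]
double cpp_lj_energy(NumericMatrix pos, double eps, double sig, double cutoff,
                     bool shift, NumericVector box) {
  int n = pos.nrow(), dim = pos.ncol();
  LJ lj(eps, sig, cutoff, shift);
  const double* b = box_ptr(box);
  double e = 0.0, d[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double r2 = 0.0;
      for (int k = 0; k < dim; ++k) d[k] = pos(i, k) - pos(j, k);
      min_image(d, dim, b);
      for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
      if (r2 <= 0.0) stop("singular configuration: atoms %d and %d coincide", i + 1, j + 1);
      e += lj.energy(r2);
    }
  }
  return e;
}

// [[Rcpp::export(name = ".cpp_lj_forces")]]
NumericMatrix cpp_lj_forces(NumericMatrix pos, double eps, double sig,
                            double cutoff, bool shift, NumericVector box) {
  int n = pos.nrow(), dim = pos.ncol();
  LJ lj(eps, sig, cutoff, shift);
  const double* b = box_ptr(box);
  NumericMatrix f(n, dim);
  double d[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double r2 = 0.0;
      for (int k = 0; k < dim; ++k) d[k] = pos(i, k) - pos(j, k);
      min_image(d, dim, b);
      for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
      if (r2 <= 0.0) stop("singular configuration: atoms %d and %d coincide", i + 1, j + 1);
      double fp = lj.fpair(r2);
      for (int k = 0; k < dim; ++k) {
        f(i, k) += fp * d[k];
        f(j, k) -= fp * d[k];
      }
    }
  }
  return f;
}

// Hessian-of-V times vector v (same shape as pos).  Used by the loss gradient.
// [[Rcpp::export(name = ".cpp_lj_hvp")]]
NumericMatrix cpp_lj_hvp(NumericMatrix pos, NumericMatrix v, double eps,
                         double sig, double cutoff, bool shift,
                         NumericVector box) {
  int n = pos.nrow(), dim = pos.ncol();
  LJ lj(eps, sig, cutoff, shift);
  const double* b = box_ptr(box);
  NumericMatrix out(n, dim);
  double d[3], dv[3];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double r2 = 0.0;
      for (int k = 0; k < dim; ++k) d[k] = pos(i, k) - pos(j, k);
      min_image(d, dim, b);
      for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
      if (r2 <= 0.0) stop("singular configuration: atoms %d and %d coincide", i + 1, j + 1);
      if (lj.cutoff > 0.0 && r2 >= lj.cutoff * lj.cutoff) continue;
      for (int k = 0; k < dim; ++k) dv[k] = v(i, k) - v(j, k);
      double p2 = lj.d2phi(r2);
      double p1r = -lj.fpair(r2);  // phi'(r)/r
      // M = phi'' u u^T + (phi'/r)(I - u u^T), u = d / r
      double ddotv = 0.0;
      for (int k = 0; k < dim; ++k) ddotv += d[k] * dv[k];
      double coef = (p2 - p1r) * ddotv / r2;
      for (int k = 0; k < dim; ++k) {
        double mk = coef * d[k] + p1r * dv[k];
        out(i, k) += mk;
        out(j, k) -= mk;
      }
    }
  }
  return out;
}

// Energies and potential gradients (∇V = -forces) for F stacked frames.
// pos is an (F, N, dim) array in R layout.
// [[Rcpp::export(name = ".cpp_lj_multi")]]
List cpp_lj_multi(NumericVector pos, int nframes, int natoms, double eps,
                  double sig, double cutoff, bool shift, NumericVector box) {
  int dim = pos.size() / (nframes * natoms);
  LJ lj(eps, sig, cutoff, shift);
  const double* b = box_ptr(box);
  NumericVector energy(nframes);
  NumericVector grad(pos.size());
  double d[3];
  const double* p = &pos[0];
  double* g = &grad[0];
  long FN = (long)nframes * natoms;
  for (int f = 0; f < nframes; ++f) {
    double e = 0.0;
    for (int i = 0; i < natoms; ++i) {
      for (int j = i + 1; j < natoms; ++j) {
        double r2 = 0.0;
        for (int k = 0; k < dim; ++k)
          d[k] = p[f + (long)nframes * i + FN * k] - p[f + (long)nframes * j + FN * k];
        min_image(d, dim, b);
        for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
        if (r2 <= 0.0)
          stop("singular configuration in frame %d: atoms %d and %d coincide",
               f + 1, i + 1, j + 1);
        e += lj.energy(r2);
        double fp = lj.fpair(r2);
        for (int k = 0; k < dim; ++k) {
          g[f + (long)nframes * i + FN * k] -= fp * d[k];
          g[f + (long)nframes * j + FN * k] += fp * d[k];
        }
      }
    }
    energy[f] = e;
  }
  return List::create(_["energy"] = energy, _["grad"] = grad);
}

// Hessian-vector products for F stacked frames (pos and v are (F, N, dim)).
// [[Rcpp::export(name = ".cpp_lj_multi_hvp")]]
NumericVector cpp_lj_multi_hvp(NumericVector pos, NumericVector v, int nframes,
                               int natoms, double eps, double sig,
                               double cutoff, bool shift, NumericVector box) {
  int dim = pos.size() / (nframes * natoms);
  LJ lj(eps, sig, cutoff, shift);
  const double* b = box_ptr(box);
  NumericVector out(pos.size());
  double d[3], dv[3];
  const double* p = &pos[0];
  const double* vv = &v[0];
  double* o = &out[0];
  long FN = (long)nframes * natoms;
  for (int f = 0; f < nframes; ++f) {
    for (int i = 0; i < natoms; ++i) {
      for (int j = i + 1; j < natoms; ++j) {
        double r2 = 0.0;
        for (int k = 0; k < dim; ++k)
          d[k] = p[f + (long)nframes * i + FN * k] - p[f + (long)nframes * j + FN * k];
        min_image(d, dim, b);
        for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
        if (r2 <= 0.0)
          stop("singular configuration in frame %d: atoms %d and %d coincide",
               f + 1, i + 1, j + 1);
        if (lj.cutoff > 0.0 && r2 >= lj.cutoff * lj.cutoff) continue;
        for (int k = 0; k < dim; ++k)
          dv[k] = vv[f + (long)nframes * i + FN * k] - vv[f + (long)nframes * j + FN * k];
        double p2 = lj.d2phi(r2);
        double p1r = -lj.fpair(r2);
        double ddotv = 0.0;
        for (int k = 0; k < dim; ++k) ddotv += d[k] * dv[k];
        double coef = (p2 - p1r) * ddotv / r2;
        for (int k = 0; k < dim; ++k) {
          double mk = coef * d[k] + p1r * dv[k];
          o[f + (long)nframes * i + FN * k] += mk;
          o[f + (long)nframes * j + FN * k] -= mk;
        }
      }
    }
  }
  return out;
}

// Velocity-Verlet NVE integrator.  Records every `stride` steps (frame 0
// included); n_steps must be a multiple of stride (checked in R).
// [[Rcpp::export(name = ".cpp_verlet")]]
List cpp_verlet(NumericMatrix q0, NumericMatrix v0, NumericVector mass,
                double dt, int n_steps, int stride, double eps, double sig,
                double cutoff, bool shift, NumericVector box) {
  int n = q0.nrow(), dim = q0.ncol();
  LJ lj(eps, sig, cutoff, shift);
  const double* b = box_ptr(box);
  int nf = n_steps / stride + 1;
  NumericVector qs((long)nf * n * dim), vs((long)nf * n * dim);
  NumericMatrix q = clone(q0), v = clone(v0), f(n, dim);
  double d[3];
  long FN = (long)nf * n;

  auto compute_forces = [&](NumericMatrix& qq, NumericMatrix& ff, int step) {
    std::fill(ff.begin(), ff.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double r2 = 0.0;
        for (int k = 0; k < dim; ++k) d[k] = qq(i, k) - qq(j, k);
        min_image(d, dim, b);
        for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
        if (r2 <= 0.0)
          stop("integration unstable at step %d: atoms %d and %d coincide",
               step, i + 1, j + 1);
        double fp = lj.fpair(r2);
        for (int k = 0; k < dim; ++k) {
          ff(i, k) += fp * d[k];
          ff(j, k) -= fp * d[k];
        }
      }
    }
  };

  auto record = [&](int frame) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < dim; ++k) {
        qs[frame + (long)nf * i + FN * k] = q(i, k);
        vs[frame + (long)nf * i + FN * k] = v(i, k);
      }
  };

  compute_forces(q, f, 0);
  record(0);
  int frame = 1;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < dim; ++k) {
        v(i, k) += 0.5 * dt * f(i, k) / mass[i];
        q(i, k) += dt * v(i, k);
      }
    compute_forces(q, f, s);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < dim; ++k) v(i, k) += 0.5 * dt * f(i, k) / mass[i];
    if (s % stride == 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < dim; ++k)
          if (!std::isfinite(q(i, k)))
            stop("integration diverged at step %d (non-finite coordinate)", s);
      record(frame++);
    }
  }
  qs.attr("dim") = IntegerVector::create(nf, n, dim);
  vs.attr("dim") = IntegerVector::create(nf, n, dim);
  return List::create(_["positions"] = qs, _["velocities"] = vs);
}

// Pair-distance histogram over stacked frames, for g(r).
// [[Rcpp::export(name = ".cpp_pair_histogram")]]
NumericVector cpp_pair_histogram(NumericVector pos, int nframes, int natoms,
                                 double r_max, int n_bins, NumericVector box) {
  int dim = pos.size() / (nframes * natoms);
  const double* b = box_ptr(box);
  NumericVector counts(n_bins);
  double d[3];
  const double* p = &pos[0];
  long FN = (long)nframes * natoms;
  double w = r_max / n_bins;
  for (int f = 0; f < nframes; ++f) {
    for (int i = 0; i < natoms; ++i) {
      for (int j = i + 1; j < natoms; ++j) {
        double r2 = 0.0;
        for (int k = 0; k < dim; ++k)
          d[k] = p[f + (long)nframes * i + FN * k] - p[f + (long)nframes * j + FN * k];
        min_image(d, dim, b);
        for (int k = 0; k < dim; ++k) r2 += d[k] * d[k];
        double r = std::sqrt(r2);
        if (r < r_max) counts[(int)(r / w)] += 2.0;  // both orderings
      }
    }
  }
  return counts;
}
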