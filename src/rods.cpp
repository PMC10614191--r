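// Compiled kernels for spherocylinder geometry, Metropolis Monte Carlo and
// Widom test-particle insertion.  All lengths are in the caller's units; a
// rod is a line segment of half-length h plus a hard-core diameter handled by
// the caller (overlap means segment-segment distance < diameter).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// minimum-image component
static inline double mi(double x, double b) {
  return x - b * std::nearbyint(x / b);
}

// Closest distance between two segments of half-length h with centre
// separation w = r1 - r2 (already minimum-imaged) and unit axes u1, u2.
// Vega-Lago style: clamp the most violated parameter, re-minimise the other,
// back-substitute; both clamp orders are tried and the smaller distance kept.
// Also reports |u1 x u2|.
static void seg_pair(const double *w, const double *u1, const double *u2,
                     double h, double &x, double &sint) {
  double b = u1[0] * u2[0] + u1[1] * u2[1] + u1[2] * u2[2];
  double p = u1[0] * w[0] + u1[1] * w[1] + u1[2] * w[2];
  double q = u2[0] * w[0] + u2[1] * w[1] + u2[2] * w[2];
  double denom = 1.0 - b * b;
  double cx = u1[1] * u2[2] - u1[2] * u2[1];
  double cy = u1[2] * u2[0] - u1[0] * u2[2];
  double cz = u1[0] * u2[1] - u1[1] * u2[0];
  double s2 = cx * cx + cy * cy + cz * cz;
  sint = s2 > 0 ? std::sqrt(s2 > 1.0 ? 1.0 : s2) : 0.0;

  if (denom < 1e-12) {
    // parallel rods: axial gap plus fixed perpendicular offset
    double w2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
    double ax = std::fabs(p) - 2.0 * h;
    if (ax < 0) ax = 0;
    double per2 = w2 - p * p;
    if (per2 < 0) per2 = 0;
    x = std::sqrt(per2 + ax * ax);
    return;
  }
  // stationary point of |w + s u1 - t u2|^2: s = t b - p, t = q + s b
  double s0 = (q * b - p) / denom;
  double t0 = (q - p * b) / denom;
  double best = R_PosInf;
  for (int order = 0; order < 2; ++order) {
    double s = s0, t = t0;
    if (std::fabs(s) > h || std::fabs(t) > h) {
      bool s_first = (std::fabs(s) - h) > (std::fabs(t) - h);
      if (order == 1) s_first = !s_first;
      if (s_first) {
        s = std::max(-h, std::min(h, s));
        t = std::max(-h, std::min(h, q + s * b));
        s = std::max(-h, std::min(h, t * b - p));
      } else {
        t = std::max(-h, std::min(h, t));
        s = std::max(-h, std::min(h, t * b - p));
        t = std::max(-h, std::min(h, q + s * b));
      }
    }
    double dx = w[0] + s * u1[0] - t * u2[0];
    double dy = w[1] + s * u1[1] - t * u2[1];
    double dz = w[2] + s * u1[2] - t * u2[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best) best = d2;
    if (std::fabs(s0) <= h && std::fabs(t0) <= h) break; // interior optimum
  }
  x = std::sqrt(best);
}

static void pair_geom(const double *r1, const double *u1, const double *r2,
                      const double *u2, double h, const double *box,
                      bool pbc, double &x, double &sint) {
  double w[3];
  for (int k = 0; k < 3; ++k) {
    w[k] = r1[k] - r2[k];
    if (pbc) w[k] = mi(w[k], box[k]);
  }
  seg_pair(w, u1, u2, h, x, sint);
}

// truncated-shifted screened-Coulomb pair energy (k_B T units); x >= D
// assumed checked by caller (hard core handled separately)
static inline double soft_u(double x, double sint, double Ap, double kappa,
                            double D, double dc, double sfloor) {
  if (Ap <= 0.0 || x >= dc) return 0.0;
  double s = sint < sfloor ? sfloor : sint;
  return Ap * (std::exp(-kappa * (x - D)) - std::exp(-kappa * (dc - D))) / s;
}

// [[Rcpp::export]]
NumericVector cpp_pair_geom(NumericVector r1, NumericVector u1,
                            NumericVector r2, NumericVector u2, double h,
                            NumericVector box, bool pbc) {
  double x, sint;
  pair_geom(r1.begin(), u1.begin(), r2.begin(), u2.begin(), h, box.begin(),
            pbc, x, sint);
  return NumericVector::create(x, sint);
}

// distances (x, sin theta) from one rod (r, u) to every rod in the
// configuration; row `exclude` (1-based; 0 = none) is set to (Inf, 0)
// [[Rcpp::export]]
NumericMatrix cpp_rod_vs_all(NumericMatrix centers, NumericMatrix us,
                             NumericVector r, NumericVector u, double h,
                             NumericVector box, int exclude) {
  int n = centers.nrow();
  NumericMatrix out(n, 2);
  double rj[3], uj[3], x, sint;
  for (int j = 0; j < n; ++j) {
    if (j == exclude - 1) {
      out(j, 0) = R_PosInf;
      out(j, 1) = 0.0;
      continue;
    }
    for (int k = 0; k < 3; ++k) {
      rj[k] = centers(j, k);
      uj[k] = us(j, k);
    }
    pair_geom(r.begin(), u.begin(), rj, uj, h, box.begin(), true, x, sint);
    out(j, 0) = x;
    out(j, 1) = sint;
  }
  return out;
}

// energy of rod i (1-based) against all others; Inf on hard-core overlap
// core_penalty <= 0: hard core (overlap -> Inf); > 0: finite linear
// overlap penalty used only to anneal random starting configurations
static double rod_energy(const NumericMatrix &centers, const NumericMatrix &us,
                         int i, const double *r, const double *u, double h,
                         const double *box, double Ap, double kappa, double D,
                         double dc, double sfloor, double core_penalty) {
  int n = centers.nrow();
  double e = 0.0, x, sint, rj[3], uj[3];
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    for (int k = 0; k < 3; ++k) {
      rj[k] = centers(j, k);
      uj[k] = us(j, k);
    }
    pair_geom(r, u, rj, uj, h, box, true, x, sint);
    if (x < D) {
      if (core_penalty <= 0.0) return R_PosInf;
      e += core_penalty * (0.1 + (D - x) / D);
      continue;
    }
    e += soft_u(x, sint, Ap, kappa, D, dc, sfloor);
  }
  return e;
}

// [[Rcpp::export]]
List cpp_total_energy(NumericMatrix centers, NumericMatrix us, double h,
                      NumericVector box, double Ap, double kappa, double D,
                      double dc, double sfloor) {
  int n = centers.nrow();
  double e = 0.0, minx = R_PosInf, x, sint, ri[3], ui[3], rj[3], uj[3];
  bool overlap = false;
  long n_overlap = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int k = 0; k < 3; ++k) {
      ri[k] = centers(i, k);
      ui[k] = us(i, k);
    }
    for (int j = i + 1; j < n; ++j) {
      for (int k = 0; k < 3; ++k) {
        rj[k] = centers(j, k);
        uj[k] = us(j, k);
      }
      pair_geom(ri, ui, rj, uj, h, box.begin(), true, x, sint);
      if (x < minx) minx = x;
      if (x < D) { overlap = true; ++n_overlap; }
      else e += soft_u(x, sint, Ap, kappa, D, dc, sfloor);
    }
  }
  return List::create(_["energy"] = overlap ? R_PosInf : e,
                      _["min_x"] = minx, _["overlap"] = overlap,
                      _["n_overlap"] = (double)n_overlap);
}

// Metropolis sweeps: one sweep = N single-particle trial moves, each a
// translation or a rotation of a uniformly chosen rod.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_run_sweeps(NumericMatrix centers_, NumericMatrix us_, double h,
                    NumericVector box, double Ap, double kappa, double D,
                    double dc, double sfloor, int nsweeps, double max_disp,
                    double max_rot, double p_trans, double core_penalty) {
  NumericMatrix centers = clone(centers_), us = clone(us_);
  int n = centers.nrow();
  double dE = 0.0;
  long acc_t = 0, try_t = 0, acc_r = 0, try_r = 0;
  double rn[3], un[3];
  for (int sw = 0; sw < nsweeps; ++sw) {
    for (int m = 0; m < n; ++m) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      double rold[3], uold[3];
      for (int k = 0; k < 3; ++k) {
        rold[k] = centers(i, k);
        uold[k] = us(i, k);
      }
      bool trans = unif_rand() < p_trans;
      if (trans) {
        ++try_t;
        for (int k = 0; k < 3; ++k) {
          rn[k] = rold[k] + max_disp * (2.0 * unif_rand() - 1.0);
          rn[k] -= box[k] * std::floor(rn[k] / box[k]);
          un[k] = uold[k];
        }
      } else {
        ++try_r;
        // rotate u about a random axis by a uniform angle in (-max_rot, max_rot)
        double a[3], nrm = 0.0;
        for (int k = 0; k < 3; ++k) {
          a[k] = norm_rand();
          nrm += a[k] * a[k];
        }
        nrm = std::sqrt(nrm);
        for (int k = 0; k < 3; ++k) a[k] /= nrm;
        double ang = max_rot * (2.0 * unif_rand() - 1.0);
        double c = std::cos(ang), s = std::sin(ang);
        double ad = a[0] * uold[0] + a[1] * uold[1] + a[2] * uold[2];
        double cr[3] = {a[1] * uold[2] - a[2] * uold[1],
                        a[2] * uold[0] - a[0] * uold[2],
                        a[0] * uold[1] - a[1] * uold[0]};
        nrm = 0.0;
        for (int k = 0; k < 3; ++k) {
          un[k] = uold[k] * c + cr[k] * s + a[k] * ad * (1.0 - c);
          nrm += un[k] * un[k];
        }
        nrm = std::sqrt(nrm);
        for (int k = 0; k < 3; ++k) {
          un[k] /= nrm;
          rn[k] = rold[k];
        }
      }
      double enew = rod_energy(centers, us, i, rn, un, h, box.begin(), Ap,
                               kappa, D, dc, sfloor, core_penalty);
      if (!R_finite(enew)) continue; // hard-core overlap: reject
      double eold = rod_energy(centers, us, i, rold, uold, h, box.begin(), Ap,
                               kappa, D, dc, sfloor, core_penalty);
      double du = enew - eold;
      if (du <= 0.0 || unif_rand() < std::exp(-du)) {
        for (int k = 0; k < 3; ++k) {
          centers(i, k) = rn[k];
          us(i, k) = un[k];
        }
        dE += du;
        if (trans) ++acc_t; else ++acc_r;
      }
    }
  }
  return List::create(
      _["centers"] = centers, _["us"] = us, _["dE"] = dE,
      _["acc_trans"] = try_t ? (double)acc_t / try_t : NA_REAL,
      _["acc_rot"] = try_r ? (double)acc_r / try_r : NA_REAL,
      _["n_trans"] = (double)try_t, _["n_rot"] = (double)try_r);
}

// Widom insertion trials on a single configuration.  Counts successes of the
// hard-overlap test at diameter Deff and (optionally) accumulates the
// Boltzmann factor exp(-dU) of the truncated-shifted interaction with hard
// core at diameter D.  Both observables share the same trial stream.
// [[Rcpp::export]]
List cpp_widom(NumericMatrix centers, NumericMatrix us, double h,
               NumericVector box, double ntrials, double Deff, double Ap,
               double kappa, double D, double dc, double sfloor,
               bool do_ref) {
  int n = centers.nrow();
  long long nt = (long long)ntrials;
  long long ns = 0, nhard = 0;
  double sum_w = 0.0, sum_w2 = 0.0;
  double r[3], u[3], uj[3], x, sint;
  double reach = 2.0 * h + std::max(Deff, do_ref ? dc : D);
  for (long long t = 0; t < nt; ++t) {
    for (int k = 0; k < 3; ++k) r[k] = unif_rand() * box[k];
    double nrm = 0.0;
    for (int k = 0; k < 3; ++k) {
      u[k] = norm_rand();
      nrm += u[k] * u[k];
    }
    nrm = std::sqrt(nrm);
    for (int k = 0; k < 3; ++k) u[k] /= nrm;
    bool ok = true, hard_ok = true;
    double e = 0.0;
    for (int j = 0; j < n; ++j) {
      double w[3], cd2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        w[k] = mi(r[k] - centers(j, k), box[k]);
        cd2 += w[k] * w[k];
      }
      if (cd2 > reach * reach) continue; // segments cannot come closer
      for (int k = 0; k < 3; ++k) uj[k] = us(j, k);
      seg_pair(w, u, uj, h, x, sint);
      if (x < Deff) ok = false;
      if (x < D) {
        hard_ok = false;
        break; // Boltzmann weight is 0 and (Deff >= D) insertion failed
      }
      if (do_ref) e += soft_u(x, sint, Ap, kappa, D, dc, sfloor);
      if (!do_ref && !ok) break;
    }
    if (ok) ++ns;
    if (hard_ok) {
      ++nhard;
      if (do_ref) {
        double wgt = std::exp(-e);
        sum_w += wgt;
        sum_w2 += wgt * wgt;
      }
    }
  }
  return List::create(_["n_trials"] = (double)nt, _["n_success"] = (double)ns,
                      _["n_hard_ok"] = (double)nhard, _["sum_w"] = sum_w,
                      _["sum_w2"] = sum_w2);
}
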