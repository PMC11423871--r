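// Hard-ellipse overlap tests and Metropolis Monte Carlo for metaphase-plate
// configurations. Overlap detection uses the Perram-Wertheim contact
// function, the standard exact criterion from the hard-ellipsoid simulation
// literature: for ellipses with shape matrices X1, X2 (interior
// (p-c)^T X (p-c) <= 1) and center separation r,
//   F(l) = l (1-l) r^T [ (1-l) X1^{-1} + l X2^{-1} ]^{-1} r,
// maximized over l in (0, 1); the ellipses overlap iff max F < 1 (tangency
// at exactly 1). F is concave with a unique interior maximum, so golden-
// section search is reliable.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Ellipse {
  double x, y, phi, A, B; // center, orientation, semi-axes
};

// inverse shape matrix X^{-1} = R diag(A^2, B^2) R^T (2x2 symmetric)
static inline void inv_shape(const Ellipse &e, double &m11, double &m12, double &m22) {
  double c = std::cos(e.phi), s = std::sin(e.phi);
  double a2 = e.A * e.A, b2 = e.B * e.B;
  m11 = a2 * c * c + b2 * s * s;
  m12 = (a2 - b2) * c * s;
  m22 = a2 * s * s + b2 * c * c;
}

static double pw_F(double l, double rx, double ry,
                   double p11, double p12, double p22,
                   double q11, double q12, double q22) {
  double m11 = (1 - l) * p11 + l * q11;
  double m12 = (1 - l) * p12 + l * q12;
  double m22 = (1 - l) * p22 + l * q22;
  double det = m11 * m22 - m12 * m12;
  // r^T M^{-1} r
  double v = (m22 * rx * rx - 2 * m12 * rx * ry + m11 * ry * ry) / det;
  return l * (1 - l) * v;
}

static double pw_contact(const Ellipse &a, const Ellipse &b) {
  double p11, p12, p22, q11, q12, q22;
  inv_shape(a, p11, p12, p22);
  inv_shape(b, q11, q12, q22);
  double rx = b.x - a.x, ry = b.y - a.y;
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double lo = 0.0, hi = 1.0;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = pw_F(x1, rx, ry, p11, p12, p22, q11, q12, q22);
  double f2 = pw_F(x2, rx, ry, p11, p12, p22, q11, q12, q22);
  for (int it = 0; it < 60; ++it) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = pw_F(x2, rx, ry, p11, p12, p22, q11, q12, q22);
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = pw_F(x1, rx, ry, p11, p12, p22, q11, q12, q22);
    }
  }
  return std::max(f1, f2);
}

// [[Rcpp::export]]
double pw_contact_cpp(double x1, double y1, double phi1, double a1, double b1,
                      double x2, double y2, double phi2, double a2, double b2) {
  Ellipse e1{x1, y1, phi1, a1, b1}, e2{x2, y2, phi2, a2, b2};
  return pw_contact(e1, e2);
}

static inline bool overlaps(const Ellipse &a, const Ellipse &b) {
  // quick reject/accept by bounding circles
  double dx = b.x - a.x, dy = b.y - a.y, d2 = dx * dx + dy * dy;
  double rsum = a.A + b.A;
  if (d2 >= rsum * rsum) return false;
  double rmin = a.B + b.B;
  if (d2 < rmin * rmin) return true;
  return pw_contact(a, b) < 1.0;
}

// largest distance from the origin to the ellipse boundary; used for
// containment in a disk centered at the origin
static double ellipse_max_radius(const Ellipse &e) {
  double best = 0.0, tbest = 0.0;
  for (int k = 0; k < 72; ++k) {
    double t = 2.0 * M_PI * k / 72.0;
    double px = e.x + e.A * std::cos(t) * std::cos(e.phi) - e.B * std::sin(t) * std::sin(e.phi);
    double py = e.y + e.A * std::cos(t) * std::sin(e.phi) + e.B * std::sin(t) * std::cos(e.phi);
    double d2 = px * px + py * py;
    if (d2 > best) { best = d2; tbest = t; }
  }
  // golden-section refinement around the best coarse angle
  double lo = tbest - 2.0 * M_PI / 72.0, hi = tbest + 2.0 * M_PI / 72.0;
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  auto rad2 = [&](double t) {
    double px = e.x + e.A * std::cos(t) * std::cos(e.phi) - e.B * std::sin(t) * std::sin(e.phi);
    double py = e.y + e.A * std::cos(t) * std::sin(e.phi) + e.B * std::sin(t) * std::cos(e.phi);
    return px * px + py * py;
  };
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = rad2(x1), f2 = rad2(x2);
  for (int it = 0; it < 40; ++it) {
    if (f1 < f2) { lo = x1; x1 = x2; f1 = f2; x2 = lo + gr * (hi - lo); f2 = rad2(x2); }
    else { hi = x2; x2 = x1; f2 = f1; x1 = hi - gr * (hi - lo); f1 = rad2(x1); }
  }
  return std::sqrt(std::max(f1, f2));
}

// [[Rcpp::export]]
bool ellipse_in_disk_cpp(double x, double y, double phi, double A, double B,
                         double R) {
  Ellipse e{x, y, phi, A, B};
  return ellipse_max_radius(e) <= R;
}

// [[Rcpp::export]]
LogicalVector config_overlaps_cpp(NumericVector x, NumericVector y,
                                  NumericVector phi, double A, double B) {
  int n = x.size();
  LogicalVector out(n * (n - 1) / 2);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      Ellipse ei{x[i], y[i], phi[i], A, B}, ej{x[j], y[j], phi[j], A, B};
      out[k++] = overlaps(ei, ej);
    }
  return out;
}

// tabulated pairwise potential, linear interpolation, 0 beyond the grid
static inline double pot_eval(double s, const NumericVector &sg,
                              const NumericVector &ug) {
  int n = sg.size();
  if (n == 0) return 0.0;
  if (s <= sg[0]) return ug[0];
  if (s >= sg[n - 1]) return ug[n - 1];
  double step = (sg[n - 1] - sg[0]) / (n - 1);
  int i = (int)((s - sg[0]) / step);
  if (i >= n - 1) i = n - 2;
  double f = (s - sg[i]) / (sg[i + 1] - sg[i]);
  return ug[i] * (1 - f) + ug[i + 1] * f;
}

// separation between two ellipses: center-to-center (mode 0) or the
// Perram-Wertheim scaled surface gap d * (1 - 1/sqrt(F)) (mode 1), which is
// exact for circles and the standard gap estimate for ellipses
static inline double pair_sep(const Ellipse &a, const Ellipse &b, int mode) {
  double dx = b.x - a.x, dy = b.y - a.y;
  double d = std::sqrt(dx * dx + dy * dy);
  if (mode == 0) return d;
  double F = pw_contact(a, b);
  if (F <= 1.0) return 0.0;
  return d * (1.0 - 1.0 / std::sqrt(F));
}

static double pair_energy(int i, const std::vector<Ellipse> &es,
                          const NumericVector &sg, const NumericVector &ug,
                          int sep_mode) {
  double e = 0.0;
  for (size_t j = 0; j < es.size(); ++j) {
    if ((int)j == i) continue;
    e += pot_eval(pair_sep(es[i], es[j], sep_mode), sg, ug);
  }
  return e;
}

// [[Rcpp::export]]
List mc_run_cpp(NumericVector x0, NumericVector y0, NumericVector phi0,
                double A, double B, double Rdisk,
                NumericVector pot_s, NumericVector pot_u,
                NumericVector temps, int moves_per_sweep,
                double step_trans, double step_rot, int sep_mode = 0) {
  int n = x0.size();
  std::vector<Ellipse> es(n);
  for (int i = 0; i < n; ++i) es[i] = Ellipse{x0[i], y0[i], phi0[i], A, B};
  int n_sweeps = temps.size();
  NumericVector energy_trace(n_sweeps);
  NumericVector acc_trace(n_sweeps);
  RNGScope scope;
  double Etot = 0.0;
  for (int i = 0; i < n; ++i) Etot += 0.5 * pair_energy(i, es, pot_s, pot_u, sep_mode);
  for (int sw = 0; sw < n_sweeps; ++sw) {
    double T = temps[sw];
    int acc = 0;
    for (int m = 0; m < moves_per_sweep; ++m) {
      int i = (int)(R::unif_rand() * n);
      if (i == n) i = n - 1;
      Ellipse trial = es[i];
      trial.x += (2.0 * R::unif_rand() - 1.0) * step_trans;
      trial.y += (2.0 * R::unif_rand() - 1.0) * step_trans;
      trial.phi += (2.0 * R::unif_rand() - 1.0) * step_rot;
      if (!ellipse_in_disk_cpp(trial.x, trial.y, trial.phi, A, B, Rdisk))
        continue;
      bool bad = false;
      for (int j = 0; j < n && !bad; ++j) {
        if (j == i) continue;
        if (overlaps(trial, es[j])) bad = true;
      }
      if (bad) continue;
      double e_old = pair_energy(i, es, pot_s, pot_u, sep_mode);
      Ellipse saved = es[i];
      es[i] = trial;
      double e_new = pair_energy(i, es, pot_s, pot_u, sep_mode);
      double dE = e_new - e_old;
      if (dE <= 0.0 || R::unif_rand() < std::exp(-dE / T)) {
        Etot += dE;
        ++acc;
      } else {
        es[i] = saved;
      }
    }
    energy_trace[sw] = Etot;
    acc_trace[sw] = (double)acc / moves_per_sweep;
  }
  NumericVector xo(n), yo(n), po(n);
  for (int i = 0; i < n; ++i) { xo[i] = es[i].x; yo[i] = es[i].y; po[i] = es[i].phi; }
  return List::create(_["x"] = xo, _["y"] = yo, _["phi"] = po,
                      _["energy"] = energy_trace, _["acceptance"] = acc_trace);
}

// [[Rcpp::export]]
List random_place_cpp(int n, double A, double B, double Rdisk,
                      int max_attempts) {
  std::vector<Ellipse> es;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts; ++att) {
      Ellipse e;
      // uniform position over the disk, uniform orientation
      double u = R::unif_rand(), v = R::unif_rand();
      double r = Rdisk * std::sqrt(u), th = 2.0 * M_PI * v;
      e.x = r * std::cos(th); e.y = r * std::sin(th);
      e.phi = M_PI * R::unif_rand();
      e.A = A; e.B = B;
      if (!ellipse_in_disk_cpp(e.x, e.y, e.phi, A, B, Rdisk)) continue;
      bool bad = false;
      for (size_t j = 0; j < es.size() && !bad; ++j)
        if (overlaps(e, es[j])) bad = true;
      if (!bad) { es.push_back(e); placed = true; break; }
    }
    if (!placed)
      return List::create(_["ok"] = false);
  }
  NumericVector xo(n), yo(n), po(n);
  for (int i = 0; i < n; ++i) { xo[i] = es[i].x; yo[i] = es[i].y; po[i] = es[i].phi; }
  return List::create(_["ok"] = true, _["x"] = xo, _["y"] = yo, _["phi"] = po);
}
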