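#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reciprocal space is in nm^-1 throughout. The incident beam runs along +z;
// the Ewald sphere for wavelength lambda (nm) and zero convergence has its
// centre at (0, 0, -1/lambda). Excitation distances use the sign convention
// e = R - |s - c|: positive when the reciprocal lattice point lies inside the
// sphere (the sphere surface is farther from the Ewald centre than the point).

static const double EPS_U = 1e-14;

// spherical cap: fraction of a sphere of radius r with signed radial
// coordinate >= t, and its derivative in t
static inline double cap_f(double t, double r) {
  double a = r - t;
  return a * a * (2.0 * r + t) / (4.0 * r * r * r);
}
static inline double cap_fp(double t, double r) {
  return -3.0 * (r * r - t * t) / (4.0 * r * r * r);
}
static inline double clamp_r(double x, double r) {
  return x < -r ? -r : (x > r ? r : x);
}

struct Extremes {
  double rhigh, rlow;      // min / max signed distance over the nest extremes
  double gh[3], gl[3];     // gradients d(rhigh)/ds, d(rlow)/ds
};

// gradient of e = R - |s - c(s)| with respect to s for one nest sphere.
// c depends on s through the tilt direction u^ = Pz s / |Pz s| (the beam is
// tilted in the plane containing the beam axis and s):
//   de/ds = -g - (sin t / (lambda |u|)) (Pz - u^ u^T) g,  g = (s-c)/|s-c|
static inline void exc_grad(const double d[3], double dn, double st,
                            double lam, double un, double uhx, double uhy,
                            bool have_u, double out[3]) {
  double gx = d[0] / dn, gy = d[1] / dn, gz = d[2] / dn;
  double tx = 0.0, ty = 0.0;
  if (have_u) {
    double proj = uhx * gx + uhy * gy;
    double fac = st / (lam * un);
    tx = fac * (gx - uhx * proj);
    ty = fac * (gy - uhy * proj);
  }
  out[0] = -gx - tx;
  out[1] = -gy - ty;
  out[2] = -gz;
}

// extreme excitation distances over the 4 nest corners
// (2 wavelengths x 2 in-plane tilts)
static void nest_extremes(const double s[3], double lambda, double bw,
                          double conv, bool want_grad, Extremes &out) {
  const double lam[2] = { lambda * (1.0 - 0.5 * bw), lambda * (1.0 + 0.5 * bw) };
  const double tilt[2] = { -0.5 * conv, 0.5 * conv };
  double un = std::sqrt(s[0] * s[0] + s[1] * s[1]);
  bool have_u = un > EPS_U;
  double uhx = have_u ? s[0] / un : 0.0;
  double uhy = have_u ? s[1] / un : 0.0;

  double emin = R_PosInf, emax = R_NegInf;
  double dmin[3] = {0, 0, 0}, dmax[3] = {0, 0, 0};
  double nmin = 1.0, nmax = 1.0;
  double stmin = 0.0, stmax = 0.0, lammin = 1.0, lammax = 1.0;

  for (int i = 0; i < 2; ++i) {
    double R = 1.0 / lam[i];
    for (int j = 0; j < 2; ++j) {
      double ct = std::cos(tilt[j]), st = std::sin(tilt[j]);
      double cx = -st * uhx * R, cy = -st * uhy * R, cz = -ct * R;
      double dx = s[0] - cx, dy = s[1] - cy, dz = s[2] - cz;
      double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
      double e = R - dn;
      if (e < emin) {
        emin = e; dmin[0] = dx; dmin[1] = dy; dmin[2] = dz; nmin = dn;
        stmin = st; lammin = lam[i];
      }
      if (e > emax) {
        emax = e; dmax[0] = dx; dmax[1] = dy; dmax[2] = dz; nmax = dn;
        stmax = st; lammax = lam[i];
      }
    }
  }
  out.rhigh = emin;
  out.rlow = emax;
  if (want_grad) {
    exc_grad(dmin, nmin, stmin, lammin, un, uhx, uhy, have_u, out.gh);
    exc_grad(dmax, nmax, stmax, lammax, un, uhx, uhy, have_u, out.gl);
  }
}

static inline double partiality_from(double rhigh, double rlow, double r) {
  double ch = clamp_r(rhigh, r), cl = clamp_r(rlow, r);
  double p = cap_f(ch, r) - cap_f(cl, r);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export]]
List cpp_excitation(NumericMatrix basis, IntegerMatrix hkl, double lambda,
                    double bw, double conv, double r, double kL,
                    bool gradients) {
  int n = hkl.nrow();
  NumericVector rhigh(n), rlow(n), p(n), L(n);
  NumericMatrix grad;
  if (gradients) grad = NumericMatrix(n, 9);
  const double *B = basis.begin();  // column-major: a* = B[0..2], b*, c*
  Extremes ex;
  for (int i = 0; i < n; ++i) {
    double h = hkl(i, 0), k = hkl(i, 1), l = hkl(i, 2);
    double s[3];
    for (int q = 0; q < 3; ++q)
      s[q] = h * B[q] + k * B[3 + q] + l * B[6 + q];
    double sn = std::sqrt(s[0] * s[0] + s[1] * s[1] + s[2] * s[2]);
    if (sn < EPS_U) stop("zero-length scattering vector (reflection 0 0 0?)");
    nest_extremes(s, lambda, bw, conv, gradients, ex);
    rhigh[i] = ex.rhigh;
    rlow[i] = ex.rlow;
    p[i] = partiality_from(ex.rhigh, ex.rlow, r);
    double T = ex.rlow - ex.rhigh;
    L[i] = (T > EPS_U) ? kL / T : NA_REAL;
    if (gradients) {
      double ch = clamp_r(ex.rhigh, r), cl = clamp_r(ex.rlow, r);
      double fh = cap_fp(ch, r), fl = cap_fp(cl, r);
      // clamped bounds give cap_fp(+-r) = 0 exactly: zero contribution
      double dpds[3];
      for (int q = 0; q < 3; ++q) dpds[q] = fh * ex.gh[q] - fl * ex.gl[q];
      for (int q = 0; q < 3; ++q) {
        grad(i, q)     = h * dpds[q];
        grad(i, 3 + q) = k * dpds[q];
        grad(i, 6 + q) = l * dpds[q];
      }
    }
  }
  if (gradients)
    return List::create(_["rhigh"] = rhigh, _["rlow"] = rlow, _["p"] = p,
                        _["L"] = L, _["grad"] = grad);
  return List::create(_["rhigh"] = rhigh, _["rlow"] = rlow, _["p"] = p,
                      _["L"] = L);
}

// All hkl (excluding 0,0,0) with |s| <= smax, using the reciprocal metric
// G = B^T B (rotation-invariant, so one enumeration serves every orientation).
// [[Rcpp::export]]
IntegerMatrix cpp_candidate_hkl(NumericMatrix G, int hmax, int kmax, int lmax,
                                double smax) {
  double s2max = smax * smax;
  std::vector<int> out;
  out.reserve(1 << 20);
  double g11 = G(0, 0), g22 = G(1, 1), g33 = G(2, 2);
  double g12 = G(0, 1), g13 = G(0, 2), g23 = G(1, 2);
  for (int h = -hmax; h <= hmax; ++h) {
    for (int k = -kmax; k <= kmax; ++k) {
      double hh = g11 * h * h + g22 * k * k + 2.0 * g12 * h * k;
      double lin = 2.0 * (g13 * h + g23 * k);
      for (int l = -lmax; l <= lmax; ++l) {
        if (h == 0 && k == 0 && l == 0) continue;
        double s2 = hh + g33 * l * l + lin * l;
        if (s2 <= s2max) { out.push_back(h); out.push_back(k); out.push_back(l); }
      }
    }
  }
  int n = out.size() / 3;
  IntegerMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = out[3 * i]; m(i, 1) = out[3 * i + 1]; m(i, 2) = out[3 * i + 2];
  }
  return m;
}

// Predict the observable reflections for one orientation: reflection sphere
// intersects the excitation slab (unclamped rhigh < +r and rlow > -r) and the
// diffracted beam, taken at the nominal wavelength, lands on the detector.
// [[Rcpp::export]]
List cpp_predict(NumericMatrix basis, IntegerMatrix cand, double lambda,
                 double bw, double conv, double r, double kL,
                 double det_side_mm, double det_dist_mm) {
  int n = cand.nrow();
  const double *B = basis.begin();
  double R0 = 1.0 / lambda;
  double margin = r + R0 * (bw + conv);   // conservative nest half-width bound
  double half = det_side_mm / 2.0;
  std::vector<int> ih, ik, il;
  std::vector<double> vrh, vrl, vp, vL, vx, vy, vd;
  Extremes ex;
  for (int i = 0; i < n; ++i) {
    double h = cand(i, 0), k = cand(i, 1), l = cand(i, 2);
    double s[3];
    for (int q = 0; q < 3; ++q)
      s[q] = h * B[q] + k * B[3 + q] + l * B[6 + q];
    // cheap prefilter on the nominal sphere
    double dz = s[2] + R0;
    double dn = std::sqrt(s[0] * s[0] + s[1] * s[1] + dz * dz);
    double e0 = R0 - dn;
    if (e0 > margin || e0 < -margin) continue;
    nest_extremes(s, lambda, bw, conv, false, ex);
    if (!(ex.rhigh < r && ex.rlow > -r)) continue;
    // detector projection at the nominal wavelength
    double koz = s[2] + R0;
    if (koz <= 0.0) continue;
    double px = det_dist_mm * s[0] / koz;
    double py = det_dist_mm * s[1] / koz;
    if (px < -half || px > half || py < -half || py > half) continue;
    double sn = std::sqrt(s[0] * s[0] + s[1] * s[1] + s[2] * s[2]);
    double T = ex.rlow - ex.rhigh;
    ih.push_back((int)h); ik.push_back((int)k); il.push_back((int)l);
    vrh.push_back(ex.rhigh); vrl.push_back(ex.rlow);
    vp.push_back(partiality_from(ex.rhigh, ex.rlow, r));
    vL.push_back(T > EPS_U ? kL / T : NA_REAL);
    vx.push_back(px); vy.push_back(py);
    vd.push_back(10.0 / sn);   // d in Angstrom from |s| in nm^-1
  }
  return List::create(_["h"] = wrap(ih), _["k"] = wrap(ik), _["l"] = wrap(il),
                      _["rhigh"] = wrap(vrh), _["rlow"] = wrap(vrl),
                      _["p"] = wrap(vp), _["L"] = wrap(vL),
                      _["x"] = wrap(vx), _["y"] = wrap(vy),
                      _["d"] = wrap(vd));
}

// Canonical (asymmetric-unit) representative: lexicographically greatest
// image of hkl over the stacked operator blocks (nops*3 x 3).
// [[Rcpp::export]]
IntegerMatrix cpp_canonical(IntegerMatrix hkl, IntegerMatrix ops) {
  int n = hkl.nrow();
  int nops = ops.nrow() / 3;
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    int h = hkl(i, 0), k = hkl(i, 1), l = hkl(i, 2);
    int bh = INT_MIN, bk = INT_MIN, bl = INT_MIN;
    for (int o = 0; o < nops; ++o) {
      int r0 = 3 * o;
      int nh = ops(r0, 0) * h + ops(r0, 1) * k + ops(r0, 2) * l;
      int nk = ops(r0 + 1, 0) * h + ops(r0 + 1, 1) * k + ops(r0 + 1, 2) * l;
      int nl = ops(r0 + 2, 0) * h + ops(r0 + 2, 1) * k + ops(r0 + 2, 2) * l;
      bool better = (nh > bh) || (nh == bh && (nk > bk || (nk == bk && nl > bl)));
      if (better) { bh = nh; bk = nk; bl = nl; }
    }
    out(i, 0) = bh; out(i, 1) = bk; out(i, 2) = bl;
  }
  return out;
}
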