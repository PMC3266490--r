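// Overdamped explicit-Euler core for the spring-based vertex model.
// Mirrors the R reference implementation in R/mechanics.R exactly; the
// test suite asserts agreement of the two force evaluations.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// force accumulation for one configuration; returns false on non-finite
static bool eval_forces(int nv, int ns, int nel,
                        const std::vector<double> &Px,
                        const std::vector<double> &Pz,
                        const int *si, const int *sj,
                        const double *kk, const double *l0,
                        const int *C, // nel x 4, column-major, 0-based
                        const double *Veq, const double *th_eq,
                        double sigma, const double *x0,
                        double k_v, double k_s, double k_h,
                        double hoop_relief, double l_reg,
                        std::vector<double> &Fx, std::vector<double> &Fz) {
  std::fill(Fx.begin(), Fx.end(), 0.0);
  std::fill(Fz.begin(), Fz.end(), 0.0);

  // Hookean springs
  for (int s = 0; s < ns; ++s) {
    int a = si[s], b = sj[s];
    double dx = Px[a] - Px[b], dz = Pz[a] - Pz[b];
    double l = std::sqrt(dx * dx + dz * dz);
    double cf = kk[s] * (l - l0[s]) / l;
    Fx[a] -= cf * dx; Fz[a] -= cf * dz;
    Fx[b] += cf * dx; Fz[b] += cf * dz;
  }

  for (int e = 0; e < nel; ++e) {
    int c0 = C[e], c1 = C[e + nel], c2 = C[e + 2 * nel],
        c3 = C[e + 3 * nel];
    const int cc[4] = {c0, c1, c2, c3};
    double X[4], Z[4];
    for (int m = 0; m < 4; ++m) { X[m] = Px[cc[m]]; Z[m] = Pz[cc[m]]; }

    // volumetric term
    double A = 0.5 * sigma *
      (X[0] * Z[1] - X[1] * Z[0] + X[1] * Z[2] - X[2] * Z[1] +
       X[2] * Z[3] - X[3] * Z[2] + X[3] * Z[0] - X[0] * Z[3]);
    double xbar = 0.25 * (X[0] + X[1] + X[2] + X[3]);
    double V = 2.0 * M_PI * xbar * A;
    double dUdV = k_v * (V - Veq[e]) / Veq[e];
    for (int m = 0; m < 4; ++m) {
      int mp = (m + 3) % 4, mn = (m + 1) % 4;
      double dAdx = sigma * 0.5 * (Z[mn] - Z[mp]);
      double dAdz = sigma * 0.5 * (X[mp] - X[mn]);
      double dVdx = 2.0 * M_PI * (A * 0.25 + xbar * dAdx);
      double dVdz = 2.0 * M_PI * xbar * dAdz;
      Fx[cc[m]] -= dUdV * dVdx;
      Fz[cc[m]] -= dUdV * dVdz;
    }

    // self-righting corner-angle term, edge-weighted: the penalty of a
    // corner fades once an incident edge drops below l_reg
    for (int m = 0; m < 4; ++m) {
      int mp = (m + 3) % 4, mn = (m + 1) % 4;
      double ux = X[mp] - X[m], uy = Z[mp] - Z[m];
      double vx = X[mn] - X[m], vy = Z[mn] - Z[m];
      double s = -sigma * (ux * vy - uy * vx);
      double c = ux * vx + uy * vy;
      double r2 = s * s + c * c;
      double th = std::atan2(s, c);
      double dth = th - th_eq[e + m * nel];
      double lu = std::sqrt(ux * ux + uy * uy);
      double lv = std::sqrt(vx * vx + vy * vy);
      double wgt = 1.0;
      bool soft = false;
      if (l_reg > 0) {
        double q = lu * lv / (l_reg * l_reg);
        if (q < 1.0) { wgt = q; soft = true; }
      }
      double w = k_s * wgt * dth;
      double du_x = (-sigma * c * vy - s * vx) / r2;
      double du_y = ( sigma * c * vx - s * vy) / r2;
      double dv_x = ( sigma * c * uy - s * ux) / r2;
      double dv_y = (-sigma * c * ux - s * uy) / r2;
      double Fa_x = -w * du_x, Fa_y = -w * du_y;
      double Fb_x = -w * dv_x, Fb_y = -w * dv_y;
      if (soft) {
        double cw = 0.5 * k_s * dth * dth / (l_reg * l_reg);
        double gu = cw * lv / lu, gv = cw * lu / lv;
        Fa_x -= gu * ux; Fa_y -= gu * uy;
        Fb_x -= gv * vx; Fb_y -= gv * vy;
      }
      Fx[cc[mp]] += Fa_x; Fz[cc[mp]] += Fa_y;
      Fx[cc[mn]] += Fb_x; Fz[cc[mn]] += Fb_y;
      Fx[cc[m]] -= Fa_x + Fb_x;
      Fz[cc[m]] -= Fa_y + Fb_y;
    }
  }

  // hoop force; compression side scaled by the relief factor
  for (int v = 0; v < nv; ++v) {
    if (x0[v] > 0) {
      double w = (Px[v] > x0[v]) ? 1.0 : (1.0 - hoop_relief);
      Fx[v] -= w * k_h * (Px[v] - x0[v]) / x0[v];
    }
  }

  for (int v = 0; v < nv; ++v)
    if (!std::isfinite(Fx[v]) || !std::isfinite(Fz[v])) return false;
  return true;
}

static void eval_energy(int nv, int ns, int nel,
                        const std::vector<double> &Px,
                        const std::vector<double> &Pz,
                        const int *si, const int *sj,
                        const double *kk, const double *l0,
                        const int *C, const double *Veq,
                        const double *th_eq, double sigma,
                        const double *x0,
                        double k_v, double k_s, double k_h,
                        double hoop_relief, double l_reg,
                        double out[4]) {
  double Ue = 0, Uv = 0, Us = 0, Uh = 0;
  for (int s = 0; s < ns; ++s) {
    double dx = Px[si[s]] - Px[sj[s]], dz = Pz[si[s]] - Pz[sj[s]];
    double l = std::sqrt(dx * dx + dz * dz);
    Ue += 0.5 * kk[s] * (l - l0[s]) * (l - l0[s]);
  }
  for (int e = 0; e < nel; ++e) {
    const int cc[4] = {C[e], C[e + nel], C[e + 2 * nel], C[e + 3 * nel]};
    double X[4], Z[4];
    for (int m = 0; m < 4; ++m) { X[m] = Px[cc[m]]; Z[m] = Pz[cc[m]]; }
    double A = 0.5 * sigma *
      (X[0] * Z[1] - X[1] * Z[0] + X[1] * Z[2] - X[2] * Z[1] +
       X[2] * Z[3] - X[3] * Z[2] + X[3] * Z[0] - X[0] * Z[3]);
    double xbar = 0.25 * (X[0] + X[1] + X[2] + X[3]);
    double V = 2.0 * M_PI * xbar * A;
    Uv += 0.5 * k_v * (V - Veq[e]) * (V - Veq[e]) / Veq[e];
    for (int m = 0; m < 4; ++m) {
      int mp = (m + 3) % 4, mn = (m + 1) % 4;
      double ux = X[mp] - X[m], uy = Z[mp] - Z[m];
      double vx = X[mn] - X[m], vy = Z[mn] - Z[m];
      double s = -sigma * (ux * vy - uy * vx);
      double c = ux * vx + uy * vy;
      double th = std::atan2(s, c);
      double d = th - th_eq[e + m * nel];
      double wgt = 1.0;
      if (l_reg > 0) {
        double lu = std::sqrt(ux * ux + uy * uy);
        double lv = std::sqrt(vx * vx + vy * vy);
        double q = lu * lv / (l_reg * l_reg);
        if (q < 1.0) wgt = q;
      }
      Us += 0.5 * k_s * wgt * d * d;
    }
  }
  for (int v = 0; v < nv; ++v)
    if (x0[v] > 0) {
      double w = (Px[v] > x0[v]) ? 1.0 : (1.0 - hoop_relief);
      Uh += 0.5 * w * k_h * (Px[v] - x0[v]) * (Px[v] - x0[v]) / x0[v];
    }
  out[0] = Ue; out[1] = Uv; out[2] = Us; out[3] = Uh;
}

// true if every element keeps a positive oriented area. A transiently
// self-intersecting corner at a tight fold apex is tolerated during a
// run (the volumetric penalty drives it back out); a non-positive area
// means a truly inverted element and aborts.
static bool elements_ok(int nel, const std::vector<double> &Px,
                        const std::vector<double> &Pz, const int *C,
                        double sigma) {
  for (int e = 0; e < nel; ++e) {
    const int cc[4] = {C[e], C[e + nel], C[e + 2 * nel], C[e + 3 * nel]};
    double X[4], Z[4];
    for (int m = 0; m < 4; ++m) { X[m] = Px[cc[m]]; Z[m] = Pz[cc[m]]; }
    double A = 0.5 * sigma *
      (X[0] * Z[1] - X[1] * Z[0] + X[1] * Z[2] - X[2] * Z[1] +
       X[2] * Z[3] - X[3] * Z[2] + X[3] * Z[0] - X[0] * Z[3]);
    if (!(A > 0)) return false;
  }
  return true;
}


// largest stable explicit step for the current configuration:
// eta / (c_safety * max per-vertex stiffness)
static double stable_dt(int nv, int ns, int nel,
                        const std::vector<double> &Px,
                        const std::vector<double> &Pz,
                        const int *si, const int *sj,
                        const double *kk, const double *l0,
                        const int *C, const double *Veq, double sigma,
                        const double *x0, double k_v, double k_s,
                        double k_h, double l_reg, double eta,
                        double c_safety) {
  std::vector<double> keff(nv, 0.0);
  for (int s = 0; s < ns; ++s) {
    double dx = Px[si[s]] - Px[sj[s]], dz = Pz[si[s]] - Pz[sj[s]];
    double l = std::sqrt(dx * dx + dz * dz);
    // longitudinal k plus the positive transverse stiffness of a
    // stretched spring; a compressed spring's transverse response is
    // destabilizing (negative curvature), not a step-size constraint
    double tr = 1.0 - l0[s] / l;
    double ks_ = kk[s] * (1.0 + (tr > 0 ? tr : 0.0));
    keff[si[s]] += ks_; keff[sj[s]] += ks_;
  }
  for (int e = 0; e < nel; ++e) {
    const int cc[4] = {C[e], C[e + nel], C[e + 2 * nel], C[e + 3 * nel]};
    double X[4], Z[4];
    for (int m = 0; m < 4; ++m) { X[m] = Px[cc[m]]; Z[m] = Pz[cc[m]]; }
    double A = 0.5 * sigma *
      (X[0] * Z[1] - X[1] * Z[0] + X[1] * Z[2] - X[2] * Z[1] +
       X[2] * Z[3] - X[3] * Z[2] + X[3] * Z[0] - X[0] * Z[3]);
    double xbar = 0.25 * (X[0] + X[1] + X[2] + X[3]);
    for (int m = 0; m < 4; ++m) {
      int mp = (m + 3) % 4, mn = (m + 1) % 4;
      double dVdx = 2.0 * M_PI *
        (A * 0.25 + xbar * sigma * 0.5 * (Z[mn] - Z[mp]));
      double dVdz = 2.0 * M_PI * xbar * sigma * 0.5 * (X[mp] - X[mn]);
      keff[cc[m]] += k_v * (dVdx * dVdx + dVdz * dVdz) / Veq[e];
      double u2 = (X[mp] - X[m]) * (X[mp] - X[m]) +
                  (Z[mp] - Z[m]) * (Z[mp] - Z[m]);
      double v2 = (X[mn] - X[m]) * (X[mn] - X[m]) +
                  (Z[mn] - Z[m]) * (Z[mn] - Z[m]);
      double fl = l_reg * l_reg;
      if (u2 < fl) u2 = fl;
      if (v2 < fl) v2 = fl;
      keff[cc[m]] += 2.0 * k_s * (1.0 / u2 + 1.0 / v2);
      keff[cc[mp]] += 2.0 * k_s / u2;
      keff[cc[mn]] += 2.0 * k_s / v2;
    }
  }
  double mx = 0.0;
  for (int v = 0; v < nv; ++v) {
    if (x0[v] > 0) keff[v] += k_h / x0[v];
    if (keff[v] > mx) mx = keff[v];
  }
  return eta / (c_safety * mx);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix P, IntegerVector si,
                         IntegerVector sj, NumericVector kk,
                         NumericVector l0, IntegerMatrix C,
                         NumericVector Veq, NumericMatrix th_eq,
                         double sigma, NumericVector x0, double k_v,
                         double k_s, double k_h, double hoop_relief,
                         double l_reg) {
  int nv = P.nrow(), ns = si.size(), nel = C.nrow();
  std::vector<double> Px(nv), Pz(nv), Fx(nv), Fz(nv);
  for (int v = 0; v < nv; ++v) { Px[v] = P(v, 0); Pz[v] = P(v, 1); }
  eval_forces(nv, ns, nel, Px, Pz, si.begin(), sj.begin(), kk.begin(),
              l0.begin(), C.begin(), Veq.begin(), th_eq.begin(), sigma,
              x0.begin(), k_v, k_s, k_h, hoop_relief, l_reg, Fx, Fz);
  NumericMatrix F(nv, 2);
  for (int v = 0; v < nv; ++v) { F(v, 0) = Fx[v]; F(v, 1) = Fz[v]; }
  return F;
}

// Integrate one inter-boundary segment [t_a, t_b] with the linear ramps
// active in that window. Ramp index vectors are 0-based; `frac` runs over
// the segment, which the R driver aligns with the ramp window.
// [[Rcpp::export]]
List cpp_run_segment(NumericMatrix P_, IntegerVector si, IntegerVector sj,
                     NumericVector kk_, NumericVector l0_,
                     IntegerMatrix C_, NumericVector Veq_,
                     NumericMatrix th_eq_, double sigma,
                     NumericVector x0_, LogicalVector free_,
                     IntegerVector pole, double k_v, double k_s,
                     double k_h, double hoop_relief, double l_reg,
                     double eta, double t_a, double t_b,
                     double dt_user, double c_safety, int recheck,
                     double max_steps, int stride,
                     IntegerVector relax_idx, double lambda,
                     double lambda_c,
                     IntegerVector l0r_idx, NumericVector l0r_base,
                     NumericVector l0r_target,
                     IntegerVector kr_idx, NumericVector kr_base,
                     NumericVector kr_target,
                     IntegerVector vr_idx, NumericVector vr_base,
                     NumericVector vr_target,
                     IntegerVector grow_idx, double G_total) {
  int nv = P_.nrow(), ns = si.size(), nel = C_.nrow();
  std::vector<double> Px(nv), Pz(nv), Fx(nv), Fz(nv);
  for (int v = 0; v < nv; ++v) { Px[v] = P_(v, 0); Pz[v] = P_(v, 1); }
  NumericVector kk = clone(kk_), l0 = clone(l0_), Veq = clone(Veq_);
  std::string status = "completed";
  List snaps;
  double t = t_a;
  double done = 0;           // steps taken (double: may be large)
  double g_prev = 1.0;
  double dt = 0.0;
  // the time step adapts to the stiffest current response, re-estimated
  // every `recheck` steps (the fold tightens element edges as it forms,
  // so a step that was stable at the segment start need not stay stable)
  while (t < t_b - 1e-12 * (t_b - t_a)) {
    if (((long long)done) % recheck == 0) {
      dt = stable_dt(nv, ns, nel, Px, Pz, si.begin(), sj.begin(),
                     kk.begin(), l0.begin(), C_.begin(), Veq.begin(),
                     sigma, x0_.begin(), k_v, k_s, k_h, l_reg, eta,
                     c_safety);
      if (dt_user > 0 && dt_user < dt) dt = dt_user;
    }
    double dt_step = dt;
    if (t + dt_step > t_b) dt_step = t_b - t;
    double frac = (t - t_a) / (t_b - t_a);
    for (int i = 0; i < l0r_idx.size(); ++i)
      l0[l0r_idx[i]] = l0r_base[i] + (l0r_target[i] - l0r_base[i]) * frac;
    for (int i = 0; i < kr_idx.size(); ++i)
      kk[kr_idx[i]] = kr_base[i] + (kr_target[i] - kr_base[i]) * frac;
    for (int i = 0; i < vr_idx.size(); ++i)
      Veq[vr_idx[i]] = vr_base[i] + (vr_target[i] - vr_base[i]) * frac;
    if (grow_idx.size() > 0) {
      // multiplicative growth of natural lengths, composing with the
      // creep applied below
      double g_t = 1.0 + (G_total - 1.0) * frac;
      double ratio = g_t / g_prev;
      for (int i = 0; i < grow_idx.size(); ++i) l0[grow_idx[i]] *= ratio;
      g_prev = g_t;
    }
    if (lambda > 0 || lambda_c > 0) {
      // asymmetric creep (see rule1_relaxation): fast release under
      // tension, slow remodelling under compression
      for (int i = 0; i < relax_idx.size(); ++i) {
        int sp = relax_idx[i];
        double dx = Px[si[sp]] - Px[sj[sp]], dz = Pz[si[sp]] - Pz[sj[sp]];
        double l = std::sqrt(dx * dx + dz * dz);
        double rate = (l > l0[sp]) ? lambda : lambda_c;
        l0[sp] += rate * (l - l0[sp]) * dt_step;
      }
    }
    bool ok = eval_forces(nv, ns, nel, Px, Pz, si.begin(), sj.begin(),
                          kk.begin(), l0.begin(), C_.begin(), Veq.begin(),
                          th_eq_.begin(), sigma, x0_.begin(), k_v, k_s,
                          k_h, hoop_relief, l_reg, Fx, Fz);
    if (!ok) { status = "nonfinite force"; break; }
    double cdt = dt_step / eta;
    for (int v = 0; v < nv; ++v) {
      if (free_[v]) { Px[v] += cdt * Fx[v]; Pz[v] += cdt * Fz[v]; }
    }
    for (int i = 0; i < pole.size(); ++i) Px[pole[i]] = 0.0;
    t += dt_step;
    done += 1;
    if (done > max_steps) { status = "step budget exceeded"; break; }
    bool at_end = (t >= t_b - 1e-12 * (t_b - t_a));
    if (((long long)done) % stride == 0 || at_end) {
      if (!elements_ok(nel, Px, Pz, C_.begin(), sigma)) {
        status = "inverted element";
        break;
      }
      double en[4];
      eval_energy(nv, ns, nel, Px, Pz, si.begin(), sj.begin(), kk.begin(),
                  l0.begin(), C_.begin(), Veq.begin(), th_eq_.begin(),
                  sigma, x0_.begin(), k_v, k_s, k_h, hoop_relief, l_reg,
                  en);
      NumericMatrix Ps(nv, 2);
      for (int v = 0; v < nv; ++v) { Ps(v, 0) = Px[v]; Ps(v, 1) = Pz[v]; }
      snaps.push_back(List::create(
        Named("time") = t,
        Named("P") = Ps,
        Named("energy") = NumericVector::create(
          Named("elastic") = en[0], Named("volumetric") = en[1],
          Named("distortion") = en[2], Named("hoop") = en[3],
          Named("total") = en[0] + en[1] + en[2] + en[3])));
    }
  }
  if (status == "completed") {
    // land the ramps exactly on their endpoints
    for (int i = 0; i < l0r_idx.size(); ++i) l0[l0r_idx[i]] = l0r_target[i];
    for (int i = 0; i < kr_idx.size(); ++i) kk[kr_idx[i]] = kr_target[i];
    for (int i = 0; i < vr_idx.size(); ++i) Veq[vr_idx[i]] = vr_target[i];
    if (grow_idx.size() > 0) {
      double r = G_total / g_prev;
      for (int i = 0; i < grow_idx.size(); ++i) l0[grow_idx[i]] *= r;
    }
  }
  NumericMatrix Pout(nv, 2);
  for (int v = 0; v < nv; ++v) { Pout(v, 0) = Px[v]; Pout(v, 1) = Pz[v]; }
  return List::create(Named("P") = Pout, Named("l0") = l0,
                      Named("kk") = kk, Named("Veq") = Veq,
                      Named("steps_done") = done,
                      Named("t_end") = t,
                      Named("snapshots") = snaps,
                      Named("status") = status);
}
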