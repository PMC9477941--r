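// Compiled core of the 1D pulse-wave solver.
//
// Finite-volume MUSCL scheme for the (A, Q) system with an elastic tube law
// inside the hyperbolic flux, explicit two-stage (Heun) time stepping,
// semi-analytic characteristic boundary solves, and an operator-split
// implicit treatment of the Voigt-type viscous wall term.  All quantities SI.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tube law (elastic part; the viscous G-term is handled by a split step)

static inline double tl_pressure(double A, double A0, double K, double pext) {
  return pext + K * (std::sqrt(A) - std::sqrt(A0)) / A0;
}
static inline double tl_dPdA(double A, double A0, double K) {
  return K / (2.0 * A0 * std::sqrt(A));
}
static inline double tl_c(double A, double A0, double K, double rho) {
  return std::sqrt(K * std::sqrt(A) / (2.0 * rho * A0));
}
// flux integral C1(A) = int c^2 dA = K A^{3/2} / (3 rho A0)
static inline double tl_C1(double A, double A0, double K, double rho) {
  return K * std::pow(A, 1.5) / (3.0 * rho * A0);
}
// area from elastic pressure (exact inversion)
static inline double tl_area_from_p(double P, double A0, double K, double pext) {
  double s = (P - pext) * A0 / K + std::sqrt(A0);
  if (s <= 0.0) stop("collapsed lumen: pressure below closure limit");
  return s * s;
}
// area from wave speed (exact inversion of c(A))
static inline double tl_area_from_c(double c, double A0, double K, double rho) {
  if (c <= 0.0) stop("unphysical boundary state: non-positive wave speed");
  double sq = c * c * 2.0 * rho * A0 / K; // = sqrt(A)
  return sq * sq;
}

// ---------------------------------------------------------------------------
// Containers

struct Vessel {
  int n;
  double dx;
  std::vector<double> A, Q, A0, K, G;
  // boundary interface states resolved once per substep
  double bAL, bQL, bAR, bQR;
};

struct Term { int vessel; double Z, R, C, Pout, Pc; };
struct Sten {
  int vessel, iface;            // interface between cells iface-1 and iface (0-based)
  double ratio, Ls, Kv, Kt, Ku; // A_s/A0, length, coefficients
  double q;                     // through-flow state (inertial memory)
};
struct Junc { int parent; std::vector<int> children; };

struct Net {
  double rho, alpha, fcoef, pext;
  int order, limiter;           // limiter: 0 none (centred), 1 minmod
  bool total_pressure;
  std::vector<Vessel> v;
  std::vector<Junc> junc;
  std::vector<Term> term;
  std::vector<Sten> sten;
};

static Net unpack_net(const List& nl) {
  Net net;
  net.rho   = as<double>(nl["rho"]);
  net.alpha = as<double>(nl["alpha"]);
  net.fcoef = as<double>(nl["fcoef"]);
  net.pext  = as<double>(nl["pext"]);
  net.order = as<int>(nl["order"]);
  net.limiter = as<int>(nl["limiter"]);
  net.total_pressure = as<bool>(nl["total_pressure"]);
  List vl = nl["vessels"];
  for (int i = 0; i < vl.size(); ++i) {
    List s = vl[i];
    Vessel vs;
    NumericVector A = s["A"], Q = s["Q"], A0 = s["A0"], K = s["K"], G = s["G"];
    vs.n = A.size();
    vs.dx = as<double>(s["dx"]);
    vs.A.assign(A.begin(), A.end());
    vs.Q.assign(Q.begin(), Q.end());
    vs.A0.assign(A0.begin(), A0.end());
    vs.K.assign(K.begin(), K.end());
    vs.G.assign(G.begin(), G.end());
    net.v.push_back(vs);
  }
  List jl = nl["junctions"];
  for (int i = 0; i < jl.size(); ++i) {
    List s = jl[i];
    Junc j;
    j.parent = as<int>(s["parent"]) - 1;
    IntegerVector ch = s["children"];
    for (int k = 0; k < ch.size(); ++k) j.children.push_back(ch[k] - 1);
    net.junc.push_back(j);
  }
  List tl = nl["terminals"];
  for (int i = 0; i < tl.size(); ++i) {
    List s = tl[i];
    Term t;
    t.vessel = as<int>(s["vessel"]) - 1;
    t.Z = as<double>(s["Z"]); t.R = as<double>(s["R"]);
    t.C = as<double>(s["C"]); t.Pout = as<double>(s["P_out"]);
    t.Pc = as<double>(s["P_state"]);
    net.term.push_back(t);
  }
  List sl = nl["stenoses"];
  for (int i = 0; i < sl.size(); ++i) {
    List s = sl[i];
    Sten st;
    st.vessel = as<int>(s["vessel"]) - 1;
    st.iface  = as<int>(s["iface"]);
    st.ratio = as<double>(s["area_ratio"]); st.Ls = as<double>(s["Ls"]);
    st.Kv = as<double>(s["Kv"]); st.Kt = as<double>(s["Kt"]); st.Ku = as<double>(s["Ku"]);
    st.q = as<double>(s["q_state"]);
    net.sten.push_back(st);
  }
  return net;
}

// ---------------------------------------------------------------------------
// Boundary solvers.  Characteristic variables of the elastic subsystem:
// forward W_f = u + 4(c - c0), backward W_b = u - 4(c - c0).

// prescribed inflow Q* at x = 0: solve A (W_b + 4(c(A) - c0)) = Q*
static void bc_inflow_q(double Ae, double Qe, double A0, double K,
                        double rho, double pext, double Qstar,
                        double& Ab, double& Qb) {
  double c0 = tl_c(A0, A0, K, rho);
  double Wb = Qe / Ae - 4.0 * (tl_c(Ae, A0, K, rho) - c0);
  double A = Ae;
  for (int it = 0; it < 60; ++it) {
    double c = tl_c(A, A0, K, rho);
    double u = Wb + 4.0 * (c - c0);
    double r = A * u - Qstar;
    double dr = u + c;                 // d(Au)/dA along the backward characteristic
    double dA = -r / dr;
    if (A + dA <= 0.0) dA = -0.5 * A;
    A += dA;
    if (std::fabs(dA) < 1e-15 * A0 + 1e-14 * A) break;
  }
  Ab = A;
  Qb = Qstar;
}

// prescribed pressure at x = 0 (exact tube-law inversion)
static void bc_pressure(double Ae, double Qe, double A0, double K,
                        double rho, double pext, double Pstar,
                        double& Ab, double& Qb) {
  double c0 = tl_c(A0, A0, K, rho);
  double Wb = Qe / Ae - 4.0 * (tl_c(Ae, A0, K, rho) - c0);
  double A = tl_area_from_p(Pstar, A0, K, pext);
  double u = Wb + 4.0 * (tl_c(A, A0, K, rho) - c0);
  Ab = A; Qb = A * u;
}

// closed (reflective) end at x = 0: u = 0
static void bc_closed_left(double Ae, double Qe, double A0, double K,
                           double rho, double pext, double& Ab, double& Qb) {
  double c0 = tl_c(A0, A0, K, rho);
  double Wb = Qe / Ae - 4.0 * (tl_c(Ae, A0, K, rho) - c0);
  double c = c0 - Wb / 4.0;
  Ab = tl_area_from_c(c, A0, K, rho);
  Qb = 0.0;
}

// aortic valve at x = 0, open state: p_cav - P(A) = B q|q| + L (q - q_prev)/dt
// returns q >= 0; closes (q = 0) if the implicit solution is non-positive.
static void bc_valve(double Ae, double Qe, double A0, double K,
                     double rho, double pext,
                     double pcav, double B, double L, double qprev, double dt,
                     double& Ab, double& Qb, double& qnew, bool& open) {
  double c0 = tl_c(A0, A0, K, rho);
  double Wb = Qe / Ae - 4.0 * (tl_c(Ae, A0, K, rho) - c0);
  double A = Ae;
  bool ok = false;
  for (int it = 0; it < 80; ++it) {
    double c = tl_c(A, A0, K, rho);
    double u = Wb + 4.0 * (c - c0);
    double q = A * u;
    double r = pcav - tl_pressure(A, A0, K, pext)
             - B * q * std::fabs(q) - (dt > 0.0 ? L * (q - qprev) / dt : 0.0);
    double dqdA = u + c;
    double dr = -tl_dPdA(A, A0, K) - (2.0 * B * std::fabs(q) + (dt > 0.0 ? L / dt : 0.0)) * dqdA;
    double dA = -r / dr;
    if (A + dA <= 0.0) dA = -0.5 * A;
    A += dA;
    if (std::fabs(dA) < 1e-16 * A0 + 1e-14 * A) { ok = true; break; }
  }
  (void)ok;
  double c = tl_c(A, A0, K, rho);
  double q = A * (Wb + 4.0 * (c - c0));
  if (q <= 0.0) { // no regurgitation: clamp shut
    bc_closed_left(Ae, Qe, A0, K, rho, pext, Ab, Qb);
    qnew = 0.0; open = false;
  } else {
    Ab = A; Qb = q; qnew = q; open = true;
  }
}

// implicit (backward Euler) capacitor update of the RCR terminal
static inline double wk_update(double Pc, double Q, double dt,
                               double R, double C, double Pout) {
  if (C <= 0.0) return Pout;
  return (Pc + (dt / C) * (Q + Pout / R)) / (1.0 + dt / (R * C));
}

// RCR Windkessel at x = L: P(A) = Pc' + Z Q with Pc' the implicit update
static void bc_windkessel(double Ae, double Qe, double A0, double K,
                          double rho, double pext, Term& t, double dt,
                          double& Ab, double& Qb, bool commit) {
  double c0 = tl_c(A0, A0, K, rho);
  double Wf = Qe / Ae + 4.0 * (tl_c(Ae, A0, K, rho) - c0);
  double A = Ae;
  double dPc_dQ = (t.C > 0.0) ? (dt / t.C) / (1.0 + dt / (t.R * t.C)) : 0.0;
  for (int it = 0; it < 80; ++it) {
    double c = tl_c(A, A0, K, rho);
    double u = Wf - 4.0 * (c - c0);
    double Q = A * u;
    double Pcn = (t.C > 0.0) ? wk_update(t.Pc, Q, dt, t.R, t.C, t.Pout)
                             : t.Pout + t.R * Q;
    double r = tl_pressure(A, A0, K, pext) - t.Z * Q - Pcn;
    double dQdA = u - c;
    double dr = tl_dPdA(A, A0, K) - (t.Z + ((t.C > 0.0) ? dPc_dQ : t.R)) * dQdA;
    double dA = -r / dr;
    if (A + dA <= 0.0) dA = -0.5 * A;
    A += dA;
    if (std::fabs(dA) < 1e-16 * A0 + 1e-14 * A) break;
  }
  double c = tl_c(A, A0, K, rho);
  double Q = A * (Wf - 4.0 * (c - c0));
  Ab = A; Qb = Q;
  if (commit) t.Pc = (t.C > 0.0) ? wk_update(t.Pc, Q, dt, t.R, t.C, t.Pout) : t.Pc;
}

// Junction of one parent outlet and 1..n child inlets.
// Unknowns: boundary areas; equations: mass balance + (total) pressure
// continuity.  Returns worst residuals through the pointers if given.
static void junction_solve_core(double rho, double pext, bool total_pressure,
                                double Ap, double Qp, double A0p, double Kp,
                                const std::vector<double>& Ac, const std::vector<double>& Qc,
                                const std::vector<double>& A0c, const std::vector<double>& Kc,
                                std::vector<double>& Ab, std::vector<double>& Qb,
                                double* mass_res = 0, double* p_res = 0) {
  int n = Ac.size();
  int m = n + 1;
  double c0p = tl_c(A0p, A0p, Kp, rho);
  double Wp = Qp / Ap + 4.0 * (tl_c(Ap, A0p, Kp, rho) - c0p);
  std::vector<double> c0c(n), Wc(n);
  for (int i = 0; i < n; ++i) {
    c0c[i] = tl_c(A0c[i], A0c[i], Kc[i], rho);
    Wc[i] = Qc[i] / Ac[i] - 4.0 * (tl_c(Ac[i], A0c[i], Kc[i], rho) - c0c[i]);
  }
  std::vector<double> x(m);
  x[0] = Ap;
  for (int i = 0; i < n; ++i) x[i + 1] = Ac[i];

  std::vector<double> u(m), cc(m), P(m), R(m);
  std::vector<std::vector<double>> J(m, std::vector<double>(m, 0.0));
  bool converged = false;

  for (int it = 0; it < 40; ++it) {
    // states from characteristics
    cc[0] = tl_c(x[0], A0p, Kp, rho);
    u[0] = Wp - 4.0 * (cc[0] - c0p);
    P[0] = tl_pressure(x[0], A0p, Kp, pext);
    for (int i = 0; i < n; ++i) {
      cc[i + 1] = tl_c(x[i + 1], A0c[i], Kc[i], rho);
      u[i + 1] = Wc[i] + 4.0 * (cc[i + 1] - c0c[i]);
      P[i + 1] = tl_pressure(x[i + 1], A0c[i], Kc[i], pext);
    }
    // residuals
    R[0] = x[0] * u[0];
    for (int i = 0; i < n; ++i) R[0] -= x[i + 1] * u[i + 1];
    for (int i = 0; i < n; ++i) {
      double lhs = P[0], rhs = P[i + 1];
      if (total_pressure) { lhs += 0.5 * rho * u[0] * u[0]; rhs += 0.5 * rho * u[i + 1] * u[i + 1]; }
      R[i + 1] = lhs - rhs;
    }
    // Jacobian
    // d(Au)/dA: parent u - c, child u + c; dP/dA; d(.5 rho u^2)/dA = rho u du/dA
    double dup = -cc[0] / x[0];
    J[0][0] = u[0] - cc[0];
    for (int i = 0; i < n; ++i) J[0][i + 1] = -(u[i + 1] + cc[i + 1]);
    for (int i = 0; i < n; ++i) {
      double dPp = tl_dPdA(x[0], A0p, Kp);
      double dPc = tl_dPdA(x[i + 1], A0c[i], Kc[i]);
      double lhs = dPp, rhs = dPc;
      if (total_pressure) {
        lhs += rho * u[0] * dup;
        rhs += rho * u[i + 1] * (cc[i + 1] / x[i + 1]);
      }
      J[i + 1][0] = lhs;
      J[i + 1][i + 1] = -rhs;
    }
    // gaussian elimination with partial pivoting (m <= small)
    std::vector<std::vector<double>> M = J;
    std::vector<double> b(m);
    for (int i = 0; i < m; ++i) b[i] = -R[i];
    for (int col = 0; col < m; ++col) {
      int piv = col;
      for (int r2 = col + 1; r2 < m; ++r2)
        if (std::fabs(M[r2][col]) > std::fabs(M[piv][col])) piv = r2;
      std::swap(M[col], M[piv]); std::swap(b[col], b[piv]);
      if (std::fabs(M[col][col]) < 1e-300) stop("junction solve: singular Jacobian");
      for (int r2 = col + 1; r2 < m; ++r2) {
        double f = M[r2][col] / M[col][col];
        for (int c2 = col; c2 < m; ++c2) M[r2][c2] -= f * M[col][c2];
        b[r2] -= f * b[col];
      }
    }
    std::vector<double> dx(m);
    for (int r2 = m - 1; r2 >= 0; --r2) {
      double s = b[r2];
      for (int c2 = r2 + 1; c2 < m; ++c2) s -= M[r2][c2] * dx[c2];
      dx[r2] = s / M[r2][r2];
    }
    double step = 0.0, scale = 0.0;
    for (int i = 0; i < m; ++i) {
      if (x[i] + dx[i] <= 0.0) dx[i] = -0.5 * x[i];
      x[i] += dx[i];
      step += std::fabs(dx[i]);
      scale += x[i];
    }
    if (step < 1e-14 * scale) { converged = true; break; }
  }
  if (!converged) stop("junction solve: no convergence in 40 iterations");
  Ab.resize(m); Qb.resize(m);
  cc[0] = tl_c(x[0], A0p, Kp, rho);
  Ab[0] = x[0]; Qb[0] = x[0] * (Wp - 4.0 * (cc[0] - c0p));
  for (int i = 0; i < n; ++i) {
    double c = tl_c(x[i + 1], A0c[i], Kc[i], rho);
    Ab[i + 1] = x[i + 1];
    Qb[i + 1] = x[i + 1] * (Wc[i] + 4.0 * (c - c0c[i]));
  }
  if (mass_res) {
    double md = Qb[0];
    for (int i = 0; i < n; ++i) md -= Qb[i + 1];
    *mass_res = md;
  }
  if (p_res) {
    double pr = 0.0;
    double lhs = tl_pressure(Ab[0], A0p, Kp, pext) + (total_pressure ? 0.5 * rho * (Qb[0] / Ab[0]) * (Qb[0] / Ab[0]) : 0.0);
    for (int i = 0; i < n; ++i) {
      double rhs = tl_pressure(Ab[i + 1], A0c[i], Kc[i], pext) + (total_pressure ? 0.5 * rho * (Qb[i + 1] / Ab[i + 1]) * (Qb[i + 1] / Ab[i + 1]) : 0.0);
      pr = std::max(pr, std::fabs(lhs - rhs));
    }
    *p_res = pr;
  }
}

// lumped stenosis pressure drop
static inline double sten_dp(const Sten& st, double A0, double D0,
                             double mu, double rho, double q, double dqdt) {
  double As = st.ratio * A0;
  double visc = st.Kv * mu / (A0 * D0) * q;
  double turb = st.Kt * rho / (2.0 * A0 * A0) * std::pow(A0 / As - 1.0, 2.0) * q * std::fabs(q);
  double iner = st.Ku * rho * st.Ls / A0 * dqdt;
  return visc + turb + iner;
}

// internal stenosis interface: equal flow, pressure jump dp(q)
static void stenosis_solve(double rho, double pext, double mu,
                           double AeL, double QeL, double A0L, double KL,
                           double AeR, double QeR, double A0R, double KR,
                           Sten& st, double dt, bool commit,
                           double& AL, double& AR, double& qout) {
  double c0L = tl_c(A0L, A0L, KL, rho);
  double c0R = tl_c(A0R, A0R, KR, rho);
  double Wf = QeL / AeL + 4.0 * (tl_c(AeL, A0L, KL, rho) - c0L);
  double Wb = QeR / AeR - 4.0 * (tl_c(AeR, A0R, KR, rho) - c0R);
  double A0s = 0.5 * (A0L + A0R);
  double D0 = 2.0 * std::sqrt(A0s / M_PI);
  double xL = AeL, xR = AeR;
  for (int it = 0; it < 60; ++it) {
    double cL = tl_c(xL, A0L, KL, rho), cR = tl_c(xR, A0R, KR, rho);
    double uL = Wf - 4.0 * (cL - c0L), uR = Wb + 4.0 * (cR - c0R);
    double qL = xL * uL, qR = xR * uR;
    double q = 0.5 * (qL + qR);
    double dqdt = (dt > 0.0) ? (q - st.q) / dt : 0.0;
    double r1 = qL - qR;
    double r2 = tl_pressure(xL, A0L, KL, pext) - tl_pressure(xR, A0R, KR, pext)
              - sten_dp(st, A0s, D0, mu, rho, q, dqdt);
    double dqLdA = uL - cL, dqRdA = uR + cR;
    // d(dp)/dq
    double As = st.ratio * A0s;
    double ddp_dq = st.Kv * mu / (A0s * D0)
                  + st.Kt * rho / (A0s * A0s) * std::pow(A0s / As - 1.0, 2.0) * std::fabs(q)
                  + ((dt > 0.0) ? st.Ku * rho * st.Ls / (A0s * dt) : 0.0);
    double J11 = dqLdA, J12 = -dqRdA;
    double J21 = tl_dPdA(xL, A0L, KL) - ddp_dq * 0.5 * dqLdA;
    double J22 = -tl_dPdA(xR, A0R, KR) - ddp_dq * 0.5 * dqRdA;
    double det = J11 * J22 - J12 * J21;
    if (std::fabs(det) < 1e-300) stop("stenosis solve: singular Jacobian");
    double dxL = (-r1 * J22 + r2 * J12) / det;
    double dxR = (-J11 * r2 + J21 * r1) / det;
    if (xL + dxL <= 0.0) dxL = -0.5 * xL;
    if (xR + dxR <= 0.0) dxR = -0.5 * xR;
    xL += dxL; xR += dxR;
    if (std::fabs(dxL) + std::fabs(dxR) < 1e-14 * (xL + xR)) break;
  }
  double cL = tl_c(xL, A0L, KL, rho), cR = tl_c(xR, A0R, KR, rho);
  double q = 0.5 * (xL * (Wf - 4.0 * (cL - c0L)) + xR * (Wb + 4.0 * (cR - c0R)));
  AL = xL; AR = xR; qout = q;
  if (commit) st.q = q;
}

// ---------------------------------------------------------------------------
// Spatial operator: MUSCL reconstruction + HLL flux + sources

static inline double limit_slope(double a, double b, int limiter) {
  if (limiter == 1) { // minmod
    if (a * b <= 0.0) return 0.0;
    return (std::fabs(a) < std::fabs(b)) ? a : b;
  }
  return 0.5 * (a + b); // centred (Fromm), for smooth problems
}

static inline void hll_flux(double AL, double QL, double AR, double QR,
                            double A0i, double Ki, double rho, double alpha,
                            double& F1, double& F2) {
  double cL = tl_c(AL, A0i, Ki, rho), cR = tl_c(AR, A0i, Ki, rho);
  double uL = QL / AL, uR = QR / AR;
  double SL = std::min(uL - cL, uR - cR);
  double SR = std::max(uL + cL, uR + cR);
  double F1L = QL, F1R = QR;
  double F2L = alpha * QL * uL + tl_C1(AL, A0i, Ki, rho);
  double F2R = alpha * QR * uR + tl_C1(AR, A0i, Ki, rho);
  if (SL >= 0.0)      { F1 = F1L; F2 = F2L; }
  else if (SR <= 0.0) { F1 = F1R; F2 = F2R; }
  else {
    F1 = (SR * F1L - SL * F1R + SL * SR * (AR - AL)) / (SR - SL);
    F2 = (SR * F2L - SL * F2R + SL * SR * (QR - QL)) / (SR - SL);
  }
}

// RHS of one vessel given resolved boundary states, optional stenosis
// overrides, and optional forcing arrays (for manufactured solutions).
static void vessel_rhs(const Net& net, const Vessel& vs,
                       const std::vector<double>& A, const std::vector<double>& Q,
                       const std::vector<Sten*>& sten_here,
                       const std::vector<double>* stenAL,
                       const std::vector<double>* stenAR,
                       const std::vector<double>* stenq,
                       const double* forcA, const double* forcQ,
                       std::vector<double>& dA, std::vector<double>& dQ) {
  int n = vs.n;
  double dx = vs.dx, rho = net.rho, alpha = net.alpha, pext = net.pext;
  std::vector<double> sA(n, 0.0), sQ(n, 0.0); // slopes
  if (net.order >= 2) {
    for (int i = 1; i < n - 1; ++i) {
      sA[i] = limit_slope(A[i] - A[i - 1], A[i + 1] - A[i], net.limiter);
      sQ[i] = limit_slope(Q[i] - Q[i - 1], Q[i + 1] - Q[i], net.limiter);
    }
  }
  // interface fluxes 0..n; boundary interfaces from resolved states
  std::vector<double> F1(n + 1), F2(n + 1);
  {
    double f1, f2;
    // left boundary: state (bAL, bQL) with first-cell props
    hll_flux(vs.bAL, vs.bQL, vs.bAL, vs.bQL, vs.A0[0], vs.K[0], rho, alpha, f1, f2);
    F1[0] = f1; F2[0] = f2;
    hll_flux(vs.bAR, vs.bQR, vs.bAR, vs.bQR, vs.A0[n - 1], vs.K[n - 1], rho, alpha, f1, f2);
    F1[n] = f1; F2[n] = f2;
  }
  for (int i = 1; i < n; ++i) {
    double AL = A[i - 1] + 0.5 * sA[i - 1], QL = Q[i - 1] + 0.5 * sQ[i - 1];
    double AR = A[i] - 0.5 * sA[i],         QR = Q[i] - 0.5 * sQ[i];
    if (AL <= 0.0) AL = A[i - 1];
    if (AR <= 0.0) AR = A[i];
    double A0i = 0.5 * (vs.A0[i - 1] + vs.A0[i]);
    double Ki  = 0.5 * (vs.K[i - 1] + vs.K[i]);
    hll_flux(AL, QL, AR, QR, A0i, Ki, rho, alpha, F1[i], F2[i]);
  }
  // stenosis overrides: flux seen by the two adjacent cells differs
  int nst = sten_here.size();
  dA.assign(n, 0.0); dQ.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double f1L = F1[i], f2L = F2[i], f1R = F1[i + 1], f2R = F2[i + 1];
    for (int k = 0; k < nst; ++k) {
      int j = sten_here[k]->iface;
      if (i == j - 1) { // right flux of the upstream cell
        double a = (*stenAL)[k], q = (*stenq)[k];
        f1R = q; f2R = alpha * q * q / a + tl_C1(a, vs.A0[i], vs.K[i], rho);
      }
      if (i == j) {     // left flux of the downstream cell
        double a = (*stenAR)[k], q = (*stenq)[k];
        f1L = q; f2L = alpha * q * q / a + tl_C1(a, vs.A0[i], vs.K[i], rho);
      }
    }
    dA[i] = -(f1R - f1L) / dx;
    dQ[i] = -(f2R - f2L) / dx;
    // friction source f/rho = -fcoef * u / rho
    dQ[i] -= net.fcoef * (Q[i] / A[i]) / rho;
    // geometric source for tapered properties
    double A0x, Kx;
    if (n > 1) {
      if (i == 0)          { A0x = (vs.A0[1] - vs.A0[0]) / dx;          Kx = (vs.K[1] - vs.K[0]) / dx; }
      else if (i == n - 1) { A0x = (vs.A0[n-1] - vs.A0[n-2]) / dx;      Kx = (vs.K[n-1] - vs.K[n-2]) / dx; }
      else                 { A0x = (vs.A0[i+1] - vs.A0[i-1]) / (2*dx);  Kx = (vs.K[i+1] - vs.K[i-1]) / (2*dx); }
    } else { A0x = 0.0; Kx = 0.0; }
    if (A0x != 0.0 || Kx != 0.0) {
      double Ai = A[i], A0i = vs.A0[i], Ki = vs.K[i];
      double dC1_dA0 = -Ki * std::pow(Ai, 1.5) / (3.0 * rho * A0i * A0i);
      double dC1_dK  = std::pow(Ai, 1.5) / (3.0 * rho * A0i);
      double dP_dA0  = Ki * (std::sqrt(A0i) / 2.0 - std::sqrt(Ai)) / (A0i * A0i);
      double dP_dK   = (std::sqrt(Ai) - std::sqrt(A0i)) / A0i;
      dQ[i] += dC1_dA0 * A0x + dC1_dK * Kx
             - (Ai / rho) * (dP_dA0 * A0x + dP_dK * Kx);
    }
    if (forcA) dA[i] += forcA[i];
    if (forcQ) dQ[i] += forcQ[i];
  }
}

// operator-split implicit diffusion step for the viscous wall term:
// dQ/dt = (A/rho) d/dx( g dQ/dx ),  g = G / (A0 sqrt(A))
static void viscous_wall_step(const Net& net, Vessel& vs, double dt) {
  int n = vs.n;
  bool any = false;
  for (int i = 0; i < n; ++i) if (vs.G[i] > 0.0) { any = true; break; }
  if (!any) return;
  double dx2 = vs.dx * vs.dx;
  std::vector<double> g(n), lo(n, 0.0), di(n, 0.0), up(n, 0.0), rhs(n);
  for (int i = 0; i < n; ++i) g[i] = vs.G[i] / (vs.A0[i] * std::sqrt(vs.A[i]));
  for (int i = 0; i < n; ++i) {
    double gm = (i > 0) ? 0.5 * (g[i - 1] + g[i]) : 0.0;     // zero-flux ends
    double gp = (i < n - 1) ? 0.5 * (g[i] + g[i + 1]) : 0.0;
    double f = dt * vs.A[i] / (net.rho * dx2);
    lo[i] = -f * gm;
    up[i] = -f * gp;
    di[i] = 1.0 + f * (gm + gp);
    rhs[i] = vs.Q[i];
  }
  // Thomas algorithm
  for (int i = 1; i < n; ++i) {
    double w = lo[i] / di[i - 1];
    di[i] -= w * up[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  vs.Q[n - 1] = rhs[n - 1] / di[n - 1];
  for (int i = n - 2; i >= 0; --i) vs.Q[i] = (rhs[i] - up[i] * vs.Q[i + 1]) / di[i];
}

// ---------------------------------------------------------------------------
// Inlet specification and waveform lookup

struct Inlet {
  int type;                    // 0 flow table, 1 pressure table, 2 closed, 3 cavity valve
  std::vector<double> wt, wv;  // waveform samples
  double period;
  double pcav, B, L, q;        // valve state (type 3)
};

static Inlet unpack_inlet(const List& il) {
  Inlet in;
  in.type = as<int>(il["type"]);
  in.period = 0.0; in.pcav = 0.0; in.B = 0.0; in.L = 0.0; in.q = 0.0;
  if (in.type <= 1) {
    NumericVector t = il["wt"], v = il["wv"];
    in.wt.assign(t.begin(), t.end());
    in.wv.assign(v.begin(), v.end());
    in.period = as<double>(il["period"]);
  } else if (in.type == 3) {
    in.pcav = as<double>(il["p_cav"]);
    in.B = as<double>(il["B"]);
    in.L = as<double>(il["L"]);
    in.q = as<double>(il["q0"]);
  }
  return in;
}

static double waveform_at(const Inlet& in, double t) {
  double tp = t - std::floor(t / in.period) * in.period;
  if (tp < 0) tp += in.period;
  const std::vector<double>& wt = in.wt;
  const std::vector<double>& wv = in.wv;
  size_t n = wt.size();
  if (tp <= wt.front()) return wv.front();
  if (tp >= wt.back()) {
    // wrap between last and first sample
    double dt = in.period - wt.back() + wt.front();
    if (dt <= 0) return wv.back();
    double w = (tp - wt.back()) / dt;
    return (1 - w) * wv.back() + w * wv.front();
  }
  size_t hi = std::upper_bound(wt.begin(), wt.end(), tp) - wt.begin();
  double w = (tp - wt[hi - 1]) / (wt[hi] - wt[hi - 1]);
  return (1 - w) * wv[hi - 1] + w * wv[hi];
}

// ---------------------------------------------------------------------------
// Network driver

struct RunDiag {
  double vol_in = 0.0;            // integral of inlet mass flux
  double vol_out_ends = 0.0;      // integral of terminal-end mass flux
  double micro_out = 0.0;         // integral of flow through peripheral R
  double cap_charge = 0.0;        // sum of C * dPc
  double max_junc_defect = 0.0;   // absolute junction mass defect (m^3/s)
  double max_junc_q = 0.0;
  double max_junc_pres = 0.0;     // junction pressure-matching residual (Pa)
  double minA = 1e300;
  double inletP_last = 0.0, inletQ_last = 0.0;
};

// resolve all boundary states for one substep; commits lumped states
static void resolve_all_bcs(Net& net, Inlet& in, double t, double dt, RunDiag& dg) {
  // inlet on vessel 0, left end
  Vessel& r0 = net.v[0];
  double Ae = r0.A[0], Qe = r0.Q[0], A0 = r0.A0[0], K = r0.K[0];
  switch (in.type) {
  case 0: { double q = waveform_at(in, t);
            bc_inflow_q(Ae, Qe, A0, K, net.rho, net.pext, q, r0.bAL, r0.bQL); break; }
  case 1: { double p = waveform_at(in, t);
            bc_pressure(Ae, Qe, A0, K, net.rho, net.pext, p, r0.bAL, r0.bQL); break; }
  case 2: bc_closed_left(Ae, Qe, A0, K, net.rho, net.pext, r0.bAL, r0.bQL); break;
  case 3: { bool open; double qn;
            bc_valve(Ae, Qe, A0, K, net.rho, net.pext, in.pcav, in.B, in.L, in.q, dt,
                     r0.bAL, r0.bQL, qn, open);
            in.q = qn; break; }
  default: stop("unknown inlet type");
  }
  dg.inletP_last = tl_pressure(r0.bAL, A0, K, net.pext);
  dg.inletQ_last = r0.bQL;

  // terminals
  for (size_t k = 0; k < net.term.size(); ++k) {
    Term& tm = net.term[k];
    Vessel& vs = net.v[tm.vessel];
    int n = vs.n;
    double PcOld = tm.Pc;
    bc_windkessel(vs.A[n - 1], vs.Q[n - 1], vs.A0[n - 1], vs.K[n - 1],
                  net.rho, net.pext, tm, dt, vs.bAR, vs.bQR, true);
    dg.vol_out_ends += dt * vs.bQR;
    if (tm.C > 0.0) {
      dg.cap_charge += tm.C * (tm.Pc - PcOld);
      dg.micro_out += dt * (tm.Pc - tm.Pout) / tm.R;
    } else {
      dg.micro_out += dt * vs.bQR;
    }
  }

  // junctions
  for (size_t k = 0; k < net.junc.size(); ++k) {
    Junc& j = net.junc[k];
    Vessel& vp = net.v[j.parent];
    int np = vp.n;
    int nc = j.children.size();
    std::vector<double> Ac(nc), Qc(nc), A0c(nc), Kc(nc);
    for (int i = 0; i < nc; ++i) {
      Vessel& vc = net.v[j.children[i]];
      Ac[i] = vc.A[0]; Qc[i] = vc.Q[0]; A0c[i] = vc.A0[0]; Kc[i] = vc.K[0];
    }
    std::vector<double> Ab, Qb;
    double mres = 0.0, pres = 0.0;
    junction_solve_core(net.rho, net.pext, net.total_pressure,
                        vp.A[np - 1], vp.Q[np - 1], vp.A0[np - 1], vp.K[np - 1],
                        Ac, Qc, A0c, Kc, Ab, Qb, &mres, &pres);
    vp.bAR = Ab[0]; vp.bQR = Qb[0];
    for (int i = 0; i < nc; ++i) {
      Vessel& vc = net.v[j.children[i]];
      vc.bAL = Ab[i + 1]; vc.bQL = Qb[i + 1];
      dg.max_junc_q = std::max(dg.max_junc_q, std::fabs(Qb[i + 1]));
    }
    dg.max_junc_q = std::max(dg.max_junc_q, std::fabs(Qb[0]));
    dg.max_junc_defect = std::max(dg.max_junc_defect, std::fabs(mres));
    dg.max_junc_pres = std::max(dg.max_junc_pres, pres);
  }
  dg.vol_in += dt * net.v[0].bQL;
}

// one substep: resolve BCs, Heun update of all vessels, viscous split
static void net_step(Net& net, Inlet& in, double t, double dt, RunDiag& dg,
                     double mu) {
  resolve_all_bcs(net, in, t, dt, dg);

  int nv = net.v.size();
  // stenosis interface states (fixed over the substep)
  int nst = net.sten.size();
  std::vector<std::vector<Sten*>> sten_by_v(nv);
  std::vector<std::vector<double>> stAL(nv), stAR(nv), stq(nv);
  for (int k = 0; k < nst; ++k) {
    Sten& st = net.sten[k];
    Vessel& vs = net.v[st.vessel];
    int j = st.iface;
    double AL, AR, q;
    stenosis_solve(net.rho, net.pext, mu,
                   vs.A[j - 1], vs.Q[j - 1], vs.A0[j - 1], vs.K[j - 1],
                   vs.A[j], vs.Q[j], vs.A0[j], vs.K[j],
                   st, dt, true, AL, AR, q);
    sten_by_v[st.vessel].push_back(&st);
    stAL[st.vessel].push_back(AL);
    stAR[st.vessel].push_back(AR);
    stq[st.vessel].push_back(q);
  }

  // Heun
  for (int iv = 0; iv < nv; ++iv) {
    Vessel& vs = net.v[iv];
    int n = vs.n;
    std::vector<double> k1A, k1Q, k2A, k2Q, A1(n), Q1(n);
    vessel_rhs(net, vs, vs.A, vs.Q, sten_by_v[iv], &stAL[iv], &stAR[iv], &stq[iv],
               0, 0, k1A, k1Q);
    for (int i = 0; i < n; ++i) { A1[i] = vs.A[i] + dt * k1A[i]; Q1[i] = vs.Q[i] + dt * k1Q[i]; }
    for (int i = 0; i < n; ++i)
      if (A1[i] <= 0.0) stop("1D instability: negative area, vessel %d element %d", iv + 1, i + 1);
    vessel_rhs(net, vs, A1, Q1, sten_by_v[iv], &stAL[iv], &stAR[iv], &stq[iv],
               0, 0, k2A, k2Q);
    for (int i = 0; i < n; ++i) {
      vs.A[i] += 0.5 * dt * (k1A[i] + k2A[i]);
      vs.Q[i] += 0.5 * dt * (k1Q[i] + k2Q[i]);
      if (vs.A[i] <= 0.0)
        stop("1D instability: negative area, vessel %d element %d", iv + 1, i + 1);
      dg.minA = std::min(dg.minA, vs.A[i]);
    }
    viscous_wall_step(net, vs, dt);
  }
}

// [[Rcpp::export(name = ".cw_run")]]
List cw_run(List net_list, List inlet_list, double dt, int nsteps, double t0,
            double mu, IntegerMatrix probes, int rec_every) {
  Net net = unpack_net(net_list);
  Inlet in = unpack_inlet(inlet_list);
  RunDiag dg;

  int np = probes.nrow();
  int nrec = 0;
  if (rec_every > 0) nrec = nsteps / rec_every;
  NumericMatrix probP(nrec, np), probQ(nrec, np);
  NumericVector recT(nrec), recInP(nrec), recInQ(nrec);
  int ir = 0;

  for (int s = 0; s < nsteps; ++s) {
    double t = t0 + s * dt;
    net_step(net, in, t, dt, dg, mu);
    if (rec_every > 0 && ((s + 1) % rec_every == 0) && ir < nrec) {
      recT[ir] = t + dt;
      recInP[ir] = dg.inletP_last;
      recInQ[ir] = dg.inletQ_last;
      for (int p = 0; p < np; ++p) {
        Vessel& vs = net.v[probes(p, 0) - 1];
        int e = probes(p, 1) - 1;
        probP(ir, p) = tl_pressure(vs.A[e], vs.A0[e], vs.K[e], net.pext);
        probQ(ir, p) = vs.Q[e];
      }
      ++ir;
    }
  }

  // pack state back
  List Aout(net.v.size()), Qout(net.v.size());
  double stored = 0.0;
  for (size_t i = 0; i < net.v.size(); ++i) {
    Aout[i] = NumericVector(net.v[i].A.begin(), net.v[i].A.end());
    Qout[i] = NumericVector(net.v[i].Q.begin(), net.v[i].Q.end());
    for (int e = 0; e < net.v[i].n; ++e) stored += net.v[i].A[e] * net.v[i].dx;
  }
  NumericVector Pc(net.term.size());
  for (size_t i = 0; i < net.term.size(); ++i) Pc[i] = net.term[i].Pc;
  NumericVector sq(net.sten.size());
  for (size_t i = 0; i < net.sten.size(); ++i) sq[i] = net.sten[i].q;

  return List::create(
    _["A"] = Aout, _["Q"] = Qout, _["P_state"] = Pc, _["sten_q"] = sq,
    _["valve_q"] = in.q,
    _["vol_in"] = dg.vol_in, _["vol_out_ends"] = dg.vol_out_ends,
    _["micro_out"] = dg.micro_out, _["cap_charge"] = dg.cap_charge,
    _["max_junc_defect"] = dg.max_junc_defect, _["max_junc_q"] = dg.max_junc_q,
    _["max_junc_pres"] = dg.max_junc_pres,
    _["min_A"] = dg.minA, _["stored_volume"] = stored,
    _["inlet_P"] = dg.inletP_last, _["inlet_Q"] = dg.inletQ_last,
    _["t_end"] = t0 + nsteps * dt,
    _["rec_t"] = recT, _["rec_inlet_P"] = recInP, _["rec_inlet_Q"] = recInQ,
    _["rec_probe_P"] = probP, _["rec_probe_Q"] = probQ);
}

// ---------------------------------------------------------------------------
// Single-segment stepper with explicit ghost cells and forcing arrays,
// used by advance() and the manufactured-solution convergence tests.
// ghostL / ghostR: 4 x (nsteps+1) matrices, rows (A_-2, Q_-2, A_-1, Q_-1)
// and (A_n, Q_n, A_n+1, Q_n+1); forcing: n x (nsteps+1) matrices (dA, dQ).

static void seg_rhs_ghost(const Net& net, const Vessel& vs,
                          const std::vector<double>& A, const std::vector<double>& Q,
                          const double* gl, const double* gr,
                          const double* fA, const double* fQ,
                          std::vector<double>& dA, std::vector<double>& dQ,
                          double* bflux = 0) {
  int n = vs.n;
  // extended arrays with two ghost cells per side
  std::vector<double> Ax(n + 4), Qx(n + 4);
  Ax[0] = gl[0]; Qx[0] = gl[1]; Ax[1] = gl[2]; Qx[1] = gl[3];
  for (int i = 0; i < n; ++i) { Ax[i + 2] = A[i]; Qx[i + 2] = Q[i]; }
  Ax[n + 2] = gr[0]; Qx[n + 2] = gr[1]; Ax[n + 3] = gr[2]; Qx[n + 3] = gr[3];
  auto prop = [&](int j) { // clamp props to vessel range for ghosts
    int i = std::min(std::max(j - 2, 0), n - 1);
    return i;
  };
  std::vector<double> sA(n + 4, 0.0), sQ(n + 4, 0.0);
  if (net.order >= 2) {
    for (int i = 1; i < n + 3; ++i) {
      sA[i] = limit_slope(Ax[i] - Ax[i - 1], Ax[i + 1] - Ax[i], net.limiter);
      sQ[i] = limit_slope(Qx[i] - Qx[i - 1], Qx[i + 1] - Qx[i], net.limiter);
    }
  }
  std::vector<double> F1(n + 1), F2(n + 1);
  for (int f = 0; f <= n; ++f) {
    int iL = f + 1, iR = f + 2; // extended indices of neighbour cells
    double AL = Ax[iL] + 0.5 * sA[iL], QL = Qx[iL] + 0.5 * sQ[iL];
    double AR = Ax[iR] - 0.5 * sA[iR], QR = Qx[iR] - 0.5 * sQ[iR];
    if (AL <= 0.0) AL = Ax[iL];
    if (AR <= 0.0) AR = Ax[iR];
    int pL = prop(iL), pR = prop(iR);
    double A0i = 0.5 * (vs.A0[pL] + vs.A0[pR]);
    double Ki  = 0.5 * (vs.K[pL] + vs.K[pR]);
    hll_flux(AL, QL, AR, QR, A0i, Ki, net.rho, net.alpha, F1[f], F2[f]);
  }
  dA.assign(n, 0.0); dQ.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    dA[i] = -(F1[i + 1] - F1[i]) / vs.dx;
    dQ[i] = -(F2[i + 1] - F2[i]) / vs.dx;
    dQ[i] -= net.fcoef * (Q[i] / A[i]) / net.rho;
    if (fA) dA[i] += fA[i];
    if (fQ) dQ[i] += fQ[i];
  }
  if (bflux) { bflux[0] = F1[0]; bflux[1] = F1[n]; }
}

// [[Rcpp::export(name = ".cw_segment_run")]]
List cw_segment_run(List seg, double dt, int nsteps,
                    NumericMatrix ghostL, NumericMatrix ghostR,
                    Nullable<NumericMatrix> forcA_, Nullable<NumericMatrix> forcQ_) {
  Net net;
  net.rho = as<double>(seg["rho"]); net.alpha = as<double>(seg["alpha"]);
  net.fcoef = as<double>(seg["fcoef"]); net.pext = as<double>(seg["pext"]);
  net.order = as<int>(seg["order"]); net.limiter = as<int>(seg["limiter"]);
  net.total_pressure = true;
  Vessel vs;
  NumericVector A = seg["A"], Q = seg["Q"], A0 = seg["A0"], K = seg["K"], G = seg["G"];
  vs.n = A.size(); vs.dx = as<double>(seg["dx"]);
  vs.A.assign(A.begin(), A.end()); vs.Q.assign(Q.begin(), Q.end());
  vs.A0.assign(A0.begin(), A0.end()); vs.K.assign(K.begin(), K.end());
  vs.G.assign(G.begin(), G.end());

  bool hasF = forcA_.isNotNull();
  NumericMatrix fA, fQ;
  if (hasF) { fA = forcA_.get(); fQ = forcQ_.get(); }
  int n = vs.n;
  std::vector<double> gl(4), gr(4), fa(n), fq(n), fa2(n), fq2(n);
  std::vector<double> k1A, k1Q, k2A, k2Q, A1(n), Q1(n);
  double bf1[2], bf2[2];
  double vol_in = 0.0, vol_out = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    for (int r = 0; r < 4; ++r) { gl[r] = ghostL(r, s); gr[r] = ghostR(r, s); }
    if (hasF) for (int i = 0; i < n; ++i) { fa[i] = fA(i, s); fq[i] = fQ(i, s); }
    seg_rhs_ghost(net, vs, vs.A, vs.Q, gl.data(), gr.data(),
                  hasF ? fa.data() : 0, hasF ? fq.data() : 0, k1A, k1Q, bf1);
    for (int i = 0; i < n; ++i) { A1[i] = vs.A[i] + dt * k1A[i]; Q1[i] = vs.Q[i] + dt * k1Q[i]; }
    for (int i = 0; i < n; ++i)
      if (A1[i] <= 0.0) stop("1D instability: negative area at element %d", i + 1);
    for (int r = 0; r < 4; ++r) { gl[r] = ghostL(r, s + 1); gr[r] = ghostR(r, s + 1); }
    if (hasF) for (int i = 0; i < n; ++i) { fa2[i] = fA(i, s + 1); fq2[i] = fQ(i, s + 1); }
    seg_rhs_ghost(net, vs, A1, Q1, gl.data(), gr.data(),
                  hasF ? fa2.data() : 0, hasF ? fq2.data() : 0, k2A, k2Q, bf2);
    for (int i = 0; i < n; ++i) {
      vs.A[i] += 0.5 * dt * (k1A[i] + k2A[i]);
      vs.Q[i] += 0.5 * dt * (k1Q[i] + k2Q[i]);
      if (vs.A[i] <= 0.0) stop("1D instability: negative area at element %d", i + 1);
    }
    vol_in += 0.5 * dt * (bf1[0] + bf2[0]);
    vol_out += 0.5 * dt * (bf1[1] + bf2[1]);
    viscous_wall_step(net, vs, dt);
  }
  return List::create(_["A"] = NumericVector(vs.A.begin(), vs.A.end()),
                      _["Q"] = NumericVector(vs.Q.begin(), vs.Q.end()),
                      _["vol_flux_in"] = vol_in, _["vol_flux_out"] = vol_out);
}

// ---------------------------------------------------------------------------
// Small exported wrappers so unit tests exercise the exact same boundary
// solvers the driver uses.

// [[Rcpp::export(name = ".cw_wk_update")]]
double cw_wk_update(double Pc, double Q, double dt, double R, double C, double Pout) {
  return wk_update(Pc, Q, dt, R, C, Pout);
}

// [[Rcpp::export(name = ".cw_bc_windkessel")]]
NumericVector cw_bc_windkessel(double Ae, double Qe, double A0, double K,
                               double rho, double pext,
                               double Z, double R, double C, double Pout,
                               double Pc, double dt) {
  if (R <= 0.0) stop("invalid terminal: R must be positive");
  Term t; t.vessel = 0; t.Z = Z; t.R = R; t.C = C; t.Pout = Pout; t.Pc = Pc;
  double Ab, Qb;
  bc_windkessel(Ae, Qe, A0, K, rho, pext, t, dt, Ab, Qb, true);
  return NumericVector::create(_["A"] = Ab, _["Q"] = Qb, _["P_state"] = t.Pc);
}

// [[Rcpp::export(name = ".cw_bc_inflow")]]
NumericVector cw_bc_inflow(double Ae, double Qe, double A0, double K,
                           double rho, double pext, int kind, double value) {
  double Ab, Qb;
  if (kind == 0) bc_inflow_q(Ae, Qe, A0, K, rho, pext, value, Ab, Qb);
  else if (kind == 1) bc_pressure(Ae, Qe, A0, K, rho, pext, value, Ab, Qb);
  else bc_closed_left(Ae, Qe, A0, K, rho, pext, Ab, Qb);
  return NumericVector::create(_["A"] = Ab, _["Q"] = Qb);
}

// [[Rcpp::export(name = ".cw_bc_valve")]]
NumericVector cw_bc_valve(double Ae, double Qe, double A0, double K,
                          double rho, double pext, double pcav,
                          double B, double L, double qprev, double dt) {
  double Ab, Qb, qn; bool open;
  bc_valve(Ae, Qe, A0, K, rho, pext, pcav, B, L, qprev, dt, Ab, Qb, qn, open);
  return NumericVector::create(_["A"] = Ab, _["Q"] = Qb, _["q"] = qn,
                               _["open"] = open ? 1.0 : 0.0);
}

// [[Rcpp::export(name = ".cw_junction_solve")]]
List cw_junction_solve(NumericVector parent_state, NumericVector parent_wall,
                       NumericMatrix child_states, NumericMatrix child_walls,
                       double rho, double pext, bool total_pressure) {
  int nc = child_states.ncol();
  std::vector<double> Ac(nc), Qc(nc), A0c(nc), Kc(nc);
  for (int i = 0; i < nc; ++i) {
    Ac[i] = child_states(0, i); Qc[i] = child_states(1, i);
    A0c[i] = child_walls(0, i); Kc[i] = child_walls(1, i);
  }
  std::vector<double> Ab, Qb;
  double mres = 0.0, pres = 0.0;
  junction_solve_core(rho, pext, total_pressure,
                      parent_state[0], parent_state[1],
                      parent_wall[0], parent_wall[1],
                      Ac, Qc, A0c, Kc, Ab, Qb, &mres, &pres);
  NumericMatrix out(2, nc + 1);
  for (int i = 0; i <= nc; ++i) { out(0, i) = Ab[i]; out(1, i) = Qb[i]; }
  return List::create(_["states"] = out, _["mass_residual"] = mres,
                      _["pressure_residual"] = pres);
}

// [[Rcpp::export(name = ".cw_stenosis_solve")]]
NumericVector cw_stenosis_solve(NumericVector left_state, NumericVector left_wall,
                                NumericVector right_state, NumericVector right_wall,
                                double ratio, double Ls,
                                double Kv, double Kt, double Ku,
                                double qprev, double dt,
                                double rho, double pext, double mu) {
  Sten st; st.vessel = 0; st.iface = 0;
  st.ratio = ratio; st.Ls = Ls; st.Kv = Kv; st.Kt = Kt; st.Ku = Ku; st.q = qprev;
  double AL, AR, q;
  stenosis_solve(rho, pext, mu,
                 left_state[0], left_state[1], left_wall[0], left_wall[1],
                 right_state[0], right_state[1], right_wall[0], right_wall[1],
                 st, dt, false, AL, AR, q);
  return NumericVector::create(_["A_left"] = AL, _["A_right"] = AR, _["q"] = q);
}
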