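// One-dimensional semi-infinite diffusion-reaction solver for cyclic voltammetry.
//
// Transport: dC_s/dt = D d2C_s/dx2 + R_s(C), common diffusion coefficient D.
// Electrode boundary (x = 0): concentration-dependent Butler-Volmer flux for each
// electroactive couple, zero flux for all other species. Bulk Dirichlet at x = L.
//
// Space: geometrically expanding grid (first interval resolves the thinner of the
// scan diffusion layer sqrt(D*RT/(F*v)) and the kinetic reaction layer sqrt(D/k)).
// Time: theta-scheme for diffusion (Crank-Nicolson default, implicit Euler
// optional; a stiffness guard switches to implicit Euler when dt*k_max > 0.8,
// where Crank-Nicolson would ring). All first-order homogeneous kinetics are
// treated fully implicitly inside the linear solve as 2x2 block-tridiagonal
// chains, so arbitrarily fast C steps reach their correct quasi-steady reaction
// layer without operator-splitting error. The Butler-Volmer boundary is fully
// implicit and solved exactly as a small dense system over the surface
// concentrations after tridiagonal elimination. DISP1 uses its limiting law
// (fast disproportionation, quasi-steady intermediate: net 2B -> A + P at rate
// ki*B), which is linear and joins the same implicit block treatment.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double FCONST = 96485.33212;   // C/mol
static const double RCONST = 8.314462618;   // J/(mol K)

struct Couple { int iO; int iR; double E0; };

static inline double clamped_exp(double x) {
  if (x > 50.0) x = 50.0;
  if (x < -50.0) x = -50.0;
  return std::exp(x);
}

// [[Rcpp::export]]
List simulate_cv_cpp(int mech, List params, double v, List protocol, List solver,
                     int save_conc_every = 0) {
  const double E0_1  = as<double>(params["E0_1"]);
  const double E0_2  = params.containsElementNamed("E0_2") && !Rf_isNull(params["E0_2"]) ?
                         as<double>(params["E0_2"]) : E0_1;
  const double k0    = as<double>(params["k0"]);
  const double alpha = as<double>(params["alpha"]);
  const double kf    = params.containsElementNamed("kf") ? as<double>(params["kf"]) : 0.0;
  const double kb    = params.containsElementNamed("kb") ? as<double>(params["kb"]) : 0.0;
  const double ki    = params.containsElementNamed("ki") ? as<double>(params["ki"]) : 0.0;
  const double kd    = params.containsElementNamed("kd") ? as<double>(params["kd"]) : 0.0;
  const double D     = as<double>(params["D"]);
  const double Cb    = as<double>(params["C_bulk"]);
  const double Cdl   = params.containsElementNamed("Cdl") ? as<double>(params["Cdl"]) : 0.0;

  const double E_start  = as<double>(protocol["E_start"]);
  const double E_vertex = as<double>(protocol["E_vertex"]);
  const int    n_cycles = as<int>(protocol["n_cycles"]);
  const double T        = as<double>(protocol["T"]);

  const int    M        = as<int>(solver["n_space"]);
  int          n_time   = as<int>(solver["n_time_per_cycle"]);
  const double Lfac     = as<double>(solver["L_factor"]);
  const std::string scheme = as<std::string>(solver["scheme"]);
  const int    kd_sub   = as<int>(solver["kd_substeps"]);

  if (v <= 0.0) stop("scan rate must be positive");
  if (M < 50) stop("n_space must be >= 50");
  if (n_time < 200) stop("n_time_per_cycle must be >= 200");
  if (n_time % 2 != 0) n_time += 1;

  const double kdcm = kd * 1000.0;   // M^-1 s^-1 -> cm^3 mol^-1 s^-1
  const double f = FCONST / (RCONST * T);
  const double span = std::fabs(E_start - E_vertex);
  const double t_cycle = 2.0 * span / v;
  const double t_total = n_cycles * t_cycle;
  const double dt = t_cycle / n_time;
  const double sgn = (E_vertex > E_start) ? 1.0 : -1.0;  // forward sweep direction

  // species bookkeeping -------------------------------------------------------
  // Each mechanism has scalar (reaction-free) species plus at most one pair
  // coupled by first-order kinetics, dy/dt = -K y with K = [[kf,-kb],[-kf,kb]]
  // (or [[ki,0],[-ki,0]] for the irreversible B -> C of ECE/DISP1).
  int ns;
  std::vector<Couple> couples;
  arma::vec bulk;
  int bp = -1, bq = -1;              // block-chain species pair
  double K11 = 0, K12 = 0, K21 = 0, K22 = 0;
  switch (mech) {
    case 1: ns = 2; couples.push_back({0, 1, E0_1});
            bulk = {Cb, 0.0}; break;
    case 2: ns = 3; couples.push_back({0, 1, E0_1});
            bulk = {Cb, 0.0, 0.0};
            bp = 1; bq = 2; K11 = kf; K12 = -kb; K21 = -kf; K22 = kb; break;
    case 3: { ns = 3; couples.push_back({1, 2, E0_1});
            double Keq = (kb > 0.0) ? kf / kb : (kf > 0.0 ? 1e12 : 0.0);
            double Afrac = (kf + kb > 0.0) ? Keq / (1.0 + Keq) : 0.0;
            bulk = {Cb * (1.0 - Afrac), Cb * Afrac, 0.0};
            bp = 0; bq = 1; K11 = kf; K12 = -kb; K21 = -kf; K22 = kb; } break;
    case 4: ns = 4; couples.push_back({0, 1, E0_1}); couples.push_back({2, 3, E0_2});
            bulk = {Cb, 0.0, 0.0, 0.0};
            bp = 1; bq = 2; K11 = ki; K21 = -ki; break;
    case 5:
            // DISP1 limiting law (fast disproportionation): C is quasi-steady,
            // net 2B -> A + P at rate ki*B, so dB/dt = -2ki B, dA/dt = +ki B,
            // dP/dt = +ki B. Block pair (B, A); P receives an explicit source.
            ns = 4; couples.push_back({0, 1, E0_1});
            bulk = {Cb, 0.0, 0.0, 0.0};
            bp = 1; bq = 0; K11 = 2.0 * ki; K21 = -ki; break;
    default: stop("unknown mechanism id");
  }

  // stiffness guard: Crank-Nicolson rings when dt * k is large ---------------
  double kmax = 0.0;
  if (mech == 2 || mech == 3) kmax = kf + kb;
  if (mech == 4) kmax = ki;
  if (mech == 5) kmax = 2.0 * ki;
  double theta = (scheme == "implicit_euler") ? 1.0 : 0.5;
  if (dt * kmax > 0.8) theta = 1.0;

  // spatial grid --------------------------------------------------------------
  const double L = Lfac * std::sqrt(D * t_total);
  double h0 = std::sqrt(D * RCONST * T / (FCONST * v)) / 16.0;
  if (kmax > 0.0) h0 = std::min(h0, std::sqrt(D / kmax) / 6.0);

  arma::vec dx(M - 1), x(M);
  if (h0 * (M - 1) >= L) {
    dx.fill(L / (M - 1));
  } else {
    double lo = 1.0 + 1e-12, hi = 2.0;
    auto tot = [&](double om) {
      return h0 * (std::pow(om, M - 1) - 1.0) / (om - 1.0);
    };
    while (tot(hi) < L) hi *= 2.0;
    for (int it = 0; it < 200; ++it) {
      double mid = 0.5 * (lo + hi);
      if (tot(mid) < L) lo = mid; else hi = mid;
    }
    double om = 0.5 * (lo + hi);
    for (int j = 0; j < M - 1; ++j) dx(j) = h0 * std::pow(om, j);
  }
  x(0) = 0.0;
  for (int j = 1; j < M; ++j) x(j) = x(j - 1) + dx(j - 1);

  // diffusion operator coefficients ------------------------------------------
  arma::vec acoef(M, arma::fill::zeros), ccoef(M, arma::fill::zeros);
  for (int j = 1; j < M - 1; ++j) {
    double w = dx(j - 1) + dx(j);
    acoef(j) = 2.0 * D / (w * dx(j - 1));
    ccoef(j) = 2.0 * D / (w * dx(j));
  }
  const double beta = 2.0 / dx(0);
  const double g0 = dt * beta * D / dx(0) * theta;     // theta-weighted diffusion
  const double gflux = dt * beta;                      // fully implicit BV flux

  // time-independent elimination factors --------------------------------------
  // scalar chain (shared by all reaction-free species)
  arma::vec fel(M, arma::fill::zeros), dinv(M, arma::fill::ones);
  for (int j = M - 2; j >= 1; --j) {
    double den = 1.0 + theta * dt * (acoef(j) + ccoef(j)) - theta * dt * ccoef(j) * fel(j + 1);
    dinv(j) = 1.0 / den;
    fel(j) = theta * dt * acoef(j) * dinv(j);
  }
  // block chain for the kinetically coupled pair
  arma::mat G11(1, 1), Fb;                    // placeholders
  arma::vec bG11, bG12, bG21, bG22, bF11, bF12, bF21, bF22;
  bool has_block = (bp >= 0);
  if (has_block) {
    bG11.zeros(M); bG12.zeros(M); bG21.zeros(M); bG22.zeros(M);
    bF11.zeros(M); bF12.zeros(M); bF21.zeros(M); bF22.zeros(M);
    double Fn11 = 0, Fn12 = 0, Fn21 = 0, Fn22 = 0;   // F_{j+1}
    for (int j = M - 2; j >= 1; --j) {
      double d0 = 1.0 + theta * dt * (acoef(j) + ccoef(j));
      double tc = theta * dt * ccoef(j), ta = theta * dt * acoef(j);
      double a11 = d0 + dt * K11 - tc * Fn11;
      double a12 =      dt * K12 - tc * Fn12;
      double a21 =      dt * K21 - tc * Fn21;
      double a22 = d0 + dt * K22 - tc * Fn22;
      double det = a11 * a22 - a12 * a21;
      double g11 =  a22 / det, g12 = -a12 / det, g21 = -a21 / det, g22 = a11 / det;
      bG11(j) = g11; bG12(j) = g12; bG21(j) = g21; bG22(j) = g22;
      Fn11 = ta * g11; Fn12 = ta * g12; Fn21 = ta * g21; Fn22 = ta * g22;
      bF11(j) = Fn11; bF12(j) = Fn12; bF21(j) = Fn21; bF22(j) = Fn22;
    }
  }

  // state ---------------------------------------------------------------------
  arma::mat C(ns, M);
  for (int s = 0; s < ns; ++s) C.row(s).fill(bulk(s));

  const int ntot = n_cycles * n_time;
  arma::vec outE(ntot), outIf(ntot), outIc(ntot);
  arma::ivec outCyc(ntot), outDir(ntot);
  double min_conc = 0.0;
  List conc_snaps;
  std::vector<double> snap_t;

  arma::mat evec(ns, M);                  // per-step elimination RHS (scalars)
  arma::vec e2p(M), e2q(M);               // block-chain RHS pair
  const int half = n_time / 2;
  arma::mat S(ns, ns);
  arma::vec rhs(ns), C0(ns);

  int idx = 0;
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    for (int k = 1; k <= n_time; ++k, ++idx) {
      bool fwd = (k <= half);
      double Enew = fwd ? E_start + sgn * v * dt * k
                        : E_vertex - sgn * v * dt * (k - half);
      double dEdt = fwd ? sgn * v : -sgn * v;

      std::vector<double> kredv(couples.size()), koxv(couples.size());
      for (size_t q = 0; q < couples.size(); ++q) {
        double eta = f * (Enew - couples[q].E0);
        kredv[q] = k0 * clamped_exp(-alpha * eta);
        koxv[q]  = k0 * clamped_exp((1.0 - alpha) * eta);
      }

      // backward elimination: scalar species
      for (int s = 0; s < ns; ++s) {
        if (s == bp || s == bq) continue;
        evec(s, M - 1) = bulk(s);
        for (int j = M - 2; j >= 1; --j) {
          double lap = acoef(j) * C(s, j - 1) - (acoef(j) + ccoef(j)) * C(s, j) +
                       ccoef(j) * C(s, j + 1);
          double r = C(s, j) + (1.0 - theta) * dt * lap;
          if (mech == 5 && s == 3) r += dt * ki * C(1, j);
          evec(s, j) = (r + theta * dt * ccoef(j) * evec(s, j + 1)) * dinv(j);
        }
      }
      // backward elimination: block pair
      if (has_block) {
        e2p(M - 1) = bulk(bp); e2q(M - 1) = bulk(bq);
        for (int j = M - 2; j >= 1; --j) {
          double lapp = acoef(j) * C(bp, j - 1) - (acoef(j) + ccoef(j)) * C(bp, j) +
                        ccoef(j) * C(bp, j + 1);
          double lapq = acoef(j) * C(bq, j - 1) - (acoef(j) + ccoef(j)) * C(bq, j) +
                        ccoef(j) * C(bq, j + 1);
          double rp = C(bp, j) + (1.0 - theta) * dt * lapp + theta * dt * ccoef(j) * e2p(j + 1);
          double rq = C(bq, j) + (1.0 - theta) * dt * lapq + theta * dt * ccoef(j) * e2q(j + 1);
          e2p(j) = bG11(j) * rp + bG12(j) * rq;
          e2q(j) = bG21(j) * rp + bG22(j) * rq;
        }
      }

      // surface system over the ns unknown surface concentrations -------------
      S.zeros(); rhs.zeros();
      for (int s = 0; s < ns; ++s) {
        double lap0 = beta * D * (C(s, 1) - C(s, 0)) / dx(0);
        rhs(s) = C(s, 0) + (1.0 - theta) * dt * lap0;
        if (mech == 5 && s == 3) rhs(s) += dt * ki * C(1, 0);
        S(s, s) += 1.0 + g0;
        if (s == bp) {
          S(s, bp) += -g0 * bF11(1); S(s, bq) += -g0 * bF12(1);
          rhs(s) += g0 * e2p(1);
        } else if (s == bq) {
          S(s, bp) += -g0 * bF21(1); S(s, bq) += -g0 * bF22(1);
          rhs(s) += g0 * e2q(1);
        } else {
          S(s, s) += -g0 * fel(1);
          rhs(s) += g0 * evec(s, 1);
        }
      }
      if (has_block) {   // node-0 homogeneous kinetics, fully implicit
        S(bp, bp) += dt * K11; S(bp, bq) += dt * K12;
        S(bq, bp) += dt * K21; S(bq, bq) += dt * K22;
      }
      for (size_t q = 0; q < couples.size(); ++q) {
        int iO = couples[q].iO, iR = couples[q].iR;
        S(iO, iO) += gflux * kredv[q]; S(iO, iR) -= gflux * koxv[q];
        S(iR, iO) -= gflux * kredv[q]; S(iR, iR) += gflux * koxv[q];
      }
      // tiny dense solve (ns <= 4): pivoted Gaussian elimination, no LAPACK
      {
        double A[4][5];
        for (int r = 0; r < ns; ++r) {
          for (int c = 0; c < ns; ++c) A[r][c] = S(r, c);
          A[r][ns] = rhs(r);
        }
        for (int c = 0; c < ns; ++c) {
          int piv = c;
          for (int r = c + 1; r < ns; ++r)
            if (std::fabs(A[r][c]) > std::fabs(A[piv][c])) piv = r;
          if (std::fabs(A[piv][c]) < 1e-300)
            stop("non-convergent surface solve (singular boundary system)");
          if (piv != c)
            for (int t = c; t <= ns; ++t) std::swap(A[piv][t], A[c][t]);
          for (int r = c + 1; r < ns; ++r) {
            double fac = A[r][c] / A[c][c];
            for (int t = c; t <= ns; ++t) A[r][t] -= fac * A[c][t];
          }
        }
        for (int r = ns - 1; r >= 0; --r) {
          double s2 = A[r][ns];
          for (int t = r + 1; t < ns; ++t) s2 -= A[r][t] * C0(t);
          C0(r) = s2 / A[r][r];
        }
        if (!C0.is_finite())
          stop("non-convergent surface solve (singular boundary system)");
      }

      double ifar = 0.0;
      for (size_t q = 0; q < couples.size(); ++q) {
        double vb = kredv[q] * C0(couples[q].iO) - koxv[q] * C0(couples[q].iR);
        ifar += -FCONST * vb;   // cathodic (reduction) current negative
      }

      // forward substitution
      for (int s = 0; s < ns; ++s) C(s, 0) = C0(s);
      if (has_block) {
        for (int j = 1; j < M - 1; ++j) {
          double pprev = C(bp, j - 1), qprev = C(bq, j - 1);
          C(bp, j) = e2p(j) + bF11(j) * pprev + bF12(j) * qprev;
          C(bq, j) = e2q(j) + bF21(j) * pprev + bF22(j) * qprev;
        }
        C(bp, M - 1) = bulk(bp); C(bq, M - 1) = bulk(bq);
      }
      for (int s = 0; s < ns; ++s) {
        if (s == bp || s == bq) continue;
        for (int j = 1; j < M - 1; ++j) C(s, j) = evec(s, j) + fel(j) * C(s, j - 1);
        C(s, M - 1) = bulk(s);
      }
      double mn = C.min();
      if (mn < min_conc) min_conc = mn;
      if (!C.is_finite())
        stop("concentration overflow/NaN: reduce the time step or increase kd_substeps");

      outE(idx) = Enew;
      outIf(idx) = ifar;
      outIc(idx) = Cdl * dEdt;
      outCyc(idx) = cyc + 1;
      outDir(idx) = fwd ? 1 : 2;

      if (save_conc_every > 0 && (idx % save_conc_every == 0)) {
        conc_snaps.push_back(wrap(C));
        snap_t.push_back((cyc * n_time + k) * dt);
      }
    }
  }

  return List::create(
    _["E"] = outE, _["i_far"] = outIf, _["i_cap"] = outIc,
    _["cycle"] = outCyc, _["direction"] = outDir,
    _["min_conc_rel"] = min_conc / Cb,
    _["x"] = x,
    _["conc"] = conc_snaps, _["conc_t"] = wrap(snap_t));
}
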