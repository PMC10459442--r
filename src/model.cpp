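// Whole-body PBPK core for IgG antibodies: organ mass balances with
// two-pore transcapillary exchange, endosomal FcRn salvage and an
// optional TMDD extension, integrated with an L-stable Rosenbrock
// (Rodas3) method.  All amounts in nmol, volumes in L, time in days.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Model {
  int nOrg;
  double Vc;                       // central plasma pool volume (L)
  arma::vec Vpl, Vis, Vendo;       // organ subspace volumes (L)
  arma::vec Q, Lf;                 // plasma and lymph flows (L/day)
  arma::mat SIG, PS, JF;           // per organ x pore-class: sigma, PS (L/day),
                                   // fraction of lymph flow through class
  double sigL;                     // lymph reflection coefficient
  arma::vec clup;                  // endosomal uptake clearance (L/day)
  double kdegE, krec, frecP;       // endosomal degradation/recycling rates
  double konFc, koffFc;            // FcRn binding (1/(nmol/L)/day, 1/day)
  arma::vec fcrnC;                 // endosomal FcRn concentration (nmol/L)
  bool fcrnDyn;                    // dynamic (conserved) FcRn vs clamped
  bool hasTarget;
  double konT, koffT, kdegT, kintT;
  double R0c;                      // central target amount at baseline (nmol)
  arma::ivec exprIdx;              // 0-based organ indices with target states
  arma::vec R0is;                  // baseline interstitial target amounts (nmol)
  int nExpr, nState, baseT, iLedE, iLedT;
};

Model unpack(const List& p) {
  Model m;
  m.nOrg  = as<int>(p["n_org"]);
  m.Vc    = as<double>(p["v_central"]);
  m.Vpl   = as<arma::vec>(p["v_plasma"]);
  m.Vis   = as<arma::vec>(p["v_interstitial"]);
  m.Vendo = as<arma::vec>(p["v_endosomal"]);
  m.Q     = as<arma::vec>(p["q_plasma"]);
  m.Lf    = as<arma::vec>(p["q_lymph"]);
  m.SIG   = as<arma::mat>(p["sigma"]);
  m.PS    = as<arma::mat>(p["ps"]);
  m.JF    = as<arma::mat>(p["j_frac"]);
  m.sigL  = as<double>(p["sigma_lymph"]);
  m.clup  = as<arma::vec>(p["cl_up"]);
  m.kdegE = as<double>(p["k_deg_endo"]);
  m.krec  = as<double>(p["k_rec"]);
  m.frecP = as<double>(p["f_recycle_plasma"]);
  m.konFc = as<double>(p["kon_fcrn"]);
  m.koffFc= as<double>(p["koff_fcrn"]);
  m.fcrnC = as<arma::vec>(p["fcrn_conc"]);
  m.fcrnDyn = as<bool>(p["fcrn_dynamic"]);
  m.hasTarget = as<bool>(p["has_target"]);
  if (m.hasTarget) {
    m.konT  = as<double>(p["kon_target"]);
    m.koffT = as<double>(p["koff_target"]);
    m.kdegT = as<double>(p["kdeg_target"]);
    m.kintT = as<double>(p["kint_target"]);
    m.R0c   = as<double>(p["r0_central"]);
    m.exprIdx = as<arma::ivec>(p["expr_idx"]);
    m.R0is  = as<arma::vec>(p["r0_interstitial"]);
    m.nExpr = m.exprIdx.n_elem;
  } else {
    m.konT = m.koffT = m.kdegT = m.kintT = m.R0c = 0.0;
    m.nExpr = 0;
  }
  m.baseT  = 1 + 5 * m.nOrg;
  int nT   = m.hasTarget ? 2 + 2 * m.nExpr : 0;
  m.iLedE  = m.baseT + nT;
  m.iLedT  = m.iLedE + 1;
  m.nState = m.iLedT + 1;
  return m;
}

// Net plasma -> interstitial two-pore flux for one organ (nmol/day).
double transcap_flux(const Model& m, int i, double Cp, double Ci) {
  double F = 0.0;
  for (arma::uword k = 0; k < m.SIG.n_cols; ++k) {
    double J  = m.JF(i, k) * m.Lf(i);
    double s  = m.SIG(i, k);
    double ps = m.PS(i, k);
    double conv = J * (1.0 - s);
    F += conv * Cp;
    if (ps > 0.0) {
      double Pe = conv / ps;
      if (Pe < 1e-8) {
        F += ps * (Cp - Ci);
      } else if (Pe < 500.0) {
        F += ps * (Cp - Ci * std::exp(-Pe)) * Pe / (std::expm1(Pe));
      } // Pe >= 500: diffusive correction vanishes
    }
  }
  return F;
}

void rhs(const Model& m, double inf_rate, const arma::vec& y, arma::vec& dy) {
  dy.zeros(m.nState);
  const double Cc = y(0) / m.Vc;
  double dAc = inf_rate;
  double elimE = 0.0, elimT = 0.0;
  for (int i = 0; i < m.nOrg; ++i) {
    const int b = 1 + 5 * i;
    const double Apl = y(b), Ais = y(b + 1), Ae = y(b + 2),
                 Afc = y(b + 3), Acx = y(b + 4);
    const double Cp = Apl / m.Vpl(i), Ci = Ais / m.Vis(i);
    // vascular exchange with central pool; lymph returns interstitial drug
    dAc += (m.Q(i) - m.Lf(i)) * Cp - m.Q(i) * Cc +
           m.Lf(i) * (1.0 - m.sigL) * Ci;
    double dApl = m.Q(i) * Cc - (m.Q(i) - m.Lf(i)) * Cp;
    double dAis = -m.Lf(i) * (1.0 - m.sigL) * Ci;
    const double F = transcap_flux(m, i, Cp, Ci);
    dApl -= F; dAis += F;
    // endosomal uptake from both sides of the endothelium
    const double upP = m.clup(i) * Cp, upI = m.clup(i) * Ci;
    dApl -= upP; dAis -= upI;
    const double fcC  = m.fcrnDyn ? Afc / m.Vendo(i) : m.fcrnC(i);
    const double bind = m.konFc * Ae * fcC;
    const double diss = m.koffFc * Acx;
    const double rec  = m.krec * Acx;
    const double deg  = m.kdegE * Ae;
    dy(b + 2) = upP + upI - bind + diss - deg;
    dy(b + 4) = bind - diss - rec;
    dy(b + 3) = m.fcrnDyn ? (-bind + diss + rec) : 0.0;
    dApl += m.frecP * rec;
    dAis += (1.0 - m.frecP) * rec;
    elimE += deg;
    dy(b) = dApl; dy(b + 1) = dAis;
  }
  if (m.hasTarget) {
    // central plasma target
    const double Rc = y(m.baseT), DRc = y(m.baseT + 1);
    const double bT = m.konT * y(0) * Rc / m.Vc;
    dy(m.baseT)     = m.kdegT * m.R0c - m.kdegT * Rc - bT + m.koffT * DRc;
    dy(m.baseT + 1) = bT - m.koffT * DRc - m.kintT * DRc;
    dAc += -bT + m.koffT * DRc;
    elimT += m.kintT * DRc;
    // interstitial target in expressing organs
    for (int j = 0; j < m.nExpr; ++j) {
      const int i = m.exprIdx(j);
      const int b = 1 + 5 * i;
      const int tb = m.baseT + 2 + 2 * j;
      const double R = y(tb), DR = y(tb + 1);
      const double bI = m.konT * y(b + 1) * R / m.Vis(i);
      dy(tb)     = m.kdegT * m.R0is(j) - m.kdegT * R - bI + m.koffT * DR;
      dy(tb + 1) = bI - m.koffT * DR - m.kintT * DR;
      dy(b + 1) += -bI + m.koffT * DR;
      elimT += m.kintT * DR;
    }
  }
  dy(0) = dAc;
  dy(m.iLedE) = elimE;
  dy(m.iLedT) = elimT;
}

void num_jacobian(const Model& m, double inf_rate, const arma::vec& y,
                  const arma::vec& f0, arma::mat& J) {
  const int n = m.nState;
  arma::vec yp = y, f1(n);
  for (int j = 0; j < n; ++j) {
    const double d = 1e-7 * std::abs(y(j)) + 1e-9;
    yp(j) = y(j) + d;
    rhs(m, inf_rate, yp, f1);
    J.col(j) = (f1 - f0) / d;
    yp(j) = y(j);
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_model_rhs")]]
arma::vec cpp_model_rhs(const arma::vec& y, const List& params,
                        double inf_rate) {
  Model m = unpack(params);
  if ((int)y.n_elem != m.nState)
    stop("state vector has length %d, model expects %d",
         (int)y.n_elem, m.nState);
  arma::vec dy;
  rhs(m, inf_rate, y, dy);
  return dy;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_state_dim")]]
int cpp_state_dim(const List& params) {
  return unpack(params).nState;
}

// Rodas3 coefficients (4-stage, order 3(2), stiffly accurate, L-stable).
// Formulation: (I/(h*gamma) - J) K_i = f(Y_i) + sum_j (C_ij/h) K_j,
//              Y_i = y + sum_j A_ij K_j,  y1 = y + sum M_i K_i,
//              err = sum E_i K_i.
//' @noRd
// [[Rcpp::export(name = ".cpp_integrate_piece")]]
List cpp_integrate_piece(const arma::vec& y0, double t0, double t1,
                         const arma::vec& out_times, double inf_rate,
                         const List& params, double rtol, double atol,
                         double h_init) {
  Model m = unpack(params);
  const int n = m.nState;
  if ((int)y0.n_elem != n) stop("bad state dimension");
  const double gam = 0.5;
  const double a31 = 2.0, a41 = 2.0, a43 = 1.0;
  const double c21 = 4.0, c31 = 1.0, c32 = -1.0,
               c41 = 1.0, c42 = -1.0, c43 = -8.0 / 3.0;
  const double m1 = 2.0, m3 = 1.0, m4 = 1.0;

  arma::mat out(out_times.n_elem, n, arma::fill::zeros);
  arma::uword iout = 0;
  while (iout < out_times.n_elem && out_times(iout) <= t0 + 1e-12) {
    out.row(iout) = y0.t();
    ++iout;
  }

  arma::vec y = y0, f0(n), f1(n), ytmp(n), ynew(n), yerr(n);
  arma::mat J(n, n), W(n, n);
  arma::vec k1(n), k2(n), k3(n), k4(n);
  double t = t0;
  double h = std::min(h_init, t1 - t0);
  if (h <= 0) h = 1e-8;
  long nstep = 0, nrej = 0;
  const long max_step = 2000000;

  while (t < t1 - 1e-12 * std::max(1.0, t1)) {
    if (++nstep > max_step)
      stop("solver exceeded %ld steps at t = %g (h = %g)", max_step, t, h);
    // do not step past the next output time or the piece end
    double tlimit = t1;
    if (iout < out_times.n_elem && out_times(iout) < tlimit)
      tlimit = out_times(iout);
    if (t + h > tlimit) h = tlimit - t;
    if (h < 1e-14) { t = tlimit; h = 1e-8; continue; }

    rhs(m, inf_rate, y, f0);
    num_jacobian(m, inf_rate, y, f0, J);
    W = arma::eye(n, n) / (h * gam) - J;
    arma::mat Winv;
    if (!arma::inv(Winv, W))
      stop("singular Rosenbrock iteration matrix at t = %g", t);

    k1 = Winv * f0;
    rhs(m, inf_rate, y, f1);                       // Y2 = y (a21 = 0)
    k2 = Winv * (f1 + (c21 / h) * k1);
    ytmp = y + a31 * k1;                           // alpha3 = 1
    rhs(m, inf_rate, ytmp, f1);
    k3 = Winv * (f1 + (c31 / h) * k1 + (c32 / h) * k2);
    ytmp = y + a41 * k1 + a43 * k3;
    rhs(m, inf_rate, ytmp, f1);
    k4 = Winv * (f1 + (c41 / h) * k1 + (c42 / h) * k2 + (c43 / h) * k3);

    ynew = y + m1 * k1 + m3 * k3 + m4 * k4;
    yerr = k4;

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::abs(y(i)), std::abs(ynew(i)));
      double e = yerr(i) / sc;
      err += e * e;
    }
    err = std::sqrt(err / n);

    bool neg_guard = ynew.min() < -1e3 * atol;
    if (err <= 1.0 && !neg_guard) {
      t += h;
      y = ynew;
      for (int i = 0; i < n; ++i) if (y(i) < 0 && y(i) > -1e3 * atol) y(i) = 0;
      while (iout < out_times.n_elem && out_times(iout) <= t + 1e-12) {
        out.row(iout) = y.t();
        ++iout;
      }
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -1.0 / 3.0);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      ++nrej;
      if (nrej > max_step) stop("step size underflow at t = %g", t);
      double fac = err > 1.0
        ? 0.9 * std::pow(err, -1.0 / 3.0) : 0.5;
      h *= std::min(0.9, std::max(0.1, fac));
      if (h < 1e-14)
        stop("step size underflow at t = %g (err = %g)", t, err);
    }
  }
  while (iout < out_times.n_elem && out_times(iout) <= t1 + 1e-9) {
    out.row(iout) = y.t();
    ++iout;
  }
  return List::create(_["states"] = out, _["y_end"] = y,
                      _["n_steps"] = (double)nstep,
                      _["n_rejected"] = (double)nrej);
}
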