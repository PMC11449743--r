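// Compiled core: full PK/PD right-hand side and a stiff integrator.
//
// The ODE system tracks LNP lipid, sgRNA, mRNA, Cas9 and the RNP complex
// across plasma, a three-layer liver (vascular / interstitial / cellular),
// the mononuclear phagocyte system, kidney (LNP and sgRNA only) and a lumped
// remainder, plus the LDL-receptor pool and three biomarker models (TTR
// indirect response, PCSK9 transit/feedback chain, LDL-C precursor model).
// Amounts are in ug, volumes in mL, flows in mL/h, PK time in hours;
// biomarker rate constants are supplied in 1/day and converted here.
//
// The integrator is a 2(3) L-stable Rosenbrock method (Shampine-Reichelt
// ode23s scheme) with a forward-difference Jacobian refreshed every step,
// adaptive step size, and exact landing on requested output times and on the
// end-of-infusion discontinuity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NS = 29;

// state indices
enum {
  S_PL_LNP = 0, S_PL_LNPO, S_PL_SG, S_PL_M,
  S_LV_LNP, S_LV_LNPO, S_LV_SG, S_LV_M,
  S_MPS,
  S_LI_LNP, S_LI_CPLX, S_LI_SG, S_LI_M,
  S_LC_SG, S_LC_M, S_LC_CAS, S_LC_RNP,
  S_RFREE,
  S_KID_LNP, S_KID_SG,
  S_REM_LNP, S_REM_SG, S_REM_M,
  S_TTR,
  S_TR1, S_TR2, S_TR3,
  S_PCSK9,
  S_LDL
};

// parameter indices -- order must match qsp_param_names() on the R side
enum {
  P_V_PLASMA = 0, P_V_LV, P_V_LI, P_V_LC, P_V_KID, P_V_REM,
  P_Q_LIV, P_Q_KID, P_Q_REM, P_LYMPH_FRACTION,
  P_SIGMA_V_LNP, P_SIGMA_V_RNA, P_SIGMA_I,
  P_K_IN_ENDO, P_K_OUT_EXO, P_K_DEG_DR, P_LDL_TOT, P_K_DIS, P_K_ASS,
  P_K_RELEASE, P_K_DEG_LNP, P_K_EL, P_K_DEG_SGRNA, P_K_DEG_MRNA,
  P_K_DEG_CAS, P_K_OFF_RNP, P_K_ON_RNP, P_K_INT, P_K_ON_LNP, P_K_OFF_LNP,
  P_FU_LNP, P_FU_RNA, P_K_TRANS, P_MW_RATIO, P_LNP_RATIO,
  P_FRAC_SGRNA, P_FRAC_MRNA, P_CL_RENAL_LNP, P_CL_RENAL_SGRNA,
  P_CARGO_CELL_FRAC,
  P_TTR0, P_K_OUT_TTR, P_IMAX_TTR, P_IC50_TTR, P_GAMMA_TTR,
  P_PCSK9_0, P_MTT, P_N_TRANSIT, P_IMAX_PCSK9, P_IC50_PCSK9, P_GAMMA_PCSK9,
  P_GAMMA_FB, P_FEEDBACK_ON, P_GAMMA_LDL, P_K_DEG_LDL, P_LDL0,
  P_CLAMP_RNP, P_INF_LNP, P_INF_SGRNA, P_INF_MRNA, P_INF_END,
  P_FU_RECEPTOR_GATE, P_CELL_EXO_FRAC, P_OPS_EXTRAVASATION,
  NPAR
};

static inline double hill_frac(double C, double Imax, double IC50, double g) {
  if (C <= 0.0) return 0.0;
  double cg = std::pow(C, g), ig = std::pow(IC50, g);
  return Imax * cg / (ig + cg);
}

static void qsp_rhs(double t, const double* y, double* dy, const double* p) {
  for (int i = 0; i < NS; ++i) dy[i] = 0.0;

  const double Vp = p[P_V_PLASMA], Vlv = p[P_V_LV], Vli = p[P_V_LI],
               Vlc = p[P_V_LC], Vk = p[P_V_KID], Vr = p[P_V_REM];
  const double Ql = p[P_Q_LIV], Qk = p[P_Q_KID], Qr = p[P_Q_REM];
  const double lf = p[P_LYMPH_FRACTION];
  const double Ll = lf * Ql, Lk = lf * Qk, Lr = lf * Qr;
  const double sVL = p[P_SIGMA_V_LNP], sVR = p[P_SIGMA_V_RNA],
               sI = p[P_SIGMA_I];

  // concentrations
  const double Cpl_LNP  = y[S_PL_LNP]  / Vp;
  const double Cpl_LNPo = y[S_PL_LNPO] / Vp;
  const double Cpl_sg   = y[S_PL_SG]   / Vp;
  const double Cpl_m    = y[S_PL_M]    / Vp;
  const double Clv_LNP  = y[S_LV_LNP]  / Vlv;
  const double Clv_LNPo = y[S_LV_LNPO] / Vlv;
  const double Clv_sg   = y[S_LV_SG]   / Vlv;
  const double Clv_m    = y[S_LV_M]    / Vlv;
  const double Cli_LNP  = y[S_LI_LNP]  / Vli;
  const double Cli_sg   = y[S_LI_SG]   / Vli;
  const double Cli_m    = y[S_LI_M]    / Vli;
  const double Ccplx    = y[S_LI_CPLX] / Vli;
  const double Clc_sg   = y[S_LC_SG]   / Vlc;
  const double Ckid_LNP = y[S_KID_LNP] / Vk;
  const double Ckid_sg  = y[S_KID_SG]  / Vk;
  const double Crem_LNP = y[S_REM_LNP] / Vr;
  const double Crem_sg  = y[S_REM_SG]  / Vr;
  const double Crem_m   = y[S_REM_M]   / Vr;

  const bool infusing = (t < p[P_INF_END]);
  const double rate_LNP = infusing ? p[P_INF_LNP]   : 0.0;
  const double rate_sg  = infusing ? p[P_INF_SGRNA] : 0.0;
  const double rate_m   = infusing ? p[P_INF_MRNA]  : 0.0;

  // --- LNP lipid -----------------------------------------------------------
  // opsonin binding (plasma and liver vascular pools)
  const double ops_pl = p[P_K_ASS] * y[S_PL_LNP] - p[P_K_DIS] * y[S_PL_LNPO];
  const double ops_lv = p[P_K_ASS] * y[S_LV_LNP] - p[P_K_DIS] * y[S_LV_LNPO];

  // vascular -> interstitial transfer for free LNP (endocytic + convective)
  const double clin_LNP  = p[P_K_IN_ENDO] * Vlv * Clv_LNP
                         + Ll * (1.0 - sVL) * Clv_LNP;
  const double clout_LNP = p[P_K_OUT_EXO] * Vli * Cli_LNP;
  // corona-bearing LNP extravasates by the same route, shedding its corona
  // on internalization (switchable); it never enters MPS or binds opsonins
  // again in the interstitium
  const double clin_ops = (p[P_OPS_EXTRAVASATION] > 0.5)
    ? p[P_K_IN_ENDO] * Vlv * Clv_LNPo + Ll * (1.0 - sVL) * Clv_LNPo
    : 0.0;

  // receptor binding in the interstitial layer; optionally gated by the
  // plasma free fraction (off by default: the corona-bearing LNP is the
  // receptor ligand, and fu is a renal-clearance-derived quantity)
  const double fu_rec = (p[P_FU_RECEPTOR_GATE] > 0.5) ? p[P_FU_LNP] : 1.0;
  const double bind   = p[P_K_ON_LNP] * fu_rec * Cli_LNP * y[S_RFREE] * Vli;
  const double unbind = p[P_K_OFF_LNP] * y[S_LI_CPLX];

  dy[S_PL_LNP] += rate_LNP
    - (Ql + Qk + Qr) * Cpl_LNP
    + (Ql - Ll) * Clv_LNP
    + (Qk - Lk) * Ckid_LNP + Lk * (1.0 - sI) * Ckid_LNP
    + (Qr - Lr) * Crem_LNP + Lr * (1.0 - sI) * Crem_LNP
    + Ll * (1.0 - sI) * Cli_LNP
    - ops_pl
    - p[P_K_DEG_LNP] * y[S_PL_LNP];

  // opsonized LNP circulates plasma <-> liver vascular only (no sieving)
  dy[S_PL_LNPO] += ops_pl - Ql * Cpl_LNPo + Ql * Clv_LNPo;
  dy[S_LV_LNPO] += ops_lv + Ql * Cpl_LNPo - Ql * Clv_LNPo - clin_ops;

  dy[S_LV_LNP] += Ql * Cpl_LNP - (Ql - Ll) * Clv_LNP
    - p[P_K_INT] * y[S_LV_LNP]
    - ops_lv
    - clin_LNP + clout_LNP
    - p[P_K_DEG_LNP] * y[S_LV_LNP];

  dy[S_MPS] += p[P_K_INT] * y[S_LV_LNP] - p[P_K_DEG_LNP] * y[S_MPS];

  dy[S_LI_LNP] += clin_LNP + clin_ops - clout_LNP
    - Ll * (1.0 - sI) * Cli_LNP
    - bind + unbind
    - p[P_K_DEG_LNP] * y[S_LI_LNP];

  dy[S_LI_CPLX] += bind - unbind - p[P_K_DEG_DR] * y[S_LI_CPLX];

  // LDL receptor pool (ug/mL in the interstitial volume), turnover
  // k_syn = LDL_tot * k_el so the undisturbed baseline is LDL_tot
  dy[S_RFREE] += p[P_LDL_TOT] * p[P_K_EL] - p[P_K_EL] * y[S_RFREE]
    - p[P_K_ON_LNP] * fu_rec * Cli_LNP * y[S_RFREE]
    + p[P_K_OFF_LNP] * Ccplx;

  dy[S_KID_LNP] += Qk * Cpl_LNP - (Qk - Lk) * Ckid_LNP
    - Lk * (1.0 - sI) * Ckid_LNP
    - p[P_CL_RENAL_LNP] * Ckid_LNP
    - p[P_K_DEG_LNP] * y[S_KID_LNP];

  dy[S_REM_LNP] += Qr * Cpl_LNP - (Qr - Lr) * Crem_LNP
    - Lr * (1.0 - sI) * Crem_LNP
    - p[P_K_DEG_LNP] * y[S_REM_LNP];

  // --- cargo release bookkeeping (LNP mass -> RNA mass via lnp_ratio) -----
  const double rel = p[P_K_RELEASE] * y[S_LI_LNP] / p[P_LNP_RATIO];
  const double dr_cargo = p[P_CARGO_CELL_FRAC] * p[P_K_DEG_DR] *
                          y[S_LI_CPLX] / p[P_LNP_RATIO];

  // --- sgRNA ---------------------------------------------------------------
  const double clin_sg_v  = p[P_FU_RNA] *
    (p[P_K_IN_ENDO] * Vlv * Clv_sg + Ll * (1.0 - sVR) * Clv_sg);
  const double clout_sg_v = p[P_K_OUT_EXO] * Vli * Cli_sg;
  // interstitial -> cellular uptake is one-way pinocytosis by default;
  // cell_exo_frac > 0 re-enables exocytic return at that interface
  const double clin_sg_c  = p[P_K_IN_ENDO] * Vli * Cli_sg;
  const double clout_sg_c = p[P_CELL_EXO_FRAC] * p[P_K_OUT_EXO] * Vlc * Clc_sg;

  dy[S_PL_SG] += rate_sg
    - (Ql + Qk + Qr) * Cpl_sg
    + (Ql - Ll) * Clv_sg
    + (Qk - Lk) * Ckid_sg + Lk * (1.0 - sI) * Ckid_sg
    + (Qr - Lr) * Crem_sg + Lr * (1.0 - sI) * Crem_sg
    + Ll * (1.0 - sI) * Cli_sg
    - p[P_K_DEG_SGRNA] * y[S_PL_SG];

  dy[S_LV_SG] += Ql * Cpl_sg - (Ql - Ll) * Clv_sg
    - clin_sg_v + clout_sg_v
    - p[P_K_DEG_SGRNA] * y[S_LV_SG];

  dy[S_LI_SG] += clin_sg_v - clout_sg_v
    - clin_sg_c + clout_sg_c
    - Ll * (1.0 - sI) * Cli_sg
    + rel * p[P_FRAC_SGRNA]
    - p[P_K_DEG_SGRNA] * y[S_LI_SG];

  dy[S_KID_SG] += Qk * Cpl_sg - (Qk - Lk) * Ckid_sg
    - Lk * (1.0 - sI) * Ckid_sg
    - p[P_CL_RENAL_SGRNA] * Ckid_sg
    - p[P_K_DEG_SGRNA] * y[S_KID_SG];

  dy[S_REM_SG] += Qr * Cpl_sg - (Qr - Lr) * Crem_sg
    - Lr * (1.0 - sI) * Crem_sg
    - p[P_K_DEG_SGRNA] * y[S_REM_SG];

  // --- mRNA (no kidney compartment) ---------------------------------------
  const double clin_m_v  = p[P_FU_RNA] *
    (p[P_K_IN_ENDO] * Vlv * Clv_m + Ll * (1.0 - sVR) * Clv_m);
  const double clout_m_v = p[P_K_OUT_EXO] * Vli * Cli_m;
  const double clin_m_c  = p[P_K_IN_ENDO] * Vli * Cli_m;
  const double clout_m_c = p[P_CELL_EXO_FRAC] * p[P_K_OUT_EXO] * y[S_LC_M];

  dy[S_PL_M] += rate_m
    - (Ql + Qr) * Cpl_m
    + (Ql - Ll) * Clv_m
    + (Qr - Lr) * Crem_m + Lr * (1.0 - sI) * Crem_m
    + Ll * (1.0 - sI) * Cli_m
    - p[P_K_DEG_MRNA] * y[S_PL_M];

  dy[S_LV_M] += Ql * Cpl_m - (Ql - Ll) * Clv_m
    - clin_m_v + clout_m_v
    - p[P_K_DEG_MRNA] * y[S_LV_M];

  dy[S_LI_M] += clin_m_v - clout_m_v
    - clin_m_c + clout_m_c
    - Ll * (1.0 - sI) * Cli_m
    + rel * p[P_FRAC_MRNA]
    - p[P_K_DEG_MRNA] * y[S_LI_M];

  dy[S_REM_M] += Qr * Cpl_m - (Qr - Lr) * Crem_m
    - Lr * (1.0 - sI) * Crem_m
    - p[P_K_DEG_MRNA] * y[S_REM_M];

  // --- intracellular layer -------------------------------------------------
  const double mw = p[P_MW_RATIO];           // sgRNA-to-Cas9 mass ratio in RNP
  const double r_ass = p[P_K_ON_RNP] * Clc_sg * y[S_LC_CAS];  // Cas9 ug/h
  const double r_dis = p[P_K_OFF_RNP] * y[S_LC_RNP];          // total RNP ug/h

  dy[S_LC_SG] += clin_sg_c - clout_sg_c
    + dr_cargo * p[P_FRAC_SGRNA]
    - mw * r_ass + r_dis * mw / (1.0 + mw)
    - p[P_K_DEG_SGRNA] * y[S_LC_SG];

  dy[S_LC_M] += clin_m_c - clout_m_c
    + dr_cargo * p[P_FRAC_MRNA]
    - p[P_K_DEG_MRNA] * y[S_LC_M];

  dy[S_LC_CAS] += p[P_K_TRANS] * y[S_LC_M]
    - r_ass + r_dis / (1.0 + mw)
    - p[P_K_DEG_CAS] * y[S_LC_CAS];

  // RNP carries Cas9 + sgRNA mass; no degradation of the complex
  dy[S_LC_RNP] += (1.0 + mw) * r_ass - r_dis;

  // --- pharmacodynamics (rates in 1/day, converted to 1/h) -----------------
  const double C_rnp = (p[P_CLAMP_RNP] >= 0.0)
    ? p[P_CLAMP_RNP] : y[S_LC_RNP] / Vlc;

  const double I_T = hill_frac(C_rnp, p[P_IMAX_TTR], p[P_IC50_TTR],
                               p[P_GAMMA_TTR]);
  dy[S_TTR] += (p[P_K_OUT_TTR] * p[P_TTR0] * (1.0 - I_T)
                - p[P_K_OUT_TTR] * y[S_TTR]) / 24.0;

  const int ntr = (int) p[P_N_TRANSIT];
  const double ktr = ntr / p[P_MTT];
  const double I_P = hill_frac(C_rnp, p[P_IMAX_PCSK9], p[P_IC50_PCSK9],
                               p[P_GAMMA_PCSK9]);
  double fb = 1.0;
  if (p[P_FEEDBACK_ON] > 0.5) {
    double Pobs = std::max(y[S_PCSK9], 1e-9);
    fb = std::pow(p[P_PCSK9_0] / Pobs, p[P_GAMMA_FB]);
  }
  const double syn_P = ktr * p[P_PCSK9_0] * (1.0 - I_P) * fb;
  const int tr_idx[3] = { S_TR1, S_TR2, S_TR3 };
  double upstream = 0.0;
  for (int j = 0; j < ntr; ++j) {
    double in_j = (j == 0) ? syn_P : ktr * y[tr_idx[j - 1]];
    dy[tr_idx[j]] += (in_j - ktr * y[tr_idx[j]]) / 24.0;
  }
  upstream = ktr * y[tr_idx[ntr - 1]];
  dy[S_PCSK9] += (upstream - ktr * y[S_PCSK9]) / 24.0;

  const double Prel = std::max(y[S_PCSK9], 1e-9) / p[P_PCSK9_0];
  dy[S_LDL] += (p[P_K_DEG_LDL] * p[P_LDL0] * std::pow(Prel, p[P_GAMMA_LDL])
                - p[P_K_DEG_LDL] * y[S_LDL]) / 24.0;
}

// [[Rcpp::export]]
NumericVector qsp_rhs_cpp(double t, NumericVector y, NumericVector params) {
  if (y.size() != NS) stop("state vector must have %d entries", NS);
  if (params.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  NumericVector dy(NS);
  qsp_rhs(t, y.begin(), dy.begin(), params.begin());
  return dy;
}

static void num_jac(double t, const arma::vec& y, const arma::vec& f0,
                    arma::mat& J, const double* p) {
  arma::vec yp = y, fp(NS);
  for (int j = 0; j < NS; ++j) {
    double dj = 1.490116e-08 * std::max(std::fabs(y[j]), 1.0);
    yp[j] = y[j] + dj;
    qsp_rhs(t, yp.memptr(), fp.memptr(), p);
    J.col(j) = (fp - f0) / dj;
    yp[j] = y[j];
  }
}

// Integrate one smooth segment [t0, t1], landing exactly on t1.
static void integrate_segment(double t0, double t1, arma::vec& y,
                              const double* p, double rtol, double atol,
                              double hmax) {
  const double d = 1.0 - std::sqrt(2.0) / 2.0;
  const double e32 = 6.0 + std::sqrt(2.0);
  const double span = t1 - t0;
  if (span <= 0.0) return;
  double t = t0;
  double h = std::min(hmax, span);
  // conservative first step from the derivative scale
  arma::vec f0(NS), f1(NS), f2(NS);
  qsp_rhs(t, y.memptr(), f0.memptr(), p);
  double dnorm = 0.0;
  for (int i = 0; i < NS; ++i) {
    double sc = atol + rtol * std::fabs(y[i]);
    dnorm = std::max(dnorm, std::fabs(f0[i]) / sc);
  }
  if (dnorm > 0.0) h = std::min(h, 0.1 / dnorm);
  h = std::max(h, 1e-12 * span);

  arma::mat J(NS, NS), L, U, Pm;
  const double hmin = 1e-13 * std::max(span, 1.0);
  int nstep = 0;
  const int max_steps = 2000000;

  while (t < t1) {
    if (++nstep > max_steps)
      stop("integrator exceeded %d steps at t = %g", max_steps, t);
    if (h > t1 - t) h = t1 - t;
    qsp_rhs(t, y.memptr(), f0.memptr(), p);
    num_jac(t, y, f0, J, p);

    bool accepted = false;
    while (!accepted) {
      if (h < hmin)
        stop("integrator step size underflow at t = %g (|y| = %g)",
             t, arma::norm(y, "inf"));
      arma::mat W = arma::eye(NS, NS) - h * d * J;
      bool ok = arma::lu(L, U, Pm, W);
      if (!ok) { h *= 0.5; continue; }
      arma::vec k1 = arma::solve(arma::trimatu(U),
                     arma::solve(arma::trimatl(L), Pm * f0));
      arma::vec ymid = y + 0.5 * h * k1;
      qsp_rhs(t + 0.5 * h, ymid.memptr(), f1.memptr(), p);
      arma::vec k2 = arma::solve(arma::trimatu(U),
                     arma::solve(arma::trimatl(L), Pm * (f1 - k1))) + k1;
      arma::vec ynew = y + h * k2;
      qsp_rhs(t + h, ynew.memptr(), f2.memptr(), p);
      arma::vec rhs3 = f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0);
      arma::vec k3 = arma::solve(arma::trimatu(U),
                     arma::solve(arma::trimatl(L), Pm * rhs3));
      arma::vec err = (h / 6.0) * (k1 - 2.0 * k2 + k3);

      double errnorm = 0.0;
      bool finite = ynew.is_finite();
      if (finite) {
        for (int i = 0; i < NS; ++i) {
          double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(ynew[i]));
          errnorm = std::max(errnorm, std::fabs(err[i]) / sc);
        }
      } else {
        errnorm = 1e10;
      }

      if (errnorm <= 1.0) {
        t += h;
        y = ynew;
        // flush round-off negatives (within the absolute tolerance band)
        for (int i = 0; i < NS; ++i)
          if (y[i] < 0.0 && y[i] > -atol) y[i] = 0.0;
        double fac = 0.8 * std::pow(std::max(errnorm, 1e-10), -1.0 / 3.0);
        h = std::min(hmax, h * std::min(5.0, std::max(0.2, fac)));
        accepted = true;
      } else {
        double fac = 0.8 * std::pow(errnorm, -1.0 / 3.0);
        h *= std::min(0.9, std::max(0.1, fac));
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix qsp_integrate_cpp(NumericVector times, NumericVector y0,
                                NumericVector params, double rtol,
                                double atol, double hmax) {
  if (y0.size() != NS) stop("state vector must have %d entries", NS);
  if (params.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  int nt = times.size();
  if (nt < 1) stop("empty time grid");
  for (int i = 1; i < nt; ++i)
    if (times[i] <= times[i - 1]) stop("time grid must be strictly increasing");

  NumericMatrix out(nt, NS);
  arma::vec y(y0.begin(), NS);
  for (int j = 0; j < NS; ++j) out(0, j) = y[j];

  // freeze the infusion status within each smooth segment: the pump is "on"
  // for the whole of [t, min(tnext, t_inf)] and "off" afterwards
  NumericVector p_on = clone(params), p_off = clone(params);
  p_on[P_INF_END] = R_PosInf;
  p_off[P_INF_END] = R_NegInf;

  const double t_inf = params[P_INF_END];
  double t = times[0];
  for (int i = 1; i < nt; ++i) {
    double tnext = times[i];
    // cut the step sequence at the infusion switch-off discontinuity
    if (t < t_inf && tnext > t_inf) {
      integrate_segment(t, t_inf, y, p_on.begin(), rtol, atol, hmax);
      t = t_inf;
    }
    const double* pseg = (tnext <= t_inf) ? p_on.begin() : p_off.begin();
    integrate_segment(t, tnext, y, pseg, rtol, atol, hmax);
    t = tnext;
    for (int j = 0; j < NS; ++j) out(i, j) = y[j];
  }
  return out;
}
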