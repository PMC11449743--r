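#' Pharmacodynamic models
#'
#' Three biomarker models are driven by the liver-cell RNP concentration
#' `C_RNP` (ug/mL): serum transthyretin (TTR) follows a type-I indirect
#' response model with inhibition of production; serum PCSK9 follows a
#' transit-compartment model with synthesis feedback; LDL cholesterol
#' follows a precursor-dependent model whose production scales with the
#' PCSK9 signal. All biomarkers are expressed as percent of baseline
#' (baselines fixed at 100) and all turnover rates are in 1/day.
#'
#' @name pd_response
NULL

#' Hill inhibition function
#'
#' `Imax * C^gamma / (IC50^gamma + C^gamma)`, the fractional inhibition of
#' biomarker production at RNP concentration `C`.
#'
#' @param C RNP concentration (ug/mL), >= 0
#' @param Imax maximum inhibition in \[0, 1\]
#' @param IC50 concentration at half-maximal inhibition (ug/mL), > 0
#' @param gamma Hill coefficient, > 0
#' @return inhibition fraction in \[0, Imax\]
#' @export
hill_inhibition <- function(C, Imax, IC50, gamma) {
  if (any(C < 0)) stop("C must be >= 0")
  if (IC50 <= 0) stop("IC50 must be > 0")
  ifelse(C == 0, 0, Imax * C^gamma / (IC50^gamma + C^gamma))
}

#' TTR indirect-response derivative
#'
#' `dTTR/dt = k_in * (1 - I(C_RNP)) - k_out_TTR * TTR` with
#' `k_in = k_out_TTR * TTR0` so the undisturbed baseline is exactly
#' stationary.
#'
#' @param TTR current TTR level (% of baseline)
#' @param C_RNP liver-cell RNP concentration (ug/mL)
#' @param pd PD parameter list (fields `TTR0`, `k_out_TTR`, `Imax_TTR`,
#'   `IC50_TTR`, `gamma_TTR`)
#' @return dTTR/dt in %/day
#' @export
ttr_rhs <- function(TTR, C_RNP, pd) {
  if (TTR < 0) stop("TTR must be >= 0")
  inh <- hill_inhibition(C_RNP, pd$Imax_TTR, pd$IC50_TTR, pd$gamma_TTR)
  pd$k_out_TTR * pd$TTR0 * (1 - inh) - pd$k_out_TTR * TTR
}

#' Steady-state TTR fraction under a constant RNP concentration
#'
#' Closed-form companion of [ttr_rhs()]: `TTR_ss / TTR0 = 1 - I(C_RNP)`,
#' independent of the turnover rate.
#'
#' @inheritParams ttr_rhs
#' @return `TTR_ss / TTR0` in `[1 - Imax, 1]`
#' @export
ttr_steady_state_fraction <- function(C_RNP, pd) {
  1 - hill_inhibition(C_RNP, pd$Imax_TTR, pd$IC50_TTR, pd$gamma_TTR)
}

#' PCSK9 transit/feedback derivatives
#'
#' A chain of `n_transit` compartments with rate `k_tr = n_transit / MTT`;
#' synthesis into the first compartment is inhibited by the Hill term and
#' modulated by the feedback `(PCSK9_0 / PCSK9)^gamma_fb` (switchable);
#' the last compartment feeds the observable PCSK9 pool, which turns over
#' at `k_tr`. At baseline every state sits at `PCSK9_0` and all
#' derivatives vanish.
#'
#' @param transit_states numeric vector of length `n_transit`
#' @param PCSK9 observable PCSK9 level (% of baseline)
#' @param C_RNP liver-cell RNP concentration (ug/mL)
#' @param pd PD parameter list (fields `PCSK9_0`, `MTT`, `n_transit`,
#'   `Imax_PCSK9`, `IC50_PCSK9`, `gamma_PCSK9`, `gamma_fb`, `feedback_on`)
#' @return list with `transit` (derivatives of the chain, %/day) and
#'   `observable` (dPCSK9/dt, %/day)
#' @export
pcsk9_rhs <- function(transit_states, PCSK9, C_RNP, pd) {
  n <- pd$n_transit
  if (length(transit_states) != n)
    stop("transit_states must have length n_transit")
  if (any(transit_states < 0) || PCSK9 < 0) stop("negative states")
  ktr <- n / pd$MTT
  inh <- hill_inhibition(C_RNP, pd$Imax_PCSK9, pd$IC50_PCSK9, pd$gamma_PCSK9)
  fb <- if (pd$feedback_on > 0.5)
    (pd$PCSK9_0 / max(PCSK9, 1e-9))^pd$gamma_fb else 1
  syn <- ktr * pd$PCSK9_0 * (1 - inh) * fb
  dtr <- numeric(n)
  for (j in seq_len(n)) {
    inflow <- if (j == 1) syn else ktr * transit_states[j - 1]
    dtr[j] <- inflow - ktr * transit_states[j]
  }
  list(transit = dtr,
       observable = ktr * transit_states[n] - ktr * PCSK9)
}

#' LDL-C precursor-dependent derivative
#'
#' `dLDL/dt = k_in_LDL * (PCSK9 / PCSK9_0)^Gamma - k_deg_LDL * LDL` with
#' `k_in_LDL = k_deg_LDL * LDL0`: LDL-C production scales with the PCSK9
#' precursor signal raised to the coupling exponent.
#'
#' @param LDL current LDL-C level (% of baseline)
#' @param PCSK9 PCSK9 level (% of baseline)
#' @param pd PD parameter list (fields `PCSK9_0`, `Gamma_LDL`,
#'   `k_deg_LDL`, `LDL0`)
#' @return dLDL/dt in %/day
#' @export
ldl_rhs <- function(LDL, PCSK9, pd) {
  if (LDL < 0 || PCSK9 < 0) stop("negative states")
  if (pd$PCSK9_0 == 0) stop("PCSK9_0 must be > 0")
  prel <- max(PCSK9, 1e-9) / pd$PCSK9_0
  pd$k_deg_LDL * pd$LDL0 * prel^pd$Gamma_LDL - pd$k_deg_LDL * LDL
}
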