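#' Dose regimens
#'
#' A regimen specifies the total-RNA dose (mg/kg), its mass split into sgRNA
#' (default 33.3%) and Cas9 mRNA (default 66.7%), the LNP-to-total-RNA mass
#' ratio (default 18.5, which reproduces the published LNP co-doses of 18.5,
#' 36.7 and 55.5 mg/kg at 1, 2 and 3 mg/kg total RNA), and the route: IV
#' bolus or a 2-h IV infusion. Absolute amounts are in ug.
#'
#' @name dosing
NULL

#' Build a dose regimen
#'
#' @param total_rna_mgkg total RNA dose in mg/kg (>= 0)
#' @param phys a `qsp_physiology` object (supplies body weight)
#' @param route `"bolus"` or `"infusion"`
#' @param frac_sgRNA,frac_mRNA mass fractions of the total RNA dose; must
#'   sum to 1 within 1e-3
#' @param lnp_ratio LNP-to-total-RNA mass ratio
#' @param lnp_dose_mgkg optional explicit LNP dose override (mg/kg), for
#'   study arms whose printed LNP dose does not equal `lnp_ratio` times the
#'   RNA dose
#' @param infusion_duration infusion duration in hours (ignored for bolus)
#' @return an object of class `qsp_regimen`
#' @export
#' @examples
#' reg <- build_regimen(3, load_physiology("nhp"), route = "infusion")
#' reg$lnp_dose_mgkg  # 55.5
build_regimen <- function(total_rna_mgkg, phys,
                          route = c("bolus", "infusion"),
                          frac_sgRNA = 0.333, frac_mRNA = 0.667,
                          lnp_ratio = 18.5, lnp_dose_mgkg = NULL,
                          infusion_duration = 2) {
  route <- match.arg(route)
  if (!is.numeric(total_rna_mgkg) || total_rna_mgkg < 0)
    stop("total RNA dose must be nonnegative")
  if (frac_sgRNA < 0 || frac_sgRNA > 1 || frac_mRNA < 0 || frac_mRNA > 1)
    stop("dose fractions must lie in [0, 1]")
  if (abs(frac_sgRNA + frac_mRNA - 1) > 1e-3)
    stop("frac_sgRNA + frac_mRNA must equal 1 (within 1e-3)")
  if (route == "infusion" && infusion_duration <= 0)
    stop("infusion_duration must be > 0")
  bw <- phys$BW
  lnp_mgkg <- if (is.null(lnp_dose_mgkg)) lnp_ratio * total_rna_mgkg
              else lnp_dose_mgkg
  # absolute amounts: mg/kg * kg * 1000 -> ug
  amt <- function(mgkg) mgkg * bw * 1000
  reg <- list(
    total_rna_mgkg = total_rna_mgkg,
    frac_sgRNA = frac_sgRNA, frac_mRNA = frac_mRNA,
    lnp_ratio = lnp_ratio, lnp_dose_mgkg = lnp_mgkg,
    route = route,
    infusion_duration = if (route == "infusion") infusion_duration else 0,
    BW = bw,
    amt_sgRNA = amt(total_rna_mgkg * frac_sgRNA),
    amt_mRNA = amt(total_rna_mgkg * frac_mRNA),
    amt_LNP = amt(lnp_mgkg)
  )
  class(reg) <- "qsp_regimen"
  reg
}

#' Infusion input rate
#'
#' For a bolus the dose is placed in plasma as an initial condition and the
#' input rate is identically zero. For an infusion the rate is
#' amount/duration on `[0, duration)` and zero afterwards, so its integral
#' equals the administered amount.
#'
#' @param regimen a `qsp_regimen`
#' @param t time (h), >= 0
#' @param component one of `"LNP"`, `"sgRNA"`, `"mRNA"`
#' @return input rate in ug/h
#' @export
infusion_input <- function(regimen, t, component = c("LNP", "sgRNA", "mRNA")) {
  component <- match.arg(component)
  if (any(t < 0)) stop("t must be >= 0")
  if (regimen$route == "bolus") return(rep(0, length(t)))
  amt <- switch(component, LNP = regimen$amt_LNP, sgRNA = regimen$amt_sgRNA,
                mRNA = regimen$amt_mRNA)
  ifelse(t < regimen$infusion_duration, amt / regimen$infusion_duration, 0)
}

#' Allometric scaling of a rate constant
#'
#' `value_ref * (bw_target / bw_ref)^exponent`; the model uses exponent
#' -0.25 to scale the endocytosis rate from monkey to mouse.
#'
#' @param value_ref reference value
#' @param bw_ref,bw_target body weights (kg), > 0
#' @param exponent allometric exponent (default -0.25)
#' @return the scaled value
#' @export
#' @examples
#' scale_allometric(0.039, 5, 0.028)  # ~0.14 1/h
scale_allometric <- function(value_ref, bw_ref, bw_target, exponent = -0.25) {
  if (bw_ref <= 0 || bw_target <= 0) stop("body weights must be > 0")
  value_ref * (bw_target / bw_ref)^exponent
}

#' @export
print.qsp_regimen <- function(x, ...) {
  cat(sprintf("Regimen: %g mg/kg total RNA, %s%s (BW %g kg)\n",
              x$total_rna_mgkg, x$route,
              if (x$route == "infusion")
                sprintf(" over %g h", x$infusion_duration) else "",
              x$BW))
  cat(sprintf("  LNP %g mg/kg | amounts (ug): LNP %g, sgRNA %g, mRNA %g\n",
              x$lnp_dose_mgkg, x$amt_LNP, x$amt_sgRNA, x$amt_mRNA))
  invisible(x)
}
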