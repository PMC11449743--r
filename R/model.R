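#' Model state and parameter layout
#'
#' The disposition model tracks amounts (ug) of LNP lipid, sgRNA, mRNA,
#' Cas9, and the RNP complex across plasma, liver vascular / interstitial /
#' cellular layers, the mononuclear phagocyte system (MPS), kidney, and a
#' lumped remainder, plus the free LDL-receptor concentration (ug/mL) and
#' the three biomarker states (percent of baseline). The kidney compartment
#' exists for LNP and sgRNA only; mRNA is too large for renal filtration
#' and has no kidney states.
#'
#' @return `qsp_state_names()` and `qsp_param_names()` return character
#'   vectors fixing the state and parameter order shared with the compiled
#'   core.
#' @export
qsp_state_names <- function() {
  c("pl_LNP", "pl_LNP_ops", "pl_sgRNA", "pl_mRNA",
    "lv_LNP", "lv_LNP_ops", "lv_sgRNA", "lv_mRNA",
    "mps_LNP",
    "li_LNP", "li_complex", "li_sgRNA", "li_mRNA",
    "lc_sgRNA", "lc_mRNA", "lc_Cas9", "lc_RNP",
    "R_free",
    "kid_LNP", "kid_sgRNA",
    "rem_LNP", "rem_sgRNA", "rem_mRNA",
    "TTR", "tr1", "tr2", "tr3", "PCSK9", "LDL")
}

#' @rdname qsp_state_names
#' @export
qsp_param_names <- function() {
  c("V_plasma", "V_liver_vasc", "V_liver_int", "V_liver_cell", "V_kidney",
    "V_remainder", "Q_liver", "Q_kidney", "Q_remainder", "lymph_fraction",
    "sigma_V_LNP", "sigma_V_RNA", "sigma_I",
    "k_in_endo", "k_out_exo", "k_deg_DR", "LDL_tot", "k_dis", "k_ass",
    "k_release", "k_deg_LNP", "k_el", "k_deg_sgRNA", "k_deg_mRNA",
    "k_deg_Cas", "k_off_RNP", "k_on_RNP", "k_int", "k_on_LNP", "k_off_LNP",
    "fu_LNP", "fu_RNA", "k_trans", "mw_ratio", "lnp_ratio",
    "frac_sgRNA", "frac_mRNA", "CL_renal_LNP", "CL_renal_sgRNA",
    "cargo_cell_frac",
    "TTR0", "k_out_TTR", "Imax_TTR", "IC50_TTR", "gamma_TTR",
    "PCSK9_0", "MTT", "n_transit", "Imax_PCSK9", "IC50_PCSK9",
    "gamma_PCSK9", "gamma_fb", "feedback_on", "Gamma_LDL", "k_deg_LDL",
    "LDL0",
    "clamp_rnp", "inf_LNP", "inf_sgRNA", "inf_mRNA", "inf_end",
    "fu_receptor_gate", "cell_exo_frac", "ops_extravasation")
}

#' Assemble the QSP model
#'
#' Binds a species physiology and a parameter set into a simulatable model
#' object exposing `rhs(t, state)`, `initial_state(regimen)`, and the packed
#' numeric parameter vector consumed by the compiled integrator.
#'
#' @param phys a `qsp_physiology` object
#' @param params a `qsp_parameters` object
#' @param topology optional list; `kidney_mRNA` must be `FALSE` (requesting
#'   a kidney compartment for mRNA is a structural error), `ops_uptake`
#'   must be `FALSE` (opsonized LNP neither enters the MPS nor binds the
#'   receptor)
#' @param regimen optional `qsp_regimen` used to fix the cargo mass
#'   fractions and LNP ratio; defaults to the standard 33.3/66.7 split at
#'   ratio 18.5
#' @param clamp_rnp if >= 0, the biomarker models see this fixed liver-cell
#'   RNP concentration (ug/mL) instead of the simulated one
#' @return an object of class `qsp_model`
#' @export
build_model <- function(phys, params, topology = list(), regimen = NULL,
                        clamp_rnp = -1) {
  stopifnot(inherits(phys, "qsp_physiology"),
            inherits(params, "qsp_parameters"))
  topo <- utils::modifyList(list(kidney_mRNA = FALSE, ops_uptake = FALSE),
                            topology)
  if (isTRUE(topo$kidney_mRNA))
    stop("structural error: mRNA has no kidney compartment")
  if (isTRUE(topo$ops_uptake))
    stop("structural error: opsonized LNP does not enter MPS or receptor")

  pk <- params$pk; pd <- params$pd
  frac_sg <- if (is.null(regimen)) 0.333 else regimen$frac_sgRNA
  frac_m <- if (is.null(regimen)) 0.667 else regimen$frac_mRNA
  lnp_ratio <- if (is.null(regimen)) 18.5 else {
    if (regimen$total_rna_mgkg > 0)
      regimen$lnp_dose_mgkg / regimen$total_rna_mgkg else regimen$lnp_ratio
  }

  pvec <- c(
    phys$V_plasma, phys$V_liver_vasc, phys$V_liver_int, phys$V_liver_cell,
    phys$V_kidney, phys$V_remainder, phys$Q_liver, phys$Q_kidney,
    phys$Q_remainder, phys$lymph_fraction, phys$sigma_V_LNP,
    phys$sigma_V_RNA, phys$sigma_I,
    pk$k_in_endo, pk$k_out_exo, pk$k_deg_DR, pk$LDL_tot, pk$k_dis, pk$k_ass,
    pk$k_release, pk$k_deg_LNP, pk$k_el, pk$k_deg_sgRNA, pk$k_deg_mRNA,
    pk$k_deg_Cas, pk$k_off_RNP, k_on_rnp(params), pk$k_int, pk$k_on_LNP,
    pk$k_off_LNP, pk$fu_LNP, pk$fu_RNA, pk$k_trans,
    pk$MW_sgRNA / pk$MW_Cas9, lnp_ratio, frac_sg, frac_m,
    pk$fu_LNP * phys$Q_kidney, pk$fu_RNA * phys$Q_kidney,
    pk$cargo_cell_frac,
    pd$TTR0, pd$k_out_TTR, pd$Imax_TTR, pd$IC50_TTR, pd$gamma_TTR,
    pd$PCSK9_0, pd$MTT, pd$n_transit, pd$Imax_PCSK9, pd$IC50_PCSK9,
    pd$gamma_PCSK9, pd$gamma_fb, pd$feedback_on, pd$Gamma_LDL,
    pd$k_deg_LDL, pd$LDL0,
    clamp_rnp, 0, 0, 0, -1,
    pk$fu_receptor_gate, pk$cell_exo_frac, pk$ops_extravasation)
  names(pvec) <- qsp_param_names()

  model <- list(phys = phys, params = params, topology = topo, pvec = pvec)
  class(model) <- "qsp_model"
  model
}

#' @rdname build_model
#' @param model a `qsp_model`
#' @export
initial_state <- function(model, regimen = NULL) {
  y <- stats::setNames(numeric(29), qsp_state_names())
  pd <- model$params$pd
  y["R_free"] <- model$params$pk$LDL_tot
  y["TTR"] <- pd$TTR0
  ntr <- pd$n_transit
  y[c("tr1", "tr2", "tr3")[seq_len(ntr)]] <- pd$PCSK9_0
  y["PCSK9"] <- pd$PCSK9_0
  y["LDL"] <- pd$LDL0
  if (!is.null(regimen) && regimen$route == "bolus") {
    y["pl_LNP"] <- regimen$amt_LNP
    y["pl_sgRNA"] <- regimen$amt_sgRNA
    y["pl_mRNA"] <- regimen$amt_mRNA
  }
  y
}

# packed parameter vector with the regimen's infusion terms set
model_pvec <- function(model, regimen = NULL) {
  pvec <- model$pvec
  if (!is.null(regimen) && regimen$route == "infusion") {
    dur <- regimen$infusion_duration
    pvec["inf_LNP"] <- regimen$amt_LNP / dur
    pvec["inf_sgRNA"] <- regimen$amt_sgRNA / dur
    pvec["inf_mRNA"] <- regimen$amt_mRNA / dur
    pvec["inf_end"] <- dur
  }
  pvec
}

# ---------------------------------------------------------------------------
# Modular flux operations (reference implementations). These are the
# building blocks the full right-hand side is assembled from; the compiled
# core is validated against the assembly in the test suite.
# ---------------------------------------------------------------------------

#' Opsonin binding flux
#'
#' Reversible bio-corona formation: free LNP binds plasma opsonins at
#' `k_ass` and dissociates at `k_dis`. Binding conserves LNP mass, so the
#' free and bound derivatives are equal and opposite.
#'
#' @param C_free,C_bound free and opsonin-bound LNP (amount or
#'   concentration, same unit)
#' @param k_ass,k_dis association / dissociation rate constants (1/h)
#' @return list with elements `d_free` and `d_bound`
#' @export
opsonin_flux <- function(C_free, C_bound, k_ass, k_dis) {
  if (C_free < 0 || C_bound < 0) stop("negative input")
  d_bound <- k_ass * C_free - k_dis * C_bound
  list(d_free = -d_bound, d_bound = d_bound)
}

#' MPS phagocytosis flux
#'
#' Irreversible first-order uptake of vascular free LNP into the
#' mononuclear phagocyte system and first-order degradation there.
#'
#' @param A_vasc_LNP free LNP amount in the liver vascular space (ug)
#' @param A_mps LNP amount in the MPS (ug)
#' @param k_int phagocytosis rate (1/h)
#' @param k_deg_LNP degradation rate in the MPS (1/h)
#' @return list with `uptake` and `degradation` rates (ug/h)
#' @export
mps_flux <- function(A_vasc_LNP, A_mps, k_int, k_deg_LNP) {
  if (A_vasc_LNP < 0 || A_mps < 0) stop("negative input")
  list(uptake = k_int * A_vasc_LNP, degradation = k_deg_LNP * A_mps)
}

#' LDL-receptor binding flux
#'
#' Second-order binding of interstitial LNP to the free LDL receptor
#' (optionally gated by the plasma free fraction when
#' `fu_receptor_gate = 1`), first-order dissociation, and internalization
#' of the complex at `k_deg_DR`. Receptor turnover is `k_syn - k_el * R_free`
#' with `k_syn = LDL_tot * k_el`, so the undisturbed receptor baseline is
#' `LDL_tot`.
#'
#' @param C_LNP_int interstitial free LNP concentration (ug/mL)
#' @param R_free free receptor concentration (ug/mL)
#' @param C_complex receptor-complex concentration (ug/mL LNP-mass units)
#' @param params a `qsp_parameters` object
#' @return list with `binding`, `unbinding`, `internalization`
#'   (concentration rates, per mL of interstitium) and `dR` (receptor
#'   derivative)
#' @export
receptor_flux <- function(C_LNP_int, R_free, C_complex, params) {
  if (C_LNP_int < 0 || R_free < 0 || C_complex < 0) stop("negative input")
  pk <- params$pk
  fu_rec <- if (pk$fu_receptor_gate > 0.5) pk$fu_LNP else 1
  binding <- pk$k_on_LNP * fu_rec * C_LNP_int * R_free
  unbinding <- pk$k_off_LNP * C_complex
  internalization <- pk$k_deg_DR * C_complex
  dR <- k_syn_receptor(params) - pk$k_el * R_free - binding + unbinding
  list(binding = binding, unbinding = unbinding,
       internalization = internalization, dR = dR)
}

#' Trans-layer transfer flux
#'
#' Exchange across the vascular-to-interstitial or
#' interstitial-to-cellular interface: endocytic uptake (`CL_in =
#' k_in_endo * V_upper`) plus convective transport through the paracellular
#' pores (`L * (1 - sigma)`), against exocytic return (`CL_out = k_out_exo
#' * V_lower`). The same lumped endocytosis/exocytosis constants are used
#' at both interfaces.
#'
#' @param C_upper,C_lower concentrations on either side (ug/mL)
#' @param V_upper,V_lower compartment volumes (mL)
#' @param k_in_endo,k_out_exo lumped endocytosis/exocytosis rates (1/h)
#' @param L lymph flow (mL/h)
#' @param sigma reflection coefficient in \[0, 1\]
#' @return list with `inward` and `outward` amount rates (ug/h)
#' @export
transfer_flux <- function(C_upper, C_lower, V_upper, V_lower,
                          k_in_endo, k_out_exo, L = 0, sigma = 0) {
  if (V_upper <= 0 || V_lower <= 0) stop("volumes must be > 0")
  list(inward = k_in_endo * V_upper * C_upper + L * (1 - sigma) * C_upper,
       outward = k_out_exo * V_lower * C_lower)
}

#' Intracellular reaction derivatives
#'
#' Translation of Cas9 from mRNA (`k_trans`), second-order RNP assembly
#' driven by the cellular sgRNA concentration, first-order RNP
#' dissociation, and degradation of the free species. The RNP complex
#' itself does not degrade. RNP mass is total (Cas9 + sgRNA) mass;
#' dissociation returns the two moieties in the `mw_ratio` proportion.
#'
#' @param cell_state named vector with `sgRNA`, `mRNA`, `Cas9`, `RNP`
#'   amounts (ug)
#' @param params a `qsp_parameters` object
#' @param V_cell liver-cell volume (mL)
#' @return named vector of derivatives (ug/h) for the four species
#' @export
intracellular_rhs <- function(cell_state, params, V_cell) {
  if (any(cell_state < 0)) stop("negative amounts")
  pk <- params$pk
  mw <- pk$MW_sgRNA / pk$MW_Cas9
  C_sg <- cell_state[["sgRNA"]] / V_cell
  r_ass <- k_on_rnp(params) * C_sg * cell_state[["Cas9"]]
  r_dis <- pk$k_off_RNP * cell_state[["RNP"]]
  c(sgRNA = -mw * r_ass + r_dis * mw / (1 + mw) -
      pk$k_deg_sgRNA * cell_state[["sgRNA"]],
    mRNA = -pk$k_deg_mRNA * cell_state[["mRNA"]],
    Cas9 = pk$k_trans * cell_state[["mRNA"]] - r_ass + r_dis / (1 + mw) -
      pk$k_deg_Cas * cell_state[["Cas9"]],
    RNP = (1 + mw) * r_ass - r_dis)
}

#' Full right-hand side
#'
#' `pk_rhs()` evaluates the complete state derivative through the compiled
#' core; `pk_rhs_ref()` is an independent pure-R assembly of the modular
#' flux operations used to validate the compiled core.
#'
#' @param t time (h)
#' @param state named state vector (see [qsp_state_names()])
#' @param model a `qsp_model`
#' @param regimen optional regimen supplying infusion inputs
#' @return named derivative vector
#' @export
pk_rhs <- function(t, state, model, regimen = NULL) {
  if (length(state) != 29) stop("state dimension mismatch")
  if (any(!is.finite(state))) stop("NaN/Inf in state")
  dy <- qsp_rhs_cpp(t, as.numeric(state), model_pvec(model, regimen))
  stats::setNames(dy, qsp_state_names())
}

#' @rdname pk_rhs
#' @export
pk_rhs_ref <- function(t, state, model, regimen = NULL) {
  p <- as.list(model_pvec(model, regimen))
  y <- as.list(stats::setNames(as.numeric(state), qsp_state_names()))
  prm <- model$params
  dy <- stats::setNames(numeric(29), qsp_state_names())

  Ll <- p$lymph_fraction * p$Q_liver
  Lk <- p$lymph_fraction * p$Q_kidney
  Lr <- p$lymph_fraction * p$Q_remainder
  conc <- function(a, v) a / v
  Cpl <- lapply(y[1:4], conc, v = p$V_plasma)
  names(Cpl) <- c("LNP", "LNPo", "sg", "m")
  Clv <- lapply(y[5:8], conc, v = p$V_liver_vasc)
  names(Clv) <- c("LNP", "LNPo", "sg", "m")
  Cli_LNP <- y$li_LNP / p$V_liver_int
  Cli_sg <- y$li_sgRNA / p$V_liver_int
  Cli_m <- y$li_mRNA / p$V_liver_int
  Ccplx <- y$li_complex / p$V_liver_int
  Clc_sg <- y$lc_sgRNA / p$V_liver_cell
  Ckid_LNP <- y$kid_LNP / p$V_kidney
  Ckid_sg <- y$kid_sgRNA / p$V_kidney
  Crem <- list(LNP = y$rem_LNP / p$V_remainder,
               sg = y$rem_sgRNA / p$V_remainder,
               m = y$rem_mRNA / p$V_remainder)

  infusing <- t < p$inf_end
  rate <- list(LNP = if (infusing) p$inf_LNP else 0,
               sg = if (infusing) p$inf_sgRNA else 0,
               m = if (infusing) p$inf_mRNA else 0)

  # LNP lipid ---------------------------------------------------------------
  ops_pl <- opsonin_flux(y$pl_LNP, y$pl_LNP_ops, p$k_ass, p$k_dis)
  ops_lv <- opsonin_flux(y$lv_LNP, y$lv_LNP_ops, p$k_ass, p$k_dis)
  tf_LNP <- transfer_flux(Clv$LNP, Cli_LNP, p$V_liver_vasc, p$V_liver_int,
                          p$k_in_endo, p$k_out_exo, Ll, p$sigma_V_LNP)
  clin_ops <- if (p$ops_extravasation > 0.5)
    transfer_flux(Clv$LNPo, 0, p$V_liver_vasc, p$V_liver_int,
                  p$k_in_endo, 0, Ll, p$sigma_V_LNP)$inward else 0
  mps <- mps_flux(y$lv_LNP, y$mps_LNP, p$k_int, p$k_deg_LNP)
  rec <- receptor_flux(Cli_LNP, y$R_free, Ccplx, prm)
  bind <- rec$binding * p$V_liver_int
  unbind <- rec$unbinding * p$V_liver_int

  dy["pl_LNP"] <- rate$LNP -
    (p$Q_liver + p$Q_kidney + p$Q_remainder) * Cpl$LNP +
    (p$Q_liver - Ll) * Clv$LNP +
    (p$Q_kidney - Lk) * Ckid_LNP + Lk * (1 - p$sigma_I) * Ckid_LNP +
    (p$Q_remainder - Lr) * Crem$LNP + Lr * (1 - p$sigma_I) * Crem$LNP +
    Ll * (1 - p$sigma_I) * Cli_LNP +
    ops_pl$d_free - p$k_deg_LNP * y$pl_LNP
  dy["pl_LNP_ops"] <- ops_pl$d_bound - p$Q_liver * Cpl$LNPo +
    p$Q_liver * Clv$LNPo
  dy["lv_LNP_ops"] <- ops_lv$d_bound + p$Q_liver * Cpl$LNPo -
    p$Q_liver * Clv$LNPo - clin_ops
  dy["lv_LNP"] <- p$Q_liver * Cpl$LNP - (p$Q_liver - Ll) * Clv$LNP -
    mps$uptake + ops_lv$d_free - tf_LNP$inward + tf_LNP$outward -
    p$k_deg_LNP * y$lv_LNP
  dy["mps_LNP"] <- mps$uptake - mps$degradation
  dy["li_LNP"] <- tf_LNP$inward + clin_ops - tf_LNP$outward -
    Ll * (1 - p$sigma_I) * Cli_LNP - bind + unbind -
    p$k_deg_LNP * y$li_LNP
  dy["li_complex"] <- bind - unbind - p$k_deg_DR * y$li_complex
  dy["R_free"] <- rec$dR
  dy["kid_LNP"] <- p$Q_kidney * Cpl$LNP - (p$Q_kidney - Lk) * Ckid_LNP -
    Lk * (1 - p$sigma_I) * Ckid_LNP - p$CL_renal_LNP * Ckid_LNP -
    p$k_deg_LNP * y$kid_LNP
  dy["rem_LNP"] <- p$Q_remainder * Cpl$LNP - (p$Q_remainder - Lr) * Crem$LNP -
    Lr * (1 - p$sigma_I) * Crem$LNP - p$k_deg_LNP * y$rem_LNP

  rel <- p$k_release * y$li_LNP / p$lnp_ratio
  dr_cargo <- p$cargo_cell_frac * p$k_deg_DR * y$li_complex / p$lnp_ratio

  # sgRNA ------------------------------------------------------------------
  tf_sg_v <- transfer_flux(Clv$sg, Cli_sg, p$V_liver_vasc, p$V_liver_int,
                           p$fu_RNA * p$k_in_endo, p$k_out_exo,
                           p$fu_RNA * Ll, p$sigma_V_RNA)
  tf_sg_c <- transfer_flux(Cli_sg, Clc_sg, p$V_liver_int, p$V_liver_cell,
                           p$k_in_endo, p$cell_exo_frac * p$k_out_exo)
  dy["pl_sgRNA"] <- rate$sg -
    (p$Q_liver + p$Q_kidney + p$Q_remainder) * Cpl$sg +
    (p$Q_liver - Ll) * Clv$sg +
    (p$Q_kidney - Lk) * Ckid_sg + Lk * (1 - p$sigma_I) * Ckid_sg +
    (p$Q_remainder - Lr) * Crem$sg + Lr * (1 - p$sigma_I) * Crem$sg +
    Ll * (1 - p$sigma_I) * Cli_sg - p$k_deg_sgRNA * y$pl_sgRNA
  dy["lv_sgRNA"] <- p$Q_liver * Cpl$sg - (p$Q_liver - Ll) * Clv$sg -
    tf_sg_v$inward + tf_sg_v$outward - p$k_deg_sgRNA * y$lv_sgRNA
  dy["li_sgRNA"] <- tf_sg_v$inward - tf_sg_v$outward -
    tf_sg_c$inward + tf_sg_c$outward - Ll * (1 - p$sigma_I) * Cli_sg +
    rel * p$frac_sgRNA - p$k_deg_sgRNA * y$li_sgRNA
  dy["kid_sgRNA"] <- p$Q_kidney * Cpl$sg - (p$Q_kidney - Lk) * Ckid_sg -
    Lk * (1 - p$sigma_I) * Ckid_sg - p$CL_renal_sgRNA * Ckid_sg -
    p$k_deg_sgRNA * y$kid_sgRNA
  dy["rem_sgRNA"] <- p$Q_remainder * Cpl$sg - (p$Q_remainder - Lr) * Crem$sg -
    Lr * (1 - p$sigma_I) * Crem$sg - p$k_deg_sgRNA * y$rem_sgRNA

  # mRNA (no kidney) ---------------------------------------------------------
  Cli_m_ <- Cli_m
  tf_m_v <- transfer_flux(Clv$m, Cli_m_, p$V_liver_vasc, p$V_liver_int,
                          p$fu_RNA * p$k_in_endo, p$k_out_exo,
                          p$fu_RNA * Ll, p$sigma_V_RNA)
  tf_m_c <- transfer_flux(Cli_m_, y$lc_mRNA / p$V_liver_cell,
                          p$V_liver_int, p$V_liver_cell,
                          p$k_in_endo, p$cell_exo_frac * p$k_out_exo)
  dy["pl_mRNA"] <- rate$m - (p$Q_liver + p$Q_remainder) * Cpl$m +
    (p$Q_liver - Ll) * Clv$m +
    (p$Q_remainder - Lr) * Crem$m + Lr * (1 - p$sigma_I) * Crem$m +
    Ll * (1 - p$sigma_I) * Cli_m_ - p$k_deg_mRNA * y$pl_mRNA
  dy["lv_mRNA"] <- p$Q_liver * Cpl$m - (p$Q_liver - Ll) * Clv$m -
    tf_m_v$inward + tf_m_v$outward - p$k_deg_mRNA * y$lv_mRNA
  dy["li_mRNA"] <- tf_m_v$inward - tf_m_v$outward -
    tf_m_c$inward + tf_m_c$outward - Ll * (1 - p$sigma_I) * Cli_m_ +
    rel * p$frac_mRNA - p$k_deg_mRNA * y$li_mRNA
  dy["rem_mRNA"] <- p$Q_remainder * Cpl$m - (p$Q_remainder - Lr) * Crem$m -
    Lr * (1 - p$sigma_I) * Crem$m - p$k_deg_mRNA * y$rem_mRNA

  # intracellular -------------------------------------------------------------
  cell <- intracellular_rhs(
    c(sgRNA = y$lc_sgRNA, mRNA = y$lc_mRNA, Cas9 = y$lc_Cas9,
      RNP = y$lc_RNP), prm, p$V_liver_cell)
  dy["lc_sgRNA"] <- cell[["sgRNA"]] + tf_sg_c$inward - tf_sg_c$outward +
    dr_cargo * p$frac_sgRNA
  dy["lc_mRNA"] <- cell[["mRNA"]] + tf_m_c$inward - tf_m_c$outward +
    dr_cargo * p$frac_mRNA
  dy["lc_Cas9"] <- cell[["Cas9"]]
  dy["lc_RNP"] <- cell[["RNP"]]

  # pharmacodynamics (1/day converted to 1/h) ---------------------------------
  C_rnp <- if (p$clamp_rnp >= 0) p$clamp_rnp else y$lc_RNP / p$V_liver_cell
  pd <- prm$pd
  dy["TTR"] <- ttr_rhs(y$TTR, C_rnp, pd) / 24
  pc <- pcsk9_rhs(c(y$tr1, y$tr2, y$tr3)[seq_len(pd$n_transit)],
                  y$PCSK9, C_rnp, pd)
  dy[c("tr1", "tr2", "tr3")[seq_len(pd$n_transit)]] <- pc$transit / 24
  dy["PCSK9"] <- pc$observable / 24
  dy["LDL"] <- ldl_rhs(y$LDL, y$PCSK9, pd) / 24
  dy
}

#' @export
print.qsp_model <- function(x, ...) {
  cat("QSP model:", x$phys$species_id, "| 29 states |",
      "kidney: LNP + sgRNA only\n")
  invisible(x)
}
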