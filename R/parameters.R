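#' Drug-specific model parameters
#'
#' Rate constants of the disposition and editing model, per species. All
#' first-order rates are in 1/h; second-order binding constants are in
#' per-(ug/mL)-per-h; biomarker turnover rates are in 1/day. Two constants
#' are derived and never stored independently: the receptor synthesis rate
#' `k_syn = LDL_tot * k_el`, and the ribonucleoprotein association rate
#' `k_on_RNP = k_off_RNP / KD_mass`, where `KD_mass` converts the reported
#' equilibrium dissociation constant (nM) to ug/mL using the Cas9 molecular
#' weight.
#'
#' @name parameters
NULL

.pk_fields <- c(
  "k_in_endo", "k_out_exo", "k_deg_DR", "LDL_tot", "k_dis", "k_ass",
  "k_release", "k_deg_LNP", "k_el", "k_deg_sgRNA", "k_deg_mRNA",
  "k_deg_Cas", "k_off_RNP", "KD_nM", "MW_Cas9", "MW_sgRNA", "k_int",
  "k_on_LNP", "k_off_LNP", "fu_LNP", "fu_RNA", "k_trans",
  "cargo_cell_frac", "fu_receptor_gate", "cell_exo_frac",
  "ops_extravasation"
)

.pd_fields <- c(
  "TTR0", "k_out_TTR", "Imax_TTR", "IC50_TTR", "gamma_TTR",
  "PCSK9_0", "MTT", "n_transit", "Imax_PCSK9", "IC50_PCSK9",
  "gamma_PCSK9", "gamma_fb", "feedback_on", "Gamma_LDL", "k_deg_LDL",
  "LDL0"
)

# shared constants across species
.pk_shared <- list(
  k_off_RNP = 0.00188, KD_nM = 0.49, MW_Cas9 = 160000, MW_sgRNA = 32000,
  k_int = 0.9063, k_on_LNP = 0.18, k_off_LNP = 33.12,
  fu_LNP = 0.002, fu_RNA = 0.15, k_trans = 0.36, cargo_cell_frac = 1.0,
  # structural switches: receptor binding ungated by the (renal) free
  # fraction, one-way interstitial -> cellular pinocytosis, and corona-
  # bearing LNP extravasating by the same endocytic/convective route
  fu_receptor_gate = 0, cell_exo_frac = 0, ops_extravasation = 1
)

.pk_defaults <- list(
  mouse = c(list(
    k_in_endo = 0.14, k_out_exo = 6.84, k_deg_DR = 2.04, LDL_tot = 539,
    k_dis = 0.47, k_ass = 1550.34, k_release = 0.0056, k_deg_LNP = 1.6486,
    k_el = 0.231, k_deg_sgRNA = 0.378, k_deg_mRNA = 0.378,
    k_deg_Cas = 0.378), .pk_shared),
  nhp = c(list(
    k_in_endo = 0.039, k_out_exo = 2690, k_deg_DR = 2.04, LDL_tot = 539,
    k_dis = 8.64, k_ass = 5.06, k_release = 0.634, k_deg_LNP = 1.6486,
    k_el = 0.231, k_deg_sgRNA = 2.01, k_deg_mRNA = 0.1232,
    k_deg_Cas = 0.1232), .pk_shared),
  human = c(list(
    k_in_endo = 0.007, k_out_exo = 775, k_deg_DR = 5.15, LDL_tot = 84.5,
    k_dis = 0.186, k_ass = 56.8, k_release = 0.0056, k_deg_LNP = 0.101,
    k_el = 0.009, k_deg_sgRNA = 2.01, k_deg_mRNA = 0.1232,
    k_deg_Cas = 0.1232), .pk_shared)
)

# Biomarker models. The human Hill coefficient for TTR is not reported and
# defaults to 1; mouse biomarker blocks are inert (Imax = 0).
.pd_inert <- list(
  TTR0 = 100, k_out_TTR = 0.493, Imax_TTR = 0, IC50_TTR = 1, gamma_TTR = 1,
  PCSK9_0 = 100, MTT = 14.5, n_transit = 3, Imax_PCSK9 = 0, IC50_PCSK9 = 1,
  gamma_PCSK9 = 1.1, gamma_fb = 1.1, feedback_on = 1, Gamma_LDL = 0.672,
  k_deg_LDL = 4.66, LDL0 = 100
)

.pd_defaults <- list(
  mouse = .pd_inert,
  nhp = utils::modifyList(.pd_inert, list(
    k_out_TTR = 0.493, Imax_TTR = 0.961, IC50_TTR = 4.77, gamma_TTR = 0.31,
    Imax_PCSK9 = 0.771, IC50_PCSK9 = 21.5)),
  human = utils::modifyList(.pd_inert, list(
    k_out_TTR = 0.247, Imax_TTR = 0.959, IC50_TTR = 0.3, gamma_TTR = 1))
)

#' Load drug-specific parameters for a species
#'
#' @param species_id `"mouse"`, `"nhp"`, `"human"`, or a JSON config path
#'   containing `pk` and `pd` blocks
#' @param overrides optional named list applied on top (PK or PD names)
#' @return object of class `qsp_parameters` with elements `pk`, `pd`,
#'   and `species_id`
#' @export
load_parameters <- function(species_id, overrides = NULL) {
  if (species_id %in% names(.pk_defaults)) {
    pk <- .pk_defaults[[species_id]]
    pd <- .pd_defaults[[species_id]]
    sid <- species_id
  } else if (file.exists(species_id)) {
    cfg <- jsonlite::read_json(species_id, simplifyVector = TRUE)
    if (!all(c("pk", "pd") %in% names(cfg)))
      stop("parameter config must contain 'pk' and 'pd' blocks")
    pk <- as.list(cfg$pk); pd <- as.list(cfg$pd)
    sid <- if (!is.null(cfg$species_id)) cfg$species_id else "custom"
  } else {
    stop("unknown species id or missing config file: '", species_id, "'")
  }
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (nm %in% .pk_fields) pk[[nm]] <- overrides[[nm]]
      else if (nm %in% .pd_fields) pd[[nm]] <- overrides[[nm]]
      else stop("unknown parameter override: '", nm, "'")
    }
  }
  validate_parameters(list(species_id = sid, pk = pk, pd = pd))
}

#' @rdname load_parameters
#' @param params candidate parameter object
#' @export
validate_parameters <- function(params) {
  pk <- as.list(params$pk); pd <- as.list(params$pd)
  extra <- c(setdiff(names(pk), .pk_fields), setdiff(names(pd), .pd_fields))
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "))
  miss <- c(setdiff(.pk_fields, names(pk)), setdiff(.pd_fields, names(pd)))
  if (length(miss))
    stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  for (f in .pk_fields) {
    v <- pk[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", f, "' must be a single finite nonnegative number")
  }
  for (f in c("fu_LNP", "fu_RNA"))
    if (pk[[f]] <= 0 || pk[[f]] > 1) stop("'", f, "' must lie in (0, 1]")
  for (f in c("fu_receptor_gate", "cell_exo_frac", "cargo_cell_frac",
              "ops_extravasation"))
    if (pk[[f]] < 0 || pk[[f]] > 1) stop("'", f, "' must lie in [0, 1]")
  if (pd$Imax_TTR < 0 || pd$Imax_TTR > 1 || pd$Imax_PCSK9 < 0 ||
      pd$Imax_PCSK9 > 1)
    stop("Imax values must lie in [0, 1]")
  if (pd$IC50_TTR <= 0 || pd$IC50_PCSK9 <= 0) stop("IC50 must be > 0")
  if (pd$MTT <= 0) stop("MTT must be > 0")
  if (!pd$n_transit %in% 1:3)
    stop("n_transit must be an integer in 1..3")
  if (pd$k_deg_LDL <= 0 || pd$k_out_TTR < 0)
    stop("biomarker turnover rates must be positive")
  out <- list(species_id = params$species_id, pk = pk, pd = pd)
  class(out) <- "qsp_parameters"
  out
}

#' Derived constants
#'
#' `kd_mass()` converts the RNP equilibrium dissociation constant from nM to
#' ug/mL via the Cas9 molecular weight; `k_on_rnp()` and `k_syn_receptor()`
#' are the derived association and receptor-synthesis rates. These are
#' recomputed on demand, never stored.
#'
#' @param params a `qsp_parameters` object
#' @return a single number
#' @export
kd_mass <- function(params) {
  pk <- params$pk
  pk$KD_nM * 1e-9 * pk$MW_Cas9 * 1000  # nM -> mol/L -> g/L -> ug/mL
}

#' @rdname kd_mass
#' @export
k_on_rnp <- function(params) params$pk$k_off_RNP / kd_mass(params)

#' @rdname kd_mass
#' @export
k_syn_receptor <- function(params) params$pk$LDL_tot * params$pk$k_el

#' @export
print.qsp_parameters <- function(x, ...) {
  cat("QSP parameters:", x$species_id, "\n")
  pk <- unlist(x$pk)
  cat("  PK:", paste(sprintf("%s=%g", names(pk), pk), collapse = ", "), "\n")
  pd <- unlist(x$pd)
  cat("  PD:", paste(sprintf("%s=%g", names(pd), pd), collapse = ", "), "\n")
  invisible(x)
}

#' Write a parameter config file
#'
#' The file mirrors the model symbol names and may carry `fixed` /
#' `estimated` annotations consumed by the calibration module.
#'
#' @param params a `qsp_parameters` object
#' @param path output JSON path
#' @param estimated optional character vector of parameter names flagged
#'   as estimated
#' @export
write_parameters <- function(params, path, estimated = character()) {
  obj <- list(species_id = params$species_id, pk = params$pk, pd = params$pd,
              estimated = estimated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
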