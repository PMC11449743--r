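#' Species physiology
#'
#' Species-specific physiological constants for the minimal PBPK model:
#' body weight, compartment volumes (plasma, liver vascular / interstitial /
#' cellular, kidney, lumped remainder), plasma flows, the lymph-flow fraction
#' (fixed at 0.2% of plasma flow), and the vascular/interstitial reflection
#' coefficients.
#'
#' Volumes and flows for the three bundled species are reconstructions from
#' standard reference physiology (plasma volume about 4.9% of body weight;
#' organ plasma flows as fractions of cardiac plasma output), since no
#' organ-level measurements accompany the calibrated parameter sets. Every
#' value can be overridden via a JSON config file, so users holding their
#' own measurements can swap them in without touching the model structure.
#'
#' @name physiology
NULL

.phys_fields <- c(
  "species_id", "BW", "V_plasma", "V_liver_vasc", "V_liver_int",
  "V_liver_cell", "V_kidney", "V_remainder", "Q_liver", "Q_kidney",
  "Q_remainder", "lymph_fraction", "sigma_V_LNP", "sigma_V_RNA", "sigma_I"
)

# Reconstructed reference physiology. Liver split: 15% vascular, 20%
# interstitial, 65% cellular of total liver volume. Flows are plasma flows
# (mL/h): cardiac plasma output partitioned liver/kidney/remainder.
.phys_defaults <- list(
  mouse = list(
    species_id = "mouse", BW = 0.028,
    V_plasma = 1.37,
    V_liver_vasc = 0.23, V_liver_int = 0.31, V_liver_cell = 1.00,
    V_kidney = 0.47, V_remainder = 14.0,
    Q_liver = 92, Q_kidney = 46, Q_remainder = 324,
    lymph_fraction = 0.002,
    sigma_V_LNP = 0.95, sigma_V_RNA = 0.90, sigma_I = 0.20
  ),
  nhp = list(
    species_id = "nhp", BW = 5,
    V_plasma = 245,
    V_liver_vasc = 20.3, V_liver_int = 27.0, V_liver_cell = 87.8,
    V_kidney = 27.5, V_remainder = 2500,
    Q_liver = 8000, Q_kidney = 4800, Q_remainder = 27200,
    lymph_fraction = 0.002,
    sigma_V_LNP = 0.95, sigma_V_RNA = 0.90, sigma_I = 0.20
  ),
  human = list(
    species_id = "human", BW = 71,
    V_plasma = 3479,
    V_liver_vasc = 273, V_liver_int = 364, V_liver_cell = 1183,
    V_kidney = 310, V_remainder = 35500,
    Q_liver = 48000, Q_kidney = 37000, Q_remainder = 100000,
    lymph_fraction = 0.002,
    sigma_V_LNP = 0.95, sigma_V_RNA = 0.90, sigma_I = 0.20
  )
)

#' Load species physiology
#'
#' Returns the physiological record for one of the bundled species
#' (`"mouse"`, `"nhp"`, `"human"`) or reads a JSON config file whose keys
#' exactly match the `SpeciesPhysiology` field names. Unknown keys are
#' rejected, and all invariants (positive volumes/flows, reflection
#' coefficients in \[0, 1\]) are enforced.
#'
#' @param species_id one of `"mouse"`, `"nhp"`, `"human"`, or a path to a
#'   JSON physiology config
#' @param overrides optional named list of field overrides applied on top
#' @return an object of class `qsp_physiology` (a named list)
#' @export
#' @examples
#' phys <- load_physiology("mouse")
#' phys$BW  # 0.028 kg
load_physiology <- function(species_id, overrides = NULL) {
  if (!is.character(species_id) || length(species_id) != 1L)
    stop("species_id must be a single string")
  if (species_id %in% names(.phys_defaults)) {
    phys <- .phys_defaults[[species_id]]
  } else if (file.exists(species_id)) {
    phys <- jsonlite::read_json(species_id, simplifyVector = TRUE)
  } else {
    stop("unknown species id or missing config file: '", species_id,
         "' (bundled: ", paste(names(.phys_defaults), collapse = ", "), ")")
  }
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    phys[names(overrides)] <- overrides
  }
  validate_physiology(phys)
}

#' @rdname load_physiology
#' @param phys candidate physiology list
#' @export
validate_physiology <- function(phys) {
  phys <- as.list(phys)
  extra <- setdiff(names(phys), .phys_fields)
  if (length(extra))
    stop("unknown physiology field(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(.phys_fields, names(phys))
  if (length(missing))
    stop("missing physiology field(s): ", paste(missing, collapse = ", "))
  num <- setdiff(.phys_fields, "species_id")
  for (f in num) {
    v <- phys[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("physiology field '", f, "' must be a single finite number")
  }
  pos <- c("BW", "V_plasma", "V_liver_vasc", "V_liver_int", "V_liver_cell",
           "V_kidney", "V_remainder", "Q_liver", "Q_kidney", "Q_remainder")
  for (f in pos)
    if (phys[[f]] <= 0) stop("physiology field '", f, "' must be > 0")
  for (f in c("sigma_V_LNP", "sigma_V_RNA", "sigma_I"))
    if (phys[[f]] < 0 || phys[[f]] > 1)
      stop("reflection coefficient '", f, "' must lie in [0, 1]")
  if (phys$lymph_fraction < 0 || phys$lymph_fraction >= 1)
    stop("lymph_fraction must lie in [0, 1)")
  phys <- phys[.phys_fields]
  class(phys) <- "qsp_physiology"
  phys
}

#' Lymph flow of an organ
#'
#' Lymph flow is the fixed fraction (default 0.2%) of the organ's plasma
#' flow.
#'
#' @param phys a `qsp_physiology` object
#' @param organ one of `"liver"`, `"kidney"`, `"remainder"`
#' @return lymph flow in mL/h
#' @export
lymph_flow <- function(phys, organ = c("liver", "kidney", "remainder")) {
  organ <- match.arg(organ)
  q <- switch(organ, liver = phys$Q_liver, kidney = phys$Q_kidney,
              remainder = phys$Q_remainder)
  phys$lymph_fraction * q
}

#' Total liver volume (single source of truth)
#'
#' @param phys a `qsp_physiology` object
#' @return sum of the vascular, interstitial, and cellular liver volumes (mL)
#' @export
liver_volume <- function(phys) {
  phys$V_liver_vasc + phys$V_liver_int + phys$V_liver_cell
}

#' @export
print.qsp_physiology <- function(x, ...) {
  cat("Species physiology:", x$species_id, sprintf("(BW %g kg)\n", x$BW))
  cat(sprintf("  V (mL): plasma %g | liver %g (vasc %g / int %g / cell %g)\n",
              x$V_plasma, liver_volume(x), x$V_liver_vasc, x$V_liver_int,
              x$V_liver_cell))
  cat(sprintf("  V (mL): kidney %g | remainder %g\n", x$V_kidney,
              x$V_remainder))
  cat(sprintf("  Q (mL/h): liver %g | kidney %g | remainder %g (lymph %.2g%%)\n",
              x$Q_liver, x$Q_kidney, x$Q_remainder, 100 * x$lymph_fraction))
  invisible(x)
}

#' Write a physiology config file
#'
#' @param phys a `qsp_physiology` object
#' @param path output JSON path
#' @export
write_physiology <- function(phys, path) {
  jsonlite::write_json(unclass(phys), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
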