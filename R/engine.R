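#' Simulation engine
#'
#' Couples the disposition model to the biomarker models (one-way: PK
#' drives PD), integrates the stiff system with the compiled Rosenbrock
#' solver, and maps states to observable outputs: plasma concentrations
#' (ug/mL) of total LNP (free + opsonized), sgRNA and mRNA, and serum TTR,
#' PCSK9 and LDL-C as percent of baseline.
#'
#' @name engine
NULL

.output_vocabulary <- c("plasma_LNP", "plasma_sgRNA", "plasma_mRNA",
                        "serum_TTR_pct", "serum_PCSK9_pct", "serum_LDL_pct")

.output_unit <- function(output_id) {
  ifelse(grepl("^plasma", output_id), "ug/mL", "%baseline")
}

#' Default solver options
#'
#' @param rtol relative tolerance
#' @param atol absolute tolerance
#' @param hmax maximum step size (h)
#' @return list of solver options
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-10, hmax = Inf) {
  list(rtol = rtol, atol = atol, hmax = hmax)
}

#' Simulate a dose regimen
#'
#' Deterministic forward simulation: integrates the full coupled PK/PD
#' system and evaluates states and observables at the requested times.
#' Bolus doses enter as plasma initial conditions; infusions as a constant
#' input over the infusion duration, with the integrator restarted at the
#' switch-off time.
#'
#' @param model a `qsp_model`
#' @param regimen a `qsp_regimen` (or `NULL` for a dose-free run)
#' @param t_grid strictly increasing output times in hours; 0 is prepended
#'   if absent
#' @param solver list from [solver_options()]
#' @return an object of class `qsp_trajectory` with fields `time` (h),
#'   `state` (matrix, one row per time), and `obs` (data.frame of
#'   observables)
#' @export
simulate_qsp <- function(model, regimen = NULL, t_grid,
                         solver = solver_options()) {
  stopifnot(inherits(model, "qsp_model"))
  t_grid <- sort(unique(as.numeric(t_grid)))
  if (any(t_grid < 0)) stop("t_grid must be nonnegative")
  if (length(t_grid) == 0) stop("empty time grid")
  prepended <- FALSE
  if (t_grid[1] > 0) { t_grid <- c(0, t_grid); prepended <- TRUE }

  y0 <- initial_state(model, regimen)
  pvec <- model_pvec(model, regimen)
  st <- qsp_integrate_cpp(t_grid, as.numeric(y0), as.numeric(pvec),
                          solver$rtol, solver$atol, solver$hmax)
  colnames(st) <- qsp_state_names()
  if (prepended) { st <- st[-1, , drop = FALSE]; t_grid <- t_grid[-1] }

  vp <- model$phys$V_plasma
  obs <- data.frame(
    time = t_grid,
    plasma_LNP = (st[, "pl_LNP"] + st[, "pl_LNP_ops"]) / vp,
    plasma_sgRNA = st[, "pl_sgRNA"] / vp,
    plasma_mRNA = st[, "pl_mRNA"] / vp,
    serum_TTR_pct = st[, "TTR"],
    serum_PCSK9_pct = st[, "PCSK9"],
    serum_LDL_pct = st[, "LDL"],
    rnp_liver = st[, "lc_RNP"] / model$phys$V_liver_cell
  )
  traj <- list(time = t_grid, state = st, obs = obs, model = model,
               regimen = regimen)
  class(traj) <- "qsp_trajectory"
  traj
}

#' Trapezoidal area under the curve
#'
#' Linear trapezoid on the requested window, with linear interpolation at
#' the window edges when they fall between grid points.
#'
#' @param time,conc sampled curve (time in h)
#' @param t_start,t_end window (defaults to the full span)
#' @return AUC in conc * h units
#' @export
auc <- function(time, conc, t_start = min(time), t_end = max(time)) {
  if (length(time) != length(conc)) stop("time/conc length mismatch")
  if (length(time) < 2) stop("need at least 2 points")
  if (t_end <= t_start) stop("empty AUC window")
  if (t_start < min(time) || t_end > max(time))
    stop("AUC window outside the sampled span")
  keep <- time > t_start & time < t_end
  tt <- c(t_start, time[keep], t_end)
  cc <- c(stats::approx(time, conc, xout = t_start)$y, conc[keep],
          stats::approx(time, conc, xout = t_end)$y)
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Extract observation records from a trajectory
#'
#' Evaluates the requested outputs at the schedule times (exact when the
#' time is on the simulation grid, linear interpolation otherwise;
#' extrapolation is an error) and returns them as tidy observation
#' records.
#'
#' @param trajectory a `qsp_trajectory`
#' @param schedule data.frame with columns `output_id` and `time`, and
#'   optionally `time_unit` (`"hours"`, default, or `"days"`)
#' @param dose_group label stored in the records
#' @return data.frame with columns `time`, `time_unit`, `species`,
#'   `dose_group`, `output_id`, `value`, `unit`
#' @export
observe <- function(trajectory, schedule, dose_group = NA_character_) {
  stopifnot(inherits(trajectory, "qsp_trajectory"))
  if (nrow(schedule) == 0)
    return(data.frame(time = numeric(), time_unit = character(),
                      species = character(), dose_group = character(),
                      output_id = character(), value = numeric(),
                      unit = character()))
  if (is.null(schedule$time_unit)) schedule$time_unit <- "hours"
  bad <- setdiff(unique(schedule$output_id), .output_vocabulary)
  if (length(bad))
    stop("unknown output_id(s): ", paste(bad, collapse = ", "))
  t_h <- ifelse(schedule$time_unit == "days", schedule$time * 24,
                schedule$time)
  if (any(t_h < min(trajectory$time) - 1e-9) ||
      any(t_h > max(trajectory$time) + 1e-9))
    stop("schedule requests extrapolation outside the trajectory span")
  value <- vapply(seq_len(nrow(schedule)), function(i) {
    stats::approx(trajectory$time, trajectory$obs[[schedule$output_id[i]]],
                  xout = t_h[i], rule = 1)$y
  }, numeric(1))
  data.frame(
    time = schedule$time,
    time_unit = schedule$time_unit,
    species = trajectory$model$phys$species_id,
    dose_group = dose_group,
    output_id = schedule$output_id,
    value = value,
    unit = .output_unit(schedule$output_id)
  )
}

#' Validate an observation table
#'
#' Checks the observation CSV schema: required columns, registered output
#' ids, and nonnegative values.
#'
#' @param df candidate data.frame
#' @return the validated data.frame (invisibly unchanged)
#' @export
validate_observations <- function(df) {
  req <- c("time", "time_unit", "species", "dose_group", "output_id",
           "value", "unit")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("observation table missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$output_id), .output_vocabulary)
  if (length(bad))
    stop("unregistered output_id(s): ", paste(bad, collapse = ", "))
  if (any(df$value < 0)) stop("observation values must be >= 0")
  df
}

#' @export
print.qsp_trajectory <- function(x, ...) {
  cat(sprintf("QSP trajectory: %s, %d time points over [%g, %g] h\n",
              x$model$phys$species_id, length(x$time), min(x$time),
              max(x$time)))
  invisible(x)
}

#' Observed-versus-fitted diagnostic plot
#'
#' Scatter of observed against model-predicted values with the identity
#' line, the standard concordance diagnostic.
#'
#' @param observed,predicted numeric vectors
#' @param ... passed to [graphics::plot()]
#' @export
plot_obs_vs_fitted <- function(observed, predicted, ...) {
  graphics::plot(predicted, observed, xlab = "Fitted", ylab = "Observed",
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}
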