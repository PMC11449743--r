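#' Fixed-effect maximum-likelihood calibration
#'
#' Reproduces the stepwise fitting workflow as fixed-effect MLE with the
#' proportional residual-error model `Var_i = sigma_slope * Y_i^2`. The
#' error slope is profiled analytically per output (its conditional MLE is
#' the mean squared relative residual), parameters are optimized on the
#' log scale with box bounds and optional Latin-hypercube multi-start, and
#' relative standard errors come from the inverse finite-difference
#' Hessian of the objective at the optimum. Population (inter-individual)
#' random effects are out of scope; variability enters only through the
#' forward Monte Carlo module.
#'
#' @name calibration
NULL

#' -2 log-likelihood under the proportional error model
#'
#' `sum(log(2 * pi * sigma_slope * Y^2) + (y - Y)^2 / (sigma_slope * Y^2))`
#' over matched prediction/observation pairs.
#'
#' @param predictions model predictions `Y` (must be > 0)
#' @param observations observed values `y`
#' @param sigma_slope proportional variance slope (> 0)
#' @return the scalar -2 log-likelihood
#' @export
neg2ll <- function(predictions, observations, sigma_slope) {
  if (length(predictions) != length(observations))
    stop("prediction/observation length mismatch")
  if (any(predictions <= 0))
    stop("proportional variance undefined: prediction <= 0 at ",
         sum(predictions <= 0), " observation(s)")
  if (sigma_slope <= 0) stop("sigma_slope must be > 0")
  v <- sigma_slope * predictions^2
  sum(log(2 * pi * v) + (observations - predictions)^2 / v)
}

#' @rdname neg2ll
#' @export
profile_sigma_slope <- function(predictions, observations) {
  if (any(predictions <= 0)) stop("prediction <= 0")
  mean(((observations - predictions) / predictions)^2)
}

#' Construct a fit specification
#'
#' @param step_id workflow step identifier; one of `step1_reduced`,
#'   `step2_mouse`, `step3_nhp_pk`, `step3_nhp_pd`, `step4_human_pk`,
#'   `step4_human_pd`, or `custom`
#' @param design a `qsp_design` the data were sampled under
#' @param estimate character vector of parameter names to estimate
#' @param fixed named list of parameter overrides held fixed
#' @param inits named numeric initial values (default: the species'
#'   bundled values)
#' @param lower,upper named bounds (default `init/100` to `init*100`,
#'   with Imax capped at 1)
#' @param tie named character vector: each name is set equal to the
#'   estimated parameter it maps to (e.g. sgRNA degradation tied to mRNA
#'   degradation in the mouse step)
#' @param n_starts number of Latin-hypercube multi-starts (>= 1; the
#'   supplied inits are always the first start)
#' @param seed seed for the multi-start draw
#' @param solver solver options used for model predictions
#' @param control options passed to [stats::optim()] (L-BFGS-B)
#' @return an object of class `qsp_fit_spec`
#' @export
fit_spec <- function(step_id = "custom", design, estimate, fixed = list(),
                     inits = NULL, lower = NULL, upper = NULL,
                     tie = NULL, n_starts = 1, seed = 1,
                     solver = solver_options(1e-6, 1e-9),
                     control = list(maxit = 300, factr = 1e8)) {
  stopifnot(inherits(design, "qsp_design"))
  if (length(estimate) == 0) stop("no parameters to estimate")
  both <- intersect(estimate, names(fixed))
  if (length(both))
    stop("parameter(s) both estimated and fixed: ",
         paste(both, collapse = ", "))
  base <- load_parameters(design$species_id, overrides = fixed)
  all_vals <- unlist(c(base$pk, base$pd))
  unknown <- setdiff(estimate, names(all_vals))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  if (is.null(inits)) inits <- all_vals[estimate]
  inits <- inits[estimate]
  if (any(inits <= 0)) stop("initial values must be > 0")
  if (is.null(lower)) lower <- inits / 100
  if (is.null(upper)) {
    upper <- inits * 100
    for (nm in intersect(c("Imax_TTR", "Imax_PCSK9"), estimate))
      upper[nm] <- min(upper[nm], 0.9999)
  }
  spec <- list(step_id = step_id, design = design, estimate = estimate,
               fixed = fixed, inits = inits, lower = lower[estimate],
               upper = upper[estimate], tie = tie, n_starts = n_starts,
               seed = seed, solver = solver, control = control,
               base = base)
  class(spec) <- "qsp_fit_spec"
  spec
}

#' Paper-workflow fit masks
#'
#' Convenience constructors for the stepwise estimated/fixed parameter
#' masks, bound to the matching bundled study design.
#'
#' @param step_id one of the six workflow steps
#' @param ... passed to [fit_spec()]
#' @return a `qsp_fit_spec`
#' @export
step_fit_spec <- function(step_id, ...) {
  designs <- bundled_designs()
  masks <- list(
    step1_reduced = list(design = designs$mouse_pk,
      estimate = c("k_ass", "k_dis", "k_off_RNP", "k_trans",
                   "k_deg_sgRNA", "k_deg_DR")),
    step2_mouse = list(design = designs$mouse_pk,
      estimate = c("k_out_exo", "k_deg_mRNA"),
      tie = c(k_deg_sgRNA = "k_deg_mRNA")),
    step3_nhp_pk = list(design = designs$nhp_pk,
      estimate = c("k_in_endo", "k_out_exo", "k_deg_DR", "LDL_tot",
                   "k_dis", "k_ass", "k_release")),
    step3_nhp_pd = list(design = designs$nhp_ttr,
      estimate = c("k_out_TTR", "Imax_TTR", "IC50_TTR", "gamma_TTR")),
    step4_human_pk = list(design = designs$human_pk,
      estimate = c("k_in_endo", "k_out_exo", "k_deg_DR", "LDL_tot",
                   "k_dis", "k_ass", "k_deg_LNP", "k_el")),
    step4_human_pd = list(design = designs$human_ttr,
      estimate = c("k_out_TTR", "IC50_TTR", "Imax_TTR"))
  )
  if (!step_id %in% names(masks))
    stop("unknown step id: '", step_id, "'")
  m <- masks[[step_id]]
  args <- utils::modifyList(
    list(step_id = step_id, design = m$design, estimate = m$estimate,
         tie = m$tie), list(...))
  do.call(fit_spec, args)
}

# concentrated objective: profiled-sigma -2LL as a function of log-params
make_objective <- function(spec, data) {
  data <- validate_observations(data)
  key <- function(d) paste(d$dose_group, d$output_id, d$time, d$time_unit)
  force(spec)
  best <- Inf
  trace <- numeric(0)
  obj <- function(logtheta) {
    theta <- exp(logtheta)
    names(theta) <- spec$estimate
    ov <- as.list(theta)
    if (!is.null(spec$tie))
      for (nm in names(spec$tie)) ov[[nm]] <- theta[[spec$tie[[nm]]]]
    ov <- utils::modifyList(as.list(spec$fixed), ov)
    val <- tryCatch({
      params <- load_parameters(spec$design$species_id, overrides = ov)
      pred <- predict_design(spec$design, params, solver = spec$solver)
      m <- match(key(data), key(pred))
      if (any(is.na(m))) stop("dataset outputs not covered by the design")
      Y <- pred$value[m]; y <- data$value
      total <- 0
      for (o in unique(data$output_id)) {
        i <- data$output_id == o
        if (any(Y[i] <= 0)) stop("prediction <= 0 for output ", o)
        s <- max(profile_sigma_slope(Y[i], y[i]), 1e-12)
        total <- total + neg2ll(Y[i], y[i], s)
      }
      total
    }, error = function(e) 1e10)
    best <<- min(best, val)
    trace <<- c(trace, best)
    val
  }
  attr(obj, "get_trace") <- function() trace
  obj
}

# central-difference Hessian of f at x; the step is on the log-parameter
# scale and deliberately coarse so ODE-solver noise does not dominate
fd_hessian <- function(f, x, h = 0.01) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- ej <- numeric(n); ei[i] <- h; ej[j] <- h
    if (i == j) {
      H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

#' Fit a model to an observation dataset
#'
#' Bounded local optimization (L-BFGS-B on log-parameters) of the
#' concentrated -2 log-likelihood, with optional Latin-hypercube
#' multi-start. Relative standard errors are `100 * SE(log theta)` from
#' the inverse Hessian (the log-scale SE is the relative SE of the
#' natural-scale estimate).
#'
#' @param spec a `qsp_fit_spec`
#' @param data observation data.frame (schema of [observe()])
#' @return an object of class `qsp_fit` with fields `estimates`,
#'   `rse_pct`, `sigma_slope`, `neg2ll`, `convergence`, `predictions`,
#'   `trace`
#' @export
fit <- function(spec, data) {
  stopifnot(inherits(spec, "qsp_fit_spec"))
  obj <- make_objective(spec, data)
  d <- length(spec$estimate)
  lo <- log(spec$lower); hi <- log(spec$upper)

  starts <- matrix(log(spec$inits), nrow = 1)
  if (spec$n_starts > 1) {
    set.seed(spec$seed)
    # Latin hypercube over the log-bounds box
    extra <- spec$n_starts - 1
    lhs <- sapply(seq_len(d), function(j) {
      (sample(extra) - stats::runif(extra)) / extra * (hi[j] - lo[j]) + lo[j]
    })
    if (extra == 1) lhs <- matrix(lhs, nrow = 1)
    starts <- rbind(starts, lhs)
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B", lower = lo,
                   upper = hi, control = spec$control),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) { best <- res
      best$start <- s }
  }
  if (is.null(best)) stop("all optimization starts failed")

  logtheta <- best$par
  theta <- stats::setNames(exp(logtheta), spec$estimate)

  # standard errors from the -2LL curvature on the log scale
  rse <- rep(NA_real_, d)
  H <- tryCatch(fd_hessian(obj, logtheta), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    cv <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      v <- diag(cv)
      ok <- is.finite(v) & v > 0
      rse[ok] <- 100 * sqrt(v[ok])
    }
  }
  names(rse) <- spec$estimate

  # final predictions and per-output error slopes at the optimum
  ov <- as.list(theta)
  if (!is.null(spec$tie))
    for (nm in names(spec$tie)) ov[[nm]] <- theta[[spec$tie[[nm]]]]
  ov <- utils::modifyList(as.list(spec$fixed), ov)
  params <- load_parameters(spec$design$species_id, overrides = ov)
  pred <- predict_design(spec$design, params, solver = spec$solver)
  key <- function(dd) paste(dd$dose_group, dd$output_id, dd$time,
                            dd$time_unit)
  m <- match(key(data), key(pred))
  predictions <- data
  predictions$predicted <- pred$value[m]
  sig <- vapply(unique(data$output_id), function(o) {
    i <- data$output_id == o
    profile_sigma_slope(predictions$predicted[i], data$value[i])
  }, numeric(1))
  n2 <- sum(vapply(unique(data$output_id), function(o) {
    i <- data$output_id == o
    neg2ll(predictions$predicted[i], data$value[i],
           max(sig[[o]], 1e-12))
  }, numeric(1)))

  out <- list(step_id = spec$step_id, estimates = theta, rse_pct = rse,
              sigma_slope = sig, neg2ll = n2,
              convergence = best$convergence == 0,
              best_start = best$start, n_eval = best$counts[1],
              predictions = predictions, params = params, spec = spec,
              trace = attr(obj, "get_trace")())
  class(out) <- "qsp_fit"
  out
}

#' @export
print.qsp_fit <- function(x, ...) {
  cat("QSP fit (", x$step_id, "): -2LL =", format(x$neg2ll), "| converged:",
      x$convergence, "\n")
  tab <- data.frame(estimate = x$estimates, rse_pct = x$rse_pct)
  print(tab)
  invisible(x)
}

#' Observed-versus-fitted concordance summary
#'
#' Pairs every observation with its model prediction and summarizes
#' agreement with the identity line: through-origin regression slope and
#' the squared correlation.
#'
#' @param result a `qsp_fit`
#' @param data optional observation data.frame (defaults to the fit data)
#' @return list with `table` (observed/predicted pairs), `slope`, `r2`,
#'   and `degenerate` (TRUE when all predictions are zero)
#' @export
predictive_check <- function(result, data = NULL) {
  stopifnot(inherits(result, "qsp_fit"))
  tab <- result$predictions
  if (!is.null(data)) {
    key <- function(dd) paste(dd$dose_group, dd$output_id, dd$time,
                              dd$time_unit)
    m <- match(key(data), key(tab))
    tab <- data
    tab$predicted <- result$predictions$predicted[m]
  }
  if (all(tab$predicted == 0)) {
    warning("degenerate fit: all predictions are zero")
    return(list(table = tab, slope = NA_real_, r2 = NA_real_,
                degenerate = TRUE))
  }
  slope <- sum(tab$value * tab$predicted) / sum(tab$predicted^2)
  r2 <- if (stats::var(tab$value) > 0 && stats::var(tab$predicted) > 0)
    stats::cor(tab$value, tab$predicted)^2 else 1
  list(table = tab, slope = slope, r2 = r2, degenerate = FALSE)
}
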