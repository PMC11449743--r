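test_that("the Saltelli design has N*(2d+2) in-bounds reproducible rows", {
  spec <- sobol_spec(list(a = c(0, 1), b = c(2, 6)), N = 4, seed = 9)
  X <- saltelli_sample(spec)
  expect_equal(nrow(X), 4 * (2 * 2 + 2))
  expect_true(all(X[, "a"] >= 0 & X[, "a"] <= 1))
  expect_true(all(X[, "b"] >= 2 & X[, "b"] <= 6))
  expect_identical(X, saltelli_sample(spec))
  expect_error(sobol_spec(list(a = c(1, 1)), N = 4), "degenerate")
  expect_error(sobol_spec(list(a = c(0, 1)), N = 1), "N must be")
})

test_that("Sobol estimators recover analytic indices of additive models", {
  # Y = a X1 + b X2 on independent uniforms: S1_i = ai^2 V_i / sum
  spec <- sobol_spec(list(x1 = c(0, 1), x2 = c(0, 1)), N = 1024, seed = 4)
  res <- sobol_indices(spec, function(X) 2 * X[, 1] + X[, 2], n_boot = 25)
  idx <- res$indices
  expect_equal(idx$S1[idx$parameter == "x1"], 0.8, tolerance = 0.07)
  expect_equal(idx$S1[idx$parameter == "x2"], 0.2, tolerance = 0.25)
  expect_equal(idx$ST[idx$parameter == "x1"], 0.8, tolerance = 0.07)
  # total >= first order up to estimator noise
  expect_true(all(idx$ST >= idx$S1 - 0.05))
  expect_true(all(idx$S1 > -0.05 & idx$S1 < 1.05))
  # the supplementary signed correlation carries the direction
  expect_gt(idx$spearman[idx$parameter == "x1"], 0.8)

  # a single active input takes all the variance
  res2 <- sobol_indices(spec, function(X) X[, 1], n_boot = 0)
  expect_equal(res2$indices$S1[res2$indices$parameter == "x1"], 1,
               tolerance = 0.05)
  expect_equal(res2$indices$S1[res2$indices$parameter == "x2"], 0,
               tolerance = 0.05)

  # an almost-collapsed parameter gets indices near zero
  spec3 <- sobol_spec(list(x1 = c(0, 1), x2 = c(0.5, 0.5 + 1e-9)), N = 512,
                      seed = 5)
  res3 <- sobol_indices(spec3, function(X) X[, 1] + X[, 2], n_boot = 0)
  expect_lt(abs(res3$indices$ST[res3$indices$parameter == "x2"]), 0.01)

  # non-finite outputs are reported with the offending row
  expect_error(sobol_indices(spec, function(X) c(NaN, rep(1, nrow(X) - 1)),
                             n_boot = 0), "non-finite model output")
})

test_that("time-variant mode returns indices per time point", {
  spec <- sobol_spec(list(x1 = c(0, 1), x2 = c(0, 1)), N = 256, seed = 6)
  res <- sobol_indices(spec, function(X)
    cbind(t1 = 2 * X[, 1] + X[, 2], t2 = X[, 1] + 2 * X[, 2]), n_boot = 0)
  expect_equal(nrow(res$indices), 4)
  s1_x1 <- res$indices$S1[res$indices$parameter == "x1"]
  expect_gt(s1_x1[1], s1_x1[2])  # x1 dominates at t1, not t2
})

test_that("population sampler hits the requested median and CV", {
  base <- load_parameters("human")
  spec <- population_spec(n_subjects = 10000, cv = 0.2,
                          varied = c("k_in_endo", "IC50_TTR"), seed = 11)
  M <- sample_population(spec, base)
  cv_emp <- apply(M, 2, function(x) sd(x) / mean(x))
  expect_true(all(cv_emp > 0.19 & cv_emp < 0.21))
  med <- apply(M, 2, median)
  expect_equal(unname(med[["k_in_endo"]] / 0.007), 1, tolerance = 0.02)
  expect_equal(unname(med[["IC50_TTR"]] / 0.3), 1, tolerance = 0.02)
  # cv = 0 reproduces the base exactly; draws are seed-reproducible
  M0 <- sample_population(population_spec(5, 0, "k_in_endo"), base)
  expect_true(all(M0 == 0.007))
  expect_identical(M, sample_population(spec, base))
  expect_error(population_spec(cv = -0.1), "cv")
  expect_error(sample_population(population_spec(2, 0.1, "nope"), base),
               "not in base set")
})

test_that("a tiny virtual population collapses to the typical subject", {
  spec <- population_spec(n_subjects = 3, cv = 0, seed = 2)
  res <- run_population(spec, arms = 0.3, t_days = c(0, 14, 28))
  s <- res$summary
  expect_equal(res$n_failed, 0)
  # all quantile bands coincide at cv = 0
  for (td in unique(s$time_d)) {
    v <- s$pct_change[s$time_d == td]
    expect_lt(max(v) - min(v), 1e-9)
  }
  # baseline percent change is exactly zero
  expect_equal(s$pct_change[s$time_d == 0], rep(0, 3))
})

test_that("model-level GSA runs end to end at a tiny sample size", {
  res <- gsa_qsp("mouse", N = 8, horizon = 4, seed = 3,
                 parameters = list(k_deg_mRNA = c(0.05, 2),
                                   k_out_exo = c(1, 50)))
  idx <- res$indices
  expect_equal(nrow(idx), 2)
  expect_true(all(is.finite(idx$S1)))
  # mRNA degradation must dominate the plasma RNA AUC over exocytosis
  expect_gt(idx$ST[idx$parameter == "k_deg_mRNA"],
            idx$ST[idx$parameter == "k_out_exo"])
})
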