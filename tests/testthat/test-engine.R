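test_that("zero dose leaves every observable at baseline", {
  model <- build_model(load_physiology("human"), load_parameters("human"))
  traj <- simulate_qsp(model, NULL, t_grid = seq(24, 672, 24))
  expect_equal(traj$obs$serum_TTR_pct, rep(100, 28), tolerance = 1e-10)
  expect_equal(traj$obs$serum_PCSK9_pct, rep(100, 28), tolerance = 1e-10)
  expect_equal(traj$obs$serum_LDL_pct, rep(100, 28), tolerance = 1e-10)
  expect_equal(max(traj$obs$plasma_LNP), 0)
})

test_that("simulation is deterministic", {
  phys <- load_physiology("nhp")
  reg <- build_regimen(2, phys, route = "infusion")
  model <- build_model(phys, load_parameters("nhp"), regimen = reg)
  a <- simulate_qsp(model, reg, t_grid = c(1.5, 4, 8))
  b <- simulate_qsp(model, reg, t_grid = c(1.5, 4, 8))
  expect_identical(a$obs, b$obs)
})

test_that("plasma LNP scales linearly with dose when binding is disabled", {
  phys <- load_physiology("nhp")
  params <- load_parameters("nhp", overrides = list(k_on_LNP = 0))
  tg <- c(1.5, 4, 8)
  conc <- lapply(c(1, 2), function(dose) {
    reg <- build_regimen(dose, phys, route = "infusion")
    model <- build_model(phys, params, regimen = reg)
    simulate_qsp(model, reg, t_grid = tg,
                 solver = solver_options(1e-8, 1e-11))$obs$plasma_LNP
  })
  expect_equal(conc[[2]] / conc[[1]], rep(2, 3), tolerance = 0.01)
})

test_that("trapezoidal AUC matches closed forms and is additive", {
  tt <- seq(0, 10, by = 0.1)
  expect_equal(auc(tt, rep(3, length(tt))), 30)
  # exponential decay out to 10/k recovers C0/k within 0.1%
  k <- 0.7; tt <- seq(0, 10 / k, length.out = 14286)
  expect_equal(auc(tt, 5 * exp(-k * tt)), 5 / k, tolerance = 1e-3)
  # additivity over adjacent windows
  cc <- 5 * exp(-k * tt)
  expect_equal(auc(tt, cc, 0, 4) + auc(tt, cc, 4, max(tt)),
               auc(tt, cc), tolerance = 1e-12)
  expect_error(auc(c(1), c(2)), "2 points")
  expect_error(auc(c(0, 1), c(1, 1), 1, 1), "empty")
})

test_that("observe extracts schedules in hours and days equivalently", {
  phys <- load_physiology("human")
  reg <- build_regimen(1, phys, route = "infusion")
  model <- build_model(phys, load_parameters("human"), regimen = reg)
  traj <- simulate_qsp(model, reg,
                       t_grid = sort(c(c(7, 14, 28) * 24, 672.5)))
  sched_d <- data.frame(output_id = "serum_TTR_pct", time = c(7, 14, 28),
                        time_unit = "days")
  sched_h <- data.frame(output_id = "serum_TTR_pct",
                        time = c(7, 14, 28) * 24, time_unit = "hours")
  rec_d <- observe(traj, sched_d, dose_group = "1 mg/kg")
  rec_h <- observe(traj, sched_h)
  expect_equal(rec_d$value, rec_h$value)
  expect_equal(rec_d$unit, rep("%baseline", 3))
  expect_equal(rec_d$species, rep("human", 3))
  # baseline exactness at t = 0
  traj0 <- simulate_qsp(model, reg, t_grid = c(0, 1, 2))
  rec0 <- observe(traj0, data.frame(output_id = "serum_TTR_pct", time = 0))
  expect_equal(rec0$value, 100)
  # empty schedule and extrapolation contracts
  expect_equal(nrow(observe(traj, data.frame(output_id = character(),
                                             time = numeric()))), 0)
  expect_error(observe(traj, data.frame(output_id = "serum_TTR_pct",
                                        time = 1e6)), "extrapolation")
  expect_error(observe(traj, data.frame(output_id = "nope", time = 1)),
               "unknown output_id")
})

test_that("observation tables validate their schema", {
  good <- data.frame(time = 1, time_unit = "hours", species = "nhp",
                     dose_group = "1 mg/kg", output_id = "plasma_LNP",
                     value = 3, unit = "ug/mL")
  expect_silent(validate_observations(good))
  expect_error(validate_observations(good[, -3]), "missing column")
  bad <- good; bad$value <- -1
  expect_error(validate_observations(bad), ">= 0")
})
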