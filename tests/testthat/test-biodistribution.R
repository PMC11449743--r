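test_that("derived constants hold by construction", {
  nhp <- load_parameters("nhp")
  expect_equal(k_syn_receptor(nhp), 539 * 0.231)
  expect_equal(kd_mass(nhp), 0.0784, tolerance = 1e-12)
  expect_equal(k_on_rnp(nhp), 0.00188 / 0.0784, tolerance = 1e-12)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(load_parameters("nhp", overrides = list(k_ass = -1)),
               "nonnegative")
  expect_error(load_parameters("nhp", overrides = list(fu_LNP = 0)),
               "fu_LNP")
  expect_error(load_parameters("nhp", overrides = list(nonsense = 1)),
               "unknown parameter override")
  expect_error(load_parameters("nhp", overrides = list(Imax_TTR = 1.2)),
               "Imax")
})

test_that("topology: mRNA never gets a kidney compartment", {
  phys <- load_physiology("human"); params <- load_parameters("human")
  expect_error(build_model(phys, params, topology = list(kidney_mRNA = TRUE)),
               "structural error")
  # kidney states exist for LNP and sgRNA only
  sn <- qsp_state_names()
  expect_true(all(c("kid_LNP", "kid_sgRNA") %in% sn))
  expect_false("kid_mRNA" %in% sn)
  # and the compiled RHS routes no mRNA through the kidney: a kidney-only
  # perturbation leaves every mRNA derivative untouched
  model <- build_model(phys, params)
  y <- blank_state(); y["pl_mRNA"] <- 100; y["R_free"] <- 84.5
  d1 <- pk_rhs(0, y, model)
  y2 <- y; y2[c("kid_LNP", "kid_sgRNA")] <- 50
  d2 <- pk_rhs(0, y2, model)
  m_states <- grep("mRNA", qsp_state_names(), value = TRUE)
  expect_equal(d1[m_states], d2[m_states])
})

test_that("flux operations satisfy their contracts", {
  # opsonin binding conserves mass and has the analytic equilibrium
  fl <- opsonin_flux(2, 3, 5.06, 8.64)
  expect_equal(fl$d_free + fl$d_bound, 0)
  expect_equal(opsonin_flux(0, 0, 5.06, 8.64)$d_bound, 0)
  expect_error(opsonin_flux(-1, 0, 1, 1), "negative")

  # MPS uptake is an internal transfer; only degradation removes mass
  fm <- mps_flux(10, 4, 0.9063, 1.6486)
  expect_equal(fm$uptake, 0.9063 * 10)
  expect_equal(fm$degradation, 1.6486 * 4)

  # receptor: no-drug steady state at LDL_tot, detailed-balance ratio
  nhp <- load_parameters("nhp")
  rf <- receptor_flux(0, 539, 0, nhp)
  expect_equal(rf$dR, 0)
  # equilibrium complex/(free*R) = k_on/k_off per (ug/mL)
  C <- 0.7; R <- 12
  eq <- receptor_flux(C, R, C * R * 0.18 / 33.12, nhp)
  expect_equal(eq$binding, eq$unbinding, tolerance = 1e-12)
  expect_equal(0.18 / 33.12, 5.435e-3, tolerance = 1e-3)

  # transfer: sigma = 1 kills convection; zero rates give zero flux
  tf <- transfer_flux(3, 1, 10, 5, 0, 0, L = 7, sigma = 1)
  expect_equal(tf$inward, 0)
  expect_equal(transfer_flux(3, 1, 10, 5, 0, 0)$inward, 0)
  expect_error(transfer_flux(1, 1, 0, 5, 1, 1), "volumes")
})

test_that("compiled RHS equals the pure-R flux assembly on random states", {
  set.seed(7)
  for (sp in c("mouse", "nhp", "human")) {
    phys <- load_physiology(sp); params <- load_parameters(sp)
    reg <- build_regimen(2, phys, route = "infusion")
    model <- build_model(phys, params, regimen = reg)
    for (k in 1:5) {
      y <- stats::setNames(runif(29, 0, 50), qsp_state_names())
      t <- runif(1, 0, 4)  # straddles the infusion switch-off
      a <- pk_rhs(t, y, model, reg)
      b <- pk_rhs_ref(t, y, model, reg)
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("all-zero rates give an identically zero derivative", {
  model <- isolated_model("nhp")
  model$pvec["MTT"] <- Inf  # transit turnover off as well
  y <- stats::setNames(runif(29, 0, 10), qsp_state_names())
  expect_equal(max(abs(pk_rhs(0, y, model))), 0)
})

test_that("RHS rejects malformed states", {
  model <- build_model(load_physiology("nhp"), load_parameters("nhp"))
  expect_error(pk_rhs(0, numeric(5), model), "dimension")
  y <- blank_state(); y[3] <- NaN
  expect_error(pk_rhs(0, y, model), "NaN")
})

test_that("isolated kinetic subsystems match their closed forms", {
  tt <- seq(0, 30, by = 0.5)

  # free-LNP first-order decay in plasma (human rate, half-life ~6.86 h)
  m <- isolated_model("human", keep = c(k_deg_LNP = 0.101))
  y0 <- blank_state(); y0["pl_LNP"] <- 500
  out <- integrate_states(m, y0, tt)
  expect_equal(out[, "pl_LNP"], 500 * exp(-0.101 * tt), tolerance = 1e-6)
  expect_equal(log(2) / 0.101, 6.86, tolerance = 1e-3)

  # opsonin two-state system: analytic solution of the linear pair
  m <- isolated_model("nhp", keep = c(k_ass = 5.06, k_dis = 8.64))
  y0 <- blank_state(); y0["pl_LNP"] <- 100
  out <- integrate_states(m, y0, tt)
  lam <- 5.06 + 8.64
  free_exact <- 100 * (8.64 + 5.06 * exp(-lam * tt)) / lam
  expect_equal(out[, "pl_LNP"], free_exact, tolerance = 1e-6)
  # equilibrium bound/free ratio = k_ass/k_dis ~ 0.586
  n <- length(tt)
  expect_equal(unname(out[n, "pl_LNP_ops"] / out[n, "pl_LNP"]), 5.06 / 8.64,
               tolerance = 1e-6)
  expect_equal(5.06 / 8.64, 0.586, tolerance = 1e-3)

  # MPS pool halves in ln2/1.6486 ~ 0.42 h
  m <- isolated_model("nhp", keep = c(k_deg_LNP = 1.6486))
  y0 <- blank_state(); y0["mps_LNP"] <- 80
  out <- integrate_states(m, y0, c(0, log(2) / 1.6486))
  expect_equal(unname(out[2, "mps_LNP"]), 40, tolerance = 1e-6)
  expect_equal(log(2) / 1.6486, 0.42, tolerance = 1e-2)

  # mRNA-only pool decays with half-life ln2/0.1232 ~ 5.63 h
  m <- isolated_model("nhp", keep = c(k_deg_mRNA = 0.1232))
  y0 <- blank_state(); y0["lc_mRNA"] <- 10
  out <- integrate_states(m, y0, tt)
  expect_equal(out[, "lc_mRNA"], 10 * exp(-0.1232 * tt), tolerance = 1e-6)

  # RNP decays mono-exponentially at k_off_RNP with all else off
  m <- isolated_model("nhp", keep = c(k_off_RNP = 0.00188))
  y0 <- blank_state(); y0["lc_RNP"] <- 6
  out <- integrate_states(m, y0, tt)
  expect_equal(out[, "lc_RNP"], 6 * exp(-0.00188 * tt), tolerance = 1e-6)

  # two-compartment exchange equilibrium C_lower/C_upper = kin*Vu/(kout*Vl)
  m <- isolated_model("nhp", keep = c(k_in_endo = 0.5, k_out_exo = 0.8))
  Vu <- m$pvec["V_liver_vasc"]; Vl <- m$pvec["V_liver_int"]
  y0 <- blank_state(); y0["lv_sgRNA"] <- 30
  # full reversibility at both interfaces so the chain equilibrates, and
  # no free-fraction gating at the vascular interface
  m$pvec["fu_RNA"] <- 1
  m$pvec["cell_exo_frac"] <- 1
  out <- integrate_states(m, y0, seq(0, 400, 50))
  n <- 9
  ratio <- (out[n, "li_sgRNA"] / Vl) / (out[n, "lv_sgRNA"] / Vu)
  expect_equal(unname(ratio), unname(0.5 * Vu / (0.8 * Vl)),
               tolerance = 1e-5)
})

test_that("intracellular kinetics honor stoichiometry and inertness", {
  nhp <- load_parameters("nhp")
  V <- 87.8
  # k_trans = 0 and no Cas9 -> RNP stays zero forever
  d <- intracellular_rhs(c(sgRNA = 5, mRNA = 3, Cas9 = 0, RNP = 0),
                         load_parameters("nhp", overrides = list(k_trans = 0)),
                         V)
  expect_equal(unname(d[["RNP"]]), 0)
  # assembly conserves Cas9 + RNP/(1+mw) when degradation is off
  p0 <- params_closed("nhp")
  d2 <- intracellular_rhs(c(sgRNA = 5, mRNA = 3, Cas9 = 2, RNP = 1), p0, V)
  mw <- 32000 / 160000
  expect_equal(unname(d2[["Cas9"]] + d2[["RNP"]] / (1 + mw)), 0,
               tolerance = 1e-14)
  expect_error(intracellular_rhs(c(sgRNA = -1, mRNA = 0, Cas9 = 0, RNP = 0),
                                 nhp, V), "negative")
})

test_that("mass is conserved with degradation and elimination off", {
  phys <- load_physiology("nhp")
  reg <- build_regimen(2, phys, route = "infusion")
  model <- no_renal(build_model(phys, params_closed("nhp"), regimen = reg))
  traj <- simulate_qsp(model, reg, t_grid = seq(2, 30, 2),
                       solver = solver_options(1e-8, 1e-10))
  st <- traj$state
  mw <- 32000 / 160000
  lnp <- rowSums(st[, c("pl_LNP", "pl_LNP_ops", "lv_LNP", "lv_LNP_ops",
                        "mps_LNP", "li_LNP", "li_complex", "kid_LNP",
                        "rem_LNP")])
  sg <- rowSums(st[, c("pl_sgRNA", "lv_sgRNA", "li_sgRNA", "lc_sgRNA",
                       "kid_sgRNA", "rem_sgRNA")]) +
    st[, "lc_RNP"] * mw / (1 + mw)
  mr <- rowSums(st[, c("pl_mRNA", "lv_mRNA", "li_mRNA", "lc_mRNA",
                       "rem_mRNA")])
  expect_lt(max(abs(lnp / reg$amt_LNP - 1)), 1e-6)
  expect_lt(max(abs(sg / reg$amt_sgRNA - 1)), 1e-6)
  expect_lt(max(abs(mr / reg$amt_mRNA - 1)), 1e-6)
})

test_that("cargo release adds RNA mass at exactly the bookkeeping rate", {
  # with k_release > 0 the released sgRNA+mRNA grows at
  # k_release * LNP_int / lnp_ratio; total RNA is deliberately not conserved
  phys <- load_physiology("nhp")
  params <- params_closed("nhp", k_release = 0.634)
  reg <- build_regimen(2, phys, route = "bolus")
  model <- no_renal(build_model(phys, params, regimen = reg))
  y <- blank_state(); y["li_LNP"] <- 100; y["R_free"] <- 539
  d <- pk_rhs(0, y, model, reg)
  sg_states <- c("pl_sgRNA", "lv_sgRNA", "li_sgRNA", "lc_sgRNA",
                 "kid_sgRNA", "rem_sgRNA")
  m_states <- c("pl_mRNA", "lv_mRNA", "li_mRNA", "lc_mRNA", "rem_mRNA")
  lr <- reg$lnp_dose_mgkg / reg$total_rna_mgkg
  expect_equal(sum(d[sg_states]), 0.634 * 100 / lr * reg$frac_sgRNA,
               tolerance = 1e-12)
  expect_equal(sum(d[m_states]), 0.634 * 100 / lr * reg$frac_mRNA,
               tolerance = 1e-12)
})

test_that("receptor baseline stays at LDL_tot without a dose", {
  model <- build_model(load_physiology("human"), load_parameters("human"))
  traj <- simulate_qsp(model, NULL, t_grid = seq(1, 100, 5))
  expect_equal(traj$state[, "R_free"], rep(84.5, 20), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("states stay nonnegative along standard trajectories", {
  for (sp in c("mouse", "human")) {
    phys <- load_physiology(sp)
    reg <- build_regimen(2, phys,
                         route = if (sp == "mouse") "bolus" else "infusion")
    model <- build_model(phys, load_parameters(sp), regimen = reg)
    traj <- simulate_qsp(model, reg, t_grid = seq(0.5, 48, 0.5),
                         solver = solver_options(1e-6, 1e-9))
    expect_gte(min(traj$state), -1e-9)
  }
})
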