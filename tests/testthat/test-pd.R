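nhp_pd <- load_parameters("nhp")$pd
human_pd <- load_parameters("human")$pd

test_that("Hill inhibition has the forced anchor points", {
  expect_equal(hill_inhibition(0, 0.9, 2, 0.31), 0)
  for (g in c(0.31, 1, 1.1, 3))
    expect_equal(hill_inhibition(2, 0.9, 2, g), 0.45)
  expect_equal(hill_inhibition(1e12, 0.9, 2, 1), 0.9, tolerance = 1e-9)
  expect_error(hill_inhibition(-1, 0.9, 2, 1), ">= 0")
  expect_error(hill_inhibition(1, 0.9, 0, 1), "IC50")
})

test_that("TTR model is stationary at baseline and saturates at 1 - Imax", {
  expect_equal(ttr_rhs(100, 0, nhp_pd), 0)
  # saturating clamp: steady state 1 - Imax for both calibrated species
  sat <- function(pd) pd$IC50_TTR * 10^(7 / pd$gamma_TTR)
  expect_equal(ttr_steady_state_fraction(sat(nhp_pd), nhp_pd), 1 - 0.961,
               tolerance = 1e-5)
  expect_equal(ttr_steady_state_fraction(sat(human_pd), human_pd), 1 - 0.959,
               tolerance = 1e-5)
  expect_equal(ttr_steady_state_fraction(0, nhp_pd), 1)
  expect_equal(ttr_steady_state_fraction(nhp_pd$IC50_TTR, nhp_pd),
               1 - 0.961 / 2)
})

test_that("steady-state fraction is monotone and bounded", {
  cs <- 10^seq(-6, 8, by = 0.25)
  fr <- vapply(cs, ttr_steady_state_fraction, numeric(1), pd = nhp_pd)
  expect_true(all(diff(fr) <= 1e-12))
  expect_true(all(fr >= 1 - nhp_pd$Imax_TTR - 1e-12 & fr <= 1))
})

test_that("TTR relaxes mono-exponentially at k_out under a constant clamp", {
  C <- nhp_pd$IC50_TTR  # sub-saturating
  ss <- 100 * ttr_steady_state_fraction(C, nhp_pd)
  f <- function(t, y) ttr_rhs(y, C, nhp_pd)
  tt <- seq(0, 30, by = 0.25)  # days
  num <- rk4(f, 100, tt)[, 1]
  exact <- ss + (100 - ss) * exp(-nhp_pd$k_out_TTR * tt)
  expect_equal(num, exact, tolerance = 1e-8)
})

test_that("PCSK9 chain is stationary at baseline and inert without drug", {
  d <- pcsk9_rhs(rep(100, 3), 100, 0, nhp_pd)
  expect_equal(max(abs(c(d$transit, d$observable))), 0)
  expect_error(pcsk9_rhs(rep(100, 2), 100, 0, nhp_pd), "length")
  expect_error(pcsk9_rhs(c(-1, 0, 0), 100, 0, nhp_pd), "negative")
})

test_that("transit chain impulse response integrates to 1 with mean MTT", {
  ktr <- 3 / nhp_pd$MTT
  f <- function(t, y) c(-ktr * y[1], ktr * (y[1] - y[2]), ktr * (y[2] - y[3]))
  tt <- seq(0, 200, by = 0.5)
  out <- rk4(f, c(1, 0, 0), tt)
  flux <- ktr * out[, 3]  # chain output flux for a unit impulse
  mass <- sum((utils::head(flux, -1) + utils::tail(flux, -1)) / 2 * diff(tt))
  mean_t <- sum((utils::head(flux * tt, -1) +
                 utils::tail(flux * tt, -1)) / 2 * diff(tt)) / mass
  expect_equal(mass, 1, tolerance = 1e-4)
  expect_equal(mean_t, 14.5, tolerance = 1e-3)
})

test_that("without feedback, saturating drug drives PCSK9 to (1-Imax)*P0", {
  pd <- utils::modifyList(nhp_pd, list(feedback_on = 0))
  ss <- (1 - pd$Imax_PCSK9) * 100
  d <- pcsk9_rhs(rep(ss, 3), ss, 1e12 * pd$IC50_PCSK9, pd)
  expect_equal(max(abs(c(d$transit, d$observable))), 0, tolerance = 1e-6)
})

test_that("LDL precursor model follows the power-law steady state", {
  expect_equal(ldl_rhs(100, 100, nhp_pd), 0)
  # PCSK9 halved, Gamma = 1 -> LDL ss at 50%
  pd1 <- utils::modifyList(nhp_pd, list(Gamma_LDL = 1))
  expect_equal(ldl_rhs(50, 50, pd1), 0)
  # PCSK9 halved at the calibrated Gamma: ss = 100 * 0.5^0.672 ~ 62.8%
  ss <- 100 * 0.5^0.672
  expect_equal(ss, 62.8, tolerance = 1e-3)
  expect_equal(ldl_rhs(ss, 50, nhp_pd), 0, tolerance = 1e-10)
  expect_error(ldl_rhs(100, 100, utils::modifyList(nhp_pd,
                                                   list(PCSK9_0 = 0))),
               "PCSK9_0")
})

test_that("all PD models are exactly stationary at baseline in the full RHS", {
  for (sp in c("nhp", "human")) {
    model <- build_model(load_physiology(sp), load_parameters(sp))
    y <- initial_state(model)
    d <- pk_rhs(0, y, model)
    expect_lt(max(abs(d[c("TTR", "tr1", "tr2", "tr3", "PCSK9", "LDL")])),
              1e-12)
  }
})
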