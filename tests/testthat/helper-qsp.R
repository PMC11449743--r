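# Shared fixtures: everything is built in code at test time.

# parameters with every degradation / elimination / release pathway off,
# for conservation properties
params_closed <- function(species = "nhp", ...) {
  load_parameters(species, overrides = utils::modifyList(
    list(k_deg_LNP = 0, k_deg_DR = 0, k_deg_sgRNA = 0, k_deg_mRNA = 0,
         k_deg_Cas = 0, k_release = 0, k_trans = 0), list(...)))
}

# zero out renal clearance on a built model (packed-vector surgery)
no_renal <- function(model) {
  model$pvec["CL_renal_LNP"] <- 0
  model$pvec["CL_renal_sgRNA"] <- 0
  model
}

# a model whose packed vector isolates one subsystem: all rates and flows
# zeroed except the ones named in `keep` (named numeric vector)
isolated_model <- function(species = "nhp", keep = c()) {
  model <- build_model(load_physiology(species), load_parameters(species))
  zap <- setdiff(qsp_param_names(),
                 c("V_plasma", "V_liver_vasc", "V_liver_int", "V_liver_cell",
                   "V_kidney", "V_remainder", "n_transit", "MTT", "TTR0",
                   "PCSK9_0", "LDL0", "IC50_TTR", "IC50_PCSK9", "gamma_TTR",
                   "gamma_PCSK9", "gamma_fb", "Gamma_LDL", "mw_ratio",
                   "lnp_ratio", "frac_sgRNA", "frac_mRNA", "clamp_rnp",
                   "inf_end"))
  model$pvec[zap] <- 0
  model$pvec["clamp_rnp"] <- -1
  model$pvec["inf_end"] <- -1
  for (nm in names(keep)) model$pvec[nm] <- keep[[nm]]
  model
}

integrate_states <- function(model, y0, times, rtol = 1e-8, atol = 1e-12) {
  out <- crisprqsp:::qsp_integrate_cpp(times, as.numeric(y0),
                                       as.numeric(model$pvec), rtol, atol,
                                       Inf)
  colnames(out) <- qsp_state_names()
  out
}

blank_state <- function() stats::setNames(numeric(29), qsp_state_names())

# classic RK4 with fixed step: local oracle for tiny systems
rk4 <- function(f, y0, times) {
  y <- y0
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y
  for (i in 2:length(times)) {
    h <- times[i] - times[i - 1]
    n_sub <- max(1L, ceiling(h / 0.005))
    hs <- h / n_sub
    t <- times[i - 1]
    for (s in seq_len(n_sub)) {
      k1 <- f(t, y); k2 <- f(t + hs / 2, y + hs / 2 * k1)
      k3 <- f(t + hs / 2, y + hs / 2 * k2); k4 <- f(t + hs, y + hs * k3)
      y <- y + hs / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hs
    }
    out[i, ] <- y
  }
  out
}
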