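# shared fixtures, all built in code

# physiology whose organs never grow and whose yolk never shrinks:
# a single constant-volume compartment (the yolk) for analytic limits
toy_physiology <- function(V0 = 0.2, k_yolk = 0, TA = 0) {
  organs <- data.frame(name = setdiff(zfe_compartments(), "yolk"),
                       Kg_TR = 0, tau_TR = 0)
  zfe_physiology(organs, yolk = list(V0 = V0, k = k_yolk),
                 V_embryo_120 = 1, TA = TA)
}

# uniform-partition compound with no medium losses
one_comp_compound <- function(P = 10, phi = 2, phi_chorion = 0.5,
                              sigma = 2) {
  compound_params("toy", MW = 228.29,
                  P_prior = setNames(rep(P, 10), zfe_compartments()),
                  f_pc = 1, phi = phi, phi_chorion = phi_chorion,
                  sigma = sigma)
}

# quiet well: huge water volume, no surfaces, no renewal
still_design <- function(conc_nM = 1000, duration = 48, start_age = 0,
                         chorionated = FALSE, V_water = 1e9,
                         n_embryos = 1) {
  exposure_design(device_spec(V_water, n_embryos = n_embryos),
                  data.frame(time_hpf = start_age, conc_nM = conc_nM),
                  duration = duration, start_age = start_age,
                  temperature = 25, chorionated = chorionated)
}

bpa_priors <- function() {
  prior_spec(data.frame(
    parameter = c("f_pc", "phi", "phi_chorion", "sigma"),
    lower = c(0.01, 0.5, 0.02, 1.05),
    upper = c(10, 40, 2.5, 8)))
}

empty_dataset <- function() {
  tk_dataset(data.frame(design_id = character(0), compound = character(0),
                        time_hpf = numeric(0), conc_body = numeric(0)),
             list())
}
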