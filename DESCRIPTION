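Package: zfetk
Title: Physiologically Based Toxicokinetic Modelling for Zebrafish Eleutheroembryos
Version: 0.1.0
Authors@R:
    person("zfetk", "developers", email = "zfetk@example.org", role = c("aut", "cre"))
Description: A ten-compartment growing-organism physiologically based
    pharmacokinetic (PBPK) model for the zebrafish eleutheroembryo (0-120
    hours post-fertilization), with chorion-switched uptake before hatching,
    Arrhenius temperature scaling of organ ontogeny and yolk resorption,
    medium mass balance (device-wall binding, volatilization, dosing and
    medium renewal), optional hepatic metabolism and uptake saturation.
    Includes Bayesian calibration of compound-specific parameters by
    Metropolis MCMC with a lognormal error model, AIC/BIC model-structure
    comparison, variance-based Sobol sensitivity analysis, a literature-like
    synthetic toxicokinetic data generator, unit harmonization utilities and
    a command-line interface. Shipped with bisphenol (BPA, BPAF, BPF, BPS)
    parameter presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
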