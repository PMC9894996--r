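#' Compound-specific parameter set
#'
#' All chemical constants of one compound: molecular weight, per-tissue
#' tissue:water partition-coefficient priors (QSAR inputs), the global
#' scaling factor `f_pc` applied to all of them, the pre-hatch (through
#' the chorion) and post-hatch exchange-rate constants, optional uptake
#' saturation and hepatic metabolism, the observation-error geometric SD,
#' and the medium loss parameters.
#'
#' @param name compound label.
#' @param MW molecular weight (g/mol).
#' @param P_prior named numeric vector of tissue:water partition
#'   coefficients (dimensionless) for all ten compartments, as produced by
#'   an external QSAR; scaled by `f_pc` inside the model.
#' @param f_pc global partition-coefficient scaling factor, > 0.
#' @param phi post-hatch exchange-rate constant per body surface area
#'   (uL/h/mm^2).
#' @param phi_chorion pre-hatch (through-chorion) exchange rate (uL/h).
#' @param Sat50_uM half-saturation water concentration (uM); `Inf`
#'   disables saturation.
#' @param metabolism list with `kind` in `"none"`, `"linear"`, `"mm"` and,
#'   as relevant, `K_met` (per-hepatocyte clearance, uL/h), `V_max`
#'   (nmol/h per hepatocyte) and `K_M` (nmol/uL).
#' @param V_liver_cell single-hepatocyte volume (uL).
#' @param sigma geometric standard deviation of the lognormal observation
#'   error, > 1.
#' @param medium a [medium_params()] object.
#' @return Object of class `zfe_compound`.
#' @seealso [compound_preset()] for the packaged bisphenol presets.
#' @export
compound_params <- function(name, MW, P_prior, f_pc = 1, phi, phi_chorion,
                            Sat50_uM = Inf,
                            metabolism = list(kind = "none"),
                            V_liver_cell = 1.5e-6, sigma = 2,
                            medium = medium_params()) {
  if (!setequal(names(P_prior), ZFE_COMPARTMENTS))
    stop_input("P_prior needs one value per compartment: ",
               paste(ZFE_COMPARTMENTS, collapse = ", "))
  P_prior <- P_prior[ZFE_COMPARTMENTS]
  if (any(P_prior <= 0)) stop_input("partition coefficients must be > 0")
  if (f_pc <= 0) stop_input("f_pc must be > 0")
  if (phi < 0 || phi_chorion < 0) stop_input("phi values must be >= 0")
  if (!is.infinite(Sat50_uM) && Sat50_uM <= 0)
    stop_input("Sat50_uM must be > 0 or Inf (disabled)")
  if (sigma <= 1) stop_input("sigma (geometric SD) must be > 1")
  metabolism$kind <- match.arg(metabolism$kind %||% "none",
                               c("none", "linear", "mm"))
  met <- list(kind = metabolism$kind, K_met = metabolism$K_met %||% 0,
              V_max = metabolism$V_max %||% 0, K_M = metabolism$K_M %||% 1)
  if (met$K_met < 0 || met$V_max < 0 || met$K_M <= 0)
    stop_input("metabolism constants must be non-negative (K_M > 0)")
  stopifnot(inherits(medium, "zfe_medium_params"))
  structure(list(name = name, MW = MW, P_prior = P_prior, f_pc = f_pc,
                 phi = phi, phi_chorion = phi_chorion, Sat50_uM = Sat50_uM,
                 metabolism = met, V_liver_cell = V_liver_cell,
                 sigma = sigma, medium = medium),
            class = "zfe_compound")
}

#' @export
print.zfe_compound <- function(x, ...) {
  cat("zfe compound:", x$name, "(MW", x$MW, "g/mol)\n  f_pc", x$f_pc,
      "| phi", x$phi, "uL/h/mm2 | phi_chorion", x$phi_chorion,
      "uL/h | sigma", x$sigma, "\n  Sat50",
      if (is.infinite(x$Sat50_uM)) "off" else paste(x$Sat50_uM, "uM"),
      "| metabolism", x$metabolism$kind, "\n")
  invisible(x)
}

#' Effective (scaled) tissue:water partition coefficients
#'
#' @param compound a [compound_params()] object.
#' @return Named numeric vector, `f_pc * P_prior`.
#' @export
effective_partition <- function(compound) compound$f_pc * compound$P_prior

#' Model structure flags
#'
#' The structural variants compared during model selection: a single
#' surface-scaled uptake flow versus a chorion-switched pair of flows,
#' optional uptake saturation, and the metabolism sub-model.
#'
#' @param chorion_switch logical; `TRUE` uses the constant through-chorion
#'   flow before hatching for chorionated embryos.
#' @param saturation logical; `TRUE` multiplies the inward uptake term by
#'   \eqn{1/(1 + C_{water}/Sat_{50})}.
#' @param metabolism `"none"`, `"linear"` or `"mm"` (Michaelis--Menten).
#' @return Object of class `zfe_structure`.
#' @export
model_structure <- function(chorion_switch = TRUE, saturation = FALSE,
                            metabolism = c("none", "linear", "mm")) {
  metabolism <- match.arg(metabolism)
  structure(list(chorion_switch = isTRUE(chorion_switch),
                 saturation = isTRUE(saturation), metabolism = metabolism),
            class = "zfe_structure")
}

#' @export
print.zfe_structure <- function(x, ...) {
  cat("zfe model structure: chorion_switch =", x$chorion_switch,
      "| saturation =", x$saturation, "| metabolism =", x$metabolism, "\n")
  invisible(x)
}

read_compound_db <- function(path = NULL) {
  path <- path %||% system.file("extdata",
                                "compounds_bisphenols_synthetic.json",
                                package = "zfetk", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Tissue:water partition priors from the composition stand-in
#'
#' Two-phase tissue model standing in for an external QSAR:
#' \eqn{P_i = f_{water,i} + f_{lipid,i} K_{ow}}. Used to build the packaged
#' presets; documented so users can substitute genuine QSAR output.
#'
#' @param logKow base-10 log octanol:water partition coefficient.
#' @param composition optional data.frame/list of per-tissue `water` and
#'   `lipid` fractions; defaults to the packaged table.
#' @return Named numeric vector over the ten compartments.
#' @export
partition_prior_from_logkow <- function(logKow, composition = NULL) {
  comp <- composition %||% read_compound_db()$tissue_composition
  Kow <- 10^logKow
  out <- vapply(ZFE_COMPARTMENTS, function(nm) {
    f <- comp[[nm]]
    f$water + f$lipid * Kow
  }, numeric(1))
  out
}

#' Packaged bisphenol compound presets
#'
#' Builds a [compound_params()] object for one of BPA, BPAF, BPF, BPS from
#' the packaged preset file. Calibrated values (`f_pc`, `phi`,
#' `phi_chorion`, `sigma`, BPF's `Sat50`) are published posterior maxima;
#' the partition priors are the synthetic composition-model stand-in (see
#' [partition_prior_from_logkow()]).
#'
#' @param name `"BPA"`, `"BPAF"`, `"BPF"` or `"BPS"`.
#' @return Object of class `zfe_compound`.
#' @export
#' @examples
#' compound_preset("BPA")
compound_preset <- function(name) {
  db <- read_compound_db()
  if (!name %in% names(db$compounds))
    stop_input("no packaged parameters for compound '", name, "'; have: ",
               paste(names(db$compounds), collapse = ", "))
  p <- db$compounds[[name]]
  compound_params(
    name = name, MW = p$MW,
    P_prior = partition_prior_from_logkow(p$logKow, db$tissue_composition),
    f_pc = p$f_pc, phi = p$phi, phi_chorion = p$phi_chorion,
    Sat50_uM = if (is.null(p$Sat50_uM)) Inf else p$Sat50_uM,
    metabolism = list(kind = p$metabolism %||% "none"),
    V_liver_cell = db$V_liver_cell %||% 1.5e-6,
    sigma = p$sigma,
    medium = medium_params(F_polymer = p$F_polymer %||% 0,
                           P_pw = p$P_pw %||% 0,
                           F_air = p$F_air %||% 0,
                           P_aw = p$P_aw %||% 0))
}
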