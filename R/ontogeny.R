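#' Arrhenius temperature correction factor
#'
#' Multiplicative correction \eqn{\exp(T_A/T_R - T_A/T)} applied to
#' biological rate constants to account for the assay temperature. At the
#' reference temperature the factor is exactly 1; for \eqn{T_A > 0} it is
#' strictly increasing in \eqn{T}.
#'
#' @param temperature_K assay temperature (Kelvin).
#' @param TA Arrhenius temperature (Kelvin), \eqn{\ge 0}.
#' @param TR reference temperature (Kelvin), default 298.15 K (25 degC).
#' @return Dimensionless multiplier.
#' @export
#' @examples
#' arrhenius_factor(301.15, TA = 6930)   # 28 degC vs 25 degC reference
arrhenius_factor <- function(temperature_K, TA, TR = 298.15) {
  if (any(temperature_K <= 0) || TR <= 0)
    stop_input("temperatures must be positive (Kelvin)")
  if (TA < 0) stop_input("TA must be >= 0")
  exp(TA / TR - TA / temperature_K)
}

#' Convert Celsius to Kelvin
#' @param temperature_C temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(temperature_C) temperature_C + 273.15

#' Eleutheroembryo physiology (ontogeny parameter set)
#'
#' Bundles the growth parameters of the nine growing organs, the yolk
#' resorption parameters and the global temperature-scaling constants.
#' Organ volumes follow
#' \deqn{V_k(t) = V_{embryo}(120) (e^{K_{gk,T}(t - \tau_{k,T} - t_{fec})} - 1)}
#' for \eqn{t > \tau_{k,T} + t_{fec}} and 0 before the onset. Growth rates
#' are multiplied by the Arrhenius factor; onset times scale inversely
#' (warmer water advances organogenesis). The yolk decays exponentially,
#' \eqn{V_{yolk}(t) = V_0 e^{-k_{yolk} A_T (t - t_{fec})}}, with the same
#' Arrhenius factor \eqn{A_T} on the consumption rate.
#'
#' @param organs data.frame with columns `name`, `Kg_TR` (growth-rate
#'   constant at the reference temperature, 1/h) and `tau_TR` (growth onset,
#'   h) for the nine growing organs (all compartments except yolk).
#' @param yolk list with `V0` (initial yolk volume, uL) and `k`
#'   (consumption-rate constant at the reference temperature, 1/h).
#' @param V_embryo_120 embryo volume at 120 hpf (uL), the shared prefactor
#'   of the organ growth law.
#' @param TA Arrhenius temperature (K).
#' @param TR reference temperature (K).
#' @param t_fec fecundation time (h); ages are hours post-fertilization so
#'   the conventional value is 0.
#' @param hatch_time hatching age (hpf), default 48.
#' @return An object of class `zfe_physiology`.
#' @seealso [default_physiology()], [organ_volume()], [total_volume()]
#' @export
zfe_physiology <- function(organs, yolk, V_embryo_120, TA = 6930,
                           TR = 298.15, t_fec = 0, hatch_time = 48) {
  organs <- as.data.frame(organs)
  need <- setdiff(ZFE_COMPARTMENTS, "yolk")
  if (!all(c("name", "Kg_TR", "tau_TR") %in% names(organs)))
    stop_input("organs needs columns name, Kg_TR, tau_TR")
  if (!setequal(organs$name, need))
    stop_input("organs must contain exactly: ", paste(need, collapse = ", "))
  organs <- organs[match(need, organs$name), , drop = FALSE]
  if (any(organs$Kg_TR < 0) || any(organs$tau_TR < 0))
    stop_input("Kg_TR and tau_TR must be >= 0")
  if (!is.list(yolk) || is.null(yolk$V0) || is.null(yolk$k))
    stop_input("yolk must be list(V0 = , k = )")
  if (yolk$V0 <= 0 || yolk$k < 0) stop_input("yolk V0 > 0 and k >= 0 required")
  if (V_embryo_120 <= 0) stop_input("V_embryo_120 must be > 0")
  if (hatch_time <= 0) stop_input("hatch_time must be > 0")
  structure(list(organs = organs, yolk = yolk,
                 V_embryo_120 = V_embryo_120, TA = TA, TR = TR,
                 t_fec = t_fec, hatch_time = hatch_time),
            class = "zfe_physiology")
}

#' @export
print.zfe_physiology <- function(x, ...) {
  cat("zfe physiology: 10 compartments, V_embryo(120) =", x$V_embryo_120,
      "uL\n  yolk V0 =", x$yolk$V0, "uL, k =", x$yolk$k,
      "/h; TA =", x$TA, "K, TR =", x$TR, "K, hatch =", x$hatch_time, "hpf\n")
  invisible(x)
}

phys_arrhenius <- function(phys, temperature) {
  arrhenius_factor(celsius_to_kelvin(temperature), phys$TA, phys$TR)
}

#' Organ volume at a given age
#'
#' Closed-form organ growth: zero before the (temperature-corrected) onset
#' time, exponential growth law above it. The growth-rate constant is
#' multiplied by the Arrhenius factor and the onset time divided by it.
#'
#' @param t age (hpf); vectorized.
#' @param organ compartment name (one of [zfe_compartments()] except
#'   `"yolk"`; for the yolk use [yolk_volume()]).
#' @param phys a [zfe_physiology()] object.
#' @param temperature water temperature (degC), default 25.
#' @return Volume (uL), same length as `t`.
#' @export
#' @examples
#' organ_volume(c(24, 72, 120), "liver", default_physiology())
organ_volume <- function(t, organ, phys, temperature = 25) {
  if (any(t < 0)) stop_input("t must be >= 0")
  if (identical(organ, "yolk")) return(yolk_volume(t, phys, temperature))
  i <- match(organ, phys$organs$name)
  if (is.na(i)) stop_input("unknown organ: ", organ)
  A <- phys_arrhenius(phys, temperature)
  KT <- phys$organs$Kg_TR[i] * A
  tauT <- phys$organs$tau_TR[i] / A
  dt <- t - tauT - phys$t_fec
  ifelse(dt > 0, phys$V_embryo_120 * (exp(KT * dt) - 1), 0)
}

#' Yolk volume at a given age
#'
#' Exponential resorption with Arrhenius-scaled consumption rate; strictly
#' positive and non-increasing.
#'
#' @inheritParams organ_volume
#' @return Volume (uL).
#' @export
yolk_volume <- function(t, phys, temperature = 25) {
  if (any(t < 0)) stop_input("t must be >= 0")
  A <- phys_arrhenius(phys, temperature)
  phys$yolk$V0 * exp(-phys$yolk$k * A * (t - phys$t_fec))
}

#' All compartment volumes at given ages
#'
#' @inheritParams organ_volume
#' @return Matrix `length(t)` x 10 with compartment columns.
#' @export
organ_volumes <- function(t, phys, temperature = 25) {
  out <- sapply(ZFE_COMPARTMENTS, function(nm)
    if (nm == "yolk") yolk_volume(t, phys, temperature)
    else organ_volume(t, nm, phys, temperature))
  out <- matrix(out, nrow = length(t),
                dimnames = list(NULL, ZFE_COMPARTMENTS))
  out
}

#' Total embryo volume (organs + yolk)
#'
#' @inheritParams organ_volume
#' @return Volume (uL), strictly positive for all ages.
#' @export
total_volume <- function(t, phys, temperature = 25) {
  rowSums(organ_volumes(t, phys, temperature))
}

#' Packaged default physiology
#'
#' Loads the packaged ontogeny parameter table
#' (`inst/extdata/physiology_zfe_synthetic.json`). The table is a
#' synthetic reconstruction assembled from open zebrafish literature
#' (organ volume fractions at 120 hpf, organogenesis onset times, egg/yolk
#' volumes, the fish-standard Arrhenius temperature 6930 K); see the
#' methods vignette for provenance and limitations.
#'
#' @return A [zfe_physiology()] object.
#' @export
default_physiology <- function() {
  load_physiology(system.file("extdata", "physiology_zfe_synthetic.json",
                              package = "zfetk", mustWork = TRUE))
}

#' Load a physiology from a JSON config file
#'
#' Schema: `{"V_embryo_120": , "TA": , "TR": , "t_fec": , "hatch_time": ,
#' "yolk": {"V0": , "k": }, "organs": [{"name": , "Kg_TR": , "tau_TR": },
#' ...]}`.
#'
#' @param path JSON file path.
#' @return A [zfe_physiology()] object.
#' @export
load_physiology <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  zfe_physiology(organs = cfg$organs, yolk = as.list(cfg$yolk),
                 V_embryo_120 = cfg$V_embryo_120, TA = cfg$TA,
                 TR = cfg$TR %||% 298.15, t_fec = cfg$t_fec %||% 0,
                 hatch_time = cfg$hatch_time %||% 48)
}
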