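#' Exposure device description
#'
#' Geometry of one exposure vessel: water volume, polymer--water and
#' air--water exchange surfaces, head-space volume and number of embryos
#' sharing the medium.
#'
#' @param V_water water volume (uL), > 0.
#' @param S_pw polymer--water exchange surface (mm^2), >= 0.
#' @param S_aw air--water exchange surface (mm^2), >= 0.
#' @param n_embryos embryos sharing the medium, >= 1.
#' @param V_air head-space volume (uL) used to convert the air quantity to
#'   a concentration; defaults to `V_water`.
#' @return Object of class `zfe_device`.
#' @export
device_spec <- function(V_water, S_pw = 0, S_aw = 0, n_embryos = 1,
                        V_air = V_water) {
  if (V_water <= 0) stop_input("V_water must be > 0")
  if (S_pw < 0 || S_aw < 0) stop_input("surfaces must be >= 0")
  if (n_embryos < 1) stop_input("n_embryos must be >= 1")
  structure(list(V_water = V_water, S_pw = S_pw, S_aw = S_aw,
                 n_embryos = n_embryos, V_air = V_air),
            class = "zfe_device")
}

#' Medium loss-process parameters
#'
#' Rates and partition coefficients for nonspecific binding to the device
#' polymer and volatilization to air. The bisphenol default is
#' volatilization off (`F_air = 0`, `P_aw = 0`): these compounds have very
#' low Henry's constants, so the air concentration is taken as null.
#'
#' @param F_polymer water--polymer exchange rate (uL/h/mm^2), >= 0.
#' @param P_pw polymer:water partition coefficient (1/mm), >= 0; 0 disables
#'   wall binding.
#' @param F_air water--air exchange rate (uL/h/mm^2), >= 0.
#' @param P_aw air:water partition coefficient (dimensionless); 0 combined
#'   with a positive `F_air` selects the one-way (air as sink) convention.
#' @return Object of class `zfe_medium_params`.
#' @export
medium_params <- function(F_polymer = 0, P_pw = 0, F_air = 0, P_aw = 0) {
  v <- c(F_polymer, P_pw, F_air, P_aw)
  if (any(v < 0)) stop_input("medium parameters must be >= 0")
  structure(list(F_polymer = F_polymer, P_pw = P_pw,
                 F_air = F_air, P_aw = P_aw),
            class = "zfe_medium_params")
}

#' Chemical state of the exposure medium
#'
#' @param Q_water quantity dissolved in water (nmol).
#' @param Q_polymer quantity bound to the device polymer (nmol).
#' @param Q_air quantity in the head space (nmol).
#' @return Object of class `zfe_medium_state`.
#' @export
medium_state <- function(Q_water, Q_polymer = 0, Q_air = 0) {
  if (any(c(Q_water, Q_polymer, Q_air) < 0))
    stop_input("quantities must be >= 0")
  structure(list(Q_water = Q_water, Q_polymer = Q_polymer, Q_air = Q_air),
            class = "zfe_medium_state")
}

#' Flux of chemical from water into the device polymer
#'
#' \eqn{F_{polymer} (S_{pw} C_{water} - Q_{polymer}/P_{pw})}; zero at the
#' sorption equilibrium \eqn{Q_{polymer} = P_{pw} S_{pw} C_{water}},
#' negative (desorption) when the wall pool exceeds it.
#'
#' @param state a [medium_state()].
#' @param params a [medium_params()].
#' @param device a [device_spec()].
#' @return Signed flux (nmol/h) into the polymer.
#' @export
polymer_flux <- function(state, params, device) {
  if (params$P_pw <= 0) {
    if (state$Q_polymer > 0)
      stop_input("P_pw = 0 with a non-empty polymer pool: wall binding is ",
                 "disabled but chemical is bound; fix the configuration")
    return(0)
  }
  C_water <- state$Q_water / device$V_water
  params$F_polymer * (device$S_pw * C_water - state$Q_polymer / params$P_pw)
}

#' Flux of chemical from water into the air
#'
#' \eqn{F_{air} S_{aw} (C_{water} - C_{air}/P_{aw})}, with
#' \eqn{C_{air} = Q_{air}/V_{air}}. Identically zero when
#' \eqn{F_{air} S_{aw} = 0} (the bisphenol default). With `P_aw = 0` and a
#' positive exchange rate the one-way convention (no back-diffusion)
#' applies and a message is emitted.
#'
#' @inheritParams polymer_flux
#' @return Signed flux (nmol/h) into air.
#' @export
air_flux <- function(state, params, device) {
  a <- params$F_air * device$S_aw
  if (a <= 0) return(0)
  C_water <- state$Q_water / device$V_water
  if (params$P_aw <= 0) {
    message("P_aw = 0 with positive air exchange: one-way volatilization ",
            "convention applied")
    return(a * C_water)
  }
  a * (C_water - (state$Q_air / device$V_air) / params$P_aw)
}

#' Exposure experiment description
#'
#' Everything that defines one exposure: the device, the dosing schedule,
#' medium renewals, temperature, age at first dosing, chorion status and
#' duration. Dose events either set the water concentration to a set-point
#' (`conc_nM`) or add a quantity (`amount_nmol`). A renewal replaces the
#' water with fresh medium at the current set-point, empties the head
#' space, and by default retains the polymer-bound pool (same well); set
#' `renewal_resets_polymer = TRUE` if the device is replaced too.
#'
#' @param device a [device_spec()].
#' @param dose_events data.frame with column `time_hpf` and one of
#'   `conc_nM` (water set-point, nM) or `amount_nmol`.
#' @param duration exposure duration (h) from `start_age`.
#' @param start_age age at first dosing (hpf); default = first dose time.
#' @param renewal_times ages (hpf) at which the medium is renewed.
#' @param renewal_resets_polymer logical, see above.
#' @param temperature assay water temperature (degC).
#' @param chorionated logical; `FALSE` models dechorionated embryos (the
#'   post-hatch uptake law applies at all ages).
#' @return Object of class `zfe_design`.
#' @export
#' @examples
#' d <- exposure_design(device_spec(2000), data.frame(time_hpf = 1,
#'                      conc_nM = 1000), duration = 144)
exposure_design <- function(device, dose_events, duration,
                            start_age = NULL, renewal_times = numeric(0),
                            renewal_resets_polymer = FALSE,
                            temperature = 26, chorionated = TRUE) {
  stopifnot(inherits(device, "zfe_device"))
  dose_events <- as.data.frame(dose_events)
  if (!"time_hpf" %in% names(dose_events) || nrow(dose_events) < 1)
    stop_input("dose_events needs >= 1 row and a time_hpf column")
  if (!any(c("conc_nM", "amount_nmol") %in% names(dose_events)))
    stop_input("dose_events needs a conc_nM or amount_nmol column")
  if (is.unsorted(dose_events$time_hpf))
    stop_input("dose event times must be non-decreasing")
  vals <- c(dose_events$conc_nM, dose_events$amount_nmol)
  if (any(vals[!is.na(vals)] < 0)) stop_input("doses must be >= 0")
  start_age <- start_age %||% dose_events$time_hpf[1]
  if (duration <= 0) stop_input("duration must be > 0")
  if (length(renewal_times) && min(renewal_times) < min(dose_events$time_hpf))
    stop_input("renewal before the first dose event")
  structure(list(device = device, dose_events = dose_events,
                 renewal_times = sort(renewal_times),
                 renewal_resets_polymer = renewal_resets_polymer,
                 temperature = temperature, start_age = start_age,
                 chorionated = chorionated, duration = duration),
            class = "zfe_design")
}

#' @export
print.zfe_design <- function(x, ...) {
  cat("zfe exposure design: start", x$start_age, "hpf,", x$duration,
      "h,", x$temperature, "degC,",
      if (x$chorionated) "chorionated" else "dechorionated", "\n  water",
      x$device$V_water, "uL,", x$device$n_embryos, "embryo(s),",
      nrow(x$dose_events), "dose event(s),",
      length(x$renewal_times), "renewal(s)\n")
  invisible(x)
}

# water set-point (nmol/uL) active at age t (last conc-type dose <= t)
design_setpoint <- function(design, t) {
  de <- design$dose_events
  if (is.null(de$conc_nM)) stop_input("design has no concentration set-point")
  i <- which(de$time_hpf <= t + 1e-9 & !is.na(de$conc_nM))
  if (!length(i)) stop_input("renewal at ", t, " hpf with no prior dose event")
  de$conc_nM[max(i)] * 1e-6
}

#' Apply a medium renewal to a medium state
#'
#' @param state a [medium_state()].
#' @param design a [exposure_design()] with concentration set-points.
#' @param t renewal age (hpf).
#' @return A new [medium_state()].
#' @export
apply_renewal <- function(state, design, t) {
  sp <- design_setpoint(design, t)
  medium_state(Q_water = sp * design$device$V_water,
               Q_polymer = if (design$renewal_resets_polymer) 0
                           else state$Q_polymer,
               Q_air = 0)
}
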