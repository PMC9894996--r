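#' FET-style exposure design
#'
#' Builds an [exposure_design()] from the packaged fish-embryo-toxicity
#' (TG 236-like) constants: one embryo in a 2 mL well, daily medium
#' renewal, 26 degC. The constants file is a synthetic reconstruction
#' (see `inst/extdata/fet_design_synthetic.json`).
#'
#' @param dose_nM nominal water concentration (nM), >= 0.
#' @param start_age age at dosing (hpf), default 1.
#' @param duration exposure duration (h), default 144.
#' @param chorionated logical; `FALSE` for dechorionated embryos.
#' @param temperature water temperature (degC), default from the file.
#' @param renewal logical; daily medium renewal on/off.
#' @return An [exposure_design()].
#' @export
#' @examples
#' fet_design(1000)   # 1 uM from 1 hpf, 144 h
fet_design <- function(dose_nM, start_age = 1, duration = 144,
                       chorionated = TRUE, temperature = NULL,
                       renewal = TRUE) {
  if (dose_nM < 0) stop_input("dose_nM must be >= 0")
  cfg <- jsonlite::read_json(system.file("extdata",
                                         "fet_design_synthetic.json",
                                         package = "zfetk",
                                         mustWork = TRUE),
                             simplifyVector = TRUE)
  dev <- device_spec(V_water = cfg$V_water, S_pw = cfg$S_pw,
                     S_aw = cfg$S_aw, n_embryos = cfg$n_embryos,
                     V_air = cfg$V_air)
  ren <- if (renewal) {
    r <- seq(start_age + cfg$renewal_every, start_age + duration,
             by = cfg$renewal_every)
    r[r < start_age + duration - 1e-9]
  } else numeric(0)
  exposure_design(dev,
                  data.frame(time_hpf = start_age, conc_nM = dose_nM),
                  duration = duration, start_age = start_age,
                  renewal_times = ren,
                  temperature = temperature %||% cfg$temperature,
                  chorionated = chorionated)
}

#' Literature-like study template
#'
#' Ranges from which heterogeneous synthetic studies are drawn, matching
#' the spread of published eleutheroembryo TK experiments: sparse sampling
#' (1--6 time points), doses spanning 0.438 nM--50 uM, first dosing at
#' 1--96 hpf, 25--28.5 degC, with or without daily medium renewal.
#'
#' @param n_studies number of studies per dataset.
#' @param timepoints range (min, max) of observation counts per study.
#' @param dose_range_nM dose range (nM), log-uniform sampling.
#' @param age_range start-age range (hpf).
#' @param temp_range temperature range (degC).
#' @param renewal_prob probability a study renews its medium daily.
#' @param dechorionated_prob probability a pre-hatch study is
#'   dechorionated.
#' @param n_embryos_range pooled embryos per analytical sample.
#' @param duration_range exposure duration range (h).
#' @return Object of class `zfe_template`.
#' @export
study_template <- function(n_studies = 5, timepoints = c(1, 6),
                           dose_range_nM = c(0.438, 5e4),
                           age_range = c(1, 96),
                           temp_range = c(25, 28.5), renewal_prob = 0.5,
                           dechorionated_prob = 0.2,
                           n_embryos_range = c(1, 20),
                           duration_range = c(24, 120)) {
  stopifnot(n_studies >= 1, timepoints[1] >= 1, timepoints[2] <= 6,
            dose_range_nM[1] > 0)
  res <- as.list(environment())
  class(res) <- "zfe_template"
  res
}

#' Generate a literature-like synthetic TK dataset
#'
#' Draws heterogeneous study designs from a [study_template()], simulates
#' them under known ground-truth parameters and perturbs the predictions
#' with i.i.d. multiplicative lognormal noise of geometric SD
#' `truth$sigma` (observed = simulated x exp(eps),
#' eps ~ Normal(0, ln sigma)). Time points whose simulated concentration
#' is zero are resampled (with a message). Bit-exact reproducible given
#' `seed`; the ground truth travels with the result for recovery tests.
#'
#' @param truth a [compound_params()] holding the generating values.
#' @param structure a [model_structure()].
#' @param template a [study_template()].
#' @param phys a [zfe_physiology()].
#' @param seed integer seed.
#' @return list with `dataset` (a [tk_dataset()]) and `truth`.
#' @export
generate_dataset <- function(truth, structure = model_structure(),
                             template = study_template(),
                             phys = default_physiology(), seed = 1) {
  stopifnot(inherits(truth, "zfe_compound"),
            inherits(template, "zfe_template"))
  set.seed(seed)
  designs <- list()
  recs <- list()
  for (s in seq_len(template$n_studies)) {
    id <- sprintf("study%02d", s)
    dose <- exp(runif(1, log(template$dose_range_nM[1]),
                      log(template$dose_range_nM[2])))
    start <- runif(1, template$age_range[1], template$age_range[2])
    dur <- runif(1, template$duration_range[1],
                 template$duration_range[2])
    dur <- min(dur, 150 - start)          # keep within the zfe window
    temp <- runif(1, template$temp_range[1], template$temp_range[2])
    renew <- runif(1) < template$renewal_prob
    chor <- if (start < phys$hatch_time)
      runif(1) >= template$dechorionated_prob else TRUE
    npt <- sample(seq(template$timepoints[1], template$timepoints[2]), 1)
    nemb <- sample(seq(template$n_embryos_range[1],
                       template$n_embryos_range[2]), 1)
    d <- fet_design(dose, start_age = start, duration = dur,
                    chorionated = chor, temperature = temp,
                    renewal = renew)
    designs[[id]] <- d
    tt <- sort(round(runif(npt, start + 1, start + dur), 1))
    sim <- simulate_zfe(d, truth, structure, phys,
                        times = sort(unique(c(start, tt))),
                        rtol = 1e-6, atol = 1e-10)
    pred <- sim$C_body_ng_mg[match(tt, sim$times)]
    for (tries in 1:20) {
      zero <- pred <= 0
      if (!any(zero)) break
      message("resampling ", sum(zero), " zero-concentration timepoint(s)",
              " in ", id)
      tt[zero] <- sort(round(runif(sum(zero), start + 1, start + dur), 1))
      sim <- simulate_zfe(d, truth, structure, phys,
                          times = sort(unique(c(start, tt))),
                          rtol = 1e-6, atol = 1e-10)
      pred <- sim$C_body_ng_mg[match(tt, sim$times)]
    }
    obs <- pred * exp(rnorm(length(pred), 0, log(truth$sigma)))
    cw <- sim$C_water[match(tt, sim$times)] * 1e6   # nmol/uL -> nM
    recs[[id]] <- data.frame(design_id = id, compound = truth$name,
                             time_hpf = tt, conc_body = obs,
                             conc_body_sd = NA, conc_water = cw,
                             n_embryos = nemb)
  }
  list(dataset = tk_dataset(do.call(rbind, recs), designs),
       truth = truth)
}
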