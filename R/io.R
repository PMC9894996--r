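#' Harmonize a raw concentration observation
#'
#' Converts the unit zoo of literature TK reports to the canonical dual
#' representation: mass basis (ng per mg wet weight) and molar basis
#' (nmol/uL, equal numerically to mmol/L), assuming tissue density
#' 1 g/mL. Per-embryo quantities use the standard average
#' eleutheroembryo mass of 0.33 mg when no mass is given.
#'
#' Accepted units: `"ng/embryo"`, `"nmol/embryo"`, `"ng/mg"`,
#' `"umol/L"` (molar whole-body), `"nmol/uL"`.
#'
#' @param value numeric observation.
#' @param unit one of the accepted unit strings.
#' @param MW molecular weight (g/mol).
#' @param embryo_mass_mg embryo wet mass (mg), default 0.33.
#' @return list with `ng_per_mg` and `nmol_per_uL`.
#' @export
#' @examples
#' harmonize_units(0.33, "ng/embryo", MW = 228.29)   # 1 ng/mg
harmonize_units <- function(value, unit, MW, embryo_mass_mg = 0.33) {
  accepted <- c("ng/embryo", "nmol/embryo", "ng/mg", "umol/L", "nmol/uL")
  if (length(unit) != 1 || !unit %in% accepted)
    stop_input("unit must be one of: ", paste(accepted, collapse = ", "))
  ng_mg <- switch(unit,
                  "ng/embryo" = value / embryo_mass_mg,
                  "nmol/embryo" = value * MW / embryo_mass_mg,
                  "ng/mg" = value,
                  "umol/L" = value * 1e-3 * MW,   # umol/L -> nmol/uL -> ng/mg
                  "nmol/uL" = value * MW)
  list(ng_per_mg = ng_mg, nmol_per_uL = ng_mg / MW)
}

#' Read a JSON configuration file
#' @param path file path.
#' @return Parsed list (vectors simplified).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# designs config: data.frame/list of rows with id, dose_nM, start_age,
# duration, chorionated, temperature, renewal
designs_from_config <- function(cfg) {
  cfg <- as.data.frame(cfg)
  out <- list()
  for (i in seq_len(nrow(cfg)))
    out[[cfg$id[i]]] <- fet_design(cfg$dose_nM[i],
                                   start_age = cfg$start_age[i],
                                   duration = cfg$duration[i],
                                   chorionated = cfg$chorionated[i] %||%
                                     TRUE,
                                   temperature = cfg$temperature[i],
                                   renewal = cfg$renewal[i] %||% TRUE)
  out
}

#' Covariate scenario runner
#'
#' Reproduces the standard covariate explorations on the packaged
#' maximum-posterior parameter sets:
#' \describe{
#'   \item{`age_sweep`}{Cmax/tmax of whole-body concentration as a
#'     function of the age at dosing (default 1--120 hpf, 1 uM, 144 h,
#'     FET design).}
#'   \item{`chorion_compare`}{paired chorionated / dechorionated
#'     trajectories and their percent difference over time.}
#'   \item{`analog_compare`}{BPA/BPAF/BPF/BPS whole-body trajectories
#'     with Cmax and AUC exposure ratios (both reported, since "exposure"
#'     is ambiguous between them).}
#' }
#'
#' @param scenario one of `"age_sweep"`, `"chorion_compare"`,
#'   `"analog_compare"`.
#' @param dose_nM water concentration (nM), default 1000 (1 uM).
#' @param ages dosing ages for the sweep (hpf).
#' @param duration exposure duration (h), default 144.
#' @param compounds preset names for `analog_compare`.
#' @param compound preset name for the single-compound scenarios.
#' @param phys a [zfe_physiology()].
#' @param dt output grid step (h).
#' @param out_dir optional directory; results are written as CSV there.
#' @return A data.frame (scenario-dependent columns), invisibly written
#'   to `out_dir` when given.
#' @export
run_covariates <- function(scenario = c("age_sweep", "chorion_compare",
                                        "analog_compare"),
                           dose_nM = 1000, ages = 1:120, duration = 144,
                           compounds = c("BPA", "BPAF", "BPF", "BPS"),
                           compound = "BPA",
                           phys = default_physiology(), dt = 0.1,
                           out_dir = NULL) {
  scenario <- match.arg(scenario)
  res <- switch(scenario,
    age_sweep = {
      cmp <- compound_preset(compound)
      rows <- lapply(ages, function(a) {
        sim <- simulate_zfe(fet_design(dose_nM, start_age = a,
                                       duration = duration),
                            cmp, phys = phys, dt = dt)
        m <- tk_metrics(sim)
        data.frame(start_age_hpf = a, Cmax_ng_mg = m$Cmax_ng_mg,
                   tmax_h_postdose = m$tmax_h,
                   AUC_ng_mg_h = m$AUC_ng_mg_h)
      })
      do.call(rbind, rows)
    },
    chorion_compare = {
      cmp <- compound_preset(compound)
      s1 <- simulate_zfe(fet_design(dose_nM, chorionated = TRUE,
                                    duration = duration),
                         cmp, phys = phys, dt = dt)
      s2 <- simulate_zfe(fet_design(dose_nM, chorionated = FALSE,
                                    duration = duration),
                         cmp, phys = phys, dt = dt)
      avg <- (s1$C_body_ng_mg + s2$C_body_ng_mg) / 2
      data.frame(time_hpf = s1$times,
                 conc_chorionated = s1$C_body_ng_mg,
                 conc_dechorionated = s2$C_body_ng_mg,
                 pct_difference = ifelse(avg > 0,
                   100 * abs(s2$C_body_ng_mg - s1$C_body_ng_mg) / avg, 0))
    },
    analog_compare = {
      sims <- lapply(compounds, function(nm)
        simulate_zfe(fet_design(dose_nM, duration = duration),
                     compound_preset(nm), phys = phys, dt = dt))
      names(sims) <- compounds
      met <- lapply(sims, tk_metrics)
      data.frame(compound = compounds,
                 Cmax_ng_mg = vapply(met, `[[`, 0, "Cmax_ng_mg"),
                 tmax_h_postdose = vapply(met, `[[`, 0, "tmax_h"),
                 AUC_ng_mg_h = vapply(met, `[[`, 0, "AUC_ng_mg_h"),
                 Cmax_rel = vapply(met, `[[`, 0, "Cmax_ng_mg") /
                   met[[1]]$Cmax_ng_mg,
                 AUC_rel = vapply(met, `[[`, 0, "AUC_ng_mg_h") /
                   met[[1]]$AUC_ng_mg_h,
                 row.names = NULL)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res, file.path(out_dir, paste0(scenario, ".csv")),
              row.names = FALSE)
  }
  res
}

cli_opts <- function(args) {
  # "--key value" and "--flag" parsing
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_input("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      out[[key]] <- args[i + 1]; i <- i + 2
    } else { out[[key]] <- TRUE; i <- i + 1 }
  }
  out
}

num <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line interface
#'
#' Subcommands: `simulate`, `calibrate`, `compare-structures`, `sobol`,
#' `covariates`, `generate-data`. All tabular output is CSV, all
#' configuration JSON. Run `zfetk_cli("help")` for usage; a ready
#' `Rscript` wrapper is installed at
#' `system.file("cli", "zfetk", package = "zfetk")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return Invisibly, the primary result object of the subcommand.
#' @export
zfetk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "zfetk <subcommand> [--options]",
    "  simulate      --dose <nM> [--start 1] [--duration 144]",
    "                [--compound BPA] [--dechorionated] [--dt 0.1]",
    "                [--out dir]",
    "  calibrate     --data obs.csv --designs designs.json",
    "                [--compound BPA] [--priors priors.json]",
    "                [--iter 2000] [--chains 3] [--seed 1] [--out dir]",
    "  compare-structures  (same options as calibrate)",
    "  sobol         [--compound BPA] [--params f_pc,phi,phi_chorion]",
    "                [--N 256] [--seed 1] [--out dir]",
    "  covariates    --scenario age_sweep|chorion_compare|analog_compare",
    "                [--dose 1000] [--out dir]",
    "  generate-data [--compound BPA] [--n-studies 5] [--seed 1]",
    "                [--out dir]", sep = "\n")
  if (!length(args) || args[1] %in% c("help", "--help", "-h")) {
    cat(usage, "\n"); return(invisible(NULL))
  }
  cmd <- args[1]
  o <- cli_opts(args[-1])
  outdir <- o$out %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    cat("wrote", p, "\n")
  }
  res <- switch(cmd,
    simulate = {
      cmp <- compound_preset(o$compound %||% "BPA")
      sim <- simulate_zfe(fet_design(num(o$dose, 1000),
                                     start_age = num(o$start, 1),
                                     duration = num(o$duration, 144),
                                     chorionated = is.null(o$dechorionated)),
                          cmp, dt = num(o$dt, 0.1))
      emit(as.data.frame(sim), "simulation.csv")
      m <- tk_metrics(sim)
      jsonlite::write_json(unclass(m)[c("Cmax_ng_mg", "Cmax_nmol_uL",
                                        "tmax_h", "AUC_ng_mg_h")],
                           file.path(outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      sim
    },
    calibrate = {
      designs <- designs_from_config(read_config(o$designs))
      ds <- read_tk_csv(o$data, designs)
      pr <- if (is.null(o$priors)) default_priors()
            else prior_spec(read_config(o$priors)$parameters)
      pr <- prune_priors(pr, model_structure())
      ch <- mcmc_sample(ds, pr, compound_preset(o$compound %||% "BPA"),
                        n_chains = num(o$chains, 3),
                        n_iter = num(o$iter, 2000),
                        seed = num(o$seed, 1))
      ps <- posterior_summary(ch)
      emit(as.data.frame(ps), "posterior_summary.csv")
      for (chn in seq_len(ch$n_chains))
        emit(as.data.frame(ch$samples[, , chn]),
             sprintf("chain%02d.csv", chn))
      ps
    },
    `compare-structures` = {
      designs <- designs_from_config(read_config(o$designs))
      ds <- read_tk_csv(o$data, designs)
      pr <- if (is.null(o$priors)) default_priors()
            else prior_spec(read_config(o$priors)$parameters)
      structures <- list(
        single_flow = model_structure(chorion_switch = FALSE),
        two_flow = model_structure(chorion_switch = TRUE),
        two_flow_sat = model_structure(saturation = TRUE),
        two_flow_met = model_structure(metabolism = "linear"))
      cs <- compare_structures(ds, structures, pr,
                               compound_preset(o$compound %||% "BPA"),
                               n_iter = num(o$iter, 1000),
                               n_chains = num(o$chains, 2),
                               seed = num(o$seed, 1))
      emit(as.data.frame(cs), "structure_comparison.csv")
      cs
    },
    sobol = {
      pars <- strsplit(o$params %||% "f_pc,phi,phi_chorion", ",")[[1]]
      sr <- sobol_pbpk(compound_preset(o$compound %||% "BPA"),
                       parameters = pars, N = num(o$N, 256),
                       seed = num(o$seed, 1))
      emit(as.data.frame(sr), "sobol_indices.csv")
      sr
    },
    covariates = {
      run_covariates(o$scenario %||% "age_sweep",
                     dose_nM = num(o$dose, 1000), out_dir = outdir)
    },
    `generate-data` = {
      tmpl <- study_template(n_studies = num(o[["n-studies"]], 5))
      g <- generate_dataset(compound_preset(o$compound %||% "BPA"),
                            template = tmpl, seed = num(o$seed, 1))
      write_tk_csv(g$dataset, file.path(outdir, "synthetic_tk.csv"))
      truth <- g$truth
      jsonlite::write_json(list(compound = truth$name, f_pc = truth$f_pc,
                                phi = truth$phi,
                                phi_chorion = truth$phi_chorion,
                                sigma = truth$sigma),
                           file.path(outdir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      cat("wrote", file.path(outdir, "synthetic_tk.csv"), "\n")
      g
    },
    { cat(usage, "\n"); stop_input("unknown subcommand: ", cmd) })
  invisible(res)
}
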