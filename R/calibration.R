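#' Uniform prior specification
#'
#' Per-parameter uniform bounds for the calibratable compound-specific
#' parameters. A row with `lower == upper` is a point prior: the
#' parameter is fixed at that value and excluded from sampling (this is
#' how the analog workflow fixes `phi`/`phi_chorion` to the BPA values).
#'
#' @param x data.frame with columns `parameter`, `lower`, `upper`;
#'   parameters among `f_pc`, `phi`, `phi_chorion`, `sigma`, `Sat50_uM`,
#'   `K_met`, `V_max`, `K_M`.
#' @return Object of class `zfe_priors`.
#' @export
prior_spec <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("parameter", "lower", "upper") %in% names(x)))
    stop_input("prior_spec needs columns parameter, lower, upper")
  ok <- c("f_pc", "phi", "phi_chorion", "sigma", "Sat50_uM", "K_met",
          "V_max", "K_M")
  bad <- setdiff(x$parameter, ok)
  if (length(bad)) stop_input("unknown parameter(s): ",
                              paste(bad, collapse = ", "))
  if (any(x$lower > x$upper)) stop_input("inverted prior bounds")
  s <- x[x$parameter == "sigma", ]
  if (nrow(s) && any(s$lower <= 1))
    stop_input("sigma prior must stay > 1 (geometric SD)")
  if (any(x$lower < 0)) stop_input("negative prior bounds not allowed")
  class(x) <- c("zfe_priors", "data.frame")
  x
}

#' Packaged default priors
#' @return A [prior_spec()] loaded from `inst/extdata/priors_default.json`.
#' @export
default_priors <- function() {
  cfg <- jsonlite::read_json(system.file("extdata", "priors_default.json",
                                         package = "zfetk", mustWork = TRUE),
                             simplifyVector = TRUE)
  prior_spec(cfg$parameters)
}

# set calibratable fields on a compound from a named vector
update_compound <- function(compound, theta) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    switch(nm,
           f_pc = { compound$f_pc <- v },
           phi = { compound$phi <- v },
           phi_chorion = { compound$phi_chorion <- v },
           sigma = { compound$sigma <- v },
           Sat50_uM = { compound$Sat50_uM <- v },
           K_met = { compound$metabolism$K_met <- v },
           V_max = { compound$metabolism$V_max <- v },
           K_M = { compound$metabolism$K_M <- v },
           stop_input("unknown parameter: ", nm))
  }
  compound
}

#' Log-likelihood of a TK dataset under the lognormal error model
#'
#' Observations are modelled as lognormal about the model prediction with
#' scale \eqn{\ln\sigma} (the geometric SD): each term is the lognormal
#' log-density with location \eqn{\ln(\hat{c})} evaluated at the observed
#' whole-body concentration (ng/mg wet). Predictions below `floor` are
#' floored and counted in the `n_floored` attribute. Water observations
#' (nM) optionally contribute a second lognormal term.
#'
#' @param dataset a [tk_dataset()].
#' @param compound a [compound_params()] carrying the candidate values.
#' @param structure a [model_structure()].
#' @param phys a [zfe_physiology()].
#' @param include_water logical; default `FALSE` (water data are
#'   diagnostics only).
#' @param floor prediction floor (ng/mg), default 1e-12.
#' @param rtol,atol solver tolerances (looser-than-simulation defaults,
#'   adequate for likelihood evaluation).
#' @return Scalar log-likelihood with attribute `n_floored`.
#' @export
log_likelihood <- function(dataset, compound, structure = model_structure(),
                           phys = default_physiology(),
                           include_water = FALSE, floor = 1e-12,
                           rtol = 1e-6, atol = 1e-10) {
  stopifnot(inherits(dataset, "zfe_tkdata"))
  if (any(dataset$records$conc_body <= 0))
    stop_input("non-positive observation")
  lsig <- log(compound$sigma)
  ll <- 0
  nfl <- 0L
  for (id in unique(dataset$records$design_id)) {
    rec <- dataset$records[dataset$records$design_id == id, , drop = FALSE]
    d <- dataset$designs[[id]]
    tt <- sort(unique(c(d$start_age, rec$time_hpf)))
    sim <- simulate_zfe(d, compound, structure, phys, times = tt,
                        rtol = rtol, atol = atol)
    pred <- sim$C_body_ng_mg[match(rec$time_hpf, sim$times)]
    low <- pred < floor
    nfl <- nfl + sum(low)
    pred[low] <- floor
    ll <- ll + sum(stats::dlnorm(rec$conc_body, meanlog = log(pred),
                                 sdlog = lsig, log = TRUE))
    if (include_water && any(!is.na(rec$conc_water))) {
      sel <- !is.na(rec$conc_water) & rec$conc_water > 0
      pw <- pmax(sim$C_water[match(rec$time_hpf[sel], sim$times)] * 1e6,
                 floor)
      ll <- ll + sum(stats::dlnorm(rec$conc_water[sel],
                                   meanlog = log(pw), sdlog = lsig,
                                   log = TRUE))
    }
  }
  attr(ll, "n_floored") <- nfl
  ll
}

#' Metropolis MCMC calibration
#'
#' Component-wise random-walk Metropolis sampling of the parameters whose
#' prior bounds differ (point priors are fixed). Proposal scales adapt
#' toward ~30% acceptance during burn-in (first half by default) and are
#' frozen afterwards. Uniform priors make the acceptance ratio a pure
#' likelihood ratio inside the support. Fully reproducible given `seed`;
#' chains start from dispersed draws of the prior.
#'
#' @inheritParams log_likelihood
#' @param priors a [prior_spec()].
#' @param n_chains number of chains (default 3).
#' @param n_iter iterations per chain (default 2000).
#' @param burn burn-in iterations discarded by summaries (default half).
#' @param seed integer seed.
#' @param max_start_tries rejection attempts for a finite-likelihood
#'   start.
#' @return Object of class `zfe_chains`: `samples`
#'   (iter x parameter x chain array), `loglik` (iter x chain), fixed
#'   parameter values, priors, acceptance rates and split-R-hat.
#' @export
mcmc_sample <- function(dataset, priors, compound,
                        structure = model_structure(),
                        phys = default_physiology(), n_chains = 3,
                        n_iter = 2000, burn = floor(n_iter / 2), seed = 1,
                        include_water = FALSE, rtol = 1e-6, atol = 1e-10,
                        max_start_tries = 50) {
  stopifnot(inherits(priors, "zfe_priors"))
  set.seed(seed)
  free <- priors[priors$lower < priors$upper, , drop = FALSE]
  fixed <- priors[priors$lower == priors$upper, , drop = FALSE]
  if (!nrow(free)) stop_input("no free parameters to sample")
  if (nrow(fixed))
    compound <- update_compound(compound,
                                setNames(fixed$lower, fixed$parameter))
  pn <- free$parameter
  np <- length(pn)
  lo <- setNames(free$lower, pn)
  hi <- setNames(free$upper, pn)
  llfun <- function(theta) {
    cm <- update_compound(compound, theta)
    log_likelihood(dataset, cm, structure, phys,
                   include_water = include_water, rtol = rtol, atol = atol)
  }
  samples <- array(NA_real_, c(n_iter, np, n_chains),
                   dimnames = list(NULL, pn, NULL))
  llmat <- matrix(NA_real_, n_iter, n_chains)
  acc <- matrix(0, np, n_chains, dimnames = list(pn, NULL))
  for (ch in seq_len(n_chains)) {
    ll <- -Inf
    for (try in seq_len(max_start_tries)) {
      theta <- setNames(runif(np, lo, hi), pn)
      ll <- as.numeric(llfun(theta))
      if (is.finite(ll)) break
    }
    if (!is.finite(ll))
      stop_input("no finite-likelihood start found in ", max_start_tries,
                 " draws from the prior")
    step <- (hi - lo) / 10
    nacc <- setNames(numeric(np), pn)
    nbatch <- 0
    for (it in seq_len(n_iter)) {
      for (j in seq_len(np)) {
        prop <- theta
        prop[j] <- theta[j] + rnorm(1, 0, step[j])
        if (prop[j] >= lo[j] && prop[j] <= hi[j]) {
          llp <- as.numeric(llfun(prop))
          if (is.finite(llp) && log(runif(1)) < llp - ll) {
            theta <- prop; ll <- llp
            nacc[j] <- nacc[j] + 1
            acc[j, ch] <- acc[j, ch] + 1
          }
        }
      }
      nbatch <- nbatch + 1
      if (it <= burn && nbatch == 25) {   # adapt during burn-in only
        rate <- nacc / nbatch
        step <- step * exp(pmin(1, pmax(-1, rate - 0.3)))
        nacc[] <- 0; nbatch <- 0
      } else if (nbatch == 25) nbatch <- 0
      samples[it, , ch] <- theta
      llmat[it, ch] <- ll
    }
  }
  res <- list(samples = samples, loglik = llmat,
              fixed = if (nrow(fixed)) setNames(fixed$lower,
                                                fixed$parameter)
                      else numeric(0),
              priors = priors, burn = burn, n_iter = n_iter,
              n_chains = n_chains, seed = seed,
              accept_rate = acc / n_iter,
              rhat = split_rhat(samples, burn))
  class(res) <- "zfe_chains"
  res
}

# split-chain potential scale reduction factor
split_rhat <- function(samples, burn) {
  post <- samples[(burn + 1):dim(samples)[1], , , drop = FALSE]
  n <- dim(post)[1]
  half <- floor(n / 2)
  vapply(seq_len(dim(post)[2]), function(j) {
    chains <- list()
    for (ch in seq_len(dim(post)[3])) {
      chains[[length(chains) + 1]] <- post[1:half, j, ch]
      chains[[length(chains) + 1]] <- post[(n - half + 1):n, j, ch]
    }
    m <- length(chains)
    means <- vapply(chains, mean, numeric(1))
    vars <- vapply(chains, var, numeric(1))
    W <- mean(vars)
    B <- half * var(means)
    if (W <= 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1)) |> setNames(dimnames(samples)[[2]])
}

#' @export
print.zfe_chains <- function(x, ...) {
  cat("zfe MCMC:", x$n_chains, "chains x", x$n_iter, "iterations (burn",
      x$burn, ")\n  parameters:",
      paste(dimnames(x$samples)[[2]], collapse = ", "), "\n  R-hat:",
      paste(sprintf("%s %.3f", names(x$rhat), x$rhat), collapse = ", "),
      "\n")
  invisible(x)
}

#' Posterior summary (MPV, median, CI95, convergence)
#'
#' MPV is the sampled parameter vector maximizing the posterior density
#' (equal to the likelihood maximizer under uniform priors); median and
#' equal-tailed 95% credibility interval come from the pooled post-burn-in
#' samples. A warning is raised when split-R-hat exceeds 1.1.
#'
#' @param chains a `zfe_chains` object from [mcmc_sample()].
#' @param rhat_warn convergence threshold, default 1.1.
#' @return data.frame (class `zfe_posterior`) with one row per free
#'   parameter: `MPV`, `median`, `ci_lo`, `ci_hi`, `rhat`; attributes
#'   `loglik_max`, `converged`, `fixed`.
#' @export
posterior_summary <- function(chains, rhat_warn = 1.1) {
  stopifnot(inherits(chains, "zfe_chains"))
  keep <- (chains$burn + 1):chains$n_iter
  pn <- dimnames(chains$samples)[[2]]
  pooled <- do.call(rbind, lapply(seq_len(chains$n_chains), function(ch)
    chains$samples[keep, , ch, drop = FALSE][, , 1, drop = TRUE] |>
      matrix(ncol = length(pn), dimnames = list(NULL, pn))))
  llpost <- as.vector(chains$loglik[keep, ])
  imax <- which.max(llpost)
  out <- data.frame(parameter = pn,
                    MPV = pooled[imax, ],
                    median = apply(pooled, 2, median),
                    ci_lo = apply(pooled, 2, quantile, 0.025),
                    ci_hi = apply(pooled, 2, quantile, 0.975),
                    rhat = chains$rhat[pn], row.names = NULL)
  conv <- all(is.finite(out$rhat)) && all(out$rhat < rhat_warn)
  if (!conv) warning("chains not converged (max R-hat ",
                     signif(max(out$rhat), 3), ")", call. = FALSE)
  attr(out, "loglik_max") <- max(llpost)
  attr(out, "converged") <- conv
  attr(out, "fixed") <- chains$fixed
  class(out) <- c("zfe_posterior", "data.frame")
  out
}

# prior rows relevant for a structure (drop switched-off sub-models)
prune_priors <- function(priors, structure) {
  keep <- priors$parameter %in% c("f_pc", "phi", "sigma") |
    (priors$parameter == "phi_chorion" & structure$chorion_switch) |
    (priors$parameter == "Sat50_uM" & structure$saturation) |
    (priors$parameter == "K_met" & structure$metabolism == "linear") |
    (priors$parameter %in% c("V_max", "K_M") & structure$metabolism == "mm")
  prior_spec(priors[keep, , drop = FALSE])
}

#' Compare model structures by information criteria
#'
#' Calibrates each candidate structure on the same dataset and ranks them
#' by AIC (ties broken by fewer parameters), mirroring a
#' Bayesian-calibration-then-information-criterion workflow: the
#' likelihood entering AIC/BIC is the maximum over the MCMC samples (at
#' the MPV), \eqn{AIC = 2k - 2\ln\hat{L}},
#' \eqn{BIC = k\ln n - 2\ln\hat{L}}. Priors irrelevant to a structure
#' (e.g. `Sat50_uM` when saturation is off) are pruned automatically.
#'
#' @inheritParams mcmc_sample
#' @param structures named list of [model_structure()] candidates.
#' @return data.frame (class `zfe_modelcomp`) ranked by AIC with columns
#'   `structure`, `k`, `n`, `logLmax`, `AIC`, `BIC`; attribute `fits`
#'   holds the per-structure posterior summaries.
#' @export
compare_structures <- function(dataset, structures, priors, compound,
                               phys = default_physiology(), n_chains = 2,
                               n_iter = 1000, seed = 1, ...) {
  stopifnot(is.list(structures), length(names(structures)) ==
              length(structures))
  n <- nrow(dataset$records)
  fits <- list()
  rows <- lapply(names(structures), function(nm) {
    st <- structures[[nm]]
    pr <- prune_priors(priors, st)
    ch <- mcmc_sample(dataset, pr, compound, st, phys,
                      n_chains = n_chains, n_iter = n_iter, seed = seed,
                      ...)
    ps <- suppressWarnings(posterior_summary(ch))
    fits[[nm]] <<- ps
    k <- sum(pr$lower < pr$upper)
    lmax <- attr(ps, "loglik_max")
    data.frame(structure = nm, k = k, n = n, logLmax = lmax,
               AIC = 2 * k - 2 * lmax, BIC = k * log(n) - 2 * lmax)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("zfe_modelcomp", "data.frame")
  out
}
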