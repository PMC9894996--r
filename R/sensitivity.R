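#' Sensitivity-analysis configuration
#'
#' Parameters are varied on independent uniform ranges, by default
#' +/- 10% around their nominal values (`range_frac = 0.1`).
#'
#' @param params named numeric vector of nominal parameter values
#'   (strictly positive when using fractional ranges).
#' @param N base sample size (>= 64); the model is evaluated
#'   `N * (d + 2)` times for `d` parameters.
#' @param range_frac half-width of the uniform range as a fraction of the
#'   nominal value.
#' @param lower,upper optional explicit bounds overriding `range_frac`.
#' @param seed integer seed for the sampling.
#' @param n_boot bootstrap replicates for the index CIs.
#' @return Object of class `zfe_sa_config`.
#' @export
sa_config <- function(params, N = 1024, range_frac = 0.1, lower = NULL,
                      upper = NULL, seed = 1, n_boot = 200) {
  if (is.null(names(params)) || any(names(params) == ""))
    stop_input("params must be a named vector")
  if (N < 64) stop_input("N must be >= 64")
  if (is.null(lower)) lower <- params * (1 - range_frac)
  if (is.null(upper)) upper <- params * (1 + range_frac)
  if (any(upper <= lower)) stop_input("ranges must be strictly positive")
  res <- list(params = params, N = as.integer(N), lower = lower,
              upper = upper, seed = seed, n_boot = n_boot)
  class(res) <- "zfe_sa_config"
  res
}

#' Variance-based (Sobol) sensitivity indices
#'
#' Saltelli-type sampling with the centered-product first-order estimator
#' and the Jansen total-order estimator:
#' \deqn{S_1^i = \mathrm{mean}[y_B (y_{AB_i} - y_A)]/V,\quad
#'       S_T^i = \tfrac12\,\mathrm{mean}[(y_A - y_{AB_i})^2]/V,}
#' where \eqn{AB_i} is the `A` sample with column `i` taken from `B` and
#' `V` the variance of the pooled `A`/`B` evaluations. Percentile
#' bootstrap CIs are computed over the base-sample index. Any non-finite
#' model output aborts the run (no silent imputation).
#'
#' @param model function taking an `n x d` matrix (columns in the order of
#'   `config$params`) and returning a length-`n` vector or an `n x m`
#'   matrix (one column per model output, named).
#' @param config a [sa_config()].
#' @return data.frame (class `zfe_sobol`) with one row per
#'   (parameter, output): `S1`, `ST` and bootstrap CI bounds.
#' @export
#' @examples
#' cfg <- sa_config(c(x1 = 1, x2 = 1), N = 256)
#' sobol_indices(function(X) 3 * X[, 1] + X[, 2], cfg)
sobol_indices <- function(model, config) {
  stopifnot(inherits(config, "zfe_sa_config"))
  d <- length(config$params)
  N <- config$N
  pn <- names(config$params)
  set.seed(config$seed)
  draw <- function() {
    X <- matrix(runif(N * d), N, d)
    sweep(sweep(X, 2, config$upper - config$lower, `*`), 2, config$lower,
          `+`)
  }
  A <- draw(); B <- draw()
  colnames(A) <- colnames(B) <- pn
  evalm <- function(X) {
    y <- model(X)
    if (is.null(dim(y))) y <- matrix(y, ncol = 1,
                                     dimnames = list(NULL, "y"))
    if (nrow(y) != nrow(X)) stop_input("model returned wrong length")
    if (any(!is.finite(y)))
      stop_input("model failed (non-finite output) on ",
                 sum(!is.finite(y)), " sample point(s); run aborted")
    y
  }
  yA <- evalm(A); yB <- evalm(B)
  m <- ncol(yA)
  yAB <- lapply(seq_len(d), function(i) {
    Xi <- A; Xi[, i] <- B[, i]; evalm(Xi)
  })
  jansen <- function(idx) {
    out <- vector("list", d)
    for (i in seq_len(d)) {
      s1 <- st <- numeric(m)
      for (k in seq_len(m)) {
        ybar <- mean(c(yA[idx, k], yB[idx, k]))
        V <- var(c(yA[idx, k], yB[idx, k]))
        dA <- yA[idx, k] - yAB[[i]][idx, k]
        s1[k] <- if (V > 0)
          mean((yB[idx, k] - ybar) *
                 (yAB[[i]][idx, k] - yA[idx, k])) / V else 0
        st[k] <- if (V > 0) mean(dA^2) / 2 / V else 0
      }
      out[[i]] <- cbind(S1 = s1, ST = st)
    }
    out
  }
  est <- jansen(seq_len(N))
  boot <- array(NA_real_, c(config$n_boot, d, m, 2))
  for (b in seq_len(config$n_boot)) {
    idx <- sample.int(N, N, replace = TRUE)
    eb <- jansen(idx)
    for (i in seq_len(d)) boot[b, i, , ] <- eb[[i]]
  }
  rows <- list()
  outn <- colnames(yA)
  for (i in seq_len(d)) for (k in seq_len(m)) {
    rows[[length(rows) + 1]] <- data.frame(
      parameter = pn[i], output = outn[k],
      S1 = est[[i]][k, "S1"], ST = est[[i]][k, "ST"],
      S1_lo = quantile(boot[, i, k, 1], 0.025, names = FALSE),
      S1_hi = quantile(boot[, i, k, 1], 0.975, names = FALSE),
      ST_lo = quantile(boot[, i, k, 2], 0.025, names = FALSE),
      ST_hi = quantile(boot[, i, k, 2], 0.975, names = FALSE))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("zfe_sobol", "data.frame")
  out
}

#' Rank parameters by total-order influence
#'
#' @param result a `zfe_sobol` data.frame.
#' @param k how many parameters to keep per output (truncated to the
#'   available number).
#' @return data.frame of the top-`k` rows per output, ST descending,
#'   deterministic alphabetical tie-break.
#' @export
rank_influential <- function(result, k = 15) {
  stopifnot(inherits(result, "zfe_sobol"))
  do.call(rbind, lapply(split(result, result$output), function(df) {
    df <- df[order(-df$ST, df$parameter), , drop = FALSE]
    utils::head(df, min(k, nrow(df)))
  })) |> `rownames<-`(NULL)
}

#' Sobol sensitivity of the PBPK model itself
#'
#' Wraps [sobol_indices()] around [simulate_zfe()]: the listed
#' compound-specific parameters are varied (+/- 10% uniform by default)
#' while the partition coefficients stay at their `f_pc`-corrected values
#' unless `f_pc` itself is varied; outputs are compartment (or
#' whole-body) concentrations at fixed developmental ages on a FET-like
#' design.
#'
#' @param compound a [compound_params()] providing nominal values.
#' @param parameters character vector among `f_pc`, `phi`, `phi_chorion`,
#'   `sigma`-free model constants `Sat50_uM`, `K_met`, `V_max`, `K_M`.
#' @param outputs character vector of compartments (or `"total"`).
#' @param at ages (hpf) at which outputs are read, default
#'   `c(24, 48, 72, 96, 120)`.
#' @param design an [exposure_design()], default [fet_design()] at 1 uM
#'   from 1 hpf.
#' @param structure,phys model structure and physiology.
#' @param N,range_frac,seed,n_boot passed to [sa_config()].
#' @param nominal optional named vector overriding the compound's nominal
#'   values (needed e.g. to probe `K_met` when the preset has metabolism
#'   off).
#' @return data.frame (class `zfe_sobol`); `output` is
#'   `"<compartment>@<age>"`.
#' @export
sobol_pbpk <- function(compound, parameters = c("f_pc", "phi",
                                                "phi_chorion"),
                       outputs = "total", at = c(24, 48, 72, 96, 120),
                       design = fet_design(1000), structure = NULL,
                       phys = default_physiology(), N = 256,
                       range_frac = 0.1, seed = 1, n_boot = 100,
                       nominal = NULL) {
  nominal_default <- vapply(parameters, function(p) switch(p,
    f_pc = compound$f_pc, phi = compound$phi,
    phi_chorion = compound$phi_chorion, Sat50_uM = compound$Sat50_uM,
    K_met = compound$metabolism$K_met, V_max = compound$metabolism$V_max,
    K_M = compound$metabolism$K_M,
    stop_input("unknown parameter: ", p)), numeric(1))
  if (!is.null(nominal))
    nominal_default[names(nominal)] <- nominal
  nominal <- nominal_default
  if (is.null(structure))
    structure <- model_structure(
      metabolism = if ("K_met" %in% parameters) "linear"
                   else if (any(c("V_max", "K_M") %in% parameters)) "mm"
                   else "none",
      saturation = "Sat50_uM" %in% parameters)
  at <- at[at >= design$start_age & at <= design$start_age +
             design$duration]
  times <- sort(unique(c(design$start_age, at)))
  outn <- unlist(lapply(outputs, function(o) paste(o, at, sep = "@")))
  model <- function(X) {
    Y <- matrix(NA_real_, nrow(X), length(outn),
                dimnames = list(NULL, outn))
    for (r in seq_len(nrow(X))) {
      cm <- update_compound(compound, setNames(X[r, ], parameters))
      sim <- simulate_zfe(design, cm, structure, phys, times = times,
                          rtol = 1e-6, atol = 1e-10)
      k <- 0
      for (o in outputs) for (a in at) {
        k <- k + 1
        i <- match(a, sim$times)
        Y[r, k] <- if (o == "total") sim$C_body[i] else sim$conc[i, o]
      }
    }
    Y
  }
  cfg <- sa_config(nominal, N = N, range_frac = range_frac, seed = seed,
                   n_boot = n_boot)
  sobol_indices(model, cfg)
}
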