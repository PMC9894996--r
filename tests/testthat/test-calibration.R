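test_that("prior_spec validates bounds and sigma support", {
  expect_error(prior_spec(data.frame(parameter = "f_pc", lower = 2,
                                     upper = 1)), "inverted")
  expect_error(prior_spec(data.frame(parameter = "sigma", lower = 0.5,
                                     upper = 3)), "> 1")
  expect_error(prior_spec(data.frame(parameter = "banana", lower = 0,
                                     upper = 1)), "unknown")
  expect_s3_class(default_priors(), "zfe_priors")
})

test_that("lognormal likelihood matches hand-evaluated densities", {
  # one design, observations planted exactly at the model prediction
  d <- fet_design(1000, start_age = 1, duration = 72)
  cmp <- compound_preset("BPA")
  tt <- c(24, 48, 70)
  sim <- simulate_zfe(d, cmp, times = c(1, tt))
  pred <- sim$C_body_ng_mg[match(tt, sim$times)]
  ds <- tk_dataset(data.frame(design_id = "a", compound = "BPA",
                              time_hpf = tt, conc_body = pred),
                   list(a = d))
  ll <- log_likelihood(ds, cmp)
  # density of a lognormal at its median: 1/(x ln(sigma) sqrt(2 pi))
  expect_equal(as.numeric(ll),
               sum(-log(pred * log(cmp$sigma) * sqrt(2 * pi))),
               tolerance = 1e-6)
  # obs = e * pred with sigma = e: -ln(obs sqrt(2 pi)) - 1/2
  cmp_e <- cmp; cmp_e$sigma <- exp(1)
  obs <- exp(1) * pred[1]
  ds1 <- tk_dataset(data.frame(design_id = "a", compound = "BPA",
                               time_hpf = tt[1], conc_body = obs),
                    list(a = d))
  expect_equal(as.numeric(log_likelihood(ds1, cmp_e)),
               -log(obs * sqrt(2 * pi)) - 0.5, tolerance = 1e-6)
  # larger sigma helps badly-fit points, hurts perfect fits
  cmp_w <- cmp; cmp_w$sigma <- 5
  expect_lt(as.numeric(log_likelihood(ds, cmp_w)), as.numeric(ll))
  ds_bad <- tk_dataset(data.frame(design_id = "a", compound = "BPA",
                                  time_hpf = tt[1],
                                  conc_body = 100 * pred[1]),
                       list(a = d))
  expect_gt(as.numeric(log_likelihood(ds_bad, cmp_w)),
            as.numeric(log_likelihood(ds_bad, cmp)))
  expect_error(tk_dataset(data.frame(design_id = "a", compound = "BPA",
                                     time_hpf = 24, conc_body = -1),
                          list(a = d)), "> 0")
})

test_that("MCMC is seed-reproducible and respects prior support", {
  ds <- empty_dataset()
  pr <- bpa_priors()
  cmp <- compound_preset("BPA")
  c1 <- mcmc_sample(ds, pr, cmp, n_chains = 2, n_iter = 150, seed = 9)
  c2 <- mcmc_sample(ds, pr, cmp, n_chains = 2, n_iter = 150, seed = 9)
  expect_identical(c1$samples, c2$samples)
  c3 <- mcmc_sample(ds, pr, cmp, n_chains = 2, n_iter = 150, seed = 10)
  expect_false(identical(c1$samples, c3$samples))
  for (p in dimnames(c1$samples)[[2]]) {
    expect_gte(min(c1$samples[, p, ]), pr$lower[pr$parameter == p])
    expect_lte(max(c1$samples[, p, ]), pr$upper[pr$parameter == p])
  }
})

test_that("flat likelihood reproduces the uniform prior (thinned KS)", {
  ch <- mcmc_sample(empty_dataset(), bpa_priors(), compound_preset("BPA"),
                    n_chains = 1, n_iter = 4000, seed = 5)
  x <- ch$samples[seq(2001, 4000, by = 20), "f_pc", 1]
  p <- suppressWarnings(stats::ks.test(x, "punif", 0.01, 10)$p.value)
  expect_gt(p, 0.01)
})

test_that("posterior summary: quantile oracle, MPV, degenerate chain", {
  # hand-built chains with known normal samples
  set.seed(1)
  n <- 4000
  sm <- array(rnorm(n * 2, mean = c(5, 5)), c(n, 1, 2),
              dimnames = list(NULL, "f_pc", NULL))
  ll <- matrix(-(sm[, 1, ] - 5.2)^2, n, 2)   # maximized nearest 5.2
  fake <- structure(list(samples = sm, loglik = ll, fixed = numeric(0),
                         priors = bpa_priors(), burn = 0, n_iter = n,
                         n_chains = 2, seed = 1,
                         rhat = c(f_pc = 1.0)),
                    class = "zfe_chains")
  ps <- posterior_summary(fake)
  expect_equal(ps$median, 5, tolerance = 0.05)
  expect_equal(ps$ci_lo, qnorm(0.025, 5, 1), tolerance = 0.1)
  expect_equal(ps$ci_hi, qnorm(0.975, 5, 1), tolerance = 0.1)
  pooled <- c(sm[, 1, 1], sm[, 1, 2])
  expect_equal(ps$MPV, pooled[which.min(abs(pooled - 5.2))])
  expect_true(attr(ps, "converged"))
  # constant chain: zero-width interval at the value
  smc <- array(3, c(100, 1, 2), dimnames = list(NULL, "f_pc", NULL))
  fake2 <- structure(list(samples = smc,
                          loglik = matrix(0, 100, 2), fixed = numeric(0),
                          priors = bpa_priors(), burn = 0, n_iter = 100,
                          n_chains = 2, seed = 1, rhat = c(f_pc = 1)),
                     class = "zfe_chains")
  ps2 <- posterior_summary(fake2)
  expect_identical(c(ps2$ci_lo, ps2$ci_hi, ps2$median), c(3, 3, 3))
})

test_that("point priors implement the analog workflow (fix phi's)", {
  pr <- prior_spec(data.frame(
    parameter = c("f_pc", "phi", "phi_chorion", "sigma"),
    lower = c(0.01, 8.00, 0.495, 1.05),
    upper = c(10, 8.00, 0.495, 8)))
  ch <- mcmc_sample(empty_dataset(), pr, compound_preset("BPS"),
                    n_chains = 1, n_iter = 100, seed = 2)
  expect_setequal(dimnames(ch$samples)[[2]], c("f_pc", "sigma"))
  expect_equal(ch$fixed, c(phi = 8.00, phi_chorion = 0.495))
})

test_that("information criteria follow the formulas; parsimony penalizes", {
  set.seed(3)
  g <- generate_dataset(compound_preset("BPA"),
                        template = study_template(n_studies = 2,
                                                  timepoints = c(3, 4)),
                        seed = 31)
  st <- list(two_flow = model_structure(),
             two_flow_sat = model_structure(saturation = TRUE))
  cs <- suppressWarnings(
    compare_structures(g$dataset, st, default_priors(),
                       compound_preset("BPA"), n_chains = 1,
                       n_iter = 250, seed = 4))
  expect_equal(cs$AIC, 2 * cs$k - 2 * cs$logLmax)
  expect_equal(cs$BIC, cs$k * log(cs$n) - 2 * cs$logLmax)
  expect_equal(cs$n, rep(nrow(g$dataset$records), 2))
  # the saturation structure has one more parameter than the base model
  expect_equal(cs$k[cs$structure == "two_flow_sat"],
               cs$k[cs$structure == "two_flow"] + 1)
})
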