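test_that("uptake flow: chorion switch, scalar oracle, dechorionated law", {
  cmp <- compound_preset("BPA")   # phi 8.00, phi_chorion 0.495
  st <- model_structure()
  expect_equal(uptake_flow(24, 0.2, cmp, st, chorionated = TRUE), 0.495)
  expect_equal(uptake_flow(72, 0.27, cmp, st, chorionated = TRUE),
               8.00 * 0.27^(2 / 3))
  expect_equal(uptake_flow(24, 0.2, cmp, st, chorionated = FALSE),
               8.00 * 0.2^(2 / 3))
  single <- model_structure(chorion_switch = FALSE)
  expect_equal(uptake_flow(24, 0.2, cmp, single, chorionated = TRUE),
               8.00 * 0.2^(2 / 3))
})

test_that("saturation factor: limits, half point, published BPF value", {
  expect_identical(saturation_factor(0, 19), 1)
  expect_equal(saturation_factor(19, 19), 0.5)
  expect_equal(saturation_factor(38.0, 19.0), 1 / 3)   # Sat50 = 19 uM
  cw <- seq(0, 100, by = 5)
  expect_true(all(diff(saturation_factor(cw, 19)) < 0))
  expect_equal(saturation_factor(c(0, 10, 1e6), Inf), c(1, 1, 1))
})

test_that("tissue flux: equilibrium, oracle, additivity over organs", {
  expect_equal(tissue_flux(0.495, 0.04, 0.2, 1e-6, 10 * 1e-6, 10), 0)
  expect_equal(tissue_flux(0.495, 0.04, 0.2, 1e-6, 0, 10), 9.9e-8)
  # equal C_i/P_i across organs collapses to the one-compartment flux
  V <- c(0.05, 0.1, 0.05); P <- c(5, 10, 20); Cw <- 2e-6
  Ci <- P * 1e-6
  total <- sum(mapply(function(v, c, p)
    tissue_flux(1.3, v, 0.2, Cw, c, p), V, Ci, P))
  expect_equal(total, 1.3 * (Cw - 1e-6))
})

test_that("liver flux: metabolism kinds and scalar oracle", {
  cmp <- one_comp_compound(P = 10)
  none <- liver_flux(1, 1e-3, 0.2, 1e-6, 0, cmp, model_structure())
  expect_identical(none$dQ_met, 0)
  expect_equal(none$dQ_liver, tissue_flux(1, 1e-3, 0.2, 1e-6, 0, 10))
  lin <- compound_params("m", 228.29, cmp$P_prior, phi = 2,
                         phi_chorion = 0.5,
                         metabolism = list(kind = "linear", K_met = 0.01),
                         V_liver_cell = 1e-6, sigma = 2)
  r <- liver_flux(0, 1e-3, 0.2, 0, 1e-5, lin,
                  model_structure(metabolism = "linear"))
  expect_equal(r$dQ_met, 1000 * 1e-5 * 0.01)   # = 1e-4 nmol/h
  mm <- compound_params("m", 228.29, cmp$P_prior, phi = 2,
                        phi_chorion = 0.5,
                        metabolism = list(kind = "mm", V_max = 2e-6,
                                          K_M = 1e-5),
                        V_liver_cell = 1e-6, sigma = 2)
  r2 <- liver_flux(0, 1e-3, 0.2, 0, 1e-5, mm,
                   model_structure(metabolism = "mm"))
  expect_equal(r2$dQ_met, 1000 * 2e-6 / 2)   # C = K_M: ncell * Vmax/2
  expect_error(compound_params("m", 228.29, cmp$P_prior, phi = 2,
                               phi_chorion = 0.5,
                               metabolism = list(kind = "linear",
                                                 K_met = -1), sigma = 2),
               "non-negative")
})

test_that("compiled RHS agrees with the R-level flux composition", {
  phys <- default_physiology()
  cmp <- compound_preset("BPF")   # exercises saturation too
  st <- model_structure(saturation = TRUE, metabolism = "linear")
  cmp$metabolism$K_met <- 1e-5
  des <- fet_design(5000, start_age = 1, duration = 100)
  pars <- zfetk:::build_cpp_pars(des, cmp, st, phys)
  P_eff <- effective_partition(cmp)
  set.seed(42)
  for (rep in 1:20) {
    t <- runif(1, 1, 101)
    y <- c(runif(10, 0, 1e-3), runif(1, 0, 10), runif(3, 0, 0.1))
    dy <- zfetk:::zfe_rhs_cpp(t, y, pars)
    vols <- organ_volumes(t, phys, des$temperature)[1, ]
    Vemb <- sum(vols)
    Cw <- y[11] / des$device$V_water
    Few <- uptake_flow(t, Vemb, cmp, st, des$chorionated,
                       phys$hatch_time)
    sat <- saturation_factor(Cw * 1e3, cmp$Sat50_uM)   # nmol/uL -> uM
    fl <- vapply(seq_len(10), function(i)
      tissue_flux(Few, vols[i], Vemb, Cw,
                  if (vols[i] > 0) y[i] / vols[i] else 0, P_eff[i], sat),
      numeric(1))
    lf <- liver_flux(Few, vols[2], Vemb, Cw,
                     if (vols[2] > 0) y[2] / vols[2] else 0, cmp, st, sat)
    dpoly <- polymer_flux(medium_state(y[11], y[12], y[13]), cmp$medium,
                          des$device)
    expected <- unname(c(fl[1], lf$dQ_liver, fl[3:10],
                         -dpoly - sum(fl), dpoly, 0, lf$dQ_met))
    expect_equal(as.numeric(dy), expected, tolerance = 1e-12)
  }
})

test_that("zero dose gives identically zero concentrations", {
  sim <- simulate_zfe(fet_design(0), compound_preset("BPA"), dt = 5)
  expect_true(all(sim$quantities == 0))
  expect_true(all(sim$C_body == 0))
})

test_that("constant-volume single-compartment limit matches closed form", {
  P <- 10; phi <- 2; V0 <- 0.2; Cw <- 1e-3
  sim <- simulate_zfe(still_design(1000, duration = 48),
                      one_comp_compound(P = P, phi = phi),
                      phys = toy_physiology(V0 = V0), dt = 0.25)
  k <- phi * V0^(2 / 3) / (V0 * P)
  analytic <- P * Cw * (1 - exp(-k * (sim$times)))
  expect_equal(sim$C_body, analytic, tolerance = 1e-4)
  # BCF approaches the partition coefficient at steady state
  m <- tk_metrics(sim)
  expect_equal(m$BCF$BCF[nrow(m$BCF)], P, tolerance = 0.01)
})

test_that("negligible depletion: 2 embryos vs 1 in a large well agree", {
  s1 <- simulate_zfe(still_design(1000, duration = 48, n_embryos = 1),
                     compound_preset("BPA"), dt = 1)
  s2 <- simulate_zfe(still_design(1000, duration = 48, n_embryos = 2),
                     compound_preset("BPA"), dt = 1)
  expect_equal(s1$C_body, s2$C_body, tolerance = 1e-3)
})

test_that("chorion barrier lowers pre-hatch exposure; phi raises Cmax", {
  cmp <- compound_preset("BPA")
  chor <- simulate_zfe(fet_design(1000, chorionated = TRUE), cmp, dt = 0.5)
  dechor <- simulate_zfe(fet_design(1000, chorionated = FALSE), cmp,
                         dt = 0.5)
  pre <- chor$times < 48
  expect_true(all(chor$C_body[pre] <= dechor$C_body[pre] + 1e-12))
  hi <- cmp; hi$phi <- cmp$phi * 2; hi$phi_chorion <- cmp$phi_chorion * 2
  expect_gte(tk_metrics(simulate_zfe(fet_design(1000), hi, dt = 0.5))$
               Cmax_ng_mg,
             tk_metrics(chor)$Cmax_ng_mg)
})

test_that("saturation bends the dose response; off keeps it linear", {
  base <- compound_preset("BPF")                  # Sat50 = 19 uM
  on <- model_structure(saturation = TRUE)
  off <- model_structure(saturation = FALSE)
  doses <- c(1e3, 1e4, 5e4)                       # 1, 10, 50 uM
  norm <- function(st) vapply(doses, function(d)
    tk_metrics(simulate_zfe(fet_design(d, duration = 72), base, st,
                            dt = 0.5))$Cmax_ng_mg / d, numeric(1))
  expect_equal(norm(off), rep(norm(off)[1], 3), tolerance = 1e-6)
  expect_true(all(diff(norm(on)) < 0))
})

test_that("growth dilution: concentration can fall while body burden rises", {
  sim <- simulate_zfe(fet_design(1000), compound_preset("BPA"), dt = 0.5)
  dC <- diff(sim$C_body); dQ <- diff(sim$Q_body)
  expect_true(any(dC < 0 & dQ > 0))
})

test_that("tk_metrics: end-of-window peak, constructed peak, errors", {
  # monotone rise -> tmax at the window end
  sim <- simulate_zfe(still_design(1000, duration = 24),
                      one_comp_compound(P = 100, phi = 0.5),
                      phys = toy_physiology(), dt = 0.5)
  expect_equal(tk_metrics(sim)$tmax_h, 24, tolerance = 1e-6)
  # constructed trajectory peaking at t = 40
  tt <- seq(0, 80, by = 0.5)
  fake <- structure(list(times = tt,
                         C_body_ng_mg = exp(-(tt - 40.17)^2 / 300),
                         C_body = exp(-(tt - 40.17)^2 / 300) / 228,
                         C_water = rep(1e-3, length(tt)),
                         design = still_design(1000, duration = 80)),
                    class = "zfe_sim")
  expect_equal(tk_metrics(fake)$tmax_h, 40.17, tolerance = 0.05)
  expect_error(tk_metrics(fake, t_dose = 100), "no simulation output")
})
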