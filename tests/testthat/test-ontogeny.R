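phys <- default_physiology()

test_that("Arrhenius factor: identities, hand-computed value, monotonicity", {
  expect_identical(arrhenius_factor(298.15, TA = 6930), 1)
  expect_identical(arrhenius_factor(310, TA = 0), 1)
  # independent scalar evaluation of the exponent
  expect_equal(arrhenius_factor(301.15, TA = 6930, TR = 298.15),
               exp(6930 / 298.15 - 6930 / 301.15))
  temps <- seq(290, 310, by = 2)
  f <- arrhenius_factor(temps, TA = 6930)
  expect_true(all(diff(f) > 0))
  expect_error(arrhenius_factor(-1, TA = 6930), "positive")
  expect_error(arrhenius_factor(300, TA = -5), "TA")
})

test_that("organ volume: onset clamp and direct scalar evaluation", {
  p <- zfe_physiology(
    data.frame(name = setdiff(zfe_compartments(), "yolk"),
               Kg_TR = c(0.01, rep(0, 8)), tau_TR = c(24, rep(0, 8))),
    yolk = list(V0 = 0.18, k = 0.02), V_embryo_120 = 1, TA = 0)
  expect_identical(organ_volume(24, "liver", p), 0)   # t = tau
  expect_identical(organ_volume(10, "liver", p), 0)   # t < tau
  expect_equal(organ_volume(48, "liver", p), exp(0.01 * 24) - 1)
  expect_error(organ_volume(-1, "liver", p), ">= 0")
  expect_error(organ_volume(10, "gills", p), "unknown organ")
})

test_that("organ volumes are continuous, non-decreasing; onsets advance with T", {
  tt <- seq(0, 120, by = 0.5)
  for (nm in setdiff(zfe_compartments(), "yolk")) {
    v <- organ_volume(tt, nm, phys)
    expect_true(all(diff(v) >= 0), info = nm)
    expect_lt(max(abs(diff(v))), 0.01)   # no jumps on a 0.5 h grid
  }
  # warmer water starts every organ earlier
  for (nm in setdiff(zfe_compartments(), "yolk")) {
    first25 <- min(tt[organ_volume(tt, nm, phys, temperature = 25) > 0])
    first28 <- min(tt[organ_volume(tt, nm, phys, temperature = 28) > 0])
    expect_lt(first28, first25)
  }
})

test_that("yolk: initial volume, scalar oracle, temperature acceleration", {
  p <- zfe_physiology(
    data.frame(name = setdiff(zfe_compartments(), "yolk"),
               Kg_TR = 0, tau_TR = 0),
    yolk = list(V0 = 0.18, k = 0.02), V_embryo_120 = 1, TA = 6930)
  expect_equal(yolk_volume(0, p), 0.18)
  expect_equal(yolk_volume(50, p, temperature = 25), 0.18 * exp(-1))
  tt <- seq(1, 120, by = 1)
  expect_true(all(yolk_volume(tt, p, 28) < yolk_volume(tt, p, 25)))
  expect_true(all(diff(yolk_volume(tt, p)) < 0))
  expect_true(all(yolk_volume(c(0, 500), p) > 0))
})

test_that("total volume: additivity and 120-hpf consistency", {
  expect_equal(total_volume(0, phys), phys$yolk$V0)
  tt <- c(3, 24, 60, 119)
  indiv <- sapply(zfe_compartments(), function(nm)
    if (nm == "yolk") yolk_volume(tt, phys) else organ_volume(tt, nm, phys))
  expect_equal(total_volume(tt, phys), rowSums(indiv))
  # organs alone reach the configured V_embryo(120) within 1%
  v120 <- total_volume(120, phys) - yolk_volume(120, phys)
  expect_equal(v120, phys$V_embryo_120, tolerance = 0.01)
  expect_true(all(total_volume(seq(0, 120, 5), phys) > 0))
})

test_that("physiology constructor and loader validate the schema", {
  expect_error(zfe_physiology(data.frame(name = "liver", Kg_TR = 1,
                                         tau_TR = 1),
                              list(V0 = 1, k = 0), 1),
               "exactly")
  expect_error(zfe_physiology(
    data.frame(name = setdiff(zfe_compartments(), "yolk"),
               Kg_TR = -1, tau_TR = 0), list(V0 = 1, k = 0), 1), ">= 0")
  expect_s3_class(default_physiology(), "zfe_physiology")
  # round-trip through a user file
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(V_embryo_120 = 0.27, TA = 6930,
                            yolk = list(V0 = 0.18, k = 0.025),
                            organs = phys$organs),
                       f, auto_unbox = TRUE, digits = NA)
  p2 <- load_physiology(f)
  expect_equal(p2$organs, phys$organs)
})
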