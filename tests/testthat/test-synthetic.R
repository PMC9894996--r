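test_that("FET design: published scenario, null dose, determinism", {
  d <- fet_design(1000, start_age = 1)   # the 1 uM / 1 hpf / 144 h scenario
  expect_equal(d$start_age, 1)
  expect_equal(d$duration, 144)
  expect_equal(d$dose_events$conc_nM, 1000)
  expect_equal(d$device$n_embryos, 1)
  expect_true(length(d$renewal_times) >= 5)   # daily renewal
  expect_identical(fet_design(1000, start_age = 1), d)
  d0 <- fet_design(0)
  expect_equal(d0$dose_events$conc_nM, 0)
  expect_error(fet_design(-1), ">= 0")
})

test_that("noise-free limit: observations equal simulations", {
  truth <- compound_preset("BPA")
  truth$sigma <- 1 + 1e-12
  g <- generate_dataset(truth, template = study_template(n_studies = 2),
                        seed = 3)
  rec <- g$dataset$records
  for (id in unique(rec$design_id)) {
    r <- rec[rec$design_id == id, ]
    sim <- simulate_zfe(g$dataset$designs[[id]], truth,
                        times = sort(unique(c(
                          g$dataset$designs[[id]]$start_age, r$time_hpf))),
                        rtol = 1e-6, atol = 1e-10)
    expect_equal(r$conc_body,
                 sim$C_body_ng_mg[match(r$time_hpf, sim$times)],
                 tolerance = 1e-7)
  }
})

test_that("fixed seed reproduces the dataset bit-exactly", {
  truth <- compound_preset("BPA")
  g1 <- generate_dataset(truth, template = study_template(n_studies = 3),
                         seed = 11)
  g2 <- generate_dataset(truth, template = study_template(n_studies = 3),
                         seed = 11)
  expect_identical(g1$dataset$records, g2$dataset$records)
  g3 <- generate_dataset(truth, template = study_template(n_studies = 3),
                         seed = 12)
  expect_false(identical(g1$dataset$records, g3$dataset$records))
})

test_that("designs stay inside the stated literature ranges", {
  tmpl <- study_template(n_studies = 8)
  g <- generate_dataset(compound_preset("BPA"), template = tmpl, seed = 5)
  for (d in g$dataset$designs) {
    expect_gte(d$start_age, 1); expect_lte(d$start_age, 96)
    expect_gte(d$temperature, 25); expect_lte(d$temperature, 28.5)
    expect_gte(d$dose_events$conc_nM, 0.438)
    expect_lte(d$dose_events$conc_nM, 5e4)
  }
  pts <- table(g$dataset$records$design_id)
  expect_true(all(pts >= 1 & pts <= 6))
})

test_that("empirical geometric SD of obs/pred matches sigma within 5%", {
  truth <- compound_preset("BPA")          # sigma 2.76
  tmpl <- study_template(n_studies = 1, timepoints = c(6, 6),
                         age_range = c(1, 72),
                         duration_range = c(48, 96))
  ratios <- numeric(0)
  for (s in 1:200) {
    g <- generate_dataset(truth, template = tmpl, seed = 1000 + s)
    rec <- g$dataset$records
    d <- g$dataset$designs[[1]]
    sim <- simulate_zfe(d, truth,
                        times = sort(unique(c(d$start_age, rec$time_hpf))),
                        rtol = 1e-6, atol = 1e-10)
    pred <- sim$C_body_ng_mg[match(rec$time_hpf, sim$times)]
    ratios <- c(ratios, rec$conc_body / pred)
  }
  gsd <- exp(sd(log(ratios)))
  expect_equal(gsd, 2.76, tolerance = 0.05)
})

test_that("TK CSV round trip is lossless", {
  g <- generate_dataset(compound_preset("BPA"),
                        template = study_template(n_studies = 2), seed = 8)
  f <- tempfile(fileext = ".csv")
  write_tk_csv(g$dataset, f)
  back <- read_tk_csv(f, g$dataset$designs)
  expect_equal(back$records$conc_body, g$dataset$records$conc_body)
  expect_equal(back$records$time_hpf, g$dataset$records$time_hpf)
  expect_identical(back$records$design_id, g$dataset$records$design_id)
})
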