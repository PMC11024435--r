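# The synthetic-collection generator and its planted ground truth.

test_that("scenario configuration validates planted counts", {
  cfg <- scenario_config(n_extracts = 50, seed = 1, n_outliers = 5,
                         n_survivors = 2)
  expect_identical(cfg$n_outliers, 5L)
  expect_error(scenario_config(n_extracts = 10, n_outliers = 11),
               "more planted outliers")
  expect_error(scenario_config(n_extracts = 50, n_outliers = 2,
                               n_survivors = 3), "subset")
})

test_that("identical seeds give byte-identical collections", {
  cfg <- scenario_config(n_extracts = 15, seed = 42, n_outliers = 2,
                         n_survivors = 1)
  c1 <- generate_collection(cfg)
  c2 <- generate_collection(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$measurements, c2$measurements)
  expect_identical(c1$spectra, c2$spectra)
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario(c1, d1); write_scenario(c2, d2)
  for (f in c("features.tsv", "taxa.tsv", "screening.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  c3 <- generate_collection(scenario_config(n_extracts = 15, seed = 43,
                                            n_outliers = 2,
                                            n_survivors = 1))
  expect_false(identical(c1$measurements, c3$measurements))
})

test_that("planted truth matches the configuration", {
  coll <- fixture_collection()
  truth <- coll$truth
  cfg <- coll$config
  expect_identical(sum(truth$survivor), cfg$n_survivors)
  expect_identical(sum(truth$outlier), cfg$n_outliers)
  expect_true(all(truth$outlier[truth$survivor]))
  # survivors are potent non-toxic inhibitors by construction
  surv <- truth[truth$survivor, ]
  expect_true(all(surv$category == "inhibitor"))
  expect_true(all(surv$true_topflash_ic50 <= 5))
  expect_false(any(surv$toxic))
  # toxicity truth obeys the 1.7x rule analytically
  tox <- truth[!is.na(truth$true_renilla_ic50), ]
  expect_identical(tox$toxic,
                   tox$true_renilla_ic50 < 1.7 * tox$true_topflash_ic50)
})

test_that("category frequencies follow the configured base rates", {
  panel <- generate_screen_panel(n_curves = 400, seed = 17)
  cfg <- scenario_config(n_extracts = 400, seed = 17)
  p_active <- mean(panel$truth$category != "inactive")
  # binomial 3-sigma band around the preset rate
  tol <- 3 * sqrt(cfg$p_active * (1 - cfg$p_active) / 400)
  expect_lt(abs(p_active - cfg$p_active), tol)
  act <- panel$truth[panel$truth$category != "inactive", ]
  p_inh <- mean(act$category == "inhibitor")
  expect_lt(abs(p_inh - cfg$p_inhibitor),
            3 * sqrt(cfg$p_inhibitor * (1 - cfg$p_inhibitor) / nrow(act)))
})

test_that("noise-free dose-response data sit exactly on the 4PL curve", {
  d <- generate_dose_response(10, 1.5, r0 = 1, rinf = 0.1, noise_cv = 0)
  mu <- 0.1 + (1 - 0.1) / (1 + (d$concentration / 10)^1.5)
  expect_equal(d$response, mu, tolerance = 1e-12)
  d2 <- generate_dose_response(10, 1.5, noise_cv = 0.2, seed = 1)
  expect_false(isTRUE(all.equal(d2$response, d$response)))
  expect_error(generate_dose_response(-1), "true_ic50 > 0")
})

test_that("planted toxic pairs are flagged by the classifier", {
  conc <- screen_concentrations()
  tf <- generate_dose_response(10, 1.5, noise_cv = 0)
  rn <- generate_dose_response(12, 1.5, noise_cv = 0)
  call <- classify_activity(fit_4pl(tf$concentration, tf$response),
                            fit_4pl(rn$concentration, rn$response), "P1")
  expect_true(call$toxic)
})

test_that("outlier spectra diverge from the shared vocabulary", {
  set.seed(21)
  shared <- sort(runif(50, 50, 400))
  priv <- sort(runif(50, 50, 400)) + 450
  a <- generate_spectra(runif(25, 1000, 1200), shared)
  b <- generate_spectra(runif(25, 1000, 1200), shared)
  out <- generate_spectra(runif(25, 1000, 1200), shared,
                          private_vocab = priv, outlier = TRUE)
  m <- build_memo_matrix(list(a = a, b = b, o = out), bin_width = 1)
  expect_gt(row_cosine(m["a", ], m["b", ]), 0.8)
  expect_lt(row_cosine(m["a", ], m["o", ]), 0.2)
  expect_error(generate_spectra(1000, shared, outlier = TRUE),
               "private vocabulary")
})

test_that("every spectrum's precursor exceeds its fragments", {
  coll <- fixture_collection()
  for (sp in coll$spectra[1:8]) {
    for (s in sp) {
      if (nrow(s$peaks)) expect_gt(s$precursor_mz, max(s$peaks[, "mz"]))
    }
  }
})
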