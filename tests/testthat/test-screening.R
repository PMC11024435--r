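# Dose-response fitting and activity classification for the dual-luciferase
# screen.

test_that("normalization maps control to 1 and scales linearly", {
  m <- data.frame(extract_id = "E1",
                  channel = rep(c("topflash", "renilla"), each = 2),
                  concentration = c(50, 25, 50, 25),
                  luminescence = c(2000, 500, 1500, 0))
  out <- normalize_responses(m, c(topflash = 2000, renilla = 1500))
  expect_equal(out$response, c(1, 0.25, 1, 0))
  expect_error(normalize_responses(m, c(topflash = 2000)), "renilla")
  expect_error(normalize_responses(m, c(topflash = 0, renilla = 1)), "> 0")
})

test_that("4PL fit recovers exact-model parameters on noise-free data", {
  conc <- screen_concentrations()
  d <- generate_dose_response(10, 1, r0 = 1, rinf = 0, noise_cv = 0)
  f <- fit_4pl(d$concentration, d$response)
  expect_true(f$converged)
  expect_identical(f$ic50_flag, "estimable")
  expect_equal(f$ic50, 10, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-4)
  expect_lte(f$bottom, f$top)
  expect_gte(f$rss, 0)
  # steeper curve, different asymptotes
  d2 <- generate_dose_response(6, 2.5, r0 = 1, rinf = 0.1, noise_cv = 0)
  f2 <- fit_4pl(d2$concentration, d2$response)
  expect_equal(f2$ic50, 6, tolerance = 1e-4)
})

test_that("flat and out-of-range curves are flagged, not extrapolated", {
  conc <- screen_concentrations()
  flat <- fit_4pl(conc, rep(1, 5))
  expect_identical(flat$ic50_flag, "not_estimable")
  expect_true(is.na(flat$ic50))
  expect_true(flat$converged)
  d80 <- generate_dose_response(80, 1, noise_cv = 0)
  f80 <- fit_4pl(d80$concentration, d80$response)
  expect_identical(f80$ic50_flag, ">max_tested")
  expect_error(fit_4pl(c(10, 5, 2), c(1, 0.5, 0.1)), "at least 4")
  expect_error(fit_4pl(c(-1, 5, 2, 1), c(1, 1, 0.5, 0.1)), "non-negative")
})

test_that("the 1.7x Renilla rule separates toxicity from inhibition", {
  conc <- screen_concentrations()
  tf <- fit_4pl(conc, generate_dose_response(10, 1.5, noise_cv = 0)$response)
  # renilla IC50 12 < 1.7 * 10 = 17 -> toxic, extract not an inhibitor
  rn12 <- fit_4pl(conc, generate_dose_response(12, 1.5, noise_cv = 0)$response)
  call_tox <- classify_activity(tf, rn12, "E1")
  expect_true(call_tox$toxic)
  expect_identical(call_tox$category, "cytotoxic_only")
  # renilla IC50 30 > 17 -> specific, non-toxic inhibitor
  rn30 <- fit_4pl(conc, generate_dose_response(30, 1.5, noise_cv = 0)$response)
  call_ok <- classify_activity(tf, rn30, "E2")
  expect_false(call_ok$toxic)
  expect_identical(call_ok$category, "inhibitor")
})

test_that("potent non-toxic inhibitors land in the <=5 tier", {
  conc <- screen_concentrations()
  tf4 <- fit_4pl(conc, generate_dose_response(4, 1.5, noise_cv = 0)$response)
  flat <- fit_4pl(conc, rep(1, 5))
  call <- classify_activity(tf4, flat, "E1")
  expect_identical(call$category, "inhibitor")
  expect_false(call$toxic)
  expect_identical(call$tier, "<=5")
  # flat TopFlash and flat Renilla -> inactive
  expect_identical(classify_activity(flat, flat, "E2")$category, "inactive")
  # rising TopFlash -> potentiator
  up <- fit_4pl(conc,
                generate_dose_response(10, 1.5, r0 = 1, rinf = 2.5,
                                       noise_cv = 0)$response)
  expect_identical(classify_activity(up, flat, "E3")$category, "potentiator")
})

test_that("the toxicity rule is invariant to rescaling concentrations", {
  set.seed(7)
  conc <- screen_concentrations()
  for (k in c(0.1, 10)) {
    d_tf <- generate_dose_response(10, 1.5, noise_cv = 0)
    d_rn <- generate_dose_response(12, 1.5, noise_cv = 0)
    base <- classify_activity(fit_4pl(conc, d_tf$response),
                              fit_4pl(conc, d_rn$response), "A")
    scaled <- classify_activity(fit_4pl(conc * k, d_tf$response),
                                fit_4pl(conc * k, d_rn$response), "A",
                                tier_thresholds = c(5, 10, 50) * k)
    expect_identical(scaled$toxic, base$toxic)
    expect_identical(scaled$category, base$category)
    expect_equal(scaled$topflash_ic50, base$topflash_ic50 * k,
                 tolerance = 1e-3)
  }
})

test_that("IC50 tiers are nested", {
  ics <- c(2, 4.9, 5, 7, 9.9, 20, 49, 50, 80, NA)
  tiers <- vapply(ics, ic50_tier, character(1))
  in5 <- ics[!is.na(ics)][tiers[!is.na(ics)] == "<=5"]
  in10 <- ics[!is.na(ics) & ics < 10]
  in50 <- ics[!is.na(ics) & ics < 50]
  expect_true(all(in5 %in% in10), all(in10 %in% in50))
  expect_identical(ic50_tier(NA), "none")
  expect_identical(ic50_tier(50), ">=50")
})

test_that("screen_extracts classifies a small panel against planted truth", {
  panel <- generate_screen_panel(n_curves = 40, seed = 3, noise_cv = 0.1)
  calls <- suppressWarnings(
    screen_extracts(panel$measurements, panel$controls))
  expect_identical(nrow(calls), 40L)
  acc <- mean(calls$category[match(panel$truth$extract_id,
                                   calls$extract_id)] ==
                panel$truth$category)
  expect_gte(acc, 0.85)
})
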