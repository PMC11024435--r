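# Component scores: FC, LC, CC, SC and the Priority Score.

test_that("feature component counts specific unannotated features", {
  mk <- function(n_det, annotated) {
    data.frame(feature_id = seq_along(n_det), n_extracts_detected = n_det,
               annotated = annotated)
  }
  # 100 features in a 100-extract collection: 20 specific & unannotated
  f <- mk(c(rep(5, 20), rep(60, 80)),
          c(rep(FALSE, 20), rep(TRUE, 80)))
  expect_equal(feature_component(f, 100), 0.20)
  expect_equal(feature_component(mk(rep(5, 10), rep(TRUE, 10)), 100), 0)
  expect_equal(feature_component(mk(rep(5, 10), rep(FALSE, 10)), 100), 1)
  # non-specific unannotated features do not count
  expect_equal(feature_component(mk(rep(50, 10), rep(FALSE, 10)), 100), 0)
  expect_error(feature_component(mk(numeric(0), logical(0)), 100),
               "no features")
})

test_that("feature component ignores feature ordering and duplication of the set", {
  set.seed(5)
  f <- data.frame(feature_id = 1:50,
                  n_extracts_detected = sample(1:100, 50, replace = TRUE),
                  annotated = sample(c(TRUE, FALSE), 50, replace = TRUE))
  fc1 <- feature_component(f, 100)
  fc2 <- feature_component(f[sample(50), ], 100)
  expect_equal(fc1, fc2)
  # merging an extract with an identical copy leaves the proportion fixed
  expect_equal(feature_component(rbind(f, f), 100), fc1)
})

test_that("literature component follows the capped linear ramp", {
  mk <- function(s, g, f) list(n_reported_species = s, n_reported_genus = g,
                               n_reported_family = f)
  expect_equal(literature_component(mk(0, 0, 0)), 1.0)
  expect_equal(literature_component(mk(20, 100, 500)), 0.0)
  expect_equal(literature_component(mk(1000, 1000, 1000)), 0.0)
  # species 0, genus 50, family 0 with default caps/weights
  expect_equal(literature_component(mk(0, 50, 0)),
               0.5 + 0.35 * 0.5 + 0.15)
  # monotone non-increasing in each count
  base <- literature_component(mk(5, 10, 50))
  expect_lte(literature_component(mk(6, 10, 50)), base)
  expect_lte(literature_component(mk(5, 11, 50)), base)
  expect_lte(literature_component(mk(5, 10, 51)), base)
})

test_that("the report filter uses strict inequality at both ranks", {
  mk <- function(s, g) list(n_reported_species = s, n_reported_genus = g)
  expect_true(passes_report_filter(mk(0, 5)))
  expect_true(passes_report_filter(mk(9, 9)))
  expect_false(passes_report_filter(mk(10, 0)))
  expect_false(passes_report_filter(mk(0, 10)))
  expect_false(passes_report_filter(mk(0, 100)))
})

test_that("class component flags unreported predicted classes", {
  expect_identical(class_component("flavones", "flavones"), 0L)
  expect_identical(class_component(c("flavones", "bicyclic polyketides"),
                                   "flavones"), 1L)
  expect_identical(class_component(character(0), "flavones"), 0L)
  # normalization: case and whitespace do not create spurious novelty
  expect_identical(class_component(" Flavones ", "flavones"), 0L)
  # confidence threshold empties the prediction set
  pred <- data.frame(class = "rare class", confidence = 0.2)
  expect_identical(class_component(pred, "flavones", 0.5), 0L)
  expect_identical(class_component(data.frame(class = "rare class",
                                              confidence = 0.9),
                                   "flavones", 0.5), 1L)
})

test_that("similarity component flags a planted orthogonal extract", {
  # 49 near-clone extracts + 1 with a disjoint fragment vocabulary
  set.seed(9)
  shared <- sort(runif(60, 50, 400))
  base <- generate_spectra(runif(12, 500, 900), shared)
  sp <- lapply(1:49, function(i) base[-sample(12, 1)])  # near-clones
  sp <- c(sp, list(generate_spectra(
    runif(12, 500, 900), shared,
    private_vocab = sort(runif(60, 420, 480)),
    outlier = TRUE, private_fraction = 1)))
  names(sp) <- sprintf("X%02d", 1:50)
  memo <- build_memo_matrix(sp, bin_width = 1)
  sc <- similarity_component(memo, seed = 4)
  expect_identical(unname(sc["X50"]), 1L)
  expect_identical(sum(sc[1:49]), 0L)
})

test_that("similarity component degenerates safely", {
  sp <- read_mgf(fixture_mgf())
  clones <- setNames(rep(list(sp), 12), sprintf("C%02d", 1:12))
  memo <- build_memo_matrix(clones)
  expect_identical(sum(similarity_component(memo)), 0L)
  small <- build_memo_matrix(clones[1:3])
  expect_warning(sc <- similarity_component(small), "fewer than 10")
  expect_identical(sum(sc), 0L)
})

test_that("vote rule 'any' flags a superset of 'majority'", {
  coll <- fixture_collection()
  memo <- build_memo_matrix(coll$spectra, bin_width = 1)
  maj <- similarity_component(memo, vote = "majority", seed = 2)
  any_ <- similarity_component(memo, vote = "any", seed = 2)
  expect_true(all(any_[maj == 1] == 1))
})

test_that("priority score is the weighted component sum", {
  expect_equal(priority_score(0.25, 1, 1, 1), 3.25)
  expect_equal(priority_score(0, 0, 0, 0), 0)
  # doubling w_L doubles only the LC contribution
  expect_equal(priority_score(0.25, 0.5, 1, 1,
                              c(lc = 2, cc = 1, sc = 1)) -
                 priority_score(0.25, 0.5, 1, 1),
               0.5)
  # monotone in each component
  expect_gte(priority_score(0.5, 1, 1, 1), priority_score(0.4, 1, 1, 1))
})

test_that("PS ranking is stable under joint positive weight rescaling", {
  set.seed(3)
  fc <- runif(10); lc <- runif(10); cc <- rbinom(10, 1, 0.5)
  sc <- rbinom(10, 1, 0.5)
  ps1 <- priority_score(fc, lc, cc, sc, c(lc = 0.8, cc = 1.2, sc = 1))
  # scaling all weights and FC jointly preserves the ordering
  ps2 <- 3 * fc + 3 * (0.8 * lc + 1.2 * cc + 1 * sc)
  expect_identical(order(ps1), order(ps2))
})

test_that("score_collection assembles per-extract component scores", {
  coll <- fixture_collection()
  pipe <- fixture_pipeline()
  sc <- pipe$scores
  expect_setequal(sc$extract_id, unique(coll$features$extract_id))
  expect_true(all(sc$FC >= 0 & sc$FC <= 1))
  expect_true(all(sc$LC >= 0 & sc$LC <= 1))
  expect_true(all(sc$CC %in% 0:1) && all(sc$SC %in% 0:1))
  expect_equal(sc$PS, sc$FC + sc$LC + sc$CC + sc$SC)
  # planted survivors carry a never-reported class -> CC = 1
  surv <- coll$truth$extract_id[coll$truth$survivor]
  expect_true(all(sc$CC[sc$extract_id %in% surv] == 1))
})
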