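# MGF parsing and MEMO fingerprints.

test_that("MGF reader parses blocks, precursors and peaks", {
  path <- fixture_mgf()
  sp <- read_mgf(path)
  expect_length(sp, 3)
  expect_identical(sp[[1]]$feature_id, "F1")
  expect_equal(sp[[1]]$precursor_mz, 479.2793)
  expect_identical(nrow(sp[[1]]$peaks), 5L)
  # PEPMASS with trailing intensity field
  expect_equal(sp[[2]]$precursor_mz, 300.15)
  expect_true(all(diff(sp[[1]]$peaks[, "mz"]) > 0))
})

test_that("MGF reader flags malformed input with a line number", {
  bad <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100.0", "50.0 10"), bad)
  expect_error(read_mgf(bad), "unterminated.*line 1")
  writeLines(c("BEGIN IONS", "PEPMASS=100.0", "50.0 xx", "END IONS"), bad)
  expect_error(read_mgf(bad), "line 3")
  empty <- tempfile(fileext = ".mgf")
  writeLines(character(0), empty)
  expect_length(read_mgf(empty), 0)
  expect_error(read_mgf(tempfile()), "no such file")
})

test_that("MGF writer round-trips spectra", {
  sp <- read_mgf(fixture_mgf())
  out <- tempfile(fileext = ".mgf")
  write_mgf(sp, out)
  sp2 <- read_mgf(out)
  expect_length(sp2, 3)
  expect_equal(sp2[[1]]$precursor_mz, sp[[1]]$precursor_mz, tolerance = 1e-6)
  expect_equal(sp2[[1]]$peaks[, "mz"], unname(sp[[1]]$peaks[, "mz"]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("memo vectors count peaks and in-range losses", {
  s <- list(list(feature_id = "a", precursor_mz = 200,
                 peaks = cbind(mz = 100, intensity = 1)))
  v <- memo_vector(s, bin_width = 0.01, loss_range = c(10, 200))
  expect_identical(v, c(`loss@100.00` = 1L, `peak@100.00` = 1L))
  expect_length(memo_vector(list()), 0)
  # two identical spectra double every count (additivity)
  v2 <- memo_vector(c(s, s))
  expect_identical(v2[names(v)], 2L * v)
  # a loss outside [10, 200] contributes only its peak token
  s2 <- list(list(feature_id = "b", precursor_mz = 205,
                  peaks = cbind(mz = 200, intensity = 1)))
  v3 <- memo_vector(s2)
  expect_identical(names(v3), "peak@200.00")
})

test_that("memo vector is additive over concatenated spectrum lists", {
  coll <- fixture_collection()
  a <- coll$spectra[[1]][1:5]; b <- coll$spectra[[1]][6:10]
  va <- memo_vector(a); vb <- memo_vector(b); vab <- memo_vector(c(a, b))
  toks <- union(names(va), names(vb))
  get <- function(v, t) ifelse(t %in% names(v), v[t], 0L)
  for (t in toks) {
    expect_identical(unname(get(vab, t)),
                     unname(get(va, t)) + unname(get(vb, t)))
  }
})

test_that("memo matrix rows identify clones and orthogonal extracts", {
  sp <- read_mgf(fixture_mgf())
  disjoint <- list(list(feature_id = "z", precursor_mz = 900,
                        peaks = cbind(mz = c(600.5, 700.5),
                                      intensity = c(1, 1))))
  m <- build_memo_matrix(list(a = sp, b = sp, c = disjoint))
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_equal(row_cosine(m["a", ], m["b", ]), 1.0)
  expect_equal(row_cosine(m["a", ], m["c", ]), 0.0)
  expect_error(build_memo_matrix(list(a = sp, a = sp)), "duplicate")
})

test_that("memo matrix is invariant to extract input order", {
  coll <- fixture_collection()
  sub <- coll$spectra[1:6]
  m1 <- build_memo_matrix(sub)
  m2 <- build_memo_matrix(rev(sub))
  expect_identical(m1, m2)
})

test_that("halving the bin width never decreases the token vocabulary", {
  coll <- fixture_collection()
  sub <- coll$spectra[1:6]
  for (bw in c(1, 0.1, 0.02)) {
    wide <- build_memo_matrix(sub, bin_width = bw)
    narrow <- build_memo_matrix(sub, bin_width = bw / 2)
    expect_gte(ncol(narrow), ncol(wide))
  }
})

test_that("ion-map summary reports annotation status counts", {
  f <- data.frame(feature_id = sprintf("F%02d", 1:10),
                  rt = seq(0.5, 5, length.out = 10),
                  mz = seq(150, 800, length.out = 10),
                  intensity = 10^(3:12),
                  annotated = rep(c(TRUE, FALSE), c(4, 6)))
  s <- ionmap_summary(f, "E1")
  expect_identical(nrow(s), 10L)
  expect_identical(attr(s, "n_annotated"), 4L)
  expect_identical(attr(s, "n_unannotated"), 6L)
  empty <- ionmap_summary(f[0, ])
  expect_identical(nrow(empty), 0L)
  # an extract built at 75% annotation rate reports exactly 0.75
  f75 <- data.frame(feature_id = sprintf("F%02d", 1:20), rt = 1, mz = 200,
                    intensity = 1, annotated = rep(c(TRUE, FALSE), c(15, 5)))
  expect_equal(attr(ionmap_summary(f75), "annotation_rate"), 0.75)
})

test_that("memo TSV serialization round-trips", {
  coll <- fixture_collection()
  m <- build_memo_matrix(coll$spectra[1:4])
  path <- tempfile(fileext = ".tsv")
  write_memo_tsv(m, path)
  m2 <- read_memo_tsv(path)
  expect_equal(unclass(m)[, ], unclass(m2)[, ], ignore_attr = FALSE)
})
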