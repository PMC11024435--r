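# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# small synthetic collection reused across spectral / novelty / cascade tests
fixture_collection <- function() {
  if (is.null(.fixture_env$coll)) {
    .fixture_env$coll <- generate_collection(scenario_config(
      n_extracts = 60, seed = 101L, n_outliers = 4L, n_survivors = 2L))
  }
  .fixture_env$coll
}

fixture_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    .fixture_env$pipe <- suppressWarnings(
      run_pipeline(fixture_collection(), quiet = TRUE))
  }
  .fixture_env$pipe
}

# tiny 3-spectrum MGF written to a temp file
fixture_mgf <- function(path = tempfile(fileext = ".mgf")) {
  writeLines(c(
    "BEGIN IONS",
    "FEATURE_ID=F1",
    "PEPMASS=479.2793",
    "100.1 500", "151.2 900", "200.3 150", "310.4 80", "461.2 1200",
    "END IONS",
    "",
    "BEGIN IONS",
    "FEATURE_ID=F2",
    "PEPMASS=300.15 12345",
    "120.05 10", "150.1 20",
    "END IONS",
    "",
    "BEGIN IONS",
    "FEATURE_ID=F3",
    "PEPMASS=200.0",
    "100.0 1.0",
    "END IONS"), path)
  path
}

# minimal joined tables for cascade tests: extracts with every combination
# of passing/failing the four filters
fixture_cascade_tables <- function() {
  ids <- sprintf("E%02d", 1:16)
  grid <- expand.grid(bio = c(TRUE, FALSE), sc = c(TRUE, FALSE),
                      lit = c(TRUE, FALSE), cc = c(TRUE, FALSE))
  calls <- data.frame(
    extract_id = ids,
    category = ifelse(grid$bio, "inhibitor", "inactive"),
    topflash_ic50 = ifelse(grid$bio, 3, NA_real_),
    topflash_flag = ifelse(grid$bio, "estimable", "not_estimable"),
    renilla_ic50 = NA_real_, renilla_flag = "not_estimable",
    toxic = FALSE, tier = ifelse(grid$bio, "<=5", "none"),
    stringsAsFactors = FALSE)
  scores <- data.frame(
    extract_id = ids, FC = seq(0.9, 0.15, length.out = 16),
    LC = 0.8, CC = as.integer(grid$cc), SC = as.integer(grid$sc),
    stringsAsFactors = FALSE)
  scores$PS <- with(scores, FC + LC + CC + SC)
  taxa <- data.frame(
    extract_id = ids, species = paste("Sp", ids), genus = "G", family = "F",
    n_reported_species = ifelse(grid$lit, 2, 40),
    n_reported_genus = ifelse(grid$lit, 5, 120),
    n_reported_family = 300,
    reported_classes = "flavones;lignans",
    stringsAsFactors = FALSE)
  list(calls = calls, scores = scores, taxa = taxa,
       pass_all = ids[grid$bio & grid$sc & grid$lit & grid$cc])
}

# random cascade inputs for fuzz/property tests
random_cascade_tables <- function(n = 30) {
  ids <- sprintf("R%03d", seq_len(n))
  calls <- data.frame(
    extract_id = ids,
    category = sample(c("inhibitor", "potentiator", "cytotoxic_only",
                        "inactive"), n, replace = TRUE),
    topflash_ic50 = ifelse(stats::runif(n) < 0.8,
                           stats::runif(n, 0.5, 60), NA_real_),
    topflash_flag = "estimable", renilla_ic50 = NA_real_,
    renilla_flag = "not_estimable",
    toxic = stats::runif(n) < 0.2, tier = "none",
    stringsAsFactors = FALSE)
  scores <- data.frame(
    extract_id = ids, FC = stats::runif(n), LC = stats::runif(n),
    CC = sample(0:1, n, replace = TRUE), SC = sample(0:1, n, replace = TRUE),
    stringsAsFactors = FALSE)
  scores$PS <- with(scores, FC + LC + CC + SC)
  taxa <- data.frame(
    extract_id = ids, species = ids, genus = "G", family = "F",
    n_reported_species = stats::rpois(n, 8),
    n_reported_genus = stats::rpois(n, 12),
    n_reported_family = stats::rpois(n, 100),
    reported_classes = "flavones",
    stringsAsFactors = FALSE)
  list(calls = calls, scores = scores, taxa = taxa)
}
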