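# Configuration, table readers, and the top-level pipeline chaining
# simulate -> screen -> fingerprint -> score -> prioritize.

#' Pipeline configuration
#'
#' All thresholds of the prioritization pipeline in one place. Defaults are
#' the screen's stated values where one exists: IC50 tiers 5/10/50 ug/mL,
#' the 1.7x Renilla toxicity ratio, strictly fewer than 10 literature
#' reports at species and genus level, SC = 1 and CC = 1 as cascade
#' requirements. The configuration round-trips through YAML.
#'
#' @param ... Overrides of the listed defaults.
#' @return Named list (class \code{pipeline_config}).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tier_thresholds = c(5, 10, 50),  # ug/mL
    toxicity_ratio = 1.7,
    effect_floor = 0.3,
    max_reports = 10,
    specificity_pct = 10,
    bin_width = 0.01,                # Da
    loss_range = c(10, 200),         # Da
    detectors = c("lof", "iforest", "ocsvm"),
    vote = "majority",
    n_components = 10,
    lc_caps = c(species = 20, genus = 100, family = 500),
    lc_weights = c(species = 0.5, genus = 0.35, family = 0.15),
    min_class_confidence = 0.5,
    ps_weights = c(lc = 1, cc = 1, sc = 1),
    max_ic50 = 5,                    # ug/mL, cascade bioactivity stage
    require_sc = 1L,
    require_cc = 1L,
    exclude = character(0),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg A \code{pipeline_config}.
#' @param path YAML file path.
#' @return The configuration (read) or \code{path} (write, invisibly).
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  # named numeric vectors must serialize as YAML maps, not bare sequences
  for (nm in c("lc_caps", "lc_weights", "ps_weights")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("tier_thresholds", "loss_range")) {
    raw[[nm]] <- as.numeric(raw[[nm]])
  }
  for (nm in c("lc_caps", "lc_weights", "ps_weights")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("exclude", "detectors")) {
    raw[[nm]] <- as.character(unlist(raw[[nm]]))
  }
  raw$require_sc <- as.integer(raw$require_sc)
  raw$require_cc <- as.integer(raw$require_cc)
  raw$seed <- as.integer(raw$seed)
  do.call(pipeline_config, raw)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read the scenario input tables
#'
#' Readers for the pipeline's plain-text interchange formats, validating
#' the documented column contracts.
#'
#' @param dir Scenario directory as written by \code{\link{write_scenario}}.
#' @return \code{read_scenario()} returns a list with \code{features},
#'   \code{taxa}, \code{measurements}, \code{controls}, \code{spectra}.
#' @export
read_scenario <- function(dir) {
  need <- c("features.tsv", "annotations.tsv", "taxa.tsv", "screening.csv",
            "controls.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("scenario directory is missing: ", paste(missing, collapse = ", "))
  }
  rt <- function(name) {
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  features <- .require_columns(rt("features.tsv"),
                               c("extract_id", "feature_id", "mz", "rt",
                                 "intensity", "n_extracts_detected"),
                               "features.tsv")
  ann <- .require_columns(rt("annotations.tsv"),
                          c("extract_id", "feature_id", "annotated",
                            "annotation_score", "predicted_class",
                            "class_confidence"),
                          "annotations.tsv")
  features <- merge(features, ann, by = c("extract_id", "feature_id"),
                    sort = TRUE)
  taxa <- .require_columns(rt("taxa.tsv"),
                           c("extract_id", "species", "genus", "family",
                             "n_reported_species", "n_reported_genus",
                             "n_reported_family", "reported_classes"),
                           "taxa.tsv")
  measurements <- .require_columns(
    utils::read.csv(file.path(dir, "screening.csv"),
                    stringsAsFactors = FALSE),
    c("extract_id", "channel", "concentration", "luminescence"),
    "screening.csv")
  ctrl <- utils::read.csv(file.path(dir, "controls.csv"),
                          stringsAsFactors = FALSE)
  controls <- stats::setNames(ctrl$luminescence, ctrl$channel)
  mgf_dir <- file.path(dir, "mgf")
  spectra <- NULL
  if (dir.exists(mgf_dir)) {
    paths <- sort(list.files(mgf_dir, pattern = "\\.mgf$",
                             full.names = TRUE))
    spectra <- stats::setNames(lapply(paths, read_mgf),
                               sub("\\.mgf$", "", basename(paths)))
  }
  list(features = features, taxa = taxa, measurements = measurements,
       controls = controls, spectra = spectra)
}

#' Run the full prioritization pipeline
#'
#' Chains the stages screen (dose-response fits and activity calls),
#' fingerprint (MEMO matrix), score (FC/LC/CC/SC and PS) and prioritize
#' (selection cascade) on an in-memory collection or a scenario directory,
#' logging per-stage counts.
#'
#' @param x A \code{synthetic_collection}, a list as returned by
#'   \code{\link{read_scenario}}, or a scenario directory path.
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional directory for intermediate tables (activity
#'   calls TSV, MEMO TSV, scores TSV, funnel JSON).
#' @param quiet Suppress stage logging.
#' @return List: \code{calls}, \code{memo}, \code{scores},
#'   \code{report} (a \code{cascade_report}), \code{tier_summary}.
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(x)) x <- read_scenario(x)
  stopifnot(is.list(x), !is.null(x$features), !is.null(x$taxa),
            !is.null(x$measurements), !is.null(x$spectra))
  log <- function(...) if (!quiet) message(sprintf(...))

  log("screen: fitting %d extracts",
      length(unique(x$measurements$extract_id)))
  calls <- screen_extracts(x$measurements, controls = x$controls,
                           effect_floor = config$effect_floor,
                           toxicity_ratio = config$toxicity_ratio,
                           tier_thresholds = config$tier_thresholds)
  ts <- tier_summary(calls, config$tier_thresholds)
  log("screen: %d active (%s)", ts$n_active,
      paste(names(ts$categories), ts$categories, collapse = ", "))

  log("fingerprint: building MEMO matrix (bin %.3g Da)", config$bin_width)
  memo <- build_memo_matrix(x$spectra, bin_width = config$bin_width,
                            loss_range = config$loss_range)
  log("fingerprint: %d extracts x %d tokens", nrow(memo), ncol(memo))

  log("score: computing FC/LC/CC/SC and PS")
  scores <- score_collection(
    x$features, x$taxa, memo,
    specificity_pct = config$specificity_pct,
    lc_caps = config$lc_caps, lc_weights = config$lc_weights,
    min_class_confidence = config$min_class_confidence,
    ps_weights = config$ps_weights, seed = config$seed)

  report <- run_cascade(calls, scores, x$taxa,
                        config = list(max_ic50 = config$max_ic50,
                                      require_sc = config$require_sc,
                                      max_reports = config$max_reports,
                                      require_cc = config$require_cc,
                                      exclude = config$exclude))
  for (i in seq_len(nrow(report$stages))) {
    log("cascade: %-13s %5d (%s)", report$stages$stage[i],
        report$stages$n_surviving[i], report$stages$criterion[i])
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(calls, "activity_calls.tsv")
    write_memo_tsv(memo, file.path(out_dir, "memo_matrix.tsv"))
    wt(scores, "component_scores.tsv")
    wt(report$shortlist, "shortlist.tsv")
    cascade_report_json(report, file.path(out_dir, "funnel.json"))
  }
  list(calls = calls, memo = memo, scores = scores, report = report,
       tier_summary = ts)
}
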