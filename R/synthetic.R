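# Synthetic extract collections with planted ground truth: features, MS2
# spectra, annotations, taxon literature counts and dual-luciferase
# dose-response plates, exercising every pipeline stage without any
# external data.

#' Scenario configuration for the synthetic generator
#'
#' Defaults mirror the screened-collection structure the pipeline targets:
#' activity base rates of roughly 31\% active, split into potentiators,
#' inhibitors and solely cytotoxic extracts in the proportions
#' 148:241:108, with about 1 in 8 inhibitors potent at or below 5 ug/mL;
#' single-replicate five-point plates at 50/25/12.5/6/3 ug/mL with 10\%
#' multiplicative noise; 5\% spectral outliers; and 4 planted extracts
#' engineered to survive the full cascade.
#'
#' @param n_extracts Collection size.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param n_outliers Planted spectral outliers (>= n_survivors).
#' @param n_survivors Planted full-cascade survivors.
#' @param noise_cv Multiplicative (lognormal) luminescence noise CV.
#' @param ... Overrides for any other listed default.
#' @return Named list (class \code{scenario_config}).
#' @export
scenario_config <- function(n_extracts = 200, seed = 42L,
                            n_outliers = max(1L, round(0.05 * n_extracts)),
                            n_survivors = 4L, noise_cv = 0.1, ...) {
  cfg <- list(
    n_extracts = as.integer(n_extracts),
    seed = as.integer(seed),
    # activity base rates (screened-collection proportions)
    p_active = 497 / 1600,
    p_potentiator = 148 / 497,
    p_inhibitor = 241 / 497,
    p_cytotoxic = 108 / 497,
    # inhibitor potency-tier mix (<=5, 5-10, 10-50, >50 ug/mL), as the
    # screened collection reports its 241 inhibitors
    inhibitor_tier_probs = c(potent = 30, low = 23, mid = 79,
                             beyond = 109) / 241,
    concentrations = c(50, 25, 12.5, 6, 3),
    noise_cv = noise_cv,
    # features
    n_features_mean = 80,
    n_shared_features = 300,
    shared_feature_fraction = 0.6,
    annotation_rate = 0.4,
    survivor_annotation_rate = 0.1,
    mz_range = c(100, 1000),
    rt_range = c(0.5, 7.0),
    # spectra / MEMO vocabulary
    n_spectra_per_extract = 20,
    fragments_per_spectrum = c(6, 12),
    shared_vocab_size = 400,
    outlier_vocab_size = 4000,
    outlier_private_fraction = 0.8,
    vocab_mz_range = c(50, 450),
    # planted truth
    n_outliers = as.integer(n_outliers),
    n_survivors = as.integer(n_survivors),
    # taxon literature counts
    class_vocabulary = c(
      "flavones", "flavanones", "isoflavonoids", "diterpenoids",
      "triterpenoids", "sesquiterpenoids", "steroidal alkaloids",
      "indole alkaloids", "lignans", "coumarins", "anthraquinones",
      "phloroglucinols", "acylphloroglucinols", "chalcones",
      "xanthones", "saponins")
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$n_outliers > cfg$n_extracts) {
    stop("more planted outliers than extracts")
  }
  if (cfg$n_survivors > cfg$n_outliers) {
    stop("planted survivors must be a subset of the planted outliers")
  }
  structure(cfg, class = c("scenario_config", "list"))
}

# lognormal multiplicative noise with unit mean and the given CV
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one dose-response plate channel
#'
#' Mean response on a 4PL curve times lognormal multiplicative noise with
#' the given CV (unit mean, so noise-free data sit exactly on the curve).
#'
#' @param true_ic50 True IC50/EC50 (> 0), same units as concentrations.
#' @param hill Hill slope (> 0).
#' @param r0,rinf Zero-dose and infinite-dose asymptotes
#'   (fraction of control).
#' @param noise_cv Noise coefficient of variation (0 = noise-free).
#' @param concentrations Tested concentrations.
#' @param seed Optional seed applied locally.
#' @return data.frame: concentration, response.
#' @export
generate_dose_response <- function(true_ic50, hill = 1, r0 = 1, rinf = 0,
                                   noise_cv = 0.1,
                                   concentrations = c(50, 25, 12.5, 6, 3),
                                   seed = NULL) {
  stopifnot(true_ic50 > 0, hill > 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- .fpl(concentrations, r0, rinf, hill, true_ic50)
  data.frame(concentration = concentrations,
             response = mu * .ln_noise(length(concentrations), noise_cv))
}

#' Simulate one extract's MS2 spectra
#'
#' Ordinary extracts draw fragment m/z values from the collection's shared
#' vocabulary; planted outliers draw at least
#' \code{outlier_private_fraction} of their fragments from a private,
#' disjoint vocabulary, making their MEMO fingerprint dissimilar from the
#' rest of the collection. Precursor m/z always exceeds every fragment.
#'
#' @param precursors Precursor m/z values, one spectrum each.
#' @param shared_vocab Numeric vector of shared fragment m/z values.
#' @param private_vocab Private fragment m/z values (outliers only).
#' @param outlier Logical: sample mostly from the private vocabulary.
#' @param private_fraction Minimum private share for outliers.
#' @param n_fragments Length-2 range of fragments per spectrum.
#' @return List of MS2 spectra (see \code{\link{read_mgf}}).
#' @export
generate_spectra <- function(precursors, shared_vocab,
                             private_vocab = numeric(0), outlier = FALSE,
                             private_fraction = 0.8,
                             n_fragments = c(6, 12)) {
  if (outlier && !length(private_vocab)) {
    stop("outlier extract requires a non-empty private vocabulary")
  }
  lapply(seq_along(precursors), function(i) {
    prec <- precursors[i]
    nf <- sample(n_fragments[1]:n_fragments[2], 1)
    pool_shared <- shared_vocab[shared_vocab < prec - 1]
    pool_priv <- private_vocab[private_vocab < prec - 1]
    frags <- if (outlier) {
      n_priv <- ceiling(private_fraction * nf)
      c(sample(pool_priv, min(n_priv, length(pool_priv)), replace = TRUE),
        sample(pool_shared, max(0, nf - n_priv), replace = TRUE))
    } else {
      sample(pool_shared, min(nf, length(pool_shared)), replace = TRUE)
    }
    frags <- sort(unique(frags))
    list(feature_id = sprintf("spec_%04d", i), precursor_mz = prec,
         peaks = cbind(mz = frags,
                       intensity = stats::runif(length(frags), 1e3, 1e6)))
  })
}

# sample per-extract activity categories and true IC50s under the
# configured base rates; survivors forced to potent non-toxic inhibitors
.sample_activity_truth <- function(cfg, ids, survivors) {
  n <- length(ids)
  category <- character(n); names(category) <- ids
  active <- stats::runif(n) < cfg$p_active
  split <- stats::runif(n)
  category[!active] <- "inactive"
  category[active & split < cfg$p_potentiator] <- "potentiator"
  category[active & split >= cfg$p_potentiator &
             split < cfg$p_potentiator + cfg$p_inhibitor] <- "inhibitor"
  category[active & split >= cfg$p_potentiator + cfg$p_inhibitor] <-
    "cytotoxic_only"
  category[survivors] <- "inhibitor"

  tf_ic50 <- rep(NA_real_, n); names(tf_ic50) <- ids
  rn_ic50 <- rep(NA_real_, n); names(rn_ic50) <- ids
  potent <- stats::setNames(rep(FALSE, n), ids)
  for (id in ids) {
    ct <- category[id]
    if (ct == "inhibitor") {
      # IC50 tier mix follows the screened collection's reported tiers:
      # of 241 inhibitors, 30 at <=5, 23 more at <10, 79 more at <50,
      # and the remainder beyond the tested range
      tier <- if (id %in% survivors) "potent"
              else sample(names(cfg$inhibitor_tier_probs), 1,
                          prob = cfg$inhibitor_tier_probs)
      potent[id] <- tier == "potent"
      tf_ic50[id] <- switch(tier,
                            potent = stats::runif(1, 1.5, 4.5),
                            low = stats::runif(1, 5.2, 9.8),
                            mid = stats::runif(1, 10.5, 48),
                            beyond = stats::runif(1, 55, 120))
    } else if (ct == "potentiator") {
      tf_ic50[id] <- stats::runif(1, 5, 40)
    } else if (ct == "cytotoxic_only") {
      tf_ic50[id] <- stats::runif(1, 2, 40)
      rn_ic50[id] <- tf_ic50[id] * stats::runif(1, 0.6, 1.2)
    }
  }
  data.frame(
    extract_id = ids, category = unname(category),
    true_topflash_ic50 = unname(tf_ic50),
    true_renilla_ic50 = unname(rn_ic50),
    toxic = unname(!is.na(rn_ic50) & rn_ic50 < 1.7 * tf_ic50),
    stringsAsFactors = FALSE)
}

# simulate both reporter channels for every extract of a truth table
.generate_plates <- function(truth, cfg) {
  conc <- cfg$concentrations
  meas <- list()
  for (i in seq_len(nrow(truth))) {
    id <- truth$extract_id[i]
    ct <- truth$category[i]
    hill <- stats::runif(1, 0.8, 2)
    tf <- switch(ct,
      inactive = data.frame(concentration = conc,
                            response = .ln_noise(length(conc), cfg$noise_cv)),
      inhibitor = ,
      cytotoxic_only = generate_dose_response(
        truth$true_topflash_ic50[i], hill, r0 = 1,
        rinf = stats::runif(1, 0, 0.12), noise_cv = cfg$noise_cv,
        concentrations = conc),
      potentiator = generate_dose_response(
        truth$true_topflash_ic50[i], hill, r0 = 1,
        rinf = stats::runif(1, 2, 3.5), noise_cv = cfg$noise_cv,
        concentrations = conc))
    rn <- if (ct == "cytotoxic_only") {
      generate_dose_response(truth$true_renilla_ic50[i], hill, r0 = 1,
                             rinf = stats::runif(1, 0, 0.12),
                             noise_cv = cfg$noise_cv, concentrations = conc)
    } else {
      data.frame(concentration = conc,
                 response = .ln_noise(length(conc), cfg$noise_cv))
    }
    meas[[id]] <- rbind(
      data.frame(extract_id = id, channel = "topflash", tf,
                 stringsAsFactors = FALSE),
      data.frame(extract_id = id, channel = "renilla", rn,
                 stringsAsFactors = FALSE))
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL
  measurements
}

#' Generate a screening panel only
#'
#' Draws activity categories and true IC50s under the configured base
#' rates and simulates the five-point dual-luciferase plates, without
#' features, spectra or taxa — the input for dose-response parameter-
#' recovery studies.
#'
#' @param n_curves Number of extracts (curve pairs).
#' @param seed Integer seed.
#' @param noise_cv Multiplicative noise CV.
#' @return List with \code{truth}, \code{measurements}, \code{controls}.
#' @export
generate_screen_panel <- function(n_curves = 500, seed = 1L,
                                  noise_cv = 0.1) {
  cfg <- scenario_config(n_extracts = n_curves, seed = seed,
                         noise_cv = noise_cv, n_survivors = 0L,
                         n_outliers = 0L)
  set.seed(cfg$seed)
  ids <- sprintf("NE%04d", seq_len(n_curves))
  truth <- .sample_activity_truth(cfg, ids, character(0))
  measurements <- .generate_plates(truth, cfg)
  controls <- c(topflash = 20000, renilla = 15000)
  measurements$luminescence <-
    measurements$response * unname(controls[measurements$channel])
  measurements$replicate <- 1L
  list(truth = truth, measurements = measurements, controls = controls)
}

#' Generate a complete synthetic extract collection
#'
#' Produces every input the prioritization pipeline consumes — feature
#' table, per-extract MS2 spectra, taxon literature table,
#' dual-luciferase screening plate — together with the planted ground
#' truth (activity category, true IC50s, spectral-outlier flag, expected
#' cascade survival). Identical seeds give identical collections.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return List (class \code{synthetic_collection}): \code{features},
#'   \code{spectra} (named list per extract), \code{taxa},
#'   \code{measurements} (long plate table), \code{controls},
#'   \code{truth} (per-extract data.frame), \code{config}.
#' @export
generate_collection <- function(config = scenario_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_extracts
  ids <- sprintf("NE%04d", seq_len(n))

  # ---- planted truth: categories, IC50s, outliers, survivors -------------
  survivors <- ids[seq_len(cfg$n_survivors)]
  outliers <- ids[seq_len(cfg$n_outliers)]  # survivors are outliers too
  # shuffle id order so planted extracts are not positionally special
  ids <- sample(ids)

  truth <- .sample_activity_truth(cfg, ids, survivors)
  truth$outlier <- truth$extract_id %in% outliers
  truth$survivor <- truth$extract_id %in% survivors

  # ---- dose-response plates ---------------------------------------------
  measurements <- .generate_plates(truth, cfg)
  # express as raw luminescence against per-channel controls
  controls <- c(topflash = 20000, renilla = 15000)
  measurements$luminescence <-
    measurements$response * unname(controls[measurements$channel])
  measurements$replicate <- 1L

  # ---- features and annotations -----------------------------------------
  shared_pool <- data.frame(
    feature_id = sprintf("FT%05d", seq_len(cfg$n_shared_features)),
    mz = stats::runif(cfg$n_shared_features, cfg$mz_range[1], cfg$mz_range[2]),
    rt = stats::runif(cfg$n_shared_features, cfg$rt_range[1], cfg$rt_range[2]),
    stringsAsFactors = FALSE)
  next_private <- cfg$n_shared_features
  feat_rows <- list()
  for (id in ids) {
    n_feat <- max(5L, stats::rpois(1, cfg$n_features_mean))
    n_shared <- round(cfg$shared_feature_fraction * n_feat)
    n_priv <- n_feat - n_shared
    sh <- shared_pool[sample.int(nrow(shared_pool), min(n_shared,
                                                        nrow(shared_pool))), ]
    pv <- data.frame(
      feature_id = sprintf("FT%05d", next_private + seq_len(n_priv)),
      mz = stats::runif(n_priv, cfg$mz_range[1], cfg$mz_range[2]),
      rt = stats::runif(n_priv, cfg$rt_range[1], cfg$rt_range[2]),
      stringsAsFactors = FALSE)
    next_private <- next_private + n_priv
    f <- rbind(sh, pv)
    f$extract_id <- id
    f$intensity <- stats::rlnorm(nrow(f), meanlog = 12, sdlog = 1.5)
    ann_rate <- if (id %in% survivors) cfg$survivor_annotation_rate
                else cfg$annotation_rate
    f$private <- c(rep(FALSE, nrow(sh)), rep(TRUE, n_priv))
    # survivors keep their private (specific) features unannotated
    p_ann <- ifelse(f$private & id %in% survivors, 0.02, ann_rate)
    f$annotated <- stats::runif(nrow(f)) < p_ann
    f$annotation_score <- ifelse(f$annotated, stats::runif(nrow(f), 0.6, 1),
                                 stats::runif(nrow(f), 0, 0.4))
    feat_rows[[id]] <- f
  }
  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL
  det <- table(unique(features[, c("feature_id", "extract_id")])$feature_id)
  features$n_extracts_detected <- as.integer(det[features$feature_id])

  # ---- taxon table and predicted classes --------------------------------
  classes <- cfg$class_vocabulary
  taxa_rows <- list()
  pred_class <- character(nrow(features))
  pred_conf <- stats::runif(nrow(features), 0.5, 1)
  genus_pool <- sprintf("Genus%03d", seq_len(ceiling(n / 3)))
  family_pool <- sprintf("Family%02d", seq_len(ceiling(n / 10)))
  for (i in seq_along(ids)) {
    id <- ids[i]
    surv <- id %in% survivors
    reported <- sample(classes, sample(3:6, 1))
    if (surv) {
      n_sp <- sample(0:5, 1); n_ge <- n_sp + sample(0:3, 1)
    } else {
      n_sp <- stats::rnbinom(1, size = 0.8, mu = 30)
      n_ge <- n_sp + stats::rnbinom(1, size = 0.8, mu = 60)
    }
    n_fa <- n_ge + stats::rnbinom(1, size = 0.8, mu = 250)
    taxa_rows[[id]] <- data.frame(
      extract_id = id, species = sprintf("Species %s", id),
      genus = sample(genus_pool, 1), family = sample(family_pool, 1),
      n_reported_species = n_sp, n_reported_genus = n_ge,
      n_reported_family = n_fa,
      reported_classes = paste(reported, collapse = ";"),
      stringsAsFactors = FALSE)
    idx <- which(features$extract_id == id)
    # most predictions recapitulate the reported chemistry; survivors carry
    # a class never reported for their taxon (novel_class token)
    pool <- if (surv) c(reported, paste0("novel_", id)) else reported
    pred_class[idx] <- sample(pool, length(idx), replace = TRUE)
    if (surv) {
      pick <- sample(idx, max(3, length(idx) %/% 10))
      pred_class[pick] <- paste0("novel_", id)
      pred_conf[pick] <- stats::runif(length(pick), 0.7, 1)
    }
  }
  features$predicted_class <- pred_class
  features$class_confidence <- pred_conf
  taxa <- do.call(rbind, taxa_rows)
  rownames(taxa) <- NULL

  # ---- MS2 spectra -------------------------------------------------------
  shared_vocab <- sort(stats::runif(cfg$shared_vocab_size,
                                    cfg$vocab_mz_range[1],
                                    cfg$vocab_mz_range[2]))
  outlier_vocab <- sort(stats::runif(cfg$outlier_vocab_size,
                                     cfg$vocab_mz_range[1],
                                     cfg$vocab_mz_range[2]) + 500)
  spectra <- list()
  for (id in ids) {
    f <- features[features$extract_id == id, ]
    eligible <- f$mz[f$mz > cfg$vocab_mz_range[2] + 20]
    if (length(eligible) < cfg$n_spectra_per_extract) {
      eligible <- c(eligible,
                    stats::runif(cfg$n_spectra_per_extract - length(eligible),
                                 cfg$vocab_mz_range[2] + 50, cfg$mz_range[2]))
    }
    prec <- sample(eligible, cfg$n_spectra_per_extract)
    is_out <- id %in% outliers
    priv <- if (is_out) {
      sample(outlier_vocab, 80)  # per-extract slice: outliers are also
    } else numeric(0)            # dissimilar from one another
    # outlier precursors must clear the shifted private vocabulary
    if (is_out) prec <- prec + max(0, (max(priv) + 50) - min(prec))
    spectra[[id]] <- generate_spectra(
      prec, shared_vocab, private_vocab = priv, outlier = is_out,
      private_fraction = cfg$outlier_private_fraction,
      n_fragments = cfg$fragments_per_spectrum)
  }

  structure(list(features = features, spectra = spectra, taxa = taxa,
                 measurements = measurements, controls = controls,
                 truth = truth, config = cfg),
            class = c("synthetic_collection", "list"))
}

#' Write a synthetic collection to a scenario directory
#'
#' Emits the plain-text input files the pipeline consumes: per-extract MGF
#' spectra, feature/annotation TSV, taxon TSV, long-format screening CSV,
#' and the planted truth as JSON.
#'
#' @param collection A \code{\link{generate_collection}} result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_scenario <- function(collection, dir) {
  dir.create(file.path(dir, "mgf"), recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  feat <- collection$features
  wt(feat[, c("extract_id", "feature_id", "mz", "rt", "intensity",
              "n_extracts_detected")], "features.tsv")
  wt(feat[, c("extract_id", "feature_id", "annotated", "annotation_score",
              "predicted_class", "class_confidence")], "annotations.tsv")
  wt(collection$taxa, "taxa.tsv")
  m <- collection$measurements
  utils::write.csv(m[, c("extract_id", "channel", "concentration",
                         "luminescence", "replicate")],
                   file.path(dir, "screening.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(channel = names(collection$controls),
               luminescence = unname(collection$controls)),
    file.path(dir, "controls.csv"), row.names = FALSE)
  for (id in names(collection$spectra)) {
    write_mgf(collection$spectra[[id]], file.path(dir, "mgf",
                                                  paste0(id, ".mgf")))
  }
  jsonlite::write_json(collection$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
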