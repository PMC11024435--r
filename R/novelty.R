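# The four per-extract structural-novelty component scores — Feature (FC),
# Literature (LC), Class (CC), Similarity (SC) — and the combined Priority
# Score (PS).

#' Feature Component (FC)
#'
#' Fraction of an extract's features that are both \emph{specific} to the
#' extract within the collection (detected in at most \code{specificity_pct}
#' percent of extracts) and structurally \emph{unannotated} (no annotation
#' at or above \code{annotation_threshold}).
#'
#' @param features data.frame of the extract's features with columns
#'   \code{n_extracts_detected} (or list-column \code{extracts_detected_in})
#'   and \code{annotated} (logical) or \code{annotation_score}.
#' @param n_extracts Number of extracts in the collection.
#' @param specificity_pct Specificity threshold, percent of the collection
#'   (default 10).
#' @param annotation_threshold Minimum annotation score to count a feature
#'   as annotated, used when \code{annotated} is absent.
#' @return FC in [0, 1].
#' @export
feature_component <- function(features, n_extracts, specificity_pct = 10,
                              annotation_threshold = 0.6) {
  if (!nrow(features)) stop("extract has no features; exclude it upstream")
  annotated <- if ("annotated" %in% names(features)) {
    as.logical(features$annotated)
  } else if ("annotation_score" %in% names(features)) {
    !is.na(features$annotation_score) &
      features$annotation_score >= annotation_threshold
  } else {
    stop("features need an annotated flag or annotation_score")
  }
  specific <- feature_specific(features, n_extracts, specificity_pct)
  mean(specific & !annotated)
}

#' Literature Component (LC)
#'
#' A taxon-level novelty score in [0, 1]: the closer to 1, the fewer
#' compounds have been reported at the species, genus and family ranks.
#' Each rank contributes a linear ramp \code{max(0, 1 - n/cap)} weighted by
#' \code{weights} (which must sum to 1); LC is exactly 1 when all three
#' counts are 0 and 0 when every count reaches its cap.
#'
#' @param taxon One-row data.frame or list with \code{n_reported_species},
#'   \code{n_reported_genus}, \code{n_reported_family}.
#' @param caps Per-rank saturation counts (species, genus, family).
#' @param weights Per-rank weights summing to 1.
#' @return LC in [0, 1].
#' @export
literature_component <- function(taxon,
                                 caps = c(species = 20, genus = 100,
                                          family = 500),
                                 weights = c(species = 0.5, genus = 0.35,
                                             family = 0.15)) {
  stopifnot(all(caps > 0), abs(sum(weights) - 1) < 1e-9)
  n <- c(species = as.numeric(taxon$n_reported_species),
         genus = as.numeric(taxon$n_reported_genus),
         family = as.numeric(taxon$n_reported_family))
  stopifnot(all(n >= 0))
  sum(weights * pmax(0, 1 - n / caps[names(weights)]))
}

#' Literature-report filter
#'
#' TRUE iff strictly fewer than \code{max_reports} compounds are reported
#' at \emph{both} the species and the genus level. The default of 10
#' reproduces the selection rule that keeps only sparsely documented taxa.
#'
#' @param taxon As in \code{\link{literature_component}}.
#' @param max_reports Strict upper bound (default 10).
#' @return Logical.
#' @export
passes_report_filter <- function(taxon, max_reports = 10) {
  stopifnot(max_reports >= 0)
  taxon$n_reported_species < max_reports &&
    taxon$n_reported_genus < max_reports
}

#' Class Component (CC)
#'
#' 1 when at least one chemical class predicted for the extract's features
#' (at or above the confidence threshold) has never been reported for the
#' taxon at the species or genus level; 0 otherwise. Matching is
#' exact-string on normalized class names (lower-cased, trimmed).
#'
#' @param predicted_classes Character vector of predicted class names, or a
#'   data.frame with columns \code{class} and \code{confidence}.
#' @param reported_classes Character vector of classes reported for the
#'   species and genus.
#' @param min_confidence Minimum prediction confidence (used with the
#'   data.frame form).
#' @return 0 or 1.
#' @export
class_component <- function(predicted_classes, reported_classes,
                            min_confidence = 0.5) {
  if (is.data.frame(predicted_classes)) {
    keep <- predicted_classes$confidence >= min_confidence
    predicted_classes <- predicted_classes$class[keep]
  }
  norm <- function(x) tolower(trimws(as.character(x)))
  pred <- unique(norm(predicted_classes))
  pred <- pred[nzchar(pred) & !is.na(pred)]
  if (!length(pred)) return(0L)
  rep_ <- unique(norm(reported_classes))
  as.integer(length(setdiff(pred, rep_)) > 0)
}

# ---- anomaly detectors over the MEMO matrix -------------------------------

# k-NN local outlier factor on a numeric score matrix; higher = more
# anomalous. Classic definition with k-distance, reachability distance and
# local reachability density.
lof_scores <- function(x, k = 10) {
  n <- nrow(x)
  k <- max(1L, min(k, n - 1L))
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn_idx <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  kdist <- vapply(seq_len(n), function(i) d[i, nn_idx[i, k]], numeric(1))
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[nn_idx[i, ]], d[i, nn_idx[i, ]])
    k / max(sum(reach), .Machine$double.eps)
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    mean(lrd[nn_idx[i, ]]) / max(lrd[i], .Machine$double.eps)
  }, numeric(1))
}

# Isolation forest: average normalized isolation depth over random binary
# trees built on subsamples; score in (0, 1), higher = more anomalous.
iforest_scores <- function(x, n_trees = 100, subsample = 256) {
  n <- nrow(x); p <- ncol(x)
  psi <- min(subsample, n)
  hlim <- ceiling(log2(max(psi, 2)))
  harm <- function(i) ifelse(i <= 0, 0, log(i) + 0.5772156649)
  cfac <- function(m) ifelse(m <= 1, 0, 2 * harm(m - 1) - 2 * (m - 1) / m)

  grow <- function(idx, depth) {
    if (depth >= hlim || length(idx) <= 1) {
      return(list(leaf = TRUE, size = length(idx)))
    }
    attempts <- 0
    repeat {
      q <- sample.int(p, 1)
      v <- x[idx, q]
      lo <- min(v); hi <- max(v)
      attempts <- attempts + 1
      if (hi > lo || attempts >= 5) break
    }
    if (hi <= lo) return(list(leaf = TRUE, size = length(idx)))
    s <- stats::runif(1, lo, hi)
    list(leaf = FALSE, q = q, s = s,
         left = grow(idx[v < s], depth + 1),
         right = grow(idx[v >= s], depth + 1))
  }
  path_len <- function(tree, xi, depth = 0) {
    if (tree$leaf) return(depth + cfac(tree$size))
    if (xi[tree$q] < tree$s) path_len(tree$left, xi, depth + 1)
    else path_len(tree$right, xi, depth + 1)
  }
  depths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, psi)
    tree <- grow(idx, 0)
    depths[, t] <- apply(x, 1, function(xi) path_len(tree, xi))
  }
  2^(-rowMeans(depths) / cfac(psi))
}

# One-class SVM (radial kernel) anomaly score: negative decision value,
# higher = more anomalous.
ocsvm_scores <- function(x, nu = 0.1) {
  # wide radial kernel (gamma well below the median-distance heuristic):
  # a tight kernel saturates for far-away rows, collapsing their decision
  # values onto the margin and hiding exactly the extracts of interest
  d2 <- stats::median(as.numeric(stats::dist(x))^2)
  gamma <- 0.01 / max(d2, .Machine$double.eps)
  fit <- e1071::svm(x, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma,
                    scale = FALSE)
  dec <- stats::predict(fit, x, decision.values = TRUE)
  -as.numeric(attr(dec, "decision.values"))
}

# Robust threshold: flag scores above median + 3 MAD.
flag_outlier_scores <- function(scores, n_mad = 3) {
  med <- stats::median(scores)
  mad <- stats::mad(scores)
  scores > med + n_mad * max(mad, 1e-8 * (abs(med) + 1))
}

#' Similarity Component (SC)
#'
#' Flags extracts whose MEMO spectral fingerprint is substantially
#' dissimilar from the rest of the collection. The MEMO matrix is row-
#' normalized to relative token frequencies, reduced by PCA to at most
#' \code{n_components} dimensions, and scored by an ensemble of anomaly
#' detectors (local outlier factor, isolation forest, one-class SVM). Each
#' detector flags extracts whose score exceeds median + 3 MAD; SC = 1 when
#' the vote rule is met (default: at least 2 of 3 detectors agree).
#'
#' @param memo A \code{memo_matrix} (extracts x tokens counts).
#' @param detectors Character subset of
#'   \code{c("lof", "iforest", "ocsvm")}.
#' @param vote \code{"majority"} (>= 2 detectors), \code{"any"} or
#'   \code{"all"}.
#' @param n_components Maximum PCA dimensionality before detection (set to
#'   \code{Inf} to disable reduction).
#' @param k LOF neighbourhood size.
#' @param seed Integer seed controlling the stochastic detectors.
#' @return Named integer vector (0/1) over the matrix's extract ids, with
#'   the per-detector flag matrix as attribute \code{"votes"}.
#' @export
similarity_component <- function(memo,
                                 detectors = c("lof", "iforest", "ocsvm"),
                                 vote = c("majority", "any", "all"),
                                 n_components = 10, k = 10, seed = 1L) {
  vote <- match.arg(vote)
  detectors <- match.arg(detectors, several.ok = TRUE)
  ids <- rownames(memo)
  n <- nrow(memo)
  if (n < 10) {
    warning("fewer than 10 extracts: SC undefined, returning all 0")
    return(stats::setNames(integer(n), ids))
  }
  m <- unclass(memo)
  storage.mode(m) <- "double"
  rs <- rowSums(m)
  all_zero <- rs == 0
  m[!all_zero, ] <- m[!all_zero, , drop = FALSE] / rs[!all_zero]
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    return(stats::setNames(integer(n), ids))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  # a compact ordination: trailing near-noise components dilute isolation-
  # and density-based detection without adding outlier signal
  ncomp <- min(n_components, ncol(pc$x))
  scores_x <- pc$x[, seq_len(ncomp), drop = FALSE]

  votes <- sapply(detectors, function(det) {
    set.seed(seed)
    sc <- switch(det,
                 lof = lof_scores(scores_x, k = k),
                 iforest = iforest_scores(scores_x),
                 ocsvm = ocsvm_scores(scores_x))
    flag_outlier_scores(sc)
  })
  votes <- matrix(votes, nrow = n,
                  dimnames = list(ids, detectors))
  need <- switch(vote, majority = ceiling((length(detectors) + 1) / 2),
                 any = 1L, all = length(detectors))
  out <- stats::setNames(as.integer(rowSums(votes) >= need), ids)
  attr(out, "votes") <- votes
  out
}

#' Priority Score (PS)
#'
#' Weighted sum of the four component scores:
#' \code{PS = FC + w_L * LC + w_C * CC + w_S * SC}. With the default unit
#' weights PS ranges over [0, 4]; it is monotone non-decreasing in every
#' component, and its ranking is invariant to a positive rescaling of all
#' weights applied jointly with FC's implicit weight.
#'
#' @param fc,lc,cc,sc Component scores (vectors recycle).
#' @param weights Named non-negative weights \code{c(lc=, cc=, sc=)}.
#' @return Numeric PS.
#' @export
priority_score <- function(fc, lc, cc, sc,
                           weights = c(lc = 1, cc = 1, sc = 1)) {
  stopifnot(all(weights >= 0))
  fc + weights[["lc"]] * lc + weights[["cc"]] * cc + weights[["sc"]] * sc
}

#' Score a whole collection
#'
#' Computes FC, LC, CC, SC and PS for every extract of a loaded collection.
#'
#' @param features data.frame of all features with columns
#'   \code{extract_id}, \code{n_extracts_detected}, \code{annotated},
#'   \code{predicted_class} (optional), \code{class_confidence} (optional).
#' @param taxa data.frame keyed by \code{extract_id} with the report counts
#'   and a \code{reported_classes} column (";"-separated string or
#'   list-column).
#' @param memo A \code{memo_matrix} over the same extract ids.
#' @param specificity_pct,lc_caps,lc_weights,min_class_confidence,ps_weights
#'   Component parameters (see the individual score functions).
#' @param seed Seed for the SC detector ensemble.
#' @return data.frame: extract_id, FC, LC, CC, SC, PS,
#'   n_reported_species, n_reported_genus.
#' @export
score_collection <- function(features, taxa, memo, specificity_pct = 10,
                             lc_caps = c(species = 20, genus = 100,
                                         family = 500),
                             lc_weights = c(species = 0.5, genus = 0.35,
                                            family = 0.15),
                             min_class_confidence = 0.5,
                             ps_weights = c(lc = 1, cc = 1, sc = 1),
                             seed = 1L) {
  ids <- sort(unique(features$extract_id))
  n_extracts <- length(ids)
  sc <- similarity_component(memo, seed = seed)
  rows <- lapply(ids, function(id) {
    f <- features[features$extract_id == id, ]
    tx <- taxa[taxa$extract_id == id, ]
    if (!nrow(tx)) stop("no taxon record for extract ", id)
    reported <- tx$reported_classes[[1]]
    if (is.character(reported) && length(reported) == 1) {
      reported <- strsplit(reported, ";", fixed = TRUE)[[1]]
    }
    pred <- if ("predicted_class" %in% names(f)) {
      data.frame(class = f$predicted_class,
                 confidence = if ("class_confidence" %in% names(f)) {
                   f$class_confidence
                 } else 1,
                 stringsAsFactors = FALSE)
    } else data.frame(class = character(0), confidence = numeric(0))
    pred <- pred[!is.na(pred$class) & nzchar(pred$class), , drop = FALSE]
    fc <- feature_component(f, n_extracts, specificity_pct)
    lc <- literature_component(tx, caps = lc_caps, weights = lc_weights)
    cc <- class_component(pred, reported, min_class_confidence)
    data.frame(extract_id = id, FC = fc, LC = lc, CC = cc,
               SC = unname(sc[id]),
               n_reported_species = tx$n_reported_species,
               n_reported_genus = tx$n_reported_genus,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$PS <- priority_score(out$FC, out$LC, out$CC, out$SC, ps_weights)
  out <- out[, c("extract_id", "FC", "LC", "CC", "SC", "PS",
                 "n_reported_species", "n_reported_genus")]
  rownames(out) <- NULL
  out
}
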