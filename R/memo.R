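# MEMO-style spectral fingerprints: extract-level count vectors over binned
# MS2 fragment peaks and neutral losses, and the extract-by-token matrix.

# number of decimals implied by a bin width (0.01 -> 2)
.bin_digits <- function(bin_width) max(0L, ceiling(-log10(bin_width)))

.bin_label <- function(mz, bin_width) {
  sprintf(paste0("%.", .bin_digits(bin_width), "f"),
          round(mz / bin_width) * bin_width)
}

#' MEMO token counts for one extract
#'
#' Every fragment peak contributes one \code{peak@bin} token; every neutral
#' loss (precursor m/z minus fragment m/z) falling inside \code{loss_range}
#' contributes one \code{loss@bin} token. Counts are occurrence counts
#' across all of the extract's spectra, so the vector is additive over
#' spectrum lists.
#'
#' @param spectra List of MS2 spectra (see \code{\link{read_mgf}}).
#' @param bin_width Bin width in Da (> 0); m/z are rounded to the nearest
#'   multiple. Default 0.01 Da.
#' @param loss_range Length-2 numeric: neutral losses outside this interval
#'   are discarded. Default [10, 200] Da.
#' @return Named integer vector of token counts (possibly empty).
#' @export
memo_vector <- function(spectra, bin_width = 0.01, loss_range = c(10, 200)) {
  stopifnot(bin_width > 0, length(loss_range) == 2)
  tokens <- character(0)
  for (s in spectra) {
    if (is.null(s$peaks) || nrow(s$peaks) == 0) next
    frag <- s$peaks[, "mz"]
    tokens <- c(tokens, paste0("peak@", .bin_label(frag, bin_width)))
    loss <- s$precursor_mz - frag
    loss <- loss[loss >= loss_range[1] & loss <= loss_range[2]]
    if (length(loss)) {
      tokens <- c(tokens, paste0("loss@", .bin_label(loss, bin_width)))
    }
  }
  if (!length(tokens)) return(stats::setNames(integer(0), character(0)))
  tab <- table(tokens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build the extract-by-token MEMO matrix
#'
#' Rows are extracts, columns the union of all MEMO tokens across the
#' collection, sorted; cell values are token occurrence counts. Row order
#' follows sorted extract ids, independent of input order.
#'
#' @param spectra_by_extract Named list: extract id -> list of MS2 spectra.
#' @param bin_width,loss_range Passed to \code{\link{memo_vector}}.
#' @return Integer matrix with extract ids as rownames and tokens as
#'   colnames; class \code{c("memo_matrix", "matrix")}.
#' @export
build_memo_matrix <- function(spectra_by_extract, bin_width = 0.01,
                              loss_range = c(10, 200)) {
  if (!length(spectra_by_extract)) stop("need at least one extract")
  ids <- names(spectra_by_extract)
  if (is.null(ids) || any(!nzchar(ids))) stop("extracts must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate extract id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vecs <- lapply(spectra_by_extract, memo_vector,
                 bin_width = bin_width, loss_range = loss_range)
  vocab <- sort(unique(unlist(lapply(vecs, names), use.names = FALSE)))
  m <- matrix(0L, nrow = length(ids), ncol = length(vocab),
              dimnames = list(sort(ids), vocab))
  for (id in ids) {
    v <- vecs[[id]]
    if (length(v)) m[id, names(v)] <- v
  }
  class(m) <- c("memo_matrix", class(m))
  m
}

#' Cosine similarity between two MEMO rows
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in [0, 1] for non-negative counts; 0 when
#'   either vector is all-zero.
#' @export
row_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Feature specificity within a collection
#'
#' A feature is \emph{specific} when it is detected in at most
#' \code{specificity_pct} percent of the collection's extracts.
#'
#' @param features data.frame with a \code{feature_id} column and an
#'   \code{n_extracts_detected} column (or a list-column
#'   \code{extracts_detected_in}).
#' @param n_extracts Total number of extracts in the collection.
#' @param specificity_pct Detection-share threshold, percent (default 10).
#' @return Logical vector, one entry per feature row.
#' @export
feature_specific <- function(features, n_extracts, specificity_pct = 10) {
  stopifnot(n_extracts >= 1)
  n_det <- if ("n_extracts_detected" %in% names(features)) {
    features$n_extracts_detected
  } else if ("extracts_detected_in" %in% names(features)) {
    lengths(features$extracts_detected_in)
  } else {
    stop("features need n_extracts_detected or extracts_detected_in")
  }
  n_det / n_extracts * 100 <= specificity_pct
}

#' Ion-map summary of one extract's features
#'
#' One row per feature with retention time, m/z, intensity and annotation
#' status — the tabular backbone of the ion-map plot in which dot size is
#' intensity and colour the annotation status. The attached counts support
#' checks such as whether the most intense features are annotated.
#'
#' @param features data.frame with columns \code{feature_id}, \code{rt},
#'   \code{mz}, \code{intensity}, \code{annotated} (logical).
#' @param extract_id Optional id recorded in the output attributes.
#' @return data.frame (feature_id, rt, mz, intensity, annotated) with
#'   attributes \code{n_annotated}, \code{n_unannotated},
#'   \code{annotation_rate}.
#' @export
ionmap_summary <- function(features, extract_id = NA_character_) {
  cols <- c("feature_id", "rt", "mz", "intensity", "annotated")
  if (!nrow(features)) {
    out <- features[cols[cols %in% names(features)]]
    attr(out, "n_annotated") <- 0L
    attr(out, "n_unannotated") <- 0L
    attr(out, "annotation_rate") <- NA_real_
    return(out)
  }
  stopifnot(all(cols %in% names(features)))
  out <- features[order(features$rt, features$mz), cols]
  rownames(out) <- NULL
  attr(out, "extract_id") <- extract_id
  attr(out, "n_annotated") <- sum(out$annotated)
  attr(out, "n_unannotated") <- sum(!out$annotated)
  attr(out, "annotation_rate") <- mean(out$annotated)
  out
}

#' Write / read a MEMO matrix as wide TSV
#'
#' @param m A \code{memo_matrix}.
#' @param path TSV path; first column \code{extract_id}, remaining columns
#'   the tokens.
#' @return \code{path} (write) or the matrix (read).
#' @export
write_memo_tsv <- function(m, path) {
  df <- data.frame(extract_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_memo_tsv
#' @export
read_memo_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$extract_id
  class(m) <- c("memo_matrix", class(m))
  m
}
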