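# MGF (Mascot generic format) reading/writing and the MS2 spectrum record.

#' Read MS2 spectra from an MGF file
#'
#' Parses the MGF dialect exported by common feature-detection tools: one
#' \code{BEGIN IONS}/\code{END IONS} block per spectrum with
#' \code{PEPMASS}, optional \code{FEATURE_ID}/\code{SCANS}, and one
#' \code{m/z intensity} pair per line.
#'
#' @param path Path to the MGF file.
#' @return List of spectra; each a list with \code{feature_id},
#'   \code{precursor_mz} and \code{peaks} (two-column matrix, m/z sorted
#'   ascending, columns \code{mz}, \code{intensity}).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_start <- NA_integer_
  feature_id <- NA_character_
  precursor <- NA_real_
  mz <- numeric(0); int <- numeric(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", i)
      in_block <- TRUE; block_start <- i
      feature_id <- NA_character_; precursor <- NA_real_
      mz <- numeric(0); int <- numeric(0)
    } else if (line == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i)
      if (is.na(precursor)) stop("block starting at line ", block_start,
                                 " has no PEPMASS")
      o <- order(mz)
      spectra[[length(spectra) + 1L]] <- list(
        feature_id = feature_id, precursor_mz = precursor,
        peaks = cbind(mz = mz[o], intensity = int[o]))
      in_block <- FALSE
    } else if (in_block) {
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*", "", line))
        val <- sub("^[^=]*=", "", line)
        if (key == "PEPMASS") {
          precursor <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
        } else if (key %in% c("FEATURE_ID", "SCANS") && is.na(feature_id)) {
          feature_id <- val
        }
      } else {
        parts <- strsplit(line, "[ \t]+")[[1]]
        v <- suppressWarnings(as.numeric(parts))
        if (length(v) < 2 || any(is.na(v[1:2]))) {
          stop("malformed peak line at line ", i, ": ", sQuote(line))
        }
        mz <- c(mz, v[1]); int <- c(int, v[2])
      }
    }
    # lines outside blocks (charset comments etc.) are ignored
  }
  if (in_block) stop("unterminated BEGIN IONS block starting at line ",
                     block_start)
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra List of spectra as returned by \code{\link{read_mgf}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    hdr <- c("BEGIN IONS",
             if (!is.na(s$feature_id)) paste0("FEATURE_ID=", s$feature_id),
             sprintf("PEPMASS=%.6f", s$precursor_mz),
             "CHARGE=1+")
    pk <- apply(s$peaks, 1, function(r) sprintf("%.6f %.2f", r[1], r[2]))
    paste(c(hdr, pk, "END IONS"), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
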