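# The sequential selection cascade: bioactivity-driven then novelty-driven
# filters reducing a screened collection to a ranked shortlist.

#' Default cascade configuration
#'
#' Stage thresholds of the selection funnel: non-toxic inhibitors with an
#' inhibitory IC50 at or below 5 ug/mL, Similarity Component 1, strictly
#' fewer than 10 reported compounds at both species and genus level, and
#' Class Component 1.
#'
#' @return Named list of thresholds.
#' @export
cascade_config <- function() {
  list(category = "inhibitor", max_ic50 = 5, require_sc = 1L,
       max_reports = 10, require_cc = 1L, exclude = character(0),
       stage_order = c("bioactivity", "similarity", "literature", "class"))
}

#' Run the selection cascade
#'
#' Applies the funnel stages in order on the joined activity-call, score
#' and taxon tables, recording the surviving extract set at every stage,
#' and ranks the final shortlist by Priority Score (ties broken by Feature
#' Component, then extract id).
#'
#' @param calls Activity-call data.frame (see \code{\link{screen_extracts}}).
#' @param scores Component-score data.frame (see
#'   \code{\link{score_collection}}).
#' @param taxa Taxon data.frame keyed by \code{extract_id} with
#'   \code{n_reported_species}, \code{n_reported_genus}.
#' @param config List of stage thresholds, see \code{\link{cascade_config}};
#'   \code{exclude} is an optional id blacklist applied as a final manual-
#'   review stage.
#' @return An object of class \code{cascade_report}: list with
#'   \code{stages} (data.frame: stage, criterion, n_surviving),
#'   \code{surviving} (list of id vectors per stage), \code{shortlist}
#'   (ranked data.frame with PS and tie-break keys) and \code{dropped}
#'   (ids present in calls but missing from scores/taxa).
#' @export
run_cascade <- function(calls, scores, taxa, config = cascade_config()) {
  cfg <- utils::modifyList(cascade_config(), config)
  ids0 <- unique(calls$extract_id)
  have <- intersect(intersect(ids0, scores$extract_id), taxa$extract_id)
  dropped <- setdiff(ids0, have)
  if (length(dropped)) {
    warning(length(dropped), " extract(s) missing scores or taxon records; ",
            "excluded: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  tab <- merge(merge(calls[calls$extract_id %in% have, ],
                     scores, by = "extract_id"),
               taxa[, c("extract_id", "n_reported_species",
                        "n_reported_genus")],
               by = "extract_id", suffixes = c("", ".taxon"))

  defs <- list(
    bioactivity = list(
      criterion = sprintf("non-toxic %s with IC50 <= %g ug/mL",
                          cfg$category, cfg$max_ic50),
      keep = tab$category == cfg$category & !tab$toxic &
        !is.na(tab$topflash_ic50) & tab$topflash_ic50 <= cfg$max_ic50),
    similarity = list(criterion = sprintf("SC = %d", cfg$require_sc),
                      keep = tab$SC == cfg$require_sc),
    literature = list(
      criterion = sprintf("< %d reported compounds at species and genus level",
                          cfg$max_reports),
      keep = tab$n_reported_species < cfg$max_reports &
        tab$n_reported_genus < cfg$max_reports),
    class = list(criterion = sprintf("CC = %d", cfg$require_cc),
                 keep = tab$CC == cfg$require_cc))
  ord <- cfg$stage_order
  if (!setequal(ord, names(defs))) {
    stop("stage_order must be a permutation of: ",
         paste(names(defs), collapse = ", "))
  }
  stages <- c(
    list(list(name = "screened", criterion = "all screened extracts",
              keep = rep(TRUE, nrow(tab)))),
    lapply(ord, function(nm) c(list(name = nm), defs[[nm]])))
  if (length(cfg$exclude)) {
    stages <- c(stages, list(list(
      name = "manual_review", criterion = "manual exclusion list",
      keep = !(tab$extract_id %in% cfg$exclude))))
  }

  alive <- rep(TRUE, nrow(tab))
  surviving <- list()
  rows <- list()
  for (st in stages) {
    alive <- alive & st$keep
    ids <- sort(tab$extract_id[alive])
    surviving[[st$name]] <- ids
    rows[[st$name]] <- data.frame(stage = st$name, criterion = st$criterion,
                                  n_surviving = length(ids),
                                  stringsAsFactors = FALSE)
  }
  final <- tab[alive, , drop = FALSE]
  o <- order(-final$PS, -final$FC, final$extract_id)
  shortlist <- final[o, c("extract_id", "PS", "FC", "LC", "CC", "SC",
                          "topflash_ic50", "n_reported_species",
                          "n_reported_genus")]
  rownames(shortlist) <- NULL
  structure(list(stages = do.call(rbind, c(rows, make.row.names = FALSE)),
                 surviving = surviving, shortlist = shortlist,
                 dropped = sort(dropped)),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-13s %5d  (%s)\n", x$stages$stage[i],
                x$stages$n_surviving[i], x$stages$criterion[i]))
  }
  cat("shortlist:", paste(utils::head(x$shortlist$extract_id, 10),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a cascade report to JSON
#'
#' @param report A \code{cascade_report}.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to \code{path}).
#' @export
cascade_report_json <- function(report, path = NULL) {
  obj <- list(stages = report$stages, surviving = report$surviving,
              shortlist = report$shortlist, dropped = report$dropped)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Category and potency-tier summary of a screen
#'
#' Counts per activity category (with the toxic/non-toxic potentiator
#' split) and cumulative nested IC50 tiers over the inhibitors
#' (<=5 within <10 within <50 ug/mL).
#'
#' @param calls Activity-call data.frame.
#' @param thresholds Tier cut-points, ug/mL.
#' @return List with \code{categories} (named counts), \code{potentiators}
#'   (toxic / non_toxic split) and \code{inhibitor_tiers} (cumulative
#'   counts, named "<=5", "<10", "<50").
#' @export
tier_summary <- function(calls, thresholds = c(5, 10, 50)) {
  if (!nrow(calls)) stop("calls must be non-empty")
  cats <- c("inhibitor", "potentiator", "cytotoxic_only", "inactive")
  categories <- vapply(cats, function(ct) sum(calls$category == ct),
                       integer(1))
  pot <- calls[calls$category == "potentiator", , drop = FALSE]
  inh <- calls[calls$category == "inhibitor" &
                 !is.na(calls$topflash_ic50), , drop = FALSE]
  tiers <- vapply(thresholds, function(th) {
    if (th == thresholds[1]) sum(inh$topflash_ic50 <= th)
    else sum(inh$topflash_ic50 < th)
  }, integer(1))
  names(tiers) <- c(paste0("<=", thresholds[1]),
                    paste0("<", thresholds[-1]))
  list(categories = categories,
       potentiators = c(toxic = sum(pot$toxic),
                        non_toxic = sum(!pot$toxic)),
       inhibitor_tiers = tiers,
       n_active = sum(calls$category != "inactive"))
}
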