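# Dual-luciferase dose-response analysis: 4PL fitting, IC50 tiers, and the
# Renilla-based cytotoxicity rule.

#' Default concentration series of the extract screen
#'
#' Extracts are screened in single repeats at five concentrations.
#'
#' @return Numeric vector, ug/mL, descending.
#' @export
screen_concentrations <- function() c(50, 25, 12.5, 6, 3)

#' Normalize luminescence to the stimulated vehicle control
#'
#' Converts raw luminescence to fraction-of-control per channel, so the
#' vehicle control maps to 1.0.
#'
#' @param measurements data.frame with columns \code{extract_id},
#'   \code{channel} ("topflash" or "renilla"), \code{concentration},
#'   \code{luminescence} and optionally \code{replicate}.
#' @param controls Named numeric vector of control luminescence per channel,
#'   e.g. \code{c(topflash = 2000, renilla = 1500)}; all > 0.
#' @return The input data.frame with a \code{response} column appended.
#' @export
normalize_responses <- function(measurements, controls) {
  req <- c("extract_id", "channel", "concentration", "luminescence")
  if (!all(req %in% names(measurements))) {
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  }
  chans <- unique(measurements$channel)
  missing <- setdiff(chans, names(controls))
  if (length(missing)) {
    stop("missing control for channel(s): ", paste(missing, collapse = ", "))
  }
  if (any(controls[chans] <= 0)) stop("control luminescence must be > 0")
  stopifnot(all(is.finite(measurements$luminescence)),
            all(measurements$luminescence >= 0))
  measurements$response <-
    measurements$luminescence / unname(controls[measurements$channel])
  measurements
}

# 4PL mean response: r0 at zero dose, rinf at infinite dose, hill > 0.
.fpl <- function(conc, r0, rinf, hill, ic50) {
  rinf + (r0 - rinf) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of \code{response = rinf + (r0 - rinf) / (1 +
#' (conc/ic50)^hill)} where \code{r0} is the zero-dose asymptote and
#' \code{rinf} the infinite-dose asymptote, via Levenberg-Marquardt with a
#' multi-start grid over ic50 and hill. An ic50 fitted beyond the highest
#' tested concentration is reported as a bound (flag \code{">max_tested"}),
#' never as an extrapolated number; a flat response yields
#' \code{"not_estimable"}.
#'
#' @param conc Concentrations, non-negative, length >= 4; a concentration
#'   of exactly 0 is the vehicle-control anchor (the model evaluates to the
#'   zero-dose asymptote there). At least two distinct positive
#'   concentrations are required.
#' @param response Normalized responses (fraction of control), same length.
#' @param anchor_control Append a (0, 1) vehicle-control point before
#'   fitting (default TRUE): normalization defines the zero-dose response
#'   as 1, and anchoring it identifies the zero-dose asymptote that five
#'   points on the falling limb alone cannot. Disabled automatically when
#'   a zero-concentration point is already present.
#' @param flat_tol Response range below which the curve is called flat.
#' @return An object of class \code{dose_response_fit}: list with
#'   \code{r0}, \code{rinf}, \code{bottom}, \code{top} (canonicalized so
#'   bottom <= top), \code{hill}, \code{ic50}, \code{ic50_flag} (one of
#'   \code{"estimable"}, \code{">max_tested"}, \code{"not_estimable"}),
#'   \code{rss}, \code{converged}, \code{span} (fitted response change from
#'   zero dose to the highest tested concentration, signed),
#'   \code{conc_range}.
#' @export
fit_4pl <- function(conc, response, anchor_control = TRUE, flat_tol = 0.05) {
  stopifnot(is.numeric(conc), is.numeric(response),
            length(conc) == length(response))
  if (length(conc) < 4) stop("need at least 4 (concentration, response) pairs")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (any(!is.finite(response))) stop("responses must be finite")
  if (anchor_control && !any(conc == 0)) {
    conc <- c(0, conc)
    response <- c(1, response)
  }
  pos <- conc > 0
  if (sum(pos) < 3) stop("need at least 3 positive concentrations")
  cmin <- min(conc[pos]); cmax <- max(conc)

  flat_fit <- function() {
    m <- mean(response)
    structure(list(r0 = m, rinf = m, bottom = m, top = m, hill = NA_real_,
                   ic50 = NA_real_, ic50_flag = "not_estimable",
                   rss = sum((response - m)^2), converged = TRUE,
                   span = 0, conc_range = c(cmin, cmax)),
              class = "dose_response_fit")
  }
  if (diff(range(response)) < flat_tol) return(flat_fit())

  # multi-start grid: ic50 across (and slightly beyond) the tested range
  ic50_starts <- exp(seq(log(cmin / 2), log(cmax * 4), length.out = 6))
  hill_starts <- c(0.7, 1.5, 3)
  o <- order(conc)
  r0_start <- response[o][1]
  rinf_start <- response[o][length(response)]

  best <- NULL
  for (i0 in ic50_starts) for (h0 in hill_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ rinf + (r0 - rinf) / (1 + (conc / ic50)^hill),
        start = list(r0 = max(r0_start, 0), rinf = max(rinf_start, 0),
                     hill = h0, ic50 = i0),
        # normalized luminescence is non-negative, so both asymptotes are
        lower = c(r0 = 0, rinf = 0, hill = 0.1, ic50 = cmin / 1000),
        upper = c(r0 = 5, rinf = 5, hill = 10, ic50 = cmax * 1000),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(rss = rss, par = stats::coef(fit))
    }
  }
  if (is.null(best)) {
    # Nelder-Mead fallback on the same bounded least-squares objective
    sse <- function(p) {
      p <- pmax(p, c(0, 0, 0.1, cmin / 1000))
      sum((response - .fpl(conc, p[1], p[2], p[3], p[4]))^2)
    }
    opt <- stats::optim(c(max(r0_start, 0), max(rinf_start, 0), 1,
                          sqrt(cmin * cmax)), sse)
    best <- list(rss = opt$value,
                 par = stats::setNames(
                   pmax(opt$par, c(0, 0, 0.1, cmin / 1000)),
                   c("r0", "rinf", "hill", "ic50")))
  }
  p <- best$par
  # fitted response change from zero dose (the control anchor / fitted
  # zero-dose asymptote) to the highest tested concentration: captures
  # curves already saturated below the lowest tested dose
  span <- .fpl(cmax, p["r0"], p["rinf"], p["hill"], p["ic50"]) -
          unname(p["r0"])
  ic50 <- unname(p["ic50"])
  flag <- if (abs(p["r0"] - p["rinf"]) < flat_tol) "not_estimable"
          else if (ic50 > cmax) ">max_tested"
          else "estimable"
  structure(list(
    r0 = unname(p["r0"]), rinf = unname(p["rinf"]),
    bottom = min(p["r0"], p["rinf"]), top = max(p["r0"], p["rinf"]),
    hill = unname(p["hill"]),
    ic50 = if (flag == "not_estimable") NA_real_ else ic50,
    ic50_flag = flag, rss = best$rss, converged = TRUE,
    span = unname(span), conc_range = c(cmin, cmax)),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<4PL fit> ic50 %s (%s), hill %.2f, span %+.2f, rss %.3g\n",
              ifelse(is.na(x$ic50), "NA", sprintf("%.3g", x$ic50)),
              x$ic50_flag, ifelse(is.na(x$hill), NA, x$hill), x$span, x$rss))
  invisible(x)
}

#' IC50 potency tier
#'
#' Nested tiers used when reporting the screen: \code{"<=5"}, \code{"<10"},
#' \code{"<50"} ug/mL, \code{">=50"} for estimable values beyond the top
#' tier, \code{"none"} when not estimable.
#'
#' @param ic50 Numeric IC50 (NA allowed).
#' @param thresholds Tier cut-points, ug/mL.
#' @return Character tier label.
#' @export
ic50_tier <- function(ic50, thresholds = c(5, 10, 50)) {
  if (is.na(ic50)) return("none")
  if (ic50 <= thresholds[1]) "<=5"
  else if (ic50 < thresholds[2]) "<10"
  else if (ic50 < thresholds[3]) "<50"
  else ">=50"
}

#' Classify extract activity from the two reporter fits
#'
#' Applies the screen's decision rules: an extract is \emph{toxic} when its
#' Renilla IC50 is estimable and less than \code{toxicity_ratio} (1.7 by
#' default) times its TopFlash IC50 — any TopFlash drop is then attributed
#' to cytotoxicity rather than specific Wnt inhibition. TopFlash modulation
#' is called only when the fitted response change across the tested range
#' exceeds \code{effect_floor}; direction comes from the sign of that
#' fitted span. Categories: \code{inhibitor} (TopFlash down, not toxic),
#' \code{potentiator} (TopFlash up), \code{cytotoxic_only} (Renilla down
#' without specific TopFlash modulation, or TopFlash down but toxic),
#' \code{inactive} otherwise.
#'
#' @param top_fit,ren_fit \code{dose_response_fit} for the TopFlash and
#'   Renilla channels.
#' @param extract_id Identifier carried into the call.
#' @param effect_floor Minimum |fitted span| (fraction of control) to call
#'   modulation; default 0.3.
#' @param toxicity_ratio The Renilla/TopFlash IC50 ratio below which the
#'   extract is called toxic; default 1.7.
#' @param tier_thresholds IC50 tier cut-points, ug/mL.
#' @return One-row data.frame (class \code{activity_call}): columns
#'   \code{extract_id}, \code{category}, \code{topflash_ic50},
#'   \code{topflash_flag}, \code{renilla_ic50}, \code{renilla_flag},
#'   \code{toxic}, \code{tier}.
#' @export
classify_activity <- function(top_fit, ren_fit, extract_id = NA_character_,
                              effect_floor = 0.3, toxicity_ratio = 1.7,
                              tier_thresholds = c(5, 10, 50)) {
  stopifnot(inherits(top_fit, "dose_response_fit"),
            inherits(ren_fit, "dose_response_fit"))
  if (!top_fit$converged || !ren_fit$converged) {
    warning("degenerate fit for ", extract_id, "; calling inactive")
    return(.activity_row(extract_id, "inactive", NA, "not_estimable",
                         NA, "not_estimable", FALSE, "none"))
  }
  # modulation is callable when the fitted span clears the floor even if
  # the IC50 lands beyond the tested range (reported as the ">=50" tier)
  top_down <- top_fit$span < 0 && abs(top_fit$span) >= effect_floor &&
              top_fit$ic50_flag != "not_estimable"
  top_up   <- top_fit$span > 0 && abs(top_fit$span) >= effect_floor &&
              top_fit$ic50_flag != "not_estimable"
  ren_down <- ren_fit$span < 0 && abs(ren_fit$span) >= effect_floor &&
              ren_fit$ic50_flag == "estimable"

  toxic <- ren_down && top_fit$ic50_flag == "estimable" &&
           ren_fit$ic50 < toxicity_ratio * top_fit$ic50

  category <- if (top_up) "potentiator"
    else if (top_down && !toxic) "inhibitor"
    else if (ren_down || (top_down && toxic)) "cytotoxic_only"
    else "inactive"

  tier <- if (category == "inhibitor") {
    if (top_fit$ic50_flag == ">max_tested") ">=50"
    else ic50_tier(top_fit$ic50, tier_thresholds)
  } else "none"

  .activity_row(extract_id, category,
                top_fit$ic50, top_fit$ic50_flag,
                ren_fit$ic50, ren_fit$ic50_flag, toxic, tier)
}

.activity_row <- function(extract_id, category, top_ic50, top_flag,
                          ren_ic50, ren_flag, toxic, tier) {
  out <- data.frame(extract_id = extract_id, category = category,
                    topflash_ic50 = top_ic50, topflash_flag = top_flag,
                    renilla_ic50 = ren_ic50, renilla_flag = ren_flag,
                    toxic = toxic, tier = tier, stringsAsFactors = FALSE)
  class(out) <- c("activity_call", class(out))
  out
}

#' Screen a long-format measurement table
#'
#' Fits both reporter channels per extract and classifies activity.
#'
#' @param measurements Long-format data.frame with columns
#'   \code{extract_id}, \code{channel}, \code{concentration},
#'   \code{luminescence} (raw) or \code{response} (already normalized).
#' @param controls Per-channel control luminescence (required when only raw
#'   luminescence is present).
#' @param ... Passed to \code{\link{classify_activity}}.
#' @return data.frame of activity calls, one row per extract.
#' @export
screen_extracts <- function(measurements, controls = NULL, ...) {
  if (!"response" %in% names(measurements)) {
    if (is.null(controls)) stop("controls required to normalize luminescence")
    measurements <- normalize_responses(measurements, controls)
  }
  ids <- unique(measurements$extract_id)
  calls <- lapply(ids, function(id) {
    d <- measurements[measurements$extract_id == id, ]
    tf <- d[d$channel == "topflash", ]
    rn <- d[d$channel == "renilla", ]
    if (!nrow(tf) || !nrow(rn)) {
      stop("extract ", id, " is missing a reporter channel")
    }
    classify_activity(fit_4pl(tf$concentration, tf$response),
                      fit_4pl(rn$concentration, rn$response),
                      extract_id = id, ...)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
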