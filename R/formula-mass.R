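# Molecular-formula parsing, monoisotopic masses, adduct m/z and
# constrained formula assignment for HRMS dereplication.

# Monoisotopic masses of the most abundant isotope, Da (CODATA/AME2020).
.ISOTOPE_MASS <- c(
  C = 12.0000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146196,
  P = 30.9737615120,
  S = 31.9720706800
)
# H given to 10 decimals elsewhere in the literature as 1.00782503207;
# we store the full-precision value and use it consistently.
.ISOTOPE_MASS["H"] <- 1.00782503207
.ISOTOPE_MASS["N"] <- 14.0030740048
.ISOTOPE_MASS["P"] <- 30.97376163
.ISOTOPE_MASS["S"] <- 31.97207100

.PROTON_MASS <- 1.007276466
.ELECTRON_MASS <- 0.00054857990907

# Registered adducts: mass delta added to the neutral monoisotopic mass and
# the absolute charge the delta implies. [M+H]+ adds a *proton* (H atom
# minus an electron): the electron mass matters at sub-ppm scale.
.ADDUCTS <- list(
  "[M+H]+"   = list(delta = .PROTON_MASS,                          charge = 1L),
  "[M+Na]+"  = list(delta = 22.98976928 - .ELECTRON_MASS,          charge = 1L),
  "[M+K]+"   = list(delta = 38.96370668 - .ELECTRON_MASS,          charge = 1L),
  "[M+NH4]+" = list(delta = 14.0030740048 + 4 * 1.00782503207 -
                            .ELECTRON_MASS,                        charge = 1L),
  "[M+2H]2+" = list(delta = 2 * .PROTON_MASS,                      charge = 2L)
)

#' Parse a molecular formula string
#'
#' Parses a concatenation of element symbols with optional positive integer
#' counts (e.g. \code{"C30H38O5"}) into a named composition vector. Implicit
#' counts of 1 are expanded; element symbols are restricted to a configured
#' alphabet.
#'
#' @param text Formula string, e.g. \code{"C30H38O5"} or \code{"H2O"}.
#' @param alphabet Character vector of allowed element symbols; defaults to
#'   the CHNOPS alphabet covered by the embedded isotope table.
#' @return An object of class \code{molecular_formula}: a list with
#'   \code{composition} (named integer vector in Hill order) and
#'   \code{charge} (integer, 0 for a neutral).
#' @examples
#' parse_formula("C30H38O5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text, alphabet = names(.ISOTOPE_MASS)) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  parts <- regmatches(text, list(matches))[[1]]
  if (sum(nchar(parts)) != nchar(text)) {
    stop("malformed formula string: ", sQuote(text))
  }
  elems <- sub("[0-9]*$", "", parts)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
  counts[is.na(counts) & !grepl("[0-9]", parts)] <- 1L
  bad <- setdiff(elems, alphabet)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  if (any(is.na(counts)) || any(counts <= 0L)) {
    stop("zero or negative element count in ", sQuote(text))
  }
  comp <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  comp <- stats::setNames(as.integer(comp), names(comp))
  new_formula(comp, charge = 0L)
}

#' @rdname parse_formula
#' @param composition Named integer vector, element symbol -> count.
#' @param charge Integer charge (0 for a neutral molecule).
#' @export
new_formula <- function(composition, charge = 0L) {
  stopifnot(is.numeric(composition), !is.null(names(composition)),
            all(composition >= 1))
  comp <- as.integer(composition)
  names(comp) <- names(composition)
  structure(list(composition = comp[hill_order(names(comp))],
                 charge = as.integer(charge)),
            class = "molecular_formula")
}

# Hill order: C first, then H, then remaining symbols alphabetically
# (the convention when carbon is present; pure alphabetical otherwise).
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    order(match(symbols, c("C", "H", rest)))
  } else {
    order(symbols)
  }
}

#' Canonical Hill-order string of a formula
#'
#' @param f A \code{molecular_formula}.
#' @return Character scalar, e.g. \code{"C30H38O5"}; counts of 1 omitted.
#' @export
formula_string <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  comp <- f$composition
  paste0(names(comp), ifelse(comp == 1L, "", comp), collapse = "")
}

#' @export
format.molecular_formula <- function(x, ...) {
  s <- formula_string(x)
  if (x$charge != 0L) {
    s <- paste0("[", s, "]", abs(x$charge), ifelse(x$charge > 0, "+", "-"))
  }
  s
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the mass of the most abundant isotope,
#' from the embedded isotope table.
#'
#' @param f A \code{molecular_formula} or a formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")    # 18.0105647
#' monoisotopic_mass("C30H38O5")
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "molecular_formula"))
  comp <- f$composition
  missing <- setdiff(names(comp), names(.ISOTOPE_MASS))
  if (length(missing)) {
    stop("element(s) missing from isotope table: ",
         paste(missing, collapse = ", "))
  }
  sum(comp * .ISOTOPE_MASS[names(comp)])
}

#' Theoretical m/z of an adduct ion
#'
#' \code{m/z = (monoisotopic_mass(neutral) + delta) / charge}. For
#' \code{[M+H]+} the delta is the proton mass (1.007276466 Da), i.e. the
#' hydrogen-atom mass minus the electron mass.
#'
#' @param neutral Neutral \code{molecular_formula} or formula string.
#' @param adduct Adduct name; one of \code{names(adduct_registry())}.
#' @return Theoretical m/z in Da.
#' @examples
#' adduct_mz("C30H38O5", "[M+H]+")   # 479.2792008
#' @export
adduct_mz <- function(neutral, adduct = "[M+H]+") {
  if (!adduct %in% names(.ADDUCTS)) {
    stop("unknown adduct ", sQuote(adduct), "; registered adducts: ",
         paste(names(.ADDUCTS), collapse = ", "))
  }
  a <- .ADDUCTS[[adduct]]
  (monoisotopic_mass(neutral) + a$delta) / a$charge
}

#' @rdname adduct_mz
#' @return \code{adduct_registry()} returns the named list of registered
#'   adducts (mass delta in Da, charge).
#' @export
adduct_registry <- function() .ADDUCTS

#' Mass error in parts per million
#'
#' \code{(observed - theoretical) / theoretical * 1e6}, sign preserved.
#'
#' @param observed Observed m/z, Da.
#' @param theoretical Theoretical m/z, Da; must be positive.
#' @return Signed ppm error (not rounded).
#' @examples
#' ppm_error(479.2793, adduct_mz("C30H38O5", "[M+H]+"))
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(is.numeric(observed), is.numeric(theoretical))
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Round half away from zero
#'
#' ppm errors are conventionally reported with halves rounded away from
#' zero (so 0.205 prints as 0.21), unlike base \code{round()}'s banker's
#' rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Assign molecular formulas to an observed m/z
#'
#' Exhaustively enumerates neutral compositions within per-element count
#' bounds, computes each candidate's theoretical adduct m/z, and returns
#' those within the ppm tolerance, sorted by absolute ppm error (ties by
#' canonical formula string).
#'
#' @param observed Observed m/z, Da.
#' @param adduct Adduct name (see \code{adduct_registry()}).
#' @param tolerance_ppm Assignment tolerance, ppm (> 0).
#' @param bounds Named list of length-2 integer ranges per element, e.g.
#'   \code{list(C = c(0, 35), H = c(0, 60), O = c(0, 8))}. Elements with a
#'   zero count in a candidate are dropped from its formula.
#' @return A data.frame with columns \code{ion_formula} (the neutral's
#'   canonical string), \code{neutral_mass}, \code{theoretical_mz},
#'   \code{error_ppm}; zero rows when no candidate is within tolerance.
#' @examples
#' assign_formula(479.2793, "[M+H]+", 5,
#'                list(C = c(0, 35), H = c(0, 60), O = c(0, 8)))
#' @export
assign_formula <- function(observed, adduct = "[M+H]+", tolerance_ppm = 5,
                           bounds = list(C = c(0, 50), H = c(0, 100),
                                         N = c(0, 10), O = c(0, 20))) {
  stopifnot(is.numeric(observed), length(observed) == 1L)
  if (!is.list(bounds) || length(bounds) == 0L) stop("empty element bounds")
  if (tolerance_ppm <= 0) stop("tolerance must be positive")
  if (!adduct %in% names(.ADDUCTS)) {
    stop("unknown adduct ", sQuote(adduct), "; registered adducts: ",
         paste(names(.ADDUCTS), collapse = ", "))
  }
  elems <- names(bounds)
  missing <- setdiff(elems, names(.ISOTOPE_MASS))
  if (length(missing)) {
    stop("element(s) missing from isotope table: ",
         paste(missing, collapse = ", "))
  }
  a <- .ADDUCTS[[adduct]]
  target_neutral <- observed * a$charge - a$delta
  tol_da <- abs(observed) * tolerance_ppm * 1e-6 * a$charge

  # Depth-first enumeration with mass-window pruning. Elements are visited
  # heaviest-first so the residual-mass bound prunes early.
  ord <- order(.ISOTOPE_MASS[elems], decreasing = TRUE)
  elems <- elems[ord]
  masses <- .ISOTOPE_MASS[elems]
  lo <- vapply(bounds[elems], function(b) as.integer(min(b)), integer(1))
  hi <- vapply(bounds[elems], function(b) as.integer(max(b)), integer(1))
  if (any(hi < lo)) stop("invalid bounds: max below min")
  n <- length(elems)
  # max residual mass attainable from elements i..n
  max_tail <- rev(cumsum(rev(masses * hi)))
  max_tail <- c(max_tail, 0)
  min_tail <- rev(cumsum(rev(masses * lo)))
  min_tail <- c(min_tail, 0)

  out_comp <- list()
  counts <- integer(n)
  recurse <- function(i, remaining) {
    if (i > n) {
      if (abs(remaining) <= tol_da && any(counts > 0L)) {
        out_comp[[length(out_comp) + 1L]] <<- counts
      }
      return(invisible())
    }
    # feasible count range for element i given the residual window
    k_max <- min(hi[i], floor((remaining - min_tail[i + 1] + tol_da) / masses[i]))
    k_min <- max(lo[i], ceiling((remaining - max_tail[i + 1] - tol_da) / masses[i]))
    if (k_max < k_min) return(invisible())
    for (k in k_min:k_max) {
      counts[i] <<- k
      recurse(i + 1L, remaining - k * masses[i])
    }
    counts[i] <<- 0L
  }
  recurse(1L, target_neutral)

  if (!length(out_comp)) {
    return(data.frame(ion_formula = character(0), neutral_mass = numeric(0),
                      theoretical_mz = numeric(0), error_ppm = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(out_comp, function(cc) {
    keep <- cc > 0L
    f <- new_formula(stats::setNames(cc[keep], elems[keep]))
    m <- monoisotopic_mass(f)
    mz <- (m + a$delta) / a$charge
    data.frame(ion_formula = formula_string(f), neutral_mass = m,
               theoretical_mz = mz, error_ppm = ppm_error(observed, mz),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(abs(res$error_ppm), res$ion_formula), , drop = FALSE]
  rownames(res) <- NULL
  res
}
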