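## Molecular formula parsing over the ten-element alphabet the model space is
## defined by.  Anything outside it (Na, charges, isotopes, hydrate dots) is
## rejected, never silently dropped.

#' The supported element alphabet
#'
#' The ten elements whose atom counts form the base feature columns, in the
#' fixed column order used throughout the package.
#'
#' @return character vector \code{c("C","H","N","O","S","P","F","Cl","Br","I")}.
#' @export
#' @examples
#' logpElements()
logpElements <- function() LOGP_ELEMENTS

LOGP_ELEMENTS <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I")

emptyCounts <- function() {
    structure(integer(length(LOGP_ELEMENTS)), names = LOGP_ELEMENTS)
}

#' Parse a molecular formula string into atom counts
#'
#' Parses a plain-text molecular formula (element symbols with optional
#' integer multiplicities and arbitrarily nested parenthesized groups with
#' integer multipliers) into a named integer vector of atom counts over the
#' ten supported elements.  Parsing is case-sensitive: \code{"Cl"} is
#' chlorine, while a stray lowercase letter is a syntax error, so \code{"Cl"}
#' can never be read as carbon plus something.
#'
#' Unsupported element symbols (e.g. \code{"Na"}), unbalanced parentheses,
#' dangling digits, zero multiplicities (a formula asserts presence) and empty
#' strings are all errors.
#'
#' @param formula a single non-empty formula string.
#' @return named integer vector of length 10 (one entry per element of
#'   \code{\link{logpElements}}, absent elements 0), with at least one
#'   positive entry.
#' @export
#' @examples
#' parseFormula("C6H6")
#' parseFormula("C6H4(OH)2")   # hydroquinone: C6 H6 O2
parseFormula <- function(formula) {
    if (!is.character(formula) || length(formula) != 1L || is.na(formula))
        stop("formula must be a single character string")
    if (!nzchar(formula)) stop("parse error: empty formula string")
    chars <- strsplit(formula, "", fixed = TRUE)[[1L]]
    pos <- 1L
    n <- length(chars)

    peek <- function() if (pos <= n) chars[pos] else NA_character_
    readNumber <- function() {
        start <- pos
        while (pos <= n && grepl("[0-9]", chars[pos])) pos <<- pos + 1L
        if (pos == start) return(NA_integer_)
        as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
    }
    parseGroup <- function(depth) {
        counts <- emptyCounts()
        any_token <- FALSE
        repeat {
            ch <- peek()
            if (is.na(ch)) {
                if (depth > 0L)
                    stop("parse error: unbalanced parentheses (unclosed group)")
                break
            }
            if (ch == ")") {
                if (depth == 0L)
                    stop(sprintf(
                        "parse error at position %d: unmatched ')'", pos))
                break
            }
            if (ch == "(") {
                pos <<- pos + 1L
                inner <- parseGroup(depth + 1L)
                if (peek() != ")" || is.na(peek()))
                    stop("parse error: unbalanced parentheses (unclosed group)")
                pos <<- pos + 1L
                mult <- readNumber()
                if (is.na(mult)) mult <- 1L
                if (mult == 0L)
                    stop("parse error: zero multiplicity is not allowed")
                counts <- counts + inner * mult
                any_token <- TRUE
            } else if (grepl("[A-Z]", ch)) {
                start <- pos
                pos <<- pos + 1L
                while (!is.na(peek()) && grepl("[a-z]", peek()))
                    pos <<- pos + 1L
                sym <- paste(chars[start:(pos - 1L)], collapse = "")
                if (!sym %in% LOGP_ELEMENTS)
                    stop(sprintf("unsupported element: %s", sym))
                mult <- readNumber()
                if (is.na(mult)) mult <- 1L
                if (mult == 0L)
                    stop("parse error: zero multiplicity is not allowed")
                counts[sym] <- counts[sym] + mult
                any_token <- TRUE
            } else {
                stop(sprintf("parse error at position %d: unexpected '%s'",
                             pos, ch))
            }
        }
        if (!any_token)
            stop(sprintf("parse error at position %d: empty group", pos))
        counts
    }
    counts <- parseGroup(0L)
    if (sum(counts) < 1L) stop("parse error: formula contains no atoms")
    counts
}

## Vectorized convenience: N x 10 integer matrix of counts, one row per
## formula string.  Internal; errors name the offending row.
parseFormulas <- function(formulas) {
    out <- matrix(0L, nrow = length(formulas), ncol = length(LOGP_ELEMENTS),
                  dimnames = list(NULL, LOGP_ELEMENTS))
    for (i in seq_along(formulas)) {
        out[i, ] <- tryCatch(parseFormula(formulas[i]), error = function(e)
            stop(sprintf("row %d ('%s'): %s", i, formulas[i],
                         conditionMessage(e)), call. = FALSE))
    }
    out
}

#' Is a compound organic?
#'
#' Operational definition used by the curation filter: a compound is organic
#' iff it contains at least one carbon atom.  No hydrogen requirement (CCl4
#' counts as organic).
#'
#' @param counts atom-count vector from \code{\link{parseFormula}}.
#' @return logical flag.
#' @export
#' @examples
#' isOrganic(parseFormula("C6H6"))  # TRUE
#' isOrganic(parseFormula("H2O"))   # FALSE
isOrganic <- function(counts) {
    counts <- checkCounts(counts)
    unname(counts["C"] >= 1L)
}

#' Canonical Hill formula string
#'
#' Serializes atom counts to Hill order: carbon first, hydrogen second, then
#' the remaining elements alphabetically by symbol; unit multiplicities are
#' omitted.  Carbon-free formulas are ordered fully alphabetically.  Used as
#' the canonical key for duplicate detection and isomer grouping.
#'
#' @param counts atom-count vector from \code{\link{parseFormula}}.
#' @return a formula string; \code{parseFormula(hillFormula(x))} recovers
#'   \code{x} for any valid counts.
#' @export
#' @examples
#' hillFormula(parseFormula("H6C6"))  # "C6H6"
#' hillFormula(parseFormula("CCl4"))  # unit multiplicity omitted: "CCl4"
hillFormula <- function(counts) {
    counts <- checkCounts(counts)
    present <- names(counts)[counts > 0L]
    if ("C" %in% present) {
        rest <- sort(setdiff(present, c("C", "H")), method = "radix")
        ord <- c("C", intersect("H", present), rest)
    } else {
        ord <- sort(present, method = "radix")
    }
    paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}

checkCounts <- function(counts) {
    if (is.matrix(counts)) stop("expected a single atom-count vector")
    if (is.null(names(counts)) || !all(names(counts) %in% LOGP_ELEMENTS))
        stop("atom counts must be named by the supported elements")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("atom counts must be non-negative integers")
    full <- emptyCounts()
    full[names(counts)] <- as.integer(counts)
    if (sum(full) < 1L) stop("atom counts must contain at least one atom")
    full
}
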