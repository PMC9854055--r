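## Feature engineering: the base 10-column representation (atom counts) and
## the extended 21-column representation (counts + 9 carbon-relative ratios +
## molar weight + double-bond equivalents).  Column order is frozen so that
## serialized models are portable across runs.

ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                    Br = 79.904, I = 126.904)
ATOMIC_WEIGHTS_VERSION <- "IUPAC-conventional-2021"

RATIO_NAMES <- paste0(setdiff(LOGP_ELEMENTS, "C"), "_C")
EXTENDED_NAMES <- c(LOGP_ELEMENTS, RATIO_NAMES, "MW", "DBE")

#' Atomic weight table
#'
#' The fixed table of conventional atomic weights (g/mol) used for the molar
#' weight feature, one entry per supported element.
#'
#' @return named numeric vector of length 10, with attribute
#'   \code{"version"} stamping the table used.
#' @export
#' @examples
#' atomicWeights()
atomicWeights <- function() {
    structure(ATOMIC_WEIGHTS, version = ATOMIC_WEIGHTS_VERSION)
}

#' Feature column names
#'
#' Names of the feature columns in their frozen order: the ten atom counts,
#' then (extended only) the nine carbon-relative ratios, molar weight
#' \code{MW} and double-bond equivalents \code{DBE}.
#'
#' @param extended logical; return the 21 extended names or the 10 base ones.
#' @return character vector of length 10 or 21.
#' @export
featureNames <- function(extended = FALSE) {
    if (extended) EXTENDED_NAMES else LOGP_ELEMENTS
}

#' Molar weight from atom counts
#'
#' Sum over the ten elements of the atom count times the element's atomic
#' weight.
#'
#' @param counts atom-count vector from \code{\link{parseFormula}}.
#' @param table atomic weight table, by default \code{\link{atomicWeights}}.
#' @return molar weight in g/mol.
#' @export
#' @examples
#' molarWeight(parseFormula("C6H6"))  # 78.114
molarWeight <- function(counts, table = atomicWeights()) {
    counts <- checkCounts(counts)
    if (!all(LOGP_ELEMENTS %in% names(table)) || any(table <= 0))
        stop("weight table must cover all ten elements with positive weights")
    sum(counts * table[names(counts)])
}

#' Double-bond equivalents
#'
#' Rings plus degrees of unsaturation implied by a molecular formula:
#' \deqn{DBE = X_C - (X_H + X_{halogens})/2 + X_N/2 + 1}
#' where the halogens are F, Cl, Br and I.  Benzene (C6H6) has DBE 4;
#' cyclohexyne (C6H8) has DBE 3; every alkane has DBE 0.
#'
#' Chemically inconsistent formulas can yield half-integer or negative
#' values; these are returned with a warning rather than rejected, since
#' mined datasets contain radicals and salts and the models treat DBE as a
#' plain numeric feature.
#'
#' @param counts atom-count vector from \code{\link{parseFormula}}.
#' @return double-bond equivalents (dimensionless).
#' @export
#' @examples
#' dbe(parseFormula("C6H6"))  # 4
#' dbe(parseFormula("C6H8"))  # 3
dbe <- function(counts) {
    counts <- checkCounts(counts)
    halogens <- sum(counts[c("F", "Cl", "Br", "I")])
    value <- unname(counts["C"] - (counts["H"] + halogens) / 2 +
                    counts["N"] / 2 + 1)
    if (value < 0 || value != round(value))
        warning(sprintf(
            "DBE %.1f is negative or non-integer (chemically inconsistent formula)",
            value))
    value
}

#' Carbon-relative elemental ratios
#'
#' The fractional content of each non-carbon element relative to the carbon
#' content: H/C, N/C, O/C, S/C, P/C, F/C, Cl/C, Br/C, I/C as exact quotients.
#' Defined only for organic formulas; carbon-free input is an error (such
#' records must be filtered upstream by \code{\link{curate}}).
#'
#' @param counts atom-count vector from \code{\link{parseFormula}}.
#' @return named numeric vector of the 9 ratios.
#' @export
#' @examples
#' elementalRatios(parseFormula("C2H6O"))  # H_C = 3, O_C = 0.5
elementalRatios <- function(counts) {
    counts <- checkCounts(counts)
    if (counts["C"] < 1L) stop("carbon-free compound")
    structure(unname(counts[setdiff(LOGP_ELEMENTS, "C")] / counts["C"]),
              names = RATIO_NAMES)
}

#' Build the feature matrix
#'
#' Assembles the N x M feature matrix from formula strings or pre-parsed atom
#' counts.  With \code{extended = FALSE} the matrix has the M = 10 atom-count
#' columns; with \code{extended = TRUE} the 9 elemental ratios, molar weight
#' and double-bond equivalents are appended for M = 21.  The first ten
#' columns of the extended matrix always equal the base matrix.
#'
#' @param records character vector of formula strings, a single atom-count
#'   vector, or an N x 10 matrix of atom counts with element column names.
#' @param extended logical; build the 21-column extended matrix.
#' @return numeric N x M matrix with columns \code{\link{featureNames}} and
#'   attribute \code{"weightsVersion"}.
#' @export
#' @examples
#' featurize("C6H6", extended = TRUE)
featurize <- function(records, extended = FALSE) {
    counts <- asCountsMatrix(records)
    if (nrow(counts) < 1L) stop("empty record list")
    if (any(counts[, "C"] < 1L))
        stop(sprintf("carbon-free record in row %d",
                     which(counts[, "C"] < 1L)[1L]))
    X <- counts
    storage.mode(X) <- "double"
    if (extended) {
        ratios <- X[, setdiff(LOGP_ELEMENTS, "C"), drop = FALSE] / X[, "C"]
        colnames(ratios) <- RATIO_NAMES
        mw <- as.vector(X %*% ATOMIC_WEIGHTS[LOGP_ELEMENTS])
        hal <- rowSums(X[, c("F", "Cl", "Br", "I"), drop = FALSE])
        dbeCol <- X[, "C"] - (X[, "H"] + hal) / 2 + X[, "N"] / 2 + 1
        X <- cbind(X, ratios, MW = mw, DBE = dbeCol)
    }
    structure(X, weightsVersion = ATOMIC_WEIGHTS_VERSION)
}

asCountsMatrix <- function(records) {
    if (is.character(records)) {
        if (length(records) < 1L) stop("empty record list")
        parseFormulas(records)
    } else if (is.matrix(records)) {
        if (!all(LOGP_ELEMENTS %in% colnames(records)))
            stop("counts matrix must have the ten element columns")
        m <- records[, LOGP_ELEMENTS, drop = FALSE]
        if (any(m < 0) || any(m != round(m)))
            stop("atom counts must be non-negative integers")
        storage.mode(m) <- "integer"
        m
    } else if (is.numeric(records)) {
        matrix(checkCounts(records), nrow = 1L,
               dimnames = list(NULL, LOGP_ELEMENTS))
    } else stop("records must be formula strings or an atom-count matrix")
}
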