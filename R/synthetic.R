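## Synthetic organic formulas with a known atom-additive LogP response, so
## every pipeline stage is testable without external data.  The defaults
## emulate the statistical shape of mined LogP collections: carbon numbers
## centered on 1-25 with a tail capped at 62, sparse heteroatoms, a response
## SD near 1.8 log units, weak single-feature correlations with the
## response, and a per-formula isomer spread near 0.46 log units
## (sqrt(sigma^2 + sigmaIso^2) with measurement noise 0.3 and isomer offsets
## 0.35).

HETERO_ELEMENTS <- setdiff(LOGP_ELEMENTS, c("C", "H"))

defaultBeta <- function() {
    beta <- structure(numeric(length(EXTENDED_NAMES)),
                      names = EXTENDED_NAMES)
    ## atom-additive truth: weight only on the count block (the derived MW
    ## and DBE columns are exact linear combinations of counts, so weight
    ## there would be unidentifiable; the ratios are nonlinear but kept at
    ## zero so noise-free recovery on the base columns is exact)
    beta[c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")] <-
        c(0.11, -0.60, -0.50, 0.35, -0.50, 0.25, 0.55, 0.60, 0.60)
    beta
}

#' Construct a synthetic-generator specification
#'
#' See \code{\linkS4class{GeneratorSpec}} for the meaning of each parameter.
#' Defaults are calibrated once to emulate a mined LogP dataset (see the
#' vignette): an atom-additive response with SD near 1.8 log units, the
#' strongest single-feature correlation near 0.45 (carbon), measurement noise
#' 0.3 log units and isomer offsets 0.35 log units so the per-formula spread
#' sits near 0.46, and carbon capped at 62.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param carbonMu,carbonSize,carbonMax carbon count distribution.
#' @param heteroProb,heteroMean heteroatom occurrence/abundance.
#' @param dbeRate unsaturation rate.
#' @param beta,beta0 response coefficients (length-21, extended column
#'   order) and intercept.
#' @param sigma,sigmaIso measurement / isomer noise SDs (log units).
#' @param duplicateRate,inorganicRate contamination probabilities.
#' @return a \code{\linkS4class{GeneratorSpec}}.
#' @export
#' @examples
#' spec <- generatorSpec(n = 100, seed = 1)
#' head(generateFormulas(spec))
generatorSpec <- function(n, seed = 1L,
                          carbonMu = 9, carbonSize = 3, carbonMax = 62L,
                          heteroProb = c(N = 0.30, O = 0.45, S = 0.07,
                                         P = 0.015, F = 0.05, Cl = 0.12,
                                         Br = 0.04, I = 0.015),
                          heteroMean = c(N = 0.5, O = 0.9, S = 0.25,
                                         P = 0, F = 1.2, Cl = 0.9,
                                         Br = 0.3, I = 0),
                          dbeRate = 0.25,
                          beta = defaultBeta(), beta0 = 0.25,
                          sigma = 0.3, sigmaIso = 0.45,
                          duplicateRate = 0, inorganicRate = 0) {
    if (!all(HETERO_ELEMENTS %in% names(heteroProb)) ||
        !all(HETERO_ELEMENTS %in% names(heteroMean)))
        stop("heteroProb and heteroMean must name all eight heteroatoms")
    if (is.null(names(beta))) names(beta) <- EXTENDED_NAMES
    new("GeneratorSpec", n = as.integer(n), seed = as.integer(seed),
        carbonMu = carbonMu, carbonSize = carbonSize,
        carbonMax = as.integer(carbonMax),
        heteroProb = heteroProb[HETERO_ELEMENTS],
        heteroMean = heteroMean[HETERO_ELEMENTS],
        dbeRate = dbeRate, beta = beta[EXTENDED_NAMES], beta0 = beta0,
        sigma = sigma, sigmaIso = sigmaIso,
        duplicateRate = duplicateRate, inorganicRate = inorganicRate)
}

setMethod("show", "GeneratorSpec", function(object) {
    cat(sprintf("GeneratorSpec: n=%d seed=%d sigma=%.2f sigmaIso=%.2f dup=%.2f inorg=%.2f\n",
                object@n, object@seed, object@sigma, object@sigmaIso,
                object@duplicateRate, object@inorganicRate))
})

## carbon-free contaminants over the supported alphabet
INORGANIC_POOL <- c("H2O", "H3N", "H2O2", "O2S", "H3O4P", "BrH", "ClH", "H2S")

drawCountsMatrix <- function(spec, n) {
    C <- pmin(1L + stats::rnbinom(n, size = spec@carbonSize,
                                  mu = spec@carbonMu), spec@carbonMax)
    counts <- matrix(0L, n, length(LOGP_ELEMENTS),
                     dimnames = list(NULL, LOGP_ELEMENTS))
    counts[, "C"] <- C
    for (el in HETERO_ELEMENTS) {
        occurs <- stats::rbinom(n, 1L, spec@heteroProb[el])
        extra <- if (spec@heteroMean[el] > 0)
            stats::rpois(n, spec@heteroMean[el]) else 0L
        counts[, el] <- occurs * (1L + extra)
    }
    hal <- rowSums(counts[, c("F", "Cl", "Br", "I"), drop = FALSE])
    hMax <- 2L * C + 2L + counts[, "N"] - hal
    ## degree of unsaturation, truncated so hydrogen stays non-negative
    dbeDraw <- stats::rbinom(n, C, spec@dbeRate)
    dbeDraw <- pmin(dbeDraw, pmax(hMax %/% 2L, 0L))
    counts[, "H"] <- pmax(hMax - 2L * dbeDraw, 0L)
    counts
}

#' Generate synthetic molecular formulas
#'
#' Draws \code{n} organic formulas (carbon >= 1, hydrogen consistent with a
#' drawn unsaturation count, sparse heteroatoms), in canonical Hill notation.
#' With a positive \code{inorganicRate}, a corresponding fraction of entries
#' is replaced by carbon-free contaminant formulas, for exercising the
#' curation filter.  Deterministic under the spec's seed.
#'
#' @param spec a \code{\linkS4class{GeneratorSpec}}.
#' @return character vector of \code{n} parseable formula strings.
#' @export
generateFormulas <- function(spec) {
    stopifnot(is(spec, "GeneratorSpec"))
    n <- spec@n
    if (n == 0L) return(character(0))
    withSeed(spec@seed, {
        counts <- drawCountsMatrix(spec, n)
        formulas <- vapply(seq_len(n),
                           function(i) hillFormula(counts[i, ]),
                           character(1L))
        if (spec@inorganicRate > 0) {
            swap <- stats::runif(n) < spec@inorganicRate
            formulas[swap] <- sample(INORGANIC_POOL, sum(swap),
                                     replace = TRUE)
        }
        formulas
    })
}

#' Generate LogP responses for a set of formulas
#'
#' Each record's LogP is the atom-additive linear response
#' \code{beta . x_extended + beta0} plus a per-record isomer offset
#' \code{N(0, sigmaIso)} (each record plays the role of a distinct isomer of
#' its formula) plus measurement noise \code{N(0, sigma)}.  Carbon-free
#' contaminant formulas receive a plain \code{N(0, 1)} value -- they exist
#' only to be removed by \code{\link{curate}}.  With a positive
#' \code{duplicateRate}, exact copies of that fraction of records are
#' appended (same identity and LogP), for exercising duplicate removal.  The
#' generating parameters are returned alongside for recovery tests.
#'
#' @param formulas character vector of formula strings.
#' @param spec a \code{\linkS4class{GeneratorSpec}}.
#' @return list with \code{records} (data.frame: \code{name}, \code{smiles},
#'   \code{formula}, \code{hill}, \code{logp}, \code{source}) and
#'   \code{truth} (list: \code{beta}, \code{beta0}, \code{sigma},
#'   \code{sigmaIso}).
#' @export
generateResponses <- function(formulas, spec) {
    stopifnot(is(spec, "GeneratorSpec"))
    n <- length(formulas)
    counts <- parseFormulas(formulas)
    organic <- counts[, "C"] >= 1L
    logp <- numeric(n)
    withSeed(spec@seed + 1L, {
        if (any(organic)) {
            Xext <- featurize(counts[organic, , drop = FALSE],
                              extended = TRUE)
            mu <- drop(Xext %*% spec@beta[colnames(Xext)]) + spec@beta0
            logp[organic] <- mu +
                stats::rnorm(sum(organic), 0, spec@sigmaIso) +
                stats::rnorm(sum(organic), 0, spec@sigma)
        }
        if (any(!organic)) logp[!organic] <- stats::rnorm(sum(!organic))
        records <- data.frame(
            name = sprintf("synth-%05d", seq_len(n)),
            smiles = NA_character_,
            formula = formulas,
            hill = vapply(seq_len(n), function(i) hillFormula(counts[i, ]),
                          character(1L)),
            logp = logp, source = "synthetic", stringsAsFactors = FALSE)
        if (spec@duplicateRate > 0) {
            dup <- which(stats::runif(n) < spec@duplicateRate)
            if (length(dup))
                records <- rbind(records, records[dup, , drop = FALSE])
        }
        rownames(records) <- NULL
        list(records = records,
             truth = list(beta = spec@beta, beta0 = spec@beta0,
                          sigma = spec@sigma, sigmaIso = spec@sigmaIso))
    })
}

#' Simulate a complete synthetic LogP dataset
#'
#' Convenience wrapper: \code{\link{generateFormulas}} then
#' \code{\link{generateResponses}}.
#'
#' @inheritParams generateResponses
#' @return as \code{\link{generateResponses}}.
#' @export
simulateLogPDataset <- function(spec) {
    generateResponses(generateFormulas(spec), spec)
}

#' A small hand-verifiable compound fixture
#'
#' A fixed set of well-known compounds (benzene, toluene, phenol, ethanol,
#' methane, carbon tetrachloride, the C4H10O isomer pair 1-butanol / diethyl
#' ether, and friends) with literature-typical LogP values, plus exactly one
#' exact duplicate row and one inorganic row so the curation rules fire once
#' each.  Cyclohexyne carries a synthetic placeholder LogP (no measured value
#' exists); it is present for its DBE of 3.
#'
#' @param raw if TRUE, return the pre-curation data.frame (21 rows, with the
#'   duplicate and the inorganic record still present); if FALSE (default),
#'   return the \code{\linkS4class{CuratedDataset}} of the 19 curated rows.
#' @return data.frame or \code{\linkS4class{CuratedDataset}}.
#' @export
#' @examples
#' provenance(makeGoldFixture())
makeGoldFixture <- function(raw = FALSE) {
    df <- data.frame(
        name = c("benzene", "toluene", "phenol", "ethanol", "methane",
                 "carbon tetrachloride", "1-butanol", "diethyl ether",
                 "acetone", "acetic acid", "chloroform", "aniline",
                 "pyridine", "naphthalene", "hexane", "cyclohexyne",
                 "benzoic acid", "dichloromethane", "acetonitrile",
                 "benzene", "water"),
        smiles = c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "CCO", "C",
                   "ClC(Cl)(Cl)Cl", "CCCCO", "CCOCC", "CC(=O)C", "CC(=O)O",
                   "ClC(Cl)Cl", "Nc1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1",
                   "CCCCCC", "C1CCC#CC1", "OC(=O)c1ccccc1", "ClCCl", "CC#N",
                   "c1ccccc1", "O"),
        formula = c("C6H6", "C7H8", "C6H6O", "C2H6O", "CH4", "CCl4",
                    "C4H10O", "C4H10O", "C3H6O", "C2H4O2", "CHCl3",
                    "C6H7N", "C5H5N", "C10H8", "C6H14", "C6H8",
                    "C7H6O2", "CH2Cl2", "C2H3N", "C6H6", "H2O"),
        logp = c(2.13, 2.73, 1.46, -0.31, 1.09, 2.83, 0.88, 0.89, -0.24,
                 -0.17, 1.97, 0.90, 0.65, 3.30, 3.90, 1.86, 1.87, 1.25,
                 -0.34, 2.13, -1.38),
        source = c(rep("literature", 15), "synthetic", rep("literature", 3),
                   "literature", "literature"),
        stringsAsFactors = FALSE)
    if (raw) df else curate(df)
}
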