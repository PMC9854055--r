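#' @import methods
NULL

#' Class \code{CuratedDataset}
#'
#' A filtered, deduplicated collection of LogP observations.  Created by
#' \code{\link{curate}}; not usually constructed directly.  The \code{records}
#' slot is a data.frame with columns \code{name}, \code{smiles},
#' \code{formula}, \code{hill} (canonical Hill formula), \code{logp} and
#' \code{source}; \code{provenance} counts the records removed per filter
#' rule.
#'
#' @slot records data.frame of curated compound records.
#' @slot provenance named integer vector with elements \code{input},
#'   \code{inorganic}, \code{duplicates} and \code{kept}.
#'
#' @seealso \code{\link{curate}}, \code{\link{records}},
#'   \code{\link{provenance}}, \code{\link{isomerDeviation}}
#' @exportClass CuratedDataset
setClass("CuratedDataset",
    representation(records = "data.frame", provenance = "integer"))

setValidity("CuratedDataset", function(object) {
    rec <- object@records
    msg <- character()
    need <- c("name", "smiles", "formula", "hill", "logp", "source")
    if (!all(need %in% names(rec)))
        msg <- c(msg, paste("records must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(rec) < 1L) msg <- c(msg, "dataset is empty")
        if (!all(is.finite(rec$logp))) msg <- c(msg, "non-finite logp values")
        counts <- tryCatch(parseFormulas(rec$hill), error = function(e) NULL)
        if (is.null(counts) || any(counts[, "C"] < 1L))
            msg <- c(msg, "all records must be organic (C >= 1)")
        key <- paste(recordIdentity(rec), rec$logp, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "exact (identity, logp) duplicates present")
    }
    pv <- object@provenance
    if (!all(c("input", "inorganic", "duplicates", "kept") %in% names(pv)))
        msg <- c(msg, "provenance must name input, inorganic, duplicates, kept")
    if (length(msg)) msg else TRUE
})

#' Class \code{ModelSpec}
#'
#' The specification of one of the six supported regressors: its kind, its
#' hyperparameters, whether it consumes the extended 21-column feature matrix,
#' and the seed governing any stochastic fitting.
#'
#' @slot kind one of \code{"mlr"}, \code{"ridge"}, \code{"lasso"},
#'   \code{"rfr"}, \code{"gbr"}, \code{"knnr"}.
#' @slot params named list of the hyperparameters relevant to \code{kind}
#'   (see \code{\link{defaultSpec}}).
#' @slot extended logical; use the 21-column extended feature matrix.
#' @slot seed integer seed for stochastic fits.
#'
#' @seealso \code{\link{modelSpec}}, \code{\link{defaultSpec}},
#'   \code{\link{fitModel}}
#' @exportClass ModelSpec
setClass("ModelSpec",
    representation(kind = "character", params = "list", extended = "logical",
                   seed = "integer"))

MODEL_KINDS <- c("mlr", "ridge", "lasso", "rfr", "gbr", "knnr")

setValidity("ModelSpec", function(object) {
    msg <- character()
    if (length(object@kind) != 1L || !object@kind %in% MODEL_KINDS)
        msg <- c(msg, paste("kind must be one of:",
                            paste(MODEL_KINDS, collapse = ", ")))
    if (length(object@extended) != 1L || is.na(object@extended))
        msg <- c(msg, "extended must be TRUE or FALSE")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Class \code{LogPModel}
#'
#' A fitted LogP regressor: the \code{\link{ModelSpec}} it was fitted under,
#' the opaque fitted state, and the names of the feature columns it expects.
#' Obtain predictions with \code{\link[=predict,LogPModel-method]{predict}}.
#'
#' @slot spec the \code{ModelSpec}.
#' @slot fit list holding the fitted state (kind-dependent).
#' @slot featureNames character vector naming the feature columns; its length
#'   is the feature width M the model predicts on.
#'
#' @seealso \code{\link{fitModel}}, \code{\link{evaluateModel}}
#' @exportClass LogPModel
setClass("LogPModel",
    representation(spec = "ModelSpec", fit = "list",
                   featureNames = "character"))

setValidity("LogPModel", function(object) {
    if (length(object@featureNames) < 1L)
        "featureNames must be non-empty" else TRUE
})

#' Class \code{FactorialExperiment}
#'
#' Result of \code{\link{runFactorial}}: the 2-level, 3-factor
#' training-protocol experiment.  \code{cells} holds one row per factor
#' combination and model kind, with mean and standard deviation of RMSE, MAE
#' and R-squared over the repeated random splits, for both the training and
#' the validation partition.
#'
#' @slot cells data.frame of per-cell summaries.
#' @slot specs nested list of the default and tuned \code{ModelSpec}s used.
#' @slot repeats integer, number of randomized repeats per cell.
#' @slot seed integer master seed.
#'
#' @seealso \code{\link{runFactorial}}, \code{\link{selectFinal}}
#' @exportClass FactorialExperiment
setClass("FactorialExperiment",
    representation(cells = "data.frame", specs = "list", repeats = "integer",
                   seed = "integer"))

#' Class \code{GeneratorSpec}
#'
#' Parameters of the synthetic compound generator: how many formulas, the
#' element count distributions, the atom-additive response coefficients, the
#' measurement and isomer noise scales, and the contamination rates used to
#' exercise the curation filters.  Construct with \code{\link{generatorSpec}}.
#'
#' @slot n integer, number of compound records to draw.
#' @slot seed integer seed; every generator operation is deterministic in it.
#' @slot carbonMu,carbonSize numeric; the carbon count is
#'   1 + NegBinomial(mu = carbonMu, size = carbonSize), capped at
#'   \code{carbonMax}.
#' @slot carbonMax integer cap on the carbon number.
#' @slot heteroProb named numeric, per-element occurrence probability for the
#'   nine non-carbon elements.
#' @slot heteroMean named numeric, mean extra atoms (beyond the first) when an
#'   element occurs.
#' @slot dbeRate numeric; rings-plus-unsaturations are drawn as
#'   Binomial(C, dbeRate), truncated to keep the hydrogen count non-negative.
#' @slot beta named numeric of length 21, response coefficients over the
#'   extended feature columns.
#' @slot beta0 numeric intercept.
#' @slot sigma numeric, measurement noise SD (log units).
#' @slot sigmaIso numeric, per-record isomer offset SD (log units).
#' @slot duplicateRate,inorganicRate numeric contamination probabilities.
#'
#' @seealso \code{\link{generatorSpec}}, \code{\link{generateFormulas}},
#'   \code{\link{generateResponses}}
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
    representation(n = "integer", seed = "integer", carbonMu = "numeric",
                   carbonSize = "numeric", carbonMax = "integer",
                   heteroProb = "numeric", heteroMean = "numeric",
                   dbeRate = "numeric", beta = "numeric", beta0 = "numeric",
                   sigma = "numeric", sigmaIso = "numeric",
                   duplicateRate = "numeric", inorganicRate = "numeric"))

setValidity("GeneratorSpec", function(object) {
    msg <- character()
    probs <- c(object@heteroProb, object@duplicateRate, object@inorganicRate,
               object@dbeRate)
    if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
    if (object@sigma < 0 || object@sigmaIso < 0)
        msg <- c(msg, "sigma and sigmaIso must be >= 0")
    if (object@n < 0L) msg <- c(msg, "n must be >= 0")
    if (length(object@beta) != 21L)
        msg <- c(msg, "beta must have length 21 (extended feature order)")
    if (length(msg)) msg else TRUE
})
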