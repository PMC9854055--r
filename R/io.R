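## Model persistence: a single file with an embedded plain-text JSON header
## (spec, feature width, atomic-weight table version) ahead of the fitted
## state, so a saved model is self-describing.

#' Save a fitted model to a file
#'
#' Serializes the model to a single file whose payload embeds a JSON header
#' recording the model kind, hyperparameters, feature width and the
#' atomic-weight table version the features were built with.
#'
#' @param model a \code{\linkS4class{LogPModel}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "LogPModel"))
    if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("saveModel needs the jsonlite package")
    header <- jsonlite::toJSON(list(
        format = "FormulaLogP-model-1",
        kind = model@spec@kind,
        params = model@spec@params[!vapply(model@spec@params, is.null,
                                           logical(1L))],
        extended = model@spec@extended,
        featureWidth = length(model@featureNames),
        featureNames = model@featureNames,
        weightsVersion = ATOMIC_WEIGHTS_VERSION), auto_unbox = TRUE)
    fit <- model@fit
    fit$booster <- NULL  # keep only the portable raw bytes for boosters
    saveRDS(list(header = as.character(header),
                 spec = model@spec, fit = fit,
                 featureNames = model@featureNames),
            path)
    invisible(path)
}

#' Load a fitted model from a file
#'
#' @param path file written by \code{\link{saveModel}}.
#' @return a \code{\linkS4class{LogPModel}}.
#' @export
loadModel <- function(path) {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$header) ||
        !grepl("FormulaLogP-model", obj$header, fixed = TRUE))
        stop("not a FormulaLogP model file")
    newLogPModel(obj$spec, obj$fit, obj$featureNames)
}
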