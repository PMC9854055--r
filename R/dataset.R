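## Dataset I/O, curation, isomer statistics and train/test splitting.

#' Read compound records from a CSV file
#'
#' Reads a CSV of compound records, mapping the file's column names onto the
#' fields the package uses.  Rows whose formula does not parse over the
#' ten-element alphabet (e.g. one containing sodium) are not silently
#' dropped: they are collected into a rejects table with the reason.
#'
#' @param path path to a CSV file with a header row (UTF-8).
#' @param columnMap named list mapping fields to file columns; \code{formula}
#'   and \code{logp} are required, \code{name}, \code{smiles} and
#'   \code{source} optional.
#' @return list with elements \code{records} (data.frame with columns
#'   \code{name}, \code{smiles}, \code{formula}, \code{hill}, \code{logp},
#'   \code{source}) and \code{rejects} (data.frame with the offending row,
#'   its formula and the parse message).
#' @export
#' @examples
#' path <- system.file("extdata", "toy_compounds.csv", package = "FormulaLogP")
#' out <- readRecords(path)
#' nrow(out$records); nrow(out$rejects)
readRecords <- function(path,
                        columnMap = list(name = "name", smiles = "smiles",
                                         formula = "formula", logp = "logp",
                                         source = "source")) {
    if (!file.exists(path)) stop(sprintf("cannot read file: %s", path))
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    for (req in c("formula", "logp")) {
        col <- columnMap[[req]]
        if (is.null(col) || !col %in% names(raw))
            stop(sprintf("config error: required column '%s' (mapped to '%s') not in file",
                         req, if (is.null(col)) "<unset>" else col))
    }
    pull <- function(field) {
        col <- columnMap[[field]]
        if (!is.null(col) && col %in% names(raw)) as.character(raw[[col]])
        else rep(NA_character_, nrow(raw))
    }
    records <- data.frame(name = pull("name"), smiles = pull("smiles"),
                          formula = as.character(raw[[columnMap$formula]]),
                          hill = rep(NA_character_, nrow(raw)),
                          logp = as.numeric(raw[[columnMap$logp]]),
                          source = pull("source"),
                          stringsAsFactors = FALSE)
    reason <- character(nrow(records))
    for (i in seq_len(nrow(records))) {
        res <- tryCatch({
            records$hill[i] <- hillFormula(parseFormula(records$formula[i]))
            if (!is.finite(records$logp[i])) stop("non-finite logp")
            ""
        }, error = function(e) conditionMessage(e))
        reason[i] <- res
    }
    bad <- nzchar(reason)
    list(records = records[!bad, , drop = FALSE],
         rejects = cbind(records[bad, c("name", "formula", "logp"),
                                 drop = FALSE],
                         reason = reason[bad]))
}

#' Curate a set of compound records
#'
#' Applies the two curation rules to parsed records: removes carbon-free
#' (inorganic) compounds, and removes exact duplicates of the (canonical
#' identity, logp) pair, keeping the first occurrence.  The canonical
#' identity is the SMILES string when present, otherwise the (name, Hill
#' formula) pair.  Repeated measurements of one compound with \emph{distinct}
#' LogP values are retained, as are isomers sharing a formula: both carry
#' real information about the spread the model must live with.
#'
#' @param records data.frame of records as returned by
#'   \code{\link{readRecords}} (column \code{hill} is recomputed if absent).
#' @return a \code{\linkS4class{CuratedDataset}}.
#' @export
#' @examples
#' raw <- makeGoldFixture(raw = TRUE)
#' ds <- curate(raw)
#' provenance(ds)
curate <- function(records) {
    if (is(records, "CuratedDataset")) records <- records@records
    if (!is.data.frame(records) || nrow(records) == 0L)
        stop("empty dataset")
    need <- c("formula", "logp")
    if (!all(need %in% names(records)))
        stop("records need at least 'formula' and 'logp' columns")
    for (opt in c("name", "smiles", "source"))
        if (!opt %in% names(records)) records[[opt]] <- NA_character_
    if (!"hill" %in% names(records) || anyNA(records$hill)) {
        records$hill <- vapply(records$formula, function(f)
            hillFormula(parseFormula(f)), character(1L), USE.NAMES = FALSE)
    }
    input <- nrow(records)
    counts <- parseFormulas(records$hill)
    organic <- counts[, "C"] >= 1L
    records <- records[organic, , drop = FALSE]
    key <- paste(recordIdentity(records), records$logp, sep = "\r")
    dup <- duplicated(key)
    records <- records[!dup, , drop = FALSE]
    if (nrow(records) == 0L) stop("empty dataset")
    rownames(records) <- NULL
    new("CuratedDataset",
        records = records[, c("name", "smiles", "formula", "hill", "logp",
                              "source")],
        provenance = c(input = input, inorganic = sum(!organic),
                       duplicates = sum(dup), kept = nrow(records)))
}

#' The curated record table
#'
#' @param object a \code{\linkS4class{CuratedDataset}}.
#' @return data.frame of records.
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' Per-rule removal counts of a curated dataset
#'
#' @param object a \code{\linkS4class{CuratedDataset}}.
#' @return named integer vector (\code{input}, \code{inorganic},
#'   \code{duplicates}, \code{kept}).
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname records
#' @export
setMethod("records", "CuratedDataset", function(object) object@records)

#' @rdname provenance
#' @export
setMethod("provenance", "CuratedDataset", function(object) object@provenance)

setMethod("show", "CuratedDataset", function(object) {
    pv <- object@provenance
    cat(sprintf("CuratedDataset with %d records (%d read, %d inorganic and %d duplicate removed)\n",
                pv["kept"], pv["input"], pv["inorganic"], pv["duplicates"]))
    cat(sprintf("  unique formulas: %d\n", length(unique(object@records$hill))))
    cat(sprintf("  logp range: [%.2f, %.2f]\n",
                min(object@records$logp), max(object@records$logp)))
})

#' Per-formula isomer LogP spread
#'
#' Groups the curated records by canonical Hill formula and reports, per
#' formula, the number of observations and the mean and sample standard
#' deviation (n - 1 denominator) of LogP.  The summary aggregates the
#' standard deviations over formulas with at least two observations: their
#' minimum, mean and maximum.  This spread bounds the accuracy any
#' formula-only predictor can reach, since isomers are indistinguishable to
#' it.
#'
#' @param ds a \code{\linkS4class{CuratedDataset}}.
#' @return list with \code{perFormula} (data.frame: \code{hill}, \code{n},
#'   \code{mean}, \code{sd}; \code{sd} is NA for n = 1) and \code{summary}
#'   (named numeric: \code{min}, \code{mean}, \code{max} over the defined
#'   sds, and \code{nFormulas} counting formulas with n >= 2).
#' @export
isomerDeviation <- function(ds) {
    stopifnot(is(ds, "CuratedDataset"))
    rec <- ds@records
    grp <- split(rec$logp, rec$hill)
    perFormula <- data.frame(
        hill = names(grp),
        n = lengths(grp),
        mean = vapply(grp, mean, numeric(1L)),
        sd = vapply(grp, function(v)
            if (length(v) >= 2L) stats::sd(v) else NA_real_, numeric(1L)),
        row.names = NULL, stringsAsFactors = FALSE)
    sds <- perFormula$sd[!is.na(perFormula$sd)]
    summary <- if (length(sds))
        c(min = min(sds), mean = mean(sds), max = max(sds),
          nFormulas = length(sds))
    else c(min = NA_real_, mean = NA_real_, max = NA_real_, nFormulas = 0)
    list(perFormula = perFormula, summary = summary)
}

#' Reproducible train/held-out split
#'
#' Draws a uniformly random permutation of \code{1:N} under the given seed
#' and assigns the first \code{floor(trainFraction * N)} indices to the
#' training partition, the remainder to the held-out partition.  The floor
#' rule is the one consistent with both published split sizes of the mined
#' dataset (15,377/2,714 at 85\% of 18,091 and 12,301/3,076 at 80\% of
#' 15,377).  Deterministic for fixed (N, fraction, seed); the caller's RNG
#' state is left untouched.
#'
#' @param N number of records (>= 2).
#' @param trainFraction fraction in (0, 1) assigned to training.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{heldOut}
#'   (disjoint, covering \code{1:N}) and the \code{seed}.
#' @export
#' @examples
#' s <- splitDataset(18091, 0.85, seed = 1)
#' length(s$train)    # 15377
#' length(s$heldOut)  # 2714
splitDataset <- function(N, trainFraction, seed) {
    if (!is.numeric(N) || length(N) != 1L || N < 2L)
        stop("N must be a single count >= 2")
    if (!is.numeric(trainFraction) || length(trainFraction) != 1L ||
        trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must lie strictly inside (0, 1)")
    N <- as.integer(N)
    perm <- withSeed(seed, sample.int(N))
    nTrain <- floor(trainFraction * N)
    list(train = sort(perm[seq_len(nTrain)]),
         heldOut = sort(perm[seq.int(nTrain + 1L, N)]),
         seed = as.integer(seed))
}
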