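## Post-hoc error analysis: functional-group stratification from SMILES,
## best/worst ranking, and feature-response correlation screening.  SMILES
## handling is confined to this module: the predictive path never needs
## structure.

FUNCTIONAL_GROUPS <- list(
    aromatic = "a",
    carbonyl = "[CX3]=[OX1]",
    alcohol = "[#6][OX2H]",
    amine_nitrile = c("[NX3;!$([NX3]=[OX1])]", "[NX1]#[CX2]"),
    unsaturated_aliphatic = c("C=C", "C#C"),
    ether_ester = "[OD2]([#6])[#6]",
    halogenated = "[F,Cl,Br,I]",
    heteroatom_other = c("[#16]", "[#15]"))

#' Functional-group SMARTS patterns
#'
#' The fixed substructure pattern list behind \code{\link{detectGroups}}: one
#' or more SMARTS patterns per group; a group's flag is set when any of its
#' patterns matches.  The taxonomy (aromatic, carbonyl, alcohol,
#' amine/nitrile, unsaturated aliphatic, ether/ester, halogenated, other
#' heteroatom) is an explicit documented stand-in for the common
#' error-stratification classes of LogP datasets; it is deliberately coarse
#' (e.g. the alcohol pattern also matches phenols and the hydroxyl of
#' carboxylic acids).
#'
#' @return named list of character vectors of SMARTS patterns.
#' @export
functionalGroupPatterns <- function() FUNCTIONAL_GROUPS

#' Detect functional groups from SMILES strings
#'
#' One-hot encodes (1 = present, 0 = absent) the presence of each functional
#' group of \code{\link{functionalGroupPatterns}} in each molecule, by SMARTS
#' substructure matching (OpenBabel via \pkg{ChemmineR}/\pkg{ChemmineOB}).
#' A single unparseable SMILES is an error; in batch mode (length > 1)
#' offending molecules are skipped with a warning naming them and their flag
#' rows are NA.
#'
#' @param smiles character vector of SMILES strings.
#' @return integer matrix, one row per molecule, one column per group.
#' @export
#' @examples
#' \donttest{detectGroups(c("c1ccccc1", "CCO", "CC(=O)C"))}
detectGroups <- function(smiles) {
    if (!is.character(smiles) || length(smiles) < 1L)
        stop("smiles must be a non-empty character vector")
    groups <- names(FUNCTIONAL_GROUPS)
    flags <- matrix(NA_integer_, nrow = length(smiles), ncol = length(groups),
                    dimnames = list(names(smiles), groups))
    ## validity scan (OpenBabel yields an empty molecule, not an error,
    ## for bad SMILES: detect via a zero atom count)
    bad <- vapply(seq_along(smiles), function(i) {
        cnt <- tryCatch(
            ChemmineR::atomcount(
                suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))),
            error = function(e) NULL)
        is.null(cnt) || length(cnt) == 0L || sum(cnt[[1L]]) == 0
    }, logical(1L))
    if (all(bad)) {
        if (length(smiles) == 1L)
            stop(sprintf("unparseable SMILES: '%s'", smiles[1L]))
        warning(sprintf("all %d SMILES unparseable; returning NA flags",
                        length(smiles)))
        return(flags)
    }
    if (any(bad))
        warning(sprintf("skipping %d unparseable SMILES (rows %s)",
                        sum(bad),
                        paste(which(bad), collapse = ", ")))
    good <- smiles[!bad]
    names(good) <- sprintf("mol%06d", which(!bad))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(good))
    for (g in groups) {
        hit <- rep(FALSE, sum(!bad))
        for (pat in FUNCTIONAL_GROUPS[[g]]) {
            m <- ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = FALSE)
            hit <- hit | (m > 0)
        }
        flags[!bad, g] <- as.integer(hit)
    }
    flags
}

#' Per-group summary of absolute prediction errors
#'
#' For each functional group, summarizes the absolute errors of the
#' molecules carrying that group's flag: count, mean, median, and the 5th
#' and 95th percentiles (linear interpolation between order statistics).  A
#' molecule flagged with several groups contributes to each of them; rows
#' with NA flags (unparseable SMILES) are excluded from every group.  Empty
#' groups are reported with n = 0.
#'
#' @param errors numeric vector of absolute errors (|predicted - observed|,
#'   log units), all >= 0.
#' @param flags integer matrix as from \code{\link{detectGroups}}, one row
#'   per error.
#' @return data.frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{median}, \code{p5}, \code{p95}.
#' @export
groupErrorSummary <- function(errors, flags) {
    if (length(errors) < 1L) stop("no error records")
    if (any(errors < 0, na.rm = TRUE)) stop("absolute errors must be >= 0")
    if (!is.matrix(flags) || nrow(flags) != length(errors))
        stop("flags must be a matrix with one row per error")
    out <- lapply(colnames(flags), function(g) {
        sel <- !is.na(flags[, g]) & flags[, g] == 1L
        e <- errors[sel]
        if (length(e) == 0L)
            data.frame(group = g, n = 0L, mean = NA_real_,
                       median = NA_real_, p5 = NA_real_, p95 = NA_real_)
        else
            data.frame(group = g, n = length(e), mean = mean(e),
                       median = stats::median(e),
                       p5 = unname(stats::quantile(e, 0.05, type = 7)),
                       p95 = unname(stats::quantile(e, 0.95, type = 7)))
    })
    do.call(rbind, out)
}

#' Best and worst predicted compounds
#'
#' Ranks records by absolute error and returns the k smallest (best
#' predictions) and k largest (worst).  Ties are broken by input order
#' (stable sort).
#'
#' @param errors numeric vector of absolute errors.
#' @param k how many records per list (\code{k <= length(errors)}).
#' @param ids optional identities parallel to \code{errors}.
#' @return list of two data.frames, \code{best} and \code{worst}, each with
#'   columns \code{index}, \code{id}, \code{error}.
#' @export
rankErrors <- function(errors, k, ids = NULL) {
    n <- length(errors)
    if (k > n) stop(sprintf("k (%d) exceeds the number of records (%d)",
                            k, n))
    if (is.null(ids)) ids <- as.character(seq_len(n))
    asc <- order(errors)            # stable: ties keep input order
    desc <- order(-errors)
    mk <- function(idx) data.frame(index = idx, id = ids[idx],
                                   error = errors[idx],
                                   stringsAsFactors = FALSE)
    list(best = mk(asc[seq_len(k)]), worst = mk(desc[seq_len(k)]))
}

#' Feature-response correlation screen
#'
#' Pairwise Pearson correlations among the feature columns and between each
#' feature and the response, plus a univariate-regression F-test of each
#' feature against the response (F statistic on (1, N - 2) degrees of
#' freedom, via \code{\link[stats]{lm}}).  Constant columns are reported as
#' NA (undefined), not an error.
#'
#' @param X feature matrix (N x M, N >= 3).
#' @param y numeric responses.
#' @return list with \code{correlations} (symmetric (M+1) x (M+1) matrix
#'   over the features and \code{LogP}, unit diagonal) and \code{ftest}
#'   (data.frame: \code{feature}, \code{statistic}, \code{p.value}).
#' @export
correlationScreen <- function(X, y) {
    X <- checkXy(X, y)
    if (nrow(X) < 3L) stop("need at least 3 rows")
    colnames(X) <- featNamesOf(X)
    A <- cbind(X, LogP = y)
    cors <- suppressWarnings(stats::cor(A))
    diag(cors) <- ifelse(apply(A, 2L, function(v) stats::sd(v) > 0), 1,
                         NA_real_)
    ftest <- do.call(rbind, lapply(colnames(X), function(f) {
        xj <- X[, f]
        if (stats::sd(xj) == 0)
            return(data.frame(feature = f, statistic = NA_real_,
                              p.value = NA_real_))
        ## exact feature-response relationships trip summary.lm's
        ## perfect-fit warning; the F statistic itself is still well defined
        fs <- suppressWarnings(summary(stats::lm(y ~ xj))$fstatistic)
        data.frame(feature = f, statistic = unname(fs[1L]),
                   p.value = stats::pf(fs[1L], fs[2L], fs[3L],
                                       lower.tail = FALSE))
    }))
    list(correlations = cors, ftest = ftest)
}
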