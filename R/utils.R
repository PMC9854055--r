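## Run an expression under a fixed seed without disturbing the caller's RNG
## stream.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Canonical identity of a record: SMILES if present, else (name, Hill
## formula).  Used for duplicate detection during curation.
recordIdentity <- function(records) {
    smiles <- as.character(records$smiles)
    hasSmiles <- !is.na(smiles) & nzchar(smiles)
    name <- as.character(records$name)
    name[is.na(name)] <- ""
    ifelse(hasSmiles, paste0("smiles:", smiles),
           paste0("nf:", name, "|", records$hill))
}
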