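# internal helpers shared across modules

# run code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# numeric threshold comparison robust to representation error; all pipeline
# cutoffs are inclusive (>=)
.at_least <- function(x, cut, tol = 1e-9) x >= cut - tol

.is_dna <- function(x) is(x, "DNAStringSet") || is(x, "DNAString")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# empty hit table: the single schema used by the whole package
.empty_hits <- function() {
    data.frame(
        query_id = character(), subject_id = character(),
        perc_identity = numeric(), align_length = integer(),
        q_start = integer(), q_end = integer(),
        s_start = integer(), s_end = integer(),
        query_cov = numeric(), subject_cov = numeric(),
        score = numeric(), strand = character(),
        stringsAsFactors = FALSE)
}
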