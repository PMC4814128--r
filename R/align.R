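#' @include classes.R
NULL

# substitution matrix cache (BLOSUM62 etc. from Biostrings)
.submat_env <- new.env(parent = emptyenv())

.get_submat <- function(name) {
    if (is.null(.submat_env[[name]])) {
        e <- new.env()
        utils::data(list = name, package = "Biostrings", envir = e)
        .submat_env[[name]] <- get(name, envir = e)
    }
    .submat_env[[name]]
}

# nucleotide substitution matrix for the oracle, with every non-ACGT letter
# (incl. N) scored as a mismatch so the oracle agrees with the engine's
# "N never matches" rule
.oracle_nt_matrix <- function(match, mismatch) {
    mat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
        baseOnly = FALSE)
    nonb <- setdiff(rownames(mat), c("A", "C", "G", "T"))
    mat[nonb, ] <- mismatch
    mat[, nonb] <- mismatch
    mat
}

.is_protein_task <- function(params) identical(params@task, "blastp_like")

.check_alphabet <- function(x, params, what) {
    if (.is_protein_task(params)) {
        if (!is(x, "AAStringSet"))
            .stopf("%s must be an AAStringSet for task %s", what, params@task)
    } else {
        if (!is(x, "DNAStringSet"))
            .stopf("%s must be a DNAStringSet for task %s", what, params@task)
    }
}

.named_set <- function(x, prefix) {
    if (is.character(x)) {
        nm <- names(x)
        x <- if (any(grepl("[^ACGTNacgtn]", x))) AAStringSet(x) else DNAStringSet(x)
        names(x) <- nm
    }
    if (is.null(names(x)) || any(names(x) == ""))
        names(x) <- paste0(prefix, seq_along(x))
    x
}

# ------------------------------------------------------------------ findHits

#' Local-alignment search between two sequence sets
#'
#' Searches every query against every subject and returns the best local
#' alignment per query/subject pair (no HSP tiling), with identity and
#' coverage metrics, filtered by whichever cutoffs in `params` are set.
#' Both strands are searched for nucleotide tasks; on the minus strand
#' `s_start > s_end` (query coordinates always ascending). Identity is
#' matches / alignment columns (gaps included) x 100; coverages are the
#' aligned span over the full query/subject length. Output is sorted by
#' (query, descending score) and is deterministic for fixed inputs.
#'
#' The default backend is the built-in seed-and-extend engine (exact k-mer
#' seeding, diagonal clustering, banded Smith-Waterman extension); the
#' `external` backend shells out to BLAST+ (`blastn`/`blastp`) and filters
#' its tabular output identically, falling back to the builtin engine with
#' a notice when the binary is absent.
#'
#' @param queries,subjects `DNAStringSet` (nucleotide tasks) or
#'   `AAStringSet` (`blastp_like`).
#' @param params an [alignParams()] object.
#' @param backend `"builtin"` or `"external"`.
#' @return a data.frame with columns `query_id`, `subject_id`,
#'   `perc_identity`, `align_length`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `query_cov`, `subject_cov`, `score`, `strand`.
#' @examples
#' q <- Biostrings::DNAStringSet(c(g = paste(rep("ACGTT", 20), collapse = "")))
#' findHits(q, q, alignParams("blastn_like"))
#' @export
findHits <- function(queries, subjects, params = alignParams(),
                     backend = c("builtin", "external")) {
    backend <- match.arg(backend)
    queries <- .named_set(queries, "Q")
    subjects <- .named_set(subjects, "S")
    .check_alphabet(queries, params, "queries")
    .check_alphabet(subjects, params, "subjects")
    if (length(queries) == 0 || length(subjects) == 0) return(.empty_hits())
    if (any(width(queries) == 0) || any(width(subjects) == 0))
        .stopf("empty sequences are not searchable")
    if (backend == "external") {
        out <- .external_search(queries, subjects, params)
        if (!is.null(out)) return(out)
        message("external alignment backend unavailable; using builtin engine")
    }
    .builtin_search(queries, subjects, params)
}

.builtin_search <- function(queries, subjects, params) {
    protein <- .is_protein_task(params)
    submat <- if (protein) .get_submat(params@submat) else NULL
    run <- function(qchar) {
        .seed_extend_search(qchar, as.character(subjects),
            params@word_size, params@min_seed_count,
            params@match, params@mismatch,
            params@gap_open, params@gap_ext,
            protein, submat, params@diag_gap, params@band_pad)
    }
    plus <- run(as.character(queries))
    if (nrow(plus)) plus$strand <- "+"
    if (!protein) {
        minus <- run(as.character(reverseComplement(queries)))
        if (nrow(minus)) {
            qlen <- width(queries)[minus$qi]
            qs <- qlen - minus$q_end + 1L
            qe <- qlen - minus$q_start + 1L
            minus$q_start <- qs
            minus$q_end <- qe
            tmp <- minus$s_start
            minus$s_start <- minus$s_end
            minus$s_end <- tmp
            minus$strand <- "-"
        }
        raw <- rbind(plus, minus)
    } else raw <- plus
    .finish_hits(raw, queries, subjects, params)
}

# shared post-processing: best hit per pair, metrics, cutoff filter, sorting
.finish_hits <- function(raw, queries, subjects, params) {
    if (is.null(raw) || nrow(raw) == 0) return(.empty_hits())
    qlen <- width(queries)[raw$qi]
    slen <- width(subjects)[raw$si]
    hit <- data.frame(
        query_id = names(queries)[raw$qi],
        subject_id = names(subjects)[raw$si],
        perc_identity = 100 * raw$matches / raw$align_length,
        align_length = as.integer(raw$align_length),
        q_start = as.integer(raw$q_start), q_end = as.integer(raw$q_end),
        s_start = as.integer(raw$s_start), s_end = as.integer(raw$s_end),
        query_cov = 100 * (raw$q_end - raw$q_start + 1) / qlen,
        subject_cov = 100 * (abs(raw$s_end - raw$s_start) + 1) / slen,
        score = raw$score,
        strand = raw$strand,
        stringsAsFactors = FALSE)
    # single best local alignment per query/subject pair
    ord <- order(hit$query_id, hit$subject_id, -hit$score,
        hit$strand != "+", pmin(hit$s_start, hit$s_end))
    hit <- hit[ord, , drop = FALSE]
    hit <- hit[!duplicated(hit[, c("query_id", "subject_id")]), , drop = FALSE]
    keep <- hitPasses(hit, params)
    hit <- hit[keep, , drop = FALSE]
    # per-query cap
    if (nrow(hit)) {
        hit <- do.call(rbind, lapply(split(hit, hit$query_id), function(h) {
            h[head(order(-h$score, h$subject_id), params@max_target_hits), , drop = FALSE]
        }))
    }
    hit <- hit[order(hit$query_id, -hit$score, hit$subject_id,
        pmin(hit$s_start, hit$s_end)), , drop = FALSE]
    rownames(hit) <- NULL
    hit
}

#' Does a hit pass the parameter cutoffs?
#'
#' A hit passes when its percent identity, query coverage and subject
#' coverage each meet the corresponding cutoff; cutoffs set to `NA` are
#' ignored. All comparisons are inclusive (`>=`).
#'
#' @param hit a hit table as returned by [findHits()] (one or more rows).
#' @param params an [alignParams()] object.
#' @return logical vector, one element per row of `hit`.
#' @export
hitPasses <- function(hit, params) {
    if (nrow(hit) == 0) return(logical(0))
    ok <- rep(TRUE, nrow(hit))
    if (!is.na(params@perc_identity_cut))
        ok <- ok & .at_least(hit$perc_identity, params@perc_identity_cut)
    if (!is.na(params@query_cov_cut))
        ok <- ok & .at_least(hit$query_cov, params@query_cov_cut)
    if (!is.na(params@subject_cov_cut))
        ok <- ok & .at_least(hit$subject_cov, params@subject_cov_cut)
    ok
}

# ----------------------------------------------------------------- DP oracle

#' Optimal local alignment (dynamic-programming oracle)
#'
#' Exact Smith-Waterman local alignment under the same scoring as the
#' built-in engine, computed with `Biostrings::pairwiseAlignment()`.
#' Intended as an independent reference in tests and during synthetic-data
#' generation; quadratic cost, guarded to a combined length of 20 kb.
#' Both strands are tried for nucleotide inputs and the better one
#' reported.
#'
#' @param q,s single sequences (`DNAString`/`AAString`, length-1 sets, or
#'   character).
#' @param params an [alignParams()] supplying the scoring.
#' @return a one-row hit table in the [findHits()] schema, or a zero-row
#'   table when no positive-scoring local alignment exists.
#' @export
dpAlignOracle <- function(q, s, params = alignParams()) {
    protein <- .is_protein_task(params)
    as_one <- function(x, what) {
        if (is.character(x)) x <- if (protein) AAStringSet(x) else DNAStringSet(x)
        if (is(x, "XStringSet")) {
            if (length(x) != 1) .stopf("%s must be a single sequence", what)
            return(x)
        }
        if (protein) AAStringSet(as.character(x)) else DNAStringSet(as.character(x))
    }
    qs <- as_one(q, "q"); ss <- as_one(s, "s")
    if (is.null(names(qs))) names(qs) <- "query"
    if (is.null(names(ss))) names(ss) <- "subject"
    if (width(qs) + width(ss) > 20000L)
        .stopf("dpAlignOracle size guard: combined length %d exceeds 20000",
            width(qs) + width(ss))
    mat <- if (protein) .get_submat(params@submat)
           else .oracle_nt_matrix(params@match, params@mismatch)
    one <- function(qq, strand) {
        pa <- pairwiseAlignment(qq, ss[[1]], type = "local",
            substitutionMatrix = mat,
            gapOpening = params@gap_open, gapExtension = params@gap_ext)
        if (score(pa) <= 0) return(NULL)
        pc <- as.character(pattern(pa)); sc <- as.character(subject(pa))
        pv <- strsplit(pc, "")[[1]]; sv <- strsplit(sc, "")[[1]]
        eq <- pv == sv
        if (!protein) eq <- eq & pv %in% c("A", "C", "G", "T")
        qs_ <- start(pattern(pa)); qe_ <- end(pattern(pa))
        ss_ <- start(subject(pa)); se_ <- end(subject(pa))
        if (strand == "-") {
            qw <- width(qs)
            tmp_qs <- qw - qe_ + 1L; tmp_qe <- qw - qs_ + 1L
            qs_ <- tmp_qs; qe_ <- tmp_qe
            tmp <- ss_; ss_ <- se_; se_ <- tmp
        }
        data.frame(
            query_id = names(qs), subject_id = names(ss),
            perc_identity = 100 * sum(eq) / length(pv),
            align_length = length(pv),
            q_start = qs_, q_end = qe_, s_start = ss_, s_end = se_,
            query_cov = 100 * (qe_ - qs_ + 1) / width(qs),
            subject_cov = 100 * (abs(se_ - ss_) + 1) / width(ss),
            score = score(pa), strand = strand,
            stringsAsFactors = FALSE)
    }
    res <- one(qs[[1]], "+")
    if (!protein) {
        res2 <- one(reverseComplement(qs[[1]]), "-")
        if (!is.null(res2) && (is.null(res) || res2$score > res$score)) res <- res2
    }
    if (is.null(res)) .empty_hits() else res
}

# --------------------------------------------------------------- translation

#' Translate an ORF with the bacterial genetic code
#'
#' Standard bacterial/archaeal code (translation table 11). The first codon
#' is rendered as M when it is a recognized start (ATG/GTG/TTG). A trailing
#' partial codon is dropped with a warning; internal stops are retained as
#' `*` with a warning. Codons containing N translate to `X`.
#'
#' @param seq a DNA sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`), length >= 3.
#' @return the protein sequence as a character string.
#' @examples
#' translateOrf("ATGGCGTAA")  # "MA*"
#' translateOrf("GTGGCG")     # alternative start -> "MA"
#' @export
translateOrf <- function(seq) {
    if (is(seq, "DNAStringSet")) seq <- as.character(seq[[1]])
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    if (n < 3) .stopf("cannot translate a sequence shorter than 3 nt (got %d)", n)
    rem <- n %% 3
    if (rem != 0) {
        .warnf("dropping trailing partial codon (%d nt)", rem)
        seq <- substr(seq, 1, n - rem)
    }
    aa <- as.character(translate(DNAString(seq),
        genetic.code = getGeneticCode("11"),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
    first <- substr(seq, 1, 3)
    if (first %in% c("ATG", "GTG", "TTG"))
        aa <- paste0("M", substr(aa, 2, nchar(aa)))
    internal <- substr(aa, 1, nchar(aa) - 1)
    if (grepl("\\*", internal))
        .warnf("internal stop codon(s) retained as '*'")
    aa
}

# translate an ORF set for protein-level comparison; trailing stops removed
.translate_set <- function(x) {
    aa <- vapply(as.character(x), function(s) {
        p <- suppressWarnings(translateOrf(s))
        sub("\\*$", "", p)
    }, character(1), USE.NAMES = FALSE)
    out <- AAStringSet(aa)
    names(out) <- names(x)
    mcols(out) <- mcols(x)
    out
}

# ----------------------------------------------------------- external BLAST+

# returns NULL when the binary is unavailable (caller falls back to builtin)
.external_search <- function(queries, subjects, params) {
    protein <- .is_protein_task(params)
    prog <- if (protein) "blastp" else "blastn"
    bin <- getOption("dmgfinder.blast_bin")[[prog]] %||% Sys.which(prog)
    if (is.null(bin) || !nzchar(bin) || !file.exists(bin)) return(NULL)
    qf <- tempfile(fileext = ".fasta"); sf <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(qf, sf)), add = TRUE)
    writeXStringSet(queries, qf)
    writeXStringSet(subjects, sf)
    args <- c("-query", qf, "-subject", sf,
        "-outfmt", "6 qseqid sseqid pident length qstart qend sstart send bitscore qlen slen",
        "-evalue", "10", "-max_target_seqs", as.character(max(params@max_target_hits, 500L)))
    if (!protein) {
        task <- switch(params@task, megablast_like = "megablast",
            dc_like = "dc-megablast", blastn_like = "blastn")
        args <- c(args, "-task", task, "-dust", "no", "-soft_masking", "false")
    } else {
        args <- c(args, "-seg", "no")
    }
    out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = FALSE))
    st <- attr(out, "status")
    if (!is.null(st) && st != 0) return(NULL)
    if (length(out) == 0) return(.empty_hits())
    tab <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
        col.names = c("qseqid", "sseqid", "pident", "length", "qstart",
            "qend", "sstart", "send", "bitscore", "qlen", "slen"))
    raw <- data.frame(
        qi = match(tab$qseqid, names(queries)),
        si = match(tab$sseqid, names(subjects)),
        score = tab$bitscore,
        q_start = tab$qstart, q_end = tab$qend,
        s_start = tab$sstart, s_end = tab$send,
        matches = round(tab$pident / 100 * tab$length),
        align_length = tab$length,
        strand = ifelse(tab$sstart > tab$send, "-", "+"),
        stringsAsFactors = FALSE)
    .finish_hits(raw, queries, subjects, params)
}
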