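#' @include utils.R
NULL

# ---------------------------------------------------------------- AlignParams

#' Alignment search parameters
#'
#' Parameters of one local-alignment search task. The four tasks mirror the
#' BLAST nucleotide/protein family in decreasing word size and increasing
#' sensitivity: `megablast_like` (word 28), `dc_like` (word 11, wider
#' diagonal band and gap-tolerant seed clustering, emulating discontiguous
#' megablast's sensitivity for diverged homologs), `blastn_like` (word 11)
#' and `blastp_like` (word 3, BLOSUM62).
#'
#' Cutoff slots (`perc_identity_cut`, `query_cov_cut`, `subject_cov_cut`)
#' are percentages in \[0, 100\]; `NA` disables a cutoff. All thresholds are
#' inclusive (a hit at exactly the cutoff passes).
#'
#' @slot task character; one of `megablast_like`, `dc_like`, `blastn_like`,
#'   `blastp_like`.
#' @slot word_size integer seed length (>= 4 nucleotide, >= 2 protein).
#' @slot perc_identity_cut,query_cov_cut,subject_cov_cut numeric cutoffs in
#'   percent, `NA` = unset.
#' @slot max_target_hits integer; hits retained per query after filtering.
#' @slot match,mismatch,gap_open,gap_ext numeric scoring (penalties as
#'   positive magnitudes; a gap of length L costs `gap_open + L * gap_ext`).
#' @slot submat substitution matrix name for protein tasks (`"BLOSUM62"`).
#' @slot min_seed_count,diag_gap,band_pad integer engine tuning: minimum
#'   seeds per cluster, maximum diagonal drift within a cluster, and band
#'   padding around the seeded diagonals.
#' @seealso [alignParams()], [findHits()]
#' @export
setClass("AlignParams", representation(
    task = "character",
    word_size = "integer",
    perc_identity_cut = "numeric",
    query_cov_cut = "numeric",
    subject_cov_cut = "numeric",
    max_target_hits = "integer",
    match = "numeric",
    mismatch = "numeric",
    gap_open = "numeric",
    gap_ext = "numeric",
    submat = "character",
    min_seed_count = "integer",
    diag_gap = "integer",
    band_pad = "integer"))

setValidity("AlignParams", function(object) {
    msg <- character()
    if (!object@task %in% c("megablast_like", "dc_like", "blastn_like", "blastp_like"))
        msg <- c(msg, sprintf("unknown task '%s'", object@task))
    minw <- if (identical(object@task, "blastp_like")) 2L else 4L
    if (object@word_size < minw)
        msg <- c(msg, sprintf("word_size must be >= %d for task %s", minw, object@task))
    for (s in c("perc_identity_cut", "query_cov_cut", "subject_cov_cut")) {
        v <- slot(object, s)
        if (!is.na(v) && (v < 0 || v > 100))
            msg <- c(msg, sprintf("%s must be in [0, 100]", s))
    }
    if (length(msg)) msg else TRUE
})

#' Construct alignment parameters for a search task
#'
#' Returns an [AlignParams-class] object with task-appropriate defaults:
#' word sizes 28/11/11/3 for megablast_like / dc_like / blastn_like /
#' blastp_like, nucleotide scoring +1/-2 with gap open 5 and extend 2,
#' protein scoring BLOSUM62 with gap open 11 and extend 1.
#'
#' @param task search task name (see [AlignParams-class]).
#' @param perc_identity_cut,query_cov_cut,subject_cov_cut percent cutoffs,
#'   `NA` to disable.
#' @param word_size,max_target_hits,match,mismatch,gap_open,gap_ext,submat,min_seed_count,diag_gap,band_pad
#'   overrides of the task defaults.
#' @return an `AlignParams` object.
#' @examples
#' alignParams("megablast_like", perc_identity_cut = 95,
#'             query_cov_cut = 95, subject_cov_cut = 95)
#' @export
alignParams <- function(task = c("megablast_like", "dc_like", "blastn_like", "blastp_like"),
                        perc_identity_cut = NA_real_,
                        query_cov_cut = NA_real_,
                        subject_cov_cut = NA_real_,
                        word_size = NULL, max_target_hits = 500L,
                        match = NULL, mismatch = NULL,
                        gap_open = NULL, gap_ext = NULL,
                        submat = NULL, min_seed_count = NULL,
                        diag_gap = NULL, band_pad = NULL) {
    task <- match.arg(task)
    def <- switch(task,
        megablast_like = list(word = 28L, seeds = 1L, dgap = 30L, pad = 32L),
        dc_like        = list(word = 11L, seeds = 2L, dgap = 60L, pad = 64L),
        blastn_like    = list(word = 11L, seeds = 2L, dgap = 30L, pad = 32L),
        blastp_like    = list(word = 3L,  seeds = 2L, dgap = 20L, pad = 24L))
    protein <- identical(task, "blastp_like")
    new("AlignParams",
        task = task,
        word_size = as.integer(word_size %||% def$word),
        perc_identity_cut = as.numeric(perc_identity_cut),
        query_cov_cut = as.numeric(query_cov_cut),
        subject_cov_cut = as.numeric(subject_cov_cut),
        max_target_hits = as.integer(max_target_hits),
        match = as.numeric(match %||% 1),
        mismatch = as.numeric(mismatch %||% -2),
        gap_open = as.numeric(gap_open %||% (if (protein) 11 else 5)),
        gap_ext = as.numeric(gap_ext %||% (if (protein) 1 else 2)),
        submat = as.character(submat %||% (if (protein) "BLOSUM62" else NA_character_)),
        min_seed_count = as.integer(min_seed_count %||% def$seeds),
        diag_gap = as.integer(diag_gap %||% def$dgap),
        band_pad = as.integer(band_pad %||% def$pad))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "AlignParams", function(object) {
    cat(sprintf("AlignParams task=%s word=%d cuts id>=%s qcov>=%s scov>=%s\n",
        object@task, object@word_size,
        format(object@perc_identity_cut), format(object@query_cov_cut),
        format(object@subject_cov_cut)))
})

# ---------------------------------------------------------------- BadgeConfig

#' Pipeline configuration
#'
#' All thresholds and mode switches of the DMG prediction pipeline, using
#' the historical flat setting names so a settings file round-trips
#' unchanged. The primary screen (steps 1-3) passes a hit when percent
#' identity, query coverage and subject coverage all meet their cutoffs;
#' step 2 drops the subject-coverage condition because its subjects are
#' whole contigs. The step-4 screen (`dc_*`) is the more sensitive one, so
#' its cutoffs must not exceed the primary cutoffs.
#'
#' @slot megablast_perc_identity_cut percent identity cutoff of the primary
#'   screen (default 95).
#' @slot query_cov_cut,subject_cov_cut percent coverage cutoffs of the
#'   primary screen (default 95).
#' @slot min_occurrence fraction (0, 1\] of target genomes a family must
#'   occur in (default 1); the comparison is inclusive.
#' @slot enable_dc_filter,dc_perc_identity_cut,dc_query_cov_cut step-4
#'   long-low-identity screen (defaults TRUE, 80, 60).
#' @slot enable_short_hit_filter,max_blastn_len_cut step-5
#'   short-high-identity screen: a family is removed when a background hit
#'   at primary identity exceeds `max_blastn_len_cut` bp (defaults TRUE, 100).
#' @slot mode one of `dna`, `dc`, `protein`, `mut_dna`, `mut_protein`.
#' @slot backend `builtin` seed-and-extend engine or `external` BLAST+.
#' @slot clean_up logical; `FALSE` keeps intermediate candidate sets in the
#'   result and writes them with [writeOutputs()].
#' @seealso [badgeConfig()], [runPipeline()]
#' @export
setClass("BadgeConfig", representation(
    megablast_perc_identity_cut = "numeric",
    query_cov_cut = "numeric",
    subject_cov_cut = "numeric",
    min_occurrence = "numeric",
    enable_dc_filter = "logical",
    dc_perc_identity_cut = "numeric",
    dc_query_cov_cut = "numeric",
    enable_short_hit_filter = "logical",
    max_blastn_len_cut = "integer",
    mode = "character",
    backend = "character",
    clean_up = "logical"))

setValidity("BadgeConfig", function(object) {
    msg <- character()
    if (object@min_occurrence <= 0 || object@min_occurrence > 1)
        msg <- c(msg, "min_occurrence must be in (0, 1]")
    if (!object@mode %in% c("dna", "dc", "protein", "mut_dna", "mut_protein"))
        msg <- c(msg, sprintf("unknown mode '%s'", object@mode))
    if (!object@backend %in% c("builtin", "external"))
        msg <- c(msg, sprintf("unknown backend '%s'", object@backend))
    if (object@dc_perc_identity_cut > object@megablast_perc_identity_cut)
        msg <- c(msg, "dc_perc_identity_cut must not exceed megablast_perc_identity_cut (the dc screen is the more sensitive one)")
    if (object@dc_query_cov_cut > object@query_cov_cut)
        msg <- c(msg, "dc_query_cov_cut must not exceed query_cov_cut")
    for (s in c("megablast_perc_identity_cut", "query_cov_cut",
                "subject_cov_cut", "dc_perc_identity_cut", "dc_query_cov_cut")) {
        v <- slot(object, s)
        if (is.na(v) || v < 0 || v > 100)
            msg <- c(msg, sprintf("%s must be in [0, 100]", s))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a pipeline configuration
#'
#' @param megablast_perc_identity_cut,query_cov_cut,subject_cov_cut,min_occurrence,enable_dc_filter,dc_perc_identity_cut,dc_query_cov_cut,enable_short_hit_filter,max_blastn_len_cut,mode,backend,clean_up
#'   see [BadgeConfig-class] for meaning and defaults.
#' @return a `BadgeConfig` object.
#' @examples
#' badgeConfig(min_occurrence = 0.5)
#' @export
badgeConfig <- function(megablast_perc_identity_cut = 95,
                        query_cov_cut = 95,
                        subject_cov_cut = 95,
                        min_occurrence = 1.0,
                        enable_dc_filter = TRUE,
                        dc_perc_identity_cut = 80,
                        dc_query_cov_cut = 60,
                        enable_short_hit_filter = TRUE,
                        max_blastn_len_cut = 100L,
                        mode = "dna",
                        backend = "builtin",
                        clean_up = TRUE) {
    new("BadgeConfig",
        megablast_perc_identity_cut = as.numeric(megablast_perc_identity_cut),
        query_cov_cut = as.numeric(query_cov_cut),
        subject_cov_cut = as.numeric(subject_cov_cut),
        min_occurrence = as.numeric(min_occurrence),
        enable_dc_filter = isTRUE(enable_dc_filter),
        dc_perc_identity_cut = as.numeric(dc_perc_identity_cut),
        dc_query_cov_cut = as.numeric(dc_query_cov_cut),
        enable_short_hit_filter = isTRUE(enable_short_hit_filter),
        max_blastn_len_cut = as.integer(max_blastn_len_cut),
        mode = as.character(mode),
        backend = as.character(backend),
        clean_up = isTRUE(clean_up))
}

# settings names in on-disk order; used by read/write and the settings file
.config_fields <- function() c(
    "megablast_perc_identity_cut", "query_cov_cut", "subject_cov_cut",
    "min_occurrence", "enable_dc_filter", "dc_perc_identity_cut",
    "dc_query_cov_cut", "enable_short_hit_filter", "max_blastn_len_cut",
    "mode", "backend", "clean_up")

setMethod("show", "BadgeConfig", function(object) {
    cat("BadgeConfig\n")
    for (f in .config_fields())
        cat(sprintf("  %s = %s\n", f, format(slot(object, f))))
})

# ---------------------------------------------------------------- GenomeGroup

#' A named group of genomes with their annotated ORF sets
#'
#' One strain group (e.g. the spoiler target group or the non-spoiler
#' background group). `genomes` holds one `DNAStringSet` of contigs
#' (chromosome plus plasmids) per strain; `orfs` holds one `DNAStringSet`
#' of annotated coding sequences per strain whose `mcols()` carry
#' `orf_id`, `strain`, `contig`, `start`, `stop`, `strand` and
#' `annotation`. ORF sequences are on the coding strand (minus-strand genes
#' reverse-complemented). Strains are kept sorted lexicographically so all
#' downstream order is independent of filesystem listing order.
#'
#' @slot name group label, e.g. `"strong_spoiler"`.
#' @slot genomes named list, strain -> `DNAStringSet` of contigs.
#' @slot orfs named list, strain -> `DNAStringSet` of ORFs with metadata.
#' @seealso [loadGroup()], [genomeGroup()], [orfSet()]
#' @export
setClass("GenomeGroup", representation(
    name = "character", genomes = "list", orfs = "list"))

setValidity("GenomeGroup", function(object) {
    msg <- character()
    gs <- names(object@genomes); os <- names(object@orfs)
    if (!identical(gs, os))
        msg <- c(msg, "genome and ORF strain sets differ")
    if (is.unsorted(gs))
        msg <- c(msg, "strains must be sorted lexicographically")
    for (s in intersect(gs, os)) {
        orf <- object@orfs[[s]]
        if (anyDuplicated(names(orf)))
            msg <- c(msg, sprintf("duplicate ORF ids in strain %s", s))
        ctg <- mcols(orf)$contig
        bad <- !is.na(ctg) & !(ctg %in% names(object@genomes[[s]]))
        if (any(bad))
            msg <- c(msg, sprintf("strain %s: ORFs reference unknown contigs: %s",
                s, paste(unique(ctg[bad]), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a genome group
#'
#' @param name group label.
#' @param genomes named list (strain -> `DNAStringSet` of contigs).
#' @param orfs named list (strain -> ORF `DNAStringSet`, see [orfSet()]).
#' @return a [GenomeGroup-class] object with strains sorted.
#' @export
genomeGroup <- function(name, genomes, orfs) {
    ord <- order(names(genomes) %||% character(0))
    new("GenomeGroup", name = as.character(name),
        genomes = genomes[ord], orfs = orfs[names(genomes)[ord]])
}

#' @describeIn GenomeGroup-class group label.
#' @param x a `GenomeGroup`.
#' @export
setGeneric("groupName", function(x) standardGeneric("groupName"))
#' @export
setMethod("groupName", "GenomeGroup", function(x) x@name)

#' @describeIn GenomeGroup-class sorted strain names.
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))
#' @export
setMethod("strains", "GenomeGroup", function(x) names(x@genomes))

#' @describeIn GenomeGroup-class named list of contig `DNAStringSet`s.
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @export
setMethod("genomes", "GenomeGroup", function(x) x@genomes)

#' @describeIn GenomeGroup-class named list of ORF `DNAStringSet`s.
#' @export
setGeneric("orfs", function(x) standardGeneric("orfs"))
#' @export
setMethod("orfs", "GenomeGroup", function(x) x@orfs)

setMethod("show", "GenomeGroup", function(object) {
    cat(sprintf("GenomeGroup '%s': %d strain(s)\n", object@name,
        length(object@genomes)))
    for (s in names(object@genomes))
        cat(sprintf("  %s: %d contig(s) (%d bp), %d ORF(s)\n", s,
            length(object@genomes[[s]]), sum(width(object@genomes[[s]])),
            length(object@orfs[[s]])))
})

# ----------------------------------------------------------------- DmgFamily

#' One predicted diagnostic marker gene family
#'
#' A connected component of mutually alignable target-group ORFs that
#' survived all filters. `members` is a `DNAStringSet` with the same
#' metadata columns as an [orfSet()]; a strain may contribute several
#' members (multi-copy genes).
#'
#' @slot dmgId identifier `DMG_<n>`, assigned in deterministic order.
#' @slot members member ORFs across the target genomes.
#' @slot percentOccurrence percent of target genomes with >= 1 member.
#' @slot perGenomeFrequency named integer, copy count per strain.
#' @slot dcBlastHit `"yes"` if a sub-threshold sensitive-screen background
#'   hit remains, else `"no"`.
#' @slot maxBlastn longest high-identity background hit in bp (0 if none).
#' @slot representative name of the representative member (longest member;
#'   ties broken by lexicographically smallest ORF id).
#' @export
setClass("DmgFamily", representation(
    dmgId = "character",
    members = "DNAStringSet",
    percentOccurrence = "numeric",
    perGenomeFrequency = "integer",
    dcBlastHit = "character",
    maxBlastn = "integer",
    representative = "character"))

setValidity("DmgFamily", function(object) {
    msg <- character()
    if (!object@representative %in% names(object@members))
        msg <- c(msg, "representative must be a member")
    if (!object@dcBlastHit %in% c("yes", "no"))
        msg <- c(msg, "dcBlastHit must be 'yes' or 'no'")
    if (object@percentOccurrence < 0 || object@percentOccurrence > 100)
        msg <- c(msg, "percentOccurrence must be in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' @describeIn DmgFamily-class family identifier.
#' @param x a `DmgFamily`.
#' @export
setGeneric("dmgId", function(x) standardGeneric("dmgId"))
#' @export
setMethod("dmgId", "DmgFamily", function(x) x@dmgId)

#' @describeIn DmgFamily-class member ORFs (`DNAStringSet` with metadata).
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))
#' @export
setMethod("familyMembers", "DmgFamily", function(x) x@members)

#' @describeIn DmgFamily-class percent of target genomes carrying the family.
#' @export
setGeneric("percentOccurrence", function(x) standardGeneric("percentOccurrence"))
#' @export
setMethod("percentOccurrence", "DmgFamily", function(x) x@percentOccurrence)

setMethod("show", "DmgFamily", function(object) {
    cat(sprintf("%s: %d member(s), occurrence %.1f%%, dc_blast_hit=%s, max_blastn=%d\n",
        object@dmgId, length(object@members), object@percentOccurrence,
        object@dcBlastHit, object@maxBlastn))
})

# ------------------------------------------------------------------ DmgResult

#' Result of one pipeline run
#'
#' @slot families list of [DmgFamily-class] objects in final `DMG_<n>` order.
#' @slot stepCounts named integer, surviving candidates after every step
#'   (ORF counts for steps 1-2, family counts for steps 3-5); non-increasing.
#' @slot distribution presence matrix (families x target strains, 0/1).
#' @slot frequency copy-number matrix (families x target strains).
#' @slot residualHits data.frame of retained sub-threshold background hits.
#' @slot config the [BadgeConfig-class] the run used.
#' @slot intermediates list of intermediate candidate sets (populated when
#'   `clean_up = FALSE`).
#' @seealso [runPipeline()], [familyTable()], [writeOutputs()]
#' @export
setClass("DmgResult", representation(
    families = "list",
    stepCounts = "integer",
    distribution = "matrix",
    frequency = "matrix",
    residualHits = "data.frame",
    config = "BadgeConfig",
    intermediates = "list"))

#' @describeIn DmgResult-class list of predicted families.
#' @param x a `DmgResult`.
#' @export
setGeneric("dmgFamilies", function(x) standardGeneric("dmgFamilies"))
#' @export
setMethod("dmgFamilies", "DmgResult", function(x) x@families)

#' @describeIn DmgResult-class named per-step survivor counts.
#' @export
setGeneric("stepCounts", function(x) standardGeneric("stepCounts"))
#' @export
setMethod("stepCounts", "DmgResult", function(x) x@stepCounts)

#' @describeIn DmgResult-class family x strain presence (0/1) matrix.
#' @export
setGeneric("distributionMatrix", function(x) standardGeneric("distributionMatrix"))
#' @export
setMethod("distributionMatrix", "DmgResult", function(x) x@distribution)

#' @describeIn DmgResult-class family x strain copy-number matrix.
#' @export
setGeneric("copyNumberMatrix", function(x) standardGeneric("copyNumberMatrix"))
#' @export
setMethod("copyNumberMatrix", "DmgResult", function(x) x@frequency)

#' @describeIn DmgResult-class retained sub-threshold background hits.
#' @export
setGeneric("residualHits", function(x) standardGeneric("residualHits"))
#' @export
setMethod("residualHits", "DmgResult", function(x) x@residualHits)

setMethod("show", "DmgResult", function(object) {
    cat(sprintf("DmgResult: %d DMG famil%s\n", length(object@families),
        if (length(object@families) == 1) "y" else "ies"))
    sc <- object@stepCounts
    if (length(sc))
        cat("  step counts:", paste(sprintf("%s=%d", names(sc), sc),
            collapse = ", "), "\n")
})

#' @describeIn DmgResult-class number of predicted families.
#' @export
setMethod("length", "DmgResult", function(x) length(x@families))
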