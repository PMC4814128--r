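#' @include classes.R align.R
NULL

# --------------------------------------------------------------- preparation

# concatenate a group's ORF sets into one DNAStringSet with globally unique
# names "strain:orf_id" (metadata columns preserved)
.concat_orfs <- function(x) {
    if (is(x, "GenomeGroup")) {
        sets <- unname(orfs(x))
        x <- if (length(sets) == 1) sets[[1]] else do.call(c, sets)
    }
    if (!is(x, "DNAStringSet"))
        .stopf("expected a GenomeGroup or an ORF DNAStringSet")
    m <- mcols(x)
    if (is.null(m$strain) || is.null(m$orf_id))
        .stopf("ORF set lacks strain/orf_id metadata; build it with orfSet()")
    uid <- paste(m$strain, m$orf_id, sep = ":")
    if (!identical(names(x), uid)) names(x) <- uid
    if (anyDuplicated(names(x)))
        .stopf("duplicate strain:orf_id combinations in ORF set")
    x
}

# concatenate a group's genomes into one DNAStringSet of contigs named
# "strain:contig"
.concat_contigs <- function(x) {
    if (is(x, "GenomeGroup")) {
        per <- lapply(strains(x), function(s) {
            g <- genomes(x)[[s]]
            out <- g
            names(out) <- paste(s, names(g), sep = ":")
            mcols(out) <- DataFrame(strain = s, contig = names(g))
            out
        })
        x <- if (length(per) == 1) per[[1]] else do.call(c, per)
    }
    if (!is(x, "DNAStringSet"))
        .stopf("expected a GenomeGroup or a contig DNAStringSet")
    x
}

# parameter sets derived from a config
.orf_params <- function(cfg, subject_cov = TRUE) {
    if (cfg@mode %in% c("protein", "mut_protein"))
        alignParams("blastp_like",
            perc_identity_cut = cfg@megablast_perc_identity_cut,
            query_cov_cut = cfg@query_cov_cut,
            subject_cov_cut = if (subject_cov) cfg@subject_cov_cut else NA)
    else
        alignParams(if (cfg@mode == "dc") "dc_like" else "megablast_like",
            perc_identity_cut = cfg@megablast_perc_identity_cut,
            query_cov_cut = cfg@query_cov_cut,
            subject_cov_cut = if (subject_cov) cfg@subject_cov_cut else NA)
}

.genome_params <- function(cfg) {
    alignParams(if (cfg@mode == "dc") "dc_like" else "megablast_like",
        perc_identity_cut = cfg@megablast_perc_identity_cut,
        query_cov_cut = cfg@query_cov_cut,
        subject_cov_cut = NA)
}

# residual-hit reporting floor: an unthresholded sensitive search against
# megabase contigs yields chance word matches; only alignments at least
# this long are recorded as residual background similarity
.RESIDUAL_MIN_LEN <- 30L

# --------------------------------------------------------------- steps 1 & 2

#' Step 1: discard target ORFs with a high-quality hit in background ORFs
#'
#' A target-group (A) ORF survives when no alignment against any
#' background-group (B) ORF passes the primary identity, query-coverage
#' and subject-coverage cutoffs. In protein mode both sides are translated
#' and compared with `blastp_like`; in dc mode the sensitive nucleotide
#' task is used throughout.
#'
#' @param a_orfs,b_orfs [GenomeGroup-class] objects or ORF `DNAStringSet`s
#'   (see [orfSet()]).
#' @param cfg a [badgeConfig()].
#' @return the surviving A ORFs (same representation, full metadata).
#' @export
step1OrfFilter <- function(a_orfs, b_orfs, cfg = badgeConfig()) {
    a_orfs <- .concat_orfs(a_orfs)
    b_orfs <- .concat_orfs(b_orfs)
    if (length(a_orfs) == 0)
        .stopf("nothing to compare: target group has no ORFs")
    if (length(b_orfs) == 0)
        .stopf("nothing to compare: background group has no ORFs")
    params <- .orf_params(cfg)
    if (cfg@mode %in% c("protein", "mut_protein")) {
        hits <- findHits(.translate_set(a_orfs), .translate_set(b_orfs),
            params, backend = cfg@backend)
    } else {
        hits <- findHits(a_orfs, b_orfs, params, backend = cfg@backend)
    }
    a_orfs[!(names(a_orfs) %in% hits$query_id)]
}

#' Step 2: discard candidates found in background genome sequence
#'
#' Catches genes that escaped step 1 because the background annotation
#' missed them (inconsistent gene calling) or carries them frameshifted:
#' candidates are aligned to the raw background contigs and removed on a
#' passing identity + query-coverage hit. Subject coverage is not applied
#' (subjects are whole contigs). Always nucleotide-level.
#'
#' @param candidates surviving ORFs from [step1OrfFilter()].
#' @param b_genomes [GenomeGroup-class] or contig `DNAStringSet`.
#' @param cfg a [badgeConfig()].
#' @return the surviving candidate ORFs.
#' @export
step2GenomeFilter <- function(candidates, b_genomes, cfg = badgeConfig()) {
    candidates <- .concat_orfs(candidates)
    if (length(candidates) == 0) return(candidates)
    contigs <- .concat_contigs(b_genomes)
    hits <- findHits(candidates, contigs, .genome_params(cfg),
        backend = cfg@backend)
    candidates[!(names(candidates) %in% hits$query_id)]
}

# ------------------------------------------------------------------- step 3

.family_new <- function(members, target_strains) {
    m <- mcols(members)
    ord <- order(m$strain, m$contig, m$start, m$orf_id, method = "radix",
        na.last = TRUE)
    members <- members[ord]
    m <- mcols(members)
    freq <- vapply(target_strains, function(s) sum(m$strain == s), integer(1))
    occ <- 100 * sum(freq > 0) / length(target_strains)
    w <- width(members)
    cand <- which(w == max(w))
    rep_i <- cand[order(m$orf_id[cand])][1]
    new("DmgFamily", dmgId = "DMG_0", members = members,
        percentOccurrence = occ, perGenomeFrequency = freq,
        dcBlastHit = "no", maxBlastn = 0L,
        representative = names(members)[rep_i])
}

.family_sort_key <- function(fam) {
    m <- mcols(fam@members)
    i <- match(fam@representative, names(fam@members))
    c(m$strain[i], as.character(m$contig[i]),
      sprintf("%012d", if (is.na(m$start[i])) 0L else m$start[i]),
      m$orf_id[i])
}

#' Step 3a: group candidate ORFs into gene families
#'
#' Single-linkage clustering of the surviving candidates: two ORFs are
#' linked when an alignment between them (either direction) passes the
#' primary cutoffs; each connected component becomes one family. A strain
#' may contribute several members (multi-copy genes); member rows are kept
#' in ascending (strain, contig, start) order. The representative is the
#' longest member, ties broken by smallest ORF id. Protein mode links on
#' translated sequences.
#'
#' @param candidates surviving ORFs from [step2GenomeFilter()].
#' @param cfg a [badgeConfig()].
#' @param target_strains character vector of all group-A strains (the
#'   occurrence denominator).
#' @return list of [DmgFamily-class] objects ordered by their
#'   representative's (strain, contig, start).
#' @export
groupFamilies <- function(candidates, cfg = badgeConfig(), target_strains) {
    candidates <- .concat_orfs(candidates)
    if (missing(target_strains))
        target_strains <- sort(unique(mcols(candidates)$strain))
    if (length(candidates) == 0) return(list())
    params <- .orf_params(cfg)
    x <- if (cfg@mode %in% c("protein", "mut_protein"))
        .translate_set(candidates) else candidates
    hits <- findHits(x, x, params, backend = cfg@backend)
    edges <- hits[hits$query_id != hits$subject_id,
        c("query_id", "subject_id"), drop = FALSE]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
        vertices = data.frame(name = names(candidates)))
    memb <- igraph::components(g)$membership[names(candidates)]
    fams <- lapply(split(names(candidates), memb), function(ids)
        .family_new(candidates[ids], target_strains))
    keys <- vapply(fams, function(f) paste(.family_sort_key(f), collapse = "\r"),
        character(1))
    unname(fams[order(keys)])
}

#' Step 3b: occurrence filter
#'
#' Retains families present in at least `min_occurrence` (a fraction) of
#' the target genomes; the comparison is inclusive, so with 50 genomes a
#' `min_occurrence` of 0.02 keeps singleton families.
#'
#' @param families list of [DmgFamily-class] objects.
#' @param min_occurrence fraction in (0, 1].
#' @return the retained families.
#' @export
occurrenceFilter <- function(families, min_occurrence = 1.0) {
    if (min_occurrence <= 0 || min_occurrence > 1)
        .stopf("min_occurrence must be in (0, 1]")
    keep <- vapply(families, function(f)
        .at_least(f@percentOccurrence, 100 * min_occurrence), logical(1))
    families[keep]
}

# ------------------------------------------------------------------- steps 4/5

# run one member-vs-contig screen shared by the dc and short-hit filters
.family_screen <- function(families, contigs, params, cfg) {
    sets <- unname(lapply(families, familyMembers))
    all_members <- if (length(sets) == 1) sets[[1]] else do.call(c, sets)
    member_fam <- rep(seq_along(families),
        vapply(families, function(f) length(f@members), integer(1)))
    names(member_fam) <- names(all_members)
    hits <- if (length(all_members))
        findHits(all_members, contigs, params, backend = cfg@backend)
    else .empty_hits()
    list(hits = hits, member_fam = member_fam)
}

#' Step 4: sensitive screen for long low-identity background hits
#'
#' Every member of every family is searched against the background contigs
#' with the sensitive (`dc_like`) task. A family is removed when any
#' member produces a hit at identity >= `dc_perc_identity_cut` and query
#' coverage >= `dc_query_cov_cut` (a diverged background homolog).
#' Surviving families with a sub-threshold hit are annotated
#' `dc_blast_hit = "yes"` and the hits retained as residual evidence.
#' Disabled (`enable_dc_filter = FALSE`) it is an identity pass-through.
#'
#' @param families list of [DmgFamily-class] objects.
#' @param b_genomes [GenomeGroup-class] or contig `DNAStringSet`.
#' @param cfg a [badgeConfig()].
#' @return list with elements `families` (survivors, annotated) and
#'   `residual` (data.frame of sub-threshold hits).
#' @export
dcFilter <- function(families, b_genomes, cfg = badgeConfig()) {
    if (!cfg@enable_dc_filter || length(families) == 0)
        return(list(families = families, residual = .empty_hits()))
    contigs <- .concat_contigs(b_genomes)
    params <- alignParams("dc_like")   # unthresholded search, filter below
    scr <- .family_screen(families, contigs, params, cfg)
    hits <- scr$hits
    if (nrow(hits) == 0)
        return(list(families = families, residual = .empty_hits()))
    pass <- .at_least(hits$perc_identity, cfg@dc_perc_identity_cut) &
            .at_least(hits$query_cov, cfg@dc_query_cov_cut)
    removed_fams <- unique(scr$member_fam[hits$query_id[pass]])
    keep <- setdiff(seq_along(families), removed_fams)
    sub <- hits[!pass & hits$align_length >= .RESIDUAL_MIN_LEN, , drop = FALSE]
    sub_fams <- scr$member_fam[sub$query_id]
    out <- families[keep]
    for (i in seq_along(keep))
        if (keep[i] %in% sub_fams) out[[i]]@dcBlastHit <- "yes"
    residual <- sub[sub_fams %in% keep, , drop = FALSE]
    if (nrow(residual)) residual$screen <- "dc"
    list(families = out, residual = residual)
}

#' Step 5: screen for short high-identity background hits
#'
#' Every member is searched against the background contigs with the
#' `blastn_like` task at the primary identity cutoff and no coverage
#' floor, catching short conserved segments inside otherwise unique genes.
#' A family is removed when any such hit is longer than
#' `max_blastn_len_cut` bp; survivors record `max_blastn`, the longest
#' remaining hit (0 if none).
#'
#' @inheritParams dcFilter
#' @return list with elements `families` and `residual` as in [dcFilter()].
#' @export
shortHitFilter <- function(families, b_genomes, cfg = badgeConfig()) {
    if (!cfg@enable_short_hit_filter || length(families) == 0)
        return(list(families = families, residual = .empty_hits()))
    contigs <- .concat_contigs(b_genomes)
    params <- alignParams("blastn_like",
        perc_identity_cut = cfg@megablast_perc_identity_cut)
    scr <- .family_screen(families, contigs, params, cfg)
    hits <- scr$hits
    if (nrow(hits) == 0) {
        return(list(families = families, residual = .empty_hits()))
    }
    long <- hits$align_length > cfg@max_blastn_len_cut
    removed_fams <- unique(scr$member_fam[hits$query_id[long]])
    keep <- setdiff(seq_along(families), removed_fams)
    sub <- hits[!long & hits$align_length >= .RESIDUAL_MIN_LEN, , drop = FALSE]
    sub_fams <- scr$member_fam[sub$query_id]
    out <- families[keep]
    for (i in seq_along(keep)) {
        lens <- sub$align_length[sub_fams == keep[i]]
        out[[i]]@maxBlastn <- if (length(lens)) max(lens) else 0L
    }
    residual <- sub[sub_fams %in% keep, , drop = FALSE]
    if (nrow(residual)) residual$screen <- "blastn"
    list(families = out, residual = residual)
}

# --------------------------------------------------------------- mut level

#' Mutation-level markers: identical within A, different in B
#'
#' Identifies genes whose sequence is exactly identical across all target
#' genomes (at the DNA level for mode `mut_dna`, at the protein level for
#' `mut_protein`) while the best background counterpart passes the primary
#' cutoffs but is not string-identical — candidate SNP / substitution
#' markers.
#'
#' @param a_orfs,b_orfs [GenomeGroup-class] objects or ORF `DNAStringSet`s.
#' @param b_genomes unused; present for interface symmetry with the other
#'   filters.
#' @param cfg a [badgeConfig()] with mode `mut_dna` or `mut_protein`.
#' @return list of [DmgFamily-class] objects (all at 100% occurrence).
#' @export
mutLevelMarkers <- function(a_orfs, b_orfs, b_genomes = NULL,
                            cfg = badgeConfig(mode = "mut_dna")) {
    if (!cfg@mode %in% c("mut_dna", "mut_protein"))
        .stopf("mutLevelMarkers requires mode mut_dna or mut_protein")
    a_orfs <- .concat_orfs(a_orfs)
    b_orfs <- .concat_orfs(b_orfs)
    if (length(a_orfs) == 0) .stopf("nothing to compare: target group has no ORFs")
    target_strains <- sort(unique(mcols(a_orfs)$strain))
    protein <- cfg@mode == "mut_protein"
    akey <- if (protein) as.character(.translate_set(a_orfs)) else as.character(a_orfs)
    bkey <- if (protein) as.character(.translate_set(b_orfs)) else as.character(b_orfs)
    groups <- split(seq_along(a_orfs), akey)
    # keep groups covering every target genome
    full <- vapply(groups, function(i)
        setequal(unique(mcols(a_orfs)$strain[i]), target_strains), logical(1))
    groups <- groups[full]
    if (length(groups) == 0) return(list())
    reps_idx <- vapply(groups, `[`, integer(1), 1)
    params <- .orf_params(cfg)
    qa <- if (protein) .translate_set(a_orfs[reps_idx]) else a_orfs[reps_idx]
    qb <- if (protein) .translate_set(b_orfs) else b_orfs
    hits <- findHits(qa, qb, params, backend = cfg@backend)
    fams <- list()
    for (k in seq_along(groups)) {
        uid <- names(a_orfs)[reps_idx[k]]
        h <- hits[hits$query_id == uid, , drop = FALSE]
        if (nrow(h) == 0) next
        subj_keys <- bkey[match(h$subject_id, names(b_orfs))]
        key <- names(groups)[k]
        # best counterpart passes the cutoffs but differs in some form
        if (any(subj_keys == key)) next
        fams[[length(fams) + 1]] <-
            .family_new(a_orfs[groups[[k]]], target_strains)
    }
    keys <- vapply(fams, function(f) paste(.family_sort_key(f), collapse = "\r"),
        character(1))
    unname(fams[order(keys)])
}

# -------------------------------------------------------------- full pipeline

.empty_result <- function(cfg, target_strains, counts) {
    new("DmgResult", families = list(), stepCounts = counts,
        distribution = matrix(0L, 0, length(target_strains),
            dimnames = list(NULL, target_strains)),
        frequency = matrix(0L, 0, length(target_strains),
            dimnames = list(NULL, target_strains)),
        residualHits = .empty_hits(), config = cfg, intermediates = list())
}

.finalize_result <- function(families, residual, cfg, target_strains, counts,
                             intermediates = list()) {
    for (i in seq_along(families))
        families[[i]]@dmgId <- sprintf("DMG_%d", i)
    ids <- vapply(families, dmgId, character(1))
    freq <- matrix(0L, length(families), length(target_strains),
        dimnames = list(ids, target_strains))
    for (i in seq_along(families))
        freq[i, ] <- families[[i]]@perGenomeFrequency[target_strains]
    dist <- (freq > 0) + 0L
    new("DmgResult", families = families, stepCounts = counts,
        distribution = dist, frequency = freq,
        residualHits = residual, config = cfg,
        intermediates = intermediates)
}

#' Run the full DMG prediction pipeline
#'
#' Executes the six-step prediction: (1) discard target ORFs with a
#' high-quality hit among background ORFs; (2) discard candidates found in
#' the raw background contigs (rescues the background from inconsistent
#' gene calling); (3) group survivors into families and apply the
#' occurrence filter; (4) optional sensitive screen removing long
#' low-identity background hits; (5) optional screen removing short
#' high-identity background hits; (6) deterministic result assembly
#' (family numbering, presence/copy-number matrices, residual hits).
#' Per-step survivor counts are reported via `message()` and stored in the
#' result.
#'
#' Modes: `dna` (default), `dc` (sensitive task throughout steps 1-3),
#' `protein` (translated comparison at steps 1 and 3; steps 2, 4, 5 stay
#' nucleotide-based), `mut_dna` / `mut_protein` (see [mutLevelMarkers()]).
#'
#' @param group_a target [GenomeGroup-class].
#' @param group_b background [GenomeGroup-class].
#' @param cfg a [badgeConfig()].
#' @return a [DmgResult-class].
#' @export
runPipeline <- function(group_a, group_b, cfg = badgeConfig()) {
    stopifnot(is(group_a, "GenomeGroup"), is(group_b, "GenomeGroup"))
    target_strains <- strains(group_a)
    a_orfs <- .concat_orfs(group_a)
    b_orfs <- .concat_orfs(group_b)
    b_contigs <- .concat_contigs(group_b)

    if (cfg@mode %in% c("mut_dna", "mut_protein")) {
        fams <- mutLevelMarkers(a_orfs, b_orfs, b_contigs, cfg)
        counts <- c(mut_level = length(fams))
        message(sprintf("mut-level: %d marker famil%s", length(fams),
            if (length(fams) == 1) "y" else "ies"))
        return(.finalize_result(fams, .empty_hits(), cfg, target_strains,
            counts))
    }

    keep_inter <- !cfg@clean_up
    inter <- list()
    counts <- integer(0)

    s1 <- step1OrfFilter(a_orfs, b_orfs, cfg)
    counts["step1_orf_filter"] <- length(s1)
    message(sprintf("step 1 (ORF filter): %d candidate ORF(s)", length(s1)))
    if (keep_inter) inter$step1_candidates <- s1
    if (length(s1) == 0)
        return(.empty_result(cfg, target_strains,
            c(counts, step2_genome_filter = 0L, step3_occurrence = 0L,
              step4_dc_filter = 0L, step5_short_hit_filter = 0L)))

    s2 <- step2GenomeFilter(s1, b_contigs, cfg)
    counts["step2_genome_filter"] <- length(s2)
    message(sprintf("step 2 (genome filter): %d candidate ORF(s)", length(s2)))
    if (keep_inter) inter$step2_candidates <- s2
    if (length(s2) == 0)
        return(.empty_result(cfg, target_strains,
            c(counts, step3_occurrence = 0L, step4_dc_filter = 0L,
              step5_short_hit_filter = 0L)))

    fams <- groupFamilies(s2, cfg, target_strains)
    fams <- occurrenceFilter(fams, cfg@min_occurrence)
    counts["step3_occurrence"] <- length(fams)
    message(sprintf("step 3 (occurrence filter): %d DMG famil%s",
        length(fams), if (length(fams) == 1) "y" else "ies"))

    dc <- dcFilter(fams, b_contigs, cfg)
    counts["step4_dc_filter"] <- length(dc$families)
    message(sprintf("step 4 (dc filter): %d DMG famil%s",
        length(dc$families), if (length(dc$families) == 1) "y" else "ies"))

    sh <- shortHitFilter(dc$families, b_contigs, cfg)
    counts["step5_short_hit_filter"] <- length(sh$families)
    message(sprintf("step 5 (short-hit filter): %d DMG famil%s",
        length(sh$families), if (length(sh$families) == 1) "y" else "ies"))

    residual <- rbind(dc$residual, sh$residual)
    .finalize_result(sh$families, residual, cfg, target_strains, counts,
        intermediates = inter)
}

#' Distribution mode: gene-by-strain presence and copy-number matrices
#'
#' Runs the pipeline with all supplied genomes as the target group against
#' a dummy background (a single short sequence that cannot produce a
#' passing hit) and a minimum occurrence corresponding to one genome, so
#' no gene is discarded. The result's distribution (0/1) and frequency
#' (copy-number) matrices describe every gene family across all genomes.
#'
#' @param group a [GenomeGroup-class] of all genomes.
#' @param cfg a [badgeConfig()] (its `min_occurrence` is overridden with
#'   `1 / number of strains`).
#' @param dummy the dummy background sequence (default `"ATGCCC"`).
#' @return a [DmgResult-class]; a warning is emitted when the dummy
#'   produced a passing hit (a badly chosen dummy).
#' @export
distributionMode <- function(group, cfg = badgeConfig(), dummy = "ATGCCC") {
    stopifnot(is(group, "GenomeGroup"))
    if (length(strains(group)) == 0)
        .stopf("distribution mode needs at least one genome")
    n_orfs <- sum(lengths(orfs(group)))
    if (n_orfs == 0) .stopf("distribution mode needs annotated ORFs")
    dummy_genome <- DNAStringSet(c(dummy_contig = dummy))
    dummy_orfs <- orfSet(DNAStringSet(c(dummy_1 = dummy)), strain = "dummy",
        contig = "dummy_contig", start = 1L, stop = nchar(dummy),
        strand = "+", annotation = "dummy background sequence")
    dummy_group <- genomeGroup("dummy_background",
        genomes = list(dummy = dummy_genome), orfs = list(dummy = dummy_orfs))
    cfg@min_occurrence <- 1 / length(strains(group))
    res <- runPipeline(group, dummy_group, cfg)
    if (res@stepCounts["step1_orf_filter"] < n_orfs ||
        res@stepCounts["step2_genome_filter"] < res@stepCounts["step1_orf_filter"])
        .warnf("dummy background sequence produced passing hits; choose a shorter/more dissimilar dummy")
    res
}

#' Per-member table of a pipeline result
#'
#' One row per member ORF, family rows contiguous in `DMG_<n>` order and
#' member rows in ascending (strain, contig, start) coordinates — so
#' identical multi-copy members are listed with ascending positions.
#'
#' @param x a [DmgResult-class].
#' @return a data.frame with columns `DMG_ID`, `percent_occurrence`,
#'   `dc_blast_hit`, `max_blastn`, `ORF_ID`, `ORF_length`, `annotation`,
#'   `contig`, `start`, `stop`, `strain`.
#' @export
familyTable <- function(x) {
    stopifnot(is(x, "DmgResult"))
    rows <- lapply(x@families, function(f) {
        m <- mcols(f@members)
        data.frame(
            DMG_ID = f@dmgId,
            percent_occurrence = f@percentOccurrence,
            dc_blast_hit = f@dcBlastHit,
            max_blastn = f@maxBlastn,
            ORF_ID = m$orf_id,
            ORF_length = width(f@members),
            annotation = m$annotation,
            contig = m$contig,
            start = m$start,
            stop = m$stop,
            strain = m$strain,
            stringsAsFactors = FALSE)
    })
    if (length(rows) == 0)
        return(data.frame(DMG_ID = character(), percent_occurrence = numeric(),
            dc_blast_hit = character(), max_blastn = integer(),
            ORF_ID = character(), ORF_length = integer(),
            annotation = character(), contig = character(),
            start = integer(), stop = integer(), strain = character(),
            stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
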