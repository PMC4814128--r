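#' @include pipeline.R
NULL

#' Equalize annotation inconsistencies within a genome group
#'
#' Prediction of marker genes from annotated ORFs is sensitive to
#' inconsistent gene calling: a gene annotated in some genomes of a group
#' but missed by the annotation of another cannot reach full occurrence
#' even though the sequence is present. This tool repairs that by
#' comparison within the group: for each strain S and every ORF o
#' annotated in any other strain, if o has no passing hit among S's
#' annotated ORFs but does have a passing hit in S's genome sequence, the
#' aligned genomic region (the best hit's subject span, strand-resolved
#' and reverse-complemented for minus-strand hits) is appended to S's ORF
#' set as an extra ORF. ORF-level passing reuses the primary cutoffs
#' (identity, query and subject coverage); genome-level passing uses
#' identity and query coverage. Overlapping additions on the same contig
#' and strand (> 50% reciprocal overlap) are collapsed to the
#' best-identity one, so many strains sharing the same missing gene
#' contribute a single extra ORF.
#'
#' Added ORFs get ids `<strain>_EQ<n>` (numbered by ascending contig and
#' start) and annotation `"equalized from <strain>:<orf_id>"`; they take
#' part in all downstream steps exactly like annotated ORFs. The operation
#' is idempotent: a second run adds nothing.
#'
#' @param group a [GenomeGroup-class].
#' @param cfg a [badgeConfig()] supplying the similarity cutoffs.
#' @return a list with elements `group` (the augmented
#'   [GenomeGroup-class]) and `report` (data.frame: `strain`,
#'   `added_orf_id`, `source_strain`, `source_orf_id`, `contig`, `start`,
#'   `stop`, `strand`, `perc_identity`), plus attributes-free counts in
#'   columns; zero additions is a valid outcome.
#' @export
equalizeGroup <- function(group, cfg = badgeConfig()) {
    stopifnot(is(group, "GenomeGroup"))
    orf_params <- alignParams("megablast_like",
        perc_identity_cut = cfg@megablast_perc_identity_cut,
        query_cov_cut = cfg@query_cov_cut,
        subject_cov_cut = cfg@subject_cov_cut)
    gen_params <- alignParams("megablast_like",
        perc_identity_cut = cfg@megablast_perc_identity_cut,
        query_cov_cut = cfg@query_cov_cut,
        subject_cov_cut = NA)
    report <- list()
    new_orfs <- orfs(group)
    all <- .concat_orfs(group)

    for (s in strains(group)) {
        own <- orfs(group)[[s]]
        others <- all[mcols(all)$strain != s]
        if (length(others) == 0 || length(own) == 0) next
        # ORFs already represented in S's annotation are satisfied
        h_orf <- findHits(others, own, orf_params, backend = cfg@backend)
        missing <- others[!(names(others) %in% h_orf$query_id)]
        if (length(missing) == 0) next
        g <- genomes(group)[[s]]
        gq <- g
        names(gq) <- names(g)
        h_gen <- findHits(missing, gq, gen_params, backend = cfg@backend)
        if (nrow(h_gen) == 0) next
        # best genomic hit per query
        h_gen <- h_gen[order(h_gen$query_id, -h_gen$score, h_gen$subject_id), ]
        h_gen <- h_gen[!duplicated(h_gen$query_id), , drop = FALSE]
        cand <- data.frame(
            source_uid = h_gen$query_id,
            contig = h_gen$subject_id,
            start = pmin(h_gen$s_start, h_gen$s_end),
            stop = pmax(h_gen$s_start, h_gen$s_end),
            strand = h_gen$strand,
            perc_identity = h_gen$perc_identity,
            stringsAsFactors = FALSE)
        # collapse >50% reciprocal overlaps on the same contig/strand,
        # keeping the best identity
        cand <- cand[order(-cand$perc_identity, cand$contig, cand$start,
            cand$source_uid), , drop = FALSE]
        keep <- rep(TRUE, nrow(cand))
        for (i in seq_len(nrow(cand))) {
            if (!keep[i]) next
            if (i == nrow(cand)) break
            for (j in seq(i + 1, nrow(cand))) {
                if (!keep[j]) next
                if (cand$contig[i] != cand$contig[j] ||
                    cand$strand[i] != cand$strand[j]) next
                ov <- min(cand$stop[i], cand$stop[j]) -
                      max(cand$start[i], cand$start[j]) + 1
                if (ov <= 0) next
                li <- cand$stop[i] - cand$start[i] + 1
                lj <- cand$stop[j] - cand$start[j] + 1
                if (ov > 0.5 * li && ov > 0.5 * lj) keep[j] <- FALSE
            }
        }
        cand <- cand[keep, , drop = FALSE]
        cand <- cand[order(cand$contig, cand$start, cand$stop), , drop = FALSE]
        if (nrow(cand) == 0) next
        seqs <- DNAStringSet(vapply(seq_len(nrow(cand)), function(i)
            as.character(subseq(g[[cand$contig[i]]], cand$start[i],
                cand$stop[i])), character(1)))
        minus <- cand$strand == "-"
        if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
        src <- mcols(all)[match(cand$source_uid, names(all)), ]
        n0 <- sum(grepl("^.*_EQ[0-9]+$", names(own)))
        ids <- sprintf("%s_EQ%d", s, n0 + seq_len(nrow(cand)))
        added <- orfSet(seqs, orf_id = ids, strain = s,
            contig = cand$contig, start = cand$start, stop = cand$stop,
            strand = cand$strand,
            annotation = sprintf("equalized from %s:%s", src$strain,
                src$orf_id))
        new_orfs[[s]] <- c(new_orfs[[s]], added)
        report[[s]] <- data.frame(
            strain = s, added_orf_id = ids,
            source_strain = src$strain, source_orf_id = src$orf_id,
            contig = cand$contig, start = cand$start, stop = cand$stop,
            strand = cand$strand,
            perc_identity = cand$perc_identity,
            stringsAsFactors = FALSE)
    }

    rep_df <- if (length(report)) do.call(rbind, unname(report)) else
        data.frame(strain = character(), added_orf_id = character(),
            source_strain = character(), source_orf_id = character(),
            contig = character(), start = integer(), stop = integer(),
            strand = character(), perc_identity = numeric(),
            stringsAsFactors = FALSE)
    rownames(rep_df) <- NULL
    out <- genomeGroup(groupName(group), genomes(group), new_orfs)
    list(group = out, report = rep_df,
         inspected = sum(lengths(orfs(group))), added = nrow(rep_df))
}

#' Write an equalization report and the augmented ORF files
#'
#' @param eq result of [equalizeGroup()].
#' @param out output directory; augmented ORF FASTAs go to `out/orfs/`,
#'   the report to `out/equalizer_report.tsv`.
#' @return `out`, invisibly.
#' @export
writeEqualized <- function(eq, out) {
    od <- file.path(out, "orfs")
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    for (s in strains(eq$group))
        writeOrfFasta(orfs(eq$group)[[s]], file.path(od, paste0(s, ".fasta")))
    write.table(eq$report, file.path(out, "equalizer_report.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}
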