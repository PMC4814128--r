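#' @include pipeline.R
NULL

# ----------------------------------------------------------- config file IO

#' Read / write a flat key=value settings file
#'
#' The on-disk configuration format: one `key = value` line per setting,
#' using the historical setting names (see [BadgeConfig-class]). Unknown
#' keys are an error; missing keys keep their defaults.
#'
#' @param path settings file path.
#' @return [readBadgeConfig()] a [BadgeConfig-class];
#'   [writeBadgeConfig()] `path`, invisibly.
#' @export
readBadgeConfig <- function(path) {
    if (!file.exists(path)) .stopf("no such settings file: %s", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
    bad <- vapply(kv, length, integer(1)) != 3
    if (any(bad))
        .stopf("unparsable settings line: '%s'", lines[which(bad)[1]])
    keys <- vapply(kv, `[`, character(1), 2)
    vals <- trimws(vapply(kv, `[`, character(1), 3))
    unknown <- setdiff(keys, .config_fields())
    if (length(unknown))
        .stopf("unknown setting(s): %s", paste(unknown, collapse = ", "))
    args <- list()
    for (i in seq_along(keys)) {
        k <- keys[i]; v <- vals[i]
        args[[k]] <- switch(k,
            mode = , backend = v,
            enable_dc_filter = , enable_short_hit_filter = , clean_up =
                toupper(v) %in% c("TRUE", "T", "YES", "1"),
            max_blastn_len_cut = as.integer(v),
            as.numeric(v))
    }
    do.call(badgeConfig, args)
}

#' @rdname readBadgeConfig
#' @param cfg a [BadgeConfig-class].
#' @export
writeBadgeConfig <- function(cfg, path) {
    lines <- vapply(.config_fields(), function(f)
        sprintf("%s = %s", f, format(slot(cfg, f))), character(1))
    writeLines(lines, path)
    invisible(path)
}

# ------------------------------------------------------------- run outputs

#' Write all output files of a pipeline run
#'
#' Produces, under `outdir`:
#' \describe{
#'   \item{`DMG_representatives.fasta`}{one representative sequence per
#'     family.}
#'   \item{`DMG_sequences/DMG_<n>.fasta`}{all member sequences of each
#'     family (ready for consensus building and primer design).}
#'   \item{`DMG_table.tsv`}{the per-member table of [familyTable()].}
#'   \item{`DMG.distribution` / `DMG.frequency`}{family-by-strain presence
#'     and copy-number matrices (TSV).}
#'   \item{`settings.txt`}{every configuration field of the run.}
#'   \item{`step_counts.txt`}{surviving candidate count after every step.}
#'   \item{`residual_alignments.txt`}{plain-text pairwise alignments of
#'     surviving families against background contigs for retained
#'     sub-threshold hits.}
#' }
#' With `clean_up = FALSE` the intermediate candidate sets kept in the
#' result are additionally dumped under `intermediate/`. Re-running with
#' identical inputs and configuration reproduces every file byte for byte.
#'
#' @param x a [DmgResult-class].
#' @param outdir output directory (created if needed; must be writable).
#' @param b_genomes optional background [GenomeGroup-class] used to render
#'   the residual alignment report; omitted, the report lists hit
#'   coordinates only.
#' @return `outdir`, invisibly.
#' @export
writeOutputs <- function(x, outdir, b_genomes = NULL) {
    stopifnot(is(x, "DmgResult"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(outdir, 2) != 0)
        .stopf("output directory not writable: %s", outdir)
    cfg <- x@config

    reps <- DNAStringSet(vapply(x@families, function(f)
        as.character(f@members[[match(f@representative, names(f@members))]]),
        character(1)))
    names(reps) <- vapply(x@families, function(f) {
        i <- match(f@representative, names(f@members))
        paste0(f@dmgId, " representative=", mcols(f@members)$orf_id[i],
            " strain=", mcols(f@members)$strain[i])
    }, character(1))
    writeXStringSet(reps, file.path(outdir, "DMG_representatives.fasta"),
        width = 70L)

    seqdir <- file.path(outdir, "DMG_sequences")
    dir.create(seqdir, showWarnings = FALSE)
    for (f in x@families) {
        y <- f@members
        m <- mcols(y)
        names(y) <- paste0(f@dmgId, "|", m$strain, "|", m$orf_id,
            " annotation=", m$annotation)
        writeXStringSet(y, file.path(seqdir, paste0(f@dmgId, ".fasta")),
            width = 70L)
    }

    tab <- familyTable(x)
    write.table(tab, file.path(outdir, "DMG_table.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)

    .write_matrix <- function(m, path) {
        df <- data.frame(DMG_ID = rownames(m), m, check.names = FALSE,
            stringsAsFactors = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .write_matrix(x@distribution, file.path(outdir, "DMG.distribution"))
    .write_matrix(x@frequency, file.path(outdir, "DMG.frequency"))

    writeBadgeConfig(cfg, file.path(outdir, "settings.txt"))

    sc <- x@stepCounts
    writeLines(sprintf("%s\t%d", names(sc), sc),
        file.path(outdir, "step_counts.txt"))

    .write_residual_report(x, b_genomes,
        file.path(outdir, "residual_alignments.txt"))

    if (length(x@intermediates)) {
        idir <- file.path(outdir, "intermediate")
        dir.create(idir, showWarnings = FALSE)
        for (nm in names(x@intermediates))
            writeOrfFasta(x@intermediates[[nm]],
                file.path(idir, paste0(nm, ".fasta")))
    }
    invisible(outdir)
}

# plain-text pairwise alignments of residual sub-threshold hits; when the
# background contigs are unavailable only the hit table is printed
.write_residual_report <- function(x, b_genomes, path) {
    res <- x@residualHits
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("# residual sub-threshold background hits of surviving DMGs", con)
    if (nrow(res) == 0) {
        writeLines("# none", con)
        return(invisible(path))
    }
    sets <- unname(lapply(x@families, familyMembers))
    members <- if (length(sets) == 1) sets[[1]] else do.call(c, sets)
    contigs <- if (!is.null(b_genomes)) .concat_contigs(b_genomes) else NULL
    for (i in seq_len(nrow(res))) {
        r <- res[i, ]
        writeLines(sprintf(
            "\n%s vs %s [%s]: identity %.2f%%, length %d, query %d..%d, subject %d..%d",
            r$query_id, r$subject_id, r$screen, r$perc_identity,
            r$align_length, r$q_start, r$q_end, r$s_start, r$s_end), con)
        if (is.null(contigs) || !(r$query_id %in% names(members)) ||
            !(r$subject_id %in% names(contigs))) next
        q <- members[[r$query_id]]
        lo <- min(r$s_start, r$s_end); hi <- max(r$s_start, r$s_end)
        s <- subseq(contigs[[r$subject_id]], lo, hi)
        if (r$strand == "-") s <- reverseComplement(s)
        pa <- pairwiseAlignment(q, s, type = "local",
            substitutionMatrix = .oracle_nt_matrix(1, -2),
            gapOpening = 5, gapExtension = 2)
        tf <- tempfile()
        writePairwiseAlignments(pa, tf)
        lines <- readLines(tf, warn = FALSE)
        # drop the run timestamp so reruns are byte-identical
        writeLines(lines[!startsWith(lines, "# Rundate")], con)
        unlink(tf)
    }
    invisible(path)
}
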