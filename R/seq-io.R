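#' @include classes.R
NULL

# ------------------------------------------------------------------- FASTA IO

#' Read a DNA FASTA file
#'
#' Reads a FASTA file into a `DNAStringSet`. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept in
#' `mcols()$description` (whitespace runs collapsed to single spaces).
#' Sequences are uppercased; IUPAC ambiguity letters other than N are
#' mapped to N with a warning, and N never counts as a match downstream.
#'
#' @param path path to a FASTA text file.
#' @return a `DNAStringSet`; empty for an empty file.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some gene", "AC", "GT"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) .stopf("no such file: %s", path)
    if (file.size(path) == 0) {
        out <- DNAStringSet()
        mcols(out) <- DataFrame(description = character())
        return(out)
    }
    raw <- tryCatch(readBStringSet(path),
        error = function(e) .stopf("not a FASTA file: %s (%s)", path,
            conditionMessage(e)))
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
        gsub("\\s+", " ", trimws(sub("^\\S+\\s*", "", headers))), "")
    if (any(ids == "")) {
        i <- which(ids == "")[1]
        .stopf("%s: record %d has an empty id in its header line", path, i)
    }
    if (anyDuplicated(ids)) {
        dup <- ids[duplicated(ids)][1]
        .stopf("%s: duplicate sequence id '%s'", path, dup)
    }
    chars <- toupper(as.character(raw))
    if (any(nchar(chars) == 0)) {
        i <- which(nchar(chars) == 0)[1]
        .stopf("%s: record '%s' has an empty sequence", path, ids[i])
    }
    n_amb <- sum(nchar(gsub("[ACGTN]", "", chars)))
    if (n_amb > 0) {
        .warnf("%s: %d ambiguity base(s) mapped to N", path, n_amb)
        chars <- chartr("RYSWKMBDHVUrsywkmbdhvu",
                        paste(rep("N", 22), collapse = ""), chars)
        chars <- gsub("[^ACGTN]", "N", chars)
    }
    out <- DNAStringSet(chars)
    names(out) <- ids
    mcols(out) <- DataFrame(description = unname(desc))
    out
}

#' Write sequences to a FASTA file
#'
#' The inverse of [readFasta()]: headers are `id description` with
#' whitespace normalized, sequences wrapped at 70 columns. Reading the file
#' back reproduces ids and sequences byte-identically.
#'
#' @param x a `DNAStringSet` (descriptions taken from `mcols()$description`
#'   when present).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
    hdr <- names(x)
    d <- mcols(x)$description
    if (!is.null(d)) {
        d <- gsub("\\s+", " ", trimws(d))
        hdr <- ifelse(is.na(d) | d == "", hdr, paste(hdr, d))
    }
    y <- x
    names(y) <- hdr
    writeXStringSet(y, path, width = 70L)
    invisible(path)
}

# ------------------------------------------------------------ ORF conventions

#' Assemble an ORF set
#'
#' Builds the `DNAStringSet`-with-metadata representation of a strain's
#' annotated coding sequences used throughout the package. Sequences are on
#' the coding strand. Missing annotation defaults to
#' `"hypothetical protein"`.
#'
#' @param seqs `DNAStringSet` (or named character) of coding sequences.
#' @param orf_id character ORF identifiers, unique within the strain.
#' @param strain strain name (recycled).
#' @param contig,start,stop,strand location on the strain's contigs
#'   (1-based inclusive; `NA` when unknown).
#' @param annotation free-text functional annotation.
#' @return a `DNAStringSet` named by `orf_id` with metadata columns
#'   `orf_id`, `strain`, `contig`, `start`, `stop`, `strand`, `annotation`.
#' @export
orfSet <- function(seqs, orf_id = names(seqs), strain,
                   contig = NA_character_, start = NA_integer_,
                   stop = NA_integer_, strand = NA_character_,
                   annotation = "hypothetical protein") {
    if (is.character(seqs)) seqs <- DNAStringSet(seqs)
    n <- length(seqs)
    if (is.null(orf_id) || any(is.na(orf_id)) || any(orf_id == ""))
        .stopf("every ORF needs a non-empty orf_id")
    if (anyDuplicated(orf_id))
        .stopf("duplicate orf_id within strain: %s",
            orf_id[duplicated(orf_id)][1])
    annotation <- ifelse(is.na(annotation) | annotation == "",
        "hypothetical protein", annotation)
    out <- seqs
    names(out) <- orf_id
    mcols(out) <- DataFrame(
        orf_id = orf_id,
        strain = rep_len(as.character(strain), n),
        contig = rep_len(as.character(contig), n),
        start = rep_len(as.integer(start), n),
        stop = rep_len(as.integer(stop), n),
        strand = rep_len(as.character(strand), n),
        annotation = rep_len(as.character(annotation), n))
    out
}

#' Parse an ORF FASTA header
#'
#' Two header dialects are supported. The `badge` dialect is the package's
#' key=value convention,
#' `">ORF_ID contig=<id> start=<int> stop=<int> strand=<+|-> annotation=<text>"`,
#' with `annotation` running to the end of the line. The `bare` dialect
#' takes the first whitespace token as the ORF id and leaves location
#' fields unset, with annotation `"hypothetical protein"`.
#'
#' @param header header text (without the leading `>`).
#' @param dialect `"badge"` or `"bare"`.
#' @return a named list with elements `orf_id`, `contig`, `start`, `stop`,
#'   `strand`, `annotation`.
#' @examples
#' parseOrfHeader("g7 contig=p1 start=100 stop=561 strand=+ annotation=dehydratase")
#' parseOrfHeader("gene7", dialect = "bare")
#' @export
parseOrfHeader <- function(header, dialect = c("badge", "bare")) {
    dialect <- match.arg(dialect)
    header <- trimws(header)
    orf_id <- sub("\\s.*$", "", header)
    if (orf_id == "")
        .stopf("ORF header is missing the orf_id field: '%s'", header)
    if (dialect == "bare")
        return(list(orf_id = orf_id, contig = NA_character_,
            start = NA_integer_, stop = NA_integer_,
            strand = NA_character_, annotation = "hypothetical protein"))
    grab <- function(key, pattern, required = TRUE) {
        m <- regmatches(header, regexec(paste0("\\b", key, "=(", pattern, ")"), header))[[1]]
        if (length(m) < 2) {
            if (required)
                .stopf("badge ORF header lacks field '%s': '%s'", key, header)
            return(NA_character_)
        }
        m[2]
    }
    start <- grab("start", "\\S+")
    stop_ <- grab("stop", "\\S+")
    if (!grepl("^[0-9]+$", start))
        .stopf("badge ORF header has unparsable coordinates in field 'start': '%s'", header)
    if (!grepl("^[0-9]+$", stop_))
        .stopf("badge ORF header has unparsable coordinates in field 'stop': '%s'", header)
    strand <- grab("strand", "\\S+")
    if (!strand %in% c("+", "-"))
        .stopf("badge ORF header field 'strand' must be + or -: '%s'", header)
    ann <- regmatches(header, regexec("\\bannotation=(.*)$", header))[[1]]
    ann <- if (length(ann) >= 2 && nzchar(trimws(ann[2]))) trimws(ann[2])
           else "hypothetical protein"
    list(orf_id = orf_id, contig = grab("contig", "\\S+"),
         start = as.integer(start), stop = as.integer(stop_),
         strand = strand, annotation = ann)
}

.badge_header <- function(m) {
    paste0(m$orf_id,
        " contig=", m$contig, " start=", m$start, " stop=", m$stop,
        " strand=", m$strand, " annotation=", m$annotation)
}

#' Write an ORF set with badge-dialect headers
#'
#' @param x an [orfSet()] `DNAStringSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeOrfFasta <- function(x, path) {
    m <- mcols(x)
    y <- x
    names(y) <- vapply(seq_along(x), function(i) .badge_header(as.list(m[i, ])),
        character(1))
    writeXStringSet(y, path, width = 70L)
    invisible(path)
}

# ------------------------------------------------------------- GFF conversion

#' Convert a genome FASTA + GFF3 annotation into an ORF set
#'
#' Extracts every CDS feature of a GFF3 file from the genome contigs:
#' coordinates are 1-based inclusive, minus-strand features are
#' reverse-complemented so the returned sequence is the coding strand. The
#' functional annotation is taken from the `product` attribute when
#' present, else `"hypothetical protein"`; the ORF id from `locus_tag`,
#' `ID`, or generated as `<strain>_<n>`.
#'
#' @param genome `DNAStringSet` of the strain's contigs (as from
#'   [readFasta()]).
#' @param gff path to a GFF3 file whose seqids name contigs of `genome`.
#' @param strain strain name recorded in the ORF metadata.
#' @return an [orfSet()] `DNAStringSet`, badge-header-ready.
#' @export
gffToOrfs <- function(genome, gff, strain) {
    gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
        error = function(e) .stopf("cannot parse GFF3 file %s: %s", gff,
            conditionMessage(e)))
    gr <- gr[gr$type == "CDS"]
    if (length(gr) == 0)
        return(orfSet(DNAStringSet(), character(), strain = strain))
    seqid <- as.character(seqnames(gr))
    unknown <- !(seqid %in% names(genome))
    if (any(unknown))
        .stopf("GFF feature %d references unknown seqid '%s'",
            which(unknown)[1], seqid[which(unknown)[1]])
    st <- start(gr); en <- end(gr)
    lens <- setNames(width(genome), names(genome))
    bad <- st < 1 | en > lens[seqid] | st > en
    if (any(bad)) {
        i <- which(bad)[1]
        .stopf("GFF CDS feature %d on seqid '%s' (%d..%d) is outside contig bounds (1..%d)",
            i, seqid[i], st[i], en[i], lens[seqid[i]])
    }
    seqs <- DNAStringSet(vapply(seq_along(gr), function(i)
        as.character(subseq(genome[[seqid[i]]], st[i], en[i])), character(1)))
    strnd <- as.character(strand(gr))
    strnd[!strnd %in% c("+", "-")] <- "+"
    minus <- strnd == "-"
    if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
    md <- mcols(gr)
    pick <- function(col) if (col %in% colnames(md)) as.character(md[[col]]) else rep(NA_character_, length(gr))
    ids <- pick("locus_tag")
    ids2 <- pick("ID")
    ids[is.na(ids)] <- ids2[is.na(ids)]
    auto <- sprintf("%s_%04d", strain, seq_along(gr))
    ids[is.na(ids) | ids == ""] <- auto[is.na(ids) | ids == ""]
    ann <- pick("product")
    orfSet(seqs, orf_id = ids, strain = strain, contig = seqid,
           start = st, stop = en, strand = strnd, annotation = ann)
}

# ----------------------------------------------------------------- load group

.fasta_files <- function(dir) {
    f <- list.files(dir, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE,
        ignore.case = TRUE)
    sort(f)
}

#' Load a paired genome/ORF group directory
#'
#' Reads one strain group from two directories of FASTA files paired by
#' base filename: `genomes_dir/<strain>.fasta` holds the contigs and
#' `orfs_dir/<strain>.fasta` the annotated coding sequences. The strain
#' name is the base filename without extension. ORF headers are parsed
#' with [parseOrfHeader()]; in the `badge` dialect an ORF referencing a
#' contig absent from its genome is an error, in the `bare` dialect a
#' warning (the location is dropped).
#'
#' @param genomes_dir,orfs_dir directories of FASTA files paired by base
#'   filename.
#' @param name group label.
#' @param dialect ORF header dialect, `"badge"` or `"bare"`.
#' @return a [GenomeGroup-class] with strains sorted lexicographically.
#' @export
loadGroup <- function(genomes_dir, orfs_dir, name,
                      dialect = c("badge", "bare")) {
    dialect <- match.arg(dialect)
    if (!dir.exists(genomes_dir)) .stopf("no such directory: %s", genomes_dir)
    if (!dir.exists(orfs_dir)) .stopf("no such directory: %s", orfs_dir)
    gf <- .fasta_files(genomes_dir)
    of <- .fasta_files(orfs_dir)
    gb <- tools::file_path_sans_ext(basename(gf))
    ob <- tools::file_path_sans_ext(basename(of))
    orphans <- c(setdiff(gb, ob), setdiff(ob, gb))
    if (length(orphans))
        .stopf("unpaired genome/ORF file(s) for: %s",
            paste(sort(orphans), collapse = ", "))
    strains_ <- sort(gb)
    genomes <- list(); orf_sets <- list()
    for (s in strains_) {
        genomes[[s]] <- readFasta(gf[match(s, gb)])
        raw <- readFasta(of[match(s, ob)])
        hdr <- paste(names(raw), mcols(raw)$description)
        meta <- lapply(trimws(hdr), parseOrfHeader, dialect = dialect)
        ctg <- vapply(meta, `[[`, character(1), "contig")
        bad <- !is.na(ctg) & !(ctg %in% names(genomes[[s]]))
        if (any(bad)) {
            which_bad <- vapply(meta[bad], `[[`, character(1), "orf_id")
            if (dialect == "badge")
                .stopf("strain %s: ORF(s) reference contigs absent from the genome: %s",
                    s, paste(which_bad, collapse = ", "))
            .warnf("strain %s: dropping unknown contig reference for ORF(s): %s",
                s, paste(which_bad, collapse = ", "))
            for (i in which(bad)) meta[[i]]$contig <- NA_character_
        }
        orf_sets[[s]] <- orfSet(
            unname(raw),
            orf_id = vapply(meta, `[[`, character(1), "orf_id"),
            strain = s,
            contig = vapply(meta, `[[`, character(1), "contig"),
            start = vapply(meta, function(m) as.integer(m$start), integer(1)),
            stop = vapply(meta, function(m) as.integer(m$stop), integer(1)),
            strand = vapply(meta, `[[`, character(1), "strand"),
            annotation = vapply(meta, `[[`, character(1), "annotation"))
    }
    genomeGroup(name, genomes, orf_sets)
}

#' Write a genome group to paired directories
#'
#' Inverse of [loadGroup()]: writes `<out>/genomes/<strain>.fasta` and
#' `<out>/orfs/<strain>.fasta` (badge-dialect ORF headers).
#'
#' @param group a [GenomeGroup-class].
#' @param out output directory (created if needed).
#' @return `out`, invisibly.
#' @export
writeGroup <- function(group, out) {
    gd <- file.path(out, "genomes"); od <- file.path(out, "orfs")
    dir.create(gd, recursive = TRUE, showWarnings = FALSE)
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    for (s in strains(group)) {
        writeFasta(genomes(group)[[s]], file.path(gd, paste0(s, ".fasta")))
        writeOrfFasta(orfs(group)[[s]], file.path(od, paste0(s, ".fasta")))
    }
    invisible(out)
}
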