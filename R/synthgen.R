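#' @include align.R seq-io.R
NULL

# ------------------------------------------------------------------ SynthSpec

#' Specification of a synthetic comparative-genomics fixture
#'
#' Describes a deterministic two-group dataset exercising every pipeline
#' filter: shared core genes, target-exclusive genes (the planted truth),
#' partial-occurrence genes, genes embedded unannotated (or frameshifted)
#' in a background contig, diverged background homologs at a chosen
#' identity, genes containing a short conserved background segment,
#' multi-copy genes, and genes inconsistently annotated within the target
#' group (the equalizer fixture). Identical spec + seed always produce
#' byte-identical files.
#'
#' @slot n_a,n_b genomes per group.
#' @slot genome_len chromosome length in bp.
#' @slot n_plasmids,plasmid_len plasmid count and length per genome;
#'   target-exclusive genes are placed on the first plasmid when it fits
#'   (marker genes of spoilage groups are typically plasmid-encoded).
#' @slot n_core genes shared and annotated in all genomes.
#' @slot n_dmg target-exclusive genes: the planted truth.
#' @slot n_partial,partial_fraction target genes present in only a
#'   fraction of target genomes.
#' @slot n_unannotated_decoys target genes also embedded verbatim in a
#'   background contig but absent from the background annotation.
#' @slot n_frameshift_decoys as above but with a 1 bp deletion at 30% of
#'   the gene length in the background copy.
#' @slot n_diverged,diverged_identity background homologs of target genes
#'   at the stated optimal-local-alignment identity (annotated in B).
#' @slot n_shortseg,shortseg_len target genes containing an exact
#'   background segment of the stated length.
#' @slot n_multicopy,multicopy_copies target genes duplicated within the
#'   first target genome.
#' @slot n_unequal_annot,unequal_annot_k target genes present in all
#'   target contigs but annotated in only k target genomes.
#' @slot gene_len_min,gene_len_max gene length range in bp.
#' @slot gc background GC fraction.
#' @slot seed RNG seed.
#' @seealso [synthSpec()], [generateDataset()]
#' @export
setClass("SynthSpec", representation(
    n_a = "integer", n_b = "integer",
    genome_len = "integer", n_plasmids = "integer", plasmid_len = "integer",
    n_core = "integer", n_dmg = "integer",
    n_partial = "integer", partial_fraction = "numeric",
    n_unannotated_decoys = "integer", n_frameshift_decoys = "integer",
    n_diverged = "integer", diverged_identity = "numeric",
    n_shortseg = "integer", shortseg_len = "integer",
    n_multicopy = "integer", multicopy_copies = "integer",
    n_unequal_annot = "integer", unequal_annot_k = "integer",
    gene_len_min = "integer", gene_len_max = "integer",
    gc = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
    msg <- character()
    counts <- c("n_a", "n_b", "n_core", "n_dmg", "n_partial",
        "n_unannotated_decoys", "n_frameshift_decoys", "n_diverged",
        "n_shortseg", "n_multicopy", "n_unequal_annot", "n_plasmids")
    for (s in counts) if (slot(object, s) < 0)
        msg <- c(msg, sprintf("%s must be >= 0", s))
    if (object@n_a < 1 || object@n_b < 1)
        msg <- c(msg, "need at least one genome per group")
    if (object@diverged_identity <= 0 || object@diverged_identity > 1)
        msg <- c(msg, "diverged_identity must be in (0, 1]")
    if (object@partial_fraction <= 0 || object@partial_fraction > 1)
        msg <- c(msg, "partial_fraction must be in (0, 1]")
    if (object@gc <= 0 || object@gc >= 1)
        msg <- c(msg, "gc must be in (0, 1)")
    if (object@gene_len_min < 90 || object@gene_len_max < object@gene_len_min)
        msg <- c(msg, "gene length range invalid (min >= 90)")
    if (object@multicopy_copies < 2 && object@n_multicopy > 0)
        msg <- c(msg, "multicopy_copies must be >= 2")
    if (object@n_unequal_annot > 0 &&
        (object@unequal_annot_k < 1 || object@unequal_annot_k >= object@n_a))
        msg <- c(msg, "unequal_annot_k must be in [1, n_a)")
    if (length(msg)) msg else TRUE
})

#' Construct a synthetic-fixture specification
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's tests: 2 target vs 3 background genomes of 200 kb plus a
#' 30 kb plasmid, 40 core genes, 3 planted marker genes, and one gene of
#' every decoy class (background homologs at 85% identity, conserved
#' segments of 150 bp).
#'
#' @param n_a,n_b,genome_len,n_plasmids,plasmid_len,n_core,n_dmg,n_partial,partial_fraction,n_unannotated_decoys,n_frameshift_decoys,n_diverged,diverged_identity,n_shortseg,shortseg_len,n_multicopy,multicopy_copies,n_unequal_annot,unequal_annot_k,gene_len_min,gene_len_max,gc,seed
#'   see [SynthSpec-class].
#' @return a `SynthSpec`.
#' @export
synthSpec <- function(n_a = 2L, n_b = 3L,
                      genome_len = 200000L, n_plasmids = 1L,
                      plasmid_len = 30000L,
                      n_core = 40L, n_dmg = 3L,
                      n_partial = 1L, partial_fraction = 0.5,
                      n_unannotated_decoys = 1L, n_frameshift_decoys = 1L,
                      n_diverged = 1L, diverged_identity = 0.85,
                      n_shortseg = 1L, shortseg_len = 150L,
                      n_multicopy = 1L, multicopy_copies = 2L,
                      n_unequal_annot = 0L, unequal_annot_k = 1L,
                      gene_len_min = 600L, gene_len_max = 1200L,
                      gc = 0.38, seed = 1L) {
    new("SynthSpec",
        n_a = as.integer(n_a), n_b = as.integer(n_b),
        genome_len = as.integer(genome_len),
        n_plasmids = as.integer(n_plasmids),
        plasmid_len = as.integer(plasmid_len),
        n_core = as.integer(n_core), n_dmg = as.integer(n_dmg),
        n_partial = as.integer(n_partial),
        partial_fraction = as.numeric(partial_fraction),
        n_unannotated_decoys = as.integer(n_unannotated_decoys),
        n_frameshift_decoys = as.integer(n_frameshift_decoys),
        n_diverged = as.integer(n_diverged),
        diverged_identity = as.numeric(diverged_identity),
        n_shortseg = as.integer(n_shortseg),
        shortseg_len = as.integer(shortseg_len),
        n_multicopy = as.integer(n_multicopy),
        multicopy_copies = as.integer(multicopy_copies),
        n_unequal_annot = as.integer(n_unequal_annot),
        unequal_annot_k = as.integer(unequal_annot_k),
        gene_len_min = as.integer(gene_len_min),
        gene_len_max = as.integer(gene_len_max),
        gc = as.numeric(gc), seed = as.integer(seed))
}

# ------------------------------------------------------------ sequence makers

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(len, gc) {
    paste(sample(.BASES, len, replace = TRUE,
        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

# random coding-like gene: ATG start, no in-frame stops, length a multiple of 3
.random_gene <- function(len, gc) {
    len <- max(90L, as.integer(len))
    len <- len - len %% 3L
    s <- .random_dna(len, gc)
    substr(s, 1, 3) <- "ATG"
    codons <- substring(s, seq(1, len - 2, 3), seq(3, len, 3))
    stops <- codons %in% c("TAA", "TAG", "TGA")
    stops[length(codons)] <- FALSE   # keep a terminal stop if one arose
    codons[stops] <- sub("^T(A|G)", "TC", codons[stops])
    paste(codons, collapse = "")
}

# -------------------------------------------------------------- mutation op

#' Mutate a sequence to a target local-alignment identity
#'
#' Introduces random substitutions (and single-base indels at the stated
#' fraction of edits) until the optimal local alignment of (input,
#' output) — computed with [dpAlignOracle()] — has an identity within one
#' percentage point of the target, resampling with an adjusted edit count
#' on a miss. Used to plant diverged homologs of known identity.
#'
#' Identity is verified under a mild +1/-1 (gap 2/1) scoring: under
#' steeper mismatch penalties the optimal local alignment of a weakly
#' similar pair trims itself to a denser subregion, which makes low
#' target identities undefined as an alignment property. At identities
#' of 85% and above the two scorings report the same value.
#'
#' @param seq DNA character string.
#' @param target_identity fraction in (0, 1]; 1 returns the input
#'   unchanged.
#' @param indel_fraction fraction of edits realised as 1 bp indels.
#' @param seed optional RNG seed for standalone use; inside
#'   [generateDataset()] the generator's stream is used.
#' @param max_tries resampling bound before giving up.
#' @return the mutated sequence (character).
#' @export
mutateSequence <- function(seq, target_identity, indel_fraction = 0,
                           seed = NULL, max_tries = 30L) {
    if (is.na(target_identity) || target_identity <= 0 || target_identity > 1)
        .stopf("target_identity must be in (0, 1]")
    seq <- toupper(as.character(seq))
    if (target_identity == 1) return(seq)
    run <- function() {
        L <- nchar(seq)
        n_edits <- max(1L, round(L * (1 - target_identity)))
        goal <- 100 * target_identity
        for (try_ in seq_len(max_tries)) {
            n_edits <- max(1L, min(L - 1L, n_edits))
            v <- strsplit(seq, "")[[1]]
            n_ind <- round(n_edits * indel_fraction)
            n_sub <- n_edits - n_ind
            if (n_sub > 0) {
                pos <- sample(length(v), n_sub)
                for (p in pos)
                    v[p] <- sample(setdiff(.BASES, v[p]), 1)
            }
            for (k in seq_len(n_ind)) {
                p <- sample(length(v), 1)
                if (stats::runif(1) < 0.5 && length(v) > 2) {
                    v <- v[-p]
                } else {
                    v <- append(v, sample(.BASES, 1), after = p)
                }
            }
            out <- paste(v, collapse = "")
            hit <- dpAlignOracle(seq, out, alignParams("megablast_like",
                match = 1, mismatch = -1, gap_open = 2, gap_ext = 1))
            id <- if (nrow(hit)) hit$perc_identity[1] else 0
            if (id < 100 && abs(id - goal) <= 1) return(out)
            # steer the edit count by the observed miss
            n_edits <- n_edits + as.integer(round((id - goal) / 100 * L * 0.8))
            if (id >= 100) n_edits <- n_edits + 1L
        }
        .stopf("could not reach target identity %.2f within %d tries (sequence too short?)",
            target_identity, max_tries)
    }
    if (is.null(seed)) run() else .with_seed(seed, run())
}

# ------------------------------------------------------------- dataset build

# place items (list of list(tag, seq, annotate, gene_id, role, annotation))
# on one contig of target length; returns list(seq, placements)
.place_items <- function(items, target_len, gc) {
    parts <- character(0)
    cur <- 0L
    placements <- list()
    for (i in seq_along(items)) {
        it <- items[[i]]
        spacer <- 50L + sample.int(101L, 1) - 1L   # 50..150 bp
        glen <- nchar(it$seq)
        strand <- if (i %% 2 == 0) "-" else "+"
        placed <- if (strand == "-")
            as.character(reverseComplement(DNAString(it$seq))) else it$seq
        parts <- c(parts, .random_dna(spacer, gc), placed)
        start <- cur + spacer + 1L
        cur <- cur + spacer + glen
        placements[[i]] <- list(tag = it$tag, gene_id = it$gene_id,
            role = it$role, annotate = it$annotate,
            annotation = it$annotation,
            start = start, stop = cur, strand = strand, seq = it$seq)
    }
    if (cur + 50L > target_len)
        .stopf("planted genes (%d bp) do not fit contig length %d; need at least %d",
            cur, target_len, cur + 50L)
    parts <- c(parts, .random_dna(target_len - cur, gc))
    list(seq = paste(parts, collapse = ""), placements = placements)
}

#' Generate a synthetic two-group dataset with ground truth
#'
#' Builds target (A) and background (B) genome groups according to a
#' [synthSpec()], together with a manifest stating every planted gene's
#' role and its expected fate under the default configuration. Genomes
#' are i.i.d. background nucleotides at the spec GC with genes planted at
#' non-overlapping positions separated by >= 50 bp spacers, on
#' alternating strands; planted genes start with ATG and avoid in-frame
#' stops so protein mode is exercisable on the same fixtures.
#'
#' Expected fates at default configuration: core genes are removed at
#' step 1; unannotated/frameshifted background copies at step 2;
#' partial-occurrence and inconsistently annotated genes at the
#' occurrence filter (step 3, `min_occurrence = 1`); diverged homologs at
#' the sensitive screen (step 4); genes with a conserved background
#' segment longer than the cutoff at the short-hit screen (step 5);
#' target-exclusive (and multi-copy) genes are reported.
#'
#' @param spec a [synthSpec()].
#' @param out_dir optional directory; when given, writes
#'   `target/{genomes,orfs}/`, `background/{genomes,orfs}/` (badge-dialect
#'   ORF headers) and `manifest.tsv`.
#' @return list with elements `group_a`, `group_b` ([GenomeGroup-class])
#'   and `truth` (the manifest data.frame with columns `gene_id`, `role`,
#'   `length`, `expected_fate`, `annotated_in`, `identity`).
#' @export
generateDataset <- function(spec, out_dir = NULL) {
    stopifnot(is(spec, "SynthSpec"))
    .with_seed(spec@seed, {
        a_strains <- sprintf("A%d", seq_len(spec@n_a))
        b_strains <- sprintf("B%d", seq_len(spec@n_b))

        glen <- function() {
            if (spec@gene_len_max > spec@gene_len_min)
                spec@gene_len_min +
                    sample.int(spec@gene_len_max - spec@gene_len_min + 1L, 1) - 1L
            else spec@gene_len_min
        }

        mk_genes <- function(n, prefix) {
            if (n == 0) return(list())
            lapply(seq_len(n), function(i)
                list(gene_id = sprintf("%s%02d", prefix, i),
                     seq = .random_gene(glen(), spec@gc)))
        }
        core <- mk_genes(spec@n_core, "core")
        dmg <- mk_genes(spec@n_dmg, "dmg")
        partial <- mk_genes(spec@n_partial, "partial")
        decoyU <- mk_genes(spec@n_unannotated_decoys, "decoyU")
        decoyF <- mk_genes(spec@n_frameshift_decoys, "decoyF")
        div <- mk_genes(spec@n_diverged, "div")
        shortseg <- mk_genes(spec@n_shortseg, "shortseg")
        multi <- mk_genes(spec@n_multicopy, "multi")
        uneq <- mk_genes(spec@n_unequal_annot, "uneq")

        # background variants
        for (i in seq_along(decoyF)) {
            s <- decoyF[[i]]$seq
            p <- max(2L, round(0.3 * nchar(s)))
            decoyF[[i]]$b_seq <- paste0(substr(s, 1, p - 1),
                substr(s, p + 1, nchar(s)))
        }
        for (i in seq_along(div))
            div[[i]]$b_seq <- mutateSequence(div[[i]]$seq,
                spec@diverged_identity, indel_fraction = 0.1)
        for (i in seq_along(shortseg)) {
            s <- shortseg[[i]]$seq
            seg <- .random_dna(spec@shortseg_len, spec@gc)
            mid <- max(2L, (nchar(s) - spec@shortseg_len) %/% 2L)
            substr(s, mid, mid + spec@shortseg_len - 1L) <- seg
            shortseg[[i]]$seq <- s
            shortseg[[i]]$segment <- seg
        }

        partial_in <- a_strains[seq_len(max(1L,
            round(spec@partial_fraction * spec@n_a)))]
        uneq_in <- a_strains[seq_len(spec@unequal_annot_k)]

        item <- function(g, role, annotate = TRUE, seq = g$seq)
            list(tag = g$gene_id, seq = seq, annotate = annotate,
                 gene_id = g$gene_id, role = role,
                 annotation = sprintf("synthetic %s gene %s", role, g$gene_id))

        build_strain <- function(strain, group) {
            chr_items <- list(); pls_items <- list()
            add <- function(where, x) {
                if (where == "chr") chr_items[[length(chr_items) + 1]] <<- x
                else pls_items[[length(pls_items) + 1]] <<- x
            }
            excl_where <- if (spec@n_plasmids >= 1) "pls" else "chr"
            if (group == "A") {
                for (g in core) add("chr", item(g, "core"))
                for (g in dmg) add(excl_where, item(g, "true_dmg"))
                for (g in multi) {
                    copies <- if (strain == a_strains[1])
                        spec@multicopy_copies else 1L
                    for (k in seq_len(copies))
                        add(excl_where, item(g, "multicopy"))
                }
                for (g in partial) if (strain %in% partial_in)
                    add(excl_where, item(g, "partial"))
                for (g in decoyU) add("chr", item(g, "decoy_unannotated"))
                for (g in decoyF) add("chr", item(g, "decoy_frameshift"))
                for (g in div) add("chr", item(g, "diverged_homolog"))
                for (g in shortseg) add("chr", item(g, "shortseg"))
                for (g in uneq)
                    add("chr", item(g, "unequal_annot",
                        annotate = strain %in% uneq_in))
            } else {
                for (g in core) add("chr", item(g, "core"))
                for (g in div)
                    add("chr", item(g, "diverged_homolog", seq = g$b_seq))
                if (strain == b_strains[1]) {
                    for (g in decoyU)
                        add("chr", item(g, "decoy_unannotated", annotate = FALSE))
                    for (g in decoyF)
                        add("chr", item(g, "decoy_frameshift", annotate = FALSE,
                            seq = g$b_seq))
                    for (g in shortseg)
                        add("chr", item(g, "shortseg", annotate = FALSE,
                            seq = g$segment))
                }
            }
            contigs <- list()
            places <- list()
            chr_name <- paste0(strain, "_chr")
            pc <- .place_items(chr_items, spec@genome_len, spec@gc)
            contigs[[chr_name]] <- pc$seq
            places[[chr_name]] <- pc$placements
            for (p in seq_len(spec@n_plasmids)) {
                pn <- paste0(strain, "_p", p)
                pi <- if (p == 1) pls_items else list()
                pp <- .place_items(pi, spec@plasmid_len, spec@gc)
                contigs[[pn]] <- pp$seq
                places[[pn]] <- pp$placements
            }
            genome <- DNAStringSet(unlist(contigs))
            mcols(genome) <- DataFrame(description = rep("", length(genome)))
            # ORF records for annotated placements, numbered in contig order
            rows <- list()
            for (cn in names(places)) for (pl in places[[cn]])
                if (isTRUE(pl$annotate))
                    rows[[length(rows) + 1]] <- c(list(contig = cn), pl)
            n <- length(rows)
            orf <- if (n == 0) {
                orfSet(DNAStringSet(), character(0), strain = strain)
            } else {
                orfSet(
                    DNAStringSet(vapply(rows, `[[`, character(1), "seq")),
                    orf_id = sprintf("%s_%04d", strain, seq_len(n)),
                    strain = strain,
                    contig = vapply(rows, `[[`, character(1), "contig"),
                    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
                    stop = vapply(rows, function(r) as.integer(r$stop), integer(1)),
                    strand = vapply(rows, `[[`, character(1), "strand"),
                    annotation = vapply(rows, `[[`, character(1), "annotation"))
            }
            list(genome = genome, orfs = orf)
        }

        a_built <- lapply(a_strains, build_strain, group = "A")
        b_built <- lapply(b_strains, build_strain, group = "B")
        names(a_built) <- a_strains
        names(b_built) <- b_strains

        group_a <- genomeGroup("target",
            genomes = lapply(a_built, `[[`, "genome"),
            orfs = lapply(a_built, `[[`, "orfs"))
        group_b <- genomeGroup("background",
            genomes = lapply(b_built, `[[`, "genome"),
            orfs = lapply(b_built, `[[`, "orfs"))

        fate <- function(role, extra = "") switch(role,
            core = "removed_step1",
            true_dmg = "reported",
            multicopy = "reported",
            partial = if (identical(extra, "full")) "reported" else "removed_step3",
            decoy_unannotated = "removed_step2",
            decoy_frameshift = "removed_step2",
            diverged_homolog = "removed_step4",
            shortseg = "removed_step5",
            unequal_annot = "removed_step3")
        row <- function(g, role, annotated_in, identity = NA_real_,
                        extra = "")
            data.frame(gene_id = g$gene_id, role = role,
                length = nchar(g$seq), expected_fate = fate(role, extra),
                annotated_in = paste(annotated_in, collapse = ","),
                identity = identity, stringsAsFactors = FALSE)
        truth <- do.call(rbind, c(
            lapply(core, row, role = "core",
                annotated_in = c(a_strains, b_strains)),
            lapply(dmg, row, role = "true_dmg", annotated_in = a_strains),
            lapply(multi, row, role = "multicopy", annotated_in = a_strains),
            lapply(partial, row, role = "partial", annotated_in = partial_in,
                extra = if (setequal(partial_in, a_strains)) "full" else ""),
            lapply(decoyU, row, role = "decoy_unannotated",
                annotated_in = a_strains),
            lapply(decoyF, row, role = "decoy_frameshift",
                annotated_in = a_strains),
            lapply(div, row, role = "diverged_homolog",
                annotated_in = c(a_strains, b_strains),
                identity = spec@diverged_identity),
            lapply(shortseg, row, role = "shortseg", annotated_in = a_strains),
            lapply(uneq, row, role = "unequal_annot", annotated_in = uneq_in)))
        if (is.null(truth))
            truth <- data.frame(gene_id = character(), role = character(),
                length = integer(), expected_fate = character(),
                annotated_in = character(), identity = numeric(),
                stringsAsFactors = FALSE)
        rownames(truth) <- NULL

        if (!is.null(out_dir)) {
            dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
            writeGroup(group_a, file.path(out_dir, "target"))
            writeGroup(group_b, file.path(out_dir, "background"))
            write.table(truth, file.path(out_dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
        list(group_a = group_a, group_b = group_b, truth = truth)
    })
}
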