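suppressPackageStartupMessages(library(Biostrings))

# ---- independent statistical oracles -------------------------------------

# brute-force two-sided Fisher: enumerate every 2x2 table with the observed
# margins via its top-left cell and sum the probabilities (multinomial
# identities only, no dhyper) of tables no more probable than the observed
brute_fisher <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
    ptab <- function(x) {
        # hypergeometric point probability from factorials
        exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
            lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
            lfactorial(r1 - x) - lfactorial(c1 - x) -
            lfactorial(r2 - c1 + x))
    }
    xs <- max(0, c1 - r2):min(r1, c1)
    ps <- vapply(xs, ptab, numeric(1))
    p0 <- ptab(a)
    sum(ps[ps <= p0 * (1 + 1e-7)])
}

# mid-rank Spearman rho from first principles
brute_spearman <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ---- sequence helpers ----------------------------------------------------

random_dna <- function(n, seed = NULL) {
    gen <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# coding-like random gene (ATG start, no in-frame stops)
random_gene <- function(n, seed = NULL) {
    gen <- function() dmgfinder:::.random_gene(n, 0.45)
    if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

dss <- function(...) {
    x <- c(...)
    DNAStringSet(setNames(unname(x), names(x)))
}

# ---- tiny two-group fixtures ---------------------------------------------

# small spec used by most pipeline tests (fast: ~30 kb genomes)
small_spec <- function(seed = 1L, ...) {
    args <- list(genome_len = 30000L, plasmid_len = 8000L, n_core = 8L,
        seed = seed)
    args[names(list(...))] <- list(...)
    do.call(synthSpec, args)
}

# a hand-built two-strain group: named list gene_id -> sequence per strain;
# genes are concatenated with fixed 60 bp spacers
manual_group <- function(name, strain_genes, seed = 99L) {
    withr::with_seed(seed, {
        genomes <- list(); orfsets <- list()
        for (s in names(strain_genes)) {
            genes <- strain_genes[[s]]
            spacer <- function() random_dna(60)
            parts <- character(); starts <- integer(); stops <- integer()
            cur <- 0L
            for (g in genes) {
                sp <- spacer()
                parts <- c(parts, sp, g)
                starts <- c(starts, cur + nchar(sp) + 1L)
                cur <- cur + nchar(sp) + nchar(g)
                stops <- c(stops, cur)
            }
            parts <- c(parts, spacer())
            contig <- paste(parts, collapse = "")
            genomes[[s]] <- DNAStringSet(setNames(contig, paste0(s, "_chr")))
            orfsets[[s]] <- orfSet(DNAStringSet(genes),
                orf_id = sprintf("%s_%03d", s, seq_along(genes)),
                strain = s, contig = paste0(s, "_chr"),
                start = starts, stop = stops, strand = "+",
                annotation = names(genes) %||% "hypothetical protein")
        }
        genomeGroup(name, genomes, orfsets)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
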