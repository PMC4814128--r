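# 7 spoilers / 13 non-spoilers: the validation panel's group sizes
tab <- function(fp, fn) matrix(c(7 - fn, fn, fp, 13 - fp), 2, 2, byrow = TRUE)

test_that("two-sided Fisher equals brute-force enumeration on small tables", {
    withr::with_seed(41, {
        for (rep in 1:60) {
            n <- sample(4:30, 1)
            cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
            t2 <- matrix(cells, 2, 2)
            expect_equal(fisherExactTwoSided(t2), brute_fisher(t2),
                tolerance = 1e-12)
            # and agrees with the stats-package implementation
            expect_equal(fisherExactTwoSided(t2),
                stats::fisher.test(t2)$p.value, tolerance = 1e-9)
        }
    })
})

test_that("Fisher P is invariant under transposition and row/column swaps", {
    withr::with_seed(42, {
        for (rep in 1:20) {
            t2 <- matrix(sample(0:9, 4, TRUE), 2, 2)
            p <- fisherExactTwoSided(t2)
            expect_equal(fisherExactTwoSided(t(t2)), p, tolerance = 1e-12)
            expect_equal(fisherExactTwoSided(t2[2:1, 2:1]), p,
                tolerance = 1e-12)
        }
    })
})

test_that("degenerate margins give P = 1 and negative cells an error", {
    expect_equal(fisherExactTwoSided(matrix(c(0, 0, 5, 8), 2, byrow = TRUE)), 1)
    expect_equal(fisherExactTwoSided(matrix(c(0, 3, 0, 8), 2, byrow = TRUE)), 1)
    expect_error(fisherExactTwoSided(matrix(c(-1, 3, 2, 8), 2)), "non-negative")
})

test_that("Spearman rho handles perfect, inverse, tied and degenerate inputs", {
    expect_equal(spearmanRho(c(1, 2, 3), c(1, 2, 3))$rho, 1)
    expect_equal(spearmanRho(c(1, 2, 3), c(3, 2, 1))$rho, -1)
    # mid-rank ties, checked against a first-principles rank computation
    x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)
    expect_equal(spearmanRho(x, y)$rho, brute_spearman(x, y))
    expect_equal(spearmanRho(x, y)$rho, 0)
    withr::with_seed(43, {
        for (rep in 1:10) {
            a <- sample(0:3, 12, TRUE); b <- sample(0:1, 12, TRUE)
            if (length(unique(a)) < 2 || length(unique(b)) < 2) next
            expect_equal(spearmanRho(a, b)$rho, brute_spearman(a, b),
                tolerance = 1e-12)
        }
    })
    expect_error(spearmanRho(c(1, 1, 1), c(1, 2, 3)), "zero variance")
    expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

pheno20 <- data.frame(
    strain = sprintf("S%02d", 1:20),
    ability = c(rep("spoiler", 7), rep("non_spoiler", 13)),
    potential_rank = c(rep(3, 4), rep(2, 3), rep(0, 13)),
    stringsAsFactors = FALSE)

test_that("confusion counts and correct discrimination match the definitions", {
    # marker present in exactly the 7 spoilers: perfect discrimination
    p <- setNames(c(rep(1, 7), rep(0, 13)), pheno20$strain)
    cc <- confusionCounts(p, pheno20)
    expect_equal(c(cc$c, cc$b), c(0L, 0L))  # FP 0/13, FN 0/7
    expect_equal(cc$correct_pct, 100)

    # two false positives
    p2 <- p; p2[c("S08", "S09")] <- 1
    cc2 <- confusionCounts(p2, pheno20)
    expect_equal(c(cc2$c, cc2$b), c(2L, 0L))
    expect_equal(cc2$correct_pct, 90)

    # marker present everywhere
    cc3 <- confusionCounts(setNames(rep(1, 20), pheno20$strain), pheno20)
    expect_equal(c(cc3$c, cc3$b), c(13L, 0L))
    expect_equal(cc3$correct_pct, 35)

    expect_error(confusionCounts(setNames(1, "nope"), pheno20), "missing")
    # complementarity: correct% + error% = 100%
    for (cc_ in list(cc, cc2, cc3))
        expect_equal(cc_$correct_pct + 100 * (cc_$c + cc_$b) / 20, 100)
})

test_that("evaluateMarkers reproduces the published marker panel statistics", {
    # reconstruct each marker's presence calls from its printed FP/FN counts
    mk <- function(fp, fn) c(rep(1, 7 - fn), rep(0, fn), rep(1, fp),
        rep(0, 13 - fp))
    mat <- rbind(
        fabZ = mk(0, 0), tnpA = mk(2, 0), npxA = mk(2, 0),
        parA = mk(1, 3), tetR = mk(1, 3),
        horA = mk(8, 0), hitA = mk(2, 4), icaA = mk(2, 4), tnpB = mk(2, 4),
        horC = mk(8, 1))
    colnames(mat) <- pheno20$strain
    res <- evaluateMarkers(mat, pheno20)
    p <- setNames(res$fisher_p, res$marker)
    expect_equal(round(p[["fabZ"]], 5), 0.00001)
    expect_equal(round(p[["tnpA"]], 5), 0.00046)
    expect_equal(round(p[["npxA"]], 5), 0.00046)
    expect_equal(round(p[["parA"]], 3), 0.031)
    expect_equal(round(p[["tetR"]], 3), 0.031)
    expect_equal(round(p[["horA"]], 2), 0.11)
    expect_equal(round(p[["hitA"]], 2), 0.29)
    expect_equal(round(p[["horC"]], 2), 0.35)
    # sorted by descending Fisher P, fabZ last
    expect_equal(res$marker[nrow(res)], "fabZ")
    expect_true(all(diff(res$fisher_p) <= 1e-12))
    cp <- setNames(res$correct_pct, res$marker)
    expect_equal(unname(cp[c("fabZ", "tnpA", "parA", "horA", "hitA", "horC")]),
        c(100, 90, 80, 60, 70, 55))
})

test_that("a random marker is non-significant on nearly all label permutations", {
    withr::with_seed(44, {
        presence <- sample(c(rep(1, 10), rep(0, 10)))
        hits <- 0L
        n_perm <- 1000L
        for (i in seq_len(n_perm)) {
            lab <- sample(pheno20$ability)
            sp <- lab == "spoiler"
            t2 <- matrix(c(sum(sp & presence == 1), sum(sp & presence == 0),
                sum(!sp & presence == 1), sum(!sp & presence == 0)),
                2, 2, byrow = TRUE)
            if (fisherExactTwoSided(t2) <= 0.05) hits <- hits + 1L
        }
        expect_lt(hits / n_perm, 0.05)
    })
})

test_that("phenotype and presence tables read from TSV with rank encoding", {
    pf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("strain\tpotential_rank", "s1\tSB", "s2\tMB", "s3\tWB",
        "s4\tNB"), pf)
    ph <- readPhenotypes(pf)
    expect_equal(ph$potential_rank, c(3, 2, 1, 0))
    # ability derived from rank: spoiler iff >= MB
    expect_equal(ph$ability,
        c("spoiler", "spoiler", "non_spoiler", "non_spoiler"))

    mf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("marker\ts1\ts2\ts3\ts4", "mk1\t1\t1\t0\t0"), mf)
    m <- readPresenceMatrix(mf)
    expect_equal(dim(m), c(1L, 4L))
    expect_equal(unname(m["mk1", ]), c(1L, 1L, 0L, 0L))

    writeLines(c("marker\ts1", "mk1\t2"), mf)
    expect_error(readPresenceMatrix(mf), "0/1")
})
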