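test_that("mutateSequence reaches target identities (oracle-verified)", {
    base <- random_gene(999, seed = 501)
    expect_identical(mutateSequence(base, 1.0), base)
    mild <- alignParams("megablast_like", match = 1, mismatch = -1,
        gap_open = 2, gap_ext = 1)
    m <- mutateSequence(base, 0.85, indel_fraction = 0, seed = 502)
    id <- dpAlignOracle(base, m, mild)$perc_identity
    expect_gte(id, 84); expect_lte(id, 86)
    expect_error(mutateSequence(base, 0), "target_identity")
    # a 20 bp sequence cannot land within a point of 99% identity
    short <- substr(base, 1, 20)
    expect_error(mutateSequence(short, 0.99, seed = 503), "could not reach")
})

test_that("the generator is deterministic: same spec + seed, identical files", {
    spec <- small_spec(seed = 91)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    generateDataset(spec, out_dir = d1)
    generateDataset(spec, out_dir = d2)
    f1 <- sort(list.files(d1, recursive = TRUE))
    expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
    for (f in f1)
        expect_identical(readLines(file.path(d1, f)),
            readLines(file.path(d2, f)), label = f)
    # and a different seed changes the sequences
    d3 <- withr::local_tempdir()
    generateDataset(small_spec(seed = 92), out_dir = d3)
    expect_false(identical(
        readLines(file.path(d1, "target/genomes/A1.fasta")),
        readLines(file.path(d3, "target/genomes/A1.fasta"))))
})

test_that("generated files reload into equivalent groups", {
    spec <- small_spec(seed = 93)
    out <- withr::local_tempdir()
    d <- generateDataset(spec, out_dir = out)
    ga <- loadGroup(file.path(out, "target/genomes"),
        file.path(out, "target/orfs"), "target")
    expect_identical(strains(ga), strains(d$group_a))
    expect_identical(lapply(orfs(ga), as.character),
        lapply(orfs(d$group_a), as.character))
    expect_identical(lapply(genomes(ga), as.character),
        lapply(genomes(d$group_a), as.character))
})

test_that("planted ORF coordinates extract the ORF sequence from its contig", {
    d <- generateDataset(small_spec(seed = 94))
    for (grp in list(d$group_a, d$group_b)) {
        for (s in strains(grp)) {
            o <- orfs(grp)[[s]]
            m <- mcols(o)
            for (i in seq_along(o)) {
                sub <- subseq(genomes(grp)[[s]][[m$contig[i]]],
                    m$start[i], m$stop[i])
                if (m$strand[i] == "-") sub <- reverseComplement(sub)
                expect_identical(as.character(sub), as.character(o[[i]]))
            }
        }
    }
})

test_that("manifest counts reflect the spec and roles are unique per gene", {
    spec <- small_spec(seed = 95, n_dmg = 4L, n_core = 6L, n_multicopy = 2L,
        plasmid_len = 16000L)
    d <- generateDataset(spec)
    tr <- d$truth
    expect_equal(sum(tr$role == "true_dmg"), 4L)
    expect_equal(sum(tr$role == "core"), 6L)
    expect_equal(sum(tr$role == "multicopy"), 2L)
    expect_false(anyDuplicated(tr$gene_id) > 0)
    expect_true(all(tr$expected_fate %in% c("reported", "removed_step1",
        "removed_step2", "removed_step3", "removed_step4", "removed_step5")))
    # multicopy genes appear twice in the first target strain's annotation
    ann <- mcols(orfs(d$group_a)$A1)$annotation
    for (g in tr$gene_id[tr$role == "multicopy"])
        expect_equal(sum(grepl(paste0("gene ", g, "$"), ann)), 2L)
})

test_that("a spec with no target-exclusive genes yields zero families", {
    spec <- small_spec(seed = 96, n_dmg = 0L, n_multicopy = 0L,
        n_partial = 0L, n_shortseg = 0L, n_unannotated_decoys = 0L,
        n_frameshift_decoys = 0L, n_diverged = 0L)
    d <- generateDataset(spec)
    res <- suppressMessages(runPipeline(d$group_a, d$group_b, badgeConfig()))
    expect_length(dmgFamilies(res), 0L)
})

test_that("oversized gene content is rejected with the required minimum", {
    spec <- small_spec(seed = 97, genome_len = 3000L, n_core = 20L)
    expect_error(generateDataset(spec), "do not fit")
})

test_that("decoy classes die at their designated steps (fate concordance)", {
    for (seed in c(11L, 12L, 13L)) {
        d <- generateDataset(small_spec(seed = seed))
        res <- suppressMessages(runPipeline(d$group_a, d$group_b, badgeConfig()))
        sc <- stepCounts(res)
        tr <- d$truth
        n_a <- length(strains(d$group_a))
        # step 1 removes only the core genes (the diverged homolog is
        # annotated in the background but sits below the identity cutoff)
        per_strain <- function(roles) sum(tr$role %in% roles)
        a_total <- sum(lengths(orfs(d$group_a)))
        expect_equal(unname(sc["step1_orf_filter"]),
            a_total - n_a * per_strain("core"))
        # step 2 removes both embedded decoy classes from every strain
        expect_equal(unname(sc["step1_orf_filter"] - sc["step2_genome_filter"]),
            n_a * per_strain(c("decoy_unannotated", "decoy_frameshift")))
        # step 3 removes partial-occurrence families
        expect_equal(unname(sc["step3_occurrence"]),
            sum(tr$expected_fate %in% c("reported", "removed_step4",
                "removed_step5")))
        # step 4 the diverged homologs, step 5 the shared-segment genes
        expect_equal(unname(sc["step3_occurrence"] - sc["step4_dc_filter"]),
            sum(tr$expected_fate == "removed_step4"))
        expect_equal(unname(sc["step4_dc_filter"] - sc["step5_short_hit_filter"]),
            sum(tr$expected_fate == "removed_step5"))
        expect_true(all(diff(sc) <= 0))
    }
})
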