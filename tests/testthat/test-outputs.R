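res_and_data <- local({
    d <- generateDataset(small_spec(seed = 201))
    res <- suppressMessages(runPipeline(d$group_a, d$group_b, badgeConfig()))
    list(d = d, res = res)
})

test_that("writeOutputs produces the full file inventory", {
    out <- withr::local_tempdir()
    writeOutputs(res_and_data$res, out, b_genomes = res_and_data$d$group_b)
    n_fam <- length(res_and_data$res)
    expect_gt(n_fam, 0L)
    expect_true(file.exists(file.path(out, "DMG_representatives.fasta")))
    reps <- readFasta(file.path(out, "DMG_representatives.fasta"))
    expect_length(reps, n_fam)
    fam_files <- list.files(file.path(out, "DMG_sequences"))
    expect_length(fam_files, n_fam)
    for (f in c("DMG_table.tsv", "DMG.distribution", "DMG.frequency",
        "settings.txt", "step_counts.txt", "residual_alignments.txt"))
        expect_true(file.exists(file.path(out, f)), label = f)

    tab <- read.delim(file.path(out, "DMG_table.tsv"))
    expect_named(tab, c("DMG_ID", "percent_occurrence", "dc_blast_hit",
        "max_blastn", "ORF_ID", "ORF_length", "annotation", "contig",
        "start", "stop", "strain"))
    # family rows contiguous
    expect_identical(tab$DMG_ID, tab$DMG_ID[order(match(tab$DMG_ID,
        unique(tab$DMG_ID)))])
    dist <- read.delim(file.path(out, "DMG.distribution"))
    expect_equal(nrow(dist), n_fam)
})

test_that("reruns with identical inputs produce byte-identical outputs", {
    o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
    d <- res_and_data$d
    r1 <- suppressMessages(runPipeline(d$group_a, d$group_b, badgeConfig()))
    r2 <- suppressMessages(runPipeline(d$group_a, d$group_b, badgeConfig()))
    writeOutputs(r1, o1, b_genomes = d$group_b)
    writeOutputs(r2, o2, b_genomes = d$group_b)
    files <- sort(list.files(o1, recursive = TRUE))
    expect_identical(files, sort(list.files(o2, recursive = TRUE)))
    for (f in files)
        expect_identical(readLines(file.path(o1, f), warn = FALSE),
            readLines(file.path(o2, f), warn = FALSE), label = f)
})

test_that("verbose runs keep and dump intermediate candidate sets", {
    d <- res_and_data$d
    r <- suppressMessages(runPipeline(d$group_a, d$group_b,
        badgeConfig(clean_up = FALSE)))
    expect_named(r@intermediates, c("step1_candidates", "step2_candidates"))
    out <- withr::local_tempdir()
    writeOutputs(r, out)
    expect_true(file.exists(
        file.path(out, "intermediate", "step1_candidates.fasta")))
})

test_that("partial-occurrence families omit the absent strain's rows", {
    d <- generateDataset(small_spec(seed = 202))
    res <- suppressMessages(runPipeline(d$group_a, d$group_b,
        badgeConfig(min_occurrence = 0.5)))
    tab <- familyTable(res)
    partial_gene <- d$truth$gene_id[d$truth$role == "partial"]
    rows <- tab[grepl(paste0("gene ", partial_gene, "$"), tab$annotation), ]
    expect_equal(nrow(rows), 1L)
    expect_lt(rows$percent_occurrence[1], 100)
})

test_that("settings files round-trip through read/write", {
    cfg <- badgeConfig(megablast_perc_identity_cut = 90,
        dc_perc_identity_cut = 85, min_occurrence = 0.25, mode = "dc",
        clean_up = FALSE)
    f <- withr::local_tempfile(fileext = ".txt")
    writeBadgeConfig(cfg, f)
    cfg2 <- readBadgeConfig(f)
    for (s in dmgfinder:::.config_fields())
        expect_identical(slot(cfg2, s), slot(cfg, s), label = s)
    writeLines(c("mystery = 4"), f)
    expect_error(readBadgeConfig(f), "unknown setting")
})

test_that("invalid configurations are rejected", {
    expect_error(badgeConfig(min_occurrence = 0), "min_occurrence")
    expect_error(badgeConfig(dc_perc_identity_cut = 99), "sensitive")
    expect_error(badgeConfig(mode = "nope"), "mode")
})

test_that("the command-line entry point runs a full prediction", {
    script <- system.file("scripts", "dmgfinder.R", package = "dmgfinder")
    expect_true(nzchar(script))
    root <- withr::local_tempdir()
    generateDataset(small_spec(seed = 203), out_dir = root)
    out <- file.path(root, "run_out")
    rscript <- file.path(R.home("bin"), "Rscript")
    status <- system2(rscript, c(script, "run",
        "--group-a-genomes", file.path(root, "target/genomes"),
        "--group-a-orfs", file.path(root, "target/orfs"),
        "--group-b-genomes", file.path(root, "background/genomes"),
        "--group-b-orfs", file.path(root, "background/orfs"),
        "--out", out), stdout = FALSE, stderr = FALSE)
    expect_equal(status, 0L)
    expect_true(file.exists(file.path(out, "DMG_table.tsv")))
})
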