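test_that("readFasta parses records, joins wrapped lines, uppercases", {
    f <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a first gene", "AC", "gt", ">b", "ACGT"), f)
    x <- readFasta(f)
    expect_equal(names(x), c("a", "b"))
    expect_equal(as.character(x[["a"]]), "ACGT")
    expect_equal(mcols(x)$description, c("first gene", ""))
    expect_equal(width(x), c(4L, 4L))
})

test_that("readFasta handles empty files and rejects malformed input", {
    f <- withr::local_tempfile(fileext = ".fasta")
    file.create(f)
    expect_length(readFasta(f), 0)

    writeLines(c("not a fasta", "ACGT"), f)
    expect_error(readFasta(f), "FASTA")

    writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
    expect_error(readFasta(f), "duplicate")

    writeLines(c(">", "ACGT"), f)
    expect_error(readFasta(f), "empty id")
})

test_that("ambiguity codes map to N with a warning", {
    f <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a", "ACGTRYN"), f)
    expect_warning(x <- readFasta(f), "ambiguity")
    expect_equal(as.character(x[[1]]), "ACGTNNN")
})

test_that("write/read round trip is byte-stable for ids and sequences", {
    withr::with_seed(11, {
        x <- DNAStringSet(vapply(1:5, function(i) random_dna(37 * i), ""))
        names(x) <- paste0("seq", 1:5)
        mcols(x) <- S4Vectors::DataFrame(
            description = c("alpha  beta", "", "g  h  i", "x", ""))
    })
    f <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(x, f)
    y <- readFasta(f)
    expect_identical(as.character(y), as.character(x))
    expect_identical(names(y), names(x))
    # description whitespace normalized to single spaces
    expect_identical(mcols(y)$description[1], "alpha beta")
})

test_that("parseOrfHeader handles both dialects and reports bad fields", {
    h <- paste("ADU70_0261 contig=p1 start=100 stop=561 strand=+",
        "annotation=3-hydroxyacyl-[acyl-carrier-protein] dehydratase")
    m <- parseOrfHeader(h)
    expect_equal(m$orf_id, "ADU70_0261")
    expect_equal(m$contig, "p1")
    expect_equal(m$start, 100L)
    expect_equal(m$stop, 561L)
    expect_equal(m$strand, "+")
    expect_equal(m$annotation,
        "3-hydroxyacyl-[acyl-carrier-protein] dehydratase")

    b <- parseOrfHeader("gene7", dialect = "bare")
    expect_equal(b$orf_id, "gene7")
    expect_true(is.na(b$contig))
    expect_equal(b$annotation, "hypothetical protein")

    expect_error(parseOrfHeader("g1 contig=c stop=5 strand=+"), "start")
    expect_error(parseOrfHeader("g1 contig=c start=x stop=5 strand=+"),
        "coordinates")
    expect_error(parseOrfHeader(""), "orf_id")
})

test_that("gffToOrfs extracts CDS features with strand handling", {
    genome <- DNAStringSet(c(chr1 = "AATGC"))
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\ttest\tCDS\t2\t4\t.\t+\t0\tID=cds1;product=widget synthase",
        "chr1\ttest\tCDS\t2\t4\t.\t-\t0\tID=cds2"), gff)
    o <- gffToOrfs(genome, gff, strain = "s1")
    expect_equal(as.character(o), setNames(c("ATG", "CAT"), c("cds1", "cds2")))
    expect_equal(mcols(o)$annotation,
        c("widget synthase", "hypothetical protein"))
    expect_equal(mcols(o)$strand, c("+", "-"))
})

test_that("gffToOrfs rejects out-of-bounds and unknown seqids", {
    genome <- DNAStringSet(c(chr1 = "AATGC"))
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
        "chr1\ttest\tCDS\t2\t9\t.\t+\t0\tID=cds1"), gff)
    expect_error(gffToOrfs(genome, gff, "s1"), "chr1.*bounds")
    writeLines(c("##gff-version 3",
        "chrX\ttest\tCDS\t1\t3\t.\t+\t0\tID=cds1"), gff)
    expect_error(gffToOrfs(genome, gff, "s1"), "chrX")
})

test_that("gffToOrfs output is a substring (or revcomp) of its contig", {
    withr::with_seed(5, {
        contig <- random_dna(3000)
        genome <- DNAStringSet(c(c1 = contig))
        gff <- withr::local_tempfile(fileext = ".gff3")
        starts <- c(101, 901, 1801)
        ends <- starts + c(299, 450, 600)
        strands <- c("+", "-", "+")
        writeLines(c("##gff-version 3", sprintf(
            "c1\tx\tCDS\t%d\t%d\t.\t%s\t0\tID=g%d", starts, ends, strands,
            seq_along(starts))), gff)
        o <- gffToOrfs(genome, gff, "s1")
        for (i in seq_along(o)) {
            s <- as.character(o[[i]])
            fwd <- grepl(s, contig, fixed = TRUE)
            rev <- grepl(as.character(reverseComplement(DNAString(s))),
                contig, fixed = TRUE)
            expect_true(fwd || rev)
        }
    })
})

test_that("loadGroup pairs files, sorts strains, validates contigs", {
    root <- withr::local_tempdir()
    gd <- file.path(root, "genomes"); od <- file.path(root, "orfs")
    dir.create(gd); dir.create(od)
    mk_strain <- function(name, gene) {
        contig <- paste0(random_dna(100), gene, random_dna(100))
        writeLines(c(paste0(">", name, "_chr"), contig),
            file.path(gd, paste0(name, ".fasta")))
        hdr <- sprintf(">%s_001 contig=%s_chr start=101 stop=%d strand=+ annotation=thing",
            name, name, 100 + nchar(gene))
        writeLines(c(hdr, gene), file.path(od, paste0(name, ".fasta")))
    }
    withr::with_seed(3, {
        # written in non-lexicographic order on purpose
        mk_strain("zeta", random_gene(300))
        mk_strain("alpha", random_gene(300))
    })
    g <- loadGroup(gd, od, "grp")
    expect_s4_class(g, "GenomeGroup")
    expect_equal(strains(g), c("alpha", "zeta"))
    expect_equal(mcols(orfs(g)$alpha)$contig, "alpha_chr")

    # orphan genome file
    writeLines(c(">x_chr", "ACGTACGT"), file.path(gd, "orphan.fasta"))
    expect_error(loadGroup(gd, od, "grp"), "orphan")
    unlink(file.path(gd, "orphan.fasta"))

    # unknown contig reference is an error in the badge dialect
    bad <- file.path(od, "alpha.fasta")
    lines <- readLines(bad)
    lines[1] <- sub("contig=alpha_chr", "contig=nope", lines[1])
    writeLines(lines, bad)
    expect_error(loadGroup(gd, od, "grp"), "absent from the genome")
})

test_that("loadGroup ordering is independent of file creation order", {
    mk <- function(root, order_) {
        gd <- file.path(root, "genomes"); od <- file.path(root, "orfs")
        dir.create(gd); dir.create(od)
        gene <- random_gene(240, seed = 8)
        for (name in order_) {
            contig <- paste0(strrep("AC", 30), gene)
            writeLines(c(paste0(">", name, "_chr"), contig),
                file.path(gd, paste0(name, ".fasta")))
            writeLines(c(sprintf(
                ">%s_001 contig=%s_chr start=61 stop=%d strand=+ annotation=z",
                name, name, 60 + nchar(gene)), gene),
                file.path(od, paste0(name, ".fasta")))
        }
        loadGroup(gd, od, "g")
    }
    g1 <- mk(withr::local_tempdir(), c("b", "a", "c"))
    g2 <- mk(withr::local_tempdir(), c("c", "b", "a"))
    expect_identical(strains(g1), strains(g2))
    expect_identical(lapply(orfs(g1), as.character),
        lapply(orfs(g2), as.character))
})
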