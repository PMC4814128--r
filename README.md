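# dmgfinder

Diagnostic marker gene (DMG) prediction for bacterial strain groups: find
genes present in (nearly) all genomes of a phenotype-defined **target
group** and absent from every genome of a **background group**, so a
single PCR can discriminate the groups — e.g. beer-spoiling versus
harmless strains of a brewery contaminant, or pathogenic versus probiotic
isolates of the same species.

## What it does

Inputs are, per strain, a genome FASTA (chromosome + plasmid contigs) and
an ORF FASTA (annotated coding sequences, DNA), arranged into the two
groups. Prediction runs in six steps, each reporting its survivor count:

1. discard target ORFs with a high-quality alignment (identity, query and
   subject coverage ≥ the primary cutoffs, default 95/95/95) to any
   background ORF;
2. discard candidates found in the raw background **contigs** — genes the
   background annotation missed or carries frameshifted;
3. group survivors into gene families (single-linkage on passing
   alignments) and keep families present in ≥ `min_occurrence` of target
   genomes;
4. remove families with a long low-identity background hit (sensitive
   discontiguous-style search, defaults 80% identity / 60% coverage);
5. remove families with a short high-identity background hit longer than
   `max_blastn_len_cut` (default 100 bp);
6. write representative and per-family FASTAs, a per-member table,
   presence and copy-number matrices, settings, counts and residual
   alignments.

Alignment uses a built-in seed-and-extend engine (exact k-mer seeding,
diagonal clustering, banded Smith–Waterman; word sizes 28/11/11/3 for the
megablast-, dc-, blastn- and blastp-like tasks) or, optionally, an
external BLAST+ installation. Additional tools: an **annotation
equalizer** that repairs inconsistent gene calling inside a group, a
**distribution mode** producing gene × strain presence/copy-number
matrices across all genomes, **protein** and **mutation-level** search
modes, marker **validation statistics** (two-sided Fisher exact test by
exact enumeration, Spearman ρ with mid-rank ties, confusion counts), a
GFF3 → ORF-FASTA converter, and a deterministic **synthetic-data
generator** with a ground-truth manifest.

## Worked example

Generate a small synthetic dataset with known truth (three planted
target-exclusive genes, one duplicated gene, plus core genes and one
confound of every class), run the pipeline, and inspect the result:

```r
library(dmgfinder)

d   <- generateDataset(synthSpec(genome_len = 50000, n_core = 12, seed = 7))
res <- runPipeline(d$group_a, d$group_b, badgeConfig())
#> step 1 (ORF filter): 18 candidate ORF(s)
#> step 2 (genome filter): 14 candidate ORF(s)
#> step 3 (occurrence filter): 6 DMG families
#> step 4 (dc filter): 5 DMG families
#> step 5 (short-hit filter): 4 DMG families

res
#> DmgResult: 4 DMG families
#>   step counts: step1_orf_filter=18, step2_genome_filter=14,
#>   step3_occurrence=6, step4_dc_filter=5, step5_short_hit_filter=4

head(familyTable(res), 8)
#>  DMG_ID percent_occurrence dc_blast_hit max_blastn  ORF_ID ORF_length contig start stop
#>   DMG_1                100           no          0 A1_0017       1131  A1_p1    90 1220
#>   DMG_1                100           no          0 A2_0017       1131  A2_p1    77 1207
#>   DMG_2                100           no          0 A1_0018        930  A1_p1  1278 2207
#>   DMG_2                100           no          0 A2_0018        930  A2_p1  1328 2257
#>   DMG_3                100           no          0 A1_0019       1062  A1_p1  2356 3417
#>   DMG_3                100           no          0 A2_0019       1062  A2_p1  2400 3461
#>   DMG_4                100           no          0 A1_0020        684  A1_p1  3491 4174
#>   DMG_4                100           no          0 A1_0021        684  A1_p1  4308 4991
```

Reading the counts: step 1 removed the 12 core genes from each of the two
target genomes; step 2 caught the two genes that are present-but-
unannotated (one of them frameshifted) in a background contig; the
occurrence filter dropped the gene present in only one of two target
genomes; the sensitive screen removed the gene with an 85%-identity
background homolog; the short-hit screen removed the gene sharing a
150 bp segment with a background contig. The four reported families are
exactly the planted target-exclusive genes; `DMG_4` is the duplicated
gene — two member ORFs in strain A1, coordinates ascending.

Validating markers on a strain panel (7 spoilers, 13 non-spoilers;
`fabZ`-like perfect marker versus a `horA`-like hop-resistance gene):

```r
pheno <- data.frame(strain = sprintf("S%02d", 1:20),
                    ability = c(rep("spoiler", 7), rep("non_spoiler", 13)),
                    potential_rank = c(rep(3, 5), rep(2, 2), rep(0, 13)))
m <- rbind(fabZ = c(rep(1, 7), rep(0, 13)),
           horA = c(rep(1, 15), rep(0, 5)))
colnames(m) <- pheno$strain
evaluateMarkers(m, pheno)
#>   marker     fisher_p spearman_rho rho_display correct_pct false_positive false_negative
#> 1   horA 0.1137125903    0.4157397          NS          60              8              0
#> 2   fabZ 0.0000128999    0.9813068        0.98         100              0              0
```

The perfect marker discriminates all 20 strains (Fisher P ≈ 1.3 × 10⁻⁵,
ρ = 0.98); the hop-resistance comparator does not separate the groups
(P = 0.11, ρ not significant at CI 95).

A thin command-line wrapper over the same functions ships at
`inst/scripts/dmgfinder.R` with subcommands `run`, `equalize`, `validate`
and `simulate`.

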