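---
title: "Predicting diagnostic marker genes between bacterial strain groups"
author: "dmgfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting diagnostic marker genes between bacterial strain groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many phenotypes of bacteria — pathogenicity, niche adaptation, the ability
of lactic acid bacteria to grow in hopped beer — track the presence or
absence of specific genes rather than point variation in shared genes. A
*diagnostic marker gene* (DMG) for a phenotype-defined group of strains is
a gene present in (nearly) every genome of that target group and absent
from every genome of a background group, so that a single PCR assay can
discriminate the groups. `dmgfinder` predicts such genes from assembled
genomes and their annotated coding sequences (ORFs), and provides the
statistics used to validate candidate markers on a strain panel.

The inputs are deliberately minimal: per strain, one FASTA of contigs
(chromosome plus plasmids) and one FASTA of annotated ORFs (DNA, coding
strand), organized into a target group A and a background group B.

## The prediction procedure

The pipeline (`runPipeline()`) proceeds in six steps, and reports the
number of surviving candidates after each one so the effect of every
setting is visible:

1. **ORF filter.** Every A ORF is aligned against all B ORFs. An ORF with
   a high-quality hit — percent identity, query coverage and subject
   coverage all at or above the primary cutoffs (default 95/95/95) — is
   discarded.
2. **Genome filter.** Survivors are aligned against the raw B contigs and
   discarded on a passing identity + query-coverage hit. This catches
   genes the background *annotation* missed: unannotated genes and
   frameshifted pseudogenes still present in the background sequence.
   Subject coverage is not applied, because the subjects are whole
   contigs.
3. **Family grouping and occurrence filter.** Surviving ORFs are grouped
   into gene families by single-linkage clustering (two ORFs are linked
   when an alignment between them passes the primary cutoffs in either
   direction). A family's occurrence is the fraction of A genomes with at
   least one member; families below `min_occurrence` (default 1.0,
   inclusive comparison) are dropped. Setting the floor to one genome in
   *n* (e.g. 0.02 for 50 genomes) retains everything.
4. **Sensitive screen.** Optional: each member is searched against the B
   contigs with the sensitive (`dc_like`) task; a family with a hit at
   identity ≥ 80 and query coverage ≥ 60 (defaults) is removed — it has a
   diverged background homolog and would cross-react. Families with only
   sub-threshold hits survive, flagged `dc_blast_hit = yes`.
5. **Short-hit screen.** Optional: a `blastn_like` search at the primary
   identity with no coverage floor removes families containing a
   conserved background segment longer than `max_blastn_len_cut`
   (default 100 bp) — such segments would compromise primer placement.
   Survivors record `max_blastn`, the longest remaining hit.
6. **Output assembly.** Families are numbered `DMG_<n>` deterministically,
   and the run produces representative and per-family FASTA files, a
   per-member table, presence and copy-number matrices, the settings used,
   per-step counts, and a plain-text report of residual sub-threshold
   alignments.

Three alternative modes reuse the same skeleton: `dc` substitutes the
sensitive task throughout steps 1–3 (more tolerant of small internal
deletions); `protein` translates both sides (bacterial code, table 11) and
compares at the protein level in steps 1 and 3 while steps 2, 4 and 5 stay
nucleotide-based; `mut_dna` / `mut_protein` instead report genes *identical*
across all A genomes whose best background counterpart passes the cutoffs
but differs in some form — candidate SNP or substitution markers.
`distributionMode()` runs the ordinary pipeline against a dummy background
(a six-base sequence that cannot produce a passing hit) with a one-genome
occurrence floor, yielding complete gene × strain presence and copy-number
matrices for exploratory grouping.

### Annotation equalization

Because the unit of comparison is the annotated ORF, inconsistent gene
calling *within the target group* hides real markers: a gene annotated in
two of three A genomes but missed in the third can never reach 100%
occurrence. `equalizeGroup()` repairs this before prediction: for each
strain, ORFs annotated in the other strains of the group that have no
passing hit among the strain's own ORFs but do hit its genome sequence are
extracted (the best hit's subject span, reverse-complemented for
minus-strand hits) and appended as extra ORFs. Inconsistent background
annotation needs no repair — the genome filter (step 2) already covers it.

Two details are deliberate choices the underlying procedure leaves open:
the equalizer reuses the primary step-1 cutoffs as its similarity
threshold (one knob, no second calibration), and additions with > 50%
reciprocal overlap on the same contig and strand are collapsed to the
best-identity one, so a gene missing from one strain but present in five
others contributes one extra ORF, not five. Extraction is exactly the
aligned span — no extension to a start codon, no frame repair; the goal is
occurrence accounting, not gene prediction. The operation is idempotent.

## The alignment engine

Every decision in the pipeline is expressed in percent identity and
coverage, not E-values, so the package ships a dependency-free
seed-and-extend engine tuned for exactly that regime (`findHits()`):

* exact k-mer seeding over an indexed subject set — word size 28 for
  `megablast_like`, 11 for `dc_like` and `blastn_like`, 3 for
  `blastp_like` (BLOSUM62);
* greedy clustering of seeds in (diagonal, position) space; word-11 and
  protein tasks require two seeds per cluster to suppress chance word
  matches against megabase contigs;
* an exact banded Smith–Waterman over the seeded window (affine gaps: a
  gap of length L costs `gap_open + L * gap_ext`; nucleotide scoring
  +1/−2, gaps 5/2). The band is padded around the seeded diagonals, so
  within the band the extension is optimal rather than heuristic. The
  best local alignment per query/subject pair is reported; there is no
  HSP tiling, and N never seeds or counts as a match.

Identity is matches over alignment columns (gaps included); coverages are
the aligned span over the full query/subject length; all thresholds are
inclusive. `dc_like` emulates the higher sensitivity of a discontiguous
search by the smaller word size, a wider band and gap-tolerant clustering
rather than true spaced seeds — an approximation that is sufficient
because the pipeline only needs it to find diverged homologs and bridge
small gaps. An `external` backend shells out to BLAST+ (`blastn`/`blastp`
with tabular output) and filters identically, falling back to the builtin
engine with a notice when the binary is absent; on the high-identity
thresholds the pipeline uses, the two backends agree on pass/fail (a
tested property, not bit-identity).

`dpAlignOracle()` exposes an exact, unbanded Smith–Waterman under the same
scoring (via `Biostrings::pairwiseAlignment`), guarded to 20 kb combined
length. It is the independent reference the tests compare the engine
against — engine scores never exceed the oracle optimum, and identities
agree within half a percentage point on planted-divergence pairs.

## Marker validation statistics

`evaluateMarkers()` scores a marker × strain presence matrix (typically
PCR results) against a phenotype table. For the binary phenotype
("spoiler" versus "non-spoiler") each marker gets a 2×2 confusion table,
the percentage of correct identifications, and a two-sided Fisher exact P
computed by exact enumeration of the hypergeometric distribution (the sum
of point probabilities not exceeding the observed one, with a 1e-7
relative tolerance on the comparison — no normal approximation). Against
the ordinal spoilage-potential classes, Spearman's ρ is computed with
mid-rank ties, and its significance by the t-approximation with n − 2
degrees of freedom at a two-sided α of 0.05 — markers below that are
rendered `NS`. The ordinal encoding NB < WB < MB < SB is 0..3 by default
and exposed as an argument, since published tables print only the class
labels; "spoiler" means rank ≥ MB (growth in the mid-bitterness test
beer). Output is sorted by descending Fisher P, worst discriminators
first.

## The synthetic-data generator

`generateDataset()` builds a fully specified two-group dataset with a
ground-truth manifest, so every filter can be tested against a known
answer without downloading anything. The default `synthSpec()` describes
the desk-scale study conditions used by this package's tests: 2 target
versus 3 background genomes, a 200 kb chromosome plus a 30 kb plasmid
each, i.i.d. background nucleotides at GC 0.38 (a *Pediococcus*-like
value), 40 core genes, 3 target-exclusive genes, and one gene of each
confound class: partial occurrence (present in half the target genomes),
a copy embedded unannotated in a background contig, the same with a 1 bp
frameshift, a background homolog at 85% identity (10% of edits as
indels), a 150 bp exact background segment inside an otherwise unique
gene, a duplicated (two-copy) gene, and — for the equalizer fixture — a
gene present in all target contigs but annotated in only some. Genes are
600–1200 bp, start with ATG and avoid in-frame stops so protein mode runs
on the same fixtures; they are planted on alternating strands with ≥ 50 bp
random spacers, and target-exclusive genes sit on the plasmid, mirroring
the plasmid-encoded markers typical of spoilage phenotypes. Identical
spec and seed reproduce every file byte for byte.

Planted divergence is verified during generation: `mutateSequence()`
resamples until the optimal local alignment of (original, mutant) is
within one percentage point of the target identity. That verification
uses a mild +1/−1 scoring — under the engine's steeper +1/−2 the optimal
local alignment of a weakly similar pair trims itself to a denser
subregion, which makes low target identities (≤ ~75%) undefined as an
alignment property; at 85% and above the two scorings agree. Unreachable
targets (say, 99% on a 20 bp sequence) are an error after bounded
retries, not a silent near-miss.

What the generator does *not* emulate: repeats beyond the planted ones
(they would make ground truth ill-defined), rearrangements, phylogenetic
correlation between genomes, codon-model evolution, and annotation-start
disagreement. Passing on these fixtures therefore demonstrates the
pipeline's filtering logic and determinism, not robustness to every
artifact of real assemblies and annotators.

## Numerical and design choices

* **Inclusive thresholds everywhere**, with a 1e-9 absolute tolerance on
  comparisons so representation error cannot flip a boundary case; a hit
  at exactly the cutoff passes, and a family at exactly the occurrence
  floor is kept.
* **Steps 4/5 semantics.** A hit *exceeding* the screen's thresholds
  removes the family; sub-threshold hits only annotate survivors
  (`dc_blast_hit`, `max_blastn`). A family is removed if *any* member
  trips a screen — a marker must discriminate for every allele.
* **Residual-hit floor.** An unthresholded sensitive search against
  hundreds of kilobases of background yields chance ~11 bp word matches;
  residual hits are only recorded from 30 aligned bp, so
  `dc_blast_hit = yes` means real local similarity.
* **Determinism.** Family numbering follows the representative's
  (strain, contig, start); the representative is the longest member, ties
  broken by smallest ORF id; member rows are listed with ascending
  coordinates (multi-copy genes: all positions ascending). The pipeline
  has no random state, identical inputs give byte-identical outputs, and
  the residual-alignment report omits run timestamps for the same reason.
* **Degenerate inputs.** An empty target ORF set is an error ("nothing to
  compare"); any stage emptying the candidate set short-circuits into a
  well-formed empty result with the step counts recorded; a zero-DMG run
  is a success, not a failure.
* **Problem sizes.** The test-suite fixtures use 16–50 kb genomes for
  oracle-checked properties (the quadratic oracle is the limit there) and
  the full 200 kb default for the 20-seed recovery study; both sizes
  exercise every filter with identical logic.

## Known limitations

* The builtin engine guarantees optimality only within its band; a true
  optimal alignment drifting further than the band padding (~32–64
  diagonals) from its seeds would be truncated. At the ≥ 60% coverage,
  ≥ 80% identity operating points of the pipeline this does not occur.
* `dc_like` is a sensitivity emulation, not a spaced-seed implementation;
  alignments below ~75% identity under-seed and may be missed. The
  screens that use it operate at 80% and above.
* Marker discovery is annotation-driven: genes absent from *every* target
  annotation are invisible even with the equalizer, which can only copy
  gene calls between strains of a group.
* Very short conserved segments (below about twice the word size) fall
  under the seeding floor of the short-hit screen; `max_blastn` can
  under-report them. The removal threshold (100 bp) is far above that
  floor.
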