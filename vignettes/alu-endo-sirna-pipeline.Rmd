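---
title: "Detecting and profiling Alu-derived endogenous siRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and profiling Alu-derived endogenous siRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alusirna)
library(dplyr)
```

## The problem

Inverted pairs of Alu short interspersed elements embedded in one
transcript fold back into long double-stranded hairpins: a sense Alu
copy, a connecting loop, and an antisense copy. DICER cleaves these
stems into 21–24 nt endogenous small interfering RNAs (endo-siRNAs)
that load onto AGO2 and can silence mRNAs carrying a complementary Alu
in their 3'UTR. Detecting these Alu endo-siRNAs in small RNA-seq data
is awkward: they are vastly outnumbered by miRNAs and rRNA/tRNA
fragments, they map to highly repetitive sequence, and their abundance
must be compared across libraries (e.g. knockdown vs control) whose
miRNA content itself shifts.

`alusirna` implements the complete computational side of this problem:

1. read preprocessing (3' adaptor removal, exogenous-siRNA removal,
   19–35 nt length gate);
2. a hierarchical annotation cascade over ordered reference
   categories;
3. strand-resolved Alu siRNA quantification (length distributions in
   CPM, consensus positional profiles, an exclusion-normalized
   differential statistic, zero-mismatch mapping of in vitro dicing
   products);
4. a target-gene screen based on single-copy 3'UTR Alu elements and
   siRNA seed complementarity;
5. a synthetic-data generator with per-read ground truth, so the whole
   pipeline is testable without external downloads.

## The annotation cascade

Each preprocessed read is aligned, ungapped and on both strands, with
at most `max_mm = 2` Hamming mismatches, against reference sets in a
fixed order:

> rRNA → tRNA → miRNA → repeat consensus → snoRNA → transcript → genome

A read is assigned to the **first** category with at least one valid
alignment; reads failing every set are `unaligned`. This
first-hit-wins design deliberately absorbs ambiguous reads into the
abundant structural-RNA categories before the repeat step, so an
"Alu siRNA" call means: not explainable as rRNA, tRNA or miRNA, and
matching an Alu subfamily consensus within two mismatches.

Within a category the reported hit is chosen deterministically —
fewest mismatches, then lowest start, then `+` before `-`, then
reference input order. Short-read aligners make an arbitrary choice
here; we fix one so identical inputs always give identical outputs.
The category assignment, which is the quantity every downstream
statistic uses, does not depend on this tie-break. Two further
numerical choices: `N` bases never match anything (not even `N`/`N`),
and a query longer than a reference yields no hits rather than an
error. The aligner is a full scan (no seed-and-extend heuristic): at
the scale of consensus libraries and desk-size genomes, exactness is
worth more than indexing, and it makes the implementation directly
checkable against a brute-force oracle, which the test suite does on
thousands of random query/reference pairs.

## Preprocessing choices

Adaptor trimming is exact-match: the leftmost cut point whose read
suffix equals a prefix of the adaptor (overlap at least `min_overlap =
6`). No error tolerance is applied because no published tolerance
exists for the original processing and the simulated data are
error-free by default; the `max_mm` path of the aligner is exercised
separately via an optional substitution rate in the generator. Reads
with no detectable adaptor are discarded by default — their true 3'
end is unknown — but `keep_untrimmed = TRUE` retains them. Exogenous
siRNA removal (the four transfected control/knockdown 21-mers,
`exogenous_sirna_blacklist()`) uses substring containment in *both*
directions so partially trimmed siRNA reads are caught too. The
preprocessing report always partitions the input exactly
(multiplicity-weighted), a property asserted throughout the tests.

## Quantifying Alu endo-siRNAs

An *Alu siRNA* is a repeat-category read on a subfamily whose name
begins with `Alu`, 19–24 nt long (`select_alu_sirnas()`); its strand
comes from the alignment (`+` = sense to the consensus). Three views
are provided:

* **Length distributions** (`length_distribution()`) in counts per
  million over the full 19–35 nt window. The CPM denominator is not
  uniquely defined by convention, so it is explicit:
  `denominator_mode` is `"preprocessed"` (default), `"aligned"`, or
  `"total_raw"`.
* **Consensus profiles** (`consensus_profile()`) histogram the 5'
  start of each hit per strand. Start positions (rather than full
  coverage) resolve the DICER cleavage register; minus-strand hits are
  indexed by their leftmost reference base so both strands share one
  axis. Full per-base coverage is used in the dicing mode instead,
  where cleavage-product extent is the question.
* **The differential statistic** (`normalized_alu_count()`,
  `differential_profile()`). Comparing Alu siRNA output between a
  knockdown and a control library through plain CPM is confounded:
  the miRNA fraction (huge) and the Alu fraction itself (the signal)
  both move. The statistic therefore divides the Alu siRNA count by
  the library total *excluding* miRNA and Alu siRNA reads, times 1e6,
  and subtracts control from treated per length. Negative values mean
  depletion after treatment. The per-length variant keeps one global
  library-level denominator — the normalization is a library property,
  not a per-length one.

The dicing mode (`map_dicing_products()`) reproduces the in vitro
analysis: its own 5'/3' adaptor pair (`dicing_adaptors()`), mapping at
**zero** mismatches onto the hairpin sequence, and per-strand,
per-position coverage. Untrimmed and unmapped reads are counted, not
errors.

## The target screen

`classify_utr_alus()` counts Alu-family repeat annotations overlapping
each gene's (single-interval) 3'UTR, with orientation taken relative
to the mRNA. By default a repeat must be fully contained
(`min_overlap_frac = 1`); the threshold is exposed because "an Alu in
the 3'UTR" is genuinely ambiguous for boundary-straddling copies.
`screen_single_alu_genes()` keeps genes with *exactly one* Alu in the
requested orientation and *none* in the other — a gene with one sense
plus one antisense copy can form a hairpin and belongs to the
inverted-repeat class, not the single-copy target class — and
expression strictly above `4.5` (log10 proteomics scale).

`predict_target_sites()` uses the standard seed convention: positions
2–8 of the siRNA (a 7-mer), matched as an exact reverse complement in
the mRNA-sense 3'UTR; `allow_seed_mm = 1` additionally reports sites
at Hamming distance one as a separate class. No thermodynamic scoring,
G:U wobbles or 3'-supplementary pairing is attempted — the screen is a
complementarity filter, not an efficacy ranking. Under a null of
i.i.d. uniform UTR sequence the expected number of perfect sites is
`(L - 6) * 4^-7` per UTR of length L; the tests verify the matcher
against this closed form over 10^4 simulated UTRs.

## The synthetic-data generator

`make_synthetic_references()` builds a self-consistent universe:
random ~300 nt Alu-like subfamily consensi; a genome with embedded,
per-copy-mutated, strand-annotated Alu copies; gene models whose
3'UTRs carry 0 / 1 sense / 1 antisense / inverted-pair configurations
(recorded in `gene_truth`); rRNA, tRNA, miRNA, snoRNA and transcript
sets rejection-sampled to share no 19-mer with the consensi on either
strand, so category cross-talk is absent *by construction* — unless
`cross_contaminate = TRUE` deliberately plants a shared 21-mer in the
rRNA set and an Alu consensus for precedence testing.

`simulate_dicer_products()` draws 21–24 nt fragments with uniform 5'
starts confined to the hairpin arms — independent cuts, no processive
phasing, matching the observed wherever-bound cleavage behaviour — so
the loop is never covered. Hairpin arms pair two *different* subfamily
consensi (as in the long intronic inverted-Alu configuration, whose
arms belong to different subfamilies): if both arms derived from one
consensus, the right arm would be the exact reverse complement of the
left, every fragment would have two equally good placements, and
strand assignment under any fixed tie-break would be arbitrary. The
default loop is 533 nt with ~300 nt arms, the configuration of the
long intronic hairpin studied in vitro.

`simulate_library()` draws each read's class from the configured mix —
defaults: 60% miRNA, 18% rRNA fragments, 10% tRNA fragments, 0.09%
each Alu sense/antisense (i.e. Alu siRNAs at 0.3% of miRNA reads, the
level observed in HeLa total small RNA), and ~11.8% unalignable
background — then appends the full 3' adaptor and truncates to the
machine read length (50 nt). Padding is never applied: a real
untruncated read would continue into downstream primer sequence that
the exact-prefix trimmer deliberately does not model. Per-class RNG
substreams are derived from the one seed so changing one class's
parameters leaves the other classes' draws untouched, which is what
makes `alu_scale`-paired libraries a clean knockdown emulation.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: ligation bias, PCR duplicates, quality
scores and sequencing errors (available only as an optional uniform
substitution rate), A-to-I editing, multi-exon 3'UTRs, and the
genomic complexity of a full repeat landscape (nested/truncated
copies, >10^6 genomic Alu loci). Results on real libraries depend on
the curated reference sets supplied; the cascade itself is agnostic.

## Problem sizes and verification

The test suite and the acceptance script regenerate everything from
code at these scales, chosen as the package's desk-scale study
conditions: 10^5-read libraries for cascade conservation, for
recovery of the 0.3%-of-miRNA Alu fraction (checked within 3 binomial
standard errors), and for the paired differential; 10^3 random
query/reference pairs at 0–2 mismatches for exact oracle agreement;
10^4 dicer fragments for the hairpin round trip; 10^4 random 1 kb
UTRs for the seed-match null calibration. For the paired differential
demonstration the Alu classes are raised to 0.5% each: the sign
property is then deterministic at 10^5 reads, whereas at the 0.3%
level per-length counts are small enough that an occasional
sampling-noise sign flip would reflect the library size, not the
statistic. Criterion-level properties that depend on the 0.3% figure
keep the 0.3% mix.

## Known limitations

* The full-scan aligner is exact but O(reads × reference length); it
  is intended for consensus libraries and desk-scale genomes, not
  whole-genome alignment.
* Repeat assignment reports one deterministic representative hit;
  multi-mapping enumeration across subfamilies is out of scope, so
  per-subfamily attribution of a read matching several consensi
  follows the tie-break, not an abundance model.
* The 3'UTR model is a single interval; spliced UTRs are rejected at
  the input boundary rather than silently mishandled.
* The differential statistic is descriptive (a normalized difference);
  no significance testing is attached.

## A compact end-to-end example

```{r example, eval = FALSE}
refs <- make_synthetic_references(seed = 7)
cfg  <- sim_config(seed = 7, n_reads = 5e4)
lib  <- simulate_library(cfg, refs)

pp   <- preprocess_reads(lib$reads, cfg$adaptor,
                         blacklist = exogenous_sirna_blacklist())
summ <- run_cascade(pp$reads, refs$ref_sets)
tidy(summ)                      # per-category read counts
glance(summ)                    # library overview

ld <- length_distribution(summ)
autoplot(ld)                    # sense/antisense CPM by length

kd  <- simulate_library(sim_config(seed = 8, n_reads = 5e4,
                                   alu_scale = 0.5), refs)
kds <- run_cascade(preprocess_reads(kd$reads, cfg$adaptor)$reads,
                   refs$ref_sets)
differential_profile(kds, summ) # negative deltas: Alu siRNA depletion

st <- classify_utr_alus(refs$genes, refs$repeats)
screen_single_alu_genes(st, orientation = "antisense")
```
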