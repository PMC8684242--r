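---
title: "Designing and evaluating a breed-specific SNP array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a breed-specific SNP array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdesign)
```

## The problem

Commercial bovine genotyping arrays are ascertained on large commercial
breeds. For a small, endangered dual-purpose population, a substantial part
of a commercial panel is uninformative, breed-private alleles are absent by
construction, and haplotype blocks segregating only in the small breed are
left uncovered — the classic marker ascertainment bias. `chipdesign`
implements the design workflow for a custom array built directly from
whole-genome sequence variants of the target population: filter variants
for technical suitability on a two-probe hybridization platform, classify
breed-unique and functionally annotated variants, tile the genome through
confidence-interval haplotype blocks, select content through an ordered
list of biological priorities, and finally audit a genotyping run of the
produced chip (call-rate QC, segregation, concordance, residual gaps).

Everything operates on standard formats (VCFv4.2 plus TSV sidecars) and a
small set of S3 containers: a variant table (`data.table`), a
`genotype_matrix` (animals x variants dosage codes with breed labels), a
block table, a `chip_design`, and `call_results`.

## The synthetic cohort: what it emulates

No external data are required: `simulate_cohort()` generates a multi-breed
sequenced cohort with the statistical structure the design pipeline
assumes, and is itself first-class, tested code.

* **Block-structured LD.** Each chromosome is partitioned into haplotype
  blocks with truncated-exponential lengths (default mean 15 kb, minimum
  1 kb). Within a block each breed owns a pool of K founder haplotypes
  (K in 2–4 by default); every animal draws two founders per block,
  independently across blocks. This gives high intra-block pairwise D',
  free recombination between blocks, and — crucially for testing — exact
  knowledge of the true block boundaries. A coalescent simulator would be
  more realistic but would not provide block-boundary truth for
  parameter-recovery tests.
* **Allele-frequency spectra.** Every variant has a target frequency drawn
  from a Beta spectrum (default shape 0.8, 2.0, skewed toward rare
  alleles); founders carry the alternative allele with that probability.
  Columns that come up empty but must be present ride on a single founder,
  which is how rare alleles behave. The realized per-breed pool frequency
  is recorded per variant (`target_aaf_<breed>`), so recovered AAFs can be
  compared against the generator's own targets rather than against the
  abstract spectrum.
* **Breed-unique variants.** A configurable fraction of variants
  (default 0.10) carries its alternative allele only on focal-breed
  founders; every non-unique variant is forced to be present in every
  breed's pool, so with `unique_fraction = 0` no allele is private by
  construction.
* **Depth.** Per-animal fold coverage is drawn once from
  Normal(18.72, 2.44) truncated at 1 — the cohort-level summary of the
  sequencing study this workflow targets — and per-variant per-animal
  depths are Poisson around it; the variant's total depth is their sum.
* **Annotation.** Consequence terms are drawn so that impact classes hit
  the proportions 97.17 / 2.19 / 0.60 / 0.04 % (modifier / low / moderate /
  high) after the reclassification overrides described below.
* **Conversion scores.** Two per-strand scores per variant from a mixture:
  80 % mass near 1 (`1 - 0.4 Beta(2, 5)`, support [0.6, 1]) plus a 20 %
  uniform tail on [0.3, 0.8]. Only the success/failure score distributions
  are published for the real platform; this mixture reproduces their
  salient feature — concentration in [0.6, 1] with enough mass in the
  0.6–0.7 band to matter after thresholding.
* **Category side-lists.** Prior-array SNPs (common SNPs, default 3 % of
  variants), trait-associated variants (0.5 %, half flagged as derived from
  imputed data), a parentage panel (25 common SNPs) and "empirical
  evidence" flags (30 %) are simulated so all ten selection categories are
  exercised.

Default cohort size is 2 breeds x 100 animals on a 5 Mb chromosome at one
variant per kb (~5,000 variants) — large enough for block structure and
category accounting to be non-trivial, small enough that the full test
suite runs in minutes on one core. What the generator does *not* emulate:
genotyping error in the sequenced truth, within-block recombination,
pedigree structure, sex chromosomes, and realistic gene annotation.
Passing tests therefore demonstrate correctness of the pipeline's logic
under its stated assumptions, not field performance on real cattle data.

## Technical-suitability filters

Four filters run in fixed order, each returning a subset of its input, with
a step-by-step accounting log (`n_in`, `n_removed`, `n_out`):

1. **Interfering neighbours.** On a two-color hybridization platform the
   target allele sits mid-probe with 35 bp of flanking sequence either
   side; a polymorphism inside the flank destabilizes hybridization. A
   variant is removed when another variant (of any kind, surviving or not)
   lies closer than `W` bp, with `W = 35` by default and `W = 20` for
   variants pre-flagged for the high-priority categories
   (trait-associated, predicted impact, breed-unique). A neighbour at
   exactly `W` bp is tolerated — the boundary-inclusive reading of
   "allowing an interfering variant located 20 bp up- or downstream".
   Distances are between start positions; indels are left-aligned to their
   minimal representation on input so the distance is well defined.
2. **Read depth.** Total depth across the cohort must reach 10 reads per
   expected carrier (3,000 reads for 300 animals). On a Y chromosome only
   the males carry the variant, so the expected-carrier count is supplied
   per chromosome (e.g. 470 reads for 47 sequenced bulls); an absolute
   override is available.
3. **Allele frequency.** Focal-breed AAF must reach 0.05, with a rescue
   clause: focal AAF > 0.01 *and* (the variant is focal-unique *or* some
   rescue breed exceeds AAF 0.05). Undefined AAFs (no genotyped animal)
   are removed, never silently treated as 0. Y and mitochondrial variants
   bypass this filter: those categories take every detected variant.
4. **Conversion score.** The in-silico assay-convertibility score must
   reach 0.6 on at least one strand.

## LD engine

All two-locus statistics come from unphased genotypes under
Hardy–Weinberg equilibrium.

* **EM haplotype frequencies.** Phase is ambiguous only for double
  heterozygotes; EM iterates the cis/trans split to convergence (max-abs
  frequency change < 1e-8, cap 1000 iterations) from three starts (cis
  weight 0.5, 0.05, 0.95) to avoid boundary stagnation. The allele-count
  margins are fixed by the data, so the likelihood has one free parameter;
  tests verify the EM optimum against a fine-grid likelihood search to
  1e-4.
* **D' confidence intervals.** The multinomial likelihood of the 3x3
  genotype table is evaluated on a fixed 101-point |D'| grid (step 0.01,
  the usual Haploview-style discretization) with allele frequencies held
  at their sample estimates and D signed by the point estimate; normalized
  to a distribution, its 5th and 95th percentiles are the reported 90 %
  interval. Because the bounds are grid percentiles, monotone properties
  (e.g. doubling the data never widening the interval) hold up to one grid
  step. Monomorphic loci are flagged `undefined`, never NaN-propagated.
* **Block calling.** Within 200 kb windows, every pair is classified as
  strong LD (ci_low >= 0.60 and ci_high >= 0.85), strong recombination
  (ci_high < 0.90), or non-informative (including pairs with fewer than 5
  doubly genotyped animals). Every candidate span whose informative pairs
  are at least 95 % strong is enumerated; overlaps are resolved
  longest-span-first, leftmost on ties. The strong-LD CI bounds are the
  design's published thresholds; the recombination bound (0.90), the
  informative fraction (0.95) and the 5-animal floor are not published for
  this design and follow the established Gabriel/Haploview defaults — all
  four are configurable in `ld_config()`. The hot loop (EM + CI for every
  pair in the window, plus the span scan) is compiled C++; an 8-SNP
  exhaustive-enumeration oracle in plain R checks it over 50 random
  instances.

## The ordered ten-category selection

Categories are processed in fixed order; a variant already selected is
attributed ("unique") to the earlier category but still counted in later
categories' totals, so unique counts always sum to the total number of
selected variants:

1. prior-array informative SNPs; 2. trait-associated variants;
3. predicted high/moderate/low impact; 4. breed-unique; 5. AAF divergence
above 0.70 (strict) between the focal breed and its closest relative;
6. Y chromosome; 7. mitochondria; 8. parentage panel; 9. haplotype-block
coverage; 10. gap filling.

Design choices the published workflow leaves open, resolved here:

* **Complete-LD pruning (cats 3+4).** "Complete LD" is r² = 1 within 1e-9
  on EM haplotype frequencies (the pairwise statistic of the PLINK-style
  toolchain used for the original design); cliques are connected
  components of complete-LD edges within a block, and the first two
  members in position order are kept, applied to the union of the two
  categories' candidates. Pruning can never strip a block of its only
  representative, since two clique members always survive.
* **Block representatives (cat 9).** Only blocks not yet covered and
  longer than 5 kb (or longer than 1 kb within 100 kb of a coding gene,
  when a gene annotation is supplied) are considered; one variant per
  block is chosen by lexicographic sort on (empirical-evidence flag,
  best-strand conversion score, MAF > 0.05 indicator, focal-vs-relative
  AAF difference), ties broken by position then id. The published criteria
  list is ordered the same way but does not state the combination rule;
  lexicographic descent is the simplest faithful reading.
* **Gap filling (cat 10).** Greedy: the longest residual gap above 250 kb
  is filled with the unselected candidate nearest the gap midpoint,
  repeated until no fillable gap remains. The original algorithm is
  unpublished; greedy midpoint insertion minimizes the larger of the two
  sub-gaps at each step.
* **Probesets.** One per variant; two for A/T and C/G SNPs (the two-dye
  chemistry cannot separate those alleles on one probeset); and
  trait-associated variants not derived from imputed data are tiled with a
  replicate factor (default 2 — "added multiple times" is published
  without a count, so the exact published probeset total is not
  reconstructable and the factor is configurable). The budget check
  defaults to a 205,000-probeset "200 k-class" capacity.
* **Category-9 totals** count blocks covered by the final design (the
  published accounting for that row), not variants.

The whole design is deterministic: identical input and configuration give
byte-identical output, which the tests assert by re-running.

## Evaluating a genotyping run

`simulate_chip_run()` provides the run to audit when no real array data
exist: assay-wide variant failure with probability rising as the
best-strand conversion score drops below 0.8 (failures concentrate in the
0.6–0.7 score band, as observed on real arrays) plus a rare-allele
clustering penalty fading to zero at MAF 0.05; per-call corruption at a
base rate (default 0.002) plus the same rare-allele penalty; confidences
Beta(0.2, 40) for correct calls (sharply concentrated near 0, ~0.25 %
above the 0.05 masking threshold) and Beta(1.5, 3) for corrupted ones.
Replicate animals are drawn independently in later batches.

Evaluation then mirrors the published workflow: calls with confidence
above 0.05 are masked *first*, then a variant is successfully called when
its post-masking call rate strictly exceeds 0.95 ("had to exceed"; an
inclusive switch exists). "Called in at least one breed" runs QC per breed
with that breed's instances as denominator and takes the union.
Segregating variants additionally need MAF strictly above 0.01 in the
focal population. Concordance compares hard genotype codes over positions
non-missing in both members of a pair; pairs with nothing to compare are
reported undefined and excluded from the mean; the SD is the sample SD
(n−1) by default with a population-SD switch. Report percentages are
rounded half-up to two decimals and a 0/0 cell is reported as missing, not
as 0 %. For every failed variant, LD against the nearest called variant in
the same block (chromosome fallback) quantifies how much genetic
information the failure actually costs.

## Numerical conventions and degenerate inputs

Coordinates are 1-based VCF positions internally (BED output would be
0-based half-open at the writer). Strict-versus-inclusive boundaries
follow the published wording everywhere: depth >= 3,000 kept, AAF >= 0.05
kept, conversion >= 0.6 kept, divergence > 0.70 flagged (with a 1e-9
floating-point guard on the difference), unique presence > 0.01, MAF
segregation > 0.01, call rate > 0.95, confidence masking > 0.05. Undefined
AAF is `NA` end to end. Empty inputs (empty VCF body, empty categories,
no failed variants) return empty results, not errors; genuine misuse
(unknown breed, unsorted positions, design referencing unknown variants,
probeset overflow) fails loudly with the offending item named.

## Problem sizes used by the test suite

Unit tests run on hand-built fixtures and cohorts of 10–60 animals over
0.1–0.5 Mb. The acceptance suite uses the generator defaults
(2 x 100 animals, 5 Mb, ~5,000 variants) for 20 seeded design runs,
2 Mb cohorts with two founders per block for block-boundary recovery
(pairwise co-membership Jaccard, averaged over four seeds, against the
generator's true boundaries), ten 0.5 Mb cohorts for spectrum recovery
(two-sample Kolmogorov–Smirnov of recovered AAFs against the generator's
recorded targets at alpha 0.01), and a 2 Mb cohort for the noise-level
checks. These sizes were chosen so the whole suite completes in a few
minutes on a single core while every property is measured with useful
power.

## Known limitations

The block caller implements the confidence-interval definition with
fraction-of-informative-pairs admissibility; like the original, spans
whose cross-boundary pairs are mostly *ambiguous* (wide CIs from rare
alleles) can merge adjacent true blocks. The EM is exact only under HWE
within the analyzed population; running it across pooled breeds mixes
allele frequencies (the pipeline therefore computes blocks on the focal
breed). Indel probe chemistry is approximated by the SNP rules apart from
the probeset count. The capacity check is a budget assertion, not an
optimizer: the selection never trades categories off against the budget.
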