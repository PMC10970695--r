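---
title: "Mapping a dominant trichome locus from low-coverage F2 resequencing"
author: "binQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant trichome locus from low-coverage F2 resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Black gram (*Vigna mungo*) and its relatives segregate a conspicuous
presence/absence trait — trichomes on stems and pods — that behaves as a
single dominant locus: an F2 between a trichome-bearing parent (P1) and
a glabrous parent (P2) splits close to 3:1. Locating that locus with
whole-genome resequencing is cheap only if the progeny are sequenced
shallowly (here ~2.9x per line, parents at 13-14x). At that depth a
single SNP genotype is unreliable: a heterozygote shows only one allele
whenever all of its 2-3 reads happen to sample the same chromosome.
`binQTL` implements the standard rescue: slide a window over
consecutive parent-informative SNPs, call window genotypes from
aggregate allele support, collapse the population's recombination
breakpoints into *bin markers*, build a genetic map on the bins, and
scan it with inclusive composite interval mapping (ICIM).

## Pipeline and models

### SNP quality control

Only SNPs where the inbred parents are homozygous for different alleles
are informative in an F2. Retained SNPs additionally need minor allele
frequency > 0.05, missing rate < 0.1, and a segregation-distortion
chi-square p-value >= 1e-8 (all inequalities strict). The distortion
test is on allele counts against 1:1; a genotype-level 1:2:1 test is
available behind `compute_qc(genotype_level = TRUE)`. A line with reads
for both alleles at a site counts as one heterozygous observation for
the allele dosages.

### Sliding-window bin genotyping

Windows of 15 SNPs advance by 1 SNP. Within a window, `SNPP1` counts
sites whose reads support only the P1 allele, `SNPP2` the P2-only
sites; a site with reads for both adds one to each. The window is
homozygous P1 when `SNPP1 >= 13 * SNPP2`, homozygous P2 symmetrically,
heterozygous otherwise. We read the published "13" as a count *ratio*;
an absolute-count variant (`rule = "count"`) is available.

`min_informative` defaults to 13, i.e. to `ratio`. This is deliberate:
a homozygous window holding one discordant site (a sequencing-error
read) can only satisfy `SNPP1 >= 13 * SNPP2` when at least 13 sites
carry data, so calling sparser windows biases homozygous tracts towards
`H`. Because adjacent windows share 14 of 15 SNPs, one error-touched
site contaminates a streak of ~15 windows, and at a looser setting
(e.g. 5) those streaks flip whole-bin majority votes: in simulations at
2.92x depth and 0.005 error, bin accuracy rises from ~98.6% to ~99.1%
when the default is 13, at the cost of ~1% missing windows.

Runs of identical window calls (missing windows never break a run)
delimit recombination breakpoints; a breakpoint's uncertainty interval
is bounded by the centre SNPs of the adjacent informative windows and
its point estimate is the midpoint. All lines' breakpoints are pooled
per chromosome, sorted, and greedily merged left-to-right whenever two
fall within 100 kb; the survivors partition the chromosome into bins.
Each line's bin genotype is the majority window call over the windows
centred in the bin, with exact ties set to missing.

### Linkage map

One linkage group per chromosome, bins in physical (reference) order —
de novo ordering is out of scope, and the map's agreement with the
reference is *checked* afterwards as Spearman rank collinearity.
Adjacent-bin recombination fractions are maximum-likelihood estimates
from the 3x3 joint genotype table via EM (the double-heterozygote cell
mixes parental and double-recombinant configurations; EM iterates its
expected recombinant-gamete count). Distances use the Kosambi function
by default (`25 ln((1+2r)/(1-2r))`), common in crop maps; Haldane is
selectable. Map summaries (marker counts, lengths, average interval =
length/markers, maximum gap) reproduce the arithmetic of published
linkage-group tables via `summarize_lg_table()`.

### ICIM scan of the binary trait

The 0/1 phenotype is treated as quantitative, the usual coding for
case-type traits in ICIM software. Phase 1 is forward-backward stepwise
regression on additive/dominance marker pairs (x in {1, 0, -1}, z in
{0, 1, 0}; entry p = 0.001, exit p = 0.002, partial-F tests). Phase 2
walks each linkage group in 1 cM steps; at each position the phenotype
is adjusted by all selected cofactors *except* any that flank the
tested interval, and each line's QTL genotype distribution is derived
from its flanking bin genotypes through the interval recombination
fractions (single-flank conditioning when one side is missing; lines
missing both flanks are skipped at that position).

The per-position test statistic is, by default, the Haley-Knott
regression LOD, `(n/2) log10(RSS0/RSS1)`, fitted on the prior-expected
additive and dominance scores. A full three-component normal-mixture EM
(`method = "em"`) is also provided and agrees with the regression at
fully informative marker positions — but for a *binary* phenotype the
mixture likelihood is unbounded (three free means can separate the two
phenotype values exactly, driving the common variance to zero), so the
regression form is the sound default for this trait type and is what
all shipped analyses use. For continuous phenotypes either method is
appropriate.

Significance uses a permutation threshold: the phenotype is shuffled
across lines, the full procedure (cofactor selection + scan) is re-run,
and the genome-wide maximum LOD recorded; the threshold is the
next-higher order statistic of the empirical 1 - alpha quantile
(conservative). The reported locus is the global LOD peak (ties broken
leftmost) with a 3-LOD-drop support interval in cM and bp, and
additive/dominance effects and explained variance (PVE =
100(1 - RSS1/RSS0)) at the peak.

### Candidate annotation and expression

The support interval is intersected with GFF3 gene models
(GenomicRanges overlap on closed 1-based spans). Parent-polymorphic
variants are classified as intron / coding (SNP, in-frame indel,
frameshift by length mod 3) inside genes, and upstream / downstream
(strand-adjusted) within a 5 kb flank outside them; beyond the flank
they are intergenic. The 5 kb default covers the largest flank distance
among the shipped candidate variants (3,098 bp). Genes without exon
annotation yield "intron" for internal variants, flagged via
`exon_annotated = FALSE`; the shipped gene models carry synthetic
placeholder exons only for the Rtf1-like gene, marked as such in the
GFF header.

qPCR validation uses the 2^-ddCt method with perfect-doubling
efficiency: technical replicates average arithmetically (flagged above
a 1-cycle spread), dCt normalises to the reference gene per biological
replicate, ddCt to the calibrator sample (glabrous parent P2) per
tissue, and between-parent significance is a two-sided Welch t-test on
the per-replicate dCt values — the conventional test for this design,
flagged at p < 0.05 and p < 0.001.

## The synthetic population

`sim_config()` emulates the study design: 193 F2 lines, 11
chromosomes, mean depth 2.92x (parents 13x), a single fully dominant
locus on the middle chromosome, 3:1 segregation, per-read allele-flip
errors, and Poisson sequencing depth. All randomness flows from one
seed through named substreams so each stage is independently
reproducible. Genome scale defaults to 50 Mb chromosomes with 3 kb SNP
spacing — the density implied by ~178k high-quality SNPs over a 574 Mb
genome; the crossover process is Poisson along each chromosome at 2.8
cM/Mb (the genome-wide average of a ~1611 cM map), i.e. Haldane with no
interference, matching the downstream map machinery. Extra site
dropout (`missing_rate`) defaults to 0 because Poisson depth at 2.92x
already leaves ~5.4% of site-line cells without reads, the dominant
source of missingness in this regime.

What the generator does *not* emulate: reference-genome errors and
paralogous mis-alignment (which inflate effective error rates far above
the per-read 0.005), segregation distortion, variable recombination
along chromosomes, crossover interference, and depth heterogeneity
between lines. Passing recovery tests therefore show the pipeline's
correctness under its stated model, not that real data of this design
will reach the same accuracy.

## Validation problem sizes

The shipped tests and the acceptance script run the full pipeline on
populations of 193 lines x 11 chromosomes of 10 Mb at 3 kb SNP spacing
(~37k SNPs, ~1000 bins, ~310 cM) — the study's line count, depth,
density and bin resolution with a proportionally shorter genome — with
50 replicate populations for parameter recovery and 500-permutation
thresholds (3000 in the defaults) for significance. Under those
conditions the planted locus is localised with a median error of ~1-3
cM, PVE 70-95%, and bin-genotype accuracy >= 99%.

One nominal expectation fails by a wide margin and is reported rather
than hidden: coverage of the 3-LOD-drop support interval. With a
near-Mendelian trait (penetrance 0.98) the peak LOD is 50-150, so the
profile drops 3 LOD within about a centimorgan of the peak, while the
peak location itself wanders a few cM under phenotype
misclassification and residual bin-call errors. LOD-drop intervals are
known to under-cover for large-effect loci; a Bayes credible interval
or a larger drop would be needed for calibrated coverage in this
regime.

## Numerical choices

* Recombination fractions are clamped to [0, 0.5]; map conversion caps
  r at 0.4999 with a warning. Adjacent-bin pairs with no complete
  observations contribute zero distance, with a warning.
* EM convergence: rf estimation stops at |dr| < 1e-9 (<= 2000
  iterations); the mixture scan stops at log-likelihood change < 1e-8
  (<= 200 iterations) with the variance floored at 1e-8 of the null
  variance.
* Stepwise selection caps cofactors at n/5, breaks partial-F ties by
  lowest marker index, and guards against entry/exit cycles by
  revisited-state detection.
* Degenerate inputs: chromosomes shorter than one window produce a
  single flagged truncated window; single-bin linkage groups have zero
  length; monomorphic or all-heterozygous markers are dropped from the
  scan design with a warning; exact majority-vote ties are missing.
* The permutation quantile uses the next-higher order statistic, so
  alpha = 1 returns the minimum and small permutation counts err
  conservative.

## Limitations

Single-QTL model only (no epistasis, no multi-QTL search); binary
traits in the linear framework rather than a liability/threshold or
logistic model; physical marker order is trusted, not estimated; the
published chromosome-level SNP counts and the genome-wide LOD/PVE of
the original data cannot be reproduced here because the underlying
sequencing data are not deposited.
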