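---
title: "Population-genetic analysis of SV callsets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of SV callsets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpopgen)
```

# Scope

svpopgen implements the population-genetic analysis layer for cohort-scale
structural variant (SV) callsets: functional-consequence annotation,
selection metrics, mutation-rate projection, gene-level constraint,
positional enrichment, complex-SV classification and clinical carrier
screens. Raw-read SV discovery is out of scope — the input is a genotyped
callset (VCF with symbolic alternate alleles) plus a sample table. Because
the analyses are meaningful only on data with particular statistical
structure (a neutral reference stratum, Hardy–Weinberg genotypes, known
trios), the package ships a synthetic-cohort generator that produces
exactly that structure with known ground truth, so every stage is testable
without any external download.

# The cohort model

A cohort is a set of SV sites (`DEL`, `DUP`, `MCNV`, `INS`, `INV`, `CPX`,
`CTX`, `BND`) with diploid genotype dosages over samples. Conventions,
fixed once:

* Internal coordinates are 0-based half-open; VCF I/O is 1-based
  inclusive; BED output is 0-based half-open.
* Allele counts (`ac`, `an`, `af`) are always computed over the unrelated
  sample subset; related samples exist only for trio checks. A singleton
  is `ac == 1` among unrelated samples.
* `BND` records are parsed but quarantined: unresolved breakends carry no
  interpretable allele structure and are excluded from every analysis.
* `MCNV` sites are multiallelic; the biallelic statistics (SFS, HWE, APS,
  LD, PCA) exclude them. They participate in per-genome counts, spatial
  enrichment and (through dosage rules) consequence annotation. Their
  stored `af` is a carrier frequency — the fraction of samples whose
  diploid copy number differs from the cohort mode.
* `CTX` records are two breakpoints; they have no genuine length, so
  `svlen` is a documented 1 kb placeholder that keeps the log-size
  covariate total.
* Rare means AF < 1%; very rare means AF < 0.1%.

# The synthetic cohort

## Site-frequency spectrum

Under the neutral infinite-sites model, the number of segregating sites in
a sample of $n$ chromosomes is $K \sim \mathrm{Poisson}(\theta a_n)$ with
$a_n = \sum_{i=1}^{n-1} 1/i$, and a site's alternate-allele count $i$ has
probability $(1/i)/a_n$. `simulate_sfs()` draws exactly this; the expected
singleton fraction is $1/a_n$. Purifying selection is injected as an
allele-count down-shift: a selected site's count is redrawn with
probability $\propto i^{-(1+s)}$, i.e. the neutral $1/i$ spectrum
reweighted by $i^{-s}$, so $s = 0$ recovers neutrality exactly and larger
$s$ monotonically lowers AF and inflates singletons. This is not an
explicit fitness model; the selection metrics only require a monotone,
recoverable AF effect.

## Genotypes, structure, trios

With population structure disabled (all Balding–Nichols $F = 0$) the drawn
allele count is placed exactly on the $2N$ sampled chromosomes, so the
realized SFS *is* the drawn SFS and genotype counts follow the
Hardy–Weinberg conditional (Levene) distribution. With $F > 0$, each
population's AF is drawn from the Balding–Nichols Beta around the global
AF and genotypes are binomial within populations — the realized spectrum
is then only approximately neutral (binomial resampling distorts the
lowest-frequency classes, and this is expected, not a bug), which is why
the neutrality invariants in the test suite are asserted at $F = 0$.

Trios are generated by Mendelian transmission from two same-population
unrelated parents; the child's genotypes are then perturbed by the
genotyping error rate (a flip to a different random genotype). The default
error of 0.04 was chosen so that the median Mendelian violation rate lands
on the few-percent scale reported for short-read SV trios; at error 0 the
violation rate is exactly 0.

## Sizes, positions, functional placement

Per-class log-normal size models; insertions are a three-component mixture
with modes near 300 bp, 2.1 kb and 6 kb (the Alu/SVA/LINE1 mobile-element
peaks). Positions are drawn on a synthetic chromosome-arm map with a
three-zone density (outer 10% of each arm weighted `telomeric`, inner 10%
weighted `centromeric`, interstitial 80% at 1). Defaults follow the
qualitative regime reported for real cohorts — biallelic deletions and
duplications mildly telomeric (weight 1.5), multiallelic CNVs strongly
centromeric (weight 3) — the magnitudes are our choice, since no source
prints them.

When gene models are supplied, a fraction of sites (default 25%) is
deliberately placed to realize a known functional category (exon-clipping
deletions, whole-transcript duplications, intragenic exonic duplications,
gene-spanning or gene-breaking inversions, exonic insertion points), and a
fraction of CNVs (10%) fully or partially covers noncoding elements. These
placements carry unambiguous truth labels used by the annotation tests.
Gene choice is weighted against the synthetic SNV-constraint rank (higher
rank = more constrained = fewer functional SVs), so gene-level depletion
increasing with constraint is part of the generated world. Selected
categories get AF down-shifts per the `selection_map`; an additional
`size_selection` term increases the shift with log-size, producing the
inverse size–frequency relationship.

## What the generator does not emulate

No haplotype or recombination structure (LD pairs are simulated directly
as correlated dosage vectors), no breakpoint sequence context, no
genotyping batch effects, no reference bias, and complex-SV subclass
weights are a plausible abundance profile rather than an estimate. A green
test therefore establishes that an algorithm recovers the stated
statistical structure — not that it is robust to every artifact of real
callsets.

# Consequence annotation

Annotation is canonical-transcript, per (SV, gene) pair, by a fixed
decision table: deletions touching one coding base are pLoF; insertion
points inside exons are pLoF; duplications containing the transcript are
copy-gain, duplications with both breakpoints inside the gene covering at
least one whole exon are intragenic exonic duplications (IED),
partial-exon duplications are `utr_partial`; inversions containing the
gene are whole-gene inversions, inversions or translocations breaking the
span are pLoF; intron-only overlap is intronic; a 2-kb strand-aware
promoter window (conventional, configurable — no printed value to follow)
catches promoter-only hits. Complex SVs are labelled per constituent
segment (deleted segments with DEL rules, duplicated with DUP rules,
inverted with INV rules, insertion points with INS rules) and the worst
label wins, under the fixed severity order
pLoF > IED > copy-gain > whole-gene inversion > utr_partial > promoter >
intronic > intergenic. A complex SV with no resolved structure that spans
a whole gene is conservatively called pLoF.

# APS: adjusted proportion of singletons

The singleton proportion of a variant set confounds selection with class,
size and genomic context. APS removes the technical part by calibrating a
binomial regression (logit link; complementary log-log available) of the
singleton indicator on SV class, $\log_{10}$ size and any extra technical
covariates, fitted on the neutral reference stratum — intergenic,
biallelic, PASS sites. Then

$$\mathrm{APS} = \overline{\mathrm{singleton}}_{\mathrm{obs}} -
\overline{p}_{\mathrm{model}}$$

for a query set. The maximum-likelihood intercept makes the reference
stratum score exactly 0 in-sample; positive values mean singleton excess
beyond covariate expectation, i.e. purifying selection. Uncertainty comes
from 100-fold bootstrap over query sites; the test against 0 is a
one-tailed t-test on site-level residuals. Noncoding analyses follow the
same pattern: per element class, full-coverage versus partial-coverage
CNVs are compared with a two-tailed paired t-test across classes, and
conservation coupling is assessed by percentile-binning CNVs on their
overlap-summed conservation score (track gaps score 0) and Spearman-testing
bin rank against per-bin APS, with a 21-point rolling mean for display.

# Mutation rate

`watterson_theta()` is $\hat\theta = K/a_n$. The projection to a
per-generation rate divides by $4N_e$ ($\mu$ per haploid genome) and
doubles for a diploid birth. $N_e$ defaults to 10,000 and is a required,
logged modelling input: the projection is exactly as credible as that
number, and no attempt is made to hide this behind a default. The CI
treats $K$ as Poisson and resamples it parametrically — "bootstrap over
sites" cannot be nonparametric here because resampling $K$ exchangeable
sites with replacement leaves $K$ unchanged.

# Gene-level constraint

Observed rare functional SV counts per gene are compared to a Poisson
log-link expectation fitted on gene covariates (log span, exon count, log
intron length, context flag). With an intercept the fitted totals
reproduce observed totals, so aggregate O/E is exactly 1 under the null —
the calibration the tests assert. Depletion is reported as $1 - O/E$ so
larger means more constrained. For the constraint-rank correlation, genes
are sorted by SNV-constraint rank into ~100 equal bins (~175 genes each at
genome scale) and per-bin depletion is computed as one minus the ratio of
sums — not the mean of per-gene ratios, which explodes when individual
expectations are tiny. Genes with expected < 0.1 events are flagged
uninformative rather than scored: at desk scale (and, frankly, at current
real cohort scales) per-gene point estimates are noise; only the binned
trend is interpretable. Poisson rather than negative-binomial is the
default because rare-SV counts per gene are low-mean; overdispersion at
scale would argue for the NB extension.

# Meta-chromosome

Every autosome arm is rescaled to unit length: p-arms map to [0, 0.5]
(p-terminus to centromere), q-arms to [0.5, 1]. SVs are located by
interval midpoint (insertions by insertion point), counted in 100-kb
source windows, averaged unweighted across arms into 100 meta bins,
normalized to mean 1 per class, smoothed with a centered 11-bin rolling
mean truncated at the edges, and re-normalized so the mean-1 invariant
survives edge truncation. Positional classes are T within 0.10 of either
telomere, C within 0.10 of the centromere, I otherwise — the 10% boundary
is a configurable convention, as is the 11-window smoother; neither value
is printed anywhere authoritative. Each (SV class × positional class)
stratum is tested with a two-sided t-test of its window enrichments
against the remaining windows, Bonferroni-adjusted for all k comparisons
(7 classes × 3 positions gives k = 21 and threshold 0.05/21 ≈ 2.38e-3).

# Complex SVs

A resolved alternate allele is an ordered set of segments with source
interval, orientation, copy state and (for dispersed segments) insertion
location, encoded in VCF INFO as ordered tokens
(`DEL|DUP|INV_chrom:start-end`, `DDUP[INV]_chrom:start-end@chrom:pos`,
`INS_len@chrom:pos` — our grammar; none is printed in any main text).
`canonicalize()` orders segments along the source and emits a signature;
mirror structures keep mirror signatures (delINV vs INVdel), and the
paired "collapsed" display is a reporting option, defaulting to the three
unambiguous mirror pairs — an interpretation, flagged as such.
`classify_cpx()` is a total decision table over signatures: the six
inversion-flank classes, dispersed duplications (with or without
insertion-site deletion), insertion with insertion-site deletion,
canonical single-signature alleles routed to their canonical classes, and
`unresolved` for everything else — never an error. The simulator inverts
the table (label to structure), which gives an exhaustive round-trip
oracle.

# Clinical screens

Carrier definitions: a genomic-disorder carrier has ≥ 1 CNV of the locus's
pathogenic dosage direction covering ≥ 50% of the critical region (the
reciprocal-overlap details of published screens are supplementary, so the
coverage fraction is exposed as a parameter); a gene-list carrier has ≥ 1
very rare (AF < 0.1%) pLoF SV in a listed gene; a large-rare carrier has
≥ 1 autosomal SV ≥ 1 Mb with AF < 1%, with the balanced/complex share
(INV, CTX, CPX) reported alongside. All intervals are Clopper–Pearson:
exact coverage at small counts, lower bound exactly 0 at zero carriers.
Gene panels are plain-text inputs; no proprietary list ships with the
package.

# Numerical and testing choices

* HWE: 1-df chi-square against $np^2, 2npq, nq^2$; monomorphic sites
  return p = 1. The exact conditional test is available for rare variants
  where the chi-square approximation is poor. Type-I calibration is
  asserted at common AFs (U(0.1, 0.9) at n = 500, where the smallest
  expected genotype class is ≥ 5, the textbook validity floor); at
  SFS-typical rare AFs the chi-square test is conservative by
  construction and a nominal-level check would be meaningless. The
  cohort-level "fraction in HWE" uses per-site p ≥ 0.05, configurable.
* PCA: dosages column-centered, missing values mean-imputed, SVD with the
  sign convention that each component's largest-magnitude loading is
  positive — fully deterministic.
* Bootstrap replicates default to 100 everywhere and every random step
  accepts a seed; the pipeline derives per-stage sub-seeds from the run
  seed so stages are decoupled and byte-identical under reruns.
* Desk-scale defaults (500 samples, ~20k drawn sites, 50 trios, 2,000
  genes) keep the full pipeline under a minute; all are overridable. At
  this sample size a neutral spectrum yields a singleton proportion of
  ~$1/a_{1000} \approx 0.13$, far below the ~50% seen in biobank-scale
  real cohorts — that figure needs tens of thousands of samples plus
  growth and selection, and is deliberately not faked here.

# Known limitations

Per-gene constraint scores are not publishable point estimates at any
currently realistic cohort size. The mutation-rate CI ignores
non-independence among sites. The meta-chromosome t-test treats windows
as exchangeable, which Poisson counts only approximate. Consequence rules
are transcript-structure-only: no reading-frame or NMD logic. The
Balding–Nichols model captures mean differentiation, not admixture or
IBD.
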