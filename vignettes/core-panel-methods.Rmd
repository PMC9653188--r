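---
title: "Core marker panels for cereal breeding: methods and design notes"
author: "CorePanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core marker panels for cereal breeding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CorePanel)
```

## The problem

Routine genomic-assisted selection in barley and wheat breeding needs a
genotyping platform that is cheap enough to run on every candidate line.
One practical design is a *core marker set*: a few hundred amplicon
markers chosen from a much larger candidate catalog so that they (i) tile
the genome at near-uniform physical spacing, (ii) are highly polymorphic
among the breeding materials actually in use, and (iii) map cleanly to
the reference (little off-target or homoeologous interference — the
latter matters in hexaploid wheat, where the A, B and D subgenomes carry
highly similar sequences). CorePanel implements the construction and
evaluation of such panels, plus the downstream analyses a breeding
program runs on the resulting genotypes: QC, allele-frequency profiles,
population structure, linkage-disequilibrium (LD) decay, and
ridge-regression BLUP (RR-BLUP) genomic prediction.

## Panel construction

`filterCandidates()` keeps candidates with missing rate strictly below
`maxMissing` (default 0.3) and mapping-quality class in `allowedClasses`
(default 1–3; class 1 is the cleanest). The strict inequality at 0.3 is
deliberate and tested.

`selectCoreSet()` then tiles each chromosome into consecutive windows of
`targetSpacingMb` (default 6 Mb, a barley-scale density; a wheat-scale
panel uses ~15 Mb). Within each window the highest-MAF candidate passing
a MAF floor wins; ties fall back to lower missing rate, then lower
mapping class, then position, then marker id, so selection is a total
order and therefore invariant to input row order. Two design choices
deserve comment because the underlying procedure is ambiguous in the
literature this mirrors:

* **Location-dependent MAF floors.** Marker-poor regions would drop out
  of the panel entirely under a single strict MAF floor. We therefore
  relax the floor from `minMafDense` (default 0.10) to `minMafSparse`
  (default 0.01) in windows holding fewer than `denseMinCount` (default
  3) candidates. This reproduces the intent — keep markers across the
  whole genome, prefer polymorphic ones where there is a choice — with a
  fully specified rule.
* **Terminal retention.** The first and last candidates of each
  chromosome are always kept, because platform coverage is measured
  between terminal markers; a panel that drops a telomeric marker loses
  coverage it could have had for free.

`summarizePlatform()` reports, per chromosome, terminal positions, cover
size (last minus first marker), mean interval `cover / (n - 1)`, maximum
adjacent gap, and `100 * cover / refseq` coverage. Totals follow two
conventions validated against the published barley and wheat panel
tables bundled in `inst/extdata`: unplaced ("Un") markers and unplaced
reference length enter only the marker total and the coverage
denominator, and the overall mean interval is the summed cover divided
by the summed per-chromosome interval counts (each chromosome with *n*
markers contributes *n − 1* intervals). Reported values are rounded
half-up (not banker's rounding) to one decimal, matching table
formatting conventions.

## Genotype QC

`loadGenotypes()` ingests VCF (via vcfR) or a dosage table; only
biallelic sites are kept and `./.` becomes NA. `siteStats()` computes
allele-count MAF — a heterozygote contributes one alternate allele;
missing calls leave both numerator and denominator. `siteFilter()`
removes sites with more than 50% missing data *or* more than 20%
heterozygous calls (strict inequalities; a site exactly at a threshold
stays). The source description of this filter is grammatically "and",
but under an AND reading the heterozygosity criterion would almost never
fire for mostly-inbred material; OR is standard QC practice and is the
default, with `combine = "and"` available.

`mafProfile()` smooths MAF along each chromosome with LOESS — local
*linear* regression with tricube weights, span 0.3, evaluated on a
200-point grid with a pointwise 95% interval from the local standard
error. Fitted values are clipped to [0, 0.5] since MAF lives there. Only
"LOESS" is conventionally reported for such profiles; degree, span and
grid are our defaults and are configurable.

## Diversity

`pcaCovariance()` performs PCA on the accession covariance matrix:
dosages are mean-imputed per site and centered but *not*
variance-scaled, so common and rare markers are weighted as covariance
PCA weights them. Explained percentages are eigenvalues over the trace
and sum to 100 over the full decomposition.

`ldPairwise()` estimates r² as the squared Pearson correlation of dosage
vectors over accessions complete at both sites (at least 20 required).
This genotype-correlation estimator coincides with haplotype-based r²
for inbred material, which is the regime after the heterozygosity
filter; on strongly heterozygous data it can differ from EM-haplotype
estimators, a documented deviation risk. Pair counts grow
quadratically, so pairs are uniformly subsampled per chromosome under a
seed; full enumeration is available via `maxPairsPerChrom = Inf`.

`binDistanceClasses()` uses eight fixed, half-open distance classes
(<1, 1–5, 5–10, 10–50, 50–100, 100–200, 200–400, ≥400 Mb).
`compareDistanceClasses()` runs one-way ANOVA plus Tukey HSD at α = 0.05
on raw r² — r² is far from normal, but this mirrors the conventional
presentation — and derives a compact letter display with the
insert-and-absorb algorithm. `ldThresholdPercentile()` reports the
empirical percentile rank of an r² cutoff (fraction of pairs at or below
it, ×100), the usual justification for treating r² = 0.1 as the floor
for declaring association.

## Genomic prediction

`fitRRBlup()` implements the RR-BLUP mixed model
`y = 1·mu + M u + e`, `u ~ N(0, I σ²u)`, `e ~ N(0, I σ²e)` from first
principles rather than calling a package, since this model *is* the
analysis core. Marker columns are centered by training means (the same
means impute missing dosages and center test data). The restricted
likelihood is profiled on the eigendecomposition of `M Mᵀ`; the single
free parameter `λ = σ²e/σ²u` is searched on a 101-point grid of
log₁₀ λ over [−5, 5] — wide enough to cover heritabilities from roughly
0.001 to 0.999 for standardized phenotypes — and refined by Brent's
method around the grid optimum. Because the centered `M` annihilates the
intercept direction, the GLS intercept reduces exactly to the training
mean and the dual-form effects `u = Mᵀ(MMᵀ + λI)⁻¹(y − ȳ)` equal the
primal ridge solution; the test suite verifies this identity against an
explicit `solve()` oracle to 1e−8 relative error. The reported genomic
heritability is `σ̂²u · meandiag(MMᵀ) / (σ̂²u · meandiag(MMᵀ) + σ̂²e)`.

`scaleByGroup()` standardizes each trait within (breeding station ×
harvest year) groups before prediction — stations differ in growth
conditions and measurement equipment, so raw values are not comparable.
Groups with fewer than two records or constant values are centered only,
with a warning; because scaling never crosses a (station, year)
boundary, no information leaks between training and test years in
cross-year prediction.

`crossValidate()` implements the evaluation protocol as repeated
hold-out: each repetition draws one random fifth as a test set, trains
on the rest, and records the Pearson correlation of predicted and
observed values; mean and SD are taken over (by default) 100
repetitions. The phrase "fivefold cross-validation" is sometimes used
for this design and sometimes for a rotating 5-fold partition; the
hold-out reading is the default and the rotation is available via
`scheme = "kfold"`. Degenerate hold-outs (constant observed values) are
redrawn and counted. `crossYearPredict()` trains on one harvest year and
tests on the other, in both directions; their arithmetic mean is
reported alongside, as in the conventional accuracy table layout
produced by `predictionReport()`.

## The simulator: what it emulates, and what it does not

`simConfig()`/`simulatePopulation()`/`simulatePhenotypes()` generate the
ground truth for the test suite. The presets mirror the two target
platforms: 1,032 barley-like accessions × 768 markers on 7 chromosomes,
or 1,798 wheat-like × 960 on 21, eight breeding stations, harvest years
2018–2019. The generative model is deliberately lightweight:

* **Station divergence.** Station allele frequencies drift from a common
  ancestral frequency (uniform on [0.1, 0.9], a polymorphism-enriched
  spectrum appropriate for a marker panel) under a Balding–Nichols Beta
  model with divergence `fst = 0.1`.
* **Founder haplotypes and LD.** Each station contributes 6 inbred
  founders. Founder haplotypes are thresholded latent Gaussian processes
  whose autocorrelation decays exponentially with physical distance
  (scale `ldScaleMb = 5`), preserving the Balding–Nichols marginal
  frequencies while concentrating LD below ~5 Mb. The small founder
  number itself adds realistic long-range within-station LD.
* **Breeding.** Each accession is a biparental cross between two
  founders of its station followed by 6 generations of selfing; meioses
  use the Haldane map function (no crossover interference) at
  0.25 cM/Mb. Residual heterozygosity is therefore (1/2)⁶ *per site
  heterozygous in the F1* — the test suite checks against this
  conditional expectation, not the unconditional 2⁻⁶.
* **Traits.** The phenotype within an accession is
  `sqrt(h2)·std(g) + sqrt(1−h2)·N(0,1)` with `g = M a` over `nQtl`
  marker-QTL, then shifted per station and station-year and multiplied
  by a mild log-normal scale factor. This composition keeps the
  within-group genetic variance share exactly interpretable as h² (the
  additive parameterisation `σ²e = var(g)(1−h2)/h2` is undefined at
  h² = 0) and produces the between-station location/scale differences
  that group scaling is designed to remove. Default traits: a
  high-heritability thousand-grain-weight-like trait (h² = 0.7), an
  intermediate heading-date-like trait (0.5) and a low-heritability
  protein-like trait (0.3), spanning the accuracy range such panels
  achieve in practice.

What the simulator does **not** reproduce: real allele-frequency
spectra shaped by selection, pedigree loops and shared ancestry between
stations, genotyping error beyond random missingness, crossover
interference, and multi-subgenome mapping artefacts. Passing tests on
synthetic data therefore demonstrate correctness of the algorithms and
qualitative behaviour (structure recovery, LD decay, accuracy ordering
by heritability), not quantitative reproduction of any real program's
accuracies.

## Numerical choices and problem sizes

* Rounding of reported platform values: half-up, with a 1e−9 guard
  against binary representation artefacts.
* REML: eigendecomposition once per fit; grid-then-Brent avoids local
  optima on the occasionally flat restricted likelihood; fits with zero
  phenotypic variance return the intercept model, flagged.
* LD: pairs with fewer than 20 complete observations or zero variance
  are skipped and counted, not errored.
* Compact letters: Tukey-adjusted p-values below α define the
  significant-pair list; insert-and-absorb then yields a minimal letter
  cover, ordered by class.
* Test-suite problem sizes are chosen for tight statistical checks at
  interactive runtimes: heritability recovery uses n = 400 accessions ×
  768 markers over 20 seeded replicates; the cross-validation checks use
  n = 600 × 250 markers so that training sets exceed the marker count
  and a noiseless marker-determined trait is recoverable (accuracy
  > 0.95); null traits are averaged over three independent draws because
  a single dataset's hold-out accuracy has sampling noise comparable to
  the ±0.1 band. The residual-heterozygosity check uses generous
  tolerances because selfing leaves heterozygosity in long linked
  blocks, so the effective number of independent observations is far
  smaller than the site count.

## Known limitations

* The exact MAF floors and window size used to build the published
  panels are not public; `selectCoreSet()` reproduces the *procedure*,
  not the member-for-member published marker lists.
* r² from genotype correlation understates haplotype r² on heterozygous
  material.
* The ANOVA/Tukey comparison of r² classes inherits the non-normality
  of r²; treat the letters as descriptive.
* Cross-year accuracy depends on year-specific noise that the simulator
  models only through the year location/scale shifts.
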