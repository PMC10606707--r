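---
title: "Mapping inbreeding depression of litter size with shared runs of homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping inbreeding depression of litter size with shared runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

Inbreeding depression — the decline of fitness-related traits with
increasing autozygosity — is classically quantified genome-wide, as a
regression of performance on an inbreeding measure. In litter-bearing
livestock the effect need not be uniform along the genome: a handful of
regions carrying (partially) recessive deleterious alleles can account for
a disproportionate share of the depression. `rohscan` implements a
two-stage mapping strategy for repeated litter-size records of genotyped
sows:

1. estimate the genome-wide picture — variance components and the slope of
   litter size on individual heterozygosity — under a single-step
   repeatability animal model; then
2. test every *shared run of homozygosity* (ROH) for a difference between
   its carriers and non-carriers, holding the variance components fixed.

A sow *carries* a shared ROH when one of her own homozygous runs fully
covers it; a region whose homozygous haplotype hides a recessive burden
shows up as carriers farrowing systematically smaller litters.

## The model

For either trait (total number born, TNB, or number born alive, NBA) the
repeated records follow

$$
\mathbf{y} = \mathbf{f}\,d + \mathbf{X}\mathbf{b} + \mathbf{T}\mathbf{h} +
\mathbf{Z}\mathbf{u} + \mathbf{W}\mathbf{p} + \mathbf{e},
$$

with $\mathbf{f}$ the per-sow percentage of heterozygous SNPs (the
genome-wide depression covariate; $d > 0$ means more heterozygous sows
have larger litters), $\mathbf{b}$ the parity-class means (five classes:
first to fourth litter, fifth and beyond; the first class doubles as the
intercept), $\mathbf{h} \sim N(0, \mathbf{I}\sigma^2_h)$ the
herd–year–season (HYS) effects, $\mathbf{u} \sim N(0, \mathbf{H}\sigma^2_a)$
the additive genetic effects, $\mathbf{p} \sim N(0, \mathbf{I}\sigma^2_p)$
the permanent sow environment and $\mathbf{e} \sim N(0,
\mathbf{I}\sigma^2_e)$ the residual. $\mathbf{H}$ is the single-step
relationship matrix combining the pedigree (all animals) with marker-based
relationships (genotyped sows), so ungenotyped ancestors contribute
through their pedigree links.

The per-segment scan refits this model once per catalog segment with one
added fixed effect, the carrier indicator. The genome-wide covariate is
*excluded* from the per-segment models by default (the second stage
re-attributes depression locally; including both absorbs the local signal
into the global slope — a flag restores it), while the HYS term is
retained. Variance components are never re-estimated inside the scan.

### Tests

All segment and covariate tests are one-sided: the covariate alternative
is $d > 0$ and the carrier alternative is a *negative* effect (carriers
farrow fewer piglets), matching the directional hypothesis of depression.
`one_sided_p()` uses the standard normal reference by default; with
roughly two thousand records the Student-t correction is invisible at two
significant figures, but a finite `df` is accepted. Benjamini–Hochberg
FDR values accompany the raw per-segment p-values; no multiple-testing
gate is applied to the headline counts.

## ROH detection and the shared-segment catalog

A run is a maximal stretch of homozygous genotypes within one chromosome
spanning at least 16 SNPs — "more than 15" read strictly; the threshold is
the `min_snps` argument. No heterozygous calls are tolerated inside a run
by default (`max_het = 0`); a tolerance knob exists because chip error
conventions differ between detection tools.

Candidate shared segments are the *distinct intervals of the individual
runs themselves* (not fixed sliding windows); a sample carries a segment
iff one of its runs covers the segment entirely, and segments are kept
when their carrier frequency falls in [5%, 95%]. This run-derived
enumeration is isolated in `build_catalog()` so an alternative windowing
scheme can be swapped in. Because a segment spans at least `min_snps`
markers, "carrier" is equivalent to "homozygous across every marker of the
segment", which is how the carrier matrix is re-verified in the tests.

Genome coverage per sow is the union length of her runs divided by the
mapped autosome length (last minus first marker position summed over
chromosomes) — reproducible from the marker map alone, with overlapping
runs counted once.

## Relationship structures

* `a_matrix()` builds the pedigree numerator relationship matrix by the
  tabular recurrence; `a_inverse()` applies Henderson's sparse rules with
  inbreeding (Mendelian-sampling variance $0.5 - 0.25(F_s + F_d)$).
* `g_matrix()` is VanRaden method 1 with observed allele frequencies,
  monomorphic markers dropped.
* `h_inverse()` assembles
  $\mathbf{H}^{-1} = \mathbf{A}^{-1} + \begin{bmatrix} 0 & 0 \\ 0 &
  \mathbf{G}_b^{-1} - \mathbf{A}_{22}^{-1}\end{bmatrix}$
  over the genotyped block.

Two numerical choices matter in inbred herds:

* **Base compatibility (`a22_compat = TRUE`).** Observed-frequency
  centering references $\mathbf{G}$ to the genotyped generation, whereas
  $\mathbf{A}_{22}$ is referenced to the pedigree founders. After a
  sustained bottleneck the two scales differ substantially, and combining
  them unadjusted biases the variance-component partition (additive
  variance leaks into the permanent-environment term; we observed the
  additive estimate collapsing to a third of its generative value on
  simulated herds). The default therefore applies the affine adjustment
  $\mathbf{G}^* = a + b\,\mathbf{G}$ matching mean diagonal and mean
  off-diagonal to $\mathbf{A}_{22}$ before blending. Set
  `a22_compat = FALSE` for the raw recipe.
* **Blending (`blend_alpha = 0.95`).** $\mathbf{G}_b = 0.95\,\mathbf{G}^*
  + 0.05\,\mathbf{A}_{22}$ guarantees invertibility; the weight is the
  field's customary default and configurable.

## AI-REML

`ai_reml()` maximizes the restricted likelihood by Newton steps with the
average-information matrix, computed from the mixed-model equations: the
gradient uses the standard trace identities on the inverse coefficient
matrix, the AI matrix uses working variates $\mathbf{Z}_k\hat{u}_k /
\sigma^2_k$ (and $\mathbf{P}\mathbf{y}$ for the residual), and steps are
halved until all components stay positive. Components driven to the zero
boundary with a downhill gradient are pinned at a floor of
$10^{-8}\,\mathrm{var}(y)$ and flagged — a tiny free component would
otherwise dominate the AI matrix and stall every other update. Convergence
requires a scaled update norm below `tol` ($10^{-8}$) *and* a stable
active set. Sampling variances are the diagonal of the inverse AI matrix
at convergence. Starting values split the phenotypic variance equally over
the included components.

Fixed-effect rank deficiencies are resolved by a corner constraint:
aliased columns (pivoted QR of the fixed block) are constrained to zero,
which leaves estimable contrasts untouched.

## Scan mechanics

The base system is factorized once per trait (sparse Cholesky); each
segment adds a single column, handled by a bordering (Schur-complement)
solve — one sparse triangular solve per segment. This is algebraically
identical to the full refit, which the test suite asserts on sampled
segments. Segments whose carrier status is constant among phenotyped sows,
or whose carrier column is confounded with the base model, are skipped
with a logged reason.

## What the simulator emulates

`sim_config()` defaults describe a closed sow herd emulating the study
system the package is designed around:

| parameter | default | why |
|---|---|---|
| pedigree | 24 founders, 8 bottleneck generations of 24, then 4 generations of 165 | sustained background autozygosity: ~330 phenotyped sows whose ROHs cover roughly 27–41% of the genome with a heterozygosity spread of a few percent |
| mating | partial full-sib, intensity 0.05 | a small dose of recent close inbreeding on top of drift; the intensity knob monotonically raises last-generation inbreeding |
| genome | 18 autosomes × 3,192 SNPs, 125 Mb each | ~57k informative autosomal markers after QC |
| recombination | Poisson(1.25) crossovers/chromosome, uniform positions, no interference | simplest model with right-skewed ROH length decay |
| founder MAF | uniform on (0.05, 0.5) | informative chip markers |
| variance components | $\sigma^2_a{=}0.145$, $\sigma^2_p{=}0.366$, $\sigma^2_h{=}0.170$, $\sigma^2_e{=}2.901$ | low-heritability litter-size trait at the reported scale |
| heterozygosity slope | 0.055 piglets/% | genome-wide depression of the reported magnitude |
| records | 6 litters per sow, parity means ≈ 8 piglets, 96 HYS levels assigned uniformly | repeated-records design; litter means ≈ 8 with SD ≈ 2 |
| NBA | TNB − Poisson(0.26) losses, floored at 0 | NBA ≤ TNB by construction |

Design choices worth knowing:

* **Genomic breeding values.** By default the simulated additive values
  are sums of infinitesimal marker effects (centered at founder
  frequencies and scaled so founders have variance $\sigma^2_a$), so their
  covariance tracks the *realized* genomic relationships that single-step
  analysis models. A pedigree-recursion mode
  (`additive_model = "pedigree"`, Mendelian-sampling variance shrunk by
  parental inbreeding) is retained; with deep pedigrees it makes the
  marker-based analysis misattribute additive variance to the
  permanent-environment term, which is itself an instructive mismatch but
  the wrong default for testing the pipeline.
* **Rounding.** Litter sizes are simulated continuously and rounded to
  non-negative integers; the analysis model is linear-Gaussian, so the
  rounding noise folds into the residual and adds $1/12 \approx 0.083$
  squared piglets to its effective value. Recovery checks therefore target
  $\sigma^2_e + 1/12$.
* **Planted effects** subtract piglets from the records of sows that are
  *homozygous across a chosen interval* — carrier status is read off the
  simulated genotypes, never assigned independently of them, so the truth
  table always agrees with what the catalog derives.
* **Heterozygosity by the pipeline's own operation.** The simulator calls
  `heterozygosity_percent()` itself, so covariate definitions cannot
  drift apart.
* **HYS assignment** is uniform at random, which likely understates the
  confounding a real farrowing calendar induces.

What it does **not** emulate: linkage disequilibrium older than the
simulated pedigree, selection, mutation, genotyping error or multi-line
structure. The practical consequence is that simulated ROHs are fewer and
much longer than chip ROHs in real herds (which are dominated by short
segments from ancient haplotype sharing); genome coverage and its spread
are calibrated to realistic values, but run-length distributions are not.
Passing tests therefore validate the statistical machinery under the
model's own assumptions — they do not certify behaviour under LD-driven
short-ROH landscapes.

## Verification design and problem sizes

The test suite (and `scripts/acceptance.R`) uses these problem sizes,
chosen to finish comfortably on one CPU:

* *Oracle equivalence*: 100 random instances each for run detection
  (brute-force window scanner), the pedigree matrix (recursive kinship),
  the mixed-model solver (dense GLS) and the single-step inverse (dense
  block-assembled H).
* *Variance-component recovery*: 20 replicate herds at the study scale
  (≈330 sows × 6 records) with a 5-chromosome, 2,000-marker genome; every
  component's mean estimate must sit within two empirical standard errors
  of its generative value.
* *Null calibration*: the per-segment p-values are marginally uniform
  under a null genome (no planted effects, zero slope — a herd with a
  *positive* genome-wide slope is not null for the scan, because carriers
  are systematically more homozygous), but they are strongly correlated
  within a herd: inbred sows carry ROHs everywhere, so all segments share
  carrier sets and record noise. A binomial reference band is only honest
  for near-independent draws, so the check pools 15 randomly sampled
  segments from each of 20 replicate null herds.
* *Planted-effect recovery*: a −0.8 piglet segment at carrier frequency
  near 0.3 must be the top-ranked hit in at least 18 of 20 replicate
  herds.

One caution for interpretation on simulated (and real) data: when the
genome-wide slope is active and the per-segment models exclude the
covariate (the default), each carrier contrast absorbs a share of the
genome-wide depression — carriers of any segment are more homozygous
overall. Estimated segment effects are then systematically more negative
than the planted values, and the share of nominally significant segments
rises well above the nominal level. That is a property of the two-stage
design itself, visible in the slight genome-wide excess the first-stage
slope predicts; effect-size recovery is assessed with the slope at zero.

## Known limitations

* Mode imputation is a deliberate stand-in for pedigree-haplotype
  imputation; it is adequate for <5% post-QC missingness and can be
  bypassed with pre-imputed input.
* The text PLINK dialect cannot round-trip the dosage orientation of
  markers whose counted allele is absent from the sample; the binary
  dialect can.
* Unknown-parent groups, metafounders and dominance relationships are out
  of scope; founders form a single base population.
* The catalog's run-derived segment enumeration follows one reading of
  shared-ROH construction; fixed-width windows would need a drop-in
  replacement for `build_catalog()`.
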