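---
title: "Family-based rare-variant collapsing tests: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant collapsing tests: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbatrare)
```

## The model

`fbatrare` tests association between a quantitative trait and the rare
variants of a genomic unit (a gene, or a fixed 100-kb window) in extended
pedigrees.  The test is a conditional score test in the FBAT tradition:
offspring genotypes are treated as random, conditioned on the parental
genotypes, so that the null distribution follows purely from Mendelian
transmission and is immune to population stratification and to any model
for the trait itself.

Extended pedigrees are decomposed into *nuclear families* — one
father–mother pair plus their common offspring
(`decompose_nuclear_families()`).  Every individual with known parents is
an offspring in exactly one nuclear family; individuals with several
mates appear as parents in several.  This decomposition loses
between-family information in large pedigrees (a known cost of the
approach), but keeps the conditioning exact and simple.

For a set of $M$ collapsed variants with weights $w_k$, each offspring
contributes the pseudo-count $X = \sum_k w_k x_k$, and each nuclear
family $i$ contributes

$$u_i = \sum_j T_{ij}\,\bigl(X_{ij} - E[X_{ij}\mid \text{parents}]\bigr),$$

with $T_{ij}$ the offset trait.  Under independent transmission of one
allele per parent, a parent with $c$ minor-allele copies transmits one
with probability $c/2$ (`offspring_conditional_dist()`), giving
closed-form conditional means and variances that sum across variants and
offspring.  The test statistic is $Z = U/\sqrt V$ with
$U = \sum_i u_i$ over informative families (those with positive
conditional variance), referenced two-sided to the standard normal.

### Assumptions

* Biallelic variants, autosomal, additive coding in minor-allele counts.
* Both parents genotyped at every collapsed variant for a family to
  contribute; offspring may be missing individual variants (dropped from
  that unit only).
* Conditional independence of transmissions across variants and across
  offspring.  For physically close collapsed variants this is wrong in
  the presence of linkage; the `variance_mode = "empirical"` estimator
  ($V = \sum_i u_i^2$) is offered because it remains valid under
  arbitrary within-family correlation of transmissions, at some cost in
  stability for few families.
* Large-sample normal reference for $Z$; no exact small-sample p-values.
  The `min_informative` threshold (default 10 families) suppresses
  reporting where the approximation is untrustworthy.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf_threshold` | 0.01 | "rare" = founder MAF strictly in (0, threshold); founder-based because the founders are the closest available stand-in for the source population |
| `scheme` | `"v1"` | `v0`: $w_k = 1$; `v1`: $w_k = 1/\sqrt{\zeta p_k (1-p_k)}$ |
| `weight_form` | `"sqrt"` | the Madsen–Browning reciprocal-square-root form; `"linear"` (no radical) retained for sensitivity analysis |
| `variance_mode` | `"model"` | conditional-moment variance; `"empirical"` robust alternative |
| `min_informative` | 10 | minimum informative families for a reportable p |
| `window_size` | 100000 | scan window width (bp), anchored at coordinate 0 |
| `offset` | sample mean | constant subtracted from the trait over the tested offspring; configurable fixed value |

Two of these deserve comment.  The v1 weight is sometimes printed without
the radical; we take the square-root form as primary because the scheme
is explicitly the Madsen–Browning one, whose weight is the reciprocal
square root of the binomial variance — and because only the square-root
form gives each variant an (approximately) equal contribution to the
collapsed variance.  The linear form stays available behind
`weight_form = "linear"` so the choice is testable rather than silent.
$\zeta$ is the *total* number of nuclear families in the data set,
constant across variants, not the per-variant informative count.

The trait offset is a free constant under the null (the score has mean
zero conditionally regardless of $T$); it affects power only.  The
sample mean over the tested offspring is the neutral default; no value is
prescribed by the method itself.

## The window scan and multiplicity

`window_scan()` tiles the chromosome into disjoint 100-kb windows
anchored at absolute coordinate 0 — never at gene starts, so results are
independent of annotation — and collapses each variant-bearing window
exactly as `gene_test()` collapses a gene.  A variant's 1-based VCF
position is converted to 0-based before window assignment; a variant
exactly on a boundary belongs to the right-hand window.

Collapsing dilutes: a large gene whose causal variants cluster in one
sub-region pays for every noncausal rare variant it drags into the sum,
since each adds variance but no signal.  Windows undo the dilution at the
price of multiple testing.  We correct with Bonferroni over *observable*
quantities: the number of tested (variant-bearing) windows — for a
gene-focused comparison, those overlapping the gene.  Correcting only
over the windows that happen to contain causal variants would require
oracle knowledge.  `window_scan()` reports the scan-wide adjusted value
in `p_bonferroni`; `bonferroni_adjust()` lets the caller apply a
different factor.

## Power and type-I summaries

Replicate p-values of one unit are summarised by the fraction strictly
below each power of ten ($10^{-7}\dots10^{-4}$ by default); the summary
detection threshold is the smallest threshold whose fraction exceeds 0.5
(`summary_power()`).  Two reading notes: the comparison is strict at the
threshold, and a fraction of exactly 0.5 does not qualify.  Replicates
where a unit is untestable count as non-detections in power but are
excluded from the type-I denominator — conservative for power, unbiased
for size.  The pooled type-I rate (all noncausal unit × replicate tests)
is primary; per-unit rates are also emitted, since either convention is
defensible when summarising size over many genes.

Phenotype adjustment (`adjust_phenotype()`) replaces the trait by OLS
residuals on intercept + sex + age + medication, per replicate, with
medication coded as a binary use flag.  Constant covariates are dropped
with a warning rather than failing the fit.

## What the simulator emulates — and what it does not

`simulate_dataset()` performs classical gene dropping: founder
minor-allele counts drawn binomially at the configured frequency,
transmissions Bernoulli(count/2) per parent, independent across variants.
Pedigrees are built top-down from one founder couple per family with
uniform offspring counts and founder spouses marrying in, reaching the
configured depth in every pedigree.  The trait is

$$Y = \beta_0 + \beta_{sex}\,\mathrm{male} + \beta_{age}\,age +
\beta_{med}\,med + \textstyle\sum_k \beta_k x_k + a_{fam} + \varepsilon,$$

with a shared within-pedigree effect $a_{fam}$ and replicated noise;
genotypes and covariates are fixed across replicates.

Causal effect sizes are attached *after* gene dropping, against realised
founder frequencies — the same logic by which workshop-style simulations
choose causal variants from real sequence data — so a causal variant is
always polymorphic and always passes the rare filter it is meant to be
discovered by.  Selecting on configured frequencies instead left the
causal architecture at the mercy of founder sampling noise (causal
variants going monomorphic, or drifting over the 0.01 cut-off).

Not modelled: linkage disequilibrium and recombination (transmissions are
independent; a haplotype-block founder model is a natural extension
point), ascertainment of the sampled families, imputation error, and
longitudinal trait structure.  Passing tests on these simulations
therefore demonstrate correctness of the statistic and the designed
power phenomena — not robustness to LD between collapsed variants, which
is precisely what the empirical variance mode exists to absorb.

### Scenario presets and their parameter choices

* **null** — 20 pedigrees of 4 generations (~500 members), 50 genes of 30
  variants, all $\beta = 0$, covariate effects zero, 20 replicates: the
  size-calibration scenario (and, with zero covariate effects, the
  adjusted-vs-unadjusted neutrality check).
* **weight_favoring** — full 5-generation scale (~1000 members), 10 of 20
  genes causal with $\beta = -10$ on every variant of realised founder
  MAF $\le 0.005$, covariate effects on, 50 replicates.  Concentrating
  effects on the rarest variants is the architecture the v1 weights are
  built for.
* **map4_like** — one 240-kb gene spanning four windows, 80 variants,
  nine causal ($\beta = -12$) confined to the two fully contained
  windows with about three quarters of the causal segregation mass in
  one of them, plus nine small noncausal genes; 50 replicates.

Effect sizes are in trait units (mmHg on a blood-pressure-like scale with
residual SD 8 and family SD 4); the values above were fixed once so that
gene-level power sits in the informative mid-range rather than at 0 or 1,
where comparisons between methods degenerate into ties.  Replicate counts
and pedigree scales are the packages's own experiment sizes; the
multi-replicate experiments in the test suite and acceptance script run
in seconds at these sizes.

## Numerical and degenerate-input choices

* Rare selection is strict on both sides: monomorphic variants
  (founder MAF 0), variants at exactly the threshold, and variants with
  no typed founder are excluded.
* Minor-allele orientation uses founder frequencies; an exact tie at 0.5
  keeps the ALT allele as minor.
* A family whose father or mother is missing *any* collapsed variant is
  dropped from that unit entirely (keeping the conditional moments
  exact); sufficient-statistic conditioning for missing parents is a
  documented extension, not implemented.
* `status` distinguishes `uninformative` (no variance) from
  `below_min_families`; neither carries a p-value, and downstream
  summaries treat both as non-detections.
* Units with no rare variants are reported with `n_variants = 0` rather
  than silently dropped.
* Regions are 0-based half-open; VCF positions are 1-based and converted
  by subtracting one.  All window arithmetic is integer.

## Known limitations

* Nuclear-family decomposition discards between-family information in
  deep pedigrees.
* Only both-parents-typed families contribute; designs rich in missing
  parents lose most of their data here.
* The normal approximation is poor for very sparse units even above the
  reporting threshold; empirical variance helps the mean–variance
  relationship but not the tail shape.
* Dichotomous traits, haplotype tests, variable-threshold and
  dispersion-style (SKAT-type) statistics are out of scope.
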