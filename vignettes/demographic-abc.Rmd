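---
title: "Inferring colonization history by coalescent simulation and ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring colonization history by coalescent simulation and ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

The Bornean elephant is a textbook case of an ambiguous colonization
history.  Historical records suggest a human introduction of a handful of
animals in the 17th century (descendants of a Sulu-archipelago stock,
itself founded from Java around the late 13th century); genetic
distinctiveness arguments suggest instead a natural colonization from the
Sunda shelf tens of thousands of years ago, when low sea levels connected
Borneo to the rest of Sundaland.  The two histories predict very different
genetic footprints in today's population: a recent founding by few animals
should have stripped allelic richness at microsatellite loci, whereas an
ancient founder event followed by slow recovery leaves moderate diversity
with a depressed Garza–Williamson ratio, and either history can fix the
population for a single mtDNA haplotype.

`demabc` implements the simulation and inference machinery needed to
confront such scenarios with data: coalescent simulation of microsatellite
and mtDNA datasets under parameterized demographic scenarios, approximate
Bayesian computation (ABC) for model choice and parameter estimation, and
the validation experiments (cross-validation of model selection,
parameter-recovery coverage, and a mitochondrial "zero diversity"
experiment) that tell you how much the answers can be trusted.  Because
the original genotypes are not publicly deposited, the package also ships
a synthetic-data module that generates datasets with the same shape
(224 diploid individuals in four localities × 18 loci; 60 mtDNA sequences
of 630 bp), so the entire pipeline runs end-to-end without restricted
data.

## The seven demographic scenarios

All scenarios end, backward in time, in a single ancestral population of
constant size `N_Anc`, and run at a generation time of 15 years (used only
to convert generations to years in reports):

* **ID** — instantaneous decline: constant `N_Cur` until `T_shrink`
  generations ago, `N_Anc` before.
* **ED** — exponential decline from `N_Anc` (at `T_shrink`) to `N_Cur`.
* **AC** — ancient colonization: a founder group of `N_shrink` effective
  individuals at `T_shrink` (prior 1000–1500 generations, i.e. roughly the
  last glacial period) grows exponentially to `N_Cur`; `N_Anc` is the
  large source population.
* **RI** — recent introduction: same shape as AC but with `T_shrink`
  20–70 generations and a small source (`N_Anc` 10^2.4–10^4, the
  Sulu/Java stock).  AC and RI differ **only through their priors**; the
  package asserts this by building both from the same parameter vector.
* **TI** — two introductions: founder events at `T_first` (out of
  `N_Anc`, into an intermediate population of size `N_Sulu`) and at
  `T_shrink` (out of the intermediate population), then growth to
  `N_Cur`.
* **ACS / RIS** — AC and RI with the present-day population fragmented
  into four demes (the four sampled localities) from `T_split` to the
  present.

Size priors are log10-uniform and time/founder-count priors uniform, as
is conventional; the AC/RI/ACS/RIS bounds follow the original field
analysis (see `inst/extdata/models.yaml`, loaded by
`default_model_specs()`).  The
mean microsatellite mutation rate is log-uniform on 10^-5–10^-3 per locus
per generation and shared across all 18 loci of a dataset.

Three pieces are deliberate package defaults because the original
supporting materials are unavailable; they are stated as assumptions, not
reproductions:

* **ID/ED priors** reuse the AC size bounds with `T_shrink` uniform on
  [20, 1500], spanning both candidate histories.
* **TI** uses RI's bounds for the recent event, `T_first` uniform on
  [40, 70] generations (a late-13th-century Java→Sulu transfer at
  15 y/generation is ~50 generations), the RI source-size bounds for the
  intermediate (Sulu) population, and an independent founder count for the
  older event.
* **ACS/RIS fragmentation** is pure: four equal demes summing to the
  pooled trajectory, no migration, `T_split` uniform on (0, `T_shrink`]
  (drawn as a fraction of `T_shrink`).  This is the fewest-parameter way
  to produce the significant differentiation observed among the real
  fragmented populations.

The GSM multistep proportion `p_gsm` has no published value ("some
proportion of multistep mutations"); the default prior is uniform on
[0, 0.3], configurable in the YAML file.

## Coalescent engine

Genealogies are simulated backward in time under a piecewise-exponential
demography.  With `k` lineages in a deme holding `G(t)` gene copies the
coalescence rate is `k(k-1)/2 / G(t)`; `G = 2N` for autosomal data and
`G = 2N × female_scale` for mtDNA (default `female_scale = 0.25`, i.e.
`N/2` maternally inherited copies — the standard quarter of the autosomal
copy number).  Waiting times across exponential segments use the
closed-form time rescaling (inverting the integrated hazard segment by
segment), so no discretization error is introduced.  Demes never exchange
migrants; at `T_split` (backward) the four demes merge.

Two caveats are inherited from the tooling the design emulates: the
continuous-time coalescent is used even when founder sizes are tiny
(`N_shrink` down to 2–8) while hundreds of lineages remain, where
simultaneous-merger corrections would in principle matter; and allele
sizes are unbounded (no microsatellite range constraints).

Mutations: microsatellites follow the generalized stepwise model — branch
mutation counts are Poisson(μ × length), each mutation steps ±k with
equiprobable sign and geometric magnitude P(k) = (1−p)p^(k−1) (p = 0 is
the strict stepwise model).  mtDNA uses infinite sites; the 630 bp length
matters only when rendering FASTA output.  The engine is verified against
closed forms in the test suite: E[TMRCA] = 2N for a pair, total tree
length 2G·Σ1/i, Watterson's E[S], Tajima's E[π] = θ, and the
Ohta–Kimura stepwise-model heterozygosity 1 − 1/√(1+2θ), each within
three Monte-Carlo standard errors.

## Summary statistics

The exact statistic list behind the original analysis is not recoverable,
so the package computes the standard microsatellite panel (configurable,
and recorded with every reference table): per-locus number of alleles K,
Nei's unbiased expected heterozygosity H, allelic size range R and
Garza–Williamson M = K/(R+1), summarised as mean and SD across loci; for
structured sampling additionally the across-deme means of K/H/R/M and
F_ST (one-way variance-components estimator, ratio of sums across loci
and alleles; computed per pair of demes and globally, negatives reported
as computed).  M is the bottleneck-sensitive member of the panel; F_ST
carries the structure signal that separates AC/RI from ACS/RIS.  mtDNA
datasets are summarised by the haplotype count H, segregating sites S and
mean pairwise differences π.  Every statistic is cross-checked against an
independent brute-force implementation to 10^-10 in the tests.

## ABC machinery

* **Standardization and rejection.** Each statistic is scaled by its
  median absolute deviation across the reference table (zero-MAD columns
  are dropped with a warning), and the `ceiling(tolerance × N)` rows
  closest in Euclidean distance are retained, ties broken by row order.
* **Model choice.** Rejection probabilities are retained-label
  proportions.  The regression estimate fits a weighted multinomial
  logistic regression of model label on the standardized statistics over
  the retained rows (Epanechnikov weights, zero at the largest retained
  distance) and evaluates it at the observed point.  The solver is a
  Newton iteration with a 10^-8 ridge; on separation or divergence it
  falls back to rejection proportions with a warning.  Bayes factors are
  posterior-probability ratios (equal model priors).
* **Model fit.** The marginal-density p-value is the fraction of retained
  simulations whose statistic-space density falls strictly below the
  observed point's.  The density is a product-Gaussian KDE with
  per-dimension Scott bandwidths — a deliberate, documented stand-in for
  the under-documented GLM density of the original toolchain; the
  p-value's contract (a calibrated "can this model produce these
  statistics?" diagnostic) only needs a consistent density estimator.
* **Parameter estimation.** Local-linear regression adjustment with
  heteroscedasticity correction: parameters are adjusted on the scale of
  their priors (log10 for log-uniform sizes and rates, linear for uniform
  times and counts), the conditional scale is fitted by regressing log
  squared residuals on the same weighted design, and adjusted draws are
  back-transformed.  Values adjusted outside their prior bounds are kept
  and flagged, not clipped.  Summaries are the weighted 5% quantile,
  mean, median, KDE mode (Silverman bandwidth) and the shortest interval
  holding 95% of the weight (HPD).

## Validation experiments

* **Cross-validation of model choice** (`cross_validate_models`):
  pseudo-observed rows are drawn from the reference table without
  replacement and classified with the row held out (leave-one-out);
  assignment is by highest posterior probability.  Production-scale
  experiments of this kind use 10^6 simulations per model; the package's
  acceptance run scales the table to 10^4 rows per model.
  How separable the structured variants (ACS/RIS) are from their simple
  counterparts depends strongly on two under-determined choices, and the
  package makes both explicit.  With the default statistic panel
  (which includes deme-level means and F_ST) and the default
  fragmentation design (four demes summing to `N_Cur`, i.e. per-deme
  effective sizes of roughly 60–250), drift after the split is fast and
  the structured variants are identified nearly perfectly — confusion
  flows mostly AC↔RI-ward.  Restricting the panel to the pooled
  statistics reverses the picture: the within-pair confusion (AC↔ACS,
  RI↔RIS) then dominates the errors for all four models, at the price of
  making the structured variants the poorly identified ones.  Neither
  extreme reproduces a world in which the pair members are *almost*
  indistinguishable yet the structured one is *better* identified; that
  regime requires a markedly weaker post-split drift signal than the
  equal-split-of-`N_Cur` design produces.  The panel is selectable
  per reference table precisely so this sensitivity can be examined.
* **Parameter recovery** (`recover_parameters`): draw truth from the
  prior, simulate, estimate, and record 95% HPD coverage — the standard
  calibration check for ABC posteriors.
* **Zero diversity** (`mtdna_zero_diversity`): simulate 60-sequence mtDNA
  samples and count how often the sample is fixed for one haplotype.
  Parameters come from `posterior_param_draws()`: log-normals matched to
  the published posterior medians and 90% intervals (a synthetic stand-in
  — the actual weighted posterior samples would require the undeposited
  genotypes).  The mtDNA mutation-rate prior is a package assumption
  (log-uniform, 10^-7–10^-5 per site per generation × 630 sites): the
  published experiment does not state it, which is why only the *ranking*
  of zero-diversity proportions across scenarios (ancient colonization
  highest, then two-introductions, then recent introduction) is treated
  as reproducible, not the absolute proportions.

## What the synthetic data does and does not establish

The generator reproduces the statistical structure the analysis assumes:
sample sizes and locus counts, deme labels, coalescent genealogies,
GSM/infinite-sites mutation, and (optionally) missing data.  It does not
emulate genotyping error, allelic dropout, null alleles, deviations from
the mutation model, or the unknown true per-locality sample sizes (the
default split is equal).  A green cross-validation or coverage test
therefore establishes that the *inference machinery* is correct and
calibrated under the model's own assumptions — it cannot establish that
the demographic models describe the real population.

## Numerical choices and degenerate inputs

* Sizes are real-valued internally (no rounding), keeping log-uniform
  priors exact; point priors (min = max) are allowed and draw exactly.
* Rejection retains `ceiling(tol × N)` rows; ties break by row order, so
  runs are bit-reproducible at fixed seed.
* The Epanechnikov weight at the largest retained distance is zero; it is
  replaced by half the smallest positive weight so the boundary row stays
  estimable in the regressions.
* Zero-MAD statistics are dropped (warning); an all-constant panel is an
  error.
* Monomorphic loci yield K = 1, H = 0, R = 0, M = 1; loci with fewer than
  two non-missing copies are excluded from the across-locus moments.
* `mu = 0` produces monomorphic data; `p_gsm = 0` is the strict SMM.
* The multinomial solver declares separation when coefficients diverge
  (|β| > 10^4) and falls back to rejection proportions.

## Limitations

Beyond the caveats above: no migration after fragmentation, at most four
demes, no recombination or selection, a single shared mean mutation rate
across loci (an optional per-locus gamma scatter exists but is off by
default), and the marginal-density p-value is KDE-based rather than
GLM-based.  The package reproduces printed simulation-only quantities at
reduced scale; real-data posterior numbers require the original
genotypes.
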