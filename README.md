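# demabc

Coalescent simulation and approximate Bayesian computation (ABC) for
demographic model choice — built around the question of how an isolated
population (the motivating case is the Bornean elephant) was founded:
anciently, by natural colonization followed by a bottleneck and slow
recovery, or recently, by the introduction of a handful of individuals.

The package simulates microsatellite and mtDNA datasets under seven
parameterized scenarios (instantaneous decline ID, exponential decline ED,
ancient colonization AC, recent introduction RI, two introductions TI, and
fragmented variants ACS/RIS), summarises them with the standard diversity
panel, and performs likelihood-free inference:

* **Coalescent engine** (Rcpp): piecewise-exponential demographies with
  deme fragmentation, closed-form time rescaling, the generalized stepwise
  mutation model (geometric multistep sizes) for microsatellites, and
  infinite-sites mutation for mtDNA.
* **Summary statistics**: per-locus number of alleles *K*, Nei's unbiased
  expected heterozygosity *H*, allelic range *R*, Garza–Williamson
  *M = K/(R+1)* (mean and SD across loci, pooled and per deme), variance
  -components *F*<sub>ST</sub>; mtDNA haplotype count *H*, segregating
  sites *S*, mean pairwise differences *π*.
* **ABC**: MAD-standardized Euclidean rejection
  (`ceiling(tol·N)` retained), model choice by retained-label proportions
  and by weighted multinomial logistic regression with Bayes factors,
  a KDE marginal-density model-fit *p*-value, and local-linear
  regression-adjusted posteriors with heteroscedasticity correction
  (weighted mean / median / mode / 95% HPD summaries).
* **Validation**: leave-one-out cross-validation of model selection,
  parameter-recovery coverage, and the mtDNA "zero diversity" experiment
  (how often a 60-sequence sample is fixed for one haplotype under each
  scenario).
* **I/O**: Genepop (2- and 3-digit dialects) and FASTA, streamed
  delimited reference tables with provenance headers, YAML prior
  configuration (`inst/extdata/models.yaml`).

Because the genotypes behind the motivating study are not deposited, the
`generate_observed_like()` module produces pseudo-observed data with the
study's shape (224 diploid individuals in four localities × 18 loci;
60 mtDNA sequences of 630 bp) plus a truth sidecar, so the entire pipeline
is exercised end-to-end on synthetic data.

## Worked example

Simulate an "observed" dataset under the ancient-colonization scenario,
build a small reference table over three competing scenarios, and run
model choice and parameter estimation:

```r
library(demabc)

obs_data <- generate_observed_like("AC", seed = 7)   # truth: N_Anc 97500,
# N_Cur 435, T_shrink 1060, N_shrink 7.2, mu 3.1e-5
obs <- stat_panel(microsat_sumstats(obs_data$genotypes, grouping = "demes"))

specs <- default_model_specs(c("AC", "RI", "ID"))
smp   <- sample_config(rep(112L, 4), n_loci = 18L)
tab   <- build_reference_table(specs, 2000, smp, seed = 8)  # ~12 s

run_model_choice(tab, obs, tolerances = 0.01)
#>       method tolerance    AC    RI        ID bf_AC bf_RI     bf_ID
#> 1  rejection      0.01 0.500 0.433  6.67e-02     1  1.15  7.50e+00
#> 2 regression      0.01 0.613 0.387 5.35e-173     1  1.59 1.15e+172

run_parameter_estimation(tab, obs, specs$AC, tolerance = 0.05)
#>   parameter       q5     mean   median     mode hpd_lower hpd_upper median_years
#> 1     N_Anc 1.11e+04 3.56e+04 2.69e+04 2.05e+04  5.54e+03  8.30e+04           NA
#> 2     N_Cur 2.04e+02 4.83e+02 4.33e+02 2.99e+02  1.76e+02  9.45e+02           NA
#> 3  T_shrink 9.27e+02 1.22e+03 1.22e+03 1.10e+03  9.13e+02  1.54e+03        18232
#> 4  N_shrink 1.64e+01 3.20e+01 3.11e+01 2.24e+01  1.46e+01  5.16e+01           NA
#> 5        mu 1.17e-05 2.24e-05 2.27e-05 2.52e-05  1.13e-05  3.75e-05           NA
#> 6     p_gsm 6.02e-02 1.45e-01 1.45e-01 1.56e-01  5.93e-02  2.39e-01           NA

marginal_density_pvalue(abc_reject(tab, obs, 0.01))
#> [1] 0.783
```

(All three candidate scenarios here are unstructured, so the F_ST columns
of the panel are constant across the table and are dropped with a warning
before distances are computed.)

The model-choice table mirrors the usual posterior-probability layout:
one probability column per scenario and Bayes factors of the best model
against each other one.  At this small table size rejection barely
separates AC from RI, while the regression method leans to the true
scenario (AC, drawn with a decline at ~1060 generations).  The estimation
table reports the weighted 5% quantile, mean, median, KDE mode and 95%
HPD per parameter on the linear scale — the current size (483 vs truth
435), decline time (median 1220 vs truth 1060; ~18,200 years at 15
y/generation) and mutation rate (2.3e-5 vs 3.1e-5) are recovered, and the
high marginal-density p-value (0.78) says the model reproduces the
observed statistics comfortably.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch, the scaled-down cross-validation experiment of
the motivating analysis: reference tables of 10^4 simulations per model
under AC, ACS, RI and RIS with the published priors; 1000 pseudo-observed
datasets per model; leave-one-out model choice at 1% tolerance with the
multinomial logistic method; and writes the per-model correct-assignment
counts (out of 1000) as JSON. Expect roughly 5–10 minutes on one CPU.

## Package layout

```
R/                 priors & models, demography, coalescent wrappers,
                   summary statistics, ABC, validation experiments,
                   synthetic data, Genepop/FASTA I/O, run drivers
src/coalsim.cpp    simulation and statistics kernels
inst/extdata/      default prior configuration (YAML)
vignettes/         methods vignette (model, assumptions, design choices)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
```
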