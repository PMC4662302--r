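---
title: "Comparing rare and widespread congeners: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing rare and widespread congeners: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecomp)
```

rarecomp implements an end-to-end comparative analysis of rare versus
widespread congeneric species: molecular diversity and structure from
codominant markers, quantitative-genetic variance partitioning from a
composite phenotype, growth-rate plasticity in two environments, population
genetic graphs, and a cross-species synthesis against range size. This
vignette explains the models, the defaults, and the design choices, and
says what the simulation-based tests do and do not demonstrate about real
data.

## The synthetic-data generator

All estimators in the package are exercised against simulated data whose
generating model is exactly the statistical structure the estimators
assume. The generator is first-class, tested code, not a fixture.

**Genotypes.** Each locus receives ancestral allele frequencies from a flat
Dirichlet. Population frequencies follow the Balding–Nichols distribution,
a Dirichlet with concentration `p_anc (1 - F)/F`, so the differentiation
parameter `F` (`target_fst`) is an analytic target: estimator-recovery
tests are exact in expectation rather than calibrated against another
simulator. Selfing is modelled at inbreeding equilibrium — the two alleles
of an individual are identical with probability `F_IS = s/(2 - s)` — rather
than by forward simulation, because selfing enters the downstream analysis
only through its equilibrium consequences (high `F_IS`, family structure),
not through its dynamics. A configurable fraction of loci carries a null
allele, modelled by masking one allele class per selected locus into a
distinguished but *scorable* allele code; missing calls are injected per
individual and locus. Maternal families are label groups whose sibs are
drawn i.i.d. from their population at equilibrium; literal parent-offspring
transmission would contradict the equilibrium model at intermediate selfing
rates (for example, observed heterozygosity would not vanish at `s = 1`
until transmission itself converged to equilibrium), so the equilibrium
rule is applied per individual.

**Phenotypes.** A latent genetic trait follows the nested random-effects
model `y = P_i + F_ij + e_ijk` with variances `v_pop`, `v_fam`, `v_err`.
Six measured rosette traits (height, leaf area, leaf number at days 21 and
55 post-germination) are linear in the latent factor *on the log scale*
with loadings near 0.1 plus log-normal trait noise, then exponentiated —
sizes are therefore strictly positive, and because the coefficient of
variation stays small the nested variance structure passes through the
exponential essentially undistorted. Growth trajectories at days 28 and 63
come from family-by-environment growth rates, so the log-difference growth
rate definitions recover the generating rates exactly. The family
plasticity contrast is scaled by solving the folded-normal SD equation so
that `SD(|GR_winter - GR_spring|)` across families equals `plasticity_sd`
exactly, accounting for the winter/spring mean offset.

**Defaults.** The defaults mirror a 15-locus SSR survey of a highly
selfing mustard: `selfing_rate = 0.95` (equilibrium `F_IS ~ 0.90`),
`null_allele_rate = 0.2` (about 3 of 15 loci), `missing_rate = 0.02`
(genotyping success above 98%), `alleles_per_locus = 8`, and moderate
differentiation `target_fst = 0.3`. Trait correlations within species are
free parameters of the loading matrix; no empirical correlation structure
was available to copy, so the default uses a single genetic factor with
unequal loadings.

**What passing tests show.** Recovery and coverage results on these
simulations certify the estimators under their own assumptions:
equilibrium inbreeding, island-model exchangeability across populations,
normal random effects, no linkage, no genotyping error beyond nulls and
missingness. Real data violate several of these (mutation processes,
isolation by distance, non-normal family effects), so the tests validate
the machinery, not the biology.

## Molecular diversity

`basic_stats()` computes Nei's gene-diversity hierarchy. The `plain`
estimator applies the definitions to sample frequencies: `H_O` is the mean
over populations of the heterozygote fraction, `H_S` the mean of
`1 - sum(p^2)`, `H_T` uses the unweighted average of population frequency
vectors, `D_ST = H_T - H_S`, `F_ST = D_ST/H_T`, `F_IS = 1 - H_O/H_S`.
Plain is the default because its algebraic identities are exact, which is
what the oracle and property tests verify. The `sample_corrected`
estimator applies the Nei–Chesser small-sample corrections with the
harmonic-mean sample size; its `H_S` is unbiased for the generating gene
diversity *even under inbreeding*, because the `H_O/2n` term cancels the
inbreeding inflation of the frequency-estimate variance.

Null alleles are one additional codominant allele class, and null/null
homozygotes count as homozygous; the alternative (treating them as missing)
is indistinguishable in the data we model, and the choice is confined to
one code path. Monomorphic loci report zero diversities with undefined
`F_ST`/`F_IS`, and across-loci summaries average only over loci where a
statistic is defined, rather than imputing zeros. `F_IS` is clamped to
`[-1, 1]` for reporting, with the raw value retained. Individuals missing
more than 4 loci are excluded by `filter_individuals()` (the screening rule
for a 15-locus panel); missing calls otherwise drop an individual at the
affected locus only.

## The rarefy-then-bootstrap interval

`rarefy_bootstrap()` first rarefies (samples without replacement) each
population to a common depth — by default the smallest population sample
size, since equalizing information across populations is the purpose of
rarefying — then resamples with replacement within each rarefied
population, recomputes the across-loci statistics, and forms percentile
intervals. Both stages are independently switchable and logged, because
the composition is genuinely a free design choice.

Two calibration decisions matter:

* Replicate statistics use the sample-corrected estimator by default. The
  plain estimator is biased downward by a factor of order `(1 + F_IS)/2n`,
  which at `n = 20` individuals and `F_IS ~ 0.9` is comparable to the
  interval half-width — a percentile interval around a biased centre has
  far-below-nominal coverage.
* Replicate distributions are recentered on the full-data point estimate
  (a bias-adjusted percentile interval; the raw replicate mean is kept in
  the returned object). Resampling data that are themselves a sample
  centres the raw replicates on the uncorrected sample value, one sampling
  layer below the point estimate; without recentring the interval need not
  even bracket its own point estimate, violating the container's
  invariant. With both choices, empirical coverage of the 95% interval for
  `H_S` sits near 0.95 in the package's calibration experiment (200
  simulated datasets, 10 populations of 20, 200 replicates each).

Significance between species uses the shared rule everywhere: two
statistics differ when their percentile intervals are disjoint; intervals
touching at an endpoint count as overlapping.

## Composite phenotype, Qst and heritability

Traits are analyzed as a single composite: rows with any missing trait are
dropped (imputation would inject structure the downstream model never
sees), traits are centered and scaled to unit variance — they live on
incommensurable scales (mm, mm², counts, and two ratio traits), so
correlation-matrix principal components are the defensible default, with
covariance-matrix components behind a flag — and each individual receives
the mean of its first three component scores weighted by percent variance
explained, normalized by the weight sum (a weighted mean conventionally
divides by its weights). The two derived ratio traits follow their printed
definitions: internode distance is leaf number over height at day 55 — the
name suggests the inverse ratio, but the printed formula is implemented
as-is with an inversion flag rather than guessing intent — and leaf size
is leaf area over leaf number.

`variance_components()` fits the nested model with population and
family-within-population random effects. The REML route uses a tightly
converged mixed-model fit (bobyqa with a 1e-10 final trust region, so that
on balanced designs with interior solutions it agrees with the closed-form
estimator to 1e-6 — the package's standing cross-check). The
`anova_mom` route is the closed-form nested ANOVA method-of-moments
estimator with Searle's coefficients for unbalanced designs, negative
solutions truncated at zero. The derived quantities use the
selfing-appropriate forms: `Qst = V_POP/(V_POP + V_FAM)` — families are
selfed sib groups, so the outcrossing factor of 2 on the family variance
is omitted — and broad-sense `H2 = V_FAM/V_TOT` with `V_TOT` including
`V_POP` (note this differs from the common within-population
heritability). Uncertainty comes from a parametric bootstrap: simulate
from the fitted normal components on the original design, refit, repeat;
more than 5% failed refits is an error.

Principal components are computed per analysis set (per species when run
per species); a pooled analysis is a caller-level choice, since the
composite is just a column passed to the variance model.

## Growth-rate plasticity

Growth rate is `(ln size_t2 - ln size_t1)/(t2 - t1)` for both stem
elongation and leaf area, giving per-day units for both traits. The
winter rate spans days 21 to 28 and the spring rate days 55 to 63 — the
only reading of the measurement schedule consistent with the chamber
phases bracketing vernalization. A published formula for the elongation
rate contains a typographic duplication of the second time point; the
intended log-difference form is used. The plasticity breeding value of a
family is the mean over sibs of the per-individual `|GR_winter -
GR_spring|` (the per-individual-first convention; the family-mean-first
alternative sits behind a flag). The cross-trait average z-standardizes
the two traits within the analysis set before averaging, because leaf-area
and elongation rates are on different per-day scales; a raw average is
available. The species-level model has species as the only fixed effect
and population (nested in species) as the random effect, with
parametric-bootstrap uncertainty on the fixed effects and the shared
CI-overlap significance rule.

## Population graphs and modularity

Individuals are encoded as multilocus half-dosages (one coordinate per
allele class, one reference class per locus dropped to avoid exact
collinearity). Population centroids are mean dosage vectors; the
among-population covariance of centroids is converted to a correlation
matrix and inverted — pseudo-inverse with a 1e-8 ridge when near-singular,
which small population counts make common; the fallback is logged. Partial
correlations give the edge-exclusion deviance `EED = -n ln(1 - r²)` with
`n` the total number of individuals (the sample actually supporting the
covariance; the population count is a documented alternative), retained
against the chi-square(1) critical value at `alpha = 0.05`. Retained-edge
sets are nested in `alpha`. Edge weights are a monotone transform of the
partial correlation; community structure deliberately ignores them — the
reported modularity is the maximum Newman–Girvan `Q` over the
edge-betweenness dendrogram on the unweighted retained topology, with `Q`
of an edgeless graph defined as 0 and logged. The exact
conditional-distance weighting has several published variants; none of
them changes the unweighted modularity reported here.

## Cross-species synthesis

Range size is the count of occupied 0.1° × 0.1° grid cells times a fixed
123 km² per cell — the printed convention is reproduced exactly
(area = 123 × cells, always), with cosine-corrected per-cell areas behind
a flag. Spatial subsampling of widespread species draws groups of 5–7
populations by seeding a random population and accreting great-circle
nearest neighbours — a reproducible stand-in for polygons originally drawn
by hand — reporting convex-hull areas so groups can be screened against a
target extent window (e.g. 236–35941 km²). One random group per widespread
species enters each of the 20 regression draws, and medians of `r²` and
`P` are reported over draws. Regressions of species means on log10 range
size are ordinary least squares; with four species the `P` value has very
low power and `r²` is the primary summary, so results carry a low-power
flag. No multiple-testing correction is applied by default (a Bonferroni
flag exists), matching the analysis convention the package reproduces.

The `Fst/Qst` ratio diagnostic pairs bootstrap replicates of the two
statistics (resampling when lengths differ), drops `Qst` replicates below
1e-6, and evaluates drift (ratio 1) by both the CI rule (default) and the
mean ± SD rule, since the two appear side by side in practice.

**A caution on averaging ratios.** The package's neutrality experiment —
marker `F` and trait `v_pop/(v_pop + v_fam)` both 0.2, 10 populations, 8
families of 4 — shows that while `Fst` and `Qst` estimates are
individually unbiased (their means match the generating values and the
ratio of means is 1.01), the *arithmetic mean of per-replicate point
ratios* is markedly inflated (about 1.8): with 10 populations, the
among-population variance estimate carries chi-square(9)-scale noise, and
`E[1/Qst]` is far above `1/E[Qst]`. The median ratio (1.03) and the ratio
of means are the calibrated summaries of such an experiment; a mean of
ratios at this design scale is not, and the acceptance experiment reports
all three so the distinction is visible.

## Numerical choices and problem sizes

REML fits use bobyqa with `rhoend = 1e-10`; variance components are
truncated at zero; `Qst` and `H2` are reported as undefined when their
denominators vanish. Percentile intervals use type-7 quantiles. The
package's own calibration experiments run at deliberately modest sizes
chosen to keep full reruns quick while leaving Monte-Carlo error well
inside the asserted bands: 100–200 replicate datasets, bootstrap depths of
120–200, fuzz batteries of 200–1000 cases; each test states its sizes.

## Known limitations

No mutation-model realism (no stepwise mutation), no linkage, no
isolation-by-distance structure, no apomixis or ploidy variation in the
generator; no AMOVA, exact Hardy–Weinberg tests, or Mantel tests; no
narrow-sense heritability from pedigrees and no G×E variance
decomposition; no map rendering or climate-envelope analysis; no
phylogenetic contrasts. How null homozygotes were distinguished from
missing data in the original scoring convention is unknowable from the
data we model; the package keeps the two codes distinct and documents the
treatment of each.
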