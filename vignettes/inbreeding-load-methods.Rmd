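---
title: "Methods: pedigree decomposition of inbreeding and REML estimation of the inbreeding load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree decomposition of inbreeding and REML estimation of the inbreeding load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbload)
```

## The problem

Inbreeding depression — the loss of performance in inbred individuals — is
usually summarized by a single regression coefficient `b` on the inbreeding
coefficient `F`. But the recessive burden exposed by inbreeding differs
among ancestors: an individual inbred through ancestor `k` expresses the
*inbreeding load* of `k`, a heritable, additive quantity. `inbload`
implements the chain from pedigree to per-ancestor load predictions:

1. **Mendelian decomposition of inbreeding.** Each animal's `F_j` is split
   into partial coefficients `F_j(k)` attributed to specific ancestors,
   `sum_k F_j(k) = F_j`.
2. **Load design.** The sparse matrices `T` (partial coefficients), `P`
   (0.5 parent pointers) and `K = T(I - P)` connect a phenotyped animal to
   the Mendelian-sampling deviations of its ancestors' load effects.
3. **Bivariate animal model.** `y = X beta + f b + Z_u u + Z_u K i + Z_p p + e`
   with `(u, i) ~ N(0, G (x) A)`, `G = [[sigma_u^2, sigma_ui],
   [sigma_ui, sigma_i^2]]`, a permanent-environment effect `p` and residual
   `e`, fitted by REML; the load variance is tested with a likelihood-ratio
   test against the boundary mixture `1/2 chi2_0 + 1/2 chi2_1`.
4. **Single-locus theory.** Closed forms for the substitution effect under
   non-random mating, split as `alpha = alpha_noF + alpha_F`, ground the
   load as an additive effect: `sigma_i^2 = 2pq alpha_F^2`, with
   `sigma_ui <= 0` always.

The load is scaled *per fully inbred (100%) descendant*: a predicted
`i_hat` of +60 means a hypothetical fully inbred descendant of that animal
would gain 60 trait units from its load, before the population-level
depression `b` (so +60 with `b = -50` nets +10).

## Mendelian decomposition

The decomposition reruns the tabular relationship recursion with the
Mendelian-sampling variance matrix zeroed everywhere except at one
ancestor `k`:

* `phi_kk = 1/4 (1 - F_s) + 1/4 (1 - F_d)` (both parents known),
  `1/2 + 1/4 (1 - F_l)` (one parent known), `1` (founder).
* The recursion with a single nonzero `phi_kk` is exactly the rank-one
  matrix `phi_kk t t'`, where `t` is the gene-flow vector of `k`
  (`t_k = 1`, `t_j = (t_sire + t_dam) / 2`). `compute_partial_inbreeding()`
  therefore performs one linear downward pass per ancestor and emits
  `F_j(k) = phi_kk t_(s_j) t_(d_j) / 2`, which is identical to the dense
  per-ancestor tabular sweep (this equivalence is asserted against a dense
  oracle in the test suite, and against a gene-dropping Monte Carlo with
  attribution of each identity-by-descent event to the ancestor whose
  Mendelian draw created it).
* Only ancestors appearing on both the sire and the dam side of at least
  one inbred animal can contribute; the sweep is restricted to that
  candidate set, which drops only structural zeros.

All strictly positive `F_j(k)` are stored unthresholded, so the closure
`sum_k F_j(k) = F_j` holds to 1e-10 (double precision over realistic
pedigree depths). The magnitude cutoff belongs to `K`, not `T`: `build_K()`
computes `T(I - P)` exactly and then drops entries with absolute value at
or below the threshold (default 0.01, settable to 0; simulation uses 0).

Unknown parents are coded 0 on input and treated as unrelated founders (no
unknown-parent groups). Pedigrees are stably topologically sorted keyed by
(birth year if present, input order), so sparse structures are
reproducible. Self-fertilization is accepted with a warning (the formulas
apply, though it is biologically impossible in the target species); an
animal appearing as both sire and dam is rejected only when sex codes are
supplied.

## The mixed model and its REML fit

`b` enters as a fixed covariate on total inbreeding `f` in `[0, 1]`, so
`b_hat` is expressed per fully inbred descendant. Fixed-effect factors are
dummy-coded dropping the *last* level of each factor plus a global
intercept; any full-rank constraint gives the same likelihood and variance
components. Load effects `i` are carried for *all* pedigree animals — they
share the relationship matrix `A` with `u`, so animals with empty `K`
columns still receive load predictions through their relatives.

The restricted likelihood is evaluated through the mixed-model equations
with `A^-1` built by Henderson's rules including inbreeding;
`log|A| = sum(log m_j)` over the Mendelian variances. The residual variance
is profiled out analytically; the remaining parameters are variance
*ratios*: `(log gamma_u, log gamma_i, atanh r, log gamma_p)` for the full
model. Nelder-Mead maximizes the profiled likelihood (convergence reltol
1e-10, one restart from the optimum). Defaults for starting values:
`sigma_e^2` = half the phenotypic variance, `sigma_u^2 = sigma_p^2` = a
quarter each, `sigma_i^2` = the phenotypic variance — the load scale is an
order of magnitude larger than the additive scale because of the small
partial coefficients, and a much smaller start stalls the climb.

Two numerical guards matter:

* **Singular `G`.** When the genetic correlation `r` approaches ±1 the
  precision penalty `G^-1 (x) A^-1` exceeds the data cross-products by
  ~1e14 and the MME-based likelihood silently loses the data information,
  creating *phantom* boundary optima whose reported likelihood can be
  hundreds of units too good (we verified this against a dense
  multivariate-normal evaluation). The correlation is therefore
  parameterized as `r = rmax tanh(z)` with `rmax = sqrt(1 - 1e-6)`, and
  the evaluator rejects relative determinants of `G` below 1e-7. Within
  those bounds the sparse and dense likelihoods agree to ~1e-9.
* **Standard errors.** The observed information is differentiated
  numerically on the unconstrained transformed scale (log ratios, `atanh`
  correlation, log residual variance) and delta-mapped to the component
  scale. Directions the data do not inform have near-zero curvature and
  produce very large — but finite — standard errors, which is the honest
  statement at desk-scale sample sizes where the load variance is weakly
  identified. This replaces an average-information update: a
  derivative-free maximizer with a profiled likelihood needs no AI matrix,
  and the AI matrix is ill-conditioned exactly where these fits end
  (near the PSD boundary).

`reml_fit(..., opts = list(fix_r = TRUE))` optionally fixes `r = 0`,
which is useful for null-calibration analysis (below).

## Likelihood-ratio test and its calibration

`likelihood_ratio_test()` computes
`LRT = (-2 logL reduced) - (-2 logL full)` and refers it to
`1/2 chi2_0 + 1/2 chi2_1` (`p = 1/2 Pr(chi2_1 >= LRT)`, `p = 1` at zero).
Tiny negative statistics (within 1e-6) are clipped to zero with a warning;
larger negatives raise an error because they indicate the models were not
nested or not converged.

This mixture is the classical null for *one* variance component on the
boundary. The full model, however, frees *two* parameters
(`sigma_i^2`, `sigma_ui`), and the correlation is unidentified when
`sigma_i^2 = 0`, so some anticonservativeness is expected. Our null
simulations quantify it: at the package's validation configuration
(~830 animals under the default mating policy, 200 replicates) the LRT
exceeded the 5% mixture critical value 2.71 in 7.5% of replicates —
above nominal but within binomial noise — while smaller pilot designs
richer in inbreeding-generating ancestors showed exceedances up to
~20%, behaving closer to `1/2 chi2_1 + 1/2 chi2_2`. Fixing the
correlation at zero (`fix_r = TRUE`, a single boundary parameter)
restores ~5% everywhere. The package keeps the half-chi-square
convention for `p`-values because it is the reporting convention of
this model class; users testing the load variance on modest datasets
should either fix the correlation under the null or treat the mixture
`p`-values as mildly anticonservative. At the scale of national
recording schemes (statistics in the hundreds) the distinction is
immaterial.

## Single-locus theory conventions

Genotypic values are `(a, d, -a)` for `(A1A1, A1A2, A2A2)` with `A1` at
frequency `p` (Falconer parameterization). The average excess is
`e = a(1 + F) + d(q - p)(1 - F)` and the substitution effect
`alpha = e / (1 + F)`; a least-squares regression of genotypic value on
gene content in a population with heterozygote deficit `F` recovers
exactly `e / (1 + F)` (checked by simulation in `empirical_check()`).

The second moments use the *genic* convention: the gene-content variance
is taken at Hardy–Weinberg proportions (`2pq`), so
`sigma_i^2 = 2pq alpha_F^2`, `sigma_u^2 = 2pq a^2 + 2pq (q - p)^2 d^2`,
`sigma_ui = -4pq F/(1+F) (q - p)^2 d^2 <= 0`, and the squared correlation
`r2 = 2pq(q-p)^2 d^2 / sigma_u^2` — the dominance fraction of the additive
variance, free of `F`. Note that this `sigma_u^2` omits the cross term
`4pq a d (q - p)` present in the textbook `2pq (a + (q-p)d)^2`; we keep
the genic forms because the correlation identity above is derived under
them. `r2` is reported as 0 with a flag at degenerate corners
(`sigma_u^2 sigma_i^2 = 0`) rather than NaN, for testability.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe a closed dairy-sheep-like nucleus:
80 founders, 8 overlapping cohorts (parents drawn from the two preceding
cohorts), 25 sires and 150 dams per cohort, matings that reject any pair
sharing a grandparent (or closer kin), records on females only
(~2 lactation records each), fixed flock-year-parity classes
(`N(0, 20^2)` liter effects), trait mean 193 liters, and true components
`sigma_u^2 = 800`, `sigma_i^2 = 10000`, `sigma_ui = -300`,
`sigma_p^2 = 400`, `sigma_e^2 = 1300` (liters squared), `b = -110` liters.
This yields a population mean `F` of about 0.01–0.03 with inbred-animal
means near 0.03, i.e. inbreeding arising from multi-generation loops, and
a load variance an order of magnitude above the additive variance because
of its per-100%-inbred scale.

Genetic pairs `(u, i)` are simulated by the pedigree recursion — founders
`N(0, G)`, non-founders parent-average plus a residual with covariance
`m_j G` — which has covariance exactly `G (x) A` in distribution and
scales linearly, with no dense Cholesky. Phenotypes follow the generative
equation with the *exact* (threshold 0) `K`.

Not emulated: selection (no progeny testing or truncation on predictions),
purging dynamics, genotyped loci (the single-locus layer is analytic),
heterogeneous flock sizes, seasonal structure, or missing-pedigree
patterns beyond unknown founders. Passing tests therefore demonstrate
correctness of the estimator under its own assumptions, not robustness to
selection or pedigree errors in field data.

## Validation-study sizes

The test suite's simulation studies use sizes chosen so that the whole
validation suite runs in minutes on a single workstation core; they are
the package's validation conditions, stated here once:

* decomposition closure: 200 random 45-animal pedigrees, tolerance 1e-10;
* gene-dropping cross-check: three pedigrees of up to 12 animals, one
  million replicates, agreement within 3 Monte-Carlo SEs;
* dense linear-algebra oracles: 300-animal systems, relative 1e-8;
* locus moments: 10,000 random parameter draws against enumeration,
  1e-12;
* parameter recovery: 20 replicates of a ~1,700-animal, 9-cohort design
  with 3 records per female and *random* mating — deliberately more
  inbred (mean F ~ 0.04) than the default generator, because under
  grandparent-avoidance at desk scale the load variance is essentially
  unidentifiable and every fit collapses to a boundary; this is a power
  choice for the validation study, not a claim about field populations.
  Criterion: each true component inside ±2 reported SEs in at least 80%
  of replicates;
* null calibration: 200 replicates of an ~830-animal default-policy
  design with `sigma_i^2 = 0`, exceedance of 2.71 compared with 5%
  within 3 binomial SEs (measured 7.5%; discussed above).

## Known limitations

* The REML maximizer is derivative-free; at a few hundred equations a fit
  costs seconds, and the implementation targets validation-scale problems
  (thousands of animals), not national evaluations (millions).
* Standard errors are curvature-based and become unstable exactly at PSD
  boundaries; they are reported large or `NA` there by design.
* The depression covariate `f` and a constant shift of the load effects
  are only softly separated (through the `A`-prior on `i`); with weak
  load information `b_hat` inherits extra uncertainty, visible in its SE.
* No unknown-parent groups, no genomic relationships, no multi-trait
  extension beyond the bivariate `(u, i)` structure.
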