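---
title: "A multi-trait fixed-regression test-day animal model for SCS and yield traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-trait fixed-regression test-day animal model for SCS and yield traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdgibbs)
```

## The model

`tdgibbs` fits a four-trait (somatic cell score, milk, fat and protein
yield) fixed-regression test-day animal model to repeated first-lactation
records of dairy cows. A record $y_{ijklmn}$ of trait $i$ is modelled as

$$
y_{ijklmn} = HYM_{ij} + \sum_{q=1}^{6}\beta_{ikq}\,z_q(t)
           + \sum_{q=1}^{5}\delta_{ilq}\,z_q(t)
           + \alpha_{im} + \rho_{im} + e_{ijklmn},
$$

where $HYM_{ij}$ is a herd-by-year-month-of-test contemporary group,
$\beta_{ikq}$ and $\delta_{ilq}$ are fixed lactation-curve coefficients
nested in the age-season-of-calving class $k$ (six normalized Legendre
coefficients) and in the herd-year-of-calving class $l$ (five
coefficients), $z_q(t)$ are the Legendre covariates of days in milk $t$
standardized to $[-1, 1]$ over the global range $[5, 305]$,
$\alpha_{im}$ is the animal's additive genetic effect, $\rho_{im}$ the
cow's permanent-environment effect and $e$ the residual. Across traits
the three random terms carry $4\times4$ covariance matrices
$\mathbf{G}_0$, $\mathbf{P}_0$ and $\mathbf{R}_0$; across animals the
additive effects are correlated through the numerator relationship
matrix $\mathbf{A}$, whose sparse inverse is assembled directly by
Henderson's rules (with inbreeding accounted for by default via
Meuwissen–Luo-style coefficients; `a_inverse(..., account_inbreeding =
FALSE)` gives the simpler rules).

Somatic cell counts enter as scores, $SCS = \log_2(SCC/100) + 3$, so a
count of 100 (×10³ cells/mL) scores 3 and every doubling adds one unit.
Records are edited to 3–75 kg milk, 1.5–8 % fat, 1–7 % protein, 1–500
(×10³/mL) SCC, 5–305 days in milk and 18–36 months age at first
calving, and cows must retain at least five records. The edit order
(range rules first, in the documented sequence, then the minimum-record
rule) is fixed and reported, because the counts per rule depend on it.
Fat and protein are edited on the percentage scale but modelled as kg
yields (`kg = milk × pct / 100`).

Heritability per trait is
$h^2_i = \sigma^2_{a,i} / (\sigma^2_{a,i} + \sigma^2_{pe,i} + \sigma^2_{e,i})$,
genetic correlations come from $\mathbf{G}_0$, phenotypic correlations
from $\mathbf{G}_0+\mathbf{P}_0+\mathbf{R}_0$. "Environmental"
correlations are computed from the pooled $\mathbf{P}_0+\mathbf{R}_0$
matrix by default; a residual-only convention is available
(`derived_parameter_samples(..., env_convention = "residual")`) because
usage in the field is ambiguous and the two differ slightly whenever
permanent-environment and residual correlations differ.

## Gibbs sampling scheme

Each cycle proceeds in the fixed order: level-wise 4-trait draws of the
fixed terms (HYM, the six age-season coefficients, the five herd-year
coefficients) from their multivariate-normal full conditionals; one
*joint* draw of the entire additive-genetic field — all animals, all
traits at once — from its multivariate-normal full conditional with
the permanent-environment effects integrated out, computed through a
sparse Cholesky factorization (CHOLMOD) of the conditional precision
$\mathbf{A}^{-1}\!\otimes\mathbf{G}_0^{-1} + \mathrm{blockdiag}\,
(\mathbf{P}_0 + \mathbf{R}_0/k_c)^{-1}$ (a cow's additive value enters
its $k_c$ records only through their mean, so the collapsed likelihood
per cow is that mean with covariance $\mathbf{P}_0 + \mathbf{R}_0 /
k_c$); then the permanent-environment vectors given the field; then
$\mathbf{G}_0$, $\mathbf{P}_0$ and $\mathbf{R}_0$ from their
inverted-Wishart full conditionals (scales: cross-products
$\boldsymbol\alpha'\mathbf{A}^{-1}\boldsymbol\alpha$,
$\boldsymbol\rho'\boldsymbol\rho$ and the residual cross-products, each
plus the prior scale; degrees of freedom: number of animals / cows /
records plus the prior df). Fixed effects carry flat priors.

Blocking the additive field is the decisive design choice. A cow's
additive and permanent-environment effects enter its records only
through their sum, so level-wise (animal-by-animal) draws move along
that confounded ridge, and through it the genetic-versus-permanent
partition of the cow-level variance, arbitrarily slowly — on desk-scale
data the integrated autocorrelation time of a heritability exceeds
thousands of cycles. The single-block draw makes covariance samples
close to independent across cycles, so short production chains give
usable posterior means. A level-wise variant (each recorded cow's two
vectors as one 8-dimensional block, other animals singly) is retained
behind `run_chain(..., animal_block = FALSE)`; both leave the
stationary distribution unchanged. Chains start from method-of-moments
values (`moment_start_values()`: within-cow covariance for the
residual, a paternal half-sib ANOVA for the genetic matrix) rather
than from an arbitrary split, which shortens the burn-in transient.

### Priors for the covariance matrices

The default prior for each covariance matrix is an inverted Wishart
with $\nu = \text{traits} + 2 = 6$ degrees of freedom and scale equal
to one third of the phenotypic covariance of the analyzed records —
i.e. a prior whose mean is an even split of the observed variance over
the three components, at the smallest df giving a finite mean. This
mirrors the common default of multivariate mixed-model MCMC software.
The choice matters: a "vague-looking" inverted Wishart with minimal df
and a *tiny* scale (say $10^{-4}\mathbf{I}$) has density proportional
to $|\mathbf{G}_0|^{-5}$ with its mode at essentially zero; in
directions the likelihood identifies only weakly — the additive versus
permanent-environment split, and genetic correlations involving a
low-variance trait — such a prior dominates and drags the chain into a
near-degenerate regime. We verified this on model-exact synthetic data:
with the tiny-scale prior the additive milk variance collapsed an order
of magnitude below its simulated value while REML on the same data
recovered it; with the weakly-informative default the chain fluctuates
around the simulated truth. Both df and scales are configurable in
`gibbs_config()`.

### Chain mechanics

`gibbs_config()` defaults to the production settings (200,000 cycles,
10,000 burn-in, storage every 10th cycle, i.e. 19,000 stored samples);
the examples below use desk-scale chains. All randomness flows through
R's RNG from a single seed, so a chain is bit-reproducible, and the
sampler runs in segments (default 10,000 cycles) with optional
checkpointing of the full state including the RNG, so an interrupted
run resumes into the identical chain. Dense level codes are assigned in
order of first appearance, which makes results invariant to relabelling
of herd or cow identifiers. Convergence is assessed by trace
inspection (`autoplot()`, `export_traces()`); `geweke_z()` is provided
as a numeric aid but is deliberately not used as a gate.

## The synthetic-data generator

Because the original recording data are not public, the package
validates itself by parameter recovery on synthetic data with known
truth. `simulation_truth()` fixes the generating covariance structure:
genetic, permanent-environment and residual variances per trait at the
magnitudes typical of first-lactation Holstein test-day analyses
(giving heritabilities of about 0.03 for SCS, 0.20 for milk, 0.10 for
fat and 0.14 for protein), genetic correlations of 0.62 / 0.90 / 0.76
among the production traits and 0.07 / 0.01 / 0.11 between SCS and
milk / fat / protein, and negative environmental correlations between
SCS and the yields (−0.177 / −0.165 / −0.152) with 0.85–0.97 among the
yields. The environmental correlations are placed identically in
$\mathbf{P}_0$ and $\mathbf{R}_0$; placing half the pooled *covariance*
in each would make $\mathbf{P}_0$ indefinite (the permanent-environment
protein variance is too small to carry half the milk–protein
covariance), so the equal-correlation convention is used and the
implied pooled correlation is attenuated by at most a few percent.
The fat–protein genetic correlation (0.76) is a package choice inside
the plausible production-trait range, as is the contemporary-group SD
(30 % of the phenotypic SD per trait) and the lactation-curve
coefficient scales (15 % of the phenotypic SD for the leading Legendre
coefficient, decaying for higher orders); all are arguments.

`simulation_design()` emulates the recording structure at reduced
scale: by default 1,000 recorded cows from 100 founder sires, with 40 %
of the cows out of 250 founder dams and the remaining 60 % daughters of
earlier recorded cows calving in later years (first-lactation recording
schemes span many years, so dams of later cows are themselves recorded
first-lactation cows), 10 herds, and eight monthly tests per cow
starting at a uniform DIM in [5, 35] (so all DIM lie in [5, 245] and
every cow survives the five-record edit by construction). The family
structure is chosen for identifiability rather than to mimic the
cows-per-sire ratio of national data: the sampling error of a
recovered genetic variance is governed by the number and size of
families (half-sib family sizes near $4W/\sigma^2_a$, with $W$ the
within-family variance of cow means, minimize it) and by the number of
parent-offspring pairs, not by the raw record count. Breeding values descend the pedigree as parent averages
plus Mendelian-sampling deviations with variance
$d\,\mathbf{G}_0$, $d$ reflecting parental knowledge and inbreeding
exactly as in the A-inverse rules. By default the generator redraws a
record's residual vector until all emitted fields fall inside the edit
ranges (the rejection rate is well under 1 %, so distortion of the
residual covariance is negligible), which makes the default data set
pass `apply_edits()` losslessly; `edit_stress = TRUE` disables the
redraw, clips SCC into [1, 500] and injects ~1 % out-of-range records
to exercise the edit rules.

What the generator deliberately does not emulate: mastitis-episode
dynamics (SCS is Gaussian on the log scale rather than a mixture with
infection spikes), selection and culling, heterogeneous variance over
DIM, and missing traits on a test day. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the model's
own assumptions, not robustness to these real-data features.

## What recovery runs show, and their limits

At the default desk scale (1,000 cows × 8 records, a 5,000-cycle chain
with 1,000 burn-in and thinning 5, a few minutes on one CPU) the
posterior mean of milk heritability recovers the simulated truth with
a replicate-to-replicate SD of about 0.03 — dominated not by chain
noise (the blocked sampler's posterior-mean error is well under 0.01)
but by the information content of a single 1,000-cow realization: the
identifiable genetic variance of one simulated population fluctuates
around its nominal value, and REML point estimates on the same data
scatter identically. Single runs therefore typically land within
±0.03 and almost always within ±0.05 of truth; the milk–protein
genetic correlation behaves better (errors within about ±0.05), and
the other heritabilities comparably. Genetic correlations involving
SCS are a different matter: with an additive SCS variance of
0.031 the information about them at this scale is intrinsically meagre
— their posterior SDs are around 0.2 — so their posterior means wander
well beyond ±0.05 of truth. That is a property of the design size, not
of the sampler (the original analyses of such models rest on around a
million records to reach standard errors of ~0.04 for these
correlations); recovery checks in the test suite therefore assert the
well-identified parameters only.

## Numerical choices and degenerate inputs

* Legendre covariates use the normalized basis
  $\phi_k(x)=\sqrt{(2k+1)/2}\,P_k(x)$ via the Bonnet recurrence;
  orthonormality is verified by dense-grid trapezoid quadrature at
  tolerance $10^{-6}$ (20,001 points — at 10,000 the quadrature error
  of the highest-order Gram entry is itself ≈$10^{-6}$).
* Equal-tail intervals use type-7 empirical quantiles; the 95 % HPD
  interval is the exhaustive shortest window over sorted samples; the
  Monte Carlo standard error uses batch means with $\lfloor\sqrt n
  \rfloor$ batches.
* Covariance draws are symmetrized and positive definite by
  construction (Bartlett decomposition); stored samples with a
  nonpositive variance (possible only for covariance matrices supplied
  from outside) are excluded from derived parameters and counted.
* Fixed-effect levels with no records (or all-zero covariates) have an
  improper flat-prior conditional and are left untouched; a permanent-
  environment level without records would draw from its prior, mean 0
  and covariance $\mathbf{P}_0$.
* Season of calving defaults to calendar quarters; any month-to-season
  map can be supplied, and the 19 monthly age classes (18–36) crossed
  with 4 seasons give at most 76 age-season classes.
* The three intercept-like fixed terms (HYM, and the constant Legendre
  coefficient of both curve sets) are mutually confounded; with flat
  priors their individual values drift along the null space while all
  identified quantities — residuals, covariance components, derived
  parameters — are unaffected. Location effects are therefore not
  reported as estimates.
* Degenerate descriptive-correlation windows (fewer than `min_n`
  records, default 30, or zero variance) report a missing correlation
  and are excluded from the record-count-weighted average.

## A short worked run

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_dataset(simulation_design(n_cows = 300, n_sires = 10,
                                          n_dams = 200))
records <- sim$records |> apply_edits() |> assign_classes()
fit <- fit_gibbs(records, sim$pedigree,
                 gibbs_config(chain_length = 3000, burn_in = 500,
                              thin = 5, seed = 2))
tidy(fit)                       # posterior summary of all parameters
autoplot(fit)                   # traces and densities of heritabilities

records |>
  precorrect() |>
  daily_correlations() |>
  average_daily_correlation()   # SCS-yield phenotypic correlations
```

The one-command pipeline (`run_all()` with a `run_config()` or a YAML
file via `read_run_config()`) chains the same steps, writes every
artifact (edit report, class maps, id map, A-inverse triplets, sample
store, summary table, trace/density exports, daily correlations) as
plain text and records an MD5 manifest; identical configuration and
seed reproduce identical hashes.
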