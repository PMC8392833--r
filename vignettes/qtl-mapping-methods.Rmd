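---
title: "Sparse Bayesian QTL mapping in outbred full-sib crosses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Bayesian QTL mapping in outbred full-sib crosses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hsqtl` implements QTL detection for "cross pollinator" (CP) mapping
populations — F1 progeny of two outbred, heterozygous parents, the standard
design for linkage mapping in conifers and other non-inbred trees — using
multi-marker Bayesian sparse regression rather than single-marker interval
mapping. This vignette describes the models, the tunable parameters and
their defaults, the numerical choices, and what the simulation-based tests
do and do not establish.

## The design: two-way pseudo-testcross

A CP cross segregates two kinds of informative marker. A pseudo-testcross
marker is heterozygous in one parent and homozygous in the other (aa x ab
or ab x aa); its progeny fall into two classes expected at 1:1, and it is
informative only for the heterozygous parent's map. Markers heterozygous in
both parents (ab x ab) are generated by the simulator but excluded from both
parental map sets, mirroring two-way pseudo-testcross practice. Each trait is
therefore scanned twice — once per parental marker set — and results are
reported per parental map.

Progeny calls are coded 0/1 (which of the heterozygous parent's alleles was
transmitted). The package's analysis matrices contain only these two-class
codes; the raw simulator output codes ab x ab markers 0/1/2 (transmitted
second-haplotype count), and those columns never enter a scan.

## The synthetic-cross generator

`sim_genetic_map()`, `sim_cross()`, `sim_phenotypes()`, and the wrapper
`sim_study()` emulate the study design the analysis assumes:

* 252 progeny, 12 linkage groups;
* about 480-520 informative markers per parental map at ~4 cM average
  per-map spacing. The generator lays both marker types on a shared frame
  (84 markers per group, exponential gaps with 2 cM mean), so each parental
  subset has ~42 markers per group at ~4 cM — the geometry of published
  conifer maps of this design;
* traits controlled by ~5 QTLs of 2-10% variance explained each (default
  five QTLs at 5-9%), placed at markers so that the realized single-locus
  R^2 matches the requested fraction;
* missing genotype calls at 5% by default (the QC rule tolerates up to
  20%) and symmetric genotyping errors at 0.5%. Neither rate is reported
  by typical source studies; both are explicit, testable parameters.

Transmission is simulated per linkage group as a Markov chain along the
chromosome with crossover probability `recomb_fraction(gap)` between
adjacent markers. The default map function is Haldane (no crossover
interference), with Kosambi available; mapping software defaults rarely
state the function, and Haldane is the simplest defensible choice for a
no-interference gamete model. Phenotypes are generated from the error-free
calls; the observed, noisy calls are what the analysis sees.

What the generator does **not** emulate: segregation distortion from
viability selection, locus-specific missingness or error patterns (both are
i.i.d.), crossover interference under the Haldane default, epistasis, and
genotype-environment interaction. Passing recovery tests on these
simulations therefore shows the inference machinery is correct and
calibrated under the assumed design, not that real data meet those
assumptions.

## Marker quality control

Three rules, applied in order, with strict inequalities exactly as
commonly printed:

1. **Missingness**: markers with > 20% missing calls are dropped;
   individuals are never dropped.
2. **Segregation**: a 1-df chi-square without continuity correction,
   `X^2 = (n0 - n1)^2/(n0 + n1)`, against the 1:1 expectation; markers with
   p < 0.001 are dropped. The continuity correction is omitted because the
   design has n ~ 250 informative calls per marker; the choice is recorded
   in the QC report. Only two-class markers are tested — the 1:1 null does
   not apply to ab x ab codes.
3. **Collinearity pruning**: before the multi-marker fit, one member of any
   same-group pair closer than 1 cM with |r| > 0.7 (Pearson on the 0/1
   codes, pairwise-complete) is removed. Absolute correlation is used; the
   sign of a 0/1 correlation is an arbitrary coding artifact. Tie-break:
   drop the member with more missing data, then the later marker in map
   order. Pairs are visited in map order, so the result is invariant to
   input column order.

## Map summaries

`summarize_map()` reports per-group marker counts, lengths, average
adjacent-marker distance, and maximum gap, plus a total row. The average
distance convention is **length / marker count**, not length/(count-1):
published per-group averages for maps of this design reproduce only under
this convention (e.g. 154.4 cM / 42 = 3.7; 1986.2 / 486 = 4.1), so the
package adopts it and keeps full precision alongside a half-up 1-decimal
display column (`round_half_up()`; base R's half-to-even disagrees on exact
ties). The bundled published tables (`fir_map_table()`, `fir_qtl_table()`)
carry one known source inconsistency: the P236 per-group lengths sum to
1933.1 while the printed total is 1932.8. The package reports full-precision
sums and does not reproduce the printed rounding error.

## The regularized horseshoe scan

For one trait and one parental marker set, with the response standardized
and marker columns standardized (missing genotypes mean-imputed per marker,
a neutral choice for codes already filtered to <= 20% missingness):

$$y = \beta_0 + X\beta + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2)$$

with the regularized horseshoe prior on the coefficients:

$$\beta_j \sim N(0, \tau^2\tilde\lambda_j^2),\qquad
  \tilde\lambda_j^2 = \frac{c^2\lambda_j^2}{c^2 + \tau^2\lambda_j^2},\qquad
  \lambda_j \sim C^+(0,1),$$

$$\tau \sim C^+(0, \tau_0),\qquad
  c^2 \sim \text{scaled-inv-}\chi^2(\nu, s^2).$$

The global scale is calibrated by the expected number of relevant markers:
$\tau_0 = \frac{p_0}{D - p_0}\frac{\sigma}{\sqrt n}$, with `p0 = 5` by
default (tree QTLs are typically many and small) and `sigma_proxy = 1`
because the response is standardized. Slab defaults are scale 2 and 4
degrees of freedom — a weakly informative bound on how large any single
standardized effect can be; the intercept has a flat prior and
$\sigma^2$ a unit-scale, 1-df scaled-inverse-chi-square. All of these are
explicit `hs_config()` values, not hidden package defaults.

### The sampler

The posterior is sampled by a blocked scheme chosen so that every update is
exact (no discretization, no approximation to the target):

* $\beta$ | scales: the closed-form ridge conditional
  $N(A^{-1}X^\top y/\sigma^2, A^{-1})$,
  $A = X^\top X/\sigma^2 + \mathrm{diag}(1/\tau^2\tilde\lambda^2)$, drawn
  via a D x D Cholesky, or via the n x n auxiliary construction when
  D > 2.1 n (cheaper for very wide designs);
* $\sigma^2$: conjugate inverse-gamma; intercept: conjugate normal;
* $\log\lambda_j$: **collapsed** slice updates — each local scale is
  sampled with its coefficient integrated out analytically (the
  conditional marginal is Gaussian in $\beta_j$), after which $\beta_j$ is
  redrawn from its conjugate conditional. Integrating the coefficient out
  lets a local scale jump between the shrunk and active regimes directly,
  the transition that a centered update makes vanishingly rarely when
  $\beta_j$ is currently near zero. The slab couples the scales in a way
  that breaks the classical inverse-gamma auxiliary conjugacy of the plain
  horseshoe, which is why slice sampling of the exact conditionals is used
  throughout rather than auxiliary-variable Gibbs;
* $\log\tau$, $\log c^2$: slice updates of their exact conditionals, plus
  an **interweaved (ASIS) update for $\tau$** — a second slice update in
  the non-centered parameterization $z_j = \beta_j/\mathrm{sd}_j$, where
  the likelihood rather than the conditional prior informs the move;
* a **pairwise swap move** exchanging $(\beta_j, \lambda_j)$ between
  tightly correlated markers (|r| > 0.4), a symmetric proposal accepted on
  the likelihood ratio, which lets the posterior hop between the
  near-equivalent modes that arise when linked markers compete for one
  signal.

The whole scale block (collapsed local scales, global scale, slab,
interweaved $\tau$) is repeated four times per coefficient-block draw: it
costs a small fraction of the $\beta$ update, and the global scale — whose
conditional is an order of magnitude narrower than its marginal because
hundreds of freshly drawn coefficients pin it — is the slowest-mixing
coordinate otherwise.

Four chains of 5000 retained draws after 1000 warmup iterations are the
reference configuration; convergence is checked with split-R-hat on every
coefficient plus intercept, $\sigma$, and $\tau$ at threshold 1.1, and the
pipeline halts before selection when the check fails. The simulation-heavy
tests and the acceptance script use two chains of 800 after 400 — the
package's scaled-down configuration for repeated-simulation studies, which
the convergence diagnostics still gate.

Correctness is not asserted by construction alone: on one- and two-marker
problems the MCMC marginals are compared against `hs_quadrature()`, an
independent dense-grid integration of the identical posterior (coefficients
marginalized in closed form, scales integrated on a log-grid), and the
frozen-scale coefficient update is compared against the closed-form ridge
posterior. A pure-R reference implementation of the same scheme
(`engine = "r"`) is kept alongside the compiled chain and validated against
the same oracle.

## Model gating and selection

**PSIS-LOO gate.** Marker effects are only interpreted when the reference
model predicts better than an intercept-only null. Leave-one-out expected
log predictive density is estimated by Pareto-smoothed importance sampling:
per observation, the largest 20% of importance ratios are replaced by
quantiles of a generalized Pareto distribution fitted to them
(Zhang-Stephens profile posterior mean with a weak stabilizing prior),
truncated at the raw maximum; shape diagnostics above 0.7 are flagged. The
gate opens when `elpd(ref) - elpd(null) > 2 SE(diff)`; the threshold
"significantly more information" is quantified as k = 2 (configurable)
since no standard rule exists. When the gate is closed the trait yields
zero QTLs.

**Projection-predictive forward search.** Because linked markers are
correlated, marginal posteriors from the reference fit are biased
yardsticks for individual markers. Instead, each posterior draw's fitted
mean is projected by least squares (the KL-minimizing projection under a
Gaussian likelihood) onto candidate submodels; the projected residual
variance absorbs the per-draw projection discrepancy. The greedy search
ranks markers by discrepancy reduction against the reference's mean fitted
values, capped at `2 p0` markers. The chosen size is the smallest whose
projected predictive score is within one standard error of the reference's
score. Both scores are leave-one-out quantities: the reference's PSIS-LOO
elpd, and for each submodel the LOO elpd obtained by reweighting its
pointwise predictive densities with the reference model's smoothed
importance weights (the submodel's predictions are a deterministic
function of the reference draws, so the reference's weights are the right
ones). Comparing LOO to LOO is deliberate: the reference's in-sample score
is optimistic by its many weakly shrunk effects by an amount no small
submodel can reach — the search would never stop against it — while an
in-sample submodel score compared against the reference's LOO elpd is
optimistic the other way and stops one to two markers early.

**Classification.** Markers in the chosen submodel are classified from the
equal-tailed credible intervals of their projected coefficients: 95%
interval excluding zero = significant (`**`), otherwise 80% excluding zero
= suggestive (`*`), otherwise unreported. Intervals come from the projected
submodel posterior, not the reference marginals, for the collinearity
reason above. Per-QTL contribution is reported as PVE = 100 R^2 of the
single-marker simple regression on the raw (unstandardized) data.

**p0 sensitivity.** `p0_sensitivity()` repeats the whole scan for p0 = 1..9
under a fixed seed policy and tabulates the detected loci per p0, for
stability inspection rather than formal testing.

## Fluorescence traits and the correlation network

Chlorophyll-fluorescence parameters are computed from dark- and
light-adapted PAM readings: Fv/Fm = (Fm - F0)/Fm, Phi_II = (Fm' - Fs)/Fm',
NPQ = (Fm - Fm')/Fm', Phi_NO = Fs/Fm, and Phi_NPQ = Fs/Fm' - Fs/Fm. The
Phi_NPQ form is fixed by algebraic closure: it is the unique expression
consistent with the partition Phi_II + Phi_NPQ + Phi_NO = 1 given
Phi_NO = Fs/Fm (printed versions of the formula are frequently garbled, and
steady-state fluorescence is written interchangeably as Fs or Fs'; the
package uses a single `Fs` reading). Readings violating the physical
ordering Fm >= Fm' >= Fs are flagged, never silently corrected.

Trait correlations are Pearson on pairwise-complete observations (the
choice is recorded in the output's metadata attribute; complete-case
deletion is the alternative when missingness is informative), with
t-distribution p-values, and the trait network is simply the edge list at
|r| >= 0.1. Network layout is presentation, left to `plot_trait_network()`.

## Numerical and degenerate-input choices

* Zero-variance markers are dropped with a warning before fitting;
  constant traits are an error.
* Markers with zero informative calls get their own QC decision
  (`dropped_no_calls`) rather than a division by zero.
* Constant chains give split-R-hat 1 and are flagged degenerate.
* A non-finite coefficient draw aborts the chain with its iteration number.
* All seeds below 2^31; every chain, simulation stage, and pipeline run
  derives independent sub-seeds deterministically from one user seed, and
  identical configuration + seed reproduces outputs byte-identically.
* Slice samplers use stepping-out with width 1-2 on the log scale, capped
  at 30 expansions.

## Problem sizes used by the test-suite studies

The recovery and calibration studies in the tests and the acceptance script
use the full assumed design (n = 252, 12 linkage groups, ~500 markers per
parental map before QC, five QTLs of 5-9% PVE) over 20 seeds, with the
scaled-down two-chain sampler configuration; the sampler-vs-quadrature
check uses D = 2, n = 30; the PSIS-LOO check uses n = 50 with 4000 draws.

One property of the PVE column deserves emphasis: the single-marker R² has
a sampling SD of roughly 2.5 percentage points at n = 252, and because a
locus is more likely to be detected in samples where its realized effect is
large, the PVE of detected QTLs is inflated on average by a comparable
amount (winner's curse). The estimator itself is unbiased at the causal
markers unconditionally; reported PVEs for detected loci should be read as
mildly optimistic.

## Known limitations

* Scans are per trait and per parental map; no multi-trait or joint-parent
  model, no epistasis, and no QTL-interval estimation beyond single-marker
  positions. Co-located QTLs across traits are reported as pairwise
  distances, not tested.
* The linkage map is an input: the package summarizes maps but does not
  build them (grouping/ordering is the province of dedicated mapping
  software).
* PSIS-LOO is computed on the standardized scale; elpd differences (the
  only quantities used) are invariant to that choice.
* With fewer than ~3 chains and short runs, split-R-hat has limited power;
  the reference four-chain configuration is recommended for real analyses.
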