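---
title: "Linking early expression to late phenotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking early expression to late phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsig)
```

## The modelling problem

A diet-intervention time course measures replicated tissue expression
(log2 ratios against the normal-diet group) at weeks 3 through 18 and a
phenotype panel — body weight, blood glucose, eight pro- and three
anti-inflammatory cytokines — per group and week. Each phenotype's
HFHSD-vs-ND difference plateaus at a *critical week* (15 for weight, 12
for glucose, 9 for cytokines); the scientific question is whether week-3/6
expression already predicts the critical-week value.

The statistical obstacle is shape: a handful of observations (groups ×
two input weeks) against hundreds of correlated genes. Partial least
squares is the standard answer in this regime: it projects `X` and `Y`
onto a few latent components chosen to maximize covariance, remains
defined for n ≪ p, and ranks genes by the VIP score. We implement PLS
regression (continuous responses); indicator-coded class responses work
through the same interface.

## The PLS engine

**Algorithm.** NIPALS with mean centering and unit-variance scaling.
NIPALS is chosen over SVD-based algorithms because the union week
protocol produces structurally missing cells, and the NIPALS inner
regressions extend to available-data projections: every inner product is
taken over observed entries and normalized by the observed weight mass.
With complete data the fit coincides with standard PLS2 (the test suite
checks coefficients against an independent implementation at 1e-6
relative tolerance).

**Diagnostics.** `R²X`/`R²Y` are cumulative explained variances in the
scaled space. `Q²(A) = 1 − PRESS(A)/SS` comes from 7-fold cross-validation
with a deterministic seeded shuffle and round-robin fold assignment;
residuals are measured in full-data unit-variance `Y` units so
multi-response cytokine panels weigh their responses comparably. Seven
folds is a conventional default for this model family; with eight
training rows it approaches leave-one-out.

**Component count.** The number of components grows while the marginal
`Q²` gain exceeds 0.01, capped at `min(n−1, p, 10)`. A model therefore
never carries a component with negative marginal predictivity.

**VIP selection.** `VIP_j = sqrt(p · Σ_a SS_a w_aj²/Σ_a SS_a)` with
unit-norm per-component weights, so mean squared VIP is identically 1.
The default cutoff 1 is the usual greater-than-average-influence rule;
genes above it are refit as the signature. The `Q² > 0.5` gate on the
refit model decides worked/not-worked, and under the `auto` protocol an
intersection failure triggers a union retry.

**Degenerate inputs.** Zero-variance columns are dropped with a warning.
When deflation exhausts `X` (rank reached, common under heavy
missingness), component extraction stops early and the model is truncated
rather than propagating a singular coefficient system; trailing
components are also dropped if the `P'W` system becomes ill-conditioned.
Ties in probe deduplication go to the lexicographically smallest probe id
so results are order-independent.

## Week protocols and the design matrix

Week 3 and week 6 enter as separate observation *rows* rather than extra
columns: per-week blind predictions for the same output require week-wise
rows. The intersection protocol uses genes present in every contributing
master list and yields a complete matrix; the union protocol takes all
genes and marks a gene missing in the rows of a week whose master list
lacks it. Control-group rows are identically zero because expression is a
ratio against that group; whether the control rows join training is a
flag (`controlGroup`), included by default since the anchor at
(0, baseline) stabilizes the small-n fit. Cytokine models use the week-9
and week-12 panels as parallel response columns (16 pro-inflammatory
responses); a row-stacked alternative was considered and rejected because
it would duplicate the gene rows without adding information.

## The evaluation scheme

Two experiments measure the same phenotype on shifted scales, so observed
values from a new cohort are aligned by the line through the two anchor
points ((new ND, ref ND) and (new HFHSD, ref HFHSD)):
`reference = m·new + c` with
`m = (ref_HFHSD − ref_ND)/(new_HFHSD − new_ND)`. Note the direction: the
map sends *new*-scale values onto the *reference* scale, which is the
direction consistent with published parameter values for this scheme;
`evaluateFormulation()` also accepts an externally supplied `(m, c)` for
cohorts whose anchors are not usable. Reference ranges sit at 25% and 50%
of the ND→HFHSD gap; boundary values classify into the milder class
because the disease class is defined by strictly exceeding its threshold.
Converted values are rounded to 2 decimals for display only.

## The synthetic study generator

The generator emulates the study conditions: five groups (ND, HFHSD and
three doses of a protective formulation), weeks 3–18 in steps of 3, three
replicate arrays per cell, and a few-observations/many-genes shape.
Fixed design choices:

- **Group severities** 0 (ND), 1 (HFHSD), 0.85/0.45/0.15 for the low,
  medium and high dose: dose-dependent protection with the high dose near
  the control state.
- **Signature genes** carry `d_g(b_g + a_g·severity)` with direction
  `d_g = ±1`, diet-shared offset `b_g ~ U(1.3, 1.8)` and severity
  amplitude `a_g ~ U(1.0, 2.0)` (log2 units), week-stationary. The offset
  keeps planted genes above the two-fold filter in every fed group (a
  diet-background effect), so the intersection protocol can see them; the
  amplitude encodes the predictive part.
- **Phenotypes** are `baseline(week) + ramp(week) · Σ_g c_g ω_g`, where
  `ω_g` is the realized mean week-3/6 cell-level expression,
  `c_g = gap · d_g/(n_sig(b_g + a_g))` so full severity spans the
  ND→HFHSD gap, and the ramp rises as a saturating exponential that
  reaches exactly 1 at the critical week ("the difference becomes
  constant"). With noise → 0 the critical-week phenotype is an exact
  linear function of planted expression — the parameter-recovery oracle.
- **Noise** is additive Gaussian in log2 space with one dial
  (`noiseSd = 0.1` by default) for both replicate scatter and cell-level
  biological variation; the simplest model consistent with log-ratio
  data.
- **Probe artifacts.** A fraction (default 0.1) of genes get a second
  probe with its own uniform(0, 0.05) p-value (only the ordering matters
  for min-p dedup); a fraction (default 0.1) of non-signature probes get
  equal-magnitude replicates with one sign flipped, deterministically
  triggering the consistency filter. Planted probes stay consistent so
  ground truth remains recoverable.
- **Phenotype replication.** One value per (group, week), as such studies
  report; replicate-level phenotype noise is not modelled.

What the generator does *not* emulate: raw probe intensities, array batch
effects, upstream GCRMA/quantile normalization, gene-gene correlation
structure beyond the single severity factor, and nonlinear
gene→phenotype links. Passing tests therefore demonstrate correctness of
the machinery under a linear single-factor world, not that real tissues
obey one.

## Problem sizes and test design

The test suite works at the study's own scale: 8 training rows (4 groups
× 2 weeks), 60–300 genes, 8–20 planted. Oracles are independent of the
code paths they check: OLS recovery of planted coefficients uses a
30-group design (20 coefficients need more than 20 observations),
leave-one-out PRESS is recomputed from explicit single-component formulas,
network statistics are recomputed from adjacency matrices by brute force,
and the power-law fit is checked on exact synthetic `P(k) ∝ k^(-2.5)`
counts. Null behaviour of `Q²` is established over 100 permuted-response
fixtures.

## Known limitations

- With 8 observations and hundreds of null genes, chance correlations are
  large: VIP > 1 recovers essentially all planted genes (recall ≈ 1 in
  simulation) but also admits many null genes, so selection *precision*
  is low at this n. The refit model still predicts well because the null
  genes carry little weight; gene lists from so few observations should
  be read as enriched, not pure.
- `Q²` conventions differ across PLS software (fold grouping, per-
  component limits); the 7-fold/0.01 choices here are documented defaults,
  not a reproduction of any proprietary scheme.
- The network module's statistics reproduce published formulas; hub-count
  rounding follows `max(1, floor(n·fraction))`, a documented convention
  (published hub counts are not always mutually consistent), and hubs are
  selected by degree with clustering coefficients reported alongside.
- The linear two-point conversion assumes the two cohorts differ by an
  affine shift only; cohorts whose printed conversion parameters
  disagree with their anchors must be handled by supplying `(m, c)`
  directly.
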