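---
title: "Methods: a toggle-switch model of CAR-T kinetics and its analysis pipeline"
author: "cartqsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a toggle-switch model of CAR-T kinetics and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

Chimeric antigen receptor (CAR) T-cell therapy shows enormous
patient-to-patient variability in expansion, persistence and tumor response.
`cartqsp` implements a mechanistic explanation: a small ODE system in which a
saturable, antigen-driven *toggle switch* coordinately controls T-cell fate.

The state comprises two dose-transfer compartments (`dose`, `dosex`), three
functional T-cell classes — memory (`t_m`), effectors split into a
non-cytotoxic precursor pool (`t_e1`) and a cytotoxic pool (`t_e2`), and
exhausted cells (`t_x`) — plus the tumor B-cell burden (`b`) and a tumor
antigen surrogate (`b_a`). All Hill switches share one half-maximum `b50` in
antigen units but carry fate-specific exponents (`km`, `kr`, `ke`, `kx`;
tumor killing uses `tk50`/`kt` in cells):

* memory cells self-renew when antigen is low
  (rate `mu_m`, maximum self-renewing fraction `f_max`) and differentiate
  into `t_e1` when antigen is high;
* `t_e1` converts into `t_e2` under antigen drive with a burst factor
  `2^n_doub`, representing `n_doub` population doublings collapsed into a
  single source term (`n_doub` is treated as continuous because it is
  estimated inside a continuous search box);
* `t_e2` exhausts at `k_ex` under antigen pressure and regenerates memory at
  `r_m` when antigen clears;
* the tumor grows logistically (`mu_b`, capacity `b_max`) and is killed at
  `k_kill` saturated in `t_e2`; antigen is produced from tumor at `k_b1` and
  cleared at `k_b2`, acting as a delayed sensor compartment.

Dosing is mechanistic rather than an initial condition: the infused dose
decays at `(1 + f_loss)` per day, of which a `1/(1 + f_loss)` fraction
reaches `dosex` and is routed into the four T-cell compartments at rates
`f_tm`, `f_te1`, `f_te2`, `f_tx` (1/day); their *ratios* set the product
composition. The unit-bearing coefficient of 1/day implicit on the
`dose -> dosex` influx is kept exactly as formulated, and we flag it as a
dimensional oddity of the published equations rather than repairing it.

Two published conventions are applied verbatim: an extinction clamp (any
cell population below one cell is set to exactly zero, checked at every
0.1-day grid boundary, which prevents artificial regrowth from fractional
cells) and the unit conversions (1 transgene copy/µg ≈ 1e4 circulating
cells; 2 L blood volume in humans, 2 µl in mice, for concentration scales).

### Numerical choices

Simulation uses an adaptive embedded Dormand–Prince 5(4) integrator
(compiled, `rtol = 1e-8`, `atol = 1e-4` cells) advancing interval-by-interval
on the 0.1-day output grid with the extinction clamp applied between
intervals. The only stiff phase is the dose-transfer transient (rates up to
~1000/day); it decays below the one-cell extinction threshold within the
first grid intervals and is clamped to exactly zero, after which all rates
are of order 1/day. The adaptive error control resolves the transient, and
agreement with an independent stiff solver (`deSolve::lsoda` at tighter
tolerance) and with closed forms (dose transfer, logistic tumor growth) is
part of the test suite. Antigen is initialized at quasi-steady state,
`b_a(0) = k_b1 * b0 / k_b2`, because the tumor is established before
infusion; a zero-antigen mode is retained for sensitivity checks.

## Calibration

Grouped mean profiles (CAR-T total cells and tumor cells over time, per
response group) are fit by minimizing the mean squared log10 difference
between simulation and data, with *both* sides clipped from below at a lower
limit of quantification of 1e6 total cells (points where both fall below the
LLQ contribute zero). CAR-T and tumor series are equally weighted as series;
reported standard deviations are carried for plotting and noise generation,
not as weights. Multi-arm designs share one parameter vector and differ only
in dose.

The optimizer is a global-best particle swarm (constriction 0.729, cognitive
= social weight 1.49445, velocity clamped to the box span, positions clipped
with velocity reset). Parameters whose bound ratio exceeds two decades
(`b50`, `tk50`, `b_max`, `f_loss` and all first-order rates) are searched in
log10 space; Hill exponents, `f_max`, `n_doub` and routing rates in linear
space. The published setting is 100 particles × 100 iterations, repeated 12
times per group with derived seeds; because single fits are
non-identifiable, every downstream analysis consumes the repeat ensemble.
Recovery is therefore asserted at the *trajectory* level (fitted curves
within 0.1 log10 of the generating ones at observed points), never at the
parameter level.

## Virtual populations and covariates

A virtual cohort draws, per subject, a whole fitted parameter vector
uniformly from the ensemble (sampling whole vectors preserves the
correlations that make each fit self-consistent) and randomizes dose
(log-uniform, 1e7–1e9 cells) and/or baseline tumor burden (log-uniform,
8.5e8–2.7e10 cells). Each subject is simulated for 365 days; exposure is
summarized as trapezoidal AUC and Cmax of CAR-T concentration (2 L blood
volume), and response is defined as tumor AUC below 1e4 cells·day/µl.
Univariable logistic regressions of response on log10 B0, log10 Cmax and
log10 Cmax/B0 use maximum likelihood with Wald intervals; complete
separation is reported as a flag instead of inflated coefficients.

Local parameter sensitivity uses the forward-difference coefficient
LPSC = (ΔY/Y)/(ΔX/X)·100 at a +10% perturbation, with the ensemble median
reported. Parameter PCA operates on log10 parameters with centering and
unit-variance scaling — the scaling is our choice (the source formulation
states only that logs are used) so that rate parameters spanning one decade
do not drown out half-maxima spanning four.

## Signature machinery

Single-sample gene-set scores follow the rank-based ssGSEA construction: per
sample, genes are ranked (average ranks on ties), and the score is the
integrated difference between the rank-weighted cumulative distribution of
set genes (weights `rank^0.25`, the conventional single-sample exponent) and
the uniform distribution of non-set genes. Scores depend only on
within-sample ranks. The score matrix is min-max normalized over the whole
matrix, `N_ij = (A_ij − min A)/(max A − min A)`.

Group contrasts are ranked by two-sided Welch t statistics on log2
counts-per-million (0.5 pseudocount) with Benjamini–Hochberg FDR — a
deliberate, documented stand-in for moderated-statistics pipelines, exposed
behind the same interface. Preranked GSEA uses the classical maximum running
deviation with weight exponent 1, gene-label permutations (default 1,000,
seeded), NES normalized by the mean same-sign permutation magnitude and
P = (1 + #{|ES_perm| ≥ |ES|})/(n_perm + 1), so the smallest attainable P is
1/(n_perm + 1). The scorecard summarizes each signature × dataset cell as
−sign(NES)·log10 P. Cross-dataset overlap of significant signatures is
tested with the exact binomial tail P(X ≥ k), X ~ Bin(n, m/M). Pseudobulk is
raw-count summation per sample.

## Response classifier

Features are normalized ssGSEA scores (or phenotype frequencies); the model
is a logistic regression on a feature subset chosen by a generational
genetic algorithm (population 100, per-bit mutation 0.001, immigration 0.3,
elitist reproduction 0.1, uniform crossover, rank-weighted parents). Fitness
is training AIC with training accuracy as tie-break — our resolution of the
ambiguous pairing of AIC with accuracy in the source description — and
subsets are capped at 8 features, consistent with the 2–6-feature models the
controls imply. Cross-validation repeats stratified 60:40 train/test splits
(stratification is our addition: with 5-vs-21 class sizes an unstratified
split can lose a class entirely), re-running the GA per split, with 2,500
iterations at published scale and 250 in the bundled benchmarks. Controls:
random 2–6-signature models drawn from the non-candidate compendium with
sizes matched to the observed selected-size distribution, and a label-free
null that predicts by coin flip. Distributions are compared by two-sided
Wilcoxon rank-sum tests; prediction threshold is 0.5; per-feature inclusion
frequency across iterations summarizes selection.

## Synthetic data: what it does and does not emulate

The generators make every stage runnable and testable without downloads:

* `gen_pk_study` simulates grouped trajectories from known archetype
  parameters, samples them at clinical-style visit times (days 3–90) and
  applies multiplicative lognormal noise (mean-one, configurable CV, default
  10%) with `sd = CV × mean` attached. Noise-free mode reproduces the model
  exactly, which pins down the calibration oracle.
* `gen_expression_cohort` draws gamma-mixed Poisson (negative-binomial-like)
  counts, with genes of the designated informative sets shifted on the log
  scale by a configured multiple of the within-group standard deviation in
  the responder class; the compendium contains disjoint informative sets and
  random background sets from the same universe.
* `gen_cell_cohort` allocates cells to samples with logit-normal phenotype
  frequencies separated between groups, supporting pseudobulk-consistency
  and bivariate-classifier checks.

The archetype presets ("CR-like": high memory proliferation, potent killing
at low `tk50`, slow exhaustion; "NR-like" the reverse) are package-defined
points inside the calibration box that reproduce the qualitative clinical
pattern — responders expand ~100-fold, clear tumor and stay largely
non-exhausted at day 60, non-responders fail to expand and exhaust. They are
not fitted clinical values. The expression generator omits batch effects,
library-size artifacts, gene–gene correlation beyond set structure, and any
single-cell biology beyond phenotype frequencies; passing benchmarks on it
demonstrates the pipeline's statistical machinery, not clinical performance.
The classifier benchmark deliberately mirrors the 5-vs-21 class imbalance of
the motivating cohort because the ordering "fitted controls beat the
label-free null" is a consequence of exploitable class imbalance; with
balanced classes both controls sit at chance.

## Problem sizes and reproducibility

Bundled analyses and tests use: 12 × (100 × 100) particle-swarm repeats for
calibration; 1,000-subject virtual populations (0.25-day grid over 365
days); 250-iteration classifier benchmarks on a 26-sample, 30-signature
cohort; 1,000 gene-label permutations for GSEA (300–500 in fast checks).
Every stochastic step is a pure function of an explicit integer seed, and
workflow outputs are reproduced bit-exactly for a fixed configuration.

## Known limitations

* Parameters are structurally non-identifiable from mean profiles; all
  conclusions are ensemble-level. No profile likelihood or Bayesian
  uncertainty is attempted.
* The dosing subsystem's printed dimensional inconsistency is preserved
  as formulated.
* Exhausted cells do not feed back on antigen dynamics, per the printed
  equations.
* The Welch-t ranking statistic approximates, but does not replicate,
  moderated differential-expression pipelines.
* For certain extreme parameter combinations inside the search box the
  effector burst (`mu_e * 2^n_doub`) combined with memory regeneration
  forms a positive feedback loop while antigen transits the toggle window;
  trajectories remain finite and integrable but can reach biologically
  implausible magnitudes. Fitted ensembles avoid these regimes because the
  data penalize them.
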