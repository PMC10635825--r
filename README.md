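# cartqsp

Quantitative systems pharmacology of CAR-T cell therapy: why do patients
receiving the same engineered cell product at the same dose show orders of
magnitude of difference in cell expansion and opposite tumor outcomes? This
package implements a mechanistic answer and the analysis pipeline around it,
for modelers and computational biologists working on cell-therapy
pharmacology:

1. **A toggle-switch ODE model of CAR-T cellular kinetics.** Memory
   (T_M), effector (T_E1, T_E2) and exhausted (T_X) T cells, tumor B cells
   (logistic growth, saturable killing) and a tumor-antigen sensor
   compartment B_A. A Hill-type antigen switch with shared half-maximum B50
   coordinately gates memory self-renewal vs differentiation
   (mu_M, f_max), effector proliferation with a 2^N burst, exhaustion
   (k_ex) and memory regeneration (r_M). Infused dose transfers through a
   loss step (1/(1+f_loss) reaches circulation) and is routed into the four
   compartments at rates whose ratios set product composition. Cell
   populations dropping below one cell are clamped to exactly zero.
2. **Calibration** of all 27 parameters to grouped mean profiles
   (complete/partial/non-responders or dose arms) by particle swarm
   optimization of a log10 mean-squared-error objective with a 10^6-cell
   quantification floor, repeated 12× per group to form parameter
   ensembles that carry the non-identifiability.
3. **Virtual populations**: Monte Carlo cohorts over fitted ensembles with
   log-uniform dose (10^7–10^9 cells) and baseline tumor burden
   (8.5×10^8–2.7×10^10 cells), exposure metrics (AUC, Cmax), logistic
   response-covariate analysis (response = tumor AUC < 10^4 cells·day/µl),
   local parameter sensitivity (LPSC) and log-parameter PCA.
4. **Signature machinery**: ssGSEA scoring, global min-max normalization
   N_ij = (A_ij − min A)/(max A − min A), pseudobulking, preranked GSEA
   with permutation P values, the scorecard statistic
   −sign(NES)·log10 P, and exact binomial overlap tests.
5. **A response classifier**: logistic regression on signature scores with
   genetic-algorithm feature selection (population 100, mutation 0.001,
   immigration 0.3, reproduction 0.1; AIC fitness), evaluated over repeated
   stratified 60:40 splits against random-pathway and null controls.
6. **Synthetic data generators** that emulate the statistical structure of
   all inputs (noisy grouped trajectories from known parameters; expression
   cohorts with designated informative gene signatures; single-cell cohorts
   with group-separated phenotype frequencies), so the entire pipeline runs
   and is tested without any external data.

See `vignettes/cart-qsp-methods.Rmd` for the model equations in prose, all
tunable parameters and the design decisions.

## Worked example

Simulate a responder-like and a non-responder-like product and compare
their kinetics:

```r
library(cartqsp)
tr <- simulate_cart(archetype_params("CR"), sim_config(t_end = 365))
em <- exposure_metrics(tr, 365)
cs <- state_composition(tr, 60)
c(cmax = em$cmax, tmax = em$tmax, tumor_auc = em$tumor_auc,
  pct_non_exhausted_d60 = cs$percent_non_exhausted)
#>                  cmax                  tmax             tumor_auc
#>             459.98019              12.80000           10566.83308
#> pct_non_exhausted_d60
#>              99.99996
```

A CR-like product expands to a peak of ~460 cells/µl at day 13
(~100-fold over the post-loss dose), drives tumor burden down (tumor AUC
~10^4 cells·day/µl instead of ~8×10^6 for the NR archetype) and is
essentially non-exhausted at day 60; the NR archetype peaks at ~28 cells/µl
and its T cells are ~60% exhausted by day 60 (run
`analysis/01_simulate_archetypes.R` for the full comparison table).

The numbered scripts under `analysis/` chain the full study on synthetic
data and narrate their findings: `01` archetype simulations, `02` repeated
swarm calibration (`--quick` for a fast pass), `03` virtual population,
covariates, sensitivities and PCA, `04` ssGSEA scorecard and overlap tests,
`05` classifier benchmark with controls. For example:

```sh
Rscript analysis/05_classifier.R --seed 1
#> Median cross-validated accuracies:
#>   ga_transcriptome   1.00
#>   fixed_bivariate    1.00
#>   random_pathway     0.80
#>   null               0.50
#> rank-sum P, transcriptome vs random pathways: 1.4e-97
```

On a 5-responder vs 21-non-responder synthetic cohort with 5 of 30
signatures truly informative, the GA-selected transcriptome classifier
dominates; random-pathway models only learn the majority class (0.80) and
the label-free null sits at chance.

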