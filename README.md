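# beeniche

Comparative niche modelling for Red List macroecology: do threatened and
non-threatened species relate to their environment differently?

`beeniche` implements, as a tested and reusable pipeline, the analysis design
behind comparative studies of threatened (Red List, RL) versus non-threatened
(Least Concern, LC) wild bees: a maximum-entropy species distribution model is
fitted per species, its variable importance is partitioned into land-use,
climate and soil contributions, and the per-species summaries (range size,
climatic extremeness, response directions) feed a group-level statistical
comparison of the two Red List classes. A synthetic-landscape generator with
known niche truth makes every stage testable end to end without any data
download. It is aimed at spatial ecologists and Red List practitioners who
want the mechanics of such a comparison — not a specific country's data —
as an auditable, scriptable package.

## The model

Each species is modelled presence-vs-background with a maximum-entropy (Gibbs)
distribution over environmental feature space,

```
p(x) ∝ exp( Σ_j λ_j f_j(x) ),
```

where the features `f_j` are linear (L), quadratic (Q), product (P), hinge (H)
and threshold (T) transforms of the predictors, rescaled to [0, 1] over the
training background. Coefficients maximise the L1-penalised log-likelihood

```
mean_presences(λ·f) − log Z(λ) − β Σ_j s_j |λ_j|
```

with per-feature smoothing weights `s_j` (sample-size- and class-dependent
defaults) and a regularization multiplier `β`. Candidate models over a grid of
`β` (1..15) and feature-class sets (L, LQ, H, LQH, LQHP, LQHPT) are compared
by AICc (raw scores standardised over the masked study grid, `k` = non-zero
coefficients), with spatial-block cross-validation (four median quadrants)
supplying test AUC, the continuous Boyce index and omission rates; exact AICc
ties are broken by the 10% training omission rate. Suitability is reported on
the cloglog scale `1 − exp(−exp(H + score − log Z))`.

Downstream, per species: permutation importance (drop in training AUC when a
variable is shuffled across the pooled presence + background sample,
normalised to percentages and summed per predictor category), marginal
response curves (other variables at their background median) classified
positive/negative when |Spearman ρ| ≥ 0.7, convex-hull extent of occurrence
(EOO, km²), and climatic extremeness (species mean of each bioclim variable in
landscape SD units). The group layer compares LC and RL species with rank-sum
tests, Kruskal–Wallis + Dunn post hoc (Holm-corrected), Cochran–Mantel–
Haenszel response-ratio tests with Fisher post hoc, and AICc-selected
parametric plus rank-based regressions of category importance on EOO and
status.

## Worked example

```r
library(beeniche)

study <- generate_study(synthetic_config(seed = 1, nx = 80, ny = 80,
                                         n_specialist = 4, n_generalist = 4,
                                         n_obs_range = c(30, 80)))
cfg <- study_config(n_background = 1000,
                    grid = tuning_grid(beta = c(1, 2), classes = "LQ"),
                    n_permutations = 5, tol = 1e-5, seed = 1)
report <- run_study(study, cfg)
print(report)
#> <group_comparison_report> 8 species modeled (4 LC, 4 RL); 0 skipped
#> summed permutation importance (mean % LC vs RL):
#>  category mean_lc mean_rl p_dunn p_adjusted
#>  land_use   79.85    6.13 0.0209     0.0628
#>   climate   15.42   91.87 0.0209     0.0628
#>      soil    4.73    2.00 0.0833     0.0833
#> extent of occurrence: W = 16, p = 0.0286
```

The synthetic study plants climate-specialist species (labelled RL, quadratic
niches with optima 1.5–2.5 landscape SDs off the landscape mean) and land-use
generalists (labelled LC): the report recovers the planted structure — land
use dominates the LC models (79.9% vs 6.1% mean summed importance), climate
dominates the RL models (91.9% vs 15.4%), and the LC species occupy a larger
extent of occurrence (rank-sum W = 16, p = 0.029). `glance()` on a fitted
model shows its complexity, e.g. 20 of 42 LQ features non-zero at β = 2 for
the first species. `write_report()` emits the per-species summary CSV, tidy
importance/response tables, and the comparison layer as JSON plus text.

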