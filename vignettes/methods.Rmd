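---
title: "Methods: comparative maximum-entropy niche modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative maximum-entropy niche modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(beeniche)
```

`beeniche` asks a comparative question of species distribution models: when
the same presence-background model family is fitted to every species in a
fauna, do threatened (RL) and non-threatened (LC) species differ
systematically in *which* parts of the environment their models lean on?
This vignette documents the model, its tunable parameters, the numerical
choices, what the synthetic-data generator does and does not emulate, and the
design decisions taken where the design was genuinely open.

## The maximum-entropy model

Presence-background modelling treats the environment at occurrence records as
a biased sample of the available environment (a uniform background draw from
the masked study area). The model is the Gibbs distribution over background
cells

$$p_\lambda(x) \propto \exp\Big(\sum_j \lambda_j f_j(x)\Big),$$

the maximum-entropy distribution subject to matching the presence means of
the features $f_j$. Feature classes follow the conventional L/Q/P/H/T
expansion: identity, squares, pairwise products, forward and reverse hinges,
and step functions. Hinge and threshold knots are evenly spaced strictly
inside each variable's training range (25 per direction by default; a
configurable compromise between a dense basis and desk-scale fitting).
Every feature is min-max rescaled to $[0,1]$ over the training background and
prediction-time inputs are clamped to the training range, so the model never
extrapolates a feature beyond what it saw.

Fitting maximises the L1-penalised log-likelihood
$\overline{\lambda\!\cdot\!f}_{\text{pres}} - \log Z(\lambda) -
\beta\sum_j s_j|\lambda_j|$. The per-feature smoothing $s_j$ defaults to an
interpolated, feature-class-specific base rate (linear/quadratic/product
rates fall with presence sample size; hinge is constant 0.5; threshold falls
from 2 to 1) times the feature's presence standard deviation on the
$1/\sqrt{m}$ scale — the published default structure for this model family.
The presence SD is floored at $1/\sqrt{m}$ so a feature that happens to be
constant on presences cannot become an unpenalised separating direction.

The optimiser is FISTA (accelerated proximal gradient) with backtracking line
search, soft-thresholding for the L1 term, and adaptive restart; it stops at
a relative objective change of `tol` (default 1e-6) or 500 iterations,
returning the best iterate flagged `converged = FALSE` if the tolerance was
not met. The unpenalised optimum satisfies per-feature moment matching
(checked in the tests to 1e-4), and the training-background raw scores always
normalise to one. Suitability output defaults to the bounded cloglog
transform $1-\exp(-e^{H+\text{score}-\log Z})$, with $H$ the entropy of the
training-background distribution; cloglog and raw are monotone in the score,
so every rank-based quantity downstream (AUC, Boyce, response classification)
is identical under either.

## Model selection and evaluation

Candidates span `tuning_grid()`: regularization multipliers 1..15 crossed
with the six feature-class sets L, LQ, H, LQH, LQHP, LQHPT. Selection is by
lowest AICc, where the likelihood uses raw scores standardised to sum to one
over the masked study grid (a `scope = "background"` variant is available;
the grid is the default because the likelihood then refers to the same area
the model is interpreted over) and $k$ counts non-zero coefficients.
Candidates with $k \ge n-1$ have no defined AICc and are excluded. Exact
AICc ties fall back to the lowest 10% training omission rate, then to the
simpler model (fewer non-zero coefficients, then lower $\beta$).

Evaluation metrics come from spatial-block cross-validation: presences are
split into the four quadrants of their median longitude and latitude (ties on
a median line go to the lower-indexed quadrant), three quadrants calibrate
and one evaluates, rotating. Reported per candidate: mean test AUC
(Mann-Whitney, ties half), mean continuous Boyce index, and the MTP and 10%
omission rates. The 10% threshold excludes `ceiling(0.1 * n_train)` lowest
training scores and uses the smallest retained score as threshold — the
ceiling rule matches common practice and makes the boundary case exact. The
Boyce index uses 101 overlapping windows of width one tenth of the
suitability range; repeated predicted-to-expected ratios are collapsed to
their first occurrence before the Spearman correlation, the usual convention
that stops runs of identical ratios (typically zeros below the occupied
range) flooding the rank correlation with ties. The selected candidate's
full-data fit — fitted during tuning on every presence with the shared
background — is the final model; cross-validation supplies metrics only.

## Importance, responses, and per-species summaries

Permutation importance shuffles one variable's values across the pooled
presence + background sample, re-predicts, and records the drop in training
AUC; drops are averaged over 10 shuffles (a repeated average rather than a
single permutation, for stability), floored at zero, and normalised to sum
to 100%. Category sums over land use, climate and soil partition that total.
Marginal response curves sweep one variable across its training range (100
points) with all other variables at their training-background median; the
response is called positive when Spearman $\rho \ge 0.7$, negative when
$\rho \le -0.7$, and none otherwise — the signed reading of the 0.7 rule,
the only one under which negative responses can be reported at all. A
variable with no non-zero feature coefficient is classed `none` without
computing $\rho$.

Per species the pipeline also records: convex-hull extent of occurrence
(shoelace area in km²; fewer than three distinct or collinear points give a
flagged 0), mean location offset from the pooled mean of all observations
(km east/north), mean natural land cover at observation cells (the summed
percent cover of layers flagged natural), and climatic extremeness — the
absolute distance of the species' mean from the landscape mean in landscape
SD units, per bioclim variable (a signed variant is available by flag;
absolute is the default since "extremeness in either direction" is the
quantity being compared).

EOO, location, natural cover and climate deviation use the *raw* (unthinned)
records by default, with a thinned option: these are observation statistics,
not model inputs, and discarding records would only coarsen them.

## Group comparisons

Two-group comparisons (EOO, location, natural cover) use the two-sided
rank-sum (Mann-Whitney) test — exact when both groups have at most ten
untied values, otherwise the tie-corrected normal approximation. Climate
deviations and importance sums are compared by Kruskal-Wallis with pairwise
Dunn z-tests on pooled ranks, Holm-corrected within each family (the three
categories form one family; each category's variables form another). The
positive:negative response ratio is compared by a continuity-corrected
Cochran-Mantel-Haenszel test pooling the per-variable 2×2 tables within a
category, with two-sided Fisher exact post-hoc tests per variable
(Holm-corrected). The CMH statistic is computed directly from the
hypergeometric moments so single-stratum families are handled uniformly.

Category importance is regressed on EOO and RL status with three candidate
formulas (EOO only, status only, both), fitted by ordinary least squares and
by rank-based R-estimation with Wilcoxon scores (Jaeckel dispersion
minimisation; intercept from the median residual; the scale parameter
$\tau = 1/(\sqrt{12}\int f^2)$ estimated from a Gaussian-kernel density of
the residuals, giving a drop-in-dispersion F-test and a dispersion-reduction
$R^2$ analogue). The reported candidate is the one with the lowest Gaussian
AICc of the parametric fit, $k$ counting intercept, slopes and the residual
variance.

## The synthetic-data generator

The generator's role is to produce data with the statistical structure the
analysis assumes, with a known answer:

* **Climate** — six surfaces built from linear gradients in rotated
  directions (spread over half a turn, so no gradient pair is collinear)
  plus smooth Gaussian-field noise with a long correlation length. A field
  that happens to align with an earlier variable is redrawn, keeping every
  retained pair under the 0.7 screening cut-off by construction.
* **Land use** — 10 percent-cover layers from a spatially clustered softmax
  allocation over short-range latent fields; covers per cell sum to at most
  100 and small covers truncate to zero, so the number-of-land-uses layer
  varies. Five layers are flagged natural.
* **Soil** — quantile bins of one long-range field, giving contiguous
  regions encoded as binary indicator layers.
* **Species** — climate specialists carry a quadratic niche on one climate
  variable with the optimum planted 1.5–2.5 landscape SDs from the landscape
  mean (labelled RL, target prevalence 0.08); land-use generalists carry
  positive linear coefficients on two or three land-use layers and zero
  climate coefficients (labelled LC, prevalence 0.25). Suitability is the
  inverse cloglog of the true linear predictor, the intercept calibrated to
  the target prevalence; presences are drawn without replacement
  proportionally to suitability and jittered within their cell. Per-species
  record counts are uniform on 30–150, mirroring a modest national recording
  scheme above the 15-record modelling threshold.

What the generator does **not** emulate: observer effort and spatial
sampling bias (presences are sampled straight from suitability, as the
modelled design assumes), temporal population trends, detection error,
taxonomic noise, or real geography. Passing recovery tests therefore shows
the *machinery* attributes importance and range structure correctly when the
world matches the model's assumptions — not that any real fauna behaves this
way, nor that recording-scheme bias would leave the contrasts intact.

Status labels derive from guild (optionally mislabelled at a configurable
rate; the default 0 keeps the planted contrast clean), not from any trend
criterion: the artifact tests the analysis, not Red List assessment rules.
The European status mirrors the national one except for a 20% Data Deficient
fraction, which exercises the three-way LC/RL/DD comparison layer.

## Numerical choices and degenerate inputs

* Temperature seasonality is $100\times$ the sample SD of the twelve
  climatological monthly means; precipitation seasonality uses the plain
  monthly mean in the denominator (the `mean_plus_one` variant is available;
  the plain mean is the default because nothing in the aggregation requires
  the arid-cell stabilisation). Zero-precipitation cells get a flagged 0.
  The wettest quarter is a consecutive 3-month window with December-January
  wraparound, ties to the earliest start.
* Collinearity screening iteratively removes, from the currently worst pair
  above the threshold, the member with the larger mean absolute correlation
  to everything else (ties drop the later variable in input order); constant
  variables drop first with a warning. The procedure is idempotent.
* Spatial thinning is a greedy randomised maximum-independent-set heuristic
  with 100 restarts, keeping the largest retained set (first found wins
  ties); it is deterministic given the seed and always maximal.
* Grids are row-major with cell centres at $(c-\tfrac12)\,\text{cellsize}$
  and 1-based cell ids, the natural indexing in R.
* Study sizes used by the test-suite and the acceptance script are desk
  scale by design: 100×100 landscapes, 1500–2000 background points, reduced
  tuning grids (LQ features, $\beta \in \{1,2\}$), five permutation repeats.
  The paper-scale defaults (10,000 background, the full 90-candidate grid,
  25 knots, 10 repeats) remain the function defaults and are exercised
  structurally by the unit tests.

## Interfaces

Rasters travel as one CSV per variable (`cell_id,x,y,value`, masked cells
only) with a JSON sidecar for grid geometry and variable metadata;
occurrences and statuses are plain CSVs; fitted models serialise to JSON
sufficient for identical re-prediction. The exported functions compose with
the pipe and `generate_study()` / `run_study()` / `write_report()` cover the
simulate / fit / report workflow end to end, so no separate command-line
wrapper is provided.

## Known limitations

The engine is not a numerical replica of any particular MaxEnt release;
coefficients agree with closed forms and independent optimisers, not with
another implementation's output bit for bit. Spatial autocorrelation beyond
the block split, phylogenetic non-independence of species, and sampling-bias
correction are out of scope. The rank-based regression inference rests on
an asymptotic $\tau$ estimate and should be read qualitatively at small n.
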