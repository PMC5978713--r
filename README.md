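# jawsearch

Automated grid search for optimal X-jaw settings in VMAT treatment planning.

## The problem

In volumetric modulated arc therapy (VMAT) the optimizer modulates the beam
with the multi-leaf collimator (MLC), but only *inside* the rectangular field
fixed by the four jaws — and the jaws themselves are set by the planner, not
by the optimizer. The choice matters: an X opening larger than the target
adds organ-at-risk (OAR) dose through inter-leaf leakage and forces long leaf
travel against the MLC's speed limits, while an over-shrunk opening starves
the target, so that after the plan is normalized back to prescription the
hotspot inflates past clinical tolerance. `jawsearch` makes the choice
systematic: it enumerates a grid of inward X-jaw offsets from a
target-conformal baseline, obtains a dose-volume histogram (DVH) set for
every candidate from a pluggable dose engine, normalizes, filters, scores and
ranks the whole cohort. It is aimed at medical-physics researchers studying
aperture sensitivity and at planners prototyping automated jaw selection.

## The score

For each OAR *i* of a candidate plan, two dose-volume products are computed
from the sampled cumulative DVH (dose samples *d_j* in Gy, cumulative
relative volumes *V_j* in %):

- **MDVP** (mean dose-volume product): `MDVP = Σ_j d_j (V_j − V_{j+1})`,
  with the trailing convention `V_{n+1} = 0`. On a fine grid `MDVP / 100` is
  the OAR mean dose.
- **HDVP** (high dose-volume product): the same sum restricted to samples
  with `d_j > d_t`, an organ-specific high-dose threshold (35 Gy for small
  bowel, 40 Gy for femoral head and urinary bladder by default, following
  RTOG 0822-style constraints).

The plan score is

```
score = Σ_i  w_i (MDVP_i + HDVP_i)  /  mean_cohort(MDVP_i + HDVP_i)
```

i.e. each organ's (equally weighted, by default) combined value is
normalized by its mean over the candidate cohort, so every organ contributes
a dimensionless relative evaluator with cohort mean 1, and the plan score
sums them. **Lower is better.** Before scoring, every plan is normalized so
the target D95 equals the prescription, and plans whose maximum dose
strictly exceeds 107% of prescription are excluded from ranking as
clinically unacceptable.

Because no treatment planning system is attached, the package ships a
parametric synthetic surrogate engine: each OAR mean dose is a convex
function of the fractional jaw opening (leakage rises with the opening,
modulation-induced dose rises as it closes, with organ-specific optima that
create realistic trade-offs), OAR curves come from a stretched-exponential
family matched to those means in closed form, and the target curve loses
coverage as the jaws encroach, reproducing the hotspot-exclusion pattern.
A jaw-invariant `predict_dvh_stub()` emulates a knowledge-based-planning
DVH predictor that does not see the actual jaws — and is therefore unusable
for discriminating apertures, which is why the pipeline always computes
final dose.

## Worked example

```r
library(jawsearch)

extent <- bev_extent(-65, 65, -75, 75)   # target BEV bounds, mm at isocenter
cfg    <- search_config(seed = 1L)       # 50 Gy, 5 mm steps, 10 offsets/bank
res    <- run_search(cfg, extent)
res
#> <search_result> 100 candidate plans (10 x 10 grid, 5 mm steps)
#>   accepted 72 | excluded (hotspot > 107%) 28 | invalid geometry 0
#>   best      plan_018  score 2.801
#>   worst     plan_012  score 3.126
#>   conformal plan_001  score 3.069
```

Of the 100 candidate jaw settings, 28 produced a post-normalization maximum
dose above 107% of the 50 Gy prescription and were excluded. Among the 72
accepted plans the best scored 2.801 and the worst 3.126; the conformal-jaw
plan (index 1, offsets 0/0) scored 3.069 — neither the best nor the worst,
i.e. conformal jaws are not the optimal choice. Per-organ statistics confirm
the cohort normalization (each organ's mean normalized score is exactly 1):

```r
subset(cohort_summary(res$table, accepted_only = FALSE),
       metric == "normalized_score")
#>        structure           metric   min  max mean     sd   n degenerate
#>      small_bowel normalized_score 0.885 1.43    1 0.1133 100      FALSE
#>     femoral_head normalized_score 0.920 1.10    1 0.0356 100      FALSE
#>  urinary_bladder normalized_score 0.926 1.16    1 0.0484 100      FALSE
```

Dosimetric endpoints of any plan are one call away (volumes in %, doses in
Gy):

```r
best <- simulate_plan(grid_setting(res$grid, 18), res$surrogate)
endpoint_metrics(normalize_to_prescription(best, "ptv", 50, 95),
                 c("V35", "V40", "mean_dose"), structures = "small_bowel")
#>    plan_id   structure    metric value
#>  jaws_5_35 small_bowel       V35 11.60
#>  jaws_5_35 small_bowel       V40  4.94
#>  jaws_5_35 small_bowel mean_dose 22.84
```

`export_heatmap(res, "heat.csv")` writes the 10 × 10 score matrix (rows =
X1 offsets, columns = X2 offsets, excluded cells marked `x`);
`run_search(..., record_dir = "records/")` persists one plain-text record
per candidate (jaw coordinates, status, normalization factor, predicted and
final DVHs) so plans themselves are disposable. `score_plans()` applies the
normalize–filter–score–rank stages to DVH CSV exports from a real planning
system, and `paired_t()` / `paired_endpoint_tests()` compare best vs
conformal endpoints across patients. A thin command-line front end is
installed as `exec/jawsearch` with subcommands `run`, `score`, `simulate`
and `compare`.

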