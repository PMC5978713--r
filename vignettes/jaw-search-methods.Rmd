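---
title: "Methods: scoring and searching VMAT jaw apertures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and searching VMAT jaw apertures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawsearch)
```

## The procedure

`jawsearch` automates a one-factor design study: how does VMAT plan quality
respond to the X-jaw aperture, all else fixed? The pipeline is

1. **Conformal baseline.** From the target's beam's-eye-view bounding box
   (mm at the isocenter plane, isocenter at the target centroid), the X jaws
   are placed on the border without margin and the Y jaws are retracted one
   adjacent MLC leaf width (5 mm by default) beyond it to capture scatter.
2. **Grid.** Each X bank is stepped inward from the conformal position in
   `step` mm increments over `n_steps_per_bank` positions *including* the
   conformal one. The Cartesian product gives `n²` candidates indexed
   row-major in (offset1, offset2), the conformal plan first. With the 5 mm /
   10-position defaults each bank travels up to 45 mm and the grid has 100
   settings. Settings narrower than `min_width` (20 mm default) are kept but
   flagged invalid rather than silently dropped, so grid bookkeeping is
   conserved.
3. **Dose.** A pluggable engine maps each setting to per-structure
   cumulative DVHs. The shipped engine is the synthetic surrogate described
   below; `score_plans()` accepts externally computed DVH CSV exports
   instead.
4. **Normalization.** Every plan is rescaled by the single factor
   `s = prescription / D95(target)` so the target meets prescription;
   volumes are untouched. D95 is a configurable convention
   (`coverage_volume`), chosen because it is the most common clinical
   coverage criterion; nothing in the method depends on the specific level.
5. **Hotspot filter.** Plans whose maximum dose strictly exceeds
   `hotspot_limit` (107% of prescription by default, following common
   clinical practice and ICRU 83-style homogeneity limits) are excluded
   from ranking. Exactly 107.0% is kept — the inequality is strict. Because
   no body contour exists in the surrogate, the maximum dose is read from a
   configurable hotspot structure, defaulting to the target; with real data
   a body or hotspot-shell structure can be supplied.
6. **Score and rank.** Per OAR, `MDVP = Σ_j d_j (V_j − V_{j+1})` (trailing
   `V_{n+1} = 0`) and `HDVP` — the same sum restricted to `d_j > d_t`
   strictly — are computed on curves resampled to a common 0.1 Gy grid.
   The combined value `w_m·MDVP + w_h·HDVP` (equal weights by default) is
   divided by its cohort mean so each organ contributes a relative evaluator
   with mean 1; the plan score sums the evaluators and accepted plans are
   ranked ascending. Exact ties resolve to the lowest plan index, making
   best/worst designations deterministic.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `prescription` | Gy | 50 | presurgical rectal protocol scale |
| `coverage_volume` | % | 95 | D95 = Rx coverage convention |
| `hotspot_limit` | % of Rx | 107 | strict clinical acceptability cut |
| `step`, `n_steps_per_bank` | mm, – | 5, 10 | 100-candidate grid, 45 mm max travel per bank |
| `leaf_width` | mm | 5 | Y-jaw scatter retraction (Millennium-120 central leaf) |
| `bin_width` | Gy | 0.1 | metric resampling grid; makes threshold sums grid-robust |
| OAR thresholds `d_t` | Gy | 35/40/40 | small bowel / femoral head / bladder high-dose regions |
| `normalization_set` | – | `"all"` | cohort used for the per-organ mean |

Two conventions deserve a note. First, the offset grid *includes* the
conformal position, so at 5 mm × 10 steps the deepest travel is 45 mm, not
50: a grid of 100 candidates that contains the conformal plan forces 10
positions per bank starting at 0. Second, the normalization cohort defaults
to **all** plans that completed dose calculation, including
hotspot-excluded ones (the cohort mean is a measurement scale, not a
quality judgement); ranking always uses accepted plans only. The policy is
configurable (`"accepted"`), and for a single OAR the choice provably
cannot reorder plans — it rescales all scores by one positive constant — a
property the test suite asserts. With several OARs the relative organ
weighting shifts slightly between policies, which is why the default is
fixed and recorded in every result object.

## The synthetic surrogate

The surrogate stands in for an optimizer-plus-dose-engine so the pipeline
is exercisable and testable end to end. It encodes qualitative structure
only — no claim of dosimetric realism — and was designed around three
behaviours jaw-aperture studies observe:

- **Convex OAR response.** With open fraction
  `a = (W0 − offset1 − offset2) / W0`, each organ's mean dose is
  `D̄_i = b_i + l_i·a + g_i·(1 − a)²`: leakage `l_i` punishes large
  apertures, the modulation penalty `g_i` punishes small ones, and the
  per-organ minimum sits at `a* = 1 − l_i / (2 g_i)`. The defaults (small
  bowel 17.3 + 6a + 15(1−a)², femoral head 8.7 + 4a + 5(1−a)², bladder
  17.1 + 7a + 8(1−a)², Gy) put the three optima at a* ≈ 0.80, 0.60 and
  0.56, so no aperture minimizes every organ simultaneously and the score
  must arbitrate — the inter-organ competition that motivates a collective
  score in the first place. Baselines were set so conformal-aperture mean
  doses land near 23, 13 and 24 Gy, typical magnitudes for rectal VMAT.
- **DVH shape.** OAR curves come from the stretched-exponential family
  `V(d) = 100·exp(−ln 2·(d/D50)^k)` — a Weibull survival with scale
  `λ = D50 / (ln 2)^{1/k}` — because two parameters span shallow-to-steep
  curves and the mean has the closed form `λ·Γ(1 + 1/k)`, so `D50` is set
  analytically from the target mean (`stretched_exp_d50()`). Shapes
  k = 2.5 / 3.5 / 2.2 give V35 ≈ 5% for small bowel, V40 ≈ 0 for femoral
  head and V40 ≈ 10% for bladder at the default means, the right order for
  this site. Curves are sampled at 0.1 Gy and truncated where the volume
  falls below 0.01%.
- **Cold target → amplified hotspot.** The target curve is flat at 100%
  with a steep linear fall-off placed so that, with encroachment
  `e = max(0, offset1 + offset2 − margin)`, pre-normalization coverage is
  `D95 = Rx·(1 − c·e/W0)` and the maximum dose is `Rx·(1.03 + c·e/W0)`.
  Normalization multiplies by `1/(1 − c·e/W0)`, so the normalized maximum
  `(1.03 + x)/(1 − x)` crosses the 107% cut once `x > 0.04/2.07 ≈ 0.0193`:
  over-shrunk jaws under-dose the target and the hotspot is amplified by
  the very normalization that restores coverage. With the default margin
  (45 mm combined travel) and cold-dose coefficient c = 0.25 on a 130 mm
  conformal field, 28 of the 100 grid settings are excluded — roughly the
  quarter of a cohort such searches lose to hotspots.
- **Noise.** Optimizer run-to-run variability is emulated by adding
  N(0, σ²) (σ = 0.3 Gy) to each OAR mean, drawn from a substream derived
  deterministically from the master seed and the (plan offsets, structure)
  pair. Cohorts are therefore bit-reproducible at a fixed seed, independent
  of simulation order, and the caller's RNG stream is never disturbed.
  σ = 0 switches the engine to a fully deterministic closed form.

`predict_dvh_stub()` returns, for *any* jaw setting, exactly the curves the
engine produces for the conformal setting: it emulates a knowledge-based
DVH predictor whose geometry-based dose model assumes target-conformal jaws
and therefore cannot see the planner's actual apertures. Its byte-identical
output across the grid is asserted in the tests; it is stored in every plan
record precisely to document that predicted DVHs cannot replace final dose
calculation in this search.

What the surrogate does **not** emulate: MLC sequencing and deliverability,
3-D dose distributions (only DVHs exist), anatomical variation between
patients, correlated OAR noise, and any absolute-volume (cc) effects.
Passing tests therefore demonstrate the pipeline's algebra, bookkeeping and
determinism — not clinical performance on real plans, which requires
attaching a real dose engine through the `score_plans()`/CSV route.

## Numerical choices and degenerate inputs

- `D_v` is the *greatest* dose with `V(d) ≥ v` (the clinical reading of
  "dose to the hottest v%"), so a flat 100% segment returns its right
  boundary and an immediate fall-off returns 0 at v = 100. The maximum dose
  of a sampled curve is the first grid point where the volume reaches a
  floor ε (default 0), i.e. the support boundary of the interpolated curve.
- All metric sums run on curves resampled to a uniform 0.1 Gy grid
  (linear interpolation; volume 0 beyond the last sample). The
  interpolation error is bounded by `L·h` with `L` the curve's maximum
  slope — asserted as a property test — and the fine 0.01 Gy grid used for
  mean-dose endpoints keeps the Riemann-sum bias below ~0.005 Gy.
- Degenerate situations raise classed errors instead of silently
  propagating: zero target dose at the coverage level
  (`jawsearch_degenerate_plan`, the plan is flagged `invalid-geometry`, not
  dropped), a fully closed aperture (`jawsearch_degenerate_aperture`), a
  zero cohort mean (`jawsearch_degenerate_normalization`), an all-excluded
  cohort (`jawsearch_empty_cohort`, with the exclusion tally in the
  message), and zero-variance paired differences
  (`jawsearch_degenerate_variance` — the paired t statistic is reported as
  undefined, never as p = 0 or 1).
- Text artifacts (DVH CSV, heat-map matrix, per-plan records) write
  numbers with 17 significant digits, so write–read cycles reproduce the
  doubles bit-exactly and re-running a seeded search reproduces every
  record byte-for-byte.

## Statistical comparison

`endpoint_metrics()` extracts `V_D` (% of structure receiving ≥ D Gy) and
mean dose (MDVP/100 on a 0.01 Gy grid) from normalized plans;
`paired_endpoint_tests()` runs classical paired t tests (two-sided,
n − 1 df, sample SD throughout) across patients for each
(structure, metric) cell, e.g. best vs conformal plans. Raw p-values are
reported unadjusted — endpoint tables in this field conventionally are —
with Holm-adjusted values alongside in a clearly labelled column for users
who prefer family-wise control.

## Problem sizes

The shipped analyses use the 10 × 10 default grid (100 candidates, three
OARs, 0.1 Gy curves to ~60 Gy); a full search, scoring and ranking runs in
a few seconds on one core, and the test suite exercises 6 × 6 grids where
the full grid adds nothing. The surrogate's closed form makes a 100-point
brute-force oracle cheap, which is how the search result is
cross-validated.

## Known limitations

- The conformal baseline uses a single beam's-eye-view bounding box; real
  VMAT targets present different extents per gantry angle, and per-angle
  conformality (or the union extent) must be decided upstream.
- Jaw travel is searched symmetrically in offset steps; collimator angle,
  beam energy, isocenter and Y jaws are out of scope.
- Relative volumes only: absolute-volume (cc) constraints, biological
  indices (EUD/NTCP), and monitor-unit/complexity metrics are not modelled.
- The score arbitrates organs linearly after cohort normalization; sites
  with hard dose limits may prefer constraint-based filters before scoring,
  which the per-OAR weights only approximate.
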