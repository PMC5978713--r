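#' Configuration of the synthetic dose surrogate
#'
#' The surrogate maps a jaw setting to per-structure cumulative DVHs with the
#' qualitative behaviour seen in jaw-aperture searches: each organ-at-risk
#' mean dose is a convex function of the open fraction
#' `a = (W0 - offset1 - offset2) / W0` (leakage grows with the opening,
#' modulation-induced dose grows as the aperture closes), organs disagree on
#' the best aperture, and over-shrunk jaws under-dose the target so that
#' normalization to prescription amplifies the hotspot.
#'
#' Per organ `i`, the (noise-free) mean dose is
#' `Dbar_i = b_i + l_i * a + g_i * (1 - a)^2`; Gaussian noise with standard
#' deviation `noise_sd` is added from a substream seeded per (plan,
#' structure). The organ DVH is the stretched-exponential family
#' `V(d) = 100 * exp(-ln 2 * (d / D50)^k)` with `D50` set in closed form so
#' the curve mean equals `Dbar_i` (see [stretched_exp_d50]). The target DVH
#' is step-like with pre-normalization coverage
#' `D95 = Rx * (1 - c * e / W0)` and maximum dose
#' `Dmax = Rx * (1.03 + c * e / W0)`, where `e = max(0, offset1 + offset2 -
#' margin)` is the encroachment of the jaws past the tolerated travel.
#'
#' Defaults emulate a presurgical rectal VMAT case: 50 Gy prescription, a
#' 130 mm conformal X opening, and three organs at risk (small bowel,
#' femoral head, urinary bladder) whose baseline mean doses, leakage and
#' modulation coefficients place their individual optima at different
#' apertures.
#'
#' @param prescription Prescription dose Rx in Gy.
#' @param conformal_width Conformal X-field width W0 in mm.
#' @param structures Data frame with one row per organ at risk and columns
#'   `structure`, `baseline` (b_i, Gy), `leakage` (l_i, Gy), `modulation`
#'   (g_i, Gy), `shape` (k_i > 0).
#' @param cold_dose Target cold-dose coefficient c (dimensionless, >= 0).
#' @param margin Encroachment margin m in mm: combined inward travel tolerated
#'   before the target starts losing coverage.
#' @param noise_sd Standard deviation of the organ mean-dose noise in Gy
#'   (0 = deterministic engine).
#' @param seed Master seed for the per-(plan, structure) noise substreams.
#' @param dvh_bin Native sampling bin of generated curves in Gy.
#' @param target_id Label of the generated target curve.
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(prescription = 50,
                             conformal_width = 130,
                             structures = data.frame(
                               structure = c("small_bowel", "femoral_head",
                                             "urinary_bladder"),
                               baseline = c(17.3, 8.7, 17.1),
                               leakage = c(6, 4, 7),
                               modulation = c(15, 5, 8),
                               shape = c(2.5, 3.5, 2.2),
                               stringsAsFactors = FALSE),
                             cold_dose = 0.25,
                             margin = 45,
                             noise_sd = 0.3,
                             seed = 1L,
                             dvh_bin = 0.1,
                             target_id = "ptv") {
  stopifnot(is.data.frame(structures),
            all(c("structure", "baseline", "leakage", "modulation", "shape")
                %in% names(structures)))
  if (prescription <= 0 || conformal_width <= 0 || dvh_bin <= 0)
    stop_jawsearch("prescription, conformal_width and dvh_bin must be positive",
                   "jawsearch_invalid_input")
  if (cold_dose < 0 || margin < 0 || noise_sd < 0)
    stop_jawsearch("cold_dose, margin and noise_sd must be non-negative",
                   "jawsearch_invalid_input")
  if (any(structures$shape <= 0))
    stop_jawsearch("DVH shape parameters must be positive", "jawsearch_invalid_input")
  if (any(structures$baseline < 0 | structures$leakage < 0 |
          structures$modulation < 0))
    stop_jawsearch("surrogate dose coefficients must be non-negative",
                   "jawsearch_invalid_input")
  structure(list(prescription = as.double(prescription),
                 conformal_width = as.double(conformal_width),
                 structures = structures,
                 cold_dose = as.double(cold_dose),
                 margin = as.double(margin),
                 noise_sd = as.double(noise_sd),
                 seed = as.integer(seed),
                 dvh_bin = as.double(dvh_bin),
                 target_id = target_id),
            class = "surrogate_config")
}

#' Closed-form D50 of the stretched-exponential DVH family
#'
#' For `V(d) = 100 * exp(-ln 2 * (d / D50)^k)` the underlying dose
#' distribution is Weibull with shape `k` and scale
#' `lambda = D50 / (ln 2)^(1/k)`, so the mean dose is
#' `mean = lambda * Gamma(1 + 1/k) = D50 * Gamma(1 + 1/k) / (ln 2)^(1/k)`.
#' This function inverts that relation:
#' `D50 = mean * (ln 2)^(1/k) / Gamma(1 + 1/k)`.
#'
#' @param mean_dose Desired curve mean in Gy (> 0).
#' @param shape Shape parameter k (> 0).
#' @return The half-volume dose D50 in Gy.
#' @export
stretched_exp_d50 <- function(mean_dose, shape) {
  stopifnot(all(mean_dose > 0), all(shape > 0))
  mean_dose * log(2)^(1 / shape) / gamma(1 + 1 / shape)
}

#' Mean of the stretched-exponential DVH family (inverse of [stretched_exp_d50])
#' @param d50 Half-volume dose in Gy.
#' @param shape Shape parameter k (> 0).
#' @return Mean dose in Gy.
#' @export
stretched_exp_mean <- function(d50, shape) {
  stopifnot(all(d50 > 0), all(shape > 0))
  d50 * gamma(1 + 1 / shape) / log(2)^(1 / shape)
}

# Deterministic substream seed per (plan offsets, structure index); all
# arithmetic stays exact in doubles and the result fits a 32-bit integer.
substream_seed <- function(seed, offset1, offset2, struct_idx) {
  m <- 2147483647
  h <- as.double(seed %% m)
  h <- (h * 48271 + round(offset1 * 97) %% m * 2654435) %% m
  h <- (h * 69621 + round(offset2 * 193) %% m * 40503 + struct_idx * 524287) %% m
  as.integer(h)
}

# Evaluate `code` under a local RNG seed without disturbing the caller's
# stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Sample a stretched-exponential organ curve with the requested mean.
oar_curve <- function(structure, mean_dose, shape, bin) {
  d50 <- stretched_exp_d50(mean_dose, shape)
  # extend until the cumulative volume falls below 0.01%
  d_end <- d50 * (log(1e4) / log(2))^(1 / shape)
  n <- as.integer(ceiling(d_end / bin))
  grid <- (0:n) * bin
  v <- 100 * exp(-log(2) * (grid / d50)^shape)
  # close the support so the sampled curve has a finite maximum dose
  grid <- c(grid, (n + 1L) * bin)
  v <- c(v, 0)
  dvh_curve(structure, grid, v)
}

# Step-like target curve: flat at 100% then a steep linear fall-off placed so
# that D95 and the maximum dose take the requested values.
target_curve <- function(structure, d95, dmax) {
  d_start <- (d95 - 0.05 * dmax) / 0.95
  if (d_start <= 0 || d_start >= dmax)
    stop_jawsearch("target curve parameters leave no admissible fall-off region",
                   "jawsearch_degenerate_plan")
  dvh_curve(structure, c(0, d_start, dmax), c(100, 100, 0))
}

#' Simulate one candidate plan
#'
#' Evaluates the parametric surrogate at a jaw setting: organ-at-risk mean
#' doses from the aperture trade-off model (plus seeded noise), organ DVHs
#' from the stretched-exponential family matched to those means, and a
#' step-like target DVH whose coverage degrades (and whose relative hotspot
#' grows) as the jaws encroach past the tolerated travel. The returned plan
#' is unnormalized (`scale_applied = 1`).
#'
#' With `noise_sd = 0` the engine is fully deterministic; otherwise the noise
#' draw for each (plan, structure) pair comes from its own substream of the
#' master seed, so a cohort is reproducible regardless of simulation order.
#'
#' @param jaws A [jaw_setting] (or any list with `offset1`, `offset2`, and
#'   optionally `plan_id`).
#' @param cfg A [surrogate_config].
#' @return A [plan_dose] with the target curve and one curve per organ.
#' @export
simulate_plan <- function(jaws, cfg) {
  stopifnot(inherits(cfg, "surrogate_config"))
  off1 <- jaws$offset1
  off2 <- jaws$offset2
  if (is.null(off1) || is.null(off2) || off1 < 0 || off2 < 0)
    stop_jawsearch("jaw setting must carry non-negative offsets",
                   "jawsearch_invalid_input")
  w0 <- cfg$conformal_width
  a <- (w0 - off1 - off2) / w0
  if (a <= 0)
    stop_jawsearch(sprintf("aperture fully closed (open fraction %.3g)", a),
                   "jawsearch_degenerate_aperture")
  e <- max(0, off1 + off2 - cfg$margin)
  x <- cfg$cold_dose * e / w0

  plan_id <- if (!is.null(jaws$plan_id)) jaws$plan_id else
    sprintf("jaws_%g_%g", off1, off2)

  st <- cfg$structures
  curves <- vector("list", nrow(st) + 1L)
  rx <- cfg$prescription
  curves[[1L]] <- target_curve(cfg$target_id,
                               d95 = rx * (1 - x),
                               dmax = rx * (1.03 + x))
  for (i in seq_len(nrow(st))) {
    mean_i <- st$baseline[i] + st$leakage[i] * a + st$modulation[i] * (1 - a)^2
    if (cfg$noise_sd > 0) {
      eps <- with_local_seed(substream_seed(cfg$seed, off1, off2, i),
                             stats::rnorm(1, 0, cfg$noise_sd))
      mean_i <- max(mean_i + eps, 0.1) # keep a physical, positive mean
    }
    curves[[i + 1L]] <- oar_curve(st$structure[i], mean_i, st$shape[i],
                                  cfg$dvh_bin)
  }
  plan_dose(plan_id, curves)
}

#' Jaw-invariant predicted-DVH stub
#'
#' Emulates a knowledge-based DVH prediction whose geometry-based dose model
#' does not see the actual jaw positions but always assumes target-conformal
#' jaws: whatever setting is passed in, the stub returns exactly the curves
#' [simulate_plan] produces for the conformal setting (offsets 0, 0) under
#' the same configuration. At a fixed seed the output is identical for every
#' jaw setting, so predicted DVHs cannot discriminate between candidate
#' apertures.
#'
#' @param jaws A [jaw_setting]; only its validity is checked, its offsets are
#'   deliberately ignored.
#' @param cfg A [surrogate_config].
#' @return A [plan_dose] with plan id `"conformal_prediction"`.
#' @export
predict_dvh_stub <- function(jaws, cfg) {
  stopifnot(inherits(cfg, "surrogate_config"))
  if (is.null(jaws$offset1) || is.null(jaws$offset2) ||
      jaws$offset1 < 0 || jaws$offset2 < 0)
    stop_jawsearch("jaw setting must carry non-negative offsets",
                   "jawsearch_invalid_input")
  conformal <- list(offset1 = 0, offset2 = 0, plan_id = "conformal_prediction")
  simulate_plan(conformal, cfg)
}
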