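#' Cumulative dose-volume histogram curve
#'
#' A `dvh_curve` stores one structure's cumulative DVH: `volume[j]` is the
#' relative volume (%) receiving at least `dose[j]` Gy. The dose grid starts
#' at 0 Gy and is strictly increasing; the volume starts at 100% and is
#' non-increasing.
#'
#' @param structure Structure label (single string), e.g. `"small_bowel"`.
#' @param dose Numeric vector of dose samples in Gy, strictly increasing,
#'   starting at 0.
#' @param volume Numeric vector of cumulative relative volumes in percent,
#'   same length as `dose`, starting at 100.
#'
#' @return An object of class `dvh_curve` with fields `structure`, `dose`,
#'   `volume`.
#' @examples
#' dvh_curve("ptv", c(0, 45, 50), c(100, 95, 0))
#' @export
dvh_curve <- function(structure, dose, volume) {
  if (!is.character(structure) || length(structure) != 1L || is.na(structure))
    stop_jawsearch("'structure' must be a single string", "jawsearch_invalid_input")
  dose <- as.double(dose)
  volume <- as.double(volume)
  if (length(dose) == 0L)
    stop_jawsearch("empty DVH curve", "jawsearch_invalid_input")
  if (length(dose) != length(volume))
    stop_jawsearch("'dose' and 'volume' must have equal length", "jawsearch_invalid_input")
  if (anyNA(dose) || anyNA(volume))
    stop_jawsearch("DVH samples must not contain NA", "jawsearch_invalid_input")
  if (dose[1L] != 0)
    stop_jawsearch("dose grid must start at 0 Gy", "jawsearch_invalid_input")
  if (length(dose) > 1L && any(diff(dose) <= 0))
    stop_jawsearch("dose grid must be strictly increasing", "jawsearch_invalid_input")
  if (abs(volume[1L] - 100) > 1e-9)
    stop_jawsearch("cumulative volume must start at 100%", "jawsearch_invalid_input")
  if (any(diff(volume) > 1e-9))
    stop_jawsearch("cumulative volume must be non-increasing", "jawsearch_invalid_input")
  if (any(volume < -1e-9) || any(volume > 100 + 1e-9))
    stop_jawsearch("volumes must lie in [0, 100]%", "jawsearch_invalid_input")
  # clamp sub-tolerance wiggle so downstream invariants hold exactly
  volume <- cummin(pmin(pmax(volume, 0), 100))
  volume[1L] <- 100
  structure(list(structure = structure, dose = dose, volume = volume),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d samples, 0-%.3g Gy, V(0)=100%%, V(max)=%.3g%%\n",
              x$structure, length(x$dose), max(x$dose), x$volume[length(x$volume)]))
  invisible(x)
}

#' Per-plan dose container
#'
#' A `plan_dose` holds the cumulative DVH curves of one candidate plan, one
#' per structure (the target and every organ at risk), plus the multiplicative
#' dose scale already applied to the curves (1 for an unnormalized plan).
#'
#' @param plan_id Plan label (single string).
#' @param curves List of [dvh_curve] objects with unique structure labels.
#' @param scale_applied Multiplicative dose factor already applied (> 0).
#'
#' @return An object of class `plan_dose`; `curves` is named by structure.
#' @export
plan_dose <- function(plan_id, curves, scale_applied = 1) {
  if (!is.character(plan_id) || length(plan_id) != 1L)
    stop_jawsearch("'plan_id' must be a single string", "jawsearch_invalid_input")
  if (!is.list(curves) || length(curves) == 0L ||
      !all(vapply(curves, inherits, logical(1), "dvh_curve")))
    stop_jawsearch("'curves' must be a non-empty list of dvh_curve objects",
                   "jawsearch_invalid_input")
  ids <- vapply(curves, `[[`, character(1), "structure")
  if (anyDuplicated(ids))
    stop_jawsearch("structure labels must be unique within a plan",
                   "jawsearch_invalid_input")
  if (!is.numeric(scale_applied) || length(scale_applied) != 1L || scale_applied <= 0)
    stop_jawsearch("'scale_applied' must be a positive scalar", "jawsearch_invalid_input")
  names(curves) <- ids
  structure(list(plan_id = plan_id, curves = curves,
                 scale_applied = as.double(scale_applied)),
            class = "plan_dose")
}

#' @export
print.plan_dose <- function(x, ...) {
  cat(sprintf("<plan_dose> %s: %d structures (%s), scale_applied = %.6g\n",
              x$plan_id, length(x$curves),
              paste(names(x$curves), collapse = ", "), x$scale_applied))
  invisible(x)
}

#' Resample a DVH curve on a uniform dose grid
#'
#' Linearly interpolates the cumulative curve onto the grid
#' `0, h, 2h, ...` extending to (at least) the last input sample; doses beyond
#' the last input sample are assigned volume 0. Metric sums over DVH curves
#' become grid-independent once every curve is resampled to a common bin
#' width.
#'
#' @param curve A [dvh_curve].
#' @param bin_width Grid spacing h in Gy (> 0).
#' @return A [dvh_curve] on the uniform grid.
#' @examples
#' resample_dvh(dvh_curve("oar", c(0, 10), c(100, 0)), 5)
#' @export
resample_dvh <- function(curve, bin_width) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop_jawsearch("'bin_width' must be a positive scalar", "jawsearch_invalid_input")
  dmax <- curve$dose[length(curve$dose)]
  n <- max(1L, as.integer(ceiling(dmax / bin_width - 1e-9)))
  grid <- (0:n) * bin_width
  v <- volume_at_dose(curve, grid)
  dvh_curve(curve$structure, grid, v)
}

#' Relative volume receiving at least a given dose
#'
#' Evaluates the cumulative curve V(d) by linear interpolation. Doses beyond
#' the last sample return 0; `d = 0` returns 100.
#'
#' @param curve A [dvh_curve].
#' @param d Dose(s) in Gy, non-negative; vectorized.
#' @return Relative volume(s) in percent.
#' @examples
#' volume_at_dose(dvh_curve("oar", c(0, 10), c(100, 0)), 2.5) # 75
#' @export
volume_at_dose <- function(curve, d) {
  stopifnot(inherits(curve, "dvh_curve"))
  d <- as.double(d)
  if (any(d < 0))
    stop_jawsearch("dose query must be non-negative", "jawsearch_invalid_input")
  if (length(curve$dose) == 1L) {
    # single sample at 0 Gy: all volume at 0, nothing beyond
    return(ifelse(d <= 0, 100, 0))
  }
  stats::approx(curve$dose, curve$volume, xout = d,
                method = "linear", yleft = 100, yright = 0, ties = "ordered")$y
}

#' Dose received by at least a given fraction of the structure
#'
#' Returns D_v, the greatest dose d such that at least `v` percent of the
#' structure receives d (the standard clinical inverse of the cumulative DVH,
#' e.g. `v = 95` gives D95). Under linear interpolation a flat 100% segment
#' yields its right boundary; a curve that falls immediately from 100% yields
#' 0 at `v = 100`. If the curve never falls to `v`, the last sampled dose is
#' returned.
#'
#' @param curve A [dvh_curve].
#' @param v Volume level(s) in percent, in \[0, 100\]; vectorized.
#' @return Dose(s) in Gy.
#' @examples
#' dose_at_volume(dvh_curve("ptv", c(0, 10), c(100, 0)), 50) # 5
#' @export
dose_at_volume <- function(curve, v) {
  stopifnot(inherits(curve, "dvh_curve"))
  v <- as.double(v)
  if (any(v < 0 | v > 100))
    stop_jawsearch("volume query must lie in [0, 100]%", "jawsearch_invalid_input")
  vol <- curve$volume
  dose <- curve$dose
  n <- length(dose)
  one <- function(vq) {
    i <- max(which(vol >= vq)) # exists: vol[1] == 100 >= vq
    if (vol[i] - vq <= 1e-12) return(dose[i])
    if (i == n) return(dose[n])
    dose[i] + (vol[i] - vq) / (vol[i] - vol[i + 1L]) * (dose[i + 1L] - dose[i])
  }
  vapply(v, one, numeric(1))
}

#' Maximum dose of a sampled cumulative DVH
#'
#' The dose at which the interpolated cumulative volume first falls to
#' `epsilon` (default 0): the first grid point with volume <= `epsilon`, or
#' the last grid point if the curve never reaches it.
#'
#' @param curve A [dvh_curve].
#' @param epsilon Volume floor in percent treated as "no volume" (default 0).
#' @return Maximum dose in Gy.
#' @export
max_dose <- function(curve, epsilon = 0) {
  stopifnot(inherits(curve, "dvh_curve"))
  idx <- which(curve$volume <= epsilon)
  if (length(idx)) curve$dose[min(idx)] else curve$dose[length(curve$dose)]
}

#' Normalize a plan to prescription coverage
#'
#' Rescales every curve's dose axis by the single factor
#' `s = prescription / D_coverage(target)`, where `D_coverage` is
#' [dose_at_volume] of the target at `coverage_volume` percent (default 95,
#' i.e. D95 of the target is driven to the prescription). Volumes are
#' unchanged; `scale_applied` accumulates the factor. Applying the same
#' normalization twice is a no-op.
#'
#' @param plan A [plan_dose].
#' @param target_id Structure label of the target (e.g. `"ptv"`).
#' @param prescription Prescription dose in Gy.
#' @param coverage_volume Coverage level in percent (default 95).
#' @return The normalized [plan_dose].
#' @export
normalize_to_prescription <- function(plan, target_id, prescription,
                                      coverage_volume = 95) {
  stopifnot(inherits(plan, "plan_dose"))
  if (!target_id %in% names(plan$curves))
    stop_jawsearch(sprintf("target structure '%s' not present in plan '%s'",
                           target_id, plan$plan_id),
                   "jawsearch_invalid_input")
  dref <- dose_at_volume(plan$curves[[target_id]], coverage_volume)
  if (dref <= 0)
    stop_jawsearch(
      sprintf("plan '%s': target dose at %g%% coverage is zero; degenerate plan",
              plan$plan_id, coverage_volume),
      "jawsearch_degenerate_plan")
  s <- prescription / dref
  plan$curves <- lapply(plan$curves, function(cv)
    dvh_curve(cv$structure, cv$dose * s, cv$volume))
  plan$scale_applied <- plan$scale_applied * s
  plan
}

#' Hotspot acceptability test
#'
#' A normalized plan is clinically unacceptable when the maximum dose of the
#' hotspot structure strictly exceeds `limit_pct`% of the prescription
#' (default 107%). A maximum dose of exactly `limit_pct`% is kept.
#'
#' @param plan A normalized [plan_dose].
#' @param target_id Structure label of the target.
#' @param prescription Prescription dose in Gy.
#' @param limit_pct Hotspot limit as percent of prescription (default 107).
#' @param hotspot_structure Structure whose maximum dose is tested; defaults
#'   to the target (useful when no body contour is available).
#' @param epsilon Volume floor passed to [max_dose].
#' @return `TRUE` if the plan must be excluded, `FALSE` if it is kept.
#' @export
is_hotspot_unacceptable <- function(plan, target_id, prescription,
                                    limit_pct = 107,
                                    hotspot_structure = target_id,
                                    epsilon = 0) {
  stopifnot(inherits(plan, "plan_dose"))
  if (!hotspot_structure %in% names(plan$curves))
    stop_jawsearch(sprintf("hotspot structure '%s' not present in plan '%s'",
                           hotspot_structure, plan$plan_id),
                   "jawsearch_invalid_input")
  dmax <- max_dose(plan$curves[[hotspot_structure]], epsilon = epsilon)
  dmax > limit_pct / 100 * prescription
}
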