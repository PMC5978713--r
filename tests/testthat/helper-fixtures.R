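# Shared fixtures: random valid DVH curves, tiny hand-built plans, and the
# independent closed-form oracle for the surrogate engine.

# Random valid cumulative DVH curve (strictly increasing doses from 0,
# non-increasing volumes from 100 down to 0).
random_curve <- function(n = 8, dmax = 60, structure = "oar") {
  dose <- c(0, sort(runif(n - 2, 0, dmax)), dmax)
  volume <- c(100, sort(runif(n - 2, 0, 100), decreasing = TRUE), 0)
  dvh_curve(structure, dose, volume)
}

# One-OAR plan whose target is a clean step at the prescription: D95 equals
# `d95`, maximum dose `dmax_frac` * d95.
step_plan <- function(plan_id, d95 = 50, dmax_frac = 1.03, oar_slope_end = 40,
                      oar_id = "small_bowel") {
  dmax <- dmax_frac * d95
  d_start <- (d95 - 0.05 * dmax) / 0.95
  tgt <- dvh_curve("ptv", c(0, d_start, dmax), c(100, 100, 0))
  oar <- dvh_curve(oar_id, c(0, oar_slope_end), c(100, 0))
  plan_dose(plan_id, list(tgt, oar))
}

# Closed-form total scores for a noise-free surrogate over a jaw grid:
# organ mean doses from the aperture model, MDVP = 100 * mean, HDVP from the
# Weibull partial expectation (pgamma), normalization scale and hotspot
# exclusion in closed form. Independent of the DVH-sampling code path.
closed_form_scores <- function(scfg, grid, oars, limit_pct,
                               normalization_set = "all") {
  stopifnot(scfg$noise_sd == 0)
  rx <- scfg$prescription
  w0 <- scfg$conformal_width
  st <- scfg$structures
  thr <- stats::setNames(vapply(oars, function(o) o$hdvp_threshold, numeric(1)),
                         vapply(oars, function(o) o$structure, character(1)))
  nrows <- nrow(grid)
  combined <- matrix(NA_real_, nrows, nrow(st))
  excluded <- logical(nrows)
  for (p in seq_len(nrows)) {
    a <- (w0 - grid$offset1[p] - grid$offset2[p]) / w0
    e <- max(0, grid$offset1[p] + grid$offset2[p] - scfg$margin)
    x <- scfg$cold_dose * e / w0
    s <- 1 / (1 - x)                       # normalization scale: Rx / D95
    excluded[p] <- (1.03 + x) / (1 - x) > limit_pct / 100
    for (i in seq_len(nrow(st))) {
      mu <- s * (st$baseline[i] + st$leakage[i] * a +
                   st$modulation[i] * (1 - a)^2)
      k <- st$shape[i]
      lam <- mu / gamma(1 + 1 / k)         # Weibull scale of the scaled curve
      dt <- thr[[st$structure[i]]]
      hd <- 100 * lam * gamma(1 + 1 / k) *
        stats::pgamma((dt / lam)^k, 1 + 1 / k, lower.tail = FALSE)
      combined[p, i] <- 100 * mu + hd
    }
  }
  idx <- if (normalization_set == "all") seq_len(nrows) else which(!excluded)
  norm <- sweep(combined, 2, colMeans(combined[idx, , drop = FALSE]), "/")
  list(total = rowSums(norm), excluded = excluded)
}

default_extent <- function() bev_extent(-65, 65, -75, 75)
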