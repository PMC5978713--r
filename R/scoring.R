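#' Organ-at-risk scoring specification
#'
#' Bundles the per-organ parameters of the plan score: the high-dose
#' threshold d_t above which HDVP accumulates, and the weights on the MDVP
#' and HDVP components (equal weighting by default).
#'
#' @param structure Structure label.
#' @param hdvp_threshold High-dose threshold d_t in Gy (>= 0).
#' @param weight_mdvp,weight_hdvp Non-negative component weights (default 1).
#' @return An object of class `oar_spec`.
#' @export
oar_spec <- function(structure, hdvp_threshold, weight_mdvp = 1, weight_hdvp = 1) {
  if (!is.character(structure) || length(structure) != 1L)
    stop_jawsearch("'structure' must be a single string", "jawsearch_invalid_input")
  if (hdvp_threshold < 0 || weight_mdvp < 0 || weight_hdvp < 0)
    stop_jawsearch("threshold and weights must be non-negative",
                   "jawsearch_invalid_input")
  structure(list(structure = structure,
                 hdvp_threshold = as.double(hdvp_threshold),
                 weight_mdvp = as.double(weight_mdvp),
                 weight_hdvp = as.double(weight_hdvp)),
            class = "oar_spec")
}

#' Default rectal-VMAT organ-at-risk set
#'
#' Small bowel, femoral head and urinary bladder with high-dose thresholds of
#' 35, 40 and 40 Gy respectively (RTOG 0822-style dose-volume constraints),
#' equal MDVP/HDVP weights.
#'
#' @return A list of three [oar_spec] objects.
#' @export
default_oars <- function() {
  list(oar_spec("small_bowel", 35),
       oar_spec("femoral_head", 40),
       oar_spec("urinary_bladder", 40))
}

#' Mean dose-volume product (MDVP)
#'
#' `MDVP = sum_j d_j (V_j - V_{j+1})` over the sampled cumulative curve, with
#' the trailing convention `V_{n+1} = 0` so the sum equals the Riemann sum of
#' dose times differential volume over the curve's full support. Units are
#' Gy.%; on a fine grid `MDVP / 100` approximates the structure mean dose in
#' Gy. Curves should be resampled to a common bin width first so cohort
#' comparisons are grid-independent.
#'
#' @param curve A [dvh_curve].
#' @return MDVP in Gy.%.
#' @examples
#' mdvp(dvh_curve("oar", c(0, 10, 20), c(100, 100, 0))) # 1000
#' @export
mdvp <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  v <- curve$volume
  dv <- v - c(v[-1L], 0)
  sum(curve$dose * dv)
}

#' High dose-volume product (HDVP)
#'
#' The MDVP sum restricted to samples with dose strictly above the threshold
#' `d_t`: `HDVP = sum_{d_j > d_t} d_j (V_j - V_{j+1})`. With `d_t = 0` the
#' value equals [mdvp] (the excluded zero-dose term contributes nothing).
#' HDVP is non-increasing in `d_t` and bounded by MDVP.
#'
#' @param curve A [dvh_curve].
#' @param d_t High-dose threshold in Gy (>= 0).
#' @return HDVP in Gy.%.
#' @examples
#' hdvp(dvh_curve("oar", c(0, 30, 40, 50), c(100, 100, 50, 0)), 35) # 2000
#' @export
hdvp <- function(curve, d_t) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(d_t) || length(d_t) != 1L || d_t < 0)
    stop_jawsearch("'d_t' must be a non-negative scalar", "jawsearch_invalid_input")
  v <- curve$volume
  dv <- v - c(v[-1L], 0)
  keep <- curve$dose > d_t
  sum((curve$dose * dv)[keep])
}

#' Score a cohort of candidate plans
#'
#' For every plan and organ at risk, computes MDVP and HDVP on curves
#' resampled to `bin_width`, combines them as
#' `combined = w_mdvp * MDVP + w_hdvp * HDVP`, and normalizes each organ's
#' combined value by its mean over the normalization cohort so each organ
#' contributes a dimensionless relative evaluator with cohort mean 1. The
#' plan score is the sum of the normalized evaluators over organs; lower
#' scores mean better organ sparing.
#'
#' The normalization cohort is, by policy, either every plan that completed
#' dose calculation (`"all"`, the default) or only the hotspot-acceptable
#' plans (`"accepted"`). Ranking downstream always uses accepted plans only.
#'
#' @param plans List of normalized [plan_dose] objects.
#' @param oars List of [oar_spec]; every plan must contain every OAR curve.
#' @param accepted Logical vector, one flag per plan (`TRUE` = clinically
#'   acceptable). Defaults to all accepted.
#' @param normalization_set `"all"` or `"accepted"`.
#' @param bin_width Resampling bin width in Gy before metric sums
#'   (default 0.1).
#' @return An object of class `organ_score_table`: list with `organ` (one row
#'   per plan x organ: `plan_id`, `structure`, `mdvp`, `hdvp`, `combined`,
#'   `normalized_score`) and `plan` (one row per plan: `plan_id`,
#'   `total_score`, `accepted`), plus the policy and OAR set used.
#' @export
score_cohort <- function(plans, oars, accepted = rep(TRUE, length(plans)),
                         normalization_set = c("all", "accepted"),
                         bin_width = 0.1) {
  normalization_set <- match.arg(normalization_set)
  stopifnot(is.list(plans), all(vapply(plans, inherits, logical(1), "plan_dose")))
  stopifnot(is.list(oars), length(oars) > 0,
            all(vapply(oars, inherits, logical(1), "oar_spec")))
  accepted <- as.logical(accepted)
  if (length(accepted) != length(plans))
    stop_jawsearch("'accepted' must have one flag per plan", "jawsearch_invalid_input")
  if (length(plans) == 0L)
    stop_jawsearch("empty cohort: no plans to score", "jawsearch_empty_cohort")

  plan_ids <- vapply(plans, `[[`, character(1), "plan_id")
  norm_idx <- if (normalization_set == "all") seq_along(plans) else which(accepted)
  if (length(norm_idx) == 0L)
    stop_jawsearch("normalization cohort is empty under policy 'accepted'",
                   "jawsearch_empty_cohort")

  rows <- vector("list", length(oars))
  for (k in seq_along(oars)) {
    sp <- oars[[k]]
    m <- h <- numeric(length(plans))
    for (i in seq_along(plans)) {
      if (!sp$structure %in% names(plans[[i]]$curves))
        stop_jawsearch(sprintf("plan '%s' lacks OAR curve '%s'",
                               plan_ids[i], sp$structure),
                       "jawsearch_invalid_input")
      cv <- resample_dvh(plans[[i]]$curves[[sp$structure]], bin_width)
      m[i] <- mdvp(cv)
      h[i] <- hdvp(cv, sp$hdvp_threshold)
    }
    combined <- sp$weight_mdvp * m + sp$weight_hdvp * h
    ref <- mean(combined[norm_idx])
    if (ref <= 0)
      stop_jawsearch(sprintf("OAR '%s': cohort mean combined value is zero; cannot normalize",
                             sp$structure),
                     "jawsearch_degenerate_normalization")
    rows[[k]] <- data.frame(plan_id = plan_ids, structure = sp$structure,
                            mdvp = m, hdvp = h, combined = combined,
                            normalized_score = combined / ref,
                            stringsAsFactors = FALSE)
  }
  organ <- do.call(rbind, rows)
  total <- rowsum(organ$normalized_score, organ$plan_id, reorder = FALSE)
  # rowsum groups in first-appearance order == plan order within each block
  total_by_plan <- total[match(plan_ids, rownames(total)), 1L]
  plan <- data.frame(plan_id = plan_ids, total_score = total_by_plan,
                     accepted = accepted, stringsAsFactors = FALSE,
                     row.names = NULL)
  structure(list(organ = organ, plan = plan, oars = oars,
                 normalization_set = normalization_set,
                 bin_width = bin_width),
            class = "organ_score_table")
}

#' @export
print.organ_score_table <- function(x, ...) {
  cat(sprintf("<organ_score_table> %d plans x %d OARs (normalization set: %s)\n",
              nrow(x$plan), length(x$oars), x$normalization_set))
  cat(sprintf("  accepted: %d / %d\n", sum(x$plan$accepted), nrow(x$plan)))
  rng <- range(x$plan$total_score[x$plan$accepted])
  if (any(x$plan$accepted))
    cat(sprintf("  total score (accepted): %.3f - %.3f\n", rng[1], rng[2]))
  invisible(x)
}

#' Rank candidate plans by total score
#'
#' Orders accepted plans by ascending total score (lower is better). Ties are
#' broken by the lowest plan index (order of appearance in the table), making
#' the designation deterministic. The conformal plan is reported alongside
#' best and worst whenever its id is supplied, whether or not it was
#' accepted.
#'
#' @param table An [score_cohort] result.
#' @param conformal_id Optional plan id of the conformal-jaw plan.
#' @return A list with `ranking` (accepted plan ids, best first), `best`,
#'   `worst`, `conformal` (id or `NA`), `conformal_accepted`, and
#'   `scores` (named total scores of those designated plans).
#' @export
rank_plans <- function(table, conformal_id = NULL) {
  stopifnot(inherits(table, "organ_score_table"))
  pl <- table$plan
  acc <- pl[pl$accepted, , drop = FALSE]
  if (nrow(acc) == 0L)
    stop_jawsearch("no accepted plans to rank", "jawsearch_empty_cohort")
  ord <- order(acc$total_score) # stable: ties keep first-appearance order
  ranking <- acc$plan_id[ord]
  best <- acc$plan_id[which.min(acc$total_score)]
  worst <- acc$plan_id[which.max(acc$total_score)]
  conformal <- if (is.null(conformal_id)) NA_character_ else conformal_id
  conf_acc <- if (is.na(conformal)) NA else {
    hit <- pl$plan_id == conformal
    if (!any(hit)) NA else pl$accepted[hit]
  }
  ids <- c(best = best, worst = worst)
  if (!is.na(conformal) && conformal %in% pl$plan_id)
    ids <- c(ids, conformal = conformal)
  scores <- stats::setNames(pl$total_score[match(ids, pl$plan_id)], names(ids))
  list(ranking = ranking, best = best, worst = worst,
       conformal = conformal, conformal_accepted = conf_acc,
       scores = scores)
}
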