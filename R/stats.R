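#' Dosimetric endpoint metrics for one plan
#'
#' Extracts V_D metrics (relative volume in percent receiving at least D Gy,
#' named like `"V35"`) and `"mean_dose"` (Gy, computed as MDVP / 100 on a
#' fine 0.01 Gy grid) for the requested structures of a normalized plan.
#'
#' @param plan A normalized [plan_dose].
#' @param metrics Character vector of metric names (`"V<dose>"` or
#'   `"mean_dose"`).
#' @param structures Structure labels to evaluate (default: all curves).
#' @param fine_bin Resampling bin for the mean-dose integral (default 0.01 Gy).
#' @return A `data.frame` with columns `plan_id`, `structure`, `metric`,
#'   `value`.
#' @examples
#' pl <- plan_dose("p", list(dvh_curve("oar", c(0, 10), c(100, 0))))
#' endpoint_metrics(pl, c("V5", "mean_dose"))
#' @export
endpoint_metrics <- function(plan, metrics = c("V35", "V40", "V45", "V50",
                                               "mean_dose"),
                             structures = names(plan$curves),
                             fine_bin = 0.01) {
  stopifnot(inherits(plan, "plan_dose"))
  missing <- setdiff(structures, names(plan$curves))
  if (length(missing))
    stop_jawsearch(sprintf("plan '%s' lacks structures: %s", plan$plan_id,
                           paste(missing, collapse = ", ")),
                   "jawsearch_invalid_input")
  one <- function(sid, metric) {
    cv <- plan$curves[[sid]]
    if (metric == "mean_dose")
      return(mdvp(resample_dvh(cv, fine_bin)) / 100)
    if (grepl("^V[0-9]+(\\.[0-9]+)?$", metric))
      return(volume_at_dose(cv, as.numeric(sub("^V", "", metric))))
    stop_jawsearch(sprintf("unknown endpoint metric '%s'", metric),
                   "jawsearch_invalid_input")
  }
  grid <- expand.grid(structure = structures, metric = metrics,
                      stringsAsFactors = FALSE)
  grid$value <- mapply(one, grid$structure, grid$metric)
  data.frame(plan_id = plan$plan_id, grid, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Paired t test between matched plan endpoints
#'
#' Classical paired t test on the per-patient differences `x - y`, two-sided
#' p from the Student t distribution with n - 1 degrees of freedom. When
#' every difference is identical the test statistic is undefined
#' (zero-variance differences); this raises a degenerate-variance error
#' rather than reporting a misleading p of 0 or 1.
#'
#' @param x,y Numeric vectors of equal length >= 2 (one value per patient).
#' @return A list with `t`, `df`, `p`, and `mean_diff`.
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1)) # differences 1, 2, 3
#' @export
paired_t <- function(x, y) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y))
    stop_jawsearch("'x' and 'y' must have equal length", "jawsearch_invalid_input")
  if (length(x) < 2L)
    stop_jawsearch("paired t test needs at least 2 pairs", "jawsearch_invalid_input")
  d <- x - y
  if (stats::sd(d) == 0)
    stop_jawsearch("all paired differences are identical: t statistic undefined",
                   "jawsearch_degenerate_variance")
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Paired endpoint comparison across patients
#'
#' Runs [paired_t] for every (structure, metric) combination of an endpoint
#' table holding one row per (patient, plan class, structure, metric), e.g.
#' comparing each patient's best plan against the conformal plan. Raw
#' two-sided p-values are reported as-is; Holm-adjusted values are added in a
#' clearly separated column.
#'
#' @param endpoints A `data.frame` with columns `patient`, `plan_class`,
#'   `structure`, `metric`, `value`.
#' @param class_a,class_b The two plan classes to compare (default
#'   `"best"` vs `"conformal"`).
#' @return A `data.frame` with one row per (structure, metric): mean and SD
#'   per class, `t`, `df`, `p` (raw), `p_holm`; degenerate comparisons carry
#'   `NA` statistics and `degenerate = TRUE`.
#' @export
paired_endpoint_tests <- function(endpoints, class_a = "best",
                                  class_b = "conformal") {
  need <- c("patient", "plan_class", "structure", "metric", "value")
  if (!all(need %in% names(endpoints)))
    stop_jawsearch(sprintf("endpoint table needs columns: %s",
                           paste(need, collapse = ", ")),
                   "jawsearch_invalid_input")
  combos <- unique(endpoints[, c("structure", "metric")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- endpoints$structure == combos$structure[i] &
      endpoints$metric == combos$metric[i]
    a <- endpoints[sel & endpoints$plan_class == class_a, ]
    b <- endpoints[sel & endpoints$plan_class == class_b, ]
    a <- a[order(a$patient), ]
    b <- b[order(b$patient), ]
    if (!identical(a$patient, b$patient))
      stop_jawsearch("plan classes must cover the same patients",
                     "jawsearch_invalid_input")
    res <- tryCatch(paired_t(a$value, b$value),
                    jawsearch_degenerate_variance = function(e) NULL)
    data.frame(structure = combos$structure[i], metric = combos$metric[i],
               mean_a = mean(a$value), sd_a = stats::sd(a$value),
               mean_b = mean(b$value), sd_b = stats::sd(b$value),
               t = if (is.null(res)) NA_real_ else res$t,
               df = if (is.null(res)) NA_real_ else res$df,
               p = if (is.null(res)) NA_real_ else res$p,
               degenerate = is.null(res),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Cohort summary of the organ score table
#'
#' Minimum, maximum, mean and sample (n - 1) standard deviation of MDVP,
#' HDVP and the normalized score, per organ at risk, over either the
#' accepted plans only or the whole scored cohort. A singleton selection is
#' flagged degenerate and reports SD 0.
#'
#' @param table An [score_cohort] result.
#' @param accepted_only Summarize accepted plans only (default `TRUE`)?
#' @return A `data.frame` with columns `structure`, `metric`, `min`, `max`,
#'   `mean`, `sd`, `n`, `degenerate`.
#' @export
cohort_summary <- function(table, accepted_only = TRUE) {
  stopifnot(inherits(table, "organ_score_table"))
  keep_ids <- if (accepted_only) table$plan$plan_id[table$plan$accepted]
  else table$plan$plan_id
  organ <- table$organ[table$organ$plan_id %in% keep_ids, , drop = FALSE]
  if (nrow(organ) == 0L)
    stop_jawsearch("empty selection: nothing to summarize",
                   "jawsearch_empty_cohort")
  out <- list()
  for (sid in unique(organ$structure)) {
    sub <- organ[organ$structure == sid, , drop = FALSE]
    n <- nrow(sub)
    for (metric in c("mdvp", "hdvp", "normalized_score")) {
      v <- sub[[metric]]
      out[[length(out) + 1L]] <- data.frame(
        structure = sid, metric = metric,
        min = min(v), max = max(v), mean = mean(v),
        sd = if (n > 1L) stats::sd(v) else 0,
        n = n, degenerate = n == 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
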