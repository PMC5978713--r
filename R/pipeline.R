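#' Search configuration
#'
#' Aggregates every tunable of the jaw search: prescription and coverage
#' level driving normalization, hotspot limit, grid geometry, organ-at-risk
#' scoring set, normalization-cohort policy, dose engine and master seed.
#'
#' @param prescription Prescription dose in Gy (default 50).
#' @param coverage_volume Target coverage level in percent used for
#'   normalization (default 95, i.e. D95 = prescription).
#' @param hotspot_limit Hotspot limit in percent of prescription (> 100,
#'   default 107; plans with a maximum dose strictly above it are excluded).
#' @param step Jaw offset increment in mm (default 5).
#' @param n_steps_per_bank Offset positions per bank including the conformal
#'   position (default 10, hence a 100-plan grid).
#' @param leaf_width MLC leaf width in mm for the Y-jaw retraction (default 5).
#' @param min_width Minimum admissible field width in mm (default 20).
#' @param bin_width DVH resampling bin in Gy for metric sums (default 0.1).
#' @param oars List of [oar_spec] (default [default_oars]).
#' @param normalization_set `"all"` (every plan that completed dose
#'   calculation; default) or `"accepted"`.
#' @param engine Dose engine identifier; `"surrogate"` selects the shipped
#'   parametric engine.
#' @param seed Master seed (also seeds the surrogate unless `surrogate` is
#'   supplied).
#' @param surrogate Optional [surrogate_config] overriding the one derived
#'   from this configuration and the target extent.
#' @param target_id Target structure label (default `"ptv"`).
#' @return An object of class `search_config`.
#' @export
search_config <- function(prescription = 50, coverage_volume = 95,
                          hotspot_limit = 107, step = 5,
                          n_steps_per_bank = 10, leaf_width = 5,
                          min_width = 20, bin_width = 0.1,
                          oars = default_oars(),
                          normalization_set = c("all", "accepted"),
                          engine = "surrogate", seed = 20180325L,
                          surrogate = NULL, target_id = "ptv") {
  normalization_set <- match.arg(normalization_set)
  if (hotspot_limit <= 100)
    stop_jawsearch("'hotspot_limit' must exceed 100%", "jawsearch_invalid_input")
  if (length(oars) == 0L)
    stop_jawsearch("at least one OAR must be configured", "jawsearch_invalid_input")
  stopifnot(all(vapply(oars, inherits, logical(1), "oar_spec")))
  if (!is.null(surrogate)) stopifnot(inherits(surrogate, "surrogate_config"))
  structure(list(prescription = as.double(prescription),
                 coverage_volume = as.double(coverage_volume),
                 hotspot_limit = as.double(hotspot_limit),
                 step = as.double(step),
                 n_steps_per_bank = as.integer(n_steps_per_bank),
                 leaf_width = as.double(leaf_width),
                 min_width = as.double(min_width),
                 bin_width = as.double(bin_width),
                 oars = oars,
                 normalization_set = normalization_set,
                 engine = engine,
                 seed = as.integer(seed),
                 surrogate = surrogate,
                 target_id = target_id),
            class = "search_config")
}

# Build the per-plan text record: jaw setting, status, scale factor, and the
# predicted-stub and final DVH blocks in the CSV dialect.
plan_record_text <- function(grid_row, status, scale_applied, predicted, final) {
  header <- c(
    "# jawsearch plan record",
    sprintf("plan_id: %s", grid_row$plan_id),
    sprintf("index: %d", grid_row$index),
    sprintf("offset1_mm: %s", fmt_num(grid_row$offset1)),
    sprintf("offset2_mm: %s", fmt_num(grid_row$offset2)),
    sprintf("x1_mm: %s", fmt_num(grid_row$x1)),
    sprintf("x2_mm: %s", fmt_num(grid_row$x2)),
    sprintf("y1_mm: %s", fmt_num(grid_row$y1)),
    sprintf("y2_mm: %s", fmt_num(grid_row$y2)),
    sprintf("status: %s", status),
    sprintf("scale_applied: %s",
            if (is.na(scale_applied)) "NA" else fmt_num(scale_applied))
  )
  dvh_block <- function(tag, plans) {
    if (is.null(plans)) return(sprintf("[%s] none", tag))
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    write_dvh_csv(plans, tmp)
    c(sprintf("[%s]", tag), readLines(tmp))
  }
  paste(c(header,
          dvh_block("predicted_dvh", predicted),
          dvh_block("final_dvh", final)),
        collapse = "\n")
}

#' Run the jaw search
#'
#' Executes the full pipeline: conformal jaws from the target extent, offset
#' grid, per-plan dose (engine), normalization to prescription, hotspot
#' filtering, cohort scoring and ranking. Every candidate ends in exactly one
#' of three states: `accepted`, `excluded-hotspot`, or `invalid-geometry`
#' (field narrower than `min_width`, or degenerate dose). Per-plan text
#' records — jaw coordinates, status, scale factor, the jaw-invariant
#' predicted DVHs and the final DVHs — are assembled before ranking (plans
#' are disposable; the records are the artifact) and written to `record_dir`
#' when one is given.
#'
#' @param cfg A [search_config].
#' @param extent A [bev_extent] for the target.
#' @param record_dir Optional directory for per-plan record files
#'   (`<plan_id>.txt`); created if missing.
#' @param engine Optional dose engine override: a `function(jaws)` returning
#'   an unnormalized [plan_dose]. Defaults to the shipped surrogate.
#' @return An object of class `search_result`: the configuration, grid,
#'   [score_cohort] table, ranking (best/worst/conformal ids and scores),
#'   per-plan statuses and record texts, the n x n `heatmap` matrix of total
#'   scores (NA where not accepted), a parallel `status` matrix, and
#'   `counts` (total, accepted, excluded, invalid).
#' @export
run_search <- function(cfg, extent, record_dir = NULL, engine = NULL) {
  stopifnot(inherits(cfg, "search_config"), inherits(extent, "bev_extent"))
  conformal <- conformal_jaws(extent, cfg$leaf_width)
  grid <- generate_grid(conformal, cfg$step, cfg$n_steps_per_bank,
                        cfg$min_width)
  scfg <- cfg$surrogate
  if (is.null(scfg))
    scfg <- surrogate_config(prescription = cfg$prescription,
                             conformal_width = conformal$x2 - conformal$x1,
                             seed = cfg$seed,
                             dvh_bin = cfg$bin_width,
                             target_id = cfg$target_id)
  if (is.null(engine)) {
    if (!identical(cfg$engine, "surrogate"))
      stop_jawsearch(sprintf("unknown engine '%s' and no engine function supplied",
                             cfg$engine),
                     "jawsearch_invalid_input")
    engine <- function(jaws) simulate_plan(jaws, scfg)
  }

  nplans <- nrow(grid)
  status <- character(nplans)
  plans <- vector("list", nplans)
  records <- character(nplans)
  scales <- rep(NA_real_, nplans)

  for (i in seq_len(nplans)) {
    row <- grid[i, , drop = FALSE]
    if (!row$valid) {
      status[i] <- "invalid-geometry"
      records[i] <- plan_record_text(row, status[i], NA_real_, NULL, NULL)
      next
    }
    jaws <- list(offset1 = row$offset1, offset2 = row$offset2,
                 plan_id = row$plan_id)
    raw <- engine(jaws)
    predicted <- predict_dvh_stub(jaws, scfg)
    norm <- tryCatch(
      normalize_to_prescription(raw, cfg$target_id, cfg$prescription,
                                cfg$coverage_volume),
      jawsearch_degenerate_plan = function(e) NULL)
    if (is.null(norm)) {
      status[i] <- "invalid-geometry"
      records[i] <- plan_record_text(row, "invalid-geometry", NA_real_,
                                     predicted, raw)
      next
    }
    hot <- is_hotspot_unacceptable(norm, cfg$target_id, cfg$prescription,
                                   cfg$hotspot_limit)
    status[i] <- if (hot) "excluded-hotspot" else "accepted"
    plans[[i]] <- norm
    scales[i] <- norm$scale_applied
    records[i] <- plan_record_text(row, status[i], norm$scale_applied,
                                   predicted, norm)
  }
  names(records) <- grid$plan_id

  if (!is.null(record_dir)) {
    dir.create(record_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nplans)) {
      con <- file(file.path(record_dir, paste0(grid$plan_id[i], ".txt")),
                  open = "wb")
      writeLines(records[i], con, sep = "\n", useBytes = TRUE)
      close(con)
    }
  }

  completed <- which(status %in% c("accepted", "excluded-hotspot"))
  counts <- list(total = nplans,
                 accepted = sum(status == "accepted"),
                 excluded = sum(status == "excluded-hotspot"),
                 invalid = sum(status == "invalid-geometry"))
  if (counts$accepted == 0L)
    stop_jawsearch(sprintf(
      "no acceptable plan in the cohort (total %d: %d hotspot-excluded, %d invalid geometry)",
      counts$total, counts$excluded, counts$invalid),
      "jawsearch_empty_cohort")

  table <- score_cohort(plans[completed], cfg$oars,
                        accepted = status[completed] == "accepted",
                        normalization_set = cfg$normalization_set,
                        bin_width = cfg$bin_width)
  conformal_id <- grid$plan_id[grid$offset1 == 0 & grid$offset2 == 0]
  ranking <- rank_plans(table, conformal_id = conformal_id)

  n <- cfg$n_steps_per_bank
  offs <- (seq_len(n) - 1L) * cfg$step
  heat <- matrix(NA_real_, n, n, dimnames = list(offset1 = offs, offset2 = offs))
  stat_m <- matrix(status, n, n, byrow = TRUE,
                   dimnames = list(offset1 = offs, offset2 = offs))
  score_of <- stats::setNames(table$plan$total_score, table$plan$plan_id)
  acc_ids <- table$plan$plan_id[table$plan$accepted]
  for (i in seq_len(nplans)) {
    if (status[i] == "accepted") {
      r <- (grid$index[i] - 1L) %/% n + 1L
      c2 <- (grid$index[i] - 1L) %% n + 1L
      heat[r, c2] <- score_of[[grid$plan_id[i]]]
    }
  }

  structure(list(config = cfg, extent = extent, conformal = conformal,
                 grid = grid, surrogate = scfg, table = table,
                 ranking = ranking, status = status, scales = scales,
                 records = records, heatmap = heat, status_matrix = stat_m,
                 counts = counts),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d candidate plans (%d x %d grid, %g mm steps)\n",
              x$counts$total, x$config$n_steps_per_bank,
              x$config$n_steps_per_bank, x$config$step))
  cat(sprintf("  accepted %d | excluded (hotspot > %g%%) %d | invalid geometry %d\n",
              x$counts$accepted, x$config$hotspot_limit, x$counts$excluded,
              x$counts$invalid))
  sc <- x$ranking$scores
  cat(sprintf("  best      %s  score %.3f\n", x$ranking$best, sc[["best"]]))
  cat(sprintf("  worst     %s  score %.3f\n", x$ranking$worst, sc[["worst"]]))
  if ("conformal" %in% names(sc))
    cat(sprintf("  conformal %s  score %.3f%s\n", x$ranking$conformal,
                sc[["conformal"]],
                if (isFALSE(x$ranking$conformal_accepted)) " (hotspot-excluded)" else ""))
  invisible(x)
}

#' Export the plan-score heat map
#'
#' Writes the n x n total-score matrix as CSV: rows are bank-1 offsets,
#' columns bank-2 offsets (mm of inward travel; cell (0, 0) is the conformal
#' plan). Hotspot-excluded cells carry the sentinel token `x`, invalid
#' geometry the token `invalid`; accepted cells carry the score at full
#' precision, so a read-back reproduces the score table exactly.
#'
#' @param result A [run_search] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(result, path) {
  stopifnot(inherits(result, "search_result"))
  heat <- result$heatmap
  stat <- result$status_matrix
  cells <- matrix("", nrow(heat), ncol(heat))
  cells[stat == "accepted"] <- fmt_num(heat[stat == "accepted"])
  cells[stat == "excluded-hotspot"] <- "x"
  cells[stat == "invalid-geometry"] <- "invalid"
  lines <- paste0("offset1_mm\\offset2_mm,",
                  paste(colnames(heat), collapse = ","))
  for (r in seq_len(nrow(heat)))
    lines <- c(lines, paste(c(rownames(heat)[r], cells[r, ]), collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read back an exported heat map
#'
#' @param path CSV written by [export_heatmap].
#' @return A list with `scores` (numeric matrix, NA at sentinel cells) and
#'   `status` (character matrix: `accepted`, `excluded-hotspot`,
#'   `invalid-geometry`).
#' @export
read_heatmap <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  cols <- header[-1L]
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  rows <- vapply(body, `[[`, character(1), 1L)
  cells <- t(vapply(body, function(x) x[-1L], character(length(cols))))
  status <- matrix("accepted", nrow(cells), ncol(cells))
  status[cells == "x"] <- "excluded-hotspot"
  status[cells == "invalid"] <- "invalid-geometry"
  scores <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  dimnames(scores) <- dimnames(status) <- list(offset1 = rows, offset2 = cols)
  list(scores = scores, status = status)
}

#' Score externally produced DVH plans
#'
#' Applies the post-engine stages of the pipeline — normalization to
#' prescription, hotspot filtering, cohort scoring, ranking — to plans that
#' were obtained elsewhere (e.g. read from DVH CSV exports of a treatment
#' planning system).
#'
#' @param plans List of unnormalized [plan_dose] objects (each must contain
#'   the target and every configured OAR curve).
#' @param cfg A [search_config].
#' @param conformal_id Optional plan id of the conformal plan, for reporting.
#' @return A list with `table` ([score_cohort] result), `ranking`
#'   ([rank_plans] result), `status` per plan, and `counts`.
#' @export
score_plans <- function(plans, cfg, conformal_id = NULL) {
  stopifnot(inherits(cfg, "search_config"))
  status <- character(length(plans))
  normed <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    norm <- tryCatch(
      normalize_to_prescription(plans[[i]], cfg$target_id, cfg$prescription,
                                cfg$coverage_volume),
      jawsearch_degenerate_plan = function(e) NULL)
    if (is.null(norm)) {
      status[i] <- "invalid-geometry"
      next
    }
    hot <- is_hotspot_unacceptable(norm, cfg$target_id, cfg$prescription,
                                   cfg$hotspot_limit)
    status[i] <- if (hot) "excluded-hotspot" else "accepted"
    normed[[i]] <- norm
  }
  keep <- which(status != "invalid-geometry")
  if (!any(status == "accepted"))
    stop_jawsearch("no acceptable plan among the supplied DVHs",
                   "jawsearch_empty_cohort")
  table <- score_cohort(normed[keep], cfg$oars,
                        accepted = status[keep] == "accepted",
                        normalization_set = cfg$normalization_set,
                        bin_width = cfg$bin_width)
  ranking <- rank_plans(table, conformal_id = conformal_id)
  list(table = table, ranking = ranking, status = status,
       counts = list(total = length(plans),
                     accepted = sum(status == "accepted"),
                     excluded = sum(status == "excluded-hotspot"),
                     invalid = sum(status == "invalid-geometry")))
}

#' Write / read a search configuration as JSON
#'
#' @param cfg A [search_config].
#' @param path JSON file path.
#' @return `path` (write) or a [search_config] (read).
#' @export
write_search_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "search_config"))
  x <- unclass(cfg)
  x$oars <- lapply(cfg$oars, unclass)
  x$surrogate <- if (is.null(cfg$surrogate)) NULL else {
    s <- unclass(cfg$surrogate)
    s$structures <- as.list(s$structures)
    s
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_search_config
#' @export
read_search_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  oars <- x$oars
  if (is.data.frame(oars)) {
    oars <- lapply(seq_len(nrow(oars)), function(i)
      oar_spec(oars$structure[i], oars$hdvp_threshold[i],
               oars$weight_mdvp[i], oars$weight_hdvp[i]))
  } else {
    oars <- lapply(oars, function(o)
      oar_spec(o$structure, o$hdvp_threshold, o$weight_mdvp, o$weight_hdvp))
  }
  surrogate <- NULL
  if (!is.null(x$surrogate)) {
    s <- x$surrogate
    surrogate <- surrogate_config(
      prescription = s$prescription, conformal_width = s$conformal_width,
      structures = as.data.frame(s$structures, stringsAsFactors = FALSE),
      cold_dose = s$cold_dose, margin = s$margin, noise_sd = s$noise_sd,
      seed = s$seed, dvh_bin = s$dvh_bin, target_id = s$target_id)
  }
  search_config(prescription = x$prescription,
                coverage_volume = x$coverage_volume,
                hotspot_limit = x$hotspot_limit, step = x$step,
                n_steps_per_bank = x$n_steps_per_bank,
                leaf_width = x$leaf_width, min_width = x$min_width,
                bin_width = x$bin_width, oars = oars,
                normalization_set = x$normalization_set,
                engine = x$engine, seed = x$seed, surrogate = surrogate,
                target_id = x$target_id)
}
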