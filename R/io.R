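#' Write plans to the DVH CSV dialect
#'
#' Persists cumulative DVH curves as plain text with the header
#' `plan_id,structure,dose_gy,volume_pct`, one row per sample, doses ascending
#' within each structure, UTF-8. Numbers are written with 17 significant
#' digits so a write/read cycle reproduces the doubles bit-exactly.
#'
#' @param plans A [plan_dose] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(plans, path) {
  if (inherits(plans, "plan_dose")) plans <- list(plans)
  stopifnot(all(vapply(plans, inherits, logical(1), "plan_dose")))
  lines <- "plan_id,structure,dose_gy,volume_pct"
  for (pl in plans) {
    for (cv in pl$curves) {
      lines <- c(lines, paste(pl$plan_id, cv$structure,
                              fmt_num(cv$dose), fmt_num(cv$volume), sep = ","))
    }
  }
  con <- file(path, open = "wb") # fixed "\n" endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read plans from the DVH CSV dialect
#'
#' Inverse of [write_dvh_csv]. Curves are validated on construction; doses
#' must be ascending within each (plan, structure) block. Read plans carry
#' `scale_applied = 1` (the dialect stores curves, not normalization state).
#'
#' @param path Input file path.
#' @return A named list of [plan_dose] objects, in file order.
#' @export
read_dvh_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric", "numeric"))
  need <- c("plan_id", "structure", "dose_gy", "volume_pct")
  if (!identical(names(df), need))
    stop_jawsearch(sprintf("DVH CSV must have header %s",
                           paste(need, collapse = ",")),
                   "jawsearch_invalid_input")
  plan_ids <- unique(df$plan_id)
  plans <- lapply(plan_ids, function(pid) {
    sub <- df[df$plan_id == pid, , drop = FALSE]
    structs <- unique(sub$structure)
    curves <- lapply(structs, function(sid) {
      blk <- sub[sub$structure == sid, , drop = FALSE]
      dvh_curve(sid, blk$dose_gy, blk$volume_pct)
    })
    plan_dose(pid, curves)
  })
  names(plans) <- plan_ids
  plans
}
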