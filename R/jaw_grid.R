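#' Beam's-eye-view extent of the target
#'
#' Bounding box of the target projection on the isocenter plane, in signed
#' millimetres with the isocenter (placed at the target centroid) at the
#' origin. The box need not be symmetric.
#'
#' @param x_min,x_max Lateral bounds in mm (`x_min < x_max`).
#' @param y_min,y_max Longitudinal bounds in mm (`y_min < y_max`).
#' @return An object of class `bev_extent`.
#' @export
bev_extent <- function(x_min, x_max, y_min, y_max) {
  if (!(x_min < x_max) || !(y_min < y_max))
    stop_jawsearch("extent bounds must satisfy x_min < x_max and y_min < y_max",
                   "jawsearch_invalid_input")
  structure(list(x_min = as.double(x_min), x_max = as.double(x_max),
                 y_min = as.double(y_min), y_max = as.double(y_max)),
            class = "bev_extent")
}

#' A single jaw setting
#'
#' Four signed jaw coordinates (mm at the isocenter plane, IEC-style: bank 1
#' negative side, `x1 <= x2`, `y1 <= y2`) plus the inward X-jaw travel of each
#' bank relative to the conformal setting. Offsets are stored separately from
#' the absolute coordinates so search grids can be indexed and plotted by
#' travel.
#'
#' @param x1,x2,y1,y2 Jaw coordinates in mm.
#' @param offset1,offset2 Inward travel of the X1 / X2 bank from conformal,
#'   mm, >= 0.
#' @return An object of class `jaw_setting`.
#' @export
jaw_setting <- function(x1, x2, y1, y2, offset1 = 0, offset2 = 0) {
  if (x2 - x1 <= 0)
    stop_jawsearch("jaw setting must have positive field width (x2 > x1)",
                   "jawsearch_invalid_input")
  if (offset1 < 0 || offset2 < 0)
    stop_jawsearch("jaw offsets must be non-negative", "jawsearch_invalid_input")
  structure(list(x1 = as.double(x1), x2 = as.double(x2),
                 y1 = as.double(y1), y2 = as.double(y2),
                 offset1 = as.double(offset1), offset2 = as.double(offset2)),
            class = "jaw_setting")
}

#' Conformal jaw setting from the target extent
#'
#' X jaws are fitted to the target's beam's-eye-view border without margin
#' (a larger opening only adds organ-at-risk exposure through MLC leakage);
#' Y jaws are retracted beyond the border by one adjacent leaf width to
#' capture scatter contribution.
#'
#' @param extent A [bev_extent].
#' @param leaf_width MLC leaf width in mm (default 5, the central-leaf width
#'   of a Millennium 120 MLC); 0 leaves the Y jaws on the border.
#' @return A [jaw_setting] with offsets (0, 0).
#' @examples
#' conformal_jaws(bev_extent(-60, 70, -80, 90), leaf_width = 5)
#' @export
conformal_jaws <- function(extent, leaf_width = 5) {
  stopifnot(inherits(extent, "bev_extent"))
  if (leaf_width < 0)
    stop_jawsearch("'leaf_width' must be non-negative", "jawsearch_invalid_input")
  jaw_setting(x1 = extent$x_min, x2 = extent$x_max,
              y1 = extent$y_min - leaf_width, y2 = extent$y_max + leaf_width,
              offset1 = 0, offset2 = 0)
}

#' Generate the X-jaw search grid
#'
#' Builds the Cartesian product of inward offsets `0, step, ...,
#' (n_steps_per_bank - 1) * step` for each X bank, yielding
#' `n_steps_per_bank^2` candidate settings that include the conformal setting
#' at offsets (0, 0). Settings are indexed row-major in (offset1, offset2)
#' with stable consecutive indices starting at 1 (the conformal plan is index
#' 1). Settings whose residual field width falls below `min_width` are kept
#' in the grid but flagged invalid rather than silently dropped.
#'
#' With the defaults of 5 mm steps and 10 positions per bank, each jaw
#' travels up to 45 mm inward and the grid has 100 settings.
#'
#' @param conformal The conformal [jaw_setting] (offsets 0, 0).
#' @param step Offset increment in mm (> 0, default 5).
#' @param n_steps_per_bank Number of offset positions per bank, including the
#'   conformal position (default 10).
#' @param min_width Minimum admissible field width in mm (default 20).
#' @return A `data.frame` of class `jaw_grid` with columns `index`,
#'   `plan_id`, `offset1`, `offset2`, `x1`, `x2`, `y1`, `y2`, `width`,
#'   `valid`.
#' @export
generate_grid <- function(conformal, step = 5, n_steps_per_bank = 10,
                          min_width = 20) {
  stopifnot(inherits(conformal, "jaw_setting"))
  if (step <= 0)
    stop_jawsearch("'step' must be positive", "jawsearch_invalid_input")
  if (n_steps_per_bank < 1)
    stop_jawsearch("'n_steps_per_bank' must be >= 1", "jawsearch_invalid_input")
  if (min_width <= 0)
    stop_jawsearch("'min_width' must be positive", "jawsearch_invalid_input")
  w0 <- conformal$x2 - conformal$x1
  if (w0 <= min_width)
    stop_jawsearch(sprintf("conformal width %.6g mm <= min_width %.6g mm: no search space",
                           w0, min_width),
                   "jawsearch_no_search_space")
  offs <- (seq_len(n_steps_per_bank) - 1L) * step
  n <- n_steps_per_bank
  # row-major in (offset1, offset2): offset2 varies fastest
  o1 <- rep(offs, each = n)
  o2 <- rep(offs, times = n)
  idx <- seq_len(n * n)
  width <- w0 - o1 - o2
  digits <- nchar(as.character(n * n))
  grid <- data.frame(
    index = idx,
    plan_id = sprintf(paste0("plan_%0", digits, "d"), idx),
    offset1 = o1, offset2 = o2,
    x1 = conformal$x1 + o1, x2 = conformal$x2 - o2,
    y1 = conformal$y1, y2 = conformal$y2,
    width = width,
    valid = width >= min_width,
    stringsAsFactors = FALSE
  )
  class(grid) <- c("jaw_grid", "data.frame")
  grid
}

#' Extract one grid row as a jaw setting
#'
#' @param grid A [generate_grid] result.
#' @param index Grid index (1-based).
#' @return A [jaw_setting].
#' @export
grid_setting <- function(grid, index) {
  stopifnot(inherits(grid, "jaw_grid"))
  row <- grid[grid$index == index, , drop = FALSE]
  if (nrow(row) != 1L)
    stop_jawsearch(sprintf("no grid setting with index %s", index),
                   "jawsearch_invalid_input")
  jaw_setting(row$x1, row$x2, row$y1, row$y2, row$offset1, row$offset2)
}
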