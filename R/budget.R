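#' Growth-zone cell-field area (trapezoid rule)
#'
#' Estimates the number of cells on the ventral growth-zone surface from
#' cell counts along its length and its two widths:
#' `length * (widthA + widthB) / 2`.
#'
#' @param length_cells GZ length in cells.
#' @param widthA_cells Width at the last En stripe, in cells.
#' @param widthB_cells Width at the GZ/telson boundary, in cells.
#' @return Real-valued cell-field area in cells.
#' @export
#' @examples
#' gz_cell_area(13, 22, 28)  # 325
gz_cell_area <- function(length_cells, widthA_cells, widthB_cells) {
  if (any(c(length_cells, widthA_cells, widthB_cells) < 0)) {
    stop("domain error: cell counts must be >= 0", call. = FALSE)
  }
  length_cells * (widthA_cells + widthB_cells) / 2
}

#' Newly added segment cell-field area (rectangle rule)
#'
#' `last segment length * width A`, both in cells.
#'
#' @param length_cells Last-segment length in cells.
#' @param widthA_cells Width at the last En stripe, in cells.
#' @return Real-valued cell-field area in cells.
#' @export
#' @examples
#' segment_cell_area(4, 22)  # 88
segment_cell_area <- function(length_cells, widthA_cells) {
  if (any(c(length_cells, widthA_cells) < 0)) {
    stop("domain error: cell counts must be >= 0", call. = FALSE)
  }
  length_cells * widthA_cells
}

#' Average divisions required of the initial growth-zone pool
#'
#' How many times, on average, each cell of the initial growth-zone pool
#' must divide for the pool to produce all new segmental tissue. Under the
#' default full-depletion lineage model (all final tissue descends from
#' the initial pool, which is itself consumed -- the growth zone shrinks),
#' `d = log2(total_new_cells / g0_cells)`, floored at 0 when the new
#' tissue does not exceed the pool. The alternative persistence model (the
#' pool survives alongside its output) gives
#' `d = log2(1 + total_new_cells / g0_cells)`.
#'
#' @param g0_cells Initial GZ cell count (> 0).
#' @param total_new_cells Total new-cell area over all added segments.
#' @param model `"depletion"` (default) or `"persistence"`.
#' @return Real-valued average number of doublings.
#' @export
#' @examples
#' divisions_required(325, 650)  # 1
divisions_required <- function(g0_cells, total_new_cells,
                               model = c("depletion", "persistence")) {
  model <- match.arg(model)
  if (!is.numeric(g0_cells) || g0_cells <= 0) {
    stop("domain error: g0_cells must be > 0", call. = FALSE)
  }
  if (total_new_cells < 0) {
    stop("domain error: total_new_cells must be >= 0", call. = FALSE)
  }
  if (model == "depletion") {
    max(0, log2(total_new_cells / g0_cells))
  } else {
    log2(1 + total_new_cells / g0_cells)
  }
}

#' Ventral-area bookkeeping: growth zone versus all added segments
#'
#' Sums the per-stage newest-segment ventral areas (each measured just as
#' the segment forms) and expresses the initial growth-zone area as a
#' percentage of that total.
#'
#' @param gz_area0_mm2 Hatchling GZ ventral area in mm^2.
#' @param per_stage_last_segment_areas_mm2 Numeric vector of newest-
#'   segment areas (mm^2), one per added segment.
#' @return List with `total_mm2` and `fraction_pct` (NA when the total is
#'   0 and the GZ area is positive; 0 when the GZ area is 0).
#' @export
#' @examples
#' area_bookkeeping(0.0118, rep(0.029 / 14, 14))$fraction_pct  # ~40.7
area_bookkeeping <- function(gz_area0_mm2, per_stage_last_segment_areas_mm2) {
  if (gz_area0_mm2 < 0 || any(per_stage_last_segment_areas_mm2 < 0)) {
    stop("domain error: areas must be >= 0", call. = FALSE)
  }
  total <- sum(per_stage_last_segment_areas_mm2)
  fraction <- if (gz_area0_mm2 == 0) {
    0
  } else if (total > 0) {
    100 * gz_area0_mm2 / total
  } else {
    NA_real_
  }
  list(total_mm2 = total, fraction_pct = fraction)
}

#' Percent change between two values
#'
#' @param v0 Baseline value (> 0).
#' @param v1 New value.
#' @return `100 * (v1 - v0) / v0`.
#' @export
#' @examples
#' percent_change(0.41, 0.98)  # ~139, "about 140%"
percent_change <- function(v0, v1) {
  if (any(v0 <= 0)) stop("domain error: v0 must be > 0", call. = FALSE)
  100 * (v1 - v0) / v0
}

#' Round to the nearest ten for "about N%" reporting
#'
#' @param x Numeric.
#' @return `x` rounded to the nearest multiple of 10.
#' @export
#' @examples
#' report_about(139.02)  # 140
report_about <- function(x) round(x / 10) * 10

#' Assemble a division budget
#'
#' Bundles the initial growth-zone cell pool, the ordered per-segment
#' new-cell areas, and optional ventral areas into a `division_budget`
#' object carrying the derived totals and required doublings.
#'
#' @param g0_cells Initial GZ cell-field area in cells (> 0).
#' @param segment_cells Ordered numeric vector of per-segment new-cell
#'   areas in cells.
#' @param gz_area0_mm2 Optional hatchling GZ ventral area (mm^2).
#' @param segment_areas_mm2 Optional per-stage newest-segment ventral
#'   areas (mm^2).
#' @param model Lineage model passed to [divisions_required()].
#' @return A `division_budget` list.
#' @export
#' @examples
#' division_budget(325, c(rep(4, 5), rep(3, 4), rep(2, 5)) * 22)
division_budget <- function(g0_cells, segment_cells,
                            gz_area0_mm2 = NA_real_,
                            segment_areas_mm2 = NULL,
                            model = c("depletion", "persistence")) {
  model <- match.arg(model)
  total <- sum(segment_cells)
  book <- if (!is.na(gz_area0_mm2) && !is.null(segment_areas_mm2)) {
    area_bookkeeping(gz_area0_mm2, segment_areas_mm2)
  } else {
    list(total_mm2 = NA_real_, fraction_pct = NA_real_)
  }
  out <- list(
    g0_cells = g0_cells,
    segment_cells = segment_cells,
    total_new_cells = total,
    divisions_required = divisions_required(g0_cells, total, model),
    model = model,
    gz_area0_mm2 = gz_area0_mm2,
    total_segment_area_mm2 = book$total_mm2,
    gz_area_fraction_pct = book$fraction_pct
  )
  class(out) <- "division_budget"
  out
}

#' @export
print.division_budget <- function(x, ...) {
  cat(sprintf("<division_budget> G0 = %.0f cells; %d segments totalling %.0f new cells\n",
              x$g0_cells, length(x$segment_cells), x$total_new_cells))
  cat(sprintf("  divisions required (%s model): %.2f\n",
              x$model, x$divisions_required))
  if (!is.na(x$gz_area_fraction_pct)) {
    cat(sprintf("  GZ area %.4f mm^2 = %.1f%% of %.4f mm^2 total new-segment area\n",
                x$gz_area0_mm2, x$gz_area_fraction_pct, x$total_segment_area_mm2))
  }
  invisible(x)
}

#' Build a division budget from a measured cohort
#'
#' Uses cell counts measured on a cohort: the growth-zone trapezoid area
#' at the earliest timepoint as the initial pool, and for each stripe
#' count above the hatchling complement, the newest segment's cell-field
#' area (median measured last-segment length times width A) as that
#' segment's new-cell area. Ventral areas are carried alongside for the
#' area bookkeeping.
#'
#' @param cohort A measured `cohort_table` (see [generate_cohort()]).
#' @param model Lineage model passed to [divisions_required()].
#' @return A `division_budget`.
#' @export
budget_from_cohort <- function(cohort, model = c("depletion", "persistence")) {
  model <- match.arg(model)
  need <- c("stage_h", "en_stripes", "gz_length_cells", "gz_widthA_cells",
            "gz_widthB_cells", "last_segment_length_cells",
            "last_segment_area_mm2", "gz_area_mm2")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    stop("cohort lacks measured columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  med <- function(x) stats::median(x, na.rm = TRUE)
  first <- cohort[cohort$stage_h == min(cohort$stage_h), , drop = FALSE]
  g0 <- gz_cell_area(med(first$gz_length_cells),
                     med(first$gz_widthA_cells),
                     med(first$gz_widthB_cells))
  gz_area0 <- med(first$gz_area_mm2)
  en0 <- min(cohort$en_stripes)
  levels_above <- sort(unique(cohort$en_stripes[cohort$en_stripes > en0]))
  seg_cells <- numeric(0)
  seg_areas <- numeric(0)
  for (k in levels_above) {
    rows <- cohort[cohort$en_stripes == k, , drop = FALSE]
    seg_cells <- c(seg_cells,
                   segment_cell_area(med(rows$last_segment_length_cells),
                                     med(rows$gz_widthA_cells)))
    seg_areas <- c(seg_areas, med(rows$last_segment_area_mm2))
  }
  division_budget(g0, seg_cells, gz_area0_mm2 = gz_area0,
                  segment_areas_mm2 = seg_areas, model = model)
}
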