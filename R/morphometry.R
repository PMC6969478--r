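# Straight midline path between two axial positions, inset by one corridor
# half-width at each end so the corridor's end caps do not leak across the
# bounding landmarks (boundary-exclusive count).
midline_span_path <- function(x0, x1, hw) {
  a <- x0 + hw
  b <- x1 - hw
  if (b < a) b <- a
  cbind(x = c(a, b), y = c(0, 0))
}

# Vertical width path across the field at axial position x.
width_path_at <- function(field, x) {
  lm <- field$landmarks
  cbind(x = c(x, x),
        y = c(interp_margin(lm$margin_left, x),
              interp_margin(lm$margin_right, x)))
}

#' Score complete En stripes in a cell field
#'
#' A stripe is scored only when its labeled nuclei form a connected chain
#' spanning the ventral surface from one lateral margin to the other:
#' consecutive nuclei (ordered mediolaterally) must be no farther apart
#' than 1.5 cell diameters, and the chain ends must come within the same
#' distance of each lateral margin. Scattered En-positive cells are not
#' counted as a segment.
#'
#' @param field A `cell_field`.
#' @param gap_factor Adjacency threshold in cell diameters (default 1.5).
#' @return Integer count of complete stripes.
#' @export
score_en_stripes <- function(field, gap_factor = 1.5) {
  stopifnot(inherits(field, "cell_field"))
  lm <- field$landmarks
  if (is.null(lm$margin_left) || is.null(lm$margin_right)) {
    stop("landmark error: lateral margins required to score stripes",
         call. = FALSE)
  }
  nuc <- field$nuclei
  thr <- gap_factor * field$config$cell_diameter_um
  ids <- sort(unique(nuc$stripe_id[!is.na(nuc$stripe_id)]))
  n_ok <- 0L
  for (id in ids) {
    s <- nuc[!is.na(nuc$stripe_id) & nuc$stripe_id == id, , drop = FALSE]
    if (nrow(s) < 2) next
    o <- order(s$y_um)
    xs <- s$x_um[o]; ys <- s$y_um[o]
    gaps <- sqrt(diff(xs)^2 + diff(ys)^2)
    if (any(gaps > thr)) next
    xm <- stats::median(xs)
    left_y <- interp_margin(lm$margin_left, xm)
    right_y <- interp_margin(lm$margin_right, xm)
    if ((ys[1] - left_y) > thr) next
    if ((right_y - ys[length(ys)]) > thr) next
    n_ok <- n_ok + 1L
  }
  n_ok
}

#' Measure one larva: the eight morphometric measures plus cell counts
#'
#' Computes the standard measure set from a cell field's landmarks:
#' body length, growth-zone length, growth-zone widths A (at the last En
#' stripe) and B (at the GZ/telson boundary), trunk ventral area, last
#' segment area, GZ area, and last segment length, each with its
#' cell-count analogue where defined, plus growth-zone mitosis counts
#' under both markers. Linear measures are polyline arclengths, areas are
#' shoelace polygon areas on landmark-bounded polygons, and cell counts
#' use [count_cells_along()] on the same paths with the default corridor
#' half-width of half a cell diameter. Millimetre values are micrometres
#' divided by 1000. The function is deterministic: repeated calls on one
#' field are identical.
#'
#' When fewer than two stripes are present the last-segment measures are
#' returned as `NA` (flagged absent).
#'
#' @param field A `cell_field`.
#' @param corridor_halfwidth Corridor half-width in micrometres for cell
#'   counts.
#' @return A one-row data frame of class `morphometric_record`.
#' @export
#' @examples
#' f <- generate_larva(0, gz_config(), seed = 0)
#' measure_larva(f)$gz_length_cells
measure_larva <- function(field,
                          corridor_halfwidth = field$config$cell_diameter_um / 2) {
  stopifnot(inherits(field, "cell_field"))
  lm <- field$landmarks
  need <- c("midline", "trunk_x_start", "stripes", "gz_x_start", "gz_x_end",
            "body_x_end", "widthA_x", "widthB_x", "margin_left", "margin_right")
  miss <- need[!vapply(need, function(n) !is.null(lm[[n]]), logical(1))]
  if (length(miss) > 0) {
    stop("landmark error: missing landmark(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  hw <- corridor_halfwidth
  en <- score_en_stripes(field)

  body_length_um <- polyline_length(lm$midline)

  gz_path <- midline_span_path(lm$gz_x_start, lm$gz_x_end, hw)
  gz_length_um <- lm$gz_x_end - lm$gz_x_start
  gz_length_cells <- count_cells_along(field, gz_path, hw)

  wa_path <- width_path_at(field, lm$widthA_x)
  wb_path <- width_path_at(field, lm$widthB_x)
  widthA_um <- polyline_length(wa_path)
  widthB_um <- polyline_length(wb_path)
  widthA_cells <- count_cells_along(field, wa_path, hw)
  widthB_cells <- count_cells_along(field, wb_path, hw)

  trunk_area_um2 <- polygon_area(region_polygon(field, lm$trunk_x_start, lm$gz_x_end))
  gz_area_um2 <- if (lm$gz_x_end > lm$gz_x_start) {
    polygon_area(region_polygon(field, lm$gz_x_start, lm$gz_x_end))
  } else 0

  if (en >= 2 && nrow(lm$stripes) >= 2) {
    ns <- nrow(lm$stripes)
    x_pen_post <- lm$stripes$x_posterior[ns - 1]
    x_last_ant <- lm$stripes$x_anterior[ns]
    last_len_um <- x_last_ant - x_pen_post
    ls_path <- midline_span_path(x_pen_post, x_last_ant, hw)
    last_len_cells <- count_cells_along(field, ls_path, hw)
    last_area_um2 <- polygon_area(region_polygon(field, x_pen_post, lm$gz_x_start))
  } else {
    last_len_um <- NA_real_
    last_len_cells <- NA_integer_
    last_area_um2 <- NA_real_
  }

  gz_nuc <- field$nuclei[field$nuclei$region == "growth_zone", , drop = FALSE]

  rec <- data.frame(
    en_stripes = en,
    body_length_mm = body_length_um / 1000,
    gz_length_mm = gz_length_um / 1000,
    gz_length_cells = as.integer(gz_length_cells),
    gz_widthA_mm = widthA_um / 1000,
    gz_widthA_cells = as.integer(widthA_cells),
    gz_widthB_mm = widthB_um / 1000,
    gz_widthB_cells = as.integer(widthB_cells),
    trunk_area_mm2 = trunk_area_um2 / 1e6,
    last_segment_area_mm2 = last_area_um2 / 1e6,
    gz_area_mm2 = gz_area_um2 / 1e6,
    last_segment_length_mm = last_len_um / 1000,
    last_segment_length_cells = as.integer(last_len_cells),
    mitoses_gz_hoechst = sum(gz_nuc$m_hoechst),
    mitoses_gz_ph3 = sum(gz_nuc$m_ph3),
    stage_h = field$stage_h,
    tagma = assign_tagma(en, quiet = TRUE),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("morphometric_record", "data.frame")
  rec
}

# The eight linear/area measures entering the PCA (cell counts and stripe
# number excluded, matching the measurement protocol).
MEASURE_COLS <- c("body_length_mm", "gz_length_mm", "gz_widthA_mm",
                  "gz_widthB_mm", "trunk_area_mm2", "last_segment_area_mm2",
                  "gz_area_mm2", "last_segment_length_mm")
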