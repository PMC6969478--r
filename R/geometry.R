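#' Absolute polygon area by the shoelace rule
#'
#' Orientation-independent area of a simple closed polygon. The closing
#' edge from the last vertex back to the first is implicit; a duplicated
#' final vertex is tolerated.
#'
#' @param vertices Two-column numeric matrix (or data frame) of vertex
#'   coordinates in order around the ring.
#' @return Area in squared input units.
#' @export
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square -> 1
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2) {
    stop("geometry error: vertices must be a 2-column numeric matrix",
         call. = FALSE)
  }
  # drop a duplicated closing vertex
  n <- nrow(v)
  if (n >= 2 && all(v[1, ] == v[n, ])) {
    v <- v[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) stop("geometry error: polygon needs >= 3 vertices", call. = FALSE)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Arclength of a polyline
#'
#' @param path Two-column numeric matrix of polyline vertices.
#' @return Total length in input units.
#' @export
polyline_length <- function(path) {
  p <- as.matrix(path)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# Minimum distance from each point to a polyline (vectorized over points).
dist_to_polyline <- function(px, py, path) {
  p <- as.matrix(path)
  if (nrow(p) < 1) stop("geometry error: empty path", call. = FALSE)
  if (nrow(p) == 1) {
    return(sqrt((px - p[1, 1])^2 + (py - p[1, 2])^2))
  }
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(p) - 1)) {
    ax <- p[i, 1]; ay <- p[i, 2]
    bx <- p[i + 1, 1]; by <- p[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    if (len2 == 0) {
      dx <- px - ax; dy <- py - ay
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
      dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    }
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Count nuclei along a measurement path
#'
#' Counts nuclei whose centre lies within a corridor of half-width
#' `corridor_halfwidth` around the polyline `path`. This is the cell-count
#' analogue of a linear measure: counting nuclei "along" a measured line.
#'
#' @param field A `cell_field` object.
#' @param path Two-column matrix of polyline vertices (micrometres).
#' @param corridor_halfwidth Corridor half-width in micrometres; default is
#'   half the configured cell diameter.
#' @return Integer count of nuclei in the corridor.
#' @export
count_cells_along <- function(field, path,
                              corridor_halfwidth = field$config$cell_diameter_um / 2) {
  stopifnot(inherits(field, "cell_field"))
  p <- as.matrix(path)
  if (nrow(p) == 0) stop("geometry error: empty path", call. = FALSE)
  if (!is.numeric(corridor_halfwidth) || corridor_halfwidth <= 0) {
    stop("geometry error: corridor_halfwidth must be > 0", call. = FALSE)
  }
  nuc <- field$nuclei
  if (nrow(nuc) == 0) return(0L)
  # cheap bounding-box prefilter before exact segment distances
  keep <- nuc$x_um >= min(p[, 1]) - corridor_halfwidth &
    nuc$x_um <= max(p[, 1]) + corridor_halfwidth &
    nuc$y_um >= min(p[, 2]) - corridor_halfwidth &
    nuc$y_um <= max(p[, 2]) + corridor_halfwidth
  if (!any(keep)) return(0L)
  d <- dist_to_polyline(nuc$x_um[keep], nuc$y_um[keep], p)
  sum(d <= corridor_halfwidth)
}

# Linear interpolation of a lateral-margin polyline (x-monotone) at x0.
interp_margin <- function(margin, x0) {
  stats::approx(margin[, 1], margin[, 2], xout = x0, rule = 2)$y
}

# Closed polygon bounded laterally by the field's margins and
# anteriorly/posteriorly by vertical lines at x0 < x1.
region_polygon <- function(field, x0, x1) {
  lm <- field$landmarks
  left <- lm$margin_left
  right <- lm$margin_right
  if (is.null(left) || is.null(right)) {
    stop("landmark error: lateral margins missing", call. = FALSE)
  }
  if (x1 <= x0) stop("geometry error: require x0 < x1", call. = FALSE)
  sel_r <- right[, 1] > x0 & right[, 1] < x1
  sel_l <- left[, 1] > x0 & left[, 1] < x1
  rx <- c(x0, right[sel_r, 1], x1)
  ry <- c(interp_margin(right, x0), right[sel_r, 2], interp_margin(right, x1))
  lx <- c(x1, rev(left[sel_l, 1]), x0)
  ly <- c(interp_margin(left, x1), rev(left[sel_l, 2]), interp_margin(left, x0))
  cbind(c(rx, lx), c(ry, ly))
}
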