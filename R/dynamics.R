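#' Mitotic index for a region under one marker
#'
#' Counts nuclei flagged as mitotic by the chosen marker within a region
#' and divides by the region's nucleus total. Hoechst (metaphase--
#' telophase morphology) and pH3 (prophase/metaphase immunolabel) are
#' scored independently; neither is a subset of the other.
#'
#' @param field A `cell_field`.
#' @param region One of `"growth_zone"`, `"segmented"`, `"telson"`.
#' @param marker One of `"hoechst"`, `"ph3"`.
#' @return List with `count`, `fraction` (NA when the region is empty),
#'   and `n_region`.
#' @export
#' @examples
#' f <- generate_larva(0, gz_config(), seed = 1)
#' mitotic_index(f, "growth_zone", "hoechst")
mitotic_index <- function(field, region = c("growth_zone", "segmented", "telson"),
                          marker = c("hoechst", "ph3")) {
  stopifnot(inherits(field, "cell_field"))
  region <- match.arg(region)
  marker <- match.arg(marker)
  nuc <- field$nuclei[field$nuclei$region == region, , drop = FALSE]
  flag <- if (marker == "hoechst") nuc$m_hoechst else nuc$m_ph3
  n <- nrow(nuc)
  cnt <- sum(flag)
  list(count = as.integer(cnt),
       fraction = if (n > 0) cnt / n else NA_real_,
       n_region = n)
}

#' Classify a spindle angle as AP or transverse
#'
#' Angles are measured to the anterior--posterior body axis in degrees.
#' The cutoff is 45 degrees with the tie assigned to AP: an angle of
#' exactly 45 classifies as `"AP"`.
#'
#' @param angle_deg Numeric angle(s) in `[0, 90]`.
#' @return Character vector of `"AP"` / `"transverse"`.
#' @export
#' @examples
#' classify_orientation(c(0, 45, 90))
classify_orientation <- function(angle_deg) {
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0) || any(angle_deg > 90)) {
    stop("domain error: angle must be in [0, 90]", call. = FALSE)
  }
  ifelse(angle_deg <= 45, "AP", "transverse")
}

#' Spindle-orientation summary by region
#'
#' Applies [classify_orientation()] to every mitotic nucleus (either
#' marker flag) and tallies AP-oriented fractions overall and within the
#' growth zone and segmented trunk.
#'
#' @param field A `cell_field`.
#' @return An `orientation_summary` list: `n_mitoses`, `n_ap`,
#'   `ap_fraction` (NA when no mitoses), and `by_region` (data frame).
#' @export
orientation_summary <- function(field) {
  stopifnot(inherits(field, "cell_field"))
  nuc <- field$nuclei
  m <- nuc$m_hoechst | nuc$m_ph3
  mn <- nuc[m, , drop = FALSE]
  cls <- if (nrow(mn) > 0) classify_orientation(mn$spindle_deg) else character(0)
  tally <- function(sel) {
    n <- sum(sel)
    nap <- sum(cls[sel] == "AP")
    c(n_mitoses = n, n_ap = nap,
      ap_fraction = if (n > 0) nap / n else NA_real_)
  }
  regions <- c("growth_zone", "segmented")
  by_region <- as.data.frame(t(vapply(regions, function(r) tally(mn$region == r),
                                      numeric(3))))
  by_region$region <- regions
  by_region <- by_region[, c("region", "n_mitoses", "n_ap", "ap_fraction")]
  out <- list(n_mitoses = nrow(mn),
              n_ap = sum(cls == "AP"),
              ap_fraction = if (nrow(mn) > 0) mean(cls == "AP") else NA_real_,
              by_region = by_region)
  class(out) <- "orientation_summary"
  out
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf("<orientation_summary> %d mitoses, %d AP (fraction %s)\n",
              x$n_mitoses, x$n_ap,
              if (is.na(x$ap_fraction)) "NA" else sprintf("%.2f", x$ap_fraction)))
  print(x$by_region, row.names = FALSE)
  invisible(x)
}

#' Detect S-phase (EdU) domains along the posterior body axis
#'
#' Computes a sliding-window S-phase-fraction profile from just posterior
#' of the penultimate En stripe to the growth-zone/telson boundary, then
#' classifies windows as `synchronous_band` (fraction >= `band_thresh`),
#' `clear` (<= `clear_thresh`) or `scattered` (otherwise), merges adjacent
#' same-class windows, and absorbs any domain narrower than one window
#' width into its anterior neighbour (such slivers arise where a window
#' straddles a true boundary and sees a mixed fraction).
#'
#' In the canonical pattern the result, anterior to posterior, is
#' `synchronous_band` (the newest segment), `clear` (anterior growth
#' zone), `scattered` (posterior growth zone).
#'
#' @param field A `cell_field` with at least two En stripes.
#' @param window_um Window width in micrometres (default two cell
#'   diameters).
#' @param step_um Window step (default half a cell diameter).
#' @param band_thresh,clear_thresh Classification thresholds on the
#'   S-phase fraction.
#' @return An `edu_domain_profile` list: `window_um`, `profile` (data
#'   frame `x_center`, `s_fraction`, `n`), `domains` (data frame `class`,
#'   `x_start`, `x_end`), `band_sync_fraction`, `ph3_in_band`.
#' @export
detect_edu_domains <- function(field,
                               window_um = 2 * field$config$cell_diameter_um,
                               step_um = field$config$cell_diameter_um / 2,
                               band_thresh = 0.8,
                               clear_thresh = 0.1) {
  stopifnot(inherits(field, "cell_field"))
  if (!is.numeric(window_um) || window_um <= 0) {
    stop("geometry error: window_um must be > 0", call. = FALSE)
  }
  lm <- field$landmarks
  if (nrow(lm$stripes) < 2) {
    stop("domain error: need >= 2 En stripes to profile the posterior",
         call. = FALSE)
  }
  x0 <- lm$stripes$x_posterior[nrow(lm$stripes) - 1]
  x1 <- lm$gz_x_end
  if (window_um > (x1 - x0)) {
    stop("geometry error: window larger than profiled span", call. = FALSE)
  }
  centers <- seq(x0 + window_um / 2, x1 - window_um / 2, by = step_um)
  nuc <- field$nuclei
  in_span <- nuc$x_um >= x0 & nuc$x_um <= x1
  sp <- nuc[in_span, , drop = FALSE]
  frac <- numeric(length(centers))
  nn <- integer(length(centers))
  for (i in seq_along(centers)) {
    sel <- abs(sp$x_um - centers[i]) <= window_um / 2
    nn[i] <- sum(sel)
    frac[i] <- if (nn[i] > 0) mean(sp$s_phase[sel]) else NA_real_
  }
  cls <- ifelse(is.na(frac), NA_character_,
                ifelse(frac >= band_thresh, "synchronous_band",
                       ifelse(frac <= clear_thresh, "clear", "scattered")))
  # carry class forward over empty windows (rare on lattice fields)
  for (i in seq_along(cls)) if (is.na(cls[i]) && i > 1) cls[i] <- cls[i - 1]
  if (any(is.na(cls))) cls[is.na(cls)] <- "scattered"

  # run-length domains over window classes; domain boundaries sit midway
  # between the last and first window centers of adjacent runs
  run_bounds <- function(cls) {
    runs <- rle(cls)
    ends <- cumsum(runs$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    inner <- if (length(ends) > 1) {
      (centers[ends[-length(ends)]] + centers[ends[-length(ends)] + 1]) / 2
    } else numeric(0)
    list(values = runs$values, starts = starts, ends = ends,
         x_start = c(x0, inner), x_end = c(inner, x1))
  }
  # absorb boundary slivers (domains narrower than one window, arising
  # where a window straddles a true boundary) into the anterior neighbour
  repeat {
    rb <- run_bounds(cls)
    if (length(rb$values) <= 1) break
    widths <- rb$x_end - rb$x_start
    small <- which(widths < window_um)
    if (length(small) == 0) break
    i <- small[which.min(widths[small])]
    donor <- if (i > 1) rb$values[i - 1] else rb$values[i + 1]
    cls[rb$starts[i]:rb$ends[i]] <- donor
  }
  rb <- run_bounds(cls)
  domains <- data.frame(class = rb$values, x_start = rb$x_start,
                        x_end = rb$x_end, stringsAsFactors = FALSE)

  band <- domains[domains$class == "synchronous_band", , drop = FALSE]
  if (nrow(band) > 0) {
    in_band <- sp$x_um >= band$x_start[1] & sp$x_um <= band$x_end[1]
    band_frac <- if (any(in_band)) mean(sp$s_phase[in_band]) else NA_real_
    ph3_in_band <- sum(sp$m_ph3[in_band])
  } else {
    band_frac <- NA_real_
    ph3_in_band <- NA_integer_
  }

  out <- list(window_um = window_um,
              span = c(x_start = x0, x_end = x1),
              profile = data.frame(x_center = centers, s_fraction = frac, n = nn),
              domains = domains,
              band_sync_fraction = band_frac,
              ph3_in_band = ph3_in_band)
  class(out) <- "edu_domain_profile"
  out
}

#' @export
print.edu_domain_profile <- function(x, ...) {
  cat(sprintf("<edu_domain_profile> window %.1f um, span %.1f-%.1f um\n",
              x$window_um, x$span[1], x$span[2]))
  print(x$domains, row.names = FALSE)
  invisible(x)
}

#' pH3 exclusion from the synchronous S-phase band
#'
#' Compares the observed number of pH3-positive nuclei inside the detected
#' synchronous band with the expectation under uniform placement (the
#' band's share of profiled nuclei times the total pH3 count in the
#' profiled span). A ratio below 1 indicates exclusion of M-phase cells
#' from the band.
#'
#' @param field A `cell_field`.
#' @param profile An [detect_edu_domains()] result for `field`.
#' @return List with `observed`, `expected`, `ratio` (NA when expectation
#'   is 0), or `absent = TRUE` when no band was detected.
#' @export
ph3_band_exclusion <- function(field, profile) {
  stopifnot(inherits(field, "cell_field"), inherits(profile, "edu_domain_profile"))
  band <- profile$domains[profile$domains$class == "synchronous_band", , drop = FALSE]
  if (nrow(band) == 0) {
    return(list(absent = TRUE, observed = NA_integer_,
                expected = NA_real_, ratio = NA_real_))
  }
  nuc <- field$nuclei
  sp <- nuc[nuc$x_um >= profile$span[1] & nuc$x_um <= profile$span[2], , drop = FALSE]
  in_band <- sp$x_um >= band$x_start[1] & sp$x_um <= band$x_end[1]
  observed <- sum(sp$m_ph3[in_band])
  total_ph3 <- sum(sp$m_ph3)
  share <- if (nrow(sp) > 0) sum(in_band) / nrow(sp) else NA_real_
  expected <- share * total_ph3
  list(absent = FALSE,
       observed = as.integer(observed),
       expected = expected,
       ratio = if (!is.na(expected) && expected > 0) observed / expected else NA_real_)
}

#' Concordance between S-phase domains and posterior expression domains
#'
#' Pairs the detected cell-cycle domains with the canonical posterior
#' expression territories (*WntA* with the S-phase-clear anterior growth
#' zone, *Wnt4* with the scattered posterior growth zone, and the
#' synchronous band's posterior edge with the anterior borders of *cad*
#' and *WntA*) and reports the signed axial offset
#' (expression minus detected) for each paired boundary in micrometres.
#'
#' @param profile An [detect_edu_domains()] result.
#' @param expression_domains Data frame with columns `gene`, `x_start`,
#'   `x_end` (ordered, non-overlapping per gene), e.g. from
#'   [expression_domains()].
#' @return Data frame with columns `pair`, `offset_um`; missing named
#'   domains yield `NA` offsets for their pairs.
#' @export
boundary_concordance <- function(profile, expression_domains) {
  stopifnot(inherits(profile, "edu_domain_profile"))
  ed <- expression_domains
  need <- c("gene", "x_start", "x_end")
  if (!all(need %in% names(ed))) {
    stop("expression_domains must have columns gene, x_start, x_end",
         call. = FALSE)
  }
  gene_int <- function(g) {
    r <- ed[ed$gene == g, , drop = FALSE]
    if (nrow(r) == 0) c(NA_real_, NA_real_) else c(r$x_start[1], r$x_end[1])
  }
  dom_int <- function(cl) {
    r <- profile$domains[profile$domains$class == cl, , drop = FALSE]
    if (nrow(r) == 0) c(NA_real_, NA_real_) else c(r$x_start[1], r$x_end[1])
  }
  wnta <- gene_int("WntA"); wnt4 <- gene_int("Wnt4"); cad <- gene_int("cad")
  clear <- dom_int("clear"); scat <- dom_int("scattered")
  band <- dom_int("synchronous_band")
  data.frame(
    pair = c("WntA_start_vs_clear_start", "WntA_end_vs_clear_end",
             "Wnt4_start_vs_scattered_start", "Wnt4_end_vs_scattered_end",
             "WntA_start_vs_band_end", "cad_start_vs_band_end"),
    offset_um = c(wnta[1] - clear[1], wnta[2] - clear[2],
                  wnt4[1] - scat[1], wnt4[2] - scat[2],
                  wnta[1] - band[2], cad[1] - band[2]),
    stringsAsFactors = FALSE
  )
}
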