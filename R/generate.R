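#' Developmental stage clock: En stripe count at a given age
#'
#' Segments are specified at a constant rate of one per `interval_h` hours
#' from `initial_stripes` trunk En stripes at hatch, capped at
#' `max_stripes`.
#'
#' @param t Hours post hatch (vectorized, non-negative).
#' @param config A [gz_config()].
#' @return Integer En stripe count(s), monotone non-decreasing in `t`.
#' @export
#' @examples
#' stage_clock(0, gz_config())    # 3
#' stage_clock(1.4, gz_config())  # 4
stage_clock <- function(t, config = gz_config()) {
  validate_gz_config(config)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("domain error: t must be finite and >= 0", call. = FALSE)
  }
  # small epsilon guards floating division at exact multiples of interval_h
  n <- config$initial_stripes + floor(t / config$interval_h + 1e-9)
  as.integer(pmin(config$max_stripes, n))
}

#' Growth-zone length (in cells) at a given age
#'
#' The GZ starts at `gz_length0_cells` and loses `gz_shrink_per_segment`
#' cells per added segment; at the first molt it gains
#' `molt_gz_gain_cells`. In `constant_gz_mode` the length is held at its
#' hatchling value (the *Artemia*-like condition).
#'
#' @inheritParams stage_clock
#' @return Real-valued GZ length in cells (the generator rounds to a whole
#'   number of nucleus rows, with a floor of 1).
#' @export
gz_length_cells_at <- function(t, config = gz_config()) {
  validate_gz_config(config)
  if (any(t < 0)) stop("domain error: t must be >= 0", call. = FALSE)
  if (config$constant_gz_mode) {
    return(rep(as.numeric(config$gz_length0_cells), length(t)))
  }
  n_added <- as.numeric(stage_clock(t, config) - config$initial_stripes)
  L <- config$gz_length0_cells - n_added * config$gz_shrink_per_segment +
    ifelse(t >= config$molt_time_h, config$molt_gz_gain_cells, 0)
  pmax(1, L)
}

# Lengths (cells, between-stripe) of segments 1..n_stripes: hatchling
# segments have a fixed length; added segments follow the configured
# order-dependent list (recycling its last entry beyond the list).
segment_lengths <- function(n_stripes, config) {
  lens <- rep(config$initial_seg_length_cells, config$initial_stripes)
  n_added <- n_stripes - config$initial_stripes
  if (n_added > 0) {
    byo <- config$seg_length_cells_by_order
    idx <- pmin(seq_len(n_added), length(byo))
    lens <- c(lens, byo[idx])
  }
  lens[seq_len(n_stripes)]
}

#' Generate one synthetic larva as a 2D ventral cell field
#'
#' Nuclei are placed on a jittered rectangular lattice (spacing
#' `cell_diameter_um`, jitter uniform within ±0.2 spacing, odd cell counts
#' per row so a nucleus column lies on the midline). Axially the field is:
#' head region, `stage_clock(t)` trunk segments (each ending in a
#' transverse En stripe row), the growth zone (width interpolating from
#' width A to width B), and the telson. Per-region S-phase and M-phase
#' labels are drawn with configured fractions; growth-zone spindle angles
#' are AP-oriented (< 45 degrees) with probability `ap_orientation_prob`,
#' segmental mitoses transverse-biased.
#'
#' @param t Hours post hatch.
#' @param config A [gz_config()].
#' @param seed Integer seed; fixed `(t, config, seed)` gives a bitwise
#'   identical field.
#' @return A `cell_field` object: list with `nuclei` (data frame with
#'   columns `x_um, y_um, stripe_id, region, s_phase, m_hoechst, m_ph3,
#'   spindle_deg`), `landmarks`, `stage_h`, `seed`, `config`.
#' @export
#' @examples
#' f <- generate_larva(0, gz_config(), seed = 0)
#' nrow(f$nuclei)
generate_larva <- function(t, config = gz_config(), seed = config$seed) {
  validate_gz_config(config)
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("domain error: t must be a single finite value >= 0", call. = FALSE)
  }
  diam <- config$cell_diameter_um
  n_stripes <- stage_clock(t, config)
  lens <- segment_lengths(n_stripes, config)
  L_gz <- max(1L, as.integer(round(gz_length_cells_at(t, config))))
  H <- config$head_length_cells
  Tt <- config$telson_length_cells

  odd <- function(w) pmax(1, 2 * round((w - 1) / 2) + 1)

  # per-row bookkeeping: width (cells), region, stripe id, zone label
  seg_rows <- lens + 1L                      # between-stripe rows + stripe row
  wa <- config$widthA_cells
  wb <- config$widthB_cells
  gz_w <- if (L_gz == 1) wa else
    odd(wa + (wb - wa) * (seq_len(L_gz) - 1) / (L_gz - 1))
  gz_w[1] <- odd(wa); gz_w[L_gz] <- odd(wb)
  tel_w <- odd(wb + (config$telson_tip_cells - wb) *
                 (seq_len(Tt) - 1) / max(1, Tt - 1))

  row_w <- c(rep(wa, H),
             rep(wa, sum(seg_rows)),
             gz_w,
             tel_w)
  n_rows <- length(row_w)
  row_x <- (seq_len(n_rows) - 0.5) * diam

  row_region <- c(rep("segmented", H + sum(seg_rows)),
                  rep("growth_zone", L_gz),
                  rep("telson", Tt))
  row_stripe <- rep(NA_integer_, n_rows)
  row_seg <- rep(NA_integer_, n_rows)          # trunk segment index per row
  pos <- H
  for (k in seq_len(n_stripes)) {
    row_seg[pos + seq_len(seg_rows[k])] <- k
    pos <- pos + seg_rows[k]
    row_stripe[pos] <- k
  }
  stripe_x <- row_x[!is.na(row_stripe)]

  # landmarks (pre-jitter geometry)
  trunk_x_start <- H * diam
  gz_x_start <- (H + sum(seg_rows)) * diam
  gz_x_end <- gz_x_start + L_gz * diam
  body_x_end <- n_rows * diam
  n_ant_gz <- max(0L, min(L_gz, round(config$gz_anterior_frac * L_gz)))
  gz_split_x <- gz_x_start + n_ant_gz * diam

  # expand rows to nuclei
  w <- row_w
  nuc_row <- rep.int(seq_len(n_rows), w)
  y0 <- unlist(lapply(w, function(wi) (seq_len(wi) - (wi + 1) / 2) * diam),
               use.names = FALSE)
  x0 <- row_x[nuc_row]
  n_nuc <- length(x0)
  region <- row_region[nuc_row]
  stripe_id <- row_stripe[nuc_row]
  seg_id <- row_seg[nuc_row]

  # zone for label frequencies
  zone <- character(n_nuc)
  zone[region == "telson"] <- "telson"
  in_gz <- region == "growth_zone"
  zone[in_gz & x0 < gz_split_x] <- "gz_anterior"
  zone[in_gz & x0 >= gz_split_x] <- "gz_posterior"
  is_band <- !is.na(seg_id) & seg_id == n_stripes
  zone[is_band] <- "band"
  zone[zone == ""] <- "segmented"

  p_s <- c(segmented = config$seg_s_frac,
           band = config$band_sync_frac,
           gz_anterior = config$edu_clear_frac,
           gz_posterior = config$edu_scatter_frac,
           telson = config$telson_s_frac)[zone]
  if (config$band_lateral_ext_prob > 0 && n_stripes >= 2) {
    lat <- !is.na(seg_id) & seg_id == n_stripes - 1L &
      abs(y0) > ((row_w[nuc_row] - 1) / 2 - 2) * diam
    p_s[lat] <- pmax(p_s[lat], config$band_lateral_ext_prob)
  }

  p_mh <- numeric(n_nuc)
  p_mh[zone %in% c("gz_anterior", "gz_posterior")] <- config$mitotic_fraction
  p_mh[zone %in% c("segmented", "band")] <- config$seg_mitotic_fraction
  p_mp <- numeric(n_nuc)
  p_mp[zone %in% c("gz_anterior", "gz_posterior")] <-
    min(1, config$mitotic_fraction * config$ph3_ratio)
  p_mp[zone == "segmented"] <- min(1, config$seg_mitotic_fraction * config$ph3_ratio)
  p_mp[zone == "band"] <-
    min(1, config$seg_mitotic_fraction * config$ph3_ratio * config$band_ph3_factor)

  p_ap <- rep(0.5, n_nuc)
  p_ap[zone %in% c("gz_anterior", "gz_posterior")] <- config$ap_orientation_prob
  p_ap[zone %in% c("segmented", "band")] <- config$seg_ap_prob

  field <- with_seed(seed, {
    jx <- stats::runif(n_nuc, -0.2, 0.2) * diam
    jy <- stats::runif(n_nuc, -0.2, 0.2) * diam
    s_phase <- stats::runif(n_nuc) < p_s
    m_hoechst <- stats::runif(n_nuc) < p_mh
    m_ph3 <- stats::runif(n_nuc) < p_mp
    m_any <- m_hoechst | m_ph3
    spindle <- rep(NA_real_, n_nuc)
    n_m <- sum(m_any)
    if (n_m > 0) {
      ap <- stats::runif(n_m) < p_ap[m_any]
      ang <- ifelse(ap, stats::runif(n_m, 0, 45), stats::runif(n_m, 45, 90))
      spindle[m_any] <- ang
    }
    x <- x0 + jx
    y <- y0 + jy

    nuclei <- data.frame(
      x_um = x, y_um = y,
      stripe_id = stripe_id,
      region = region,
      s_phase = s_phase,
      m_hoechst = m_hoechst,
      m_ph3 = m_ph3,
      spindle_deg = spindle,
      stringsAsFactors = FALSE
    )

    # lateral margins follow the jittered row extremes plus one cell radius
    ymax <- tapply(y, nuc_row, max)
    ymin <- tapply(y, nuc_row, min)
    margin_right <- cbind(row_x, as.numeric(ymax) + diam / 2)
    margin_left <- cbind(row_x, as.numeric(ymin) - diam / 2)
    colnames(margin_right) <- colnames(margin_left) <- c("x", "y")

    landmarks <- list(
      midline = cbind(x = c(0, body_x_end), y = c(0, 0)),
      trunk_x_start = trunk_x_start,
      stripes = data.frame(
        stripe_id = seq_len(n_stripes),
        x_row = stripe_x,
        x_anterior = stripe_x - diam / 2,
        x_posterior = stripe_x + diam / 2
      ),
      gz_x_start = gz_x_start,
      gz_split_x = gz_split_x,
      gz_x_end = gz_x_end,
      telson_x_start = gz_x_end,
      body_x_end = body_x_end,
      widthA_x = stripe_x[n_stripes],
      widthB_x = gz_x_end - diam / 2,
      margin_left = margin_left,
      margin_right = margin_right
    )

    structure(list(nuclei = nuclei,
                   landmarks = landmarks,
                   stage_h = t,
                   seed = as.integer(seed),
                   config = config),
              class = "cell_field")
  })
  field
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> %d nuclei, %d En stripes, stage %.2f h, seed %d\n",
              nrow(x$nuclei), nrow(x$landmarks$stripes), x$stage_h, x$seed))
  tab <- table(x$nuclei$region)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth posterior gene-expression domains for a synthetic larva
#'
#' Returns the axial intervals over which the generator's geometry places
#' the canonical posterior expression domains: *caudal* throughout the
#' growth zone, *WntA* in the anterior (S-phase-clear) growth zone, *Wnt4*
#' in the posterior (scattered S-phase) growth zone, and *Wnt6* in the
#' telson. Used as the aligned-expression truth for
#' [boundary_concordance()].
#'
#' @param field A `cell_field`.
#' @return Data frame with columns `gene`, `x_start`, `x_end` (micrometres),
#'   ordered and non-overlapping within each gene.
#' @export
expression_domains <- function(field) {
  stopifnot(inherits(field, "cell_field"))
  lm <- field$landmarks
  data.frame(
    gene = c("cad", "WntA", "Wnt4", "Wnt6"),
    x_start = c(lm$gz_x_start, lm$gz_x_start, lm$gz_split_x, lm$telson_x_start),
    x_end = c(lm$gz_x_end, lm$gz_split_x, lm$gz_x_end, lm$body_x_end),
    stringsAsFactors = FALSE
  )
}

#' Generate a staged cohort of synthetic larvae
#'
#' Emulates the staged-collection design: hatchlings collected on a fixed
#' interval (uniform hatch-time jitter), raised to nominal hourly ages, and
#' scored for En stripe count with integer observation noise. With
#' `measure = TRUE` each larva's cell field is generated and measured,
#' yielding a full morphometric record per row.
#'
#' @param config A [gz_config()].
#' @param n_per_timepoint Larvae per timepoint (>= 1).
#' @param timepoints Nominal hours post hatch (non-empty).
#' @param seed Integer top-level seed; per-larva seeds are derived with
#'   [derive_seed()].
#' @param measure Logical; also generate and measure each larva's field.
#' @return A `cohort_table` data frame with columns `larva_id`, `stage_h`
#'   (nominal), `age_h` (jittered), `en_stripes` (observed, noisy),
#'   `tagma`, and, when `measure = TRUE`, the [measure_larva()] columns.
#' @export
#' @examples
#' coh <- generate_cohort(gz_config(), 5, 0:2, seed = 1, measure = FALSE)
#' table(coh$stage_h)
generate_cohort <- function(config = gz_config(),
                            n_per_timepoint = 25,
                            timepoints = 0:18,
                            seed = config$seed,
                            measure = TRUE) {
  validate_gz_config(config)
  if (length(timepoints) == 0) {
    stop("domain error: timepoints must be non-empty", call. = FALSE)
  }
  if (n_per_timepoint < 1) {
    stop("domain error: n_per_timepoint must be >= 1", call. = FALSE)
  }
  rows <- vector("list", length(timepoints) * n_per_timepoint)
  i <- 0L
  for (tp in timepoints) {
    for (j in seq_len(n_per_timepoint)) {
      i <- i + 1L
      sd_larva <- derive_seed(seed, sprintf("larva_%g_%d", tp, j))
      obs <- with_seed(sd_larva, {
        jit <- stats::runif(1, 0, config$hatch_jitter_min / 60)
        s <- config$stage_noise_stripes
        noise <- if (s > 0) sample(seq.int(-s, s), 1) else 0L
        list(jit = jit, noise = noise)
      })
      age <- tp + obs$jit
      en_true <- stage_clock(age, config)
      en_obs <- max(0L, en_true + obs$noise)
      base <- data.frame(
        larva_id = sprintf("t%g_%03d", tp, j),
        stage_h = tp,
        age_h = age,
        en_stripes = en_obs,
        tagma = assign_tagma(en_obs, quiet = TRUE),
        stringsAsFactors = FALSE
      )
      if (measure) {
        fld <- generate_larva(age, config, derive_seed(sd_larva, "field"))
        rec <- measure_larva(fld)
        rec$en_stripes <- NULL  # cohort uses the noisy observed count
        rec$stage_h <- NULL
        rec$tagma <- NULL
        base <- cbind(base, rec)
      }
      rows[[i]] <- base
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
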