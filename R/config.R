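#' Generator configuration for synthetic staged larvae
#'
#' Builds the configuration object driving [generate_larva()] and
#' [generate_cohort()]. Defaults encode the study conditions for
#' *Thamnocephalus*-type anamorphic development: one new segment every
#' 1.4 h from 3 initial trunk Engrailed (En) stripes, a molt at 3.7 h that
#' lengthens the growth zone (GZ) by 2.5 cells, a GZ that shrinks as
#' segments are added while its widths stay constant, a 1--4% mitotic
#' fraction in the GZ with ~80% of spindles oriented along the
#' anterior--posterior (AP) axis, and the tri-domain S-phase pattern
#' (synchronous band in the newest segment, clear anterior GZ, scattered
#' posterior GZ).
#'
#' All count-to-length conversions go through `cell_diameter_um`. The
#' hatchling GZ defaults (13 cells long, widths 23 and 27 cells) give a
#' trapezoidal GZ cell-field area of 13 * (23 + 27) / 2 = 325 cells and a
#' ventral GZ area of 0.0117 mm^2.
#'
#' @param interval_h Hours per added segment.
#' @param initial_stripes Trunk En stripes present at hatch.
#' @param max_stripes Cap on total trunk En stripes.
#' @param molt_time_h Hours post hatch of the first molt.
#' @param molt_gz_gain_cells GZ length gain (cells) at the molt.
#' @param cell_diameter_um Mean nucleus spacing in micrometres.
#' @param gz_length0_cells,widthA_cells,widthB_cells Hatchling GZ
#'   dimensions in cells. Width A is the mediolateral extent at the last En
#'   stripe, width B at the GZ/telson boundary. Widths should be odd so a
#'   nucleus column lies on the midline.
#' @param gz_shrink_per_segment GZ length decrease (cells) per added segment.
#' @param seg_length_cells_by_order Lengths (cells, between-stripe counts)
#'   of successively added segments; early segments about 4 cells, late
#'   about 2.
#' @param initial_seg_length_cells Length (cells) of each segment already
#'   specified at hatch.
#' @param head_length_cells,telson_length_cells,telson_tip_cells Axial
#'   extents (cells) of head region and telson, and telson tip width.
#' @param mitotic_fraction Fraction of GZ nuclei in M phase (Hoechst
#'   criterion).
#' @param seg_mitotic_fraction Same for the segmented trunk.
#' @param ap_orientation_prob Probability a GZ mitosis is AP-oriented.
#' @param seg_ap_prob Probability a segmental mitosis is AP-oriented
#'   (segmental mitoses are transverse-biased).
#' @param ph3_ratio Expected pH3:Hoechst mitosis-count ratio.
#' @param band_ph3_factor Multiplier on the segmental pH3 rate inside the
#'   synchronous S-phase band (pH3 is typically excluded from the band).
#' @param edu_scatter_frac S-phase fraction in the posterior GZ.
#' @param edu_clear_frac S-phase fraction in the anterior GZ (near 0).
#' @param band_sync_frac S-phase fraction in the newest segment (near 1).
#' @param seg_s_frac S-phase fraction in older specified segments.
#' @param telson_s_frac S-phase fraction in the telson.
#' @param gz_anterior_frac Fraction of GZ length forming the anterior
#'   (S-phase-clear) domain.
#' @param band_lateral_ext_prob Per-nucleus probability that a lateral-edge
#'   cell of the penultimate segment joins the synchronous band.
#' @param stage_noise_stripes Half-width of the uniform integer observation
#'   noise on scored stripe counts (0 disables; 1 gives noise on
#'   \{-1, 0, +1\}).
#' @param hatch_jitter_min Uniform hatch-time jitter in minutes (collection
#'   interval).
#' @param constant_gz_mode Logical; if `TRUE` the GZ keeps its hatchling
#'   length as segments are added (*Artemia*-like mode).
#' @param seed Default seed used when an operation is not given one.
#'
#' @return An object of class `gz_config` (a validated named list).
#' @export
#' @examples
#' cfg <- gz_config()
#' cfg$interval_h
gz_config <- function(interval_h = 1.4,
                      initial_stripes = 3L,
                      max_stripes = 17L,
                      molt_time_h = 3.7,
                      molt_gz_gain_cells = 2.5,
                      cell_diameter_um = 6,
                      gz_length0_cells = 13L,
                      widthA_cells = 23L,
                      widthB_cells = 27L,
                      gz_shrink_per_segment = 0.75,
                      seg_length_cells_by_order = c(rep(4L, 5), rep(3L, 4), rep(2L, 5)),
                      initial_seg_length_cells = 4L,
                      head_length_cells = 32L,
                      telson_length_cells = 8L,
                      telson_tip_cells = 13L,
                      mitotic_fraction = 0.025,
                      seg_mitotic_fraction = 0.03,
                      ap_orientation_prob = 0.8,
                      seg_ap_prob = 0.2,
                      ph3_ratio = 2.4,
                      band_ph3_factor = 0.15,
                      edu_scatter_frac = 0.4,
                      edu_clear_frac = 0.02,
                      band_sync_frac = 0.95,
                      seg_s_frac = 0.3,
                      telson_s_frac = 0.1,
                      gz_anterior_frac = 0.5,
                      band_lateral_ext_prob = 0,
                      stage_noise_stripes = 1L,
                      hatch_jitter_min = 15,
                      constant_gz_mode = FALSE,
                      seed = 0L) {
  cfg <- list(
    interval_h = interval_h,
    initial_stripes = as.integer(initial_stripes),
    max_stripes = as.integer(max_stripes),
    molt_time_h = molt_time_h,
    molt_gz_gain_cells = molt_gz_gain_cells,
    cell_diameter_um = cell_diameter_um,
    gz_length0_cells = as.integer(gz_length0_cells),
    widthA_cells = as.integer(widthA_cells),
    widthB_cells = as.integer(widthB_cells),
    gz_shrink_per_segment = gz_shrink_per_segment,
    seg_length_cells_by_order = as.integer(seg_length_cells_by_order),
    initial_seg_length_cells = as.integer(initial_seg_length_cells),
    head_length_cells = as.integer(head_length_cells),
    telson_length_cells = as.integer(telson_length_cells),
    telson_tip_cells = as.integer(telson_tip_cells),
    mitotic_fraction = mitotic_fraction,
    seg_mitotic_fraction = seg_mitotic_fraction,
    ap_orientation_prob = ap_orientation_prob,
    seg_ap_prob = seg_ap_prob,
    ph3_ratio = ph3_ratio,
    band_ph3_factor = band_ph3_factor,
    edu_scatter_frac = edu_scatter_frac,
    edu_clear_frac = edu_clear_frac,
    band_sync_frac = band_sync_frac,
    seg_s_frac = seg_s_frac,
    telson_s_frac = telson_s_frac,
    gz_anterior_frac = gz_anterior_frac,
    band_lateral_ext_prob = band_lateral_ext_prob,
    stage_noise_stripes = as.integer(stage_noise_stripes),
    hatch_jitter_min = hatch_jitter_min,
    constant_gz_mode = isTRUE(constant_gz_mode),
    seed = as.integer(seed)
  )
  class(cfg) <- "gz_config"
  validate_gz_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the invariants of a [gz_config()] object and stops with a
#' config error when one is violated.
#'
#' @param cfg A `gz_config` object or compatible named list.
#' @return The validated config, invisibly classed as `gz_config`.
#' @export
validate_gz_config <- function(cfg) {
  stopifnot(is.list(cfg))
  err <- function(msg) stop("gz_config error: ", msg, call. = FALSE)
  if (!is.numeric(cfg$interval_h) || cfg$interval_h <= 0) {
    err("interval_h must be > 0")
  }
  counts <- c("initial_stripes", "max_stripes", "gz_length0_cells",
              "widthA_cells", "widthB_cells", "initial_seg_length_cells",
              "head_length_cells", "telson_length_cells", "telson_tip_cells")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] < 1)) {
      err(paste0(nm, " must be >= 1"))
    }
  }
  if (any(cfg$seg_length_cells_by_order < 1)) {
    err("seg_length_cells_by_order entries must be >= 1")
  }
  probs <- c("mitotic_fraction", "seg_mitotic_fraction", "ap_orientation_prob",
             "seg_ap_prob", "band_ph3_factor", "edu_scatter_frac",
             "edu_clear_frac", "band_sync_frac", "seg_s_frac",
             "telson_s_frac", "gz_anterior_frac", "band_lateral_ext_prob")
  for (nm in probs) {
    p <- cfg[[nm]]
    if (!is.numeric(p) || p < 0 || p > 1) {
      err(paste0(nm, " must be a probability in [0, 1]"))
    }
  }
  if (!(cfg$edu_clear_frac < cfg$edu_scatter_frac &&
        cfg$edu_scatter_frac < cfg$band_sync_frac)) {
    err("require edu_clear_frac < edu_scatter_frac < band_sync_frac")
  }
  if (cfg$cell_diameter_um <= 0) err("cell_diameter_um must be > 0")
  if (cfg$gz_shrink_per_segment < 0) err("gz_shrink_per_segment must be >= 0")
  if (cfg$hatch_jitter_min < 0) err("hatch_jitter_min must be >= 0")
  if (cfg$stage_noise_stripes < 0) err("stage_noise_stripes must be >= 0")
  invisible(structure(cfg, class = "gz_config"))
}

#' @export
print.gz_config <- function(x, ...) {
  cat("<gz_config>\n")
  cat(sprintf("  segment interval: %.2f h; initial stripes: %d (cap %d)\n",
              x$interval_h, x$initial_stripes, x$max_stripes))
  cat(sprintf("  molt at %.1f h (+%.1f GZ cells); cell diameter %.1f um\n",
              x$molt_time_h, x$molt_gz_gain_cells, x$cell_diameter_um))
  cat(sprintf("  hatchling GZ: %d x (%d,%d) cells; shrink %.2f cells/segment%s\n",
              x$gz_length0_cells, x$widthA_cells, x$widthB_cells,
              x$gz_shrink_per_segment,
              if (x$constant_gz_mode) " [constant-GZ mode]" else ""))
  cat(sprintf("  mitotic fraction %.3f (AP prob %.2f, pH3 ratio %.1f)\n",
              x$mitotic_fraction, x$ap_orientation_prob, x$ph3_ratio))
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' @param path File path.
#' @return `read_gz_config()` returns a validated [gz_config()];
#'   `write_gz_config()` returns `path` invisibly.
#' @export
read_gz_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- gz_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("gz_config error: unknown config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(unclass(defaults), raw)
  validate_gz_config(cfg)
  structure(cfg, class = "gz_config")
}

#' @rdname read_gz_config
#' @param cfg A `gz_config` object.
#' @export
write_gz_config <- function(cfg, path) {
  validate_gz_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Deterministic per-stage seed derivation: mixes the top-level seed with a
# stage name by a 31-multiplier rolling hash modulo 2^31 - 1. No global
# RNG state is consulted.
#' Derive a stage seed from a top-level seed and a stage name
#'
#' All randomness in the pipeline flows from one top-level seed; each
#' stochastic stage uses `derive_seed(seed, "stage-name")` so stages are
#' independent and reproducible.
#'
#' @param seed Integer top-level seed.
#' @param name Character stage name.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(seed, name) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(as.character(name))) {
    h <- (h * 31 + c) %% m
  }
  as.integer(h)
}

# Evaluate code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
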