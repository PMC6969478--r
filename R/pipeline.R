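# 31-multiplier rolling hash of the serialized config, for provenance.
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 15)),
             collapse = "\n")
  sprintf("%08x", derive_seed(0L, s))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate a staged cohort, measure every larva, and assemble the
#' cohort-level analyses into one report: segment-addition rate, per-stage
#' morphometric summaries, the division budget, S-phase domain and
#' orientation summaries (on a dedicated early-stage subset), PCA of the
#' eight measures, the permutation test of tagma separation, and the
#' PC1-on-tagma regression. Deterministic for fixed `(config, seed)`.
#'
#' @param config A [gz_config()].
#' @param seed Top-level integer seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @param timepoints Nominal collection hours.
#' @param n_per_timepoint Larvae per timepoint.
#' @param n_dynamics Larvae per early timepoint (0--4 h) for the S-phase
#'   domain and orientation summaries.
#' @param n_permutations Permutations for the tagma separation test.
#' @return An `analysis_report` list; see [write_report()].
#' @export
run_pipeline <- function(config = gz_config(), seed = config$seed,
                         timepoints = 0:18, n_per_timepoint = 25,
                         n_dynamics = 5, n_permutations = 999) {
  validate_gz_config(config)
  cohort <- generate_cohort(config, n_per_timepoint, timepoints,
                            seed = derive_seed(seed, "cohort"), measure = TRUE)
  rate <- segment_addition_rate(cohort)

  num_cols <- c(MEASURE_COLS, "gz_length_cells", "gz_widthA_cells",
                "gz_widthB_cells", "last_segment_length_cells",
                "mitoses_gz_hoechst", "mitoses_gz_ph3")
  summarize_tp <- function(tp) {
    rows <- cohort[cohort$stage_h == tp, , drop = FALSE]
    stats_list <- lapply(num_cols, function(cn) {
      v <- rows[[cn]]
      data.frame(stage_h = tp, measure = cn,
                 mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v, na.rm = TRUE),
                 n = sum(!is.na(v)))
    })
    do.call(rbind, stats_list)
  }
  stage_summary <- do.call(rbind, lapply(sort(unique(cohort$stage_h)), summarize_tp))

  budget <- budget_from_cohort(cohort)
  gz_nondecreasing <- with(stats::aggregate(gz_length_cells ~ stage_h,
                                            cohort, stats::median),
                           all(diff(gz_length_cells) >= 0))

  # cell-cycle dynamics on an early-stage subset
  dyn_t <- timepoints[timepoints <= 4]
  if (length(dyn_t) == 0) dyn_t <- timepoints[1]
  dyn_fields <- list()
  for (tp in dyn_t) {
    for (j in seq_len(n_dynamics)) {
      dyn_fields[[length(dyn_fields) + 1]] <-
        generate_larva(tp, config, derive_seed(seed, sprintf("dyn_%g_%d", tp, j)))
    }
  }
  dom_rows <- lapply(dyn_fields, function(f) {
    prof <- try(detect_edu_domains(f), silent = TRUE)
    if (inherits(prof, "try-error")) return(NULL)
    excl <- ph3_band_exclusion(f, prof)
    data.frame(stage_h = f$stage_h,
               n_domains = nrow(prof$domains),
               domain_order = paste(prof$domains$class, collapse = ">"),
               band_sync_fraction = prof$band_sync_fraction,
               ph3_band_ratio = excl$ratio)
  })
  edu_summary <- do.call(rbind, dom_rows)
  ori <- lapply(dyn_fields, orientation_summary)
  gz_n <- sum(vapply(ori, function(o) {
    o$by_region$n_mitoses[o$by_region$region == "growth_zone"]
  }, numeric(1)))
  gz_ap <- sum(vapply(ori, function(o) {
    o$by_region$n_ap[o$by_region$region == "growth_zone"]
  }, numeric(1)))
  mit <- vapply(dyn_fields, function(f) {
    mitotic_index(f, "growth_zone", "hoechst")$fraction
  }, numeric(1))
  orientation <- list(gz_n_mitoses = gz_n, gz_n_ap = gz_ap,
                      gz_ap_fraction = if (gz_n > 0) gz_ap / gz_n else NA_real_,
                      gz_mitotic_fraction_mean = mean(mit, na.rm = TRUE))

  # a constant measure column (e.g. GZ length in constant-GZ mode) makes the
  # standardized PCA degenerate; record the degeneracy instead of failing
  pca_block <- tryCatch({
    pca <- pca_morphometrics(cohort)
    lab <- cohort$tagma[pca$kept]
    ok <- !is.na(lab)
    sep <- tagma_separation(pca$scores[ok, , drop = FALSE], lab[ok],
                            n_permutations = n_permutations,
                            seed = derive_seed(seed, "separation"))
    reg <- regress_pc1_on_group(pca$scores[ok, 1], lab[ok])
    list(pca = list(variance_fractions = pca$variance_fractions,
                    loadings = pca$loadings),
         separation = sep, regression = reg)
  }, error = function(e) {
    message("pipeline: cohort statistics skipped: ", conditionMessage(e))
    list(pca = list(error = conditionMessage(e)),
         separation = list(error = conditionMessage(e)),
         regression = list(error = conditionMessage(e)))
  })

  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("gzmorph")),
      config_hash = config_hash(config),
      seed = as.integer(seed),
      n_larvae = nrow(cohort),
      timepoints = timepoints
    ),
    rate_fit = unclass(rate),
    stage_summary = stage_summary,
    division_budget = unclass(budget)[c("g0_cells", "total_new_cells",
                                        "divisions_required", "model",
                                        "gz_area0_mm2", "total_segment_area_mm2",
                                        "gz_area_fraction_pct")],
    gz_length_nondecreasing = gz_nondecreasing,
    constant_gz_mode = config$constant_gz_mode,
    edu_summary = edu_summary,
    orientation = orientation,
    pca = pca_block$pca,
    tagma_separation = pca_block$separation,
    pc1_regression = pca_block$regression
  )
  attr(report, "cohort") <- cohort
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  cohort: %d larvae over %d timepoints (seed %d, config %s)\n",
              x$provenance$n_larvae, length(x$provenance$timepoints),
              x$provenance$seed, x$provenance$config_hash))
  cat(sprintf("  segment addition: %.3f segments/h (SE %.4f)\n",
              x$rate_fit$slope, x$rate_fit$slope_se))
  cat(sprintf("  division budget: G0 = %.0f cells, %.0f new cells, %.2f divisions (%s)\n",
              x$division_budget$g0_cells, x$division_budget$total_new_cells,
              x$division_budget$divisions_required, x$division_budget$model))
  cat(sprintf("  GZ area %.4f mm^2 = %.1f%% of total new-segment area\n",
              x$division_budget$gz_area0_mm2,
              x$division_budget$gz_area_fraction_pct))
  cat(sprintf("  GZ AP spindle fraction: %.2f (%d mitoses)\n",
              x$orientation$gz_ap_fraction, x$orientation$gz_n_mitoses))
  if (is.null(x$pca$error)) {
    cat(sprintf("  PCA: PC1 %.1f%%; tagma separation p = %.4g; PC1~tagma adj R2 = %.2f\n",
                100 * x$pca$variance_fractions[1], x$tagma_separation$p,
                x$pc1_regression$adj_r2))
  } else {
    cat("  cohort statistics skipped:", x$pca$error, "\n")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON and CSV tables
#'
#' Writes `report.json` (fixed key order) plus `cohort.csv` and
#' `stage_summary.csv` into `dir`.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  cohort <- attr(report, "cohort")
  if (!is.null(cohort)) {
    utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  }
  utils::write.csv(report$stage_summary, file.path(dir, "stage_summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}
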