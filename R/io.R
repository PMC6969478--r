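CELLFIELD_COLS <- c("x_um", "y_um", "stripe_id", "region", "s_phase",
                    "m_hoechst", "m_ph3", "spindle_deg")

# sidecar path for a nucleus CSV
landmark_sidecar_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0(".landmarks.json")
}

#' Write a cell field to CSV with a JSON landmark sidecar
#'
#' The nucleus table goes to `path` (UTF-8 CSV, header row, one nucleus
#' per row with columns `x_um, y_um, stripe_id, region, s_phase,
#' m_hoechst, m_ph3, spindle_deg`); landmarks, stage, seed and the
#' generator configuration go to a JSON sidecar named
#' `<path minus .csv>.landmarks.json`.
#'
#' @param field A `cell_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cellfield_csv <- function(field, path) {
  stopifnot(inherits(field, "cell_field"))
  nuc <- field$nuclei[, CELLFIELD_COLS]
  utils::write.csv(format(nuc, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  lm <- field$landmarks
  side <- list(
    stage_h = field$stage_h,
    seed = field$seed,
    config = unclass(field$config),
    landmarks = list(
      midline = unname(apply(lm$midline, 1, as.numeric, simplify = FALSE)),
      trunk_x_start = lm$trunk_x_start,
      stripes = lm$stripes,
      gz_x_start = lm$gz_x_start,
      gz_split_x = lm$gz_split_x,
      gz_x_end = lm$gz_x_end,
      telson_x_start = lm$telson_x_start,
      body_x_end = lm$body_x_end,
      widthA_x = lm$widthA_x,
      widthB_x = lm$widthB_x,
      margin_left = unname(apply(lm$margin_left, 1, as.numeric, simplify = FALSE)),
      margin_right = unname(apply(lm$margin_right, 1, as.numeric, simplify = FALSE))
    )
  )
  jsonlite::write_json(side, landmark_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cell field written by [write_cellfield_csv()]
#'
#' The CSV schema is checked strictly: a missing or unknown column raises
#' a named-column error; a missing landmark sidecar raises a landmark
#' error.
#'
#' @param path CSV path.
#' @return A `cell_field`.
#' @export
read_cellfield_csv <- function(path) {
  nuc <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CELLFIELD_COLS, names(nuc))
  if (length(missing_cols) > 0) {
    stop("named-column error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(nuc), CELLFIELD_COLS)
  if (length(unknown) > 0) {
    stop("named-column error: unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(nuc) > 0 && (!is.numeric(nuc$x_um) || !is.numeric(nuc$y_um))) {
    stop("named-column error: non-numeric coordinate column", call. = FALSE)
  }
  sp <- landmark_sidecar_path(path)
  if (!file.exists(sp)) {
    stop("landmark error: sidecar not found: ", sp, call. = FALSE)
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  cfg <- validate_gz_config(side$config)
  to_mat <- function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("x", "y")
    m
  }
  lm <- side$landmarks
  lm$midline <- to_mat(lm$midline)
  lm$margin_left <- to_mat(lm$margin_left)
  lm$margin_right <- to_mat(lm$margin_right)
  lm$stripes <- as.data.frame(lm$stripes)
  if (nrow(nuc) > 0) {
    nuc$stripe_id <- as.integer(nuc$stripe_id)
    nuc$s_phase <- as.logical(nuc$s_phase)
    nuc$m_hoechst <- as.logical(nuc$m_hoechst)
    nuc$m_ph3 <- as.logical(nuc$m_ph3)
    nuc$spindle_deg <- as.numeric(nuc$spindle_deg)
  }
  structure(list(nuclei = nuc,
                 landmarks = lm,
                 stage_h = side$stage_h,
                 seed = as.integer(side$seed),
                 config = cfg),
            class = "cell_field")
}
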