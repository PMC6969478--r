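# Shared fixtures, built in code at test time.

# Hand-built rectangular toy field: trunk 0..trunk_len, margins at
# +/- trunk_w/2, two complete En stripes, then a growth zone that can be
# collapsed (gz_len_um = 0) to exercise degenerate geometry.
make_toy_field <- function(trunk_w_um = 100, trunk_len_um = 200,
                           gz_len_um = 0, config = gz_config()) {
  half <- trunk_w_um / 2
  gz_x_start <- trunk_len_um - gz_len_um
  stripe_x <- c(gz_x_start - 18, gz_x_start - 6)
  ys <- seq(-half + 2, half - 2, by = 6)
  nuclei <- do.call(rbind, lapply(seq_along(stripe_x), function(k) {
    data.frame(x_um = stripe_x[k], y_um = ys, stripe_id = k,
               region = "segmented", s_phase = FALSE,
               m_hoechst = FALSE, m_ph3 = FALSE, spindle_deg = NA_real_)
  }))
  landmarks <- list(
    midline = cbind(x = c(0, trunk_len_um), y = c(0, 0)),
    trunk_x_start = 0,
    stripes = data.frame(stripe_id = seq_along(stripe_x), x_row = stripe_x,
                         x_anterior = stripe_x - 3, x_posterior = stripe_x + 3),
    gz_x_start = gz_x_start,
    gz_split_x = gz_x_start + gz_len_um / 2,
    gz_x_end = trunk_len_um,
    telson_x_start = trunk_len_um,
    body_x_end = trunk_len_um,
    widthA_x = stripe_x[2],
    widthB_x = trunk_len_um - 3,
    margin_left = cbind(x = c(0, trunk_len_um), y = c(-half, -half)),
    margin_right = cbind(x = c(0, trunk_len_um), y = c(half, half))
  )
  structure(list(nuclei = nuclei, landmarks = landmarks,
                 stage_h = 0, seed = 0L, config = config),
            class = "cell_field")
}

# Memoized default measured cohort shared by the statistics tests.
.fixture_env <- new.env(parent = emptyenv())
default_measured_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(gz_config(), n_per_timepoint = 8,
                                           timepoints = 0:18, seed = 42,
                                           measure = TRUE)
  }
  .fixture_env$cohort
}
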