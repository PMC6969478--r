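test_that("mitotic index counts flags per region and marker", {
  toy <- make_toy_field()
  gz <- data.frame(x_um = rep(seq(150, 197, by = 6), each = 25),
                   y_um = rep(seq(-48, 48, length.out = 25), 8),
                   stripe_id = NA_integer_, region = "growth_zone",
                   s_phase = FALSE, m_hoechst = FALSE, m_ph3 = FALSE,
                   spindle_deg = NA_real_)
  gz$m_hoechst[1:8] <- TRUE
  gz$spindle_deg[1:8] <- 10
  toy$nuclei <- rbind(toy$nuclei, gz)
  mi <- mitotic_index(toy, "growth_zone", "hoechst")
  expect_identical(mi$count, 8L)
  expect_equal(mi$fraction, 8 / 200)
  expect_identical(mitotic_index(toy, "growth_zone", "ph3")$count, 0L)
  expect_identical(mitotic_index(toy, "telson", "hoechst"),
                   list(count = 0L, fraction = NA_real_, n_region = 0L))
})

test_that("GZ mitotic fraction sits in the configured 1-4% band", {
  cfg <- gz_config()
  fr <- vapply(1:40, function(s) {
    mitotic_index(generate_larva(0, cfg, seed = s), "growth_zone", "hoechst")$fraction
  }, numeric(1))
  expect_gte(mean(fr), 0.01)
  expect_lte(mean(fr), 0.04)
})

test_that("pooled pH3:Hoechst count ratio matches the configured 2.4x", {
  cfg <- gz_config()
  nh <- 0; np <- 0
  rats <- vapply(1:50, function(s) {
    f <- generate_larva(0, cfg, seed = 100 + s)
    h <- mitotic_index(f, "growth_zone", "hoechst")$count
    p <- mitotic_index(f, "growth_zone", "ph3")$count
    nh <<- nh + h; np <<- np + p
    p / max(1, h)
  }, numeric(1))
  ratio <- np / nh
  # delta-method SE of a ratio of Poisson-like counts
  se <- ratio * sqrt(1 / np + 1 / nh)
  expect_lt(abs(ratio - cfg$ph3_ratio), 3 * se)
})

test_that("orientation classification uses the 45-degree tie-to-AP rule", {
  expect_identical(classify_orientation(0), "AP")
  expect_identical(classify_orientation(45), "AP")
  expect_identical(classify_orientation(90), "transverse")
  expect_error(classify_orientation(91), "domain error")
  expect_error(classify_orientation(-1), "domain error")
})

test_that("orientation summary recovers configured AP probabilities", {
  cfg <- gz_config()
  n <- 0; nap <- 0
  for (s in 1:50) {
    o <- orientation_summary(generate_larva(0, cfg, seed = s))
    gz <- o$by_region[o$by_region$region == "growth_zone", ]
    n <- n + gz$n_mitoses; nap <- nap + gz$n_ap
  }
  p <- cfg$ap_orientation_prob
  expect_lt(abs(nap / n - p), 3 * sqrt(p * (1 - p) / n))
  # uniform angles straddle the cutoff at 0.5
  n <- 0; nap <- 0
  for (s in 1:30) {
    f <- generate_larva(0, cfg, seed = s)
    m <- f$nuclei$m_hoechst | f$nuclei$m_ph3
    f$nuclei$spindle_deg[m] <- with_seed(s, stats::runif(sum(m), 0, 90))
    o <- orientation_summary(f)
    n <- n + o$n_mitoses; nap <- nap + o$n_ap
  }
  expect_lt(abs(nap / n - 0.5), 3 * sqrt(0.25 / n))
  # no mitoses: undefined fraction
  f <- generate_larva(0, cfg, seed = 1)
  f$nuclei$m_hoechst <- FALSE
  f$nuclei$m_ph3 <- FALSE
  o <- orientation_summary(f)
  expect_identical(o$n_mitoses, 0L)
  expect_true(is.na(o$ap_fraction))
})

test_that("the tri-domain S-phase pattern is detected in canonical order", {
  cfg <- gz_config()
  f <- generate_larva(2, cfg, seed = 1)
  prof <- detect_edu_domains(f)
  expect_identical(prof$domains$class,
                   c("synchronous_band", "clear", "scattered"))
  # windows partition the span: contiguous, ordered, non-overlapping
  expect_equal(prof$domains$x_start[-1],
               prof$domains$x_end[-nrow(prof$domains)])
  expect_equal(prof$domains$x_start[1], unname(prof$span[1]))
  expect_equal(prof$domains$x_end[nrow(prof$domains)], unname(prof$span[2]))
  # the detected band interval may include up to one boundary row of
  # non-cycling nuclei on each side, diluting the within-band S fraction
  expect_gte(prof$band_sync_fraction, 0.75)
  expect_error(detect_edu_domains(f, window_um = 1e5), "window larger")
})

test_that("an all-S field collapses to a single synchronous band", {
  f <- generate_larva(2, gz_config(), seed = 3)
  f$nuclei$s_phase <- TRUE
  prof <- detect_edu_domains(f)
  expect_identical(prof$domains$class, "synchronous_band")
})

test_that("domain detection is invariant to uniform translation", {
  f <- generate_larva(2, gz_config(), seed = 5)
  p1 <- detect_edu_domains(f)
  shift <- 137.5
  f2 <- f
  f2$nuclei$x_um <- f2$nuclei$x_um + shift
  lmn <- c("trunk_x_start", "gz_x_start", "gz_split_x", "gz_x_end",
           "telson_x_start", "body_x_end", "widthA_x", "widthB_x")
  for (nm in lmn) f2$landmarks[[nm]] <- f2$landmarks[[nm]] + shift
  f2$landmarks$stripes[, c("x_row", "x_anterior", "x_posterior")] <-
    f2$landmarks$stripes[, c("x_row", "x_anterior", "x_posterior")] + shift
  for (nm in c("midline", "margin_left", "margin_right")) {
    f2$landmarks[[nm]][, 1] <- f2$landmarks[[nm]][, 1] + shift
  }
  p2 <- detect_edu_domains(f2)
  expect_identical(p2$domains$class, p1$domains$class)
  expect_equal(p2$domains$x_start - shift, p1$domains$x_start, tolerance = 1e-9)
})

test_that("detected domain boundaries land within one window of truth", {
  cfg <- gz_config()
  w <- 2 * cfg$cell_diameter_um
  for (s in 1:20) {
    f <- generate_larva(2, cfg, seed = s)
    prof <- detect_edu_domains(f, window_um = w)
    lm <- f$landmarks
    band <- prof$domains[prof$domains$class == "synchronous_band", ]
    clr <- prof$domains[prof$domains$class == "clear", ]
    scat <- prof$domains[prof$domains$class == "scattered", ]
    expect_lte(abs(band$x_end[1] - lm$gz_x_start), w)
    expect_lte(abs(clr$x_end[1] - lm$gz_split_x), w)
    expect_lte(abs(scat$x_end[1] - lm$gz_x_end), w)
  }
})

test_that("pH3 cells are depleted from the band relative to uniformity", {
  cfg <- gz_config()
  # generator default: exclusion, ratio < 1 pooled over seeds
  obs <- 0; expd <- 0
  for (s in 1:50) {
    f <- generate_larva(2, cfg, seed = s)
    e <- ph3_band_exclusion(f, detect_edu_domains(f))
    obs <- obs + e$observed; expd <- expd + e$expected
  }
  expect_lt(obs / expd, 1)
  # permutation oracle: uniformly shuffled pH3 flags give ratio ~ 1
  rs <- vapply(1:30, function(s) {
    f <- generate_larva(2, cfg, seed = s)
    f$nuclei$m_ph3 <- with_seed(1000 + s, sample(f$nuclei$m_ph3))
    ph3_band_exclusion(f, detect_edu_domains(f))$ratio
  }, numeric(1))
  m <- mean(rs, na.rm = TRUE)
  se <- sd(rs, na.rm = TRUE) / sqrt(sum(!is.na(rs)))
  expect_lt(abs(m - 1), 3 * se)
  # no band: absent flag
  f <- generate_larva(2, cfg, seed = 2)
  f$nuclei$s_phase <- FALSE
  prof <- detect_edu_domains(f)
  expect_true(ph3_band_exclusion(f, prof)$absent)
})

test_that("boundary concordance reports exact signed offsets", {
  f <- generate_larva(2, gz_config(), seed = 4)
  prof <- detect_edu_domains(f)
  d <- prof$domains
  # expression intervals copied from the detected domains: zero offsets
  ed <- data.frame(
    gene = c("WntA", "Wnt4", "cad"),
    x_start = c(d$x_start[d$class == "clear"], d$x_start[d$class == "scattered"],
                d$x_start[d$class == "clear"]),
    x_end = c(d$x_end[d$class == "clear"], d$x_end[d$class == "scattered"],
              d$x_end[d$class == "scattered"]))
  bc <- boundary_concordance(prof, ed)
  expect_equal(bc$offset_um[bc$pair == "WntA_start_vs_clear_start"], 0)
  expect_equal(bc$offset_um[bc$pair == "Wnt4_end_vs_scattered_end"], 0)
  # translation by +10 um shifts every offset by +10
  ed10 <- ed
  ed10$x_start <- ed10$x_start + 10
  ed10$x_end <- ed10$x_end + 10
  bc10 <- boundary_concordance(prof, ed10)
  expect_equal(bc10$offset_um, bc$offset_um + 10)
  # generator truth concordant within one window width
  bct <- boundary_concordance(prof, expression_domains(f))
  expect_true(all(abs(bct$offset_um[1:4]) <= prof$window_um))
  # missing named domain flagged absent
  bc_na <- boundary_concordance(prof, ed[ed$gene != "Wnt4", ])
  expect_true(is.na(bc_na$offset_um[bc_na$pair == "Wnt4_start_vs_scattered_start"]))
})
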