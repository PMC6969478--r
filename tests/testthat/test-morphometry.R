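test_that("shoelace area is exact, orientation-invariant, and validated", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)
  expect_equal(polygon_area(rbind(sq, sq[1, ])), 1)  # closed ring tolerated
  expect_error(polygon_area(sq[1:2, ]), "geometry error")
})

test_that("shoelace area matches a Monte-Carlo hit-count oracle within 1%", {
  set.seed(101)
  for (rep in 1:3) {
    th <- sort(runif(10, 0, 2 * pi))
    a <- runif(1, 1, 3); b <- runif(1, 1, 3)
    poly <- cbind(a * cos(th), b * sin(th))  # convex decagon on an ellipse
    area <- polygon_area(poly)
    n <- 2e5
    px <- runif(n, min(poly[, 1]), max(poly[, 1]))
    py <- runif(n, min(poly[, 2]), max(poly[, 2]))
    # ray-cast point-in-polygon hit counting
    inside <- rep(FALSE, n)
    m <- nrow(poly)
    j <- m
    for (i in seq_len(m)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      cross <- (yi > py) != (yj > py) &
        px < (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, cross)
      j <- i
    }
    box <- diff(range(poly[, 1])) * diff(range(poly[, 2]))
    mc <- mean(inside) * box
    expect_lt(abs(mc - area) / area, 0.01)
  }
})

test_that("corridor cell counts follow constructed fixtures", {
  f <- make_toy_field()
  f$nuclei <- data.frame(x_um = seq(0, 60, by = 6), y_um = 0,
                         stripe_id = NA_integer_, region = "segmented",
                         s_phase = FALSE, m_hoechst = FALSE, m_ph3 = FALSE,
                         spindle_deg = NA_real_)
  path <- cbind(c(0, 60), c(0, 0))
  expect_identical(count_cells_along(f, path, 3), 11L)
  # corridor displaced away from all nuclei
  expect_identical(count_cells_along(f, cbind(c(0, 60), c(50, 50)), 3), 0L)
  expect_error(count_cells_along(f, path[0, , drop = FALSE], 3), "empty path")
  expect_error(count_cells_along(f, path, 0), "corridor_halfwidth")
})

test_that("generator round-trip recovers configured cell counts", {
  cfg <- gz_config()
  f <- generate_larva(0, cfg, seed = 0)
  rec <- measure_larva(f)
  expect_lte(abs(rec$gz_length_cells - cfg$gz_length0_cells), 1)
  expect_lte(abs(rec$gz_widthA_cells - cfg$widthA_cells), 1)
  expect_lte(abs(rec$gz_widthB_cells - cfg$widthB_cells), 1)
  expect_identical(rec$en_stripes, 3L)
  # measurement is pure
  expect_identical(rec, measure_larva(f))
})

test_that("En stripes are scored only when complete and connected", {
  cfg <- gz_config()
  f <- generate_larva(0, cfg, seed = 2)
  expect_identical(score_en_stripes(f), 3L)
  # delete one lateral half of stripe 2: chain no longer reaches the margin
  broken <- f
  drop <- !is.na(broken$nuclei$stripe_id) & broken$nuclei$stripe_id == 2 &
    broken$nuclei$y_um > 0
  broken$nuclei <- broken$nuclei[!drop, ]
  expect_identical(score_en_stripes(broken), 2L)
  # a sub-threshold mid-stripe gap still counts: nuclei packed at 4 um with
  # one 8 um gap (< 1.5 x 6 um)
  toy <- make_toy_field()
  ys <- setdiff(seq(-48, 48, by = 4), 0)
  toy$nuclei <- data.frame(x_um = 100, y_um = ys, stripe_id = 1L,
                           region = "segmented", s_phase = FALSE,
                           m_hoechst = FALSE, m_ph3 = FALSE,
                           spindle_deg = NA_real_)
  toy$landmarks$stripes <- data.frame(stripe_id = 1L, x_row = 100,
                                      x_anterior = 97, x_posterior = 103)
  expect_identical(score_en_stripes(toy), 1L)
  # missing margins is a landmark error
  toy$landmarks$margin_left <- NULL
  expect_error(score_en_stripes(toy), "landmark error")
})

test_that("toy geometries give exact areas and degenerate GZ gives zero", {
  toy <- make_toy_field(trunk_w_um = 100, trunk_len_um = 200, gz_len_um = 0)
  rec <- measure_larva(toy)
  expect_equal(rec$trunk_area_mm2, 0.02)
  expect_equal(rec$gz_area_mm2, 0)
  expect_equal(rec$gz_length_mm, 0)
})

test_that("cell-count product approximates the nuclei in the GZ polygon", {
  cfg <- gz_config()
  for (t in c(0, 3, 6)) {
    f <- generate_larva(t, cfg, seed = 7)
    rec <- measure_larva(f)
    n_poly <- sum(f$nuclei$region == "growth_zone")
    prod <- rec$gz_widthA_cells * rec$gz_length_cells
    expect_lt(abs(prod - n_poly) / n_poly, 0.15)
  }
})

test_that("stage trends mirror a shrinking growth zone with constant width", {
  coh <- default_measured_cohort()
  gz <- aggregate(gz_length_mm ~ stage_h, coh, mean)
  cfg <- gz_config()
  d <- diff(gz$gz_length_mm)
  crosses_molt <- vapply(seq_len(nrow(gz) - 1), function(i) {
    gz$stage_h[i] < cfg$molt_time_h && gz$stage_h[i + 1] >= cfg$molt_time_h
  }, logical(1))
  # sign test: no non-molt step increases (ties allowed where shrinkage is
  # below one whole nucleus row), decreases clearly dominate, and the only
  # rise is the molt rebound
  expect_true(all(d[!crosses_molt] <= 0))
  expect_gte(sum(d < 0), 5)
  expect_gt(d[crosses_molt], 0)
  expect_lt(gz$gz_length_mm[nrow(gz)], gz$gz_length_mm[1])
  # width A stays relatively constant: CV of stage means < 10%
  wa <- aggregate(gz_widthA_mm ~ stage_h, coh, mean)$gz_widthA_mm
  expect_lt(sd(wa) / mean(wa), 0.10)
})
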