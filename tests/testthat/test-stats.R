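test_that("tagma assignment follows the stripe-count lookup", {
  expect_identical(as.character(assign_tagma(c(3, 6))),
                   rep("thoracic_premolt", 2))
  expect_identical(as.character(assign_tagma(c(7, 11))),
                   rep("thoracic_postmolt", 2))
  expect_identical(as.character(assign_tagma(12)), "genital")
  expect_identical(as.character(assign_tagma(c(14, 17))),
                   rep("abdominal", 2))
  expect_warning(out <- assign_tagma(c(2, 18)), "out-of-range")
  expect_true(all(is.na(out)))
})

test_that("the rate fit recovers the clock exactly on noiseless data", {
  cfg <- gz_config(stage_noise_stripes = 0, hatch_jitter_min = 0)
  # timepoints on multiples of the interval: the staircase is exactly linear
  coh <- generate_cohort(cfg, 5, seq(0, 16.8, by = 1.4), seed = 1,
                         measure = FALSE)
  fit <- suppressWarnings(segment_addition_rate(coh))  # exact fit: lm warns
  expect_equal(fit$slope, 1 / 1.4, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # constant stripe count: zero slope
  flat <- data.frame(stage_h = rep(0:5, each = 3), en_stripes = 7L)
  expect_equal(suppressWarnings(segment_addition_rate(flat)$slope), 0)
  expect_error(segment_addition_rate(data.frame(stage_h = rep(1, 9),
                                                en_stripes = 1:9)),
               "degenerate-fit")
})

test_that("slope estimates are unbiased across seeds with honest CIs", {
  cfg <- gz_config()
  slopes <- numeric(40)
  ses <- numeric(40)
  for (s in seq_along(slopes)) {
    coh <- generate_cohort(cfg, 10, 0:18, seed = s, measure = FALSE)
    fit <- segment_addition_rate(coh)
    slopes[s] <- fit$slope
    ses[s] <- fit$slope_se
  }
  true <- 1 / cfg$interval_h
  expect_lt(abs(mean(slopes) - true), 3 * sd(slopes))
  covered <- abs(slopes - true) <= 1.96 * ses
  expect_gte(mean(covered), 0.90)
})

test_that("PCA standardizes, orders variance, and flags degeneracies", {
  coh <- default_measured_cohort()
  pca <- pca_morphometrics(coh)
  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-9)
  expect_equal(unname(colMeans(pca$scores)), rep(0, 8), tolerance = 1e-9)
  # sign convention: largest-magnitude loading positive
  for (j in 1:8) {
    expect_gte(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  # the shared size trend dominates and orders the tagmata along PC1
  expect_gt(pca$variance_fractions[1], 0.5)
  lab <- coh$tagma[pca$kept]
  m <- tapply(pca$scores[, 1], lab, mean)
  expect_true(all(diff(m) > 0) || all(diff(m) < 0))
  # collinear records: PC1 carries everything
  base <- as.data.frame(matrix(rep(seq(1, 2, length.out = 12), 8), ncol = 8))
  names(base) <- c("body_length_mm", "gz_length_mm", "gz_widthA_mm",
                   "gz_widthB_mm", "trunk_area_mm2", "last_segment_area_mm2",
                   "gz_area_mm2", "last_segment_length_mm")
  expect_equal(pca_morphometrics(base)$variance_fractions[1], 1)
  # isotropic noise: fractions near 1/8 each
  iso <- with_seed(9, as.data.frame(matrix(rnorm(8 * 4000), ncol = 8)))
  names(iso) <- names(base)
  expect_true(all(abs(pca_morphometrics(iso)$variance_fractions - 1 / 8) < 0.02))
  # constant column named in the error
  cc <- base
  cc$gz_widthA_mm <- 1
  expect_error(pca_morphometrics(cc), "gz_widthA_mm")
})

test_that("the permutation group test separates tagmata and honors the null", {
  coh <- default_measured_cohort()
  pca <- pca_morphometrics(coh)
  lab <- coh$tagma[pca$kept]
  ok <- !is.na(lab)
  sep <- tagma_separation(pca$scores[ok, ], lab[ok],
                          n_permutations = 1999, seed = 1)
  expect_lte(sep$p, 0.001)
  # two identical groups: statistic ~ 0, p ~ 1
  x <- matrix(rep(seq_len(10), 3), ncol = 3)
  same <- tagma_separation(rbind(x, x),
                           rep(c("a", "b"), each = 10),
                           n_permutations = 199, seed = 2)
  expect_lt(same$statistic, 1e-9)
  expect_gt(same$p, 0.9)
  expect_error(tagma_separation(x, c("a", rep("b", 9))), "grouping error")
})

test_that("permutation type-I error stays at the nominal level", {
  alpha <- 0.05
  n_sim <- 200
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    sc <- with_seed(5000 + i, matrix(rnorm(40 * 3), ncol = 3))
    lab <- rep(letters[1:4], each = 10)
    p <- tagma_separation(sc, lab, n_permutations = 99, seed = i)$p
    rej[i] <- p <= alpha
  }
  bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / n_sim)
  expect_lte(mean(rej), bound)
})

test_that("PC1-on-tagma regression quantifies the axial trend", {
  # perfectly separated groups
  g <- rep(c("thoracic_premolt", "thoracic_postmolt", "genital", "abdominal"),
           each = 5)
  pc1 <- rep(c(1, 2, 3, 4), each = 5)
  r <- suppressWarnings(
    regress_pc1_on_group(pc1, factor(g, levels = levels(assign_tagma(3)))))
  expect_gt(r$adj_r2, 0.999)
  # independent scores: adjusted R^2 near zero
  r0 <- regress_pc1_on_group(with_seed(3, rnorm(200)),
                             rep(1:4, each = 50))
  expect_lt(abs(r0$adj_r2), 0.05)
  # the synthetic cohort trend is strong
  coh <- default_measured_cohort()
  pca <- pca_morphometrics(coh)
  lab <- coh$tagma[pca$kept]
  ok <- !is.na(lab)
  rc <- regress_pc1_on_group(pca$scores[ok, 1], lab[ok])
  expect_gt(rc$adj_r2, 0.5)
  expect_lt(rc$p, 0.001)
  expect_error(regress_pc1_on_group(1:5, rep(1, 5)), "degenerate-fit")
})

test_that("pairwise tagma comparisons use studentized-range adjustment", {
  # identical groups: all adjusted p near 1
  d <- data.frame(tagma = rep(c("a", "b", "c"), each = 8),
                  m = rep(rep(c(1, 2, 3, 4), 2), 3))
  cmp <- tagma_group_compare(d, "m")
  expect_true(all(cmp$p_adj > 0.99))
  # one strongly shifted group: its pairs significant
  d$m[d$tagma == "c"] <- d$m[d$tagma == "c"] + 100
  cmp2 <- tagma_group_compare(d, "m")
  sig <- grepl("c", cmp2$pair)
  expect_true(all(cmp2$p_adj[sig] < 0.001))
  expect_true(all(cmp2$p_adj[!sig] > 0.5))
  # cohort growth-zone lengths: first and last tagma differ
  coh <- default_measured_cohort()
  cg <- tagma_group_compare(coh[!is.na(coh$tagma), ], "gz_length_mm")
  pair <- cg[cg$pair == "abdominal-thoracic_premolt", ]
  expect_lt(pair$p_adj, 0.05)
  expect_lt(pair$diff, 0)
})
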