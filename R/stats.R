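TAGMA_LEVELS <- c("thoracic_premolt", "thoracic_postmolt", "genital", "abdominal")

#' Assign a tagma group from an En stripe count
#'
#' Stripe counts map to axial body regions: 3--6 thoracic pre-molt, 7--11
#' thoracic post-molt, 12--13 genital, 14--17 abdominal. Counts outside
#' 3--17 are flagged out of range and return `NA` (with a warning unless
#' `quiet = TRUE`).
#'
#' @param en_stripes Integer vector of trunk En stripe counts.
#' @param quiet Suppress the out-of-range warning.
#' @return Factor with levels thoracic_premolt, thoracic_postmolt,
#'   genital, abdominal.
#' @export
#' @examples
#' assign_tagma(c(6, 12, 17))
assign_tagma <- function(en_stripes, quiet = FALSE) {
  out <- rep(NA_character_, length(en_stripes))
  out[en_stripes >= 3 & en_stripes <= 6] <- "thoracic_premolt"
  out[en_stripes >= 7 & en_stripes <= 11] <- "thoracic_postmolt"
  out[en_stripes >= 12 & en_stripes <= 13] <- "genital"
  out[en_stripes >= 14 & en_stripes <= 17] <- "abdominal"
  if (!quiet && any(is.na(out) & !is.na(en_stripes))) {
    warning("en_stripes outside 3-17: tagma set to NA (out-of-range flag)",
            call. = FALSE)
  }
  factor(out, levels = TAGMA_LEVELS)
}

#' Segment-addition rate by ordinary least squares
#'
#' Fits `en_stripes ~ stage_h` over a staged cohort and returns the slope
#' (segments per hour), its standard error, the intercept, and R^2.
#'
#' @param table A `cohort_table` or data frame with columns `stage_h` and
#'   `en_stripes`.
#' @return A `rate_fit` list: `slope`, `intercept`, `slope_se`, `r2`, `n`.
#' @export
#' @examples
#' coh <- generate_cohort(gz_config(), 10, 0:10, seed = 0, measure = FALSE)
#' segment_addition_rate(coh)
segment_addition_rate <- function(table) {
  if (!all(c("stage_h", "en_stripes") %in% names(table))) {
    stop("table needs columns stage_h and en_stripes", call. = FALSE)
  }
  tt <- table[stats::complete.cases(table[, c("stage_h", "en_stripes")]), ]
  if (length(unique(tt$stage_h)) < 3) {
    stop("degenerate-fit error: need >= 3 distinct timepoints", call. = FALSE)
  }
  fit <- stats::lm(en_stripes ~ stage_h, data = tt)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              slope_se = unname(sm$coefficients[2, 2]),
              r2 = sm$r.squared,
              n = nrow(tt))
  class(out) <- "rate_fit"
  out
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "<rate_fit> %.3f segments/h (SE %.4f), intercept %.2f, R2 %.3f, n = %d\n",
    x$slope, x$slope_se, x$intercept, x$r2, x$n))
  cat(sprintf("  implied interval: %.2f h per segment\n", 1 / x$slope))
  invisible(x)
}

#' PCA of the eight standardized morphometric measures
#'
#' Standardizes the eight linear/area measures (body length, GZ length,
#' widths A and B, trunk area, last-segment area, GZ area, last-segment
#' length) to zero mean and unit variance and eigendecomposes their
#' correlation matrix (via [stats::prcomp()]). Components follow the sign
#' convention that each component's largest-magnitude loading is positive.
#'
#' @param records Data frame containing the eight measure columns
#'   (complete rows only are used; at least 9 required).
#' @return A `gz_pca` list: `variance_fractions` (sums to 1), `loadings`
#'   (8 x 8 matrix), `scores` (one row per record), `n`.
#' @export
pca_morphometrics <- function(records) {
  miss <- setdiff(MEASURE_COLS, names(records))
  if (length(miss) > 0) {
    stop("records lack measure column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- records[, MEASURE_COLS]
  keep <- stats::complete.cases(x)
  x <- as.matrix(x[keep, , drop = FALSE])
  if (nrow(x) < 9) {
    stop("need >= 9 complete records for the 8-measure PCA", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate-column error: constant measure column(s): ",
         paste(MEASURE_COLS[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  out <- list(variance_fractions = pc$sdev^2 / sum(pc$sdev^2),
              loadings = pc$rotation,
              scores = pc$x,
              kept = which(keep),
              n = nrow(x))
  class(out) <- "gz_pca"
  out
}

#' @export
print.gz_pca <- function(x, ...) {
  cat(sprintf("<gz_pca> n = %d records\n", x$n))
  vf <- round(100 * x$variance_fractions, 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Permutation test of multivariate group separation
#'
#' Tests whether groups (e.g. tagmata) differ in multivariate position
#' over the first three principal components using a pseudo-F statistic
#' (between-group over within-group dispersion) whose null distribution is
#' obtained by permuting group labels. The p-value is
#' `(1 + #(perm >= obs)) / (1 + n_permutations)`.
#'
#' @param scores Numeric matrix of component scores (first 3 columns used,
#'   or fewer if not available).
#' @param labels Group labels, one per score row; each group needs >= 2
#'   rows.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return List with `statistic`, `p`, `n_permutations`, `groups`.
#' @export
tagma_separation <- function(scores, labels, n_permutations = 999, seed = 0) {
  x <- as.matrix(scores)[, seq_len(min(3, ncol(as.matrix(scores)))), drop = FALSE]
  labels <- droplevels(factor(labels))
  if (nrow(x) != length(labels)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("grouping error: need >= 2 groups with >= 2 rows each", call. = FALSE)
  }
  n <- nrow(x); g <- length(tab)
  grand <- colMeans(x)
  sst <- sum(sweep(x, 2, grand)^2)
  pseudo_f <- function(lab) {
    gm <- rowsum(x, lab) / as.vector(table(lab))
    ssb <- sum(as.vector(table(lab)) * rowSums(sweep(gm, 2, grand)^2))
    ssw <- sst - ssb
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  obs <- pseudo_f(labels)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) pseudo_f(sample(labels)), numeric(1))
  })
  list(statistic = obs,
       p = (1 + sum(perm >= obs)) / (1 + n_permutations),
       n_permutations = n_permutations,
       groups = as.integer(g))
}

#' Regress PC1 on an ordered group coding
#'
#' Fits `pc1 ~ group` by least squares with the group coded as an integer
#' (tagma order thoracic_premolt = 1 ... abdominal = 4, or the stripe
#' count itself) and reports the adjusted R^2 and the F-test p-value.
#'
#' @param pc1 Numeric vector of first-component scores.
#' @param group Tagma factor or integer stripe counts.
#' @return List with `adj_r2`, `p`, `n`.
#' @export
regress_pc1_on_group <- function(pc1, group) {
  if (is.factor(group) || is.character(group)) {
    code <- as.integer(factor(group, levels = TAGMA_LEVELS))
  } else {
    code <- as.integer(group)
  }
  keep <- !is.na(pc1) & !is.na(code)
  pc1 <- pc1[keep]; code <- code[keep]
  if (length(pc1) < 3) stop("need >= 3 rows", call. = FALSE)
  if (length(unique(code)) < 2) {
    stop("degenerate-fit error: a single group level", call. = FALSE)
  }
  fit <- stats::lm(pc1 ~ code)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(adj_r2 = sm$adj.r.squared,
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       n = length(pc1))
}

#' Pairwise tagma comparisons of one measure (Tukey HSD)
#'
#' All pairwise mean differences of `measure` between tagma groups with
#' familywise-adjusted p-values from the studentized-range distribution
#' (one-way ANOVA followed by Tukey's honest significant difference).
#'
#' @param records Data frame with a `tagma` column and the measure column.
#' @param measure Name of the measure column.
#' @return Data frame with columns `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tagma_group_compare <- function(records, measure) {
  if (!measure %in% names(records)) {
    stop("unknown measure column: ", measure, call. = FALSE)
  }
  d <- data.frame(y = records[[measure]],
                  g = droplevels(factor(records$tagma)))
  d <- d[stats::complete.cases(d), ]
  tab <- table(d$g)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("grouping error: need >= 2 groups with >= 2 rows each", call. = FALSE)
  }
  hsd <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
  data.frame(pair = rownames(hsd),
             diff = hsd[, "diff"],
             lwr = hsd[, "lwr"],
             upr = hsd[, "upr"],
             p_adj = hsd[, "p adj"],
             row.names = NULL,
             stringsAsFactors = FALSE)
}
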