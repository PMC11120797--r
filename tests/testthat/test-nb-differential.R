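test_that("median-of-ratios size factors match hand computation and DESeq2", {
  m <- matrix(c(10, 30, 20, 60), 2, 2)  # features x samples
  expect_equal(size_factors_median_ratios(m), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-12)
  same <- matrix(rep(c(5, 9, 13), 3), 3, 3)
  expect_equal(size_factors_median_ratios(same), rep(1, 3))
  # column scaling is homogeneous up to the overall scale (factors are
  # defined relative to the geometric-mean pseudo-reference, so ratios
  # between samples carry the scaling)
  set.seed(1)
  m2 <- matrix(rpois(300, 50) + 1L, 100, 3)
  sf <- size_factors_median_ratios(m2)
  m3 <- m2; m3[, 2] <- m3[, 2] * 4L
  sf3 <- size_factors_median_ratios(m3)
  expect_equal(sf3[2] / sf3[1], 4 * sf[2] / sf[1], tolerance = 1e-12)
  expect_equal(sf3[3] / sf3[1], sf[3] / sf[1], tolerance = 1e-12)
  expect_error(size_factors_median_ratios(matrix(c(0, 1, 1, 0), 2)),
               "all-positive")
  # independent implementation agrees
  expect_equal(size_factors_median_ratios(m2),
               unname(DESeq2::estimateSizeFactorsForMatrix(m2)),
               tolerance = 1e-8)
})

test_that("dispersion estimates recover simulated values", {
  set.seed(17)
  n <- 200
  pois <- matrix(rpois(50 * n, 100), 50, n)
  a_pois <- estimate_dispersion(pois, rep(1, n), shrink = FALSE)
  expect_true(mean(a_pois) < 0.05)

  nb <- matrix(rnbinom(200 * n, mu = 100, size = 1 / 0.4), 200, n)
  a_nb <- estimate_dispersion(nb, rep(1, n), shrink = FALSE)
  expect_true(mean(a_nb) > 0.3 && mean(a_nb) < 0.5)

  zero <- rbind(nb[1:5, ], 0)
  a0 <- estimate_dispersion(zero, rep(1, n), shrink = FALSE)
  expect_equal(a0[6], 1e-8)

  # within-group moments ignore a planted fold change
  y <- cbind(matrix(rnbinom(300 * 3, mu = 100, size = 50), 300, 3),
             matrix(rnbinom(300 * 3, mu = 400, size = 50), 300, 3))
  pooled <- estimate_dispersion(y, rep(1, 6), shrink = FALSE)
  grouped <- estimate_dispersion(y, rep(1, 6), groups = rep(c("a", "b"), each = 3),
                                 shrink = FALSE)
  expect_true(median(grouped) < 0.1)
  # the 4-fold shift masquerades as dispersion when groups are pooled:
  # between-group variance (3/5)*150^2 over mean^2 250^2 gives ~0.2
  expect_true(median(pooled) > 0.2)
})

test_that("the NB Wald test is symmetric, unbiased on planted effects, and matches glm", {
  sheet <- two_condition_sheet(3)
  ident <- matrix(rep(c(10L, 25L, 40L), 6), 3, 6,
                  dimnames = list(paste0("f", 1:3), sheet$sample))
  tab <- nb_wald_test(ident, sheet)
  expect_equal(tab$log2_fold_change, rep(0, 3))
  expect_equal(tab$p_value, rep(1, 3))

  set.seed(23)
  counts <- cbind(matrix(rnbinom(50 * 3, mu = 50, size = 20), 50, 3),
                  matrix(rnbinom(50 * 3, mu = 800, size = 20), 50, 3))
  dimnames(counts) <- list(paste0("f", 1:50), sheet$sample)
  # unit size factors: every feature carries the planted 16-fold shift,
  # which depth normalisation would otherwise absorb
  tab16 <- nb_wald_test(counts, sheet, size_factors = rep(1, 6))
  expect_true(mean(tab16$log2_fold_change) > 3.7 &&
              mean(tab16$log2_fold_change) < 4.3)

  # swapping condition labels negates the fold change, p unchanged
  sheet_rev <- sheet[c(4:6, 1:3), ]
  tab_rev <- nb_wald_test(counts, sheet_rev, size_factors = rep(1, 6))
  expect_equal(tab_rev$log2_fold_change, -tab16$log2_fold_change)
  expect_equal(tab_rev$p_value, tab16$p_value)

  # against an independent GLM fit with the same fixed dispersion
  alpha <- 0.05
  disp <- rep(alpha, 50)
  ours <- nb_wald_test(counts, sheet, size_factors = rep(1, 6),
                       dispersions = disp)
  grp <- factor(sheet$condition, levels = c("A", "B"))
  for (i in c(1, 7, 20)) {
    fit <- suppressWarnings(stats::glm(
      counts[i, ] ~ grp, family = MASS::negative.binomial(theta = 1 / alpha)))
    expect_equal(ours$log2_fold_change[i], unname(coef(fit)[2]) / log(2),
                 tolerance = 1e-5)
    se_glm <- summary(fit, dispersion = 1)$coefficients[2, 2]
    expect_equal(ours$se[i], se_glm / log(2), tolerance = 1e-4)
  }

  # all-zero conventions
  z <- matrix(0L, 2, 6, dimnames = list(c("z1", "z2"), sheet$sample))
  z[2, 4:6] <- c(30L, 40L, 50L)
  tz <- nb_wald_test(z, sheet, size_factors = rep(1, 6),
                     dispersions = c(0.05, 0.05))
  expect_equal(tz$log2_fold_change[1], 0)
  expect_equal(tz$p_value[1], 1)
  expect_equal(tz$log2_fold_change[2], Inf)
  expect_true(is.na(tz$p_value[2]))
})

test_that("BH adjustment and significance flags follow the strict rule", {
  expect_equal(bh_adjust(0.013), 0.013)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(3)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p) && all(adj <= 1))

  tab <- data.frame(feature_id = paste0("f", 1:4),
                    log2_fold_change = c(1.5, 4.0, -3.6, -4),
                    padj = c(1e-9, 1e-6, 1e-5, NA))
  out <- apply_significance(tab, 1.5, 1e-5)
  # |lfc| exactly at the threshold, and padj exactly at it, do not pass
  expect_equal(out$significant, c(FALSE, TRUE, FALSE, FALSE))
  out2 <- apply_significance(tab, 3.5, 1e-5)
  expect_equal(out2$significant, c(FALSE, TRUE, FALSE, FALSE))
  # elementwise oracle on random tables
  rt <- data.frame(feature_id = paste0("g", 1:200),
                   log2_fold_change = rnorm(200, sd = 3),
                   padj = runif(200))
  flag <- apply_significance(rt, 2, 0.1)$significant
  for (i in sample.int(200, 20))
    expect_equal(flag[i], abs(rt$log2_fold_change[i]) > 2 && rt$padj[i] < 0.1)
})

test_that("delta-delta-Ct returns relative expression", {
  expect_equal(delta_delta_ct(20, 18, 22, 20), 1)
  expect_equal(delta_delta_ct(19, 20, 20, 20), 2)
  expect_equal(delta_delta_ct(24, 20, 22, 20), 0.25)
})

test_that("nb_diff wraps the pipeline with thresholds and methods", {
  set.seed(29)
  sheet <- two_condition_sheet(3)
  counts <- cbind(matrix(rnbinom(100 * 3, mu = 100, size = 50), 100, 3),
                  matrix(rnbinom(100 * 3, mu = 100, size = 50), 100, 3))
  counts[1, 4:6] <- rnbinom(3, mu = 1600, size = 50)
  dimnames(counts) <- list(paste0("f", 1:100), sheet$sample)
  tab <- nb_diff(counts, sheet, lfc_threshold = 3.5, padj_threshold = 1e-5)
  expect_s3_class(tab, "nb_diff")
  expect_true(tab$significant[1])
  expect_equal(sum(tab$significant), 1)
  expect_output(print(tab), "1 significant")
  expect_equal(summary(tab)$n_up, 1)
})
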