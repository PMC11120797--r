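test_that("segmentation simulation tiles the chromosome deterministically", {
  two <- simulate_segmentation(100, 2, seed = 1)
  expect_equal(two$start[1], 0)
  expect_equal(two$end[2], 100)
  expect_equal(two$start[2], two$end[1])

  seg <- simulate_segmentation(1e5, 80, seed = 5)
  expect_equal(seg$start[-1], seg$end[-80])  # contiguous, disjoint
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[80], 1e5)
  expect_equal(anyDuplicated(seg$segment_id), 0)
  expect_true(all(seg$label %in% names(default_label_probs())))
  expect_identical(seg, simulate_segmentation(1e5, 80, seed = 5))
  expect_error(simulate_segmentation(10, 20), "exceeds")
})

test_that("gene simulation plants recoverable divergent pairs", {
  g <- simulate_genes(1e6, 10, divergent_gaps = 53, seed = 3)
  pairs <- find_divergent_pairs(g, max_gap = 1000)
  truth <- attr(g, "pairs")
  hit <- pairs[pairs$minus_gene == truth$minus_gene &
               pairs$plus_gene == truth$plus_gene, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$tss_gap, 53)
  expect_true(hit$strict)

  # without planted pairs and a wide spacing, no divergent pair arises
  g2 <- simulate_genes(1e6, 8, seed = 4, min_tss_spacing = 5000)
  expect_equal(nrow(find_divergent_pairs(g2, 1000)), 0)
  expect_identical(simulate_genes(1e6, 10, divergent_gaps = 53, seed = 3), g)
  expect_true(all(tss_of(g) >= 0 & tss_of(g) < 1e6))
})

test_that("4C counts follow length-weighted decay with planted peaks", {
  seg <- simulate_segmentation(2e5, 100, seed = 2)
  vp <- genome_interval("chrS", 99000, 101000)

  # monotone decay: expected count per bp falls with distance
  sim0 <- simulate_4c_counts(seg, vp, n_reps = 1, seed = 7)
  lam <- sim0$truth$lambda
  d <- abs((seg$start + seg$end) / 2 - 1e5)
  len <- seg$end - seg$start
  expect_equal(suppressWarnings(cor(lam / len, d, method = "spearman")), -1)

  # limiting case: one overwhelming peak takes essentially all reads
  big <- setNames(1e12, seg$segment_id[10])
  simp <- simulate_4c_counts(seg, vp, n_reps = 1, background = 0,
                             peaks = big, dispersion = 0, seed = 8)
  expect_true(simp$truth$lambda[10] / sum(simp$truth$lambda) > 0.99)

  # Monte-Carlo: replicate means match lambda within 3 MC-SE
  sim <- simulate_4c_counts(seg, vp, n_reps = 200, dispersion = 0.05,
                            seed = 9)
  mu <- rowMeans(sim$counts)
  lam <- sim$truth$lambda
  se <- sqrt((lam + 0.05 * lam^2) / 200)
  frac_in <- mean(abs(mu - lam) <= 3 * se + 1e-9)
  expect_true(frac_in > 0.97)
  expect_identical(sim$counts,
                   simulate_4c_counts(seg, vp, n_reps = 200,
                                      dispersion = 0.05, seed = 9)$counts)
})

test_that("condition pairs plant multiplicative contact changes", {
  seg <- simulate_segmentation(2e5, 100, seed = 12)
  vp <- genome_interval("chrS", 99000, 101000)
  none <- simulate_condition_pair(seg, vp, seed = 1)
  expect_equal(none$truth$lambda, none$truth$lambda_b)
  expect_equal(nrow(none$sheet), 6)

  target <- seg$segment_id[20]
  peaks <- setNames(500 / fourcseg:::contact_lambda(seg, vp, 3, 4e-7, NULL, 5e5)[20],
                    target)
  chg <- setNames(-4, target)
  sim <- simulate_condition_pair(seg, vp, contact_changes = chg, n_reps = 150,
                                 peaks = peaks, dispersion = 0.02, seed = 2)
  expect_true(all(names(chg) %in% seg$segment_id))
  a <- mean(sim$counts[target, sim$sheet$condition == "WT"])
  b <- mean(sim$counts[target, sim$sheet$condition == "MUT"])
  lam_a <- sim$truth$lambda[target]
  se_ratio <- 3 * sqrt(lam_a + 0.02 * lam_a^2) / sqrt(150) / lam_a
  expect_true(abs(b / a - 1 / 16) < 2 * se_ratio + 0.02)
})

test_that("expression counts exercise size-factor recovery and nulls", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:2000), chrom = "chrS",
                      start = (1:2000) * 400, end = (1:2000) * 400 + 200,
                      strand = "+", biotype = "coding")
  sim <- simulate_expression_counts(genes, n_reps = 3, seed = 31,
                                    depth_factors = rep(c(0.5, 1, 2), 2))
  sf <- size_factors_median_ratios(sim$counts)
  truth <- rep(c(0.5, 1, 2), 2)
  truth <- truth / exp(mean(log(truth)))
  sf <- sf / exp(mean(log(sf)))
  expect_true(all(abs(sf / truth - 1) < 0.05))

  # null simulation stays null under the strict expression thresholds
  tab <- nb_diff(sim$counts, sim$sheet, lfc_threshold = 1.5,
                 padj_threshold = 1e-4)
  expect_true(sum(tab$significant) <= 2)
  expect_identical(sim$counts,
                   simulate_expression_counts(genes, n_reps = 3, seed = 31,
                                              depth_factors = rep(c(0.5, 1, 2), 2))$counts)
})

test_that("sequence simulation hits GC targets with tunable CpG enrichment", {
  s1 <- simulate_sequence(10000, gc_target = 0.5, cpg_enrichment = 1, seed = 41)
  c1 <- sequence_composition(s1)
  expect_true(abs(c1$gc_fraction - 0.5) < 0.03)
  expect_true(abs(c1$cpg_obs_exp - 1) < 0.15)

  s0 <- simulate_sequence(10000, gc_target = 0.5, cpg_enrichment = 0, seed = 42)
  expect_true(sequence_composition(s0)$cpg_obs_exp < 0.2)

  obsexp <- sapply(c(0.2, 1, 1.8), function(e)
    sequence_composition(simulate_sequence(8000, 0.45, e, seed = 43))$cpg_obs_exp)
  expect_true(all(diff(obsexp) > 0))

  s6 <- simulate_sequence(5000, gc_target = 0.6, cpg_enrichment = 1.5, seed = 44)
  expect_true(abs(sequence_composition(s6)$gc_fraction - 0.6) < 0.03)
  expect_identical(simulate_sequence(200, seed = 9), simulate_sequence(200, seed = 9))
})

test_that("the study generator wires planted truth through its files", {
  study <- simulate_study(seed = 2)
  expect_true(all(names(study$truth$peaks) %in% study$segments$segment_id))
  expect_true(all(names(study$truth$contact_changes) %in%
                  study$segments$segment_id))
  expect_equal(ncol(study$contacts$counts), 6)
  expect_equal(nrow(study$expression$counts), nrow(study$genes))
  # generated files parse cleanly through the package readers
  dir <- withr::local_tempdir()
  write_bed(study$segments, file.path(dir, "seg.bed"))
  write_bed(study$genes, file.path(dir, "genes.bed"))
  expect_silent(seg2 <- read_bed(file.path(dir, "seg.bed"), "segments"))
  expect_equal(seg2$start, study$segments$start)
  expect_silent(g2 <- read_bed(file.path(dir, "genes.bed"), "genes"))
  expect_equal(g2$strand, study$genes$strand)
})
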