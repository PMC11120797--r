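test_that("log transform and 8-bit scaling follow their definitions", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(1, pseudocount = exp(1) - 1), 1)
  v <- log_transform(0:20)
  expect_true(all(diff(v) > 0))
  expect_error(log_transform(c(1, -2)), "negative")

  s <- scale_to_8bit(c(0, log(2), log(10)))
  expect_equal(as.integer(s), c(0L, 77L, 255L))  # 255*ln2/ln10 = 76.76
  expect_error(scale_to_8bit(c(5, 5, 5)), class = "degenerate_profile")

  set.seed(2)
  x <- rnorm(100)
  expect_equal(as.integer(scale_to_8bit(x)),
               as.integer(scale_to_8bit(3.7 * x + 11)))  # affine invariance
})

test_that("Otsu threshold equals the exhaustive argmax with smallest-k ties", {
  h <- integer(256)
  h[51] <- 100L; h[201] <- 100L  # bins 50 and 200
  res <- otsu_threshold(h)
  expect_equal(res$threshold, 50L)
  expect_equal(res$between_class_variance[51], 5625)
  expect_equal(res$threshold, brute_otsu(h))
  expect_equal(sum(res$histogram), 200)

  h1 <- integer(256); h1[8] <- 40L
  expect_true(otsu_threshold(h1)$degenerate)

  set.seed(13)
  for (rep in 1:200) {
    h <- integer(256)
    nb <- sample(2:30, 1)
    h[sample.int(256, nb)] <- sample.int(50, nb, replace = TRUE)
    res <- otsu_threshold(h)
    expect_equal(res$threshold, brute_otsu(h))
    expect_equal(max(res$between_class_variance),
                 res$between_class_variance[res$threshold + 1])
  }
})

test_that("valid-interaction calls respect consensus rules and replicate structure", {
  counts <- cbind(r1 = c(0L, 2L, 50L, 4L, 1L, 0L),
                  r2 = c(1L, 1L, 60L, 30L, 0L, 2L))
  rownames(counts) <- paste0("f", 1:6)
  sheet <- data.frame(sample = c("r1", "r2"), condition = "WT",
                      replicate = 1:2)
  all_c <- call_valid_interactions(counts, sheet, consensus_rule = "all")
  any_c <- call_valid_interactions(counts, sheet, consensus_rule = "any")
  # f4 exceeds the threshold in replicate 2 only
  expect_true(any_c$valid["f4", "r2"] && !all_c$valid["f4", "r1"])
  expect_false(all_c$consensus["f4", "WT"])
  expect_true(any_c$consensus["f4", "WT"])
  expect_true(all_c$consensus["f3", "WT"])

  # identical replicate columns: consensus equals single-replicate calls
  dup <- counts[, c(1, 1)]
  colnames(dup) <- c("r1", "r2")
  for (rule in c("all", "any", "majority")) {
    cc <- call_valid_interactions(dup, sheet, consensus_rule = rule)
    expect_equal(unname(cc$consensus[, "WT"]), unname(cc$valid[, "r1"]))
  }

  # a constant replicate is degenerate and contributes no calls
  counts2 <- cbind(counts, r3 = rep(5L, 6))
  sheet3 <- data.frame(sample = c("r1", "r2", "r3"), condition = "WT",
                       replicate = 1:3)
  deg <- call_valid_interactions(counts2, sheet3, consensus_rule = "all")
  expect_equal(deg$degenerate_samples, "r3")
  expect_true(all(is.na(deg$valid[, "r3"])))
  expect_equal(unname(deg$consensus[, "WT"]),
               unname(deg$valid[, "r1"] & deg$valid[, "r2"]))
})

test_that("call sets are identical under any logarithm base", {
  set.seed(21)
  for (rep in 1:10) {
    counts <- matrix(rnbinom(200 * 4, mu = rexp(200, 1 / 50), size = 5),
                     200, 4, dimnames = list(paste0("f", 1:200),
                                             paste0("s", 1:4)))
    sheet <- two_condition_sheet(2)
    a <- call_valid_interactions(counts, sheet, log_base = exp(1))
    b <- call_valid_interactions(counts, sheet, log_base = 10)
    expect_identical(a$valid, b$valid)
    expect_identical(a$consensus, b$consensus)
    expect_identical(a$thresholds, b$thresholds)
  }
})

test_that("viewpoint exclusion masks segments before thresholding", {
  seg <- random_tiling(40, span = 40000)
  set.seed(5)
  counts <- matrix(rpois(80, 20), 40, 2,
                   dimnames = list(seg$segment_id, c("r1", "r2")))
  sheet <- data.frame(sample = c("r1", "r2"), condition = "WT", replicate = 1:2)
  vp <- genome_interval("chrA", 20000, 20100)
  cc <- call_valid_interactions(counts, sheet, segments = seg, viewpoint = vp,
                                exclusion_radius = 5000)
  expect_true(any(cc$excluded))
  expect_true(all(is.na(cc$valid[cc$excluded, ])))
  expect_true(all(is.na(cc$consensus[cc$excluded, ])))
  want <- seg$chrom == "chrA" &
    interval_overlaps(seg$start, seg$end, 15000, 20100 + 5000)
  expect_equal(cc$excluded, want)
})

test_that("per-gene contact summaries honour the flank and match a window scan", {
  seg <- data.frame(segment_id = c("p", "q"), chrom = "chr1",
                    start = c(9500, 20000), end = c(10500, 21000),
                    label = c("TSS", "R"))
  genes <- data.frame(gene_id = c("near", "far"), chrom = "chr1",
                      start = c(10000, 24500), end = c(12000, 26000),
                      strand = "+", biotype = "coding")
  counts <- cbind(r1 = c(100L, 90L), r2 = c(110L, 95L))
  rownames(counts) <- seg$segment_id
  # add background rows so the threshold is meaningful
  bg <- matrix(rpois(60, 1), 30, 2)
  rownames(bg) <- paste0("b", 1:30)
  seg_bg <- data.frame(segment_id = rownames(bg), chrom = "chr1",
                       start = 30000 + 0:29 * 100,
                       end = 30000 + 0:29 * 100 + 100, label = "R")
  counts <- rbind(counts, bg)
  seg <- rbind(seg, seg_bg)
  sheet <- data.frame(sample = c("r1", "r2"), condition = "WT", replicate = 1:2)
  calls <- call_valid_interactions(counts, sheet, segments = seg)
  expect_true(all(calls$consensus[c("p", "q"), "WT"]))

  s3 <- summarize_calls(calls, genes, flank = 3000)
  expect_true(s3$contacted[s3$gene_id == "near"])
  # segment q ends 3.5 kb before gene "far"'s TSS at 24500
  expect_false(s3$contacted[s3$gene_id == "far"])
  s5 <- summarize_calls(calls, genes, flank = 5000)
  expect_true(s5$contacted[s5$gene_id == "far"])
  expect_match(s3$segments[s3$gene_id == "near"], "p")

  # randomized instance against a brute-force window scan
  set.seed(31)
  rg <- random_genes(15, chroms = "chr1", span = 35000)
  got <- summarize_calls(calls, rg, flank = 2000)
  cons <- calls$consensus[, "WT"]
  for (i in seq_len(nrow(rg))) {
    tss <- if (rg$strand[i] == "+") rg$start[i] else rg$end[i] - 1
    hit <- which(cons & seg$start < tss + 2001 & seg$end > tss - 2000)
    expect_equal(got$contacted[i], length(hit) > 0)
  }
})

test_that("call sets serialise to TSV plus JSON summary", {
  dir <- withr::local_tempdir()
  seg <- random_tiling(30, span = 3000)
  set.seed(8)
  counts <- matrix(rpois(60, 10), 30, 2,
                   dimnames = list(seg$segment_id, c("r1", "r2")))
  sheet <- data.frame(sample = c("r1", "r2"), condition = "WT", replicate = 1:2)
  calls <- call_valid_interactions(counts, sheet, segments = seg)
  path <- file.path(dir, "calls.tsv")
  write_calls(calls, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 30)
  expect_true(all(c("segment_id", "label", "scaled_r1", "valid_r2",
                    "consensus_WT") %in% names(tab)))
  expect_equal(tab$consensus_WT, unname(calls$consensus[, "WT"]))
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$n_segments, 30)
  expect_equal(js$consensus_valid$WT, sum(calls$consensus[, "WT"]))
})
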