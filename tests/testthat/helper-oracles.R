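# Independent brute-force oracles used across the suite. These are
# deliberately naive reimplementations (loops, exhaustive enumeration)
# kept free of any package internals they are checking.

# exhaustive argmax of the between-class variance over all 255 cuts
brute_otsu <- function(h) {
  n <- sum(h)
  best_k <- NA_integer_
  best <- -Inf
  for (k in 0:254) {
    w0 <- sum(h[1:(k + 1)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:k) * h[1:(k + 1)]) / sum(h[1:(k + 1)])
    mu1 <- sum(((k + 1):255) * h[(k + 2):256]) / sum(h[(k + 2):256])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) {
      best <- v
      best_k <- k
    }
  }
  best_k
}

# per-read assignment by scanning every segment
brute_count <- function(reads, segments, rule) {
  counts <- stats::setNames(integer(nrow(segments)), segments$segment_id)
  unassigned <- 0L
  ambiguous <- 0L
  for (i in seq_len(nrow(reads))) {
    ov <- numeric(nrow(segments))
    for (j in seq_len(nrow(segments))) {
      if (reads$chrom[i] == segments$chrom[j] &&
          reads$start[i] < segments$end[j] &&
          segments$start[j] < reads$end[i])
        ov[j] <- min(segments$end[j], reads$end[i]) -
          max(segments$start[j], reads$start[i])
    }
    hit <- which(ov > 0)
    if (length(hit) == 0L) unassigned <- unassigned + 1L
    else if (rule == "all") counts[hit] <- counts[hit] + 1L
    else if (rule == "unique") {
      if (length(hit) > 1L) ambiguous <- ambiguous + 1L
      else counts[hit] <- counts[hit] + 1L
    } else {
      # leftmost among maximal overlaps
      cand <- hit[ov[hit] == max(ov[hit])]
      best <- cand[which.min(segments$start[cand])]
      counts[best] <- counts[best] + 1L
    }
  }
  list(counts = counts, unassigned = unassigned, ambiguous = ambiguous)
}

# quadratic enumeration of divergent pairs
brute_divergent <- function(genes, max_gap) {
  out <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(genes))) {
    if (i >= j) next
    a <- genes[i, ]; b <- genes[j, ]
    if (a$chrom != b$chrom || a$strand == b$strand) next
    minus <- if (a$strand == "-") a else b
    plus <- if (a$strand == "+") a else b
    tm <- if (minus$strand == "+") minus$start else minus$end - 1
    tp <- if (plus$strand == "+") plus$start else plus$end - 1
    if (abs(tp - tm) <= max_gap)
      out[[length(out) + 1L]] <- data.frame(
        minus_gene = minus$gene_id, plus_gene = plus$gene_id,
        tss_gap = tp - tm, strict = tm <= tp, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(minus_gene = character(), plus_gene = character(),
                      tss_gap = numeric(), strict = logical()))
  do.call(rbind, out)
}

# per-item half-open overlap scan
brute_overlap_subset <- function(items, tad) {
  keep <- logical(nrow(items))
  for (i in seq_len(nrow(items)))
    keep[i] <- items$chrom[i] == tad$chrom &&
      items$start[i] < tad$end && tad$start < items$end[i]
  items[keep, , drop = FALSE]
}

random_genes <- function(n, chroms = c("chrA", "chrB"), span = 1e5) {
  start <- sample.int(span, n)
  len <- sample(50:5000, n, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = "coding", stringsAsFactors = FALSE)
}

# a tiling segmentation over [0, span) on one chromosome
random_tiling <- function(n_seg, span = 1e4, chrom = "chrA") {
  breaks <- sort(sample.int(span - 1L, n_seg - 1L))
  data.frame(segment_id = sprintf("s%03d", seq_len(n_seg)),
             chrom = chrom, start = c(0, breaks), end = c(breaks, span),
             label = sample(c("TSS", "E", "T", "R"), n_seg, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_reads <- function(n, span = 1e4, chrom = "chrA") {
  start <- sample.int(span + 200L, n) - 100L
  data.frame(chrom = chrom, start = start,
             end = start + sample(20:150, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

two_condition_sheet <- function(n_reps = 2, conditions = c("A", "B"),
                                prefix = "s") {
  data.frame(sample = paste0(prefix, seq_len(2 * n_reps)),
             condition = rep(conditions, each = n_reps),
             replicate = rep(seq_len(n_reps), 2),
             stringsAsFactors = FALSE)
}
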