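#' Default chromatin-state label vocabulary
#'
#' A small combined-segmentation-style state set with rough genomic
#' proportions: `TSS` (promoter-like), `PF` (promoter flanking), `E`
#' (enhancer), `WE` (weak enhancer), `CTCF`, `T` (transcribed), `R`
#' (repressed/quiescent).
#'
#' @return named numeric vector of label probabilities summing to 1
#' @export
default_label_probs <- function() {
  c(TSS = 0.04, PF = 0.06, E = 0.08, WE = 0.10, CTCF = 0.05,
    T = 0.27, R = 0.40)
}

#' Simulate a contiguous labelled segmentation
#'
#' Tiles `[0, chrom_length)` with `n_segments` contiguous half-open
#' segments (breakpoints drawn uniformly without replacement) and
#' assigns labels i.i.d. from `label_probs`, emulating a
#' chromatin-state segmentation of one chromosome.
#'
#' @param chrom_length chromosome length in bp
#' @param n_segments number of segments (`2 <= n_segments <=
#'   chrom_length`)
#' @param label_probs named probability vector over state labels
#' @param seed RNG seed (`NULL` to use the current RNG state)
#' @param chrom chromosome name
#' @return segment data.frame (`segment_id`, `chrom`, `start`, `end`,
#'   `label`)
#' @export
simulate_segmentation <- function(chrom_length, n_segments,
                                  label_probs = default_label_probs(),
                                  seed = NULL, chrom = "chrS") {
  stopifnot(n_segments >= 2L)
  if (n_segments > chrom_length)
    stop("n_segments exceeds chrom_length; cannot tile")
  if (!is.null(seed)) set.seed(seed)
  breaks <- sort(sample.int(chrom_length - 1L, n_segments - 1L))
  data.frame(segment_id = sprintf("seg%06d", seq_len(n_segments)),
             chrom = chrom,
             start = c(0, breaks), end = c(breaks, chrom_length),
             label = sample(names(label_probs), n_segments, replace = TRUE,
                            prob = label_probs),
             stringsAsFactors = FALSE)
}

#' Simulate gene annotations with plantable divergent pairs
#'
#' Places `n_genes` random stranded genes on a chromosome; for each
#' entry of `divergent_gaps` one '-'/'+' gene pair is planted with
#' exactly that signed TSS gap (`tss(plus) - tss(minus)`), so a
#' divergent-pair scan can be validated against known truth. TSS
#' positions can be constrained to a range and to a minimum mutual
#' spacing (planted pair members are exempt from the spacing rule
#' with respect to each other).
#'
#' @param chrom_length chromosome length in bp
#' @param n_genes total number of genes (including planted pair
#'   members)
#' @param divergent_gaps numeric vector of TSS gaps to plant (bp)
#' @param seed RNG seed
#' @param chrom chromosome name
#' @param tss_range optional `c(lo, hi)` restricting TSS placement
#' @param min_tss_spacing minimum distance between TSSs of distinct
#'   placements (default 0)
#' @param forbidden_tss optional list of `c(lo, hi)` ranges no TSS may
#'   fall into (e.g. a viewpoint exclusion zone)
#' @return gene data.frame; attribute `pairs` records the planted
#'   pairs (`minus_gene`, `plus_gene`, `tss_gap`)
#' @export
simulate_genes <- function(chrom_length, n_genes, divergent_gaps = numeric(0),
                           seed = NULL, chrom = "chrS", tss_range = NULL,
                           min_tss_spacing = 0, forbidden_tss = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- length(divergent_gaps)
  stopifnot(n_genes >= 2L * n_pairs)
  if (is.null(tss_range)) tss_range <- c(0, chrom_length - 1)
  rand_len <- function(n) round(exp(stats::runif(n, log(2000), log(50000))))

  placed_tss <- numeric(0)
  place_tss <- function() {
    for (try in 1:1000) {
      t <- round(stats::runif(1, tss_range[1], tss_range[2]))
      if (length(placed_tss) > 0L && min(abs(placed_tss - t)) < min_tss_spacing)
        next
      if (!is.null(forbidden_tss) &&
          any(vapply(forbidden_tss, function(f) t >= f[1] && t <= f[2],
                     logical(1))))
        next
      return(t)
    }
    stop("could not place gene TSS after 1000 retries; relax min_tss_spacing")
  }

  rows <- list()
  k <- 0L
  for (gap in divergent_gaps) {
    t_minus <- place_tss()
    placed_tss <- c(placed_tss, t_minus)
    t_plus <- t_minus + gap
    lm <- rand_len(1); lp <- rand_len(1)
    k <- k + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sprintf("gene%03d", k), chrom = chrom,
      start = max(0, t_minus + 1 - lm), end = t_minus + 1,
      strand = "-", biotype = "lncRNA", stringsAsFactors = FALSE)
    k <- k + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sprintf("gene%03d", k), chrom = chrom,
      start = t_plus, end = min(chrom_length, t_plus + lp),
      strand = "+", biotype = "lncRNA", stringsAsFactors = FALSE)
  }
  pairs <- if (n_pairs > 0L) data.frame(
    minus_gene = sprintf("gene%03d", seq(1L, by = 2L, length.out = n_pairs)),
    plus_gene = sprintf("gene%03d", seq(2L, by = 2L, length.out = n_pairs)),
    tss_gap = divergent_gaps, stringsAsFactors = FALSE)
  else data.frame(minus_gene = character(), plus_gene = character(),
                  tss_gap = numeric())

  for (i in seq_len(n_genes - 2L * n_pairs)) {
    t <- place_tss()
    placed_tss <- c(placed_tss, t)
    len <- rand_len(1)
    strand <- sample(c("+", "-"), 1L)
    k <- k + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sprintf("gene%03d", k), chrom = chrom,
      start = if (strand == "+") t else max(0, t + 1 - len),
      end = if (strand == "+") min(chrom_length, t + len) else t + 1,
      strand = strand,
      biotype = sample(c("coding", "lncRNA", "pseudogene"), 1L,
                       prob = c(0.7, 0.2, 0.1)),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  attr(genes, "pairs") <- pairs
  genes
}

# expected per-segment contact rate: length-weighted power-law decay
# from the viewpoint midpoint plus a flat background; planted peaks
# multiply the local expected signal by their enrichment factor
contact_lambda <- function(segments, viewpoint, decay_alpha, background,
                           peaks, depth) {
  if (is.character(viewpoint)) viewpoint <- parse_region(viewpoint)
  d <- abs(interval_midpoint(segments) - interval_midpoint(viewpoint))
  len <- segments$end - segments$start
  local <- background + (1 + d / 1000)^(-decay_alpha)
  rate <- len * local
  if (length(peaks) > 0) {
    idx <- match(names(peaks), segments$segment_id)
    if (anyNA(idx)) stop("peak ids missing from segmentation: ",
                         paste(names(peaks)[is.na(idx)], collapse = ", "))
    rate[idx] <- rate[idx] * peaks
  }
  stats::setNames(depth * rate / sum(rate), segments$segment_id)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate viewpoint-anchored 4C segment counts
#'
#' Expected counts follow a length-weighted proximity-ligation decay
#' `lambda_i  propto  len_i * (background + (1 + d_i/1000)^-alpha)`
#' with `d_i` the distance from segment midpoint to viewpoint
#' midpoint, rescaled to a total sequencing depth; planted interaction
#' peaks multiply the local expected signal by their enrichment
#' factor. Per replicate, counts are independent NB draws with the
#' given dispersion (`Var = mu + alpha*mu^2`; 0 means Poisson).
#'
#' @param segments segment data.frame
#' @param viewpoint interval data.frame or `"chrom:start-end"` string
#' @param n_reps replicates (default 3)
#' @param depth total expected read count per replicate (default 5e5)
#' @param decay_alpha power-law decay exponent (> 0, default 3: contact
#'   probability is concentrated within tens of kb of the viewpoint, as
#'   in proximity-ligation data)
#' @param background flat far-cis background weight per bp (default
#'   4e-7 in units where the decay term is 1 at the viewpoint, leaving
#'   typical distal segments with near-zero expected counts)
#' @param peaks named numeric vector: segment id -> enrichment fold
#'   over the local expected signal
#' @param dispersion NB dispersion (default 0.02)
#' @param seed RNG seed
#' @param sample_prefix prefix for replicate column names
#' @return list with `counts` (segments x reps integer matrix) and
#'   `truth` (lambda, peaks, parameters)
#' @export
simulate_4c_counts <- function(segments, viewpoint, n_reps = 3,
                               depth = 5e5, decay_alpha = 3,
                               background = 4e-7, peaks = NULL,
                               dispersion = 0.02, seed = NULL,
                               sample_prefix = "S") {
  stopifnot(decay_alpha > 0, depth > 0)
  if (!is.null(seed)) set.seed(seed)
  lambda <- contact_lambda(segments, viewpoint, decay_alpha, background,
                           peaks, depth)
  counts <- vapply(seq_len(n_reps),
                   function(j) rnb(length(lambda), lambda, dispersion),
                   numeric(length(lambda)))
  counts <- matrix(as.integer(counts), nrow = length(lambda),
                   dimnames = list(segments$segment_id,
                                   sprintf("%s_rep%d", sample_prefix, seq_len(n_reps))))
  list(counts = counts,
       truth = list(lambda = lambda, peaks = peaks,
                    params = list(depth = depth, decay_alpha = decay_alpha,
                                  background = background,
                                  dispersion = dispersion, seed = seed)))
}

#' Simulate a two-condition 4C experiment with planted contact changes
#'
#' Both conditions share one expected-count profile (including any
#' planted peaks); the second condition multiplies the expected count
#' of each planted segment by `2^log2FC`. Returns a combined count
#' matrix and a matching sample sheet.
#'
#' @inheritParams simulate_4c_counts
#' @param contact_changes named numeric vector: segment id -> true
#'   log2 fold change (condition 2 vs condition 1)
#' @param conditions two condition names (default `c("WT", "MUT")`)
#' @return list with `counts` (segments x 2*n_reps), `sheet`, `truth`
#'   (base lambda, per-condition lambda, planted changes, peaks,
#'   params)
#' @export
simulate_condition_pair <- function(segments, viewpoint,
                                    contact_changes = NULL, n_reps = 3,
                                    conditions = c("WT", "MUT"),
                                    depth = 5e5, decay_alpha = 3,
                                    background = 4e-7, peaks = NULL,
                                    dispersion = 0.02, seed = NULL) {
  stopifnot(length(conditions) == 2L)
  if (!is.null(seed)) set.seed(seed)
  lambda <- contact_lambda(segments, viewpoint, decay_alpha, background,
                           peaks, depth)
  lambda_b <- lambda
  if (length(contact_changes) > 0) {
    idx <- match(names(contact_changes), segments$segment_id)
    if (anyNA(idx)) stop("contact-change ids missing from segmentation")
    lambda_b[idx] <- lambda_b[idx] * 2^contact_changes
  }
  n <- length(lambda)
  cols <- c(lapply(seq_len(n_reps), function(j) rnb(n, lambda, dispersion)),
            lapply(seq_len(n_reps), function(j) rnb(n, lambda_b, dispersion)))
  counts <- matrix(as.integer(unlist(cols)), nrow = n,
                   dimnames = list(segments$segment_id,
                                   paste0(rep(conditions, each = n_reps), "_rep",
                                          rep(seq_len(n_reps), 2L))))
  sheet <- data.frame(sample = colnames(counts),
                      condition = rep(conditions, each = n_reps),
                      replicate = rep(seq_len(n_reps), 2L),
                      stringsAsFactors = FALSE)
  list(counts = counts, sheet = sheet,
       truth = list(lambda = lambda, lambda_b = lambda_b,
                    contact_changes = contact_changes, peaks = peaks,
                    params = list(depth = depth, decay_alpha = decay_alpha,
                                  background = background,
                                  dispersion = dispersion, seed = seed)))
}

#' Simulate gene-expression counts with planted differential genes
#'
#' NB counts for two conditions with lognormal baseline means,
#' per-sample depth factors (to exercise size-factor recovery) and
#' planted fold changes in the second condition.
#'
#' @param genes gene data.frame (supplies gene ids)
#' @param planted_de named numeric vector: gene id -> true log2 fold
#'   change
#' @param n_reps replicates per condition (default 3)
#' @param conditions two condition names
#' @param meanlog,sdlog lognormal parameters of the baseline means
#'   (defaults `log(200)`, 1.2)
#' @param base_means optional explicit baseline means (overrides the
#'   lognormal draw), recycled/named by gene id
#' @param dispersion NB dispersion (default 0.02)
#' @param depth_factors per-sample depth multipliers, length
#'   `2*n_reps` (default all 1)
#' @param seed RNG seed
#' @return list with `counts` (genes x samples), `sheet`, `truth`
#'   (`base_means`, `planted_de`, `depth_factors`)
#' @export
simulate_expression_counts <- function(genes, planted_de = NULL, n_reps = 3,
                                       conditions = c("WT", "MUT"),
                                       meanlog = log(200), sdlog = 1.2,
                                       base_means = NULL, dispersion = 0.02,
                                       depth_factors = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ng <- nrow(genes)
  if (is.null(base_means))
    base_means <- stats::rlnorm(ng, meanlog, sdlog)
  base_means <- stats::setNames(rep_len(base_means, ng), genes$gene_id)
  if (is.null(depth_factors)) depth_factors <- rep(1, 2L * n_reps)
  stopifnot(length(depth_factors) == 2L * n_reps, all(depth_factors > 0))

  fold <- stats::setNames(rep(1, ng), genes$gene_id)
  if (length(planted_de) > 0) {
    if (!all(names(planted_de) %in% genes$gene_id))
      stop("planted DE ids missing from gene annotation")
    fold[names(planted_de)] <- 2^planted_de
  }
  mu_a <- base_means
  mu_b <- base_means * fold
  cols <- lapply(seq_len(2L * n_reps), function(j) {
    mu <- if (j <= n_reps) mu_a else mu_b
    rnb(ng, mu * depth_factors[j], dispersion)
  })
  counts <- matrix(as.integer(unlist(cols)), nrow = ng,
                   dimnames = list(genes$gene_id,
                                   paste0(rep(conditions, each = n_reps), "_rna",
                                          rep(seq_len(n_reps), 2L))))
  sheet <- data.frame(sample = colnames(counts),
                      condition = rep(conditions, each = n_reps),
                      replicate = rep(seq_len(n_reps), 2L),
                      stringsAsFactors = FALSE)
  list(counts = counts, sheet = sheet,
       truth = list(base_means = base_means, planted_de = planted_de,
                    depth_factors = depth_factors,
                    params = list(dispersion = dispersion, seed = seed)))
}

#' Simulate DNA sequence with tunable GC and CpG enrichment
#'
#' First-order Markov chain over ACGT whose stationary GC content is
#' tuned to `gc_target` and whose C-to-G transition probability is
#' scaled by `cpg_enrichment` relative to independence, so the
#' realised CpG observed/expected ratio grows monotonically with the
#' enrichment (1 = island-like neutrality, 0 = CpG-free).
#'
#' @param length sequence length in bp
#' @param gc_target target GC fraction (default 0.5)
#' @param cpg_enrichment CpG dinucleotide enrichment factor (>= 0,
#'   default 1)
#' @param seed RNG seed
#' @return a single DNA string
#' @export
simulate_sequence <- function(length, gc_target = 0.5, cpg_enrichment = 1,
                              seed = NULL) {
  stopifnot(length >= 1, gc_target > 0, gc_target < 1, cpg_enrichment >= 0)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  build <- function(gc) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    tm <- matrix(p, 4L, 4L, byrow = TRUE, dimnames = list(bases, bases))
    pg <- min(0.95, p[3] * cpg_enrichment)
    rest <- p[-3] * (1 - pg) / sum(p[-3])
    tm["C", ] <- c(rest[1], rest[2], pg, rest[3])
    tm
  }
  stationary <- function(tm) {
    e <- eigen(t(tm))
    v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
    v / sum(v)
  }
  # fixed-point tuning of the underlying gc parameter
  g <- gc_target
  for (i in 1:25) {
    tm <- build(g)
    pi_ <- stationary(tm)
    g <- min(0.98, max(0.02, g + (gc_target - (pi_[2] + pi_[3]))))
  }
  tm <- build(g)
  pi_ <- stationary(tm)
  cum <- t(apply(tm, 1L, cumsum))
  u <- stats::runif(length)
  s <- integer(length)
  s[1L] <- findInterval(u[1L], cumsum(pi_)) + 1L
  for (i in seq_len(length - 1L))
    s[i + 1L] <- findInterval(u[i + 1L], cum[s[i], ], left.open = TRUE) + 1L
  paste(bases[pmin(s, 4L)], collapse = "")
}
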