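#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: for each feature with a
#' positive geometric mean across samples, the ratio of its count to
#' that geometric mean is computed; a sample's size factor is the
#' median of these ratios.
#'
#' @param counts integer matrix, features x samples
#' @return positive numeric vector, one factor per sample
#' @examples
#' size_factors_median_ratios(matrix(c(10, 30, 20, 60), 2))  # 0.707, 1.414
#' @export
size_factors_median_ratios <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no feature has all-positive counts; cannot compute ",
         "median-of-ratios size factors (pseudo-reference fallback not implemented)")
  apply(counts, 2L, function(k) exp(stats::median(log(k[use]) - log_geo[use])))
}

#' Method-of-moments dispersion estimates
#'
#' On size-factor-normalised counts `q_ij = K_ij / sf_j` the NB2
#' relation `Var = mu + alpha * mu^2` gives the moment estimator
#' `alpha_i = (s_i^2 - m_i) / m_i^2` from the per-feature sample mean
#' and variance. With few replicates these are noisy, so estimates are
#' optionally shrunk on the log scale towards their ensemble mean:
#' `alpha~_i = exp(w * log alpha_i + (1 - w) * mean(log alpha))`
#' (default `w = 0.7`). When a per-sample grouping (condition) vector
#' is given, means and variances are taken within groups and pooled,
#' so genuine between-condition fold changes do not masquerade as
#' overdispersion. Features whose moment estimate is
#' non-positive (sampling noise can push the sample variance below
#' the mean) carry no usable overdispersion information and take the
#' ensemble mean directly; all estimates are floored at `alpha_min`.
#'
#' @param counts integer matrix, features x samples (>= 2 samples)
#' @param size_factors per-sample positive factors
#' @param groups optional per-sample condition labels for pooled
#'   within-group moments
#' @param shrink apply log-scale shrinkage (default TRUE)
#' @param w shrinkage weight on the per-feature estimate
#' @param alpha_min lower bound (default 1e-8)
#' @return numeric vector of per-feature dispersions `>= alpha_min`
#' @export
estimate_dispersion <- function(counts, size_factors, groups = NULL,
                                shrink = TRUE, w = 0.7, alpha_min = 1e-8) {
  stopifnot(ncol(counts) >= 2L, length(size_factors) == ncol(counts),
            all(size_factors > 0))
  q <- sweep(counts, 2L, size_factors, "/")
  if (is.null(groups)) {
    m <- rowMeans(q)
    s2 <- apply(q, 1L, stats::var)
    raw <- ifelse(m > 0, (s2 - m) / m^2, NA_real_)
  } else {
    stopifnot(length(groups) == ncol(counts))
    # pooled within-group moment estimator of alpha in Var = mu + alpha mu^2
    num <- 0; den <- 0
    for (g in unique(groups)) {
      qg <- q[, groups == g, drop = FALSE]
      if (ncol(qg) < 2L) next
      mg <- rowMeans(qg)
      s2g <- apply(qg, 1L, stats::var)
      num <- num + (ncol(qg) - 1L) * (s2g - mg)
      den <- den + (ncol(qg) - 1L) * mg^2
    }
    raw <- ifelse(den > 0, num / den, NA_real_)
  }
  pos <- !is.na(raw) & raw > 0
  # ensemble prior from adequately covered features only: moment
  # estimates at near-zero means are pure noise
  informative <- pos & rowMeans(q) >= 5
  if (!any(informative)) informative <- pos
  prior <- if (any(informative)) mean(log(raw[informative])) else log(alpha_min)
  alpha <- if (shrink) {
    ifelse(pos, exp(w * log(pmax(raw, alpha_min)) + (1 - w) * prior), exp(prior))
  } else {
    ifelse(pos, raw, alpha_min)
  }
  pmax(alpha, alpha_min)
}

# Fisher-scoring fit of per-feature NB group means on the log scale
# with size-factor offsets and fixed dispersion. y: features x reps.
# Returns log-mean beta and expected information per feature.
fit_nb_group <- function(y, sf, alpha) {
  q <- sweep(y, 2L, sf, "/")
  beta <- log(pmax(rowMeans(q), 1e-8))
  zero <- rowSums(y) == 0
  for (iter in 1:100) {
    mu <- exp(beta) %o% sf
    u <- rowSums((y - mu) / (1 + alpha * mu))
    info <- rowSums(mu / (1 + alpha * mu))
    step <- ifelse(info > 0, u / info, 0)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  mu <- exp(beta) %o% sf
  info <- rowSums(mu / (1 + alpha * mu))
  beta[zero] <- -Inf
  info[zero] <- 0
  list(beta = beta, info = info)
}

#' Negative-binomial Wald test between two conditions
#'
#' A deliberately simple NB differential test: per feature, group
#' means are fitted by maximum likelihood on a log-link model with
#' size-factor offsets and fixed dispersion; `log2FC =
#' log2(mu_B / mu_A)` (second condition over first), its standard
#' error comes from the expected Fisher information, and a two-sided
#' p-value from the standard normal. Benjamini-Hochberg adjustment is
#' applied across features. Features with all-zero counts in both
#' groups get `log2FC = 0`, `p = 1` by convention; features all-zero
#' in exactly one group get an infinite `log2FC` and `NA` p-value
#' (no finite Wald statistic exists without shrinkage).
#'
#' @param counts integer matrix, features x samples
#' @param sheet sample sheet with exactly two conditions; the first
#'   condition (in sheet order) is the reference
#' @param size_factors optional; computed by
#'   [size_factors_median_ratios()] when `NULL`
#' @param dispersions optional per-feature dispersions; computed by
#'   [estimate_dispersion()] when `NULL`
#' @return data.frame with `feature_id`, `base_mean` (mean normalised
#'   count), `log2_fold_change`, `se`, `wald_stat`, `p_value`, `padj`;
#'   attributes `conditions`, `size_factors`, `dispersions`
#' @export
nb_wald_test <- function(counts, sheet, size_factors = NULL,
                         dispersions = NULL) {
  stopifnot(is.matrix(counts))
  if (!setequal(colnames(counts), sheet$sample))
    stop("count matrix columns do not match sample sheet")
  counts <- counts[, sheet$sample, drop = FALSE]
  conditions <- unique(sheet$condition)
  if (length(conditions) != 2L)
    stop("exactly two conditions required, found: ",
         paste(conditions, collapse = ", "))
  if (any(table(sheet$condition) < 2L))
    warning("a condition has a single replicate; estimates will be unstable")

  if (is.null(size_factors)) size_factors <- size_factors_median_ratios(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, size_factors,
                                       groups = sheet$condition)
  a_cols <- sheet$condition == conditions[1L]
  fa <- fit_nb_group(counts[, a_cols, drop = FALSE], size_factors[a_cols], dispersions)
  fb <- fit_nb_group(counts[, !a_cols, drop = FALSE], size_factors[!a_cols], dispersions)

  lfc <- (fb$beta - fa$beta) / log(2)
  se <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  both_zero <- !is.finite(fa$beta) & !is.finite(fb$beta)
  lfc[both_zero] <- 0
  se[both_zero] <- NA_real_
  stat[both_zero] <- NA_real_
  p[both_zero] <- 1
  one_zero <- xor(is.finite(fa$beta), is.finite(fb$beta))
  se[one_zero] <- NA_real_
  stat[one_zero] <- NA_real_
  p[one_zero] <- NA_real_

  out <- data.frame(
    feature_id = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts))) else rownames(counts),
    base_mean = rowMeans(sweep(counts, 2L, size_factors, "/")),
    log2_fold_change = lfc, se = se, wald_stat = stat,
    p_value = p, padj = bh_adjust(p),
    stringsAsFactors = FALSE)
  attr(out, "conditions") <- conditions
  attr(out, "size_factors") <- size_factors
  attr(out, "dispersions") <- dispersions
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement, capped at 1 (`stats::p.adjust(method = "BH")`); `NA`
#' p-values stay `NA` and do not enter the correction.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Flag significant features at a threshold pair
#'
#' `significant <=> |log2FC| > lfc_threshold AND padj <
#' padj_threshold`, both strict, so features exactly at a threshold
#' are excluded. The conventional pairs are (3.5, 1e-5) for
#' differential 4C contacts and (1.5, 1e-4) for differential
#' expression. `NA` entries are never significant.
#'
#' @param table differential table from [nb_wald_test()]
#' @param lfc_threshold positive log2 fold-change cutoff
#' @param padj_threshold adjusted p-value cutoff
#' @return the table with a logical `significant` column and the
#'   thresholds recorded as attributes
#' @export
apply_significance <- function(table, lfc_threshold, padj_threshold) {
  stopifnot(lfc_threshold > 0, padj_threshold > 0)
  sig <- abs(table$log2_fold_change) > lfc_threshold &
    table$padj < padj_threshold
  table$significant <- !is.na(sig) & sig
  attr(table, "lfc_threshold") <- lfc_threshold
  attr(table, "padj_threshold") <- padj_threshold
  table
}

#' Two-condition NB differential analysis
#'
#' Convenience wrapper: size factors, dispersions, Wald test, BH
#' adjustment and significance flags in one call, returning a classed
#' table with print/summary methods.
#'
#' @inheritParams nb_wald_test
#' @param lfc_threshold,padj_threshold significance thresholds (see
#'   [apply_significance()]); defaults are the differential-contact
#'   pair (3.5, 1e-5)
#' @return a `nb_diff` data.frame (see [nb_wald_test()] plus
#'   `significant`)
#' @export
nb_diff <- function(counts, sheet, lfc_threshold = 3.5,
                    padj_threshold = 1e-5, size_factors = NULL,
                    dispersions = NULL) {
  tab <- nb_wald_test(counts, sheet, size_factors, dispersions)
  tab <- apply_significance(tab, lfc_threshold, padj_threshold)
  class(tab) <- c("nb_diff", "data.frame")
  tab
}

#' @export
print.nb_diff <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("NB differential test: %s vs %s (reference %s), %d features\n",
              cond[2], cond[1], cond[1], nrow(x)))
  cat(sprintf("  thresholds: |log2FC| > %g and padj < %g -> %d significant (%d up, %d down)\n",
              attr(x, "lfc_threshold"), attr(x, "padj_threshold"),
              sum(x$significant), sum(x$significant & x$log2_fold_change > 0),
              sum(x$significant & x$log2_fold_change < 0)))
  invisible(x)
}

#' @export
summary.nb_diff <- function(object, ...) {
  list(n_features = nrow(object),
       conditions = attr(object, "conditions"),
       size_factors = attr(object, "size_factors"),
       n_significant = sum(object$significant),
       n_up = sum(object$significant & object$log2_fold_change > 0),
       n_down = sum(object$significant & object$log2_fold_change < 0))
}

#' Write a differential table as TSV
#'
#' @param table `nb_diff` or plain differential table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_differential_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-ddCt` with `ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,control - Ct_ref,control)`: RT-qPCR fold change of a
#' target transcript relative to a reference transcript and a control
#' condition.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   finite Ct values (vectors recycled)
#' @return relative expression `2^-ddCt`
#' @examples
#' delta_delta_ct(24, 20, 22, 20)  # 0.25
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
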