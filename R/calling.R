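#' Call valid viewpoint interactions per replicate and condition
#'
#' The core interaction-calling procedure: for each replicate library,
#' segment counts are log-transformed, min-max scaled to the 8-bit
#' interval, histogrammed, and an Otsu threshold is computed; segments
#' whose scaled value lies strictly above the threshold are that
#' replicate's valid interactions. Per condition, replicate calls are
#' combined by a consensus rule (`all` = valid in every replicate,
#' default; `any`; `majority` = strictly more than half).
#'
#' Segments overlapping the viewpoint anchor expanded by
#' `exclusion_radius` are removed before scaling/histogramming and
#' flagged `excluded` (self-ligation artefacts around a 4C viewpoint
#' are conventionally masked; the default radius is 0, i.e. only
#' segments overlapping the anchor itself when a viewpoint is given).
#' A replicate whose transformed profile is constant is degenerate:
#' it contributes no calls and is reported.
#'
#' @param counts integer matrix, segments x samples (rownames =
#'   segment ids)
#' @param sheet sample sheet data.frame (`sample`, `condition`,
#'   `replicate`); samples must match the matrix columns
#' @param segments segment data.frame matching the matrix rows;
#'   required when `viewpoint` is given, otherwise optional (used for
#'   coordinates in downstream summaries)
#' @param viewpoint viewpoint anchor: one-row interval data.frame or
#'   `"chrom:start-end"` string, or `NULL` for no exclusion
#' @param exclusion_radius bp added on both sides of the viewpoint
#'   anchor before masking (default 0)
#' @param consensus_rule `"all"`, `"any"` or `"majority"`
#' @param pseudocount pseudocount for the log transform (default 1)
#' @param log_base base of the log transform; the calls are provably
#'   independent of it
#' @return object of class `interaction_calls`: list with `scaled`
#'   (segments x samples integer matrix, `NA` for excluded segments or
#'   degenerate replicates), `otsu` (per-sample [otsu_threshold()]
#'   results), `thresholds` (named vector), `valid` (logical matrix,
#'   segments x samples), `consensus` (logical matrix, segments x
#'   conditions), `excluded` (logical vector), `degenerate_samples`,
#'   plus the inputs (`sheet`, `segments`, parameters)
#' @export
call_valid_interactions <- function(counts, sheet, segments = NULL,
                                    viewpoint = NULL, exclusion_radius = 0,
                                    consensus_rule = c("all", "any", "majority"),
                                    pseudocount = 1, log_base = exp(1)) {
  consensus_rule <- match.arg(consensus_rule)
  stopifnot(is.matrix(counts))
  if (!setequal(colnames(counts), sheet$sample) ||
      ncol(counts) != nrow(sheet))
    stop("count matrix columns do not match sample sheet samples")
  counts <- counts[, sheet$sample, drop = FALSE]
  nf <- nrow(counts)
  if (!is.null(segments)) {
    stopifnot(nrow(segments) == nf)
    if (!is.null(rownames(counts)) &&
        !identical(rownames(counts), segments$segment_id))
      stop("count matrix rows do not match segment ids")
  }

  excluded <- rep(FALSE, nf)
  if (!is.null(viewpoint)) {
    if (is.null(segments))
      stop("viewpoint exclusion requires segment coordinates")
    if (is.character(viewpoint)) viewpoint <- parse_region(viewpoint)
    stopifnot(exclusion_radius >= 0)
    excluded <- segments$chrom == viewpoint$chrom &
      interval_overlaps(segments$start, segments$end,
                        viewpoint$start - exclusion_radius,
                        viewpoint$end + exclusion_radius)
  }
  keep <- !excluded
  if (sum(keep) < 2L) stop("fewer than 2 segments remain after viewpoint exclusion")

  scaled <- matrix(NA_integer_, nf, ncol(counts),
                   dimnames = dimnames(counts))
  valid <- matrix(NA, nf, ncol(counts), dimnames = dimnames(counts))
  otsu <- vector("list", ncol(counts))
  names(otsu) <- colnames(counts)
  thresholds <- stats::setNames(rep(NA_integer_, ncol(counts)), colnames(counts))
  degenerate <- character(0)
  for (j in seq_len(ncol(counts))) {
    v <- log_transform(counts[keep, j], pseudocount, base = log_base)
    s <- tryCatch(scale_to_8bit(v), degenerate_profile = function(e) NULL)
    if (is.null(s)) {
      degenerate <- c(degenerate, colnames(counts)[j])
      next
    }
    res <- otsu_threshold(hist_256(s))
    otsu[[j]] <- res
    if (res$degenerate) {
      degenerate <- c(degenerate, colnames(counts)[j])
      next
    }
    scaled[keep, j] <- s
    thresholds[j] <- res$threshold
    valid[keep, j] <- s > res$threshold  # strictly above
  }

  conditions <- unique(sheet$condition)
  consensus <- matrix(NA, nf, length(conditions),
                      dimnames = list(rownames(counts), conditions))
  for (cond in conditions) {
    reps <- sheet$sample[sheet$condition == cond]
    reps <- setdiff(reps, degenerate)
    if (length(reps) == 0L) next
    v <- valid[, reps, drop = FALSE]
    consensus[, cond] <- switch(consensus_rule,
      all = rowSums(v) == length(reps),
      any = rowSums(v) > 0,
      majority = rowSums(v) > length(reps) / 2)
  }
  consensus[excluded, ] <- NA

  structure(list(scaled = scaled, otsu = otsu, thresholds = thresholds,
                 valid = valid, consensus = consensus, excluded = excluded,
                 degenerate_samples = degenerate, sheet = sheet,
                 segments = segments, consensus_rule = consensus_rule,
                 pseudocount = pseudocount,
                 viewpoint = viewpoint, exclusion_radius = exclusion_radius),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat("Valid-interaction call set\n")
  cat(sprintf("  %d segments (%d excluded at viewpoint), %d samples, consensus rule '%s'\n",
              nrow(x$valid), sum(x$excluded), ncol(x$valid), x$consensus_rule))
  cat("  Otsu thresholds: ",
      paste(sprintf("%s=%s", names(x$thresholds), x$thresholds), collapse = ", "),
      "\n", sep = "")
  nv <- colSums(x$consensus, na.rm = TRUE)
  cat("  consensus valid per condition: ",
      paste(sprintf("%s=%d", names(nv), nv), collapse = ", "), "\n", sep = "")
  if (length(x$degenerate_samples))
    cat("  degenerate replicates (no calls): ",
        paste(x$degenerate_samples, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.interaction_calls <- function(object, ...) {
  per_sample <- colSums(object$valid, na.rm = TRUE)
  per_condition <- colSums(object$consensus, na.rm = TRUE)
  out <- list(per_sample_valid = per_sample,
              per_condition_valid = per_condition,
              thresholds = object$thresholds,
              excluded = sum(object$excluded),
              degenerate_samples = object$degenerate_samples)
  if (!is.null(object$segments)) {
    lab <- object$segments$label
    cons <- object$consensus[, 1L]
    out$label_table <- table(label = lab[which(cons)])
  }
  class(out) <- "summary.interaction_calls"
  out
}

#' @export
print.summary.interaction_calls <- function(x, ...) {
  cat("Valid interactions per sample:\n")
  print(x$per_sample_valid)
  cat("Consensus valid per condition:\n")
  print(x$per_condition_valid)
  if (!is.null(x$label_table)) {
    cat("Labels of consensus-valid segments (first condition):\n")
    print(x$label_table)
  }
  invisible(x)
}

#' Summarise consensus calls per gene TSS window
#'
#' Marks each gene as contacted if at least one consensus-valid
#' segment (in the chosen condition) overlaps its TSS +/- `flank`
#' window, and reports the overlapping segment ids and labels.
#'
#' @param calls an `interaction_calls` object carrying segments
#' @param genes gene data.frame
#' @param flank TSS window flank in bp (default 3000)
#' @param condition condition whose consensus calls to use (default:
#'   first condition in the sheet)
#' @return data.frame `gene_id`, `contacted`, `segments`, `labels`
#'   (comma-separated)
#' @export
summarize_calls <- function(calls, genes, flank = 3000,
                            condition = calls$sheet$condition[1]) {
  stopifnot(inherits(calls, "interaction_calls"), !is.null(calls$segments))
  cons <- calls$consensus[, condition]
  seg <- calls$segments
  win <- tss_window(genes, flank)
  res <- lapply(seq_len(nrow(win)), function(i) {
    hit <- which(!is.na(cons) & cons & seg$chrom == win$chrom[i] &
                 interval_overlaps(seg$start, seg$end, win$start[i], win$end[i]))
    data.frame(gene_id = win$gene_id[i], contacted = length(hit) > 0,
               segments = paste(seg$segment_id[hit], collapse = ","),
               labels = paste(seg$label[hit], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a call set as TSV plus a JSON run summary
#'
#' The TSV holds segment coordinates and label, the per-replicate
#' scaled values, per-replicate validity, and the per-condition
#' consensus flags; the JSON summary records thresholds, excluded
#' segments and degenerate replicates.
#'
#' @param calls an `interaction_calls` object carrying segments
#' @param path output TSV path; the JSON summary goes to
#'   `<path>.json` unless `summary_path` is given
#' @param summary_path optional JSON path
#' @return `path`, invisibly
#' @export
write_calls <- function(calls, path, summary_path = paste0(path, ".json")) {
  stopifnot(inherits(calls, "interaction_calls"), !is.null(calls$segments))
  seg <- calls$segments
  df <- data.frame(seg[, c("chrom", "start", "end", "segment_id", "label")],
                   excluded = calls$excluded, check.names = FALSE)
  sc <- calls$scaled
  colnames(sc) <- paste0("scaled_", colnames(sc))
  vd <- calls$valid
  colnames(vd) <- paste0("valid_", colnames(vd))
  cs <- calls$consensus
  colnames(cs) <- paste0("consensus_", colnames(cs))
  df <- cbind(df, sc, vd, cs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    thresholds = as.list(calls$thresholds),
    consensus_rule = calls$consensus_rule,
    pseudocount = calls$pseudocount,
    exclusion_radius = calls$exclusion_radius,
    n_segments = nrow(calls$valid),
    n_excluded = sum(calls$excluded),
    degenerate_samples = calls$degenerate_samples,
    consensus_valid = as.list(colSums(calls$consensus, na.rm = TRUE))),
    summary_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
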