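#' Map differential contact segments to gene TSS windows
#'
#' For each gene, significant differential-contact segments
#' overlapping its TSS +/- `flank` window determine the gene's
#' contact change: `gained` if any overlapping significant segment
#' has `log2FC > 0`, `lost` if any has `log2FC < 0`, `unchanged`
#' otherwise. When both directions occur the gene is flagged `mixed`
#' and classified by the segment with the largest `|log2FC|`.
#' Per-gene flank overrides support the wider windows used for
#' segments around an extended regulatory locus (e.g. 5 kb instead of
#' the default 3 kb).
#'
#' @param diff_contacts differential table over segments (from
#'   [nb_diff()] / [apply_significance()]; must have a `significant`
#'   column and `feature_id`s matching `segments$segment_id`)
#' @param segments segment data.frame supplying coordinates
#' @param genes gene data.frame
#' @param flank default TSS window flank in bp (default 3000)
#' @param extended_flank optional named numeric vector of per-gene
#'   flank overrides (names = gene ids)
#' @return data.frame `gene_id`, `contact_change` (`gained`, `lost`,
#'   `unchanged`), `mixed`, `segments`, `labels`, `top_log2fc`
#' @export
map_segments_to_tss <- function(diff_contacts, segments, genes,
                                flank = 3000, extended_flank = NULL) {
  stopifnot(!is.null(diff_contacts$significant))
  idx <- match(diff_contacts$feature_id, segments$segment_id)
  if (anyNA(idx))
    stop("differential features missing from segment annotation: ",
         paste(utils::head(diff_contacts$feature_id[is.na(idx)], 5), collapse = ", "))
  seg <- segments[idx, , drop = FALSE]
  sig <- which(diff_contacts$significant)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    fl <- flank
    if (!is.null(extended_flank) && g$gene_id %in% names(extended_flank))
      fl <- extended_flank[[g$gene_id]]
    w <- tss_window(g, fl)
    hit <- sig[seg$chrom[sig] == w$chrom &
               interval_overlaps(seg$start[sig], seg$end[sig], w$start, w$end)]
    lfc <- diff_contacts$log2_fold_change[hit]
    change <- if (length(hit) == 0L) "unchanged"
      else if (all(lfc > 0)) "gained"
      else if (all(lfc < 0)) "lost"
      else if (lfc[which.max(abs(lfc))] > 0) "gained" else "lost"
    data.frame(gene_id = g$gene_id, contact_change = change,
               mixed = length(hit) > 0L && any(lfc > 0) && any(lfc < 0),
               segments = paste(seg$segment_id[hit], collapse = ","),
               labels = paste(seg$label[hit], collapse = ","),
               top_log2fc = if (length(hit)) lfc[which.max(abs(lfc))] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-gene expression change from a differential table
#'
#' @param de differential-expression table with `significant` flags
#' @return data.frame `gene_id`, `expression_change` (`up`, `down`,
#'   `unchanged`)
#' @export
expression_change <- function(de) {
  stopifnot(!is.null(de$significant))
  data.frame(
    gene_id = de$feature_id,
    expression_change = ifelse(!de$significant, "unchanged",
                               ifelse(de$log2_fold_change > 0, "up", "down")),
    stringsAsFactors = FALSE)
}

#' Combine expression calls across mutant clones
#'
#' A gene is called up (down) when at least `min_clones` of the
#' per-clone differential tables call it significantly up (down);
#' mirroring a "significant in at least two out of three clones"
#' criterion. Conflicting directions resolve to the majority
#' direction, ties to `unchanged`.
#'
#' @param tables list of per-clone differential tables (same gene set)
#' @param min_clones minimum number of concordant clones (default 2)
#' @return data.frame `gene_id`, `expression_change`
#' @export
combine_expression_calls <- function(tables, min_clones = 2) {
  stopifnot(length(tables) >= 1L)
  ids <- tables[[1L]]$feature_id
  for (t in tables)
    if (!setequal(t$feature_id, ids)) stop("clone tables cover different gene sets")
  calls <- vapply(tables, function(t)
    expression_change(t)$expression_change[match(ids, t$feature_id)],
    character(length(ids)))
  calls <- matrix(calls, nrow = length(ids))
  n_up <- rowSums(calls == "up")
  n_down <- rowSums(calls == "down")
  data.frame(
    gene_id = ids,
    expression_change = ifelse(n_up >= min_clones & n_up > n_down, "up",
                        ifelse(n_down >= min_clones & n_down > n_up, "down",
                               "unchanged")),
    stringsAsFactors = FALSE)
}

target_class_levels <- c("repressive_contact", "activating_contact",
                         "neutral_contact", "indirect", "no_evidence",
                         "repressive_contact_inverse",
                         "activating_contact_inverse")

#' Classify genes by contact-change / expression-change concordance
#'
#' The target-classification rule table: a regulatory contact whose
#' loss coincides with up-regulation acted repressively; one whose
#' gain coincides with up-regulation acted as an activating contact;
#' contact changes without expression change are neutral; expression
#' changes without any contact change are indirect. The two
#' inverse-concordance combinations are reported as distinct classes
#' rather than folded in:
#'
#' | contact change | expression change | class |
#' |---|---|---|
#' | lost | up | repressive_contact |
#' | gained | up | activating_contact |
#' | lost/gained | unchanged | neutral_contact |
#' | unchanged | up/down | indirect |
#' | unchanged | unchanged | no_evidence |
#' | lost | down | repressive_contact_inverse |
#' | gained | down | activating_contact_inverse |
#'
#' @param expression data.frame `gene_id`, `expression_change` (from
#'   [expression_change()] or [combine_expression_calls()])
#' @param contacts data.frame from [map_segments_to_tss()]
#' @param contacted_in_reference optional data.frame `gene_id`,
#'   `contacted` (from [summarize_calls()]) recording reference-
#'   condition TSS-window contacts
#' @return object of class `target_report`: data.frame with one row
#'   per gene: `gene_id`, `contacted_in_reference`, `contact_change`,
#'   `expression_change`, `target_class`, `segments`, `labels`
#' @export
classify_targets <- function(expression, contacts,
                             contacted_in_reference = NULL) {
  only_e <- setdiff(expression$gene_id, contacts$gene_id)
  only_c <- setdiff(contacts$gene_id, expression$gene_id)
  if (length(only_e) || length(only_c))
    stop("gene sets differ between tables; only in expression: [",
         paste(only_e, collapse = ", "), "]; only in contacts: [",
         paste(only_c, collapse = ", "), "]")
  m <- contacts
  ec <- expression$expression_change[match(m$gene_id, expression$gene_id)]
  cc <- m$contact_change
  cls <- ifelse(cc == "lost" & ec == "up", "repressive_contact",
         ifelse(cc == "gained" & ec == "up", "activating_contact",
         ifelse(cc != "unchanged" & ec == "unchanged", "neutral_contact",
         ifelse(cc == "unchanged" & ec != "unchanged", "indirect",
         ifelse(cc == "lost" & ec == "down", "repressive_contact_inverse",
         ifelse(cc == "gained" & ec == "down", "activating_contact_inverse",
                "no_evidence"))))))
  contacted <- if (is.null(contacted_in_reference)) rep(NA, nrow(m)) else
    contacted_in_reference$contacted[match(m$gene_id, contacted_in_reference$gene_id)]
  out <- data.frame(gene_id = m$gene_id,
                    contacted_in_reference = contacted,
                    contact_change = cc,
                    expression_change = ec,
                    target_class = factor(cls, levels = target_class_levels),
                    segments = m$segments, labels = m$labels,
                    stringsAsFactors = FALSE)
  class(out) <- c("target_report", "data.frame")
  out
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("Target report: %d genes\n", nrow(x)))
  print(table(x$target_class))
  invisible(x)
}

#' @export
summary.target_report <- function(object, ...) {
  table(object$target_class)
}

#' Write a target report as TSV plus a JSON class-count summary
#'
#' @param report a `target_report`
#' @param path output TSV path; JSON summary goes to `<path>.json`
#'   unless `summary_path` is given
#' @param summary_path optional JSON path
#' @return `path`, invisibly
#' @export
write_target_report <- function(report, path,
                                summary_path = paste0(path, ".json")) {
  df <- as.data.frame(report)
  df$target_class <- as.character(df$target_class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- as.list(table(factor(report$target_class, target_class_levels)))
  jsonlite::write_json(c(list(n_genes = nrow(report)), counts),
                       summary_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read back a target report TSV
#'
#' @param path TSV written by [write_target_report()]
#' @return a `target_report` data.frame
#' @export
read_target_report <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$target_class <- factor(df$target_class, levels = target_class_levels)
  if (is.null(df$segments)) df$segments <- ""
  df$segments[is.na(df$segments)] <- ""
  df$labels[is.na(df$labels)] <- ""
  class(df) <- c("target_report", "data.frame")
  df
}
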