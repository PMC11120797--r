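#' Assign read intervals to segmentation regions
#'
#' Counts aligned read intervals over a genome-tiling labelled
#' segmentation, the step that turns 4C alignments into a per-segment
#' count vector. Three assignment rules are supported:
#' \describe{
#'   \item{`largest_overlap`}{(default) each read overlapping at least
#'     one segment increments exactly the segment with the largest
#'     overlap in bp; ties go to the leftmost segment. Conserves reads:
#'     `sum(counts) + unassigned == n_reads`.}
#'   \item{`all`}{a read increments every segment it overlaps (segments
#'     may overlap each other under this rule).}
#'   \item{`unique`}{reads overlapping more than one segment are
#'     discarded (tallied as `ambiguous`), mimicking strict unique
#'     assignment.}
#' }
#' Reads overlapping no segment are tallied as `unassigned`.
#'
#' @param reads data.frame of read intervals (`chrom`, `start`, `end`)
#' @param segments segment data.frame (`segment_id`, `chrom`, `start`,
#'   `end`); must be non-overlapping within each chromosome except
#'   under rule `all`
#' @param rule assignment rule, see above
#' @return list with integer `counts` named by `segment_id` (in input
#'   segment order), `unassigned` and `ambiguous` tallies
#' @export
count_reads_in_segments <- function(reads, segments,
                                    rule = c("largest_overlap", "all", "unique")) {
  rule <- match.arg(rule)
  if (nrow(segments) == 0L) stop("empty segment list")
  if (anyDuplicated(segments$segment_id)) stop("duplicate segment ids")
  if (rule != "all") validate_nonoverlapping(segments)

  counts <- stats::setNames(integer(nrow(segments)), segments$segment_id)
  unassigned <- 0L
  ambiguous <- 0L
  seg_row <- seq_len(nrow(segments))
  for (chr in unique(reads$chrom)) {
    r <- reads[reads$chrom == chr, , drop = FALSE]
    in_chr <- segments$chrom == chr
    if (!any(in_chr)) {
      unassigned <- unassigned + nrow(r)
      next
    }
    s <- segments[in_chr, , drop = FALSE]
    rows <- seg_row[in_chr]
    ord <- order(s$start, s$end)
    s <- s[ord, , drop = FALSE]
    rows <- rows[ord]
    for (i in seq_len(nrow(r))) {
      rs <- r$start[i]; re <- r$end[i]
      if (rule == "all") {
        hit <- which(interval_overlaps(s$start, s$end, rs, re))
      } else {
        # non-overlapping sorted segments: overlaps form a contiguous run
        lo <- findInterval(rs, s$end) + 1L          # first with end > rs
        hi <- findInterval(re - 1, s$start)         # last with start < re
        hit <- if (lo <= hi) lo:hi else integer(0)
      }
      n_hit <- length(hit)
      if (n_hit == 0L) {
        unassigned <- unassigned + 1L
      } else if (rule == "all") {
        counts[rows[hit]] <- counts[rows[hit]] + 1L
      } else if (rule == "unique") {
        if (n_hit > 1L) ambiguous <- ambiguous + 1L
        else counts[rows[hit]] <- counts[rows[hit]] + 1L
      } else {
        ov <- pmin(s$end[hit], re) - pmax(s$start[hit], rs)
        best <- hit[which.max(ov)]  # which.max -> first max = leftmost
        counts[rows[best]] <- counts[rows[best]] + 1L
      }
    }
  }
  list(counts = counts, unassigned = unassigned, ambiguous = ambiguous)
}

validate_nonoverlapping <- function(segments) {
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    if (nrow(s) > 1L && any(s$end[-nrow(s)] > s$start[-1L]))
      stop("segments overlap within ", chr,
           "; overlapping segments are only allowed under rule 'all'")
  }
  invisible(TRUE)
}

#' Build a segments x samples count matrix from a sample sheet
#'
#' Reads each sample's aligned read intervals (BED3, `reads_path`
#' column) and assigns them to the segmentation with
#' [count_reads_in_segments()]. Columns follow sample-sheet order.
#'
#' @param sheet sample sheet data.frame, see [read_sample_sheet()]
#' @param segments segment data.frame
#' @param rule assignment rule, see [count_reads_in_segments()]
#' @return integer matrix (segments x samples) with `segment_id`
#'   rownames; attribute `unassigned` holds the per-sample unassigned
#'   (and ambiguous) tallies
#' @export
build_count_matrix <- function(sheet, segments, rule = "largest_overlap") {
  stopifnot(!is.null(sheet$reads_path))
  cols <- lapply(seq_len(nrow(sheet)), function(j) {
    count_reads_in_segments(read_bed(sheet$reads_path[j], "reads"),
                            segments, rule)
  })
  m <- vapply(cols, `[[`, integer(nrow(segments)), "counts")
  dimnames(m) <- list(segments$segment_id, sheet$sample)
  attr(m, "unassigned") <- data.frame(
    sample = sheet$sample,
    unassigned = vapply(cols, `[[`, integer(1), "unassigned"),
    ambiguous = vapply(cols, `[[`, integer(1), "ambiguous"))
  m
}

#' Read and write count matrices as TSV
#'
#' TSV with a header line `feature_id<TAB>sample1<TAB>...`; cells must
#' be non-negative integers and feature ids unique. Round-trips
#' losslessly.
#'
#' @param path TSV file path
#' @return `read_count_matrix`: integer matrix with feature rownames
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character"), sep = "\t")
  if (ncol(df) < 2L) stop("count matrix needs feature_id plus >= 1 sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !grepl("^[0-9]+$", vals)
  if (any(bad))
    stop("count matrix cells must be non-negative integers; offending values: ",
         paste(utils::head(unique(vals[bad]), 5L), collapse = ", "))
  m <- matrix(as.integer(vals), nrow = nrow(df),
              dimnames = list(ids, colnames(df)[-1L]))
  if (anyDuplicated(colnames(m))) stop("duplicate sample names")
  m
}

#' @rdname read_count_matrix
#' @param m integer count matrix with feature rownames
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with header columns `sample`, `condition`, `replicate` and
#' optionally `reads_path`. Sample names must be unique and every
#' condition must have at least one replicate row.
#'
#' @param path TSV file path
#' @return data.frame with the validated sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[names(df) == "sample_name"] <- "sample"
  req <- c("sample", "condition", "replicate")
  if (!all(req %in% names(df)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample names: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  df
}
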