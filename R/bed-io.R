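#' Read a BED file as segments, reads or genes
#'
#' Minimal BED3 (reads), BED4 (segments: column 4 is the functional
#' label, e.g. a chromatin-state category) or BED6 (genes: column 4 is
#' the gene id, column 6 the strand, an optional column 7 the biotype).
#' Coordinates are kept 0-based half-open as in the file. Malformed
#' lines are reported with their line numbers; `track`, `browser` and
#' `#` comment lines are skipped.
#'
#' Segment ids are assigned positionally (`seg000001`, ...) because
#' chromatin-segmentation BED names are state labels, not unique keys.
#'
#' @param path file path
#' @param kind one of `"segments"`, `"reads"`, `"genes"`
#' @return data.frame of segments (`segment_id`, `chrom`, `start`,
#'   `end`, `label`), intervals (`chrom`, `start`, `end`) or genes
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`, `biotype`), in file
#'   order
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, kind = c("segments", "reads", "genes")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(switch(kind,
      reads = data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE),
      segments = data.frame(segment_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            label = character(), stringsAsFactors = FALSE),
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         strand = character(), biotype = character(),
                         stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  min_cols <- if (kind == "genes") 6L else 3L

  errs <- character(0)
  bad <- nf < min_cols
  if (any(bad))
    errs <- c(errs, sprintf("line %d: expected >= %d columns, found %d%s",
                            lineno[bad], min_cols, nf[bad],
                            if (kind == "genes") " (strand required for genes)" else ""))
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get_col(1L)
  s_chr <- get_col(2L)
  e_chr <- get_col(3L)
  non_int <- !bad & (!grepl("^[0-9]+$", s_chr) | !grepl("^[0-9]+$", e_chr))
  if (any(non_int))
    errs <- c(errs, sprintf("line %d: non-integer coordinates '%s'..'%s'",
                            lineno[non_int], s_chr[non_int], e_chr[non_int]))
  start <- suppressWarnings(as.numeric(s_chr))
  end <- suppressWarnings(as.numeric(e_chr))
  rev_coord <- !bad & !non_int & start >= end
  if (any(rev_coord))
    errs <- c(errs, sprintf("line %d: start >= end (%s >= %s)",
                            lineno[rev_coord], s_chr[rev_coord], e_chr[rev_coord]))
  if (kind == "genes") {
    strand <- get_col(6L)
    bad_strand <- !bad & !strand %in% c("+", "-")
    if (any(bad_strand))
      errs <- c(errs, sprintf("line %d: strand must be '+' or '-', found '%s'",
                              lineno[bad_strand], strand[bad_strand]))
  }
  if (length(errs) > 0L)
    stop("malformed BED file ", path, ":\n  ", paste(errs, collapse = "\n  "))

  switch(kind,
    reads = data.frame(chrom = chrom, start = start, end = end,
                       stringsAsFactors = FALSE),
    segments = data.frame(
      segment_id = sprintf("seg%06d", seq_along(chrom)),
      chrom = chrom, start = start, end = end,
      label = ifelse(nf >= 4L, get_col(4L), "."),
      stringsAsFactors = FALSE),
    genes = {
      gene_id <- get_col(4L)
      if (anyDuplicated(gene_id))
        stop("duplicate gene ids in ", path, ": ",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
      data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = get_col(6L),
                 biotype = ifelse(nf >= 7L, get_col(7L), "coding"),
                 stringsAsFactors = FALSE)
    })
}

#' Write segments, reads or genes as BED
#'
#' Tab-separated, headerless. Segments are written as BED4 (label in
#' column 4), genes as BED6 plus a biotype column, plain intervals as
#' BED3. A file read with [read_bed()] round-trips byte-identically for
#' tab-separated input.
#'
#' @param x data.frame as returned by [read_bed()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  num <- function(v) format(v, scientific = FALSE, trim = TRUE)
  cols <- if ("gene_id" %in% names(x)) {
    data.frame(x$chrom, num(x$start), num(x$end), x$gene_id, 0L, x$strand,
               if (is.null(x$biotype)) "coding" else x$biotype)
  } else if ("label" %in% names(x)) {
    data.frame(x$chrom, num(x$start), num(x$end), x$label)
  } else {
    data.frame(x$chrom, num(x$start), num(x$end))
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-record FASTA file
#'
#' Wrapped lines are supported; record names are truncated at the first
#' whitespace.
#'
#' @param path FASTA file path
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
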