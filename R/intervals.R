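#' Genomic interval utilities
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`,
#' i.e. BED-native. An interval is represented as a data.frame row with
#' columns `chrom`, `start`, `end`; segments additionally carry
#' `segment_id` and `label`, genes carry `gene_id`, `strand`, `biotype`.
#'
#' @param chrom chromosome name(s), non-empty strings
#' @param start 0-based inclusive start position(s)
#' @param end exclusive end position(s); must satisfy `start < end`
#' @return data.frame with columns `chrom`, `start`, `end`
#' @examples
#' genome_interval("chr3", 100, 200)
#' @export
genome_interval <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!nzchar(chrom)) || anyNA(chrom)) stop("chrom must be non-empty")
  if (anyNA(start) || anyNA(end)) stop("coordinates must be numeric")
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("coordinates must be integers")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(start >= end)) stop("start must be < end")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Vectorised half-open overlap test
#'
#' Two half-open intervals `[a0, a1)` and `[b0, b1)` overlap iff
#' `a0 < b1 && b0 < a1`; touching intervals (`a1 == b0`) do not overlap.
#'
#' @param a_start,a_end,b_start,b_end coordinate vectors (recycled)
#' @return logical vector
#' @export
interval_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

#' Parse a region string
#'
#' Accepts `"chrom:start-end"` with optional thousands separators
#' (commas), e.g. the TAD bounds passed on the command line.
#'
#' @param region region string, 0-based half-open coordinates
#' @return one-row interval data.frame
#' @examples
#' parse_region("chr3:107,240,000-108,720,000")
#' @export
parse_region <- function(region) {
  region <- gsub(",", "", region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region '", region, "'; expected chrom:start-end")
  genome_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' Restrict items to a TAD
#'
#' Keeps segments, genes or plain intervals overlapping a topologically
#' associating domain (half-open overlap on the same chromosome). Input
#' order is preserved.
#'
#' @param items data.frame with `chrom`, `start`, `end` columns
#' @param tad one-row interval data.frame or a `"chrom:start-end"` string
#' @return the overlapping subset of `items`
#' @export
restrict_to_tad <- function(items, tad) {
  if (is.character(tad)) tad <- parse_region(tad)
  stopifnot(is.data.frame(items), all(c("chrom", "start", "end") %in% names(items)))
  keep <- items$chrom == tad$chrom &
    interval_overlaps(items$start, items$end, tad$start, tad$end)
  items[keep, , drop = FALSE]
}

# midpoint of half-open interval(s), may fall on a half-coordinate
interval_midpoint <- function(x) (x$start + x$end) / 2
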