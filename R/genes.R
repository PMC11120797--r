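#' Transcription start site of a gene
#'
#' Under the 0-based half-open convention the TSS of a '+' gene is
#' `start`; for a '-' gene it is `end - 1`, the last covered base, so
#' the TSS always lies inside the gene interval.
#'
#' @param genes gene data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`)
#' @return numeric vector of TSS positions, one per gene
#' @examples
#' g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
#'                 start = c(100, 100), end = c(500, 500),
#'                 strand = c("+", "-"))
#' tss_of(g)  # 100, 499
#' @export
tss_of <- function(genes) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Symmetric window around gene TSSs
#'
#' Returns `[max(0, tss - flank), tss + flank + 1)` per gene: a
#' strand-independent window of width `2*flank + 1` covering the TSS
#' base itself, clipped at the chromosome origin.
#'
#' @param genes gene data.frame
#' @param flank flank size in bp, `>= 0` (default 3000, i.e. a
#'   TSS +/- 3 kb window)
#' @return data.frame `gene_id`, `chrom`, `start`, `end`
#' @export
tss_window <- function(genes, flank = 3000) {
  stopifnot(flank >= 0, flank == floor(flank))
  tss <- tss_of(genes)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, tss - flank), end = tss + flank + 1,
             stringsAsFactors = FALSE)
}

#' Find divergent (bidirectional-promoter-like) gene pairs
#'
#' Enumerates all opposite-strand gene pairs on the same chromosome
#' whose TSSs lie within `max_gap` bp of each other, the operational
#' definition of a divergent arrangement around a candidate
#' bidirectional promoter. The `strict` flag marks truly divergent
#' orientation (the '-' gene's TSS at or left of the '+' gene's TSS, so
#' transcription proceeds outward); pairs with overlapping, inverted
#' TSSs are still reported with `strict = FALSE`.
#'
#' @param genes gene data.frame
#' @param max_gap maximum absolute TSS distance in bp (default 1000)
#' @return data.frame `minus_gene`, `plus_gene`,
#'   `tss_gap` (= tss(plus) - tss(minus), signed), `strict`; one row per
#'   unordered pair, sorted by chromosome and leftmost TSS
#' @export
find_divergent_pairs <- function(genes, max_gap = 1000) {
  stopifnot(max_gap > 0)
  out <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    minus <- g[g$strand == "-", , drop = FALSE]
    plus <- g[g$strand == "+", , drop = FALSE]
    if (nrow(minus) == 0L || nrow(plus) == 0L) next
    tm <- tss_of(minus)
    tp <- tss_of(plus)
    gap <- outer(tm, tp, function(m, p) p - m)  # rows: minus, cols: plus
    hit <- which(abs(gap) <= max_gap, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    out[[chr]] <- data.frame(
      chrom = chr,
      minus_gene = minus$gene_id[hit[, 1]],
      plus_gene = plus$gene_id[hit[, 2]],
      tss_gap = gap[hit],
      strict = tm[hit[, 1]] <= tp[hit[, 2]],
      .pos = pmin(tm[hit[, 1]], tp[hit[, 2]]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), minus_gene = character(),
                      plus_gene = character(), tss_gap = numeric(),
                      strict = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$.pos, res$tss_gap, res$minus_gene,
                   res$plus_gene), , drop = FALSE]
  res$.pos <- NULL
  rownames(res) <- NULL
  res
}
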