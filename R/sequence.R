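#' GC content and CpG observed/expected ratio of a sequence
#'
#' Computes the two classical promoter-composition metrics: GC fraction
#' and the Gardiner-Garden CpG dinucleotide observed/expected ratio
#' `N * n(CG) / (n(C) * n(G))`, where `N` is the effective (non-N)
#' length. `N` bases are excluded from all tallies, including
#' dinucleotide pairs containing them; elevated values mark
#' CpG-island-like promoter sequence.
#'
#' @param seq a single DNA string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive)
#' @return list with `gc_fraction` in `[0, 1]`, `cpg_obs_exp >= 0`
#'   (0 when the sequence has no C or no G) and effective `length`
#' @examples
#' sequence_composition("CGCG")  # gc 1, obs/exp 2
#' @export
sequence_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside {A,C,G,T,N}")
  eff <- sum(chars != "N")
  if (eff == 0L) stop("empty effective sequence (all N or zero length)")
  nc <- sum(chars == "C")
  ng <- sum(chars == "G")
  n <- length(chars)
  ncg <- if (n >= 2L) sum(chars[-n] == "C" & chars[-1L] == "G") else 0L
  list(
    gc_fraction = (nc + ng) / eff,
    cpg_obs_exp = if (nc * ng == 0) 0 else eff * ncg / (nc * ng),
    length = eff)
}
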