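#' Simulate a complete two-condition regulatory study
#'
#' Generates every input of the full pipeline with planted ground
#' truth, emulating a viewpoint-4C plus RNA-seq comparison of a
#' wild-type and a promoter-deletion condition on one chromosome:
#'
#' * a contiguous labelled segmentation (default 500 segments on 1 Mb),
#' * a viewpoint at mid-chromosome with a 75 kb exclusion radius
#'   masking the proximity-ligation core,
#' * a TAD spanning the central region, with genes placed inside it,
#'   TSSs kept 12 kb apart and 110 kb clear of the viewpoint,
#' * planted background interaction peaks (20-40 fold over the local
#'   expected signal) on adequately covered segments away from all
#'   TSS windows, plus two focal promoter contacts on the segments
#'   containing the first two genes' TSSs, planted at a strong-loop
#'   coverage of ~700 expected reads,
#' * a planted contact loss (log2FC -4) on both focal TSS peaks in
#'   the mutant condition,
#' * planted up-regulation (log2FC +2) of the first gene only, so the
#'   full pipeline should classify gene 1 as a repressive contact and
#'   gene 2 as a neutral contact.
#'
#' @param seed RNG seed driving every draw (default 1)
#' @param chrom_length,n_segments,n_genes,n_reps scenario scale
#' @param contact_lfc planted contact log2 fold change (default -4)
#' @param de_lfc planted expression log2 fold change (default +2)
#' @param n_background_peaks additional unchanged interaction peaks
#'   (default 40, ~8% of segments as true contacts)
#' @param focal_lambda expected read count planted on the two focal
#'   TSS contacts (default 700)
#' @param dispersion NB dispersion for both assays (default 0.02)
#' @param depth 4C sequencing depth per replicate
#' @return list with `segments`, `genes`, `viewpoint` (interval),
#'   `exclusion_radius`, `tad` (interval), `contacts`
#'   (counts/sheet/truth from [simulate_condition_pair()]),
#'   `expression` (from [simulate_expression_counts()]), and `truth`
#'   (`repressive_gene`, `neutral_gene`, planted segment ids)
#' @export
simulate_study <- function(seed = 1, chrom_length = 1e6, n_segments = 500,
                           n_genes = 20, n_reps = 3, contact_lfc = -4,
                           de_lfc = 2, n_background_peaks = 40,
                           focal_lambda = 700, dispersion = 0.02,
                           depth = 5e5) {
  set.seed(seed)
  chrom <- "chrS"
  segments <- simulate_segmentation(chrom_length, n_segments, seed = NULL,
                                    chrom = chrom)
  vp_centre <- chrom_length / 2
  viewpoint <- genome_interval(chrom, vp_centre - 500, vp_centre + 500)
  exclusion_radius <- 75000
  tad <- genome_interval(chrom, round(chrom_length * 0.125),
                         round(chrom_length * 0.875))

  # genes inside the TAD, well clear of the masked viewpoint core,
  # TSSs spaced out
  lo <- tad$start + 25000
  hi <- tad$end - 25000
  seg_at <- function(pos) which(segments$start <= pos & segments$end > pos)
  genes <- NULL
  for (attempt in 1:50) {
    g <- simulate_genes(chrom_length, n_genes, seed = NULL, chrom = chrom,
                        tss_range = c(lo, hi), min_tss_spacing = 12000,
                        forbidden_tss = list(c(vp_centre - 110000,
                                               vp_centre + 110000)))
    t <- tss_of(g)
    s1 <- seg_at(t[1L]); s2 <- seg_at(t[2L])
    # focal TSS segments must be distinct and confined to their own
    # gene's window so the two planted classifications cannot bleed
    w <- tss_window(g[1:2, ], 3000)
    ok <- s1 != s2 &&
      !interval_overlaps(segments$start[s1], segments$end[s1],
                         w$start[2L], w$end[2L]) &&
      !interval_overlaps(segments$start[s2], segments$end[s2],
                         w$start[1L], w$end[1L])
    if (ok) { genes <- g; break }
  }
  if (is.null(genes)) stop("could not place genes clear of the viewpoint")
  tss <- tss_of(genes)

  # force the two focal TSS segments to a promoter-like label and
  # plant them as strong viewpoint contacts
  repressive_gene <- genes$gene_id[1L]
  neutral_gene <- genes$gene_id[2L]
  seg_repr <- seg_at(tss[1L])
  seg_neut <- seg_at(tss[2L])
  segments$label[c(seg_repr, seg_neut)] <- "TSS"

  # background peaks: better-covered far segments (top 60% of expected
  # unpeaked coverage beyond 100 kb) away from every gene window
  lambda0 <- contact_lambda(segments, viewpoint, 3, 4e-7, NULL, depth)
  far <- abs(interval_midpoint(segments) - vp_centre) > 100000
  win <- tss_window(genes, 6000)  # keep background peaks clear of windows
  free <- which(!vapply(seq_len(nrow(segments)), function(i) {
    any(interval_overlaps(segments$start[i], segments$end[i],
                          win$start, win$end))
  }, logical(1)) &
    far & lambda0 >= stats::quantile(lambda0[far], 0.4))
  free <- setdiff(free, c(seg_repr, seg_neut))
  bg_peaks <- sample(free, min(n_background_peaks, length(free)))

  # enrichment 20-40x the local expected signal, floored so every
  # planted peak is detectable (>= ~8 expected reads)
  bg_enr <- pmax(stats::runif(length(bg_peaks), 20, 40), 8 / lambda0[bg_peaks])
  peak_ids <- segments$segment_id[c(seg_repr, seg_neut, bg_peaks)]
  peaks <- stats::setNames(
    c(focal_lambda / lambda0[seg_repr], focal_lambda / lambda0[seg_neut],
      bg_enr),
    peak_ids)
  changes <- stats::setNames(c(contact_lfc, contact_lfc),
                             segments$segment_id[c(seg_repr, seg_neut)])

  contacts <- simulate_condition_pair(
    segments, viewpoint, contact_changes = changes, n_reps = n_reps,
    depth = depth, peaks = peaks, dispersion = dispersion, seed = NULL)

  base_means <- stats::rlnorm(n_genes, log(200), 1.2)
  base_means[1L] <- 500  # strong focal target expression
  expression <- simulate_expression_counts(
    genes, planted_de = stats::setNames(de_lfc, repressive_gene),
    n_reps = n_reps, base_means = base_means, dispersion = dispersion,
    seed = NULL)

  list(segments = segments, genes = genes, viewpoint = viewpoint,
       exclusion_radius = exclusion_radius, tad = tad,
       contacts = contacts, expression = expression,
       truth = list(repressive_gene = repressive_gene,
                    neutral_gene = neutral_gene,
                    repressive_segment = segments$segment_id[seg_repr],
                    neutral_segment = segments$segment_id[seg_neut],
                    peaks = peaks, contact_changes = changes,
                    seed = seed))
}

#' Run the full analysis pipeline on study inputs
#'
#' Chains the stages: restrict genes to the TAD, call consensus valid
#' interactions in the reference condition, test differential
#' contacts and differential expression, map significant contact
#' changes to gene TSS windows, and classify target genes.
#'
#' @param study a list shaped like [simulate_study()] output (or
#'   assembled from files)
#' @param flank TSS window flank in bp (default 3000)
#' @param extended_flank optional named per-gene flank overrides
#' @param consensus_rule replicate consensus rule (default `"all"`)
#' @param contact_lfc,contact_alpha differential-contact significance
#'   thresholds (defaults 3.5, 1e-5)
#' @param de_lfc,de_alpha differential-expression thresholds
#'   (defaults 1.5, 1e-4)
#' @param pseudocount log-transform pseudocount (default 1)
#' @return list with `calls` (interaction_calls), `contacted`
#'   (per-gene reference contacts), `diff_contacts`, `diff_expression`
#'   (nb_diff tables), `contact_map`, and `report` (target_report)
#' @export
run_pipeline <- function(study, flank = 3000, extended_flank = NULL,
                         consensus_rule = "all", contact_lfc = 3.5,
                         contact_alpha = 1e-5, de_lfc = 1.5,
                         de_alpha = 1e-4, pseudocount = 1) {
  genes <- restrict_to_tad(study$genes, study$tad)
  calls <- call_valid_interactions(
    study$contacts$counts, study$contacts$sheet, segments = study$segments,
    viewpoint = study$viewpoint,
    exclusion_radius = if (is.null(study$exclusion_radius)) 0 else study$exclusion_radius,
    consensus_rule = consensus_rule, pseudocount = pseudocount)
  contacted <- summarize_calls(calls, genes, flank = flank,
                               condition = study$contacts$sheet$condition[1])
  diff_contacts <- nb_diff(study$contacts$counts, study$contacts$sheet,
                           lfc_threshold = contact_lfc,
                           padj_threshold = contact_alpha)
  diff_expression <- nb_diff(study$expression$counts, study$expression$sheet,
                             lfc_threshold = de_lfc, padj_threshold = de_alpha)
  contact_map <- map_segments_to_tss(diff_contacts, study$segments, genes,
                                     flank = flank,
                                     extended_flank = extended_flank)
  de_genes <- diff_expression[match(genes$gene_id, diff_expression$feature_id), ]
  report <- classify_targets(expression_change(de_genes), contact_map,
                             contacted_in_reference = contacted)
  list(calls = calls, contacted = contacted, diff_contacts = diff_contacts,
       diff_expression = diff_expression, contact_map = contact_map,
       report = report)
}
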