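#' CLIP peak density over introns
#'
#' Counts CLIP peaks overlapping each intron (one nucleotide of overlap
#' suffices; a peak spanning two introns counts for both) and normalises by
#' intron length: density = peaks per kilobase. With
#' `weighted = TRUE` the base-pair coverage of peaks over the intron is used
#' instead of the peak count.
#'
#' @param peaks `GRanges` of CLIP peak intervals (e.g. from
#'   `rtracklayer::import(path, format = "bed")`).
#' @param introns data.frame from [intron_records()].
#' @param weighted Coverage-weighted density instead of peak counts
#'   (default FALSE).
#' @return data.frame: `gene_id`, `intron_index`, `length`, `peak_count`,
#'   `density` (per kb).
#' @export
peak_density <- function(peaks, introns, weighted = FALSE) {
  igr <- GRanges(introns$chrom, IRanges(introns$start, introns$end),
                 strand = introns$strand)
  if (length(peaks) && nrow(introns) &&
      !any(unique(as.character(seqnames(peaks))) %in%
             unique(introns$chrom)))
    warning("no shared chromosome names between peaks and introns; ",
            "possible assembly mismatch")
  count <- countOverlaps(igr, peaks, ignore.strand = TRUE)
  dens <- if (weighted) {
    cov <- vapply(seq_along(igr), function(k)
      sum(width(GenomicRanges::intersect(
        igr[k], GenomicRanges::reduce(peaks, ignore.strand = TRUE),
        ignore.strand = TRUE))), numeric(1))
    cov / (width(igr) / 1000)
  } else count / (width(igr) / 1000)
  data.frame(gene_id = introns$gene_id, intron_index = introns$intron_index,
             length = width(igr), peak_count = count, density = dens)
}

#' Contrast CLIP peak densities of retained versus control introns
#'
#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test on per-intron peak
#' densities. Control introns should be the non-retained introns of the same
#' genes.
#'
#' @param retained_densities,control_densities Numeric density vectors or
#'   data.frames from [peak_density()] (their `density` column is used).
#' @return list with `statistic`, `p`, `median_retained`, `median_control`,
#'   `n`.
#' @export
density_contrast <- function(retained_densities, control_densities) {
  r <- if (is.data.frame(retained_densities)) retained_densities$density
       else retained_densities
  ctl <- if (is.data.frame(control_densities)) control_densities$density
         else control_densities
  if (length(r) == 0 || length(ctl) == 0)
    stop("both density groups must be non-empty")
  wt <- wilcox.test(r, ctl, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_retained = median(r), median_control = median(ctl),
       n = c(retained = length(r), control = length(ctl)))
}
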