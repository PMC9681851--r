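#' Length bias of retained introns against a background set
#'
#' Two-sided Wilcoxon rank-sum comparison of intron lengths between a
#' retained set and a background set (typically every intron of the
#' annotation for genome-wide bias, or the non-retained introns of the same
#' genes for a within-gene contrast). Also reports a length-decile
#' enrichment table: for each decile of the background length distribution,
#' the fraction of retained introns falling in it (uniform 0.1 under no
#' bias).
#'
#' @param retained,background data.frames with a `length` column (e.g. from
#'   [intron_records()]).
#' @return list with `statistic`, `p`, `median_retained`,
#'   `median_background`, `n`, and `decile_table`.
#' @export
length_bias_test <- function(retained, background) {
  if (nrow(retained) == 0 || nrow(background) == 0)
    stop("both intron sets must be non-empty")
  wt <- wilcox.test(retained$length, background$length, exact = NULL)
  br <- unique(quantile(background$length, probs = seq(0, 1, 0.1)))
  brks <- c(-Inf, br[-c(1, length(br))], Inf)  # open-ended extremes
  dec <- cut(retained$length, breaks = brks, labels = FALSE)
  decile_table <- data.frame(
    decile = seq_len(length(br) - 1),
    upper = unname(br[-1]),
    retained_fraction = as.numeric(
      table(factor(dec, levels = seq_len(length(br) - 1)))) / nrow(retained))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_retained = median(retained$length),
       median_background = median(background$length),
       n = c(retained = nrow(retained), background = nrow(background)),
       decile_table = decile_table)
}

#' Positional bias of retained introns within their host transcripts
#'
#' Compares the `relative_position` distributions (intron index over intron
#' count, in (0, 1]; a 5'-proximal intron scores low) of two intron sets by
#' a two-sided Wilcoxon rank-sum test: retained versus background introns,
#' or sloping versus classic retained introns. With
#' `scale = "nucleotide"` the nucleotide-distance fraction of the intron
#' start along the pre-mRNA can be supplied in a `relative_position_nt`
#' column instead.
#'
#' @param set_a,set_b data.frames with a `relative_position` column.
#' @param scale `"index"` (default) or `"nucleotide"`.
#' @return list with `statistic`, `p`, `median_a`, `median_b`, `n`.
#' @export
position_bias <- function(set_a, set_b, scale = c("index", "nucleotide")) {
  scale <- match.arg(scale)
  col <- if (scale == "index") "relative_position" else "relative_position_nt"
  if (nrow(set_a) == 0 || nrow(set_b) == 0)
    stop("both intron sets must be non-empty")
  a <- set_a[[col]]; b <- set_b[[col]]
  wt <- wilcox.test(a, b, exact = NULL)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_a = median(a), median_b = median(b),
       n = c(a = length(a), b = length(b)))
}

#' Length contrast between classic and sloping retained introns
#'
#' Wilcoxon rank-sum test on intron length between the two IR-transcript
#' categories, with medians.
#'
#' @param classic,sloping data.frames with a `length` column.
#' @return list with `statistic`, `p`, `median_classic`, `median_sloping`,
#'   `n` (total records ingested).
#' @export
class_length_contrast <- function(classic, sloping) {
  if (nrow(classic) == 0 || nrow(sloping) == 0)
    stop("both intron sets must be non-empty")
  wt <- wilcox.test(sloping$length, classic$length, exact = NULL)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_classic = median(classic$length),
       median_sloping = median(sloping$length),
       n = nrow(classic) + nrow(sloping))
}
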