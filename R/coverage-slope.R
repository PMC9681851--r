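#' Count reads per binned gene feature
#'
#' coverageBed-style semantics: a read (or read pair / fragment) increments
#' every bin it overlaps by at least one nucleotide, once per bin even when
#' the bin is split across an exon junction. Spliced (gapped) reads may be
#' given as a `GRangesList`, one element per read, in which case any aligned
#' segment can create the overlap.
#'
#' @param reads `GRanges` (one interval per read/fragment) or `GRangesList`
#'   (one element per read, gapped alignments).
#' @param bins `GRanges` of binned features from [bin_genes()].
#' @return An object of class `feature_counts`: list with `counts` (integer
#'   matrix, genes x bins, rows named by gene_id, 5'->3' column order),
#'   `total` (per-gene totals) and `excluded` (logical; total below
#'   `min_reads`).
#' @param min_reads Genes with fewer total reads are flagged `excluded`
#'   (default 50).
#' @export
count_features <- function(reads, bins, min_reads = 50) {
  n_bins <- attr(bins, "n_bins") %||% max(bins$bin)
  read_seqs <- if (is(reads, "GRangesList"))
    unique(unlist(lapply(reads, function(r) as.character(seqnames(r))),
                  use.names = FALSE))
  else unique(as.character(seqnames(reads)))
  bin_seqs <- unique(as.character(seqnames(bins)))
  if (length(read_seqs) && !any(read_seqs %in% bin_seqs))
    stop("chromosome names of alignments and annotation are disjoint: ",
         "alignments [", paste(utils::head(read_seqs, 5), collapse = ", "),
         "] vs annotation [", paste(utils::head(bin_seqs, 5), collapse = ", "),
         "]")
  genes <- unique(bins$gene_id)
  counts <- matrix(0L, nrow = length(genes), ncol = n_bins,
                   dimnames = list(genes, paste0("bin_", seq_len(n_bins))))
  total <- setNames(numeric(length(genes)), genes)
  hits <- findOverlaps(bins, reads, ignore.strand = TRUE)
  if (length(hits)) {
    key <- paste(bins$gene_id[queryHits(hits)], bins$bin[queryHits(hits)],
                 subjectHits(hits), sep = "\r")
    uh <- !duplicated(key)  # one increment per (bin, read)
    qh <- queryHits(hits)[uh]
    tab <- table(factor(bins$gene_id[qh], levels = genes), bins$bin[qh])
    counts[rownames(tab), as.integer(colnames(tab))] <-
      counts[rownames(tab), as.integer(colnames(tab))] + as.integer(tab)
    # the read filter counts distinct reads per gene, not per-bin increments
    gkey <- paste(bins$gene_id[queryHits(hits)], subjectHits(hits),
                  sep = "\r")
    gh <- queryHits(hits)[!duplicated(gkey)]
    gtab <- table(factor(bins$gene_id[gh], levels = genes))
    total[names(gtab)] <- as.numeric(gtab)
  }
  feature_counts(counts, min_reads = min_reads, total = total)
}

#' Construct a feature_counts object from a count matrix
#'
#' @param counts genes x bins matrix of non-negative integer read counts,
#'   rows named by gene_id, columns ordered 5'->3'.
#' @param min_reads Exclusion threshold on per-gene totals (default 50).
#' @param total Optional per-gene distinct-read totals; defaults to row
#'   sums (an upper bound when reads straddle bin boundaries).
#' @return A `feature_counts` object (see [count_features()]).
#' @export
feature_counts <- function(counts, min_reads = 50, total = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), all(counts >= 0))
  if (is.null(total)) total <- rowSums(counts)
  structure(list(counts = counts, total = total,
                 excluded = total < min_reads, min_reads = min_reads),
            class = "feature_counts")
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("feature_counts: %d genes x %d bins, %d excluded (< %d reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$excluded), x$min_reads))
  invisible(x)
}

#' Write / read a feature count matrix as TSV
#'
#' Column contract: `gene_id`, `bin_1` .. `bin_<n>`.
#' @param fc A `feature_counts` object.
#' @param path TSV path.
#' @return `path` invisibly; for the reader, a `feature_counts` object.
#' @export
write_feature_counts <- function(fc, path) {
  df <- data.frame(gene_id = rownames(fc$counts), fc$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_counts
#' @param min_reads Exclusion threshold re-applied on read (default 50).
#' @export
read_feature_counts <- function(path, min_reads = 50) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  feature_counts(m, min_reads = min_reads)
}

#' Fit the 5'->3' coverage slope of one gene
#'
#' Bin counts are normalised to relative coverage with mean one,
#' `c_i = n * r_i / sum(r)`, and regressed on the bin index `i = 1..n` by
#' ordinary least squares. The returned p-value is the two-sided t-test of
#' slope = 0 on `n - 2` degrees of freedom. A perfectly flat profile returns
#' `m = 0, p = 1`; an exact non-flat linear profile (zero residual) returns
#' `p = 0`.
#'
#' @param r Numeric vector of per-bin read counts, 5'->3'.
#' @return Named numeric vector `c(m = slope, p = p.value)`; both `NA` when
#'   `sum(r) == 0`.
#' @export
fit_slope <- function(r) {
  n <- length(r)
  s <- sum(r)
  if (n < 3 || s <= 0) return(c(m = NA_real_, p = NA_real_))
  cc <- n * r / s
  i <- seq_len(n)
  ibar <- mean(i)
  sxx <- sum((i - ibar)^2)
  m <- sum((i - ibar) * (cc - mean(cc))) / sxx
  rss <- sum((cc - mean(cc) - m * (i - ibar))^2)
  if (rss < 1e-12) {
    p <- if (abs(m) < 1e-12) 1 else 0
  } else {
    se <- sqrt(rss / (n - 2) / sxx)
    p <- 2 * pt(-abs(m / se), df = n - 2)
  }
  c(m = m, p = p)
}

#' Fit coverage slopes for every gene of a count matrix
#'
#' @param fc A `feature_counts` object.
#' @return data.frame with `gene_id`, `total`, `excluded`, `m`, `p`.
#'   Excluded genes (total < min_reads) get `NA` slope and p-value.
#' @export
fit_slopes <- function(fc) {
  stopifnot(is(fc, "feature_counts"))
  res <- t(apply(fc$counts, 1, fit_slope))
  out <- data.frame(gene_id = rownames(fc$counts), total = fc$total,
                    excluded = fc$excluded, m = res[, "m"], p = res[, "p"],
                    row.names = NULL)
  out$m[out$excluded] <- NA_real_
  out$p[out$excluded] <- NA_real_
  out
}

#' delta.slope between conditions
#'
#' Difference of the per-gene slope in the null condition and in the sibling
#' (control) condition, `m_null - m_sibling`. With `ratio = TRUE` the ratio
#' `m_null / m_sibling` is returned instead. Missing values propagate.
#'
#' @param m_null,m_sibling Numeric slope vectors (recycled as usual).
#' @param ratio Return the ratio instead of the difference (default FALSE).
#' @return Numeric vector of delta.slope values.
#' @export
delta_slope <- function(m_null, m_sibling, ratio = FALSE) {
  if (ratio) m_null / m_sibling else m_null - m_sibling
}

#' Per-gene slope table across the two conditions
#'
#' @param fc_null,fc_sibling `feature_counts` for the null and sibling
#'   condition (replicates merged).
#' @return data.frame with `gene_id`, `m_sibling`, `m_null`, `p_sibling`,
#'   `p_null`, `delta_slope`. Genes excluded in either condition carry `NA`.
#' @export
slope_table <- function(fc_null, fc_sibling) {
  sn <- fit_slopes(fc_null)
  ss <- fit_slopes(fc_sibling)
  common <- intersect(sn$gene_id, ss$gene_id)
  sn <- sn[match(common, sn$gene_id), ]
  ss <- ss[match(common, ss$gene_id), ]
  data.frame(gene_id = common,
             m_sibling = ss$m, m_null = sn$m,
             p_sibling = ss$p, p_null = sn$p,
             delta_slope = delta_slope(sn$m, ss$m),
             row.names = NULL)
}

#' Classify IR genes as classic versus sloping (PreT-IR)
#'
#' Within the supplied IR gene set, slope p-values from the null condition
#' are BH-adjusted; a gene is called `sloping` when `q < alpha`,
#' `m_null < 0` and `delta_slope < 0`, `classic` otherwise, and
#' `unclassified` when the read filter removed it in either condition.
#' A strict-sloping subset additionally requires `m_null < strict_m`.
#'
#' @param slopes data.frame from [slope_table()].
#' @param ir_genes Character vector of IR gene ids to classify.
#' @param alpha FDR threshold (default 0.05).
#' @param strict_m Strict slope threshold for the strict subset
#'   (default -0.1).
#' @return list with `labels` (data.frame: `gene_id`, `m_null`,
#'   `delta_slope`, `q`, `class`, `strict_sloping`), `counts` and
#'   `proportions` over \{classic, sloping, unclassified\}.
#' @export
classify_ir_genes <- function(slopes, ir_genes, alpha = 0.05,
                              strict_m = -0.1) {
  lv <- c("classic", "sloping", "unclassified")
  if (length(ir_genes) == 0) {
    labels <- data.frame(gene_id = character(), m_null = numeric(),
                         delta_slope = numeric(), q = numeric(),
                         class = factor(character(), levels = lv),
                         strict_sloping = logical())
    counts <- setNames(integer(3), lv)
    return(list(labels = labels, counts = counts,
                proportions = counts / max(1, sum(counts))))
  }
  s <- slopes[match(ir_genes, slopes$gene_id), ]
  s$gene_id <- ir_genes
  q <- p.adjust(s$p_null, method = "BH")
  cls <- ifelse(is.na(s$m_null) | is.na(s$delta_slope), "unclassified",
                ifelse(!is.na(q) & q < alpha & s$m_null < 0 &
                         s$delta_slope < 0, "sloping", "classic"))
  labels <- data.frame(gene_id = ir_genes, m_null = s$m_null,
                       delta_slope = s$delta_slope, q = q,
                       class = factor(cls, levels = lv),
                       strict_sloping = cls == "sloping" &
                         !is.na(s$m_null) & s$m_null < strict_m)
  counts <- table(labels$class)
  list(labels = labels, counts = c(counts),
       proportions = c(counts) / sum(counts))
}

#' Correlation between retained intron length and coverage slope
#'
#' Pearson correlation of retained-intron length against the null-condition
#' slope across IR genes, as used to relate premature termination to intron
#' length.
#'
#' @param slopes data.frame with `gene_id` and `m_null`.
#' @param intron_lengths data.frame with `gene_id` and `length` (one row per
#'   gene; for multi-intron genes supply the retained intron).
#' @return list with `r`, `p`, `n`. `r` is `NA` when either vector is
#'   constant or fewer than 3 pairs remain.
#' @export
length_slope_correlation <- function(slopes, intron_lengths) {
  d <- merge(slopes[, c("gene_id", "m_null")], intron_lengths,
             by = "gene_id")
  d <- d[stats::complete.cases(d[, c("m_null", "length")]), ]
  if (nrow(d) < 3 || stats::sd(d$m_null) == 0 || stats::sd(d$length) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(d)))
  ct <- cor.test(d$length, d$m_null, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
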