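#' Transcripts-per-million from gene counts
#'
#' Standard TPM: counts are divided by mature (spliced) length in kb, then
#' scaled so each sample sums to one million.
#'
#' @param counts genes x samples matrix (or vector) of read counts, rows
#'   named by gene_id.
#' @param lengths Named numeric vector of mature lengths (nt) covering every
#'   gene in `counts`.
#' @return Matrix of TPM values with the shape of `counts`.
#' @export
compute_tpm <- function(counts, lengths) {
  if (is.vector(counts)) counts <- cbind(sample = counts)
  stopifnot(!is.null(rownames(counts)),
            all(rownames(counts) %in% names(lengths)))
  rate <- counts / (lengths[rownames(counts)] / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Filter lowly expressed genes on reference-sample TPM
#'
#' Genes whose mean TPM over the reference samples (by default the sibling
#' neurite samples) is below `min_tpm` are removed; the boundary is a strict
#' less-than, so a gene at exactly `min_tpm` is retained.
#'
#' @param tpm genes x samples TPM matrix (see [compute_tpm()]).
#' @param reference_samples Column names of the reference samples.
#' @param min_tpm Threshold (default 20).
#' @return list with `tpm` (kept rows), `kept`, `removed` (gene ids) — the
#'   removal log.
#' @export
tpm_filter <- function(tpm, reference_samples, min_tpm = 20) {
  if (!all(reference_samples %in% colnames(tpm)))
    stop("reference samples missing from TPM table: ",
         paste(setdiff(reference_samples, colnames(tpm)), collapse = ", "))
  if (nrow(tpm) == 0)
    return(list(tpm = tpm, kept = character(), removed = character()))
  ref <- rowMeans(tpm[, reference_samples, drop = FALSE])
  keep <- ref >= min_tpm
  list(tpm = tpm[keep, , drop = FALSE],
       kept = rownames(tpm)[keep], removed = rownames(tpm)[!keep])
}

#' Log2 fold changes from library-size-normalised counts
#'
#' Per compartment, counts are normalised to the library size, averaged over
#' replicates, and the null/sibling log2 ratio is taken with a +0.5
#' pseudocount on the normalised means. This deliberately sidesteps
#' dispersion modelling: the downstream rules operate on the fold-change
#' point estimates only.
#'
#' @param counts_null,counts_sibling genes x replicates count matrices for
#'   one compartment, rows named by gene_id.
#' @return data.frame with `gene_id` and `log2fc`.
#' @export
log2fc_table <- function(counts_null, counts_sibling) {
  norm_mean <- function(m) {
    m <- sweep(m, 2, colSums(m), "/") * mean(colSums(m))
    rowMeans(m)
  }
  g <- intersect(rownames(counts_null), rownames(counts_sibling))
  data.frame(gene_id = g,
             log2fc = log2(norm_mean(counts_null[g, , drop = FALSE]) + 0.5) -
               log2(norm_mean(counts_sibling[g, , drop = FALSE]) + 0.5))
}

#' Flag neurite-specific downregulated genes
#'
#' A downregulated gene is neurite-specific when its neurite log2 fold
#' change undercuts the cellular one by more than the margin:
#' `log2FC_neurite - log2FC_cellular < margin` with both log2FCs negative.
#' Genes missing either compartment are skipped and logged.
#'
#' @param fc_table data.frame with `gene_id`, `log2fc_neurite`,
#'   `log2fc_cellular`.
#' @param margin Specificity margin (default -0.2, strict inequality).
#' @return list with `flagged` (gene ids), `table` (input plus
#'   `neurite_specific_down` flag) and `skipped` (gene ids with missing
#'   values).
#' @export
neurite_specific_down <- function(fc_table, margin = -0.2) {
  miss <- is.na(fc_table$log2fc_neurite) | is.na(fc_table$log2fc_cellular)
  if (any(miss))
    message(sum(miss), " gene(s) missing a compartment log2FC skipped")
  t2 <- fc_table[!miss, , drop = FALSE]
  flag <- (t2$log2fc_neurite - t2$log2fc_cellular < margin) &
    t2$log2fc_neurite < 0 & t2$log2fc_cellular < 0
  t2$neurite_specific_down <- flag
  list(flagged = t2$gene_id[flag], table = t2,
       skipped = fc_table$gene_id[miss])
}
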