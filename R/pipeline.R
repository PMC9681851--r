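#' Run the full IR / PreT-IR analysis pipeline
#'
#' Executes the analysis stages in dependency order on a simulated (or
#' equivalently structured) experiment: gene models and binning, per-gene
#' coverage slopes (neurite compartment, replicates merged), differential
#' intron retention with neurite-specificity flags, classic/sloping
#' classification of IR genes, cohort intron statistics, CLIP peak density
#' contrast (skipped with a warning when no peak set is present), intronic
#' polyadenylation statistics, and expression filters. Every stage's filter
#' counts land in the returned report; when `outdir` is given, per-stage
#' TSV tables and a `report.json` are written.
#'
#' @param exp An `ir_experiment` from [simulate_experiment()], or a
#'   [sim_config()] (simulated on the fly with `seed`).
#' @param outdir Optional output directory for TSVs and the JSON report.
#' @param seed Seed used only when `exp` is a config.
#' @param min_reads Per-gene read filter for the slope analysis
#'   (default 50).
#' @param delta_threshold,alpha,specificity_margin IR-calling thresholds
#'   (defaults 0.1, 0.05, 0.05).
#' @param strict_m Strict sloping threshold (default -0.1).
#' @param min_tpm Expression filter on sibling neurite TPM (default 20).
#' @param fc_margin Neurite-specific downregulation margin (default -0.2).
#' @param merge_distance,min_cluster_reads 3'-end clustering parameters
#'   (defaults 25 and 5).
#' @return list of class `ir_report` with elements `slopes`, `ir`,
#'   `classification`, `features`, `clip`, `ipas`, `expression` and
#'   `summary` (the flat numeric report).
#' @export
run_pipeline <- function(exp, outdir = NULL, seed = 1,
                         min_reads = 50, delta_threshold = 0.1,
                         alpha = 0.05, specificity_margin = 0.05,
                         strict_m = -0.1, min_tpm = 20, fc_margin = -0.2,
                         merge_distance = 25, min_cluster_reads = 5) {
  if (is(exp, "sim_config")) exp <- simulate_experiment(exp, seed = seed)
  stopifnot(is(exp, "ir_experiment"))
  ann <- exp$annotation
  models <- ann$models
  introns_rec <- intron_records(models)

  ## -- slopes (neurite, merged replicates) ----------------------------
  fc_null <- feature_counts(exp$merged$null.neurite$bin_counts,
                            min_reads = min_reads)
  fc_sib <- feature_counts(exp$merged$sibling.neurite$bin_counts,
                           min_reads = min_reads)
  slopes <- slope_table(fc_null, fc_sib)

  ## -- differential intron retention ----------------------------------
  quants <- do.call(rbind, lapply(exp$merged, function(s)
    data.frame(s$introns[, c("gene_id", "intron_index", "ir_ratio",
                             "intron_reads")],
               condition = s$condition, compartment = s$compartment,
               library_size = s$library_size)))
  ir <- diff_ir(quants, delta_threshold = delta_threshold, alpha = alpha,
                specificity_margin = specificity_margin)
  inc <- ir$results[ir$results$significant &
                      ir$results$direction == "increase", ]
  ir_genes <- unique(inc$gene_id)

  ## -- classic / sloping classification -------------------------------
  classification <- classify_ir_genes(slopes, ir_genes, alpha = alpha,
                                      strict_m = strict_m)

  ## -- cohort intron features -----------------------------------------
  key <- function(d) paste(d$gene_id, d$intron_index, sep = "\r")
  retained_rec <- introns_rec[key(introns_rec) %in% key(inc), ]
  features <- NULL
  if (nrow(retained_rec) > 0) {
    cls <- classification$labels
    ret_cls <- cls$class[match(retained_rec$gene_id, cls$gene_id)]
    features <- list(
      length_bias = length_bias_test(retained_rec, introns_rec),
      position_bias = position_bias(retained_rec, introns_rec))
    if (sum(ret_cls == "classic", na.rm = TRUE) > 0 &&
        sum(ret_cls == "sloping", na.rm = TRUE) > 0) {
      features$class_length <- class_length_contrast(
        retained_rec[which(ret_cls == "classic"), ],
        retained_rec[which(ret_cls == "sloping"), ])
      features$class_position <- position_bias(
        retained_rec[which(ret_cls == "sloping"), ],
        retained_rec[which(ret_cls == "classic"), ])
    }
    features$length_slope <- length_slope_correlation(
      slopes, retained_rec[, c("gene_id", "length")])
  }

  ## -- CLIP density contrast ------------------------------------------
  clip_res <- NULL
  if (!is.null(exp$clip) && length(exp$clip) > 0 && nrow(retained_rec)) {
    dens <- peak_density(exp$clip, introns_rec)
    is_ret <- key(dens) %in% key(inc)
    same_gene_ctl <- !is_ret & dens$gene_id %in% retained_rec$gene_id
    if (any(is_ret) && any(same_gene_ctl))
      clip_res <- density_contrast(dens[is_ret, ], dens[same_gene_ctl, ])
  } else {
    warning("no CLIP peaks supplied; CLIP stage skipped")
  }

  ## -- intronic polyadenylation ---------------------------------------
  cl_null <- cluster_3p_ends(exp$merged$null.neurite$end3,
                             merge_distance = merge_distance,
                             min_reads = min_cluster_reads)
  cl_sib <- cluster_3p_ends(exp$merged$sibling.neurite$end3,
                            merge_distance = merge_distance,
                            min_reads = min_cluster_reads)
  ipas_res <- NULL
  if (nrow(cl_null)) {
    cl_null <- assign_clusters(annotate_pas(cl_null, ann$genome),
                               models, introns_rec)
    cl_sib <- assign_clusters(annotate_pas(cl_sib, ann$genome),
                              models, introns_rec)
    if (nrow(retained_rec) && nrow(classification$labels))
      ipas_res <- intronic_cluster_stats(
        cl_null, retained_rec[, c("gene_id", "intron_index")],
        classification$labels, clusters_sibling = cl_sib)
  }

  ## -- expression filters ---------------------------------------------
  sample_mat <- function(cond, comp) {
    reps <- exp$samples[grepl(paste0("^", cond, "\\.", comp, "\\."),
                              names(exp$samples))]
    do.call(cbind, lapply(reps, `[[`, "gene_counts"))
  }
  counts_all <- cbind(sample_mat("sibling", "cellular"),
                      sample_mat("sibling", "neurite"),
                      sample_mat("null", "cellular"),
                      sample_mat("null", "neurite"))
  colnames(counts_all) <- names(exp$samples)
  lens <- setNames(models$genes$mature_length, models$genes$gene_id)
  tpm <- compute_tpm(counts_all, lens)
  ref_cols <- grep("^sibling\\.neurite\\.", colnames(tpm), value = TRUE)
  filt <- tpm_filter(tpm, ref_cols, min_tpm = min_tpm)
  fc_neu <- log2fc_table(sample_mat("null", "neurite"),
                         sample_mat("sibling", "neurite"))
  fc_cel <- log2fc_table(sample_mat("null", "cellular"),
                         sample_mat("sibling", "cellular"))
  fc_table <- data.frame(gene_id = fc_neu$gene_id,
                         log2fc_neurite = fc_neu$log2fc,
                         log2fc_cellular =
                           fc_cel$log2fc[match(fc_neu$gene_id,
                                               fc_cel$gene_id)])
  fc_table <- fc_table[fc_table$gene_id %in% filt$kept, ]
  nsd <- neurite_specific_down(fc_table, margin = fc_margin)
  # downregulated set: clear neurite decrease (no GLM testing here)
  down_genes <- fc_table$gene_id[fc_table$log2fc_neurite < -0.5]
  expression <- list(
    tpm_removed = length(filt$removed), n_down = length(down_genes),
    n_neurite_specific_down = sum(nsd$flagged %in% down_genes),
    flagged = nsd$flagged, table = nsd$table)

  ## -- summary ---------------------------------------------------------
  prop <- classification$proportions
  classified <- sum(classification$counts[c("classic", "sloping")])
  summary <- list(
    n_genes = nrow(models$genes),
    n_introns_tested = ir$summary$n_tested,
    n_ir_increase = ir$summary$n_increase,
    n_ir_decrease = ir$summary$n_decrease,
    pct_neurite_specific = 100 * ir$summary$n_neurite_specific /
      max(1, ir$summary$n_increase),
    median_ir_null = ir$summary$median_ir_null,
    median_delta_ir = ir$summary$median_delta_ir,
    pct_classic = 100 * unname(classification$counts["classic"]) /
      max(1, classified),
    pct_sloping = 100 * unname(classification$counts["sloping"]) /
      max(1, classified),
    length_bias_p = if (!is.null(features)) features$length_bias$p else NA,
    clip_p = if (!is.null(clip_res)) clip_res$p else NA,
    ipas_slope_r = if (!is.null(ipas_res)) ipas_res$slope_correlation$r
                   else NA,
    pct_neurite_specific_down = 100 * expression$n_neurite_specific_down /
      max(1, expression$n_down))

  report <- structure(list(slopes = slopes, ir = ir,
                           classification = classification,
                           features = features, clip = clip_res,
                           ipas = ipas_res, expression = expression,
                           summary = summary),
                      class = "ir_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.ir_report <- function(x, ...) {
  s <- x$summary
  cat("IR / PreT-IR pipeline report\n")
  cat(sprintf("  genes: %d, introns tested: %d\n", s$n_genes,
              s$n_introns_tested))
  cat(sprintf("  IR increases: %d (%.1f%% neurite-specific), decreases: %d\n",
              s$n_ir_increase, s$pct_neurite_specific, s$n_ir_decrease))
  cat(sprintf("  median IR ratio (null) %.3f, median delta IR %.3f\n",
              s$median_ir_null, s$median_delta_ir))
  cat(sprintf("  IR gene classes: %.1f%% classic / %.1f%% sloping\n",
              s$pct_classic, s$pct_sloping))
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(report$slopes, "slopes.tsv")
  wt(report$ir$results, "ir_results.tsv")
  wt(report$classification$labels, "ir_classes.tsv")
  if (!is.null(report$ipas)) wt(report$ipas$per_gene, "ipas_per_gene.tsv")
  wt(report$expression$table, "expression_flags.tsv")
  jsonlite::write_json(report$summary,
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
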