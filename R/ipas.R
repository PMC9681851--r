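#' Polyadenylation signal hexamers
#'
#' The canonical AATAAA and its reported single-base variants, in priority
#' order (strongest first), as scanned by [annotate_pas()].
#'
#' @return Character vector of 12 hexamers.
#' @export
pas_hexamers <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Cluster 3'-end read positions into cleavage-site clusters
#'
#' Single-linkage merging of strand-aware read 3'-end positions: positions
#' on the same chromosome and strand closer than or equal to
#' `merge_distance` are chained into one cluster. The cluster position is
#' the modal end (the position carrying the most reads; ties resolved to
#' the 5'-most), the read count is the summed ends, and clusters with fewer
#' than `min_reads` reads are dropped. Input order is irrelevant; a merge
#' distance of 0 returns one cluster per distinct position.
#'
#' @param ends data.frame with `chrom`, `pos` (genomic coordinate of the
#'   read 3' end), `strand`, `count`.
#' @param merge_distance Maximum gap (nt) chained into one cluster
#'   (default 25).
#' @param min_reads Minimum reads per kept cluster (default 5).
#' @return data.frame: `chrom`, `pos` (modal cleavage position), `strand`,
#'   `read_count`, `n_positions`, sorted by chrom/strand/pos.
#' @export
cluster_3p_ends <- function(ends, merge_distance = 25, min_reads = 5) {
  if (nrow(ends) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), read_count = numeric(),
                      n_positions = integer()))
  ends <- stats::aggregate(count ~ chrom + pos + strand, ends, sum)
  ends <- ends[order(ends$chrom, ends$strand, ends$pos), ]
  grp <- paste(ends$chrom, ends$strand, sep = "\r")
  out <- lapply(split(ends, grp), function(e) {
    gap <- c(Inf, diff(e$pos))
    cl <- cumsum(gap > merge_distance)
    do.call(rbind, lapply(split(e, cl), function(x) {
      modal <- x$pos[which.max(x$count)]   # which.max: first (5'-most) tie
      data.frame(chrom = x$chrom[1], pos = modal, strand = x$strand[1],
                 read_count = sum(x$count), n_positions = nrow(x))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[out$read_count >= min_reads, , drop = FALSE]
  out[order(out$chrom, out$strand, out$pos), ]
}

#' Annotate cleavage clusters with upstream PAS hexamers
#'
#' Scans a strand-aware window upstream of each cleavage position for the
#' 12 polyadenylation-signal hexamers of [pas_hexamers()]. Hexamer starts
#' between `window[1]` and `window[2]` nt upstream of the cleavage site are
#' considered; the hit with highest set priority is recorded, and among
#' hits of the same hexamer the one closest to the cleavage site. Clusters
#' without any hit are retained with `pas_hexamer = NA` and flagged
#' `pas_supported = FALSE`. Windows running off the contig are truncated.
#'
#' @param clusters data.frame from [cluster_3p_ends()].
#' @param genome A [Biostrings::DNAStringSet] named by chromosome, or a
#'   FASTA file path.
#' @param window Length-2 integer vector: scan from `window[1]` to
#'   `window[2]` nt upstream (default `c(10, 40)`).
#' @return `clusters` with added `pas_hexamer`, `pas_offset` (nt from
#'   hexamer start to cleavage position) and `pas_supported` columns.
#' @export
annotate_pas <- function(clusters, genome, window = c(10, 40)) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  hex <- pas_hexamers()
  n <- nrow(clusters)
  hx <- rep(NA_character_, n)
  off <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    chr <- clusters$chrom[k]
    if (!chr %in% names(genome)) next
    p <- clusters$pos[k]
    len <- length(genome[[chr]])
    offsets <- seq.int(window[1], window[2])
    if (clusters$strand[k] == "+") {
      starts <- p - offsets
      okb <- starts >= 1 & starts + 5 <= len
      seqs <- rep(NA_character_, length(offsets))
      if (any(okb))
        seqs[okb] <- as.character(Biostrings::extractAt(
          genome[[chr]], IRanges(starts[okb], width = 6)))
    } else {
      s2 <- p + offsets - 5
      okb <- s2 >= 1 & s2 + 5 <= len
      seqs <- rep(NA_character_, length(offsets))
      if (any(okb))
        seqs[okb] <- as.character(reverseComplement(Biostrings::extractAt(
          genome[[chr]], IRanges(s2[okb], width = 6))))
    }
    for (h in hex) {
      hit <- which(!is.na(seqs) & seqs == h)
      if (length(hit)) {
        hx[k] <- h
        off[k] <- offsets[min(hit)]  # closest to cleavage
        break
      }
    }
  }
  clusters$pas_hexamer <- hx
  clusters$pas_offset <- off
  clusters$pas_supported <- !is.na(hx)
  clusters
}

#' Assign clusters to genes and compute usage efficiencies
#'
#' Each cluster is assigned to the gene whose span contains its cleavage
#' position (same strand); usage efficiency is its read count divided by the
#' summed read count of all clusters of that gene, so per-gene efficiencies
#' sum to one. Clusters falling inside an intron are marked with the intron
#' index.
#'
#' @param clusters data.frame from [cluster_3p_ends()] (optionally through
#'   [annotate_pas()]).
#' @param models A `gene_models` object.
#' @param introns Optional data.frame from [intron_records()]; defaults to
#'   `intron_records(models)`.
#' @return `clusters` with added `gene_id`, `intron_index` (NA when exonic
#'   or intergenic) and `usage_efficiency`. Unassigned clusters are dropped.
#' @export
assign_clusters <- function(clusters, models, introns = NULL) {
  if (is.null(introns)) introns <- intron_records(models)
  spans <- unlist(range(models$exons))
  cgr <- GRanges(clusters$chrom, IRanges(clusters$pos, clusters$pos),
                 strand = clusters$strand)
  hit <- findOverlaps(cgr, spans, ignore.strand = FALSE)
  clusters$gene_id <- NA_character_
  clusters$gene_id[queryHits(hit)] <- names(spans)[subjectHits(hit)]
  clusters <- clusters[!is.na(clusters$gene_id), , drop = FALSE]
  cgr <- GRanges(clusters$chrom, IRanges(clusters$pos, clusters$pos),
                 strand = clusters$strand)
  igr <- GRanges(introns$chrom, IRanges(introns$start, introns$end),
                 strand = introns$strand)
  ih <- findOverlaps(cgr, igr, ignore.strand = FALSE)
  clusters$intron_index <- NA_integer_
  same_gene <- clusters$gene_id[queryHits(ih)] ==
    introns$gene_id[subjectHits(ih)]
  clusters$intron_index[queryHits(ih)[same_gene]] <-
    introns$intron_index[subjectHits(ih)[same_gene]]
  tot <- tapply(clusters$read_count, clusters$gene_id, sum)
  clusters$usage_efficiency <-
    clusters$read_count / as.numeric(tot[clusters$gene_id])
  rownames(clusters) <- NULL
  clusters
}

#' Intronic cleavage-site statistics across IR-transcript classes
#'
#' Counts PAS-supported clusters inside the retained intron of each
#' classified IR gene, correlates the intronic cluster count of sloping
#' genes with their coverage slope, and contrasts intronic cleavage-site
#' usage efficiency (summed intronic usage per gene) between classes and,
#' when a sibling cluster set is supplied, between conditions within the
#' sloping class.
#'
#' @param clusters Assigned and annotated clusters of the null condition
#'   (from [assign_clusters()] after [annotate_pas()]).
#' @param retained data.frame mapping `gene_id` to the retained
#'   `intron_index`.
#' @param classes data.frame with `gene_id`, `m_null` and `class`
#'   (`"classic"`/`"sloping"`), e.g. `classify_ir_genes()$labels`.
#' @param clusters_sibling Optional sibling-condition clusters for the
#'   between-condition contrast.
#' @return list with `per_gene` (gene_id, class, m_null,
#'   `intronic_clusters`, `intronic_usage`), `slope_correlation`
#'   (`r`, `p`, `n` over sloping genes), `class_usage_contrast`
#'   (Mann-Whitney classic vs sloping) and `condition_usage_contrast`
#'   (sloping genes, sibling vs null; NULL when no sibling set given).
#' @export
intronic_cluster_stats <- function(clusters, retained, classes,
                                   clusters_sibling = NULL) {
  if (is.null(classes$class)) stop("class labels missing")
  per_gene <- function(cl) {
    key <- paste(cl$gene_id, cl$intron_index, sep = "\r")
    rkey <- paste(retained$gene_id, retained$intron_index, sep = "\r")
    in_ret <- key %in% rkey & cl$pas_supported
    data.frame(gene_id = classes$gene_id,
               intronic_clusters = vapply(classes$gene_id, function(g)
                 sum(in_ret & cl$gene_id == g), numeric(1)),
               intronic_usage = vapply(classes$gene_id, function(g)
                 sum(cl$usage_efficiency[in_ret & cl$gene_id == g]),
                 numeric(1)))
  }
  pg <- per_gene(clusters)
  pg$class <- classes$class[match(pg$gene_id, classes$gene_id)]
  pg$m_null <- classes$m_null[match(pg$gene_id, classes$gene_id)]

  # steeper (more negative) slopes should carry more intronic cleavage
  # sites; classic genes anchor the correlation at (m ~ 0, count 0)
  cor_set <- pg[pg$class %in% c("classic", "sloping") & !is.na(pg$m_null), ]
  slo <- pg[pg$class == "sloping" & !is.na(pg$m_null), ]
  slope_correlation <- if (nrow(cor_set) >= 3 &&
                           stats::sd(cor_set$m_null) > 0 &&
                           stats::sd(cor_set$intronic_clusters) > 0) {
    ct <- cor.test(cor_set$m_null, cor_set$intronic_clusters,
                   method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(cor_set))
  } else list(r = NA_real_, p = NA_real_, n = nrow(cor_set))

  cla <- pg$intronic_usage[pg$class == "classic"]
  sl <- pg$intronic_usage[pg$class == "sloping"]
  class_usage_contrast <- if (length(cla) && length(sl)) {
    wt <- wilcox.test(cla, sl, exact = FALSE)
    list(p = wt$p.value, median_classic = median(cla),
         median_sloping = median(sl))
  } else NULL

  condition_usage_contrast <- NULL
  if (!is.null(clusters_sibling)) {
    ps <- per_gene(clusters_sibling)
    u_sib <- ps$intronic_usage[match(slo$gene_id, ps$gene_id)]
    u_sib[is.na(u_sib)] <- 0
    if (nrow(slo)) {
      wt <- wilcox.test(u_sib, slo$intronic_usage, exact = FALSE)
      condition_usage_contrast <- list(
        p = wt$p.value, median_sibling = median(u_sib),
        median_null = median(slo$intronic_usage))
    }
  }
  list(per_gene = pg, slope_correlation = slope_correlation,
       class_usage_contrast = class_usage_contrast,
       condition_usage_contrast = condition_usage_contrast)
}
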