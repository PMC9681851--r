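#' Read exon annotation from a GTF file
#'
#' Imports a GTF (1-based, closed intervals), keeps `exon` records and splits
#' them per gene. Coordinate conversion and attribute parsing are delegated
#' to [rtracklayer::import()].
#'
#' @param path Path to a GTF file. The `gene_id` attribute must be present.
#' @return A [GenomicRanges::GRangesList] of exon intervals, one element per
#'   gene, suitable for [reduce_exons()].
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(gr$type)) gr <- gr[gr$type == "exon"]
  if (is.null(gr$gene_id)) stop("GTF has no 'gene_id' attribute")
  GenomicRanges::split(gr, gr$gene_id)
}

#' Build union-exon gene models
#'
#' Collapses all transcript isoforms of each gene into a single spliced model:
#' exons are the interval union (redundant exons from alternative isoforms are
#' merged), introns are the complementary gaps between adjacent union exons,
#' and the mature length is the summed exon length. Genes whose mature length
#' falls below `min_length` are dropped and reported, as are malformed genes
#' (exons on more than one chromosome or strand, or no exons at all).
#'
#' @param exons_by_gene A `GRangesList` of exon intervals per gene (e.g. from
#'   [read_gene_annotation()]), or a named list of `GRanges`.
#' @param min_length Minimum mature (spliced) length in nt; shorter genes are
#'   dropped. Default 50.
#' @return An object of class `gene_models`: a list with elements
#'   \describe{
#'     \item{exons}{`GRangesList` of union exons per kept gene (genomic order).}
#'     \item{introns}{`GRangesList` of introns per kept gene (genomic order).}
#'     \item{genes}{data.frame with `gene_id`, `chrom`, `strand`,
#'       `mature_length`, `n_exons`, `n_introns`.}
#'     \item{dropped}{data.frame with `gene_id` and `reason` for every
#'       rejected or filtered gene.}
#'   }
#' @export
reduce_exons <- function(exons_by_gene, min_length = 50) {
  if (is.list(exons_by_gene) && !is(exons_by_gene, "GRangesList"))
    exons_by_gene <- GenomicRanges::GRangesList(exons_by_gene)
  ids <- names(exons_by_gene)
  if (is.null(ids)) stop("exons_by_gene must be named by gene_id")

  n_seq <- vapply(exons_by_gene, function(g)
    length(unique(as.character(seqnames(g)))), integer(1))
  n_str <- vapply(exons_by_gene, function(g)
    length(unique(as.character(strand(g)))), integer(1))
  n_ex  <- lengths(exons_by_gene)

  bad_empty  <- n_ex == 0L
  bad_chrom  <- !bad_empty & n_seq != 1L
  bad_strand <- !bad_empty & !bad_chrom & (n_str != 1L |
    vapply(exons_by_gene, function(g) any(as.character(strand(g)) == "*"),
           logical(1)))
  ok <- !(bad_empty | bad_chrom | bad_strand)

  red <- GenomicRanges::reduce(exons_by_gene[ok])
  mature <- vapply(red, function(g) sum(width(g)), numeric(1))
  short <- mature < min_length

  drop_df <- function(id, why)
    data.frame(gene_id = id, reason = rep(why, length(id)))
  dropped <- rbind(
    drop_df(ids[bad_empty], "no exons"),
    drop_df(ids[bad_chrom], "exons on multiple chromosomes"),
    drop_df(ids[bad_strand], "inconsistent strand"),
    drop_df(names(red)[short], sprintf("mature length < %d", min_length))
  )
  red <- red[!short]
  mature <- mature[!short]

  introns <- psetdiff(unlist(range(red)), red)
  genes <- data.frame(
    gene_id = names(red),
    chrom = vapply(red, function(g) as.character(seqnames(g)[1]), character(1)),
    strand = vapply(red, function(g) as.character(strand(g)[1]), character(1)),
    mature_length = as.integer(mature),
    n_exons = lengths(red),
    n_introns = lengths(introns),
    row.names = NULL
  )
  structure(list(exons = red, introns = introns, genes = genes,
                 dropped = dropped),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d dropped), %d introns\n",
              nrow(x$genes), nrow(x$dropped), sum(x$genes$n_introns)))
  invisible(x)
}

#' Per-intron records with length and relative position
#'
#' Introns are indexed 1-based from the transcriptional 5' end of the gene
#' (so on the minus strand, intron 1 has the highest genomic coordinates).
#' `relative_position` is `intron_index / n_introns`, in (0, 1].
#'
#' @param models A `gene_models` object from [reduce_exons()].
#' @return data.frame with `gene_id`, `intron_index`, `chrom`, `start`,
#'   `end`, `strand`, `length`, `relative_position` (1-based closed
#'   coordinates). Intron-less genes contribute no rows.
#' @export
intron_records <- function(models) {
  stopifnot(is(models, "gene_models"))
  keep <- models$genes$n_introns > 0
  if (!any(keep))
    return(data.frame(gene_id = character(), intron_index = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      relative_position = numeric()))
  gid <- rep(models$genes$gene_id[keep], models$genes$n_introns[keep])
  ir <- unlist(models$introns[models$genes$gene_id[keep]], use.names = FALSE)
  str <- rep(models$genes$strand[keep], models$genes$n_introns[keep])
  n_int <- rep(models$genes$n_introns[keep], models$genes$n_introns[keep])
  # introns come in genomic order; transcriptional index flips on minus strand
  genomic_idx <- unlist(lapply(models$genes$n_introns[keep], seq_len))
  idx <- ifelse(str == "-", n_int - genomic_idx + 1L, genomic_idx)
  data.frame(gene_id = gid, intron_index = as.integer(idx),
             chrom = as.character(seqnames(ir)),
             start = start(ir), end = end(ir), strand = str,
             length = width(ir),
             relative_position = idx / n_int)
}

#' Partition spliced genes into equal-sized ordered bins
#'
#' Each gene's mature (exon-union) sequence of length L is cut into `n_bins`
#' contiguous features of near-equal size: base size `floor(L / n_bins)`,
#' with the `L %% n_bins` transcriptionally 5'-most bins one nucleotide
#' larger. Bin 1 is always the transcriptional 5' end, so on minus-strand
#' genes it occupies the highest genomic coordinates. Bins that straddle an
#' exon-exon junction map back to more than one genomic sub-interval.
#'
#' @param models A `gene_models` object.
#' @param n_bins Number of features per gene (default 50).
#' @return A `GRanges` with one row per genomic sub-interval and metadata
#'   columns `gene_id`, `bin` (1-based, 5'->3') and `bin_length` (total
#'   mature length of that bin). Attribute `n_bins` records the partition
#'   size. Genes with `mature_length < n_bins` are skipped with a warning.
#' @export
bin_genes <- function(models, n_bins = 50) {
  stopifnot(is(models, "gene_models"), n_bins >= 1)
  short <- models$genes$mature_length < n_bins
  if (any(short))
    warning(sprintf("%d gene(s) with mature length < %d bins skipped: %s",
                    sum(short), n_bins,
                    paste(utils::head(models$genes$gene_id[short], 5),
                          collapse = ", ")))
  out <- vector("list", sum(!short))
  gi <- 0L
  for (g in which(!short)) {
    gi <- gi + 1L
    id <- models$genes$gene_id[g]
    str <- models$genes$strand[g]
    ex <- models$exons[[id]]
    if (str == "-") ex <- rev(ex)  # transcriptional order
    w <- width(ex)
    L <- sum(w)
    base <- L %/% n_bins
    sizes <- base + as.integer(seq_len(n_bins) <= L %% n_bins)
    b_end <- cumsum(sizes)            # mature coordinate of each bin end
    b_start <- c(1L, b_end[-n_bins] + 1L)
    e_end <- cumsum(w)                # mature coordinate of each exon end
    e_start <- c(1L, e_end[-length(w)] + 1L)
    # which exons each bin touches
    rows <- list()
    for (b in seq_len(n_bins)) {
      hit <- which(e_start <= b_end[b] & e_end >= b_start[b])
      for (e in hit) {
        m1 <- max(b_start[b], e_start[e])  # mature sub-interval
        m2 <- min(b_end[b], e_end[e])
        if (str == "+") {
          gs <- start(ex)[e] + (m1 - e_start[e])
          ge <- start(ex)[e] + (m2 - e_start[e])
        } else {
          ge <- end(ex)[e] - (m1 - e_start[e])
          gs <- end(ex)[e] - (m2 - e_start[e])
        }
        rows[[length(rows) + 1L]] <- c(b, gs, ge, sizes[b])
      }
    }
    m <- do.call(rbind, rows)
    out[[gi]] <- GRanges(models$genes$chrom[g],
                         IRanges(m[, 2], m[, 3]), strand = str,
                         gene_id = id, bin = as.integer(m[, 1]),
                         bin_length = as.integer(m[, 4]))
  }
  bins <- if (length(out)) do.call(c, out) else empty_bins()
  attr(bins, "n_bins") <- as.integer(n_bins)
  bins
}

empty_bins <- function() {
  g <- GRanges()
  mcols(g) <- S4Vectors::DataFrame(gene_id = character(0), bin = integer(0),
                                   bin_length = integer(0))
  g
}

#' Write binned gene features to a BED6 file
#'
#' One BED row per genomic sub-interval (0-based half-open on disk);
#' `name` is `gene_id|bin_index`, `score` is the bin's total mature length.
#' The file round-trips losslessly through [read_bins_bed()].
#'
#' @param bins `GRanges` from [bin_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pretir binned spliced genes (BED6: name=gene_id|bin, score=bin length)",
             con)
  if (length(bins)) {
    df <- data.frame(chrom = as.character(seqnames(bins)),
                     start = start(bins) - 1L, end = end(bins),
                     name = paste(bins$gene_id, bins$bin, sep = "|"),
                     score = bins$bin_length,
                     strand = as.character(strand(bins)))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read binned gene features from a BED6 file written by [write_bins_bed()]
#'
#' @param path BED file path.
#' @return `GRanges` with `gene_id`, `bin`, `bin_length` metadata columns.
#' @export
read_bins_bed <- function(path) {
  bed <- rtracklayer::import(path, format = "bed")
  if (length(bed) == 0) return(empty_bins())
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  gr <- GRanges(seqnames(bed), ranges(bed), strand = strand(bed),
                gene_id = vapply(parts, `[`, character(1), 1),
                bin = as.integer(vapply(parts, `[`, character(1), 2)),
                bin_length = as.integer(bed$score))
  n_bins <- max(gr$bin)
  attr(gr, "n_bins") <- n_bins
  gr
}
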