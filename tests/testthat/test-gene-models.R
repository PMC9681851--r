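test_that("overlapping exons collapse to their union and gaps become introns", {
  m <- toy_models(list(
    gA = list(chrom = "chr1", strand = "+",
              exons = rbind(c(1, 100), c(51, 150))),
    gB = list(chrom = "chr1", strand = "+",
              exons = rbind(c(1, 100), c(201, 300)))))
  expect_equal(nrow(m$genes), 2)
  exA <- m$exons[["gA"]]
  expect_equal(length(exA), 1)
  expect_equal(c(start(exA), end(exA)), c(1, 150))
  expect_equal(length(m$introns[["gA"]]), 0)
  inB <- m$introns[["gB"]]
  expect_equal(c(start(inB), end(inB)), c(101, 200))
  expect_equal(m$genes$mature_length, c(150L, 200L))
})

test_that("short genes and malformed records are dropped with reasons", {
  m <- toy_models(list(
    short = list(chrom = "chr1", strand = "+", exons = rbind(c(1, 40))),
    mixed = list(chrom = "chr1", strand = "+",
                 exons = rbind(c(1, 100), c(1, 100))),
    ok = list(chrom = "chr2", strand = "-",
              exons = rbind(c(1, 100), c(201, 260)))))
  # force the mixed gene onto two chromosomes
  grl <- list(
    short = GRanges("chr1", IRanges(1, 40), strand = "+"),
    mixed = c(GRanges("chr1", IRanges(1, 100), strand = "+"),
              GRanges("chr2", IRanges(1, 100), strand = "+")),
    none = GRanges(),
    ok = GRanges("chr2", IRanges(c(1, 201), c(100, 260)), strand = "-"))
  m <- reduce_exons(GenomicRanges::GRangesList(grl))
  expect_equal(m$genes$gene_id, "ok")
  expect_setequal(m$dropped$gene_id, c("short", "mixed", "none"))
  expect_match(m$dropped$reason[m$dropped$gene_id == "mixed"],
               "chromosome")
  expect_match(m$dropped$reason[m$dropped$gene_id == "short"], "< 50")
})

test_that("reduce_exons is idempotent", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    st <- sort(sample(1:2000, n))
    ex <- GRanges("chr1", IRanges(st, st + sample(30:200, n, TRUE)),
                  strand = sample(c("+", "-"), 1))
    m1 <- reduce_exons(GenomicRanges::GRangesList(list(g = ex)))
    if (nrow(m1$genes) == 0) next
    m2 <- reduce_exons(m1$exons)
    expect_identical(as.data.frame(m1$exons[["g"]]),
                     as.data.frame(m2$exons[["g"]]))
    expect_identical(m1$genes$mature_length, m2$genes$mature_length)
  }
})

test_that("binning follows the floor/remainder rule with 5'-priority", {
  m <- toy_models(list(
    even = list(chrom = "chr1", strand = "+", exons = rbind(c(1, 500))),
    odd = list(chrom = "chr1", strand = "+", exons = rbind(c(1001, 1503)))))
  b <- bin_genes(m, n_bins = 50)
  be <- b[b$gene_id == "even"]
  expect_equal(length(be), 50)
  expect_true(all(width(be) == 10))
  expect_equal(be$bin, 1:50)
  bo <- b[b$gene_id == "odd"]
  expect_equal(bo$bin_length[bo$bin <= 3], rep(11L, 3))
  expect_equal(bo$bin_length[bo$bin > 3], rep(10L, 47))
  expect_equal(sum(width(bo)), 503)
})

test_that("minus-strand bin 1 sits at the highest genomic coordinates", {
  m <- toy_models(list(
    gm = list(chrom = "chr1", strand = "-",
              exons = rbind(c(1, 250), c(501, 750)))))
  b <- bin_genes(m, n_bins = 50)
  b1 <- b[b$bin == 1]
  expect_equal(end(b1), 750)
  b50 <- b[b$bin == 50]
  expect_equal(start(b50), 1)
})

test_that("bins partition the exon chain exactly (property)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    st <- cumsum(sample(100:1000, n))
    w <- sample(60:400, n, TRUE)
    m <- reduce_exons(GenomicRanges::GRangesList(list(
      g = GRanges("chr1", IRanges(st, st + w - 1),
                  strand = sample(c("+", "-"), 1)))))
    b <- suppressWarnings(bin_genes(m, n_bins = 50))
    if (length(b) == 0) next
    expect_equal(sum(width(b)), m$genes$mature_length)
    # each bin's sub-intervals sum to the declared bin length
    per_bin <- tapply(width(b), b$bin, sum)
    decl <- tapply(b$bin_length, b$bin, unique)
    expect_equal(unname(per_bin), unname(unlist(decl)))
    # any two bins differ by at most 1 nt
    expect_lte(diff(range(b$bin_length)), 1)
  }
})

test_that("strand flip reverses bin order but preserves bin sizes", {
  ex <- rbind(c(101, 400), c(1001, 1300), c(2001, 2203))
  mp <- toy_models(list(g = list(chrom = "chr1", strand = "+", exons = ex)))
  mm <- toy_models(list(g = list(chrom = "chr1", strand = "-", exons = ex)))
  bp <- bin_genes(mp, 50)
  bm <- bin_genes(mm, 50)
  szp <- tapply(bp$bin_length, bp$bin, unique)
  szm <- tapply(bm$bin_length, bm$bin, unique)
  expect_equal(unname(unlist(szp)), unname(unlist(szm)))
  # genomic footprint of bin k on + equals bin (5'-flip) on - only when
  # sizes are uniform; at minimum the extreme bins swap ends
  expect_equal(min(start(bp[bp$bin == 1])), min(start(bm[bm$bin == 50])))
  expect_equal(max(end(bp[bp$bin == 50])), max(end(bm[bm$bin == 1])))
})

test_that("bins BED round-trips losslessly and empty sets are legal", {
  m <- toy_models(list(
    g1 = list(chrom = "chr1", strand = "+",
              exons = rbind(c(1, 260), c(501, 800))),
    g2 = list(chrom = "chr2", strand = "-", exons = rbind(c(11, 310)))))
  b <- bin_genes(m, 50)
  path <- tempfile(fileext = ".bed")
  write_bins_bed(b, path)
  b2 <- read_bins_bed(path)
  expect_equal(as.character(seqnames(b)), as.character(seqnames(b2)))
  expect_equal(start(b), start(b2))
  expect_equal(end(b), end(b2))
  expect_equal(b$gene_id, b2$gene_id)
  expect_equal(b$bin, b2$bin)
  expect_equal(b$bin_length, b2$bin_length)
  # per-gene BED length sums equal mature lengths
  expect_equal(as.vector(tapply(width(b2), b2$gene_id, sum)),
               m$genes$mature_length[match(sort(unique(b2$gene_id)),
                                           m$genes$gene_id)])
  # empty set (the only gene fails the length filter): file with header
  # comment only, reads back empty
  p2 <- tempfile(fileext = ".bed")
  write_bins_bed(bin_genes(toy_models(list(
    tiny = list(chrom = "chr1", strand = "+",
                exons = rbind(c(1, 40))))), 50), p2)
  expect_true(startsWith(readLines(p2)[1], "#"))
  expect_equal(length(read_bins_bed(p2)), 0)
})

test_that("intron records carry transcriptional index and relative position", {
  m <- toy_models(list(
    gp = list(chrom = "chr1", strand = "+",
              exons = rbind(c(1, 100), c(201, 300), c(401, 500))),
    gm = list(chrom = "chr1", strand = "-",
              exons = rbind(c(1, 100), c(201, 300), c(401, 500)))))
  ir <- intron_records(m)
  p <- ir[ir$gene_id == "gp", ]
  expect_equal(p$intron_index, 1:2)
  expect_equal(p$start, c(101, 301))
  expect_equal(p$relative_position, c(0.5, 1))
  mrec <- ir[ir$gene_id == "gm", ]
  # on minus strand intron 1 is the gap nearest the 3'-most coordinate
  expect_equal(mrec$intron_index[mrec$start == 301], 1)
  expect_equal(mrec$intron_index[mrec$start == 101], 2)
  expect_equal(sort(mrec$relative_position), c(0.5, 1))
  expect_true(all(ir$length == 100))
})
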