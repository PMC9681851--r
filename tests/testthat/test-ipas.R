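test_that("3'-end clustering merges by distance and keeps modal positions", {
  ends <- data.frame(chrom = "chrS",
                     pos = c(100, 105, 400),
                     strand = "+",
                     count = c(10, 5, 8))
  cl <- cluster_3p_ends(ends, merge_distance = 25, min_reads = 5)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$pos, c(100, 400))
  expect_equal(cl$read_count, c(15, 8))
  # identical positions collapse to one cluster
  same <- data.frame(chrom = "chrS", pos = rep(77, 4), strand = "+",
                     count = c(2, 3, 1, 4))
  expect_equal(nrow(cluster_3p_ends(same)), 1)
  # below min_reads dropped
  weak <- data.frame(chrom = "chrS", pos = 50, strand = "+", count = 4)
  expect_equal(nrow(cluster_3p_ends(weak, min_reads = 5)), 0)
})

test_that("clustering is order-invariant and radius 0 keeps distinct sites", {
  set.seed(51)
  ends <- data.frame(chrom = "chrS",
                     pos = sample(c(10, 12, 40, 200, 210), 40, TRUE),
                     strand = sample(c("+", "-"), 40, TRUE),
                     count = sample(1:20, 40, TRUE))
  c1 <- cluster_3p_ends(ends)
  c2 <- cluster_3p_ends(ends[sample(nrow(ends)), ])
  expect_equal(c1, c2)
  c0 <- cluster_3p_ends(ends, merge_distance = 0, min_reads = 1)
  expect_equal(nrow(c0),
               nrow(unique(ends[, c("chrom", "pos", "strand")])))
  # strands never merge across each other
  expect_true(all(table(paste(c0$pos, c0$strand)) == 1))
})

make_genome <- function(len = 600, plant = list()) {
  # A/C/G alternating backbone cannot contain any PAS hexamer
  s <- strsplit(paste(rep("ACG", ceiling(len / 3)), collapse = ""), "")[[1]][1:len]
  for (p in plant) s[p$at:(p$at + nchar(p$seq) - 1)] <- strsplit(p$seq, "")[[1]]
  DNAStringSet(setNames(list(DNAString(paste(s, collapse = ""))), "chrS"))
}

test_that("annotate_pas finds planted hexamers at the right offset", {
  # cleavage at 500 (+): AATAAA planted at 480 means offset 20
  genome <- make_genome(600, list(list(at = 480, seq = "AATAAA")))
  cl <- data.frame(chrom = "chrS", pos = 500, strand = "+",
                   read_count = 50, n_positions = 1)
  a <- annotate_pas(cl, genome)
  expect_equal(a$pas_hexamer, "AATAAA")
  expect_equal(a$pas_offset, 20)
  expect_true(a$pas_supported)
  # no hexamer in window: flagged but retained
  a2 <- annotate_pas(data.frame(chrom = "chrS", pos = 200, strand = "+",
                                read_count = 9, n_positions = 1), genome)
  expect_true(is.na(a2$pas_hexamer))
  expect_false(a2$pas_supported)
})

test_that("hexamer set priority beats proximity", {
  # ATTAAA closer (offset 15) but AATAAA present farther (offset 30)
  genome <- make_genome(600, list(list(at = 500 - 30, seq = "AATAAA"),
                                  list(at = 500 - 15, seq = "ATTAAA")))
  a <- annotate_pas(data.frame(chrom = "chrS", pos = 500, strand = "+",
                               read_count = 10, n_positions = 1), genome)
  expect_equal(a$pas_hexamer, "AATAAA")
  expect_equal(a$pas_offset, 30)
  # same hexamer twice: closest wins
  genome2 <- make_genome(600, list(list(at = 500 - 35, seq = "AATAAA"),
                                   list(at = 500 - 15, seq = "AATAAA")))
  a2 <- annotate_pas(data.frame(chrom = "chrS", pos = 500, strand = "+",
                                read_count = 10, n_positions = 1), genome2)
  expect_equal(a2$pas_offset, 15)
})

test_that("minus-strand scan equals plus-strand scan of the reverse complement", {
  genome <- make_genome(600, list(list(at = 480, seq = "AATAAA")))
  rc <- DNAStringSet(setNames(list(
    reverseComplement(genome[["chrS"]])), "chrS"))
  L <- 600
  plus <- annotate_pas(data.frame(chrom = "chrS", pos = 500, strand = "+",
                                  read_count = 10, n_positions = 1), genome)
  minus <- annotate_pas(data.frame(chrom = "chrS", pos = L - 500 + 1,
                                   strand = "-", read_count = 10,
                                   n_positions = 1), rc)
  expect_equal(minus$pas_hexamer, plus$pas_hexamer)
  expect_equal(minus$pas_offset, plus$pas_offset)
})

test_that("window truncates at contig bounds instead of erroring", {
  genome <- make_genome(60)
  a <- annotate_pas(data.frame(chrom = "chrS", pos = 12, strand = "+",
                               read_count = 10, n_positions = 1), genome)
  expect_false(a$pas_supported)
})

test_that("per-gene usage efficiencies sum to one after assignment", {
  exp <- cached("exp_noiseless_small", simulate_experiment(
    sim_config(n_genes = 30), seed = 5, noise = FALSE))
  ends <- exp$merged$null.neurite$end3
  cl <- cluster_3p_ends(ends)
  cl <- assign_clusters(annotate_pas(cl, exp$annotation$genome),
                        exp$annotation$models)
  sums <- tapply(cl$usage_efficiency, cl$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("intronic cluster stats find the planted slope relationship", {
  exp <- cached("exp_noiseless_small", simulate_experiment(
    sim_config(n_genes = 30), seed = 5, noise = FALSE))
  rep <- cached("report_noiseless_small",
                suppressWarnings(run_pipeline(exp)))
  expect_false(is.null(rep$ipas))
  pg <- rep$ipas$per_gene
  # judged against the planted truth: sloping genes carry intronic
  # clusters, classic genes none
  tcls <- exp$truth$class[match(pg$gene_id, exp$truth$gene_id)]
  expect_gt(min(pg$intronic_clusters[tcls == "sloping"]), 0)
  expect_equal(max(pg$intronic_clusters[tcls == "classic"]), 0)
  expect_lt(rep$ipas$slope_correlation$r, 0)
  expect_error(
    intronic_cluster_stats(data.frame(), data.frame(),
                           data.frame(gene_id = "g")), "class labels")
})
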