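test_that("audic_claverie_p reproduces exact reference values", {
  # both libraries empty at a site: p(0|0) = 0.5 each tail, two-sided 1
  expect_equal(audic_claverie_p(0, 0, 1e6, 1e6), 1)
  # 5 vs 0 with equal libraries: 2 * p(0|5) = 2/64
  expect_equal(audic_claverie_p(5, 0, 1e6, 1e6), 0.03125, tolerance = 1e-12)
  expect_error(audic_claverie_p(-1, 0, 1e6, 1e6), "non-negative")
  expect_error(audic_claverie_p(1, 0, 0, 1e6), "positive")
  expect_error(audic_claverie_p(1.5, 0, 1e6, 1e6), "integer")
})

test_that("audic_claverie_p is symmetric under library swap", {
  set.seed(13)
  for (i in 1:50) {
    x <- rpois(1, 30); y <- rpois(1, 30)
    N1 <- sample(1e5:1e6, 1); N2 <- sample(1e5:1e6, 1)
    expect_equal(audic_claverie_p(x, y, N1, N2),
                 audic_claverie_p(y, x, N2, N1), tolerance = 1e-14)
  }
})

test_that("audic_claverie_p matches the naive summation oracle", {
  set.seed(14)
  grid <- expand.grid(x = c(0, 1, 3, 10, 40), y = c(0, 2, 7, 25, 50))
  for (k in seq_len(nrow(grid))) {
    for (ratio in c(1, 2.5)) {
      got <- audic_claverie_p(grid$x[k], grid$y[k], 1e6, ratio * 1e6)
      want <- ac_oracle(grid$x[k], grid$y[k], 1e6, ratio * 1e6)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("ir_ratio follows D/(D+S) with the undefined-at-zero rule", {
  expect_equal(ir_ratio(5, 45), 0.1)
  expect_equal(ir_ratio(0, 10), 0)
  expect_equal(ir_ratio(7, 7), 0.5)
  expect_true(is.na(ir_ratio(0, 0)))
  # monotone in D for fixed S, bounded in [0, 1]
  d <- seq(0, 50, by = 5)
  r <- ir_ratio(d, 20)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("quantify_ir computes masked median depth and exact junction counts", {
  m <- toy_models(list(
    g1 = list(chrom = "chr1", strand = "+",
              exons = rbind(c(1, 100), c(201, 300))),
    # neighbour whose exon covers half of g1's intron
    g2 = list(chrom = "chr1", strand = "+",
              exons = rbind(c(101, 150), c(401, 460)))))
  introns <- intron_records(m)
  g1i <- introns[introns$gene_id == "g1", ]
  exon_mask <- unlist(m$exons)
  # depth 5 across the intron, junctions observed 45x
  reads <- rep(GRanges("chr1", IRanges(101, 200)), 5)
  jx <- data.frame(chrom = "chr1", start = 101, end = 200, count = 45)
  q <- quantify_ir(reads, g1i, exon_mask, jx)
  expect_equal(q$intron_depth, 5)
  expect_equal(q$junction_reads, 45)
  expect_equal(q$ir_ratio, 0.1)
  expect_equal(q$masked_fraction, 0.5)  # g2 exon masks 101..150
  # junction spans must match boundaries exactly
  jx_off <- data.frame(chrom = "chr1", start = 102, end = 200, count = 45)
  q2 <- quantify_ir(reads, g1i, exon_mask, jx_off)
  expect_equal(q2$junction_reads, 0)
})

test_that("a fully exon-masked intron yields a missing quantification", {
  m <- toy_models(list(
    g1 = list(chrom = "chr1", strand = "+",
              exons = rbind(c(1, 100), c(201, 300))),
    g3 = list(chrom = "chr1", strand = "-",
              exons = rbind(c(90, 210), c(401, 460)))))
  g1i <- intron_records(m)
  g1i <- g1i[g1i$gene_id == "g1", ]
  q <- quantify_ir(GRanges("chr1", IRanges(101, 200)), g1i,
                   unlist(m$exons),
                   data.frame(chrom = character(), start = integer(),
                              end = integer(), count = integer()))
  expect_true(is.na(q$intron_depth))
  expect_match(q$note, "masked")
})

sim_quants <- function(n, delta, depth = 100, len = 2000, rl = 50,
                       base = 0.02, compartments = "neurite",
                       delta_cellular = delta, seed = 1) {
  # per-intron D, K, S draws under the generative retention model
  with_seed_local <- function(s, code) { set.seed(s); code }
  with_seed_local(seed, {
    out <- list()
    for (comp in compartments) {
      d_here <- if (comp == "neurite") delta else delta_cellular
      for (cond in c("sibling", "null")) {
        lvl <- if (cond == "null") base + d_here else rep(base, n)
        lvl <- rep(lvl, length.out = n)
        K <- rpois(n, lvl * depth * len / rl)
        D <- K * rl / len
        S <- rpois(n, (1 - lvl) * depth)
        out[[paste(comp, cond)]] <- data.frame(
          gene_id = sprintf("g%04d", 1:n), intron_index = 1L,
          condition = cond, compartment = comp,
          ir_ratio = ir_ratio(D, S), intron_reads = K,
          library_size = round(depth * 1e4))
      }
    }
    do.call(rbind, out)
  })
}

test_that("diff_ir calls nothing when conditions are identical", {
  q <- sim_quants(50, delta = 0, seed = 4)
  # make null identical to sibling
  q[q$condition == "null",
    c("ir_ratio", "intron_reads")] <- q[q$condition == "sibling",
                                        c("ir_ratio", "intron_reads")]
  res <- diff_ir(q)
  expect_equal(res$summary$n_increase + res$summary$n_decrease, 0)
})

test_that("diff_ir recovers planted increases and honours strict thresholds", {
  q <- sim_quants(200, delta = 0.3, seed = 8)
  res <- diff_ir(q)
  expect_gte(res$summary$n_increase, 190)
  expect_equal(res$summary$n_decrease, 0)
  expect_lt(abs(median(res$results$delta_ir) - 0.3), 0.02)
  # missing condition is dropped, not an error
  q2 <- q[!(q$gene_id == "g0001" & q$condition == "null"), ]
  expect_message(res2 <- diff_ir(q2), "dropped")
  expect_false("g0001" %in% res2$results$gene_id)
})

test_that("neurite-specificity needs the change to exceed cellular by > 0.05", {
  q <- sim_quants(100, delta = 0.3, delta_cellular = 0.05,
                  compartments = c("neurite", "cellular"), seed = 15)
  res <- diff_ir(q)
  inc <- res$results[res$results$significant &
                       res$results$direction == "increase", ]
  expect_gte(mean(inc$neurite_specific), 0.9)
  # equal changes in both compartments: not neurite-specific
  q2 <- sim_quants(100, delta = 0.3, delta_cellular = 0.3,
                   compartments = c("neurite", "cellular"), seed = 16)
  res2 <- diff_ir(q2)
  inc2 <- res2$results[res2$results$significant, ]
  expect_lte(mean(inc2$neurite_specific), 0.1)
})
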