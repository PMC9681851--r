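suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Build a gene_models object from a compact spec:
# list(g1 = list(chrom = "chr1", strand = "+", exons = rbind(c(1,100), ...)))
toy_models <- function(spec, min_length = 50) {
  grl <- lapply(spec, function(g)
    GRanges(g$chrom, IRanges(g$exons[, 1], g$exons[, 2]),
            strand = g$strand))
  reduce_exons(GenomicRanges::GRangesList(grl), min_length = min_length)
}

# n reads of given width tiled uniformly over an interval
tile_reads <- function(chrom, start, end, n, width = 50) {
  pos <- round(seq(start, max(start, end - width + 1), length.out = n))
  GRanges(chrom, IRanges(pos, width = width))
}

# independent OLS oracle: solve the normal equations directly
ols_slope_oracle <- function(r) {
  n <- length(r)
  cc <- n * r / sum(r)
  X <- cbind(1, seq_len(n))
  beta <- solve(t(X) %*% X, t(X) %*% cc)
  m <- beta[2]
  resid <- cc - X %*% beta
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  p <- if (s2 < 1e-14) { if (abs(m) < 1e-12) 1 else 0 }
       else 2 * pt(-abs(m / se), df = n - 2)
  c(m = m, p = p)
}

# independent Audic-Claverie oracle: naive log-factorial summation of
# p(k|x) tails, symmetrised the same way as the implementation
ac_oracle <- function(x, y, N1, N2, kmax = 2000) {
  pmf <- function(k, x, N1, N2) {
    f <- N2 / N1
    exp(k * log(f) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
          (x + k + 1) * log(1 + f))
  }
  one <- function(x, y, N1, N2) {
    ks <- 0:max(kmax, y + 200)
    pr <- pmf(ks, x, N1, N2)
    p_le <- sum(pr[ks <= y])
    p_ge <- sum(pr[ks >= y])
    min(1, 2 * min(p_le, p_ge))
  }
  min(one(x, y, N1, N2), one(y, x, N2, N1))
}

# cache heavyweight simulations across test files within one run
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}
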