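#' Configuration for the synthetic compartment RNA-seq experiment
#'
#' Defines the generative conditions the package is tested against: gene
#' geometry, planted gene classes (normal, classic-IR, sloping/PreT-IR),
#' retention and termination levels, compartment bias, sequencing depth,
#' 3'-end and CLIP rates. Defaults emulate the statistical structure of an
#' SFPQ-null compartment experiment: a 0.2 retention level over a 0.02
#' baseline (a median IR ratio near 0.2 and a median IR increase near 0.18),
#' a 0.8 termination fraction for prematurely terminated genes, a class mix
#' giving 31% classic / 69% sloping within the IR gene set, a 3x CLIP peak
#' rate on retained introns, and 31% of downregulated genes planted as
#' neurite-specific.
#'
#' @param n_genes Number of genes (default 100).
#' @param exon_count Integer range of exons per gene (default `c(5, 9)`).
#' @param exon_length Range of exon lengths in nt (default `c(120, 300)`).
#' @param intron_meanlog,intron_sdlog Log-normal parameters for ordinary
#'   intron lengths (defaults `log(800)`, 0.6).
#' @param retained_meanlog_classic,retained_meanlog_sloping Log-normal
#'   mean-log of retained intron lengths per class (defaults `log(2000)`
#'   and `log(5000)`: sloping retained introns are longer).
#' @param retained_sdlog Common sd-log for retained introns (default 0.4).
#' @param min_retained_length Lower clamp on retained intron length, nt
#'   (default 1500, so planted PAS geometry always fits).
#' @param class_props Named proportions of `normal`, `classic`, `sloping`
#'   genes; must sum to 1 (default `c(0.5, 0.155, 0.345)`).
#' @param ir_level Retention fraction rho of classic-IR introns in null
#'   neurites (default 0.2).
#' @param termination_fraction Per-site capture efficiency of a planted
#'   intronic PAS in null (default 0.8). A sloping gene with `k` planted
#'   sites terminates `1 - (1 - efficiency)^k` of its transcripts, so the
#'   gene-level termination equals this value when a single site is
#'   planted.
#' @param baseline_ir Baseline retention rho0 in sibling samples and
#'   non-retained introns (default 0.02).
#' @param neurite_bias Extra IR-change planted in the neurite over the
#'   cellular compartment (default 0.15).
#' @param depth Mean per-base exonic read coverage, x (default 100).
#' @param read_length Read length in nt used to convert coverage to read
#'   counts (default 50).
#' @param threeprime_depth Mean 3'-end reads per gene (default 300).
#' @param ipas_range Range of planted intronic PAS sites per sloping gene
#'   (default `c(1, 3)`).
#' @param pas_offset Planted hexamer offset upstream of the cleavage site,
#'   nt (default 20).
#' @param clip_rate_retained,clip_rate_control CLIP peaks per kb of intron
#'   for retained versus control introns (defaults 1.5 and 0.5).
#' @param clip_peak_width CLIP peak width in nt (default 30).
#' @param down_lfc Planted log2 fold change of IR genes in null (default
#'   -0.8).
#' @param neurite_extra_down Additional neurite log2FC for neurite-specific
#'   downregulated genes (default -0.6).
#' @param neurite_specific_fraction Fraction of downregulated genes planted
#'   neurite-specific (default 0.31).
#' @param n_bins Features per gene (default 50).
#' @param intergenic_gap Gap between simulated genes, nt (default 2000).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100,
                       exon_count = c(5, 9),
                       exon_length = c(120, 300),
                       intron_meanlog = log(800), intron_sdlog = 0.6,
                       retained_meanlog_classic = log(2000),
                       retained_meanlog_sloping = log(5000),
                       retained_sdlog = 0.4,
                       min_retained_length = 1500,
                       class_props = c(normal = 0.5, classic = 0.155,
                                       sloping = 0.345),
                       ir_level = 0.2,
                       termination_fraction = 0.8,
                       baseline_ir = 0.02,
                       neurite_bias = 0.15,
                       depth = 100,
                       read_length = 50,
                       threeprime_depth = 300,
                       ipas_range = c(1, 3),
                       pas_offset = 20,
                       clip_rate_retained = 1.5,
                       clip_rate_control = 0.5,
                       clip_peak_width = 30,
                       down_lfc = -0.8,
                       neurite_extra_down = -0.6,
                       neurite_specific_fraction = 0.31,
                       n_bins = 50,
                       intergenic_gap = 2000) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(class_props) - 1) < 1e-8,
            all(class_props >= 0),
            ir_level >= 0, ir_level <= 1,
            termination_fraction >= 0, termination_fraction <= 1,
            baseline_ir >= 0, clip_rate_retained >= 0,
            clip_rate_control >= 0, depth > 0)
  structure(cfg, class = "sim_config")
}

# sample one value from an integer range, robust to length-1 ranges
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# compartment-adjusted retention/termination level
eff_level <- function(level, compartment, cfg) {
  if (compartment == "neurite") level
  else cfg$baseline_ir + pmax(0, level - cfg$baseline_ir - cfg$neurite_bias)
}

#' Simulate gene annotation, genome sequence and ground truth
#'
#' Samples gene structures on a single synthetic chromosome, assigns each
#' gene a class (`normal`, `classic` IR, `sloping` PreT-IR), designates one
#' retained intron per IR gene (long and 5'-proximal for sloping genes),
#' plants 1-3 intronic PAS hexamers plus a cleavage site inside the
#' retained intron of every sloping gene and a terminal PAS for every gene,
#' and emits a genome sequence that is PAS-free everywhere else (all 12
#' hexamers and their reverse complements are scrubbed before planting).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical annotations.
#' @return Object of class `ir_annotation`: list with `config`, `models`
#'   (a `gene_models`), `truth` (per-gene data.frame), `ipas` (planted
#'   cleavage sites and hexamer positions), `genome`
#'   (`DNAStringSet`, one chromosome `chrS`).
#' @export
simulate_annotation <- function(config = sim_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    n <- cfg$n_genes
    classes <- sample(names(cfg$class_props), n, replace = TRUE,
                      prob = cfg$class_props)
    # zero termination degenerates the sloping class to classic IR
    if (cfg$termination_fraction == 0)
      classes[classes == "sloping"] <- "classic"
    cursor <- cfg$intergenic_gap
    exons_by_gene <- vector("list", n)
    truth <- vector("list", n)
    ipas <- list()
    ids <- sprintf("g%04d", seq_len(n))
    for (g in seq_len(n)) {
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample_range(cfg$exon_count[1], cfg$exon_count[2])
      ex_len <- cfg$exon_length[1] +
        sample.int(cfg$exon_length[2] - cfg$exon_length[1] + 1L, n_ex,
                   replace = TRUE) - 1L
      n_int <- n_ex - 1L
      int_len <- pmax(80L, round(rlnorm(n_int, cfg$intron_meanlog,
                                        cfg$intron_sdlog)))
      cls <- classes[g]
      ri <- NA_integer_
      if (cls != "normal") {
        ml <- if (cls == "sloping") cfg$retained_meanlog_sloping
              else cfg$retained_meanlog_classic
        ri <- if (cls == "sloping") sample_range(1L, min(2L, n_int))
              else sample_range(1L, n_int)
        int_len[ri] <- max(cfg$min_retained_length,
                           round(rlnorm(1, ml, cfg$retained_sdlog)))
      }
      # genomic layout (ascending coordinates); transcriptional order is
      # reversed on the minus strand
      ex_g <- if (strand == "+") ex_len else rev(ex_len)
      int_g <- if (strand == "+") int_len else rev(int_len)
      widths <- integer(2 * n_ex - 1L)
      widths[seq(1, by = 2, length.out = n_ex)] <- ex_g
      if (n_int) widths[seq(2, by = 2, length.out = n_int)] <- int_g
      starts <- cursor + 1L + c(0L, cumsum(widths)[-length(widths)])
      ends <- starts + widths - 1L
      is_ex <- rep(c(TRUE, FALSE), length.out = 2 * n_ex - 1L)
      exons_by_gene[[g]] <- GRanges("chrS",
                                    IRanges(starts[is_ex], ends[is_ex]),
                                    strand = strand, gene_id = ids[g])
      gene_start <- starts[1]; gene_end <- ends[length(ends)]

      # terminal cleavage site for every gene
      term_pos <- if (strand == "+") gene_end else gene_start
      ipas[[length(ipas) + 1L]] <- data.frame(
        gene_id = ids[g], type = "terminal", intron_index = NA_integer_,
        cleavage_pos = term_pos, strand = strand, frac = NA_real_)

      n_ipas <- 0L
      if (cls == "sloping") {
        n_ipas <- sample_range(cfg$ipas_range[1], cfg$ipas_range[2])
        L <- int_len[ri]
        fr <- sort(runif(n_ipas, 0.55, 0.85))
        if (n_ipas > 1 && min(diff(fr)) * L < 60)
          fr <- seq(0.55, 0.85, length.out = n_ipas)
        gi <- if (strand == "+") ri else n_int - ri + 1L  # genomic index
        i_start <- starts[!is_ex][gi]; i_end <- ends[!is_ex][gi]
        pos <- if (strand == "+") i_start + floor(fr * L)
               else i_end - floor(fr * L)
        ipas[[length(ipas) + 1L]] <- data.frame(
          gene_id = ids[g], type = "intronic", intron_index = ri,
          cleavage_pos = pos, strand = strand, frac = fr)
      }
      truth[[g]] <- data.frame(
        gene_id = ids[g], class = cls, strand = strand,
        n_exons = n_ex, mature_length = sum(ex_len),
        retained_intron = ri,
        retained_length = if (is.na(ri)) NA_integer_ else int_len[ri],
        retained_frac1 = if (cls == "sloping")
          sort(ipas[[length(ipas)]]$frac)[1] else NA_real_,
        # per-site capture compounds: more planted sites terminate more
        # transcripts, tying cleavage-site number to slope steepness
        theta = if (cls == "sloping")
          1 - (1 - cfg$termination_fraction)^n_ipas else 0,
        rho = if (cls == "classic") cfg$ir_level else cfg$baseline_ir,
        n_ipas = n_ipas)
      cursor <- gene_end + cfg$intergenic_gap
    }
    names(exons_by_gene) <- ids
    truth <- do.call(rbind, truth)
    ipas <- do.call(rbind, ipas)

    # planted downregulation: IR genes are downregulated in null, a fixed
    # fraction of them more strongly in the neurite compartment
    ir_idx <- which(truth$class != "normal")
    nspec <- ir_idx[sample.int(length(ir_idx),
                               round(cfg$neurite_specific_fraction *
                                       length(ir_idx)))]
    truth$down <- "none"
    truth$down[ir_idx] <- "shared"
    truth$down[nspec] <- "neurite_specific"
    truth$lfc_cellular <- ifelse(truth$down == "none", 0, cfg$down_lfc)
    truth$lfc_neurite <- truth$lfc_cellular +
      ifelse(truth$down == "neurite_specific", cfg$neurite_extra_down, 0)
    # expected IR changes (null - sibling) per compartment
    lvl <- ifelse(truth$class == "sloping", truth$theta,
                  ifelse(truth$class == "classic", truth$rho,
                         cfg$baseline_ir))
    truth$true_delta_ir_neurite <- lvl - cfg$baseline_ir
    truth$true_delta_ir_cellular <- vapply(lvl, eff_level, numeric(1),
                                           compartment = "cellular",
                                           cfg = cfg) - cfg$baseline_ir

    genome_len <- cursor + cfg$intergenic_gap
    genome <- make_pas_free_genome(genome_len)
    # plant hexamers upstream of every cleavage site, then break any motif
    # accidentally created at a plant/flank junction
    dna <- genome[["chrS"]]
    planted_starts <- integer(nrow(ipas))
    for (k in seq_len(nrow(ipas))) {
      p <- ipas$cleavage_pos[k]
      if (ipas$strand[k] == "+") {
        s <- p - cfg$pas_offset
        dna <- replace_subseq(dna, s, "AATAAA")
      } else {
        s <- p + cfg$pas_offset - 5L
        dna <- replace_subseq(dna, s, "TTTATT")  # revcomp(AATAAA)
      }
      planted_starts[k] <- s
    }
    dna <- scrub_except(dna, planted_starts)
    genome <- DNAStringSet(setNames(list(dna), "chrS"))
    models <- reduce_exons(GenomicRanges::GRangesList(exons_by_gene),
                           min_length = 50)
    structure(list(config = cfg, models = models, truth = truth,
                   ipas = ipas, genome = genome),
              class = "ir_annotation")
  })
}

replace_subseq <- function(dna, at, what) {
  subseq(dna, at, at + nchar(what) - 1L) <- DNAString(what)
  dna
}

pas_patterns_both_strands <- function() {
  unique(c(pas_hexamers(),
           vapply(pas_hexamers(), function(h)
             as.character(reverseComplement(DNAString(h))), character(1))))
}

# break every PAS-motif occurrence except the protected (planted) hexamers.
# Repairs are made one occurrence at a time: a substitution is only accepted
# when a local rescan shows it created no new motif, so junction contexts
# where several letters all complete some PAS variant cannot oscillate.
scrub_except <- function(dna, protected_starts) {
  pats <- pas_patterns_both_strands()
  prot <- IRanges(protected_starts, width = 6)
  len <- length(dna)
  scan_occ <- function(d) {
    occ <- integer(0)
    for (p in pats) occ <- c(occ, start(matchPattern(p, d)))
    sort(setdiff(unique(occ), protected_starts))
  }
  repair <- function(d, s) {
    cand <- s:(s + 5L)
    cand <- cand[!overlapsAny(IRanges(cand, width = 1), prot)]
    for (p in cand) for (lett in c("C", "G", "T", "A")) {
      if (as.character(subseq(d, p, p)) == lett) next
      d2 <- Biostrings::replaceLetterAt(d, p, lett)
      lo <- max(1L, p - 5L); hi <- min(len, p + 5L)
      w <- subseq(d2, lo, hi)
      hit <- FALSE
      for (pat in pats) {
        m <- start(matchPattern(pat, w)) + lo - 1L
        if (length(setdiff(m, protected_starts))) { hit <- TRUE; break }
      }
      if (!hit) return(d2)
    }
    Biostrings::replaceLetterAt(d, cand[1], "C")  # last resort
  }
  for (pass in 1:25) {
    occ <- scan_occ(dna)
    if (!length(occ)) break
    last <- -100L
    for (s in occ) {
      if (s - last < 12L) next  # interacting repairs wait for the next pass
      dna <- repair(dna, s)
      last <- s
    }
  }
  dna
}

# random sequence with every PAS hexamer (both strands) scrubbed
make_pas_free_genome <- function(len) {
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  dna <- DNAString(base)
  pats <- pas_patterns_both_strands()
  for (iter in 1:25) {
    hits <- integer(0)
    for (p in pats)
      hits <- c(hits, start(matchPattern(p, dna)))
    if (!length(hits)) break
    at <- unique(hits) + 2L  # break the motif at its third base
    lett <- rep("C", length(at))
    dna <- Biostrings::replaceLetterAt(dna, at, lett)
  }
  DNAStringSet(setNames(list(dna), "chrS"))
}

#' Simulate one sequencing sample from a synthetic annotation
#'
#' Emits per-feature count tables (the deposited-data surrogate): binned
#' exonic read counts, per-intron intronic depth/read/junction counts,
#' per-gene expression counts, 3'-end read positions and CLIP peaks, under
#' the generative model: normal genes have uniform exonic coverage and
#' baseline intronic signal; classic-IR genes (null) retain their designated
#' intron at depth `rho x` exon depth with downstream exons unchanged;
#' sloping genes (null) terminate a fraction `theta` of transcripts at the
#' planted intronic PAS, covering the intron up to the site and depleting
#' downstream exons to `(1 - theta)`; the cellular compartment sees the
#' effect reduced by `neurite_bias`. Counts are Poisson unless
#' `noise = FALSE`, in which case expectations are emitted (rounded for
#' integer quantities).
#'
#' @param ann An `ir_annotation` from [simulate_annotation()].
#' @param condition `"sibling"` or `"null"`.
#' @param compartment `"cellular"` or `"neurite"`.
#' @param replicate Replicate number (labelling only).
#' @param seed Integer seed.
#' @param noise Poisson noise (default TRUE).
#' @return list with `sample_id`, `condition`, `compartment`, `replicate`,
#'   `bin_counts` (gene x bin matrix), `introns` (per-intron data.frame
#'   with `intron_depth`, `intron_reads`, `junction_reads`, `ir_ratio`),
#'   `gene_counts`, `end3` (3'-end positions with counts), `clip`
#'   (`GRanges` peaks) and `library_size`.
#' @export
simulate_reads <- function(ann, condition = c("null", "sibling"),
                           compartment = c("neurite", "cellular"),
                           replicate = 1, seed = 1, noise = TRUE) {
  condition <- match.arg(condition)
  compartment <- match.arg(compartment)
  cfg <- ann$config
  truth <- ann$truth
  with_seed(seed, {
    draw <- function(lambda) if (noise) rpois(length(lambda), lambda)
                             else round(lambda)
    rl <- cfg$read_length
    genes <- truth$gene_id
    nb <- cfg$n_bins
    e <- if (condition == "null") {
      2^(if (compartment == "neurite") truth$lfc_neurite
         else truth$lfc_cellular)
    } else rep(1, nrow(truth))
    # termination level driving the coverage slope
    theta_eff <- ifelse(truth$class == "sloping",
                        if (condition == "null")
                          vapply(truth$theta, eff_level, numeric(1),
                                 compartment = compartment, cfg = cfg)
                        else cfg$baseline_ir,
                        0)
    # retention level of the designated intron
    ret_eff <- ifelse(truth$class == "classic",
                      if (condition == "null")
                        vapply(truth$rho, eff_level, numeric(1),
                               compartment = compartment, cfg = cfg)
                      else cfg$baseline_ir,
                      cfg$baseline_ir)

    # --- binned exonic counts ---
    bin_counts <- matrix(0L, nrow(truth), nb,
                         dimnames = list(genes, paste0("bin_", 1:nb)))
    introns_rec <- intron_records(ann$models)
    for (g in seq_len(nrow(truth))) {
      L <- truth$mature_length[g]
      base <- L %/% nb
      sizes <- base + as.integer(seq_len(nb) <= L %% nb)
      lvl <- rep(1, nb)
      if (truth$class[g] == "sloping") {
        # mature offset of the retained intron = end of its upstream exon
        ex <- ann$models$exons[[truth$gene_id[g]]]
        if (truth$strand[g] == "-") ex <- rev(ex)
        M <- cumsum(width(ex))[truth$retained_intron[g]]
        b_start <- cumsum(c(1L, sizes[-nb]))
        lvl[b_start > M] <- 1 - theta_eff[g]
      }
      bin_counts[g, ] <- draw(cfg$depth * e[g] * sizes / rl * lvl)
    }

    # --- per-intron quantities ---
    ir_lvl <- numeric(nrow(introns_rec))
    len1 <- introns_rec$length  # covered (5') portion of the intron
    for (k in seq_len(nrow(introns_rec))) {
      g <- match(introns_rec$gene_id[k], truth$gene_id)
      retained <- !is.na(truth$retained_intron[g]) &&
        introns_rec$intron_index[k] == truth$retained_intron[g]
      if (retained && truth$class[g] == "sloping") {
        ir_lvl[k] <- theta_eff[g]
        len1[k] <- max(1L, floor(truth$retained_frac1[g] *
                                   introns_rec$length[k]))
      } else if (retained && truth$class[g] == "classic") {
        ir_lvl[k] <- ret_eff[g]
      } else ir_lvl[k] <- cfg$baseline_ir
    }
    gm <- match(introns_rec$gene_id, truth$gene_id)
    K1 <- draw(ir_lvl * cfg$depth * e[gm] * len1 / rl)
    K2 <- draw(cfg$baseline_ir * cfg$depth * e[gm] *
                 (introns_rec$length - len1) / rl)
    D <- K1 * rl / len1
    S <- draw((1 - ir_lvl) * cfg$depth * e[gm])
    introns <- data.frame(introns_rec,
                          intron_depth = D, intron_reads = K1 + K2,
                          junction_reads = S, ir_ratio = ir_ratio(D, S))

    gene_counts <- setNames(
      draw(cfg$depth * e * truth$mature_length / rl), genes)

    # --- 3'-end reads (embryo-level: theta unaffected by compartment) ---
    th3 <- ifelse(truth$class == "sloping",
                  if (condition == "null") truth$theta else cfg$baseline_ir,
                  0)
    end3 <- list()
    for (g in seq_len(nrow(truth))) {
      sites <- ann$ipas[ann$ipas$gene_id == truth$gene_id[g], ]
      d3 <- cfg$threeprime_depth * e[g]
      # per-site usage: the 5'-most site captures first, later sites see
      # what remains (geometric weights summing to the gene-level theta)
      q <- cfg$termination_fraction
      intr <- which(sites$type == "intronic")
      w <- if (length(intr)) q * (1 - q)^(seq_along(intr) - 1) else numeric(0)
      if (length(intr) && th3[g] > 0 && sum(w) > 0)
        w <- w * th3[g] / sum(w)
      for (j in seq_len(nrow(sites))) {
        lam <- if (sites$type[j] == "terminal") (1 - th3[g]) * d3
               else w[match(j, intr)] * d3
        cnt <- draw(lam)
        if (cnt <= 0) next
        if (noise) {
          spread <- rmultinom(1, cnt, c(.05, .2, .5, .2, .05))[, 1]
          pos <- sites$cleavage_pos[j] + (-2:2)
          keep <- spread > 0
          end3[[length(end3) + 1L]] <- data.frame(
            chrom = "chrS", pos = pos[keep], strand = sites$strand[j],
            count = spread[keep], gene_id = truth$gene_id[g],
            true_site = sites$type[j])
        } else {
          end3[[length(end3) + 1L]] <- data.frame(
            chrom = "chrS", pos = sites$cleavage_pos[j],
            strand = sites$strand[j], count = cnt,
            gene_id = truth$gene_id[g], true_site = sites$type[j])
        }
      }
    }
    end3 <- if (length(end3)) do.call(rbind, end3) else
      data.frame(chrom = character(), pos = integer(), strand = character(),
                 count = numeric(), gene_id = character(),
                 true_site = character())

    clip <- simulate_clip_peaks(ann, seed = NULL, noise = noise)

    library_size <- sum(bin_counts) + sum(introns$intron_reads) +
      sum(introns$junction_reads)
    list(sample_id = paste(condition, compartment, replicate, sep = "."),
         condition = condition, compartment = compartment,
         replicate = replicate, bin_counts = bin_counts, introns = introns,
         gene_counts = gene_counts, end3 = end3, clip = clip,
         library_size = library_size)
  })
}

#' Simulate a CLIP peak set over the annotated introns
#'
#' Peak counts per intron are Poisson with rate `clip_rate_retained` per kb
#' for retained introns of IR genes and `clip_rate_control` per kb for all
#' other introns; peaks are placed uniformly within the intron.
#'
#' @param ann An `ir_annotation`.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param noise Poisson peak counts (default TRUE); otherwise rounded
#'   expectations, evenly placed.
#' @return `GRanges` of CLIP peaks.
#' @export
simulate_clip_peaks <- function(ann, seed = 1, noise = TRUE) {
  run <- function() {
    cfg <- ann$config
    introns <- intron_records(ann$models)
    g <- match(introns$gene_id, ann$truth$gene_id)
    retained <- !is.na(ann$truth$retained_intron[g]) &
      introns$intron_index == ann$truth$retained_intron[g]
    rate <- ifelse(retained, cfg$clip_rate_retained, cfg$clip_rate_control)
    lam <- rate * introns$length / 1000
    n <- if (noise) rpois(length(lam), lam) else round(lam)
    out <- list()
    for (k in which(n > 0)) {
      w <- min(cfg$clip_peak_width, introns$length[k])
      smax <- introns$end[k] - w + 1L
      st <- if (noise) introns$start[k] +
              sample.int(smax - introns$start[k] + 1L, n[k],
                         replace = TRUE) - 1L
            else round(seq(introns$start[k], smax,
                           length.out = n[k] + 2))[-c(1, n[k] + 2)]
      out[[length(out) + 1L]] <- GRanges(introns$chrom[k],
                                         IRanges(st, width = w),
                                         strand = introns$strand[k])
    }
    if (length(out)) do.call(c, out) else GRanges()
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate the full compartment experiment
#'
#' Generates the annotation plus 3 replicates x \{sibling, null\} x
#' \{cellular, neurite\} samples, merges replicates per condition and
#' compartment (summed counts, as done before comparative analysis), and
#' attaches a single CLIP peak set.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param noise Poisson noise (default TRUE).
#' @return Object of class `ir_experiment`: list with `config`,
#'   `annotation`, `truth`, `samples` (list of 12), `merged` (list keyed
#'   `condition.compartment`) and `clip`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1,
                                noise = TRUE) {
  ann <- simulate_annotation(config, seed)
  base <- (seed %% 20000000L) * 100L
  samples <- list()
  idx <- 0L
  for (cond in c("sibling", "null"))
    for (comp in c("cellular", "neurite"))
      for (r in 1:3) {
        idx <- idx + 1L
        s <- simulate_reads(ann, cond, comp, r, seed = base + idx,
                            noise = noise)
        samples[[s$sample_id]] <- s
      }
  merged <- list()
  for (cond in c("sibling", "null"))
    for (comp in c("cellular", "neurite")) {
      reps <- samples[grepl(paste0("^", cond, "\\.", comp, "\\."),
                            names(samples))]
      m <- reps[[1]]
      m$replicate <- NA_integer_
      m$sample_id <- paste(cond, comp, sep = ".")
      m$bin_counts <- Reduce(`+`, lapply(reps, `[[`, "bin_counts"))
      m$gene_counts <- Reduce(`+`, lapply(reps, `[[`, "gene_counts"))
      for (col in c("intron_depth", "intron_reads", "junction_reads"))
        m$introns[[col]] <- Reduce(`+`, lapply(reps, function(s)
          s$introns[[col]]))
      m$introns$ir_ratio <- ir_ratio(m$introns$intron_depth,
                                     m$introns$junction_reads)
      e3 <- do.call(rbind, lapply(reps, `[[`, "end3"))
      m$end3 <- if (nrow(e3)) stats::aggregate(
        count ~ chrom + pos + strand + gene_id + true_site, e3, sum) else e3
      m$library_size <- sum(vapply(reps, `[[`, numeric(1), "library_size"))
      merged[[m$sample_id]] <- m
    }
  clip <- simulate_clip_peaks(ann, seed = base + 50L, noise = noise)
  structure(list(config = config, annotation = ann, truth = ann$truth,
                 samples = samples, merged = merged, clip = clip),
            class = "ir_experiment")
}

#' @export
print.ir_experiment <- function(x, ...) {
  cat(sprintf("ir_experiment: %d genes (%s), %d samples\n",
              nrow(x$truth),
              paste(names(table(x$truth$class)),
                    table(x$truth$class), sep = "=", collapse = ", "),
              length(x$samples)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits GTF + FASTA for the annotation, per-sample TSV count tables, 3'-end
#' BED-like TSVs, a CLIP BED, the truth table, and a manifest listing every
#' artifact with its md5 checksum.
#'
#' @param exp An `ir_experiment`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  gtf <- file.path(dir, "annotation.gtf")
  ex <- unlist(exp$annotation$models$exons)
  ex$gene_id <- rep(names(exp$annotation$models$exons),
                    lengths(exp$annotation$models$exons))
  ex$type <- "exon"
  ex$source <- "pretir_sim"
  rtracklayer::export(ex, gtf, format = "gtf")
  paths <- c(paths, gtf)
  fa <- file.path(dir, "genome.fa")
  writeXStringSet(exp$annotation$genome, fa)
  paths <- c(paths, fa)
  tr <- file.path(dir, "truth.tsv")
  write.table(exp$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tr)
  for (id in names(exp$merged)) {
    s <- exp$merged[[id]]
    p1 <- file.path(dir, paste0(id, ".bins.tsv"))
    write_feature_counts(feature_counts(s$bin_counts), p1)
    p2 <- file.path(dir, paste0(id, ".introns.tsv"))
    write.table(s$introns, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    p3 <- file.path(dir, paste0(id, ".end3.tsv"))
    write.table(s$end3, p3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p1, p2, p3)
  }
  cb <- file.path(dir, "clip_peaks.bed")
  rtracklayer::export(exp$clip, cb, format = "bed")
  paths <- c(paths, cb)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
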