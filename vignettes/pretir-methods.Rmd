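---
title: "Detecting intron retention and premature termination with pretir"
author: "pretir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intron retention and premature termination with pretir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pretir` analyses compartment-resolved RNA-seq (neurite versus cellular
fractions of cultured neurons) for two related splicing pathologies that
arise when SFPQ is lost: **intron retention** (IR), where a spliced mRNA
keeps an intron, and **premature termination within a retained intron**
(PreT-IR), where Pol-II drop-off plus intronic cleavage/polyadenylation
produces a stable, truncated, polyadenylated mRNA. This vignette documents
the models, the tunable parameters and their defaults, the synthetic data
the package validates itself against, and the numerical and design choices
a maintainer should know about.

## Gene models and binning

All isoforms of a gene are collapsed to a union-exon model
(`reduce_exons()`): exons are the interval union, introns the gaps between
adjacent union exons, and genes with a mature (spliced) length under 50 nt
are dropped. Internally everything lives in `GRanges` (1-based, closed),
the Bioconductor convention; BED input/output converts coordinate systems
through `rtracklayer`, so files on disk are standard 0-based half-open
BED6.

`bin_genes()` partitions each gene's mature sequence into `n_bins = 50`
ordered features: base size `floor(L/50)`, with the `L mod 50`
transcriptionally 5'-most bins one nucleotide larger. Putting the
remainder at the 5' end is a deterministic choice that leaves the 3' end —
the end diagnostic for termination — unaffected by the off-by-one. Bin 1
is always transcriptionally 5', so on minus-strand genes it occupies the
highest genomic coordinates.

We do not restrict the gene set by biotype before binning: the functions
operate on whatever gene set the caller supplies, and subsetting the input
`GRangesList` is the supported way to apply a biotype (or any other)
filter. Overlapping genes are not masked from each other at the binning
stage; exon masking is applied where it matters statistically, in the
intronic depth computation.

## The coverage-slope model

Reads are counted per bin with coverageBed semantics — a read increments
every bin it overlaps by at least 1 nt (`count_features()`); replicates
are merged (summed) before analysis, and genes with fewer than 50 distinct
reads are excluded. Counts are normalised to relative coverage with mean
one,

$$c_i = \frac{n \, r_i}{\sum_j r_j}, \qquad i = 1 \dots n = 50,$$

and regressed on the bin index by ordinary least squares. The slope $m$ of
a uniformly covered transcript is 0; loss of downstream exons makes it
negative. The mean-one normalisation (rather than sum-one) keeps slopes on
a scale where the strict threshold $m < -0.1$ used for the
high-confidence sloping subset is attainable; with sum-one normalisation
every slope would be bounded far inside $\pm 0.1/50$. We regress coverage
on bin index — the only direction in which the "slope" of a coverage
profile is meaningful — and report the two-sided t-test of $m = 0$ on
$n - 2$ degrees of freedom.

Degenerate inputs are handled by convention: an all-equal profile returns
$m = 0$, $p = 1$; an exactly linear profile has zero residual variance and
returns $p = 0$; an all-zero gene returns missing values. `delta.slope` is
the difference $m_\text{null} - m_\text{sibling}$ (a ratio mode exists
behind a flag, but the difference is what the name promises and what the
classifier uses).

`classify_ir_genes()` BH-adjusts the null-condition slope p-values within
the IR gene set and labels a gene *sloping* when $q < 0.05$,
$m_\text{null} < 0$ and `delta.slope` $< 0$; otherwise *classic*; genes
removed by the read filter stay *unclassified*.

One subtlety worth knowing: in **noiseless** simulations the ±1 nt
bin-size remainder produces a minuscule, perfectly systematic 5' excess,
so residuals are near zero and even a trivial slope becomes "significant".
With any realistic counting noise this vanishes (flat genes show the
nominal ~5% false-positive rate before FDR correction). Noiseless mode is
therefore used to verify bookkeeping (positions, offsets, usage sums),
never classification.

## Intron retention and the Audic–Claverie test

For each intron, intronic abundance $D$ is the median per-base read depth
over intron bases that overlap no exon of any gene, and spliced abundance
$S$ is the count of junction reads matching the intron boundaries exactly.
The IR ratio is

$$\mathrm{IR} = \frac{D}{D + S} \in [0, 1],$$

the fraction of the gene's transcripts retaining the intron. Differential
retention between genotypes requires $|\Delta \mathrm{IR}| > 0.1$
(strict inequality; ties at exactly 0.1 are excluded) and an
Audic–Claverie p below 0.05. An increase is **neurite-specific** when the
neurite $\Delta \mathrm{IR}$ exceeds the cellular one by more than 0.05.

The Audic–Claverie statistic compares two counts $x, y$ from libraries of
sizes $N_1, N_2$ through the posterior predictive

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$

which is negative binomial with size $x + 1$ and success probability
$N_1/(N_1+N_2)$; tails are evaluated in log-gamma space via `pnbinom`.
The two-sided p-value is $\min(1, 2\min(P(Y \le y), P(Y \ge y)))$. For a
discrete statistic the two conditioning directions give slightly different
tails, so we symmetrise by taking the minimum over the two orientations;
the test is then exactly invariant under swapping the libraries, and its
type-I error under a paired Poisson null is verified by the test suite to
sit at the nominal 5% (the calibration uses Poisson rate 50, a typical
unmasked intronic read count at the default simulated depth). Counts fed
to the test are the integer-rounded unmasked intronic read counts with
total mapped reads as library sizes, matching the test's tag-count
formulation. We deliberately do not re-create IRFinder: the downstream
thresholds operate on IR ratio and ΔIR, which the $D/(D+S)$ definition
provides directly.

## Cohort statistics on retained introns

`length_bias_test()` and `position_bias()` compare retained introns
against either all annotated introns (genome-wide bias) or the
non-retained introns of the same genes (within-gene contrasts), by
two-sided Wilcoxon rank-sum tests; `stats::wilcox.test` picks the exact
method at small n. Positional bias uses the intron-index fraction
(index / intron count) by default; a nucleotide-distance fraction can be
supplied via the `scale = "nucleotide"` column contract — the paper-scale
datasets we emulate do not distinguish the two materially.

## CLIP peak density

Binding is scored as peaks per kilobase of intron (`peak_density()`); a
peak counts toward every intron it overlaps by ≥ 1 nt. Peaks are counted,
not coverage-weighted (a weighted mode exists), because only the rank-sum
contrast between retained and control introns is interpreted and that
contrast is invariant to the per-kb versus per-nt scaling.

## Intronic polyadenylation

3'-end read positions are clustered per chromosome and strand by
single-linkage with a 25 nt radius; a cluster's position is its modal end
(5'-most on ties), and clusters under 5 reads are dropped. Both values are
defaults in `cluster_3p_ends()` — 25 nt reflects the positional wobble of
cleavage around a single PAS, and 5 reads is a floor against stray
priming. `annotate_pas()` scans a strand-aware window 10–40 nt upstream of
the cleavage position — the canonical spacing between the poly(A) signal
and the cleavage site — for the 12-hexamer PAS set (AATAAA first, then the
reported variants); set order is priority, and among hits of the same
hexamer the closest wins. Unsupported clusters are kept but flagged.
Usage efficiency is each cluster's read share within its gene, so per-gene
efficiencies sum to one exactly.

`intronic_cluster_stats()` correlates the coverage slope with the number
of PAS-supported clusters inside the retained intron across all classified
IR genes; classic genes anchor the correlation near $(m \approx 0,\ 0)$
and more heavily terminated sloping genes carry both steeper slopes and
more used sites, giving the expected negative r.

## Expression filters

TPM is computed from counts and mature lengths; genes with mean sibling
neurite TPM below 20 are removed (strict less-than: a gene at exactly 20
is retained). Log2 fold changes are taken from library-size-normalised
mean counts with a +0.5 pseudocount — dispersion modelling and GLM testing
are intentionally out of scope, since the rules downstream consume only
the fold-change point estimates. A downregulated gene is neurite-specific
when log2FC(neurite) − log2FC(cellular) < −0.2 with both negative. In the
pipeline report the "downregulated" set is genes with neurite log2FC below
−0.5, a conservative point-estimate cut chosen because the planted effect
sizes (−0.8 and below) separate cleanly from the Poisson noise floor at
the simulated depths.

## The synthetic-data generator

`simulate_experiment()` emulates the full design: 3 replicates ×
{sibling, null} × {cellular, neurite}, a synthetic chromosome with
union-exon genes, and a truth table for every planted effect. The
generative model per gene class:

* **normal** — uniform exonic coverage; introns at the baseline retention
  `baseline_ir` (ρ₀ = 0.02, reflecting the low-level retention real
  sibling samples show).
* **classic IR** — in the null, the designated intron is retained in a
  fraction `ir_level` (ρ = 0.2) of transcripts: intronic depth ρ·d,
  junctions (1−ρ)·d, downstream exons unchanged. The default echoes the
  reported cohort medians (IR ratio ≈ 0.2, ΔIR ≈ 0.18 over baseline).
* **sloping / PreT-IR** — 1–3 PAS hexamers with cleavage sites are planted
  at 55–85% of a long (≥ 1.5 kb, log-normal median 5 kb) 5'-proximal
  intron. Each site captures a fraction `termination_fraction` (0.8) of
  the transcripts that reach it, so a gene with k sites terminates
  1 − 0.2ᵏ of its transcripts — tying cleavage-site number to slope
  steepness, as the slope/cleavage-count correlation requires. The intron
  is covered up to the first site at θ·d; downstream exons drop to
  (1−θ)·d; 3'-end reads are placed at the planted sites with geometric
  (5'-first) weights and at the annotated terminus with the remainder.

The cellular compartment sees every retention/termination effect reduced
by `neurite_bias` (0.15), floored at baseline — equivalently, neurite
samples get the extra ΔIR. IR genes are downregulated in the null
(log2FC −0.8), and 31% of them additionally by −0.6 in neurites only,
mirroring the reported fraction of neurite-specific downregulation. CLIP
peaks fall on introns as a Poisson process at 1.5/kb (retained) versus
0.5/kb (control), the 3× contrast the density test is specified against.
Class proportions default to 50% normal / 15.5% classic / 34.5% sloping,
i.e. 31% / 69% within the IR set. Sequencing depth defaults to 100×
exonic coverage with 50 nt reads; 3'-end depth is 300 reads per gene so
that even the least-used planted site of a strongly downregulated gene
stays above the cluster floor. All counts are Poisson (`noise = FALSE`
switches to rounded expectations), and every draw is seeded: identical
seeds give byte-identical outputs, which `write_experiment()` checks via
a checksummed manifest.

The genome sequence is scrubbed of all 12 PAS hexamers and their reverse
complements before the signals are planted, and junction contexts where a
planted motif would accidentally complete a second variant are repaired
with locally verified substitutions — so every hexamer in the genome is a
planted one, and motif recovery can be asserted exactly.

What the generator does **not** emulate: sequencing error, fragment-length
and GC biases, read-level overdispersion beyond Poisson, isoform
complexity (alternative first/last exons, cassette exons), multimapping,
and incomplete annotation. Passing tests therefore demonstrate the
statistical machinery — thresholds, tests, recovery of planted effects at
realistic depths — not robustness to alignment artefacts or biological
overdispersion; on real data the Poisson-calibrated p-values will be
anti-conservative in proportion to the extra-Poisson variance.

## Problem sizes and runtime

The test suite and the acceptance script run on cohorts of 30–500 genes
(most commonly 100–200) at 100× depth — sizes chosen so the planted
proportions are estimated to within a few percentage points while a full
run stays in the minutes range on one CPU. The end-to-end pipeline on the
default 100-gene cohort takes under a minute.

## Known limitations

* The IR quantification is a deliberate simplification of IRFinder: no
  mappability correction, no trimming of repetitive intron segments
  beyond exon masking.
* Library sizes for the Audic–Claverie test are total mapped reads of the
  merged samples; spike-in or TMM-style normalisation is not applied.
* `run_pipeline()` consumes the generator's count-table representation;
  for BAM-backed data the module functions (`count_features()`,
  `quantify_ir()`, `cluster_3p_ends()`) accept interval objects directly
  and the orchestration is a few lines of glue, but a BAM-to-report
  one-liner is not provided.
* Differential-expression significance (GLM dispersion modelling) is out
  of scope by design; the expression module implements the filters and
  the compartment rule only.
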