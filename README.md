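# pretir

Detection of intron-retaining (IR) and prematurely terminated
intron-retaining (PreT-IR) transcripts from compartment-resolved RNA-seq.

## The problem

When the splicing factor SFPQ is lost from developing neurons, aberrant
transcripts that retain long, SFPQ-bound introns accumulate specifically in
neurites (axons and dendrites). A large fraction of these IR mRNAs are not
full-length: elongating Pol-II drops off inside the retained intron, the
truncated pre-mRNA is cleaved and polyadenylated at an intronic
polyadenylation site (iPAS), and the resulting PreT-IR mRNA is exported and
transported into neurites. `pretir` is for transcriptomics researchers who
want to detect and classify these events from a compartmentalised
(neurite vs cellular) RNA-seq design, 3'-end sequencing and CLIP peak data
— in this disease model or any comparable system.

## The methods at its core

- **Union-exon gene models and 50-feature binning.** All isoforms of a gene
  are reduced to a single spliced model (genes < 50 bp are dropped), and
  each gene's mature sequence is partitioned into 50 ordered bins,
  transcriptionally 5'→3'.
- **Coverage-slope regression.** Per-bin read counts *r*ᵢ (genes with < 50
  reads are excluded) are normalised to relative coverage
  *c*ᵢ = 50·*r*ᵢ/Σ*r* and regressed on bin index by OLS. The slope *m* of a
  full-length transcript is ≈ 0; premature termination depletes 3' bins and
  gives *m* < 0. `delta.slope = m(null) − m(sibling)` contrasts genotypes,
  and IR genes are classified **classic** (full-length) versus **sloping**
  (PreT-IR) at BH-FDR < 0.05, with a strict subset at *m* < −0.1.
- **IR quantification.** Per intron, IR ratio = D/(D + S), where D is the
  median exon-masked intronic read depth and S the exact splice-junction
  count. Differential retention requires |ΔIR| > 0.1 with an
  **Audic–Claverie** exact count test p < 0.05; an increase is
  neurite-specific when the neurite ΔIR exceeds the cellular ΔIR by > 0.05.
- **iPAS calling.** Strand-aware 3'-end read clusters (single-linkage,
  25 nt, ≥ 5 reads) are annotated by scanning 10–40 nt upstream for the
  canonical PAS hexamer AATAAA and its 11 reported variants; per-gene
  cleavage-site usage efficiencies sum to one.
- **CLIP peak density.** SFPQ binding per intron is scored as peaks per kb
  and contrasted between retained and control introns (Mann–Whitney).
- **Expression filters.** Genes < 20 TPM in sibling neurites are removed;
  a downregulated gene is neurite-specific when
  log2FC(neurite) − log2FC(cellular) < −0.2 with both negative.

A synthetic-data generator (`simulate_experiment()`) emulates the whole
design — 3 replicates × {sibling, null} × {cellular, neurite} with planted
normal / classic-IR / PreT-IR genes, intronic PAS hexamers, 3'-end reads
and CLIP peaks — so every stage can be validated against known truth.

## Worked example

```r
library(pretir)

exp <- simulate_experiment(sim_config(n_genes = 60), seed = 12)
print(exp)
#> ir_experiment: 60 genes (classic=6, normal=32, sloping=22), 12 samples

report <- run_pipeline(exp)
print(report)
#> IR / PreT-IR pipeline report
#>   genes: 60, introns tested: 367
#>   IR increases: 28 (100.0% neurite-specific), decreases: 0
#>   median IR ratio (null) 0.902, median delta IR 0.882
#>   IR gene classes: 21.4% classic / 78.6% sloping

head(report$classification$labels, 4)
#>   gene_id        m_null   delta_slope            q   class strict_sloping
#> 1   g0002 -0.0793291386 -0.0771770730 1.089507e-09 sloping          FALSE
#> 2   g0003  0.0006857178  0.0008663566 5.693230e-01 classic          FALSE
#> 3   g0008 -0.0438056564 -0.0422245793 5.019216e-08 sloping          FALSE
#> 4   g0012 -0.0773580020 -0.0747031698 3.587250e-07 sloping          FALSE
```

Reading the output: 28 of 367 introns are called as retention increases in
null neurites — exactly the planted IR genes of this cohort — and all of
them pass the neurite-specificity margin. Gene `g0002` slopes downwards
(*m* = −0.079, FDR ≈ 1e-9): a PreT-IR candidate; `g0003` is flat and stays
classic. The cohort medians are high here because this simulated cohort is
dominated by strongly terminated sloping genes.

`run_pipeline(exp, outdir = "results")` additionally writes per-stage TSV
tables (`slopes.tsv`, `ir_results.tsv`, `ir_classes.tsv`, …) and a
`report.json`.

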