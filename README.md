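# kisflux

Quantitative analysis of **mRNA buffering** — the reciprocal coupling of
mRNA synthesis and decay that keeps steady-state mRNA levels constant —
for transcriptomics of budding yeast, built around the kinetics of
nucleocytoplasmic shuttling of the major 5'→3' exonuclease.

The package is for computational biologists who work with genomic run-on
(GRO) style measurements, transcription-shutoff decay courses, RIP-seq
style read data or spike-in-normalized count tables, and who want the
whole inference chain — from raw signals to classified, binned gene sets
— as tested, seedable R functions.

## What it computes

At steady state `dM/dt = TR − kd·M = 0`, so the half-life in arbitrary
units is `HL = RA / TR` per gene (RA = mRNA abundance, TR =
transcription rate). Comparing an import-blocked mutant to wild type,
each gene gets a **Kis value**

```
Kis = HL_mut/HL_wt + TR_wt/TR_mut
```

— the sum of its stabilization fold-change and its inverse synthesis
fold-change. Genes with both terms ≥ 2 are classified import-sensitive
("Kis") mRNAs; genes are ranked by Kis value into equal-size bins
(bin 1 = most affected) and summarized by per-bin log2 medians.
Buffering is tested by comparing RA distributions (Wilcoxon rank-sum)
and by the Pearson correlation of the two log2 defect vectors.

Around this core: geometric-mean replicate aggregation and cell-volume
normalization for GRO samples; reference-normalized log-linear decay
fitting (`HL = ln2/|slope|`); strict `>15` trailing-adenine poly(A)
read filtering, inclusive ±250 bp polyadenylation-site window counting,
replicate summation and RPKM; spike-in count normalization; closed-form
single-gene response dynamics (`dM/dt = TR(t) − kd·M`); and a seeded
synthetic-data generator implementing a two-pathway decay model
(classical + import-sensitive, with an exosome backup) under tunable
buffering, so every stage is testable against ground truth.

## A worked example

```r
library(kisflux)

res <- runPipeline(runConfig(list(n_genes = 1000, seed = 42)))
res$report$counts
#> $hl_affected  695
#> $tr_affected  706
#> $kis          648
res$report$median_hl_ratio
#> [1] 2.490803
res$report$buffering$p_value
#> [1] 0.9960147
res$bin_summary
#>   bin n_genes    median       q25       q75
#> 1   1     167 2.2635739 2.0932414 2.5296784
#> 2   2     167 1.7720628 1.6802626 1.8751312
#> 3   3     167 1.4479410 1.3363952 1.5384583
#> 4   4     167 1.2192144 1.1041365 1.2855953
#> 5   5     166 0.9052175 0.7881075 0.9872863
#> 6   6     166 0.4415772 0.2742503 0.5982084
```

Reading the output: of 1000 simulated genes, 648 have both synthesis
and decay affected ≥ 2-fold (the Kis set), the median stabilization is
2.49-fold while the rank-sum test finds no abundance shift (p = 0.996)
— synthesis and decay moved together, abundance did not — and the
per-bin medians of log2 HL ratios fall monotonically from the most
affected bin (2.26, ~4.8-fold) to the least (0.44, ~1.4-fold).

Individual stages are plain functions: `generateTruth()`,
`applyCondition()`, `simulateGro()`, `groKinetics()`,
`computeKisValues()`, `classifyKis()`, `assignBins()`, `binSummary()`,
`fitDecayCurve()`, `filterPolyaReads()`, `countNearPolya()`, `rpkm()`,
`spikeNormalize()`, `simulateResponse()`. See the methods vignette
(`vignettes/kisflux-methods.Rmd`) for the model, parameter defaults and
numerical conventions.

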