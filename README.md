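# ecmatlas

Quantitative mapping of extracellular matrix (ECM) specialization in the
mouse hair follicle. The package implements the analysis workflow that turns
sorted-population RNA-seq and regional immunofluorescence into an ECM atlas:
which ECM genes each epithelial and dermal compartment expresses, which
tissue (epithelium or dermis) supplies each basement-membrane (BM) protein,
which region-specific ECM programs exist, and where the corresponding
proteins are actually deposited along the follicle's BM.

It is written for skin and ECM biologists who have (or simulate) the study's
data structure: a gene-by-sample count table over seven sorted populations —
five epithelial (Basal/IFE, lower isthmus LI, upper bulge UB, mid-bulge MB,
hair germ HG) and two dermal (dermal papilla DP, pan-dermal fibroblasts
pan-DF) — plus per-protein intensity measurements over six BM zones (IFE,
LI, UB, MB, lateral HG, HG–DP interface).

## What it computes

- **Matrisome catalogue** — 281 ECM genes partitioned into 67 BM and 214
  interstitial genes, the gene universe for every gene-set-restricted step.
  The packaged fixture transcribes the genes named in the primary literature
  and reconstructs the remaining membership from the mouse core-matrisome
  annotation (flagged per row; see `?matrisome_path`).
- **Expression core** — median-of-ratios size factors
  (`f_s = median_g(k_gs / (prod_s k_gs)^{1/S})` over genes positive in every
  sample), `log2(x + 1)` transformation and per-gene z-scores.
- **Differential expression** — negative-binomial tests with
  `Var(K) = mu + alpha mu^2`: a two-group Wald z on
  `log2((mean_A + 1)/(mean_B + 1))` with delta-method standard errors, and a
  multi-group likelihood-ratio chi-square with closed-form group means;
  Benjamini–Hochberg adjustment; origin calling
  (`padj < 0.05` and fold change `> 4` toward Basal or pan-DF).
- **Correlation profiling** — sample-pairwise Spearman rho on five gene
  sets (all / matrisome / non-matrisome / BM / interstitial) with
  mean ± SD summaries per population pair.
- **Epi-groups** — LRT-significant (`padj < 0.001`) matrisome genes,
  hierarchically clustered and cut to K = 10 groups; each group's
  "relatively high expression" regions labeled by the exact 1-D two-means
  partition of the five per-region mean z-scores.
- **GSEA** — weighted running-sum enrichment scores on a DP vs pan-DF
  signal-to-noise ranking with gene-set permutation nulls
  (NES, nominal p, FDR q; significant at FDR < 25% and p < 5%).
- **Deposition atlas** — background-subtracted zone intensities from
  labeled images, percent-of-max normalization (peak zone = 100), Friedman +
  pairwise Wilcoxon/Bonferroni region enrichment, mRNA–protein concordance
  (consistent iff shared peak zone and Pearson `r > 0.5`), and morphometry
  helpers (hemidesmosome density per µm, 3-D DP volumes, pigmented-area
  fractions).
- **Synthetic data** — a seeded generator planting region-specific NB
  programs, matched six-zone deposition profiles with controllable
  discordance, and labeled images, with machine-readable ground truth.
- **Pipeline** — `run_pipeline()` chains every stage behind one validated
  (YAML-able) config and writes deterministic TSV/JSON outputs plus a
  manifest; `inst/scripts/ecmatlas.R` is a thin shell wrapper.

## Worked example

Simulate the study design (7 populations × 3 replicates, ten planted
12-gene ECM programs with log2 effect 3), discover epi-groups, and score
recovery against the planted truth:

```r
library(ecmatlas)

sim <- simulate_counts(sim_config(seed = 42))
epi <- epigroups(sim$counts, sim$samples, sim$catalogue, k = 10)
epi
#> <ecm_epigroups> 120 genes in 10 groups (padj < 0.001)
#>  group  pattern  n
#>      1    HG+MB 12
#>      2 Basal+MB 12
#>      3    LI+UB 12
#>      4    Basal 12
#>      5       UB 12
#>      6    MB+UB 12
#>      7 Basal+LI 12
#>      8       LI 12
#>      9       HG 12
#>     10       MB 12

recovery_score(epi, sim$truth)
#> # A tibble: 1 × 4
#>     ari label_accuracy n_truth n_recovered
#>   <dbl>          <dbl>   <int>       <int>
#> 1     1              1     120         120
```

Every planted program is recovered as its own epi-group (adjusted Rand
index 1) and every group is labeled with exactly the planted high-expression
regions (`pattern` column; label accuracy 1). Testing the planted HG∩DP
shared program on the DP vs pan-DF ranking:

```r
nm <- normalize_counts(sim$counts)
ranked <- rank_signal_to_noise(nm, sim$samples, "DP", "panDF")
run_gsea(ranked, list(shared_hg_dp = sim$truth$gene[sim$truth$program == 5]),
         n_perm = 500, seed = 1)
#> <ecm_gsea> 1 set(s), 500 permutations (gene-set mode)
#>           set size es  nes p_value fdr_q significant
#>  shared_hg_dp   12  1 2.46       0     0        TRUE
```

The shared program concentrates at the very top of the DP ranking
(enrichment score 1) and is significant under both the nominal-p and FDR
criteria. `autoplot()` draws the running-sum curve, the correlation
heatmaps and the epi-group region map; `tidy()`/`glance()` return the
result tables.

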