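# matridrg

Matrisome expression profiling of dorsal root ganglia (DRG).

The extracellular matrix of a tissue is described *in silico* by the
**matrisome**: a curated gene universe split into a *core* division
(glycoproteins, collagens, proteoglycans) and a *matrisome-associated*
division (ECM-affiliated proteins, ECM regulators, secreted factors).
`matridrg` implements a complete, tested analysis pipeline for asking which
matrisome genes a DRG expresses, which cell populations express them, and
how that changes between species and between pain states:

- **Catalog bookkeeping** — load and validate a matrisome catalog
  (category/division partition enforced), resolve measured symbols through
  aliases, and translate gene sets between human and mouse through a
  many-to-many ortholog map.
- **Data-adaptive expression cutoff** — the TPM threshold is derived from
  the data as the mean TPM of genes detected in exactly one sample
  (genes at the detection boundary), and genes are called expressed when
  they strictly exceed it, per sample or on the cohort mean:

  $$c = \operatorname{mean}\{x_{g,s} : x_{g,s} > 0,\; |\{s': x_{g,s'} > 0\}| = 1\},
  \qquad \text{expressed}(g,s) \iff x_{g,s} > c .$$

- **Category profiles and species comparison** — per-sample percentages of
  expressed genes per category/division (mean ± SEM across samples,
  unpaired two-tailed *t*-test between divisions), mean-TPM rankings, and
  cross-species overlap of expressed and top-ranked gene sets via
  orthologs.
- **Spatial marker co-expression** — per spatial sample (two serial
  sections pooled), a barcode is *positive* for a gene when its
  scaled-and-normalised expression strictly exceeds the first quartile of
  the gene's positive values. For a gene *g* and marker *M* (nociceptors:
  *SCN10A*; fibroblast-like/VLMC-like cells: *DCN*), with *D* the
  double-marker barcodes,

  $$r(g, M) = \frac{|\,\mathrm{pos}(g) \cap \mathrm{pos}(M) \setminus D\,|}
                   {|\,\mathrm{pos}(M) \setminus D\,|},$$

  and the paired per-sample ratios against the two markers are compared
  with an **exact Wilcoxon matched-pairs signed-rank test** (full
  sign-assignment null distribution, midranks for ties, zeros dropped).
- **Differential-expression overlay** — intersect per-condition
  upregulated-gene lists (male/female × pain/no-pain) with the catalog,
  find multi-condition genes, and rebuild a Table-1-style report of DEGs
  grouped by their preferred marker with pass-through interaction partners.
- **Per-cell dot quantification** — RNAscope-style calling (positive at
  ≥ 2 dots per probe), image → sample → cohort aggregation with SEM across
  donors.
- **Synthetic data** — deterministic generators for every input (catalog
  with aliases/orthologs, log-normal TPM with planted singleton genes,
  spatial barcodes with planted fibroblast-like and nociceptor-like
  populations, Poisson dot counts), with ground truth returned so recovery
  is testable end to end.

## Worked example

Everything runs on synthetic cohorts shaped like the real study (1,110-gene
murine catalog, 11 bulk samples, 9 spatial samples × 2 sections):

```r
library(matridrg)

sim <- simulate_catalog(seed = 1)            # murine category sizes
tp  <- simulate_tpm(sim$catalog, seed = 1)   # 11 samples, 80% planted expressed

cutoff <- derive_cutoff(tp$tpm, restrict_to = sim$catalog$symbol)
cutoff
#> [1] 0.101

calls <- call_expressed(tp$tpm, cutoff, "per-sample")
prof  <- category_percentages(calls, sim$catalog,
                              resolve_symbols(sim$catalog, tp$tpm$symbol))
tidy(prof)
#> # A tibble: 9 × 6
#>   level    group                mean_pct sem_pct n_samples n_genes
#>   <chr>    <chr>                   <dbl>   <dbl>     <int>   <int>
#> 1 category ECM-affiliated           79.2  0.218         11     165
#> 2 category ECM-regulators           79.1  0.143         11     304
#> 3 category collagens                78.7  0.633         11      44
#> 4 category glycoproteins            79.4  0.162         11     194
#> 5 category proteoglycans            80.1  0.505         11      36
#> 6 category secreted-factors         79.5  0.111         11     367
#> 7 division core-matrisome           79.4  0.134         11     274
#> 8 division matrisome-associated     79.3  0.0757        11     836
#> 9 overall  overall                  79.3  0.0587        11    1110
```

The derived cutoff lands on the planted singleton scale (TPM ≈ 0.1) and the
per-category percentages recover the planted 80% expressed fraction (the
≈ 0.8-point shortfall is the planted 1% dropout). On spatial data, a
collagen-like gene planted in the fibroblast-like population prefers *DCN*,
a receptor-like gene prefers *SCN10A*, and a neutral gene shows no
significant preference:

```r
sp  <- simulate_spatial(seed = 1)
res <- run_coexpression(sp$samples, c("COL1A1", "CD44", "NTRL1"))
#>   gene   mean_ratio_a mean_ratio_b     W p_value preference
#> 1 COL1A1        0.149        0.339     0 0.00391 DCN
#> 2 CD44          0.323        0.137    45 0.00391 SCN10A
#> 3 NTRL1         0.146        0.152    21 0.910   DCN
```

`ratio_a` is co-expression with *SCN10A*, `ratio_b` with *DCN*;
`p = 0.0039 = 2/2⁹` is the exact two-sided floor for 9 concordant samples.
`autoplot()` methods produce the matching figures for profiles,
co-expression results and cell summaries.

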