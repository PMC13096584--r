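# liverspatial

Spatial zonation and immune colocalization analysis for the aging liver.

Liver tissue is zonated along the lobule axis from the central vein (CV,
pericentral) to the portal vein (PV, periportal). `liverspatial` is an R
package for asking where immune populations — in particular exhausted CD8+
T cells (Tex; *Pdcd1*, *Lag3*, *Tigit*, *Tox*, *Havcr2*, *Cxcl13*) — sit
along that axis, whether they expand in aged versus young livers, and which
cell types they spatially co-occur with. It works on spot-level spatial
transcriptomics counts, externally produced spot × cell-type abundance
matrices (any deconvolution tool), and two-group single-cell data.

## Methods at a glance

- **Signature (module) scores** — mean expression of a gene set minus the
  mean of expression-matched control genes drawn from average-expression
  bins (`nbins = 24`, `nctrl = 100`), seeded and exactly zero on
  constant input.
- **Zonation layers** — per-spot region score = CV signature score − PV
  signature score; within each sample, spots are sorted by descending score
  and split into nine equal-count layers (1–3 CV, 4–6 intermediate, 7–9
  PV).
- **Ro/e enrichment** — for cell type X in a stated universe, the 2×2 table
  (X / not-X) × (old / young) gives Ro/e = observed/expected old-group
  counts and a Pearson chi-square (df = 1).
- **Bhattacharyya divergence** — old-vs-young distance per cell type from
  Gaussian fits in a 10-dimensional PCA embedding,
  `D = (1/8) Δμᵀ Σ̄⁻¹ Δμ + (1/2) ln( det Σ̄ / √(det Σ₁ det Σ₂) )`,
  on repeated subsamples of 250 cells per group (100 repetitions), ranked
  by median.
- **Colocalization** — layer-profile and score correlations, plus a
  permutation test: within-sample spot-level Pearson correlation of two
  cell types' densities averaged over samples, against a null from
  permuting one type's densities within each sample (10,000 permutations,
  one-sided add-one p-value).
- **Differential expression** — Wilcoxon rank-sum per gene with BH
  adjustment; genes called at |log2FC| > 1 (or the lenient 0.25) and
  adjusted p < 0.05; three-way DEG intersection across comparisons.
- **Synthetic lobule generator** — seeded spatial and single-cell data with
  a smooth latent CV→PV coordinate, zone-graded negative-binomial markers,
  configurable cell-type abundance surfaces and planted composition/DE
  effects, with serialized ground truth; every analysis stage is validated
  against it.

See `vignettes/liverspatial-methods.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

```r
library(liverspatial)
cfg <- default_run_config(seed = 1)
rep <- run_pipeline(cfg)   # simulate -> qc -> score -> layers -> enrich ->
                           # diverge -> coloc -> de, all outputs + digests

rep$results$enrich[, c("cell_type", "n_old_X", "n_young_X", "roe", "chi2", "p")]
#>   cell_type n_old_X n_young_X   roe    chi2        p
#> 1       Tex     376        86 1.628 197.221 8.44e-45
#> 2     CD8_T     790      1151 0.814  99.248 2.23e-23
#> 3         B     895       873 1.012   0.388 5.33e-01
#> 4   Myeloid     939       890 1.027   1.888 1.69e-01
```

The simulated old group carries Tex at 12% versus 3% in young; the pooled
2×2 test recovers the enrichment (Ro/e 1.63, p ≈ 1e-44) while the types
with equal planted composition sit near Ro/e 1.

```r
rep$results$diverge$summary
#>   cell_type median n_old n_young with_replacement
#> 1       Tex 0.2882   376      86             TRUE
#> 2   Myeloid 0.0693   939     890            FALSE
#> 3     CD8_T 0.0672   790    1151            FALSE
#> 4         B 0.0579   895     873            FALSE
```

Tex is the only type with planted old-group effect genes and tops the
divergence ranking; the other medians reflect the finite-sample floor of
the estimator. The small young Tex group fell back to with-replacement
subsampling and is flagged.

```r
rep$results$coloc$old
#> Permutation colocalization: Tex ~ PP_hepatocyte (pearson)
#>   observed = 0.9692, p_perm = 9.999e-05 (10000 permutations)
rep$results$coloc$young
#> Permutation colocalization: Tex ~ PP_hepatocyte (pearson)
#>   observed = 0.003374, p_perm = 0.4083 (10000 permutations)
```

Tex and the periportal hepatocyte type are both PV-graded in the old group
only: the permutation test detects colocalization there (minimum possible
p at 10,000 permutations) and reports a null result in the young group.

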