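# profda

Differential-abundance analysis and visualization for **predicted
functional profiles** of microbial communities — the KO / EC / MetaCyc /
KEGG-pathway abundance tables that PICRUSt2 derives from 16S rRNA
marker-gene data. Marker genes say *who* is there; predicted functional
profiles say *what the community can do*, and testing which functions
differ between sample groups is where the biology usually lives. profda is
for microbiome researchers who have a `pred_metagenome_unstrat.tsv` and a
sample sheet and want defensible group comparisons and publication figures
without hand-wiring a dozen statistical packages.

## What it does

* **Reads the PICRUSt2 output dialect without reformatting** (TSV/CSV/TXT;
  any first-column header), infers the feature namespace from the ids, and
  aligns tables to sample metadata.
* **Aggregates KO abundances to KEGG pathways**: for pathway *p* and sample
  *s*, `abundance(p, s) = Σ_{k ∈ members(p)} abundance(k, s)` over the
  member KOs present in the table, from a pinned packaged membership
  snapshot or a user-supplied map.
* **Runs a registry of natively implemented DA methods** under one tidy
  contract — Welch's *t*, Kruskal–Wallis, and simplified analogues of
  ALDEx2 (Dirichlet Monte-Carlo + CLR), LinDA (CLR regression with
  mode-centering bias correction), limma-voom (moderated *t* on log2-CPM),
  metagenomeSeq (cumulative-sum scaling), Maaslin2 (log-linear model with
  covariates) and LEfSe (rank screen + effect score). Per feature *i* the
  CLR backbone is `clr(x)_i = ln x_i − (1/G) Σ_j ln x_j`; effects are
  reported on the log2 scale; p-values are corrected by BH (or
  bonferroni/holm/BY).
* **Annotates** features with descriptions and KEGG pathway name, class and
  map link from packaged offline tables.
* **Compares methods** (common/unique significant features, pairwise
  Jaccard) and **compares metagenomes** (per-sample Spearman rho across
  shared features, plus a DA run between sources).
* **Computes figure layers before drawing** — errorbar (group means ± SEM),
  PCA (TSS → centering → SVD) and row-z-score heatmap are tibbles you can
  test, with ggplot2 `autoplot()` on top.
* **Simulates benchmark data** with known spiked truth for calibration,
  FDR and power studies.

## Worked example

```r
library(profda)

sim  <- simulate_profile(n_features = 300, n_per_group = 12, seed = 42)
kegg <- ko2kegg_abundance(sim$abundance)        # KO table -> KEGG pathways
res  <- pathway_daa(kegg, sim$metadata, method = "linda")
dplyr::arrange(res, p_adjust)
#> # A tibble: 50 × 8
#>   feature method group1 group2 effect    p_value p_adjust adjust_method
#>   <chr>   <chr>  <chr>  <chr>   <dbl>      <dbl>    <dbl> <chr>
#> 1 ko00860 linda  A      B       1.28  0.00000535 0.000267 BH
#> 2 ko00620 linda  A      B       0.689 0.000135   0.00169  BH
#> 3 ko00650 linda  A      B       1.28  0.000129   0.00169  BH
#> 4 ko00710 linda  A      B       0.548 0.0000776  0.00169  BH
#> 5 ko00290 linda  A      B       0.535 0.000323   0.00304  BH
```

Each row is one feature in one contrast: `effect` is the log2-scale
group-2-vs-reference effect (here a bias-corrected CLR slope), `p_value`
the raw test p, `p_adjust` its BH q-value. Annotate and summarize:

```r
ann <- pathway_annotation(res, namespace = "KEGG_PATHWAY")
#> annotated 50/50 KEGG_PATHWAY id(s); 0 unmatched
dplyr::select(dplyr::arrange(ann, p_adjust), feature, pathway_name, effect, p_adjust)
#> # A tibble: 50 × 4
#>   feature pathway_name         effect p_adjust
#> 1 ko00860 Porphyrin metabolism  1.28  0.000267
#> 2 ko00620 Pyruvate metabolism   0.689 0.00169
#> 3 ko00650 Butanoate metabolism  1.28  0.00169

glance(res)
#> # A tibble: 1 × 6
#>   method group1 group2 n_features n_significant n_significant_adj
#> 1 linda  A      B              50            17                15
```

The errorbar layer holds exactly what the figure draws — group mean
relative abundance, SEM, effect and q-value per significant pathway:

```r
eb <- pathway_errorbar(kegg, sim$metadata, res)
tidy(eb)
#> # A tibble: 30 × 7
#>   feature group mean_rel_abundance      sem effect p_adjust order
#> 1 ko00860 A                0.00677 0.000758  1.28  0.000267     1
#> 2 ko00860 B                0.0132  0.00113   1.28  0.000267     1
#> 3 ko00620 A                0.0175  0.00127   0.689 0.00169      2
#> 4 ko00620 B                0.0237  0.00197   0.689 0.00169      2
autoplot(eb)           # or plot(eb); write_figure(eb, "errorbar")
```

`run_workflow()` chains the whole pipeline (read → convert → DA → annotate
→ errorbar) into an output directory with a YAML manifest, and
`inst/scripts/profda` exposes the same functions as a command line
(`profda run --abundance pred_metagenome_unstrat.tsv --metadata meta.tsv
--out results/`). The packaged KEGG reference is a synthetic offline
snapshot (real pathway ids/names, generated KO memberships) — point
`load_reference_map()` at a current two-column `pathway<TAB>ko` table for
real analyses.

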