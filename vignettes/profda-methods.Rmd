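---
title: "Methods and design of profda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of profda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

profda is a downstream toolkit for predicted functional profiles of
microbial communities — the feature-by-sample abundance tables that PICRUSt2
writes for KEGG orthologs (KO), enzyme classes (EC) and MetaCyc pathways.
These tables are *predicted*, real-valued, deeply compositional (each sample
is effectively a scaled composition of gene-family abundances) and usually
arrive with a sample metadata sheet defining a two-group contrast. This
vignette explains the statistical models the package implements, the
parameters that matter, what the synthetic benchmark does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

```{r setup, message = FALSE}
library(profda)
```

## Data model

An abundance table is a tibble whose first column `feature` holds unique
ids and whose remaining columns are samples; values must be finite and
non-negative but need not be integers, because PICRUSt2 predictions are
real-valued. The feature namespace (KO, EC, MetaCyc, KEGG pathway) is
inferred from the id patterns or supplied explicitly. Metadata is a tibble
with `sample`, a `group` factor whose first level is the reference, and
optional covariate columns. `align_samples()` restricts both objects to
their shared samples in the *table's* column order, which is treated as
canonical so that all downstream output is deterministic.

## KO-to-pathway aggregation

`ko2kegg_abundance()` computes, for each KEGG pathway and sample, the
unweighted sum of the abundances of the pathway's member KOs present in the
table. Members absent from the table contribute zero; a KO shared by
several pathways counts fully in each, because gene-family abundances are
additive predictions and no defensible fractional-assignment scheme exists
at this resolution. Pathways that end up all-zero are dropped by default
(`drop_zero = FALSE` keeps them). The packaged membership snapshot is
pinned and its version string travels with the output (`ref_map_version`
attribute and `# ref_map_version:` header line in written files), because
KEGG membership drifts over time.

The packaged reference under `inst/extdata/kegg_ref_synthetic/` is a
*synthetic snapshot*: the ~50 pathway ids, names and class strings are real
KEGG pathways, but the KO memberships and all KO/EC/MetaCyc descriptions
are generated, so that the package is fully self-contained and its tests
hermetic. Analyses of real data should supply a current KO-to-pathway
table via `load_reference_map(path)`.

## The differential-abundance registry

All methods share one contract: input an abundance table plus metadata,
output one tidy record per feature and contrast with a log2-scale effect, a
raw p-value and an adjusted p-value. With more than two groups, two-group
methods run pairwise against the reference level and the adjustment is
pooled over the whole feature-by-contrast set; `kruskal_wallis` is the
omnibus exception. Features with zero total abundance are dropped (with a
warning) before testing. Significance anywhere downstream means adjusted
p < 0.05 unless the caller changes the threshold.

Per-method models (each a documented, simplified analogue — numeric parity
with the original Bioconductor tools is explicitly not a goal; the target
is correct statistical behavior, which the acceptance checks measure as
calibration, FDR, power and effect recovery):

* **welch_t** — Welch's unequal-variance t on TSS relative abundances;
  effect is the log2 ratio of group means with a half-minimum pseudo.
* **kruskal_wallis** — tie-corrected rank H test on relative abundances,
  chi-squared reference.
* **aldex2** — Monte-Carlo Dirichlet resampling: counts (predictions
  rounded to integers, with a warning when rounding is material) plus a 0.5
  prior parameterize per-sample Dirichlet draws; each of `M` (default 128)
  instances is CLR-transformed (log2 scale) and tested per feature (Welch,
  or rank test via `test = "wilcoxon"`); the reported p-value is the mean
  raw p over instances, the q-value the mean of per-instance BH, the effect
  the median over instances of the between-group difference of median CLR
  values. Deterministic given `seed`.
* **linda** — CLR regression with compositional-bias correction: per
  feature, an OLS slope of the CLR value (pseudocount 0.5) on the group
  indicator; the mode of the slope distribution — a Gaussian KDE with
  Silverman's rule-of-thumb bandwidth evaluated on a 512-point grid
  spanning the slope range, argmax ties resolved toward the smallest value
  — is subtracted from every slope before the t-test, absorbing the common
  shift that compositionality induces.
* **limma** — moderated t on log2-CPM (prior count 0.5 added to counts and
  doubled in the library size): per-feature OLS, then empirical-Bayes
  variance shrinkage with prior degrees of freedom and scale estimated by
  method of moments on the log residual variances (trigamma inversion by
  Newton's method); voom's mean-variance precision weights are deliberately
  omitted — shrinkage dominates behavior at these scales and the lowess
  smoother has no testable anchor here. A non-finite prior estimate falls
  back to the ordinary t with a warning.
* **css** — cumulative-sum scaling: each sample is divided by the sum of
  its counts at or below its median nonzero count (quantile configurable),
  rescaled by 1000, and Welch-tested on log2(x + 1); the zero-inflated
  Gaussian of the original tool is out of scope.
* **maaslin2** — TSS, log2 with a half-minimum pseudocount, per-feature
  linear model on group plus any metadata covariates (additively);
  collinear covariates raise an error naming the offending columns.
* **lefse** — Kruskal-Wallis screen at `alpha_screen` (0.05), then a
  univariate effect score `sign(m2 - m1) * log10(1 + |m2 - m1|)` on group
  mean counts-per-million; features failing the screen score 0. The
  original's subclass stage and multivariate LDA are replaced by this
  deterministic score; `lda_threshold` (2.0) is attached for callers that
  want the conventional biomarker cut.

`deseq2` and `edger` are reserved registry names that error as not
implemented; ANCOM and ANCOM-BC are deliberately excluded. Where the
wrapped originals never document which scale they receive, the per-method
input scales above are this package's own standardization, as is the
uniform log2 effect convention.

p-value adjustment goes through `stats::p.adjust` (BH, bonferroni, holm,
BY, none); the BH path is verified against an independent brute-force
step-up implementation in the test suite.

## Consensus and metagenome comparison

`compare_daa_results()` summarizes agreement between methods at a
threshold: per-method significant counts, the intersection across all
methods, features unique to exactly one method, and pairwise Jaccard
similarity (defined as 1 when both sets are empty, so that perfect
agreement on "nothing significant" reads as agreement).

`compare_metagenome_results()` compares sources (e.g. predictions of the
same samples by different pipelines): tables are restricted to their
*intersection* of features — padding with zeros would fabricate rank ties —
then concatenated with the source as group label for a DA run, and for each
source pair the Spearman correlation across features is computed per
matched sample name and averaged. Correlating matched samples (rather than
grand means) preserves sample-level signal; the alternative could be added
behind a flag. The Spearman p-value uses the two-sided t approximation
`t = rho * sqrt((n-2)/(1-rho^2))`, with p = 0 by convention at |rho| = 1
and an error on constant (zero rank variance) input.

## Visualization layers

Every figure is computed as a data layer first — a tibble retrievable with
`tidy()` — and only then drawn with ggplot2 (`autoplot()`/`plot()`), so
every plotted quantity is testable and byte-stable; rendering never touches
the layer.

* `pathway_errorbar()` — per-group mean TSS relative abundance with SEM
  whiskers (SEM, not SD, because the display is about the precision of the
  group mean) for features passing the threshold, annotated with effect and
  adjusted p. More than 30 significant features is an error whose message
  carries the count and the `select` remedy — beyond that the figure is
  unreadable. Ordering is by adjusted p, name, or effect sign, ties broken
  by feature id.
* `pathway_pca()` — TSS, per-feature centering, SVD over samples. Features
  are not rescaled to unit variance by default since relative abundances
  already share a scale (`scale = TRUE` exposes the alternative). Variance
  fractions are normalized squared singular values; requesting more
  components than the matrix rank is an error. The figure shows PC1/PC2
  with normal-theory 95% ellipses per group when group sizes allow.
* `pathway_heatmap()` — per-feature z-scores using the sample standard
  deviation; constant rows become zeros with a warning; columns are ordered
  by group then sample id (metadata-driven, never clustered).

## The synthetic benchmark

`simulate_profile()` generates KO tables with known truth: a log-normal(0,1)
baseline composition; a chosen fraction of features multiplied by
`2^effect_log2` in non-reference groups and the composition renormalized;
Poisson per-sample depths; counts multinomial (`dispersion = 0`) or
gamma-Poisson with a unit-mean gamma multiplier of variance `dispersion`.
Feature ids are drawn from the packaged KO universe so aggregation and
annotation run end to end on simulated data.

Two consequences are intentional and worth understanding:

* Renormalization after one-directional spiking gives every null feature a
  small induced *negative* effect (about -log2 of the spiked mass gain,
  -0.38 at the default 10% spiked fraction and effect 4x). This is exactly
  the compositional bias that linda's mode correction absorbs; methods
  without bias correction (welch_t, limma, css, maaslin2) pay for it in
  empirical FDR on this benchmark, which the acceptance checks make
  visible rather than hide.
* `dispersion = 0.5` is the default level of between-sample biological
  overdispersion (unit-mean gamma multiplier, so roughly 70% CV on
  per-cell rates), a moderate value for stool-like communities; it was
  fixed as part of the benchmark design together with the standard fixture
  (500 features, 20 samples/group, 10% spiked at log2 effect 2, depth
  50,000, seeds 1-3), sized to keep the full suite fast while leaving
  binomial error on calibration fractions near ±0.01.

What the generator does **not** emulate: phylogenetic or pathway-level
correlation between KOs, batch effects, longitudinal designs, and the
extreme zero-inflation of shallow sequencing. Passing the benchmark
therefore shows correct behavior under idealized compositional sampling,
not performance guarantees on arbitrary real data.

## Numerical conventions

* Degenerate tests: two constant equal groups give t = 0, p = 1; constant
  unequal groups give p = 0 with a warning; all-identical Kruskal-Wallis
  input gives H = 0, p = 1; zero-variance features in regression methods
  get p = 1 with a warning.
* CLR sums per sample are zero to well below 1e-9; the transform is
  scale-invariant on positive data.
* KDE mode grid ties resolve to the smallest grid value; the KDE grid
  spans exactly the observed slope range.
* All randomness (aldex2, the simulator) is seeded locally and restores the
  caller's RNG state, so identical calls are bit-identical and independent
  of session history.

## Workflow and command line

`run_workflow()` chains read, optional KO-to-KEGG conversion, DA,
annotation and the errorbar layer, writing every intermediate table, the
figures, and a YAML manifest (package and reference-map versions, seed,
parameters). Stage failures are re-raised with the stage name prefixed. A
thin command-line wrapper over these same functions ships in
`inst/scripts/profda` with subcommands `run`, `convert`, `daa`, `annotate`,
`compare`, `metacompare`, `plot` and `simulate` (exit codes: 0 success, 2
usage error, 3 data error); it adds no logic of its own, so R sessions and
shell pipelines produce byte-identical tables.

## Known limitations

* Annotation is served entirely from the packaged offline snapshot; the
  online KEGG hook is a stub by design, and the packaged snapshot's KO
  memberships are synthetic (see above).
* No negative-binomial GLM methods; no paired or longitudinal designs;
  covariates enter only the maaslin2-style linear model.
* Effects are standardized to the log2 scale but their precise definition
  is method-specific (CLR differences vs log-CPM slopes vs CPM scores);
  cross-method effect magnitudes are not directly comparable, only their
  significance calls are (via `compare_daa_results()`).
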