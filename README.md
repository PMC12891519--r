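# coexnet

Cross-cohort validated weighted gene co-expression network analysis for
bulk transcriptomics, with community-level clinical association and
survival prognosis.

## What it is for

Case-control transcriptome studies of moderate size (tens of samples)
cannot support gene-by-gene inference, but they can support *network*
inference: genes are grouped into co-expression communities, each
community is summarized by its eigengene (first principal component),
and the eigengene is related to clinical traits and outcomes. The
catch is reproducibility — correlations estimated from ~60 samples are
noisy, so every edge and every community must be re-validated in
independent cohorts before interpretation. `coexnet` implements that
whole workflow, originally motivated by skeletal-muscle RNA-seq in
severe heart failure (a small patient cohort validated against large
population muscle datasets):

1. **Preprocess** — TMM normalization to log2 CPM
   (`tmm_normalize()`), detection filter (count > 1 in ≥ 20% of
   libraries, `filter_expressed()`), array informativeness filter
   (IQR ≥ 2, `iqr_filter()`), location-scale batch adjustment
   (`batch_adjust()`).
2. **Network** — Pearson correlation, soft-threshold adjacency
   `a_ij = |r_ij|^β` (default β = 13; `scan_soft_threshold()` reports
   the scale-free fit R² per candidate power), topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
   average-linkage clustering of `1 − TOM` with a deterministic
   modularity-optimal static cut, eigengene-based merging at
   dissimilarity 0.25.
3. **Cross-cohort validation** — every network edge is recomputed in
   each external cohort and pruned unless some cohort replicates it
   with the same sign at p < 0.05 (`revalidate_edges()`); each
   community gets permutation preservation statistics
   `Z_summary = mean(Z_density, Z_connectivity)` and is retained only
   if `Z_summary ≥ 3` in at least one cohort (`preservation_z()`,
   `retain_modules()`).
4. **Association** — community eigengenes vs continuous traits
   (Pearson), patient/control contrast (Welch t), multi-group
   contrasts (one-way ANOVA).
5. **Enrichment** — one-sided Fisher over-representation of GMT gene
   sets against a rest-of-network background with BH FDR
   (`ora_community()`, `bh_fdr()`); the same exact 2×2 test
   (`fisher_exact_2x2()`) serves two-sided categorical table
   comparisons.
6. **Prognosis** — eigengenes split into terciles
   (`tercile_split()`), Cox proportional-hazards fits (Breslow ties,
   Newton on the partial likelihood, `cox_fit()`) under ordinal-trend
   and high-vs-low codings (`prognosis_scan()`); ordinal death-class
   validation by ANOVA (`deathclass_anova()`).
7. **Matching** — propensity scores (logistic regression on age, sex,
   diabetes, BMI) and 1:1 nearest-neighbor matching without
   replacement within a caliper (`propensity_scores()`, `nn_match()`).

A bundled synthetic generator (`sim_config()`,
`generate_multi_cohort()`) produces multi-cohort data with planted
communities (one-factor model: standardized expression = loading ×
latent eigengene + noise, so within-module correlation → loading²),
negative-binomial counts or Gaussian log-intensities, trait links,
exponential proportional-hazards survival, and per-cohort batch
effects — with full ground truth, so the pipeline is testable offline.

## Worked example

```r
library(coexnet)
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
str(res$summary[c("n_genes_universe", "communities_detected",
                  "communities_retained", "edge_confirmation_rate",
                  "matched_controls")])
```

With the default synthetic world (1200 genes, six planted 80-gene
communities, a 78-sample discovery cohort of 58 patients + 20
controls, a 200-sample count cohort and a 125-sample array cohort)
this prints:

```
List of 5
 $ n_genes_universe      : int 1198
 $ communities_detected  : int 6
 $ communities_retained  : int 6
 $ edge_confirmation_rate: num 0.085
 $ matched_controls      : int 55
```

All six planted communities are detected and preserved
(`Z_summary ≥ 3` in both external cohorts); 8.5% of all within-network
gene pairs replicate at p < 0.05 with matching sign (the planted
within-community pairs at near-100%, the background pairs at ~α/2);
and 55 of the 58 patients find a propensity-matched external control
within the default caliper. The community carrying the planted
survival link (here `C1`) is the only one with a strong ordinal
tercile Cox association:

```
C1 ordinal tercile Cox: HR 2.74 (p = 6.24e-09)   # planted: HR 2 per eigengene SD
C5 ordinal tercile Cox: HR 0.67 (p = 0.016)
(all other communities p > 0.1)
```

Stage outputs (partition, eigengenes, association/enrichment/prognosis
tables, preservation reports, matches, `summary.json`) are written to
the run directory; identical seeds reproduce them bit-exactly.

### Command line

```sh
Rscript inst/cli/coexnet.R simulate --seed 3 --out sim_dir   # write synthetic cohorts
Rscript inst/cli/coexnet.R run --seed 1 --out run_dir        # full pipeline
```

### File formats

* expression: TSV, first column `gene`, one column per sample
* annotations: CSV with `sample`, `cohort`, `group`, traits,
  `time`/`event`, covariates, `death_class`
* gene sets: GMT (name, description, members; tab-separated)
* networks: edge-list TSV (`gene_a`, `gene_b`, `correlation`,
  `adjacency`, `tom`) and GraphML
* simulation config: YAML mirroring `sim_config()`

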