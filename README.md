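# biogeo — multi-organ microbiome biogeography analysis

`biogeo` is an R package for analysing intra-individual, multi-organ 16S
amplicon surveys: ASV count tables collected from many body sites of the same
subjects (skin, oral cavity, esophagus, stomach, small intestine, appendix,
large intestine), with paired lumen/mucosa sampling in the digestive tract
and negative controls processed alongside. It is aimed at microbiome
researchers who want a tested, reusable implementation of the full analysis
chain from a raw ASV table to biological summaries — and at method users who
want every stage validated against planted ground truth.

The pipeline covers:

* **IO**: validated readers/writers for ASV count tables (TSV, BIOM-JSON
  read-only), sample metadata, Greengenes-style 7-rank taxonomy and newick
  phylogenies, assembled into a cross-checked study bundle.
* **Contamination control**: rarefaction to a common depth (default 10,000
  reads), rare-taxon removal (< 0.1% everywhere), and prevalence-based
  contaminant scoring against negative controls (one-sided chi-squared with
  exact hypergeometric fallback, threshold 0.5).
* **Diversity**: inverse Simpson (plain and richness-normalized), taxonomic
  rank collapsing, unweighted/weighted UniFrac, PCoA, and covariate-adjusted
  PERMANOVA.
* **Paired-niche enrichment** — the statistical core: for each taxon at each
  site, an overdispersed beta-binomial logistic regression

  ```
  C ~ Binomial(N, p),   p ~ Beta(a, b)
  logit(mu) = b0 + b_type R_type + b1 S1 + b2 S2 + ...
  a = mu (1 - rho) / rho,   b = (1 - mu)(1 - rho) / rho
  ```

  where `C` is the taxon's read count, `N` the library size, `R_type` the
  mucosa indicator and `S_k` subject covariates (age, sex, BMI). `b_type` is
  the mucosa-vs-lumen log-odds shift; a single `rho` per fit captures
  overdispersion (`Var[C] = N mu (1-mu)(1 + (N-1) rho)`). Wald tests with
  per-site Benjamini–Hochberg FDR classify taxa as mucosa-/lumen-enriched,
  and enriched sets are compared across organs by percent Jaccard overlap.
* **Correlation networks**: a full SparCC implementation (log-ratio
  variances, basis-variance system under sparsity, iterative strong-pair
  exclusion, Dirichlet resampling, permutation pseudo p-values), cross-site
  consistency filtering within organs, and the two organ-specificity rules
  (between-organ difference > 0.6, or unique edge with |rho| > 0.6).
* **Inter-organ translocation**: strict presence calls (> 0.1% relative
  abundance), species collapse with ASV multiplicity, per-organ prevalence
  (> 50%), positive-correlation ratios between organ pairs (Spearman,
  partial Spearman, Pearson used simultaneously), and intra-individual
  core-species calls (an exact ASV present in every organ of a group).
* **Synthetic data**: `sim_config()` / `generate_study()` produce full study
  bundles with planted enrichment effects, contaminants, correlated taxon
  pairs and core species — with a ground-truth record that lets every stage
  be scored by parameter recovery.

## Worked example

```r
library(biogeo)

cfg <- sim_config(n_subjects = 12, seed = 20)   # 5 organs, paired niches
st  <- generate_study(cfg)
b   <- st$bundle

# 1. contamination control
dec <- decontaminate(b$counts, b$samples, seed = 21)
sum(dec$report$is_contaminant)     # 5  (all five planted contaminants)
dim(as.matrix(dec$table))          # 120 taxa x 240 samples retained

# 2. diversity
g  <- collapse_rank(dec$table, b$taxonomy, "genus")
ad <- alpha_diversity(g)           # inverse Simpson per sample
d  <- unifrac(dec$table, b$tree)
permanova(d, dec$samples, "organ", covariates = c("age", "sex", "BMI"),
          n_perm = 999, seed = 22)
#> PERMANOVA: pseudo-F = 135.915, R2 = 0.699, p = 0.001 (999 permutations;
#> adjusted for age, sex, BMI)

# 3. mucosa/lumen enrichment in the small intestine
fits <- classify_enrichment(fit_enrichment(dec$table, dec$samples,
                                           "small_intestine"))
enriched_sets(fits)$mucosa
#> [1] "ASV_0034" "ASV_0044"        # exactly the two planted mucosal taxa
```

The PERMANOVA p-value of 0.001 (the minimum attainable with 999
permutations) says organ identity explains ~70% of the UniFrac variance in
this simulated study; the enrichment stage recovers precisely the two taxa
planted with a +2 mucosal log-odds shift in that organ.

A thin command-line wrapper (`exec/biogeo`) exposes the same stages as
subcommands: `validate`, `simulate`, `decontam`, `diversity`, `enrich`,
`network`, `translocate`.

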