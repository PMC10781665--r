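---
title: "Methods: multi-organ microbiome biogeography with biogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-organ microbiome biogeography with biogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biogeo)
```

# Scope

`biogeo` analyses intra-individual, multi-organ 16S amplicon surveys: ASV
count tables collected from many body sites of the same subjects — skin, oral
cavity and the digestive tract, with paired lumen/mucosa sampling in the
stomach and intestines, and negative controls processed alongside. The
package covers six analysis stages (contamination control, diversity,
paired-niche enrichment, correlation networks, inter-organ translocation) and
a synthetic-data generator that plants known effects for every stage, so the
whole pipeline can be validated by parameter recovery rather than by eye.

Raw-read processing (denoising, chimera removal, taxonomic classification) is
out of scope: the pipeline starts from an ASV table, sample metadata, a
7-rank taxonomy and, optionally, a rooted phylogeny.

# Contamination control

Three controls are applied in a fixed order by `decontaminate()`:

1. **Rarefaction** to a common depth (default 10,000 reads). "Reducing read
   counts to a fixed library size" is implemented as subsampling without
   replacement — the dominant reading in amplicon practice — with a
   `mode = "scale"` alternative that rescales and rounds instead. Samples
   below the target depth are dropped with a warning, never upsampled.
2. **Rare-taxon removal**: a taxon is kept only if its relative abundance
   reaches the threshold (default 0.1%) in at least one sample; taxa below it
   everywhere are treated as noise.
3. **Prevalence-based contaminant scoring** against negative controls. For
   each taxon, detection (count > 0) is tabulated in a 2×2 of controls versus
   biological samples. The score is the one-sided p-value that control
   prevalence exceeds biological prevalence — chi-squared with continuity
   correction, with an exact hypergeometric fallback whenever an expected
   cell is below 5 (the common case with a handful of controls). A taxon is
   flagged when the score falls below the threshold (default 0.5) *and* its
   control prevalence is at least its biological prevalence. The directional
   rule means genuine taxa sparsely detected in controls are never flagged;
   the permissive 0.5 threshold mirrors the convention for discriminating
   true positives from contaminations in prevalence-based screening. A
   `mode = "strict"` variant removes every taxon detected in any control.

# Diversity

* **Alpha diversity** is the inverse Simpson index `1 / sum(p_i^2)`. The
  "relative" form is not standardised in the literature; here it is inverse
  Simpson divided by observed richness — an evenness value in (0, 1] that
  equals 1 only for a perfectly even community. Both columns are always
  emitted so either convention can be used downstream.
* **Rank collapsing** sums counts over taxa sharing a lineage prefix; ASVs
  unclassified at the target rank are pooled into one `unclassified` bucket
  per parent lineage rather than silently merged across families.
* **UniFrac** (unweighted by default, weighted-normalized by flag) is
  delegated to phyloseq behind the package's interface; the wrapper enforces
  a rooted tree with branch lengths and refuses tables whose nonzero taxa are
  missing from the tree. Unweighted UniFrac was chosen as the default because
  the downstream presence/prevalence logic of the pipeline is
  detection-driven; the weighted form is available via `weighted = TRUE`.
* **PCoA** is classical scaling (`cmdscale`); negative eigenvalues are
  reported but their axes never returned.
* **PERMANOVA** uses vegan's `adonis2` with sequential sums of squares,
  covariates (typically age, sex, BMI) entered before the factor under test,
  permuting raw sample labels. Residual-based permutation schemes are not
  attempted; sequential SS with covariates first is the simplest defensible
  reading of "adjusting for age, sex, BMI". The p-value is
  `(1 + #{F* >= F}) / (1 + n_perm)`, so `n_perm` bounds the attainable
  resolution. 999 permutations are the testing default; final analyses
  typically use 10,000.

# Paired-niche enrichment (beta-binomial logistic regression)

For each taxon at each site with paired niches, the read count `C` out of
library size `N` follows

\[
C \sim \mathrm{Binomial}(N, p), \qquad p \sim \mathrm{Beta}(a, b),
\]

with mean `mu = logistic(b0 + b_type R_type + b_k S_k + ...)`, where
`R_type` is 1 for mucosa and 0 for lumen/gastric juice and `S_k` are subject
covariates (default age, sex, BMI). The Beta parameters are
`a = mu (1 - rho) / rho`, `b = (1 - mu)(1 - rho) / rho`, so a single scalar
`rho` per fit is the within-model overdispersion correlation:
`Var[C] = N mu (1 - mu)(1 + (N - 1) rho)`. `b_type` is the log-odds shift of
the taxon's relative abundance in mucosa versus lumen — the quantity plotted
and classified downstream.

Numerical choices:

* Likelihood in log-beta form; below `rho = 1e-8` the binomial limit is used
  directly, because the `lbeta` differences cancel catastrophically there
  while the true pmf is binomial to far better than the switching error.
* Maximisation by BFGS from a plain logistic initial fit and `rho = 0.05`,
  with `rho` optimised on the logit scale for its (0, 1) box.
* Standard errors from the inverse observed information; two-sided Wald
  p-values for `b_type`. Complete separation or a singular information
  matrix yields `converged = FALSE`, an infinite SE and p = 1 — never a crash.
* Taxa detected in fewer than 4 samples at a site are skipped and logged; a
  3+-parameter model has no business there.

Fits are per taxon per site by default (matching per-site effect displays),
with a pooled per-organ mode (site entered as a covariate) behind a flag.
Benjamini–Hochberg q-values are computed within site (a pooled variant is
available), and a taxon is classified mucosa- or lumen-enriched at q < 0.05
by the sign of `b_type`. Organ-level sets are the union over sites;
`compare_enriched_sets()` reports the percent Jaccard overlap between organs.

# Correlation networks (SparCC)

SparCC estimates taxon–taxon correlations from compositions: with log-ratio
variances `t_ij = var(log(x_i / x_j))` and basis variances `w_i`, the model
`t_ij = w_i + w_j - 2 rho_ij sqrt(w_i w_j)` under a sparsity assumption gives
a linear system for `w` (summing over partners and dropping the correlation
terms), from which `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, clipped
to [-1, 1]. The strongest pair above the exclusion threshold (default 0.1) is
iteratively removed from the system and the system re-solved (default 10
iterations). Counts are smoothed by Dirichlet resampling with +1
pseudocounts (default 20 resamples) and the estimate is the element-wise
median. At least 4 taxa are required — the basis system is under-determined
below that.

Pseudo p-values permute each taxon's samples independently and compare
permuted `|rho|` against the observed value, two-sided on magnitude, with
`p = (1 + hits) / (1 + n_perm)`. Because BH-corrected retention at FDR 0.05
across `E` edges needs `p_min * E < 0.05`, the default 100 permutations are
suitable for screening but not for FDR across hundreds of edges; for that,
raise `n_permutations` and set `n_perm_resamples = 1` (a single Dirichlet
resample per permutation widens the null slightly, i.e. errs conservative,
and makes tens of thousands of permutations affordable).

Within an organ, an edge is retained only if significant at every site *and*
of identical sign at every site; the reported correlation is the mean across
sites. An edge is organ-specific if its correlation differs by more than 0.6
from every other organ where it is retained, or if it exceeds 0.6 in
magnitude and is retained nowhere else.

# Inter-organ translocation

* **Presence**: a taxon is present in a subject's organ when its relative
  abundance strictly exceeds 0.1% in at least one sample of that
  subject-organ (organs have multiple sites; an all-samples variant exists).
* **Species collapse**: species presence is the OR over member ASVs; the
  multiplicity (how many ASVs individually pass) distinguishes single- from
  multi-ASV support. ASVs unclassified at species rank are kept as their own
  pseudo-species rather than pooled.
* **Prevalence**: fraction of subjects with presence, per organ; "prevalent"
  means strictly above 50%.
* **Positive-correlation ratio**: for each species prevalent in either organ
  of a pair, its subject-level abundance (mean relative abundance over the
  subject's samples in the organ, summed over member ASVs) is correlated
  between the organs across subjects by Spearman, partial Spearman (rank
  residuals after regressing out age, sex, BMI, t-test on n-2-k df) and
  Pearson, used simultaneously. The default combination rule counts a
  species as positive if at least one method gives a positive coefficient
  with p < 0.05 (`combine = "all"` requires all three). P-values are used
  raw at 0.05, not FDR-corrected — deliberately, since the ratio is a
  descriptive summary, but users should know the any-of-three rule inflates
  the per-species false-positive rate somewhat above 2.5%. Species with
  fewer than 5 paired subjects are skipped and excluded from the
  denominator.
* **Core species**: a species is core for a (subject, organ-group) when at
  least one of its ASVs is individually present in *every* organ of the
  group for that subject — the exact-sequence-variant reading of
  co-existence; two or more such ASVs upgrade the call to multi-ASV support.
  Requiring one ASV across all organs (rather than species-level OR per
  organ) is the stricter and intended semantics: one exact sequence variant
  shared across organs is the evidence for translocation.

Default organ groups are upper GI = {esophagus, stomach} and lower GI =
{small intestine, appendix, large intestine}; the oral cavity is excluded
from upper GI (oral prevalence is an annotation, not a group member) and the
groups are configurable since no canonical enumeration exists.

# The synthetic-data generator

`sim_config()` + `generate_study()` emulate the statistical structure the
analysis assumes, at desk scale, with every planted effect recorded in a
ground-truth object:

* **Design**: default 6 subjects; organs oral cavity, esophagus, stomach,
  small intestine, large intestine with 2–3 sites each; paired mucosa/lumen
  (or gastric juice) in stomach and intestines; 6 negative controls; library
  sizes uniform on 20,000–40,000.
* **Composition layers**: core-species ASVs present in every organ of their
  group at ~3% each (percent-level abundance keeps planted presence robustly
  above the 0.1% detection threshold under the configured noise); shared
  taxa present in all organs; organ-exclusive taxa (zero base elsewhere —
  which makes "no false core call" scoring exact by construction);
  contaminant taxa with zero biological base.
* **Sampling model**: per-sample latent log abundances = log base
  composition + subject-level core effects (variance shared across the
  group's organs in proportion `core_correlation`, default 0.8) + per-organ
  correlated pair noise (Gaussian copula in log space — the simplest
  structure SparCC is designed to detect) + iid lognormal noise
  (`sample_log_sigma`, default 0.6), closed to the simplex; mucosal samples
  then receive the planted log-odds shifts; counts are drawn per taxon by
  beta-binomial thinning at the configured `rho` (default 0.05).
* **Mass balance of planted shifts**: a `+beta` logit shift on a rare taxon
  adds ~`w (e^beta - 1)` of mucosal mass while `-beta` removes
  ~`w (1 - e^-beta)`; lumen-enriched taxa therefore get `e^|beta|` times the
  base weight of mucosa-enriched ones, so the planted set perturbs the rest
  of the composition only at second order and null taxa stay null. Without
  this, closure would turn large planted shifts into spurious shifts on
  every other taxon.
* **Contaminants** appear in negative controls with probability
  `control_prevalence` (default 0.9) and leak into biological samples at the
  `carryover` rate (default 5%) at ~0.4% relative abundance. Controls carry
  library sizes in the same range as biological samples so they survive
  rarefaction and can be scored afterwards.
* **Tree**: random coalescent over all taxa (needed only for UniFrac);
  **taxonomy**: a consistent 7-rank hierarchy in which core species own
  multiple ASVs and a tail of taxa is left unclassified at species rank to
  exercise the pseudo-species path.

What the generator does *not* emulate: real phylogenetic signal in
abundances, taxon-specific overdispersion (a single `rho` means rare taxa
have overdispersion CV^2 ≈ rho/p — strong for the rarest taxa), sequencing
error or chimeras, and covariate effects on composition (hospitalization and
antibiotic flags are generated but effect-free, as no effect sizes are
published to calibrate against). Passing tests therefore demonstrate the
correctness and calibration of the *methods* under the stated model, not
performance guarantees on real data.

# Benchmark conditions

Fixed scenarios in `benchmark_*_config()` are shared by the test suite and
`scripts/acceptance.R`:

* **Enrichment**: 40 subject-pairs, one site, fixed N = 10,000,
  `rho = 0.05`, `sample_log_sigma = 0` (the regime in which the regression's
  p-values are exactly calibrated), ten planted taxa at log-odds ±2.
  Sensitivity and the false-discovery proportion are averaged over 10
  replicate studies because BH controls FDR in expectation, not per run.
* **Translocation**: 30 subjects (enough for per-species correlation tests
  to operate at their nominal level), small + large intestine, 6 planted
  translocating species among 14 uncoupled shared species; the
  positive-correlation ratio is compared with the planted fraction, averaged
  over 3 replicate studies.
* **Null and recovery checks** for the beta-binomial engine use direct
  draws (500 null taxa; 200 replicates of the planted shift); PERMANOVA
  type-I error uses 1000 null data sets with 999 permutations each; SparCC
  uses 50 independent lognormal taxa over 200 samples (null) and a planted
  proportional pair among 14 taxa.

These problem sizes keep the full suite and the acceptance script to a few
minutes on a single core while leaving each check enough resolution to fail
loudly when a stage is wrong.

# Known limitations

* The regression treats samples as independent given covariates; subject
  random effects are not modelled (paired designs enter through `R_type` and
  the subject covariates).
* SparCC pseudo p-value resolution is bounded by the permutation count;
  FDR-based retention over large edge sets needs a large `n_permutations`.
* The "relative inverse Simpson" normalization and the per-site FDR pooling
  are conventions chosen here (both alternatives are exposed as options).
* `positive_correlation_ratio` with the default any-of-three rule is
  intentionally descriptive; treat the ratio, not the per-species calls, as
  the object of inference.
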