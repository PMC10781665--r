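# Benchmark study conditions: fixed synthetic scenarios used to validate each
# analysis stage against planted ground truth. Centralised here so the test
# suite and the acceptance script exercise identical conditions.

#' Benchmark scenario: paired-niche enrichment
#'
#' One organ (large intestine, one site) sampled in paired mucosa/lumen
#' niches across `n_subjects` subjects, fixed library size 10,000, pure
#' beta-binomial overdispersion (`rho = 0.05`, no lognormal sample noise) and
#' ten planted taxa with log-odds shifts of +/-2 — the regime in which the
#' regression's estimates and error rates are interpretable against truth.
#'
#' @param seed integer seed.
#' @param n_subjects subjects (default 40 pairs).
#' @param beta planted |log-odds| shift (default 2).
#' @param n_taxa total taxa (default 60).
#' @return a `sim_config`.
#' @export
benchmark_enrichment_config <- function(seed, n_subjects = 40, beta = 2,
                                        n_taxa = 60) {
  sim_config(
    n_subjects = n_subjects,
    organs = list(large_intestine = list(sites = "sigmoid_colon",
                                         types = c("mucosa", "lumen"))),
    n_taxa = n_taxa, n_controls = 0, n_shared_taxa = 0,
    organ_groups = list(),
    core_species = data.frame(species = character(), group = character(),
                              n_asv = integer()),
    sample_log_sigma = 0, rho = 0.05,
    library_size_range = c(10000L, 10000L),
    n_enriched_per_organ = 10, enrichment_beta = beta,
    network_effects = data.frame(organ = character(), taxon_a = character(),
                                 taxon_b = character(), latent_r = numeric()),
    contaminants = list(n = 0, control_prevalence = 0, carryover = 0,
                        mean_proportion = 0),
    seed = seed)
}

#' Benchmark scenario: inter-organ translocation
#'
#' Small and large intestine (two luminal sites each) in `n_subjects`
#' subjects. When `translocating = TRUE`, six single-ASV core species span
#' both organs with a subject-level abundance correlation of 0.8 (the planted
#' translocators) among 14 shared but uncoupled species and one
#' organ-exclusive species per organ; with `translocating = FALSE` no species
#' is coupled, giving the null for the positive-correlation ratio.
#'
#' @param seed integer seed.
#' @param n_subjects subjects (default 30, enough for per-species
#'   correlation tests at nominal level).
#' @param translocating plant the coupled core species?
#' @return a `sim_config`.
#' @export
benchmark_translocation_config <- function(seed, n_subjects = 30,
                                           translocating = TRUE) {
  n_core <- if (translocating) 6L else 0L
  core <- if (n_core) {
    data.frame(species = sprintf("Translocating_%02d", seq_len(n_core)),
               group = "lower_gi", n_asv = 1L, stringsAsFactors = FALSE)
  } else {
    data.frame(species = character(), group = character(), n_asv = integer(),
               stringsAsFactors = FALSE)
  }
  sim_config(
    n_subjects = n_subjects,
    organs = list(
      small_intestine = list(sites = c("jejunum", "ileum"), types = "lumen"),
      large_intestine = list(sites = c("ascending_colon", "sigmoid_colon"),
                             types = "lumen")),
    n_taxa = n_core + 14L + 2L, n_controls = 0, n_shared_taxa = 14,
    organ_groups = list(lower_gi = c("small_intestine", "large_intestine")),
    core_species = core, n_enriched_per_organ = 0,
    network_effects = data.frame(organ = character(), taxon_a = character(),
                                 taxon_b = character(), latent_r = numeric()),
    contaminants = list(n = 0, control_prevalence = 0, carryover = 0,
                        mean_proportion = 0),
    seed = seed)
}

#' Run the translocation analysis on a study and score it against truth
#'
#' Convenience wrapper: presence calling, species collapse, prevalence,
#' positive-correlation ratio between small and large intestine, and the
#' planted fraction of tested species.
#'
#' @param study result of [generate_study()] under
#'   [benchmark_translocation_config()].
#' @return list with `ratio`, `n_tested`, `planted_fraction`.
#' @export
score_translocation <- function(study) {
  b <- study$bundle
  pres <- call_presence(b$counts, b$samples)
  sp <- suppressMessages(collapse_species(pres, b$taxonomy))
  prev <- prevalence_by_organ(sp$presence)
  pv <- rownames(prev$prevalence)[
    prev$prevalent[, "small_intestine"] | prev$prevalent[, "large_intestine"]]
  ab <- species_organ_abundance(b$counts, b$samples, b$taxonomy)
  subj <- unique(as.data.frame(b$samples)[c("subject_id", "age", "sex",
                                            "BMI")])
  rownames(subj) <- subj$subject_id
  r <- suppressWarnings(positive_correlation_ratio(
    ab, pv, "small_intestine", "large_intestine",
    subject_covariates = subj[, c("age", "sex", "BMI")]))
  planted <- unique(study$truth$core$species)
  list(ratio = r$ratio, n_tested = r$n_tested,
       planted_fraction = if (r$n_tested)
         mean(r$records$species %in% planted) else NA_real_)
}
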