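# Niche enrichment: per-taxon, per-site beta-binomial logistic regression of
# mucosa vs lumen/gastric-juice membership, FDR classification, and
# cross-organ comparison of the enriched sets.

#' Fit mucosa/lumen enrichment models across an organ
#'
#' For every taxon at every site of the organ (default), builds an
#' [enrichment_model()] from the paired lumen/mucosa (or gastric-juice/mucosa)
#' samples and fits the overdispersed beta-binomial logistic regression
#' ([fit_taxon()]). The sample-type coefficient `beta_type` is the log-odds
#' shift of the taxon's relative abundance in mucosa versus lumen. Taxa
#' detected in fewer than `min_detected` samples at a site are skipped
#' (too thin for a multi-parameter model) and recorded in the `skipped`
#' attribute.
#'
#' @param table `count_table` or matrix (taxa x samples).
#' @param samples `sample_table`.
#' @param organ organ to analyse (must have both niches sampled).
#' @param covariates subject covariate columns entered into the design
#'   (default `c("age", "sex", "BMI")`, the standard adjustment set). Use
#'   `character()` for none.
#' @param by `"site"` (default; one fit per taxon per site) or `"organ"`
#'   (pooled across sites with site as an additional covariate).
#' @param min_detected minimum number of samples with a nonzero count.
#' @return data frame of class `enrichment_fits` with columns `taxon_id`,
#'   `site`, `beta_type`, `se`, `wald_p`, `rho_hat`, `converged`; skipped
#'   taxa in `attr(, "skipped")`.
#' @export
fit_enrichment <- function(table, samples, organ,
                           covariates = c("age", "sex", "BMI"),
                           by = c("site", "organ"), min_detected = 4) {
  by <- match.arg(by)
  m <- as_counts(table)
  df <- as.data.frame(samples)
  df <- df[match(colnames(m), df$sample_id), , drop = FALSE]
  sel <- df$organ == organ &
    df$sample_type %in% c("mucosa", "lumen", "gastric_juice")
  if (!any(sel)) stop(sprintf("no niche samples for organ '%s'", organ),
                      call. = FALSE)
  df <- df[sel, , drop = FALSE]
  m <- m[, sel, drop = FALSE]
  type <- as.numeric(df$sample_type == "mucosa")
  if (length(unique(type)) < 2)
    stop(sprintf("organ '%s' lacks paired niches", organ), call. = FALSE)
  depths <- colSums(m)
  units <- if (by == "site") split(seq_len(ncol(m)), df$site)
           else list(pooled = seq_len(ncol(m)))
  fits <- list(); skipped <- list()
  for (site in names(units)) {
    idx <- units[[site]]
    if (length(unique(type[idx])) < 2) next
    cv <- NULL
    cv_cols <- covariates
    if (by == "organ" && length(unique(df$site[idx])) > 1)
      cv_cols <- c(cv_cols, "site")
    if (length(cv_cols)) cv <- df[idx, cv_cols, drop = FALSE]
    for (t in rownames(m)) {
      C <- m[t, idx]
      if (sum(C > 0) < min_detected) {
        skipped[[length(skipped) + 1]] <-
          data.frame(taxon_id = t, site = site,
                     reason = sprintf("detected in %d < %d samples",
                                      sum(C > 0), min_detected),
                     stringsAsFactors = FALSE)
        next
      }
      model <- enrichment_model(C, depths[idx], type[idx], cv)
      fit <- fit_taxon(model)
      fits[[length(fits) + 1]] <- data.frame(
        taxon_id = t, site = site, beta_type = fit$beta_type, se = fit$se,
        wald_p = fit$wald_p, rho_hat = fit$rho_hat,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(fits)) do.call(rbind, fits) else
    data.frame(taxon_id = character(), site = character(),
               beta_type = numeric(), se = numeric(), wald_p = numeric(),
               rho_hat = numeric(), converged = logical(),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "organ") <- organ
  class(out) <- c("enrichment_fits", "data.frame")
  out
}

#' Classify fits into mucosa-/lumen-enriched at an FDR level
#'
#' Benjamini-Hochberg q-values are computed within each site (the default) or
#' pooled across sites. A fit is `mucosa_enriched` if `q < alpha` and
#' `beta_type > 0`, `lumen_enriched` if `q < alpha` and `beta_type < 0`, and
#' `ns` otherwise.
#'
#' @param fits an `enrichment_fits` data frame (or compatible).
#' @param alpha FDR level, default 0.05.
#' @param pool_sites compute BH across all sites jointly instead of within
#'   site?
#' @return the fits with added columns `fdr_q` and `class`.
#' @export
classify_enrichment <- function(fits, alpha = 0.05, pool_sites = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  fits <- as.data.frame(fits)
  if (nrow(fits) == 0) {
    fits$fdr_q <- numeric(); fits$class <- character()
    return(fits)
  }
  fits$fdr_q <- if (pool_sites) stats::p.adjust(fits$wald_p, "BH") else
    stats::ave(fits$wald_p, fits$site,
               FUN = function(p) stats::p.adjust(p, "BH"))
  fits$class <- ifelse(fits$fdr_q < alpha & fits$beta_type > 0,
                       "mucosa_enriched",
                       ifelse(fits$fdr_q < alpha & fits$beta_type < 0,
                              "lumen_enriched", "ns"))
  class(fits) <- c("enrichment_fits", "data.frame")
  fits
}

#' Extract the organ-level enriched taxon sets
#'
#' Pools classified fits over sites: a taxon belongs to the organ's
#' mucosa-enriched set if it is `mucosa_enriched` at any site (and likewise
#' for lumen).
#'
#' @param fits classified `enrichment_fits`.
#' @return list with sorted character vectors `mucosa` and `lumen`.
#' @export
enriched_sets <- function(fits) {
  fits <- as.data.frame(fits)
  list(mucosa = sort(unique(fits$taxon_id[fits$class == "mucosa_enriched"])),
       lumen = sort(unique(fits$taxon_id[fits$class == "lumen_enriched"])))
}

#' Jaccard comparison of two enriched sets
#'
#' `jaccard_percent = 100 * |A intersect B| / |A union B|` (0 when both sets
#' are empty), with the shared members listed sorted.
#'
#' @param set_a,set_b character vectors of taxon identifiers.
#' @return list with `jaccard_percent`, `shared`, `n_a`, `n_b`, `n_shared`.
#' @export
compare_enriched_sets <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  shared <- sort(intersect(set_a, set_b))
  union_n <- length(union(set_a, set_b))
  jac <- if (union_n == 0) 0 else 100 * length(shared) / union_n
  list(jaccard_percent = jac, shared = shared,
       n_a = length(set_a), n_b = length(set_b), n_shared = length(shared))
}
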