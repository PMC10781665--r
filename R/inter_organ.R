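# Inter-organ translocation analysis: presence calling, species collapse,
# organ prevalence, inter-organ positive-correlation ratios, and
# intra-individual core-species co-existence.

#' Call taxon presence per (subject, organ)
#'
#' A taxon is present in a subject's organ iff its relative abundance
#' strictly exceeds `threshold` in at least one sample of that subject-organ
#' (organs are sampled at several sites). `require_all = TRUE` demands the
#' threshold in every sample instead.
#'
#' @param table `count_table` or matrix.
#' @param samples `sample_table`; negative controls are ignored.
#' @param threshold relative-abundance fraction, strict `>` (default 0.001,
#'   i.e. 0.1%).
#' @param require_all require the threshold in all samples of the
#'   subject-organ?
#' @return logical array `[taxon, subject, organ]`.
#' @export
call_presence <- function(table, samples, threshold = 0.001,
                          require_all = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  m <- as_counts(table)
  df <- as.data.frame(samples)
  df <- df[match(colnames(m), df$sample_id), , drop = FALSE]
  bio <- df$organ != "negative_control"
  m <- m[, bio, drop = FALSE]; df <- df[bio, , drop = FALSE]
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  hit <- rel > threshold
  subjects <- sort(unique(df$subject_id))
  organs <- sort(unique(df$organ))
  out <- array(FALSE, dim = c(nrow(m), length(subjects), length(organs)),
               dimnames = list(rownames(m), subjects, organs))
  grp <- interaction(df$subject_id, df$organ, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    agg <- if (require_all) rowSums(hit[, idx, drop = FALSE]) == length(idx)
           else rowSums(hit[, idx, drop = FALSE]) > 0
    out[, df$subject_id[idx[1]], df$organ[idx[1]]] <- agg
  }
  out
}

# Map taxa to species keys; ASVs with an empty species rank are retained as
# their own pseudo-species keyed by ASV id.
species_keys <- function(taxa, taxonomy) {
  tax <- as.data.frame(taxonomy)
  idx <- match(taxa, tax$taxon_id)
  if (any(is.na(idx)))
    stop(sprintf("taxa missing from taxonomy: %s",
                 paste(taxa[is.na(idx)], collapse = ", ")), call. = FALSE)
  sp <- tax$species[idx]
  empty <- is.na(sp) | sp == ""
  if (any(empty))
    message(sprintf("%d ASV(s) unclassified at species rank kept as pseudo-species",
                    sum(empty)))
  sp[empty] <- paste0("asv:", taxa[empty])
  sp
}

#' Collapse a presence tensor to species level
#'
#' Species presence is the OR over member ASVs; multiplicity counts how many
#' member ASVs individually meet the presence criterion.
#'
#' @param presence logical array `[taxon, subject, organ]` from
#'   [call_presence()].
#' @param taxonomy `taxonomy_table` covering the taxa.
#' @return list with `presence` (logical `[species, subject, organ]`),
#'   `multiplicity` (integer, same shape), and `members` (named list,
#'   species -> ASVs).
#' @export
collapse_species <- function(presence, taxonomy) {
  taxa <- dimnames(presence)[[1]]
  sp <- species_keys(taxa, taxonomy)
  species <- sort(unique(sp))
  dims <- dim(presence)
  mult <- array(0L, dim = c(length(species), dims[2], dims[3]),
                dimnames = c(list(species), dimnames(presence)[2:3]))
  for (s in species) {
    member <- which(sp == s)
    block <- presence[member, , , drop = FALSE]
    mult[s, , ] <- apply(block, c(2, 3), sum)
  }
  list(presence = mult > 0, multiplicity = mult,
       members = split(taxa, sp)[species])
}

#' Prevalence of taxa (or species) per organ
#'
#' Prevalence is the fraction of subjects in which the taxon is present in
#' that organ; a taxon is "prevalent" iff prevalence strictly exceeds
#' `cutoff`.
#'
#' @param presence logical array `[taxon, subject, organ]`.
#' @param cutoff prevalence cutoff, strict `>` (default 0.5).
#' @return list with `prevalence` (matrix taxon x organ) and `prevalent`
#'   (logical matrix).
#' @export
prevalence_by_organ <- function(presence, cutoff = 0.5) {
  stopifnot(dim(presence)[2] >= 1, cutoff > 0, cutoff < 1)
  prev <- apply(presence, c(1, 3), mean)
  list(prevalence = prev, prevalent = prev > cutoff)
}

#' Species abundance per (subject, organ)
#'
#' The subject-organ abundance of a species is the mean (over that subject's
#' samples in the organ) of the summed relative abundance of its member ASVs.
#' Subjects without samples in an organ get `NA`.
#'
#' @param table `count_table` or matrix.
#' @param samples `sample_table`.
#' @param taxonomy `taxonomy_table`.
#' @return numeric array `[species, subject, organ]`.
#' @export
species_organ_abundance <- function(table, samples, taxonomy) {
  m <- as_counts(table)
  df <- as.data.frame(samples)
  df <- df[match(colnames(m), df$sample_id), , drop = FALSE]
  bio <- df$organ != "negative_control"
  m <- m[, bio, drop = FALSE]; df <- df[bio, , drop = FALSE]
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  sp <- suppressMessages(species_keys(rownames(m), taxonomy))
  rel_sp <- rowsum(rel, group = sp, reorder = TRUE)
  subjects <- sort(unique(df$subject_id))
  organs <- sort(unique(df$organ))
  out <- array(NA_real_, dim = c(nrow(rel_sp), length(subjects),
                                 length(organs)),
               dimnames = list(rownames(rel_sp), subjects, organs))
  grp <- interaction(df$subject_id, df$organ, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    out[, df$subject_id[idx[1]], df$organ[idx[1]]] <-
      rowMeans(rel_sp[, idx, drop = FALSE])
  }
  out
}

# Partial Spearman correlation: Pearson correlation of rank residuals after
# regressing out the (ranked) covariates, with a t-test on n - 2 - k df.
partial_spearman <- function(x, y, covars) {
  rx <- rank(x); ry <- rank(y)
  Z <- as.matrix(as.data.frame(lapply(as.data.frame(covars), function(z) {
    if (is.numeric(z)) rank(z) else as.numeric(factor(z))
  })))
  ex <- stats::lm.fit(cbind(1, Z), rx)$residuals
  ey <- stats::lm.fit(cbind(1, Z), ry)$residuals
  r <- suppressWarnings(stats::cor(ex, ey))
  n <- length(x); k <- ncol(Z)
  df <- n - 2 - k
  if (!is.finite(r) || df < 1) return(list(estimate = NA_real_, p = 1))
  tval <- r * sqrt(df / max(1 - r^2, 1e-12))
  list(estimate = r, p = 2 * stats::pt(-abs(tval), df))
}

#' Ratio of positively correlated species between two organs
#'
#' For each species prevalent in either organ, correlates its subject-level
#' abundance between the two organs across subjects quantified in both
#' (Spearman, partial Spearman adjusting for covariates, and Pearson, used
#' simultaneously). A species counts as positive iff the coefficient is
#' positive and p < `alpha` under the combination rule: `"any"` (default, at
#' least one method) or `"all"`. The ratio is positives over species tested;
#' species with fewer than `min_subjects` paired subjects are skipped and not
#' counted in the denominator.
#'
#' @param abundance array `[species, subject, organ]` from
#'   [species_organ_abundance()].
#' @param prevalent_species character vector (typically species prevalent in
#'   either organ, see [prevalence_by_organ()]).
#' @param organ_a,organ_b organ names.
#' @param subject_covariates data frame with rownames = subject ids and the
#'   adjustment columns for partial Spearman (default none -> partial
#'   Spearman reduces to Spearman).
#' @param methods subset of `c("spearman", "partial_spearman", "pearson")`.
#' @param alpha per-test significance level, used raw (default 0.05).
#' @param combine `"any"` or `"all"`.
#' @param min_subjects minimum paired subjects per species (default 5).
#' @return list with `ratio`, `n_tested`, `n_positive`, `skipped`, and
#'   `records` (one row per tested species with per-method estimates and
#'   p-values).
#' @export
positive_correlation_ratio <- function(abundance, prevalent_species,
                                       organ_a, organ_b,
                                       subject_covariates = NULL,
                                       methods = c("spearman",
                                                   "partial_spearman",
                                                   "pearson"),
                                       alpha = 0.05,
                                       combine = c("any", "all"),
                                       min_subjects = 5) {
  combine <- match.arg(combine)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(organ_a %in% dimnames(abundance)[[3]],
            organ_b %in% dimnames(abundance)[[3]])
  species <- intersect(prevalent_species, dimnames(abundance)[[1]])
  records <- list(); skipped <- character()
  for (s in species) {
    x <- abundance[s, , organ_a]; y <- abundance[s, , organ_b]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_subjects) { skipped <- c(skipped, s); next }
    x <- x[ok]; y <- y[ok]
    res <- list()
    if ("spearman" %in% methods) {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      res$spearman <- list(estimate = unname(ct$estimate), p = ct$p.value)
    }
    if ("pearson" %in% methods) {
      ct <- stats::cor.test(x, y, method = "pearson")
      res$pearson <- list(estimate = unname(ct$estimate), p = ct$p.value)
    }
    if ("partial_spearman" %in% methods) {
      cv <- if (!is.null(subject_covariates))
        subject_covariates[names(x), , drop = FALSE] else NULL
      res$partial_spearman <- if (is.null(cv) || ncol(cv) == 0) {
        ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
        list(estimate = unname(ct$estimate), p = ct$p.value)
      } else partial_spearman(x, y, cv)
    }
    pos <- vapply(res, function(r)
      is.finite(r$estimate) && r$estimate > 0 && r$p < alpha, logical(1))
    row <- data.frame(species = s, n_subjects = length(x),
                      positive = if (combine == "any") any(pos) else all(pos),
                      stringsAsFactors = FALSE)
    for (meth in names(res)) {
      row[[paste0(meth, "_r")]] <- res[[meth]]$estimate
      row[[paste0(meth, "_p")]] <- res[[meth]]$p
    }
    records[[s]] <- row
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(species = character(), n_subjects = integer(),
               positive = logical(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  n_tested <- nrow(records)
  n_positive <- sum(records$positive)
  list(ratio = if (n_tested) n_positive / n_tested else NA_real_,
       n_tested = n_tested, n_positive = n_positive,
       skipped = skipped, records = records)
}

#' Intra-individual core-species calls over organ groups
#'
#' A species is core for (subject, group) iff at least one of its ASVs is
#' individually present in every organ of the group for that subject; the
#' status is `core_multi_asv` when two or more ASVs each satisfy this
#' (otherwise `core_single_asv`, or `absent`).
#'
#' @param presence logical ASV-level array `[taxon, subject, organ]` from
#'   [call_presence()].
#' @param taxonomy `taxonomy_table`.
#' @param organ_groups named list (group -> organ set); every organ must
#'   appear in the presence array.
#' @return list with `calls` (data frame: species, subject, group, status,
#'   n_core_asvs) and `summary` (per species x group: fraction of subjects
#'   core).
#' @export
core_species <- function(presence, taxonomy,
                         organ_groups = list(
                           upper_gi = c("esophagus", "stomach"),
                           lower_gi = c("small_intestine", "appendix",
                                        "large_intestine"))) {
  organs_avail <- dimnames(presence)[[3]]
  for (g in names(organ_groups)) {
    missing_org <- setdiff(organ_groups[[g]], organs_avail)
    if (length(missing_org))
      stop(sprintf("organ group '%s' references organs absent from the study: %s",
                   g, paste(missing_org, collapse = ", ")), call. = FALSE)
  }
  taxa <- dimnames(presence)[[1]]
  sp <- suppressMessages(species_keys(taxa, taxonomy))
  subjects <- dimnames(presence)[[2]]
  calls <- list()
  for (g in names(organ_groups)) {
    organs <- organ_groups[[g]]
    # ASV core iff present in every organ of the group for that subject
    asv_core <- apply(presence[, , organs, drop = FALSE], c(1, 2), all)
    n_core <- rowsum(asv_core * 1L, group = sp, reorder = TRUE)
    status <- matrix("absent", nrow(n_core), ncol(n_core),
                     dimnames = dimnames(n_core))
    status[n_core == 1] <- "core_single_asv"
    status[n_core >= 2] <- "core_multi_asv"
    calls[[g]] <- data.frame(
      species = rep(rownames(n_core), times = ncol(n_core)),
      subject = rep(colnames(n_core), each = nrow(n_core)),
      group = g,
      status = as.vector(status),
      n_core_asvs = as.vector(n_core),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  summary <- stats::aggregate(
    list(fraction_core = calls$status != "absent"),
    by = list(species = calls$species, group = calls$group), FUN = mean)
  list(calls = calls, summary = summary)
}
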