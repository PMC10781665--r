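# Correlation-network module: SparCC compositional correlations per site,
# cross-site consistency within an organ, and organ-specific edge rules.
#
# SparCC estimates basis correlations from pairwise log-ratio variances
# t_ij = var(log(x_i/x_j)) under a sparsity assumption: summing
# t_ij = w_i + w_j - 2 rho_ij sqrt(w_i w_j) over partners and dropping the
# correlation terms yields a linear system for the basis variances w, from
# which rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j)). Strongly correlated
# pairs (which violate sparsity) are iteratively excluded from the system and
# it is re-solved; counts are smoothed by Dirichlet resampling with +1
# pseudocounts and the final estimate is the median across resamples.

#' SparCC basis correlations from a fraction matrix
#'
#' Deterministic core of the SparCC estimator: computes log-ratio variances,
#' solves the basis-variance system with iterative exclusion of the strongest
#' pairs, and returns clipped basis correlations. Exposed separately so the
#' solver can be checked against a direct solve on small instances.
#'
#' @param fractions taxa-by-samples matrix of strictly positive proportions.
#' @param n_exclusion_iterations maximum strong-pair exclusions (default 10).
#' @param exclusion_threshold absolute correlation above which the strongest
#'   pair is excluded from the basis system (default 0.1).
#' @return symmetric correlation matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
sparcc_fractions <- function(fractions, n_exclusion_iterations = 10,
                             exclusion_threshold = 0.1) {
  lf <- log(fractions)
  if (any(!is.finite(lf)))
    stop("fractions must be strictly positive", call. = FALSE)
  D <- nrow(lf)
  if (D < 4)
    stop("SparCC needs at least 4 taxa (basis system under-determined)",
         call. = FALSE)
  S <- stats::cov(t(lf))
  v <- diag(S)
  Tm <- outer(v, v, "+") - 2 * S          # log-ratio variance matrix
  excluded <- matrix(FALSE, D, D)
  R <- NULL
  for (iter in seq_len(n_exclusion_iterations + 1)) {
    included <- !excluded
    diag(included) <- FALSE
    m <- rowSums(included)
    if (any(m < 2)) break
    A <- included * 1
    diag(A) <- m
    trow <- rowSums(Tm * included)
    w <- tryCatch(solve(A, trow), error = function(e) NULL)
    if (is.null(w)) break
    w <- pmax(w, .Machine$double.eps)
    Rnew <- (outer(w, w, "+") - Tm) / (2 * sqrt(outer(w, w)))
    Rnew <- pmin(pmax(Rnew, -1), 1)
    diag(Rnew) <- 1
    R <- Rnew
    if (iter > n_exclusion_iterations) break
    cand <- abs(R)
    cand[!included] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    hit <- which(cand == mx, arr.ind = TRUE)[1, ]
    excluded[hit[1], hit[2]] <- excluded[hit[2], hit[1]] <- TRUE
  }
  if (is.null(R))
    stop("basis-variance system became singular before any solution",
         call. = FALSE)
  dimnames(R) <- list(rownames(fractions), rownames(fractions))
  R
}

# One Dirichlet(+1)-resampled SparCC estimate from a count matrix.
sparcc_resample <- function(counts, n_exclusion_iterations,
                            exclusion_threshold) {
  D <- nrow(counts)
  frac <- apply(counts + 1, 2, function(x) {
    g <- stats::rgamma(D, shape = x, rate = 1)
    g / sum(g)
  })
  rownames(frac) <- rownames(counts)
  sparcc_fractions(frac, n_exclusion_iterations, exclusion_threshold)
}

#' SparCC correlations with permutation pseudo p-values
#'
#' Runs the SparCC estimator over `n_dirichlet_resamples` Dirichlet(+1)
#' resamples of the counts and reports the element-wise median correlation.
#' Pseudo p-values come from permuting each taxon's samples independently
#' (destroying all between-taxon association while keeping marginals) and
#' comparing the permuted `|rho|` to the observed one:
#' `p = (1 + hits) / (1 + n_permutations)`, two-sided on magnitude.
#'
#' @param table `count_table` or taxa-by-samples matrix (>= 4 taxa; fewer
#'   than 10 samples triggers a warning).
#' @param n_dirichlet_resamples resamples for the point estimate (default 20).
#' @param n_exclusion_iterations strong-pair exclusions per solve (default 10).
#' @param exclusion_threshold see [sparcc_fractions()] (default 0.1).
#' @param n_permutations permutations for pseudo p-values (default 100; 0
#'   skips them and returns `pseudo_p = NULL`).
#' @param n_perm_resamples Dirichlet resamples used within each permutation
#'   (default: same as `n_dirichlet_resamples`). A single resample per
#'   permutation makes large permutation counts affordable at the cost of a
#'   slightly wider (conservative) null.
#' @param seed integer seed.
#' @return list with `correlation` (median SparCC matrix) and `pseudo_p`.
#' @export
sparcc <- function(table, n_dirichlet_resamples = 20,
                   n_exclusion_iterations = 10, exclusion_threshold = 0.1,
                   n_permutations = 100,
                   n_perm_resamples = n_dirichlet_resamples, seed = 1L) {
  m <- as_counts(table)
  if (nrow(m) < 4)
    stop("SparCC needs at least 4 taxa", call. = FALSE)
  if (ncol(m) < 10)
    warning("fewer than 10 samples; SparCC estimates will be noisy",
            call. = FALSE)
  with_seed(seed, {
    est <- function(counts, n_rep) {
      reps <- lapply(seq_len(n_rep), function(i)
        sparcc_resample(counts, n_exclusion_iterations, exclusion_threshold))
      if (n_rep == 1) return(reps[[1]])
      arr <- simplify2array(reps)
      R <- apply(arr, c(1, 2), stats::median)
      R <- (R + t(R)) / 2
      diag(R) <- 1
      dimnames(R) <- dimnames(reps[[1]])
      R
    }
    R <- est(m, n_dirichlet_resamples)
    pseudo_p <- NULL
    if (n_permutations > 0) {
      hits <- matrix(0, nrow(m), nrow(m))
      for (b in seq_len(n_permutations)) {
        perm <- t(apply(m, 1, sample))
        rownames(perm) <- rownames(m)
        Rp <- est(perm, n_perm_resamples)
        hits <- hits + (abs(Rp) >= abs(R))
      }
      pseudo_p <- (1 + hits) / (1 + n_permutations)
      diag(pseudo_p) <- NA_real_
      dimnames(pseudo_p) <- dimnames(R)
    }
    list(correlation = R, pseudo_p = pseudo_p)
  })
}

#' Cross-site consistent correlations of one organ
#'
#' An edge is retained iff its BH q-value (computed across edges within each
#' site) is below `fdr_alpha` in every site of the organ AND its correlation
#' sign is identical in every site; the reported correlation is the
#' arithmetic mean across sites.
#'
#' @param per_site named list (site -> list(correlation, pseudo_p)) as
#'   returned by [sparcc()]; all sites must share the same taxa.
#' @param fdr_alpha FDR level (default 0.05).
#' @param organ optional organ label stored with the network.
#' @return data frame of class `organ_network`: `taxon_a < taxon_b`,
#'   `mean_correlation`, `max_q`, `sign`, plus one `corr_<site>` column per
#'   site.
#' @export
consistent_organ_correlations <- function(per_site, fdr_alpha = 0.05,
                                          organ = NA_character_) {
  stopifnot(length(per_site) >= 1, fdr_alpha > 0, fdr_alpha < 1)
  taxa <- rownames(per_site[[1]]$correlation)
  for (s in per_site) {
    if (!identical(rownames(s$correlation), taxa))
      stop("all sites must share the same taxa in the same order",
           call. = FALSE)
  }
  ut <- which(upper.tri(per_site[[1]]$correlation), arr.ind = TRUE)
  corr <- sapply(per_site, function(s) s$correlation[ut])
  qmat <- sapply(per_site, function(s)
    stats::p.adjust(s$pseudo_p[ut], method = "BH"))
  if (is.null(dim(corr))) { corr <- matrix(corr, ncol = length(per_site)) }
  if (is.null(dim(qmat))) { qmat <- matrix(qmat, ncol = length(per_site)) }
  sgn <- sign(corr)
  keep <- apply(qmat < fdr_alpha, 1, all) &
    apply(sgn, 1, function(s) all(s == s[1]) && s[1] != 0)
  out <- data.frame(
    taxon_a = pmin(taxa[ut[, 1]], taxa[ut[, 2]]),
    taxon_b = pmax(taxa[ut[, 1]], taxa[ut[, 2]]),
    mean_correlation = rowMeans(corr),
    max_q = apply(qmat, 1, max),
    stringsAsFactors = FALSE)
  site_names <- names(per_site) %||% paste0("site", seq_along(per_site))
  for (j in seq_along(per_site))
    out[[paste0("corr_", site_names[j])]] <- corr[, j]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "organ") <- organ
  attr(out, "fdr_alpha") <- fdr_alpha
  class(out) <- c("organ_network", "data.frame")
  out
}

#' Annotate organ-specific edges across organ networks
#'
#' An edge is specific to organ O if (a) the absolute difference between its
#' correlation in O and in every other organ where the edge is retained
#' exceeds `diff_threshold`, or (b) its absolute correlation exceeds
#' `strength_threshold` and the edge is retained in no other organ.
#'
#' @param networks named list (organ -> `organ_network`).
#' @param diff_threshold between-organ correlation difference (default 0.6).
#' @param strength_threshold unique-edge strength (default 0.6).
#' @param any_organ if TRUE, rule (a) requires the difference against at
#'   least one other organ rather than against all of them.
#' @return the networks with added columns `specific` and
#'   `specificity_reason`.
#' @export
organ_specific_edges <- function(networks, diff_threshold = 0.6,
                                 strength_threshold = 0.6,
                                 any_organ = FALSE) {
  stopifnot(length(networks) >= 2)
  key <- function(nw) paste(nw$taxon_a, nw$taxon_b, sep = "|")
  keys <- lapply(networks, key)
  for (o in names(networks)) {
    nw <- networks[[o]]
    specific <- logical(nrow(nw)); reason <- rep(NA_character_, nrow(nw))
    if (nrow(nw)) {
      for (i in seq_len(nrow(nw))) {
        k <- keys[[o]][i]
        others <- setdiff(names(networks), o)
        corr_others <- unlist(lapply(others, function(oo) {
          j <- match(k, keys[[oo]])
          if (is.na(j)) NULL else networks[[oo]]$mean_correlation[j]
        }))
        if (length(corr_others) == 0) {
          if (abs(nw$mean_correlation[i]) > strength_threshold) {
            specific[i] <- TRUE
            reason[i] <- sprintf("unique_strength_gt_%g", strength_threshold)
          }
        } else {
          diffs <- abs(nw$mean_correlation[i] - corr_others)
          hit <- if (any_organ) any(diffs > diff_threshold) else
            all(diffs > diff_threshold)
          if (hit) {
            specific[i] <- TRUE
            reason[i] <- sprintf("difference_gt_%g", diff_threshold)
          }
        }
      }
    }
    nw$specific <- specific
    nw$specificity_reason <- reason
    networks[[o]] <- nw
  }
  networks
}

#' Per-organ SparCC network pipeline
#'
#' Splits the table by organ and site, restricts to taxa detected in at least
#' `taxa_min_prevalence` of the organ's samples, runs [sparcc()] per site,
#' applies the cross-site consistency rule, and annotates organ-specific
#' edges across organs.
#'
#' @param table `count_table` or matrix.
#' @param samples `sample_table`.
#' @param fdr_alpha FDR level for edge retention (default 0.05).
#' @param taxa_min_prevalence minimum detection fraction within the organ
#'   (default 0.3).
#' @param min_site_samples sites with fewer samples are skipped (default 5).
#' @param diff_threshold,strength_threshold see [organ_specific_edges()].
#' @param seed integer seed.
#' @param ... further arguments passed to [sparcc()].
#' @return named list (organ -> annotated `organ_network`).
#' @export
organ_networks <- function(table, samples, fdr_alpha = 0.05,
                           taxa_min_prevalence = 0.3, min_site_samples = 5,
                           diff_threshold = 0.6, strength_threshold = 0.6,
                           seed = 1L, ...) {
  m <- as_counts(table)
  df <- as.data.frame(samples)
  df <- df[match(colnames(m), df$sample_id), , drop = FALSE]
  organs <- setdiff(unique(df$organ), "negative_control")
  networks <- list()
  for (o in organs) {
    sel <- df$organ == o
    mo <- m[, sel, drop = FALSE]
    keep <- rowMeans(mo > 0) >= taxa_min_prevalence
    if (sum(keep) < 4) next
    mo <- mo[keep, , drop = FALSE]
    sites <- split(seq_len(ncol(mo)), df$site[sel])
    sites <- sites[vapply(sites, length, integer(1)) >= min_site_samples]
    if (!length(sites)) next
    per_site <- lapply(seq_along(sites), function(j)
      sparcc(mo[, sites[[j]], drop = FALSE], seed = seed + j, ...))
    names(per_site) <- names(sites)
    networks[[o]] <- consistent_organ_correlations(per_site, fdr_alpha,
                                                   organ = o)
  }
  if (length(networks) >= 2)
    networks <- organ_specific_edges(networks, diff_threshold,
                                     strength_threshold)
  networks
}
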