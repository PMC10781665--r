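# Diversity module: inverse Simpson alpha diversity, rank collapsing,
# UniFrac beta diversity, PCoA ordination, covariate-adjusted PERMANOVA.

#' Inverse Simpson diversity of one sample
#'
#' With proportions `p_i`, returns `1 / sum(p_i^2)` — the effective number of
#' equally abundant taxa. The relative form divides by the observed richness
#' `S`, giving an evenness value in (0, 1] that equals 1 iff the observed
#' taxa are perfectly even.
#'
#' @param x vector of non-negative counts with at least one positive entry.
#' @param relative divide by observed richness?
#' @return scalar diversity value.
#' @export
inverse_simpson <- function(x, relative = FALSE) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(x)
  if (tot == 0)
    stop("diversity undefined for an all-zero sample", call. = FALSE)
  p <- x / tot
  d <- 1 / sum(p^2)
  if (relative) d / sum(x > 0) else d
}

#' Per-sample alpha diversity table
#'
#' Emits both the plain inverse Simpson index and its richness-normalized
#' (relative) form, plus the observed richness, for every sample.
#'
#' @param table `count_table` or matrix.
#' @return data frame with columns `sample_id`, `richness`, `invsimpson`,
#'   `relative_invsimpson`.
#' @export
alpha_diversity <- function(table) {
  m <- as_counts(table)
  keep <- colSums(m) > 0
  if (any(!keep))
    warning(sprintf("skipping %d empty sample(s)", sum(!keep)), call. = FALSE)
  m <- m[, keep, drop = FALSE]
  data.frame(
    sample_id = colnames(m),
    richness = colSums(m > 0),
    invsimpson = apply(m, 2, inverse_simpson),
    relative_invsimpson = apply(m, 2, inverse_simpson, relative = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse a count table to a taxonomic rank
#'
#' Counts are summed over taxa sharing the lineage down to `rank`. Taxa
#' unclassified at `rank` are pooled into one `unclassified` bucket per parent
#' lineage. The collapsed table's taxon ids are the `;`-joined lineages; a
#' matching collapsed taxonomy is attached as attribute `"taxonomy"` so
#' collapses can be chained.
#'
#' @param table `count_table` or matrix.
#' @param taxonomy `taxonomy_table` covering the table's taxa.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return collapsed `count_table`.
#' @export
collapse_rank <- function(table, taxonomy, rank) {
  rank <- match.arg(rank, .RANKS)
  m <- as_counts(table)
  tax <- as.data.frame(taxonomy)
  idx <- match(rownames(m), tax$taxon_id)
  if (any(is.na(idx)))
    stop(sprintf("taxa missing from taxonomy: %s",
                 paste(rownames(m)[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  depth <- match(rank, .RANKS)
  lin <- tax[idx, .RANKS[seq_len(depth)], drop = FALSE]
  unclassified <- lin[[rank]] == ""
  lin[[rank]][unclassified] <- "unclassified"
  key <- apply(lin, 1, paste, collapse = ";")
  collapsed <- rowsum(m, group = key, reorder = TRUE)
  out <- count_table(collapsed)
  parts <- strsplit(rownames(collapsed), ";", fixed = TRUE)
  tax_out <- data.frame(taxon_id = rownames(collapsed),
                        stringsAsFactors = FALSE)
  for (j in seq_along(.RANKS)) {
    tax_out[[.RANKS[j]]] <- if (j <= depth)
      vapply(parts, `[`, character(1), j) else ""
  }
  tax_out[tax_out == "unclassified"] <- ""
  attr(out, "taxonomy") <- taxonomy_table(tax_out)
  out
}

#' UniFrac distances between samples
#'
#' Unweighted UniFrac is the fraction of tree branch length unique to one of
#' the two communities, over the branch length spanned by their union; the
#' weighted variant is the standard abundance-weighted, normalized form. The
#' computation is delegated to [phyloseq::UniFrac()]; this wrapper enforces a
#' rooted tree with branch lengths and that every taxon with nonzero counts is
#' a tree leaf.
#'
#' @param table `count_table` or matrix.
#' @param tree rooted `phylo` with branch lengths.
#' @param weighted use abundance-weighted (normalized) UniFrac?
#' @return a `dist` over the table's samples, entries in `[0, 1]`.
#' @export
unifrac <- function(table, tree, weighted = FALSE) {
  m <- as_counts(table)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; UniFrac is undefined", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("UniFrac requires a rooted tree", call. = FALSE)
  nonzero <- rownames(m)[rowSums(m) > 0]
  missing_tips <- setdiff(nonzero, tree$tip.label)
  if (length(missing_tips))
    stop(sprintf("taxa absent from the tree: %s",
                 paste(missing_tips, collapse = ", ")), call. = FALSE)
  m <- m[intersect(rownames(m), tree$tip.label), , drop = FALSE]
  if (length(setdiff(tree$tip.label, rownames(m))) > 0)
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, rownames(m)))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(m, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  phyloseq::UniFrac(ps, weighted = weighted, normalized = TRUE)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling of the double-centered squared-distance matrix. Axes are
#' ordered by decreasing eigenvalue; negative eigenvalues are reported but
#' their axes are never returned.
#'
#' @param dm `dist` or symmetric matrix with zero diagonal.
#' @param k number of axes requested (`<=` samples - 1).
#' @return list with `coordinates` (samples x k', k' <= k positive axes) and
#'   `eigenvalues` (all of them, including any negative ones).
#' @export
pcoa_ordination <- function(dm, k = 2) {
  m <- as.matrix(dm)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  n <- nrow(m)
  stopifnot(k >= 1, k <= n - 1)
  sc <- stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE)
  eig <- sc$eig
  pos <- which(eig[seq_len(k)] > 1e-12)
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  if (length(pos) < k)
    warning(sprintf("only %d positive-eigenvalue axes available (requested %d)",
                    length(pos), k), call. = FALSE)
  list(coordinates = coords, eigenvalues = eig)
}

#' Covariate-adjusted PERMANOVA
#'
#' Sequential sums-of-squares partition of a distance matrix with covariates
#' entered before the grouping factor (vegan's `adonis2` with `by = "terms"`),
#' permuting raw sample labels. The p-value is
#' `(1 + #{permuted F >= observed F}) / (1 + n_perm)` for the group term, so
#' it can never fall below `1 / (n_perm + 1)`.
#'
#' @param dm `dist` or symmetric matrix over samples.
#' @param samples `sample_table` (or data frame) covering the samples.
#' @param group_var column whose effect is tested (>= 2 levels, each with
#'   >= 2 samples).
#' @param covariates character vector of adjustment columns (default none);
#'   the usual set is `c("age", "sex", "BMI")`.
#' @param n_perm number of permutations (default 999; 10000 for final runs).
#' @param seed integer seed making the permutations reproducible.
#' @return list of class `permanova_result`: `pseudo_F`, `p_value`, `R2`,
#'   `n_permutations`, `terms`, `table` (the full adonis2 table).
#' @export
permanova <- function(dm, samples, group_var, covariates = character(),
                      n_perm = 999, seed = 1L) {
  m <- as.matrix(dm)
  ids <- rownames(m) %||% colnames(m)
  df <- as.data.frame(samples)
  df <- df[match(ids, df$sample_id), , drop = FALSE]
  if (any(is.na(df$sample_id)))
    stop("metadata does not cover all samples in the distance matrix",
         call. = FALSE)
  g <- df[[group_var]]
  tab <- table(g)
  if (length(tab) < 2)
    stop(sprintf("'%s' needs at least two levels", group_var), call. = FALSE)
  if (any(tab < 2))
    stop(sprintf("every level of '%s' needs at least two samples", group_var),
         call. = FALSE)
  rhs <- paste(c(covariates, group_var), collapse = " + ")
  # adonis2 resolves the response in the calling frame, so the distance must
  # live as a local here (the promise below evaluates in this frame)
  .biogeo_lhs_dist <- stats::as.dist(m)
  fml <- stats::as.formula(paste(".biogeo_lhs_dist ~", rhs),
                           env = environment())
  res <- with_seed(seed,
                   vegan::adonis2(fml, data = df, permutations = n_perm,
                                  by = "terms"))
  row <- match(group_var, rownames(res))
  structure(list(pseudo_F = res$F[row], p_value = res$`Pr(>F)`[row],
                 R2 = res$R2[row], n_permutations = n_perm,
                 terms = covariates, table = as.data.frame(res)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations%s)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations,
              if (length(x$terms))
                paste0("; adjusted for ", paste(x$terms, collapse = ", "))
              else ""))
  invisible(x)
}
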