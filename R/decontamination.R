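# Contamination / noise controls: depth rarefaction, rare-taxon removal,
# and prevalence-based contaminant scoring against negative controls.
# Stage order in the pipeline wrapper is fixed: rarefy -> filter_rare ->
# score/remove.

#' Rarefy a count table to a fixed depth
#'
#' Subsamples reads without replacement so each retained sample has library
#' size exactly `depth`. Samples below `depth` are dropped with a warning
#' (never upsampled). `mode = "scale"` instead rescales counts to the target
#' depth and rounds, keeping all samples.
#'
#' @param table `count_table` or taxa-by-samples matrix.
#' @param depth target library size (default 10000).
#' @param seed integer seed for the subsampling.
#' @param mode `"subsample"` (default, without replacement) or `"scale"`.
#' @return rarefied `count_table`.
#' @export
rarefy_counts <- function(table, depth = 10000, seed = 1L,
                          mode = c("subsample", "scale")) {
  mode <- match.arg(mode)
  m <- as_counts(table)
  stopifnot(depth >= 1)
  ls <- colSums(m)
  if (mode == "scale") {
    out <- round(sweep(m, 2, pmax(ls, 1), "/") * depth)
    return(count_table(out))
  }
  keep <- ls >= depth
  if (!any(keep))
    stop(sprintf("all %d samples are below depth %d", ncol(m), depth),
         call. = FALSE)
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(m)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  m <- m[, keep, drop = FALSE]
  # muffle vegan's advisory about uniformly large counts; inputs here are
  # validated integer counts by construction
  out <- with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(m), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  count_table(out)
}

#' Remove taxa that never reach a relative-abundance threshold
#'
#' A taxon is retained iff its relative abundance is at least `threshold` in
#' at least one sample; taxa below the threshold in all samples are discarded
#' as noise. The default 0.001 corresponds to 0.1%.
#'
#' @param table `count_table` or matrix.
#' @param threshold relative-abundance fraction in (0, 1).
#' @return filtered `count_table` (possibly with zero taxa).
#' @export
filter_rare <- function(table, threshold = 0.001) {
  stopifnot(threshold > 0, threshold < 1)
  m <- as_counts(table)
  ls <- colSums(m)
  rel <- sweep(m, 2, pmax(ls, 1), "/")
  keep <- apply(rel, 1, max) >= threshold
  count_table(m[keep, , drop = FALSE])
}

#' Score taxa as contaminants from negative-control prevalence
#'
#' For each taxon, detection (count > 0) is tabulated in a 2x2 of negative
#' controls versus biological samples. The score is a one-sided p-value that
#' control prevalence exceeds biological prevalence, from a chi-squared test
#' with continuity correction, falling back to the exact hypergeometric
#' (one-sided Fisher) test whenever any expected cell is below 5. Taxa whose
#' control prevalence does not exceed their biological prevalence get score 1
#' (the test is directional: genuine taxa sparsely present in controls are
#' never flagged). A taxon is a contaminant iff score < `score_threshold` and
#' control prevalence >= sample prevalence.
#'
#' @param table `count_table` or matrix (controls included as columns).
#' @param samples `sample_table` covering the table's samples; negative
#'   controls are rows with organ `"negative_control"`.
#' @param score_threshold flag threshold in (0, 1), default 0.5.
#' @return data frame of class `contaminant_report`: `taxon_id`,
#'   `prevalence_in_controls`, `prevalence_in_samples`, `score`,
#'   `is_contaminant`; control sample ids kept in attribute
#'   `control_samples`.
#' @export
score_contaminants <- function(table, samples, score_threshold = 0.5) {
  stopifnot(score_threshold > 0, score_threshold < 1)
  m <- as_counts(table)
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id)))
    stop("metadata does not cover all samples in the table", call. = FALSE)
  is_ctrl <- samples$organ == "negative_control"
  if (!any(is_ctrl))
    stop("no negative controls present; cannot score contaminants",
         call. = FALSE)
  if (all(is_ctrl))
    stop("no biological samples present", call. = FALSE)
  pres <- m > 0
  k_c <- rowSums(pres[, is_ctrl, drop = FALSE]); n_c <- sum(is_ctrl)
  k_s <- rowSums(pres[, !is_ctrl, drop = FALSE]); n_s <- sum(!is_ctrl)
  prev_c <- k_c / n_c
  prev_s <- k_s / n_s
  score <- vapply(seq_len(nrow(m)), function(i) {
    if (prev_c[i] <= prev_s[i]) return(1)
    tab <- matrix(c(k_c[i], n_c - k_c[i], k_s[i], n_s - k_s[i]), nrow = 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      stats::fisher.test(tab, alternative = "greater")$p.value
    } else {
      suppressWarnings(stats::prop.test(
        x = c(k_c[i], k_s[i]), n = c(n_c, n_s),
        alternative = "greater", correct = TRUE)$p.value)
    }
  }, numeric(1))
  score[!is.finite(score)] <- 1
  rep <- data.frame(taxon_id = rownames(m),
                    prevalence_in_controls = prev_c,
                    prevalence_in_samples = prev_s,
                    score = score,
                    is_contaminant = score < score_threshold & prev_c >= prev_s,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(rep, "control_samples") <- samples$sample_id[is_ctrl]
  attr(rep, "score_threshold") <- score_threshold
  class(rep) <- c("contaminant_report", "data.frame")
  rep
}

#' Remove flagged contaminants (and the control columns)
#'
#' @param table `count_table` or matrix.
#' @param report a `contaminant_report` covering all taxa of the table.
#' @return `count_table` without flagged taxa and without negative-control
#'   samples.
#' @export
remove_contaminants <- function(table, report) {
  m <- as_counts(table)
  missing_taxa <- setdiff(rownames(m), report$taxon_id)
  if (length(missing_taxa))
    stop(sprintf("report does not cover taxa: %s",
                 paste(missing_taxa, collapse = ", ")), call. = FALSE)
  flagged <- report$taxon_id[report$is_contaminant]
  keep_taxa <- setdiff(rownames(m), flagged)
  keep_samples <- setdiff(colnames(m), attr(report, "control_samples"))
  count_table(m[keep_taxa, keep_samples, drop = FALSE])
}

#' Full decontamination pipeline
#'
#' Applies the three noise controls in their fixed order: rarefaction to
#' `target_depth`, rare-taxon filtering at `rare_threshold`, then contaminant
#' scoring and removal. `mode = "strict"` removes every taxon detected in any
#' negative control instead of only the scored contaminants.
#'
#' @param table `count_table` or matrix (with control columns).
#' @param samples `sample_table`.
#' @param target_depth rarefaction depth (default 10000).
#' @param rare_threshold relative-abundance floor (default 0.001).
#' @param score_threshold contaminant score threshold (default 0.5).
#' @param mode `"decontam"` (scored flags) or `"strict"` (any detection in a
#'   control).
#' @param seed integer seed for rarefaction.
#' @return list with `table` (cleaned `count_table`), `report`
#'   (`contaminant_report`), and `samples` (metadata restricted to retained
#'   samples).
#' @export
decontaminate <- function(table, samples, target_depth = 10000,
                          rare_threshold = 0.001, score_threshold = 0.5,
                          mode = c("decontam", "strict"), seed = 1L) {
  mode <- match.arg(mode)
  rare <- rarefy_counts(table, depth = target_depth, seed = seed)
  filt <- filter_rare(rare, threshold = rare_threshold)
  report <- score_contaminants(filt, samples, score_threshold = score_threshold)
  if (mode == "strict") {
    report$is_contaminant <- report$prevalence_in_controls > 0
  }
  cleaned <- remove_contaminants(filt, report)
  kept <- samples[match(sample_ids(cleaned), samples$sample_id), ,
                  drop = FALSE]
  class(kept) <- c("sample_table", "data.frame")
  list(table = cleaned, report = report, samples = kept)
}
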