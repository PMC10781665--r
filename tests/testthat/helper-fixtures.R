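# Shared fixture builders; everything is generated in code.

rand_counts <- function(n_taxa = 10, n_samples = 6, seed = 1,
                        lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("T%03d", seq_len(n_taxa)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

write_newick <- function(text) {
  path <- tempfile(fileext = ".nwk")
  writeLines(text, path)
  path
}

small_meta <- function(sample_ids, organ = "stomach", subject = "sub01",
                       sample_type = "mucosa", site = "fundus") {
  sample_table(data.frame(
    sample_id = sample_ids,
    subject_id = subject,
    organ = organ,
    site = site,
    sample_type = sample_type,
    stringsAsFactors = FALSE))
}

# multinomial counts from a fraction matrix (taxa x samples)
counts_from_fractions <- function(frac, depth = 20000, seed = 1) {
  set.seed(seed)
  counts <- sapply(seq_len(ncol(frac)), function(j)
    rmultinom(1, depth, frac[, j])[, 1])
  dimnames(counts) <- list(rownames(frac) %||%
                             sprintf("T%03d", seq_len(nrow(frac))),
                           sprintf("S%03d", seq_len(ncol(frac))))
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
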