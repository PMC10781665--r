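# IO module: count tables, sample metadata, taxonomy, trees, study bundles.
#
# TSV is the canonical interchange format; BIOM-JSON is accepted read-only.
# All loaders preserve file order and are deterministic; no loader consumes
# random numbers.

#' Construct a validated count table
#'
#' A count table is the universal currency of the pipeline: a non-negative
#' integer matrix of taxa (rows) by samples (columns). Library sizes are the
#' column sums, recomputed on construction.
#'
#' @param counts numeric matrix with unique rownames (taxon ids) and unique
#'   colnames (sample ids); all cells non-negative integers.
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("count table requires taxon ids as rownames", call. = FALSE)
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("count table requires sample ids as colnames", call. = FALSE)
  rn <- normalize_id(rownames(counts) %||% character(), "taxon id")
  cn <- normalize_id(colnames(counts) %||% character(), "sample id")
  check_unique(rn, "taxon id")
  check_unique(cn, "sample id")
  bad <- which(!is_wholenumber(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "counts must be non-negative integers; first offender: taxon '%s', sample '%s' (value %s)",
      rn[bad[1, 1]], cn[bad[1, 2]], format(counts[bad[1, , drop = FALSE]])),
      call. = FALSE)
  }
  counts <- round(counts)
  rownames(counts) <- rn
  colnames(counts) <- cn
  structure(list(counts = counts), class = "count_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @export
as.matrix.count_table <- function(x, ...) x$counts

#' Accessors for count tables
#'
#' @param x a `count_table`.
#' @return `taxon_ids()` and `sample_ids()` return character vectors;
#'   `library_sizes()` returns the named vector of per-sample column sums.
#' @export
taxon_ids <- function(x) rownames(as_counts(x))

#' @rdname taxon_ids
#' @export
sample_ids <- function(x) colnames(as_counts(x))

#' @rdname taxon_ids
#' @export
library_sizes <- function(x) colSums(as_counts(x))

# Accept count_table or bare matrix everywhere downstream.
as_counts <- function(x) {
  if (inherits(x, "count_table")) return(x$counts)
  if (inherits(x, "study_bundle")) return(x$counts$counts)
  if (is.matrix(x)) return(count_table(x)$counts)
  stop("expected a count_table or a taxa-by-samples matrix", call. = FALSE)
}

#' Read a count table
#'
#' TSV dialect: UTF-8, tab-delimited, first row `taxon_id` followed by sample
#' ids, taxa as rows. BIOM-JSON files are read through the biomformat package.
#'
#' @param path file path.
#' @param dialect `"tsv"` (canonical) or `"biom-json"` (read-only support).
#' @return a `count_table`; row/column ordering preserved from the file.
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (dialect == "biom-json") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(m))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("malformed count table: no columns", call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) && length(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric count at taxon '%s', sample '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
    }
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  count_table(m)
}

#' Write a count table as TSV
#'
#' Row/column order of the object is preserved, so `read_count_table()` of the
#' written file round-trips bit-exactly.
#'
#' @param x a `count_table`.
#' @param path output file path.
#' @export
write_count_table <- function(x, path) {
  m <- as_counts(x)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated sample table
#'
#' Per-sample metadata driving pairing, grouping and covariate adjustment.
#' Required columns: `sample_id`, `subject_id`, `organ`, `site`,
#' `sample_type`. `organ` and `sample_type` are normalized
#' (see [normalize_label()]) and validated against the controlled
#' vocabularies; any further columns are retained verbatim as covariates.
#' Negative controls must carry `organ = "negative_control"` and
#' `sample_type = "control"` (and vice versa).
#'
#' @param df data frame of per-sample metadata.
#' @return object of class `sample_table` (a validated data frame).
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "subject_id", "organ", "site", "sample_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("sample table missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- normalize_id(df$sample_id, "sample id")
  check_unique(df$sample_id, "sample id")
  df$subject_id <- normalize_id(df$subject_id, "subject id")
  df$organ <- normalize_label(df$organ)
  df$sample_type <- normalize_label(df$sample_type)
  df$site <- trimws(as.character(df$site))
  bad_org <- setdiff(unique(df$organ), .ORGANS)
  if (length(bad_org)) {
    stop(sprintf("unknown organ level(s): %s (allowed: %s)",
                 paste(bad_org, collapse = ", "),
                 paste(.ORGANS, collapse = ", ")), call. = FALSE)
  }
  bad_typ <- setdiff(unique(df$sample_type), .SAMPLE_TYPES)
  if (length(bad_typ)) {
    stop(sprintf("unknown sample_type level(s): %s (allowed: %s)",
                 paste(bad_typ, collapse = ", "),
                 paste(.SAMPLE_TYPES, collapse = ", ")), call. = FALSE)
  }
  inconsistent <- xor(df$organ == "negative_control", df$sample_type == "control")
  if (any(inconsistent)) {
    stop(sprintf(
      "negative controls must have organ 'negative_control' and sample_type 'control'; offenders: %s",
      paste(df$sample_id[inconsistent], collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read / write a sample table (TSV)
#'
#' @param path file path.
#' @return a `sample_table`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  sample_table(utils::read.delim(path, header = TRUE, sep = "\t",
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE,
                                 colClasses = NA))
}

#' @rdname read_sample_table
#' @param x a `sample_table`.
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a taxonomy table
#'
#' Holds a 7-rank lineage (kingdom..species) per taxon. Accepts either a data
#' frame with a `lineage` column of Greengenes-style semicolon strings
#' (optional `k__`-style rank prefixes are stripped) or with the seven rank
#' columns spelled out. Empty strings denote unclassified ranks.
#'
#' @param df data frame with column `taxon_id` and either `lineage` or the
#'   seven rank columns.
#' @return object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df))
    stop("taxonomy table requires a 'taxon_id' column", call. = FALSE)
  df$taxon_id <- normalize_id(df$taxon_id, "taxon id")
  check_unique(df$taxon_id, "taxon id")
  if ("lineage" %in% names(df)) {
    ranks <- parse_lineage(df$lineage)
    df <- cbind(df["taxon_id"], ranks)
  } else {
    miss <- setdiff(.RANKS, names(df))
    if (length(miss)) {
      stop(sprintf("taxonomy table missing rank column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (r in .RANKS) df[[r]] <- trimws(as.character(df[[r]]))
    df <- df[c("taxon_id", .RANKS)]
  }
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Parse Greengenes-style lineage strings
#'
#' Splits on `;`, trims whitespace, strips optional rank prefixes such as
#' `g__`, and pads/truncates to the 7 standard ranks.
#'
#' @param lineage character vector of semicolon-separated lineages.
#' @return data frame with one column per rank.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-zA-Z]__", "", p)
    length(p) <- length(.RANKS)
    p[is.na(p)] <- ""
    p
  }, character(length(.RANKS))))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- .RANKS
  out
}

#' Format lineages back to semicolon strings
#' @param tax a `taxonomy_table`.
#' @return character vector of `;`-joined lineages (no rank prefixes).
#' @export
format_lineage <- function(tax) {
  apply(as.data.frame(tax)[.RANKS], 1, paste, collapse = ";")
}

#' Read / write a taxonomy table (TSV)
#'
#' @param path file path.
#' @return a `taxonomy_table`.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  taxonomy_table(utils::read.delim(path, header = TRUE, sep = "\t",
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE,
                                   colClasses = "character"))
}

#' @rdname read_taxonomy_table
#' @param x a `taxonomy_table`.
#' @export
write_taxonomy_table <- function(x, path) {
  df <- data.frame(taxon_id = x$taxon_id, lineage = format_lineage(x),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that additionally enforces the
#' presence of branch lengths (UniFrac is undefined without them).
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
read_phylo_tree <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("could not parse newick file: %s", path),
                          call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; UniFrac is undefined", call. = FALSE)
  tree
}

#' Assemble a cross-validated study bundle
#'
#' Collects the count table, sample metadata, taxonomy and optional phylogeny
#' into one object, checking referential integrity. All mismatches are
#' reported at once. Taxa missing from the taxonomy are tolerated: they get an
#' empty lineage with a warning. Tree tips not present in the count table are
#' pruned with a warning.
#'
#' @param counts `count_table`.
#' @param samples `sample_table`.
#' @param taxonomy optional `taxonomy_table`.
#' @param tree optional rooted `phylo` with branch lengths.
#' @return object of class `study_bundle` with elements `counts`, `samples`,
#'   `taxonomy`, `tree`.
#' @export
assemble_bundle <- function(counts, samples, taxonomy = NULL, tree = NULL) {
  if (!inherits(counts, "count_table")) counts <- count_table(counts)
  if (!inherits(samples, "sample_table")) samples <- sample_table(samples)
  problems <- character()
  extra_counts <- setdiff(sample_ids(counts), samples$sample_id)
  if (length(extra_counts)) {
    problems <- c(problems, sprintf(
      "samples in counts absent from metadata: %s",
      paste(extra_counts, collapse = ", ")))
  }
  extra_meta <- setdiff(samples$sample_id, sample_ids(counts))
  if (length(extra_meta)) {
    problems <- c(problems, sprintf(
      "samples in metadata absent from counts: %s",
      paste(extra_meta, collapse = ", ")))
  }
  if (length(problems)) {
    stop(paste(c("study bundle integrity error:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  samples <- samples[match(sample_ids(counts), samples$sample_id), ,
                     drop = FALSE]
  class(samples) <- c("sample_table", "data.frame")
  if (!is.null(taxonomy)) {
    if (!inherits(taxonomy, "taxonomy_table")) taxonomy <- taxonomy_table(taxonomy)
    missing_tax <- setdiff(taxon_ids(counts), taxonomy$taxon_id)
    if (length(missing_tax)) {
      warning(sprintf("taxa missing from taxonomy, lineage left empty: %s",
                      paste(missing_tax, collapse = ", ")), call. = FALSE)
      pad <- data.frame(taxon_id = missing_tax, stringsAsFactors = FALSE)
      for (r in .RANKS) pad[[r]] <- ""
      taxonomy <- taxonomy_table(rbind(as.data.frame(taxonomy), pad))
    }
  }
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(tree$edge.length))
      stop("tree has no branch lengths", call. = FALSE)
    extra_tips <- setdiff(tree$tip.label, taxon_ids(counts))
    if (length(extra_tips)) {
      warning(sprintf("pruning %d tree tip(s) absent from the count table",
                      length(extra_tips)), call. = FALSE)
      tree <- ape::drop.tip(tree, extra_tips)
    }
  }
  structure(list(counts = counts, samples = samples, taxonomy = taxonomy,
                 tree = tree),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("study_bundle: %d taxa, %d samples (%d subjects, %d organs)%s%s\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              length(unique(x$samples$subject_id)),
              length(setdiff(unique(x$samples$organ), "negative_control")),
              if (is.null(x$taxonomy)) "" else ", taxonomy",
              if (is.null(x$tree)) "" else ", tree"))
  invisible(x)
}

#' Validate an on-disk study for integrity
#'
#' Loads the files and runs [assemble_bundle()]; instead of stopping, returns
#' the collected problems as a character vector (empty when valid). Used by
#' the command-line `validate` entry point.
#'
#' @param counts_path,meta_path,tax_path,tree_path file paths; taxonomy and
#'   tree optional.
#' @return character vector of human/machine-readable problems.
#' @export
validate_study <- function(counts_path, meta_path, tax_path = NULL,
                           tree_path = NULL) {
  problems <- character()
  res <- tryCatch({
    counts <- read_count_table(counts_path)
    samples <- read_sample_table(meta_path)
    taxonomy <- if (!is.null(tax_path)) read_taxonomy_table(tax_path)
    tree <- if (!is.null(tree_path)) read_phylo_tree(tree_path)
    withCallingHandlers(
      assemble_bundle(counts, samples, taxonomy, tree),
      warning = function(w) {
        problems <<- c(problems, paste("warning:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) problems <- c(problems, paste("error:", res))
  problems
}
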