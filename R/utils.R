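# Shared vocabularies and small helpers.

#' Controlled vocabularies
#'
#' Organ, sample-type and taxonomic-rank vocabularies used throughout the
#' package. Labels are stored in normalized form (lower case, internal
#' whitespace replaced by underscores).
#'
#' @name vocabularies
#' @keywords internal
NULL

.ORGANS <- c("skin", "oral_cavity", "esophagus", "stomach",
             "small_intestine", "appendix", "large_intestine",
             "negative_control")

.SAMPLE_TYPES <- c("mucosa", "lumen", "gastric_juice", "surface", "control")

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Normalize a categorical label
#'
#' Trims surrounding whitespace, lower-cases, and replaces internal runs of
#' whitespace with a single underscore, so that e.g. `"Oral cavity "` and
#' `"oral_cavity"` denote the same level.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("\\s+", "_", x)
  tolower(x)
}

# Identifiers: case-sensitive after trimming; internal whitespace forbidden.
normalize_id <- function(x, what = "identifier") {
  x <- trimws(as.character(x))
  bad <- grepl("\\s", x)
  if (any(bad)) {
    stop(sprintf("internal whitespace forbidden in %ss: %s",
                 what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d)) {
    stop(sprintf("duplicate %ss: %s", what, paste(d, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Seed handling: every randomized operation takes an explicit integer seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
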