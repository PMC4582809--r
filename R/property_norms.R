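#' Property-norm container
#'
#' A set of property norms is a concept-by-feature matrix of production
#' frequencies: the number of norming participants who listed a given feature
#' for a given concept. Concepts optionally carry a domain label
#' (living/nonliving/other) and a finer category label (animal, tool, ...).
#'
#' @param pf integer-valued matrix, concepts in rows, features in columns,
#'   with unique row and column names. Zeros denote absent concept-feature
#'   pairs.
#' @param domain optional character vector of per-concept domain labels,
#'   recycled or named by concept.
#' @param category optional character vector of per-concept category labels.
#' @return An object of class `property_norms` with elements `pf`, `domain`,
#'   `category`.
#' @export
property_norms <- function(pf, domain = NULL, category = NULL) {
  if (!is.matrix(pf) || !is.numeric(pf))
    stop("`pf` must be a numeric matrix (concepts x features)")
  if (is.null(rownames(pf)) || is.null(colnames(pf)))
    stop("`pf` must have concept row names and feature column names")
  if (anyDuplicated(rownames(pf))) stop("duplicate concept labels")
  if (anyDuplicated(colnames(pf))) stop("duplicate feature labels")
  if (any(!is.finite(pf)) || any(pf < 0))
    stop("production frequencies must be finite and non-negative")
  if (any(pf != round(pf)))
    stop("production frequencies must be integer counts")
  if (any(rowSums(pf > 0) == 0))
    stop("every concept must have at least one feature with pf > 0")
  domain <- norm_concept_labels(domain, rownames(pf), "other")
  category <- norm_concept_labels(category, rownames(pf), "unknown")
  structure(list(pf = pf, domain = domain, category = category),
            class = "property_norms")
}

norm_concept_labels <- function(x, concepts, default) {
  if (is.null(x)) return(stats::setNames(rep(default, length(concepts)), concepts))
  if (!is.null(names(x))) {
    missing <- setdiff(concepts, names(x))
    if (length(missing))
      stop("labels missing for concepts: ", paste(missing, collapse = ", "))
    return(x[concepts])
  }
  if (length(x) == 1L) x <- rep(x, length(concepts))
  if (length(x) != length(concepts))
    stop("label vector length does not match number of concepts")
  stats::setNames(x, concepts)
}

#' @export
print.property_norms <- function(x, ...) {
  cat(sprintf("Property norms: %d concepts x %d features (%s)\n",
              nrow(x$pf), ncol(x$pf),
              paste(sprintf("%s=%d", names(table(x$domain)), table(x$domain)),
                    collapse = ", ")))
  invisible(x)
}

#' Read property norms from a long-format delimited file
#'
#' Expects one row per attested concept-feature pair with columns
#' `concept`, `feature`, `production_frequency` and optional `domain` and
#' `category` columns. Absent pairs become zeros in the assembled matrix.
#' Labels are matched as exact strings; no case or whitespace normalisation
#' is applied unless `strip_whitespace` is set.
#'
#' @param path path to a CSV (`.csv`) or TSV (anything else) file.
#' @param strip_whitespace trim surrounding whitespace from labels.
#' @return A [property_norms] object.
#' @export
load_property_norms <- function(path, strip_whitespace = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("concept", "feature", "production_frequency")
  if (!all(need %in% names(df)))
    stop("norms file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("no records in norms file")
  if (strip_whitespace) {
    df$concept <- trimws(df$concept)
    df$feature <- trimws(df$feature)
  }
  pfv <- df$production_frequency
  if (!is.numeric(pfv)) {
    pfn <- suppressWarnings(as.numeric(pfv))
    if (anyNA(pfn)) stop("non-numeric production_frequency values")
    pfv <- pfn
  }
  if (any(!is.finite(pfv)) || any(pfv < 0))
    stop("negative or non-finite production_frequency values")
  key <- paste(df$concept, df$feature, sep = ",")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (concept,feature) rows: ", paste(dup, collapse = "; "))
  }
  concepts <- unique(df$concept)
  features <- unique(df$feature)
  pf <- matrix(0, length(concepts), length(features),
               dimnames = list(concepts, features))
  pf[cbind(match(df$concept, concepts), match(df$feature, features))] <- pfv
  dom <- if ("domain" %in% names(df))
    stats::setNames(df$domain, df$concept)[concepts] else NULL
  cat_ <- if ("category" %in% names(df))
    stats::setNames(df$category, df$concept)[concepts] else NULL
  property_norms(pf, domain = dom, category = cat_)
}
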