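#' Score picture-naming responses against target names
#'
#' A response is correct when, after case-folding and trimming, it equals the
#' item's canonical name or any listed synonym. Missing responses (NA or
#' empty, e.g. no answer given) score 0 and are counted in the `n_missing`
#' attribute.
#'
#' @param responses data.frame with columns `participant`, `group`, `item`,
#'   `response`.
#' @param targets data.frame with columns `item`, `name` and optional
#'   `synonyms` (semicolon-separated string or list column).
#' @return data.frame with columns `participant`, `group`, `item`, `correct`
#'   (0/1); attribute `n_missing` counts missing responses.
#' @export
score_naming <- function(responses, targets) {
  stopifnot(all(c("participant", "group", "item", "response") %in% names(responses)),
            all(c("item", "name") %in% names(targets)))
  unknown <- setdiff(responses$item, targets$item)
  if (length(unknown))
    stop("responses for unknown item(s): ", paste(unique(unknown), collapse = ", "))
  canon <- function(s) tolower(trimws(s))
  syn <- if ("synonyms" %in% names(targets)) {
    if (is.list(targets$synonyms)) lapply(targets$synonyms, canon)
    else lapply(strsplit(ifelse(is.na(targets$synonyms), "", targets$synonyms),
                         ";", fixed = TRUE), canon)
  } else rep(list(character()), nrow(targets))
  accepted <- stats::setNames(
    Map(function(nm, sy) unique(c(canon(nm), sy[nzchar(sy)])),
        targets$name, syn), targets$item)
  resp <- responses$response
  missing <- is.na(resp) | !nzchar(trimws(resp))
  correct <- integer(nrow(responses))
  ok <- !missing
  correct[ok] <- mapply(function(r, it) as.integer(r %in% accepted[[it]]),
                        canon(resp[ok]), as.character(responses$item[ok]))
  out <- data.frame(participant = responses$participant,
                    group = responses$group, item = responses$item,
                    correct = correct, stringsAsFactors = FALSE)
  attr(out, "n_missing") <- sum(missing)
  out
}

#' Accuracy summary by grouping factors
#'
#' Mean percent correct and between-participant SEM per cell. Participant
#' means are computed first within each cell, then averaged, so the SEM
#' reflects between-participant variability (the unit of the group-level
#' analyses). Empty cells are flagged.
#'
#' @param acc data.frame with columns `participant`, `correct` and the
#'   factors in `by` (e.g. `group`, `category`, `condition`).
#' @param by character vector of factor columns to summarise over.
#' @return data.frame with per-cell `mean_pct`, `sem_pct`, `n_participants`
#'   and an `empty` flag.
#' @export
accuracy_summary <- function(acc, by = "group") {
  stopifnot(all(c("participant", "correct", by) %in% names(acc)))
  pm <- stats::aggregate(acc$correct,
                         by = c(list(participant = acc$participant),
                                lapply(acc[by], identity)),
                         FUN = mean)
  names(pm)[ncol(pm)] <- "pmean"
  cells <- unique(pm[by])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(pm))
    for (b in by) sel <- sel & pm[[b]] == cells[[b]][i]
    v <- pm$pmean[sel] * 100
    cbind(cells[i, , drop = FALSE],
          data.frame(mean_pct = if (length(v)) mean(v) else NA_real_,
                     sem_pct = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                               else if (length(v)) 0 else NA_real_,
                     n_participants = length(v), empty = length(v) == 0L))
  }))
  rownames(out) <- NULL
  out
}

#' Per-participant accuracy means in wide format
#'
#' Convenience pivot: one row per participant, one column per level of a
#' factor, values are percent correct. Used to feed paired comparisons.
#'
#' @param acc data.frame with `participant`, `correct` and `factor_col`.
#' @param factor_col column whose levels become columns.
#' @return data.frame, first columns `participant` (and `group` if present).
#' @export
participant_means <- function(acc, factor_col) {
  stopifnot(all(c("participant", "correct", factor_col) %in% names(acc)))
  m <- tapply(acc$correct, list(acc$participant, acc[[factor_col]]),
              mean) * 100
  out <- data.frame(participant = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(acc)) {
    g <- acc$group[!duplicated(acc$participant)]
    names(g) <- acc$participant[!duplicated(acc$participant)]
    out <- cbind(out[1], group = unname(g[out$participant]), out[-1])
  }
  rownames(out) <- NULL
  out
}
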