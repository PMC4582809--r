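#' Load a packaged per-patient fixture table
#'
#' The package ships three per-patient summary tables from the lesion study
#' it reanalyses: `table1_volumes` (demographics and lesion volume in cm^3
#' for 14 patients), `table4_naming` (percent correct picture naming by
#' object category) and `table8_wpm` (percent correct word-picture matching
#' for close and distant pairs, by domain). The naming and word-picture
#' tables also carry the printed group mean and SEM rows (including the
#' healthy-control summaries, whose per-participant data were not printed),
#' distinguished by the `row_type` column.
#'
#' @param name one of `"table1_volumes"`, `"table4_naming"`, `"table8_wpm"`.
#' @param rows for the behavioural tables, which rows to return:
#'   `"patient"` (default: per-patient values only) or `"all"`.
#' @return data.frame.
#' @export
load_fixture <- function(name, rows = c("patient", "all")) {
  rows <- match.arg(rows)
  known <- c("table1_volumes", "table4_naming", "table8_wpm")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".csv"), package = "semconf",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("row_type" %in% names(df) && rows == "patient")
    df <- df[df$row_type == "patient", ]
  rownames(df) <- NULL
  df
}

#' Group summaries recomputed from a fixture's per-patient rows
#'
#' Recomputes mean and between-patient SEM per group for every numeric
#' column of a behavioural fixture, for comparison against the printed
#' group rows.
#'
#' @param fixture per-patient fixture data.frame (see [load_fixture]).
#' @return data.frame with one row per group and statistic.
#' @export
fixture_group_summary <- function(fixture) {
  num <- names(fixture)[vapply(fixture, is.numeric, TRUE)]
  groups <- unique(fixture$group)
  do.call(rbind, lapply(groups, function(g) {
    sub <- fixture[fixture$group == g, num, drop = FALSE]
    rbind(data.frame(group = g, stat = "mean", t(colMeans(sub))),
          data.frame(group = g, stat = "sem",
                     t(apply(sub, 2, function(v) stats::sd(v) / sqrt(length(v))))))
  }))
}
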