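#' Run configuration for a reproduction report
#'
#' @param out_dir output directory (created if absent).
#' @param seed seed recorded in the provenance (the fixture analyses are
#'   deterministic; the seed matters only when simulation stages are added).
#' @param alpha significance threshold.
#' @param min_shared shared-feature threshold for norms statistics.
#' @param control_roi ROI partialled out in damage mapping, when profiles
#'   are supplied.
#' @param profiles optional list of `damage_profile` objects.
#' @param effects optional effect-score data.frame (see
#'   [damage_effect_table]).
#' @param directions per-effect one-tailed directions for damage mapping.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, alpha = 0.05, min_shared = 3L,
                       control_roi = "Fusiform", profiles = NULL,
                       effects = NULL, directions = "less") {
  structure(as.list(environment()), class = "run_config")
}

tr_row <- function(effect, tr) {
  data.frame(effect = effect, kind = tr$kind, statistic = tr$statistic,
             df1 = tr$df[1], df2 = if (length(tr$df) > 1) tr$df[2] else NA,
             p = tr$p, tail = tr$tail,
             flags = paste(tr$flags, collapse = ","),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Reproduce the study's summary statistics from the packaged fixtures
#'
#' Runs the available analysis stages and writes a TSV report bundle:
#' recomputed naming group summaries and category comparisons (from the
#' naming fixture), the lesion-volume group comparison (from the volumes
#' fixture), the word-picture matching distance effects (from the
#' word-picture fixture), and — when damage profiles and effect scores are
#' supplied — the damage-by-effect correlation table. The configuration is
#' serialised alongside the outputs for provenance.
#'
#' @param cfg a [run_config].
#' @return (invisibly) a named list of the result tables, also written under
#'   `cfg$out_dir`.
#' @export
run_report <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("semconf %s; R %s",
                   as.character(utils::packageVersion("semconf")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %d", cfg$seed))
  out <- list()

  naming <- load_fixture("table4_naming")
  out$naming_summary <- fixture_group_summary(naming)
  dmg <- naming[naming$group == "vATL-damaged", ]
  tests <- rbind(
    tr_row("living_vs_nonliving_damaged",
           t_test(dmg$living, dmg$nonliving, paired = TRUE)),
    tr_row("animal_vs_tool_damaged",
           t_test(dmg$animal, dmg$tool, paired = TRUE)),
    tr_row("animal_vs_vehicle_damaged",
           t_test(dmg$animal, dmg$vehicle, paired = TRUE)),
    tr_row("fruit_veg_vs_vehicle_damaged",
           t_test(dmg$fruit_veg, dmg$vehicle, paired = TRUE)),
    tr_row("fruit_veg_vs_tool_damaged",
           t_test(dmg$fruit_veg, dmg$tool, paired = TRUE)),
    tr_row("tool_vs_vehicle_damaged",
           t_test(dmg$tool, dmg$vehicle, paired = TRUE)))
  out$naming_tests <- tests

  vols <- load_fixture("table1_volumes")
  vd <- vols$lesion_volume_cm3[vols$group == "vATL-damaged"]
  vi <- vols$lesion_volume_cm3[vols$group == "vATL-intact"]
  out$volume_summary <- data.frame(
    group = c("vATL-damaged", "vATL-intact"),
    mean_cm3 = c(mean(vd), mean(vi)), n = c(length(vd), length(vi)))
  out$volume_test <- tr_row("lesion_volume_group", t_test(vd, vi))

  wpm <- load_fixture("table8_wpm")
  out$wpm_summary <- fixture_group_summary(wpm)
  out$wpm_tests <- do.call(rbind, lapply(unique(wpm$group), function(g) {
    sub <- wpm[wpm$group == g, ]
    tr_row(paste0("close_vs_distant_", g),
           t_test(sub$close, sub$distant, paired = TRUE))
  }))

  if (!is.null(cfg$profiles) && !is.null(cfg$effects)) {
    det <- damage_effect_table(cfg$profiles, cfg$effects, tail = "one",
                               directions = cfg$directions,
                               alpha = cfg$alpha)
    out$damage_effects <- data.frame(roi = rownames(det$rho), det$rho,
                                     check.names = FALSE)
    out$damage_effects_p <- data.frame(roi = rownames(det$p), det$p,
                                       check.names = FALSE)
    log <- c(log, sprintf("damage mapping: %d ROIs, excluded: %s",
                          nrow(det$rho),
                          if (length(det$excluded))
                            paste(det$excluded, collapse = ", ") else "none"))
  } else {
    log <- c(log, "damage mapping skipped: no profiles/effects supplied")
  }

  for (nm in names(out))
    write_tsv(out[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")))
  cfg_ser <- cfg[c("seed", "alpha", "min_shared", "control_roi", "directions")]
  yaml::write_yaml(cfg_ser, file.path(cfg$out_dir, "config.yaml"))
  writeLines(c(log, paste("written:", paste(names(out), collapse = ", "))),
             file.path(cfg$out_dir, "log.txt"))
  invisible(out)
}
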