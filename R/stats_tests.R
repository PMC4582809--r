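#' Container for a single statistical test result
#'
#' @param statistic test statistic value.
#' @param df degrees of freedom (length 1 or 2).
#' @param p p-value.
#' @param tail "one" or "two".
#' @param kind one of "F", "t", "r", "rho".
#' @param flags character vector of quality flags (e.g. "degenerate").
#' @return object of class `test_result`.
#' @export
test_result <- function(statistic, df, p, tail = "two", kind = "t",
                        flags = character()) {
  stopifnot(tail %in% c("one", "two"), kind %in% c("F", "t", "r", "rho"))
  if (!is.na(p) && (p < 0 || p > 1)) stop("p outside [0, 1]")
  structure(list(statistic = unname(statistic), df = unname(df), p = unname(p),
                 tail = tail, kind = kind, flags = flags),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.4g, p = %.4g (%s-tailed)%s\n", x$kind,
              paste(signif(x$df, 4), collapse = ", "), x$statistic, x$p,
              x$tail,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Two-sample or paired t test
#'
#' Classical pooled-variance, Welch-Satterthwaite or paired t test. A
#' one-tailed test halves the two-tailed p when the observed effect lies in
#' the hypothesised direction (`direction` refers to mean(x) - mean(y)).
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired paired test on x - y.
#' @param welch use Welch's unequal-variance form (ignored when paired).
#' @param tail "one" or "two".
#' @param direction hypothesised sign of mean(x) - mean(y) for one-tailed
#'   tests: "greater" or "less".
#' @return a [test_result] of kind "t".
#' @export
t_test <- function(x, y, paired = FALSE, welch = FALSE, tail = "two",
                   direction = "greater") {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (paired && length(x) != length(y)) stop("paired samples must have equal length")
  flags <- character()
  degenerate <- if (paired) stats::var(x - y) == 0 else
    stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate) {
    if (paired && all(x == y) || !paired && mean(x) == mean(y))
      return(test_result(0, if (paired) length(x) - 1 else length(x) + length(y) - 2,
                         1, tail, "t", flags = "zero_variance"))
    stop("zero variance with unequal means: t undefined")
  }
  alt <- if (tail == "two") "two.sided" else direction
  tt <- stats::t.test(x, y, paired = paired,
                      var.equal = !welch && !paired, alternative = alt)
  if (tail == "one" && tt$p.value > 0.5) flags <- c(flags, "effect_opposite_to_hypothesis")
  test_result(tt$statistic, tt$parameter, tt$p.value, tail, "t", flags)
}

#' Mixed between/within-participants ANOVA
#'
#' Classical univariate repeated-measures ANOVA on participant-level cell
#' means, with one between-participants grouping factor and up to two
#' within-participants factors, fitted with participant as the error stratum
#' for within effects (via `aov` with an `Error()` term). The design must be
#' balanced within participants: every participant contributes every
#' within-factor cell. No sphericity correction is applied by default;
#' Greenhouse-Geisser corrected p-values can be requested for within effects.
#'
#' @param data data.frame of participant-level cell means.
#' @param dv name of the response column.
#' @param id name of the participant identifier column.
#' @param between name of the grouping factor column.
#' @param within character vector (length 1 or 2) of within-factor columns.
#' @param gg apply a Greenhouse-Geisser correction to within effects (only
#'   meaningful for factors with more than 2 levels).
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `stratum`, `degenerate`.
#' @export
mixed_anova <- function(data, dv, id, between, within, gg = FALSE) {
  stopifnot(all(c(dv, id, between, within) %in% names(data)),
            length(within) %in% 1:2)
  df <- data
  df[[id]] <- factor(df[[id]])
  df[[between]] <- factor(df[[between]])
  for (w in within) df[[w]] <- factor(df[[w]])
  if (nlevels(df[[between]]) < 2L) stop("need at least 2 groups")
  if (any(table(df[[between]][!duplicated(df[[id]])]) < 2L))
    stop("every group needs at least 2 participants")
  if (all(vapply(within, function(w) nlevels(df[[w]]), 1L) == 1L)) {
    # degenerate within design: classical one-way ANOVA on participant means
    fit <- stats::aov(stats::as.formula(paste(dv, "~", between)), data = df)
    tab <- summary(fit)[[1]]
    return(data.frame(effect = between, df1 = tab[1, "Df"], df2 = tab[2, "Df"],
                      F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
                      stratum = id,
                      degenerate = tab[2, "Mean Sq"] <=
                        max(mean(df[[dv]]^2), .Machine$double.xmin) * 1e-20,
                      stringsAsFactors = FALSE))
  }
  cells <- table(df[[id]], do.call(interaction, df[within]))
  if (any(cells != 1L)) {
    bad <- which(cells != 1L, arr.ind = TRUE)
    stop("unbalanced within design; participant x cell counts != 1 for: ",
         paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  wterm <- paste(within, collapse = "*")
  form <- stats::as.formula(sprintf("%s ~ %s * %s + Error(%s/(%s))",
                                    dv, between, wterm, id, wterm))
  fit <- stats::aov(form, data = df)
  # a residual mean square this far below the response scale is accumulated
  # floating-point noise from an exactly-zero error stratum
  eps_ms <- max(mean(df[[dv]]^2), .Machine$double.xmin) * 1e-20
  out <- do.call(rbind, lapply(names(summary(fit)), function(sn) {
    tab <- summary(fit)[[sn]][[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    res_df <- tab[eff == "Residuals", "Df"]
    res_ms <- tab[eff == "Residuals", "Mean Sq"]
    if (!any(keep)) return(NULL)
    data.frame(effect = eff[keep], df1 = tab[keep, "Df"], df2 = res_df,
               F = tab[keep, "F value"], p = tab[keep, "Pr(>F)"],
               stratum = sub("^Error: ", "", sn),
               degenerate = !is.finite(res_ms) | res_ms <= eps_ms,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  deg <- out$degenerate | !is.finite(out$F)
  out$F[deg] <- 0
  out$p[deg] <- NA_real_
  out$degenerate <- deg
  if (gg) out <- gg_correct(out, df, dv, id, within)
  out
}

# Greenhouse-Geisser epsilon per within factor, applied to df and p of the
# effects in that factor's error stratum
gg_correct <- function(out, df, dv, id, within) {
  out$gg_epsilon <- NA_real_
  for (w in within) {
    if (nlevels(df[[w]]) <= 2L) next
    wide <- tapply(df[[dv]], list(df[[id]], df[[w]]), mean)
    S <- stats::cov(wide)
    k <- ncol(S)
    num <- (k * (mean(diag(S)) - mean(S)))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2)
    eps <- num / den
    rows <- vapply(strsplit(out$effect, ":"), function(e) w %in% e, TRUE)
    out$gg_epsilon[rows] <- eps
    out$p[rows] <- stats::pf(out$F[rows], out$df1[rows] * eps,
                             out$df2[rows] * eps, lower.tail = FALSE)
  }
  out
}

#' Item-wise ANCOVA interaction between group and a covariate
#'
#' Fits `accuracy ~ group + covariate + group:covariate` on long-format
#' item-by-group mean accuracies, with items as the observational unit, and
#' returns the group-by-covariate interaction test: does the relationship
#' between the covariate (e.g. the correlation-by-distinctiveness slope) and
#' accuracy differ across participant groups?
#'
#' @param item_acc data.frame with columns `item`, `group`, `accuracy`.
#' @param covariate named numeric vector of per-item covariate values (names
#'   are item ids) or a numeric vector aligned with `unique(item_acc$item)`.
#' @return a [test_result] of kind "F" for the interaction.
#' @export
itemwise_ancova_interaction <- function(item_acc, covariate) {
  stopifnot(all(c("item", "group", "accuracy") %in% names(item_acc)))
  items <- unique(item_acc$item)
  if (is.null(names(covariate))) {
    if (length(covariate) != length(items))
      stop("unnamed covariate must align with unique items")
    covariate <- stats::setNames(covariate, items)
  }
  miss <- setdiff(items, names(covariate))
  if (length(miss)) stop("covariate missing for items: ", paste(miss, collapse = ", "))
  x <- covariate[as.character(item_acc$item)]
  if (any(!is.finite(x))) stop("non-finite covariate values")
  if (stats::var(x) == 0) stop("covariate is constant")
  d <- data.frame(accuracy = item_acc$accuracy,
                  group = factor(item_acc$group), covariate = as.numeric(x))
  fit <- stats::lm(accuracy ~ group * covariate, data = d)
  at <- stats::anova(fit)
  i <- which(rownames(at) == "group:covariate")
  test_result(at[i, "F value"], c(at[i, "Df"], at["Residuals", "Df"]),
              at[i, "Pr(>F)"], "two", "F")
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)`, the variance-stabilising transform applied to
#' per-participant correlation coefficients before they are related to
#' damage scores. Odd and strictly increasing; infinite at r = +/-1.
#'
#' @param r correlation coefficient(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) atanh(r)

#' Correlations between accuracy and per-item covariates
#'
#' Group level: per-item group mean accuracies (and the pairwise differences
#' between group accuracies) are correlated with each covariate across items
#' (Pearson). Participant level: each participant's item-wise point-biserial
#' correlation between trial correctness and the covariate, returned with its
#' Fisher z; participants with |r| = 1 get infinite z and are flagged so they
#' can be excluded from downstream correlations with damage.
#'
#' @param acc data.frame with columns `participant`, `group`, `item`,
#'   `correct` (0/1) for the participant level, or item-level accuracies
#'   aggregated internally for the group level.
#' @param covariates data.frame of per-item covariates, with an `item`
#'   column; or a named list of named numeric vectors.
#' @param level "group" or "participant".
#' @return data.frame; group level: `covariate`, `contrast`, `r`, `p`, `n`;
#'   participant level: `participant`, `group`, `covariate`, `r`, `z`,
#'   `n`, `flagged`.
#' @export
accuracy_covariate_correlations <- function(acc, covariates,
                                            level = c("participant", "group")) {
  level <- match.arg(level)
  stopifnot(all(c("participant", "group", "item", "correct") %in% names(acc)))
  if (is.data.frame(covariates)) {
    stopifnot("item" %in% names(covariates))
    cv <- covariates[setdiff(names(covariates), "item")]
    cv <- lapply(cv, stats::setNames, as.character(covariates$item))
  } else cv <- covariates
  if (level == "participant") {
    parts <- unique(acc$participant)
    out <- do.call(rbind, lapply(parts, function(pp) {
      sub <- acc[acc$participant == pp, ]
      do.call(rbind, lapply(names(cv), function(cn) {
        x <- cv[[cn]][as.character(sub$item)]
        r <- if (stats::sd(sub$correct) == 0 || stats::sd(x) == 0) NA_real_
             else stats::cor(sub$correct, x)
        if (!is.na(r) && abs(r) >= 1 - 1e-12) r <- sign(r)  # numerically perfect
        z <- fisher_z(r)
        data.frame(participant = pp, group = sub$group[1], covariate = cn,
                   r = r, z = z, n = nrow(sub),
                   flagged = is.na(r) || !is.finite(z),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(out) <- NULL
    return(out)
  }
  im <- stats::aggregate(correct ~ item + group, data = acc, FUN = mean)
  groups <- unique(im$group)
  wide <- stats::reshape(im, idvar = "item", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^correct\\.", "", names(wide))
  contrasts <- c(as.list(stats::setNames(groups, groups)),
                 unlist(lapply(utils::combn(as.character(groups), 2,
                                            simplify = FALSE),
                               function(pr) stats::setNames(
                                 list(pr), paste(pr, collapse = " - "))),
                        recursive = FALSE))
  out <- do.call(rbind, lapply(names(contrasts), function(ct) {
    spec <- contrasts[[ct]]
    y <- if (length(spec) == 1L) wide[[spec]] else wide[[spec[1]]] - wide[[spec[2]]]
    do.call(rbind, lapply(names(cv), function(cn) {
      x <- cv[[cn]][as.character(wide$item)]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(data.frame(covariate = cn, contrast = ct, r = NA_real_,
                          p = NA_real_, n = sum(ok), stringsAsFactors = FALSE))
      ctst <- stats::cor.test(x[ok], y[ok])
      data.frame(covariate = cn, contrast = ct, r = unname(ctst$estimate),
                 p = ctst$p.value, n = sum(ok), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
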