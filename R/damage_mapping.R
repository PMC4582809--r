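#' Spearman rank correlation with one- or two-tailed p
#'
#' Rho is the Pearson correlation of mid-ranks (ties receive their average
#' rank). The default p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` with n-2 degrees of freedom; with
#' `exact = TRUE` and n <= 8 the permutation null is enumerated in full.
#' One-tailed tests take the hypothesised sign via `direction`.
#'
#' @param x,y numeric vectors, equal length >= 4.
#' @param tail "one" or "two".
#' @param direction hypothesised sign of rho for one-tailed tests:
#'   "greater" (positive) or "less" (negative).
#' @param exact enumerate the permutation null (n <= 8 only).
#' @return a [test_result] of kind "rho" with df = n - 2.
#' @export
spearman_test <- function(x, y, tail = "two", direction = "greater",
                          exact = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L, tail %in% c("one", "two"),
            direction %in% c("greater", "less"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact permutation null supported for n <= 8 only")
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1, function(pp) stats::cor(rx, ry[pp]))
    p <- switch(tail,
                two = mean(abs(null_rho) >= abs(rho) - 1e-12),
                one = if (direction == "greater")
                  mean(null_rho >= rho - 1e-12)
                else mean(null_rho <= rho + 1e-12))
    return(test_result(rho, n - 2, p, tail, "rho", flags = "exact"))
  }
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- switch(tail,
              two = 2 * stats::pt(-abs(tt), n - 2),
              one = if (direction == "greater")
                stats::pt(tt, n - 2, lower.tail = FALSE)
              else stats::pt(tt, n - 2))
  test_result(rho, n - 2, min(p, 1), tail, "rho")
}

# all permutations of 1..n as rows (n! x n matrix); n small
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- sub + (sub >= i)
    cbind(i, rest, deparse.level = 0)
  }))
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms all three vectors and computes the first-order partial
#' Pearson correlation on the ranks:
#' `(r_xy - r_xc r_yc) / sqrt((1 - r_xc^2)(1 - r_yc^2))`, with df = n - 3 and
#' a t-approximation p-value. Used to ask whether a damage-behaviour
#' relationship survives controlling for damage in a neighbouring region.
#'
#' @param x,y numeric vectors of interest.
#' @param control vector whose rank association is partialled out.
#' @inheritParams spearman_test
#' @return a [test_result] of kind "rho" with df = n - 3.
#' @export
partial_spearman <- function(x, y, control, tail = "two",
                             direction = "greater") {
  n <- length(x)
  stopifnot(length(y) == n, length(control) == n, n >= 5L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(control) == 0)
    stop("constant vector")
  rx <- rank(x); ry <- rank(y); rc <- rank(control)
  r_xy <- stats::cor(rx, ry)
  r_xc <- stats::cor(rx, rc)
  r_yc <- stats::cor(ry, rc)
  den <- (1 - r_xc^2) * (1 - r_yc^2)
  if (den <= .Machine$double.eps)
    stop("control is collinear with x or y on ranks")
  prho <- (r_xy - r_xc * r_yc) / sqrt(den)
  df <- n - 3
  tt <- prho * sqrt(df / pmax(1 - prho^2, .Machine$double.eps))
  p <- switch(tail,
              two = 2 * stats::pt(-abs(tt), df),
              one = if (direction == "greater")
                stats::pt(tt, df, lower.tail = FALSE)
              else stats::pt(tt, df))
  test_result(prho, df, min(p, 1), tail, "rho")
}

#' Damage-by-effect Spearman correlation table
#'
#' Correlates per-ROI damage proportions with per-patient behavioural effect
#' scores, one Spearman correlation per ROI-by-effect cell, mirroring the
#' layout of a lesion-behaviour correlation table. ROIs in which fewer than
#' `min_nonzero` patients have nonzero damage are excluded (reported as NA
#' columns) since their rank correlations are uninformative. Optionally a
#' partial version controls for damage in a named ROI.
#'
#' @param profiles list of `damage_profile` objects, or a patients-by-ROI
#'   damage matrix with patient row names.
#' @param effects data.frame with a `patient` column and one numeric column
#'   per effect score, or a named list of named numeric vectors.
#' @param tail,directions tail and per-effect hypothesised sign; `directions`
#'   is a named character vector ("greater"/"less") or a single value
#'   recycled over effects.
#' @param control optional ROI name to partial out (that ROI's row is
#'   dropped from the partial table).
#' @param alpha significance threshold for the flag matrix.
#' @param min_nonzero minimum patients with nonzero damage for an ROI to
#'   enter.
#' @param exact use the exact permutation null (plain Spearman only, n <= 8).
#' @return list with matrices `rho`, `p`, `sig` (ROIs x effects), the
#'   excluded ROI names, and the settings used.
#' @export
damage_effect_table <- function(profiles, effects, tail = "one",
                                directions = "less", control = NULL,
                                alpha = 0.05, min_nonzero = 3L,
                                exact = FALSE) {
  dm <- if (is.matrix(profiles)) profiles else damage_matrix(profiles)
  if (is.data.frame(effects)) {
    stopifnot("patient" %in% names(effects))
    eff <- lapply(effects[setdiff(names(effects), "patient")],
                  stats::setNames, as.character(effects$patient))
  } else eff <- effects
  pts <- rownames(dm)
  for (e in names(eff)) {
    bad <- c(setdiff(pts, names(eff[[e]])), setdiff(names(eff[[e]]), pts))
    if (length(bad))
      stop("patient ids misaligned for effect '", e, "': ",
           paste(unique(bad), collapse = ", "))
    eff[[e]] <- eff[[e]][pts]
  }
  if (length(directions) == 1L)
    directions <- stats::setNames(rep(directions, length(eff)), names(eff))
  stopifnot(all(names(eff) %in% names(directions)))
  usable <- colSums(dm > 0, na.rm = TRUE) >= min_nonzero &
    apply(dm, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  excluded <- colnames(dm)[!usable]
  rois <- colnames(dm)
  if (!is.null(control)) {
    if (!control %in% rois) stop("unknown control ROI: ", control)
    rois <- setdiff(rois, control)
  }
  rho <- p <- matrix(NA_real_, length(rois), length(eff),
                     dimnames = list(rois, names(eff)))
  for (r in rois) {
    if (!usable[r]) next
    for (e in names(eff)) {
      tr <- if (is.null(control))
        spearman_test(dm[, r], eff[[e]], tail = tail,
                      direction = directions[[e]], exact = exact)
      else partial_spearman(dm[, r], eff[[e]], dm[, control], tail = tail,
                            direction = directions[[e]])
      rho[r, e] <- tr$statistic
      p[r, e] <- tr$p
    }
  }
  list(rho = rho, p = p, sig = !is.na(p) & p < alpha, excluded = excluded,
       settings = list(tail = tail, directions = directions,
                       control = control, alpha = alpha,
                       min_nonzero = min_nonzero, exact = exact))
}
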