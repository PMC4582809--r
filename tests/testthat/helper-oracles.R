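# Independent brute-force oracles. Deliberately slow and literal: elementwise
# loops, textbook formulas, and stats::cor.test where a reference p-value is
# needed. They never call the implementation paths they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

oracle_midrank <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

oracle_spearman_rho <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))$r
}

oracle_partial_rho <- function(x, y, control) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y); rc <- oracle_midrank(control)
  r_xy <- oracle_pearson(rx, ry)$r
  r_xc <- oracle_pearson(rx, rc)$r
  r_yc <- oracle_pearson(ry, rc)$r
  (r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) * (1 - r_yc^2))
}

oracle_cosine <- function(a, b) {
  num <- 0; na_ <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na_ <- na_ + a[i]^2
    nb <- nb + b[i]^2
  }
  unname(num / sqrt(na_ * nb))
}

oracle_feature_stats <- function(pf, min_shared = 3, alpha = 0.05,
                                 positive_only = TRUE) {
  nf <- ncol(pf)
  n_concepts <- vapply(seq_len(nf), function(j) sum(pf[, j] > 0), 0)
  shared <- n_concepts >= min_shared
  strength <- rep(NA_real_, nf)
  for (j in which(shared)) {
    vals <- numeric()
    for (k in which(shared)) {
      if (k == j) next
      if (stats::sd(pf[, j]) == 0 || stats::sd(pf[, k]) == 0) next
      ct <- suppressWarnings(stats::cor.test(pf[, j], pf[, k]))
      if (is.na(ct$estimate)) next
      if (ct$p.value < alpha && (!positive_only || ct$estimate > 0))
        vals <- c(vals, unname(ct$estimate))
    }
    if (length(vals)) strength[j] <- mean(vals)
  }
  data.frame(feature = colnames(pf), n_concepts = as.integer(n_concepts),
             distinctiveness = 1 / n_concepts, is_shared = shared,
             correlational_strength = strength, stringsAsFactors = FALSE)
}

oracle_concept_stats <- function(pf, min_shared = 3, alpha = 0.05,
                                 positive_only = TRUE, undef_zero = TRUE) {
  fs <- oracle_feature_stats(pf, min_shared, alpha, positive_only)
  out <- data.frame(concept = rownames(pf),
                    mean_distinctiveness = NA_real_,
                    correlational_strength = NA_real_,
                    corr_x_dist_slope = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pf))) {
    has <- which(pf[i, ] > 0)
    out$mean_distinctiveness[i] <- mean(fs$distinctiveness[has])
    csh <- has[fs$is_shared[has]]
    vals <- numeric()
    if (length(csh) >= 2) {
      for (a in seq_along(csh)) for (b in seq_along(csh)) {
        if (b <= a) next
        j <- csh[a]; k <- csh[b]
        if (stats::sd(pf[, j]) == 0 || stats::sd(pf[, k]) == 0) next
        ct <- suppressWarnings(stats::cor.test(pf[, j], pf[, k]))
        if (is.na(ct$estimate)) next
        if (ct$p.value < alpha && (!positive_only || ct$estimate > 0))
          vals <- c(vals, unname(ct$estimate))
      }
    }
    if (length(vals)) out$correlational_strength[i] <- mean(vals)
    d <- fs$distinctiveness[has]
    s <- fs$correlational_strength[has]
    if (undef_zero) s[is.na(s)] <- 0 else { d <- d[!is.na(s)]; s <- s[!is.na(s)] }
    if (length(d) >= 2 && stats::sd(d) > 0)
      out$corr_x_dist_slope[i] <- unname(stats::coef(stats::lm(s ~ d))[2])
  }
  out
}

oracle_roi_damage <- function(lesion_arr, label_arr, codes) {
  out <- stats::setNames(numeric(length(codes)), names(codes))
  for (r in names(codes)) {
    tot <- 0; dam <- 0
    for (i in seq_along(label_arr)) {
      if (label_arr[i] == codes[[r]]) {
        tot <- tot + 1
        dam <- dam + lesion_arr[i]
      }
    }
    out[r] <- if (tot == 0) NA_real_ else dam / tot
  }
  out
}

# small random norms for property-based checks
random_norms <- function(n_concepts = 8, n_features = 15, seed = 1,
                         density = 0.45) {
  set.seed(seed)
  repeat {
    pf <- matrix(ifelse(stats::runif(n_concepts * n_features) < density,
                        sample(1:20, n_concepts * n_features, replace = TRUE),
                        0L),
                 n_concepts, n_features,
                 dimnames = list(sprintf("c%02d", 1:n_concepts),
                                 sprintf("f%02d", 1:n_features)))
    if (all(rowSums(pf > 0) > 0) && all(colSums(pf > 0) > 0)) return(pf)
  }
}
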