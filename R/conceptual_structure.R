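#' Pairwise Pearson correlations with p-values
#'
#' Correlates the columns of a matrix and returns the coefficient matrix plus
#' two-tailed p-values from the exact t transform
#' `t = r * sqrt((n-2)/(1-r^2))` with n-2 degrees of freedom. Columns with
#' zero variance yield NA.
#'
#' @param m numeric matrix, observations in rows.
#' @return list with matrices `r` and `p`.
#' @keywords internal
pairwise_pearson <- function(m) {
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 observations for pairwise correlations")
  r <- suppressWarnings(stats::cor(m))
  rc <- pmin(pmax(r, -1), 1)
  t <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[abs(rc) >= 1 - 1e-15] <- 0
  diag(p) <- NA_real_
  list(r = r, p = p)
}

#' Feature-level conceptual structure statistics
#'
#' For each feature in a set of property norms, computes the number of
#' concepts it occurs in, its distinctiveness (1 / number of concepts, so a
#' feature unique to one concept is maximally distinctive), whether it is a
#' shared feature (occurring in at least `min_shared` concepts), and its
#' correlational strength: the mean of its retained pairwise Pearson
#' correlations with all other shared features, computed across all concepts'
#' production-frequency columns. A correlation is retained when its two-tailed
#' p-value is below `alpha` (and the coefficient is positive, when
#' `positive_only`). Features with no retained partner, and non-shared
#' features, get NA strength.
#'
#' @param norms a [property_norms] object.
#' @param min_shared minimum number of concepts for a feature to count as
#'   shared (>= 2).
#' @param alpha significance threshold for retaining a pairwise correlation.
#' @param positive_only retain only positive correlations.
#' @param distinctiveness_fun function mapping the per-feature concept count
#'   to distinctiveness; the default is the reciprocal.
#' @return data.frame with columns `feature`, `n_concepts`,
#'   `distinctiveness`, `is_shared`, `correlational_strength`; the retained
#'   correlation matrix is attached as attribute `retained_r` and the
#'   parameters as `params`.
#' @export
feature_statistics <- function(norms, min_shared = 3L, alpha = 0.05,
                               positive_only = TRUE,
                               distinctiveness_fun = function(n) 1 / n) {
  stopifnot(inherits(norms, "property_norms"))
  pf <- norms$pf
  if (nrow(pf) < 2L) stop("norms with a single concept: no correlation is computable")
  if (min_shared < 2L) stop("`min_shared` must be >= 2")
  if (min_shared > nrow(pf))
    stop("`min_shared` exceeds the number of concepts (", nrow(pf), ")")
  n_concepts <- colSums(pf > 0)
  distinct <- distinctiveness_fun(n_concepts)
  shared <- n_concepts >= min_shared
  strength <- rep(NA_real_, ncol(pf))
  retained_r <- NULL
  if (sum(shared) >= 2L) {
    pw <- pairwise_pearson(pf[, shared, drop = FALSE])
    keep <- !is.na(pw$p) & pw$p < alpha
    if (positive_only) keep <- keep & !is.na(pw$r) & pw$r > 0
    retained_r <- ifelse(keep, pw$r, NA_real_)
    diag(retained_r) <- NA_real_
    s <- rowMeans(retained_r, na.rm = TRUE)
    s[rowSums(!is.na(retained_r)) == 0] <- NA_real_
    strength[shared] <- s
  }
  out <- data.frame(feature = colnames(pf),
                    n_concepts = as.integer(n_concepts),
                    distinctiveness = as.numeric(distinct),
                    is_shared = shared,
                    correlational_strength = strength,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "retained_r") <- retained_r
  attr(out, "params") <- list(min_shared = min_shared, alpha = alpha,
                              positive_only = positive_only)
  out
}

#' Concept-level conceptual structure statistics
#'
#' Per concept, over its attested features (pf > 0): mean distinctiveness;
#' correlational strength, the mean of all retained pairwise correlations
#' whose both features are shared features of the concept (NA when no such
#' pair exists); and the correlation-by-distinctiveness slope, the
#' unstandardised OLS slope of feature-level correlational strength on
#' feature distinctiveness over the concept's features. Low slopes typify
#' confusable concepts whose shared features are strongly intercorrelated
#' (e.g. animals); high slopes typify concepts with correlated distinctive
#' features (e.g. tools).
#'
#' Features with undefined norm-wide strength enter the slope regression with
#' strength 0 when `undefined_strength_as_zero` (the default: distinctive
#' features are treated as uncorrelated), else they are excluded. The slope is
#' NA when fewer than 2 usable features remain or the predictor has zero
#' variance.
#'
#' @param norms a [property_norms] object.
#' @param fstats the [feature_statistics] output computed from `norms`.
#' @param undefined_strength_as_zero replace undefined feature strengths with
#'   0 in the slope regression instead of dropping the features.
#' @return data.frame with columns `concept`, `domain`, `category`,
#'   `n_features`, `n_shared_features`, `mean_distinctiveness`,
#'   `correlational_strength`, `corr_x_dist_slope`.
#' @export
concept_statistics <- function(norms, fstats, undefined_strength_as_zero = TRUE) {
  stopifnot(inherits(norms, "property_norms"))
  pf <- norms$pf
  if (!identical(fstats$feature, colnames(pf)))
    stop("`fstats` does not match the features of `norms`")
  retained_r <- attr(fstats, "retained_r")
  shared_names <- fstats$feature[fstats$is_shared]
  concepts <- rownames(pf)
  out <- data.frame(concept = concepts,
                    domain = unname(norms$domain),
                    category = unname(norms$category),
                    n_features = 0L, n_shared_features = 0L,
                    mean_distinctiveness = NA_real_,
                    correlational_strength = NA_real_,
                    corr_x_dist_slope = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_along(concepts)) {
    has <- pf[i, ] > 0
    out$n_features[i] <- sum(has)
    out$mean_distinctiveness[i] <- mean(fstats$distinctiveness[has])
    csh <- intersect(fstats$feature[has & fstats$is_shared], shared_names)
    out$n_shared_features[i] <- length(csh)
    if (length(csh) >= 2L && !is.null(retained_r)) {
      rr <- retained_r[csh, csh]
      vals <- rr[upper.tri(rr)]
      vals <- vals[!is.na(vals)]
      if (length(vals)) out$correlational_strength[i] <- mean(vals)
    }
    d <- fstats$distinctiveness[has]
    s <- fstats$correlational_strength[has]
    if (undefined_strength_as_zero) s[is.na(s)] <- 0
    use <- !is.na(s)
    out$corr_x_dist_slope[i] <- ols_slope(d[use], s[use])
  }
  out
}

# unstandardised OLS slope of y on x; NA when < 2 points or zero x variance
ols_slope <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) return(NA_real_)
  stats::cov(x, y) / vx
}

#' Cosine similarity between two concepts' production-frequency vectors
#'
#' The semantic distance measure used to build close/distant word-picture
#' pairs: the cosine of the angle between the two concepts' feature vectors
#' over the full feature space. For non-negative vectors the value lies in
#' \[0, 1\], with 1 for proportional vectors and 0 for disjoint feature sets.
#'
#' @param norms a [property_norms] object.
#' @param a,b concept labels.
#' @return cosine similarity in \[0, 1\].
#' @export
cosine_similarity <- function(norms, a, b) {
  stopifnot(inherits(norms, "property_norms"))
  pf <- norms$pf
  for (cc in c(a, b)) if (!cc %in% rownames(pf)) stop("unknown concept: ", cc)
  va <- pf[a, ]; vb <- pf[b, ]
  na_ <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na_ == 0 || nb == 0) stop("empty concept vector")
  sum(va * vb) / (na_ * nb)
}

#' Summarise cosine distances by condition and domain
#'
#' Used to verify stimulus-set construction: close pairs should have much
#' higher mean cosine than distant pairs, matched across living and nonliving
#' domains.
#'
#' @param pairs data.frame with columns `cosine`, `condition` (close |
#'   distant) and `domain` (living | nonliving).
#' @return data.frame with one row per condition-by-domain cell: `mean`,
#'   `sd`, `n` and an `empty` flag for cells with no pairs.
#' @export
pair_condition_summary <- function(pairs) {
  need <- c("cosine", "condition", "domain")
  if (!all(need %in% names(pairs)))
    stop("`pairs` must have columns: ", paste(need, collapse = ", "))
  cells <- expand.grid(condition = unique(pairs$condition),
                       domain = unique(pairs$domain),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    v <- pairs$cosine[pairs$condition == cells$condition[i] &
                        pairs$domain == cells$domain[i]]
    data.frame(condition = cells$condition[i], domain = cells$domain[i],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else if (length(v)) 0 else NA_real_,
               n = length(v), empty = length(v) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
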