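#' Configuration for the synthetic property-norm generator
#'
#' Defaults emulate the structure of feature-listing norms for a two-domain
#' stimulus set: living concepts carry more shared features (target mean
#' 12.7) than nonliving concepts (target mean 11.1), on top of a fixed
#' number of concept-unique distinctive features. Production frequencies are
#' drawn from a truncated geometric distribution on 1..`pf_max`, emulating
#' the small positive counts of feature-listing studies.
#'
#' @param n_living,n_nonliving number of concepts per domain.
#' @param shared_pool_size number of reusable shared features.
#' @param mean_shared_living,mean_shared_nonliving target mean number of
#'   shared features per concept, by domain.
#' @param sd_shared between-concept SD of the shared-feature count.
#' @param distinctive_per_concept concept-unique features per concept.
#' @param pf_max,pf_prob truncated-geometric support maximum and success
#'   probability for production frequencies.
#' @param seed RNG seed recorded in the output provenance.
#' @return list of class `norm_gen_config`.
#' @export
norm_gen_config <- function(n_living = 30L, n_nonliving = 30L,
                            shared_pool_size = 40L,
                            mean_shared_living = 12.7,
                            mean_shared_nonliving = 11.1,
                            sd_shared = 2, distinctive_per_concept = 5L,
                            pf_max = 30L, pf_prob = 0.25, seed = 1L) {
  stopifnot(n_living >= 0, n_nonliving >= 0, n_living + n_nonliving > 0,
            shared_pool_size > 0, sd_shared >= 0,
            distinctive_per_concept >= 1, pf_max >= 1,
            pf_prob > 0, pf_prob < 1)
  structure(as.list(environment()), class = "norm_gen_config")
}

rpf <- function(n, pf_max, pf_prob) {
  probs <- stats::dgeom(0:(pf_max - 1), pf_prob)
  sample.int(pf_max, n, replace = TRUE, prob = probs / sum(probs))
}

#' Generate synthetic property norms with known ground truth
#'
#' Each concept receives a domain-dependent number of features sampled from
#' a common shared pool (features reused across many concepts) plus its own
#' distinctive features (each occurring in exactly one concept). Living
#' concepts draw more shared features than nonliving ones. The realised
#' per-concept shared-feature counts are attached as the `ground_truth`
#' attribute; the configuration (including the seed) as `provenance`.
#'
#' @param cfg a [norm_gen_config].
#' @return a [property_norms] object with `ground_truth` and `provenance`
#'   attributes.
#' @export
gen_property_norms <- function(cfg) {
  stopifnot(inherits(cfg, "norm_gen_config"))
  if (max(cfg$mean_shared_living * (cfg$n_living > 0),
          cfg$mean_shared_nonliving * (cfg$n_nonliving > 0)) >
      cfg$shared_pool_size)
    stop("shared pool too small for the requested per-concept shared counts")
  set.seed(cfg$seed)
  domains <- c(rep("living", cfg$n_living), rep("nonliving", cfg$n_nonliving))
  cats <- c(rep_len(c("animal", "fruit_veg"), cfg$n_living),
            rep_len(c("tool", "vehicle"), cfg$n_nonliving))
  n <- length(domains)
  concepts <- sprintf("concept_%03d", seq_len(n))
  pool <- sprintf("sf_%03d", seq_len(cfg$shared_pool_size))
  mu <- ifelse(domains == "living", cfg$mean_shared_living,
               cfg$mean_shared_nonliving)
  k <- pmin(cfg$shared_pool_size,
            pmax(1L, round(stats::rnorm(n, mu, cfg$sd_shared))))
  rows <- lapply(seq_len(n), function(i) {
    sf <- sample(pool, k[i])
    df <- sprintf("%s_df_%02d", concepts[i],
                  seq_len(cfg$distinctive_per_concept))
    data.frame(concept = concepts[i], feature = c(sf, df),
               production_frequency = rpf(k[i] + length(df),
                                          cfg$pf_max, cfg$pf_prob),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  features <- c(pool[pool %in% long$feature],
                long$feature[!long$feature %in% pool])
  pf <- matrix(0L, n, length(features), dimnames = list(concepts, features))
  pf[cbind(match(long$concept, concepts), match(long$feature, features))] <-
    long$production_frequency
  norms <- property_norms(pf, domain = domains, category = cats)
  attr(norms, "ground_truth") <- data.frame(concept = concepts,
                                            domain = domains,
                                            n_shared = k,
                                            stringsAsFactors = FALSE)
  attr(norms, "provenance") <- unclass(cfg)
  norms
}

#' Default disjoint-box ROI layout for synthetic cohorts
#'
#' Six anterior-temporal ROIs as disjoint boxes on a small grid, ordered
#' back-to-front along the anterior axis (axis 2, index increasing towards
#' anterior) with the temporal pole most anterior.
#'
#' @param grid_dim grid dimensions the layout must fit.
#' @return named list of per-ROI index ranges (`x`, `y`, `z`).
#' @export
default_roi_layout <- function(grid_dim = c(24L, 30L, 12L)) {
  stopifnot(all(grid_dim >= c(24, 30, 6)))
  list(TPole    = list(x = 3:10,  y = 25:29, z = 3:8),
       PRc      = list(x = 3:8,   y = 14:24, z = 3:6),
       ERc      = list(x = 9:12,  y = 14:24, z = 3:6),
       Fusiform = list(x = 13:17, y = 10:24, z = 3:6),
       ITG      = list(x = 18:21, y = 8:24,  z = 3:6),
       MTG      = list(x = 18:21, y = 8:24,  z = 8:11))
}

#' Configuration for the synthetic lesion cohort and behaviour generator
#'
#' The default cohort has 8 patients with graded perirhinal damage (0 to
#' 0.7 of the ROI), variable damage elsewhere, and entorhinal damage in only
#' two patients (so the entorhinal exclusion rule is exercised). The
#' behavioural model is per-trial Bernoulli with
#' `logit p = b0 + b_dmg * damage + b_int * damage * s + e`, where `s` is the
#' item's standardised correlation-by-distinctiveness slope and `e` is
#' Gaussian logit noise.
#'
#' @param n_patients number of patients.
#' @param grid_dim,voxel_dims grid shape and voxel size (mm).
#' @param roi_layout named list of disjoint ROI boxes.
#' @param target_damage patients-by-ROI matrix of target damage fractions;
#'   NULL for the default graded design.
#' @param b0 baseline log-odds of a correct response.
#' @param b_dmg main effect of damage on the log-odds.
#' @param b_int damage-by-structure interaction coefficient.
#' @param noise_sd SD of per-trial Gaussian noise on the log-odds.
#' @param n_items number of items presented to every patient.
#' @param damage_roi ROI whose damage drives behaviour.
#' @param stochastic_placement sample lesioned voxels at random instead of
#'   the deterministic raster fill.
#' @param seed RNG seed.
#' @return list of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_patients = 8L, grid_dim = c(24L, 30L, 12L),
                              voxel_dims = c(2, 2, 2),
                              roi_layout = default_roi_layout(grid_dim),
                              target_damage = NULL,
                              b0 = 2, b_dmg = -2, b_int = 0, noise_sd = 0.5,
                              n_items = 100L, damage_roi = "PRc",
                              stochastic_placement = FALSE, seed = 1L) {
  if (is.null(target_damage)) {
    stopifnot(n_patients == 8L)
    target_damage <- cbind(
      TPole    = c(0.3, 0.0, 0.1, 0.2, 0.5, 0.6, 0.0, 0.4),
      PRc      = seq(0, 0.7, by = 0.1),
      ERc      = c(0, 0, 0.3, 0, 0, 0.2, 0, 0),
      Fusiform = c(0.2, 0.0, 0.4, 0.1, 0.5, 0.3, 0.6, 0.2),
      ITG      = c(0.1, 0.3, 0.0, 0.4, 0.2, 0.5, 0.1, 0.3),
      MTG      = c(0.0, 0.2, 0.1, 0.3, 0.1, 0.4, 0.2, 0.1))
    rownames(target_damage) <- sprintf("SP%02d", seq_len(n_patients))
  }
  stopifnot(nrow(target_damage) == n_patients,
            all(colnames(target_damage) %in% names(roi_layout)),
            all(target_damage >= 0 & target_damage <= 1),
            noise_sd >= 0, n_items > 0)
  structure(as.list(environment()), class = "cohort_gen_config")
}

roi_voxel_index <- function(box, grid_dim) {
  g <- expand.grid(x = box$x, y = box$y, z = box$z)
  # raster order: x fastest, matching R array linear indexing
  sort((g$z - 1) * grid_dim[1] * grid_dim[2] + (g$y - 1) * grid_dim[1] + g$x)
}

#' Generate a synthetic lesion cohort with exact ground truth
#'
#' Builds a label atlas from the configured disjoint ROI boxes and, for each
#' patient, a binary lesion mask damaging each ROI to its target fraction
#' rounded to voxel resolution. Deterministic raster-order placement makes
#' the realised fractions exact and reproducible; stochastic placement
#' samples voxels instead. Realised fractions are returned as ground-truth
#' damage profiles.
#'
#' @param cfg a [cohort_gen_config].
#' @return list with `atlas` (an [roi_atlas]), `masks` (named list of
#'   `binary_mask`) and `profiles` (list of ground-truth `damage_profile`).
#' @export
gen_lesion_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_gen_config"))
  set.seed(cfg$seed)
  gd <- cfg$grid_dim
  labels <- array(0L, dim = gd)
  legend <- stats::setNames(seq_along(cfg$roi_layout), names(cfg$roi_layout))
  vox <- lapply(cfg$roi_layout, roi_voxel_index, grid_dim = gd)
  if (length(unlist(vox)) != length(unique(unlist(vox))))
    stop("ROI boxes overlap")
  for (r in names(vox)) labels[vox[[r]]] <- legend[[r]]
  atlas <- roi_atlas(labels, legend, voxel_dims = cfg$voxel_dims)
  td <- cfg$target_damage
  masks <- list(); profiles <- list()
  for (i in seq_len(nrow(td))) {
    m <- array(0, dim = gd)
    realised <- stats::setNames(numeric(ncol(td)), colnames(td))
    for (r in colnames(td)) {
      nv <- length(vox[[r]])
      ndam <- round(td[i, r] * nv)
      if (abs(ndam - td[i, r] * nv) > 1)
        stop("target fraction unachievable at grid resolution for ", r)
      if (ndam > 0) {
        sel <- if (cfg$stochastic_placement) sample(vox[[r]], ndam)
               else vox[[r]][seq_len(ndam)]
        m[sel] <- 1
      }
      realised[r] <- ndam / nv
    }
    mask <- binary_mask(m, voxel_dims = cfg$voxel_dims)
    pid <- rownames(td)[i]
    masks[[pid]] <- mask
    profiles[[pid]] <- structure(
      list(patient = pid, damage = realised,
           lesion_volume_cm3 = lesion_volume_cm3(mask)),
      class = "damage_profile")
  }
  list(atlas = atlas, masks = masks, profiles = profiles)
}

#' Generate synthetic behavioural responses from norms and damage
#'
#' Per participant-by-item Bernoulli responses under the logistic model in
#' [cohort_gen_config], with the item covariate `s` the standardised
#' correlation-by-distinctiveness slope computed from the norms through the
#' package's own conceptual-structure pipeline. Items whose slope is
#' undefined are dropped. Patients with nonzero damage in `damage_roi` are
#' labelled "vATL-damaged", the rest "vATL-intact".
#'
#' @param norms a [property_norms] object.
#' @param profiles list of `damage_profile` objects (ground truth or
#'   measured).
#' @param cfg a [cohort_gen_config] carrying the behavioural coefficients.
#' @return data.frame with columns `participant`, `group`, `item`,
#'   `correct`; attributes `covariates` (data.frame item, slope, s) and
#'   `provenance`.
#' @export
gen_behaviour <- function(norms, profiles, cfg) {
  stopifnot(inherits(norms, "property_norms"),
            inherits(cfg, "cohort_gen_config"))
  fs <- feature_statistics(norms)
  cs <- concept_statistics(norms, fs)
  cs <- cs[is.finite(cs$corr_x_dist_slope), ]
  if (nrow(cs) < 2L) stop("too few items with a defined slope")
  if (stats::sd(cs$corr_x_dist_slope) == 0) stop("non-finite covariates")
  s <- as.numeric(scale(cs$corr_x_dist_slope))
  n_items <- min(cfg$n_items, nrow(cs))
  idx <- seq_len(n_items)
  set.seed(cfg$seed + 1L)
  dmg <- vapply(profiles, function(p) p$damage[[cfg$damage_roi]], numeric(1))
  if (any(!is.finite(dmg))) stop("non-finite damage covariate")
  out <- do.call(rbind, lapply(seq_along(profiles), function(j) {
    eta <- cfg$b0 + cfg$b_dmg * dmg[j] + cfg$b_int * dmg[j] * s[idx] +
      stats::rnorm(n_items, 0, cfg$noise_sd)
    data.frame(participant = names(profiles)[j],
               group = if (dmg[j] > 0) "vATL-damaged" else "vATL-intact",
               item = cs$concept[idx],
               correct = stats::rbinom(n_items, 1, stats::plogis(eta)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "covariates") <- data.frame(item = cs$concept[idx],
                                        slope = cs$corr_x_dist_slope[idx],
                                        s = s[idx], stringsAsFactors = FALSE)
  attr(out, "provenance") <- unclass(cfg)
  out
}

#' Per-patient structure-effect scores and their damage correlation
#'
#' Computes each patient's item-wise point-biserial correlation between
#' correctness and the standardised slope covariate, Fisher-transforms it,
#' and correlates the resulting z scores with damage in one ROI
#' (one-tailed Spearman, positive direction: more damage predicts a more
#' positive accuracy-by-slope correlation).
#'
#' @param behaviour output of [gen_behaviour] (or any accuracy table with a
#'   `covariates` attribute).
#' @param profiles list of `damage_profile` objects aligned by patient.
#' @param roi ROI whose damage is tested.
#' @param alpha significance threshold.
#' @return list with `z` (named per-patient scores), `test` (a
#'   [test_result]) and `significant`.
#' @export
slope_effect_damage_test <- function(behaviour, profiles, roi = "PRc",
                                     alpha = 0.05) {
  cov <- attr(behaviour, "covariates")
  pc <- accuracy_covariate_correlations(
    behaviour, list(s = stats::setNames(cov$s, cov$item)),
    level = "participant")
  z <- stats::setNames(pc$z, pc$participant)
  z[pc$flagged] <- NA_real_
  dmg <- vapply(profiles, function(p) p$damage[[roi]], numeric(1))
  names(dmg) <- vapply(profiles, function(p) as.character(p$patient), "")
  ok <- names(z)[is.finite(z[names(dmg)])]
  tr <- spearman_test(dmg[ok], z[ok], tail = "one", direction = "greater")
  list(z = z, test = tr, significant = tr$p < alpha & tr$statistic > 0)
}

#' Type-I error calibration of the damage-effect correlation
#'
#' Simulates cohorts under the null behavioural model (`b_dmg = b_int = 0`)
#' and reports the fraction in which the one-tailed damage-by-slope-effect
#' Spearman test rejects at `alpha`. Norms and the lesion cohort are drawn
#' once; each run redraws the behavioural responses.
#'
#' @param n_runs number of simulated cohorts.
#' @param ncfg,ccfg generator configurations; `ccfg` coefficients are forced
#'   to the null.
#' @param alpha nominal level.
#' @param seed base seed.
#' @return list with `rejection_rate`, `n_runs`, `alpha`.
#' @export
null_rejection_rate <- function(n_runs = 400L, ncfg = norm_gen_config(),
                                ccfg = cohort_gen_config(), alpha = 0.05,
                                seed = 1L) {
  ccfg$b_dmg <- 0; ccfg$b_int <- 0
  ncfg$seed <- seed
  norms <- gen_property_norms(ncfg)
  ccfg$seed <- seed
  cohort <- gen_lesion_cohort(ccfg)
  rej <- vapply(seq_len(n_runs), function(i) {
    cfg_i <- ccfg
    cfg_i$seed <- seed + i
    beh <- gen_behaviour(norms, cohort$profiles, cfg_i)
    slope_effect_damage_test(beh, cohort$profiles, ccfg$damage_roi,
                             alpha)$significant
  }, logical(1))
  list(rejection_rate = mean(rej), n_runs = n_runs, alpha = alpha)
}

#' Power of the pipeline to recover an injected damage-by-structure link
#'
#' Runs the full pipeline repeatedly — generate norms, generate a lesion
#' cohort, measure damage from the masks and atlas, generate behaviour with
#' a positive damage-by-slope interaction, compute per-patient effect
#' scores, and test the damage-effect Spearman correlation — and reports the
#' fraction of runs with a significant positive correlation.
#'
#' @param n_runs number of simulated pipelines.
#' @param ncfg,ccfg generator configurations (`ccfg$b_int` sets the injected
#'   interaction strength).
#' @param alpha nominal level.
#' @param seed base seed.
#' @return list with `power`, `n_runs`, `alpha`, `b_int`.
#' @export
interaction_recovery_power <- function(n_runs = 200L,
                                       ncfg = norm_gen_config(
                                         n_living = 100L, n_nonliving = 100L),
                                       ccfg = cohort_gen_config(
                                         b_int = 3, n_items = 200L),
                                       alpha = 0.05, seed = 1L) {
  ccfg$seed <- seed
  cohort <- gen_lesion_cohort(ccfg)
  measured <- Map(function(m, id) roi_damage_profile(m, cohort$atlas, id),
                  cohort$masks, names(cohort$masks))
  hit <- vapply(seq_len(n_runs), function(i) {
    ncfg_i <- ncfg; ncfg_i$seed <- seed + i
    norms <- gen_property_norms(ncfg_i)
    cfg_i <- ccfg; cfg_i$seed <- seed + n_runs + i
    beh <- gen_behaviour(norms, measured, cfg_i)
    slope_effect_damage_test(beh, measured, ccfg$damage_roi,
                             alpha)$significant
  }, logical(1))
  list(power = mean(hit), n_runs = n_runs, alpha = alpha, b_int = ccfg$b_int)
}
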