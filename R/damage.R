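#' Per-ROI damage profile for one patient
#'
#' Damage to an ROI is the mean lesion value over that ROI's voxels, which
#' for a 0/1 mask is the proportion of the ROI that is damaged. The total
#' lesion volume is counted over the whole mask. Empty ROIs get NA damage
#' (missing, never 0). When `merge_hemispheres` and legend names carry an
#' `L_`/`R_` prefix, homologous ROIs are pooled by stripped name, matching a
#' cohort in which left- and right-lesion patients are analysed together.
#'
#' @param lesion a `binary_mask` on the same grid as `atlas`.
#' @param atlas an [roi_atlas].
#' @param patient patient identifier stored in the profile.
#' @param merge_hemispheres pool `L_`/`R_`-prefixed ROIs by stripped name.
#' @return object of class `damage_profile`: list with `patient`, `damage`
#'   (named proportions, NA for empty ROIs) and `lesion_volume_cm3`.
#' @export
roi_damage_profile <- function(lesion, atlas, patient = NA_character_,
                               merge_hemispheres = TRUE) {
  stopifnot(inherits(lesion, "binary_mask"), inherits(atlas, "roi_atlas"))
  if (!identical(dim(lesion$data), dim(atlas$labels)) ||
      !isTRUE(all.equal(lesion$voxel_dims, atlas$voxel_dims)))
    stop("lesion and atlas grids do not match")
  legend <- atlas$legend
  groups <- names(legend)
  if (merge_hemispheres) groups <- sub("^[LR]_", "", groups)
  damage <- vapply(unique(groups), function(g) {
    codes <- legend[groups == g]
    v <- lesion$data[atlas$labels %in% codes]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  structure(list(patient = patient, damage = damage,
                 lesion_volume_cm3 = lesion_volume_cm3(lesion)),
            class = "damage_profile")
}

#' Assemble damage profiles into a patients-by-ROI matrix
#'
#' @param profiles list of `damage_profile` objects.
#' @return numeric matrix, rows named by patient, columns by ROI.
#' @export
damage_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  rois <- names(profiles[[1]]$damage)
  for (p in profiles)
    if (!identical(names(p$damage), rois))
      stop("profiles do not share ROI names")
  m <- t(vapply(profiles, function(p) p$damage, numeric(length(rois))))
  rownames(m) <- vapply(profiles, function(p) as.character(p$patient), "")
  m
}

#' Pairwise correlations between per-ROI damage scores
#'
#' Pearson correlations across patients between every pair of ROI damage
#' columns, with two-tailed p-values and a p < alpha significance flag.
#' Zero-variance ROIs yield NA for their pairs.
#'
#' @param profiles list of `damage_profile` objects (>= 3).
#' @param alpha significance threshold for flagging.
#' @return list with matrices `r`, `p` and logical `sig`.
#' @export
damage_intercorrelations <- function(profiles, alpha = 0.05) {
  m <- damage_matrix(profiles)
  if (nrow(m) < 3L) stop("need at least 3 damage profiles")
  pw <- pairwise_pearson(m)
  sdev <- apply(m, 2, stats::sd)
  zero <- !is.finite(sdev) | sdev == 0
  pw$r[zero, ] <- NA_real_; pw$r[, zero] <- NA_real_
  pw$p[zero, ] <- NA_real_; pw$p[, zero] <- NA_real_
  diag(pw$r) <- 1
  list(r = pw$r, p = pw$p, sig = !is.na(pw$p) & pw$p < alpha)
}
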