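#' Region-of-interest label atlas
#'
#' A label volume assigning each voxel an integer ROI code, with a legend
#' mapping codes to ROI names. Code 0 is reserved for background and for
#' voxels left undefined by ties in atlas construction.
#'
#' @param labels 3-D integer array of ROI codes.
#' @param legend named integer vector, names are ROI names, values codes.
#' @param voxel_dims,space,anterior_axis see [volume_grid].
#' @return object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, legend, voxel_dims = c(1, 1, 1), space = "MNI",
                      anterior_axis = 2L) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be non-negative integer codes")
  if (is.null(names(legend)) || anyDuplicated(names(legend)) ||
      anyDuplicated(legend))
    stop("`legend` must map unique ROI names to unique codes")
  if (any(legend == 0)) stop("code 0 is reserved for background")
  extra <- setdiff(unique(as.vector(labels)), c(0L, unname(legend)))
  if (length(extra)) stop("labels contain codes absent from legend: ",
                          paste(extra, collapse = ", "))
  structure(list(labels = labels, legend = legend,
                 voxel_dims = as.numeric(voxel_dims), space = space,
                 anterior_axis = as.integer(anterior_axis)),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("roi_atlas %s: %s\n", paste(dim(x$labels), collapse = "x"),
              paste(names(x$legend), collapse = ", ")))
  invisible(x)
}

#' Build a maximum-probability ROI atlas from rater drawings
#'
#' Each ROI is drawn as a binary mask by one or more raters on a common grid.
#' Per ROI, the probability map is the fraction of raters marking each voxel;
#' the atlas assigns each voxel to the ROI with the highest probability among
#' voxels with a positive maximum. Voxels where two or more ROIs tie for
#' first place are left undefined (assigned `tie_code`).
#'
#' @param drawings named list (one element per ROI) of lists of
#'   `binary_mask` objects (one per rater), all on the same grid.
#' @param tie_code label assigned at exact ties (default 0, background).
#' @return list with `prob_maps` (named list of [volume_grid]) and `atlas`
#'   (an [roi_atlas] whose legend numbers the ROIs in input order).
#' @export
build_max_prob_atlas <- function(drawings, tie_code = 0L) {
  if (!length(drawings) || is.null(names(drawings)))
    stop("`drawings` must be a named list with at least one ROI")
  if (any(vapply(drawings, length, 1L) == 0L))
    stop("every ROI needs at least one rater drawing")
  ref <- drawings[[1]][[1]]
  all_masks <- unlist(drawings, recursive = FALSE)
  for (m in all_masks) {
    stopifnot(inherits(m, "binary_mask"))
    if (!same_grid(m, ref)) stop("drawings do not share grid shape and space")
  }
  probs <- lapply(drawings, function(roi) {
    Reduce(`+`, lapply(roi, `[[`, "data")) / length(roi)
  })
  parr <- array(unlist(probs), dim = c(dim(ref$data), length(probs)))
  pm <- apply(parr, 1:3, max)
  n_at_max <- apply(parr, 1:3, function(v) sum(v == max(v)))
  lab <- apply(parr, 1:3, which.max)
  lab[pm == 0] <- 0L
  lab[pm > 0 & n_at_max > 1] <- as.integer(tie_code)
  legend <- stats::setNames(seq_along(drawings), names(drawings))
  if (tie_code != 0L) {
    if (tie_code %in% legend || tie_code < 0)
      stop("`tie_code` collides with an ROI code")
    legend <- c(legend, undefined = as.integer(tie_code))
  }
  prob_maps <- lapply(probs, volume_grid, voxel_dims = ref$voxel_dims,
                      space = ref$space, anterior_axis = ref$anterior_axis)
  list(prob_maps = prob_maps,
       atlas = roi_atlas(array(as.integer(lab), dim = dim(ref$data)), legend,
                         voxel_dims = ref$voxel_dims, space = ref$space,
                         anterior_axis = ref$anterior_axis))
}

#' Truncate ROIs posterior to a reference ROI
#'
#' Restricts the listed ROIs to the anterior-posterior extent of a reference
#' ROI: voxels posterior to the most posterior coronal slice containing the
#' reference are set to background. Posterior is the direction of decreasing
#' index along the atlas's `anterior_axis`.
#'
#' @param atlas an [roi_atlas].
#' @param rois_to_truncate character vector of ROI names to truncate.
#' @param reference_roi name of the reference ROI (must be nonempty).
#' @return the truncated [roi_atlas].
#' @export
truncate_posterior <- function(atlas, rois_to_truncate, reference_roi) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (!length(rois_to_truncate)) return(atlas)
  miss <- setdiff(c(rois_to_truncate, reference_roi), names(atlas$legend))
  if (length(miss)) stop("unknown ROI(s): ", paste(miss, collapse = ", "))
  ax <- atlas$anterior_axis
  ref_code <- atlas$legend[[reference_roi]]
  ref_slices <- which(apply(atlas$labels == ref_code, ax, any))
  if (!length(ref_slices)) stop("reference ROI is empty: ", reference_roi)
  cutoff <- min(ref_slices)
  idx <- slice.index(atlas$labels, ax)
  kill <- (idx < cutoff) &
    (atlas$labels %in% atlas$legend[rois_to_truncate])
  atlas$labels[kill] <- 0L
  atlas
}
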