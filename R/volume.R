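#' 3-D volume grid
#'
#' Minimal container for a voxel volume: a 3-D numeric array plus voxel
#' dimensions in mm, a space identifier and an axis-orientation record. The
#' orientation record names the array axis running posterior-to-anterior
#' (`anterior_axis`, by convention axis 2 with the index increasing towards
#' anterior), which the posterior-truncation step consults.
#'
#' @param data 3-D numeric array.
#' @param voxel_dims numeric length-3, voxel size in mm along each axis.
#' @param space space identifier string (e.g. "MNI").
#' @param anterior_axis array axis along which the index increases towards
#'   anterior (so posterior = decreasing index).
#' @return object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_dims = c(1, 1, 1), space = "MNI",
                        anterior_axis = 2L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(!is.finite(data))) stop("volume contains non-finite values")
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("`voxel_dims` must be 3 positive sizes in mm")
  stopifnot(anterior_axis %in% 1:3)
  structure(list(data = data, voxel_dims = as.numeric(voxel_dims),
                 space = space, anterior_axis = as.integer(anterior_axis)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid %s, %s mm voxels, space %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$voxel_dims, collapse = "x"), x$space))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_dims, b$voxel_dims)) &&
    identical(a$space, b$space)
}

#' Binarise an interpolated lesion mask
#'
#' Lesion masks drawn in native space and warped to template space carry
#' interpolated values in \[0, 1\]; binarisation restores a 0/1 mask. The
#' comparison is strict: a voxel is damaged iff its value exceeds the
#' threshold, so a value exactly at the threshold maps to 0.
#'
#' @param warped a [volume_grid] with values in \[0, 1\].
#' @param threshold binarisation threshold.
#' @return a `binary_mask` (a [volume_grid] with 0/1 data).
#' @export
binarize_mask <- function(warped, threshold = 0.5) {
  stopifnot(inherits(warped, "volume_grid"))
  if (any(warped$data < -1e-6) || any(warped$data > 1 + 1e-6))
    stop("mask values outside [0, 1]")
  out <- warped
  out$data <- (warped$data > threshold) + 0
  class(out) <- c("binary_mask", "volume_grid")
  out
}

#' Construct a binary mask directly from 0/1 data
#' @inheritParams volume_grid
#' @export
binary_mask <- function(data, voxel_dims = c(1, 1, 1), space = "MNI",
                        anterior_axis = 2L) {
  if (!all(data %in% c(0, 1))) stop("binary mask data must be 0/1")
  out <- volume_grid(data, voxel_dims, space, anterior_axis)
  class(out) <- c("binary_mask", "volume_grid")
  out
}

#' Lesion volume in cubic centimetres
#'
#' Counts the damaged (value 1) voxels and converts through the voxel size.
#'
#' @param mask a `binary_mask`.
#' @return volume in cm^3.
#' @export
lesion_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$voxel_dims) / 1000
}

#' Read or write a volume as NIfTI
#'
#' Thin wrappers over RNifti for interoperating with standard imaging files;
#' the in-memory representation stays a [volume_grid].
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param space,anterior_axis metadata to attach on read.
#' @return `read_volume_nifti` returns a [volume_grid].
#' @export
read_volume_nifti <- function(path, space = "MNI", anterior_axis = 2L) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input")
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]),
              voxel_dims = RNifti::pixdim(img)[1:3],
              space = space, anterior_axis = anterior_axis)
}

#' @param vol a [volume_grid] to write.
#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}
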