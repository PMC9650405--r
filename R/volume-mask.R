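#' Binary volumetric mask with physical spacing
#'
#' A `volume_mask` wraps a 3D binary voxel grid together with its anisotropic
#' voxel spacing (mm) and physical origin (mm). All geometry downstream is
#' done in physical millimetre coordinates: the centre of voxel `(i, j, k)`
#' (0-based) sits at `origin + (i*sx, j*sy, k*sz)`. The first array index is
#' the fastest-varying in-plane axis and the third index is the slice axis.
#'
#' @param voxels 3D array coercible to binary (values are thresholded at 0.5).
#' @param spacing_mm Numeric length-3, positive voxel spacing in mm.
#' @param origin_mm Numeric length-3 physical position of voxel (0,0,0), mm.
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("non-3D volume", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("non-positive spacing", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin must be a finite length-3 numeric", call. = FALSE)
  vox <- array(as.integer(as.numeric(voxels) >= 0.5), dim = dim(voxels))
  structure(
    list(voxels = vox, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "volume_mask"
  )
}

#' @export
print.volume_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_mask> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, %d foreground\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    sum(x$voxels)
  ))
  invisible(x)
}

is_volume_mask <- function(x) inherits(x, "volume_mask")

stopifnot_mask <- function(mask) {
  if (!is_volume_mask(mask)) stop("expected a volume_mask", call. = FALSE)
  invisible(mask)
}

# physical coordinates (mm) of all voxel centres, n x 3 (only where idx given)
voxel_to_mm <- function(mask, idx0) {
  sweep(sweep(idx0, 2, mask$spacing_mm, "*"), 2, mask$origin_mm, "+")
}

# mm -> fractional 0-based voxel coordinates
mm_to_voxel <- function(mask, pts_mm) {
  sweep(sweep(pts_mm, 2, mask$origin_mm, "-"), 2, mask$spacing_mm, "/")
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Voxel values are binarized at 0.5; spacing is taken from the header
#' `pixdim` fields and the origin from the stored transform translation.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3D volume: ", paste(d, collapse = "x"), call. = FALSE)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(spacing <= 0)) stop("non-positive spacing in header", call. = FALSE)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  # RNifti stores RAS+ transforms; our writer emits a positive-diagonal sform,
  # so the translation column is the physical position of voxel (0,0,0).
  volume_mask(array(as.numeric(img), dim = d), spacing, origin)
}

#' Write a binary mask to a NIfTI-1 file
#'
#' @param mask A [volume_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  xf <- diag(4)
  diag(xf)[1:3] <- mask$spacing_mm
  xf[1:3, 4] <- mask$origin_mm
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing_mm
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 1L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Keep the largest connected foreground component
#'
#' Preprocessing contract for centerline extraction: thinning assumes a
#' single connected structure. A warning is emitted when more than one
#' component was present.
#'
#' @param mask A [volume_mask()].
#' @param connectivity Voxel adjacency: 6 (faces), 18 (+edges) or 26 (+corners).
#' @return A [volume_mask()] containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot_mask(mask)
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  if (sum(mask$voxels) == 0L) stop("empty segmentation", call. = FALSE)
  lab <- cpp_label(array(mask$voxels == 1L, dim = dim(mask$voxels)),
                   dim(mask$voxels), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) > 1L)
    warning(sprintf("mask had %d connected components; keeping the largest (%d voxels)",
                    length(sizes), max(sizes)), call. = FALSE)
  keep <- which.max(sizes)
  volume_mask(array(as.integer(lab == keep), dim = dim(mask$voxels)),
              mask$spacing_mm, mask$origin_mm)
}

#' Count connected foreground components
#'
#' @inheritParams largest_component
#' @return Integer component count.
#' @export
count_components <- function(mask, connectivity = 26) {
  stopifnot_mask(mask)
  lab <- cpp_label(array(mask$voxels == 1L, dim = dim(mask$voxels)),
                   dim(mask$voxels), as.integer(connectivity))
  max(lab)
}
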