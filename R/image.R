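#' 3D volumetric image with voxel spacing
#'
#' A minimal container for a FLAIR-like scalar volume: a 3D numeric array
#' plus the physical voxel size in mm and a 4x4 voxel-to-world affine.
#' All segmentation operators in this package work in voxel space; the
#' affine is carried along for NIfTI round-trips and reporting only.
#'
#' @param values 3D numeric array of intensities (finite).
#' @param voxel_size Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return An object of class `vol_image`.
#' @export
vol_image <- function(values, voxel_size = c(1, 1, 1), affine = NULL) {
  values <- as_array3d(values)
  storage.mode(values) <- "double"
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(values = values, voxel_size = voxel_size, affine = affine),
    class = "vol_image"
  )
}

#' Binary mask aligned to a volumetric image
#'
#' @param values 3D logical (or coercible) array.
#' @param voxel_size Numeric length-3, mm.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return An object of class `vol_mask`.
#' @export
vol_mask <- function(values, voxel_size = c(1, 1, 1), affine = NULL) {
  values <- as_array3d(values)
  if (!is.logical(values)) {
    values <- array(as.logical(values), dim = dim(values))
  }
  if (anyNA(values)) stop("mask values must not be NA", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(values = values, voxel_size = voxel_size, affine = affine),
    class = "vol_mask"
  )
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("expected a 3D array", call. = FALSE)
  if (length(dim(x)) != 3) {
    # tolerate trailing singleton dims from NIfTI readers
    d <- dim(x)
    if (length(d) > 3 && all(d[-(1:3)] == 1)) {
      dim(x) <- d[1:3]
    } else {
      stop("expected a 3D array, got dims ", paste(d, collapse = "x"),
        call. = FALSE
      )
    }
  }
  x
}

#' @export
dim.vol_image <- function(x) dim(x$values)

#' @export
dim.vol_mask <- function(x) dim(x$values)

#' @export
print.vol_image <- function(x, ...) {
  cat(
    "<vol_image> ", paste(dim(x$values), collapse = " x "),
    " voxels @ ", paste(format(x$voxel_size), collapse = " x "), " mm, ",
    "intensity [", format(min(x$values)), ", ", format(max(x$values)), "]\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.vol_mask <- function(x, ...) {
  cat(
    "<vol_mask> ", paste(dim(x$values), collapse = " x "),
    " voxels @ ", paste(format(x$voxel_size), collapse = " x "), " mm, ",
    sum(x$values), " voxels set (", format(volume_ml(x), digits = 4),
    " ml)\n",
    sep = ""
  )
  invisible(x)
}

# stop() unless two image/mask objects share grid shape and voxel size
check_aligned <- function(a, b, what = "objects") {
  if (!identical(dim(a$values), dim(b$values)) ||
    max(abs(a$voxel_size - b$voxel_size)) > 1e-8) {
    stop(what, " are not aligned: shapes ",
      paste(dim(a$values), collapse = "x"), " vs ",
      paste(dim(b$values), collapse = "x"), ", voxel sizes ",
      paste(a$voxel_size, collapse = "x"), " vs ",
      paste(b$voxel_size, collapse = "x"),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Read / write volumes and masks as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()].
#' Masks are stored as 0/1 volumes; on reading, any voxel > 0.5 is TRUE.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` a `vol_image`; `read_mask()` a `vol_mask`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vol_image(
    as_array3d(array(as.numeric(img), dim = dim(img))),
    voxel_size = abs(RNifti::pixdim(img))[1:3],
    affine = structure(RNifti::xform(img), class = NULL)
  )
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as_array3d(array(as.numeric(img), dim = dim(img)))
  vol_mask(arr > 0.5,
    voxel_size = abs(RNifti::pixdim(img))[1:3],
    affine = structure(RNifti::xform(img), class = NULL)
  )
}

#' @rdname read_volume
#' @param x A `vol_image` or `vol_mask`.
#' @export
write_volume <- function(x, path) {
  arr <- x$values
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim = dim(arr))
  }
  nif <- RNifti::asNifti(arr)
  RNifti::pixdim(nif) <- x$voxel_size
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- write_volume

#' Volume of a binary mask in millilitres
#'
#' Counts TRUE voxels and multiplies by the single-voxel volume
#' (product of the voxel edge lengths), converting mm^3 to ml.
#'
#' @param mask A `vol_mask`.
#' @return Volume in ml (scalar).
#' @examples
#' m <- vol_mask(array(TRUE, c(10, 10, 10)), voxel_size = c(1, 1, 1))
#' volume_ml(m) # 1 ml
#' @export
volume_ml <- function(mask) {
  stopifnot(inherits(mask, "vol_mask"))
  sum(mask$values) * prod(mask$voxel_size) / 1000
}

# distance (mm) from every voxel to the nearest TRUE voxel of `mask`
distance_to <- function(mask) {
  d <- cpp_edt(
    as.logical(mask$values), dim(mask$values),
    as.numeric(mask$voxel_size)
  )
  array(d, dim = dim(mask$values))
}

# connected-component labels of a vol_mask (0 = background)
label_components <- function(mask, connectivity = 26) {
  connectivity <- match_connectivity(connectivity)
  array(
    cpp_label_components(as.logical(mask$values), dim(mask$values),
      connectivity
    ),
    dim = dim(mask$values)
  )
}

match_connectivity <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) {
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  }
  connectivity
}

#' Remove small connected components from a mask
#'
#' Scripted stand-in for the interactive cleanup of scattered
#' misclassified voxels: every connected component with fewer than
#' `min_voxels` voxels is dropped.
#'
#' @param mask A `vol_mask`.
#' @param min_voxels Minimum component size (voxels) to keep.
#' @param connectivity 6 or 26 (default) neighbourhood.
#' @return A `vol_mask`.
#' @export
filter_small_components <- function(mask, min_voxels = 5, connectivity = 26) {
  stopifnot(inherits(mask, "vol_mask"), min_voxels >= 1)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  out <- array(lab %in% keep & lab > 0L, dim = dim(mask$values))
  vol_mask(out, mask$voxel_size, mask$affine)
}
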