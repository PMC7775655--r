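#' Image volumes and lesion masks
#'
#' `image_volume()` wraps a 3D intensity array together with its voxel
#' spacing (mm), a modality tag and a grid-to-world affine.  `lesion_mask()`
#' wraps a binary 3D array aligned to a volume grid together with its
#' ROI-variant tag.  These are the two containers every stage of the
#' pipeline consumes and produces.
#'
#' Grid-to-world convention: world = affine %*% c(i - 1, j - 1, k - 1, 1)
#' for 1-based voxel index (i, j, k); the default affine is
#' diag(spacing) with a zero origin.
#'
#' @param data numeric (volume) or logical/0-1 (mask) 3D array.
#' @param spacing positive length-3 numeric, voxel spacing in mm.
#' @param modality modality tag, `"T1CE"` or `"T2"`.
#' @param affine optional 4x4 grid-to-world matrix.
#' @param variant ROI variant tag: `"original"`, `"eroded_025"` or
#'   `"eroded_05"`.
#' @return an object of class `image_volume` or `lesion_mask`.
#' @export
image_volume <- function(data, spacing, modality = c("T1CE", "T2"),
                         affine = NULL) {
  modality <- match.arg(modality)
  stop_if_not(is.array(data) && length(dim(data)) == 3,
              "image data must be a 3D array")
  stop_if_not(length(spacing) == 3 && all(spacing > 0),
              "voxel spacing must be 3 strictly positive values (mm)")
  stop_if_not(all(is.finite(data)), "image intensities must be finite")
  if (is.null(affine)) affine <- affine_from_spacing(spacing)
  stop_if_not(is.matrix(affine) && all(dim(affine) == c(4, 4)),
              "affine must be a 4x4 matrix")
  structure(list(data = data, spacing = as.numeric(spacing),
                 modality = modality, affine = affine),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
lesion_mask <- function(data, spacing, variant = "original") {
  stop_if_not(is.array(data) && length(dim(data)) == 3,
              "mask data must be a 3D array")
  stop_if_not(length(spacing) == 3 && all(spacing > 0),
              "voxel spacing must be 3 strictly positive values (mm)")
  stop_if_not(variant %in% c("original", "eroded_025", "eroded_05"),
              "unknown mask variant '%s'", variant)
  m <- array(as.logical(data), dim = dim(data))
  stop_if_not(!anyNA(m), "mask must be binary with no missing values")
  structure(list(data = m, spacing = as.numeric(spacing), variant = variant),
            class = "lesion_mask")
}

affine_from_spacing <- function(spacing, origin = c(0, 0, 0)) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- origin
  a
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask %s> %s grid, %d voxels in mask\n", x$variant,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.lesion_mask <- function(x) dim(x$data)

#' Read and write volumes/masks as NIfTI-1
#'
#' Voxel spacing is carried in the NIfTI pixdim header.  Masks are stored
#' as uint8 0/1.
#'
#' @param x an `image_volume` or `lesion_mask`.
#' @param file path to a `.nii` / `.nii.gz` file.
#' @param modality,variant tags to attach on read (the header does not
#'   carry them).
#' @return `write_volume()`/`write_mask()` return the path invisibly;
#'   readers return the reconstructed object.
#' @export
write_volume <- function(x, file) {
  stopifnot(inherits(x, "image_volume"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, file) {
  stopifnot(inherits(x, "lesion_mask"))
  img <- RNifti::asNifti(array(as.integer(x$data), dim = dim(x$data)))
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, file, datatype = "uint8")
  invisible(file)
}

#' @rdname write_volume
#' @export
read_volume <- function(file, modality = "T1CE") {
  img <- RNifti::readNifti(file)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3], modality = modality)
}

#' @rdname write_volume
#' @export
read_mask <- function(file, variant = "original") {
  img <- RNifti::readNifti(file)
  lesion_mask(array(as.numeric(img) > 0.5, dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3], variant = variant)
}
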