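# NIfTI I/O. Files follow the NIfTI (x, y, z[, c]) axis order; in memory
# the package uses (z, y, x, c), so axes are permuted on the way in/out
# and the spacing triple is reordered accordingly.

#' Read a volume (and optional mask) from NIfTI files
#'
#' @param image_path Path to a `.nii`/`.nii.gz` image.
#' @param mask_path Optional path to a binary mask of the same geometry;
#'   values are binarised with `> 0`.
#' @param id Volume id; defaults to the file name without extension.
#' @return A [volume_record()] with spacing taken from the image header.
#' @export
read_volume <- function(image_path, mask_path = NULL, id = NULL) {
  img <- RNifti::readNifti(image_path)
  if (is.null(id)) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  }
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 3) {
    arr <- aperm(arr, c(3, 2, 1))                 # (x,y,z) -> (z,y,x)
    arr <- array(arr, c(dim(arr), 1L))
  } else if (nd == 4) {
    arr <- aperm(arr, c(3, 2, 1, 4))              # keep channels last
  } else {
    stop("expected a 3D or 4D NIfTI image", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)[1:3]
  spacing <- rev(pd)                              # (sx,sy,sz) -> (sz,sy,sx)
  gt <- NULL
  if (!is.null(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    if (length(dim(m)) != 3) stop("mask must be 3D", call. = FALSE)
    gt <- (aperm(m, c(3, 2, 1)) > 0) * 1
  }
  volume_record(id, arr, spacing = spacing, gt_masks = gt)
}

#' Write a volume record to NIfTI files
#'
#' The image is written as-is; the mask (if present) is written as
#' unsigned 8-bit. Voxel spacing is stored in the headers.
#'
#' @param record A [volume_record()].
#' @param image_path Output image path.
#' @param mask_path Optional output path for `gt_masks`.
#' @return `image_path`, invisibly.
#' @export
write_volume <- function(record, image_path, mask_path = NULL) {
  stopifnot(inherits(record, "volume_record"))
  sp <- rev(record$spacing)                       # back to (sx, sy, sz)
  img <- record$image
  img <- if (dim(img)[4] == 1L) {
    aperm(array(img, dim(img)[1:3]), c(3, 2, 1))
  } else {
    aperm(img, c(3, 2, 1, 4))
  }
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- sp
  RNifti::writeNifti(nii, image_path)
  if (!is.null(mask_path)) {
    if (is.null(record$gt_masks)) {
      stop("record carries no gt_masks to write", call. = FALSE)
    }
    m <- aperm(record$gt_masks, c(3, 2, 1))
    storage.mode(m) <- "integer"
    mn <- RNifti::asNifti(m)
    RNifti::pixdim(mn) <- sp
    RNifti::writeNifti(mn, mask_path, datatype = "uint8")
  }
  invisible(image_path)
}

#' Write a pseudo-label stack as a NIfTI mask
#'
#' @param stack Binary `(z, y, x)` array (e.g. one element of
#'   [run_selflabel()]'s `stacks`).
#' @param path Output path.
#' @param spacing Voxel spacing `(sz, sy, sx)` in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(stack, path, spacing = c(1, 1, 1)) {
  m <- aperm(stack, c(3, 2, 1))
  storage.mode(m) <- "integer"
  mn <- RNifti::asNifti(m)
  RNifti::pixdim(mn) <- rev(spacing)
  RNifti::writeNifti(mn, path, datatype = "uint8")
  invisible(path)
}
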