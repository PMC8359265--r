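#' Neuromelanin-sensitive image volume
#'
#' A light container for a 3-D intensity grid plus the voxel geometry needed
#' for volumetry. Slice (third-axis) ordering is declared, never guessed:
#' `orientation = "IS"` means slice index 1 is the most inferior (caudal)
#' slice, `"SI"` the reverse.
#'
#' @param intensities 3-D numeric array of signal values.
#' @param voxel_size length-3 numeric, voxel dimensions in mm (dx, dy, dz).
#'   Default is the in-plane 0.4 mm / 3 mm slice geometry of midbrain
#'   turbo-spin-echo neuromelanin imaging.
#' @param orientation `"IS"` (index 1 = most inferior) or `"SI"`.
#' @return An object of class `nm_image`.
#' @export
nm_image <- function(intensities, voxel_size = c(0.4, 0.4, 3),
                     orientation = c("IS", "SI")) {
  orientation <- match.arg(orientation)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("image intensities must be finite", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths in mm", call. = FALSE)
  structure(
    list(intensities = intensities, voxel_size = voxel_size,
         orientation = orientation),
    class = "nm_image"
  )
}

#' @export
print.nm_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<nm_image> %d x %d x %d voxels, %.2g x %.2g x %.2g mm, %s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$orientation))
  invisible(x)
}

#' Paired SN and background ROI masks
#'
#' The SN mask delineates the hyperintense substantia nigra; the background
#' mask a signal-reference region (tegmentum / superior cerebral peduncles).
#' Both live on the image grid and must be disjoint; the background must be
#' present on every slice where the SN is, since SNR/CNR are slice-wise
#' ratios.
#'
#' @param sn_mask,bnd_mask logical 3-D arrays of identical shape.
#' @return An object of class `roi_mask_pair`.
#' @export
roi_mask_pair <- function(sn_mask, bnd_mask) {
  if (!identical(dim(sn_mask), dim(bnd_mask)))
    stop("SN and background masks must share a grid", call. = FALSE)
  sn_mask <- array(as.logical(sn_mask), dim(sn_mask))
  bnd_mask <- array(as.logical(bnd_mask), dim(bnd_mask))
  if (any(sn_mask & bnd_mask))
    stop("SN and background masks overlap", call. = FALSE)
  sn_slices <- which(apply(sn_mask, 3, any))
  bnd_slices <- which(apply(bnd_mask, 3, any))
  missing_bnd <- setdiff(sn_slices, bnd_slices)
  if (length(missing_bnd))
    stop("background mask empty on SN-bearing slice(s) ",
         paste(missing_bnd, collapse = ", "), call. = FALSE)
  structure(list(sn_mask = sn_mask, bnd_mask = bnd_mask),
            class = "roi_mask_pair")
}

check_mask_grid <- function(image, masks) {
  if (!identical(dim(image$intensities), dim(masks$sn_mask)))
    stop("mask grid does not match image grid", call. = FALSE)
  invisible(TRUE)
}

#' Write an image and its ROI labelmap as NIfTI-1
#'
#' The two masks are stored as a single labelmap (1 = SN, 2 = background),
#' the convention accepted back by [read_nm_scan()].
#'
#' @param image an [nm_image].
#' @param masks an [roi_mask_pair].
#' @param image_path,labels_path output `.nii` / `.nii.gz` paths.
#' @return Invisibly, the two paths.
#' @export
write_nm_scan <- function(image, masks, image_path, labels_path) {
  check_mask_grid(image, masks)
  img <- RNifti::asNifti(image$intensities)
  RNifti::pixdim(img) <- image$voxel_size
  RNifti::writeNifti(img, image_path)
  labels <- array(0L, dim(masks$sn_mask))
  labels[masks$sn_mask] <- 1L
  labels[masks$bnd_mask] <- 2L
  lab <- RNifti::asNifti(labels)
  RNifti::pixdim(lab) <- image$voxel_size
  RNifti::writeNifti(lab, labels_path)
  invisible(c(image = image_path, labels = labels_path))
}

#' Read an image and ROI labelmap written by [write_nm_scan()]
#'
#' @inheritParams write_nm_scan
#' @param orientation declared inferior-to-superior convention of the file.
#' @return `list(image = nm_image, masks = roi_mask_pair)`.
#' @export
read_nm_scan <- function(image_path, labels_path, orientation = "IS") {
  img <- RNifti::readNifti(image_path)
  vox <- RNifti::pixdim(img)[1:3]
  labels <- RNifti::readNifti(labels_path)
  arr <- array(as.numeric(img), dim(img)[1:3])
  lab <- array(as.integer(round(as.numeric(labels))), dim(labels)[1:3])
  list(
    image = nm_image(arr, voxel_size = vox, orientation = orientation),
    masks = roi_mask_pair(lab == 1L, lab == 2L)
  )
}
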