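#' Midbrain phantom specification
#'
#' Parameters of a synthetic neuromelanin-sensitive midbrain slab: a noisy
#' tegmentum-like background with two hyperintense SN blobs. Intensities are
#' expressed relative to the background mean, so `sn_target_snr` is on the
#' conventional scale where 100 means no contrast.
#'
#' The default grid (96 x 96 x 12) is a scaled-down field of view relative to
#' a clinical acquisition; the voxel size is kept at the 0.4 x 0.4 x 3 mm of
#' the imaging protocol so all volumetry runs at the real voxel volume.
#'
#' @param grid_shape integer length-3, grid size in voxels.
#' @param voxel_size numeric length-3, voxel size in mm.
#' @param bnd_mean background mean intensity (arbitrary units).
#' @param bnd_sd background (and SN) noise SD; `0` gives a noiseless phantom.
#' @param sn_target_volume target SN volume per side, mm^3.
#' @param sn_target_snr target SNR of the SN relative to background (x100
#'   scale; must be > 0).
#' @param n_sn_slices number of contiguous slices the SN spans (>= 3 so that
#'   the three-lowest-slices measurement rule applies).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 12),
                         voxel_size = c(0.4, 0.4, 3),
                         bnd_mean = 100, bnd_sd = 1.5,
                         sn_target_volume = 135,
                         sn_target_snr = 112,
                         n_sn_slices = 3) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("`grid_shape` must be three dimensions of at least 8 voxels",
         call. = FALSE)
  if (sn_target_snr <= 0)
    stop("`sn_target_snr` must be positive", call. = FALSE)
  if (bnd_sd < 0) stop("`bnd_sd` must be >= 0", call. = FALSE)
  if (bnd_mean <= 0) stop("`bnd_mean` must be positive", call. = FALSE)
  if (n_sn_slices < 3) stop("`n_sn_slices` must be >= 3", call. = FALSE)
  if (n_sn_slices > grid_shape[3])
    stop("SN slice span exceeds the grid: resize the grid or reduce ",
         "`n_sn_slices`", call. = FALSE)
  if (sn_target_volume <= 0)
    stop("`sn_target_volume` must be positive", call. = FALSE)
  structure(
    list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
         bnd_mean = bnd_mean, bnd_sd = bnd_sd,
         sn_target_volume = sn_target_volume,
         sn_target_snr = sn_target_snr,
         n_sn_slices = as.integer(n_sn_slices)),
    class = "phantom_spec"
  )
}

# Deterministic footprint of one SN side on the axial grid: take, slice by
# slice, the n_k voxels closest to the blob centre under an anteroposteriorly
# elongated metric (the SN is longer along y than x). Exact voxel counts per
# slice make the realized volume match the target to within one voxel.
sn_side_footprint <- function(nx, ny, x0, y0, counts) {
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  d2 <- ((xs - x0))^2 + ((ys - y0) / 1.8)^2
  ord <- order(d2, xs, ys)
  lapply(counts, function(n_k) {
    idx <- ord[seq_len(n_k)]
    cbind(x = xs[idx], y = ys[idx])
  })
}

# Split N voxels over k slices, middle slices heavier, counts summing to N.
split_slice_counts <- function(n_total, k) {
  pos <- seq_len(k) - (k + 1) / 2
  w <- 1 - 0.3 * abs(pos) / max(abs(pos), 1)
  cum <- round(cumsum(w / sum(w)) * n_total)
  counts <- diff(c(0L, cum))
  if (any(counts < 1L))
    stop("SN target volume too small for ", k, " slices", call. = FALSE)
  counts
}

#' Generate a synthetic midbrain phantom with SN and background ROIs
#'
#' Builds Gaussian background noise `N(bnd_mean, bnd_sd^2)` everywhere, then
#' raises two ellipsoid-like SN blobs (one per side) to a mean intensity of
#' `bnd_mean * sn_target_snr / 100`. The SN mask is the union of the two
#' blobs and spans exactly `n_sn_slices` contiguous slices; the background
#' mask is a fixed rectangular tegmentum-like region dorsal to the blobs,
#' disjoint from them by construction and present on every slice.
#'
#' @param spec a [phantom_spec].
#' @param seed integer seed; the same spec and seed give bit-identical output.
#' @return `list(image = nm_image, masks = roi_mask_pair, sn_slices = ...)`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  voxvol <- prod(spec$voxel_size)

  n_side <- max(spec$n_sn_slices, round(spec$sn_target_volume / voxvol))
  counts <- split_slice_counts(n_side, spec$n_sn_slices)

  z0 <- (nz - spec$n_sn_slices) %/% 2 + 1L
  sn_slices <- seq.int(z0, length.out = spec$n_sn_slices)

  # SN centres ~6.4 mm either side of the midline (closer on small grids),
  # ventral half of the slab
  dx_vox <- max(3L, min(round(6.4 / spec$voxel_size[1]), nx %/% 4))
  y_sn <- round(ny * 0.40)
  x_l <- round(nx / 2) - dx_vox
  x_r <- round(nx / 2) + dx_vox

  sn_mask <- array(FALSE, c(nx, ny, nz))
  for (side_x in c(x_l, x_r)) {
    foot <- sn_side_footprint(nx, ny, side_x, y_sn, counts)
    for (k in seq_along(sn_slices)) {
      xy <- foot[[k]]
      if (any(xy[, 1] <= 1 | xy[, 1] >= nx | xy[, 2] <= 1 | xy[, 2] >= ny))
        stop("SN geometry does not fit the grid: enlarge `grid_shape` or ",
             "shrink `sn_target_volume`", call. = FALSE)
      sn_mask[cbind(xy, sn_slices[k])] <- TRUE
    }
  }
  if (sum(sn_mask) != 2L * n_side)  # overlap of the two sides collapses voxels
    stop("SN blobs overlap: enlarge `grid_shape`", call. = FALSE)

  # tegmentum-like background box, dorsal to the SN blobs, on every slice
  bx <- seq.int(round(nx / 2) - round(nx / 8), round(nx / 2) + round(nx / 8))
  by <- seq.int(round(ny * 0.62), round(ny * 0.78))
  bnd_mask <- array(FALSE, c(nx, ny, nz))
  bnd_mask[bx, by, ] <- TRUE
  if (any(bnd_mask & sn_mask))
    stop("background region intersects the SN: enlarge `grid_shape`",
         call. = FALSE)

  set.seed(as.integer(seed))
  vox <- array(stats::rnorm(nx * ny * nz, spec$bnd_mean, spec$bnd_sd),
               c(nx, ny, nz))
  sn_mean <- spec$bnd_mean * spec$sn_target_snr / 100
  vox[sn_mask] <- stats::rnorm(sum(sn_mask), sn_mean, spec$bnd_sd)

  list(
    image = nm_image(vox, voxel_size = spec$voxel_size, orientation = "IS"),
    masks = roi_mask_pair(sn_mask, bnd_mask),
    sn_slices = sn_slices
  )
}

# Face-connected (6-neighbourhood) boundary of a 3-D mask: voxels of the mask
# touching the outside plus outside voxels touching the mask.
mask_boundary <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1L) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else          { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  nb_any <- array(FALSE, d)
  nb_all <- array(TRUE, d)
  for (ax in 1:3) for (by in c(1L, -1L)) {
    s <- shift(mask, ax, by)
    nb_any <- nb_any | s
    nb_all <- nb_all & s        # grid edge counts as outside
  }
  (mask & !nb_all) | (!mask & nb_any)
}

#' Perturb a mask at its boundary to emulate rater variability
#'
#' Each boundary voxel (a mask voxel facing the outside, or an outside voxel
#' facing the mask, 6-connectivity) is toggled independently with probability
#' `boundary_shift_prob`. Interior and far-field voxels are untouched, so the
#' expected Dice overlap with the original decreases monotonically with the
#' shift probability.
#'
#' @param mask logical 3-D array, nonempty.
#' @param boundary_shift_prob per-voxel toggle probability in \[0, 1\].
#' @param seed integer seed.
#' @return A logical array of the same shape.
#' @export
perturb_mask <- function(mask, boundary_shift_prob, seed = 1L) {
  if (!any(mask)) stop("cannot perturb an empty mask", call. = FALSE)
  if (boundary_shift_prob < 0 || boundary_shift_prob > 1)
    stop("`boundary_shift_prob` must be in [0, 1]", call. = FALSE)
  boundary <- which(mask_boundary(mask))
  set.seed(as.integer(seed))
  toggle <- boundary[stats::runif(length(boundary)) < boundary_shift_prob]
  out <- mask
  out[toggle] <- !out[toggle]
  out
}
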