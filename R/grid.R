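#' Define a volumetric grid
#'
#' A `vol_grid` is the common space every volume in an analysis lives on: a
#' 3-D array shape, a 4x4 affine mapping voxel indices (0-based, as in the
#' NIfTI convention) to millimetre coordinates, and a logical brain mask.
#' All maps entering a comparison must share the same grid.
#'
#' @param shape Integer vector of length 3, all positive.
#' @param affine 4x4 invertible numeric matrix (voxel index -> mm). Defaults
#'   to an isotropic `voxel_size_mm` scaling centred at the origin.
#' @param mask Logical array of dimension `shape`, or `NULL` for all-TRUE.
#' @param voxel_size_mm Isotropic voxel edge in mm used when `affine` is not
#'   given.
#' @return An object of class `vol_grid` with elements `shape`, `affine`,
#'   `mask`.
#' @examples
#' g <- vol_grid(c(10, 10, 10), voxel_size_mm = 2)
#' sum(g$mask)
#' @export
vol_grid <- function(shape, affine = NULL, mask = NULL, voxel_size_mm = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- -voxel_size_mm * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) {
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  }
  if (abs(det(affine)) < .Machine$double.eps * 100) {
    stop("`affine` must be invertible", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim = shape)
  }
  mask <- array(as.logical(mask), dim = shape)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  structure(list(shape = shape, affine = affine, mask = mask),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat("<vol_grid> ", paste(x$shape, collapse = " x "),
      " | mask voxels: ", sum(x$mask),
      " | voxel size (mm): ",
      paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3), collapse = " x "),
      "\n", sep = "")
  invisible(x)
}

#' Spherical brain mask on a grid
#'
#' Convenience constructor for a grid whose mask is a centred ball, the
#' synthetic stand-in for a brain mask.
#'
#' @param shape Integer vector of length 3.
#' @param radius_frac Ball radius as a fraction of the smallest half-extent.
#' @param voxel_size_mm Isotropic voxel edge in mm.
#' @return A `vol_grid`.
#' @export
sphere_grid <- function(shape = c(24, 24, 24), radius_frac = 0.9,
                        voxel_size_mm = 2) {
  shape <- as.integer(shape)
  ctr <- (shape - 1) / 2
  idx <- expand.grid(i = seq_len(shape[1]) - 1,
                     j = seq_len(shape[2]) - 1,
                     k = seq_len(shape[3]) - 1)
  r2 <- (idx$i - ctr[1])^2 + (idx$j - ctr[2])^2 + (idx$k - ctr[3])^2
  rad <- radius_frac * min(shape - 1) / 2
  mask <- array(r2 <= rad^2, dim = shape)
  vol_grid(shape, mask = mask, voxel_size_mm = voxel_size_mm)
}

#' Millimetre coordinates of mask voxels
#'
#' @param grid A `vol_grid`.
#' @param mask Optional logical array overriding `grid$mask`.
#' @return Matrix with one row per in-mask voxel (array order) and columns
#'   x, y, z in mm.
#' @export
mask_coords <- function(grid, mask = NULL) {
  stopifnot(inherits(grid, "vol_grid"))
  if (is.null(mask)) mask <- grid$mask
  idx <- which(mask, arr.ind = TRUE) - 1L  # 0-based voxel indices
  xyz <- cbind(idx, 1) %*% t(grid$affine)
  colnames(xyz) <- c("x", "y", "z", "w")
  xyz[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) < tol
}

# values of a volume restricted to the mask, in which() order
mask_values <- function(volume, grid, mask = NULL) {
  if (is.null(mask)) mask <- grid$mask
  as.numeric(volume[mask])
}

# place a masked value vector back into a full volume (NA outside mask)
unmask <- function(values, grid, mask = NULL, fill = NA_real_) {
  if (is.null(mask)) mask <- grid$mask
  vol <- array(fill, dim = grid$shape)
  vol[mask] <- values
  vol
}
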