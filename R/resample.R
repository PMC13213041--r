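#' Resample a volume onto a target grid
#'
#' Maps every target-mask voxel through both affines into the source voxel
#' lattice and interpolates. Nearest-neighbour is mandatory for label
#' volumes; voxels falling outside the source lattice (or outside the source
#' mask, for `nearest`) come back as `NA` and are excluded from downstream
#' correlations.
#'
#' @param volume 3-D numeric array on `source_grid`.
#' @param source_grid,target_grid [vol_grid()]s.
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @param is_label Set `TRUE` for label volumes; trilinear is then refused.
#' @return 3-D array on the target grid (`NA` outside coverage/mask).
#' @export
resample_to_grid <- function(volume, source_grid, target_grid,
                             interpolation = c("trilinear", "nearest"),
                             is_label = FALSE) {
  interpolation <- match.arg(interpolation)
  if (is_label && interpolation != "nearest") {
    stop("label volumes must use nearest-neighbour interpolation",
         call. = FALSE)
  }
  stopifnot(all(dim(volume) == source_grid$shape))
  tgt_idx <- which(target_grid$mask, arr.ind = TRUE) - 1L
  xyz <- cbind(tgt_idx, 1) %*% t(target_grid$affine)
  src_idx <- xyz %*% t(solve(source_grid$affine))[, 1:3]  # 0-based, fractional
  colnames(src_idx) <- c("i", "j", "k")
  d <- source_grid$shape
  out_vals <- rep(NA_real_, nrow(src_idx))

  if (interpolation == "nearest") {
    nn <- round(src_idx)
    ok <- nn[, 1] >= 0 & nn[, 1] <= d[1] - 1 &
          nn[, 2] >= 0 & nn[, 2] <= d[2] - 1 &
          nn[, 3] >= 0 & nn[, 3] <= d[3] - 1
    lin <- nn[ok, 1] + 1 + nn[ok, 2] * d[1] + nn[ok, 3] * d[1] * d[2]
    out_vals[ok] <- volume[lin]
  } else {
    f <- floor(src_idx)
    ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 &
          f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
          f[, 3] >= 0 & f[, 3] <= d[3] - 2
    fo <- f[ok, , drop = FALSE]
    w <- src_idx[ok, , drop = FALSE] - fo
    acc <- numeric(sum(ok))
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      wt <- (if (di) w[, 1] else 1 - w[, 1]) *
            (if (dj) w[, 2] else 1 - w[, 2]) *
            (if (dk) w[, 3] else 1 - w[, 3])
      lin <- (fo[, 1] + di) + 1 + (fo[, 2] + dj) * d[1] +
             (fo[, 3] + dk) * d[1] * d[2]
      acc <- acc + wt * volume[lin]
    }
    out_vals[ok] <- acc
  }
  out <- array(NA_real_, dim = target_grid$shape)
  out[target_grid$mask] <- out_vals
  if (is_label) out[] <- as.integer(round(out))
  out
}
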