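#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Deterministic per-stage seed derived from a master seed and a stage name.
# Keeps results of one stage reproducible without rerunning predecessors.
stage_seed <- function(master_seed, stage) {
  chars <- utf8ToInt(stage)
  h <- (sum(chars * seq_along(chars)) * 2654435761) %% 2147483647
  as.integer((as.numeric(master_seed) * 31 + h) %% 2147483647)
}

# run code under a local RNG state so generators do not disturb the caller
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaussian FWHM (mm) -> sd in voxels along each axis
fwhm_to_sigma_vox <- function(fwhm_mm, grid) {
  vox_mm <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  (fwhm_mm / (2 * sqrt(2 * log(2)))) / vox_mm
}

# separable Gaussian smoothing of a 3-D array (reflective edge handling via
# kernel renormalization on a constant field)
smooth_volume <- function(vol, sigma_vox) {
  stopifnot(length(dim(vol)) == 3L)
  out <- vol
  ones <- array(1, dim = dim(vol))
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    out <- convolve_axis(out, k, axis)
    ones <- convolve_axis(ones, k, axis)
  }
  out / ones
}

# 1-D convolution along one axis of a 3-D array, zero padded
convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- matrix(v, nrow = dv[1])
  half <- (length(kernel) - 1L) / 2L
  n <- nrow(m)
  res <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(kernel)) {
    off <- t - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    res[ok, ] <- res[ok, ] + kernel[t] * m[src[ok], ]
  }
  v <- array(res, dim = dv)
  aperm(v, order(perm))
}

# nearest positive-definite projection by eigenvalue clipping
nearest_pd <- function(S, eps = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values > eps)) return(S)
  vals <- pmax(e$values, eps)
  V <- e$vectors
  out <- V %*% (vals * t(V))
  # restore unit diagonal scale (correlation-like input)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  (out + t(out)) / 2
}

upper_pairs <- function(ids) {
  ids <- sort(ids)
  m <- length(ids)
  if (m < 2) stop("need at least two component ids", call. = FALSE)
  i <- rep(ids[-m], times = (m - 1):1)
  j <- unlist(lapply(seq_len(m - 1), function(a) ids[(a + 1):m]))
  tibble::tibble(edge = paste0("IC", i, "_IC", j), i = i, j = j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
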