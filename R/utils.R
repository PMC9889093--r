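#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif quantile sd approx
NULL

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards so library code never disturbs user-level reproducibility.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Deterministic child seed from a master seed and an index; stays inside the
# 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103L + as.double(index) * 7919L) %% 2147483647)
}

# Flat disc structuring element: pixel included iff its centre lies within
# Euclidean distance `radius_px` of the origin.
disc_kernel <- function(radius_px) {
  stopifnot(radius_px >= 1)
  r <- as.integer(ceiling(radius_px))
  d <- expand.grid(dx = -r:r, dy = -r:r)
  k <- matrix(0L, 2L * r + 1L, 2L * r + 1L)
  inside <- d$dx^2 + d$dy^2 <= radius_px^2
  k[cbind(d$dx[inside] + r + 1L, d$dy[inside] + r + 1L)] <- 1L
  k
}

# Centred moving average with truncated (shrinking) edge windows.
moving_average <- function(x, window) {
  window <- as.integer(window)
  stopifnot(window >= 1)
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# Separable Gaussian blur of a 3D array; sigma per axis in voxels. Kernels are
# truncated at 3 sigma and renormalised at the edges (weights of out-of-bounds
# taps are dropped), so constant inputs are preserved exactly.
gauss_blur3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, as.integer(ceiling(3 * s)))
    offs <- -half:half
    w <- exp(-offs^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(arr))
    norm <- array(0, dim(arr))
    n_ax <- dim(arr)[axis]
    for (j in seq_along(offs)) {
      o <- offs[j]
      src <- seq_len(n_ax) + o
      keep <- src >= 1L & src <= n_ax
      if (!any(keep)) next
      dst_idx <- which(keep)
      src_idx <- src[keep]
      if (axis == 1L) {
        acc[dst_idx, , ] <- acc[dst_idx, , ] + w[j] * arr[src_idx, , ]
        norm[dst_idx, , ] <- norm[dst_idx, , ] + w[j]
      } else if (axis == 2L) {
        acc[, dst_idx, ] <- acc[, dst_idx, ] + w[j] * arr[, src_idx, ]
        norm[, dst_idx, ] <- norm[, dst_idx, ] + w[j]
      } else {
        acc[, , dst_idx] <- acc[, , dst_idx] + w[j] * arr[, , src_idx]
        norm[, , dst_idx] <- norm[, , dst_idx] + w[j]
      }
    }
    arr <- acc / norm
  }
  arr
}
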