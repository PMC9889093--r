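# Independent brute-force oracles used across test files. These deliberately
# re-derive results voxel by voxel, sharing no code with the package paths
# they check.

# Exhaustive per-voxel accumulation of per-plane metrics.
naive_plane_metrics <- function(voxels, mask) {
  d <- dim(voxels)
  out <- data.frame(fraction = numeric(d[3]), signal = numeric(d[3]),
                    noise = numeric(d[3]), snr = numeric(d[3]))
  for (z in seq_len(d[3])) {
    n_in <- 0; n_out <- 0; s_in <- 0; s_out <- 0
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        if (mask[i, j, z]) {
          n_in <- n_in + 1; s_in <- s_in + voxels[i, j, z]
        } else {
          n_out <- n_out + 1; s_out <- s_out + voxels[i, j, z]
        }
      }
    }
    out$fraction[z] <- n_in / (d[1] * d[2])
    out$signal[z] <- if (n_in > 0) s_in / n_in else NA_real_
    out$noise[z] <- if (n_out > 0) s_out / n_out else NA_real_
    out$snr[z] <- if (n_in > 0 && n_out > 0 && out$noise[z] > 0) {
      out$signal[z] / out$noise[z]
    } else {
      NA_real_
    }
  }
  out
}

# Naive sliding-ball min-then-max over the discrete disc neighbourhood
# (pixels within Euclidean distance radius of the centre), restricted to the
# image domain at the borders.
naive_rolling_ball <- function(plane, radius) {
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  n <- nrow(plane); m <- ncol(plane)
  sweep1 <- function(x, f, init) {
    out <- matrix(init, n, m)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        v <- init
        for (k in seq_len(nrow(offs))) {
          ii <- i + offs$dx[k]; jj <- j + offs$dy[k]
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) v <- f(v, x[ii, jj])
        }
        out[i, j] <- v
      }
    }
    out
  }
  sweep1(sweep1(plane, min, Inf), max, -Inf)
}

# Discrete ball voxel count: centre-inclusion rule, isotropic unit voxels.
naive_ball_count <- function(radius, centre, shape) {
  cnt <- 0L
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      for (k in seq_len(shape[3])) {
        if ((i - centre[1])^2 + (j - centre[2])^2 + (k - centre[3])^2 <= radius^2) {
          cnt <- cnt + 1L
        }
      }
    }
  }
  cnt
}

# Pooled-variance two-sample t statistic and two-sided p from the t CDF.
naive_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive Otsu: for each of the 256 bin edges, split the *binned* values
# and compute the between-class variance directly from the class members.
naive_otsu <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bins <- pmin(pmax(findInterval(values, edges, all.inside = TRUE), 1L), n_bins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  binned <- centers[bins]
  best_v <- -Inf
  best_t <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    lo <- binned[bins <= k]
    hi <- binned[bins > k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(binned)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-15) {
      best_v <- v
      best_t <- edges[k + 1L]
    }
  }
  best_t
}

# Small test fixtures -------------------------------------------------------

tiny_scene_params <- function(shape = c(24L, 24L, 30L), spacing = 5,
                              density = 0.04, size = 8, seed = 1L, ...) {
  scene_params(shape = shape, plane_spacing_um = spacing,
               feature_density = density, feature_size_um = size,
               seed = seed, ...)
}

noise_free <- function() {
  noise_params(background_level = 0, gaussian_sd = 0, poisson_like = FALSE,
               blur_sigma_um = 0)
}

random_stack <- function(shape, seed) {
  set.seed(seed)
  image_stack(array(runif(prod(shape)), shape), plane_spacing_um = 5)
}
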