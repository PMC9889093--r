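#' Percentile-normalize a stack
#'
#' Linearly rescales intensities so that the `low_pct` percentile maps to 0
#' and the `high_pct` percentile to 1, then clips to \[0, 1\]. The percentiles
#' are computed over the whole stack, never per plane, so genuine depth
#' attenuation survives normalization. The slightly inset defaults (0.1 /
#' 99.9) make the mapping robust to hot pixels.
#'
#' @param stack An [image_stack()].
#' @param low_pct,high_pct Percentiles in \[0, 100\], `low_pct < high_pct`.
#' @return A normalized [image_stack()]; the percentile bounds used are
#'   recorded in `$meta$normalization`.
#' @export
normalize_stack <- function(stack, low_pct = 0.1, high_pct = 99.9) {
  stopifnot(inherits(stack, "image_stack"))
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct) {
    stop("need 0 <= low_pct < high_pct <= 100", call. = FALSE)
  }
  q <- quantile(stack$voxels, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("stack is constant between the chosen percentiles; returning all zeros",
            call. = FALSE)
    v <- array(0, dim(stack$voxels))
  } else {
    v <- pmin(pmax((stack$voxels - q[1]) / (q[2] - q[1]), 0), 1)
    dim(v) <- dim(stack$voxels)
  }
  out <- stack
  out$voxels <- v
  out$meta$normalization <- list(low_pct = low_pct, high_pct = high_pct,
                                 low_value = q[1], high_value = q[2])
  out
}

# Non-flat (paraboloid/ball-surface) grayscale erosion or dilation: classic
# rolling-ball with the structuring function s(o) = sqrt(r^2 - |o|^2) - r
# (<= 0, 0 at the centre), scaled to intensity units by `height`.
nonflat_morph <- function(plane, radius_px, height, op = c("erode", "dilate")) {
  op <- match.arg(op)
  r <- as.integer(ceiling(radius_px))
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius_px^2, ]
  s <- height * (sqrt(radius_px^2 - offs$dx^2 - offs$dy^2) - radius_px) / radius_px
  n <- nrow(plane); m <- ncol(plane)
  out <- matrix(if (op == "erode") Inf else -Inf, n, m)
  for (j in seq_len(nrow(offs))) {
    dx <- offs$dx[j]; dy <- offs$dy[j]
    ri <- max(1L, 1L - dx):min(n, n - dx)
    ci <- max(1L, 1L - dy):min(m, m - dy)
    shifted <- plane[ri + dx, ci + dy, drop = FALSE]
    if (op == "erode") {
      out[ri, ci] <- pmin(out[ri, ci], shifted - s[j])
    } else {
      out[ri, ci] <- pmax(out[ri, ci], shifted + s[j])
    }
  }
  out
}

#' Rolling-ball background of a single plane
#'
#' Estimates the smooth background of a 2D intensity image by grayscale
#' morphological opening (erosion then dilation) with a flat disc-shaped
#' structuring element of the given radius: features narrower than the
#' element cannot support the "ball" and fall out of the background. The
#' background never exceeds the input and the operation is idempotent.
#'
#' `method = "paraboloid"` instead rolls a curved ball surface (the classic
#' intensity-paraboloid variant), with `ball_height` controlling the ball's
#' intensity-axis radius.
#'
#' @param plane Numeric matrix of intensities.
#' @param radius_px Element radius in pixels (>= 1). Must not exceed both
#'   image dimensions.
#' @param method `"opening"` (flat disc, default) or `"paraboloid"`.
#' @param ball_height Intensity-axis scale of the curved ball
#'   (`"paraboloid"` only).
#' @return Background matrix of the same shape.
#' @export
rolling_ball_background <- function(plane, radius_px,
                                    method = c("opening", "paraboloid"),
                                    ball_height = 0.1) {
  method <- match.arg(method)
  if (!is.matrix(plane)) stop("`plane` must be a matrix", call. = FALSE)
  if (radius_px < 1) stop("`radius_px` must be >= 1", call. = FALSE)
  if (radius_px > nrow(plane) && radius_px > ncol(plane)) {
    stop("radius ", radius_px, " px exceeds both image dimensions (",
         nrow(plane), " x ", ncol(plane), ")", call. = FALSE)
  }
  if (method == "opening") {
    kern <- disc_kernel(radius_px)
    EBImage::dilate(EBImage::erode(plane, kern), kern)
  } else {
    nonflat_morph(nonflat_morph(plane, radius_px, ball_height, "erode"),
                  radius_px, ball_height, "dilate")
  }
}

#' Subtract rolling-ball background from every plane
#'
#' Applies [rolling_ball_background()] independently to each z-plane (2D, as
#' is standard for depth stacks, since illumination and background vary by
#' plane) and subtracts it, clipping at zero.
#'
#' @param stack An [image_stack()].
#' @param radius_px Element radius in pixels. The default, 5 feature radii in
#'   pixels when the stack was rendered synthetically (falling back to 8),
#'   comfortably exceeds any real feature so the background cannot swallow it.
#' @inheritParams rolling_ball_background
#' @return An [image_stack()] of background-subtracted intensities.
#' @export
subtract_background <- function(stack, radius_px = NULL,
                                method = c("opening", "paraboloid"),
                                ball_height = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  if (is.null(radius_px)) {
    radius_px <- default_radius_px(stack)
  }
  if (radius_px > dim(stack$voxels)[1] && radius_px > dim(stack$voxels)[2]) {
    stop("radius ", radius_px, " px exceeds both plane dimensions", call. = FALSE)
  }
  if (radius_px < 1) stop("`radius_px` must be >= 1", call. = FALSE)
  v <- stack$voxels
  if (method == "opening") {
    kern <- disc_kernel(radius_px)
    bg <- EBImage::dilate(EBImage::erode(v, kern), kern)
  } else {
    bg <- array(0, dim(v))
    for (z in seq_len(dim(v)[3])) {
      bg[, , z] <- rolling_ball_background(v[, , z], radius_px, method,
                                           ball_height)
    }
  }
  out <- stack
  res <- pmax(v - bg, 0)
  dim(res) <- dim(v)
  out$voxels <- res
  out$meta$background <- list(radius_px = radius_px, method = method)
  out
}

default_radius_px <- function(stack) {
  fs <- stack$meta$feature_size_um
  if (is.null(fs)) {
    8
  } else {
    max(1, ceiling(5 * fs / stack$pixel_size_um))
  }
}

#' Otsu threshold of a value vector
#'
#' Builds a 256-bin histogram over the value range and returns the bin edge
#' maximizing the between-class variance (first maximum on ties).
#'
#' @param values Numeric vector.
#' @param n_bins Number of histogram bins.
#' @return The threshold value (a bin edge).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(values, edges, all.inside = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w <- counts / sum(counts)
  cum_w <- cumsum(w)
  cum_mu <- cumsum(w * centers)
  mu_t <- cum_mu[n_bins]
  # between-class variance for a cut after bin k
  valid <- cum_w > 0 & cum_w < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  k <- seq_len(n_bins - 1L)
  vk <- valid[k]
  sigma_b[vk] <- (mu_t * cum_w[k][vk] - cum_mu[k][vk])^2 /
    (cum_w[k][vk] * (1 - cum_w[k][vk]))
  best <- which.max(sigma_b)
  edges[best + 1L]
}

#' Threshold a stack into a segmentation mask
#'
#' Voxels strictly above the threshold become foreground. The Otsu threshold
#' is computed on the whole-stack histogram (256 bins), never per plane.
#'
#' @param stack An [image_stack()], typically normalized and
#'   background-subtracted.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param value Threshold in (0, 1); required for `method = "fixed"`.
#' @return A [segmentation_mask()] with `threshold_used` recorded.
#' @export
threshold_mask <- function(stack, method = c("otsu", "fixed"), value = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("method = \"fixed\" requires `value`", call. = FALSE)
    if (value <= 0 || value >= 1) stop("`value` must lie in (0, 1)", call. = FALSE)
    thr <- value
  } else {
    thr <- otsu_threshold(as.vector(stack$voxels))
  }
  segmentation_mask(array(stack$voxels > thr, dim(stack$voxels)),
                    source = "internal", threshold_used = thr)
}

#' Import an externally produced segmentation mask
#'
#' Reads a single-channel multipage TIFF exported by an external segmentation
#' tool (e.g. a trained pixel classifier). Binary files are taken as-is;
#' probability maps in \[0, 1\] are binarized at `prob_threshold` (strictly
#' greater than).
#'
#' @param path Path to a single-channel multipage TIFF.
#' @param prob_threshold Binarization threshold for probability maps.
#' @return A [segmentation_mask()] with `source = "imported"`.
#' @export
import_mask <- function(path, prob_threshold = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("TIFF has zero pages: ", path, call. = FALSE)
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop("multi-channel TIFF not supported for masks: ", path, call. = FALSE)
  }
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (any(arr < 0 | arr > 1)) {
    stop("mask values outside [0, 1] in ", path,
         "; expected binary or probability data", call. = FALSE)
  }
  is_binary <- all(arr %in% c(0, 1))
  vox <- if (is_binary) arr > 0.5 else arr > prob_threshold
  segmentation_mask(array(vox, dim(arr)), source = "imported",
                    threshold_used = if (is_binary) "external" else prob_threshold)
}

#' Full internal segmentation path
#'
#' Convenience wrapper chaining [normalize_stack()], [subtract_background()]
#' and [threshold_mask()] — the default route from a raw stack to a mask when
#' no external segmentation is supplied.
#'
#' The default is a fixed threshold of 0.2 in normalized units: after
#' background subtraction a voxel counts as stained when it exceeds
#' background by 20% of the bright-staining intensity range. A fixed,
#' permissive cut keeps the mask independent of how staining intensity is
#' distributed over depth; an automatic (Otsu) threshold adapts to that
#' distribution and truncates the depth profile of the very intensities it
#' was derived from, which biases intensity-based half-max depths toward the
#' threshold's own cutoff.
#'
#' @inheritParams normalize_stack
#' @inheritParams subtract_background
#' @inheritParams threshold_mask
#' @return A [segmentation_mask()].
#' @export
segment_stack <- function(stack, radius_px = NULL,
                          method = c("fixed", "otsu"), value = 0.2,
                          low_pct = 0.1, high_pct = 99.9) {
  method <- match.arg(method)
  processed <- stack |>
    normalize_stack(low_pct = low_pct, high_pct = high_pct) |>
    subtract_background(radius_px = radius_px)
  mask <- threshold_mask(processed, method = method, value = value)
  mask$radius_px <- processed$meta$background$radius_px
  mask
}
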