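#' Per-plane staining metrics
#'
#' The pipeline's central statistic: for every z-plane, the fraction of
#' voxels inside the segmentation mask (the "indexed" voxels, i.e. area of
#' staining), the mean intensity inside the mask (signal), the mean intensity
#' outside (noise), and their ratio (SNR). Planes with an empty mask have
#' `NA` signal and SNR — undefined, never zero, so a plane without any
#' detected staining cannot masquerade as a half-max crossing.
#'
#' @param stack An [image_stack()].
#' @param mask A congruent [segmentation_mask()].
#' @return A `depth_profile`: tibble with columns `plane` (0-based z index),
#'   `depth_um`, `fraction`, `signal`, `noise`, `snr`, plus the stack's
#'   metadata as columns `condition_id`, `replicate_id`, `fluorophore`.
#' @export
plane_metrics <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "segmentation_mask"))
  check_congruent(stack, mask)
  d <- dim(stack$voxels)
  nxy <- d[1] * d[2]
  nz <- d[3]
  v <- matrix(stack$voxels, nxy, nz)
  m <- matrix(mask$voxels, nxy, nz)
  n_in <- colSums(m)
  n_out <- nxy - n_in
  sum_in <- colSums(v * m)
  sum_all <- colSums(v)
  signal <- ifelse(n_in > 0, sum_in / n_in, NA_real_)
  noise <- ifelse(n_out > 0, (sum_all - sum_in) / n_out, NA_real_)
  snr <- ifelse(!is.na(signal) & !is.na(noise) & noise > 0,
                signal / noise, NA_real_)
  out <- tibble::tibble(
    plane = seq_len(nz) - 1L,
    depth_um = (seq_len(nz) - 1L) * stack$plane_spacing_um,
    fraction = n_in / nxy,
    signal = signal,
    noise = noise,
    snr = snr,
    condition_id = stack$condition_id,
    replicate_id = stack$replicate_id,
    fluorophore = stack$channel_label
  )
  attr(out, "plane_spacing_um") <- stack$plane_spacing_um
  class(out) <- c("depth_profile", class(out))
  out
}

profile_spacing <- function(profile) {
  sp <- attr(profile, "plane_spacing_um")
  if (!is.null(sp)) return(sp)
  if (nrow(profile) >= 2) return(diff(profile$depth_um[1:2]))
  1
}

#' Detect the first tissue plane of a profile
#'
#' Stacks often start above the tissue surface (mounting medium), so depth is
#' measured from the plane where staining first appears. The chosen metric is
#' smoothed by a centred moving average (edge windows truncated; `NA` planes
#' counted as 0) and the start is the first plane whose smoothed value
#' reaches `onset_frac` of the smoothed global maximum. An all-zero profile
#' starts at plane 0.
#'
#' @param profile A [plane_metrics()] result.
#' @param metric Column to use, `"signal"` or `"fraction"`.
#' @param onset_frac Fraction of the smoothed maximum defining onset.
#' @param smooth_window Moving-average window in planes.
#' @return 0-based integer plane index.
#' @export
find_start_plane <- function(profile, metric = c("signal", "fraction"),
                             onset_frac = 0.1, smooth_window = 3L) {
  metric <- match.arg(metric)
  if (!nrow(profile)) stop("empty profile", call. = FALSE)
  x <- profile[[metric]]
  x[is.na(x)] <- 0
  sm <- moving_average(x, smooth_window)
  mx <- max(sm)
  if (mx <= 0) return(0L)
  profile$plane[which(sm >= onset_frac * mx)[1]]
}

#' Depth at which staining falls to half its maximum
#'
#' The penetration-quality statistic: from `start_plane` onward the metric's
#' maximum is located (undefined planes skipped), then the first pair of
#' consecutive defined planes at or after the maximum where the metric
#' crosses half the maximum from above is found, and the crossing depth is
#' linearly interpolated. Depth is reported in µm relative to the start
#' plane. Profiles that never drop below half the maximum get an `NA` depth
#' with the maximum still recorded.
#'
#' @param profile A [plane_metrics()] result.
#' @param metric `"signal"` (mean in-mask staining intensity; default) or
#'   `"fraction"` (segmented area proportion).
#' @param start_plane 0-based start plane; `NULL` (default) detects it with
#'   [find_start_plane()].
#' @param onset_frac,smooth_window Passed to [find_start_plane()] when
#'   `start_plane` is `NULL`.
#' @return A one-row `half_max_result` tibble: `metric`, `start_plane`,
#'   `max_value`, `half_max_depth_um`, `condition_id`, `replicate_id`,
#'   `fluorophore`.
#' @export
half_max_depth <- function(profile, metric = c("signal", "fraction"),
                           start_plane = NULL, onset_frac = 0.1,
                           smooth_window = 3L) {
  metric <- match.arg(metric)
  if (is.null(start_plane)) {
    start_plane <- find_start_plane(profile, metric, onset_frac, smooth_window)
  }
  if (start_plane < 0 || start_plane > max(profile$plane)) {
    stop("`start_plane` out of range", call. = FALSE)
  }
  spacing <- profile_spacing(profile)
  sub <- profile[profile$plane >= start_plane, ]
  x <- sub[[metric]]
  ok <- !is.na(x)
  if (!any(ok)) {
    stop("metric `", metric, "` is undefined at every plane from start_plane onward",
         call. = FALSE)
  }
  xd <- x[ok]
  depths <- sub$depth_um[ok]
  imax <- which.max(xd)
  max_value <- xd[imax]
  half <- max_value / 2
  depth_hm <- NA_real_
  if (imax < length(xd)) {
    for (i in imax:(length(xd) - 1L)) {
      if (xd[i] >= half && xd[i + 1L] < half) {
        frac <- (xd[i] - half) / (xd[i] - xd[i + 1L])
        depth_hm <- depths[i] + frac * (depths[i + 1L] - depths[i]) -
          start_plane * spacing
        break
      }
    }
  }
  meta_col <- function(col) {
    if (col %in% names(profile)) profile[[col]][1] else NA_character_
  }
  out <- tibble::tibble(
    metric = metric,
    start_plane = as.integer(start_plane),
    max_value = max_value,
    half_max_depth_um = depth_hm,
    condition_id = meta_col("condition_id"),
    replicate_id = meta_col("replicate_id"),
    fluorophore = meta_col("fluorophore")
  )
  class(out) <- c("half_max_result", class(out))
  out
}

#' Bind per-sample profiles into one long table
#'
#' @param profiles A list of [plane_metrics()] results (or a single one).
#' @return A long tibble; per-sample metadata columns are preserved.
#' @export
bind_profiles <- function(profiles) {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  spacings <- unique(vapply(profiles, profile_spacing, numeric(1)))
  out <- dplyr::bind_rows(lapply(profiles, function(p) {
    class(p) <- setdiff(class(p), "depth_profile")
    p
  }))
  if (length(spacings) == 1) attr(out, "plane_spacing_um") <- spacings
  out
}

#' Normalized staining-quality score across conditions
#'
#' Within each fluorophore group, every per-plane value is divided by the
#' single global maximum over all planes of all profiles in that group. The
#' resulting scores lie in \[0, 1\], attain 1 somewhere in each group, and
#' are invariant to any common positive rescaling of the raw intensities —
#' which is what makes heatmaps comparable across protocols imaged with the
#' same settings.
#'
#' @param profiles A list of [plane_metrics()] results, or the long tibble
#'   from [bind_profiles()].
#' @param metric Column to normalize (`"fraction"`, `"signal"` or `"snr"`).
#' @param group_by Grouping column (default `"fluorophore"`).
#' @return A `normalized_score` tibble: grouping column, `condition_id`,
#'   `replicate_id`, `plane`, `depth_um`, `score`, `reference_max`.
#' @export
normalize_across_conditions <- function(profiles,
                                        metric = c("fraction", "signal", "snr"),
                                        group_by = "fluorophore") {
  metric <- match.arg(metric)
  long <- if (is.data.frame(profiles)) profiles else bind_profiles(profiles)
  if (!nrow(long)) stop("no profiles supplied", call. = FALSE)
  if (!group_by %in% names(long)) {
    stop("grouping column `", group_by, "` not found", call. = FALSE)
  }
  out <- long |>
    dplyr::group_by(.data[[group_by]]) |>
    dplyr::group_modify(function(df, key) {
      vals <- df[[metric]]
      ref <- suppressWarnings(max(vals, na.rm = TRUE))
      if (!is.finite(ref) || ref <= 0) {
        warning("group `", key[[1]], "` has no positive ", metric,
                " values; scores set to 0", call. = FALSE)
        score <- rep(0, nrow(df))
        ref <- 0
      } else {
        score <- vals / ref
      }
      tibble::tibble(
        condition_id = df$condition_id,
        replicate_id = df$replicate_id,
        plane = df$plane,
        depth_um = df$depth_um,
        score = score,
        reference_max = ref
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("normalized_score", class(out))
  out
}

#' Choose the figure of merit for a profile
#'
#' For antigens with a roughly constant distribution over depth (e.g.
#' neuronal nuclei in cortex), the segmented area per plane is a valid figure
#' of merit. For non-constant distributions, the area-normalized mean
#' staining intensity per plane is used instead, so sparse-but-bright planes
#' are not penalized. Pure function: the input profile is not modified.
#'
#' @param profile A [plane_metrics()] result.
#' @param distribution `"constant"` or `"nonconstant"`.
#' @return A tibble `plane`, `depth_um`, `value` with attribute `label`
#'   (`"area_fraction"` or `"mean_intensity"`).
#' @export
figure_of_merit <- function(profile, distribution = c("constant", "nonconstant")) {
  distribution <- match.arg(distribution)
  col <- if (distribution == "constant") "fraction" else "signal"
  out <- tibble::tibble(
    plane = profile$plane,
    depth_um = profile$depth_um,
    value = profile[[col]]
  )
  attr(out, "label") <- if (distribution == "constant") "area_fraction" else "mean_intensity"
  out
}
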