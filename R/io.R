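#' Read an image stack from a multipage TIFF
#'
#' Pages are taken as ascending z. Plane spacing is not stored in the TIFF;
#' it comes from the manifest (or this argument).
#'
#' @param path Single-channel multipage TIFF.
#' @param plane_spacing_um Plane spacing, µm.
#' @param pixel_size_um In-plane pixel size, µm.
#' @param condition_id,replicate_id,channel_label,blind_code Sample metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, plane_spacing_um = 1, pixel_size_um = plane_spacing_um,
                       condition_id = NA_character_, replicate_id = NA_character_,
                       channel_label = NA_character_, blind_code = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("TIFF has zero pages: ", path, call. = FALSE)
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop("multi-channel TIFF not supported: ", path,
         " (each page must be a single-channel matrix)", call. = FALSE)
  }
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  image_stack(arr, plane_spacing_um = plane_spacing_um,
              pixel_size_um = pixel_size_um, condition_id = condition_id,
              replicate_id = replicate_id, channel_label = channel_label,
              blind_code = blind_code)
}

#' Write an image stack as multipage TIFF
#'
#' Intensities are stored as 32-bit float, one page per z-plane. The TIFF
#' float path carries values in \[0, 1\] (single precision), which is what
#' normalized and rendered stacks contain; out-of-range stacks are refused
#' with advice to normalize first.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (min(v) < 0 || max(v) > 1) {
    stop("stack intensities outside [0, 1]; run normalize_stack() before writing",
         call. = FALSE)
  }
  planes <- lapply(seq_len(dim(v)[3]), function(z) v[, , z])
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "LZW")
  invisible(path)
}

#' Write a segmentation mask as multipage TIFF
#'
#' Stored 8-bit binary (0/1 after scaling); round-trips exactly through
#' [import_mask()].
#'
#' @param mask A [segmentation_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  v <- mask$voxels
  planes <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] * 1)
  tiff::writeTIFF(planes, path, bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}

manifest_known_keys <- list(
  top = c("settings", "samples", "simulate"),
  settings = c("seed", "threshold_method", "threshold_value", "metric",
               "radius_px", "onset_frac", "smooth_window", "variant",
               "low_pct", "high_pct"),
  sample = c("file", "condition", "replicate", "fluorophore",
             "plane_spacing_um", "pixel_size_um", "baseline", "mask")
)

manifest_defaults <- list(
  seed = 1L, threshold_method = "fixed", threshold_value = 0.2,
  metric = "signal", radius_px = NULL, onset_frac = 0.1, smooth_window = 3L,
  variant = "student", low_pct = 0.1, high_pct = 99.9
)

#' Load and validate an experiment manifest
#'
#' The manifest is a YAML file describing an analysis run: a `settings` block
#' (seed, threshold method, metric, …), a `samples` list mapping files to
#' condition / replicate / fluorophore / plane spacing / baseline flag and an
#' optional mask path — or, alternatively, a `simulate` block describing
#' synthetic conditions to generate. Exactly one condition per fluorophore
#' group must be flagged baseline; file paths must be unique; plane spacings
#' positive. Unknown keys warn rather than fail. All defaults that were
#' filled in are recorded for the run log.
#'
#' @param path Path to the YAML manifest.
#' @return A `manifest` object: list with `settings`, `samples` (tibble; may
#'   be empty when simulating), `simulate` (list or NULL), and
#'   `defaults_applied` (character).
#' @export
load_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), manifest_known_keys$top)
  if (length(unknown)) {
    warning("unknown manifest keys ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  settings <- raw$settings %||% list()
  unknown_s <- setdiff(names(settings), manifest_known_keys$settings)
  if (length(unknown_s)) {
    warning("unknown settings keys ignored: ", paste(unknown_s, collapse = ", "),
            call. = FALSE)
  }
  defaults_applied <- character()
  for (key in names(manifest_defaults)) {
    if (is.null(settings[[key]])) {
      settings[[key]] <- manifest_defaults[[key]]
      if (!is.null(manifest_defaults[[key]])) {
        defaults_applied <- c(defaults_applied,
                              sprintf("settings.%s = %s", key,
                                      format(manifest_defaults[[key]])))
      }
    }
  }
  samples <- NULL
  if (!is.null(raw$samples)) {
    samples <- purrr::map_dfr(seq_along(raw$samples), function(i) {
      s <- raw$samples[[i]]
      unknown_k <- setdiff(names(s), manifest_known_keys$sample)
      if (length(unknown_k)) {
        warning("sample ", i, ": unknown keys ignored: ",
                paste(unknown_k, collapse = ", "), call. = FALSE)
      }
      for (req in c("file", "condition")) {
        if (is.null(s[[req]])) {
          stop("sample ", i, ": missing required key `", req, "`", call. = FALSE)
        }
      }
      tibble::tibble(
        file = s$file,
        condition_id = as.character(s$condition),
        replicate_id = as.character(s$replicate %||% paste0("r", i)),
        fluorophore = as.character(s$fluorophore %||% "FL1"),
        plane_spacing_um = as.numeric(s$plane_spacing_um %||% 1),
        pixel_size_um = as.numeric(s$pixel_size_um %||% s$plane_spacing_um %||% 1),
        baseline = isTRUE(s$baseline),
        mask = as.character(s$mask %||% NA_character_)
      )
    })
    if (anyDuplicated(samples$file)) {
      stop("duplicate sample file paths: ",
           paste(unique(samples$file[duplicated(samples$file)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(samples$plane_spacing_um <= 0)) {
      bad <- samples$file[samples$plane_spacing_um <= 0]
      stop("non-positive plane spacing for: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    n_base <- tapply(samples$baseline, samples$fluorophore,
                     function(b) length(unique(samples$condition_id[b])))
    bad <- names(n_base)[n_base != 1L]
    if (length(bad)) {
      stop("each fluorophore group needs exactly one baseline condition; violated for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(settings = settings, samples = samples,
                 simulate = raw$simulate, defaults_applied = defaults_applied,
                 dir = dirname(normalizePath(path))),
            class = "manifest")
}

simulate_from_manifest <- function(manifest, out_dir, seed) {
  sim <- manifest$simulate
  if (is.null(sim) || is.null(sim$conditions)) {
    stop("manifest has no `simulate.conditions` block", call. = FALSE)
  }
  conditions <- purrr::map_dfr(sim$conditions, function(co) {
    tibble::tibble(
      condition_id = as.character(co$id),
      d_half_um = as.numeric(co$d_half_um %||% 150),
      kind = as.character(co$kind %||% "sigmoid"),
      front_width_um = as.numeric(co$front_width_um %||% 15),
      fluorophore = as.character(co$fluorophore %||% "FL1"),
      baseline = isTRUE(co$baseline)
    )
  })
  scene_args <- sim$scene %||% list()
  if (!is.null(scene_args$shape)) scene_args$shape <- unlist(scene_args$shape)
  if (is.null(scene_args$seed)) scene_args$seed <- seed
  sp <- do.call(scene_params, scene_args)
  np <- do.call(noise_params, sim$noise %||% list())
  set <- generate_condition_set(
    conditions, n_replicates = as.integer(sim$n_replicates %||% 3L),
    scene = sp, noise = np, seed = seed
  )
  stack_dir <- file.path(out_dir, "stacks")
  dir.create(stack_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(set))
  for (i in seq_len(nrow(set))) {
    fn <- sprintf("%s_%s.tif", set$condition_id[i], set$replicate_id[i])
    write_stack(set$stack[[i]], file.path(stack_dir, fn))
    files[i] <- file.path("stacks", fn)
  }
  tibble::tibble(
    file = files,
    condition_id = set$condition_id,
    replicate_id = set$replicate_id,
    fluorophore = set$fluorophore,
    plane_spacing_um = vapply(set$stack, function(s) s$plane_spacing_um, numeric(1)),
    pixel_size_um = vapply(set$stack, function(s) s$pixel_size_um, numeric(1)),
    baseline = set$baseline,
    mask = NA_character_,
    stack = set$stack
  )
}

#' Run the full analysis pipeline
#'
#' For every sample in the manifest: segment (or import the provided mask),
#' compute per-plane metrics, detect the start plane, measure the half-max
#' depth; then normalize scores within each fluorophore group, export heatmap
#' matrices, and compare every condition against the baseline. All outputs
#' are CSV files under `out_dir` plus a structured run log recording the
#' seed, package version, and every default applied. A failing sample is
#' logged and reported without aborting the others.
#'
#' @param manifest A [load_manifest()] result, or a path to a manifest file.
#' @param out_dir Output directory (created if needed).
#' @param simulate If `TRUE`, generate the stacks described in the manifest's
#'   `simulate` block first (written under `out_dir/stacks`).
#' @param seed Overrides the manifest seed when non-NULL.
#' @return Invisibly, a `pipeline_result`: list with `halfmax` (per-replicate
#'   tibble), `summary` ([compare_conditions()] output), `scores`, `failed`
#'   (character vector of failed sample files).
#' @export
run_pipeline <- function(manifest, out_dir, simulate = FALSE, seed = NULL) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  stopifnot(inherits(manifest, "manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- manifest$settings
  seed <- seed %||% st$seed
  log_lines <- c(
    paste0("clearquant version: ", as.character(utils::packageVersion("clearquant"))),
    paste0("seed: ", seed),
    paste0("defaults applied: ",
           if (length(manifest$defaults_applied)) {
             paste(manifest$defaults_applied, collapse = "; ")
           } else "none")
  )
  if (simulate) {
    samples <- simulate_from_manifest(manifest, out_dir, seed)
    log_lines <- c(log_lines,
                   sprintf("simulated %d stacks under stacks/", nrow(samples)))
  } else {
    samples <- manifest$samples
    if (is.null(samples) || !nrow(samples)) {
      stop("manifest lists no samples (use simulate = TRUE for synthetic runs)",
           call. = FALSE)
    }
    samples$stack <- vector("list", nrow(samples))
  }
  profile_dir <- file.path(out_dir, "profiles")
  dir.create(profile_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- list()
  halfmax <- list()
  failed <- character()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    res <- tryCatch({
      resolve <- function(p) {
        if (file.exists(p) || is.null(manifest$dir)) p else file.path(manifest$dir, p)
      }
      stack <- if (!is.null(samples$stack[[i]])) {
        samples$stack[[i]]
      } else {
        read_stack(resolve(s$file),
                   plane_spacing_um = s$plane_spacing_um,
                   pixel_size_um = s$pixel_size_um,
                   condition_id = s$condition_id, replicate_id = s$replicate_id,
                   channel_label = s$fluorophore)
      }
      stack$condition_id <- s$condition_id
      stack$replicate_id <- s$replicate_id
      stack$channel_label <- s$fluorophore
      mask <- if (!is.na(s$mask)) {
        import_mask(resolve(s$mask))
      } else {
        segment_stack(stack, radius_px = st$radius_px,
                      method = st$threshold_method, value = st$threshold_value,
                      low_pct = st$low_pct, high_pct = st$high_pct)
      }
      prof <- plane_metrics(stack, mask)
      hm <- half_max_depth(prof, metric = st$metric,
                           onset_frac = st$onset_frac,
                           smooth_window = st$smooth_window)
      fn <- sprintf("%s_%s_profile.csv", s$condition_id, s$replicate_id)
      readr::write_csv(prof, file.path(profile_dir, fn), na = "")
      list(profile = prof, halfmax = dplyr::mutate(hm, baseline = s$baseline),
           threshold_used = mask$threshold_used, radius_px = mask$radius_px)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, s$file)
      log_lines <- c(log_lines,
                     sprintf("FAILED %s: %s", s$file, conditionMessage(res)))
    } else {
      profiles[[length(profiles) + 1L]] <- res$profile
      halfmax[[length(halfmax) + 1L]] <- res$halfmax
      log_lines <- c(log_lines,
                     sprintf("ok %s (threshold=%s%s)", s$file,
                             format(res$threshold_used),
                             if (is.null(res$radius_px)) "" else
                               sprintf(", rolling-ball radius_px=%g", res$radius_px)))
    }
  }
  if (!length(profiles)) {
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    stop("all samples failed; see run_log.txt", call. = FALSE)
  }
  halfmax <- dplyr::bind_rows(halfmax)
  readr::write_csv(halfmax, file.path(out_dir, "halfmax.csv"), na = "")
  scores <- normalize_across_conditions(
    profiles,
    metric = if (st$metric == "signal") "signal" else "fraction"
  )
  for (grp in unique(scores$fluorophore)) {
    export_heatmap_matrix(scores[scores$fluorophore == grp, ],
                          file.path(out_dir, sprintf("heatmap_%s.csv", grp)))
  }
  summary_tbl <- compare_conditions(halfmax, variant = st$variant)
  readr::write_csv(tidy(summary_tbl), file.path(out_dir, "summary.csv"), na = "")
  log_lines <- c(log_lines,
                 sprintf("completed %d/%d samples", length(profiles), nrow(samples)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  out <- structure(
    list(halfmax = halfmax, summary = summary_tbl, scores = scores,
         failed = failed),
    class = "pipeline_result"
  )
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d samples quantified, %d failed\n",
              nrow(x$halfmax), length(x$failed)))
  if (length(x$failed)) cat("  failed:", paste(x$failed, collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}
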