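#' Create an image stack
#'
#' The unit of analysis: a 3D grid of fluorescence intensities (x, y, z) with
#' physical plane spacing and sample metadata. Planes are indexed 0-based along
#' z (matching multipage-TIFF page order), so plane `k` sits at depth
#' `k * plane_spacing_um` below the imaged surface.
#'
#' @param voxels Numeric 3D array of intensities, dimensions (nx, ny, nz).
#'   All values must be finite.
#' @param plane_spacing_um Physical distance between consecutive z-planes, µm.
#' @param pixel_size_um In-plane pixel size, µm. Defaults to the plane spacing
#'   (isotropic voxels).
#' @param channel_label,condition_id,replicate_id Optional sample metadata
#'   carried through the pipeline into profile tables.
#' @param blind_code Optional blinded identifier (see [blind_assign()]).
#' @param meta Free-form list of extra metadata (the synthetic renderer records
#'   its ground truth here).
#' @return An object of class `image_stack`.
#' @seealso [read_stack()], [write_stack()], [render_stack()]
#' @export
image_stack <- function(voxels, plane_spacing_um, pixel_size_um = plane_spacing_um,
                        channel_label = NA_character_, condition_id = NA_character_,
                        replicate_id = NA_character_, blind_code = NA_character_,
                        meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array (nx, ny, nz); got dimensions [",
         paste(dim(voxels), collapse = ", "), "]", call. = FALSE)
  }
  if (!all(is.finite(voxels))) {
    stop("stack intensities must all be finite", call. = FALSE)
  }
  if (!is.numeric(plane_spacing_um) || length(plane_spacing_um) != 1L ||
      plane_spacing_um <= 0) {
    stop("`plane_spacing_um` must be a single positive number", call. = FALSE)
  }
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive", call. = FALSE)
  structure(
    list(
      voxels = voxels,
      plane_spacing_um = plane_spacing_um,
      pixel_size_um = pixel_size_um,
      channel_label = channel_label,
      condition_id = condition_id,
      replicate_id = replicate_id,
      blind_code = blind_code,
      meta = meta
    ),
    class = "image_stack"
  )
}

#' Number of z-planes in a stack or mask
#' @param x An `image_stack` or `segmentation_mask`.
#' @return Integer plane count.
#' @export
n_planes <- function(x) {
  dim(x$voxels)[3L]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d x %d planes, %.3g um/plane, %.3g um/px\n",
    d[1], d[2], d[3], x$plane_spacing_um, x$pixel_size_um
  ))
  if (!is.na(x$condition_id)) {
    cat("  condition:", x$condition_id,
        if (!is.na(x$replicate_id)) paste0("replicate: ", x$replicate_id) else "",
        "\n")
  }
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Create a segmentation mask
#'
#' A binary grid congruent with an [image_stack()]; voxels inside the mask are
#' the "indexed", stained voxels counted by [plane_metrics()].
#'
#' @param voxels Logical (or 0/1 numeric) 3D array.
#' @param source `"internal"` for masks produced by [threshold_mask()],
#'   `"imported"` for externally generated masks (e.g. a pixel-classifier
#'   export read with [import_mask()]).
#' @param threshold_used The threshold that produced the mask, or the string
#'   `"external"` when unknown.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(voxels, source = c("internal", "imported"),
                              threshold_used = "external") {
  source <- match.arg(source)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("mask `voxels` must be a 3D array", call. = FALSE)
  }
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1))) {
      stop("numeric mask voxels must be strictly 0/1", call. = FALSE)
    }
    voxels <- array(voxels > 0.5, dim(voxels))
  }
  if (!is.logical(voxels)) {
    stop("mask voxels must be logical or 0/1 numeric", call. = FALSE)
  }
  structure(
    list(voxels = voxels, source = source, threshold_used = threshold_used),
    class = "segmentation_mask"
  )
}

#' @export
print.segmentation_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<segmentation_mask> %d x %d x %d, source=%s, %.3g%% voxels in mask\n",
    d[1], d[2], d[3], x$source, 100 * mean(x$voxels)
  ))
  invisible(x)
}

check_congruent <- function(stack, mask) {
  ds <- dim(stack$voxels)
  dm <- dim(mask$voxels)
  if (!identical(ds, dm)) {
    stop("stack and mask shapes differ: stack [",
         paste(ds, collapse = ", "), "] vs mask [",
         paste(dm, collapse = ", "), "]", call. = FALSE)
  }
  invisible(TRUE)
}
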