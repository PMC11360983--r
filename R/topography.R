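#' Per-voxel topographic index of a clone inside a neuropil
#'
#' For every clone voxel that lies inside the neuropil reference mask, the
#' topographic index of voxel i is
#' \deqn{TI_i = d_i / (d_i + v_i)}
#' where \eqn{d_i} is the distance (um, along the designated dorsal-ventral
#' axis) from the dorsal neuropil boundary to the voxel and \eqn{v_i} the
#' distance from the voxel to the ventral boundary. Both distances are
#' clipped at zero, so clone voxels beyond a boundary (possible with
#' per-column boundaries or independent channel thresholds) score 0 or 1
#' instead of being dropped. The clone-level TI is the unweighted arithmetic
#' mean of the per-voxel values: 0 means dorsal extreme, 1 ventral extreme.
#'
#' @param clone_mask [label_mask()] of the clone (single labelled neuron)
#'   channel.
#' @param neuropil_mask [label_mask()] of the reference neuropil channel, on
#'   the same grid.
#' @param boundaries A `boundary_profile` from [extract_boundaries()]
#'   computed on `neuropil_mask`.
#' @param clone_id Optional label carried into the result.
#' @return An object of class `ti_result`: `clone_id`, `ti_mean`,
#'   `ti_per_voxel`, `di`, `vi` (um), `n_voxels_inside`,
#'   `n_voxels_excluded` (clone voxels outside the neuropil, ignored), and
#'   `mode` (boundary mode used). Clone voxels inside the neuropil but in a
#'   degenerate (single-voxel-thick) per-column boundary are counted as
#'   excluded.
#' @export
voxel_ti <- function(clone_mask, neuropil_mask, boundaries, clone_id = NA_character_) {
  cm <- as_mask_array(clone_mask)
  nm <- as_mask_array(neuropil_mask)
  if (!identical(dim(cm), dim(nm))) {
    stop("clone and neuropil masks are on different grids", call. = FALSE)
  }
  stopifnot(inherits(boundaries, "boundary_profile"))
  dv_axis <- if (inherits(neuropil_mask, "label_mask")) neuropil_mask$dv_axis else boundaries$dv_axis
  if (!identical(dv_axis, boundaries$dv_axis)) {
    stop("boundary profile D-V axis does not match the masks", call. = FALSE)
  }
  ax <- spatial_axis_index(boundaries$dv_axis)
  sp <- boundaries$dv_spacing

  inside <- cm & nm
  n_inside <- sum(inside)
  n_excluded <- sum(cm) - n_inside
  if (n_inside == 0L) {
    stop("no clone voxels inside the neuropil mask (clone/neuropil intersection empty)",
         call. = FALSE)
  }
  w <- which(inside, arr.ind = TRUE, useNames = FALSE)
  coord <- unname((w[, ax] - 1) * sp)

  if (boundaries$mode == "global") {
    d_ext <- rep(boundaries$dorsal_extent, nrow(w))
    v_ext <- rep(boundaries$ventral_extent, nrow(w))
  } else {
    other <- boundaries$other_axes
    ij <- cbind(w[, other[1]], w[, other[2]])
    d_ext <- boundaries$dorsal_extent[ij]
    v_ext <- boundaries$ventral_extent[ij]
    drop_degenerate <- is.na(d_ext) | is.na(v_ext)
    if (any(drop_degenerate)) {
      n_excluded <- n_excluded + sum(drop_degenerate)
      n_inside <- n_inside - sum(drop_degenerate)
      if (n_inside == 0L) {
        stop("all clone voxels fall in degenerate single-voxel columns", call. = FALSE)
      }
      coord <- coord[!drop_degenerate]
      d_ext <- d_ext[!drop_degenerate]
      v_ext <- v_ext[!drop_degenerate]
    }
  }

  di <- pmax(coord - d_ext, 0)
  vi <- pmax(v_ext - coord, 0)
  ti <- di / (di + vi)
  structure(
    list(clone_id = clone_id, ti_mean = mean(ti), ti_per_voxel = ti,
         di = di, vi = vi, n_voxels_inside = n_inside,
         n_voxels_excluded = n_excluded, mode = boundaries$mode),
    class = "ti_result"
  )
}

#' @export
print.ti_result <- function(x, ...) {
  cat("<ti_result> ", if (!is.na(x$clone_id)) paste0(x$clone_id, ": ") else "",
      "TI = ", sprintf("%.4f", x$ti_mean), " over ", x$n_voxels_inside,
      " voxels (", x$n_voxels_excluded, " excluded; ", x$mode, " boundaries)\n",
      sep = "")
  invisible(x)
}

#' Default analysis configuration for TI computation
#'
#' @param clone_channel,reference_channel Channel names in the stack.
#' @param threshold_method Thresholding for both channels
#'   (see [segment_channel()]).
#' @param threshold_value,threshold_fraction Parameters for the fixed /
#'   fraction-of-max methods.
#' @param boundary_mode `"global"` (default) or `"per_column"`.
#' @param background Optional constant background to subtract first.
#' @param crop Logical; crop to the reference mask bounding box (with
#'   `crop_margin` voxels) before analysis. TI is invariant to this; it only
#'   bounds memory/time.
#' @param crop_margin Margin voxels for cropping.
#' @return A named list of settings understood by [clone_ti_from_stack()].
#' @export
ti_config <- function(clone_channel = "clone", reference_channel = "reference",
                      threshold_method = "otsu", threshold_value = NULL,
                      threshold_fraction = 0.5, boundary_mode = "global",
                      background = 0, crop = FALSE, crop_margin = 2L) {
  list(clone_channel = clone_channel, reference_channel = reference_channel,
       threshold_method = threshold_method, threshold_value = threshold_value,
       threshold_fraction = threshold_fraction, boundary_mode = boundary_mode,
       background = background, crop = crop, crop_margin = crop_margin)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Full single-stack TI pipeline: segment, extract boundaries, score
#'
#' Composes [segment_channel()] on the clone and reference channels,
#' [extract_boundaries()] on the reference mask, and [voxel_ti()], with the
#' thresholds and boundary mode recorded in the result's provenance. Errors
#' from any stage are rethrown with the stage name attached.
#'
#' @param stack An [image_stack()] with clone and reference channels.
#' @param config Settings from [ti_config()].
#' @param clone_id Optional label carried into the result.
#' @return A `ti_result` with an added `provenance` list (thresholds,
#'   methods, boundary mode).
#' @export
clone_ti_from_stack <- function(stack, config = ti_config(), clone_id = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  if (config$background > 0) {
    stack <- with_stage("background", subtract_background(stack, "constant",
                                                          value = config$background))
  }
  ref_mask <- with_stage("segment-reference",
    segment_channel(stack, config$reference_channel, method = config$threshold_method,
                    value = config$threshold_value, fraction = config$threshold_fraction))
  if (isTRUE(config$crop)) {
    stack <- with_stage("crop", crop_to_mask(stack, ref_mask, config$crop_margin))
    ref_mask <- with_stage("segment-reference",
      segment_channel(stack, config$reference_channel, method = config$threshold_method,
                      value = config$threshold_value, fraction = config$threshold_fraction))
  }
  clone_mask <- with_stage("segment-clone",
    segment_channel(stack, config$clone_channel, method = config$threshold_method,
                    value = config$threshold_value, fraction = config$threshold_fraction))
  bounds <- with_stage("boundaries", extract_boundaries(ref_mask, config$boundary_mode))
  res <- with_stage("topographic-index", voxel_ti(clone_mask, ref_mask, bounds, clone_id))
  res$provenance <- list(
    threshold_method = config$threshold_method,
    clone_threshold = clone_mask$threshold_value,
    reference_threshold = ref_mask$threshold_value,
    boundary_mode = config$boundary_mode
  )
  res
}

#' Batch TI over a manifest of stacks
#'
#' Processes every row of a manifest (columns `path`, `clone_id`, `group`),
#' computing the clone TI for each stack. Per-file failures do not abort the
#' run: they are collected, reported as a warning, and attached to the
#' result.
#'
#' @param manifest Data frame (or path to a CSV) with columns `path`,
#'   `clone_id`, `group`.
#' @param config Settings from [ti_config()].
#' @return A tidy data frame with one row per successfully processed stack:
#'   `clone_id`, `group`, `ti_mean`, `n_voxels_inside`, `n_voxels_excluded`,
#'   `mode`, `clone_threshold`, `reference_threshold`, `path`. Failures (if
#'   any) are in `attr(result, "failures")` as a data frame of `path` and
#'   `error`.
#' @export
batch_ti <- function(manifest, config = ti_config()) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("path", "clone_id", "group")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    res <- tryCatch({
      stk <- read_stack(r$path)
      clone_ti_from_stack(stk, config, clone_id = as.character(r$clone_id))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        path = r$path, error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = as.character(r$clone_id), group = as.character(r$group),
        ti_mean = res$ti_mean, n_voxels_inside = res$n_voxels_inside,
        n_voxels_excluded = res$n_voxels_excluded, mode = res$mode,
        clone_threshold = res$provenance$clone_threshold,
        reference_threshold = res$provenance$reference_threshold,
        path = r$path, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clone_id = character(), group = character(), ti_mean = numeric(),
               n_voxels_inside = integer(), n_voxels_excluded = integer(),
               mode = character(), clone_threshold = numeric(),
               reference_threshold = numeric(), path = character(),
               stringsAsFactors = FALSE)
  if (length(fails)) {
    fdf <- do.call(rbind, fails)
    warning(nrow(fdf), " of ", nrow(manifest), " stacks failed; see attr(result, 'failures')",
            call. = FALSE)
    attr(out, "failures") <- fdf
  }
  out
}
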