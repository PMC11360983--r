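#' Multi-channel 3D image stack
#'
#' Container for voxel intensities from a multi-channel 3D fluorescence
#' stack, together with the physical voxel spacing and the anatomical role
#' of the array axes. The array layout is fixed to `(channel, z, y, x)`;
#' anatomy is attached by declaring which of the three spatial axes is the
#' dorsal-ventral (D-V) axis and in which direction dorsal lies.
#'
#' @param voxels Numeric array of non-negative intensities with dimensions
#'   `(channel, z, y, x)`. A 3D array is accepted and treated as a single
#'   channel.
#' @param spacing_um Named numeric vector `c(z=, y=, x=)` of physical voxel
#'   spacing in micrometers; all entries must be positive. The default z
#'   step of 0.3 um matches typical confocal acquisition for this assay.
#' @param dv_axis Which spatial axis (`"z"`, `"y"` or `"x"`) is the
#'   dorsal-ventral axis.
#' @param dorsal_low Logical; `TRUE` means dorsal is at low index along
#'   `dv_axis` (the canonical orientation used by all downstream analysis).
#' @param channel_names Character vector of channel labels, e.g.
#'   `c("clone", "reference")`. Defaults to `channel_1`, `channel_2`, ...
#'
#' @return An object of class `image_stack`: a list with elements `voxels`,
#'   `spacing_um`, `dv_axis`, `dorsal_low`, `channel_names`.
#' @examples
#' vox <- array(runif(2 * 4 * 8 * 6), dim = c(2, 4, 8, 6))
#' stk <- image_stack(vox, channel_names = c("clone", "reference"))
#' dim(stk$voxels)
#' @export
image_stack <- function(voxels,
                        spacing_um = c(z = 0.3, y = 0.15, x = 0.15),
                        dv_axis = "y",
                        dorsal_low = TRUE,
                        channel_names = NULL) {
  if (length(dim(voxels)) == 3L) {
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  }
  if (length(dim(voxels)) != 4L) {
    stop("`voxels` must be a 4D array (channel, z, y, x) or a 3D array", call. = FALSE)
  }
  if (any(voxels < 0)) stop("intensities must be >= 0", call. = FALSE)
  spacing_um <- spacing_um[c("z", "y", "x")]
  if (anyNA(spacing_um) || any(spacing_um <= 0)) {
    stop("`spacing_um` must be a named vector c(z=, y=, x=) with positive entries", call. = FALSE)
  }
  dv_axis <- match.arg(dv_axis, c("z", "y", "x"))
  nc <- dim(voxels)[1]
  if (is.null(channel_names)) channel_names <- paste0("channel_", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("`channel_names` length (", length(channel_names),
         ") does not match channel count (", nc, ")", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing_um = spacing_um, dv_axis = dv_axis,
         dorsal_low = isTRUE(dorsal_low), channel_names = channel_names),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<image_stack> ", d[1], " channel(s) [", paste(x$channel_names, collapse = ", "),
      "], z*y*x = ", d[2], "*", d[3], "*", d[4], "\n", sep = "")
  cat("  spacing (um): z=", x$spacing_um["z"], " y=", x$spacing_um["y"],
      " x=", x$spacing_um["x"], "; D-V axis: ", x$dv_axis,
      if (x$dorsal_low) " (dorsal at low index)" else " (dorsal at HIGH index)",
      "\n", sep = "")
  invisible(x)
}

# spatial axis name -> index into the (z, y, x) spatial dims (1..3)
spatial_axis_index <- function(axis) match(axis, c("z", "y", "x"))

# index of a channel by name, with a clear diagnostic
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(stack$channel_names)) {
      stop("channel index ", ch, " out of range 1..", length(stack$channel_names), call. = FALSE)
    }
    return(ch)
  }
  ch <- match(channel, stack$channel_names)
  if (is.na(ch)) {
    stop("channel '", channel, "' not found; available: ",
         paste(stack$channel_names, collapse = ", "), call. = FALSE)
  }
  ch
}

# extract one channel as a 3D (z, y, x) array
channel_array <- function(stack, channel) {
  ch <- channel_index(stack, channel)
  arr <- stack$voxels[ch, , , , drop = FALSE]
  dim(arr) <- dim(stack$voxels)[-1]
  arr
}

# physical coordinate (um) of voxel centers along the D-V axis
dv_coordinates <- function(stack) {
  ax <- spatial_axis_index(stack$dv_axis)
  n <- dim(stack$voxels)[1 + ax]
  (seq_len(n) - 1) * stack$spacing_um[[stack$dv_axis]]
}

flip_spatial_axis <- function(voxels, ax) {
  # ax in 1..3 over the spatial (z, y, x) dims of a (c, z, y, x) array
  idx <- rep(list(quote(expr = )), 4)
  n <- dim(voxels)[1 + ax]
  idx[[1 + ax]] <- rev(seq_len(n))
  do.call(`[`, c(list(voxels), idx, list(drop = FALSE)))
}

#' Orient a stack into the canonical dorsal-to-ventral convention
#'
#' Replaces the manual 3D reorientation step of the original workflow with a
#' declarative permutation/flip: after orientation the designated D-V axis
#' runs dorsal (low index) to ventral (high index).
#'
#' @param stack An [image_stack()].
#' @param flip_dv Logical; reverse the D-V axis (and toggle the recorded
#'   dorsal direction).
#' @param transpose Optional permutation of the spatial axes, given as a
#'   character vector naming the current axes in their new order, e.g.
#'   `c("z", "x", "y")` swaps y and x. Axis roles and spacing follow the
#'   axes they describe.
#' @return The reoriented `image_stack`. With `flip_dv = FALSE` and an
#'   identity (or `NULL`) permutation the input is returned unchanged.
#' @export
orient_stack <- function(stack, flip_dv = FALSE, transpose = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  out <- stack
  if (!is.null(transpose)) {
    perm <- spatial_axis_index(transpose)
    if (length(perm) != 3L || anyNA(perm) || anyDuplicated(perm)) {
      stop("`transpose` must be a permutation of c('z','y','x')", call. = FALSE)
    }
    out$voxels <- aperm(out$voxels, c(1L, 1L + perm))
    # axis labels are positional (z, y, x): spacing and the D-V role move
    # with the data, then get relabelled by new position
    moved_spacing <- out$spacing_um[perm]
    names(moved_spacing) <- c("z", "y", "x")
    out$spacing_um <- moved_spacing
    new_pos <- match(spatial_axis_index(out$dv_axis), perm)
    out$dv_axis <- c("z", "y", "x")[new_pos]
  }
  if (isTRUE(flip_dv)) {
    ax <- spatial_axis_index(out$dv_axis)
    out$voxels <- flip_spatial_axis(out$voxels, ax)
    out$dorsal_low <- !out$dorsal_low
  }
  out
}

#' Crop a stack to the bounding box of a mask
#'
#' Crops all channels to the minimal axis-aligned bounding box of the mask
#' voxels, expanded by `margin_vox` and clipped to the stack bounds. Axis
#' metadata (spacing, D-V designation) is preserved; the topographic index
#' is invariant under this operation because clone and reference are cropped
#' together.
#'
#' @param stack An [image_stack()].
#' @param mask A [label_mask()] (or plain logical 3D array) on the same
#'   spatial grid as `stack`.
#' @param margin_vox Non-negative integer margin, in voxels, added on every
#'   side of the bounding box.
#' @return The cropped `image_stack`.
#' @export
crop_to_mask <- function(stack, mask, margin_vox = 0L) {
  stopifnot(inherits(stack, "image_stack"))
  m <- as_mask_array(mask)
  sdim <- dim(stack$voxels)[-1]
  if (!identical(dim(m), sdim)) {
    stop("mask grid ", paste(dim(m), collapse = "x"),
         " does not match stack grid ", paste(sdim, collapse = "x"), call. = FALSE)
  }
  if (!any(m)) stop("cannot crop to an empty mask", call. = FALSE)
  if (margin_vox < 0) stop("`margin_vox` must be >= 0", call. = FALSE)
  w <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - margin_vox, 1L)
  hi <- pmin(apply(w, 2, max) + margin_vox, sdim)
  out <- stack
  out$voxels <- stack$voxels[, lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out
}

#' Subtract background from all channels
#'
#' Stands in for deconvolution as an optional preprocessing step. Either a
#' constant offset or a per-slice percentile (computed per channel and
#' z-slice, a simple rolling-background estimate) is subtracted; results are
#' clipped at zero.
#'
#' @param stack An [image_stack()].
#' @param method `"constant"` or `"rolling_percentile"`.
#' @param value Non-negative constant to subtract (method `"constant"`).
#' @param percentile Percentile in `[0, 1]` used as the per-slice background
#'   level (method `"rolling_percentile"`; default 0.05).
#' @return The background-subtracted `image_stack`.
#' @export
subtract_background <- function(stack, method = c("constant", "rolling_percentile"),
                                value = 0, percentile = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  out <- stack
  if (method == "constant") {
    if (value < 0) stop("background constant must be >= 0", call. = FALSE)
    out$voxels <- pmax(stack$voxels - value, 0)
  } else {
    if (percentile < 0 || percentile > 1) stop("`percentile` must be in [0, 1]", call. = FALSE)
    d <- dim(stack$voxels)
    v <- stack$voxels
    for (ch in seq_len(d[1])) {
      for (z in seq_len(d[2])) {
        slice <- v[ch, z, , ]
        bg <- stats::quantile(slice, percentile, names = FALSE)
        v[ch, z, , ] <- pmax(slice - bg, 0)
      }
    }
    out$voxels <- v
  }
  out
}

#' Maximum-intensity projection along the depth axis
#'
#' Collapses the z axis by per-pixel maximum, per channel, as used for
#' nuclear intensity quantification on projection images. The result is a
#' single-slice `image_stack` so ROI utilities apply unchanged.
#'
#' @param stack An [image_stack()].
#' @param axis Axis to project over (default `"z"`; must not be the D-V axis).
#' @return An `image_stack` whose projected axis has length 1.
#' @export
max_project <- function(stack, axis = "z") {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis, c("z", "y", "x"))
  if (identical(axis, stack$dv_axis)) {
    stop("refusing to project over the dorsal-ventral axis", call. = FALSE)
  }
  ax <- 1L + spatial_axis_index(axis)
  proj <- apply(stack$voxels, setdiff(1:4, ax), max)
  newdim <- dim(stack$voxels)
  newdim[ax] <- 1L
  out <- stack
  out$voxels <- array(proj, dim = newdim)
  out
}
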