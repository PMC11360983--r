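#' Region of interest on an image grid
#'
#' ROIs are inputs here (drawn on the channel named by
#' `definition_channel`, e.g. the pan-neuronal nuclear marker for nuclear
#' ROIs); no auto-detection is performed.
#'
#' @param mask Logical 2D matrix or 3D array marking the region.
#' @param id Label.
#' @param definition_channel Channel the ROI was drawn on.
#' @return An object of class `roi`.
#' @export
roi <- function(mask, id = "roi", definition_channel = NA_character_) {
  if (!(length(dim(mask)) %in% c(2L, 3L))) {
    stop("`mask` must be a 2D or 3D logical array", call. = FALSE)
  }
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  structure(list(mask = mask, id = id, definition_channel = definition_channel),
            class = "roi")
}

roi_mask <- function(r) if (inherits(r, "roi")) r$mask else r

extract_image <- function(img, channel = NULL) {
  # accept a bare numeric array/matrix or an image_stack + channel name
  if (inherits(img, "image_stack")) {
    if (is.null(channel)) stop("a channel must be named when passing an image_stack",
                               call. = FALSE)
    a <- channel_array(img, channel)
    if (dim(a)[1] == 1L) a <- array(a, dim = dim(a)[-1])  # single slice -> 2D
    a
  } else {
    img
  }
}

#' Ratio of a signal to a reference intensity over one ROI
#'
#' Computes the chosen statistic (mean by default) of the signal and
#' reference channels over the identical region and returns their ratio, as
#' used for nuclear pMad normalized to Elav or somatic ligand signal
#' normalized to a clone marker. Because both statistics are taken over the
#' same voxel set, the ratio is identical for `stat = "mean"` and
#' `stat = "sum"`; the choice is still recorded.
#'
#' @param signal,reference Numeric arrays on the same grid (2D projections
#'   or 3D volumes), or [image_stack()]s with `signal_channel` /
#'   `reference_channel` named via `...` helpers upstream.
#' @param roi An [roi()] (or logical array) within the image bounds.
#' @param stat `"mean"` or `"sum"`.
#' @return One-row data frame: `roi_id`, `signal_stat`, `reference_stat`,
#'   `ratio`, `stat`, `n_pixels`. A zero reference statistic is an error
#'   (the normalization is undefined).
#' @export
roi_ratio <- function(signal, reference, roi, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  sig <- extract_image(signal)
  ref <- extract_image(reference)
  m <- roi_mask(roi)
  if (!identical(dim(sig), dim(ref))) {
    stop("signal and reference images are on different grids", call. = FALSE)
  }
  if (!identical(dim(m), dim(sig))) {
    stop("ROI grid does not match the images", call. = FALSE)
  }
  f <- if (stat == "mean") mean else sum
  s_stat <- f(sig[m]); r_stat <- f(ref[m])
  if (r_stat <= 0) {
    stop("reference statistic is zero in ROI '",
         if (inherits(roi, "roi")) roi$id else "roi",
         "': normalization undefined", call. = FALSE)
  }
  data.frame(
    roi_id = if (inherits(roi, "roi")) roi$id else "roi",
    signal_stat = s_stat, reference_stat = r_stat, ratio = s_stat / r_stat,
    stat = stat, n_pixels = sum(m), stringsAsFactors = FALSE
  )
}

#' Synaptic-contact (GRASP) signal normalized to presynaptic marker level
#'
#' Ratio of reconstituted GFP signal to the expression level of the
#' presynaptic split-GFP fragment over the same region (the axon-terminal /
#' neuropil mask), so that differences in reporter expression do not
#' masquerade as differences in synaptic contact. Operates on 3D sums by
#' default.
#'
#' @param grasp_channel,syb_channel Numeric arrays (3D volumes or 2D
#'   projections) on the same grid.
#' @param region A [label_mask()], [roi()] or logical array: the region over
#'   which both channels are integrated.
#' @param stat `"sum"` (default) or `"mean"`.
#' @return One-row data frame as in [roi_ratio()].
#' @export
grasp_ratio <- function(grasp_channel, syb_channel, region, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  m <- if (inherits(region, "label_mask")) region$mask else roi_mask(region)
  r <- if (inherits(region, "roi")) region else roi(m, id = "grasp_region")
  roi_ratio(grasp_channel, syb_channel, r, stat = stat)
}

#' Quantify a set of ROIs on a two-channel image or stack
#'
#' Convenience wrapper: optionally max-projects the stack along z (the
#' workflow used for nuclear quantification), then applies [roi_ratio()] to
#' every ROI.
#'
#' @param stack An [image_stack()] with the named channels.
#' @param rois List of [roi()] objects (2D masks if projecting).
#' @param signal_channel,reference_channel Channel names.
#' @param stat `"mean"` or `"sum"`.
#' @param project Logical; max-project along z first (default `TRUE`).
#' @return Data frame with one row per ROI, plus a `projection` column.
#' @export
quantify_rois <- function(stack, rois, signal_channel = "signal",
                          reference_channel = "reference",
                          stat = "mean", project = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  if (project && dim(stack$voxels)[2] > 1L) stack <- max_project(stack, "z")
  sig <- extract_image(stack, signal_channel)
  ref <- extract_image(stack, reference_channel)
  out <- do.call(rbind, lapply(rois, function(r) roi_ratio(sig, ref, r, stat = stat)))
  out$projection <- if (project) "max_z" else "none"
  out
}
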