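#' Boolean voxel mask with thresholding provenance
#'
#' @param mask Logical 3D array on the stack's spatial grid `(z, y, x)`.
#' @param channel Name of the source channel.
#' @param threshold_method One of `"otsu"`, `"fixed"`, `"fraction_of_max"`.
#' @param threshold_value Intensity cut actually applied (voxels strictly
#'   above it are in the mask).
#' @param dv_axis,spacing_um,dorsal_low Axis metadata inherited from the
#'   source stack, so boundary extraction can work in physical units.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(mask, channel = NA_character_,
                       threshold_method = NA_character_,
                       threshold_value = NA_real_,
                       dv_axis = "y",
                       spacing_um = c(z = 0.3, y = 0.15, x = 0.15),
                       dorsal_low = TRUE) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D logical array", call. = FALSE)
  storage.mode(mask) <- "logical"
  structure(
    list(mask = mask, channel = channel, threshold_method = threshold_method,
         threshold_value = threshold_value, dv_axis = dv_axis,
         spacing_um = spacing_um[c("z", "y", "x")], dorsal_low = dorsal_low),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", sum(x$mask), "/", length(x$mask), " voxels (channel ",
      x$channel, ", ", x$threshold_method, " threshold ",
      signif(x$threshold_value, 5), ")\n", sep = "")
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "label_mask")) mask$mask else {
    stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
    m <- mask
    storage.mode(m) <- "logical"
    m
  }
}

#' Otsu's threshold for a vector of intensities
#'
#' Histogram-based maximization of the between-class variance over 256 bins
#' spanning the data range. Returns an intensity cut; values strictly above
#' the cut form the foreground class.
#'
#' @param x Numeric intensities (length >= 2, not all equal).
#' @param n_bins Number of histogram bins.
#' @return The threshold intensity (a bin edge).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot apply Otsu's method to a constant image", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)                 # class-0 probability up to each cut
  mu <- cumsum(p * mids)             # class-0 mean * omega
  mu_t <- mu[n_bins]
  # between-class variance at each candidate cut (after bin k)
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(sigma_b)
  edges[k + 1L]
}

#' Threshold one channel of a stack into a mask
#'
#' Voxels with intensity strictly above the threshold are foreground. The
#' method and the numeric threshold applied are recorded in the mask for
#' provenance.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param method `"otsu"` (default; data-driven two-class cut),
#'   `"fixed"` (use `value`), or `"fraction_of_max"` (cut at
#'   `fraction * max(intensity)`).
#' @param value Threshold intensity for `method = "fixed"`.
#' @param fraction Fraction of the channel maximum for
#'   `method = "fraction_of_max"` (default 0.5).
#' @return A [label_mask()]. An empty result (nothing above threshold) is an
#'   error, signalling failed staining or a bad threshold.
#' @export
segment_channel <- function(stack, channel,
                            method = c("otsu", "fixed", "fraction_of_max"),
                            value = NULL, fraction = 0.5) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  arr <- channel_array(stack, channel)
  thr <- switch(method,
    otsu = otsu_threshold(as.vector(arr)),
    fixed = {
      if (is.null(value)) stop("method 'fixed' requires `value`", call. = FALSE)
      value
    },
    fraction_of_max = {
      if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]", call. = FALSE)
      fraction * max(arr)
    }
  )
  m <- arr > thr
  if (!any(m)) {
    stop("empty mask: no voxels above threshold ", signif(thr, 6),
         " in channel '", channel, "'", call. = FALSE)
  }
  ch_name <- if (is.numeric(channel)) stack$channel_names[channel_index(stack, channel)] else channel
  label_mask(m, channel = ch_name, threshold_method = method, threshold_value = thr,
             dv_axis = stack$dv_axis, spacing_um = stack$spacing_um,
             dorsal_low = stack$dorsal_low)
}

#' Extract dorsal and ventral neuropil boundaries from a reference mask
#'
#' The dorsal extent is the D-V coordinate of the dorsal-most reference
#' voxel and the ventral extent that of the ventral-most one, either for the
#' whole volume (`mode = "global"`, the default) or independently per
#' (A-P, depth) column (`mode = "per_column"`). Coordinates are physical
#' (index times spacing), with dorsal at the smaller coordinate.
#'
#' @param reference_mask A nonempty [label_mask()] of the neuropil reference
#'   channel.
#' @param mode `"global"` or `"per_column"`.
#' @return An object of class `boundary_profile` with fields `mode`,
#'   `dorsal_extent`, `ventral_extent` (scalars, or matrices over the two
#'   non-D-V axes with `NA` for columns not crossing the mask),
#'   `dv_axis` and `dv_spacing`. A zero-thickness neuropil (dorsal extent
#'   equal to ventral extent globally) is an error: the topographic index is
#'   undefined there.
#' @export
extract_boundaries <- function(reference_mask, mode = c("global", "per_column")) {
  stopifnot(inherits(reference_mask, "label_mask"))
  mode <- match.arg(mode)
  m <- reference_mask$mask
  if (!any(m)) stop("reference mask is empty", call. = FALSE)
  ax <- spatial_axis_index(reference_mask$dv_axis)
  sp <- reference_mask$spacing_um[[reference_mask$dv_axis]]
  coord <- function(idx) (idx - 1) * sp

  if (mode == "global") {
    w <- which(m, arr.ind = TRUE)
    d_idx <- min(w[, ax]); v_idx <- max(w[, ax])
    if (d_idx == v_idx) {
      stop("degenerate neuropil: zero dorsal-ventral thickness (topographic index undefined)",
           call. = FALSE)
    }
    prof <- list(mode = mode, dorsal_extent = coord(d_idx), ventral_extent = coord(v_idx))
  } else {
    other <- setdiff(1:3, ax)
    # any() over the D-V axis: TRUE where the column intersects the mask
    dmin <- apply(m, other, function(col) if (any(col)) min(which(col)) else NA_real_)
    dmax <- apply(m, other, function(col) if (any(col)) max(which(col)) else NA_real_)
    ok <- !is.na(dmin) & dmax > dmin
    if (!any(ok)) {
      stop("degenerate neuropil: no column has nonzero dorsal-ventral thickness", call. = FALSE)
    }
    dor <- coord(dmin); ven <- coord(dmax)
    dor[!ok & !is.na(dmin)] <- NA_real_  # single-voxel columns: TI undefined there
    ven[!ok & !is.na(dmax)] <- NA_real_
    prof <- list(mode = mode, dorsal_extent = dor, ventral_extent = ven, other_axes = other)
  }
  prof$dv_axis <- reference_mask$dv_axis
  prof$dv_spacing <- sp
  structure(prof, class = "boundary_profile")
}

#' @export
print.boundary_profile <- function(x, ...) {
  if (x$mode == "global") {
    cat("<boundary_profile> global: dorsal ", x$dorsal_extent, " um, ventral ",
        x$ventral_extent, " um along ", x$dv_axis, "\n", sep = "")
  } else {
    cat("<boundary_profile> per-column over ", sum(!is.na(x$dorsal_extent)),
        " columns along ", x$dv_axis, "\n", sep = "")
  }
  invisible(x)
}
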