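# Ground-truth synthetic stacks emulating the assay's imaging data: a
# compact neuropil volume in the reference channel and a single clone's
# terminal blob at a known fractional dorsal-ventral position in the clone
# channel, degraded by optical blur and shot/read noise.

# run expr with a local RNG state; restores the caller's .Random.seed
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for one synthetic two-channel stack
#'
#' Defines the "stated world" of the generator: geometry, signal levels and
#' noise. Defaults describe a realistic confocal acquisition of this assay:
#' 0.3 um z-steps, ~0.15 um lateral sampling, a neuropil ~6 um deep along
#' the dorsal-ventral (y) axis, a terminal blob of 150 voxels, signal ~10x
#' above background and shot-noise-limited SNR of roughly 8.
#'
#' @param stack_shape Named voxel counts `c(z=, y=, x=)`.
#' @param spacing_um Physical voxel spacing `c(z=, y=, x=)` in micrometers.
#' @param neuropil_shape `"box"` (default; the topographic index only uses
#'   the D-V extent) or `"ellipsoid"` (inscribed in the same bounds).
#' @param neuropil_bounds List of 1-based inclusive index ranges
#'   `list(z=c(lo,hi), y=c(lo,hi), x=c(lo,hi))` bounding the neuropil; the
#'   `y` range is the dorsal-ventral extent.
#' @param clone_position_q Fractional D-V position of the clone blob center
#'   in `[0, 1]` (0 = dorsal boundary, 1 = ventral boundary).
#' @param clone_size_vox Number of voxels in the clone blob.
#' @param blur_sigma_um Gaussian optical blur sigma (um, isotropic in
#'   physical space); 0 disables blur.
#' @param shot_scale Poisson shot-noise gain (expected photons per intensity
#'   unit); 0 disables shot noise.
#' @param read_noise_sd Gaussian read noise sd (intensity units); 0 disables.
#' @param background_level Constant intensity offset.
#' @param reference_level,clone_level Signal amplitudes above background.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(stack_shape = c(z = 12, y = 64, x = 28),
                           spacing_um = c(z = 0.3, y = 0.15, x = 0.15),
                           neuropil_shape = c("box", "ellipsoid"),
                           neuropil_bounds = list(z = c(3, 10), y = c(13, 52), x = c(5, 24)),
                           clone_position_q = 0.5,
                           clone_size_vox = 150L,
                           blur_sigma_um = 0.3,
                           shot_scale = 1,
                           read_noise_sd = 3,
                           background_level = 10,
                           reference_level = 100,
                           clone_level = 120,
                           seed = 1L) {
  neuropil_shape <- match.arg(neuropil_shape)
  stack_shape <- stack_shape[c("z", "y", "x")]
  spacing_um <- spacing_um[c("z", "y", "x")]
  if (anyNA(stack_shape) || any(stack_shape < 2)) {
    stop("`stack_shape` must name z, y, x with at least 2 voxels each", call. = FALSE)
  }
  if (clone_position_q < 0 || clone_position_q > 1) {
    stop("`clone_position_q` must be in [0, 1]", call. = FALSE)
  }
  for (axn in c("z", "y", "x")) {
    b <- neuropil_bounds[[axn]]
    if (is.null(b) || length(b) != 2L || b[1] < 1 || b[2] > stack_shape[[axn]] || b[1] > b[2]) {
      stop("invalid neuropil bounds for axis ", axn, call. = FALSE)
    }
  }
  if (neuropil_bounds$y[1] >= neuropil_bounds$y[2]) {
    stop("degenerate neuropil geometry: zero dorsal-ventral extent", call. = FALSE)
  }
  if (blur_sigma_um < 0 || shot_scale < 0 || read_noise_sd < 0 || background_level < 0) {
    stop("blur, noise and background parameters must be >= 0", call. = FALSE)
  }
  if (clone_size_vox < 1) stop("`clone_size_vox` must be >= 1", call. = FALSE)
  structure(
    list(stack_shape = stack_shape, spacing_um = spacing_um,
         neuropil_shape = neuropil_shape, neuropil_bounds = neuropil_bounds,
         clone_position_q = clone_position_q, clone_size_vox = as.integer(clone_size_vox),
         blur_sigma_um = blur_sigma_um, shot_scale = shot_scale,
         read_noise_sd = read_noise_sd, background_level = background_level,
         reference_level = reference_level, clone_level = clone_level,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# separable Gaussian blur of a 3D array; sigma_vox per (z, y, x) axis
gaussian_blur_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.05 || d[ax] == 1L) next
    r <- ceiling(3 * s)
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    pd <- dim(a)
    m <- matrix(a, nrow = pd[1])
    n <- pd[1]
    m_pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    f <- stats::filter(m_pad, k, sides = 2)
    m <- f[(r + 1):(r + n), , drop = FALSE]
    a <- array(m, dim = pd)
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate a synthetic two-channel stack with ground truth
#'
#' Builds the noiseless reference (neuropil solid) and clone (terminal blob)
#' channels, records the pre-noise masks and the true fractional position as
#' ground truth, then applies Gaussian blur, Poisson shot noise and Gaussian
#' read noise, and quantizes to non-negative integer intensities (as a
#' detector would). Ground-truth masks are never touched by blur or noise.
#'
#' The blob is the set of `clone_size_vox` voxels nearest (in physical
#' distance; a Gaussian-profile sphere thresholded to that count) to a
#' center placed at fraction `clone_position_q` of the way from the dorsal
#' to the ventral neuropil boundary.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `stack` (an [image_stack()] with channels
#'   `clone` and `reference`) and `truth` (class `synthetic_ground_truth`:
#'   `true_q`, `true_neuropil_mask`, `true_clone_mask`, `dorsal_index`,
#'   `ventral_index`, `seed`).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- as.integer(spec$stack_shape)  # (z, y, x)
  sp <- as.numeric(spec$spacing_um)
  b <- spec$neuropil_bounds

  npil <- array(FALSE, dim = d)
  if (spec$neuropil_shape == "box") {
    npil[b$z[1]:b$z[2], b$y[1]:b$y[2], b$x[1]:b$x[2]] <- TRUE
  } else {
    ctr <- c((b$z[1] + b$z[2]) / 2, (b$y[1] + b$y[2]) / 2, (b$x[1] + b$x[2]) / 2)
    rad <- c((b$z[2] - b$z[1]) / 2, (b$y[2] - b$y[1]) / 2, (b$x[2] - b$x[1]) / 2)
    zi <- (seq_len(d[1]) - ctr[1]) / rad[1]
    yi <- (seq_len(d[2]) - ctr[2]) / rad[2]
    xi <- (seq_len(d[3]) - ctr[3]) / rad[3]
    r2 <- outer(outer(zi^2, yi^2, `+`), xi^2, `+`)
    npil <- r2 <= 1
  }

  # true boundary indices along D-V (y) come from the constructed mask
  w <- which(npil, arr.ind = TRUE)
  y_d <- min(w[, 2]); y_v <- max(w[, 2])
  q <- spec$clone_position_q
  center <- c(mean(range(w[, 1])), y_d + q * (y_v - y_d), mean(range(w[, 3])))

  # physical squared distance of each voxel center to the blob center
  dz2 <- ((seq_len(d[1]) - center[1]) * sp[1])^2
  dy2 <- ((seq_len(d[2]) - center[2]) * sp[2])^2
  dx2 <- ((seq_len(d[3]) - center[3]) * sp[3])^2
  r2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  ord <- order(as.vector(r2))  # stable: deterministic tie-break
  clone <- array(FALSE, dim = d)
  clone[ord[seq_len(min(spec$clone_size_vox, length(ord)))]] <- TRUE

  ref_img <- spec$background_level + spec$reference_level * npil
  clone_img <- spec$background_level + spec$clone_level * clone

  sig_vox <- spec$blur_sigma_um / sp
  if (spec$blur_sigma_um > 0) {
    ref_img <- gaussian_blur_3d(ref_img, sig_vox)
    clone_img <- gaussian_blur_3d(clone_img, sig_vox)
  }

  noisify <- function(img) {
    v <- as.vector(img)
    if (spec$shot_scale > 0) {
      v <- stats::rpois(length(v), lambda = pmax(v, 0) * spec$shot_scale) / spec$shot_scale
    }
    if (spec$read_noise_sd > 0) {
      v <- v + stats::rnorm(length(v), sd = spec$read_noise_sd)
    }
    array(pmax(round(v), 0), dim = d)
  }
  with_seed(spec$seed, {
    clone_img <- noisify(clone_img)
    ref_img <- noisify(ref_img)
  })

  vox <- array(0, dim = c(2L, d))
  vox[1, , , ] <- clone_img
  vox[2, , , ] <- ref_img
  stack <- image_stack(vox,
                       spacing_um = c(z = sp[1], y = sp[2], x = sp[3]),
                       dv_axis = "y", dorsal_low = TRUE,
                       channel_names = c("clone", "reference"))
  truth <- structure(
    list(true_q = q, true_neuropil_mask = npil, true_clone_mask = clone,
         dorsal_index = y_d, ventral_index = y_v, seed = spec$seed),
    class = "synthetic_ground_truth"
  )
  list(stack = stack, truth = truth)
}

#' Generate a paired-channel ROI fixture with known intensity ratios
#'
#' Emulates the ratio quantifications (e.g. nuclear pMad normalized to Elav,
#' or somatic ligand signal normalized to a membrane marker): disk ROIs on a
#' 2D field, a reference channel of constant level inside each ROI, and a
#' signal channel equal to `ratio_true * reference` inside the ROI plus
#' Gaussian noise.
#'
#' @param n_cells Number of ROIs (>= 1).
#' @param ratio_true Positive true ratio(s); recycled to `n_cells`.
#' @param noise_sd Gaussian noise sd added to the signal channel.
#' @param seed Integer RNG seed.
#' @param reference_level Reference intensity inside each ROI.
#' @return List with `stack` (single-slice two-channel [image_stack()],
#'   channels `signal` and `reference`), `rois` (list of [roi()] objects)
#'   and `truth` (data frame `roi_id`, `ratio_true`).
#' @export
generate_roi_fixture <- function(n_cells, ratio_true, noise_sd = 0, seed = 1L,
                                 reference_level = 100) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  ratio_true <- rep_len(ratio_true, n_cells)
  if (any(ratio_true <= 0)) stop("`ratio_true` must be positive", call. = FALSE)
  cell_pitch <- 14L; radius <- 4
  h <- 16L; wdt <- as.integer(n_cells * cell_pitch + 4L)
  sig <- matrix(0, h, wdt); ref <- matrix(0, h, wdt)
  rois <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cx <- (i - 1) * cell_pitch + cell_pitch / 2 + 2
    cy <- h / 2
    m <- outer(seq_len(h) - cy, seq_len(wdt) - cx,
               function(a, b) a^2 + b^2 <= radius^2)
    ref[m] <- reference_level
    sig[m] <- ratio_true[i] * reference_level
    rois[[i]] <- roi(m, id = sprintf("cell_%02d", i), definition_channel = "reference")
  }
  if (noise_sd > 0) {
    sig <- with_seed(seed, sig + matrix(stats::rnorm(h * wdt, sd = noise_sd), h, wdt))
    sig <- pmax(sig, 0)
  }
  vox <- array(0, dim = c(2L, 1L, h, wdt))
  vox[1, 1, , ] <- sig
  vox[2, 1, , ] <- ref
  stack <- image_stack(vox, spacing_um = c(z = 0.3, y = 0.15, x = 0.15),
                       dv_axis = "y", channel_names = c("signal", "reference"))
  list(stack = stack, rois = rois,
       truth = data.frame(roi_id = vapply(rois, `[[`, "", "id"),
                          ratio_true = ratio_true, stringsAsFactors = FALSE))
}

#' Generate a tidy grouped Gaussian dataset
#'
#' Fixture for the statistics module, mirroring per-clone TI values compared
#' across groups.
#'
#' @param group_means,group_sds Per-group mean and sd (equal lengths;
#'   sds >= 0).
#' @param n_per_group Observations per group (scalar or per-group; all >= 2).
#' @param seed Integer RNG seed.
#' @param group_names Optional labels (default `group_1`, ...).
#' @return Data frame with columns `group` (factor) and `value`.
#' @export
generate_group_dataset <- function(group_means, group_sds, n_per_group, seed = 1L,
                                   group_names = NULL) {
  k <- length(group_means)
  if (length(group_sds) != k) stop("`group_means` and `group_sds` lengths differ", call. = FALSE)
  if (any(group_sds < 0)) stop("`group_sds` must be >= 0", call. = FALSE)
  n_per_group <- rep_len(n_per_group, k)
  if (any(n_per_group < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (is.null(group_names)) group_names <- paste0("group_", seq_len(k))
  with_seed(seed, {
    vals <- lapply(seq_len(k), function(i) {
      stats::rnorm(n_per_group[i], mean = group_means[i], sd = group_sds[i])
    })
    data.frame(
      group = factor(rep(group_names, n_per_group), levels = group_names),
      value = unlist(vals)
    )
  })
}
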