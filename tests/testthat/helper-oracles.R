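# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: the TI oracle is a plain nested loop over
# voxels, the Otsu oracle an exhaustive search over all cut points.

# Brute-force topographic index: enumerate every voxel; global boundaries
# from an exhaustive scan of the reference mask. dv_ax indexes the (z,y,x)
# dims; spacing is the physical step along that axis.
brute_ti <- function(clone, npil, dv_ax = 2L, spacing = 1) {
  n_dv <- dim(npil)[dv_ax]
  dmin <- Inf; dmax <- -Inf
  for (z in seq_len(dim(npil)[1])) for (y in seq_len(dim(npil)[2])) {
    for (x in seq_len(dim(npil)[3])) {
      if (npil[z, y, x]) {
        idx <- c(z, y, x)[dv_ax]
        if (idx < dmin) dmin <- idx
        if (idx > dmax) dmax <- idx
      }
    }
  }
  if (!is.finite(dmin) || dmin == dmax) return(NULL)  # degenerate
  d_co <- (dmin - 1) * spacing; v_co <- (dmax - 1) * spacing
  tis <- c(); n_out <- 0L
  for (z in seq_len(dim(clone)[1])) for (y in seq_len(dim(clone)[2])) {
    for (x in seq_len(dim(clone)[3])) {
      if (clone[z, y, x]) {
        if (!npil[z, y, x]) { n_out <- n_out + 1L; next }
        co <- (c(z, y, x)[dv_ax] - 1) * spacing
        di <- max(co - d_co, 0); vi <- max(v_co - co, 0)
        tis <- c(tis, di / (di + vi))
      }
    }
  }
  if (!length(tis)) return(NULL)
  list(ti_mean = mean(tis), ti = tis, n_inside = length(tis), n_excluded = n_out)
}

# Exhaustive two-class Otsu: try every midpoint between consecutive sorted
# unique values, maximize between-class variance, return the foreground set.
brute_otsu_foreground <- function(x) {
  u <- sort(unique(x))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; best_cut <- NA
  n <- length(x)
  for (ct in cuts) {
    lo <- x[x <= ct]; hi <- x[x > ct]
    w0 <- length(lo) / n; w1 <- 1 - w0
    sb <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (sb > best) { best <- sb; best_cut <- ct }
  }
  x > best_cut
}

random_mask <- function(dims, p = 0.3) {
  array(stats::runif(prod(dims)) < p, dim = dims)
}

# a stack-free label_mask on a unit grid (spacing 1 along y)
mk_mask <- function(arr, dv_axis = "y", sp = c(z = 1, y = 1, x = 1)) {
  label_mask(arr, channel = "test", threshold_method = "fixed", threshold_value = 0,
             dv_axis = dv_axis, spacing_um = sp)
}

# box neuropil + hand-placed clone voxels, on a (nz, ny, nx) grid
box_npil <- function(dims = c(4, 21, 5), y_lo = 3, y_hi = 19) {
  a <- array(FALSE, dims)
  a[, y_lo:y_hi, ] <- TRUE
  a
}

# quick noiseless synthetic spec for fast pipeline tests
quiet_spec <- function(q, seed = 1L, ...) {
  synthetic_spec(clone_position_q = q, blur_sigma_um = 0, shot_scale = 0,
                 read_noise_sd = 0, seed = seed, ...)
}
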