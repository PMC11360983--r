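test_that("voxel_ti boundary and symmetry cases", {
  npil <- box_npil(c(3, 21, 3), y_lo = 1, y_hi = 21)
  nm <- mk_mask(npil)
  bounds <- extract_boundaries(nm)

  at <- function(y) { a <- array(FALSE, dim(npil)); a[2, y, 2] <- TRUE; mk_mask(a) }
  expect_identical(voxel_ti(at(1), nm, bounds)$ti_mean, 0)    # dorsal extreme
  expect_identical(voxel_ti(at(21), nm, bounds)$ti_mean, 1)   # ventral extreme
  expect_identical(voxel_ti(at(11), nm, bounds)$ti_mean, 0.5) # equidistant

  # hand-built 4-voxel clone at fractions 0.2/0.4/0.6/0.8 of the 1..21 span
  clone <- array(FALSE, dim(npil))
  for (y in c(5, 9, 13, 17)) clone[2, y, 2] <- TRUE
  res <- voxel_ti(mk_mask(clone), nm, bounds)
  expect_equal(sort(res$ti_per_voxel), c(0.2, 0.4, 0.6, 0.8))
  expect_identical(res$ti_mean, 0.5)
  expect_identical(res$n_voxels_inside, 4L)
  expect_identical(res$n_voxels_excluded, 0L)
})

test_that("physical spacing cancels for a grid-aligned D-V axis", {
  npil <- box_npil(c(3, 15, 3), y_lo = 2, y_hi = 14)
  clone <- array(FALSE, dim(npil)); clone[2, 5, 2] <- clone[2, 11, 2] <- TRUE
  for (sp in c(0.1, 0.3, 2)) {
    nm <- mk_mask(npil, sp = c(z = 1, y = sp, x = 1))
    res <- voxel_ti(mk_mask(clone), nm, extract_boundaries(nm))
    expect_equal(res$ti_per_voxel, c(0.25, 0.75), label = paste("spacing", sp))
  }
})

test_that("voxel_ti matches brute-force enumeration on random small grids", {
  n_checked <- 0
  for (s in 1:300) {
    set.seed(s)
    dims <- c(sample(2:3, 1), sample(2:6, 1), sample(2:6, 1))[c(3, 2, 1)]
    dims <- pmin(dims, c(6, 6, 3))  # grids up to 6 x 6 x 3
    npil <- random_mask(dims, p = runif(1, 0.2, 0.7))
    clone <- random_mask(dims, p = runif(1, 0.2, 0.6))
    want <- brute_ti(clone, npil, dv_ax = 2L, spacing = 1)
    nm <- mk_mask(npil)
    if (is.null(want)) next
    bounds <- tryCatch(extract_boundaries(nm), error = function(e) NULL)
    if (is.null(bounds)) next
    got <- tryCatch(voxel_ti(mk_mask(clone), nm, bounds), error = function(e) NULL)
    if (is.null(got)) next
    n_checked <- n_checked + 1
    expect_identical(sort(got$ti_per_voxel), sort(want$ti), label = paste("seed", s))
    expect_identical(got$ti_mean, want$ti_mean)
    expect_identical(got$n_voxels_inside, want$n_inside)
    expect_identical(got$n_voxels_excluded, want$n_excluded)
    expect_true(all(got$ti_per_voxel >= 0 & got$ti_per_voxel <= 1))
  }
  expect_gt(n_checked, 100)
})

test_that("clone voxels outside the neuropil are excluded; empty overlap errors", {
  npil <- box_npil(c(3, 21, 3), y_lo = 5, y_hi = 15)
  nm <- mk_mask(npil); bounds <- extract_boundaries(nm)
  clone <- array(FALSE, dim(npil))
  clone[2, 3, 2] <- TRUE   # outside (dorsal of the neuropil)
  clone[2, 10, 2] <- TRUE  # inside
  res <- voxel_ti(mk_mask(clone), nm, bounds)
  expect_identical(res$n_voxels_inside, 1L)
  expect_identical(res$n_voxels_excluded, 1L)
  expect_equal(res$ti_mean, 0.5)

  outside_only <- array(FALSE, dim(npil)); outside_only[2, 2, 2] <- TRUE
  expect_error(voxel_ti(mk_mask(outside_only), nm, bounds), "intersection empty")
})

test_that("per-column boundaries clip out-of-band voxels to TI 0/1", {
  # wedge-shaped neuropil: column x=1 spans y 3..9, column x=3 spans y 5..11
  npil <- array(FALSE, c(1, 13, 3))
  npil[1, 3:9, 1] <- TRUE; npil[1, 4:10, 2] <- TRUE; npil[1, 5:11, 3] <- TRUE
  nm <- mk_mask(npil)
  pc <- extract_boundaries(nm, "per_column")
  clone <- array(FALSE, dim(npil))
  clone[1, 3, 1] <- TRUE   # at its column's dorsal boundary -> 0
  clone[1, 8, 2] <- TRUE   # fraction (8-4)/(10-4) = 2/3
  res <- voxel_ti(mk_mask(clone), nm, pc)
  expect_equal(sort(res$ti_per_voxel), c(0, 2 / 3))
  expect_identical(res$mode, "per_column")
})

test_that("reflection, translation and ventral-shift monotonicity hold", {
  for (s in 1:100) {
    set.seed(400 + s)
    dims <- c(3, 16, 4)
    npil <- array(FALSE, dims)
    npil[, 3:14, 1:3] <- TRUE
    clone <- array(FALSE, dims)
    # clone strictly interior so shifted variants stay inside the neuropil
    # (and clear of the x = 4 plane, so an x-translation loses no voxels)
    pick <- random_mask(c(3, 8, 3), 0.2)
    if (!any(pick)) pick[2, 4, 2] <- TRUE
    clone[, 5:12, 1:3][pick] <- TRUE

    nm <- mk_mask(npil)
    ti0 <- voxel_ti(mk_mask(clone), nm, extract_boundaries(nm))$ti_mean

    # reflection about the D-V axis
    flip <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
    nmf <- mk_mask(flip(npil))
    tif <- voxel_ti(mk_mask(flip(clone)), nmf, extract_boundaries(nmf))$ti_mean
    expect_equal(tif, 1 - ti0, tolerance = 1e-12)

    # joint translation (whole scene moves one voxel ventrally and laterally)
    shift <- function(a) {
      b <- array(FALSE, dim(a)); b[, 2:dim(a)[2], 2:dim(a)[3]] <-
        a[, 1:(dim(a)[2] - 1), 1:(dim(a)[3] - 1)]; b
    }
    nms <- mk_mask(shift(npil))
    tis <- voxel_ti(mk_mask(shift(clone)), nms, extract_boundaries(nms))$ti_mean
    expect_equal(tis, ti0, tolerance = 1e-12)

    # ventral shift of the clone alone never decreases TI
    vshift <- array(FALSE, dims)
    vshift[, 2:16, ] <- clone[, 1:15, ]
    tiv <- voxel_ti(mk_mask(vshift), nm, extract_boundaries(nm))$ti_mean
    expect_gte(tiv, ti0 - 1e-12)
  }
})

test_that("clone_ti_from_stack recovers q and attaches provenance and stages", {
  out <- generate_stack(quiet_spec(0.25, seed = 6))
  res <- clone_ti_from_stack(out$stack, clone_id = "c1")
  voxel_frac <- 1 / (out$truth$ventral_index - out$truth$dorsal_index)
  expect_lt(abs(res$ti_mean - 0.25), voxel_frac)
  expect_identical(res$clone_id, "c1")
  expect_identical(res$provenance$boundary_mode, "global")
  expect_true(is.numeric(res$provenance$clone_threshold))

  # clone entirely outside the neuropil -> stage-tagged error
  spec <- quiet_spec(0.5, seed = 2)
  bad <- generate_stack(spec)
  vox <- bad$stack$voxels
  vox[1, , , ] <- 0
  vox[1, 1, 1:3, 1:3] <- 200  # clone blob far outside the neuropil box
  bad$stack$voxels <- vox
  expect_error(clone_ti_from_stack(bad$stack), "\\[topographic-index\\]")
})

test_that("batch_ti processes manifests and records failures without aborting", {
  dir <- withr::local_tempdir()
  paths <- character(3); qs <- c(0.2, 0.55, 0.8)
  for (i in 1:3) {
    out <- generate_stack(synthetic_spec(clone_position_q = qs[i], seed = i))
    paths[i] <- file.path(dir, sprintf("s%d.tif", i))
    write_stack(out$stack, paths[i])
  }
  man <- data.frame(path = paths, clone_id = c("D1", "M1", "V1"),
                    group = c("D", "M", "V"))
  tab <- batch_ti(man)
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$ti_mean) > 0))  # D < M < V ordering

  man2 <- rbind(man, data.frame(path = file.path(dir, "missing.tif"),
                                clone_id = "X", group = "D"))
  expect_warning(tab2 <- batch_ti(man2), "1 of 4")
  expect_identical(nrow(tab2), 3L)
  expect_identical(nrow(attr(tab2, "failures")), 1L)
  expect_error(batch_ti(data.frame(path = "x")), "manifest must have columns")
})
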