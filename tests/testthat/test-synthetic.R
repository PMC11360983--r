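test_that("generate_stack stores truth verbatim, is deterministic, and validates", {
  spec <- synthetic_spec(clone_position_q = 0.25, seed = 7)
  out1 <- generate_stack(spec)
  expect_identical(out1$truth$true_q, 0.25)
  expect_identical(out1$truth$seed, 7L)
  out2 <- generate_stack(spec)
  expect_identical(out1$stack$voxels, out2$stack$voxels)
  expect_identical(out1$truth, out2$truth)
  # different seed, same geometry: masks conserved, intensities differ
  out3 <- generate_stack(synthetic_spec(clone_position_q = 0.25, seed = 8))
  expect_identical(out3$truth$true_clone_mask, out1$truth$true_clone_mask)
  expect_identical(out3$truth$true_neuropil_mask, out1$truth$true_neuropil_mask)
  expect_false(identical(out3$stack$voxels, out1$stack$voxels))

  expect_error(synthetic_spec(clone_position_q = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(neuropil_bounds = list(z = c(3, 10), y = c(20, 20),
                                                     x = c(5, 24))),
               "degenerate")
  expect_error(synthetic_spec(read_noise_sd = -1), ">= 0")
})

test_that("noise is applied to intensities only, never to ground-truth masks", {
  clean <- generate_stack(quiet_spec(0.4, seed = 1))
  noisy <- generate_stack(synthetic_spec(clone_position_q = 0.4, seed = 1))
  expect_identical(clean$truth$true_clone_mask, noisy$truth$true_clone_mask)
  expect_identical(clean$truth$true_neuropil_mask, noisy$truth$true_neuropil_mask)
  expect_identical(sum(clean$truth$true_clone_mask), 150L)
})

test_that("noiseless blur-free stacks recover q through the full pipeline", {
  for (q in c(0.2, 0.5, 0.8)) {
    out <- generate_stack(quiet_spec(q, seed = 3))
    res <- clone_ti_from_stack(out$stack)
    # one voxel's fractional width of the 40-voxel-deep neuropil
    voxel_frac <- 1 / (out$truth$ventral_index - out$truth$dorsal_index)
    expect_lt(abs(res$ti_mean - q), voxel_frac)
  }
})

test_that("ground-truth masks reproduce q under the TI definition itself", {
  out <- generate_stack(quiet_spec(0.35, seed = 2))
  cm <- mk_mask(aperm(out$truth$true_clone_mask, c(1, 2, 3)))
  nm <- mk_mask(out$truth$true_neuropil_mask)
  res <- voxel_ti(cm, nm, extract_boundaries(nm))
  expect_lt(abs(res$ti_mean - 0.35), 0.03)
})

test_that("ellipsoid neuropil geometry is supported end to end", {
  out <- generate_stack(quiet_spec(0.5, seed = 5, neuropil_shape = "ellipsoid"))
  expect_true(any(out$truth$true_neuropil_mask))
  res <- clone_ti_from_stack(out$stack)
  expect_lt(abs(res$ti_mean - 0.5), 0.05)
})

test_that("ROI fixtures encode exact ratios and recover noisy ones", {
  # exact with zero noise
  fx <- generate_roi_fixture(2, ratio_true = c(1, 2), noise_sd = 0, seed = 1)
  q <- quantify_rois(fx$stack, fx$rois)
  expect_equal(q$ratio, c(1, 2))
  # recovery within 5% at small noise, across several seeds
  for (s in 1:5) {
    fx <- generate_roi_fixture(3, ratio_true = c(0.5, 1, 1.5), noise_sd = 2, seed = s)
    q <- quantify_rois(fx$stack, fx$rois)
    expect_true(all(abs(q$ratio - fx$truth$ratio_true) / fx$truth$ratio_true < 0.05),
                label = paste("seed", s))
  }
  expect_error(generate_roi_fixture(0, 1), ">= 1")
  expect_error(generate_roi_fixture(2, c(1, -1)), "positive")
})

test_that("generate_group_dataset has the stated structure and is deterministic", {
  d1 <- generate_group_dataset(c(0.2, 0.55, 0.8), c(0.05, 0.05, 0.05), 12, seed = 4,
                               group_names = c("D", "M", "V"))
  expect_identical(nrow(d1), 36L)
  expect_identical(levels(d1$group), c("D", "M", "V"))
  expect_identical(d1, generate_group_dataset(c(0.2, 0.55, 0.8), rep(0.05, 3), 12,
                                              seed = 4, group_names = c("D", "M", "V")))
  means <- tapply(d1$value, d1$group, mean)
  expect_true(means["D"] < means["M"] && means["M"] < means["V"])
  expect_error(generate_group_dataset(c(0, 1), c(1, 1), 1), "n >= 2")
  expect_error(generate_group_dataset(c(0, 1), c(1, -1), 5), ">= 0")
  # large-n three-group separation is detected by the ANOVA (power check)
  big <- generate_group_dataset(c(0.2, 0.55, 0.8), rep(0.08, 3), 30, seed = 11)
  expect_lt(one_way_anova(big)$p, 0.05)
})

test_that("generator RNG is self-contained (caller's RNG stream untouched)", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_stack(synthetic_spec(seed = 99)))
  invisible(generate_group_dataset(c(0, 1), c(1, 1), 3, seed = 5))
  expect_identical(runif(1), before)
})
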