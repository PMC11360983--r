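test_that("one_way_anova: F = 0 for identical group distributions; errors as specified", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 3), value = rep(c(1, 2, 3), 3))
  res <- one_way_anova(d)
  expect_identical(res$F, 0)
  expect_identical(res$p, 1)
  expect_identical(res$df1, 2L)
  expect_identical(res$df2, 6L)

  expect_error(one_way_anova(data.frame(group = "a", value = 1:4)), "at least 2 groups")
  expect_error(one_way_anova(data.frame(group = c("a", "a", "b", "b"),
                                        value = rep(5, 4))),
               "zero within-group variance")
  expect_error(one_way_anova(data.frame(group = c("a", "b"), value = 1:2)), "n >= 2")
})

test_that("one_way_anova matches stats::aov on random tables", {
  for (s in 1:20) {
    set.seed(600 + s)
    k <- sample(2:5, 1)
    d <- data.frame(
      group = rep(letters[1:k], times = sample(3:9, k, replace = TRUE)))
    d$value <- rnorm(nrow(d), mean = as.integer(factor(d$group)), sd = runif(1, 0.5, 3))
    mine <- one_way_anova(d)
    orac <- summary(stats::aov(value ~ group, data = d))[[1]]
    expect_equal(mine$F, orac$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, orac$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(c(mine$df1, mine$df2), c(orac$Df[1], orac$Df[2]))
    expect_equal(mine$MSE, orac$`Mean Sq`[2], tolerance = 1e-10)
  }
})

test_that("f_sf matches the df1=2 closed form and is monotone", {
  expect_identical(f_sf(0, 3, 10), 1)
  for (df2 in seq(10, 100, by = 10)) {
    fs <- seq(0, 100, length.out = 41)
    expect_true(all(abs(f_sf(fs, 2, df2) - (1 + 2 * fs / df2)^(-df2 / 2)) < 1e-10),
                label = paste("df2", df2))
    expect_true(all(diff(f_sf(fs, 2, df2)) < 0))
  }
  expect_error(f_sf(1, 0, 10), "degrees of freedom")
  expect_error(f_sf(-1, 2, 10), ">= 0")
})

test_that("ANOVA is invariant to shifts and F to positive rescaling", {
  set.seed(77)
  d <- data.frame(group = rep(c("a", "b", "c"), each = 6), value = rnorm(18, 0, 2))
  base <- one_way_anova(d)
  shifted <- d; shifted$value <- d$value + 123.4
  scaled <- d; scaled$value <- d$value * 7.7
  expect_equal(one_way_anova(shifted)$F, base$F, tolerance = 1e-10)
  expect_equal(one_way_anova(scaled)$F, base$F, tolerance = 1e-10)
})

test_that("fisher_lsd matches a step-by-step hand computation", {
  set.seed(88)
  d <- data.frame(group = rep(c("D", "M", "V"), times = c(5, 7, 6)),
                  value = rnorm(18, rep(c(0.2, 0.55, 0.8), times = c(5, 7, 6)), 0.1))
  a <- one_way_anova(d)
  # independent hand computation of the M vs V comparison
  m_vals <- d$value[d$group == "M"]; v_vals <- d$value[d$group == "V"]
  ss_w <- sum(unlist(lapply(split(d$value, d$group), function(v) sum((v - mean(v))^2))))
  mse <- ss_w / (18 - 3)
  t_hand <- (mean(m_vals) - mean(v_vals)) / sqrt(mse * (1 / 7 + 1 / 6))
  p_hand <- 2 * stats::pt(-abs(t_hand), 15)
  cmp <- fisher_lsd(a, c("M", "V"))
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p, p_hand, tolerance = 1e-12)
  expect_identical(cmp$df, 15L)
  expect_identical(cmp$adjusted, "none")
  expect_error(fisher_lsd(a, c("M", "X")), "not among groups")

  # identical group means -> t = 0, p = 1
  d0 <- data.frame(group = rep(c("a", "b"), each = 3), value = rep(c(1, 2, 3), 2))
  cmp0 <- fisher_lsd(one_way_anova(d0), c("a", "b"))
  expect_identical(cmp0$t, 0)
  expect_identical(cmp0$p, 1)
})

test_that("LSD with exactly two groups equals the pooled-variance t test", {
  for (s in 1:10) {
    set.seed(700 + s)
    a <- rnorm(sample(4:10, 1), 0, 1)
    b <- rnorm(sample(4:10, 1), 0.8, 1.3)
    d <- data.frame(group = rep(c("a", "b"), c(length(a), length(b))), value = c(a, b))
    cmp <- fisher_lsd(one_way_anova(d), c("a", "b"))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(cmp$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(cmp$p, tt$p.value, tolerance = 1e-12)
    expect_identical(cmp$df, as.integer(tt$parameter))
  }
})

test_that("two_sample_t matches stats::t.test for both variants", {
  for (s in 1:10) {
    set.seed(800 + s)
    a <- rnorm(sample(3:12, 1), 0, 1)
    b <- rnorm(sample(3:12, 1), 0.5, 2)
    for (v in c("pooled", "welch")) {
      mine <- two_sample_t(a, b, v)
      orac <- stats::t.test(a, b, var.equal = (v == "pooled"))
      expect_equal(mine$t, unname(orac$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(orac$parameter), tolerance = 1e-12)
      expect_equal(mine$p, orac$p.value, tolerance = 1e-12)
    }
    # antisymmetry
    expect_equal(two_sample_t(a, b)$t, -two_sample_t(b, a)$t, tolerance = 1e-12)
    expect_equal(two_sample_t(a, b)$p, two_sample_t(b, a)$p, tolerance = 1e-12)
  }
  expect_identical(two_sample_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_identical(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
  expect_error(two_sample_t(c(2, 2), c(2, 2)), "t undefined")
})

test_that("formatted report follows the field's reporting conventions", {
  set.seed(99)
  d <- generate_group_dataset(c(0.2, 0.55, 0.8), rep(0.06, 3), 12, seed = 5,
                              group_names = c("D", "M", "V"))
  rep <- stats_report(d)
  expect_match(rep$text[1], "^One-way ANOVA: F\\(2,33\\) = [0-9.]+; p [<=] ")
  expect_match(rep$text[2], "Fisher's LSD$")
  expect_identical(nrow(rep$pairwise), 3L)
  # tiny p values are printed as the conventional "< 0.0001"
  expect_identical(format_p(5e-6), "p < 0.0001")
  expect_identical(format_p(0.0343), "p = 0.0343")
})
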