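# One-way ANOVA, Fisher's LSD post hoc and two-sample t tests, computed
# explicitly from their sums-of-squares / pooled-variance definitions.
# Distribution tail probabilities come from base R (pf, pt); everything
# above the distribution functions is first-principles so the test suite
# can check it against independent oracles (stats::aov, stats::t.test, and
# the df1 = 2 closed form for the F tail).

#' Upper-tail probability of the F distribution
#'
#' `f_sf(F, df1, df2)` is the probability that an F(df1, df2) variate
#' exceeds `F` — the p value of an observed ANOVA F statistic. For
#' `df1 = 2` it equals the closed form `(1 + 2F/df2)^(-df2/2)`, which the
#' test suite uses as an independent oracle.
#'
#' @param f Observed F statistic (>= 0).
#' @param df1 Between-group (numerator) degrees of freedom (>= 1).
#' @param df2 Within-group (denominator) degrees of freedom (>= 1).
#' @return The upper-tail probability in `(0, 1]`.
#' @export
f_sf <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1", call. = FALSE)
  if (any(f < 0)) stop("F statistic must be >= 0", call. = FALSE)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' One-way analysis of variance
#'
#' Partitions the total sum of squares into between-group and within-group
#' components: `F = MS_between / MS_within` with `df1 = k - 1` and
#' `df2 = N - k`; the p value is the F upper tail. The pooled within-group
#' mean square (MSE) and error df are retained for Fisher's LSD.
#'
#' @param values A tidy data frame with columns `group` and `value` (or a
#'   path to such a CSV).
#' @return An object of class `group_stats`: `groups`, `n_per_group`,
#'   `means`, `F`, `df1`, `df2`, `p`, `MSE`, plus the underlying `data`.
#' @export
one_way_anova <- function(values) {
  if (is.character(values)) values <- utils::read.csv(values, stringsAsFactors = FALSE)
  if (!all(c("group", "value") %in% names(values))) {
    stop("`values` must have columns `group` and `value`", call. = FALSE)
  }
  values <- values[stats::complete.cases(values[, c("group", "value")]), ]
  g <- factor(values$group)
  y <- as.numeric(values$value)
  k <- nlevels(g)
  if (k < 2L) stop("one-way ANOVA needs at least 2 groups", call. = FALSE)
  n <- as.vector(table(g))
  if (any(n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  N <- length(y)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum((y - means[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ss_within == 0) {
    stop("zero within-group variance everywhere: F statistic undefined", call. = FALSE)
  }
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  structure(
    list(groups = levels(g), n_per_group = n, means = as.numeric(means),
         F = f, df1 = df1, df2 = df2, p = f_sf(f, df1, df2), MSE = mse,
         data = data.frame(group = g, value = y)),
    class = "group_stats"
  )
}

#' @export
print.group_stats <- function(x, ...) {
  cat("One-way ANOVA: ", format_stat_line(x), "\n", sep = "")
  for (i in seq_along(x$groups)) {
    cat(sprintf("  %s: n = %d, mean = %.4f\n", x$groups[i], x$n_per_group[i], x$means[i]))
  }
  invisible(x)
}

#' Fisher's LSD pairwise comparison
#'
#' Unadjusted pairwise t test using the pooled error mean square and error
#' degrees of freedom from the omnibus ANOVA:
#' `t = (mean_a - mean_b) / sqrt(MSE * (1/n_a + 1/n_b))`, two-sided p from
#' the t(df2) distribution. With exactly two groups this reduces to the
#' pooled-variance two-sample t test.
#'
#' @param stats A `group_stats` object from [one_way_anova()].
#' @param pair Character vector of two group names.
#' @return An object of class `pairwise_comparison`: `pair`, `t`, `df`,
#'   `p`, `mean_diff`, `adjusted = "none"`.
#' @export
fisher_lsd <- function(stats, pair) {
  stopifnot(inherits(stats, "group_stats"))
  ia <- match(pair[1], stats$groups)
  ib <- match(pair[2], stats$groups)
  if (anyNA(c(ia, ib))) {
    stop("pair (", paste(pair, collapse = ", "), ") not among groups: ",
         paste(stats$groups, collapse = ", "), call. = FALSE)
  }
  diff <- stats$means[ia] - stats$means[ib]
  se <- sqrt(stats$MSE * (1 / stats$n_per_group[ia] + 1 / stats$n_per_group[ib]))
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df = stats$df2)
  structure(
    list(pair = pair, t = t, df = stats$df2, p = p, mean_diff = diff,
         adjusted = "none"),
    class = "pairwise_comparison"
  )
}

#' All pairwise LSD comparisons of an ANOVA
#'
#' @param stats A `group_stats` object.
#' @return Data frame with one row per unordered pair: `group_a`, `group_b`,
#'   `mean_diff`, `t`, `df`, `p`.
#' @export
fisher_lsd_all <- function(stats) {
  stopifnot(inherits(stats, "group_stats"))
  pairs <- utils::combn(stats$groups, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    cmp <- fisher_lsd(stats, pairs[, j])
    data.frame(group_a = cmp$pair[1], group_b = cmp$pair[2],
               mean_diff = cmp$mean_diff, t = cmp$t, df = cmp$df, p = cmp$p,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(x$pair[1], " vs ", x$pair[2], ": ", format_stat_line(x), " (Fisher's LSD)\n", sep = "")
  invisible(x)
}

#' Two-sample t test (pooled or Welch)
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param variant `"pooled"` (Student, default — the convention when only
#'   "t test" is reported) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided), `variant`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0 && mean(a) == mean(b)) {
    stop("zero variance in both samples with equal means: t undefined", call. = FALSE)
  }
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df), variant = variant)
}

format_p <- function(p) {
  if (p < 1e-4) "p < 0.0001" else sprintf("p = %.4f", p)
}

# "F(2,42) = 0.9672; p = 0.3885" / "t(12) = 2.2340; p = 0.0453" style line
format_stat_line <- function(x) {
  if (inherits(x, "group_stats")) {
    sprintf("F(%d,%d) = %.4f; %s", x$df1, x$df2, x$F, format_p(x$p))
  } else {
    sprintf("t(%s) = %.4f; %s",
            format(round(x$df, 2)), x$t, format_p(x$p))
  }
}

#' Formatted statistics report for a grouped dataset
#'
#' Runs the omnibus one-way ANOVA and all pairwise LSD comparisons and
#' renders them in the conventional reporting style
#' (`F(df1,df2) = ...; p = ...`), with p values below 1e-4 shown as
#' `p < 0.0001`. Full precision is kept in the returned object.
#'
#' @param values Tidy data frame with `group` and `value` columns.
#' @return List of class `stats_report`: `anova` (`group_stats`),
#'   `pairwise` (data frame), `text` (character vector of formatted lines).
#' @export
stats_report <- function(values) {
  a <- one_way_anova(values)
  pw <- fisher_lsd_all(a)
  lines <- c(
    sprintf("One-way ANOVA: %s", format_stat_line(a)),
    vapply(seq_len(nrow(pw)), function(i) {
      sprintf("%s vs %s, %s; Fisher's LSD", pw$group_a[i], pw$group_b[i], format_p(pw$p[i]))
    }, character(1))
  )
  structure(list(anova = a, pairwise = pw, text = lines), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
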