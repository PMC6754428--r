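#' Two-sample pooled t-test from summary statistics
#'
#' Student's pooled-variance t-test computed directly from group means,
#' SDs and sizes — the form needed to reproduce demographic-table
#' p-values from printed summaries (`df = n_a + n_b - 2`, two-sided).
#'
#' @param mean_a,sd_a,n_a group A mean, SD, size.
#' @param mean_b,sd_b,n_b group B mean, SD, size.
#' @return List with `t`, `df`, `p_two_sided` and the echoed
#'   summaries.
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stopf("both groups need n >= 2")
  if (sd_a < 0 || sd_b < 0) stopf("SDs must be nonnegative")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- if (se > 0) (mean_a - mean_b) / se else 0
  p <- if (se > 0) 2 * stats::pt(-abs(t), df) else 1
  list(mean_a = mean_a, sd_a = sd_a, n_a = n_a,
       mean_b = mean_b, sd_b = sd_b, n_b = n_b,
       t = t, df = df, p_two_sided = p)
}

#' Partial correlation with confound adjustment
#'
#' Residualises `x` and `y` on the confound columns (least squares,
#' with intercept), then correlates the residuals. The p-value comes
#' from `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees
#' of freedom, where k is the number of confounds. With no confounds
#' this reduces exactly to the Pearson correlation test.
#'
#' @param x,y numeric vectors (one value per subject).
#' @param confounds data frame / matrix of numeric confound columns
#'   (e.g. age and 0/1-coded gender), or `NULL`.
#' @param metric_name,score_name labels carried into the result.
#' @return List with `r_partial`, `p`, `df`, `n`, `confounds`
#'   (column names) and a `degenerate` flag (TRUE when a residual
#'   vector is constant and r is undefined).
#' @export
partial_correlation <- function(x, y, confounds = NULL,
                                metric_name = "x", score_name = "y") {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  Z <- if (is.null(confounds)) NULL else as.matrix(as.data.frame(confounds))
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= k + 2) stopf("need n > k + 2 subjects (n = %d, k = %d)", n, k)
  resid_on <- function(v) {
    if (is.null(Z)) return(v - mean(v))
    stats::lm.fit(cbind(1, Z), v)$residuals
  }
  rx <- resid_on(x)
  ry <- resid_on(y)
  # residuals that are numerically zero relative to the input scale mean
  # the variable is constant or fully absorbed by the confounds
  degen <- function(r, v) stats::sd(r) <= 1e-10 * max(stats::sd(v), 1e-300)
  if (degen(rx, x) || degen(ry, y)) {
    return(list(metric_name = metric_name, score_name = score_name,
                r_partial = NA_real_, p = NA_real_, df = n - 2L - k, n = n,
                confounds = colnames(Z), degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df)
  list(metric_name = metric_name, score_name = score_name,
       r_partial = r, p = p, df = df, n = n,
       confounds = colnames(Z), degenerate = FALSE)
}

#' Between-group tests on a metric table
#'
#' For each metric column, compares the two groups with any subset of
#' the Mann-Whitney U test, the two-sample Kolmogorov-Smirnov test and
#' Student's pooled t-test (all two-sided).
#'
#' @param groupA_metrics,groupB_metrics data frames with identical
#'   numeric metric columns, one row per subject.
#' @param tests character subset of `c("mwu", "ks", "t")`.
#' @param var_equal pooled-variance t-test when TRUE (default); Welch
#'   when FALSE.
#' @return Data frame with one row per metric and one p-value column
#'   per requested test.
#' @export
group_compare_metrics <- function(groupA_metrics, groupB_metrics,
                                  tests = c("mwu", "ks", "t"),
                                  var_equal = TRUE) {
  tests <- match.arg(tests, several.ok = TRUE)
  cols <- intersect(names(groupA_metrics), names(groupB_metrics))
  cols <- cols[vapply(groupA_metrics[cols], is.numeric, logical(1))]
  rows <- lapply(cols, function(cn) {
    a <- groupA_metrics[[cn]]
    b <- groupB_metrics[[cn]]
    if (length(a) < 2 || length(b) < 2) stopf("need >= 2 values per group")
    out <- data.frame(metric = cn, mean_a = mean(a), mean_b = mean(b),
                      stringsAsFactors = FALSE)
    if ("mwu" %in% tests)
      out$p_mwu <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    if ("ks" %in% tests)
      out$p_ks <- suppressWarnings(stats::ks.test(a, b)$p.value)
    if ("t" %in% tests)
      out$p_t <- stats::t.test(a, b, var.equal = var_equal)$p.value
    out
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH q-values with rejection flags at level `alpha`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha FDR level for the rejection flags (default 0.05).
#' @return Data frame with columns `p`, `q`, `reject`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, reject = q <= alpha)
}

#' Associate a network metric with clinical scores across subjects
#'
#' Convenience wrapper: extracts a per-subject network metric and one
#' or more score columns from a cohort, then runs
#' [partial_correlation()] against each score with the requested
#' confound columns (gender is recoded 0 = M, 1 = F).
#'
#' @param ch a [cohort()].
#' @param metric_values numeric vector, one value per subject (in
#'   cohort order), e.g. a node's nodal efficiency.
#' @param scores character vector of score column names in the
#'   covariates table.
#' @param confounds character vector of confound column names
#'   (default `c("age", "gender")`).
#' @param metric_name label for the metric.
#' @return Data frame with one row per score: `metric`, `score`, `r`,
#'   `p`, `n`, `df`.
#' @export
associate_metric <- function(ch, metric_values, scores,
                             confounds = c("age", "gender"),
                             metric_name = "metric") {
  cov <- ch$covariates
  Z <- NULL
  if (length(confounds) > 0) {
    Z <- cov[confounds]
    if ("gender" %in% names(Z)) Z$gender <- as.numeric(Z$gender == "F")
    Z <- as.data.frame(lapply(Z, as.numeric))
  }
  rows <- lapply(scores, function(sc) {
    res <- partial_correlation(metric_values, as.numeric(cov[[sc]]), Z,
                               metric_name = metric_name, score_name = sc)
    data.frame(metric = metric_name, score = sc, r = res$r_partial,
               p = res$p, n = res$n, df = res$df, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
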