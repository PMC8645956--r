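# Nonparametric statistics following the conventions of SPSS: paired
# Wilcoxon signed-rank with asymptotic two-sided significance (midranks,
# tie-corrected variance, zero differences dropped, no continuity
# correction) and Spearman correlation with t-approximation p-values.

#' Median and interquartile range
#'
#' IQR = Q3 - Q1 with the weighted-average (linear-interpolation)
#' percentile convention; the default `type = 6` matches the SPSS
#' HAVERAGE definition. Other `stats::quantile` types are available via
#' `type`.
#'
#' @param x Non-empty numeric vector.
#' @param type Quantile type passed to [stats::quantile()].
#'
#' @return List with `median`, `q1`, `q3`, `iqr`, `n`.
#' @export
median_iqr <- function(x, type = 6) {
  x <- x[!is.na(x)]
  if (!length(x)) .stop_data("median_iqr: empty input")
  q <- stats::quantile(x, c(0.25, 0.75), type = type, names = FALSE)
  list(median = stats::median(x), q1 = q[1L], q3 = q[2L],
       iqr = q[2L] - q[1L], n = length(x))
}

#' Paired Wilcoxon signed-rank test, asymptotic two-sided
#'
#' Differences `b - a` are computed; zero differences are dropped;
#' absolute differences receive midranks. With `W+` the positive-rank
#' sum and `n` the retained pairs,
#' `Z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)`
#' (tie correction over tie-group sizes `t`), and
#' `p = 2 * (1 - Phi(|Z|))` without continuity correction.
#'
#' @param a,b Paired numeric vectors (condition A and B), equal length.
#'   Alternatively pass the differences directly as `a` with `b = NULL`.
#'
#' @return Object of class `wilcoxon_result`: `n_used`, `w_plus`,
#'   `w_minus`, `z`, `p`.
#' @export
wilcoxon_asymptotic <- function(a, b = NULL) {
  d <- if (is.null(b)) a else {
    if (length(a) != length(b))
      .stop_data("wilcoxon_asymptotic: unequal lengths")
    b - a
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L)
    .stop_data("wilcoxon_asymptotic: fewer than 2 nonzero differences")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_plus - n * (n + 1) / 4) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  structure(list(n_used = n, w_plus = w_plus, w_minus = w_minus,
                 z = z, p = p),
            class = "wilcoxon_result")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' `rho` is the Pearson correlation of midranks (equal to
#' `1 - 6*sum(d^2)/(n(n^2-1))` without ties);
#' `t = rho * sqrt((n-2)/(1-rho^2))` with `n - 2` df gives the two-sided
#' p-value. `|rho| = 1` yields `p = 0` with `degenerate = TRUE` (below
#' any machine floor).
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#'
#' @return Object of class `spearman_result`: `rho`, `n`, `t`, `p`,
#'   `degenerate`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) .stop_data("spearman: need n >= 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    .stop_data("spearman: constant input, rho undefined")
  rho <- stats::cor(rx, ry)
  degenerate <- abs(rho) >= 1 - 1e-15
  if (degenerate) {
    t <- sign(rho) * Inf
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(rho = rho, n = n, t = t, p = p, degenerate = degenerate),
            class = "spearman_result")
}

#' Correlation panel of respiratory variables against an outcome
#'
#' One Spearman correlation per variable column against the outcome
#' column (e.g. per-animal delta KiS), with significance flags at
#' p < 0.05 and no multiple-testing correction.
#'
#' @param cohort Data frame, one row per animal.
#' @param outcome Name of the outcome column.
#' @param variables Character vector of variable columns; defaults to
#'   all numeric columns except the outcome. Missing columns are listed
#'   in the `skipped` attribute and skipped.
#' @param alpha Significance level for the flag.
#'
#' @return Data frame with `variable`, `rho`, `n`, `t`, `p`,
#'   `significant`.
#' @export
correlation_panel <- function(cohort, outcome = "delta_kis",
                              variables = NULL, alpha = 0.05) {
  if (!(outcome %in% names(cohort)))
    .stop_data("correlation_panel: outcome column '%s' missing", outcome)
  if (is.null(variables)) {
    num <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    variables <- setdiff(num, outcome)
  }
  skipped <- setdiff(variables, names(cohort))
  variables <- intersect(variables, names(cohort))
  rows <- lapply(variables, function(v) {
    s <- spearman(cohort[[v]], cohort[[outcome]])
    data.frame(variable = v, rho = s$rho, n = s$n, t = s$t, p = s$p,
               significant = s$p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
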