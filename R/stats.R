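#' One-way random, single-measures intraclass correlation (ICC(1,1))
#'
#' Quantifies test-retest reliability from a one-way random-effects ANOVA
#' over subjects: `(MSB - MSW) / (MSB + (k - 1) MSW)` with k sessions
#' (here 2). Negative estimates are reported as computed rather than
#' floored at zero, since flooring hides degenerate reliability.
#'
#' @param session1,session2 numeric vectors of per-subject measurements
#'   (test and retest), equal length, at least 3 subjects.
#' @return scalar in `(-Inf, 1]`.
#' @export
#' @examples
#' icc_1_1(c(1, 3, 5, 7), c(2, 4, 6, 8))
icc_1_1 <- function(session1, session2) {
  x <- cbind(session1, session2)
  if (nrow(x) < 3L) stop("ICC needs at least 3 subjects")
  if (anyNA(x)) stop("ICC input contains missing values")
  k <- ncol(x)
  n <- nrow(x)
  grand <- mean(x)
  subj_means <- rowMeans(x)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((x - subj_means)^2) / (n * (k - 1))
  if (msb + (k - 1) * msw == 0)
    stop("ICC undefined: zero total variance (all measurements equal)")
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Categorize an ICC value
#'
#' Good reliability is ICC >= 0.75, moderate is 0.5 <= ICC < 0.75, poor is
#' ICC < 0.5 (boundaries inclusive on the better category).
#'
#' @param icc numeric vector of finite ICC values.
#' @return character vector in `{"good", "moderate", "poor"}`.
#' @export
categorize_reliability <- function(icc) {
  stopifnot(is.numeric(icc), all(is.finite(icc)))
  ifelse(icc >= 0.75, "good", ifelse(icc >= 0.5, "moderate", "poor"))
}

#' Test-retest reliability table
#'
#' Computes ICC(1,1) and its reliability category for every
#' bundle-descriptor cell of a tidy cohort table, plus the median ICC per
#' descriptor across bundles as an overall performance indicator.
#'
#' @param df data.frame with columns `subject`, `session` (two levels),
#'   `bundle`, `descriptor`, `value`.
#' @return a list with `cells` (data.frame: bundle, descriptor, icc,
#'   category) and `median_icc` (data.frame: descriptor, median_icc).
#' @export
reliability_table <- function(df) {
  need <- c("subject", "session", "bundle", "descriptor", "value")
  if (!all(need %in% names(df)))
    stop("df must have columns ", paste(need, collapse = ", "))
  sess <- sort(unique(df$session))
  if (length(sess) != 2L) stop("exactly two sessions are required")
  cells <- expand.grid(bundle = unique(df$bundle),
                       descriptor = unique(df$descriptor),
                       stringsAsFactors = FALSE)
  cells$icc <- vapply(seq_len(nrow(cells)), function(i) {
    sub <- df[df$bundle == cells$bundle[i] & df$descriptor == cells$descriptor[i], ]
    s1 <- sub[sub$session == sess[1L], ]
    s2 <- sub[sub$session == sess[2L], ]
    s2 <- s2[match(s1$subject, s2$subject), ]
    icc_1_1(s1$value, s2$value)
  }, numeric(1))
  cells$category <- categorize_reliability(cells$icc)
  med <- aggregate(icc ~ descriptor, data = cells, FUN = median)
  names(med)[2L] <- "median_icc"
  list(cells = cells, median_icc = med)
}

#' Paired left-right asymmetry test
#'
#' Two-sided paired t-test of the left-right differences, with significance
#' stars (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05), the percentage
#' difference `100 (a - b) / a` where `a` is the side with the larger mean
#' (the dominant side), and Cohen's d. The paired form of d,
#' `mean(diff) / sd(diff)`, is the default since it matches paired-t
#' reporting; `d_form = "pooled"` divides by the pooled side SD instead.
#'
#' @param left,right numeric per-subject values, paired, length >= 3.
#' @param d_form `"paired"` (default) or `"pooled"`.
#' @return a list of class `asymmetry_result`: `p_value`, `stars`,
#'   `percent_difference`, `dominant_side` (`"left"`/`"right"`),
#'   `cohens_d`, `t_statistic`, `degenerate` (TRUE when the difference
#'   variance is zero and the t-test is undefined).
#' @export
asymmetry_test <- function(left, right, d_form = c("paired", "pooled")) {
  d_form <- match.arg(d_form)
  stopifnot(length(left) == length(right), length(left) >= 3L)
  diffs <- left - right
  dominant <- if (mean(left) >= mean(right)) "left" else "right"
  a <- if (dominant == "left") mean(left) else mean(right)
  b <- if (dominant == "left") mean(right) else mean(left)
  pct <- if (a == 0) NA_real_ else 100 * (a - b) / a
  degenerate <- stats::sd(diffs) == 0
  if (degenerate) {
    p <- if (all(diffs == 0)) NA_real_ else 0
    tstat <- NA_real_
  } else {
    tt <- stats::t.test(left, right, paired = TRUE)
    p <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  denom <- switch(d_form,
                  paired = stats::sd(diffs),
                  pooled = sqrt((stats::var(left) + stats::var(right)) / 2))
  d <- if (degenerate && d_form == "paired") NA_real_ else mean(diffs) / denom
  structure(list(p_value = p, stars = significance_stars(p),
                 percent_difference = pct, dominant_side = dominant,
                 cohens_d = d, t_statistic = tstat, degenerate = degenerate),
            class = "asymmetry_result")
}

significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Between-subject variation by absolute deviation from the median
#'
#' Each subject's deviation is `|x_i - median(x)| / median(x)`, a unit-free
#' measure of between-subject spread that is comparable across descriptors
#' of different scale.
#'
#' @param values numeric per-subject descriptor values; the median must be
#'   nonzero.
#' @return a list: `deviation` (per-subject nonnegative values), and the
#'   summary quartiles `median`, `q1`, `q3` of the deviations.
#' @export
between_subject_deviation <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  med <- stats::median(values)
  if (med == 0) stop("deviation undefined: median is zero")
  dev <- abs(values - med) / abs(med)
  q <- stats::quantile(dev, c(0.25, 0.5, 0.75), names = FALSE)
  list(deviation = dev, median = q[2L], q1 = q[1L], q3 = q[3L])
}
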