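# Midrank-tied Spearman rho: Pearson correlation of the rank-transformed
# series. With allow_constant, a constant series gives NA + warning instead
# of an error (used for fit-quality reporting on degenerate fits).
midrank_rho <- function(x, y, allow_constant = FALSE) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    if (allow_constant) {
      warn("Constant series: rank correlation is undefined, returning NA.")
      return(NA_real_)
    }
    abort("Rank correlation is undefined for a constant series.")
  }
  cor(rx, ry)
}

drop_incomplete_pairs <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("Dropped %d incomplete pair(s).", n_drop))
  }
  list(x = x[keep], y = y[keep])
}

ba_stats <- function(d, conf_mult) {
  bias <- mean(d)
  s <- sd(d)
  tibble(
    n = length(d), bias = bias, sd = s,
    loa_low = bias - conf_mult * s,
    loa_high = bias + conf_mult * s
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences `x - y` between two methods measuring the same quantity:
#' bias (mean difference), its sample standard deviation (n - 1
#' denominator) and the 95% limits of agreement, bias ± 1.96·SD. Pairs
#' with a missing value in either method are dropped with a message.
#'
#' @param data Data frame of paired measurements.
#' @param x,y Unquoted column names of the two methods (e.g. Gy/GBq dose
#'   coefficients from two software systems).
#' @param conf_mult Limits-of-agreement multiplier, default 1.96 (the
#'   normal 95% interval).
#' @return One-row tibble of class `bland_altman`: `n`, `bias`, `sd`,
#'   `loa_low`, `loa_high`, with the per-pair differences attached for
#'   [autoplot()][autoplot.bland_altman].
#' @export
#' @examples
#' pm <- tibble::tibble(a = c(1, 2, 4), b = c(0, 2, 1))
#' bland_altman(pm, a, b)
bland_altman <- function(data, x, y, conf_mult = 1.96) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  p <- drop_incomplete_pairs(xv, yv)
  if (length(p$x) < 2L) abort("At least 2 complete pairs are required.")
  out <- ba_stats(p$x - p$y, conf_mult)
  out$scale <- "absolute"
  attr(out, "pairs") <- tibble(x = p$x, y = p$y, mean = (p$x + p$y) / 2, diff = p$x - p$y)
  class(out) <- c("bland_altman", class(out))
  out
}

#' Relative-difference Bland-Altman analysis
#'
#' Expresses each paired difference relative to the pair average,
#' \eqn{r_i = (x_i - y_i) / ((x_i + y_i)/2) \times 100\%}, then runs the
#' Bland-Altman analysis on the percentages. Pairs whose average is zero
#' are excluded with a warning (the relative difference is undefined
#' there).
#'
#' @inheritParams bland_altman
#' @return As [bland_altman()], with `scale = "relative_percent"`; `bias`,
#'   `sd` and the limits of agreement are percentages.
#' @export
#' @examples
#' pm <- tibble::tibble(a = c(3, 2), b = c(1, 2))
#' relative_differences(pm, a, b)
relative_differences <- function(data, x, y, conf_mult = 1.96) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  p <- drop_incomplete_pairs(xv, yv)
  avg <- (p$x + p$y) / 2
  zero <- avg == 0
  if (any(zero)) {
    warn(sprintf("Excluded %d pair(s) with zero average: relative difference undefined.", sum(zero)))
  }
  xk <- p$x[!zero]; yk <- p$y[!zero]; avgk <- avg[!zero]
  if (length(xk) < 2L) abort("At least 2 usable pairs are required.")
  r <- (xk - yk) / avgk * 100
  out <- ba_stats(r, conf_mult)
  out$scale <- "relative_percent"
  attr(out, "pairs") <- tibble(x = xk, y = yk, mean = avgk, diff = r)
  class(out) <- c("bland_altman", class(out))
  out
}

#' Bland-Altman plot
#'
#' Pair averages against differences, with horizontal lines at the bias
#' (solid) and the limits of agreement (dashed).
#'
#' @param object A [bland_altman()] or [relative_differences()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ylab <- if (object$scale == "relative_percent") "Relative difference (%)" else "Difference"
  ggplot2::ggplot(pairs, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Pair average", y = ylab,
                  title = sprintf("Bias %.3g, 95%% LOA [%.3g, %.3g]",
                                  object$bias, object$loa_low, object$loa_high))
}

#' Spearman rank correlation of paired measurements
#'
#' Tie-corrected (midrank) Spearman rho: the Pearson correlation of the
#' rank-transformed series. With unique values this reduces to the classic
#' \eqn{1 - 6\sum d_i^2 / (n(n^2-1))}.
#'
#' @inheritParams bland_altman
#' @return A single rho in \[-1, 1\].
#' @export
#' @examples
#' pm <- tibble::tibble(a = 1:4, b = c(1, 3, 2, 4))
#' spearman_rho(pm, a, b)
spearman_rho <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  p <- drop_incomplete_pairs(xv, yv)
  if (length(p$x) < 3L) abort("At least 3 complete pairs are required.")
  midrank_rho(p$x, p$y)
}

#' Intraclass correlation, absolute agreement, single rater — ICC(A,1)
#'
#' McGraw-Wong ICC(A,1) from the two-way ANOVA decomposition with the two
#' methods as raters (k = 2):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' error mean squares. Absolute agreement penalises systematic offsets
#' between the methods, so a consistent bias can drive the estimate
#' negative; negative estimates are returned as-is and flagged.
#'
#' @inheritParams bland_altman
#' @return One-row tibble: `icc`, `n`, `k`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `negative`.
#' @export
#' @examples
#' pm <- tibble::tibble(a = c(1, 2, 3), b = c(1.1, 2.0, 2.9))
#' icc_agreement_single(pm, a, b)
icc_agreement_single <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  p <- drop_incomplete_pairs(xv, yv)
  n <- length(p$x)
  if (n < 3L) abort("At least 3 complete pairs are required.")
  k <- 2
  m <- cbind(p$x, p$y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_error + (k / n) * (ms_cols - ms_error)
  if (denom <= 0) {
    abort("Degenerate input: zero between-subject variance, ICC is undefined.")
  }
  icc <- (ms_rows - ms_error) / denom
  tibble(icc = icc, n = n, k = k, ms_rows = ms_rows, ms_cols = ms_cols,
         ms_error = ms_error, negative = icc < 0)
}

#' Full agreement report per stratum
#'
#' Runs the complete software-comparison battery — absolute and relative
#' Bland-Altman, Spearman rho and ICC(A,1) — on paired dose outcomes,
#' grouped by any stratifying columns (target class, fit model, ...). This
#' is the analysis behind a software-comparison summary table.
#'
#' @inheritParams bland_altman
#' @param ... Unquoted grouping columns (e.g. `stratum`, `model`).
#' @return A tibble with one row per group: `n`, `bias`, `sd`, `loa_low`,
#'   `loa_high`, `rel_bias`, `rel_sd`, `rel_loa_low`, `rel_loa_high`,
#'   `spearman`, `icc`, `icc_negative`.
#' @export
#' @examples
#' pm <- tibble::tibble(
#'   stratum = rep(c("kidneys", "lesions"), each = 4),
#'   a = c(1, 2, 3, 4, 2, 4, 6, 8), b = c(1, 2, 3, 4.2, 2, 4.1, 6, 8)
#' )
#' build_comparison_table(pm, a, b, stratum)
build_comparison_table <- function(data, x, y, ..., conf_mult = 1.96) {
  xq <- enquo(x); yq <- enquo(y)
  grouped <- dplyr::group_by(as_tibble(data), ...)
  dplyr::reframe(grouped, agreement_row(dplyr::pick(dplyr::everything()), !!xq, !!yq, conf_mult))
}

agreement_row <- function(d, x, y, conf_mult) {
  if (nrow(d) == 0) abort("Empty stratum.")
  ab <- bland_altman(d, {{ x }}, {{ y }}, conf_mult = conf_mult)
  rel <- relative_differences(d, {{ x }}, {{ y }}, conf_mult = conf_mult)
  rho <- tryCatch(spearman_rho(d, {{ x }}, {{ y }}), error = function(e) NA_real_)
  icc_res <- tryCatch(icc_agreement_single(d, {{ x }}, {{ y }}),
                      error = function(e) tibble(icc = NA_real_, negative = NA))
  tibble(
    n = ab$n, bias = ab$bias, sd = ab$sd,
    loa_low = ab$loa_low, loa_high = ab$loa_high,
    rel_bias = rel$bias, rel_sd = rel$sd,
    rel_loa_low = rel$loa_low, rel_loa_high = rel$loa_high,
    spearman = rho, icc = icc_res$icc, icc_negative = icc_res$negative
  )
}
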