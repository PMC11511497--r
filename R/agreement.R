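# Nonparametric Bland-Altman agreement and method-comparison summaries.

moment_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# non-excess (normal = 3) moment kurtosis
moment_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}

#' Nonparametric Bland-Altman analysis
#'
#' Agreement between a reference and a test method via the differences
#' `d = y - x` against the means `(x + y) / 2`. The limits of agreement are
#' nonparametric: median(d) +/- RPC with the reproducibility coefficient
#' RPC = 1.45 * IQR(d), which approximates the parametric 1.96 sd for
#' Gaussian differences. Quantiles use linear interpolation between order
#' statistics (R type 7).
#'
#' @param x Reference values.
#' @param y Test values (same length; see [truncate_pair()]).
#' @return An object of class `eit_bland_altman`: `n`, `means`, `diffs`,
#'   `diff_median`, `diff_sd`, `iqr`, `rpc`, `limits` (lower/upper),
#'   `pct_within`, `skewness`, `kurtosis`.
#' @export
bland_altman_np <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch (", length(x), " vs ", length(y),
         "); truncate to a common length first")
  }
  if (length(x) < 4) stop("need n >= 4 for nonparametric limits")
  d <- y - x
  md <- stats::median(d)
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  rpc <- 1.45 * iqr
  lim <- c(lower = md - rpc, upper = md + rpc)
  structure(list(n = length(x), means = (x + y) / 2, diffs = d,
                 diff_median = md, diff_sd = stats::sd(d), iqr = iqr, rpc = rpc,
                 limits = lim,
                 pct_within = 100 * mean(d >= lim[1] & d <= lim[2]),
                 skewness = moment_skewness(d), kurtosis = moment_kurtosis(d)),
            class = "eit_bland_altman")
}

#' @exportS3Method base::print
print.eit_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Nonparametric Bland-Altman (n=%d): median %.4f, RPC = 1.45 x IQR = %.4f, limits [%.4f, %.4f], %.1f%% within\n",
    x$n, x$diff_median, x$rpc, x$limits[1], x$limits[2], x$pct_within))
  invisible(x)
}

#' Method-comparison summary
#'
#' The full comparison record for two paired measurement series: sample
#' size, OLS regression of `y` on `x` (slope, intercept), Pearson r,
#' Spearman rho, RMSE, and the nonparametric Bland-Altman block
#' (difference SD, difference median, RPC, skewness, kurtosis).
#'
#' @param x Reference series.
#' @param y Test series.
#' @return An object of class `eit_comparison` (also a named list ready for
#'   CSV serialization via [as.data.frame()]).
#' @export
comparison_summary <- function(x, y) {
  ba <- bland_altman_np(x, y)
  fit <- stats::lm(y ~ x)
  structure(list(n = length(x),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(x, y),
                 spearman_rho = stats::cor(x, y, method = "spearman"),
                 rmse = sqrt(mean((y - x)^2)),
                 diff_sd = ba$diff_sd,
                 diff_median = ba$diff_median,
                 rpc = ba$rpc,
                 skewness = ba$skewness,
                 kurtosis = ba$kurtosis),
            class = c("eit_comparison", "list"))
}

#' @export
as.data.frame.eit_comparison <- function(x, ...) {
  data.frame(statistic = names(unclass(x)),
             value = unlist(unclass(x), use.names = FALSE))
}

#' @exportS3Method base::print
print.eit_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Method comparison:\n")
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s %.4f\n", df$statistic[i], df$value[i]))
  }
  invisible(x)
}
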