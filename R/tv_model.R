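# Per-subject tidal-volume prediction from voltage breath amplitudes.

#' Per-breath inspiratory amplitudes
#'
#' One amplitude per breath: the signal value at a peak minus the value at
#' the immediately preceding valley (the inspiratory rise). Peaks with no
#' preceding valley are skipped and counted.
#'
#' @param signal Numeric vector.
#' @param annotation An `eit_breaths` on the same sampling grid.
#' @return Numeric vector of amplitudes with attributes `peak_index`
#'   (the peak of each emitted breath) and `skipped` (count of peaks without
#'   a preceding valley).
#' @export
breath_amplitudes <- function(signal, annotation) {
  stopifnot(inherits(annotation, "eit_breaths"))
  amps <- numeric(0); pk <- integer(0); skipped <- 0L
  for (p in annotation$peaks) {
    v <- annotation$valleys[annotation$valleys < p]
    if (!length(v)) { skipped <- skipped + 1L; next }
    v <- max(v)
    amps <- c(amps, signal[p] - signal[v])
    pk <- c(pk, p)
  }
  structure(amps, peak_index = pk, skipped = skipped)
}

#' Fit the per-subject tidal-volume regression
#'
#' Ordinary least squares of observed tidal volume on voltage amplitude with
#' the point (0, 0) appended as one extra observation — an anchor pulling
#' the line towards the origin without constraining it through it (fitted
#' intercepts stay nonzero in general). A strict through-origin fit is
#' available with `through_origin = TRUE`.
#'
#' @param amplitudes Per-breath voltage amplitudes (V).
#' @param volumes Per-breath observed tidal volumes (L).
#' @param through_origin Constrain the fit through (0, 0) instead of
#'   anchoring.
#' @return An object of class `eit_tv_model`: `intercept` (a, L), `slope`
#'   (b, L/V), `n_breaths`, `through_origin`.
#' @export
fit_tv <- function(amplitudes, volumes, through_origin = FALSE) {
  stopifnot(length(amplitudes) == length(volumes))
  if (length(amplitudes) < 2) stop("need at least 2 breaths to fit")
  if (stats::var(amplitudes) == 0) stop("zero variance in amplitudes; cannot fit")
  if (through_origin) {
    fit <- stats::lm(volumes ~ 0 + amplitudes)
    a <- 0; b <- unname(stats::coef(fit)[1])
  } else {
    x <- c(amplitudes, 0); y <- c(volumes, 0)
    fit <- stats::lm(y ~ x)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  }
  structure(list(intercept = a, slope = b, n_breaths = length(amplitudes),
                 through_origin = through_origin),
            class = "eit_tv_model")
}

#' @exportS3Method base::print
print.eit_tv_model <- function(x, ...) {
  cat(sprintf("TV regression: TV = %.4f + %.4f * amplitude (%d breaths%s)\n",
              x$intercept, x$slope, x$n_breaths,
              if (x$through_origin) ", through origin" else ", (0,0) anchored"))
  invisible(x)
}

#' Predict tidal volumes from a fitted model
#'
#' @param object An `eit_tv_model`.
#' @param amplitudes Voltage amplitudes (V).
#' @param ... Unused.
#' @return Predicted tidal volumes (L).
#' @export
predict.eit_tv_model <- function(object, amplitudes, ...) {
  object$intercept + object$slope * amplitudes
}

#' Evaluate a tidal-volume model
#'
#' Observed-vs-predicted metrics per subject: Pearson r, Spearman rho, RMSE
#' (L) and MAPE, defined as `mean(|obs - pred| / obs) * 100`.
#'
#' @param model An `eit_tv_model`.
#' @param amplitudes,volumes The subject's breaths.
#' @return List with `n`, `pearson_r`, `spearman_rho`, `rmse`, `mape_pct`,
#'   `mean_observed`, `mean_predicted`.
#' @export
evaluate_tv <- function(model, amplitudes, volumes) {
  stopifnot(length(amplitudes) == length(volumes))
  if (length(volumes) < 3) stop("correlation undefined with fewer than 3 breaths")
  pred <- predict(model, amplitudes)
  safe_cor <- function(...) {
    if (stats::sd(volumes) == 0 || stats::sd(pred) == 0) return(NA_real_)
    stats::cor(volumes, pred, ...)
  }
  list(n = length(volumes),
       pearson_r = safe_cor(),
       spearman_rho = safe_cor(method = "spearman"),
       rmse = sqrt(mean((volumes - pred)^2)),
       mape_pct = mean(abs(volumes - pred) / volumes) * 100,
       mean_observed = mean(volumes),
       mean_predicted = mean(pred))
}

#' Breath-count-weighted cohort means
#'
#' Weighted mean of per-subject correlation coefficients, weighted by each
#' subject's breath count.
#'
#' @param values Per-subject metric values (e.g. Pearson r).
#' @param n_breaths Per-subject breath counts.
#' @return Weighted mean.
#' @examples
#' weighted_cohort_mean(c(0.8, 0.9), c(40, 10))  # 0.82
#' @export
weighted_cohort_mean <- function(values, n_breaths) {
  stopifnot(length(values) == length(n_breaths), all(n_breaths > 0))
  sum(values * n_breaths) / sum(n_breaths)
}

#' Select the voltage measurement best correlated with volume
#'
#' For each measurement row of a peak-to-peak voltage matrix, upsamples to
#' the volume rate, aligns by cross-correlation, and returns the row with
#' the highest aligned Pearson correlation.
#'
#' @param vm An `eit_voltage_matrix`.
#' @param volume Volume series at `fs` (typically drift-removed).
#' @param fs Volume sample rate (Hz).
#' @param max_lag_s Alignment window (s).
#' @param volume_times Optional times (s) of the volume samples on the
#'   device clock; when given, each measurement row is interpolated onto
#'   this grid before alignment (the clipped-volume case).
#' @param interp Interpolation for the frame-rate rows: `"linear"`
#'   (plain factor-100 upsampling) or `"spline"` (natural cubic,
#'   sub-frame extremum timing).
#' @return List: `measurement` (row index), `r` (its aligned correlation),
#'   `r_all` (all rows' correlations), `aligned` (the best row's aligned,
#'   upsampled series), `lag_s`.
#' @export
select_best_measurement <- function(vm, volume, fs = 200, max_lag_s = 5,
                                    volume_times = NULL,
                                    interp = c("linear", "spline")) {
  stopifnot(inherits(vm, "eit_voltage_matrix"))
  interp <- match.arg(interp)
  n <- length(volume)
  r_all <- numeric(nrow(vm$pp))
  best <- NULL
  interp_row <- function(values, xout) {
    if (interp == "spline") {
      y <- stats::spline(vm$frame_times, values, xout = xout, method = "natural")$y
      # clamp extrapolated ends to the boundary values
      y[xout < vm$frame_times[1]] <- values[1]
      y[xout > vm$frame_times[length(vm$frame_times)]] <- values[length(values)]
      y
    } else {
      stats::approx(vm$frame_times, values, xout = xout, rule = 2)$y
    }
  }
  for (m in seq_len(nrow(vm$pp))) {
    if (is.null(volume_times)) {
      up <- upsample_voltage(vm$pp[m, ], vm$frame_rate, fs, times = vm$frame_times)
      tr <- truncate_pair(up$values, volume)
    } else {
      tr <- list(a = interp_row(vm$pp[m, ], volume_times), b = volume)
    }
    if (stats::sd(tr$a) == 0) { r_all[m] <- NA_real_; next }
    al <- align_by_xcorr(tr$a, tr$b, fs, max_lag_s)
    r_all[m] <- al$r_after
    if (is.null(best) || al$r_after > best$r) {
      best <- list(measurement = m, r = al$r_after, aligned = al$shifted,
                   lag_s = al$lag_s)
    }
  }
  if (is.null(best)) stop("no measurement with nonzero variance")
  c(best, list(r_all = r_all))
}
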