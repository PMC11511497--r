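# Flow calibration, integration to volume between breath-midpoint bounds,
# and removal of sub-0.1 Hz drift from the integrated signal.

#' Integration bounds from flow extrema
#'
#' The volume integral runs from the midpoint of the first valley/peak pair
#' to the midpoint of the last, so the integrated signal is not shifted
#' vertically: `p1 = floor((valley_1 + peak_1)/2)`,
#' `p2 = floor((valley_end + peak_end)/2)` (sample indices).
#'
#' @param valley_indices,peak_indices Integer sample indices of flow valleys
#'   and peaks; the first and last valley must precede the first and last
#'   peak respectively.
#' @return Integer vector `c(p1, p2)`.
#' @examples
#' integration_bounds(c(100, 900), c(300, 1100))  # 200 1000
#' @export
integration_bounds <- function(valley_indices, peak_indices) {
  v <- as.numeric(valley_indices); p <- as.numeric(peak_indices)
  if (!length(v) || !length(p)) stop("need at least one valley and one peak")
  if (v[1] >= p[1]) {
    stop("ordering violated: first valley (", v[1],
         ") must precede first peak (", p[1], ")")
  }
  if (v[length(v)] >= p[length(p)]) {
    stop("ordering violated: last valley (", v[length(v)],
         ") must precede last peak (", p[length(p)], ")")
  }
  p1 <- floor((v[1] + p[1]) / 2)
  p2 <- floor((v[length(v)] + p[length(p)]) / 2)
  if (p1 >= p2) {
    stop("degenerate bounds: p1 (", p1, ") >= p2 (", p2,
         "); at least two breaths are required")
  }
  c(p1 = as.integer(p1), p2 = as.integer(p2))
}

#' Integrate flow to volume
#'
#' Cumulative trapezoidal integral of the flow record between the bounds,
#' starting at zero volume at `p1`.
#'
#' @param flow Numeric flow samples (L/s) at rate `fs`.
#' @param p1,p2 Sample-index bounds (from [integration_bounds()]).
#' @param fs Sample rate (S/s).
#' @return An object of class `eit_volume`: `volume` (L, length
#'   `p2 - p1 + 1`), `index` (original sample indices), `fs`, `p1`, `p2`.
#' @export
integrate_volume <- function(flow, p1, p2, fs = 200) {
  n <- length(flow)
  if (p1 < 1 || p2 > n || p1 >= p2) {
    stop("bounds [", p1, ", ", p2, "] out of range for ", n, " samples")
  }
  f <- flow[p1:p2]
  vol <- c(0, cumsum((f[-1] + f[-length(f)]) / 2)) / fs
  structure(list(volume = vol, index = p1:p2, fs = fs,
                 p1 = as.integer(p1), p2 = as.integer(p2), drift_removed = FALSE),
            class = "eit_volume")
}

#' Remove sub-0.1 Hz drift from a volume record
#'
#' Flowmeter orientation changes put slow components (0-0.1 Hz) into the
#' flow; their integral accumulates and dominates the volume trace. A
#' zero-phase order-2 Butterworth high-pass at 0.1 Hz attenuates them while
#' leaving the breathing band (>= 0.15 Hz) essentially untouched.
#'
#' @param vol An `eit_volume` (or plain numeric vector with `fs` given).
#' @param fs Sample rate; taken from the record when available.
#' @param cutoff_hz High-pass cutoff (Hz).
#' @return Same class as the input, drift-filtered.
#' @export
remove_drift <- function(vol, fs = NULL, cutoff_hz = 0.1) {
  x <- if (inherits(vol, "eit_volume")) vol$volume else as.numeric(vol)
  fs <- if (inherits(vol, "eit_volume")) vol$fs else fs
  stopifnot(!is.null(fs))
  if (length(x) / fs <= 10) stop("record too short for drift removal (need > 10 s)")
  d <- butter_design(2L, cutoff_hz, fs, "high")
  y <- filtfilt2(d$b, d$a, x)
  if (inherits(vol, "eit_volume")) {
    vol$volume <- y
    vol$drift_removed <- TRUE
    vol
  } else y
}

#' Calibrate flow against a syringe
#'
#' Scales raw flowmeter output so that the mean integrated stroke volume of
#' a calibration-syringe maneuver equals the nominal syringe volume.
#'
#' @param raw_samples Uncalibrated flow samples.
#' @param syringe_strokes List of `c(start, end)` sample-index windows, one
#'   per stroke.
#' @param syringe_volume Nominal syringe volume (L).
#' @param fs Sample rate (S/s).
#' @return Scale factor to multiply raw samples by.
#' @export
calibrate_flow <- function(raw_samples, syringe_strokes, syringe_volume, fs = 200) {
  if (!length(syringe_strokes)) stop("no syringe strokes identified")
  stopifnot(syringe_volume > 0)
  vols <- vapply(syringe_strokes, function(w) {
    f <- raw_samples[w[1]:w[2]]
    abs(sum((f[-1] + f[-length(f)]) / 2) / fs)
  }, 0)
  m <- mean(vols)
  if (m <= 0 || !is.finite(m)) stop("stroke windows integrate to zero; cannot calibrate")
  syringe_volume / m
}
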