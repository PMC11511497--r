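# Breath detection on respiratory signals, voltage/volume alignment,
# instantaneous respiratory rate, and detection scoring.

# peak prominence: height above the higher of the two interval minima
# between the peak and the nearest higher peak (or signal end) on each side
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    l <- p
    while (l > 1 && x[l] <= h) l <- l - 1
    left_min <- min(x[l:p])
    r <- p
    n <- length(x)
    while (r < n && x[r] <= h) r <- r + 1
    right_min <- min(x[p:r])
    h - max(left_min, right_min)
  }, 0)
}

# plateau-tolerant strict local maxima: first sample of any run that is
# preceded by a rise and followed by a fall
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  cand
}

#' Detect breathing extrema
#'
#' Finds local maxima and minima of a respiratory signal, keeping extrema
#' whose prominence is at least `min_prominence_frac` of the signal range
#' and that are separated by at least `min_separation_s` (the lesser of two
#' close same-type extrema is dropped). Peaks and valleys are then forced to
#' alternate, again keeping the more extreme of any same-type run. Defaults
#' suit adult breathing at 6-60 breaths/min.
#'
#' @param signal Numeric vector.
#' @param fs Sample rate (Hz).
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   signal range.
#' @param min_separation_s Minimum separation between same-type extrema (s).
#' @return An object of class `eit_breaths`: `peaks`, `valleys` (sample
#'   indices, strictly increasing, alternating), `fs`, `peak_times`,
#'   `valley_times` (s). A flat signal yields empty annotations.
#' @export
detect_extrema <- function(signal, fs, min_prominence_frac = 0.2,
                           min_separation_s = 1) {
  stopifnot(all(is.finite(signal)), fs > 0)
  rng <- diff(range(signal))
  empty <- structure(list(peaks = integer(0), valleys = integer(0), fs = fs,
                          peak_times = numeric(0), valley_times = numeric(0)),
                     class = "eit_breaths")
  if (rng == 0) return(empty)
  thr <- min_prominence_frac * rng
  sep <- round(min_separation_s * fs)
  pick <- function(x) {
    cand <- local_maxima(x)
    if (!length(cand)) return(integer(0))
    prom <- peak_prominences(x, cand)
    cand <- cand[prom >= thr]
    # enforce separation, dropping the lesser of close neighbours
    repeat {
      if (length(cand) < 2) break
      gaps <- diff(cand)
      bad <- which(gaps < sep)
      if (!length(bad)) break
      i <- bad[1]
      drop <- if (x[cand[i]] >= x[cand[i + 1]]) i + 1 else i
      cand <- cand[-drop]
    }
    cand
  }
  peaks <- pick(signal)
  valleys <- pick(-signal)
  if (!length(peaks) || !length(valleys)) return(empty)
  # enforce alternation: in runs of same-type extrema keep the most extreme
  ev <- rbind(data.frame(i = peaks, type = 1), data.frame(i = valleys, type = -1))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  j <- 1
  while (j < nrow(ev)) {
    k <- which(keep)
    k <- k[k >= j]
    if (length(k) < 2) break
    a <- k[1]; b <- k[2]
    if (ev$type[a] == ev$type[b]) {
      va <- signal[ev$i[a]] * ev$type[a]
      vb <- signal[ev$i[b]] * ev$type[b]
      keep[if (va >= vb) b else a] <- FALSE
    } else j <- a + 1
  }
  ev <- ev[keep, ]
  peaks <- ev$i[ev$type == 1]
  valleys <- ev$i[ev$type == -1]
  structure(list(peaks = peaks, valleys = valleys, fs = fs,
                 peak_times = (peaks - 1) / fs,
                 valley_times = (valleys - 1) / fs),
            class = "eit_breaths")
}

#' @exportS3Method base::print
print.eit_breaths <- function(x, ...) {
  cat(sprintf("Breath annotation: %d peaks, %d valleys at %g Hz\n",
              length(x$peaks), length(x$valleys), x$fs))
  invisible(x)
}

#' Upsample a frame-rate series to the flowmeter rate
#'
#' Linear interpolation of a 2 Hz voltage (or pixel) series onto a 200 Hz
#' grid spanning the same duration; original samples are preserved at their
#' own instants.
#'
#' @param values Series sampled at `fs_in`.
#' @param fs_in Input rate (Hz).
#' @param fs_out Output rate (Hz).
#' @param times Optional sample times (s) of `values`; default
#'   `(seq_along(values) - 1) / fs_in`.
#' @return List with `time` (s) and `values` at `fs_out`.
#' @export
upsample_voltage <- function(values, fs_in = 2, fs_out = 200, times = NULL) {
  if (length(values) < 2) stop("need at least 2 frames to interpolate")
  if (is.null(times)) times <- (seq_along(values) - 1) / fs_in
  tout <- seq(times[1], times[length(times)], by = 1 / fs_out)
  list(time = tout, values = stats::approx(times, values, xout = tout)$y)
}

#' Align a voltage series to a volume series by cross-correlation
#'
#' Finds the lag within `max_lag_s` that maximizes the Pearson correlation
#' between the mean-removed series on their overlap, shifts the voltage
#' series accordingly (padding with edge values), and reports the
#' correlation before and after. Lag 0 is always a candidate, so the
#' reported `r_after >= r_before`.
#'
#' @param voltage,volume Equal-rate numeric series of equal length.
#' @param fs Common sample rate (Hz).
#' @param max_lag_s Lag search half-window (s).
#' @return List: `lag_s`, `shifted` (voltage moved by the lag), `r_before`,
#'   `r_after`.
#' @export
align_by_xcorr <- function(voltage, volume, fs = 200, max_lag_s = 5) {
  n <- length(voltage)
  stopifnot(n == length(volume))
  maxlag <- min(round(max_lag_s * fs), n - round(10 * fs))
  if (maxlag < 0 || n - maxlag < 10 * fs) {
    stop("insufficient overlap: need >= 10 s after the maximum shift")
  }
  r_at <- function(lag) {
    if (lag >= 0) { a <- voltage[1:(n - lag)]; b <- volume[(1 + lag):n] }
    else { a <- voltage[(1 - lag):n]; b <- volume[1:(n + lag)] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }
  # coarse-to-fine lag search (correlation varies slowly vs. one sample)
  stride <- max(1L, as.integer(fs) %/% 20L)
  coarse <- unique(c(seq(-maxlag, maxlag, by = stride), 0L, maxlag))
  rc <- vapply(coarse, r_at, 0)
  lag0 <- coarse[which.max(rc)]
  fine <- max(-maxlag, lag0 - stride):min(maxlag, lag0 + stride)
  rf <- vapply(fine, r_at, 0)
  best_lag <- fine[which.max(rf)]
  best_r <- max(rf)
  # shifted[t] = voltage[t - best_lag]: the voltage series moved onto the
  # volume clock (positive lag_s means the voltage lagged and is advanced)
  shifted <- if (best_lag >= 0) {
    c(rep(voltage[1], best_lag), voltage[1:(n - best_lag)])
  } else {
    c(voltage[(1 - best_lag):n], rep(voltage[n], -best_lag))
  }
  r_before <- if (stats::sd(voltage) > 0 && stats::sd(volume) > 0) {
    stats::cor(voltage, volume)
  } else 0
  list(lag_s = -best_lag / fs, shifted = shifted,
       r_before = r_before, r_after = if (is.finite(best_r)) best_r else 0)
}

#' Instantaneous respiratory rate
#'
#' A breath is the cycle from one peak to the next: durations are the
#' successive differences of the peak time vector (s), and rates their
#' reciprocal in breaths/min.
#'
#' @param annotation An `eit_breaths`.
#' @return List: `durations_s`, `rates_bpm`, `breath_times` (time of the
#'   opening peak of each breath, s).
#' @export
instantaneous_rate <- function(annotation) {
  stopifnot(inherits(annotation, "eit_breaths"))
  if (length(annotation$peaks) < 2) stop("need at least 2 peaks for a rate")
  d <- diff(annotation$peak_times)
  list(durations_s = d, rates_bpm = 60 / d,
       breath_times = annotation$peak_times[-length(annotation$peak_times)])
}

#' Truncate two sequences to their common length
#'
#' Keeps the leading `min(length(a), length(b))` elements of each.
#'
#' @param a,b Vectors.
#' @return List with truncated `a` and `b`.
#' @export
truncate_pair <- function(a, b) {
  n <- min(length(a), length(b))
  list(a = a[seq_len(n)], b = b[seq_len(n)])
}

#' Match detected breaths against a reference annotation
#'
#' Greedy nearest-peak matching: reference and test peak times are paired in
#' order of increasing time difference, each peak used at most once, pairs
#' beyond the tolerance left unmatched. Unmatched reference peaks are false
#' negatives; unmatched test peaks are false positives.
#'
#' @param ref,test `eit_breaths` annotations on a common clock.
#' @param tolerance_s Matching tolerance (s); default half the median
#'   reference breath duration.
#' @return An object of class `eit_match`: `TP`, `FP`, `FN`, `pairs`
#'   (matrix of matched ref/test indices), `tolerance_s`.
#' @export
match_breaths <- function(ref, test, tolerance_s = NULL) {
  stopifnot(inherits(ref, "eit_breaths"), inherits(test, "eit_breaths"))
  rt <- ref$peak_times; tt <- test$peak_times
  if (is.null(tolerance_s)) {
    tolerance_s <- if (length(rt) >= 2) stats::median(diff(rt)) / 2 else Inf
  }
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("ref", "test")))
  if (length(rt) && length(tt)) {
    dmat <- abs(outer(rt, tt, `-`))
    used_r <- logical(length(rt)); used_t <- logical(length(tt))
    ord <- order(dmat)
    for (k in ord) {
      if (dmat[k] > tolerance_s) break
      i <- (k - 1) %% length(rt) + 1
      j <- (k - 1) %/% length(rt) + 1
      if (used_r[i] || used_t[j]) next
      used_r[i] <- used_t[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  tp <- nrow(pairs)
  structure(list(TP = tp, FP = length(tt) - tp, FN = length(rt) - tp,
                 pairs = pairs, tolerance_s = tolerance_s),
            class = "eit_match")
}

#' Breath-detection metrics
#'
#' Sensitivity `Se = TP/(TP+FN)`, precision `Pr = TP/(TP+FP)` and their
#' harmonic mean `F1 = 2 Se Pr / (Se + Pr)`.
#'
#' @param m An `eit_match`, or a list with `TP`, `FP`, `FN`.
#' @return List with `Se`, `Pr`, `F1`.
#' @examples
#' detection_metrics(list(TP = 902, FP = 2, FN = 0))
#' @export
detection_metrics <- function(m) {
  tp <- m$TP; fp <- m$FP; fn <- m$FN
  if (tp + fn == 0 || tp + fp == 0) {
    stop("undefined metric: TP+FN and TP+FP must both be positive")
  }
  se <- tp / (tp + fn)
  pr <- tp / (tp + fp)
  list(Se = se, Pr = pr,
       F1 = if (se + pr > 0) 2 * se * pr / (se + pr) else 0)
}

#' Zero-phase triangular smoothing
#'
#' Symmetric triangular moving average (width an odd number of samples),
#' edges handled by replicating the end values. Used to steady peak timing
#' on frame-rate series before interpolation.
#'
#' @param x Numeric vector.
#' @param width Odd window width in samples.
#' @return Smoothed vector, same length.
#' @export
smooth_triangular <- function(x, width = 3L) {
  width <- as.integer(width)
  stopifnot(width >= 1L, width %% 2L == 1L)
  if (width == 1L || length(x) < width) return(x)
  h <- width %/% 2L
  w <- (h + 1L) - abs(seq(-h, h))
  w <- w / sum(w)
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  stats::filter(xp, w, sides = 2)[(h + 1L):(h + length(x))]
}
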