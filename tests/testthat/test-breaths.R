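test_that("detect_extrema finds sinusoid extrema and handles flat signals", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ann <- detect_extrema(sin(2 * pi * t / 4), fs, 0.2, 1)
  expect_equal(length(ann$peaks), 15L)
  expect_equal(length(ann$valleys), 15L)
  # peak times at T/4 + k T
  expect_equal(ann$peak_times, 1 + 4 * (0:14), tolerance = 1 / fs)
  # alternation invariant
  ev <- sort(c(ann$peaks, ann$valleys))
  types <- ifelse(ev %in% ann$peaks, 1, -1)
  expect_true(all(diff(types) != 0))
  # flat signal: empty annotation, not an error
  flat <- detect_extrema(rep(1, 1000), fs)
  expect_equal(length(flat$peaks), 0L)
  # small wiggles below the prominence threshold are ignored
  ann2 <- detect_extrema(sin(2 * pi * t / 4) + 0.05 * sin(2 * pi * t * 3), fs, 0.2, 1)
  expect_equal(length(ann2$peaks), 15L)
})

test_that("detect_extrema recovers the generated breath count under jitter", {
  br <- breath_trace(duration = 120, period = 4, tidal = 0.5,
                     period_jitter = 0.08, tidal_jitter = 0.2,
                     maneuvers = NULL, seed = 9)
  ann <- detect_extrema(br$volume, br$fs, 0.2, 1)
  expect_equal(length(ann$peaks), length(br$peaks))
  expect_lt(max(abs(ann$peak_times - br$peaks)), 0.1)
})

test_that("upsample_voltage interpolates linearly and preserves properties", {
  up <- upsample_voltage(c(0, 1), fs_in = 2, fs_out = 200)
  expect_equal(up$values[up$time == 0.25], 0.5)
  expect_equal(length(up$values), 101L)
  expect_equal(upsample_voltage(rep(3, 5), 2, 200)$values, rep(3, 401))
  mono <- upsample_voltage(c(1, 2, 5, 9), 2, 200)$values
  expect_true(all(diff(mono) >= 0))
  expect_error(upsample_voltage(1), "at least 2")
})

test_that("cross-correlation alignment finds known lags", {
  fs <- 200
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * t / 5) + 0.3 * sin(2 * pi * t / 11)
  lagn <- round(1.5 * fs)
  delayed <- c(rep(x[1], lagn), x[1:(length(x) - lagn)])
  al <- align_by_xcorr(delayed, x, fs, max_lag_s = 5)
  expect_equal(al$lag_s, 1.5, tolerance = 2 / fs)
  expect_gt(al$r_after, 0.999)
  expect_gte(al$r_after, al$r_before)
  expect_gt(cor(al$shifted, x), 0.99)
  # uncorrelated noise stays near zero
  set.seed(1)
  a <- rnorm(4001); b <- rnorm(4001)
  expect_lt(abs(align_by_xcorr(a, b, fs, 2)$r_after), 0.2)
  expect_error(align_by_xcorr(a[1:100], b[1:100], fs, 5), "overlap")
})

test_that("instantaneous rate converts peak times to durations and bpm", {
  ann <- structure(list(peaks = c(401, 1001, 1801), valleys = c(1, 700, 1400),
                        fs = 200, peak_times = c(2, 5, 9),
                        valley_times = c(0, 3.495, 6.995)),
                   class = "eit_breaths")
  ir <- instantaneous_rate(ann)
  expect_equal(ir$durations_s, c(3, 4))
  expect_equal(ir$rates_bpm, c(20, 15))
  ann$peaks <- ann$peaks[1]; ann$peak_times <- ann$peak_times[1]
  expect_error(instantaneous_rate(ann), "2 peaks")
})

test_that("truncate_pair keeps leading elements of the shorter length", {
  tp <- truncate_pair(1:10, 1:8)
  expect_equal(lengths(tp), c(a = 8L, b = 8L))
  expect_equal(tp$a, 1:8)
  tp2 <- truncate_pair(1:5, 11:15)
  expect_equal(tp2$a, 1:5)
  expect_equal(tp2$b, 11:15)
  tp3 <- truncate_pair(1:5, numeric(0))
  expect_equal(lengths(tp3), c(a = 0L, b = 0L))
})

test_that("breath matching counts TP/FP/FN with the invariants", {
  mk <- function(pt) structure(list(peaks = round(pt * 200) + 1, valleys = integer(0),
                                    fs = 200, peak_times = pt, valley_times = numeric(0)),
                               class = "eit_breaths")
  ref <- mk(c(2, 6, 10, 14))
  expect_equal(unclass(match_breaths(ref, ref))[c("TP", "FP", "FN")],
               list(TP = 4L, FP = 0L, FN = 0L))
  m_fn <- match_breaths(ref, mk(c(2, 10, 14)))
  expect_equal(m_fn$FN, 1L); expect_equal(m_fn$FP, 0L)
  m_fp <- match_breaths(ref, mk(c(2, 4.1, 6, 10, 14)))
  expect_equal(m_fp$FP, 1L); expect_equal(m_fp$FN, 0L)
  # MatchResult invariants
  for (m in list(m_fn, m_fp)) {
    expect_equal(m$TP + m$FN, 4L)
  }
  expect_equal(m_fp$TP + m_fp$FP, 5L)
  # tolerance respected: a far-off peak is not matched
  m_far <- match_breaths(ref, mk(c(2, 6, 10, 30)), tolerance_s = 1)
  expect_equal(m_far$TP, 3L)
})

test_that("detection metrics reproduce the published confusion-matrix values", {
  # voltage signals: TP 902, FP 2, FN 0
  mv <- detection_metrics(list(TP = 902, FP = 2, FN = 0))
  expect_equal(mv$Se, 1)
  expect_equal(round(mv$Pr, 4), 0.9978)
  expect_equal(round(mv$F1, 4), 0.9989)
  # pixel values: TP 895, FP 5, FN 7
  mp <- detection_metrics(list(TP = 895, FP = 5, FN = 7))
  expect_equal(round(mp$Se, 4), 0.9922)
  expect_equal(round(mp$Pr, 4), 0.9944)
  # perfect detection
  m1 <- detection_metrics(list(TP = 10, FP = 0, FN = 0))
  expect_equal(unlist(m1), c(Se = 1, Pr = 1, F1 = 1))
  expect_error(detection_metrics(list(TP = 0, FP = 0, FN = 0)), "undefined")
})

test_that("triangular smoothing preserves means and flattens jitter", {
  x <- sin(seq(0, 6 * pi, length.out = 200))
  set.seed(2)
  noisy <- x + rnorm(200, sd = 0.1)
  sm <- smooth_triangular(noisy, 5L)
  expect_equal(length(sm), 200L)
  expect_lt(sd(sm - x), sd(noisy - x))
  expect_equal(smooth_triangular(rep(2, 50), 3L), rep(2, 50))
  expect_error(smooth_triangular(x, 4L), "%%|odd")
})
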