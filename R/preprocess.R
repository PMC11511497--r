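# Raw-stream decoding and peak-to-peak demodulation:
# bytes -> 64 x 208 x F voltage cube -> 208 x F peak-to-peak matrix.

#' Decode a raw device stream
#'
#' Scans the byte stream for the first offset at which a full frame of valid
#' words decodes: the 4-bit slot fields must step through the periodic
#' measurement-slot sequence (0..12 for each of the 16 stimulation patterns,
#' 64 samples per measurement) starting at slot 0. Device streams carry
#' invalid data at the head (the acquisition loop is already running when
#' logging starts), so everything before the sync point is discarded and its
#' length reported. A trailing partial measurement is dropped with a count.
#'
#' @param bytes Raw vector.
#' @param protocol An `eit_protocol`.
#' @param n_samples Samples per measurement burst.
#' @return List: `codes` (integer vector of ADC codes, a multiple of
#'   `n_samples`), `slots` (per-measurement slot indices),
#'   `discarded_prefix` (bytes), `dropped_tail_samples`.
#' @export
decode_stream <- function(bytes, protocol = build_protocol(16L), n_samples = 64L) {
  stopifnot(is.raw(bytes))
  ns <- as.integer(n_samples)
  nm <- protocol$n_measurements
  frame_words <- nm * ns
  slots_frame <- rep(protocol_table(protocol)$slot, each = ns)
  if (length(bytes) < 2L * frame_words) {
    stop("decode error: stream shorter than one frame after sync")
  }
  v <- as.integer(bytes)
  max_off <- length(bytes) - 2L * frame_words
  sync <- NA_integer_
  for (off in 0:max_off) {
    # cheap pre-check keeps the scan fast: a frame must open with slot 0
    if (bitwShiftR(v[off + 1L], 4L) != 0L) next
    hi <- v[off + seq(1L, 2L * frame_words, by = 2L)]
    if (identical(bitwShiftR(hi, 4L), slots_frame)) { sync <- off; break }
  }
  if (is.na(sync)) stop("decode error: no valid frame synchronization found")
  w <- unpack_words(bytes[(sync + 1L):length(bytes)])
  n_meas <- length(w$codes) %/% ns
  dropped <- length(w$codes) - n_meas * ns
  keep <- seq_len(n_meas * ns)
  slots <- matrix(w$slots[keep], nrow = ns)[1L, ]
  list(codes = w$codes[keep], slots = slots,
       discarded_prefix = sync, dropped_tail_samples = dropped)
}

#' Reshape decoded samples into the voltage cube
#'
#' Arranges ADC codes into a `n_samples x n_measurements x F` array of
#' ADC-input voltages (code times converter resolution). The trailing
#' remainder beyond a whole number of frames is clipped.
#'
#' @param codes Integer vector of ADC codes (from [decode_stream()]).
#' @param protocol An `eit_protocol`.
#' @param chain_cfg An `eit_chain_config`; sets ADC resolution and frame rate.
#' @param n_samples Samples per burst.
#' @return An object of class `eit_voltage_cube`: `volts`
#'   (64 x 208 x F array), `frame_times` (s, frame midpoints at the frame
#'   rate), `clipped_samples` (count beyond whole frames).
#' @export
reshape_frames <- function(codes, protocol = build_protocol(16L),
                           chain_cfg = signal_chain_config(), n_samples = 64L) {
  ns <- as.integer(n_samples)
  nm <- protocol$n_measurements
  frame_len <- ns * nm
  F <- length(codes) %/% frame_len
  if (F < 1L) stop("fewer than one frame of samples (", length(codes), " < ", frame_len, ")")
  clipped <- length(codes) - F * frame_len
  res <- signal_chain_constants(chain_cfg)$adc_res_v
  cube <- array(codes[seq_len(F * frame_len)] * res, dim = c(ns, nm, F))
  structure(list(volts = cube,
                 frame_times = (seq_len(F) - 0.5) / chain_cfg$frame_rate,
                 frame_rate = chain_cfg$frame_rate,
                 clipped_samples = clipped),
            class = "eit_voltage_cube")
}

#' Band-pass filter a measurement burst
#'
#' Zero-phase order-4 Butterworth band-pass around the 50 kHz carrier
#' (40-60 kHz by default), removing the DC offset and out-of-band
#' interference while leaving the carrier amplitude intact.
#'
#' @param samples Numeric vector (one burst) or matrix with one burst per
#'   column.
#' @param fs Burst sample rate (Hz).
#' @param band Pass band (Hz).
#' @return Filtered data, same shape.
#' @export
bandpass_measurement <- function(samples, fs = 350e3, band = c(40e3, 60e3)) {
  d <- butter_design(2L, band, fs, "band")
  filtfilt2(d$b, d$a, samples)
}

#' Demodulate a voltage cube to the peak-to-peak matrix
#'
#' Estimates the carrier peak-to-peak amplitude of every measurement burst.
#' Two estimators are available:
#'
#' * `"sine"` (default): least-squares fit of a 50 kHz sine/cosine pair plus
#'   a DC term to the raw burst; peak-to-peak is twice the fitted amplitude.
#'   With 7 samples per carrier cycle the sample grid rarely lands on the
#'   true extrema, so the sample max-min underestimates the amplitude by a
#'   carrier-phase-dependent 0-5%; that jitter aliases into the respiration
#'   band and dominates all other noise at realistic amplitudes. The fit is
#'   phase-insensitive and rejects DC and out-of-band interference.
#' * `"minmax"`: band-pass filter around the carrier, then max minus min of
#'   the burst with `trim` samples excluded at each end (the estimator the
#'   device's original off-line processing used).
#'
#' Voltages are reported at the ADC input (after amplification); divide by
#' the INA gain for physical units at the electrodes.
#'
#' @param cube An `eit_voltage_cube`.
#' @param method `"sine"` or `"minmax"`.
#' @param band Carrier pass band (Hz), used by `"minmax"`.
#' @param fs Burst sample rate (Hz).
#' @param carrier_hz Carrier frequency for the `"sine"` fit.
#' @param trim Samples excluded at each burst end (`"minmax"`).
#' @param gain Divide the result by this gain (default 1: ADC-input volts).
#' @return An object of class `eit_voltage_matrix`: `pp` (208 x F matrix,
#'   V), `frame_times`, `frame_rate`.
#' @export
peak_to_peak <- function(cube, method = c("sine", "minmax"),
                         band = c(40e3, 60e3), fs = 350e3,
                         carrier_hz = 50e3, trim = 8L, gain = 1) {
  stopifnot(inherits(cube, "eit_voltage_cube"))
  method <- match.arg(method)
  d <- dim(cube$volts)
  flat <- matrix(cube$volts, nrow = d[1])
  if (method == "sine") {
    t <- (seq_len(d[1]) - 1) / fs
    B <- cbind(sin(2 * pi * carrier_hz * t), cos(2 * pi * carrier_hz * t), 1)
    coefs <- solve(crossprod(B), crossprod(B, flat))
    ppv <- 2 * sqrt(coefs[1, ]^2 + coefs[2, ]^2)
  } else {
    des <- butter_design(2L, band, fs, "band")
    filt <- filtfilt2(des$b, des$a, flat)
    core <- filt[(trim + 1L):(d[1] - trim), , drop = FALSE]
    ppv <- apply(core, 2L, max) - apply(core, 2L, min)
  }
  pp <- matrix(ppv, nrow = d[2]) / gain
  structure(list(pp = pp, frame_times = cube$frame_times,
                 frame_rate = cube$frame_rate),
            class = "eit_voltage_matrix")
}

#' @exportS3Method base::print
print.eit_voltage_matrix <- function(x, ...) {
  cat(sprintf("Peak-to-peak voltage matrix: %d measurements x %d frames at %g fps\n",
              nrow(x$pp), ncol(x$pp), x$frame_rate))
  invisible(x)
}

#' Voltage profile of one frame
#'
#' Returns the 208 peak-to-peak voltages of a frame. The profile has the
#' characteristic U-shape within each 13-measurement stimulation block:
#' amplitudes fall towards the measurement pair diametrically opposite the
#' drive pair. The per-block minima positions are attached for inspection.
#'
#' @param vm An `eit_voltage_matrix`.
#' @param frame Frame index.
#' @param block Measurements per stimulation pattern (13 for 16 electrodes).
#' @return Numeric vector of length `nrow(vm$pp)` with attribute
#'   `block_minima` (position of the minimum within each block).
#' @export
voltage_profile <- function(vm, frame, block = 13L) {
  stopifnot(inherits(vm, "eit_voltage_matrix"))
  if (frame < 1L || frame > ncol(vm$pp)) {
    stop("frame index ", frame, " out of range 1..", ncol(vm$pp))
  }
  prof <- vm$pp[, frame]
  nb <- length(prof) %/% block
  mins <- vapply(seq_len(nb), function(j) {
    which.min(prof[(j - 1L) * block + seq_len(block)])
  }, 0L)
  attr(prof, "block_minima") <- mins
  prof
}

# full decode -> demodulate convenience used by the CLI
demodulate_stream <- function(bytes, protocol = build_protocol(16L),
                              chain_cfg = signal_chain_config(), trim = 8L) {
  dec <- decode_stream(bytes, protocol, chain_cfg$n_samples)
  cube <- reshape_frames(dec$codes, protocol, chain_cfg, chain_cfg$n_samples)
  vm <- peak_to_peak(cube, fs = chain_cfg$sample_rate, trim = trim)
  list(decode = dec, cube = cube, voltage = vm)
}
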