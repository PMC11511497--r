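# Analog-chain emulator: measurement bursts, raw-stream packing, and the
# matching flowmeter channel.

#' Signal-chain configuration
#'
#' Component values and timing of the acquisition chain: a 50 kHz sinusoidal
#' drive of 1 mA RMS, instrumentation-amplifier gain set by a split gain
#' resistor, passive input high-pass filters, and a 12-bit 5 V ADC sampling
#' 64-sample bursts at 350 kS/s with a 2.5 V output offset centering the
#' amplified signal in the converter range.
#'
#' @param carrier_hz Drive frequency (Hz).
#' @param current_rms Drive current (A RMS).
#' @param v_ref DAC reference/offset voltage (V).
#' @param atten Control-signal attenuation of the differential circuit.
#' @param r_gain Total INA gain resistance (ohm); gain = 1 + 50e3 / r_gain.
#' @param r_filter,c_filter Input high-pass components (ohm, farad).
#' @param adc_range,adc_bits ADC reference voltage (V) and resolution (bits).
#' @param offset Amplifier output offset (V).
#' @param sample_rate ADC burst sample rate (S/s).
#' @param n_samples Samples per burst.
#' @param settle_s Multiplexer settling time (s), timing bookkeeping only.
#' @param frame_rate Frames per second.
#' @param noise_rms Additive noise at the ADC input (V RMS).
#' @return An object of class `eit_chain_config`.
#' @export
signal_chain_config <- function(carrier_hz = 50e3, current_rms = 1e-3,
                                v_ref = 1.65, atten = 220 / 5000,
                                r_gain = 500, r_filter = 1e3, c_filter = 1e-6,
                                adc_range = 5, adc_bits = 12L, offset = 2.5,
                                sample_rate = 350e3, n_samples = 64L,
                                settle_s = 2e-3, frame_rate = 2,
                                noise_rms = 0) {
  cfg <- list(carrier_hz = carrier_hz, current_rms = current_rms, v_ref = v_ref,
              atten = atten, r_gain = r_gain, r_filter = r_filter,
              c_filter = c_filter, adc_range = adc_range, adc_bits = as.integer(adc_bits),
              offset = offset, sample_rate = sample_rate, n_samples = as.integer(n_samples),
              settle_s = settle_s, frame_rate = frame_rate, noise_rms = noise_rms)
  stopifnot(all(vapply(cfg[c("carrier_hz", "current_rms", "v_ref", "r_gain",
                             "r_filter", "c_filter", "adc_range", "sample_rate",
                             "frame_rate")], function(v) v > 0, TRUE)),
            cfg$noise_rms >= 0, cfg$n_samples >= 2L)
  structure(cfg, class = "eit_chain_config")
}

#' Derived constants of the signal chain
#'
#' Evaluates the analytic constants of the analog front end from component
#' values: the INA gain `1 + 50k/R_G`, the input high-pass cutoff
#' `1 / (2 pi sqrt(R1 C1 R2 C2))`, the ADC resolution `range / 2^bits`, and
#' the control-signal amplitude `v_ref * atten`.
#'
#' @param cfg An `eit_chain_config`.
#' @return List with `gain`, `cutoff_hz`, `adc_res_v` (V/bit),
#'   `control_amp_v` (V peak).
#' @examples
#' c(signal_chain_constants(signal_chain_config())$gain)  # 101
#' @export
signal_chain_constants <- function(cfg = signal_chain_config()) {
  stopifnot(inherits(cfg, "eit_chain_config"))
  list(gain = 1 + 50e3 / cfg$r_gain,
       cutoff_hz = 1 / (2 * pi * sqrt((cfg$r_filter * cfg$c_filter)^2)),
       adc_res_v = cfg$adc_range / 2^cfg$adc_bits,
       control_amp_v = cfg$v_ref * cfg$atten)
}

#' Synthesize one ADC measurement burst
#'
#' Models the digitization of one differential measurement: a carrier
#' sinusoid of the given amplitude, amplified and offset, with optional
#' additive noise, sampled and quantized by the ADC. The carrier phase is
#' random (or given): the free-running waveform generator gives no cycle
#' marker, so measurements are non-phase-sensitive.
#'
#' @param v_amp Differential amplitude at the amplifier input (V peak).
#' @param cfg An `eit_chain_config`.
#' @param phase Carrier phase (rad); `NULL` draws one uniformly.
#' @param rng Optional RNG (from the internal seeded generator).
#' @return List with `codes` (integer ADC codes) and `clipped` (TRUE if any
#'   sample hit the converter rails; such samples are pinned, not wrapped).
#' @export
synth_burst <- function(v_amp, cfg = signal_chain_config(), phase = NULL, rng = NULL) {
  cst <- signal_chain_constants(cfg)
  if (is.null(phase)) {
    phase <- if (is.null(rng)) stats::runif(1, 0, 2 * pi) else rng$unif(1, 0, 2 * pi)
  }
  t <- (seq_len(cfg$n_samples) - 1) / cfg$sample_rate
  v <- cfg$offset + cst$gain * v_amp * sin(2 * pi * cfg$carrier_hz * t + phase)
  if (cfg$noise_rms > 0) {
    v <- v + cfg$noise_rms * (if (is.null(rng)) stats::rnorm(length(v)) else rng$norm(length(v)))
  }
  code <- round(v / cst$adc_res_v)
  clipped <- any(code < 0 | code > 2^cfg$adc_bits - 1)
  list(codes = as.integer(pmin(pmax(code, 0), 2^cfg$adc_bits - 1)), clipped = clipped)
}

#' Flowmeter channel configuration
#'
#' Acquisition settings of the pneumotach channel: 200 S/s sampling, a
#' second-order 66.5 Hz low-pass with quality factor 0.5, zero flow
#' compensation, plus a slow sinusoidal drift term (sensor orientation
#' changes concentrate below 0.1 Hz) and optional white noise.
#'
#' @param fs Sample rate (S/s).
#' @param lowpass_hz,lowpass_q Hardware low-pass parameters.
#' @param gain Hardware gain (metadata only; traces are in L/s).
#' @param compensation Additive flow offset (L/s).
#' @param drift_amp Drift amplitude (L/s).
#' @param drift_hz Drift frequency (Hz), must be < 0.1.
#' @param noise_rms White noise (L/s RMS).
#' @return An object of class `eit_flow_config`.
#' @export
flowmeter_config <- function(fs = 200, lowpass_hz = 66.5, lowpass_q = 0.5,
                             gain = 5000, compensation = 0,
                             drift_amp = 0.05, drift_hz = 0.04, noise_rms = 0) {
  stopifnot(fs > 0, lowpass_hz > 0, lowpass_hz < fs / 2, drift_hz >= 0,
            drift_hz < 0.1, drift_amp >= 0, noise_rms >= 0)
  structure(list(fs = fs, lowpass_hz = lowpass_hz, lowpass_q = lowpass_q,
                 gain = gain, compensation = compensation, drift_amp = drift_amp,
                 drift_hz = drift_hz, noise_rms = noise_rms),
            class = "eit_flow_config")
}

# simulate the flowmeter output for a breath trace
simulate_flow <- function(breath, cfg = flowmeter_config(), rng = NULL) {
  stopifnot(inherits(breath, "eit_breath_trace"), breath$fs == cfg$fs)
  f <- breath$flow + cfg$compensation
  if (cfg$drift_amp > 0) {
    ph <- if (is.null(rng)) 0 else rng$unif(1, 0, 2 * pi)
    f <- f + cfg$drift_amp * sin(2 * pi * cfg$drift_hz * breath$time + ph)
  }
  if (cfg$noise_rms > 0) {
    f <- f + cfg$noise_rms * (if (is.null(rng)) stats::rnorm(length(f)) else rng$norm(length(f)))
  }
  lp <- biquad_lowpass(cfg$lowpass_hz, cfg$lowpass_q, cfg$fs)
  data.frame(time_s = breath$time, flow_L_per_s = iir_filter(lp$b, lp$a, f))
}

#' Simulate a full device recording
#'
#' Runs the complete forward chain: at each frame midpoint the phantom's lung
#' conductivity is set from the breathing volume, all 208 differential
#' voltages are solved on the mesh, each is digitized as a 64-sample carrier
#' burst with a random phase and packed into the device byte dialect;
#' the matching flowmeter trace is generated at 200 S/s. Conductivity is
#' frozen within a frame (breathing is far slower than the 2 fps frame
#' time); the multiplexer settling time enters only the timing budget.
#'
#' @param phantom An `eit_phantom`.
#' @param breath An `eit_breath_trace`.
#' @param protocol An `eit_protocol`.
#' @param chain_cfg An `eit_chain_config`.
#' @param flow_cfg An `eit_flow_config`.
#' @param mesh An `eit_mesh`; default a medium-density disk.
#' @param seed Integer seed; identical seed gives a byte-identical stream.
#' @return An object of class `eit_recording`: `raw` (raw byte vector),
#'   `flow` (data.frame `time_s`, `flow_L_per_s`), and `truth` with per-frame
#'   times/volumes, true signed voltages (208 x F), breath annotations of the
#'   generator, clipped-sample count, and all configuration objects.
#' @export
simulate_recording <- function(phantom, breath, protocol = build_protocol(16L),
                               chain_cfg = signal_chain_config(),
                               flow_cfg = flowmeter_config(),
                               mesh = build_mesh(6L, protocol$n_electrodes, 32L),
                               seed = 1L) {
  stopifnot(inherits(phantom, "eit_phantom"), inherits(breath, "eit_breath_trace"))
  F <- floor(breath$duration * chain_cfg$frame_rate)
  if (F < 2L) stop("recording too short: need at least 2 frames")
  # reject configurations that go non-conductive anywhere in the excursion
  vmax <- max(breath$volume)
  if (phantom$sigma_lung + phantom$slope * vmax <= 0) {
    stop("lung conductivity reaches zero within the breathing excursion")
  }
  rng <- local_rng(seed)
  cst <- signal_chain_constants(chain_cfg)
  tab <- protocol_table(protocol)
  nm <- protocol$n_measurements
  ns <- chain_cfg$n_samples
  frame_t <- (seq_len(F) - 0.5) / chain_cfg$frame_rate
  vol_mid <- stats::approx(breath$time, breath$volume, xout = frame_t, rule = 2)$y

  tgrid <- (seq_len(ns) - 1) / chain_cfg$sample_rate
  slots_frame <- rep(tab$slot, each = ns)
  raw <- vector("list", F)
  vtruth <- matrix(NA_real_, nm, F)
  clipped <- 0L
  for (f in seq_len(F)) {
    # sheet conductance: 2D solve of a slab of the phantom's thickness
    sigma <- phantom_conductivity(phantom, mesh, vol_mid[f]) * phantom$thickness
    v <- forward_solve_all(mesh, sigma, protocol, current = chain_cfg$current_rms)
    vtruth[, f] <- v
    amp <- sqrt(2) * v  # RMS solution -> sinusoid peak amplitude
    phase <- rng$unif(nm, 0, 2 * pi)
    # 64 x 208 matrix of ADC-input voltages
    arg <- outer(2 * pi * chain_cfg$carrier_hz * tgrid, phase, `+`)
    S <- chain_cfg$offset + sin(arg) * rep(cst$gain * amp, each = ns)
    if (chain_cfg$noise_rms > 0) S <- S + chain_cfg$noise_rms * rng$norm(length(S))
    code <- round(S / cst$adc_res_v)
    clipped <- clipped + sum(code < 0 | code > 2^chain_cfg$adc_bits - 1)
    code <- pmin(pmax(code, 0), 2^chain_cfg$adc_bits - 1)
    raw[[f]] <- pack_words(slots_frame, as.integer(code))
  }
  flow <- simulate_flow(breath, flow_cfg, rng)
  structure(list(
    raw = do.call(c, raw),
    flow = flow,
    truth = list(frame_times = frame_t, frame_volumes = vol_mid,
                 voltages = vtruth, breath = breath, clipped_samples = clipped,
                 n_frames = F, seed = seed, phantom = phantom,
                 chain_cfg = chain_cfg, flow_cfg = flow_cfg, mesh = mesh,
                 protocol = protocol)),
    class = "eit_recording")
}

#' @exportS3Method base::print
print.eit_recording <- function(x, ...) {
  cat(sprintf("EIT recording: %d frames, %d raw bytes, %d flow samples, %d clipped samples\n",
              x$truth$n_frames, length(x$raw), nrow(x$flow), x$truth$clipped_samples))
  invisible(x)
}
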