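test_that("signal-chain constants reproduce the published component math", {
  cst <- signal_chain_constants(signal_chain_config())
  expect_equal(cst$gain, 101)                              # 1 + 50k / (2 x 250)
  expect_equal(cst$cutoff_hz, 159.1549, tolerance = 1e-4)  # 1/(2 pi RC), R=1k C=1uF
  expect_equal(cst$adc_res_v * 1000, 1.2207, tolerance = 1e-4)  # 5 V / 2^12
  expect_equal(cst$control_amp_v, 1.65 * 220 / 5000)       # 0.0726 V peak
})

test_that("synth_burst digitizes the offset carrier correctly", {
  cfg <- signal_chain_config()
  cst <- signal_chain_constants(cfg)
  # zero amplitude, zero noise: every code equals the code of 2.5 V
  b0 <- synth_burst(0, cfg, phase = 1.1)
  expect_true(all(b0$codes == round(2.5 / cst$adc_res_v)))
  expect_false(b0$clipped)
  # known amplitude: LS-demodulated pk-pk within 2 quantization steps
  for (A in c(2e-4, 2e-3)) {
    for (ph in c(0, 1, 2.5)) {
      b <- synth_burst(A, cfg, phase = ph)
      v <- b$codes * cst$adc_res_v
      t <- (0:63) / cfg$sample_rate
      B <- cbind(sin(2 * pi * 50e3 * t), cos(2 * pi * 50e3 * t), 1)
      ab <- solve(crossprod(B), crossprod(B, v))
      pp <- 2 * sqrt(sum(ab[1:2]^2))
      expect_lt(abs(pp - 2 * cst$gain * A), 2 * cst$adc_res_v)
    }
  }
  # overdrive clips and is flagged, codes pinned at the rails
  bc <- synth_burst(0.05, cfg, phase = 0.3)  # 101 x 0.05 = 5 V swing
  expect_true(bc$clipped)
  expect_true(all(bc$codes >= 0 & bc$codes <= 4095))
})

test_that("forward solver obeys symmetry, reciprocity, linearity", {
  mesh <- fixture_mesh()
  p <- fixture_protocol()
  V <- matrix(eitresp:::forward_solve_all(mesh, 0.5, p), nrow = 13)
  # rotational symmetry of the homogeneous disk: identical 13-voltage
  # profile for every pattern
  expect_lt(max(abs(sweep(V, 1, V[, 1]))) / max(abs(V)), 1e-10)
  # U-shape: magnitude minimum at the central (diametrically opposite) pair
  expect_true(all(apply(abs(V), 2, which.min) == 7))
  # linearity: sigma x2 halves all voltages
  v1 <- forward_solve(mesh, 0.5, 1, p)
  v2 <- forward_solve(mesh, 1.0, 1, p)
  expect_equal(v2, v1 / 2, tolerance = 1e-12)
  expect_equal(length(v1), 13L)
  # reciprocity: drive (1,2)/measure (5,6) vs drive (5,6)/measure (1,2)
  U <- eitresp:::electrode_fields(mesh, rep(0.5, nrow(mesh$tris)))
  en <- mesh$electrode_nodes
  r1 <- (U[, 1] - U[, 2])[en[5]] - (U[, 1] - U[, 2])[en[6]]
  r2 <- (U[, 5] - U[, 6])[en[1]] - (U[, 5] - U[, 6])[en[2]]
  expect_lt(abs(r1 - r2) / abs(r1), 1e-8)
  # guards
  expect_error(forward_solve(mesh, -0.5, 1, p), "positive")
})

test_that("mesh refinement converges", {
  p <- fixture_protocol()
  v_c <- forward_solve(build_mesh(6, 16, 32), 0.5, 1, p)
  v_f <- forward_solve(build_mesh(12, 16, 64), 0.5, 1, p)
  v_ff <- forward_solve(build_mesh(18, 16, 96), 0.5, 1, p)
  # successive refinements change voltages by < 2%
  expect_lt(max(abs(v_ff - v_f) / abs(v_ff)), 0.02)
  expect_lt(max(abs(v_f - v_c) / abs(v_f)), 0.06)
})

test_that("phantom conductivity modulates lungs only, rejects collapse", {
  mesh <- fixture_mesh()
  ph <- thorax_phantom()
  s0 <- phantom_conductivity(ph, mesh, 0)
  s1 <- phantom_conductivity(ph, mesh, 0.5)
  in_lung <- s0 == ph$sigma_lung
  expect_true(any(in_lung) && any(!in_lung))
  expect_equal(unique(s1[!in_lung]), ph$sigma_bg)
  expect_equal(unique(s1[in_lung]), ph$sigma_lung + ph$slope * 0.5)
  expect_error(phantom_conductivity(ph, mesh, 10), "non-positive")
})

test_that("breath trace is consistent: flow integrates to volume", {
  br <- breath_trace(duration = 60, period = 4, tidal = 0.5,
                     period_jitter = 0.05, tidal_jitter = 0.2,
                     maneuvers = NULL, seed = 3)
  # numeric integral of flow recovers the volume waveform
  v_int <- cumsum(br$flow) / br$fs
  expect_lt(sqrt(mean((v_int - br$volume)^2)), 0.01 * max(br$volume))
  # annotations alternate and match waveform extrema count
  expect_equal(length(br$peaks), length(br$valleys))
  expect_true(all(br$peaks > br$valleys))
  expect_true(all(br$tidal_volumes > 0))
  # maneuvers marked at the configured times
  br2 <- breath_trace(duration = 300, seed = 5)
  expect_equal(length(br2$maneuver_times), 2L)
  expect_true(all(abs(br2$maneuver_times - c(180, 250)) < 2 * 4))
})

test_that("recordings are seeded, correctly sized, and static media freeze", {
  rec <- fixture_recording()
  # stream length = frames x 208 x 64 x 2 bytes
  expect_equal(length(rec$raw), 60L * 208L * 64L * 2L)
  expect_equal(rec$truth$n_frames, 60L)
  expect_equal(rec$truth$clipped_samples, 0L)
  # same seed, byte-identical; different seed differs
  br <- rec$truth$breath
  rec2 <- simulate_recording(thorax_phantom(), br, fixture_protocol(),
                             mesh = fixture_mesh(), seed = 11)
  expect_identical(rec2$raw, rec$raw)
  rec3 <- simulate_recording(thorax_phantom(), br, fixture_protocol(),
                             mesh = fixture_mesh(), seed = 12)
  expect_false(identical(rec3$raw, rec$raw))
  # zero conductivity modulation (flat volume) -> all frame voltages equal
  ph0 <- thorax_phantom(slope = 0)
  brf <- breath_trace(duration = 2, period = 1, tidal = 1e-9, period_jitter = 0,
                      tidal_jitter = 0, maneuvers = NULL, seed = 1)
  recf <- simulate_recording(ph0, brf, fixture_protocol(),
                             mesh = fixture_mesh_coarse(), seed = 1)
  expect_equal(recf$truth$voltages[, 1], recf$truth$voltages[, 4], tolerance = 1e-12)
  # excursions that collapse the lungs are rejected up front
  brx <- breath_trace(duration = 10, period = 4, tidal = 7, period_jitter = 0,
                      tidal_jitter = 0, maneuvers = NULL, seed = 1)
  expect_error(simulate_recording(thorax_phantom(), brx, fixture_protocol(),
                                  mesh = fixture_mesh_coarse(), seed = 1),
               "conductivity")
})

test_that("flowmeter trace carries drift and respects its low-pass", {
  br <- breath_trace(duration = 60, period = 4, tidal = 0.5, period_jitter = 0,
                     tidal_jitter = 0, maneuvers = NULL, seed = 2)
  fl <- eitresp:::simulate_flow(br, flowmeter_config(drift_amp = 0.05, drift_hz = 0.04))
  expect_equal(nrow(fl), length(br$time))
  # drift present: correlation with the drift sinusoid
  resid <- fl$flow_L_per_s - br$flow
  expect_gt(abs(cor(resid, sin(2 * pi * 0.04 * br$time))), 0.9)
  expect_error(flowmeter_config(drift_hz = 0.2), "drift_hz")
})
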