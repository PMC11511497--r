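# Shared fixtures, built once per test run.

fx <- new.env()

fixture_protocol <- function() {
  if (is.null(fx$protocol)) fx$protocol <- build_protocol(16L)
  fx$protocol
}

fixture_mesh_coarse <- function() {
  if (is.null(fx$mesh_coarse)) fx$mesh_coarse <- build_mesh(4L, 16L, 16L)
  fx$mesh_coarse
}

fixture_mesh <- function() {
  if (is.null(fx$mesh)) fx$mesh <- build_mesh(6L, 16L, 32L)
  fx$mesh
}

# 30 s clean recording: regular 4 s breathing, no maneuvers, no noise
fixture_recording <- function() {
  if (is.null(fx$rec)) {
    br <- breath_trace(duration = 30, period = 4, tidal = 0.5,
                       period_jitter = 0, tidal_jitter = 0,
                       maneuvers = NULL, seed = 11)
    fx$rec <- simulate_recording(thorax_phantom(), br, fixture_protocol(),
                                 mesh = fixture_mesh(), seed = 11)
  }
  fx$rec
}
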