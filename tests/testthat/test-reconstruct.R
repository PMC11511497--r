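test_that("Jacobian matches finite-difference perturbation of the solver", {
  mesh <- fixture_mesh_coarse()
  p <- fixture_protocol()
  sig0 <- rep(0.5, nrow(mesh$tris))
  J <- build_jacobian(mesh, sig0, p)
  expect_equal(dim(J), c(208L, nrow(mesh$tris)))
  v0 <- eitresp:::forward_solve_all(mesh, sig0, p)
  set.seed(14)
  rows <- c(1L, 50L, 120L, 208L)
  for (e in sample(nrow(mesh$tris), 4)) {
    h <- 1e-6
    sp <- sig0; sp[e] <- sp[e] + h
    fd <- (eitresp:::forward_solve_all(mesh, sp, p) - v0) / h
    expect_lt(max(abs(fd[rows] - J[rows, e]) / pmax(abs(fd[rows]), 1e-12)), 1e-3)
  }
  # sensitivity scaling: sigma x c scales J by 1/c^2
  J2 <- build_jacobian(mesh, 2 * sig0, p)
  expect_equal(J2, J / 4, tolerance = 1e-10)
  # zero perturbation predicts zero voltage change
  expect_equal(max(abs(J %*% rep(0, ncol(J)))), 0)
})

test_that("difference reconstruction localizes an inclusion with the right sign", {
  mesh <- fixture_mesh()
  p <- fixture_protocol()
  sig0 <- rep(0.48, nrow(mesh$tris))
  cen <- eitresp:::mesh_centroids(mesh)
  incl <- ((cen[, 1] - 0.5) / 0.35)^2 + (cen[, 2] / 0.55)^2 <= 1
  sig1 <- sig0; sig1[incl] <- 0.48 * 0.8   # -20% in one lung ellipse
  v0 <- eitresp:::forward_solve_all(mesh, sig0, p)
  v1 <- eitresp:::forward_solve_all(mesh, sig1, p)
  J <- build_jacobian(mesh, sig0, p)
  img <- reconstruct_diff(v1, v0, J, mesh, lambda = 1e-2)
  expect_s3_class(img, "eit_diff_image")
  expect_equal(dim(img$pixels), c(32L, 32L))
  # centroid of the strongest (negative) change inside the true ellipse
  w <- pmax(-img$dsigma, 0); w[w < 0.5 * max(w)] <- 0
  cg <- c(sum(w * cen[, 1]), sum(w * cen[, 2])) / sum(w)
  expect_lt(sqrt(sum((cg - c(0.5, 0))^2)), 0.55 / 2)
  # conductivity decrease reconstructs negative in the inclusion
  expect_lt(mean(img$dsigma[incl]), 0)
  # identical frames give a zero image
  z <- reconstruct_diff(v0, v0, J, mesh)
  expect_equal(max(abs(z$dsigma)), 0, tolerance = 1e-15)
  # doubling lambda never increases the solution norm
  n1 <- sum(reconstruct_diff(v1, v0, J, mesh, 1e-2)$dsigma^2)
  n2 <- sum(reconstruct_diff(v1, v0, J, mesh, 2e-2)$dsigma^2)
  expect_lte(n2, n1)
  # guards
  expect_error(reconstruct_diff(v1[1:10], v0, J, mesh), "row count")
  expect_error(reconstruct_diff(v1, v0, J, mesh, lambda = 0), "positive")
})

test_that("pixel series and correlation maps track the breathing phantom", {
  # reconstruct from the demodulated pipeline output (the noiseless truth
  # voltages make every pixel correlate exactly +-1 with volume - the
  # phantom has one degree of freedom - so the argmax would be a tie)
  rec <- fixture_recording()
  mesh <- fixture_mesh()
  p <- fixture_protocol()
  sig0 <- rep(0.48, nrow(mesh$tris)) * 0.15   # sheet conductance at thickness
  J <- build_jacobian(mesh, sig0, p)
  vm <- eitresp:::demodulate_stream(rec$raw)$voltage
  cst <- signal_chain_constants(signal_chain_config())
  vref <- eitresp:::forward_solve_all(mesh, sig0, p)
  Jpp <- J * (2 * sqrt(2) * cst$gain * sign(vref))
  stack <- reconstruct_series(vm, Jpp, mesh, reference = 1L)
  expect_equal(ncol(stack$dsigma), 60L)
  expect_equal(dim(stack$element_map), c(32L, 32L))
  br <- rec$truth$breath
  cp <- correlate_pixels(stack, br$volume, fs = 200)
  expect_equal(dim(cp$map), c(32L, 32L))
  # best pixel: strong negative correlation (inspiration lowers conductivity)
  expect_lt(cp$best_r, -0.8)
  # and it lies inside a lung ellipse (checked geometrically: the mapped
  # element's centroid can straddle the boundary on a coarse mesh)
  ph <- thorax_phantom()
  g <- stack$grid
  px <- (cp$best[2] - 0.5) / g * 2 - 1   # col -> x in [-1, 1]
  py <- 1 - (cp$best[1] - 0.5) / g * 2   # row -> y, row 1 at top
  in_ellipse <- any(vapply(ph$lungs, function(L) {
    ((px - L$center[1]) / L$semi_axes[1])^2 +
      ((py - L$center[2]) / L$semi_axes[2])^2 <= 1.2
  }, TRUE))
  expect_true(in_ellipse)
  # pixel series: in-domain works, background errors
  ps <- pixel_series(stack, cp$best[1], cp$best[2])
  expect_equal(length(ps), 60L)
  expect_error(pixel_series(stack, 1, 1), "outside the domain")
  # static stack: zero-variance guarded
  stat <- stack; stat$dsigma[] <- 0
  cps <- correlate_pixels(stat, br$volume, fs = 200)
  expect_true(all(is.na(cps$map)))
})

test_that("breath detection on the best pixel mirrors the voltage result", {
  rec <- fixture_recording()
  mesh <- fixture_mesh()
  J <- build_jacobian(mesh, rep(0.48, nrow(mesh$tris)) * 0.15, fixture_protocol())
  stack <- reconstruct_series(rec$truth$voltages, J, mesh, reference = 1L,
                              frame_times = rec$truth$frame_times)
  br <- rec$truth$breath
  cp <- correlate_pixels(stack, br$volume, fs = 200)
  ps <- pixel_series(stack, cp$best[1], cp$best[2])
  up <- upsample_voltage(-ps, fs_in = 2, fs_out = 200, times = stack$frame_times)
  ann <- detect_extrema(up$values, 200, 0.2, 1)
  ref <- detect_extrema(br$volume, br$fs, 0.2, 1)
  # compare on the overlap covered by the frame grid
  keep <- ref$peak_times > min(up$time) & ref$peak_times < max(up$time)
  m <- match_breaths(structure(list(peaks = ref$peaks[keep], valleys = integer(0),
                                    fs = 200, peak_times = ref$peak_times[keep],
                                    valley_times = numeric(0)), class = "eit_breaths"),
                     ann)
  met <- detection_metrics(m)
  expect_gte(met$Se, 0.99)
})
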