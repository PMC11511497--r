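# Linearized difference imaging: adjoint Jacobian, one-step Tikhonov
# reconstruction onto a pixel grid, and pixel-level respiratory analysis.

#' Sensitivity (Jacobian) matrix of the protocol measurements
#'
#' Adjoint-method sensitivities of every differential measurement voltage
#' with respect to each element's conductivity, evaluated at a reference
#' (usually homogeneous) conductivity: for drive field `u` and measurement
#' (adjoint) field `w`, `dV/dsigma_e = -area_e * grad(u) . grad(w)` on each
#' linear triangle. Rows follow protocol order (208 for 16 electrodes).
#'
#' @param mesh An `eit_mesh`.
#' @param sigma_ref Reference per-element conductivity (scalar or vector).
#' @param protocol An `eit_protocol`.
#' @param current Drive current (A), as used for the measured voltages.
#' @return Matrix `n_measurements x n_elements` (V per S/m).
#' @export
build_jacobian <- function(mesh, sigma_ref, protocol = build_protocol(mesh$n_electrodes),
                           current = 1e-3) {
  U <- electrode_fields(mesh, sigma_ref)
  g <- tri_gradients(mesh)
  t <- mesh$tris
  # per-element gradients of all electrode fields: n_elem x n_electrodes
  GX <- g$gx[, 1] * U[t[, 1], ] + g$gx[, 2] * U[t[, 2], ] + g$gx[, 3] * U[t[, 3], ]
  GY <- g$gy[, 1] * U[t[, 1], ] + g$gy[, 2] * U[t[, 2], ] + g$gy[, 3] * U[t[, 3], ]
  tab <- protocol_table(protocol)
  pos <- ifelse(tab$meas_first %% 2L == 0L, tab$meas_first, tab$meas_second)
  neg <- ifelse(tab$meas_first %% 2L == 0L, tab$meas_second, tab$meas_first)
  J <- matrix(0, nrow(tab), nrow(t))
  for (m in seq_len(nrow(tab))) {
    gdx <- GX[, tab$source[m]] - GX[, tab$sink[m]]
    gdy <- GY[, tab$source[m]] - GY[, tab$sink[m]]
    gmx <- GX[, pos[m]] - GX[, neg[m]]
    gmy <- GY[, pos[m]] - GY[, neg[m]]
    J[m, ] <- -current * g$area * (gdx * gmx + gdy * gmy)
  }
  J
}

#' One-step Tikhonov difference reconstruction
#'
#' Solves `J dsigma ~ v_frame - v_reference` with an identity-weighted
#' Tikhonov prior: `dsigma = (J'J + lambda * s * I)^{-1} J' dv`, where `s`
#' is the mean diagonal of `J'J` so that `lambda` is dimensionless. The
#' per-element solution is rasterized to a square pixel grid.
#'
#' @param v_frame,v_reference Measurement vectors (length 208).
#' @param jacobian From [build_jacobian()].
#' @param mesh The mesh the Jacobian was built on.
#' @param lambda Regularization weight (> 0), relative to the normalized
#'   Jacobian scale.
#' @param grid Pixel grid side (default 32).
#' @return An object of class `eit_diff_image`: `dsigma` (per element),
#'   `pixels` (grid x grid matrix, NA outside the domain; row 1 at the top,
#'   i.e. anterior), `grid`, `lambda`.
#' @export
reconstruct_diff <- function(v_frame, v_reference, jacobian, mesh,
                             lambda = 1e-2, grid = 32L) {
  if (length(v_frame) != nrow(jacobian) || length(v_reference) != nrow(jacobian)) {
    stop("voltage vectors must match the Jacobian row count (", nrow(jacobian), ")")
  }
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  dv <- v_frame - v_reference
  JtJ <- crossprod(jacobian)
  s <- mean(diag(JtJ))
  dsig <- solve(JtJ + lambda * s * diag(nrow(JtJ)), crossprod(jacobian, dv))
  img <- rasterize_elements(mesh, as.vector(dsig), grid)
  structure(list(dsigma = as.vector(dsig), pixels = img, grid = as.integer(grid),
                 lambda = lambda), class = "eit_diff_image")
}

# map per-element values onto a grid x grid pixel image covering the domain
# bounding box; pixels whose center falls outside the mesh are NA background.
# row 1 = top of the image (+y, anterior).
rasterize_elements <- function(mesh, values, grid = 32L) {
  g <- as.integer(grid)
  xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
  cx <- xr[1] + (seq_len(g) - 0.5) / g * diff(xr)
  cy <- yr[2] - (seq_len(g) - 0.5) / g * diff(yr)  # row 1 at top
  pix <- expand.grid(col = seq_len(g), row = seq_len(g))
  pts <- cbind(cx[pix$col], cy[pix$row])
  el <- locate_points(mesh, pts)
  img <- matrix(NA_real_, g, g)
  img[cbind(pix$row, pix$col)] <- ifelse(is.na(el), NA_real_, values[el])
  img
}

# cached pixel -> element lookup for image stacks
pixel_element_map <- function(mesh, grid = 32L) {
  g <- as.integer(grid)
  xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
  cx <- xr[1] + (seq_len(g) - 0.5) / g * diff(xr)
  cy <- yr[2] - (seq_len(g) - 0.5) / g * diff(yr)
  pix <- expand.grid(col = seq_len(g), row = seq_len(g))
  el <- locate_points(mesh, cbind(cx[pix$col], cy[pix$row]))
  m <- matrix(NA_integer_, g, g)
  m[cbind(pix$row, pix$col)] <- el
  m
}

#' Reconstruct a sequence of difference images
#'
#' Difference reconstruction of every frame of a voltage matrix against a
#' reference frame (default: the first).
#'
#' @param vm An `eit_voltage_matrix` (or plain 208 x F matrix).
#' @param jacobian,mesh As for [reconstruct_diff()].
#' @param reference Reference frame index, or a length-208 vector.
#' @param lambda,grid As for [reconstruct_diff()].
#' @param frame_times Frame timestamps (s); taken from `vm` when it is an
#'   `eit_voltage_matrix`, else defaulting to midpoints at 2 frames/s.
#' @return An object of class `eit_image_stack`: `dsigma` (n_elem x F),
#'   `element_map` (pixel -> element lookup), `grid`, `frame_times`.
#' @export
reconstruct_series <- function(vm, jacobian, mesh, reference = 1L,
                               lambda = 1e-2, grid = 32L, frame_times = NULL) {
  pp <- if (inherits(vm, "eit_voltage_matrix")) vm$pp else vm
  ft <- if (inherits(vm, "eit_voltage_matrix")) vm$frame_times
        else if (!is.null(frame_times)) frame_times
        else (seq_len(ncol(pp)) - 0.5) / 2
  vref <- if (length(reference) == 1L) pp[, reference] else reference
  JtJ <- crossprod(jacobian)
  s <- mean(diag(JtJ))
  A <- solve(JtJ + lambda * s * diag(nrow(JtJ)))
  D <- A %*% crossprod(jacobian, sweep(pp, 1, vref))
  structure(list(dsigma = D, element_map = pixel_element_map(mesh, grid),
                 grid = as.integer(grid), frame_times = ft, lambda = lambda),
            class = "eit_image_stack")
}

#' Time series of one image pixel
#'
#' @param stack An `eit_image_stack`.
#' @param row,col Pixel address (row 1 = top/anterior).
#' @return Numeric per-frame series at the frame rate.
#' @export
pixel_series <- function(stack, row, col) {
  stopifnot(inherits(stack, "eit_image_stack"))
  el <- stack$element_map[row, col]
  if (is.na(el)) stop("pixel (", row, ", ", col, ") is outside the domain")
  stack$dsigma[el, ]
}

#' Correlate every pixel's series with the volume signal
#'
#' Pearson correlation of each in-domain pixel's conductivity-change series
#' with the volume waveform resampled to the frame times; zero-variance
#' pixels are NA. Returns the map and the best (largest |r|) pixel.
#'
#' @param stack An `eit_image_stack`.
#' @param volume Volume series.
#' @param fs Volume sample rate (Hz); the series is interpolated onto the
#'   stack's frame times.
#' @param volume_times Optional explicit times for `volume`.
#' @return List: `map` (grid x grid of r), `best` (`c(row, col)`), `best_r`.
#' @export
correlate_pixels <- function(stack, volume, fs = 200, volume_times = NULL) {
  stopifnot(inherits(stack, "eit_image_stack"))
  if (ncol(stack$dsigma) < 10) stop("need at least 10 frames")
  tv <- if (is.null(volume_times)) (seq_along(volume) - 1) / fs else volume_times
  vq <- stats::approx(tv, volume, xout = stack$frame_times, rule = 2)$y
  g <- stack$grid
  map <- matrix(NA_real_, g, g)
  els <- stack$element_map
  # correlate each distinct element once
  uniq <- unique(as.vector(els[!is.na(els)]))
  rs <- vapply(uniq, function(e) {
    s <- stack$dsigma[e, ]
    if (stats::sd(s) == 0 || stats::sd(vq) == 0) NA_real_ else stats::cor(s, vq)
  }, 0)
  lut <- setNames(rs, uniq)
  inside <- which(!is.na(els))
  map[inside] <- lut[as.character(els[inside])]
  if (all(is.na(map))) {
    best <- c(NA_integer_, NA_integer_); best_r <- NA_real_
  } else {
    k <- which.max(abs(map))
    best <- c(row = (k - 1) %% g + 1, col = (k - 1) %/% g + 1)
    best_r <- map[k]
  }
  list(map = map, best = best, best_r = best_r)
}
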