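# Breathing thorax phantom and ventilation waveform generator.

#' Two-lung conductivity phantom
#'
#' A 2D thorax-like conductivity distribution: uniform background with two
#' elliptical lung regions whose conductivity decreases linearly with lung
#' air volume (air is a poor conductor, so inspiration lowers regional
#' conductivity). Defaults are physiologically ordered rather than measured:
#' lungs half as conductive as the surrounding tissue average, with a
#' negative conductivity-volume slope. The default lung ellipses reach to
#' about 0.85 of the domain radius and cover ~42% of the cross-section,
#' matching the anatomy of a chest slice at the electrode plane (lungs
#' nearly touch the chest wall laterally).
#'
#' @param sigma_bg Background conductivity (S/m).
#' @param sigma_lung Lung conductivity at end-expiration (S/m).
#' @param slope Conductivity change per litre of inhaled air (S/m/L, < 0).
#' @param thickness Effective slab thickness (m) of the 2D model, the axial
#'   extent over which the injected current spreads around the electrode
#'   plane; scales all simulated voltages by `1/thickness`.
#' @param lungs List of two ellipses, each `list(center, semi_axes, rotation)`
#'   (rotation in radians).
#' @return An object of class `eit_phantom`.
#' @export
thorax_phantom <- function(sigma_bg = 0.48, sigma_lung = 0.24, slope = -0.04,
                           thickness = 0.15,
                           lungs = list(
                             list(center = c(-0.5, 0), semi_axes = c(0.35, 0.55), rotation = 0),
                             list(center = c(0.5, 0), semi_axes = c(0.35, 0.55), rotation = 0))) {
  stopifnot(sigma_bg > 0, sigma_lung > 0, thickness > 0, length(lungs) >= 1)
  structure(list(sigma_bg = sigma_bg, sigma_lung = sigma_lung, slope = slope,
                 thickness = thickness, lungs = lungs), class = "eit_phantom")
}

# logical matrix: element centroid inside each lung ellipse
lung_elements <- function(phantom, mesh) {
  cen <- mesh_centroids(mesh)
  sapply(phantom$lungs, function(L) {
    d <- sweep(cen, 2, L$center)
    ca <- cos(L$rotation); sa <- sin(L$rotation)
    xr <- d[, 1] * ca + d[, 2] * sa
    yr <- -d[, 1] * sa + d[, 2] * ca
    (xr / L$semi_axes[1])^2 + (yr / L$semi_axes[2])^2 <= 1
  })
}

#' Per-element conductivity of a phantom at a given lung volume
#'
#' @param phantom An `eit_phantom`.
#' @param mesh An `eit_mesh`.
#' @param volume Inhaled air volume above end-expiration (L).
#' @return Numeric vector of per-element conductivities (S/m).
#' @export
phantom_conductivity <- function(phantom, mesh, volume = 0) {
  sig <- rep(phantom$sigma_bg, nrow(mesh$tris))
  in_lung <- rowSums(lung_elements(phantom, mesh)) > 0
  sl <- phantom$sigma_lung + phantom$slope * volume
  if (sl <= 0) {
    stop("lung conductivity non-positive at volume ", volume,
         " L; reduce the excursion or the slope magnitude")
  }
  sig[in_lung] <- sl
  sig
}

#' Synthetic breathing volume/flow waveform
#'
#' Breath-by-breath synthesis of a lung volume trace: each breath is a
#' raised-cosine inhale/exhale of configurable period and tidal volume with
#' multiplicative jitter, optionally interrupted by two respiratory
#' maneuvers (a forced inspiration and a forced expiration with an
#' end-expiratory overshoot), by default near 180 s and 250 s of a 300 s
#' recording. Flow is the exact analytic derivative of the volume waveform.
#'
#' @param duration Recording length (s).
#' @param fs Sample rate (Hz; flowmeter rate, 200 S/s).
#' @param period Mean breath period (s).
#' @param tidal Mean tidal volume (L).
#' @param period_jitter,tidal_jitter Coefficients of variation of the
#'   per-breath period and tidal volume.
#' @param maneuvers List of maneuvers, each `list(time =, type =
#'   c("inspiration","expiration"), volume =)`; `NULL` for none.
#' @param seed Integer seed for the jitter.
#' @return An object of class `eit_breath_trace`: `time` (s), `volume` (L),
#'   `flow` (L/s), `peaks`/`valleys` (times, s), `tidal_volumes` (L),
#'   `maneuver_times` (s), plus the generating parameters.
#' @export
breath_trace <- function(duration = 300, fs = 200, period = 4, tidal = 0.5,
                         period_jitter = 0.05, tidal_jitter = 0.2,
                         maneuvers = list(
                           list(time = 180, type = "inspiration", volume = 2.5),
                           list(time = 250, type = "expiration", volume = 2.0)),
                         seed = 1L) {
  stopifnot(duration > period, fs > 0, tidal > 0)
  rng <- local_rng(seed)
  segs <- list()   # each: t0, t1, v0, v1 (half-cosine segment)
  peaks <- c(); valleys <- c(); tvs <- c(); man_times <- c()
  pending <- if (is.null(maneuvers)) list() else maneuvers[order(vapply(maneuvers, `[[`, 0, "time"))]
  t0 <- 0
  while (t0 < duration) {
    man <- NULL
    if (length(pending) && t0 >= pending[[1]]$time) {
      man <- pending[[1]]; pending <- pending[-1]
    }
    if (is.null(man)) {
      Tk <- period * max(0.3, 1 + period_jitter * rng$norm(1))
      VT <- tidal * max(0.2, 1 + tidal_jitter * rng$norm(1))
      segs <- c(segs, list(c(t0, t0 + Tk / 2, 0, VT), c(t0 + Tk / 2, t0 + Tk, VT, 0)))
      valleys <- c(valleys, t0); peaks <- c(peaks, t0 + Tk / 2); tvs <- c(tvs, VT)
      t0 <- t0 + Tk
    } else if (man$type == "inspiration") {
      Tk <- 2 * period
      segs <- c(segs, list(c(t0, t0 + Tk / 2, 0, man$volume), c(t0 + Tk / 2, t0 + Tk, man$volume, 0)))
      valleys <- c(valleys, t0); peaks <- c(peaks, t0 + Tk / 2); tvs <- c(tvs, man$volume)
      man_times <- c(man_times, t0); t0 <- t0 + Tk
    } else {
      # forced expiration: inhale to volume, blow out past baseline, recover
      Tk <- 2 * period; B <- 0.3 * man$volume
      segs <- c(segs, list(c(t0, t0 + Tk / 2, 0, man$volume),
                           c(t0 + Tk / 2, t0 + 0.8 * Tk, man$volume, -B),
                           c(t0 + 0.8 * Tk, t0 + Tk, -B, 0)))
      valleys <- c(valleys, t0); peaks <- c(peaks, t0 + Tk / 2); tvs <- c(tvs, man$volume)
      man_times <- c(man_times, t0); t0 <- t0 + Tk
    }
  }
  tt <- seq(0, duration, by = 1 / fs)
  vol <- numeric(length(tt)); flo <- numeric(length(tt))
  for (s in segs) {
    sel <- tt >= s[1] & tt < s[2]
    if (!any(sel)) next
    ph <- pi * (tt[sel] - s[1]) / (s[2] - s[1])
    vol[sel] <- s[3] + (s[4] - s[3]) * (1 - cos(ph)) / 2
    flo[sel] <- (s[4] - s[3]) * pi / (2 * (s[2] - s[1])) * sin(ph)
  }
  keep <- peaks <= duration
  structure(list(time = tt, volume = vol, flow = flo,
                 peaks = peaks[keep], valleys = valleys[keep], tidal_volumes = tvs[keep],
                 maneuver_times = man_times, fs = fs, duration = duration,
                 period = period, tidal = tidal, seed = seed),
            class = "eit_breath_trace")
}

#' @exportS3Method base::print
print.eit_breath_trace <- function(x, ...) {
  cat(sprintf("Breathing trace: %.0f s at %g S/s, %d breaths, %d maneuver(s)\n",
              x$duration, x$fs, length(x$peaks), length(x$maneuver_times)))
  invisible(x)
}

# self-contained seeded RNG that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  use <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = function(n, ...) use(stats::rnorm, n, ...),
       unif = function(n, ...) use(stats::runif, n, ...))
}
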