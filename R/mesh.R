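# Structured triangular meshes of a unit-radius 2D domain with 16 (or n)
# boundary electrode nodes. A stand-in for the EIDORS chest models: difference
# imaging is robust to the exact mesh, so a regular polar mesh is sufficient
# and keeps the package dependency-free.

#' Build a 2D disk (or thorax-like) mesh with ring electrodes
#'
#' Polar mesh: a center node plus `n_rings` concentric rings of
#' `nodes_per_ring` nodes each, triangulated as a central fan plus quad
#' strips split into triangles. Electrode k sits on the outermost ring at
#' angle `2*pi*(k-1)/n_electrodes`, numbered counter-clockwise with electrode
#' 1 at angle 0.
#'
#' @param n_rings Number of concentric rings (mesh density).
#' @param n_electrodes Number of boundary electrodes; `nodes_per_ring` must be
#'   a multiple of it.
#' @param nodes_per_ring Nodes on each ring (default `3 * n_electrodes`).
#' @param boundary `"circle"` (default) or `"thorax"`, an ellipse with
#'   left-right semi-axis 1 and anterior-posterior semi-axis 0.8
#'   approximating a chest slice.
#' @return An object of class `eit_mesh`: `nodes` (n x 2), `tris` (m x 3,
#'   positively oriented), `electrode_nodes` (length `n_electrodes`),
#'   `boundary`.
#' @export
build_mesh <- function(n_rings = 8L, n_electrodes = 16L,
                       nodes_per_ring = 3L * n_electrodes,
                       boundary = c("circle", "thorax")) {
  boundary <- match.arg(boundary)
  n_rings <- as.integer(n_rings); m <- as.integer(nodes_per_ring)
  stopifnot(n_rings >= 2L, m %% n_electrodes == 0L, m >= 8L)
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  rad <- seq_len(n_rings) / n_rings
  nodes <- rbind(c(0, 0),
                 do.call(rbind, lapply(rad, function(r) cbind(r * cos(ang), r * sin(ang)))))
  if (boundary == "thorax") nodes[, 2] <- nodes[, 2] * 0.8
  ring_idx <- function(k) 1L + (k - 1L) * m + seq_len(m)  # node ids of ring k
  tris <- matrix(0L, 0L, 3L)
  r1 <- ring_idx(1L)
  nxt <- c(seq_len(m)[-1L], 1L)
  tris <- rbind(tris, cbind(1L, r1, r1[nxt]))
  if (n_rings > 1L) {
    for (k in seq_len(n_rings - 1L)) {
      inner <- ring_idx(k); outer <- ring_idx(k + 1L)
      tris <- rbind(tris,
                    cbind(inner, outer, outer[nxt]),
                    cbind(inner, outer[nxt], inner[nxt]))
    }
  }
  # enforce positive orientation
  ax <- nodes[tris[, 1], 1]; ay <- nodes[tris[, 1], 2]
  bx <- nodes[tris[, 2], 1]; by <- nodes[tris[, 2], 2]
  cx <- nodes[tris[, 3], 1]; cy <- nodes[tris[, 3], 2]
  det <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  flip <- det < 0
  if (any(flip)) tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  elec <- ring_idx(n_rings)[1L + (seq_len(n_electrodes) - 1L) * (m %/% n_electrodes)]
  structure(list(nodes = nodes, tris = tris, electrode_nodes = elec,
                 n_electrodes = n_electrodes, boundary = boundary),
            class = "eit_mesh")
}

#' @exportS3Method base::print
print.eit_mesh <- function(x, ...) {
  cat(sprintf("EIT mesh (%s): %d nodes, %d triangles, %d electrodes\n",
              x$boundary, nrow(x$nodes), nrow(x$tris), x$n_electrodes))
  invisible(x)
}

# per-triangle areas
mesh_areas <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tris
  abs((n[t[, 2], 1] - n[t[, 1], 1]) * (n[t[, 3], 2] - n[t[, 1], 2]) -
      (n[t[, 3], 1] - n[t[, 1], 1]) * (n[t[, 2], 2] - n[t[, 1], 2])) / 2
}

# triangle centroids (m x 2)
mesh_centroids <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tris
  cbind((n[t[, 1], 1] + n[t[, 2], 1] + n[t[, 3], 1]) / 3,
        (n[t[, 1], 2] + n[t[, 2], 2] + n[t[, 3], 2]) / 3)
}

# index of the triangle containing each query point, NA if outside.
# brute-force barycentric test, vectorized over triangles per point.
locate_points <- function(mesh, pts) {
  n <- mesh$nodes; t <- mesh$tris
  ax <- n[t[, 1], 1]; ay <- n[t[, 1], 2]
  bx <- n[t[, 2], 1]; by <- n[t[, 2], 2]
  cx <- n[t[, 3], 1]; cy <- n[t[, 3], 2]
  d <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  eps <- -1e-12
  apply(pts, 1L, function(p) {
    l1 <- ((by - cy) * (p[1] - cx) + (cx - bx) * (p[2] - cy)) / d
    l2 <- ((cy - ay) * (p[1] - cx) + (ax - cx) * (p[2] - cy)) / d
    hit <- which(l1 >= eps & l2 >= eps & (1 - l1 - l2) >= eps)
    if (length(hit)) hit[1L] else NA_integer_
  })
}
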