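# Linear (P1) finite-element solver for the 2D conductivity equation
#   div(sigma grad u) = 0  with point-electrode current injection.
# Point/gap electrode model: current I enters at the source electrode node
# and leaves at the sink node; one interior reference node is grounded.

# per-triangle gradient operators: list(gx, gy) each m x 3, so that for nodal
# values u, grad u on triangle e = (gx[e,] %*% u[tris[e,]], gy[e,] %*% u[tris[e,]])
tri_gradients <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tris
  x1 <- n[t[, 1], 1]; y1 <- n[t[, 1], 2]
  x2 <- n[t[, 2], 1]; y2 <- n[t[, 2], 2]
  x3 <- n[t[, 3], 1]; y3 <- n[t[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)  # 2 * area, > 0
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  list(gx = gx, gy = gy, area = det / 2)
}

# assemble the stiffness matrix for per-element conductivity sigma (length m)
assemble_stiffness <- function(mesh, sigma) {
  g <- tri_gradients(mesh)
  m <- nrow(mesh$tris)
  if (length(sigma) == 1L) sigma <- rep(sigma, m)
  stopifnot(length(sigma) == m)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("conductivity must be strictly positive and finite")
  }
  w <- sigma * g$area
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- mesh$tris[, a]
    jj[[k]] <- mesh$tris[, b]
    vv[[k]] <- w * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = rep(nrow(mesh$nodes), 2L))
}

# Nodal potential fields for unit current (1 A) injected at each electrode,
# returned as an n_nodes x n_electrodes matrix. The center node (node 1) is
# grounded; the balancing return current exits there, so the difference of
# two columns is the field of a +1/-1 A electrode-pair injection with no net
# current at the reference.
electrode_fields <- function(mesh, sigma) {
  K <- assemble_stiffness(mesh, sigma)
  free <- seq_len(nrow(mesh$nodes))[-1L]  # ground node 1 (domain center)
  Kf <- K[free, free, drop = FALSE]
  ne <- length(mesh$electrode_nodes)
  B <- matrix(0, length(free), ne)
  for (j in seq_len(ne)) B[match(mesh$electrode_nodes[j], free), j] <- 1
  Uf <- as.matrix(Matrix::solve(Kf, B))
  U <- matrix(0, nrow(mesh$nodes), ne)
  U[free, ] <- Uf
  U
}

#' Solve the EIT forward problem for one stimulation pattern
#'
#' Computes the 13 differential measurement voltages for one stimulation
#' pattern of the protocol on a given mesh and conductivity distribution,
#' scaled to the drive current. Within each measurement pair the even
#' electrode is taken as the positive terminal (it is wired to the
#' instrumentation amplifier's non-inverting input).
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element conductivities (S/m), or a scalar.
#' @param pattern Stimulation pattern index (1-based), or a signed column of
#'   [stim_pattern_matrix()].
#' @param protocol An `eit_protocol` matching the mesh's electrode count.
#' @param current Drive current in amperes (default 1 mA).
#' @return Numeric vector of differential voltages (V), one per measurement
#'   pair of the pattern.
#' @export
forward_solve <- function(mesh, sigma, pattern, protocol = build_protocol(mesh$n_electrodes),
                          current = 1e-3) {
  U <- electrode_fields(mesh, sigma)
  if (length(pattern) > 1L) {
    src <- which(pattern > 0); snk <- which(pattern < 0)
    j <- which(protocol$stim_pairs[, "source"] == src &
               protocol$stim_pairs[, "sink"] == snk)
    if (length(j) != 1L) stop("pattern column does not match a protocol stimulation pair")
    pattern <- j
  }
  j <- as.integer(pattern)
  stopifnot(j >= 1L, j <= protocol$n_electrodes)
  u <- current * (U[, protocol$stim_pairs[j, "source"]] -
                  U[, protocol$stim_pairs[j, "sink"]])
  mp <- protocol$meas_pairs[[j]]
  pos <- ifelse(mp[, "first"] %% 2L == 0L, mp[, "first"], mp[, "second"])
  neg <- ifelse(mp[, "first"] %% 2L == 0L, mp[, "second"], mp[, "first"])
  u[mesh$electrode_nodes[pos]] - u[mesh$electrode_nodes[neg]]
}

# all 208 differential voltages for one conductivity state, in protocol order
forward_solve_all <- function(mesh, sigma, protocol, current = 1e-3) {
  U <- electrode_fields(mesh, sigma)
  out <- vector("list", protocol$n_electrodes)
  for (j in seq_len(protocol$n_electrodes)) {
    u <- current * (U[, protocol$stim_pairs[j, "source"]] -
                    U[, protocol$stim_pairs[j, "sink"]])
    mp <- protocol$meas_pairs[[j]]
    pos <- ifelse(mp[, "first"] %% 2L == 0L, mp[, "first"], mp[, "second"])
    neg <- ifelse(mp[, "first"] %% 2L == 0L, mp[, "second"], mp[, "first"])
    out[[j]] <- u[mesh$electrode_nodes[pos]] - u[mesh$electrode_nodes[neg]]
  }
  unlist(out)
}
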