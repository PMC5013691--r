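# Pathway scoring: intermediate approach profiles, forward/reverse
# asymmetry, free-energy-style projection histograms.

#' Closest-approach profile of a pathway to candidate intermediates
#'
#' For every frame of the pathway and every intermediate structure, the
#' RMSD (after optimal superposition) and the PC1-2 Euclidean distance are
#' computed; the per-intermediate minima and their frame indices summarise
#' how closely the route passes each experimentally solved state.
#'
#' @param path An [run_transition()] result (or a [ca_trajectory()]).
#' @param intermediates List of [ca_model()]s corresponded with the path
#'   frames.
#' @param basis A [fit_pca()] basis for the PC distances.
#' @return Object of class `path_score`: `summary` data frame
#'   (intermediate, min_rmsd, min_pc_dist, frame_min_rmsd,
#'   frame_min_pc_dist) and full `rmsd_profile` / `pc_profile` matrices
#'   (frames x intermediates).
#' @export
approach_profile <- function(path, intermediates, basis) {
  traj <- if (inherits(path, "ebdims_path")) path$trajectory else path
  stopifnot(inherits(traj, "ca_trajectory"))
  if (length(traj$frames) == 0L) stop("empty path")
  if (inherits(intermediates, "ca_model")) intermediates <- list(intermediates)
  nI <- length(intermediates)
  nF <- length(traj$frames)

  proj_path <- project_structures(basis, traj, 2L)
  proj_int <- lapply(intermediates, function(m)
    project_structures(basis, m, 2L))

  rmsd_prof <- matrix(NA_real_, nF, nI)
  pc_prof <- matrix(NA_real_, nF, nI)
  for (i in seq_len(nI)) {
    ic <- .as_coords(intermediates[[i]])
    pi <- .pc_vec(proj_int[[i]])
    for (f in seq_len(nF)) {
      rmsd_prof[f, i] <- rmsd(traj$frames[[f]], ic)
      pc_prof[f, i] <- pc_distance(as.numeric(proj_path[f, c("PC1", "PC2")]), pi)
    }
  }
  labs <- vapply(seq_len(nI), function(i) {
    m <- intermediates[[i]]
    if (inherits(m, "ca_model")) m$id else sprintf("intermediate_%d", i)
  }, "")
  summary <- data.frame(
    intermediate = labs,
    min_rmsd = apply(rmsd_prof, 2L, min),
    min_pc_dist = apply(pc_prof, 2L, min),
    frame_min_rmsd = apply(rmsd_prof, 2L, which.min),
    frame_min_pc_dist = apply(pc_prof, 2L, which.min),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, rmsd_profile = rmsd_prof,
                 pc_profile = pc_prof),
            class = "path_score")
}

#' @export
print.path_score <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

# resample a 2-column path to m points by linear interpolation in the
# frame-fraction parameter t in [0, 1]
.resample_path <- function(P, m) {
  n <- nrow(P)
  if (n == 1L) return(matrix(P[1L, ], m, 2L, byrow = TRUE))
  t0 <- seq(0, 1, length.out = n)
  t1 <- seq(0, 1, length.out = m)
  cbind(stats::approx(t0, P[, 1L], xout = t1)$y,
        stats::approx(t0, P[, 2L], xout = t1)$y)
}

#' Forward/reverse pathway asymmetry in the PC1-2 plane
#'
#' The reverse path is flipped to run start-to-target and both paths are
#' resampled to a common progress parameter; the between-path spread
#' (variance of half the matched forward-reverse separation, i.e. each
#' path's deviation from their common mid-line, which removes the shared
#' start-to-target trend) is compared with the leading eigenvalue of the
#' pooled PC1-2 covariance. The score is the resulting minor/major axis
#' ratio of the divergence ellipse: 0 when forward and reverse coincide
#' exactly, approaching 1 for maximally divergent loops, and equal to b/a
#' for a symmetric elliptical loop with axis ratio b/a.
#'
#' @param forward,reverse [project_structures()] tables (PC1, PC2 columns)
#'   of the two pathways, forward given start-to-target and reverse
#'   target-to-start (project an [asymmetry_inputs()] bundle's trajectories
#'   first).
#' @param m Number of resampling points (default 200).
#' @return Score in `[0, 1]`.
#' @export
asymmetry_score <- function(forward, reverse = NULL, m = 200L) {
  if (inherits(forward, "path_pair"))
    stop("project the bundled paths first (see project_structures)")
  F <- as.matrix(forward[, c("PC1", "PC2")])
  R <- as.matrix(reverse[, c("PC1", "PC2")])
  pooled <- rbind(F, R)
  if (all(abs(sweep(pooled, 2L, pooled[1L, ])) < 1e-12))
    stop("degenerate input: all points identical")
  Rflip <- R[rev(seq_len(nrow(R))), , drop = FALSE]  # start -> target
  Fr <- .resample_path(F, m)
  Rr <- .resample_path(Rflip, m)
  dev <- (Fr - Rr) / 2                # each path's offset from the mid-line
  var_perp <- mean(rowSums(dev^2))
  lam1 <- max(eigen(stats::cov(pooled), symmetric = TRUE)$values)
  if (lam1 <= 0) return(0)
  min(1, sqrt(var_perp / lam1))
}

#' Free-energy-style histogram of PC1-2 projections
#'
#' Pools the projection sets, bins them on a regular PC1-2 grid, and maps
#' normalized density to `-kB T ln(p)`, shifted so the minimum is 0. Empty
#' bins are NA (masked). This is a display utility for comparing sampling
#' densities with energy landscapes; it does not compute free energies from
#' physical sampling weights.
#'
#' @param sets A [project_structures()] table or list of them.
#' @param bins Number of bins per axis (>= 2, default 40).
#' @param temperature Kelvin (default 300), sets the energy scale.
#' @return List of class `projection_fel`: `x`, `y` bin centres and matrix
#'   `G` (kcal/mol, bins x bins).
#' @export
projection_histogram <- function(sets, bins = 40L, temperature = 300) {
  if (bins < 2L) stop("bins must be >= 2")
  if (is.data.frame(sets)) sets <- list(sets)
  if (length(sets) == 0L) stop("no projection sets")
  P <- do.call(rbind, lapply(sets, function(s)
    as.matrix(s[, c("PC1", "PC2")])))
  xr <- range(P[, 1L]); yr <- range(P[, 2L])
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  xr <- pad(xr); yr <- pad(yr)
  xb <- seq(xr[1L], xr[2L], length.out = bins + 1L)
  yb <- seq(yr[1L], yr[2L], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(P[, 1L], xb, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(P[, 2L], yb, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  for (k in seq_len(nrow(P)))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  p <- counts / sum(counts)
  G <- -(.kB * temperature) * log(p)
  G[!is.finite(G)] <- NA
  G <- G - min(G, na.rm = TRUE)
  structure(list(x = (xb[-1L] + xb[-(bins + 1L)]) / 2,
                 y = (yb[-1L] + yb[-(bins + 1L)]) / 2, G = G,
                 temperature = temperature),
            class = "projection_fel")
}
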