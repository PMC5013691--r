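# Essential-dynamics calibrated elastic network: topology, forces, Hessian,
# normal modes, Monte-Carlo mode ensembles.

#' Parameters of the ED-ENM force field
#'
#' The network mixes two spring classes. Near chain neighbours (sequence
#' separation `s <= n_seq`, same chain, no gap) get stiff MD-calibrated
#' constants `c_seq / s^2` that preserve backbone stereochemistry; all other
#' pairs within `cutoff` get a distance-decaying constant
#' `energy_scale * (c_cart / d0)^power`. Defaults are configuration values
#' standing in for the published essential-dynamics calibration and are
#' freely settable.
#'
#' @param c_seq Sequential spring scale, kcal mol^-1 A^-2 (default 60).
#' @param n_seq Number of chain neighbours with fixed springs (default 3).
#' @param c_cart Long-range length scale, Angstrom (default 6).
#' @param power Long-range decay exponent (default 6).
#' @param cutoff Interaction cutoff, Angstrom (default 12).
#' @param energy_scale Long-range prefactor, kcal mol^-1 A^-2 (default 6).
#' @return List of class `enm_params`.
#' @export
enm_params <- function(c_seq = 60, n_seq = 3L, c_cart = 6, power = 6,
                       cutoff = 12, energy_scale = 6) {
  stopifnot(c_seq > 0, n_seq >= 1L, c_cart > 0, power > 0,
            cutoff > 3.8, energy_scale > 0)
  structure(list(c_seq = c_seq, n_seq = as.integer(n_seq), c_cart = c_cart,
                 power = power, cutoff = cutoff, energy_scale = energy_scale),
            class = "enm_params")
}

#' Build the ED-ENM spring network of a structure
#'
#' Equilibrium lengths `d0` are the pair distances in the build structure.
#' A gap in author numbering or a chain change demotes a near-neighbour pair
#' to the long-range rule, so springs across chain breaks do not inherit
#' backbone stiffness. Pairs beyond `cutoff` (and not sequential) carry no
#' spring. Warns if the resulting network is not a single connected
#' component.
#'
#' @param model A [ca_model()].
#' @param params An [enm_params()].
#' @return List of class `enm_topology`: integer matrix `pairs` (i < j),
#'   `K` (kcal mol^-1 A^-2), `d0` (Angstrom), plus the build coordinates.
#' @export
#' @examples
#' m <- ca_model("dimer", c("A", "A"), 1:2, c("ALA", "ALA"),
#'               rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' top <- build_ed_enm(m, enm_params())
#' top$K  # c_seq for the s = 1 backbone pair
build_ed_enm <- function(model, params = enm_params()) {
  stopifnot(inherits(model, "ca_model"), inherits(params, "enm_params"))
  n <- model$n
  x <- model$coords
  resno <- .resno_numeric(model$res_ids)
  has_icode <- grepl("[A-Za-z]$", model$res_ids)

  ii <- jj <- integer(0); KK <- dd <- numeric(0)
  D <- as.matrix(stats::dist(x))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- j - i
      sequential <- s <= params$n_seq &&
        model$chain_ids[i] == model$chain_ids[j] &&
        !has_icode[i] && !has_icode[j] &&
        (resno[j] - resno[i]) == s
      d0 <- D[i, j]
      if (sequential) {
        k <- params$c_seq / s^2
      } else if (d0 <= params$cutoff) {
        k <- params$energy_scale * (params$c_cart / d0)^params$power
      } else next
      ii <- c(ii, i); jj <- c(jj, j); KK <- c(KK, k); dd <- c(dd, d0)
    }
  }
  if (any(dd <= 0)) stop("coincident residues in build structure")
  top <- structure(list(pairs = cbind(i = ii, j = jj), K = KK, d0 = dd,
                        coords = x, n = n),
                   class = "enm_topology")
  if (!.network_connected(top))
    warning("elastic network is not a single connected component")
  top
}

# breadth-first connectivity over the spring list
.network_connected <- function(top) {
  n <- top$n
  adj <- vector("list", n)
  for (k in seq_len(nrow(top$pairs))) {
    i <- top$pairs[k, 1L]; j <- top$pairs[k, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]; new <- nb[!seen[nb]]
    seen[new] <- TRUE; queue <- c(queue, new)
  }
  all(seen)
}

#' @export
print.enm_topology <- function(x, ...) {
  cat("enm_topology: ", x$n, " residues, ", nrow(x$pairs), " springs\n",
      sep = "")
  invisible(x)
}

#' Network potential energy
#'
#' `V = sum_pairs K (d - d0)^2` (note: no 1/2 factor; the force constant
#' convention matches [enm_forces()] and [enm_hessian()]).
#'
#' @param topology An [build_ed_enm()] topology.
#' @param coords N x 3 coordinates, Angstrom.
#' @return Energy in kcal mol^-1; 0 at the build geometry.
#' @export
enm_energy <- function(topology, coords) {
  coords <- .as_coords(coords)
  dv <- coords[topology$pairs[, 2L], , drop = FALSE] -
        coords[topology$pairs[, 1L], , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  sum(topology$K * (d - topology$d0)^2)
}

#' Spring forces on every residue
#'
#' Analytic gradient of the network potential: `F = -grad V` with
#' `V = sum K (d - d0)^2`, so a pair stretched by `delta` pulls each partner
#' with magnitude `2 K delta`. Internal forces: the net force and torque are
#' zero.
#'
#' @inheritParams enm_energy
#' @return N x 3 matrix, kcal mol^-1 A^-1.
#' @export
enm_forces <- function(topology, coords) {
  coords <- .as_coords(coords)
  if (nrow(coords) != topology$n) stop("coords do not conform to topology")
  i <- topology$pairs[, 1L]; j <- topology$pairs[, 2L]
  dv <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  if (any(d == 0)) stop("coincident bonded pair: force undefined")
  coef <- 2 * topology$K * (d - topology$d0) / d   # dV/dd / d
  F <- matrix(0, topology$n, 3L)
  pull <- dv * coef
  for (a in 1:3) {
    F[, a] <- F[, a] + tapply(c(pull[, a], -pull[, a]),
                              factor(c(i, j), levels = seq_len(topology$n)),
                              sum, default = 0)
  }
  F
}

#' Analytic Hessian of the network potential
#'
#' Exact second derivatives of `V = sum K (d - d0)^2` evaluated at the build
#' geometry (`d = d0`), where each pair contributes the rank-1 block
#' `2 K u u^T` along its bond unit vector. Symmetric and positive
#' semidefinite, with 6 zero eigenvalues for a connected 3-D network.
#'
#' @param topology An [build_ed_enm()] topology.
#' @return Dense 3N x 3N matrix (x1, y1, z1, x2, ... ordering).
#' @export
enm_hessian <- function(topology) {
  n <- topology$n
  H <- matrix(0, 3L * n, 3L * n)
  for (k in seq_len(nrow(topology$pairs))) {
    i <- topology$pairs[k, 1L]; j <- topology$pairs[k, 2L]
    u <- topology$coords[j, ] - topology$coords[i, ]
    u <- u / sqrt(sum(u^2))
    B <- (2 * topology$K[k]) * tcrossprod(u)
    ix <- (3L * (i - 1L) + 1L):(3L * i)
    jx <- (3L * (j - 1L) + 1L):(3L * j)
    H[ix, ix] <- H[ix, ix] + B
    H[jx, jx] <- H[jx, jx] + B
    H[ix, jx] <- H[ix, jx] - B
    H[jx, ix] <- H[jx, ix] - B
  }
  H
}

#' Normal modes of the elastic network
#'
#' Diagonalizes the Hessian and discards the rigid-body modes, identified by
#' the eigenvalue gap above the near-zero cluster rather than by a fixed
#' count of 6 (collinear toy systems have 5). Residue mass is uniform
#' (100 Da), so mass weighting is a scalar and the returned eigenvectors are
#' the Cartesian ones.
#'
#' @param topology An [build_ed_enm()] topology (connected network).
#' @param n_modes Number of lowest non-rigid modes to keep (default: all).
#' @return List of class `enm_modes`: `eigenvalues` (ascending,
#'   kcal mol^-1 A^-2), `vectors` (3N x n_modes, orthonormal columns),
#'   `n_zero`, and the build coordinates `coords`.
#' @export
normal_modes <- function(topology, n_modes = NULL) {
  H <- enm_hessian(topology)
  eig <- eigen(H, symmetric = TRUE)
  ev <- rev(eig$values)                       # ascending
  V <- eig$vectors[, rev(seq_along(ev)), drop = FALSE]
  tol <- max(ev) * 1e-8
  n_zero <- sum(ev < tol)
  if (n_zero < 3L || n_zero > 6L) {
    # fall back on the largest relative gap in the low spectrum
    lo <- pmax(ev[1:8], .Machine$double.eps)
    gaps <- diff(log(lo))
    n_zero <- which.max(gaps)
  }
  avail <- length(ev) - n_zero
  if (is.null(n_modes)) n_modes <- avail
  if (n_modes > avail)
    stop("n_modes = ", n_modes, " exceeds the ", avail, " non-rigid modes")
  idx <- seq(n_zero + 1L, n_zero + n_modes)
  structure(list(eigenvalues = ev[idx],
                 vectors = V[, idx, drop = FALSE],
                 n_zero = n_zero, coords = topology$coords, n = topology$n),
            class = "enm_modes")
}

#' @export
print.enm_modes <- function(x, ...) {
  cat("enm_modes: ", length(x$eigenvalues), " non-rigid modes (",
      x$n_zero, " rigid-body modes removed)\n", sep = "")
  invisible(x)
}

#' Overlap of a mode with a difference vector
#'
#' Absolute normalized inner product, the standard measure of how much of a
#' conformational change a single mode captures.
#'
#' @param mode 3N vector (a column of `enm_modes$vectors`).
#' @param delta 3N displacement vector (e.g. target minus start,
#'   flattened row-wise as x1, y1, z1, ...).
#' @return Fraction in `[0, 1]`.
#' @export
mode_overlap <- function(mode, delta) {
  nd <- sqrt(sum(delta^2))
  if (nd == 0) stop("zero difference vector")
  abs(sum(mode * delta)) / (sqrt(sum(mode^2)) * nd)
}

# flatten N x 3 coordinates to the 3N ordering used by the Hessian
.flatten_xyz <- function(x) as.numeric(t(x))
.unflatten_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Monte-Carlo ensemble along low-frequency normal modes
#'
#' Draws mode amplitudes from the harmonic Boltzmann distribution at
#' temperature `T`: `a_k ~ N(0, kB T / lambda_k)` (equipartition under the
#' `V = sum K (d - d0)^2` convention, whose curvature along mode k is
#' `lambda_k`), and adds `sum_k a_k v_k` to the build coordinates.
#'
#' @param modes An [normal_modes()] object.
#' @param temperature Kelvin (default 300).
#' @param n_samples Number of frames.
#' @param seed Integer seed; same seed, same trajectory.
#' @return A [ca_trajectory()].
#' @export
mc_sample_along_modes <- function(modes, temperature = 300, n_samples,
                                  seed = 1L) {
  stopifnot(inherits(modes, "enm_modes"), n_samples >= 1L)
  if (any(modes$eigenvalues <= 0)) stop("non-positive eigenvalue among modes")
  x0 <- .flatten_xyz(modes$coords)
  sds <- sqrt(.kB * temperature / modes$eigenvalues)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nm <- length(sds)
  frames <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    a <- rnorm(nm, 0, sds)
    frames[[s]] <- .unflatten_xyz(x0 + as.numeric(modes$vectors %*% a))
  }
  ca_trajectory(frames)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
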