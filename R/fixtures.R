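# Deterministic synthetic hinge proteins: two helical-lattice domains
# joined by a short linker, conformers generated by rotating the second
# domain about the hinge axis. Emulates a two-domain hinge-bending motion
# (the classic open/closed periplasmic-binding-protein geometry) so that
# every module can be exercised without downloading structures.

#' Specification of a synthetic two-domain hinge protein
#'
#' @param n_per_domain Residues per rigid domain (>= 10, default 30).
#' @param hinge_angle_open Hinge angle of the open end-state, degrees
#'   (default 0).
#' @param hinge_angle_closed Hinge angle of the closed end-state, degrees
#'   (default -90; with the default geometry the open/closed RMSD is about
#'   5 Angstrom).
#' @param n_intermediates Conformers interpolated strictly between the
#'   end-states (default 0).
#' @param noise_sd Gaussian coordinate noise, Angstrom (default 0).
#' @param seed Integer seed for the noise (default 1).
#' @return List of class `hinge_spec`.
#' @export
hinge_spec <- function(n_per_domain = 30L, hinge_angle_open = 0,
                       hinge_angle_closed = -90, n_intermediates = 0L,
                       noise_sd = 0, seed = 1L) {
  stopifnot(n_per_domain >= 10L, hinge_angle_open != hinge_angle_closed,
            noise_sd >= 0, n_intermediates >= 0L)
  structure(list(n_per_domain = as.integer(n_per_domain),
                 hinge_angle_open = hinge_angle_open,
                 hinge_angle_closed = hinge_angle_closed,
                 n_intermediates = as.integer(n_intermediates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "hinge_spec")
}

# compact rigid domain: a triangular bundle of 10-residue helices on an
# idealized lattice (rise 1.5 A, radius 2.3 A, 100 deg/residue, so
# consecutive C-alpha separations sit at the canonical 3.8 A), helix
# centres 9 A apart so no non-bonded pair clashes. A compact, internally
# well-connected domain is essential: it makes the inter-domain hinge the
# softest motion of the elastic network rather than domain bending.
.domain_points <- function(n, origin = c(0, 0, 0)) {
  offs <- rbind(c(0, 0), c(9, 0), c(4.5, 7.8),
                c(13.5, 7.8), c(9, 15.6), c(0, 15.6))
  out <- matrix(0, n, 3L)
  for (g in seq_len(n)) {
    i <- g - 1L
    s <- i %/% 10L                        # helix index within the bundle
    l <- i %% 10L                         # position within the helix
    along <- if (s %% 2L == 0L) 1.5 * l else 1.5 * (9L - l)
    theta <- l * 100 * pi / 180
    out[g, ] <- origin + c(along, 2.3 * cos(theta) + offs[s %% 6L + 1L, 1L],
                           2.3 * sin(theta) + offs[s %% 6L + 1L, 2L])
  }
  out
}

.rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  ux <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
               3L, 3L, byrow = TRUE)
  ca * diag(3) + sa * ux + (1 - ca) * tcrossprod(u)
}

#' Generate the conformers of a synthetic hinge protein
#'
#' Domain 1 is a compact helix bundle ending at the hinge; a 3-residue
#' linker bridges to domain 2, an equivalent bundle beyond it. Conformers
#' rotate domain 2 (and the linker, proportionally) about the network's
#' natural soft axis through the hinge point (the axis about which the
#' lowest normal mode of the open-state elastic network is an almost pure
#' rigid counter-rotation of the domains), at angles linearly interpolated
#' from open to closed. The models are ordered open, intermediates,
#' closed, and are bit-reproducible from the spec.
#'
#' @param spec A [hinge_spec()].
#' @return List of `2 + n_intermediates` [ca_model()]s with ids
#'   `hinge_<angle>`.
#' @export
#' @examples
#' models <- make_hinge_models(hinge_spec())
#' rmsd(models[[1]], models[[2]])  # open/closed amplitude
make_hinge_models <- function(spec = hinge_spec()) {
  stopifnot(inherits(spec, "hinge_spec"))
  nd <- spec$n_per_domain
  d1 <- .domain_points(nd)
  hinge <- d1[nd, ] + c(3.8, 0, 0)
  linker <- rbind(hinge,
                  hinge + c(2.7, 2.7, 0),
                  hinge + c(5.4, 0, 0))
  d2_origin <- linker[3L, ] + c(3.8, 0, 0)
  d2 <- .domain_points(nd, origin = d2_origin)
  base <- rbind(d1, linker, d2)
  n <- nrow(base)

  angles <- seq(spec$hinge_angle_open, spec$hinge_angle_closed,
                length.out = spec$n_intermediates + 2L)
  moving <- seq(nd + 2L, n)       # linker residues 2-3 + domain 2
  weight <- c(0.5, rep(1, length(moving) - 1L))  # mid-linker moves halfway
  axis <- c(1, 2, 0) / sqrt(5)    # axis of the network's softest hinge mode

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lapply(angles, function(ang) {
    x <- base
    for (k in seq_along(moving)) {
      Rk <- .rotation_about_axis(axis, ang * weight[k])
      x[moving[k], ] <- as.numeric(Rk %*% (base[moving[k], ] - hinge)) + hinge
    }
    if (spec$noise_sd > 0)
      x <- x + matrix(rnorm(3L * n, 0, spec$noise_sd), n, 3L)
    ca_model(sprintf("hinge_%03d", round(ang)), rep("A", n),
             seq_len(n), rep("ALA", n), x)
  })
}

#' Synthetic ensemble with known principal components
#'
#' Members are `mean + sum_k a_k v_k` with independent Gaussian amplitudes
#' `a_k ~ N(0, amplitudes_sd[k]^2)` along user-supplied orthonormal 3N
#' vectors: the ground truth against which PCA recovery is judged.
#'
#' @param mean_model A [ca_model()] providing the mean coordinates and
#'   metadata.
#' @param basis_vectors 3N x k matrix (or list) of orthonormal columns.
#' @param amplitudes_sd Standard deviation per vector, Angstrom.
#' @param n Number of members.
#' @param seed Integer seed.
#' @return A `ca_ensemble` whose first member is the reference.
#' @export
make_pca_ensemble <- function(mean_model, basis_vectors, amplitudes_sd, n,
                              seed = 1L) {
  stopifnot(inherits(mean_model, "ca_model"), n >= 2L)
  V <- if (is.list(basis_vectors)) do.call(cbind, basis_vectors)
       else as.matrix(basis_vectors)
  if (nrow(V) != 3L * mean_model$n)
    stop("basis vectors must have length 3N")
  G <- crossprod(V)
  if (max(abs(G - diag(ncol(V)))) > 1e-8)
    stop("basis vectors are not orthonormal")
  if (length(amplitudes_sd) != ncol(V))
    stop("one amplitude sd per basis vector")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- .flatten_xyz(mean_model$coords)
  members <- lapply(seq_len(n), function(s) {
    a <- rnorm(ncol(V), 0, amplitudes_sd)
    ca_model(sprintf("%s_m%03d", mean_model$id, s), mean_model$chain_ids,
             mean_model$res_ids, mean_model$res_names,
             .unflatten_xyz(mu + as.numeric(V %*% a)))
  })
  structure(list(members = members, reference_index = 1L),
            class = "ca_ensemble")
}

#' Write hinge conformers as PDB files
#'
#' One file per conformer, named by the model id.
#'
#' @param spec A [hinge_spec()].
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
write_hinge_fixtures <- function(spec = hinge_spec(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  models <- make_hinge_models(spec)
  paths <- vapply(models, function(m) {
    p <- file.path(dir, paste0(m$id, ".pdb"))
    write_multimodel_pdb(m, NULL, p)
    p
  }, "")
  invisible(paths)
}
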