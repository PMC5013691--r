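# Dynamic importance sampling: the Maxwell demon that turns unbiased
# Langevin dynamics into a directed transition pathway.

#' Demon (dynamic importance sampling) parameters
#'
#' Every `k_unbiased` Langevin steps the progress variable Gamma towards the
#' target is re-evaluated; the stretch is kept only if Gamma strictly
#' decreased, otherwise coordinates and velocities revert to the last
#' accepted checkpoint (the RNG stream continues, so the retry explores a
#' new random branch). Iteration stops when the structure reaches the
#' target basin: RMSD within the range of thermal oscillations.
#'
#' @param k_unbiased Unbiased steps per demon cycle (default 100). Larger k
#'   samples more widely but converges more slowly.
#' @param convergence_rmsd Convergence threshold in Angstrom. Default
#'   `NA`, resolved at run time to 1.5 A, widened to 3.0 A for systems with
#'   more than 1000 residues.
#' @param max_cycles Demon cycles before giving up (default 40000).
#' @param pair_subset Optional integer matrix of residue index pairs
#'   restricting Gamma (partial-target restraints when the target has
#'   missing regions).
#' @param seed Integer RNG seed.
#' @return List of class `dims_params`.
#' @export
dims_params <- function(k_unbiased = 100L, convergence_rmsd = NA,
                        max_cycles = 40000L, pair_subset = NULL, seed = 1L) {
  stopifnot(k_unbiased >= 1L, max_cycles >= 1L)
  if (!is.na(convergence_rmsd))
    stopifnot(convergence_rmsd > 0, convergence_rmsd <= 5)
  structure(list(k_unbiased = as.integer(k_unbiased),
                 convergence_rmsd = convergence_rmsd,
                 max_cycles = as.integer(max_cycles),
                 pair_subset = pair_subset, seed = as.integer(seed)),
            class = "dims_params")
}

.resolve_conv_rmsd <- function(conv, n) {
  if (!is.na(conv)) return(conv)
  if (n > 1000L) 3.0 else 1.5
}

#' Progress variable Gamma towards a target structure
#'
#' `Gamma = sum_(i,j in P) (d_ij(coords) - d_ij(target))^2` over the pair
#' set P (all residue pairs of the correspondence by default). Built from
#' inter-residue distances only, so it is invariant under rigid motion of
#' either structure and needs no superposition; Gamma = 0 exactly at the
#' target geometry.
#'
#' @param coords N x 3 coordinates or [ca_model()].
#' @param target [ca_model()] (or N x 3 matrix) corresponded with `coords`.
#' @param pair_subset Optional 2-column integer matrix of index pairs.
#' @return Gamma in Angstrom^2.
#' @export
#' @examples
#' a <- matrix(c(0, 0, 0, 1, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE)
#' b <- matrix(c(0, 0, 0, 2, 0, 0, 6, 0, 0), 3, 3, byrow = TRUE)
#' progress_variable(a, b)  # (1-2)^2 + (3-6)^2 + (2-4)^2 = 14
progress_variable <- function(coords, target, pair_subset = NULL) {
  x <- .as_coords(coords); y <- .as_coords(target)
  if (nrow(x) != nrow(y)) stop("coords and target are not corresponded")
  if (is.null(pair_subset)) {
    n <- nrow(x)
    if (n < 2L) stop("empty pair set")
    pair_subset <- t(utils::combn(n, 2L))
  }
  if (nrow(pair_subset) == 0L) stop("empty pair set")
  i <- pair_subset[, 1L]; j <- pair_subset[, 2L]
  dx <- sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
  dy <- sqrt(rowSums((y[i, , drop = FALSE] - y[j, , drop = FALSE])^2))
  sum((dx - dy)^2)
}

#' Demon acceptance rule
#'
#' Accept iff the progress variable strictly decreased; equality is
#' rejected, which prevents stagnation loops on Gamma plateaus.
#'
#' @param gamma_now,gamma_prev Progress variable now and at the last
#'   accepted checkpoint, Angstrom^2.
#' @return Logical.
#' @export
demon_accept <- function(gamma_now, gamma_prev) {
  stopifnot(is.finite(gamma_now), is.finite(gamma_prev))
  gamma_now < gamma_prev
}

#' Generate a biased transition pathway between two structures
#'
#' Builds the elastic network from the start structure, then alternates
#' stretches of unbiased Langevin dynamics with demon accept/reject tests
#' on the pairwise-distance progress variable until the trajectory reaches
#' the target basin (RMSD below the convergence threshold) or `max_cycles`
#' demon cycles have run. The reverse pathway is the same call with the
#' roles of start and target swapped.
#'
#' Start and target are corresponded by (chain, residue id); the start
#' model may contain residues absent from the target (they move but do not
#' enter Gamma or the RMSD), which is how partial-target restraints work.
#'
#' @param start,target [ca_model()]s.
#' @param enm_parameters An [enm_params()].
#' @param bd_parameters A [bd_params()].
#' @param dims_parameters A [dims_params()]; its `seed` controls the run.
#' @return Object of class `ebdims_path`: `trajectory` (accepted
#'   checkpoints, first frame = start), `gamma_series` (A^2, strictly
#'   decreasing), `rmsd_to_target` (A, over the corresponded residues),
#'   `converged`, `n_rejections`, `cycles_run`, `model` (the start model)
#'   and `correspondence` (start-model indices used against the target).
#' @export
run_transition <- function(start, target, enm_parameters = enm_params(),
                           bd_parameters = bd_params(),
                           dims_parameters = dims_params()) {
  stopifnot(inherits(start, "ca_model"), inherits(target, "ca_model"))
  # correspondence: target residues present in the start model
  tkey <- .res_key(target); skey <- .res_key(start)
  sidx <- match(tkey, skey)
  keep <- !is.na(sidx)
  if (sum(keep) < 2L) stop("start and target share fewer than 2 residues")
  sidx <- sidx[keep]
  tcoords <- target$coords[keep, , drop = FALSE]

  ps <- dims_parameters$pair_subset
  if (is.null(ps)) {
    gp <- t(utils::combn(length(sidx), 2L))
    gamma_pairs <- cbind(sidx[gp[, 1L]], sidx[gp[, 2L]])
    tp <- gp
  } else {
    gamma_pairs <- ps          # indices into the start model
    tp <- cbind(match(ps[, 1L], sidx), match(ps[, 2L], sidx))
    if (any(is.na(tp))) stop("pair_subset refers to residues absent from target")
  }
  dtarg <- sqrt(rowSums((tcoords[tp[, 1L], , drop = FALSE] -
                         tcoords[tp[, 2L], , drop = FALSE])^2))

  topology <- build_ed_enm(start, enm_parameters)
  conv <- .resolve_conv_rmsd(dims_parameters$convergence_rmsd, start$n)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(dims_parameters$seed)
  out <- cpp_run_transition(start$coords, topology$pairs, topology$K,
                            topology$d0,
                            matrix(as.integer(gamma_pairs), ncol = 2L),
                            dtarg, as.integer(sidx), tcoords,
                            dims_parameters$k_unbiased,
                            dims_parameters$max_cycles, conv,
                            bd_parameters$dt, bd_parameters$gamma * 1e-3,
                            bd_parameters$temperature, bd_parameters$mass)
  nf <- dim(out$frames)[3L]
  frames <- lapply(seq_len(nf), function(k) out$frames[, , k])
  structure(list(trajectory = ca_trajectory(frames),
                 gamma_series = as.numeric(out$gamma_series),
                 rmsd_to_target = as.numeric(out$rmsd_to_target),
                 converged = out$converged,
                 n_rejections = out$n_rejections,
                 cycles_run = out$cycles_run,
                 convergence_rmsd = conv,
                 model = start, correspondence = sidx),
            class = "ebdims_path")
}

#' @export
print.ebdims_path <- function(x, ...) {
  cat("ebdims_path: ", length(x$trajectory$frames), " checkpoints, ",
      if (x$converged) "converged" else "NOT converged",
      sprintf(" (final rMSD %.2f A, %d rejections)\n",
              tail(x$rmsd_to_target, 1L), x$n_rejections), sep = "")
  invisible(x)
}

#' Bundle forward and reverse pathways for projection analysis
#'
#' Keeps the pair ordered (forward first) for downstream PC projection and
#' asymmetry scoring.
#'
#' @param forward,reverse [run_transition()] results.
#' @return List of class `path_pair`.
#' @export
asymmetry_inputs <- function(forward, reverse) {
  if (missing(reverse) || is.null(reverse))
    stop("both forward and reverse paths are required")
  stopifnot(inherits(forward, "ebdims_path"), inherits(reverse, "ebdims_path"))
  structure(list(forward = forward, reverse = reverse), class = "path_pair")
}
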