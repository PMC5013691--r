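# C-alpha models, PDB I/O, residue correspondence, superposition.

#' Construct a C-alpha model
#'
#' A `ca_model` is one protein structure reduced to its C-alpha trace:
#' per-residue chain label, author residue id (insertion codes kept as part
#' of the id string), 3-letter residue name, and an N x 3 coordinate matrix
#' in Angstrom.
#'
#' Residues must be unique by (chain, residue id) and ordered chain-by-chain.
#'
#' @param id Text label (e.g. a PDB code).
#' @param chain_ids Character vector, one chain label per residue.
#' @param res_ids Character (or integer) vector of author residue numbers;
#'   insertion codes are appended to the number (e.g. `"52A"`).
#' @param res_names Character vector of 3-letter residue codes.
#' @param coords Numeric N x 3 matrix of positions in Angstrom.
#' @return An object of class `ca_model`.
#' @export
#' @examples
#' m <- ca_model("toy", rep("A", 3), 1:3, rep("ALA", 3),
#'               matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE))
#' m$n
ca_model <- function(id, chain_ids, res_ids, res_names, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 2L) stop("a ca_model needs at least 2 residues")
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  if (!all(is.finite(coords))) stop("coords must be finite")
  chain_ids <- as.character(chain_ids)
  res_ids <- as.character(res_ids)
  res_names <- as.character(res_names)
  if (length(chain_ids) != n || length(res_ids) != n || length(res_names) != n)
    stop("chain_ids, res_ids, res_names must match nrow(coords)")
  key <- paste(chain_ids, res_ids, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain, res_id) pairs: ", key[duplicated(key)][1])
  dimnames(coords) <- NULL
  structure(list(id = as.character(id)[1], chain_ids = chain_ids,
                 res_ids = res_ids, res_names = res_names,
                 coords = coords, n = n),
            class = "ca_model")
}

#' @export
print.ca_model <- function(x, ...) {
  cat("ca_model '", x$id, "': ", x$n, " residues, ",
      length(unique(x$chain_ids)), " chain(s)\n", sep = "")
  invisible(x)
}

# numeric part of an author residue id ("52A" -> 52)
.resno_numeric <- function(res_ids) {
  as.integer(sub("^(-?[0-9]+).*$", "\\1", res_ids))
}

.res_key <- function(model) paste(model$chain_ids, model$res_ids, sep = "|")

#' Read the C-alpha trace of one model from a PDB file
#'
#' Parses the file with [bio3d::read.pdb()] and keeps one CA atom per
#' standard (ATOM-record) residue. HETATM records and residues without a CA
#' are skipped; insertion codes are appended to the residue id.
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based index of the MODEL to read (multi-model files).
#' @param altloc_policy How to resolve alternate locations of a CA atom:
#'   `"occupancy"` keeps the highest-occupancy conformer (ties: first
#'   listed), `"first"` keeps the first listed, `"strict"` errors.
#' @return A [ca_model()].
#' @export
read_pdb_ca <- function(path, model_index = 1L,
                        altloc_policy = c("occupancy", "first", "strict")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  atom <- pdb$atom
  sel <- atom$type == "ATOM" & atom$elety == "CA"
  if (!any(sel)) stop("no CA atoms in ", path)
  atom <- atom[sel, , drop = FALSE]
  rows <- which(sel)

  ins <- atom$insert
  ins[is.na(ins)] <- ""
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  resid_full <- paste0(atom$resno, ins)
  key <- paste(chain, resid_full, sep = "|")

  keep <- logical(nrow(atom))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      if (altloc_policy == "strict")
        stop("duplicate CA (altloc) for residue ", k)
      if (altloc_policy == "occupancy") {
        occ <- atom$o[idx]
        occ[is.na(occ)] <- 0
        idx <- idx[which.max(occ)]  # which.max: first of ties
      } else idx <- idx[1L]
    }
    keep[idx] <- TRUE
  }
  atom <- atom[keep, , drop = FALSE]
  rows <- rows[keep]

  nmod <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ", nmod, ")")
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)[rows, , drop = FALSE]

  ins2 <- atom$insert
  ins2[is.na(ins2)] <- ""
  chain2 <- atom$chain
  chain2[is.na(chain2)] <- " "
  id <- sub("\\.pdb$", "", basename(path))
  ca_model(id, chain2, paste0(atom$resno, ins2), atom$resid, xyz)
}

#' Write a C-alpha model or trajectory as a (multi-model) PDB file
#'
#' Each trajectory frame becomes one MODEL/ENDMDL block; coordinates are
#' written at 3 decimals in standard ATOM fixed-column format. With
#' `traj = NULL` the model's own coordinates are written as a single model.
#'
#' @param model A [ca_model()] providing residue metadata.
#' @param traj Optional [ca_trajectory()] (or list of N x 3 matrices)
#'   conforming to `model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(model, traj = NULL, path) {
  frames <- if (is.null(traj)) list(model$coords) else {
    fr <- if (inherits(traj, "ca_trajectory")) traj$frames else traj
    if (length(fr) == 0L) stop("empty trajectory")
    fr
  }
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != model$n || ncol(f) != 3L)
      stop("trajectory frame does not conform to model (", model$n, " x 3)")

  resno <- .resno_numeric(model$res_ids)
  icode <- sub("^-?[0-9]+", "", model$res_ids)
  icode[icode == ""] <- " "
  chain <- substr(model$chain_ids, 1L, 1L)

  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    x <- frames[[k]]
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(model$n) %% 100000L, substr(model$res_names, 1L, 3L),
      chain, resno, icode, x[, 1L], x[, 2L], x[, 3L], 1, 0)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a trajectory of conformations of one model
#'
#' @param frames List of N x 3 coordinate matrices.
#' @param steps Optional integer vector of per-frame step indices.
#' @return An object of class `ca_trajectory`.
#' @export
ca_trajectory <- function(frames, steps = seq_along(frames)) {
  if (length(frames) == 0L) stop("empty trajectory")
  n <- nrow(frames[[1L]])
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      stop("all frames must share the same N x 3 shape")
  structure(list(frames = frames, steps = as.integer(steps)),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat("ca_trajectory: ", length(x$frames), " frames of ",
      nrow(x$frames[[1L]]), " residues\n", sep = "")
  invisible(x)
}

#' Build the residue correspondence across an ensemble of models
#'
#' Keeps the residues resolved in all members, matched by (chain, residue
#' id), and trims every member to that common set (order taken from the
#' first model). Pairwise sequence identity over the matched positions must
#' reach `min_identity`; the ensembles this supports are same-protein
#' crystal forms, so no alignment algorithm is involved.
#'
#' @param models List of [ca_model()] (at least 2).
#' @param min_identity Minimum pairwise fraction of identical residue names
#'   over matched positions (default 0.95).
#' @param reference_index Which member is the designated reference
#'   (inactive/resting) state, default 1.
#' @return An object of class `ca_ensemble`: list of trimmed members plus
#'   `reference_index`.
#' @export
residue_correspondence <- function(models, min_identity = 0.95,
                                   reference_index = 1L) {
  if (length(models) < 2L) stop("need at least 2 models")
  nch <- vapply(models, function(m) length(unique(m$chain_ids)), 1L)
  if (length(unique(nch)) != 1L)
    stop("members have different chain counts (", paste(nch, collapse = ","), ")")
  keys <- lapply(models, .res_key)
  common <- Reduce(intersect, keys)
  if (length(common) < 2L) stop("empty residue intersection across members")
  # preserve first model's order
  common <- keys[[1L]][keys[[1L]] %in% common]

  trimmed <- lapply(models, function(m) {
    idx <- match(common, .res_key(m))
    ca_model(m$id, m$chain_ids[idx], m$res_ids[idx], m$res_names[idx],
             m$coords[idx, , drop = FALSE])
  })
  M <- length(trimmed)
  for (i in seq_len(M - 1L)) for (j in seq(i + 1L, M)) {
    ident <- mean(trimmed[[i]]$res_names == trimmed[[j]]$res_names)
    if (ident < min_identity)
      stop(sprintf("sequence identity %s/%s = %.2f below min_identity %.2f",
                   trimmed[[i]]$id, trimmed[[j]]$id, ident, min_identity))
  }
  if (reference_index < 1L || reference_index > M)
    stop("reference_index out of range")
  structure(list(members = trimmed, reference_index = as.integer(reference_index)),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat("ca_ensemble: ", length(x$members), " members x ",
      x$members[[1L]]$n, " residues (reference: ",
      x$members[[x$reference_index]]$id, ")\n", sep = "")
  invisible(x)
}

.as_coords <- function(x) {
  if (inherits(x, "ca_model")) x$coords
  else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop("expected an N x 3 coordinate matrix")
    x
  }
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid fit of `mobile` onto `target` over `subset`, with a
#' proper rotation (det = +1) enforced via SVD. Degenerate point sets (all
#' coincident, or collinear so the in-plane rotation is undetermined) are
#' flagged and get a translation-only fit.
#'
#' @param mobile,target N x 3 coordinate matrices or [ca_model()]s.
#' @param subset Optional integer indices of the residues used for the fit
#'   and the RMSD (default: all).
#' @return List with `rotation` (3 x 3), `translation` (length-3; the fit is
#'   `coords %*% rotation + translation`), `rmsd` (Angstrom, over `subset`
#'   after the fit), `coords` (all mobile coordinates transformed) and
#'   `degenerate` flag.
#' @export
superpose <- function(mobile, target, subset = NULL) {
  P <- .as_coords(mobile); Q <- .as_coords(target)
  if (nrow(P) != nrow(Q)) stop("mobile and target lengths differ")
  if (is.null(subset)) subset <- seq_len(nrow(P))
  if (length(subset) == 0L) stop("empty subset")
  Ps <- P[subset, , drop = FALSE]; Qs <- Q[subset, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  A <- sweep(Ps, 2L, cp); B <- sweep(Qs, 2L, cq)

  H <- crossprod(A, B)
  sv <- svd(H)
  degenerate <- sv$d[2L] <= max(sv$d[1L], 1e-12) * 1e-8
  if (degenerate && sv$d[1L] <= 1e-12) {
    R <- diag(3)                      # coincident points: translation only
  } else if (degenerate) {
    R <- diag(3)                      # collinear: rotation undetermined
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  tr <- cq - as.numeric(cp %*% R)
  fitted <- P %*% R + matrix(tr, nrow(P), 3L, byrow = TRUE)
  dev <- fitted[subset, , drop = FALSE] - Qs
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums(dev^2))),
       coords = fitted, degenerate = degenerate)
}

#' Root mean square deviation after optimal superposition
#'
#' @param a,b Coordinate matrices or [ca_model()]s of equal length.
#' @param subset Optional indices over which to fit and measure.
#' @param fit Superpose first (default TRUE); with `fit = FALSE` the raw
#'   deviation is measured.
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' rmsd(a, a)  # 0
rmsd <- function(a, b, subset = NULL, fit = TRUE) {
  A <- .as_coords(a); B <- .as_coords(b)
  if (fit) return(superpose(A, B, subset)$rmsd)
  if (is.null(subset)) subset <- seq_len(nrow(A))
  dev <- A[subset, , drop = FALSE] - B[subset, , drop = FALSE]
  sqrt(mean(rowSums(dev^2)))
}
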