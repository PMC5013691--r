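# Ensemble PCA: reference alignment, covariance eigendecomposition,
# projections, variance and transition-coverage fractions.

#' Principal component analysis of a structural ensemble
#'
#' Every member is superposed once onto the reference member (no iterative
#' mean realignment); the covariance of the aligned C-alpha coordinates is
#' taken about the ensemble mean (`center = "mean"`, standard PCA) or about
#' the reference structure (`center = "reference"`), and decomposed by SVD.
#' Projections ([project_structures()]) always subtract the REFERENCE
#' structure, so deformations are read relative to a real structure rather
#' than a geometric average; consequence: the reference itself generally
#' projects away from the origin of the mean-centred cloud, and its own
#' projection is part of any projection table.
#'
#' Component signs are fixed deterministically: each PC is flipped so the
#' member with the largest absolute projection projects positively.
#'
#' @param ensemble A [residue_correspondence()] ensemble with >= 3 members.
#' @param center `"mean"` (default) or `"reference"`.
#' @return Object of class `pca_basis`: `reference_coords`, `mean_coords`
#'   (both N x 3, aligned frame), `components` (3N x n_comp, descending
#'   eigenvalue, orthonormal), `eigenvalues` (A^2), `variance_fractions`
#'   (sum to 1 over the retained spectrum).
#' @export
fit_pca <- function(ensemble, center = c("mean", "reference")) {
  center <- match.arg(center)
  stopifnot(inherits(ensemble, "ca_ensemble"))
  M <- length(ensemble$members)
  if (M < 3L) stop("ensemble PCA needs at least 3 members")
  ref <- ensemble$members[[ensemble$reference_index]]
  aligned <- lapply(ensemble$members, function(m)
    superpose(m$coords, ref$coords)$coords)
  X <- do.call(rbind, lapply(aligned, .flatten_xyz))   # M x 3N
  mu <- colMeans(X)
  C0 <- if (center == "mean") mu else .flatten_xyz(ref$coords)
  Xc <- sweep(X, 2L, C0)

  sv <- svd(Xc)
  eig <- sv$d^2 / (M - 1L)
  keep <- eig > max(eig, 0) * 1e-12
  if (!any(keep)) stop("ensemble has no structural variance")
  eig <- eig[keep]
  V <- sv$v[, keep, drop = FALSE]

  # deterministic sign: largest-|projection| member projects positively
  refv <- .flatten_xyz(ref$coords)
  P <- sweep(X, 2L, refv) %*% V
  for (k in seq_len(ncol(V))) {
    s <- P[which.max(abs(P[, k])), k]
    if (s < 0) V[, k] <- -V[, k]
  }
  structure(list(reference_coords = ref$coords,
                 mean_coords = .unflatten_xyz(mu),
                 components = V, eigenvalues = eig,
                 variance_fractions = eig / sum(eig),
                 center = center, n = ref$n,
                 labels = vapply(ensemble$members, `[[`, "", "id")),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("pca_basis: ", length(x$eigenvalues), " components over ",
      x$n, " residues; PC1-2 variance ",
      sprintf("%.1f%%", 100 * sum(x$variance_fractions[1:min(2,
              length(x$variance_fractions))])), "\n", sep = "")
  invisible(x)
}

#' Project structures or trajectory frames onto principal components
#'
#' Each input conformation is superposed onto the basis reference and its
#' deviation FROM THE REFERENCE is dotted with the selected components:
#' `p_k = (x_aligned - x_ref) . PC_k`. Rigid motions applied to the input
#' are absorbed by the superposition.
#'
#' @param basis A [fit_pca()] basis.
#' @param x A [ca_model()], an N x 3 matrix, a [ca_trajectory()], or a list
#'   of N x 3 matrices.
#' @param k_components Number of leading PCs (default 2).
#' @param labels Optional per-conformation labels.
#' @return Data frame of class `pc_projection`: `label`, `PC1`, `PC2`, ...
#'   (Angstrom).
#' @export
project_structures <- function(basis, x, k_components = 2L, labels = NULL) {
  stopifnot(inherits(basis, "pca_basis"))
  if (k_components > ncol(basis$components))
    stop("k_components exceeds the ", ncol(basis$components),
         " stored components")
  frames <- if (inherits(x, "ca_trajectory")) x$frames
    else if (inherits(x, "ca_model")) list(x$coords)
    else if (is.matrix(x)) list(x)
    else x
  if (is.null(labels)) {
    labels <- if (inherits(x, "ca_model")) x$id
      else sprintf("frame_%d", seq_along(frames))
  }
  refv <- .flatten_xyz(basis$reference_coords)
  Vk <- basis$components[, seq_len(k_components), drop = FALSE]
  P <- t(vapply(frames, function(f) {
    fit <- superpose(f, basis$reference_coords)$coords
    as.numeric((.flatten_xyz(fit) - refv) %*% Vk)
  }, numeric(k_components)))
  if (k_components == 1L) P <- matrix(P, ncol = 1L)
  out <- data.frame(label = labels, P, stringsAsFactors = FALSE)
  names(out) <- c("label", paste0("PC", seq_len(k_components)))
  class(out) <- c("pc_projection", "data.frame")
  out
}

#' Fraction of a transition captured by the leading components
#'
#' With `Delta = aligned(target) - aligned(start)`, the coverage of the
#' first k PCs is `sum_(j<=k) (Delta . PC_j)^2 / |Delta|^2`.
#'
#' @param basis A [fit_pca()] basis.
#' @param start,target [ca_model()]s corresponded with the basis.
#' @param k Number of leading components (default 2).
#' @return Fraction in `[0, 1]`.
#' @export
transition_coverage <- function(basis, start, target, k = 2L) {
  stopifnot(inherits(basis, "pca_basis"))
  a <- superpose(.as_coords(start), basis$reference_coords)$coords
  b <- superpose(.as_coords(target), basis$reference_coords)$coords
  delta <- .flatten_xyz(b) - .flatten_xyz(a)
  n2 <- sum(delta^2)
  if (n2 == 0) stop("start and target coincide: zero difference vector")
  k <- min(k, ncol(basis$components))
  sum(as.numeric(delta %*% basis$components[, seq_len(k), drop = FALSE])^2) / n2
}

#' Euclidean distance in PC space
#'
#' The PC1-2 distance weights structural differences by the dominant
#' ensemble motions, filtering out the local fluctuations that inflate an
#' RMSD.
#'
#' @param a,b Numeric vectors of PC coordinates (same length), or single
#'   rows of a [project_structures()] table.
#' @return Distance in Angstrom.
#' @export
#' @examples
#' pc_distance(c(0, 0), c(3, 4))  # 5
pc_distance <- function(a, b) {
  a <- .pc_vec(a); b <- .pc_vec(b)
  if (length(a) != length(b)) stop("PC coordinate dimensions differ")
  sqrt(sum((a - b)^2))
}

.pc_vec <- function(x) {
  if (is.data.frame(x)) as.numeric(x[1L, startsWith(names(x), "PC")])
  else as.numeric(x)
}

#' Write a projection table as TSV
#'
#' @param projections A [project_structures()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_projections <- function(projections, path) {
  write.table(projections, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a projection table written by [write_projections()]
#'
#' @param path TSV path.
#' @return A `pc_projection` data frame.
#' @export
read_projections <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  class(out) <- c("pc_projection", "data.frame")
  out
}

#' Persist a PCA basis as plain text
#'
#' Reference coordinates, components and eigenvalues in a single
#' whitespace-delimited archive readable by [read_pca_basis()].
#'
#' @param basis A [fit_pca()] basis.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pca_basis <- function(basis, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# ebdims pca_basis n=%d n_comp=%d center=%s",
                     basis$n, ncol(basis$components), basis$center), con)
  writeLines(paste(format(basis$eigenvalues, digits = 17), collapse = " "), con)
  utils::write.table(basis$reference_coords, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(basis$mean_coords, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(basis$components, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_pca_basis
#' @export
read_pca_basis <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ebdims pca_basis ", "", lines[1L]), " ")[[1L]]
  kv <- do.call(rbind, strsplit(hdr, "="))
  n <- as.integer(kv[kv[, 1L] == "n", 2L])
  nc <- as.integer(kv[kv[, 1L] == "n_comp", 2L])
  center <- kv[kv[, 1L] == "center", 2L]
  eig <- as.numeric(strsplit(lines[2L], " +")[[1L]])
  body <- lines[-(1:2)]
  num <- function(rows) {
    m <- do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(trimws(l), " +")[[1L]])))
    m
  }
  refc <- num(body[seq_len(n)])
  meanc <- num(body[n + seq_len(n)])
  comp <- num(body[2L * n + seq_len(3L * n)])
  structure(list(reference_coords = refc, mean_coords = meanc,
                 components = comp, eigenvalues = eig,
                 variance_fractions = eig / sum(eig),
                 center = center, n = n, labels = NULL),
            class = "pca_basis")
}
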