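# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# straight same-chain C-alpha trace at canonical 3.8 A spacing
chain_model <- function(n, id = "chain", spacing = 3.8) {
  ca_model(id, rep("A", n), seq_len(n), rep("GLY", n),
           cbind(spacing * (seq_len(n) - 1L), 0, 0))
}

# two beads d0 apart on one chain: the analytic ENM reference system
two_bead_topology <- function(K = 60, d0 = 3.8) {
  m <- ca_model("dimer", c("A", "A"), 1:2, c("ALA", "ALA"),
                rbind(c(0, 0, 0), c(d0, 0, 0)))
  build_ed_enm(m, enm_params(c_seq = K))
}

# small non-degenerate 3-D fixture: 10-residue helical fragment
helix10 <- function() cached("helix10", {
  i <- 0:9
  th <- i * 100 * pi / 180
  ca_model("helix10", rep("A", 10), 1:10, rep("ALA", 10),
           cbind(1.5 * i, 2.3 * cos(th), 2.3 * sin(th)))
})

hinge_pair <- function() cached("hinge_pair", make_hinge_models(hinge_spec()))

hinge_family <- function() cached("hinge_family",
  make_hinge_models(hinge_spec(n_intermediates = 9)))

hinge_topology <- function() cached("hinge_topology",
  build_ed_enm(hinge_pair()[[1L]]))

# one forward transition on the toy hinge, reused by several test files
hinge_forward_path <- function() cached("hinge_forward_path", {
  m <- hinge_pair()
  run_transition(m[[1L]], m[[2L]], dims_parameters = dims_params(seed = 1L))
})

# orthonormal 3N vectors with no rigid-body (translation/rotation)
# component, so superposition during PCA leaves them intact
internal_vectors <- function(model, k, seed = 99) {
  x <- sweep(model$coords, 2L, colMeans(model$coords))
  n <- nrow(x)
  rigid <- cbind(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    as.numeric(t(cbind(0, -x[, 3], x[, 2]))),
    as.numeric(t(cbind(x[, 3], 0, -x[, 1]))),
    as.numeric(t(cbind(-x[, 2], x[, 1], 0))))
  Q <- qr.Q(qr(rigid))
  set.seed(seed)
  V <- matrix(rnorm(3 * n * k), 3 * n, k)
  V <- V - Q %*% crossprod(Q, V)
  qr.Q(qr(V))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

apply_rigid <- function(x, R, t) x %*% R + matrix(t, nrow(x), 3, byrow = TRUE)
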