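# Ensemble PCA: fitting, projection, coverage, persistence.

# planted components free of rigid-body content (helper internal_vectors):
# superposition would silently strip any translation/rotation component of
# a planted vector and bias the recovered eigenvalues
toy_vectors <- function(n3, k) internal_vectors(helix10(), k)

test_that("fit_pca enforces the ensemble contract", {
  m <- helix10()
  expect_error(fit_pca(structure(list(members = list(m, m),
                                      reference_index = 1L),
                                 class = "ca_ensemble")), "at least 3")
  ens3 <- make_pca_ensemble(m, toy_vectors(30, 2), c(1, 0.5), 3, seed = 2)
  b <- fit_pca(ens3)
  expect_lte(length(b$eigenvalues), 2L)          # rank M - 1
  expect_equal(sum(b$variance_fractions), 1, tolerance = 1e-8)
})

test_that("known planted components are recovered from a large ensemble", {
  m <- helix10()
  V <- toy_vectors(30, 2)
  ens <- make_pca_ensemble(m, V, c(2, 1), 200, seed = 5)
  b <- fit_pca(ens)
  expect_gt(abs(sum(b$components[, 1L] * V[, 1L])), 0.99)
  expect_gt(abs(sum(b$components[, 2L] * V[, 2L])), 0.99)
  # eigenvalues track the realized variance of the drawn amplitudes
  mu <- as.numeric(t(m$coords))
  A <- t(vapply(ens$members, function(mm)
    as.numeric((as.numeric(t(mm$coords)) - mu) %*% V), numeric(2)))
  expect_equal(b$eigenvalues[1L], var(A[, 1L]), tolerance = 0.02)
  expect_equal(b$eigenvalues[2L], var(A[, 2L]), tolerance = 0.02)
  # and sit within sampling error of the nominal 4 and 1
  expect_equal(b$eigenvalues[1L], 4, tolerance = 0.3)
  expect_equal(b$eigenvalues[2L], 1, tolerance = 0.3)
  expect_lt(max(abs(crossprod(b$components) -
                    diag(ncol(b$components)))), 1e-8)
})

test_that("decomposition agrees with a covariance + eigen oracle", {
  m <- helix10()
  ens <- make_pca_ensemble(m, toy_vectors(30, 3), c(1.5, 1, 0.5), 25,
                           seed = 11)
  b <- fit_pca(ens)
  ref <- ens$members[[1L]]$coords
  X <- do.call(rbind, lapply(ens$members, function(mm)
    as.numeric(t(superpose(mm$coords, ref)$coords))))
  C <- cov(X)                                  # brute-force covariance route
  eo <- eigen(C, symmetric = TRUE)
  keep <- seq_along(b$eigenvalues)
  expect_equal(b$eigenvalues, eo$values[keep], tolerance = 1e-8)
  for (k in keep) {
    expect_equal(abs(sum(b$components[, k] * eo$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
})

test_that("projections subtract the reference and are linear", {
  m <- helix10()
  ens <- make_pca_ensemble(m, toy_vectors(30, 2), c(1, 0.6), 40, seed = 3)
  b <- fit_pca(ens)
  ref <- ens$members[[1L]]
  expect_equal(as.numeric(unlist(project_structures(b, ref)[1, c("PC1", "PC2")])),
               c(0, 0), tolerance = 1e-8)

  d <- matrix(b$components[, 1L], ncol = 3, byrow = TRUE)
  p1 <- project_structures(b, b$reference_coords + d)
  p2 <- project_structures(b, b$reference_coords + 2 * d)
  expect_equal(2 * p1$PC1, p2$PC1, tolerance = 1e-6)
})

test_that("re-projection onto all components reconstructs each member", {
  m <- helix10()
  ens <- make_pca_ensemble(m, toy_vectors(30, 3), c(1, 0.7, 0.4), 12,
                           seed = 21)
  b <- fit_pca(ens)
  nc <- ncol(b$components)
  refv <- as.numeric(t(b$reference_coords))
  for (i in c(1L, 5L, 12L)) {
    al <- superpose(ens$members[[i]]$coords, b$reference_coords)$coords
    p <- as.numeric(unlist(project_structures(b, al, nc)[1, -1]))
    rec <- refv + as.numeric(b$components %*% p)
    expect_equal(rec, as.numeric(t(al)), tolerance = 1e-6)
  }
})

test_that("projections are invariant to rigid motion of the input", {
  m <- hinge_family()
  b <- fit_pca(residue_correspondence(m))
  x <- m[[7L]]$coords
  R <- random_rotation(13)
  p0 <- project_structures(b, x)
  p1 <- project_structures(b, apply_rigid(x, R, c(10, -4, 2)))
  expect_equal(p0$PC1, p1$PC1, tolerance = 1e-6)
  expect_equal(p0$PC2, p1$PC2, tolerance = 1e-6)
})

test_that("the target projects positively on PC1 from the reference", {
  m <- hinge_family()
  b <- fit_pca(residue_correspondence(m))
  expect_gte(project_structures(b, m[[11L]])$PC1[1L], 0)
})

test_that("transition coverage accumulates squared projections of delta", {
  m <- helix10()
  V <- toy_vectors(30, 2)
  ens <- make_pca_ensemble(m, V, c(2, 1), 100, seed = 8)
  b <- fit_pca(ens)
  mk <- function(x) ca_model("q", m$chain_ids, m$res_ids, m$res_names, x)
  ref <- b$reference_coords

  along1 <- mk(ref + matrix(b$components[, 1L], 10, 3, byrow = TRUE))
  expect_equal(transition_coverage(b, mk(ref), along1, 1L), 1,
               tolerance = 1e-8)

  both <- mk(ref + matrix(b$components[, 1L] + b$components[, 2L],
                          10, 3, byrow = TRUE))
  expect_equal(transition_coverage(b, mk(ref), both, 1L), 0.5,
               tolerance = 1e-8)
  expect_equal(transition_coverage(b, mk(ref), both, 2L), 1,
               tolerance = 1e-8)

  # random difference vector versus brute-force accumulation
  set.seed(4)
  tgt <- mk(ref + matrix(rnorm(30, sd = 0.7), 10, 3))
  a <- superpose(mk(ref)$coords, b$reference_coords)$coords
  t2 <- superpose(tgt$coords, b$reference_coords)$coords
  delta <- as.numeric(t(t2)) - as.numeric(t(a))
  brute <- sum(vapply(1:2, function(j)
    sum(delta * b$components[, j])^2, 0)) / sum(delta^2)
  expect_equal(transition_coverage(b, mk(ref), tgt, 2L), brute,
               tolerance = 1e-10)
  expect_error(transition_coverage(b, mk(ref), mk(ref)), "coincide")
})

test_that("pc_distance is the Euclidean metric in PC space", {
  expect_equal(pc_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pc_distance(c(1, 1), c(1, 1)), 0)
  a <- c(0.3, -2); b <- c(1.5, 0.7)
  expect_equal(pc_distance(a, b), pc_distance(b, a))
  expect_error(pc_distance(c(1, 2), c(1, 2, 3)), "dimensions")
})

test_that("variance fractions of mode ensembles match equipartition ratios", {
  top <- build_ed_enm(helix10())
  nm <- normal_modes(top, 3L)
  tr <- mc_sample_along_modes(nm, 300, n_samples = 500, seed = 14)
  m <- helix10()
  members <- lapply(seq_along(tr$frames), function(k)
    ca_model(sprintf("s%d", k), m$chain_ids, m$res_ids, m$res_names,
             tr$frames[[k]]))
  b <- fit_pca(structure(list(members = members, reference_index = 1L),
                         class = "ca_ensemble"))
  expected <- (1 / nm$eigenvalues) / sum(1 / nm$eigenvalues)
  expect_equal(b$variance_fractions[1:3], expected, tolerance = 0.1)
})

test_that("three well-chosen structures reproduce the dominant motion", {
  m <- hinge_family()
  full <- fit_pca(residue_correspondence(m))
  expect_gt(full$variance_fractions[1L], 0.7)
  three <- fit_pca(residue_correspondence(m[c(1L, 6L, 11L)]))
  expect_gt(abs(sum(full$components[, 1L] * three$components[, 1L])), 0.9)
})

test_that("basis and projection tables persist through plain text", {
  m <- hinge_family()
  b <- fit_pca(residue_correspondence(m))
  f <- withr::local_tempfile(fileext = ".txt")
  write_pca_basis(b, f)
  b2 <- read_pca_basis(f)
  expect_equal(b2$eigenvalues, b$eigenvalues, tolerance = 1e-12)
  expect_equal(b2$components, b$components, tolerance = 1e-12,
               ignore_attr = TRUE)
  p0 <- project_structures(b, m[[4L]])
  p1 <- project_structures(b2, m[[4L]], labels = p0$label)
  expect_equal(p1$PC1, p0$PC1, tolerance = 1e-9)

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_projections(p0, tf)
  expect_equal(read_projections(tf)$PC1, p0$PC1, tolerance = 1e-12)
})
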