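# ED-ENM network construction, forces, Hessian, normal modes.

test_that("spring assignment follows the sequential and long-range rules", {
  p <- enm_params()
  top <- two_bead_topology(K = p$c_seq)
  expect_equal(nrow(top$pairs), 1L)
  expect_equal(top$K, p$c_seq)                      # s = 1 backbone pair

  # 5 collinear residues at 3.8 A: s = 1,2,3 sequential, (1,5) beyond cutoff
  m <- chain_model(5)
  top5 <- suppressWarnings(build_ed_enm(m, p))
  key <- paste(top5$pairs[, 1L], top5$pairs[, 2L])
  expect_false("1 5" %in% key)                      # 15.2 A > 12 A cutoff
  for (s in 1:3) {
    ks <- top5$K[match(paste(1:(5 - s), (1 + s):5), key)]
    expect_equal(ks, rep(p$c_seq / s^2, 5 - s))
  }

  # residues on different chains get the distance-decay constant
  mc <- ca_model("2ch", c("A", "B"), c(1, 1), c("ALA", "ALA"),
                 rbind(c(0, 0, 0), c(5, 0, 0)))
  topc <- build_ed_enm(mc, p)
  expect_equal(topc$K, p$energy_scale * (p$c_cart / 5)^p$power)

  # a numbering gap demotes the pair to the long-range rule
  mg <- ca_model("gap", c("A", "A"), c(1, 10), c("ALA", "ALA"),
                 rbind(c(0, 0, 0), c(3.8, 0, 0)))
  topg <- build_ed_enm(mg, p)
  expect_equal(topg$K, p$energy_scale * (p$c_cart / 3.8)^p$power)
})

test_that("a fragmented network triggers the connectivity warning", {
  m <- ca_model("frag", c("A", "B"), c(1, 1), c("ALA", "ALA"),
                rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_warning(build_ed_enm(m), "connected")
})

test_that("forces are the analytic gradient of the pair potential", {
  top <- hinge_topology()
  x0 <- hinge_pair()[[1L]]$coords
  expect_lt(max(abs(enm_forces(top, x0))), 1e-10)   # equilibrium
  expect_equal(enm_energy(top, x0), 0)

  # two beads stretched by delta: magnitude 2 K delta, attractive
  K <- 60; delta <- 0.3
  top2 <- two_bead_topology(K = K, d0 = 3.8)
  F2 <- enm_forces(top2, rbind(c(0, 0, 0), c(3.8 + delta, 0, 0)))
  expect_equal(F2[1L, 1L], 2 * K * delta, tolerance = 1e-12)
  expect_equal(F2[2L, 1L], -2 * K * delta, tolerance = 1e-12)

  # internal forces: zero net force and torque on a distorted configuration
  set.seed(11)
  x <- x0 + matrix(rnorm(length(x0), sd = 0.4), nrow(x0), 3)
  F <- enm_forces(top, x)
  expect_lt(max(abs(colSums(F))), 1e-8)
  torque <- colSums(cbind(x[, 2] * F[, 3] - x[, 3] * F[, 2],
                          x[, 3] * F[, 1] - x[, 1] * F[, 3],
                          x[, 1] * F[, 2] - x[, 2] * F[, 1]))
  expect_lt(max(abs(torque)), 1e-8)
  expect_error(enm_forces(top2, rbind(c(0, 0, 0), c(0, 0, 0))), "coincident")
})

test_that("potential is zero at build geometry and non-negative elsewhere", {
  top <- hinge_topology()
  x0 <- hinge_pair()[[1L]]$coords
  set.seed(5)
  for (i in 1:10) {
    x <- x0 + matrix(rnorm(length(x0), sd = runif(1, 0, 1)), nrow(x0), 3)
    expect_gte(enm_energy(top, x), 0)
  }
})

test_that("two-bead Hessian has the analytic spectrum {0 x5, 4K}", {
  K <- 60
  H <- enm_hessian(two_bead_topology(K = K))
  ev <- sort(eigen(H, symmetric = TRUE)$values)
  expect_lt(max(abs(ev[1:5])), 1e-10)
  expect_equal(ev[6L], 4 * K, tolerance = 1e-10)
  expect_equal(H, t(H))
})

test_that("Hessian matches central finite differences of the energy", {
  m <- helix10()
  top <- build_ed_enm(m)
  H <- enm_hessian(top)
  x0 <- as.numeric(t(m$coords))
  h <- 1e-5
  n3 <- length(x0)
  grad <- function(x) {
    -as.numeric(t(enm_forces(top, matrix(x, ncol = 3, byrow = TRUE))))
  }
  Hfd <- matrix(0, n3, n3)
  for (a in seq_len(n3)) {
    xp <- x0; xp[a] <- xp[a] + h
    xm <- x0; xm[a] <- xm[a] - h
    Hfd[, a] <- (grad(xp) - grad(xm)) / (2 * h)
  }
  expect_lt(max(abs(H - Hfd)) / max(abs(H)), 1e-5)
})

test_that("forces linearize to -H (x - x0) near equilibrium", {
  top <- hinge_topology()
  x0 <- hinge_pair()[[1L]]$coords
  H <- enm_hessian(top)
  set.seed(3)
  u <- rnorm(length(x0)); u <- u / sqrt(sum(u^2)) * 0.01   # 0.01 A
  Fnum <- as.numeric(t(enm_forces(top, x0 + matrix(u, nrow(x0), 3,
                                                   byrow = TRUE))))
  Flin <- -as.numeric(H %*% u)
  expect_lt(sqrt(sum((Fnum - Flin)^2)) / sqrt(sum(Flin^2)), 1e-3)
})

test_that("normal modes split rigid-body and internal motion cleanly", {
  top <- hinge_topology()
  H <- enm_hessian(top)
  ev <- sort(eigen(H, symmetric = TRUE)$values)
  expect_equal(sum(ev < 1e-8 * max(ev)), 6L)

  nm <- normal_modes(top, 10L)
  expect_equal(nm$n_zero, 6L)
  expect_lt(max(abs(crossprod(nm$vectors) - diag(10L))), 1e-8)
  expect_error(normal_modes(top, 3L * top$n), "exceeds")

  # the fixture is built with a single soft hinge: the lowest mode carries
  # the open->closed change
  m <- hinge_pair()
  delta <- as.numeric(t(superpose(m[[2L]]$coords, m[[1L]]$coords)$coords -
                        m[[1L]]$coords))
  expect_gt(mode_overlap(nm$vectors[, 1L], delta), 0.7)
})

test_that("mode overlap is the normalized absolute inner product", {
  v <- c(1, 0, 0, 0, 0, 0)
  expect_equal(mode_overlap(v, 3 * v), 1)
  expect_equal(mode_overlap(v, c(0, 2, 0, 0, 0, 0)), 0)
  expect_equal(mode_overlap(v, c(1, 1, 0, 0, 0, 0)), sqrt(0.5),
               tolerance = 1e-4)
  expect_error(mode_overlap(v, rep(0, 6)), "zero")
})

test_that("Monte-Carlo mode ensembles obey equipartition and the seed", {
  top <- build_ed_enm(helix10())
  nm <- normal_modes(top, 1L)
  lam <- nm$eigenvalues[1L]
  kB <- ebdims_constants()$kB

  t0 <- mc_sample_along_modes(nm, temperature = 0, n_samples = 3, seed = 1)
  for (f in t0$frames) expect_equal(f, nm$coords)

  tr <- mc_sample_along_modes(nm, temperature = 300, n_samples = 1e4,
                              seed = 42)
  proj <- vapply(tr$frames, function(f)
    sum((as.numeric(t(f)) - as.numeric(t(nm$coords))) * nm$vectors[, 1L]),
    0)
  expect_equal(var(proj), kB * 300 / lam, tolerance = 0.05)

  tr2 <- mc_sample_along_modes(nm, temperature = 300, n_samples = 5,
                               seed = 7)
  tr3 <- mc_sample_along_modes(nm, temperature = 300, n_samples = 5,
                               seed = 7)
  expect_identical(tr2, tr3)
})

test_that("PCA of a mode-sampled ensemble recovers the input modes", {
  # the two lowest eigenvalues differ by only ~30%, so the sample size has
  # to be large enough that PC estimation does not mix the pair
  top <- build_ed_enm(helix10())
  nm <- normal_modes(top, 2L)
  tr <- mc_sample_along_modes(nm, 300, n_samples = 5000, seed = 9)
  m <- helix10()
  members <- lapply(seq_along(tr$frames), function(k)
    ca_model(sprintf("s%03d", k), m$chain_ids, m$res_ids, m$res_names,
             tr$frames[[k]]))
  basis <- fit_pca(structure(list(members = members, reference_index = 1L),
                             class = "ca_ensemble"))
  # softer mode has larger variance -> PC1 pairs with mode 1
  expect_gt(abs(sum(basis$components[, 1L] * nm$vectors[, 1L])), 0.99)
  expect_gt(abs(sum(basis$components[, 2L] * nm$vectors[, 2L])), 0.99)
})
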