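test_that("Lennard-Jones potential has its minimum -eps0 at r = sigma", {
  expect_equal(lj_potential(1, 1), -1)
  expect_equal(lj_potential(2, 1), 2^-12 - 2 * 2^-6)  # -0.031006 to 6 d.p.
  expect_equal(round(lj_potential(2, 1), 6), -0.031006)
  # monotone approach to 0 from below beyond the minimum
  r <- seq(1, 50, length.out = 200)
  v <- lj_potential(r, 1)
  expect_true(all(diff(v) > 0) && all(v < 0))
  expect_error(lj_potential(0, 1), "positive")
  expect_error(lj_potential(-1, 1), "positive")
})

test_that("pair forces vanish at equilibrium, repel below it, and balance", {
  cfg <- ck_configuration(1, 1, "sphere")
  adj <- build_adjacency(cfg, "auto")
  D <- as.matrix(dist(cfg$points))
  e <- adjacency_edges(adj)

  # force zero at exactly sigma
  mod_eq <- uniform_sigma(D[e[1, 1], e[1, 2]])
  expect_equal(pair_force(e[1, 1], e[1, 2], cfg, adj, mod_eq), c(0, 0, 0),
               tolerance = 1e-14)

  # below sigma the force on i points away from j, and it matches the
  # finite-difference gradient of the pair potential
  mod <- uniform_sigma(1.1 * max(D[e]))
  i <- e[5, 1]; j <- e[5, 2]
  f <- pair_force(i, j, cfg, adj, mod)
  rij <- cfg$points[j, ] - cfg$points[i, ]
  expect_lt(sum(f * rij), 0)   # repulsion: along -r_ij
  h <- 1e-6
  num <- vapply(1:3, function(d) {
    shift <- function(s) {
      p <- cfg$points; p[i, d] <- p[i, d] + s
      sqrt(sum((p[j, ] - p[i, ])^2))
    }
    s <- mod$sigma[[capsidstress:::.pair_class(cfg$kind[i], cfg$kind[j])]]
    -(lj_potential(shift(h), s) - lj_potential(shift(-h), s)) / (2 * h)
  }, 0)
  expect_equal(f, num, tolerance = 1e-6)

  # Newton's third law on every adjacent pair
  mod2 <- calibrate_model(cfg, adj)
  for (k in seq_len(nrow(e))) {
    expect_equal(pair_force(e[k, 1], e[k, 2], cfg, adj, mod2),
                 -pair_force(e[k, 2], e[k, 1], cfg, adj, mod2),
                 tolerance = 1e-14)
  }
  # non-adjacent pairs carry no force
  nonadj <- which(adj$A == 0 & upper.tri(adj$A), arr.ind = TRUE)[1, ]
  expect_equal(pair_force(nonadj[1], nonadj[2], cfg, adj, mod2), c(0, 0, 0))
})

test_that("total energy double-counts ordered pairs as defined", {
  # two adjacent points at distance sigma: E = -2 eps0
  pts <- rbind(icosahedron_vertices(5), c(20, 0, 0), c(21, 0, 0))
  cfg <- capsomer_configuration(pts, rep(c("pentamer", "hexamer"), c(12, 2)),
                                center = FALSE)
  adj <- build_adjacency(cfg, delta = 1.5, check = FALSE)
  adj$A[] <- 0L; adj$A[13, 14] <- adj$A[14, 13] <- 1L
  expect_equal(total_energy(cfg, adj, uniform_sigma(1)), -2)
  # empty adjacency: zero energy
  adj$A[] <- 0L
  expect_equal(total_energy(cfg, adj, uniform_sigma(1)), 0)
  # energy decreases when a stretched shell relaxes to its equilibrium spacing
  c1 <- ck_configuration(1, 0, "icosahedron", spacing = NULL)
  a1 <- build_adjacency(c1, 1.4 * min(dist(c1$points)), check = FALSE)
  sig <- min(dist(c1$points))
  stretched <- capsomer_configuration(c1$points * 1.2, c1$kind)
  a2 <- build_adjacency(stretched, 1.4 * 1.2 * sig, check = FALSE)
  m <- uniform_sigma(sig)
  expect_lt(total_energy(c1, a1, m), total_energy(stretched, a2, m))
})

test_that("virial stress matches a naive double-loop oracle", {
  for (seed in 1:20) {
    cfg <- random_configuration(n_hex = 18, seed = seed)
    adj <- build_adjacency(cfg, delta = 1.5, check = FALSE)
    mod <- uniform_sigma(1.05, eps0 = 0.7)
    surf <- triangulate(cfg)
    Tv <- virial_stress(cfg, adj, mod, surf)
    # independent re-statement: T_i = 1/(2|S|) sum_{j != i} f_ij (x) r_ij
    P <- cfg$points
    for (i in c(1, 7, 30)) {
      acc <- matrix(0, 3, 3)
      for (j in seq_len(nrow(P))) {
        if (j == i || adj$A[i, j] == 0) next
        rij <- P[j, ] - P[i, ]
        r <- sqrt(sum(rij^2))
        sr6 <- (1.05 / r)^6
        dv <- 12 * 0.7 / r * (sr6 - sr6^2)
        acc <- acc + outer(dv / r * rij, rij)
      }
      expect_equal(Tv[, , i], acc / (2 * surf$area), tolerance = 1e-12)
    }
  }
})

test_that("stress is frame covariant and its invariants frame invariant", {
  cfg <- random_configuration(n_hex = 30, seed = 5)
  adj <- build_adjacency(cfg, delta = 1.4, check = FALSE)
  mod <- uniform_sigma(0.9)
  surf <- triangulate(cfg)
  fld <- stress_field(cfg, adj, mod, surf)
  R <- random_rotation(99)
  rcfg <- capsomer_configuration(cfg$points %*% t(R), cfg$kind, center = FALSE)
  radj <- build_adjacency(rcfg, delta = 1.4, check = FALSE)
  rsurf <- triangulate(rcfg)
  rfld <- stress_field(rcfg, radj, mod, rsurf)
  for (i in c(2, 19, 42)) {
    expect_equal(rfld$virial[, , i], R %*% fld$virial[, , i] %*% t(R),
                 tolerance = 1e-9)
  }
  expect_equal(rfld$lateral, fld$lateral, tolerance = 1e-9)
  expect_equal(rfld$shear, fld$shear, tolerance = 1e-9)
  expect_equal(rfld$energy, fld$energy, tolerance = 1e-9)
})

test_that("a shell with every adjacent pair at sigma is stress-free", {
  c1 <- ck_configuration(1, 0, "icosahedron", spacing = NULL)
  sig <- min(dist(c1$points))
  a1 <- build_adjacency(c1, 1.4 * sig, check = FALSE)
  m <- uniform_sigma(sig)
  s1 <- triangulate(c1)
  Tv <- virial_stress(c1, a1, m, s1)
  expect_lt(max(abs(Tv)), 1e-12)
  expect_equal(total_energy(c1, a1, m), -2 * sum(a1$A) / 2)  # -eps0 * 2 * pairs
})

test_that("tangential projection annihilates the normal and keeps the 2x2 spectrum", {
  n <- c(0, 0, 1)
  # identity stress: tangential part is the projector, eigenvalues (1, 1)
  td <- tangential_stress(diag(3), n)
  expect_equal(td$Ttilde, diag(c(1, 1, 0)))
  expect_equal(c(td$lambda_max, td$lambda_min), c(1, 1))
  # purely normal stress: nothing tangential remains
  td2 <- tangential_stress(outer(n, n), n)
  expect_equal(td2$Ttilde, matrix(0, 3, 3))
  expect_equal(c(td2$lambda_max, td2$lambda_min), c(0, 0))
  # random symmetric tensor, n = e_z: eigenvalues of the upper-left block
  set.seed(8)
  for (k in 1:10) {
    A <- matrix(rnorm(9), 3, 3); S <- (A + t(A)) / 2
    td3 <- tangential_stress(S, n)
    ev <- eigen(S[1:2, 1:2], symmetric = TRUE)$values
    expect_equal(c(td3$lambda_max, td3$lambda_min), ev, tolerance = 1e-12)
    expect_lt(max(abs(td3$Ttilde %*% n)), 1e-10)
  }
  # asymmetric input is symmetrized before projection
  A <- matrix(1:9, 3, 3)
  td4 <- tangential_stress(A, n)
  expect_equal(td4$Ttilde, tangential_stress((A + t(A)) / 2, n)$Ttilde)
})

test_that("lateral and shear stresses follow the principal-value arithmetic", {
  expect_equal(lateral_and_shear(1, 1), list(lateral = 1, shear = 0))
  expect_equal(lateral_and_shear(3, -1), list(lateral = 1, shear = 2))
  expect_error(lateral_and_shear(0, 1), "lambda_max")
  # uniaxial tension (lambda, 0): tau = lambda / 2
  expect_equal(lateral_and_shear(0.8, 0)$shear, 0.4)
})

test_that("maximum shear is attained at pi/4 to the principal axes (direction scan)", {
  set.seed(21)
  n <- rnorm(3); n <- n / sqrt(sum(n^2))
  A <- matrix(rnorm(9), 3, 3); S <- (A + t(A)) / 2
  td <- tangential_stress(S, n)
  tau <- (td$lambda_max - td$lambda_min) / 2
  # brute-force scan over 3600 tangent directions
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- capsidstress:::cross3(n, ref); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- capsidstress:::cross3(n, t1)
  alphas <- 2 * pi * (0:3599) / 3600
  shear_of <- function(a) {
    v <- cos(a) * t1 + sin(a) * t2            # curve normal in tangent plane
    w <- capsidstress:::cross3(n, v)          # curve tangent
    abs(sum(w * (td$Ttilde %*% v)))
  }
  sh <- vapply(alphas, shear_of, 0)
  expect_equal(max(sh), tau, tolerance = 1e-4)
  # the maximizing direction sits at pi/4 to the principal direction
  best <- cos(alphas[which.max(sh)]) * t1 + sin(alphas[which.max(sh)]) * t2
  ang <- acos(min(1, abs(sum(best * td$e_max))))
  expect_equal(ang, pi / 4, tolerance = 2 * pi / 3600)
})

test_that("stress invariants are constant on symmetry orbits", {
  cfg <- ck_configuration(1, 2, "sphere")
  adj <- build_adjacency(cfg, "auto")
  mod <- calibrate_model(cfg, adj)
  fld <- stress_field(cfg, adj, mod, triangulate(cfg))
  orb <- group_orbits(cfg$points, icosahedral_rotations(), tol = 1e-6)
  for (v in list(fld$lateral, fld$shear)) {
    spread <- max(tapply(v, orb, function(x) diff(range(x))))
    expect_lt(spread, 1e-8 * max(diff(range(v)), 1e-30))
  }
  # tangential tensor annihilates the node normal everywhere
  surf <- triangulate(cfg)
  for (i in seq_len(nrow(cfg$points)))
    expect_lt(max(abs(fld$tangential[, , i] %*% surf$node_normals[i, ])), 1e-10)
  expect_true(all(fld$shear >= 0))
  expect_true(all(fld$lambda_min <= fld$lateral & fld$lateral <= fld$lambda_max))
})

test_that("model calibration makes the reference configuration near-equilibrium", {
  cfg <- ck_configuration(1, 1, "sphere")
  adj <- build_adjacency(cfg, "auto")
  mod <- calibrate_model(cfg, adj)
  D <- as.matrix(dist(cfg$points))
  e <- adjacency_edges(adj)
  cls <- capsidstress:::.pair_class(cfg$kind[e[, 1]], cfg$kind[e[, 2]])
  for (cl in unique(cls))
    expect_equal(mod$sigma[[cl]], mean(D[e][cls == cl]), tolerance = 1e-12)
  expect_error(interaction_model(1, c(bogus = 1)), "pair class")
  expect_warning(interaction_model(1, c("hexamer-hexamer" = 1), delta = 2),
                 "second")
})
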