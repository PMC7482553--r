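test_that("configuration constructor enforces the capsid invariants", {
  pts <- icosahedron_vertices()
  cfg <- capsomer_configuration(pts, rep("pentamer", 12))
  expect_equal(colMeans(cfg$points), c(0, 0, 0), tolerance = 1e-12)
  expect_error(capsomer_configuration(pts, rep("hexamer", 12)), "12 pentamers")
  expect_error(capsomer_configuration(pts[1:11, ], rep("pentamer", 11)),
               "at least 12")
  expect_error(
    capsomer_configuration(rbind(pts, pts[1, ]),
                           rep(c("pentamer", "hexamer"), c(12, 1))),
    "coincident")
  bad_order <- rep(c("hexamer", "pentamer", "pentamer"), c(1, 12, 0))
  expect_error(capsomer_configuration(rbind(c(3, 0, 0), pts),
                                      bad_order), "indices 1..12")
})

test_that("adjacency follows the cutoff rule and the 5/6 coordination law", {
  cfg <- ck_configuration(1, 1, "sphere")
  adj <- build_adjacency(cfg, "auto")
  deg <- rowSums(adj$A)
  expect_true(all(deg[cfg$kind == "pentamer"] == 5))
  expect_true(all(deg[cfg$kind == "hexamer"] == 6))
  expect_true(isSymmetric(adj$A))
  expect_true(all(diag(adj$A) == 0))

  # two points below cutoff are not adjacent
  pts <- rbind(icosahedron_vertices(4), c(10, 0, 0), c(12, 0, 0))
  cfg2 <- capsomer_configuration(pts, rep(c("pentamer", "hexamer"), c(12, 2)),
                                 center = FALSE)
  adj2 <- build_adjacency(cfg2, delta = 1, check = FALSE)
  expect_equal(sum(adj2$A), 0)

  # T=28 sphere: degree sum = 2E = 3F with F = 2N - 4 = 560
  cfg3 <- ck_configuration(2, 4, "sphere")
  adj3 <- build_adjacency(cfg3, "auto")
  expect_equal(sum(rowSums(adj3$A)), 3 * 560)
})

test_that("adjacency is invariant under rigid motions", {
  cfg <- ck_configuration(1, 1, "sphere")
  adj <- build_adjacency(cfg, "auto")
  R <- random_rotation(7)
  moved <- capsomer_configuration(cfg$points %*% t(R) + 0.73, cfg$kind)
  adj2 <- build_adjacency(moved, "auto")
  expect_identical(adj$A, adj2$A)
})

test_that("triangulation is a closed outward genus-0 surface", {
  # regular unit-edge icosahedron: 20 faces, area 5*sqrt(3)
  a <- 1 / min(dist(icosahedron_vertices()))
  cfg <- capsomer_configuration(icosahedron_vertices(a), rep("pentamer", 12))
  s <- triangulate(cfg)
  expect_equal(nrow(s$triangles), 20)
  expect_equal(s$area, 5 * sqrt(3), tolerance = 1e-12)

  # T=4 icosahedral embedding: V=42, F=80, E=120, Euler characteristic 2
  cfg4 <- ck_configuration(2, 0, "icosahedron")
  s4 <- triangulate(cfg4)
  V <- length(unique(as.vector(s4$triangles)))
  Fc <- nrow(s4$triangles); E <- 3 * Fc / 2
  expect_equal(c(V, Fc, E), c(42, 80, 120))
  expect_equal(V - E + Fc, 2)

  # T=3 as well (F = 2V - 4 for hull triangulations)
  s3 <- triangulate(ck_configuration(1, 1, "icosahedron"))
  expect_equal(nrow(s3$triangles), 2 * 32 - 4)

  # every triangle oriented outward
  P <- s4$points
  for (t in seq_len(nrow(s4$triangles))) {
    v <- s4$triangles[t, ]
    nrm <- capsidstress:::cross3(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])
    expect_gt(sum(nrm * colMeans(P[v, ])), 0)
  }

  # unit sphere sampled by a 282-point code: hull area within 5% of 4*pi
  code <- ck_configuration(2, 4, "sphere", spacing = NULL)
  u <- code$points / sqrt(rowSums(code$points^2))
  su <- triangulate(capsomer_configuration(u, code$kind, center = FALSE))
  expect_lt(abs(su$area - 4 * pi) / (4 * pi), 0.05)
})

test_that("an interior capsomer is rejected by name", {
  pts <- rbind(icosahedron_vertices(3), c(0.2, 0.1, 0.05))
  cfg <- capsomer_configuration(pts, rep(c("pentamer", "hexamer"), c(12, 1)),
                                center = FALSE)
  expect_error(triangulate(cfg), "13")
})

test_that("node normals are unit, outward, and exact on symmetric stars", {
  cfg <- ck_configuration(2, 4, "sphere")
  s <- triangulate(cfg)
  nn <- s$node_normals
  expect_true(all(abs(sqrt(rowSums(nn^2)) - 1) < 1e-12))
  rad <- cfg$points / sqrt(rowSums(cfg$points^2))
  # positive radial component everywhere (star-shaped configuration)
  expect_true(all(rowSums(nn * rad) > 0))
  # nodes on symmetry axes have rotationally symmetric stars: exactly radial
  ax <- icosahedral_axes(cfg)
  onaxis <- ax$dist_twofold < 1e-6 * sqrt(sum(cfg$points[1, ]^2))
  expect_lt(max(sqrt(rowSums((nn[1:12, ] - rad[1:12, ])^2))), 1e-6)
  expect_lt(max(sqrt(rowSums((nn[onaxis, ] - rad[onaxis, ])^2))), 1e-6)

  # interior node of a flat patch: normal equals the plane normal
  patch <- flat_patch_surface()
  pn <- node_normals(patch)
  expect_equal(abs(pn[7, 3]), 1, tolerance = 1e-12)
})

test_that("configuration CSV round-trips", {
  cfg <- ck_configuration(1, 1, "sphere")
  f <- withr::local_tempfile(fileext = ".csv")
  write_configuration_csv(cfg, f)
  back <- read_configuration_csv(f)
  expect_equal(back$points, cfg$points, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$kind, cfg$kind)
})
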