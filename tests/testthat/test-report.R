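test_that("stress summary takes maxima over capsomers", {
  fake <- structure(list(lateral = c(-2, 1), shear = c(0.5, 3)),
                    class = "stress_field")
  expect_equal(summarize_stress(fake),
               c(max_abs_lateral = 2, max_shear = 3))
  # a relaxed shell reports (0, 0)
  c1 <- ck_configuration(1, 0, "icosahedron", spacing = NULL)
  sig <- min(dist(c1$points))
  a1 <- build_adjacency(c1, 1.4 * sig, check = FALSE)
  fld <- stress_field(c1, a1, uniform_sigma(sig), triangulate(c1))
  expect_equal(unname(summarize_stress(fld)), c(0, 0), tolerance = 1e-12)
})

test_that("shared-bin histograms are consistent and discriminate variants", {
  cfg_i <- ck_configuration(1, 4, "icosahedron")
  cfg_s <- ck_configuration(1, 4, "sphere")
  adj_i <- build_adjacency(cfg_i, "auto")
  adj_s <- build_adjacency(cfg_s, "auto")
  mod <- calibrate_model(cfg_s, adj_s)     # one shared interaction model
  f_i <- stress_field(cfg_i, adj_i, mod, triangulate(cfg_i))
  f_s <- stress_field(cfg_s, adj_s, mod, triangulate(cfg_s))

  rep2 <- stress_histogram(list(icosahedral = f_i, spherical = f_s))
  expect_equal(unname(rowSums(rep2$counts)), c(212, 212))
  # identical fields give identical histograms and tail masses
  rep1 <- stress_histogram(list(a = f_s, b = f_s))
  expect_identical(rep1$counts["a", ], rep1$counts["b", ])
  expect_equal(rep1$tail_mass[["a"]], rep1$tail_mass[["b"]])
  # different geometries at the same T produce different histograms
  chisq <- sum((rep2$counts["icosahedral", ] - rep2$counts["spherical", ])^2 /
                 pmax(1, rep2$counts["spherical", ]))
  expect_gt(chisq, 0)
  # mismatched capsomer counts are rejected
  f_small <- stress_field(ck_configuration(1, 1, "sphere"),
                          build_adjacency(ck_configuration(1, 1, "sphere"), "auto"),
                          mod, triangulate(ck_configuration(1, 1, "sphere")))
  expect_error(stress_histogram(list(a = f_i, b = f_small)), "mismatch")
})

test_that("the pipeline runs end to end and is deterministic", {
  cfg <- ck_configuration(1, 1, "sphere")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rep1 <- run_pipeline(cfg, outdir = d1, seed = 3)
  rep2 <- run_pipeline(cfg, outdir = d2, seed = 3)
  expect_equal(nrow(rep1$table), 32)
  expect_true(all(c("configuration.csv", "stress.csv", "curvature_nodes.csv",
                    "curvature_edges.csv", "report.json") %in% list.files(d1)))
  # byte-identical outputs on identical inputs
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # report metadata suffices to re-run: sigma, delta, eps0, seed embedded
  meta <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_true(all(c("delta", "sigma", "eps0", "seed") %in% names(meta)))
  mod <- interaction_model(meta$eps0,
                           unlist(meta$sigma)[c("pentamer-pentamer",
                                                "pentamer-hexamer",
                                                "hexamer-hexamer")],
                           meta$delta)
  adj <- build_adjacency(cfg, meta$delta)
  fld <- stress_field(cfg, adj, mod, triangulate(cfg))
  expect_equal(max(fld$shear), max(rep1$stress$shear), tolerance = 1e-12)
})

test_that("the pipeline imports a structure file end to end", {
  # a T=3 particle as deposited: 3 pseudo-chains in the asymmetric unit
  # (one near a five-fold axis, two near a three-fold axis) + 60 operators
  R <- 10
  V <- icosahedron_vertices()
  fc <- colMeans(V[capsidstress:::icosahedron_faces()[1, ], ])
  fc <- fc / sqrt(sum(fc^2))
  v1 <- V[1, ]
  tang <- function(n) {
    ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- capsidstress:::cross3(n, ref); t1 / sqrt(sum(t1^2))
  }
  onto_sphere <- function(x) R * x / sqrt(sum(x^2))
  rot60 <- capsidstress:::.rotation_about(fc, pi / 3)
  reps <- rbind(onto_sphere(v1 + 0.15 * tang(v1)),
                onto_sphere(fc + 0.15 * tang(fc)),
                onto_sphere(as.numeric(rot60 %*% (fc + 0.15 * tang(fc)))))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_assembly_pdb(reps, f)
  rep <- run_pipeline(f, expected_T = 3)
  expect_equal(nrow(rep$table), 32)
  expect_equal(sum(rep$configuration$kind == "pentamer"), 12)
  # the fully symmetric particle is near-equilibrium under calibration
  expect_lt(max(rep$stress$shear), 1e-8)
  expect_false(is.null(rep$curvature$H_true))
  expect_true(all(rep$curvature$H_true$H >= 0))
  expect_equal(sum(rep$curvature$K), 4 * pi, tolerance = 1e-9)
})

test_that("mesh export writes valid OFF and PLY", {
  s <- triangulate(ck_configuration(1, 1, "sphere"))
  off <- withr::local_tempfile(fileext = ".off")
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh_off(s, off)
  write_mesh_ply(s, ply, scalar = gaussian_curvature(s))
  loff <- readLines(off)
  expect_identical(loff[1], "OFF")
  expect_identical(loff[2], "32 60 90")
  lply <- readLines(ply)
  expect_identical(lply[1], "ply")
  expect_equal(sum(grepl("^3 ", lply)), 60)
})
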