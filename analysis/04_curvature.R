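#!/usr/bin/env Rscript
# Curvature analysis of the T=28 shell models: discrete Gaussian curvature
# (angle defect per capsomer) and mean curvature (exterior dihedral per
# edge) for the faceted icosahedral and spherical renderings of the (2,4)
# lattice. On the faceted shell the Gaussian curvature concentrates entirely
# at the 12 five-fold vertices and the mean curvature at the inter-face
# creases; on the sphere both spread uniformly - the signature used to judge
# whether a capsid is closer to a sphere or an icosahedron. Writes CSVs and
# colour-mappable PLY meshes to results/.

suppressMessages(library(capsidstress))
dir.create("results/meshes", recursive = TRUE, showWarnings = FALSE)

for (shape in c("icosahedron", "sphere")) {
  cfg <- ck_configuration(2, 4, shape)
  surf <- triangulate(cfg)
  K <- gaussian_curvature(surf)
  H <- mean_curvature(surf)
  write.csv(data.frame(index = seq_along(K), kind = cfg$kind, K = K),
            sprintf("results/curvature_T28_%s_nodes.csv", shape),
            row.names = FALSE, quote = FALSE)
  write.csv(H, sprintf("results/curvature_T28_%s_edges.csv", shape),
            row.names = FALSE, quote = FALSE)
  write_mesh_ply(surf, sprintf("results/meshes/T28_%s_K.ply", shape),
                 scalar = K)
  cat(sprintf("%-12s sum K = %.9f (4 pi = %.9f)\n", shape, sum(K), 4 * pi))
  cat(sprintf("  K: pentamers %.4f-%.4f, hexamers %.4f-%.4f\n",
              min(K[1:12]), max(K[1:12]), min(K[13:282]), max(K[13:282])))
  cat(sprintf("  H: median %.4f, max %.4f, flat edges (H < 1e-9): %d of %d\n",
              median(H$H), max(H$H), sum(H$H < 1e-9), nrow(H)))
}
cat("\nThe faceted shell pins all Gaussian curvature at the five-fold\n")
cat("vertices (pi/3-scale defects, zero on flat faces); the sphere spreads\n")
cat("positive curvature over every capsomer. Real capsids in this size\n")
cat("range sit between the two, which is what validates a central-force\n")
cat("model without bending terms.\n")
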