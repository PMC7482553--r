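# shared fixtures: built in code at test time

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random near-spherical configuration: 12 "pentamers" + extra "hexamers"
# jittered on a sphere (generic position, no symmetry)
random_configuration <- function(n_hex = 18, seed = 1, jitter = 0) {
  set.seed(seed)
  n <- 12 + n_hex
  pts <- matrix(rnorm(3 * n), n, 3)
  # exact radius keeps every point in convex position; directions random
  pts <- pts / sqrt(rowSums(pts^2)) * (2 + rnorm(n, sd = jitter))
  capsomer_configuration(pts, rep(c("pentamer", "hexamer"), c(12, n_hex)),
                         source = "random fixture")
}

# flat triangulated patch: regular hexagon + centre node (node 7 interior)
flat_patch_surface <- function() {
  ang <- 2 * pi * (0:5) / 6
  P <- rbind(cbind(cos(ang), sin(ang), 0), c(0, 0, 0))
  tri <- cbind(1:6, c(2:6, 1), 7)
  structure(list(triangles = tri, points = P,
                 area = sum(capsidstress:::.triangle_areas(P, tri)),
                 node_normals = NULL),
            class = "capsid_surface")
}

uniform_sigma <- function(s, eps0 = 1, delta = NULL) {
  interaction_model(eps0, c("pentamer-pentamer" = s, "pentamer-hexamer" = s,
                            "hexamer-hexamer" = s), delta)
}
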