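#' Regular icosahedron vertices
#'
#' Canonical vertex set built from the golden ratio, scaled to a given
#' circumradius. The 12 vertices are the five-fold symmetry sites (pentamer
#' positions of a T = 1 shell).
#'
#' @param circumradius distance of each vertex from the centre.
#' @return 12 x 3 matrix of vertex coordinates (centroid at the origin).
#' @export
icosahedron_vertices <- function(circumradius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(1 + phi^2) * circumradius
}

#' Faces of the canonical icosahedron
#'
#' Outward-oriented triangles over [icosahedron_vertices()].
#' @return 20 x 3 integer matrix.
#' @keywords internal
icosahedron_faces <- function() {
  v <- icosahedron_vertices()
  quickhull3d(v)$triangles
}

.rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' The chiral icosahedral rotation group
#'
#' All 60 rotation matrices mapping the canonical icosahedron
#' ([icosahedron_vertices()]) to itself, generated by closure from a five-fold
#' and a two-fold generator.
#'
#' @return list of 60 orthogonal 3 x 3 matrices (identity first).
#' @export
icosahedral_rotations <- function() {
  v <- icosahedron_vertices()
  g5 <- .rotation_about(v[1, ], 2 * pi / 5)
  ## two-fold axis through the midpoint of an edge incident to vertex 1
  nb <- order(as.matrix(stats::dist(v))[1, ])[2]
  g2 <- .rotation_about(v[1, ] + v[nb, ], pi)
  elems <- list(diag(3))
  keys <- paste(round(diag(3), 8), collapse = ",")
  queue <- list(diag(3))
  while (length(queue) > 0) {
    g <- queue[[1]]; queue <- queue[-1]
    for (gen in list(g5, g2)) {
      h <- gen %*% g
      k <- paste(round(h, 8), collapse = ",")
      if (!(k %in% keys)) {
        keys <- c(keys, k)
        elems[[length(elems) + 1L]] <- h
        queue[[length(queue) + 1L]] <- h
      }
    }
  }
  stopifnot(length(elems) == 60L)
  elems
}

#' Decompose a point set into orbits of a rotation group
#'
#' @param points n x 3 matrix.
#' @param rotations list of 3 x 3 rotation matrices.
#' @param tol matching tolerance (same units as the points).
#' @return integer vector of orbit ids (1-based, in order of first member).
#' @export
group_orbits <- function(points, rotations, tol = 1e-6) {
  n <- nrow(points)
  orbit <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!is.na(orbit[i])) next
    nxt <- nxt + 1L
    for (g in rotations) {
      img <- as.numeric(g %*% points[i, ])
      d2 <- rowSums(sweep(points, 2, img)^2)
      j <- which.min(d2)
      if (d2[j] < tol^2) orbit[j] <- nxt
    }
    orbit[i] <- nxt
  }
  orbit
}

#' Icosahedral symmetry axes of a capsomer configuration
#'
#' Recovers the six five-fold, ten three-fold and fifteen two-fold rotation
#' axes from the twelve pentamer directions, and annotates every capsomer with
#' its distance to the nearest two-fold axis (where symmetry-breaking features
#' concentrate in the capsids studied with this model).
#'
#' @param config a [capsomer_configuration()].
#' @param angle_tol maximal deviation (degrees) of pentamer-pentamer angles
#'   from the icosahedral value before the configuration is rejected.
#' @return list with \code{fivefold} (6 x 3), \code{threefold} (10 x 3),
#'   \code{twofold} (15 x 3) unit axis directions and \code{dist_twofold}
#'   (per-capsomer distance, input length units).
#' @export
icosahedral_axes <- function(config, angle_tol = 2) {
  P <- config$points
  dirs <- P[1:12, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ## neighbouring five-fold directions subtend acos(1/sqrt(5)) ~ 63.435 deg
  ref <- acos(1 / sqrt(5)) * 180 / pi
  ang <- matrix(acos(pmin(1, pmax(-1, tcrossprod(dirs)))) * 180 / pi, 12, 12)
  for (i in 1:12) {
    a <- sort(ang[i, ])[2:6]      # the five nearest non-self directions
    if (any(abs(a - ref) > angle_tol))
      stop("pentamer directions are not icosahedral (angle error > ",
           angle_tol, " degrees)")
  }
  merge_antipodal <- function(m) {
    keep <- matrix(0, 0, 3)
    for (i in seq_len(nrow(m))) {
      u <- m[i, ] / sqrt(sum(m[i, ]^2))
      if (nrow(keep) == 0 || all(abs(keep %*% u) < 1 - 1e-8))
        keep <- rbind(keep, u)
    }
    keep
  }
  five <- merge_antipodal(dirs)
  hull <- quickhull3d(dirs)
  tri <- hull$triangles
  three <- merge_antipodal(t(apply(tri, 1, function(v) colMeans(dirs[v, ]))))
  edges <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]),
                          1, sort)))
  two <- merge_antipodal(t(apply(edges, 1, function(e) colMeans(dirs[e, ]))))
  stopifnot(nrow(five) == 6, nrow(three) == 10, nrow(two) == 15)
  dist_axis <- function(x, axes) {
    r2 <- sum(x^2)
    min(sqrt(pmax(0, r2 - (axes %*% x)^2)))
  }
  d2f <- apply(P, 1, dist_axis, axes = two)
  list(fivefold = five, threefold = three, twofold = two, dist_twofold = d2f)
}
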