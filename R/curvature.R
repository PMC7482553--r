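## Discrete curvature measures on the triangulated capsid surface:
## Gaussian curvature as the angle defect at each node, mean curvature from
## the exterior dihedral angle at each triangulation edge, and a capsomer
## analogue of the mean curvature that uses the median-plane normals of the
## capsomers instead of the triangle normals.

.tri_angle <- function(a, b, c) {
  ## interior angle at vertex a of triangle (a, b, c)
  u <- b - a; v <- c - a
  atan2(sqrt(sum(cross3(u, v)^2)), sum(u * v))
}

#' Discrete Gaussian curvature (angle defect)
#'
#' K_i = 2 pi - sum of the interior angles at node i over its incident
#' triangles. On a closed genus-0 surface the defects sum to exactly 4 pi
#' (discrete Gauss-Bonnet); on a faceted icosahedral shell the curvature
#' concentrates at the 12 five-fold vertices (pi/3 each) and vanishes at
#' nodes interior to flat faces.
#'
#' @param surface a [triangulate()]d capsid surface.
#' @return numeric vector of per-node curvatures (radians).
#' @export
gaussian_curvature <- function(surface) {
  P <- surface$points
  tri <- surface$triangles
  areas <- .triangle_areas(P, tri)
  if (any(areas < 1e-12 * max(areas)))
    stop("degenerate (zero-area) triangle in the surface")
  K <- rep(2 * pi, nrow(P))
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    K[v[1]] <- K[v[1]] - .tri_angle(P[v[1], ], P[v[2], ], P[v[3], ])
    K[v[2]] <- K[v[2]] - .tri_angle(P[v[2], ], P[v[3], ], P[v[1], ])
    K[v[3]] <- K[v[3]] - .tri_angle(P[v[3], ], P[v[1], ], P[v[2], ])
  }
  K
}

## oriented edge table: for every undirected edge the two incident triangles
.edge_faces <- function(tri) {
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  f <- rep(seq_len(nrow(tri)), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sp <- split(seq_along(key), key)
  if (any(lengths(sp) != 2)) stop("non-manifold edge in triangulation")
  t(vapply(sp, function(id)
    c(min(e[id[1], ]), max(e[id[1], ]), f[id[1]], f[id[2]]),
    integer(4)))
}

#' Discrete mean curvature (edge dihedral)
#'
#' H_ij = (2 / r_ij) sin(theta_ij / 2), where theta_ij is the exterior
#' dihedral angle between the outward normals of the two triangles meeting at
#' edge (i, j) and r_ij the edge length. Flat junctions give 0; on a faceted
#' icosahedron the curvature concentrates at the icosahedral edges.
#'
#' @param surface a [triangulate()]d capsid surface.
#' @param adjacency optional [build_adjacency()]; when given, the triangulation
#'   edge set is checked against the adjacency edge set (they coincide for
#'   hull triangulations with the auto cutoff) and a warning is issued if not.
#' @return data.frame with columns \code{i}, \code{j}, \code{r},
#'   \code{theta}, \code{H} (inverse input length units).
#' @export
mean_curvature <- function(surface, adjacency = NULL) {
  P <- surface$points
  tri <- surface$triangles
  ef <- .edge_faces(tri)
  fnorm <- t(apply(tri, 1, function(v) {
    nr <- cross3(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])
    nr / sqrt(sum(nr^2))
  }))
  out <- data.frame(i = ef[, 1], j = ef[, 2], r = 0, theta = 0, H = 0)
  for (k in seq_len(nrow(ef))) {
    n1 <- fnorm[ef[k, 3], ]; n2 <- fnorm[ef[k, 4], ]
    theta <- atan2(sqrt(sum(cross3(n1, n2)^2)), sum(n1 * n2))
    r <- sqrt(sum((P[ef[k, 1], ] - P[ef[k, 2], ])^2))
    out$r[k] <- r
    out$theta[k] <- theta
    out$H[k] <- 2 / r * sin(theta / 2)
  }
  rownames(out) <- NULL
  if (!is.null(adjacency)) {
    ae <- adjacency_edges(adjacency)
    te <- out[order(out$i, out$j), 1:2]
    if (nrow(ae) != nrow(te) || !all(ae == as.matrix(te)))
      warning("triangulation edges differ from adjacency edges; ",
              "mean curvature is reported on the triangulation edges")
  }
  out
}

#' Capsomer-plane ("true") curvature
#'
#' The analogue of the discrete mean curvature on the capsomer contact
#' structure: for each pair of adjacent capsomers, the angle between their
#' median-plane outward normals replaces the triangle dihedral,
#' Htrue_ij = (2 / r_ij) sin(theta_ij / 2). Only defined when per-capsomer
#' plane normals are available (structures imported from atomic coordinates;
#' see [capsomer_planes()]).
#'
#' @param config a [capsomer_configuration()].
#' @param adjacency its [build_adjacency()].
#' @param capsomer_normals N x 3 matrix of outward unit capsomer normals.
#' @return data.frame with columns \code{i}, \code{j}, \code{r},
#'   \code{theta}, \code{H} (inverse input length units).
#' @export
true_curvature <- function(config, adjacency, capsomer_normals) {
  if (is.null(capsomer_normals))
    stop("capsomer normals are required; compute them with capsomer_planes()")
  capsomer_normals <- as.matrix(capsomer_normals)
  if (nrow(capsomer_normals) != nrow(config$points))
    stop("need one capsomer normal per capsomer")
  e <- adjacency_edges(adjacency)
  out <- data.frame(i = e[, 1], j = e[, 2], r = 0, theta = 0, H = 0)
  for (k in seq_len(nrow(e))) {
    n1 <- capsomer_normals[e[k, 1], ]; n2 <- capsomer_normals[e[k, 2], ]
    theta <- atan2(sqrt(sum(cross3(n1, n2)^2)), sum(n1 * n2))
    r <- sqrt(sum((config$points[e[k, 1], ] - config$points[e[k, 2], ])^2))
    out$r[k] <- r
    out$theta[k] <- theta
    out$H[k] <- 2 / r * sin(theta / 2)
  }
  out
}

#' All curvature measures of a capsid in one call
#'
#' @param config a [capsomer_configuration()].
#' @param surface its [triangulate()]d surface (built when NULL).
#' @param adjacency its [build_adjacency()] (built when NULL).
#' @param capsomer_normals optional N x 3 capsomer median-plane normals; when
#'   given, the capsomer-plane curvature is included.
#' @return object of class \code{curvature_field}: \code{K} (per node),
#'   \code{H} (per-edge data.frame) and optionally \code{H_true}.
#' @export
curvature_field <- function(config, surface = NULL, adjacency = NULL,
                            capsomer_normals = NULL) {
  if (is.null(surface)) surface <- triangulate(config)
  if (is.null(adjacency)) adjacency <- build_adjacency(config, "auto", check = FALSE)
  out <- list(K = gaussian_curvature(surface),
              H = mean_curvature(surface, adjacency = NULL))
  if (!is.null(capsomer_normals))
    out$H_true <- true_curvature(config, adjacency, capsomer_normals)
  structure(out, class = "curvature_field")
}
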