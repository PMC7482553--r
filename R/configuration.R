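#' Capsomer centroid configuration
#'
#' The basic object of the coarse-grained model: a capsid reduced to the set
#' of its capsomer centroids. Pentamers (exactly 12, sitting on the five-fold
#' axes) occupy indices 1..12; hexamers follow. Coordinates are centred on the
#' configuration centroid.
#'
#' @param points numeric N x 3 matrix of centroids (Angstrom for imported
#'   structures, arbitrary units for synthetic lattices).
#' @param kind character vector ("pentamer"/"hexamer"), one entry per point.
#' @param source free-text provenance tag.
#' @param center recentre the points on their centroid (default TRUE).
#' @return object of class \code{capsomer_configuration} with fields
#'   \code{points}, \code{kind}, \code{source}.
#' @export
capsomer_configuration <- function(points, kind, source = "", center = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must be an N x 3 matrix")
  n <- nrow(points)
  if (n < 12) stop("a capsid needs at least 12 capsomers")
  kind <- match.arg(kind, c("pentamer", "hexamer"), several.ok = TRUE)
  if (length(kind) == 1) kind <- rep(kind, n)
  if (length(kind) != n) stop("kind must have one entry per point")
  if (sum(kind == "pentamer") != 12)
    stop("a capsid has exactly 12 pentamers (got ", sum(kind == "pentamer"), ")")
  if (!all(kind[1:12] == "pentamer"))
    stop("pentamers must occupy indices 1..12")
  if (center) points <- sweep(points, 2, colMeans(points))
  dmin <- min(stats::dist(points))
  if (dmin <= 0) stop("degenerate configuration: coincident capsomer centroids")
  structure(list(points = points, kind = kind, source = source),
            class = "capsomer_configuration")
}

#' @export
print.capsomer_configuration <- function(x, ...) {
  cat("capsomer configuration:", nrow(x$points), "capsomers (",
      sum(x$kind == "pentamer"), "pentamers,",
      sum(x$kind == "hexamer"), "hexamers )\n")
  if (nzchar(x$source)) cat("source:", x$source, "\n")
  invisible(x)
}

#' @export
as.data.frame.capsomer_configuration <- function(x, ...) {
  data.frame(index = seq_len(nrow(x$points)), kind = x$kind,
             x = x$points[, 1], y = x$points[, 2], z = x$points[, 3])
}

#' Read/write a configuration as CSV (index, kind, x, y, z)
#' @param config a [capsomer_configuration()].
#' @param path file path.
#' @export
write_configuration_csv <- function(config, path) {
  utils::write.csv(as.data.frame(config), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_configuration_csv
#' @export
read_configuration_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  capsomer_configuration(as.matrix(d[, c("x", "y", "z")]), d$kind,
                         source = path, center = FALSE)
}

#' Scale a configuration to a target mean adjacent-capsomer spacing
#'
#' Stress units in this model are arbitrary; synthetic lattices are scaled so
#' that the mean centre-to-centre distance of adjacent capsomers matches a
#' common target, making stress values comparable across shapes.
#'
#' @param config a [capsomer_configuration()].
#' @param spacing target mean adjacent distance (default 1).
#' @return rescaled configuration.
#' @export
scale_to_spacing <- function(config, spacing = 1) {
  D <- as.matrix(stats::dist(config$points))
  n <- nrow(D)
  nn <- apply(D + diag(Inf, n), 1, min)
  delta <- 1.4 * stats::median(nn)   # same first-shell rule as auto adjacency
  adj <- build_adjacency(config, delta, check = FALSE)
  mean_d <- mean(D[adj$A == 1])
  capsomer_configuration(config$points * (spacing / mean_d), config$kind,
                         source = config$source, center = FALSE)
}

#' Capsomer adjacency by distance cutoff
#'
#' Two capsomers are adjacent when their centre distance is below the cutoff
#' delta, chosen on the order of one inter-capsomer spacing (about twice a
#' hexamer radius). With a well-chosen delta every pentamer touches 5
#' neighbours and every hexamer 6.
#'
#' @param config a [capsomer_configuration()].
#' @param delta numeric cutoff, or \code{"auto"} for 1.4 x the median
#'   nearest-neighbour distance (captures the first neighbour shell, excludes
#'   the second on both icosahedral and spherical embeddings).
#' @param check when delta is "auto", verify the 5/6 coordination rule and
#'   warn with the achieved degree histogram if it fails.
#' @return object of class \code{capsid_adjacency}: \code{A} (0/1 symmetric
#'   matrix, zero diagonal) and \code{delta}.
#' @export
build_adjacency <- function(config, delta = "auto", check = TRUE) {
  P <- config$points
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  if (min(D[upper.tri(D)]) <= 0)
    stop("degenerate configuration: coincident points")
  if (identical(delta, "auto")) {
    if (n < 13) stop("auto delta needs at least 13 capsomers")
    nn <- apply(D + diag(Inf, n), 1, min)
    delta <- 1.4 * stats::median(nn)
  }
  A <- (D < delta) * 1L
  diag(A) <- 0L
  if (check) {
    deg <- rowSums(A)
    want <- ifelse(config$kind == "pentamer", 5L, 6L)
    if (!all(deg == want))
      warning("coordination check failed for auto delta; degree histogram: ",
              paste(names(table(deg)), table(deg), sep = ":", collapse = " "))
  }
  structure(list(A = A, delta = delta), class = "capsid_adjacency")
}

#' Edge list of an adjacency
#' @param adjacency a \code{capsid_adjacency}.
#' @return 2-column integer matrix, each adjacent pair once (i < j).
#' @export
adjacency_edges <- function(adjacency) {
  w <- which(adjacency$A == 1 & upper.tri(adjacency$A), arr.ind = TRUE)
  unname(w[order(w[, 1], w[, 2]), , drop = FALSE])
}

#' Triangulated capsid surface
#'
#' Builds the closed outward-oriented triangulation whose nodes are the
#' capsomer centroids. Centroids are radially projected onto the unit sphere
#' and the convex hull of the projections is taken, which keeps capsomers on
#' flat icosahedral faces as mesh vertices; a capsomer strictly interior to
#' the hull of the raw points is an error (capsids are convex at capsomer
#' resolution). Areas and normals are computed from the original coordinates.
#'
#' @param config a [capsomer_configuration()].
#' @return object of class \code{capsid_surface}: \code{triangles} (F x 3,
#'   outward oriented), \code{points}, \code{area} (total, squared input
#'   units), \code{node_normals} (N x 3 outward unit vectors).
#' @export
triangulate <- function(config) {
  P <- config$points
  n <- nrow(P)
  r <- sqrt(rowSums(P^2))
  if (any(r < 1e-9 * max(r)))
    stop("point at the configuration centre cannot lie on the surface")
  ## interior-point check against the hull of the raw coordinates
  raw <- quickhull3d(P)
  planes <- t(apply(raw$triangles, 1, function(v) {
    nrm <- cross3(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])
    nrm <- nrm / sqrt(sum(nrm^2))
    c(nrm, sum(nrm * P[v[1], ]))
  }))
  side <- P %*% t(planes[, 1:3, drop = FALSE])
  side <- sweep(side, 2, planes[, 4])
  inner <- which(apply(side, 1, max) < -1e-7 * max(r))
  if (length(inner) > 0)
    stop("capsomer ", paste(inner, collapse = ", "),
         " is interior to the hull; ",
         "the capsid surface must contain all capsomers as nodes")
  U <- P / r
  hull <- quickhull3d(U, insert_coplanar = TRUE)
  tri <- hull$triangles
  if (length(unique(as.vector(tri))) != n)
    stop("capsomer(s) ",
         paste(setdiff(seq_len(n), unique(as.vector(tri))), collapse = ", "),
         " could not be meshed as surface nodes")
  ## orient outward with respect to the original coordinates
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    nrm <- cross3(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])
    ctr <- colMeans(P[v, ])
    if (sum(nrm * ctr) < 0) tri[t, ] <- tri[t, c(1, 3, 2)]
  }
  ## manifold check: every edge shared by exactly two triangles
  ek <- paste(pmin(tri[, c(1, 2, 3)], tri[, c(2, 3, 1)]),
              pmax(tri[, c(1, 2, 3)], tri[, c(2, 3, 1)]))
  if (any(table(ek) != 2L)) stop("triangulation is not a closed manifold")
  surf <- structure(list(triangles = tri, points = P,
                         area = sum(.triangle_areas(P, tri)),
                         node_normals = NULL),
                    class = "capsid_surface")
  surf$node_normals <- node_normals(surf)
  surf
}

#' @export
print.capsid_surface <- function(x, ...) {
  v <- length(unique(as.vector(x$triangles)))
  f <- nrow(x$triangles)
  cat("capsid surface: V =", v, "F =", f, "E =", 3 * f / 2,
      " area =", signif(x$area, 6), "\n")
  invisible(x)
}

#' Outward unit normals at surface nodes
#'
#' Area-weighted mean of the outward normals of the triangles incident to each
#' node, renormalized to unit length; falls back to the radial direction (with
#' a warning) if the mean degenerates.
#'
#' @param surface a \code{capsid_surface}.
#' @return N x 3 matrix of unit vectors.
#' @export
node_normals <- function(surface) {
  P <- surface$points
  tri <- surface$triangles
  n <- nrow(P)
  acc <- matrix(0, n, 3)
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    nrm <- 0.5 * cross3(P[v[2], ] - P[v[1], ], P[v[3], ] - P[v[1], ])
    acc[v, ] <- acc[v, ] + rep(nrm, each = 3)  # weight = triangle area
  }
  len <- sqrt(rowSums(acc^2))
  bad <- len < 1e-12 * max(len)
  if (any(bad)) {
    warning("degenerate normal fan at node(s) ",
            paste(which(bad), collapse = ", "), "; falling back to radial")
    acc[bad, ] <- P[bad, , drop = FALSE]
    len[bad] <- sqrt(rowSums(acc[bad, , drop = FALSE]^2))
  }
  acc / len
}
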