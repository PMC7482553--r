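#' Convex hull triangulation of a 3D point cloud
#'
#' Incremental quickhull. Returns outward-oriented triangles (counter-clockwise
#' seen from outside) indexing rows of \code{points}. Points that lie exactly on
#' a hull facet (coplanar degeneracies, e.g. lattice points on a flat
#' icosahedral face after radial projection ties) are re-inserted by splitting
#' the containing facet, so that every distinct input point in convex position
#' appears as a mesh vertex when \code{insert_coplanar = TRUE}.
#'
#' @param points numeric matrix, one point per row (3 columns).
#' @param tol relative tolerance for plane-side tests.
#' @param insert_coplanar also mesh points lying on (not strictly outside)
#'   facets, keeping them as vertices of the triangulation.
#' @return list with \code{triangles} (integer matrix, k x 3), \code{volume}
#'   and \code{area} of the hull.
#' @keywords internal
quickhull3d <- function(points, tol = 1e-12, insert_coplanar = FALSE) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  n <- nrow(P)
  if (n < 4L) stop("need at least 4 points for a 3D hull")
  scale <- max(abs(P), 1)
  eps <- tol * scale

  plane <- function(a, b, c) {
    nrm <- cross3(P[b, ] - P[a, ], P[c, ] - P[a, ])
    len <- sqrt(sum(nrm^2))
    if (len < eps) return(NULL)
    nrm <- nrm / len
    list(n = nrm, d = sum(nrm * P[a, ]))
  }

  ## initial simplex from extreme points
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) { i1 <- which.min(P[, 2]); i2 <- which.max(P[, 2]) }
  if (i1 == i2) stop("degenerate point set (all points coincide)")
  ab <- P[i2, ] - P[i1, ]
  d2 <- vapply(seq_len(n), function(i) {
    v <- P[i, ] - P[i1, ]
    sum(cross3(ab, v)^2)
  }, 0)
  i3 <- which.max(d2)
  if (d2[i3] < eps^2) stop("degenerate point set (collinear)")
  pl <- plane(i1, i2, i3)
  d3 <- abs(P %*% pl$n - pl$d)
  i4 <- which.max(d3)
  if (d3[i4] < eps) stop("degenerate point set (coplanar)")
  interior <- colMeans(P[c(i1, i2, i3, i4), ])

  faces <- list()   # each: v (3 ints), n, d, out (int vec), alive
  mkface <- function(a, b, c) {
    pl <- plane(a, b, c)
    if (is.null(pl)) return(NULL)
    if (sum(pl$n * interior) - pl$d > 0) {  # flip outward
      tmp <- b; b <- c; c <- tmp
      pl$n <- -pl$n; pl$d <- -pl$d
    }
    list(v = c(a, b, c), n = pl$n, d = pl$d, out = integer(0), alive = TRUE)
  }
  for (tri in list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4)))
    faces[[length(faces) + 1L]] <- mkface(tri[1], tri[2], tri[3])

  assign_out <- function(face_ids, cand) {
    ## claim each candidate point for the first face it is strictly outside of
    for (fi in face_ids) {
      if (length(cand) == 0L) break
      f <- faces[[fi]]
      s <- P[cand, , drop = FALSE] %*% f$n - f$d
      sel <- s > eps
      if (any(sel)) {
        faces[[fi]]$out <<- cand[sel]
        cand <- cand[!sel]
      }
    }
    invisible(NULL)
  }
  cand0 <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  assign_out(seq_along(faces), cand0)

  repeat {
    fi <- 0L
    for (k in seq_along(faces))
      if (faces[[k]]$alive && length(faces[[k]]$out) > 0L) { fi <- k; break }
    if (fi == 0L) break
    f <- faces[[fi]]
    s <- P[f$out, , drop = FALSE] %*% f$n - f$d
    p <- f$out[which.max(s)]

    visible <- integer(0)
    for (k in seq_along(faces)) {
      if (!faces[[k]]$alive) next
      if (sum(P[p, ] * faces[[k]]$n) - faces[[k]]$d > eps) visible <- c(visible, k)
    }
    ## horizon = unordered edges used by exactly one visible face
    ev <- do.call(rbind, lapply(visible, function(k) {
      v <- faces[[k]]$v
      rbind(sort(c(v[1], v[2])), sort(c(v[2], v[3])), sort(c(v[3], v[1])))
    }))
    key <- paste(ev[, 1], ev[, 2])
    horizon <- ev[key %in% names(which(table(key) == 1L)), , drop = FALSE]

    cand <- setdiff(unique(unlist(lapply(visible, function(k) faces[[k]]$out))), p)
    for (k in visible) { faces[[k]]$alive <- FALSE; faces[[k]]$out <- integer(0) }

    new_ids <- integer(0)
    for (e in seq_len(nrow(horizon))) {
      nf <- mkface(horizon[e, 1], horizon[e, 2], p)
      if (is.null(nf)) next
      faces[[length(faces) + 1L]] <- nf
      new_ids <- c(new_ids, length(faces))
    }
    assign_out(new_ids, cand)
  }

  tri <- do.call(rbind, lapply(faces, function(f) if (f$alive) f$v else NULL))
  if (insert_coplanar) tri <- .insert_coplanar(P, tri, eps)
  list(triangles = tri,
       volume = .mesh_volume(P, tri),
       area = sum(.triangle_areas(P, tri)))
}

## re-insert points that sit exactly on a hull facet (vertices of nothing)
.insert_coplanar <- function(P, tri, eps) {
  missing <- setdiff(seq_len(nrow(P)), unique(as.vector(tri)))
  for (m in missing) {
    x <- P[m, ]
    ## find a facet whose plane contains x and whose triangle contains x
    placed <- FALSE
    for (t in seq_len(nrow(tri))) {
      a <- P[tri[t, 1], ]; b <- P[tri[t, 2], ]; c <- P[tri[t, 3], ]
      nrm <- cross3(b - a, c - a)
      len <- sqrt(sum(nrm^2))
      if (len < eps) next
      nrm <- nrm / len
      if (abs(sum(nrm * (x - a))) > 1e3 * eps) next
      ## barycentric coordinates in the facet plane
      M <- cbind(b - a, c - a, nrm)
      bc <- tryCatch(solve(M, x - a), error = function(e) NULL)
      if (is.null(bc)) next
      u <- bc[1]; v <- bc[2]
      if (u < -1e-9 || v < -1e-9 || u + v > 1 + 1e-9) next
      i <- tri[t, 1]; j <- tri[t, 2]; k <- tri[t, 3]
      if (u > 1e-9 && v > 1e-9 && u + v < 1 - 1e-9) {
        ## interior: split into three
        tri <- rbind(tri[-t, , drop = FALSE],
                     c(i, j, m), c(j, k, m), c(k, i, m))
      } else {
        ## on an edge: split both incident triangles
        edge <- if (v <= 1e-9) c(i, j) else if (u <= 1e-9) c(i, k) else c(j, k)
        inc <- which(apply(tri, 1, function(tv) all(edge %in% tv)))
        newt <- list()
        for (t2 in inc) {
          opp <- setdiff(tri[t2, ], edge)
          ## preserve orientation of the split triangles
          v3 <- tri[t2, ]
          pos <- match(edge, v3)
          for (ee in edge) {
            tt <- v3
            tt[match(setdiff(edge, ee), v3)] <- m
            newt[[length(newt) + 1L]] <- tt
          }
        }
        tri <- rbind(tri[-inc, , drop = FALSE], do.call(rbind, newt))
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("point ", m, " is interior to the convex hull and cannot be a surface node")
  }
  tri
}

.triangle_areas <- function(P, tri) {
  vapply(seq_len(nrow(tri)), function(t) {
    a <- P[tri[t, 1], ]; b <- P[tri[t, 2], ]; c <- P[tri[t, 3], ]
    0.5 * sqrt(sum(cross3(b - a, c - a)^2))
  }, 0)
}

.mesh_volume <- function(P, tri) {
  ctr <- colMeans(P[unique(as.vector(tri)), , drop = FALSE])
  v <- 0
  for (t in seq_len(nrow(tri))) {
    a <- P[tri[t, 1], ] - ctr; b <- P[tri[t, 2], ] - ctr; c <- P[tri[t, 3], ] - ctr
    v <- v + det(cbind(a, b, c)) / 6
  }
  abs(v)
}

## volume of the polyhedron enclosed by a fixed star-shaped triangulation:
## a fast lower bound of the hull volume, exact while the triangulation is
## the hull (vectorized scalar triple products)
.fixed_tri_volume <- function(P, tri) {
  a <- P[tri[, 1], , drop = FALSE]
  b <- P[tri[, 2], , drop = FALSE]
  c <- P[tri[, 3], , drop = FALSE]
  cx <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(a * cx)) / 6
}

#' Volume of the convex hull of a point set
#'
#' @param points numeric matrix (rows = 3D points).
#' @return hull volume (cubic input units).
#' @export
hull_volume <- function(points) quickhull3d(points)$volume

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
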