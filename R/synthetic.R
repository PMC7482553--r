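#' Caspar-Klug (h, k) capsomer lattice
#'
#' Generates the capsomer centroids of a T = h^2 + hk + k^2 shell by laying
#' the planar hexagonal lattice of capsomer centres over the 20 faces of an
#' icosahedron: the face triangle spans h steps along one lattice direction
#' and k along the second (at a counter-clockwise pi/3 angle, so (2, 4) is the
#' dextro T = 28 layout). Pentamers sit at the 12 icosahedral vertices and
#' come first in index order; lattice points shared between faces are emitted
#' once (lowest face index wins). For \code{shape = "sphere"} every point is
#' radially projected onto the circumscribed sphere.
#'
#' @param h,k non-negative integers, not both zero.
#' @param shape "icosahedron" (faceted shell) or "sphere" (radial projection).
#' @param spacing target mean adjacent-capsomer spacing; NULL keeps the raw
#'   unit-edge-lattice scale.
#' @return a [capsomer_configuration()] with N = 10 T + 2 capsomers, plus
#'   attributes \code{T}, \code{h}, \code{k}, \code{chirality}.
#' @export
ck_configuration <- function(h, k, shape = c("icosahedron", "sphere"),
                             spacing = 1) {
  shape <- match.arg(shape)
  h <- as.integer(h); k <- as.integer(k)
  if (h < 0 || k < 0 || (h == 0 && k == 0)) stop("(h, k) must be non-negative, not both zero")
  Tn <- h^2 + h * k + k^2

  ## planar hexagonal lattice of capsomer centres, basis at pi/3
  a1 <- c(1, 0)
  a2 <- c(0.5, sqrt(3) / 2)
  B <- h * a1 + k * a2
  R60 <- matrix(c(cos(pi / 3), sin(pi / 3), -sin(pi / 3), cos(pi / 3)), 2, 2)
  C <- as.numeric(R60 %*% B)
  ## barycentric coordinates of all lattice points in triangle (0, B, C)
  M <- cbind(B, C)
  rng <- -(h + k):(2 * (h + k))
  grid <- as.matrix(expand.grid(m = rng, n = rng))
  pts2 <- grid %*% rbind(a1, a2)
  uv <- t(solve(M, t(pts2)))
  tol <- 1e-9
  keep <- uv[, 1] >= -tol & uv[, 2] >= -tol & uv[, 1] + uv[, 2] <= 1 + tol
  uv <- uv[keep, , drop = FALSE]

  V <- icosahedron_vertices()
  faces <- icosahedron_faces()
  pts <- matrix(0, 0, 3)
  for (f in seq_len(nrow(faces))) {
    v1 <- V[faces[f, 1], ]; v2 <- V[faces[f, 2], ]; v3 <- V[faces[f, 3], ]
    al <- 1 - uv[, 1] - uv[, 2]
    p <- al %o% v1 + uv[, 1] %o% v2 + uv[, 2] %o% v3
    pts <- rbind(pts, p)
  }
  ## deduplicate shared edge/vertex points; first (lowest face) occurrence wins
  key <- apply(round(pts, 7), 1, paste, collapse = ",")
  pts <- pts[!duplicated(key), , drop = FALSE]
  if (nrow(pts) != 10 * Tn + 2)
    stop("internal error: lattice emitted ", nrow(pts),
         " points, expected ", 10 * Tn + 2)

  ## pentamers = icosahedral vertices, listed first in vertex order
  pent_idx <- apply(V, 1, function(v) {
    which.min(rowSums(sweep(pts, 2, v)^2))
  })
  hex_idx <- setdiff(seq_len(nrow(pts)), pent_idx)
  pts <- rbind(pts[pent_idx, , drop = FALSE], pts[hex_idx, , drop = FALSE])
  kind <- c(rep("pentamer", 12), rep("hexamer", nrow(pts) - 12))

  if (shape == "sphere") {
    r <- sqrt(rowSums(pts^2))
    pts <- pts / r   # unit circumsphere
  }
  chir <- if (h == 0 || k == 0 || h == k) "achiral" else if (h < k) "dextro" else "laevo"
  cfg <- capsomer_configuration(pts, kind,
                                source = sprintf("CK(h=%d,k=%d,T=%d,%s)", h, k, Tn, shape))
  if (!is.null(spacing)) cfg <- scale_to_spacing(cfg, spacing)
  attr(cfg, "T") <- Tn; attr(cfg, "h") <- h; attr(cfg, "k") <- k
  attr(cfg, "chirality") <- chir
  cfg
}

.hk_for_T <- function(T) {
  for (h in 0:floor(sqrt(T))) {
    disc <- -3 * h^2 + 4 * T
    if (disc < 0) next
    k <- (-h + sqrt(disc)) / 2
    if (abs(k - round(k)) < 1e-9 && round(k) >= h && (h + round(k)) > 0)
      return(c(h, round(k)))
  }
  stop("T = ", T, " is not a Caspar-Klug triangulation number")
}

#' Icosahedrally symmetric spherical code maximizing convex-hull volume
#'
#' Builds the 10T+2-point arrangement on the unit sphere that (locally)
#' maximizes the volume of the convex hull under exact chiral icosahedral
#' symmetry. These point sets approximately minimize the Lennard-Jones energy
#' of the shell and stand in for highly spherical capsids with no deposited
#' structure. Points are parametrized by symmetry orbits (pentamers fixed on
#' the five-fold axes; hexamer orbits of size 20/30 pinned to three-/two-fold
#' axes; orbits of size 60 free), and the free orbit representatives are
#' optimized by seeded multi-start Nelder-Mead, starting from the radially
#' projected Caspar-Klug lattice, so the result never falls below the
#' projected lattice's hull volume.
#'
#' @param T triangulation number (must be realizable as h^2+hk+k^2).
#' @param seed integer seed controlling the restarts.
#' @param n_restarts number of local searches (the first starts unperturbed).
#' @return list of class \code{spherical_code}: \code{configuration} (unit
#'   sphere, pentamers first), \code{hull_volume}, \code{seed},
#'   \code{n_restarts}, \code{restart_volumes}.
#' @export
spherical_code <- function(T, seed = 0, n_restarts = 8) {
  hk <- .hk_for_T(T)
  base <- ck_configuration(hk[1], hk[2], shape = "sphere", spacing = NULL)
  P <- base$points
  P <- P / sqrt(rowSums(P^2))
  G <- icosahedral_rotations()

  pent <- P[1:12, , drop = FALSE]
  hexp <- P[-(1:12), , drop = FALSE]
  vols <- numeric(0)
  if (nrow(hexp) == 0 || T == 3) {
    ## no free orbits: T=1 is the icosahedron, T=3 pins all hexamers to
    ## three-fold axes
    pts <- P
    best_vol <- hull_volume(pts)
    vols <- best_vol
  } else {
    orb <- group_orbits(hexp, G, tol = 1e-6)
    sizes <- table(orb)
    free_reps <- list(); fixed_pts <- matrix(0, 0, 3)
    for (o in as.integer(names(sizes))) {
      members <- hexp[orb == o, , drop = FALSE]
      if (sizes[[as.character(o)]] == 60L) {
        free_reps[[length(free_reps) + 1L]] <- members[1, ]
      } else {
        fixed_pts <- rbind(fixed_pts, members)  # on 2-/3-fold axes: immobile
      }
    }
    if (length(free_reps) == 0) {
      pts <- rbind(pent, fixed_pts)
      best_vol <- hull_volume(pts)
      vols <- best_vol
      kind <- c(rep("pentamer", 12), rep("hexamer", nrow(pts) - 12))
      cfg <- capsomer_configuration(pts, kind,
                                    source = sprintf("spherical_code(T=%d,seed=%d)", T, seed),
                                    center = FALSE)
      attr(cfg, "T") <- T
      return(structure(list(configuration = cfg, hull_volume = best_vol,
                            seed = seed, n_restarts = n_restarts,
                            restart_volumes = vols),
                       class = "spherical_code"))
    }
    to_par <- function(reps) unlist(lapply(reps, function(x)
      c(acos(max(-1, min(1, x[3]))), atan2(x[2], x[1]))))
    from_par <- function(par) {
      m <- matrix(par, ncol = 2, byrow = TRUE)
      cbind(sin(m[, 1]) * cos(m[, 2]), sin(m[, 1]) * sin(m[, 2]), cos(m[, 1]))
    }
    assemble <- function(par) {
      reps <- from_par(par)
      free <- do.call(rbind, lapply(G, function(g) reps %*% t(g)))
      rbind(pent, fixed_pts, free)
    }
    par0 <- to_par(free_reps)
    ## the objective uses the volume of a frozen star-shaped triangulation:
    ## exact while that triangulation is the hull (and a lower bound of the
    ## hull volume otherwise), and an order of magnitude cheaper per
    ## evaluation. The triangulation is re-frozen whenever the true hull
    ## volume of a local optimum exceeds the frozen value.
    set.seed(seed)
    best_par <- NULL; best_vol <- -Inf
    for (r in seq_len(n_restarts)) {
      par <- if (r == 1) par0 else par0 + stats::rnorm(length(par0), sd = 0.05)
      tri <- quickhull3d(assemble(par))$triangles
      for (refreeze in 1:5) {
        objective <- function(p) -.fixed_tri_volume(assemble(p), tri)
        fit <- stats::optim(par, objective, method = "Nelder-Mead",
                            control = list(maxit = 300 * length(par0),
                                           reltol = 1e-12))
        fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                            control = list(maxit = 150 * length(par0),
                                           reltol = 1e-12))
        par <- fit$par
        hull <- quickhull3d(assemble(par))
        if (hull$volume <= -fit$value + 1e-10) break
        tri <- hull$triangles   # combinatorics changed: re-freeze and refine
      }
      vols <- c(vols, hull$volume)
      if (hull$volume > best_vol) { best_vol <- hull$volume; best_par <- par }
    }
    ## never fall below the radially projected lattice start
    v0 <- hull_volume(assemble(par0))
    if (best_vol < v0) { best_par <- par0; best_vol <- v0 }
    pts <- assemble(best_par)
  }
  kind <- c(rep("pentamer", 12), rep("hexamer", nrow(pts) - 12))
  cfg <- capsomer_configuration(pts, kind,
                                source = sprintf("spherical_code(T=%d,seed=%d)", T, seed),
                                center = FALSE)
  attr(cfg, "T") <- T
  structure(list(configuration = cfg, hull_volume = best_vol, seed = seed,
                 n_restarts = n_restarts, restart_volumes = vols),
            class = "spherical_code")
}

#' @export
print.spherical_code <- function(x, ...) {
  cat("icosahedral spherical code: N =", nrow(x$configuration$points),
      " hull volume =", signif(x$hull_volume, 8),
      " (", x$n_restarts, "restarts, seed", x$seed, ")\n")
  invisible(x)
}
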