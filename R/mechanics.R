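#' Lennard-Jones interaction model between capsomers
#'
#' Pairwise potential V(r) = eps0 ((sigma/r)^12 - 2 (sigma/r)^6) with minimum
#' -eps0 exactly at the equilibrium distance r = sigma. The equilibrium
#' distance depends on the unordered pair class (pentamer-pentamer,
#' pentamer-hexamer, hexamer-hexamer).
#'
#' @param eps0 positive energy scale (arbitrary units; stresses inherit it).
#' @param sigma named numeric vector of equilibrium distances with names among
#'   "pentamer-pentamer", "pentamer-hexamer", "hexamer-hexamer".
#' @param delta adjacency cutoff the model was calibrated with.
#' @return object of class \code{interaction_model}.
#' @export
interaction_model <- function(eps0 = 1, sigma, delta = NULL) {
  classes <- c("pentamer-pentamer", "pentamer-hexamer", "hexamer-hexamer")
  if (is.null(names(sigma)) || !all(names(sigma) %in% classes))
    stop("sigma must be named with pair classes: ", paste(classes, collapse = ", "))
  if (any(sigma <= 0) || eps0 <= 0) stop("sigma and eps0 must be positive")
  ## a cutoff reaching far beyond the first-shell spacing would pull
  ## second-neighbour shells (at about sqrt(3) sigma) into the interactions
  if (!is.null(delta) && delta > sqrt(3) * mean(sigma))
    warning("delta exceeds the second-shell onset (sqrt(3) x min sigma); ",
            "second neighbour shells may enter the model")
  structure(list(eps0 = eps0, sigma = sigma, delta = delta),
            class = "interaction_model")
}

#' Calibrate equilibrium distances from a reference configuration
#'
#' Sets sigma for each pair class to the mean observed adjacent-pair distance
#' of that class in a reference configuration, making the reference
#' near-equilibrium. An explicitly supplied sigma table should be preferred
#' when one is available.
#'
#' @param config reference [capsomer_configuration()].
#' @param adjacency its [build_adjacency()] (auto-built when NULL).
#' @param eps0 energy scale.
#' @return an [interaction_model()].
#' @export
calibrate_model <- function(config, adjacency = NULL, eps0 = 1) {
  if (is.null(adjacency)) adjacency <- build_adjacency(config, "auto", check = FALSE)
  D <- as.matrix(stats::dist(config$points))
  e <- adjacency_edges(adjacency)
  cls <- .pair_class(config$kind[e[, 1]], config$kind[e[, 2]])
  d <- D[e]
  sig <- tapply(d, cls, mean)
  sigma <- stats::setNames(as.numeric(sig), names(sig))
  ## absent classes (e.g. no pentamer-pentamer contacts for T > 1) fall back
  ## to the overall mean spacing
  all_cls <- c("pentamer-pentamer", "pentamer-hexamer", "hexamer-hexamer")
  miss <- setdiff(all_cls, names(sigma))
  if (length(miss) > 0) sigma[miss] <- mean(d)
  interaction_model(eps0 = eps0, sigma = sigma[all_cls], delta = adjacency$delta)
}

.pair_class <- function(k1, k2) {
  a <- pmin(k1, k2); b <- pmax(k1, k2)   # "hexamer" < "pentamer" alphabetically
  ifelse(a == "pentamer", "pentamer-pentamer",
         ifelse(b == "pentamer", "pentamer-hexamer", "hexamer-hexamer"))
}

.sigma_matrix <- function(config, model) {
  n <- length(config$kind)
  cls <- outer(config$kind, config$kind, .pair_class)
  matrix(model$sigma[cls], n, n)
}

#' Lennard-Jones pair potential
#'
#' @param r centre distance (> 0); vectorized.
#' @param sigma equilibrium distance.
#' @param eps0 energy scale.
#' @return potential energy; equals -eps0 at r = sigma.
#' @export
lj_potential <- function(r, sigma, eps0 = 1) {
  if (any(r <= 0)) stop("r must be positive")
  sr6 <- (sigma / r)^6
  eps0 * (sr6^2 - 2 * sr6)
}

## dV/dr = (12 eps0 / r) ((sigma/r)^6 - (sigma/r)^12)
.lj_dVdr <- function(r, sigma, eps0 = 1) {
  sr6 <- (sigma / r)^6
  12 * eps0 / r * (sr6 - sr6^2)
}

#' Interaction force between two capsomers
#'
#' Force exerted on capsomer i by capsomer j (the negative gradient of the
#' pair potential with respect to x_i), gated by the adjacency matrix:
#' attractive along r_ij = x_j - x_i beyond the equilibrium distance,
#' repulsive (pushing i away from j) below it, zero at r = sigma and for
#' non-adjacent pairs. Forces obey f_ij = -f_ji.
#'
#' @param i,j capsomer indices (i != j).
#' @param config a [capsomer_configuration()].
#' @param adjacency a [build_adjacency()].
#' @param model an [interaction_model()].
#' @return 3-vector.
#' @export
pair_force <- function(i, j, config, adjacency, model) {
  if (i == j) stop("i and j must differ")
  rij <- config$points[j, ] - config$points[i, ]
  r <- sqrt(sum(rij^2))
  if (r <= 0) stop("coincident capsomers ", i, " and ", j)
  if (adjacency$A[i, j] == 0) return(c(0, 0, 0))
  sigma <- model$sigma[.pair_class(config$kind[i], config$kind[j])]
  (.lj_dVdr(r, sigma, model$eps0) / r) * rij
}

#' Total Lennard-Jones energy of a configuration
#'
#' Double sum over ordered pairs gated by adjacency, so each adjacent pair
#' contributes twice; the ground state with every adjacent pair at its sigma
#' has E = -eps0 x (2 x number of adjacent pairs).
#'
#' @inheritParams pair_force
#' @return scalar energy.
#' @export
total_energy <- function(config, adjacency, model) {
  e <- adjacency_edges(adjacency)
  if (nrow(e) == 0) return(0)
  D <- as.matrix(stats::dist(config$points))
  sig <- model$sigma[.pair_class(config$kind[e[, 1]], config$kind[e[, 2]])]
  2 * sum(lj_potential(D[e], sig, model$eps0))
}

#' Static virial stress tensor per capsomer
#'
#' T_i = 1/(2|S|) sum_{j != i} f_ij (x) r_ij, with f_ij the pair force on i
#' from j, r_ij = x_j - x_i, and |S| the total triangulated surface area.
#' The tensor is generally nonzero even where the forces on a capsomer
#' balance.
#'
#' @inheritParams pair_force
#' @param surface the [triangulate()]d capsid surface (supplies |S|).
#' @return 3 x 3 x N array.
#' @export
virial_stress <- function(config, adjacency, model, surface) {
  P <- config$points
  n <- nrow(P)
  if (surface$area <= 0) stop("surface area must be positive")
  sig <- .sigma_matrix(config, model)
  out <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    js <- which(adjacency$A[i, ] == 1)
    acc <- matrix(0, 3, 3)
    for (j in js) {
      rij <- P[j, ] - P[i, ]
      r <- sqrt(sum(rij^2))
      f <- (.lj_dVdr(r, sig[i, j], model$eps0) / r) * rij
      acc <- acc + outer(f, rij)
    }
    out[, , i] <- acc / (2 * surface$area)
  }
  out
}

#' Tangential part of the stress tensor and its principal values
#'
#' Symmetrizes T, projects it onto the tangent plane orthogonal to the node
#' normal (P = I - n n^T; Ttilde = P sym(T) P) and returns the two in-plane
#' principal stresses (the third eigenvalue, along the normal, is identically
#' zero and discarded).
#'
#' @param T_i 3 x 3 stress tensor.
#' @param normal unit node normal.
#' @return list: \code{Ttilde} (3 x 3, annihilates the normal),
#'   \code{lambda_max}, \code{lambda_min}, \code{e_max}, \code{e_min}
#'   (in-plane unit principal directions).
#' @export
tangential_stress <- function(T_i, normal) {
  n <- normal / sqrt(sum(normal^2))
  S <- (T_i + t(T_i)) / 2
  Pm <- diag(3) - outer(n, n)
  Tt <- Pm %*% S %*% Pm
  ## orthonormal tangent basis
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- cross3(n, ref); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- cross3(n, t1)
  M <- rbind(c(t1 %*% S %*% t1, t1 %*% S %*% t2),
             c(t1 %*% S %*% t2, t2 %*% S %*% t2))
  tr <- M[1, 1] + M[2, 2]
  dd <- sqrt(((M[1, 1] - M[2, 2]) / 2)^2 + M[1, 2]^2)
  lmax <- tr / 2 + dd; lmin <- tr / 2 - dd
  ang <- 0.5 * atan2(2 * M[1, 2], M[1, 1] - M[2, 2])
  emax <- cos(ang) * t1 + sin(ang) * t2
  emin <- -sin(ang) * t1 + cos(ang) * t2
  list(Ttilde = Tt, lambda_max = lmax, lambda_min = lmin,
       e_max = emax, e_min = emin)
}

#' Lateral stress and maximum tangential shear stress
#'
#' Lambda = (lambda_max + lambda_min)/2 is the mean in-plane tension;
#' tau_max = (lambda_max - lambda_min)/2 is the maximum tangential shear,
#' attained along directions at pi/4 to the principal axes.
#'
#' @param lambda_max,lambda_min in-plane principal stresses (vectorized),
#'   with lambda_max >= lambda_min.
#' @return list with \code{lateral} and \code{shear} (tau_max >= 0).
#' @export
lateral_and_shear <- function(lambda_max, lambda_min) {
  if (any(lambda_max < lambda_min - 1e-12))
    stop("lambda_max must be >= lambda_min")
  list(lateral = (lambda_max + lambda_min) / 2,
       shear = pmax(0, (lambda_max - lambda_min) / 2))
}

#' Full per-capsomer stress field
#'
#' Runs the virial-stress and tangential-decomposition chain for every
#' capsomer and gathers the per-node tensors, principal values, lateral and
#' maximum shear stresses together with the global energy and surface area.
#'
#' @inheritParams virial_stress
#' @return object of class \code{stress_field}: arrays \code{virial} and
#'   \code{tangential} (3 x 3 x N), vectors \code{lambda_max},
#'   \code{lambda_min}, \code{lateral}, \code{shear}, matrices \code{e_max},
#'   \code{e_shear} (N x 3; shear direction at pi/4 to the principal axes),
#'   scalars \code{energy}, \code{area}.
#' @export
stress_field <- function(config, adjacency, model, surface) {
  Tv <- virial_stress(config, adjacency, model, surface)
  n <- dim(Tv)[3]
  Tt <- array(0, c(3, 3, n))
  lmax <- lmin <- numeric(n)
  emax <- eshear <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    td <- tangential_stress(Tv[, , i], surface$node_normals[i, ])
    Tt[, , i] <- td$Ttilde
    lmax[i] <- td$lambda_max; lmin[i] <- td$lambda_min
    emax[i, ] <- td$e_max
    ## maximum shear acts at pi/4 between the principal directions
    eshear[i, ] <- (td$e_max + td$e_min) / sqrt(2)
  }
  ls <- lateral_and_shear(lmax, lmin)
  structure(list(virial = Tv, tangential = Tt,
                 lambda_max = lmax, lambda_min = lmin,
                 lateral = ls$lateral, shear = ls$shear,
                 e_max = emax, e_shear = eshear,
                 energy = total_energy(config, adjacency, model),
                 area = surface$area),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat("stress field over", length(x$lateral), "capsomers\n")
  cat("  E =", signif(x$energy, 6), " |S| =", signif(x$area, 6), "\n")
  cat("  max |lateral| =", signif(max(abs(x$lateral)), 6),
      " max shear =", signif(max(x$shear), 6), "\n")
  invisible(x)
}
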