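## Synthetic atomic stand-ins for experimental capsid structures: each
## capsomer centroid is decorated with a planar ring of pseudo-chain
## "atoms", giving the import chain (assembly expansion, capsomer clustering,
## median-plane fitting) a ground truth to recover.

#' Decorate a configuration with synthetic pseudo-chain atoms
#'
#' Places a planar ring of single-atom chain copies (5 for pentamers, 6 for
#' hexamers) in the tangent plane of each capsomer, centred exactly on the
#' capsomer centroid, so clustering the chains must reproduce the generating
#' configuration. Optional isotropic jitter emulates coordinate noise.
#'
#' @param config a [capsomer_configuration()].
#' @param ring_radius ring radius, in units of the configuration spacing.
#' @param jitter standard deviation of Gaussian noise added per atom.
#' @param seed seed used when jitter > 0.
#' @return a \code{capsid_atoms} data.frame (as from [expand_assembly()]).
#' @export
synthetic_capsid_atoms <- function(config, ring_radius = 0.2, jitter = 0,
                                   seed = 0) {
  if (jitter > 0) set.seed(seed)
  P <- config$points
  rows <- list()
  for (i in seq_len(nrow(P))) {
    m <- if (config$kind[i] == "pentamer") 5L else 6L
    nrm <- P[i, ] / sqrt(sum(P[i, ]^2))
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- cross3(nrm, ref); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- cross3(nrm, t1)
    ang <- 2 * pi * (seq_len(m) - 1) / m
    ring <- P[rep(i, m), , drop = FALSE] +
      ring_radius * (cos(ang) %o% t1 + sin(ang) %o% t2)
    if (jitter > 0) ring <- ring + matrix(stats::rnorm(3 * m, sd = jitter), m, 3)
    rows[[i]] <- data.frame(x = ring[, 1], y = ring[, 2], z = ring[, 3],
                            chain = "A", copy = i,
                            chain_copy = sprintf("c%d_%d", i, seq_len(m)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("capsid_atoms", "data.frame")
  out
}

#' Write a synthetic asymmetric unit plus assembly operators as PDB
#'
#' Emits one single-atom CA chain per row of \code{points} and a REMARK 350
#' block carrying the given rotation operators, producing a minimal but valid
#' PDB file whose biological assembly is the full particle. With the 60
#' icosahedral rotations, [expand_assembly()] yields 60 copies per chain.
#'
#' @param points asymmetric-unit atom coordinates (n x 3).
#' @param path output file.
#' @param rotations list of 3 x 3 rotation matrices (default: the chiral
#'   icosahedral group); translations are zero.
#' @param chains chain identifiers, one per point (default A, B, C, ...).
#' @return the path, invisibly.
#' @export
write_synthetic_assembly_pdb <- function(points, path,
                                         rotations = icosahedral_rotations(),
                                         chains = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(chains)) chains <- LETTERS[seq_len(n)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK 350 BIOMOLECULE: 1", con)
  writeLines(paste0("REMARK 350 APPLY THE FOLLOWING TO CHAINS: ",
                    paste(unique(chains), collapse = ", ")), con)
  for (o in seq_along(rotations)) {
    R <- rotations[[o]]
    for (r in 1:3)
      writeLines(sprintf("REMARK 350   BIOMT%d %3d %9.6f %9.6f %9.6f %14.5f",
                         r, o, R[r, 1], R[r, 2], R[r, 3], 0), con)
  }
  for (i in seq_len(n))
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, chains[i], 1L, points[i, 1], points[i, 2], points[i, 3]), con)
  writeLines("END", con)
  invisible(path)
}
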