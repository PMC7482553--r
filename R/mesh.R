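#' Export a capsid surface as an OFF mesh
#'
#' @param surface a [triangulate()]d capsid surface.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mesh_off <- function(surface, path) {
  P <- surface$points
  tri <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(P), nrow(tri), 3 * nrow(tri) / 2), con)
  writeLines(apply(format(P, digits = 10, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste(3, tri[, 1] - 1, tri[, 2] - 1, tri[, 3] - 1), con)
  invisible(path)
}

#' Export a capsid surface as an ASCII PLY mesh with an optional scalar field
#'
#' Attaches a per-vertex scalar (e.g. shear stress or Gaussian curvature) as
#' a \code{quality} property for colour-mapped rendering.
#'
#' @param surface a [triangulate()]d capsid surface.
#' @param path output file path.
#' @param scalar optional per-node numeric vector.
#' @return the path, invisibly.
#' @export
write_mesh_ply <- function(surface, path, scalar = NULL) {
  P <- surface$points
  tri <- surface$triangles
  if (!is.null(scalar) && length(scalar) != nrow(P))
    stop("scalar must have one value per surface node")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(P)),
               "property float x", "property float y", "property float z"), con)
  if (!is.null(scalar)) writeLines("property float quality", con)
  writeLines(c(paste("element face", nrow(tri)),
               "property list uchar int vertex_indices", "end_header"), con)
  V <- format(P, digits = 10, trim = TRUE)
  lines <- apply(V, 1, paste, collapse = " ")
  if (!is.null(scalar))
    lines <- paste(lines, format(scalar, digits = 10, trim = TRUE))
  writeLines(lines, con)
  writeLines(paste(3, tri[, 1] - 1, tri[, 2] - 1, tri[, 3] - 1), con)
  invisible(path)
}
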