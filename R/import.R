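## Coarse-graining of experimental capsid structures: expand the icosahedral
## assembly from the deposited asymmetric unit, cluster protein chain copies
## into capsomers, reduce each capsomer to its centroid, and fit the
## median-plane normal used by the capsomer-plane curvature.

#' Expand a structure file to the full icosahedral particle
#'
#' Reads a PDB or mmCIF file (via bio3d) and instantiates all assembly
#' operators from the REMARK 350 / biomatrix records: with a full icosahedral
#' operator set, the atom count is 60 x the asymmetric-unit count. Files with
#' an identity operator only (or particles deposited complete) are returned
#' unchanged. Only polymer (ATOM) records are kept; heteroatoms and solvent
#' are excluded.
#'
#' @param file path to a .pdb/.ent or .cif structure file.
#' @return object of class \code{capsid_atoms}: data.frame with columns
#'   \code{x}, \code{y}, \code{z}, \code{chain}, \code{copy},
#'   \code{chain_copy} (one id per chain copy in the expanded particle).
#' @export
expand_assembly <- function(file) {
  ext <- tolower(tools::file_ext(file))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(file) else bio3d::read.pdb(file)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer (ATOM) records in ", file)
  base <- data.frame(x = at$x, y = at$y, z = at$z, chain = at$chain,
                     stringsAsFactors = FALSE)
  bm <- pdb$remark$biomat
  if (is.null(bm) || length(bm$mat) == 0) {
    out <- cbind(base, copy = 1L)
  } else {
    if (bm$num > 1)
      stop("ambiguous assembly: file lists ", bm$num,
           " biological assemblies (", paste(names(bm$mat), collapse = ", "),
           "); extract the icosahedral one first")
    ops <- bm$mat[[1]]
    chains <- bm$chain[[1]]
    sel <- base$chain %in% chains
    if (!any(sel)) stop("assembly operators apply to no chain in the file")
    pieces <- vector("list", length(ops))
    for (o in seq_along(ops)) {
      M <- ops[[o]]
      xyz <- as.matrix(base[sel, c("x", "y", "z")]) %*% t(M[, 1:3])
      xyz <- sweep(xyz, 2, -M[, 4])
      pieces[[o]] <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                chain = base$chain[sel], copy = o,
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces)
  }
  out$chain_copy <- paste(out$chain, out$copy, sep = "_")
  class(out) <- c("capsid_atoms", "data.frame")
  out
}

#' Cluster chain copies into capsomers
#'
#' Chain-copy centroids are merged by single-linkage clustering; the merge
#' radius is chosen automatically in the widest gap of the single-linkage
#' merge heights (the stable plateau of the cluster-count curve), which
#' separates intra-capsomer from inter-capsomer distances without manual
#' curation. Capsomers are classified pentamer/hexamer by their coordination
#' number in the resulting centroid configuration (degree 5 vs 6); capsomer
#' centroids are the unweighted means of all member-chain atom positions.
#'
#' @param atoms a [expand_assembly()] result (or any data.frame with x, y, z
#'   and chain_copy columns).
#' @param expected_T optional triangulation number; the capsomer count must
#'   then equal 10 T + 2.
#' @return object of class \code{capsomer_assignment}: \code{configuration}
#'   (a [capsomer_configuration()], pentamers first), \code{capsomer}
#'   (data.frame: config index, kind, member chain count), \code{membership}
#'   (named vector mapping chain_copy to config index).
#' @export
assign_capsomers <- function(atoms, expected_T = NULL) {
  cc <- split(seq_len(nrow(atoms)), atoms$chain_copy)
  cent <- t(vapply(cc, function(id)
    colMeans(as.matrix(atoms[id, c("x", "y", "z")])), numeric(3)))
  hc <- stats::hclust(stats::dist(cent), method = "single")
  h <- sort(hc$height)
  gaps <- diff(h)
  gi <- which.max(gaps)
  if (gaps[gi] < 0.5 * h[gi])
    stop("ambiguous clustering: no clear merge-radius plateau ",
         "(largest gap ", signif(gaps[gi], 3), " at height ", signif(h[gi], 3), ")")
  radius <- (h[gi] + h[gi + 1]) / 2
  cl <- stats::cutree(hc, h = radius)
  ncl <- max(cl)
  sizes <- tabulate(cl)
  if (!is.null(expected_T) && ncl != 10 * expected_T + 2)
    stop("capsomer count ", ncl, " does not match 10T+2 = ",
         10 * expected_T + 2, "; cluster-size histogram: ",
         paste(names(table(sizes)), table(sizes), sep = ":", collapse = " "))
  ## capsomer centroid = unweighted mean over all atoms of the member chains
  cap_of_atom <- cl[match(atoms$chain_copy, names(cc))]
  cent_cap <- t(vapply(seq_len(ncl), function(k) {
    colMeans(as.matrix(atoms[cap_of_atom == k, c("x", "y", "z")]))
  }, numeric(3)))
  ## classify by coordination in the centroid configuration
  tmp <- capsomer_configuration(cent_cap, rep(c("pentamer", "hexamer"),
                                              c(12, ncl - 12)),
                                center = TRUE)  # placeholder kinds
  adj <- build_adjacency(tmp, "auto", check = FALSE)
  deg <- rowSums(adj$A)
  kind <- ifelse(deg == 5, "pentamer", ifelse(deg == 6, "hexamer", NA))
  if (any(is.na(kind)))
    stop("cannot classify capsomer(s) ", paste(which(is.na(kind)), collapse = ", "),
         " (coordination ", paste(deg[is.na(kind)], collapse = ", "), ")")
  if (sum(kind == "pentamer") != 12)
    stop("expected 12 five-coordinated capsomers, found ", sum(kind == "pentamer"))
  ## cross-check against cluster sizes when stoichiometry is uniform
  if (length(unique(sizes[kind == "hexamer"])) == 1 &&
      length(unique(sizes[kind == "pentamer"])) == 1 &&
      sizes[which(kind == "pentamer")[1]] == sizes[which(kind == "hexamer")[1]])
    warning("pentamer and hexamer clusters have identical chain counts; ",
            "classification rests on geometry alone")
  ord <- c(which(kind == "pentamer"), which(kind == "hexamer"))
  cfg <- capsomer_configuration(cent_cap[ord, , drop = FALSE], kind[ord],
                                source = "imported structure")
  config_index <- match(seq_len(ncl), ord)  # cluster id -> config row
  membership <- config_index[cl]
  names(membership) <- names(cc)
  structure(list(configuration = cfg,
                 capsomer = data.frame(index = seq_len(ncl),
                                       kind = kind[ord],
                                       n_chains = sizes[ord]),
                 membership = membership,
                 merge_radius = radius),
            class = "capsomer_assignment")
}

#' Median-plane outward normals of the capsomers
#'
#' For each capsomer, the normal of the least-squares plane through its atom
#' positions, oriented outward (positive dot product with the direction from
#' the particle centre to the capsomer centroid). These normals feed the
#' capsomer-plane curvature ([true_curvature()]).
#'
#' @param atoms a [expand_assembly()] result.
#' @param assignment a [assign_capsomers()] result.
#' @return N x 3 matrix of unit normals, rows aligned with the configuration
#'   node order.
#' @export
capsomer_planes <- function(atoms, assignment) {
  cap <- assignment$membership[atoms$chain_copy]
  n <- nrow(assignment$configuration$points)
  ctr_all <- colMeans(as.matrix(atoms[, c("x", "y", "z")]))
  normals <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    X <- as.matrix(atoms[cap == k, c("x", "y", "z")])
    if (nrow(X) < 3) stop("capsomer ", k, " has fewer than 3 atoms")
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc, nu = 0, nv = 3)
    if (sv$d[2] < 1e-9 * sv$d[1])
      stop("capsomer ", k, " atoms are collinear; no plane normal")
    nrm <- sv$v[, 3]
    out_dir <- colMeans(X) - ctr_all
    if (sum(nrm * out_dir) < 0) nrm <- -nrm
    normals[k, ] <- nrm
  }
  normals
}
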