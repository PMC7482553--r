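#' Stress maxima over all capsomers
#'
#' The two Table-style headline numbers of a stress field: the maximum
#' absolute lateral stress and the maximum shear stress over all capsomers.
#'
#' @param field a [stress_field()].
#' @return named numeric vector: \code{max_abs_lateral}, \code{max_shear}.
#' @export
summarize_stress <- function(field) {
  c(max_abs_lateral = max(abs(field$lateral)),
    max_shear = max(field$shear))
}

#' Shared-bin stress histograms across model variants
#'
#' Compares the per-capsomer stress distribution of two or more model
#' variants of the same capsid (e.g. the structure-derived configuration
#' against its idealized icosahedral and spherical renderings) on a common
#' binning, and reports a tail-mass statistic (the fraction of capsomers
#' beyond the 90th percentile of the pooled distribution) that quantifies how
#' strongly stress concentrates in each variant.
#'
#' @param fields named list of [stress_field()]s with equal capsomer counts.
#' @param n_bins number of shared bins (pooled min/max range).
#' @param measure which per-capsomer stress to histogram.
#' @return object of class \code{comparison_report}: \code{breaks},
#'   \code{counts} (variant x bin matrix, rows sum to N), \code{tail_mass},
#'   \code{summaries}, \code{measure}, \code{n}.
#' @export
stress_histogram <- function(fields, n_bins = 20,
                             measure = c("shear", "lateral")) {
  measure <- match.arg(measure)
  if (length(fields) < 2) stop("need at least two variants to compare")
  if (is.null(names(fields)) || any(!nzchar(names(fields))))
    stop("fields must be a named list")
  vals <- lapply(fields, function(f)
    if (measure == "shear") f$shear else f$lateral)
  n <- unique(lengths(vals))
  if (length(n) != 1)
    stop("variants have mismatched capsomer counts: ",
         paste(lengths(vals), collapse = ", "))
  pooled <- unlist(vals)
  rng <- range(pooled)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- t(vapply(vals, function(v)
    graphics::hist(v, breaks = breaks, plot = FALSE)$counts, numeric(n_bins)))
  q90 <- stats::quantile(pooled, 0.9, names = FALSE)
  tail_mass <- vapply(vals, function(v) mean(v > q90), 0)
  structure(list(measure = measure, breaks = breaks, counts = counts,
                 tail_mass = tail_mass,
                 summaries = lapply(fields, summarize_stress),
                 n = n),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("stress comparison (", x$measure, ", ", x$n, " capsomers, ",
      length(x$breaks) - 1, " shared bins)\n", sep = "")
  for (v in rownames(x$counts))
    cat(sprintf("  %-14s tail mass %.4f  max %s %.4f\n", v, x$tail_mass[[v]],
                x$measure,
                x$summaries[[v]][[if (x$measure == "shear") "max_shear"
                                  else "max_abs_lateral"]]))
  invisible(x)
}

#' Run the full coarse-grained analysis of one capsid
#'
#' From a capsomer configuration (synthetic or imported), builds adjacency,
#' surface, interaction model (calibrated on the configuration unless a sigma
#' table is supplied), stress field and curvature field, and optionally
#' writes the result bundle (configuration/stress/curvature CSVs plus a JSON
#' report embedding every parameter needed to re-run the analysis). Output is
#' deterministic for identical inputs.
#'
#' @param config a [capsomer_configuration()], or a structure file path (then
#'   imported via [expand_assembly()] / [assign_capsomers()]).
#' @param model optional [interaction_model()]; calibrated from the
#'   configuration when NULL.
#' @param delta adjacency cutoff, or "auto".
#' @param eps0 energy scale for the calibrated model.
#' @param expected_T passed to [assign_capsomers()] for file input.
#' @param capsomer_normals optional N x 3 capsomer median-plane normals (for
#'   file input they are computed from the atoms).
#' @param outdir optional output directory for the bundle.
#' @param seed integer recorded in the report (and controlling any stochastic
#'   stage an upstream caller adds).
#' @return list of class \code{capsid_report}: configuration, adjacency,
#'   surface, model, stress, curvature, axes, and the per-capsomer results
#'   table.
#' @export
run_pipeline <- function(config, model = NULL, delta = "auto", eps0 = 1,
                         expected_T = NULL, capsomer_normals = NULL,
                         outdir = NULL, seed = 0) {
  if (is.character(config)) {
    atoms <- expand_assembly(config)
    assignment <- assign_capsomers(atoms, expected_T = expected_T)
    capsomer_normals <- capsomer_planes(atoms, assignment)
    config <- assignment$configuration
  }
  adjacency <- build_adjacency(config, delta)
  surface <- triangulate(config)
  if (is.null(model)) model <- calibrate_model(config, adjacency, eps0 = eps0)
  stress <- stress_field(config, adjacency, model, surface)
  curv <- curvature_field(config, surface, adjacency, capsomer_normals)
  axes <- tryCatch(icosahedral_axes(config), error = function(e) NULL)
  tab <- data.frame(index = seq_len(nrow(config$points)),
                    kind = config$kind,
                    lateral = stress$lateral, shear = stress$shear,
                    lambda_max = stress$lambda_max,
                    lambda_min = stress$lambda_min,
                    K = curv$K,
                    dist_twofold = if (is.null(axes)) NA_real_ else axes$dist_twofold)
  out <- structure(list(configuration = config, adjacency = adjacency,
                        surface = surface, model = model, stress = stress,
                        curvature = curv, axes = axes, table = tab,
                        seed = seed),
                   class = "capsid_report")
  if (!is.null(outdir)) write_report_bundle(out, outdir)
  out
}

#' @export
print.capsid_report <- function(x, ...) {
  print(x$configuration)
  s <- summarize_stress(x$stress)
  cat(sprintf("E = %.6g  |S| = %.6g  max|lateral| = %.6g  max shear = %.6g\n",
              x$stress$energy, x$stress$area, s[1], s[2]))
  cat(sprintf("sum K = %.6f (4 pi = %.6f)\n", sum(x$curvature$K), 4 * pi))
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Writes configuration.csv, stress.csv, curvature_nodes.csv,
#' curvature_edges.csv and report.json (metadata: delta, sigma table, eps0,
#' seed, counts, energy, area, stress maxima). Two runs with identical inputs
#' produce byte-identical files.
#'
#' @param report a [run_pipeline()] result.
#' @param outdir directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report_bundle <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_configuration_csv(report$configuration, file.path(outdir, "configuration.csv"))
  utils::write.csv(report$table, file.path(outdir, "stress.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(index = seq_along(report$curvature$K),
                              K = report$curvature$K),
                   file.path(outdir, "curvature_nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  edges <- report$curvature$H
  if (!is.null(report$curvature$H_true)) {
    edges$H_true <- report$curvature$H_true$H[
      match(paste(edges$i, edges$j),
            paste(report$curvature$H_true$i, report$curvature$H_true$j))]
  }
  utils::write.csv(edges, file.path(outdir, "curvature_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  s <- summarize_stress(report$stress)
  meta <- list(
    n_capsomers = nrow(report$configuration$points),
    n_pentamers = sum(report$configuration$kind == "pentamer"),
    source = report$configuration$source,
    delta = report$adjacency$delta,
    eps0 = report$model$eps0,
    sigma = as.list(report$model$sigma),
    seed = report$seed,
    energy = report$stress$energy,
    area = report$stress$area,
    max_abs_lateral = unname(s["max_abs_lateral"]),
    max_shear = unname(s["max_shear"]),
    gauss_bonnet_sum = sum(report$curvature$K))
  jsonlite::write_json(meta, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
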