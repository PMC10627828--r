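#' Read a count table
#'
#' TSV tables have samples in rows (first column = sample id) and taxa
#' in columns. BIOM files (classic JSON or HDF5, via the biomformat
#' package) are transposed to the same samples x taxa orientation.
#'
#' @param path file path.
#' @param format \code{"tsv"} (default) or \code{"biom"}.
#' @return samples x taxa numeric matrix.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM input requires the biomformat package")
    b <- biomformat::read_biom(path)
    t(as.matrix(biomformat::biom_data(b)))  # biom stores taxa x samples
  }
}

#' Write a count (or abundance) table as TSV
#'
#' @param x samples x taxa matrix.
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a correlation network as a TSV edge list plus JSON parameters
#'
#' One row per unordered taxon pair: \code{taxon_a}, \code{taxon_b},
#' \code{rho} and (when present) \code{p}. The SparCC parameters go to
#' a JSON sidecar.
#'
#' @param network a \code{sparcc_network}.
#' @param path edge-list TSV path.
#' @param params_path JSON sidecar path (default: \code{path} with a
#'   \code{.params.json} suffix).
#' @export
write_network <- function(network, path,
                          params_path = paste0(path, ".params.json")) {
  stopifnot(inherits(network, "sparcc_network"))
  idx <- which(upper.tri(network$rho), arr.ind = TRUE)
  df <- data.frame(taxon_a = network$taxa[idx[, 1L]],
                   taxon_b = network$taxa[idx[, 2L]],
                   rho = network$rho[idx])
  if (!is.null(network$pvalues)) df$p <- network$pvalues[idx]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(network$params, params_path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a module set as JSON
#'
#' @param modules a \code{module_set}.
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  jsonlite::write_json(
    list(min_size = modules$min_size, modules = modules$modules,
         clusters = as.list(modules$clusters)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Write an eigentaxa matrix as TSV with a JSON sidecar
#'
#' The sidecar records each module's anchor taxon, the sign applied and
#' the variance explained by PC1.
#'
#' @param eigentaxa an \code{eigentaxa_matrix}.
#' @param path TSV output path.
#' @param sidecar_path JSON sidecar path (default \code{path} +
#'   \code{.meta.json}).
#' @export
write_eigentaxa <- function(eigentaxa, path,
                            sidecar_path = paste0(path, ".meta.json")) {
  write_count_table(unclass(eigentaxa), path)
  jsonlite::write_json(
    list(anchor = as.list(attr(eigentaxa, "anchor")),
         sign = as.list(attr(eigentaxa, "sign")),
         var_explained = as.list(attr(eigentaxa, "var_explained")),
         z_standardized = attr(eigentaxa, "z_standardized")),
    sidecar_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds the arguments of \code{\link{sim_config}} (module,
#' archetype and covariate specs as nested lists).
#'
#' @param path file path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return a validated \code{\link{sim_config}}.
#' @export
read_sim_config <- function(path) {
  args <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML input requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (f in c("modules", "archetypes", "covariates"))
    if (!is.null(args[[f]])) args[[f]] <- lapply(args[[f]], as.list)
  do.call(sim_config, args)
}

#' Write a simulated cohort to disk
#'
#' Count table and metadata as TSV, ground truth as a JSON sidecar.
#'
#' @param cohort a \code{sim_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write.table(data.frame(sample_id = rownames(cohort$metadata), cohort$metadata),
              file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$run_info, file.path(dir, "run_info.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(planted_membership = as.list(tr$planted_membership),
         planted_effects = tr$planted_effects,
         true_depths = tr$true_depths,
         archetype_assignment = tr$archetype_assignment,
         latent_factors = as.data.frame(tr$latent_factors)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
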