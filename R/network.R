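#' Extract modules from MCL clusters
#'
#' Modules are the clusters with at least \code{min_size} members
#' (default three (sub)genera), each named after its most abundant
#' member taxon (highest mean relative abundance across the cohort).
#'
#' @param clusters an \code{\link{mcl}} result, or a named membership
#'   vector.
#' @param abundances samples x taxa relative-abundance matrix covering
#'   the clustered taxa (used for module naming).
#' @param min_size minimum module size (default 3).
#' @return object of class \code{module_set}: list with
#'   \code{clusters} (full membership vector), \code{modules} (named
#'   list of member-taxon character vectors) and \code{min_size}.
#' @export
extract_modules <- function(clusters, abundances, min_size = 3) {
  membership <- if (inherits(clusters, "mcl_result")) clusters$membership else clusters
  if (is.null(names(membership))) stop("cluster membership must be named by taxon")
  mean_ab <- colMeans(abundances)
  split_taxa <- split(names(membership), membership)
  big <- split_taxa[lengths(split_taxa) >= min_size]
  modules <- list()
  for (taxa in big) {
    ab <- mean_ab[taxa]
    if (anyNA(ab)) stop("module taxa missing from abundance table: ",
                        paste(taxa[is.na(ab)], collapse = ", "))
    modules[[names(which.max(ab))]] <- taxa
  }
  if (!length(modules)) warning("no cluster reaches min_size; empty module set")
  else modules <- modules[order(names(modules))]
  structure(list(clusters = membership, modules = modules,
                 min_size = min_size), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s) (>= %d members) from %d cluster(s)\n",
              length(x$modules), x$min_size, length(unique(x$clusters))))
  for (nm in names(x$modules))
    cat(sprintf("  %s: %s\n", nm, paste(x$modules[[nm]], collapse = ", ")))
  invisible(x)
}

#' Mantel test between two square matrices
#'
#' Pearson correlation of the upper triangles of two symmetric matrices
#' (correlation networks or distance matrices), with a one-sided
#' permutation p-value obtained by jointly permuting the row/column
#' labels of the second matrix: \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}.
#' With \code{restrict_shared = TRUE} both matrices are first restricted
#' to their shared (dim)name set, e.g. to compare two cohorts' networks
#' on module taxa only.
#'
#' @param mat_a,mat_b symmetric square matrices.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @param restrict_shared restrict to shared dimnames first?
#' @return list: \code{r}, \code{p}, \code{n_perm}, \code{n_items}.
#' @export
mantel_test <- function(mat_a, mat_b, n_perm = 10000, seed = 1L,
                        restrict_shared = FALSE) {
  if (restrict_shared) {
    shared <- intersect(rownames(mat_a), rownames(mat_b))
    if (length(shared) < 3L) stop("fewer than 3 shared items after mapping")
    mat_a <- mat_a[shared, shared]
    mat_b <- mat_b[shared, shared]
  }
  if (!all(dim(mat_a) == dim(mat_b)))
    stop("matrix dimensions differ (after any mapping)")
  r_obs <- cor(upper_tri_vec(mat_a), upper_tri_vec(mat_b))
  p <- nrow(mat_a)
  set.seed(stage_seed(seed, 31L))
  ge <- 0L
  va <- upper_tri_vec(mat_a)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(p)
    ge <- ge + (cor(va, upper_tri_vec(mat_b[idx, idx])) >= r_obs)
  }
  list(r = r_obs, p = (1 + ge) / (1 + n_perm), n_perm = as.integer(n_perm),
       n_items = p)
}
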