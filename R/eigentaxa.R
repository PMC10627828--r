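#' Per-module eigentaxon scores
#'
#' The eigentaxon of a module is the first principal component of the
#' module taxa's CLR-transformed abundances (per-taxon centred,
#' unscaled by default), sign-anchored so that it correlates
#' non-negatively with the CLR abundance of the module's most abundant
#' taxon (the anchor). Columns are z-standardised by default, matching
#' their use in downstream linear models. Entirely deterministic.
#'
#' Constant-CLR taxa are dropped from a module's PCA with a warning; a
#' module left with fewer than two usable taxa is an error. If the
#' anchor-correlation is exactly zero the sign is +1 and the module is
#' flagged.
#'
#' @param clr_table samples x taxa CLR matrix
#'   (\code{\link{clr_transform}}).
#' @param modules a \code{\link{extract_modules}} result (or a named
#'   list of member-taxon vectors).
#' @param abundances samples x taxa relative-abundance matrix, used to
#'   pick each module's anchor taxon.
#' @param z_standardize z-standardise the scores (default \code{TRUE})?
#' @param scale_pca use correlation-PCA (scale taxa to unit variance)
#'   instead of covariance-PCA (default \code{FALSE})?
#' @return samples x modules matrix of class \code{eigentaxa_matrix}
#'   with attributes \code{anchor}, \code{sign}, \code{var_explained}
#'   (share of module variance on PC1), \code{zero_sign_flag} and
#'   \code{z_standardized}.
#' @export
compute_eigentaxa <- function(clr_table, modules, abundances,
                              z_standardize = TRUE, scale_pca = FALSE) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  if (!length(mods)) stop("no modules supplied")
  miss <- setdiff(unlist(mods), colnames(clr_table))
  if (length(miss)) stop("module taxa absent from CLR table: ",
                         paste(miss, collapse = ", "))
  n <- nrow(clr_table)
  mean_ab <- colMeans(abundances)
  E <- matrix(NA_real_, n, length(mods),
              dimnames = list(rownames(clr_table), names(mods)))
  anchor <- sign_applied <- character(0)
  varexp <- numeric(length(mods)); signs <- integer(length(mods))
  zero_flag <- logical(length(mods)); anchors <- character(length(mods))
  for (m in seq_along(mods)) {
    taxa <- mods[[m]]
    X <- clr_table[, taxa, drop = FALSE]
    usable <- apply(X, 2L, sd) > 0
    if (!all(usable)) {
      warning("dropping constant-CLR taxa from module '", names(mods)[m],
              "': ", paste(taxa[!usable], collapse = ", "))
      taxa <- taxa[usable]
      X <- X[, usable, drop = FALSE]
    }
    if (ncol(X) < 2L)
      stop("module '", names(mods)[m], "' has fewer than 2 usable taxa")
    pc <- prcomp(X, center = TRUE, scale. = scale_pca)
    scores <- pc$x[, 1L]
    anchors[m] <- taxa[which.max(mean_ab[taxa])]
    r <- cor(scores, clr_table[, anchors[m]])
    s <- sign(r)
    if (s == 0 || is.na(s)) { s <- 1; zero_flag[m] <- TRUE }
    signs[m] <- s
    scores <- scores * s
    varexp[m] <- pc$sdev[1L]^2 / sum(pc$sdev^2)
    E[, m] <- if (z_standardize) (scores - mean(scores)) / sd(scores) else scores
  }
  structure(E, anchor = setNames(anchors, names(mods)),
            sign = setNames(signs, names(mods)),
            var_explained = setNames(varexp, names(mods)),
            zero_sign_flag = setNames(zero_flag, names(mods)),
            z_standardized = z_standardize,
            class = c("eigentaxa_matrix", class(E)))
}

#' @export
print.eigentaxa_matrix <- function(x, ...) {
  cat(sprintf("eigentaxa_matrix: %d samples x %d module(s)%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "z_standardized"))) ", z-standardized" else ""))
  info <- data.frame(anchor = attr(x, "anchor"),
                     var_explained = round(attr(x, "var_explained"), 3))
  print(info)
  invisible(x)
}
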