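#' Markov clustering (MCL)
#'
#' Standard MCL on a non-negative adjacency matrix: add self-loops,
#' column-normalise, then alternate expansion (matrix power
#' \code{expansion}) and inflation (element-wise power \code{inflation}
#' followed by column renormalisation) until the matrix changes by less
#' than \code{tol} or \code{max_iter} iterations are reached. Clusters
#' are read off as the connected components of the non-zero pattern of
#' the converged (idempotent, attractor-structured) matrix. Fully
#' deterministic.
#'
#' When given a \code{sparcc_network} the adjacency is first derived via
#' \code{\link{network_adjacency}} with the supplied \code{edge_rule}.
#'
#' @param x non-negative square adjacency matrix, or a
#'   \code{sparcc_network}.
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param edge_rule,p_cut,rho_cut passed to
#'   \code{\link{network_adjacency}} when \code{x} is a network.
#' @param add_self_loops add unit self-loops before normalisation
#'   (default \code{TRUE}, standard MCL practice)?
#' @param max_iter,tol convergence controls.
#' @param prune entries below this are zeroed after each inflation.
#' @return list of class \code{mcl_result}: \code{membership} (named
#'   integer cluster ids), \code{n_iter}, \code{converged}.
#' @references van Dongen S (2000) Graph clustering by flow simulation.
#'   PhD thesis, University of Utrecht.
#' @export
mcl <- function(x, inflation = 2, expansion = 2,
                edge_rule = c("significant_abs", "positive", "abs_threshold"),
                p_cut = 0.05, rho_cut = 0.1,
                add_self_loops = TRUE, max_iter = 100, tol = 1e-6,
                prune = 1e-8) {
  if (inherits(x, "sparcc_network"))
    x <- network_adjacency(x, rule = match.arg(edge_rule),
                           p_cut = p_cut, rho_cut = rho_cut)
  if (!is.matrix(x) || nrow(x) != ncol(x)) stop("adjacency must be square")
  if (any(x < 0)) stop("adjacency must be non-negative")
  M <- x
  if (add_self_loops) diag(M) <- pmax(diag(M), 1)
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    prev <- M
    for (k in seq_len(expansion - 1L)) M <- M %*% prev  # expansion: M^e
    M <- M^inflation                                    # inflation
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2L, cs, "/")
    if (max(abs(M - prev)) < tol) { converged <- TRUE; break }
  }
  g <- igraph::graph_from_adjacency_matrix((M > prune) | t(M > prune),
                                           mode = "undirected")
  membership <- igraph::components(g)$membership
  names(membership) <- colnames(x) %||% as.character(seq_len(ncol(x)))
  structure(list(membership = membership, n_iter = it, converged = converged),
            class = "mcl_result")
}

#' @export
print.mcl_result <- function(x, ...) {
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat(sprintf("mcl_result: %d node(s) in %d cluster(s) (sizes %s); %s after %d iteration(s)\n",
              length(x$membership), length(sizes),
              paste(head(as.integer(sizes), 8L), collapse = ","),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Derive an MCL adjacency from a correlation network
#'
#' Rules: \code{"significant_abs"} (default) keeps \eqn{|\rho|} for
#' pairs whose permutation p-value is below \code{p_cut} and zeroes the
#' rest (requires \code{\link{sparcc_pvalues}} to have been attached to
#' the network); \code{"positive"} keeps positive \eqn{\rho} only;
#' \code{"abs_threshold"} keeps \eqn{|\rho|} above \code{rho_cut}.
#' Self-loops are left to \code{\link{mcl}}.
#'
#' @param network a \code{sparcc_network}.
#' @param rule edge rule (see above).
#' @param p_cut significance cut-off for \code{"significant_abs"}.
#' @param rho_cut magnitude cut-off for \code{"abs_threshold"}.
#' @return non-negative symmetric adjacency matrix, zero diagonal.
#' @export
network_adjacency <- function(network,
                              rule = c("significant_abs", "positive",
                                       "abs_threshold"),
                              p_cut = 0.05, rho_cut = 0.1) {
  stopifnot(inherits(network, "sparcc_network"))
  rule <- match.arg(rule)
  rho <- network$rho
  adj <- switch(rule,
    significant_abs = {
      if (is.null(network$pvalues))
        stop("edge rule 'significant_abs' needs network$pvalues (see sparcc_pvalues)")
      a <- abs(rho)
      a[!(network$pvalues < p_cut)] <- 0
      a
    },
    positive = pmax(rho, 0),
    abs_threshold = { a <- abs(rho); a[a < rho_cut] <- 0; a })
  diag(adj) <- 0
  adj[is.na(adj)] <- 0
  adj
}
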