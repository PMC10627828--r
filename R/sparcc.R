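#' SparCC compositional correlation network
#'
#' Estimates correlations between the latent absolute abundances of taxa
#' from compositional count data. Per Dirichlet draw: taxon fractions
#' are resampled from Dirichlet(counts + 1) per sample; the log-ratio
#' variation matrix \eqn{t_{ij} = Var_s \log(x_{is}/x_{js})} is formed;
#' the basis (latent log-abundance) variances \eqn{\omega} are solved
#' from the linear system implied by
#' \eqn{t_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}}
#' under the sparsity approximation \eqn{\sum_j \rho_{ij} \approx 0};
#' correlations are recovered as
#' \eqn{\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / 2\sqrt{\omega_i\omega_j}}
#' and clamped to [-1, 1]; and the strongest-correlated pair above
#' \code{exclusion_threshold} is iteratively excluded from the system
#' and the basis re-solved, up to \code{n_exclusion_iterations} times.
#' The reported \eqn{\rho} is the element-wise median over Dirichlet
#' draws. With \code{n_dirichlet_draws = 0} the observed count fractions
#' are used directly (a single closed-form solve; requires strictly
#' positive counts), which is exactly invariant to per-sample count
#' rescaling.
#'
#' Taxa should be prefiltered to at least 10\% prevalence
#' (\code{\link{filter_prevalence}}) before network inference.
#'
#' @param counts samples x taxa count matrix (>= 4 taxa; >= 10 samples
#'   recommended).
#' @param n_dirichlet_draws number of Dirichlet resamplings (default 20;
#'   0 = use observed fractions).
#' @param exclusion_threshold correlation magnitude above which the
#'   strongest pair is excluded from the basis system (default 0.1).
#' @param n_exclusion_iterations maximum pair exclusions per draw
#'   (default 10; 0 disables the exclusion loop).
#' @param seed integer seed for the Dirichlet draws.
#' @return an object of class \code{sparcc_network}: list with
#'   \code{taxa}, \code{rho} (symmetric, unit diagonal),
#'   \code{pvalues} (\code{NULL} until \code{\link{sparcc_pvalues}}),
#'   and \code{params}.
#' @references Friedman J, Alm EJ (2012) Inferring correlation networks
#'   from genomic survey data. PLoS Comput Biol 8:e1002687.
#' @export
sparcc <- function(counts, n_dirichlet_draws = 20, exclusion_threshold = 0.1,
                   n_exclusion_iterations = 10, seed = 1L) {
  check_count_matrix(counts)
  p <- ncol(counts)
  if (p < 4L) stop("SparCC needs at least 4 taxa (basis system underdetermined)")
  draws <- as.integer(n_dirichlet_draws)
  if (draws == 0L) {
    frac <- counts / rowSums(counts)
    if (any(frac == 0))
      stop("n_dirichlet_draws = 0 requires strictly positive counts")
    keep <- apply(log(frac), 2L, var) > 1e-12
    if (!all(keep)) {
      warning("excluding degenerate constant-fraction taxa: ",
              paste(colnames(counts)[!keep], collapse = ", "))
      frac <- frac[, keep, drop = FALSE]
      if (ncol(frac) < 4L) stop("fewer than 4 non-degenerate taxa remain")
    }
    rho <- .sparcc_one(log(frac), exclusion_threshold, n_exclusion_iterations)
    taxa <- colnames(frac)
  } else {
    set.seed(stage_seed(seed, 21L))
    acc <- array(NA_real_, c(p, p, draws))
    alpha <- counts + 1
    n <- nrow(counts)
    for (d in seq_len(draws)) {
      g <- matrix(rgamma(n * p, shape = alpha), n, p)
      acc[, , d] <- .sparcc_one(log(g / rowSums(g)),
                                exclusion_threshold, n_exclusion_iterations)
    }
    rho <- apply(acc, c(1L, 2L), median)
    taxa <- colnames(counts)
  }
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(taxa, taxa)
  structure(list(taxa = taxa, rho = rho, pvalues = NULL,
                 params = list(n_dirichlet_draws = draws,
                               exclusion_threshold = exclusion_threshold,
                               n_exclusion_iterations = n_exclusion_iterations,
                               seed = as.integer(seed))),
            class = "sparcc_network")
}

# One SparCC pass on a log-fraction matrix: variation matrix, basis
# solve, correlation recovery, exclusion loop.
.sparcc_one <- function(logf, exclusion_threshold, n_excl) {
  p <- ncol(logf)
  C <- cov(logf)
  v <- diag(C)
  Tm <- outer(v, v, "+") - 2 * C          # t_ij = Var(log x_i - log x_j)
  A <- matrix(1, p, p); diag(A) <- 0      # included-pair adjacency
  rho <- NULL
  for (iter in seq_len(n_excl + 1L)) {
    w <- tryCatch(sparcc_basis_variance(Tm, A), error = function(e) NULL)
    if (is.null(w)) break                 # system degenerate: keep last solution
    # a non-positive basis variance means the sparsity approximation broke
    # down for that taxon; fall back to its observed log-fraction variance
    bad <- w <= 0
    w[bad] <- pmax(v[bad], 1e-12)
    sw <- sqrt(w)
    rho_new <- (outer(w, w, "+") - Tm) / (2 * outer(sw, sw))
    rho <- pmin(pmax(rho_new, -1), 1)
    diag(rho) <- 1
    if (iter > n_excl) break
    # exclusion candidates: keep every taxon attached to >= 3 pairs so
    # the basis system stays well determined
    deg <- rowSums(A)
    cand <- abs(rho) * A; diag(cand) <- 0
    cand[deg <= 3, ] <- 0; cand[, deg <= 3] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1L, ]
    A[ij[1L], ij[2L]] <- A[ij[2L], ij[1L]] <- 0
  }
  rho
}

# Basis-variance solve under the sparsity approximation: with included
# pairs A, sum_{j in A_i} t_ij = d_i * w_i + sum_{j in A_i} w_j, i.e.
# (diag(d) + A) w = rowSums(T * A).
sparcc_basis_variance <- function(Tm, A = NULL) {
  p <- ncol(Tm)
  if (is.null(A)) { A <- matrix(1, p, p); diag(A) <- 0 }
  M <- diag(rowSums(A)) + A
  as.numeric(solve(M, rowSums(Tm * A)))
}

#' @export
print.sparcc_network <- function(x, ...) {
  off <- abs(upper_tri_vec(x$rho))
  cat(sprintf("sparcc_network: %d taxa; median |rho| %.3f, max |rho| %.3f; %s\n",
              length(x$taxa), median(off), max(off),
              if (is.null(x$pvalues)) "no p-values yet"
              else sprintf("%d permutation p-values", x$params$n_perm %||% NA_integer_)))
  invisible(x)
}

#' Permutation p-values for a SparCC network
#'
#' Each permutation independently shuffles every taxon's counts across
#' samples (destroying all between-taxon association while keeping each
#' taxon's marginal distribution), recomputes the SparCC correlation
#' matrix, and compares magnitudes. Two-sided p-values use the add-one
#' estimator \eqn{p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\}) / (1 + n_{perm})},
#' so the minimum attainable p is \eqn{1/(1+n_{perm})}.
#'
#' @param counts the count matrix the network was computed on.
#' @param observed a \code{sparcc_network} from \code{\link{sparcc}}.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param perm_draws Dirichlet draws used inside each permutation
#'   (default: same as the observed network; smaller values trade
#'   stability for speed).
#' @return symmetric p-value matrix (diagonal \code{NA}).
#' @export
sparcc_pvalues <- function(counts, observed, n_perm = 1000, seed = 1L,
                           perm_draws = NULL) {
  stopifnot(inherits(observed, "sparcc_network"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  check_count_matrix(counts)
  if (!identical(colnames(counts), observed$taxa))
    stop("count-table taxa do not match the observed network")
  pm <- observed$params
  perm_draws <- perm_draws %||% pm$n_dirichlet_draws
  n <- nrow(counts)
  obs <- abs(observed$rho)
  ge <- matrix(0L, ncol(counts), ncol(counts))
  set.seed(stage_seed(seed, 22L))
  for (b in seq_len(n_perm)) {
    shuf <- apply(counts, 2L, sample, size = n)
    rownames(shuf) <- rownames(counts)
    net <- sparcc(shuf, n_dirichlet_draws = perm_draws,
                  exclusion_threshold = pm$exclusion_threshold,
                  n_exclusion_iterations = pm$n_exclusion_iterations,
                  seed = sample.int(2^30, 1L))
    ge <- ge + (abs(net$rho) >= obs)
  }
  pv <- (1 + ge) / (1 + n_perm)
  pv <- (pv + t(pv)) / 2
  diag(pv) <- NA_real_
  dimnames(pv) <- dimnames(observed$rho)
  pv
}
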