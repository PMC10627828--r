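# Fast multi-response OLS: one design, one response per taxon.
# Returns effect, se, t, p for the requested coefficient column.
ols_multi <- function(X, Y, coef_col) {
  qx <- qr(X)
  k <- qx$rank
  cf <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- nrow(X) - k
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))  # X full rank enforced upstream
  se <- sqrt(sigma2 * xtx_inv[coef_col, coef_col])
  eff <- cf[coef_col, ]
  tt <- eff / se
  list(effect = eff, se = se, t = tt, p = 2 * pt(-abs(tt), df))
}

#' Consensus differential abundance
#'
#' Tests every (>= 10\% prevalence) taxon for association with the
#' effect of interest using several covariate-adjusted methods and
#' reports the consensus. Built-in methods:
#' \describe{
#'   \item{clr_lm}{OLS of the CLR-transformed abundance on the model.}
#'   \item{dirichlet_clr_lm}{Monte-Carlo Dirichlet instances
#'     (counts + 0.5), CLR each, per-instance OLS; p = mean over
#'     instances, effect = median (ALDEx2-style).}
#'   \item{rank_lm}{OLS on the within-taxon rank-transformed relative
#'     abundance.}
#' }
#' Additional methods can be supplied as named functions
#' \code{function(counts, X, eff_col) -> list(effect, p)} (per-taxon
#' vectors), e.g. adapters around external tools. Per method, p-values
#' are BH-adjusted across all taxa of the call (one correction family
#' per method; never across methods). A taxon is a consensus hit when
#' at least \code{min_agree} methods give q < \code{alpha}.
#'
#' For effects with several non-reference levels the first design
#' column of the effect is tested; recode multi-level questionnaire
#' factors to targeted contrasts upstream where needed.
#'
#' @param counts samples x taxa count matrix.
#' @param metadata data frame of covariates, rownames = sample ids.
#' @param spec a \code{\link{model_spec}}.
#' @param methods character vector of built-in method names and/or a
#'   named list mixing names and adapter functions.
#' @param alpha per-method q-value significance level (default 0.05).
#' @param min_agree methods that must agree for a consensus hit
#'   (default 3).
#' @param prevalence_min prevalence filter applied before testing
#'   (default 0.10).
#' @param n_mc Monte-Carlo instances for \code{dirichlet_clr_lm}
#'   (default 128).
#' @param pseudocount CLR pseudocount (default 0.5).
#' @param seed integer seed (Dirichlet instances).
#' @return \code{association_result} data frame: one row per tested
#'   taxon with the clr_lm effect/p/q as the headline columns,
#'   per-method effect and q columns, \code{n_methods_significant} and
#'   a \code{consensus} column.
#' @export
consensus_da <- function(counts, metadata, spec,
                         methods = c("clr_lm", "dirichlet_clr_lm", "rank_lm"),
                         alpha = 0.05, min_agree = 3, prevalence_min = 0.10,
                         n_mc = 128, pseudocount = 0.5, seed = 1L) {
  check_count_matrix(counts)
  if (is.character(methods)) methods <- setNames(as.list(methods), methods)
  if (min_agree > length(methods))
    stop("min_agree exceeds the number of configured methods")
  counts <- filter_prevalence(counts, prevalence_min)
  shared <- intersect(rownames(counts), rownames(metadata))
  des <- build_design(metadata[shared, , drop = FALSE], spec)
  cts <- counts[des$rows, , drop = FALSE]
  X <- des$X_full
  eff_col <- des$eff_idx[1L]
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design; check for collinear covariates")
  taxa <- colnames(cts)

  run_method <- function(m) {
    if (is.function(m)) return(m(cts, X, eff_col))
    switch(m,
      clr_lm = {
        Y <- clr_transform(cts, pseudocount)
        r <- ols_multi(X, Y, eff_col)
        list(effect = r$effect, p = r$p)
      },
      rank_lm = {
        R <- apply(relative_abundance(cts), 2L, rank)
        r <- ols_multi(X, R, eff_col)
        list(effect = r$effect, p = r$p)
      },
      dirichlet_clr_lm = {
        set.seed(stage_seed(seed, 41L))
        n <- nrow(cts); p <- ncol(cts)
        alpha_mat <- cts + 0.5
        eff_acc <- matrix(NA_real_, n_mc, p)
        p_acc <- matrix(NA_real_, n_mc, p)
        for (i in seq_len(n_mc)) {
          g <- matrix(rgamma(n * p, shape = alpha_mat), n, p)
          lf <- log(g / rowSums(g))
          Y <- lf - rowMeans(lf)
          r <- ols_multi(X, Y, eff_col)
          eff_acc[i, ] <- r$effect
          p_acc[i, ] <- r$p
        }
        list(effect = apply(eff_acc, 2L, median), p = colMeans(p_acc))
      },
      stop("unknown method: ", m))
  }

  fits <- lapply(methods, run_method)
  qmat <- vapply(fits, function(f) bh_adjust(f$p), numeric(length(taxa)))
  if (is.null(dim(qmat))) qmat <- matrix(qmat, nrow = length(taxa))
  n_sig <- rowSums(qmat < alpha, na.rm = TRUE)
  headline <- fits[[1L]]
  res <- association_result(
    level = "taxon", factor = spec$effect, unit = taxa, n_used = des$n_used,
    effect = headline$effect, p = headline$p, q = qmat[, 1L],
    n_methods_significant = as.integer(n_sig))
  res$consensus <- n_sig >= min_agree
  for (j in seq_along(methods)) {
    res[[paste0("effect_", names(methods)[j])]] <- fits[[j]]$effect
    res[[paste0("q_", names(methods)[j])]] <- qmat[, j]
  }
  attr(res, "alpha") <- alpha
  attr(res, "min_agree") <- min_agree
  attr(res, "methods") <- names(methods)
  res
}
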