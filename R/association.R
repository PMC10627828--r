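#' Specify a covariate-adjusted association model
#'
#' Every association test in the framework fits
#' \code{response ~ effect + adjusters + technical}: one effect of
#' interest, the standard host adjusters (age, antibiotic use in the
#' past 3 months, intercourse in the past 24 h) and the technical
#' covariates (sequencing run, normalized read concentration, library
#' size). Categorical covariates are dummy-encoded against their most
#' frequent level; missing data are removed listwise per test.
#'
#' @param effect name of the covariate of interest.
#' @param adjusters host adjustment covariates (default
#'   \code{c("age", "antibiotic", "intercourse")}).
#' @param technical technical covariates (default none; supply e.g.
#'   \code{c("run_id", "nrc", "library_size")} when available).
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(effect,
                       adjusters = c("age", "antibiotic", "intercourse"),
                       technical = character()) {
  if (effect %in% c(adjusters, technical))
    stop("the effect of interest must not appear in the adjustment set")
  structure(list(effect = effect, adjusters = adjusters,
                 technical = technical), class = "model_spec")
}

# Listwise-complete model frame + design matrices with the effect's
# columns last (so they are identifiable and permutable as a block).
build_design <- function(metadata, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$adjusters, spec$technical, spec$effect)
  miss <- setdiff(vars, colnames(metadata))
  if (length(miss)) stop("covariates absent from metadata: ",
                         paste(miss, collapse = ", "))
  mf <- metadata[, vars, drop = FALSE]
  for (v in vars) {
    if (is.character(mf[[v]]) || is.logical(mf[[v]])) mf[[v]] <- factor(mf[[v]])
    if (is.factor(mf[[v]])) {
      if (all(is.na(mf[[v]]))) stop("covariate '", v, "' is 100% missing")
      ref <- names(which.max(table(mf[[v]])))  # most frequent level = reference
      mf[[v]] <- stats::relevel(droplevels(mf[[v]]), ref = ref)
    } else if (all(is.na(mf[[v]]))) stop("covariate '", v, "' is 100% missing")
  }
  keep <- complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  constant <- vapply(mf, function(x) {
    if (is.factor(x)) nlevels(droplevels(x)) < 2L else var(x) == 0
  }, logical(1))
  if (constant[spec$effect])
    stop("effect '", spec$effect, "' is constant in the usable samples")
  if (any(constant)) {
    warning("dropping constant adjuster(s): ",
            paste(vars[constant], collapse = ", "))
    vars <- vars[!constant]
    mf <- droplevels(mf[, vars, drop = FALSE])
  }
  X_full <- model.matrix(stats::reformulate(vars), data = mf)
  assign <- attr(X_full, "assign")
  eff_idx <- which(assign == length(vars))     # effect entered last
  list(mf = mf, rows = rownames(metadata)[keep],
       X_full = X_full, X_red = X_full[, -eff_idx, drop = FALSE],
       eff_idx = eff_idx, n_used = sum(keep))
}

# tr(H G) with H the hat matrix of X, via the thin Q factor.
.tr_hg <- function(X, G) {
  Q <- qr.Q(qr(X))
  sum(Q * (G %*% Q))
}

# Gower-centred inner-product matrix of a distance matrix.
gower_center <- function(distances) {
  D <- as.matrix(distances)
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Marginal adaptive-permutation PERMANOVA
#'
#' Permutational multivariate ANOVA for one covariate of interest,
#' adjusted for the model's other covariates. The marginal (type
#' III-like) sum of squares of the effect is
#' \eqn{SS = tr(H_{full} G) - tr(H_{reduced} G)} on the Gower-centred
#' distance matrix \eqn{G}; \eqn{R^2 = SS / tr(G)}. Significance is
#' assessed by permuting only the effect's values across samples while
#' holding the adjusters fixed and recomputing the marginal pseudo-F;
#' the p-value uses the add-one estimator. Adaptive schedule: an
#' initial \code{n_perm_initial} permutations are run and, whenever the
#' resulting p-value is at or below \code{escalate_at}, the test is
#' re-run (fresh permutations from a derived seed) with
#' \code{n_perm_full} permutations.
#'
#' @param distances sample distance matrix (\code{dist} or square
#'   symmetric), labelled by sample.
#' @param metadata data frame of covariates, rownames = sample ids.
#' @param spec a \code{\link{model_spec}}.
#' @param n_perm_initial,n_perm_full,escalate_at adaptive permutation
#'   schedule (defaults 1000, 10000, 0.001).
#' @param seed integer seed.
#' @return one-row \code{association_result} data frame: level
#'   \code{"beta"}, effect size \eqn{R^2}, pseudo-F, p, n_used and
#'   permutations_used.
#' @export
permanova_marginal <- function(distances, metadata, spec,
                               n_perm_initial = 1000, n_perm_full = 10000,
                               escalate_at = 0.001, seed = 1L) {
  D <- as.matrix(distances)
  shared <- intersect(rownames(D), rownames(metadata))
  des <- build_design(metadata[shared, , drop = FALSE], spec)
  ids <- des$rows
  G <- gower_center(D[ids, ids])
  n <- length(ids)
  X_full <- des$X_full; X_red <- des$X_red
  r_full <- qr(X_full)$rank; r_red <- qr(X_red)$rank
  df_eff <- r_full - r_red
  if (df_eff < length(des$eff_idx))
    stop("effect '", spec$effect, "' is collinear with the adjustment set (",
         paste(c(spec$adjusters, spec$technical), collapse = ", "), ")")
  tr_g <- sum(diag(G))
  tr_red <- .tr_hg(X_red, G)
  tr_full <- .tr_hg(X_full, G)
  ss_eff <- tr_full - tr_red
  ss_res <- tr_g - tr_full
  df_res <- n - r_full
  f_obs <- (ss_eff / df_eff) / (ss_res / df_res)
  Xeff <- X_full[, des$eff_idx, drop = FALSE]

  run_perms <- function(n_perm, s) {
    set.seed(stage_seed(s, 51L))
    ge <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      Xp <- cbind(X_red, Xeff[idx, , drop = FALSE])
      tr_full_p <- .tr_hg(Xp, G)
      f_p <- ((tr_full_p - tr_red) / df_eff) / ((tr_g - tr_full_p) / df_res)
      ge <- ge + (f_p >= f_obs)
    }
    (1 + ge) / (1 + n_perm)
  }
  p <- run_perms(n_perm_initial, seed)
  perms_used <- n_perm_initial
  if (p <= escalate_at && n_perm_full > n_perm_initial) {
    p <- run_perms(n_perm_full, seed + 1L)  # escalation re-draws permutations
    perms_used <- n_perm_full
  }
  association_result(level = "beta", factor = spec$effect, unit = NA_character_,
                     n_used = n, effect = ss_eff / tr_g, statistic = f_obs,
                     ci_low = NA_real_, ci_high = NA_real_, p = p,
                     permutations_used = perms_used)
}

# canonical result-row constructor shared by every level
association_result <- function(level, factor, unit, n_used, effect,
                               statistic = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, p = NA_real_,
                               q = NA_real_, n_methods_significant = NA_integer_,
                               permutations_used = NA_integer_,
                               flag = NA_character_) {
  out <- data.frame(level = level, factor = factor, unit = unit,
                    n_used = n_used, effect = effect, statistic = statistic,
                    ci_low = ci_low, ci_high = ci_high, p = p, q = q,
                    n_methods_significant = n_methods_significant,
                    permutations_used = permutations_used, flag = flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Covariate-adjusted linear model for a per-sample response
#'
#' Ordinary least squares of a z-standardised response (Shannon
#' diversity or an eigentaxon score) on the effect of interest plus the
#' adjustment set. One result row per non-reference level of the
#' effect (a single row for binary or continuous effects), with the
#' standardised coefficient, its 95\% confidence interval and two-sided
#' p-value.
#'
#' @param response named numeric vector (names = sample ids) or a
#'   single-column matrix.
#' @param metadata data frame of covariates, rownames = sample ids.
#' @param spec a \code{\link{model_spec}}.
#' @param level result label, \code{"alpha"} (default) or
#'   \code{"eigentaxon"}.
#' @param unit unit label for the result rows (e.g. the module name).
#' @return \code{association_result} data frame.
#' @export
lm_response <- function(response, metadata, spec, level = "alpha",
                        unit = NA_character_) {
  if (is.matrix(response)) response <- setNames(response[, 1L], rownames(response))
  shared <- intersect(names(response), rownames(metadata))
  y <- response[shared]
  ok <- is.finite(y)
  des <- build_design(metadata[shared[ok], , drop = FALSE], spec)
  y <- y[des$rows]
  if (length(y) < 10) stop("fewer than 10 usable samples")
  if (sd(y) == 0) stop("zero-variance response")
  z <- (y - mean(y)) / sd(y)
  fit <- lm(z ~ des$X_full - 1)
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(confint(fit))
  rows <- paste0("des$X_full", colnames(des$X_full)[des$eff_idx])
  lev_names <- sub(paste0("^", spec$effect), "", colnames(des$X_full)[des$eff_idx])
  lev_names[lev_names == ""] <- spec$effect
  res <- lapply(seq_along(rows), function(i) {
    association_result(
      level = level,
      factor = if (lev_names[i] == spec$effect) spec$effect
               else paste0(spec$effect, ":", lev_names[i]),
      unit = unit, n_used = des$n_used,
      effect = sm[rows[i], "Estimate"], statistic = sm[rows[i], "t value"],
      ci_low = ci[rows[i], 1L], ci_high = ci[rows[i], 2L],
      p = sm[rows[i], "Pr(>|t|)"])
  })
  do.call(rbind, res)
}

#' One-versus-all CST logistic regression
#'
#' For every community state type with at least \code{min_group}
#' samples, fits a logistic regression of membership in that CST
#' (versus all others) on the effect of interest plus the adjustment
#' set. The effect is the log-odds coefficient. Perfect or
#' quasi-perfect separation is detected and the affected rows flagged
#' \code{"separation"} rather than treated as reliable estimates.
#' Skipped CSTs are recorded in the \code{skipped} attribute.
#'
#' @param cst_labels character/factor vector of CST assignments, named
#'   by sample id (or a \code{\link{assign_cst}} data frame).
#' @param metadata data frame of covariates, rownames = sample ids.
#' @param spec a \code{\link{model_spec}}.
#' @param min_group minimum per-CST sample count (default 120).
#' @return \code{association_result} data frame, one row per retained
#'   CST x effect level.
#' @export
cst_logistic_ova <- function(cst_labels, metadata, spec, min_group = 120) {
  if (is.data.frame(cst_labels))
    cst_labels <- setNames(cst_labels$cst, cst_labels$sample_id)
  if (length(unique(cst_labels)) < 2L) stop("need at least 2 CST labels")
  shared <- intersect(names(cst_labels), rownames(metadata))
  des <- build_design(metadata[shared, , drop = FALSE], spec)
  lab <- as.character(cst_labels[des$rows])
  counts <- table(lab)
  keep <- names(counts)[counts >= min_group]
  skipped <- setdiff(names(counts), keep)
  out <- list()
  for (cstlab in sort(keep)) {
    y <- as.integer(lab == cstlab)
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ des$X_full - 1, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    rows <- paste0("des$X_full", colnames(des$X_full)[des$eff_idx])
    sep <- sep || any(abs(sm[rows, "Estimate"]) > 15)
    lev_names <- sub(paste0("^", spec$effect), "", colnames(des$X_full)[des$eff_idx])
    lev_names[lev_names == ""] <- spec$effect
    for (i in seq_along(rows)) {
      est <- sm[rows[i], "Estimate"]; se <- sm[rows[i], "Std. Error"]
      out[[length(out) + 1L]] <- association_result(
        level = "cst",
        factor = if (lev_names[i] == spec$effect) spec$effect
                 else paste0(spec$effect, ":", lev_names[i]),
        unit = cstlab, n_used = des$n_used, effect = est,
        statistic = sm[rows[i], "z value"],
        ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
        p = sm[rows[i], "Pr(>|z|)"],
        flag = if (sep) "separation" else NA_character_)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- data.frame(
    cst = skipped, n = as.integer(counts[skipped]),
    reason = sprintf("fewer than %d samples", min_group))
  res
}

#' Benjamini-Hochberg adjustment by correction family
#'
#' Step-up false-discovery-rate adjustment,
#' \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j}, applied separately
#' within each correction family (e.g. all modules/CSTs x factors in
#' one family; all taxa x factors in another, never across methods).
#'
#' @param p p-values in [0, 1] (NA allowed).
#' @param family optional vector of family labels (default: one family).
#' @return vector of q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  q <- rep(NA_real_, length(p))
  for (f in split(seq_along(p), family)) q[f] <- p.adjust(p[f], method = "BH")
  q
}

#' Cumulative variance explained by a set of factors
#'
#' Total PERMANOVA model \eqn{R^2} of a single fit including all listed
#' factors simultaneously, with sequential (order-reported) sums of
#' squares. A factor whose design columns add no rank (collinear with
#' those before it) is dropped with a warning.
#'
#' @param distances sample distance matrix.
#' @param metadata data frame of covariates, rownames = sample ids.
#' @param factors character vector of covariate names, in entry order.
#' @return data frame with per-factor sequential and cumulative
#'   \eqn{R^2}; total model \eqn{R^2} in attribute \code{total_r2}.
#' @export
variance_explained <- function(distances, metadata, factors) {
  D <- as.matrix(distances)
  shared <- intersect(rownames(D), rownames(metadata))
  if (!length(factors)) {
    out <- data.frame(factor = character(), r2 = numeric(), r2_cum = numeric())
    attr(out, "total_r2") <- 0
    return(out)
  }
  miss <- setdiff(factors, colnames(metadata))
  if (length(miss)) stop("factors absent from metadata: ",
                         paste(miss, collapse = ", "))
  mf <- metadata[shared, factors, drop = FALSE]
  for (v in factors) if (is.character(mf[[v]]) || is.logical(mf[[v]]))
    mf[[v]] <- factor(mf[[v]])
  keep <- complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  ids <- shared[keep]
  G <- gower_center(D[ids, ids])
  tr_g <- sum(diag(G))
  X <- matrix(1, nrow(mf), 1)
  rank_cur <- 1L
  r2 <- numeric(0); kept <- character(0)
  tr_prev <- 0  # G is double-centred: the intercept explains nothing
  for (v in factors) {
    Xv <- model.matrix(stats::reformulate(v), data = mf)[, -1, drop = FALSE]
    Xnew <- cbind(X, Xv)
    rk <- qr(Xnew)$rank
    if (rk <= rank_cur) {
      warning("dropping '", v, "': collinear with preceding factors")
      next
    }
    X <- Xnew; rank_cur <- rk
    tr_now <- .tr_hg(X, G)
    r2 <- c(r2, (tr_now - tr_prev) / tr_g)
    kept <- c(kept, v)
    tr_prev <- tr_now
  }
  out <- data.frame(factor = kept, r2 = r2, r2_cum = cumsum(r2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total_r2") <- sum(r2)
  out
}
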