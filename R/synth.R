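#' Build a synthetic-cohort simulation configuration
#'
#' Describes a multi-run amplicon cohort with log-normal latent taxon
#' abundances, planted co-abundance modules (taxa sharing a latent
#' factor), community-state-like dominance archetypes, questionnaire-like
#' covariates with planted effects, per-run batch effects and a
#' log-normal library-size model. The configuration is validated here;
#' \code{\link{simulate_cohort}} realises it.
#'
#' @param n_samples,n_taxa,n_runs cohort dimensions. Samples are spread
#'   over \code{n_runs} sequencing runs at random.
#' @param modules list of planted co-abundance modules; each element a
#'   list with \code{taxa} (taxon indices or names) and \code{loading}
#'   (non-negative scalar or per-member vector). Modules must be
#'   disjoint.
#' @param archetypes list of dominance archetypes; each element a list
#'   with \code{dominant} (taxon index/name), \code{dominance} (target
#'   mean dominant fraction in \eqn{[0,1]}) and \code{weight} (mixing
#'   weight). Weights must sum to 1. Empty list: no archetype structure.
#' @param covariates list of planted covariates; each element a list with
#'   \code{name}, \code{type} (\code{"binary"}, \code{"categorical"} or
#'   \code{"continuous"}), optional \code{levels} (categorical only,
#'   default 3), and \code{effects}: a list of \code{list(target =, size =)}
#'   pairs where \code{target} is either \code{"module:k"} (effect of
#'   \code{size} on module k's latent factor) or a taxon index/name
#'   (effect on that taxon's log abundance). Covariates named
#'   \code{age}, \code{antibiotic} and \code{intercourse} are always
#'   generated (null unless listed here) so downstream model
#'   specifications have their standard adjusters.
#' @param depth_log_mean,depth_log_sd log-normal library-size model
#'   (natural-log scale). Defaults give a median depth of 10,000 reads.
#' @param run_effect_sd standard deviation of the per-run, per-taxon
#'   batch offset on log abundance.
#' @param baseline_log_abundance per-taxon baseline log abundance;
#'   default \code{rep(0, n_taxa)}.
#' @param taxon_noise_sd per-sample per-taxon log-abundance noise sd.
#' @param latent_sd sd of each module's latent factor.
#' @param seed integer root seed; fans out to per-stage streams.
#' @return an object of class \code{sim_config}.
#' @seealso \code{\link{simulate_cohort}}, \code{\link{simulate_negative_controls}}
#' @export
sim_config <- function(n_samples, n_taxa, n_runs = 3L,
                       modules = list(), archetypes = list(),
                       covariates = list(),
                       depth_log_mean = log(1e4), depth_log_sd = 0.3,
                       run_effect_sd = 0.3,
                       baseline_log_abundance = NULL,
                       taxon_noise_sd = 0.5, latent_sd = 1, seed = 1L) {
  stopifnot(n_samples >= 1, n_taxa >= 1, n_runs >= 1, run_effect_sd >= 0,
            taxon_noise_sd >= 0, latent_sd >= 0, depth_log_sd >= 0)
  taxa <- sprintf("taxon%03d", seq_len(n_taxa))
  resolve_taxon <- function(x) {
    if (is.character(x)) {
      i <- match(x, taxa)
      if (anyNA(i)) stop("unknown taxon id(s): ", paste(x[is.na(i)], collapse = ", "))
      i
    } else {
      x <- as.integer(x)
      if (any(x < 1L | x > n_taxa)) stop("taxon index out of range")
      x
    }
  }
  modules <- lapply(modules, function(m) {
    idx <- resolve_taxon(m$taxa)
    loading <- m$loading %||% 1
    if (length(loading) == 1L) loading <- rep(loading, length(idx))
    if (length(loading) != length(idx)) stop("loading length must match module size")
    if (any(loading < 0)) stop("module loadings must be >= 0")
    list(taxa = idx, loading = as.numeric(loading))
  })
  all_members <- unlist(lapply(modules, `[[`, "taxa"))
  if (anyDuplicated(all_members)) stop("modules must be disjoint taxon sets")
  archetypes <- lapply(archetypes, function(a) {
    list(dominant = resolve_taxon(a$dominant),
         dominance = as.numeric(a$dominance %||% 0.7),
         weight = as.numeric(a$weight %||% 1))
  })
  if (length(archetypes)) {
    w <- vapply(archetypes, `[[`, numeric(1), "weight")
    if (any(w < 0)) stop("archetype weights must be >= 0")
    if (abs(sum(w) - 1) > 1e-8) stop("archetype mixing weights must sum to 1")
    dom <- vapply(archetypes, `[[`, numeric(1), "dominance")
    if (any(dom < 0 | dom > 1)) stop("dominance fractions must lie in [0, 1]")
  }
  covariates <- lapply(covariates, function(cv) {
    type <- match.arg(cv$type, c("binary", "categorical", "continuous"))
    effects <- lapply(cv$effects %||% list(), function(e) {
      tgt <- e$target
      if (is.character(tgt) && grepl("^module:", tgt)) {
        k <- as.integer(sub("^module:", "", tgt))
        if (k < 1L || k > length(modules)) stop("effect targets unknown module: ", tgt)
        list(type = "module", target = k, size = as.numeric(e$size))
      } else {
        list(type = "taxon", target = resolve_taxon(tgt), size = as.numeric(e$size))
      }
    })
    list(name = cv$name, type = type,
         levels = as.integer(cv$levels %||% 3L), effects = effects)
  })
  structure(list(
    n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
    n_runs = as.integer(n_runs), taxa = taxa, modules = modules,
    archetypes = archetypes, covariates = covariates,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    run_effect_sd = run_effect_sd,
    baseline_log_abundance = as.numeric(baseline_log_abundance %||% rep(0, n_taxa)),
    taxon_noise_sd = taxon_noise_sd, latent_sd = latent_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d samples x %d taxa, %d runs, %d planted module(s), %d archetype(s), %d covariate(s), seed %d\n",
              x$n_samples, x$n_taxa, x$n_runs, length(x$modules),
              length(x$archetypes), length(x$covariates), x$seed))
  invisible(x)
}

# standard adjusters always present in the metadata
.default_covariates <- function(cfg) {
  have <- vapply(cfg$covariates, `[[`, character(1), "name")
  defaults <- list(
    list(name = "age", type = "continuous", levels = 3L, effects = list()),
    list(name = "antibiotic", type = "binary", levels = 3L, effects = list()),
    list(name = "intercourse", type = "binary", levels = 3L, effects = list()))
  c(cfg$covariates, defaults[!vapply(defaults, function(d) d$name %in% have, logical(1))])
}

#' Simulate a synthetic amplicon cohort
#'
#' Realises a \code{\link{sim_config}}: per sample, a dominance archetype
#' and covariate values are drawn; the latent log abundance of each
#' taxon is baseline + archetype dominance boost + module loading times
#' latent factor + planted covariate effects + run batch effect +
#' taxon-level Gaussian noise; the library size is drawn from the
#' log-normal depth model; and counts are drawn multinomially from the
#' softmax of the log abundances. Identical seeds give bit-identical
#' output; count-table row sums equal the drawn depths exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list of class \code{sim_cohort} with elements
#'   \describe{
#'     \item{counts}{samples x taxa integer matrix}
#'     \item{run_info}{data frame: sample_id, run_id, pooled_volume,
#'       is_control, control_type}
#'     \item{metadata}{data frame of covariates (rownames = sample ids)}
#'     \item{truth}{ground truth: latent_factors (samples x modules),
#'       planted_membership (taxon -> module id or NA), planted_effects,
#'       true_depths, archetype_assignment}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_samples; p <- cfg$n_taxa
  samples <- sprintf("S%05d", seq_len(n))
  covs <- .default_covariates(cfg)

  # archetypes
  set.seed(stage_seed(cfg$seed, 1L))
  if (length(cfg$archetypes)) {
    w <- vapply(cfg$archetypes, `[[`, numeric(1), "weight")
    arch <- sample.int(length(cfg$archetypes), n, replace = TRUE, prob = w)
  } else arch <- rep(0L, n)

  # covariates
  set.seed(stage_seed(cfg$seed, 2L))
  metadata <- data.frame(row.names = samples)
  xnum <- list()  # numeric encoding used for effect injection
  for (cv in covs) {
    val <- switch(cv$type,
      binary = rbinom(n, 1L, 0.5),
      categorical = factor(sample(paste0("L", seq_len(cv$levels)), n, replace = TRUE)),
      continuous = rnorm(n))
    metadata[[cv$name]] <- if (cv$type == "binary") factor(val, levels = c(0, 1),
                                                           labels = c("no", "yes")) else val
    xnum[[cv$name]] <- switch(cv$type,
      binary = as.numeric(val),
      categorical = as.numeric(val != levels(val)[1L]),  # indicator of non-reference
      continuous = as.numeric(val))
  }

  # latent module factors (+ covariate effects on factors)
  set.seed(stage_seed(cfg$seed, 3L))
  n_mod <- length(cfg$modules)
  Z <- matrix(rnorm(n * max(n_mod, 1L), sd = cfg$latent_sd), n, max(n_mod, 1L))
  if (n_mod == 0L) Z <- Z[, 0, drop = FALSE]
  planted_effects <- list()
  for (cv in covs) for (e in cv$effects) {
    if (e$type == "module") Z[, e$target] <- Z[, e$target] + e$size * xnum[[cv$name]]
    planted_effects[[length(planted_effects) + 1L]] <-
      data.frame(covariate = cv$name, target_type = e$type,
                 target = if (e$type == "module") paste0("module:", e$target)
                          else cfg$taxa[e$target],
                 size = e$size)
  }
  planted_effects <- if (length(planted_effects)) do.call(rbind, planted_effects)
                     else data.frame(covariate = character(), target_type = character(),
                                     target = character(), size = numeric())

  # run assignment + run x taxon batch effects + pooled volumes
  set.seed(stage_seed(cfg$seed, 4L))
  run <- sample.int(cfg$n_runs, n, replace = TRUE)
  run_eff <- matrix(rnorm(cfg$n_runs * p, sd = cfg$run_effect_sd), cfg$n_runs, p)
  volume <- exp(rnorm(n, mean = log(2), sd = 0.2))  # ~2 ul pooled

  # assemble log abundances
  logA <- matrix(cfg$baseline_log_abundance, n, p, byrow = TRUE)
  if (length(cfg$archetypes)) {
    base <- cfg$baseline_log_abundance
    for (a in seq_along(cfg$archetypes)) {
      at <- cfg$archetypes[[a]]
      f <- min(max(at$dominance, 1e-6), 1 - 1e-6)
      others <- sum(exp(base[-at$dominant]))
      boost <- log(f / (1 - f) * others) - base[at$dominant]
      rows <- which(arch == a)
      logA[rows, at$dominant] <- logA[rows, at$dominant] + boost
    }
  }
  for (m in seq_along(cfg$modules)) {
    mod <- cfg$modules[[m]]
    logA[, mod$taxa] <- logA[, mod$taxa] + outer(Z[, m], mod$loading)
  }
  for (cv in covs) for (e in cv$effects) if (e$type == "taxon")
    logA[, e$target] <- logA[, e$target] + e$size * xnum[[cv$name]]
  logA <- logA + run_eff[run, , drop = FALSE]

  set.seed(stage_seed(cfg$seed, 5L))
  logA <- logA + matrix(rnorm(n * p, sd = cfg$taxon_noise_sd), n, p)

  # depths and counts
  set.seed(stage_seed(cfg$seed, 6L))
  depth <- pmax(1L, as.integer(round(rlnorm(n, cfg$depth_log_mean, cfg$depth_log_sd))))
  set.seed(stage_seed(cfg$seed, 7L))
  prob <- softmax_rows(logA)
  counts <- matrix(0L, n, p, dimnames = list(samples, cfg$taxa))
  for (s in seq_len(n)) counts[s, ] <- as.integer(rmultinom(1L, depth[s], prob[s, ]))

  membership <- rep(NA_integer_, p); names(membership) <- cfg$taxa
  for (m in seq_along(cfg$modules)) membership[cfg$modules[[m]]$taxa] <- m
  if (n_mod) dimnames(Z) <- list(samples, paste0("module", seq_len(n_mod)))

  run_info <- data.frame(
    sample_id = samples, run_id = factor(paste0("run", run)),
    pooled_volume = volume, is_control = FALSE, control_type = "none",
    stringsAsFactors = FALSE)
  structure(list(
    counts = counts, run_info = run_info, metadata = metadata,
    truth = list(latent_factors = Z, planted_membership = membership,
                 planted_effects = planted_effects, true_depths = depth,
                 archetype_assignment = arch),
    config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples x %d taxa over %d run(s); median depth %d\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$run_info$run_id),
              as.integer(median(rowSums(x$counts)))))
  invisible(x)
}

#' Simulate negative-control samples
#'
#' Extraction/PCR-control-like samples whose library sizes are a small
#' fraction (\code{contamination_rate}) of the cohort depth model, with
#' composition drawn from the baseline profile. With rate 0 the control
#' rows are all zero.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_controls number of control samples.
#' @param contamination_rate multiplier on the depth model (>= 0).
#' @return list with \code{counts} (controls x taxa) and \code{run_info}
#'   (with \code{is_control = TRUE}); both empty if \code{n_controls} is 0.
#' @export
simulate_negative_controls <- function(config, n_controls, contamination_rate) {
  stopifnot(inherits(config, "sim_config"), n_controls >= 0)
  if (contamination_rate < 0) stop("contamination_rate must be >= 0")
  cfg <- config
  ids <- if (n_controls) sprintf("CTRL%03d", seq_len(n_controls)) else character()
  set.seed(stage_seed(cfg$seed, 11L))
  n <- as.integer(n_controls); p <- cfg$n_taxa
  counts <- matrix(0L, n, p, dimnames = list(ids, cfg$taxa))
  depth <- integer(n)
  if (n > 0L) {
    depth <- as.integer(round(contamination_rate *
                                rlnorm(n, cfg$depth_log_mean, cfg$depth_log_sd)))
    logA <- matrix(cfg$baseline_log_abundance, n, p, byrow = TRUE) +
      matrix(rnorm(n * p, sd = cfg$taxon_noise_sd), n, p)
    prob <- softmax_rows(logA)
    for (s in seq_len(n)) if (depth[s] > 0L)
      counts[s, ] <- as.integer(rmultinom(1L, depth[s], prob[s, ]))
  }
  ctype <- rep(c("extraction", "PCR"), length.out = n)
  run_info <- data.frame(
    sample_id = ids,
    run_id = factor(rep(paste0("run", seq_len(cfg$n_runs)), length.out = n)),
    pooled_volume = rep(2, n), is_control = rep(TRUE, n),
    control_type = ctype[seq_len(n)], stringsAsFactors = FALSE)
  list(counts = counts, run_info = run_info)
}

#' Derive menstrual-cycle phase from cycle day
#'
#' Labels the luteal phase as the final 14 days of the reported cycle
#' (standard physiology): \code{luteal} if the day offset since the last
#' cycle start is at least \code{cycle_length_days - 14} and still within
#' the cycle; \code{follicular} before that; \code{indeterminate} when
#' the offset runs past the reported cycle length (irregular or
#' suppressed cycles).
#'
#' @param cycle_start_offset_days days since last reported cycle start
#'   (0-59). Vectorised.
#' @param cycle_length_days reported average cycle length (> 0).
#' @return character vector: \code{"follicular"}, \code{"luteal"} or
#'   \code{"indeterminate"}.
#' @examples
#' derive_cycle_phase(c(5, 20, 30), 28)
#' @export
derive_cycle_phase <- function(cycle_start_offset_days, cycle_length_days) {
  off <- cycle_start_offset_days; len <- cycle_length_days
  if (any(off < 0) || any(len < 0)) stop("cycle inputs must be non-negative")
  if (any(len == 0)) stop("cycle_length_days must be > 0")
  if (any(off >= 60)) stop("cycle_start_offset_days must be < 60")
  n <- max(length(off), length(len))
  off <- rep_len(off, n); len <- rep_len(len, n)
  ifelse(off >= len, "indeterminate",
         ifelse(off >= len - 14, "luteal", "follicular"))
}
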