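# Shared fixtures and independent oracles for the test suite.

# Brute-force BH step-up straight from the definition:
# q_(i) = min_{j: p_(j) >= p_(i)} m * p_(j) / j, capped at 1.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(pmin(1, m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Simple taxonomy covering a count table's taxa: all bacterial,
# lengths 250, four taxa assigned to Lactobacillus subgenera.
make_taxonomy <- function(taxa) {
  n <- length(taxa)
  data.frame(
    taxon_id = taxa,
    genus = paste0("Genus_", taxa),
    subgenus = NA_character_,
    is_bacterial = TRUE,
    sequence_length = 250,
    stringsAsFactors = FALSE)
}

# Null cohort: no modules, no archetypes, no planted effects.
null_cohort <- function(n_samples, n_taxa, seed, depth_log_mean = log(1e4)) {
  simulate_cohort(sim_config(n_samples, n_taxa, n_runs = 2,
                             depth_log_mean = depth_log_mean,
                             run_effect_sd = 0, seed = seed))
}

# The planted 4-module recovery design used by the network and
# acceptance suites: 4 modules x 4 taxa, loading 1, 30 background
# taxa, n = 600, depth 2e4.
planted_module_cohort <- function(seed = 11) {
  mods <- lapply(0:3, function(k) list(taxa = k * 4 + 1:4, loading = 1))
  simulate_cohort(sim_config(600, 46, n_runs = 3, modules = mods,
                             depth_log_mean = log(2e4), depth_log_sd = 0.2,
                             run_effect_sd = 0.1, seed = seed))
}

# sparcc -> pvalues -> mcl -> extract_modules on a cohort; returns the
# module_set plus the mcl membership.
recover_modules <- function(cohort, n_perm = 200, perm_draws = 5, seed = 3) {
  cts <- filter_prevalence(cohort$counts, 0.10)
  net <- sparcc(cts, seed = seed)
  net$pvalues <- sparcc_pvalues(cts, net, n_perm = n_perm, seed = seed,
                                perm_draws = perm_draws)
  cl <- mcl(net)
  list(net = net, clusters = cl,
       modules = extract_modules(cl, relative_abundance(cohort$counts)))
}

# ARI of the recovered clustering against the planted membership,
# restricted to the planted (module-member) taxa.
planted_ari <- function(cohort, clusters) {
  truth <- cohort$truth$planted_membership
  planted <- names(truth)[!is.na(truth)]
  mclust::adjustedRandIndex(truth[planted], clusters$membership[planted])
}
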