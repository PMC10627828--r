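make_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 35, 8),
             antibiotic = factor(sample(c("no", "yes"), n, TRUE, c(0.7, 0.3))),
             intercourse = factor(sample(c("no", "yes"), n, TRUE)),
             group = factor(sample(c("a", "b"), n, TRUE)),
             row.names = sprintf("S%05d", seq_len(n)))
}

test_that("model_spec validates the adjustment set", {
  expect_error(model_spec("age"), "must not appear")
  sp <- model_spec("group")
  expect_s3_class(sp, "model_spec")
  md <- make_meta(30)
  expect_error(vagmod:::build_design(md, model_spec("missing_var")), "absent")
})

test_that("marginal PERMANOVA matches adonis2 and detects separation", {
  co <- null_cohort(40, 10, seed = 2)
  md <- make_meta(40, seed = 3)
  d <- bray_curtis(relative_abundance(co$counts))
  res <- permanova_marginal(d, md, model_spec("group"), n_perm_initial = 99,
                            seed = 1)
  a2 <- vegan::adonis2(d ~ group + age + antibiotic + intercourse, data = md,
                       by = "margin", permutations = 19)
  expect_equal(res$effect, a2["group", "R2"], tolerance = 1e-10)
  expect_equal(res$statistic, a2["group", "F"], tolerance = 1e-10)
  # two groups with disjoint compositional supports: minimum attainable p
  ab <- rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
              matrix(c(0, 1), 10, 2, byrow = TRUE))
  rownames(ab) <- sprintf("S%05d", 1:20); colnames(ab) <- c("t1", "t2")
  md20 <- make_meta(20, seed = 4)
  md20$block <- factor(rep(c("x", "y"), each = 10))
  sep <- permanova_marginal(bray_curtis(ab), md20, model_spec("block"),
                            n_perm_initial = 99, n_perm_full = 99, seed = 1)
  expect_equal(sep$p, 1 / 100)
  # duplicating the effect as its own adjuster is a collinearity error
  md20$block2 <- md20$block
  expect_error(permanova_marginal(bray_curtis(ab), md20,
                                  model_spec("block2", adjusters = "block")),
               "collinear")
})

test_that("PERMANOVA escalates permutations for small p-values", {
  ab <- rbind(matrix(c(1, 0), 15, 2, byrow = TRUE),
              matrix(c(0, 1), 15, 2, byrow = TRUE))
  rownames(ab) <- sprintf("S%05d", 1:30); colnames(ab) <- c("t1", "t2")
  md <- make_meta(30, seed = 5)
  md$block <- factor(rep(c("x", "y"), each = 15))
  res <- permanova_marginal(bray_curtis(ab), md, model_spec("block"),
                            n_perm_initial = 999, n_perm_full = 2000,
                            escalate_at = 0.001, seed = 2)
  expect_equal(res$permutations_used, 2000L)
  expect_equal(res$p, 1 / 2001)
  null <- permanova_marginal(bray_curtis(relative_abundance(
    null_cohort(30, 8, seed = 6)$counts)), md, model_spec("group"),
    n_perm_initial = 99, n_perm_full = 2000, seed = 3)
  expect_equal(null$permutations_used, 99L)
})

test_that("lm_response recovers a perfect group difference and is affine invariant", {
  md <- make_meta(100, seed = 7)
  y <- setNames(as.numeric(md$group == "b"), rownames(md))
  # closed-form OLS oracle (no adjusters): regressing the z-scored
  # indicator on its own dummy gives |beta| = 1 / sd(y)
  res0 <- suppressWarnings(  # perfect fit is the point of the oracle
    lm_response(y, md, model_spec("group", adjusters = character())))
  expect_equal(abs(res0$effect), 1 / sd(y), tolerance = 1e-9)
  res <- suppressWarnings(lm_response(y, md, model_spec("group")))
  expect_lt(res$p, 1e-6)
  res_scaled <- suppressWarnings(lm_response(10 + 5 * y, md, model_spec("group")))
  expect_equal(res_scaled$effect, res$effect, tolerance = 1e-9)
  expect_equal(res_scaled$p, res$p, tolerance = 1e-9)
  expect_error(lm_response(y * 0, md, model_spec("group")), "zero-variance")
})

test_that("lm_response p-values are uniform under the null", {
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    md <- make_meta(50, seed = s)
    y <- setNames(rnorm(50), rownames(md))
    lm_response(y, md, model_spec("group"))$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("one-vs-all CST logistic respects the group-size rule and flags separation", {
  md <- make_meta(300, seed = 9)
  cst <- setNames(sample(c(rep("I", 150), rep("III", 130), rep("IV", 20))),
                  rownames(md))
  res <- cst_logistic_ova(cst, md, model_spec("group"), min_group = 120)
  expect_setequal(unique(res$unit), c("I", "III"))
  expect_equal(attr(res, "skipped")$cst, "IV")
  expect_true(all(abs(res$effect) < 0.6))   # membership independent of group
  # 119 members at min_group 120: skipped
  cst2 <- setNames(c(rep("A", 119), rep("B", 181)), rownames(md))
  res2 <- cst_logistic_ova(cst2, md, model_spec("group"), min_group = 120)
  expect_false("A" %in% res2$unit)
  # effect perfectly predicting membership raises the separation flag
  md$sep <- factor(ifelse(cst == "I", "yes", "no"))
  res3 <- cst_logistic_ova(cst, md, model_spec("sep"), min_group = 120)
  expect_true(any(res3$flag[res3$unit == "I"] == "separation"))
  expect_error(cst_logistic_ova(setNames(rep("I", 300), rownames(md)), md,
                                model_spec("group")), "at least 2")
})

test_that("BH adjustment matches the hand-computed step-up and handles families", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.01, 0.5, 0.01, 0.5)
  fam <- c("a", "a", "b", "b")
  expect_equal(bh_adjust(p, fam), c(p.adjust(p[1:2], "BH"), p.adjust(p[3:4], "BH")))
  # property: equals the brute-force step-up on random vectors
  set.seed(8)
  for (i in 1:25) {
    pv <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(pv), brute_force_bh(pv))
  }
})

test_that("consensus DA recovers a planted fold change and filters by prevalence", {
  cfg <- sim_config(300, 15, covariates = list(
    list(name = "exposure", type = "binary",
         effects = list(list(target = 3, size = log(4))))), seed = 23)
  co <- simulate_cohort(cfg)
  res <- consensus_da(co$counts, co$metadata, model_spec("exposure"),
                      n_mc = 16, seed = 1)
  hit <- res[res$unit == "taxon003", ]
  expect_true(hit$consensus)
  expect_equal(hit$n_methods_significant, 3L)
  # a rare taxon never enters the results
  cts <- co$counts
  cts[, 1] <- 0; cts[1:20, 1] <- 1   # 6.7% prevalence
  res2 <- consensus_da(cts, co$metadata, model_spec("exposure"),
                       n_mc = 8, seed = 1)
  expect_false("taxon001" %in% res2$unit)
  expect_error(consensus_da(co$counts, co$metadata, model_spec("exposure"),
                            methods = c("clr_lm", "rank_lm"), min_agree = 3),
               "min_agree")
  # determinism
  res3 <- consensus_da(co$counts, co$metadata, model_spec("exposure"),
                       n_mc = 16, seed = 1)
  expect_identical(res$q, res3$q)
})

test_that("variance explained is sequential, consistent and monotone", {
  co <- null_cohort(50, 10, seed = 27)
  md <- make_meta(50, seed = 10)
  d <- bray_curtis(relative_abundance(co$counts))
  empty <- variance_explained(d, md, character())
  expect_equal(attr(empty, "total_r2"), 0)
  one <- variance_explained(d, md, "group")
  a2 <- vegan::adonis2(d ~ group, data = md, permutations = 2)
  expect_equal(attr(one, "total_r2"), a2["Model", "R2"], tolerance = 1e-10)
  # adding factors never decreases cumulative R2 (nested-model oracle)
  two <- variance_explained(d, md, c("group", "age"))
  three <- variance_explained(d, md, c("group", "age", "intercourse"))
  expect_gte(attr(two, "total_r2"), attr(one, "total_r2"))
  expect_gte(attr(three, "total_r2"), attr(two, "total_r2"))
  # collinear factor dropped with warning
  md$group_copy <- md$group
  expect_warning(vc <- variance_explained(d, md, c("group", "group_copy")),
                 "collinear")
  expect_equal(attr(vc, "total_r2"), attr(one, "total_r2"), tolerance = 1e-10)
})
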