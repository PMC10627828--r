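test_that("aggregation sums within labels and preserves row sums", {
  cts <- matrix(c(5, 2, 7, 3, 1, 4), 1, 6,
                dimnames = list("s1", paste0("asv", 1:6)))
  tax <- make_taxonomy(paste0("asv", 1:6))
  tax$genus <- c("Lactobacillus", "Lactobacillus", "Gardnerella",
                 "Prevotella", "Prevotella", "Gardnerella")
  tax$subgenus <- c("L.crispatus_grp", "L.crispatus_grp", NA, NA, NA, NA)
  agg <- aggregate_taxa(cts, tax)
  expect_equal(colnames(agg), sort(c("L.crispatus_grp", "Gardnerella", "Prevotella")))
  expect_equal(agg[1, "L.crispatus_grp"], 5 + 2)   # two ASVs of one subgenus
  expect_equal(agg[1, "Gardnerella"], 7 + 4)
  expect_equal(rowSums(agg), rowSums(cts))
  # already at label resolution: identity up to column order
  tax2 <- make_taxonomy(paste0("asv", 1:6)); tax2$genus <- paste0("asv", 1:6)
  expect_equal(sort(colnames(aggregate_taxa(cts, tax2))), sort(colnames(cts)))
})

test_that("relative abundance closes rows and is scale invariant", {
  cts <- matrix(c(3, 1, 6, 2), 2, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("a", "b")))
  ab <- relative_abundance(cts)
  expect_equal(unname(ab[1, ]), c(0.75, 0.25))
  expect_equal(unname(rowSums(ab)), c(1, 1))
  expect_equal(relative_abundance(cts * 10), ab, ignore_attr = TRUE)
  bad <- rbind(cts, zero = c(0, 0))
  expect_error(relative_abundance(bad), "zero")
})

test_that("CLR matches the closed form and its rows sum to zero", {
  x <- matrix(c(0.5, 0.25, 0.25), 1, 3, dimnames = list("s", c("a", "b", "c")))
  cl <- clr_transform(x, pseudocount = 0)
  expect_equal(round(unname(cl[1, ]), 4), c(0.4621, -0.2310, -0.2310))
  co <- null_cohort(30, 8, seed = 2)
  cl2 <- clr_transform(co$counts)
  expect_lt(max(abs(rowSums(cl2))), 1e-9)
  # permutation equivariance in taxa
  perm <- c(3, 1, 4, 2, 8, 5, 7, 6)
  expect_equal(clr_transform(co$counts[, perm])[, colnames(co$counts)],
               cl2[, colnames(co$counts)], ignore_attr = TRUE)
  # clr o relative_abundance invariant to per-sample count scaling
  sc <- co$counts * sample(1:5, nrow(co$counts), replace = TRUE)
  expect_equal(clr_transform(relative_abundance(sc), pseudocount = 1e-9),
               clr_transform(relative_abundance(co$counts), pseudocount = 1e-9),
               ignore_attr = TRUE)
  expect_error(clr_transform(matrix(0, 1, 2, dimnames = list("s", c("a", "b")))),
               "all-zero")
})

test_that("dominance calls follow the 30% rule, dual dominance and ties", {
  ab <- rbind(
    nodom = c(0.29, 0.28, 0.23, 0.20),
    dual  = c(0.35, 0.33, 0.32, 0.00),
    mono  = c(1.00, 0.00, 0.00, 0.00),
    tie   = c(0.40, 0.40, 0.20, 0.00))
  colnames(ab) <- c("t1", "t2", "t3", "t4")
  dc <- call_dominance(ab)
  expect_equal(dc$call, c("No dominance", "t1", "t1", "t1"))
  expect_equal(dc$dual_dominant, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(dc$top_fraction, c(0.29, 0.35, 1, 0.4))
  expect_true(dc$tie[4])
  expect_false(any(dc$tie[1:3]))
  # boundary: exactly 30% is dominant (>= threshold)
  dc30 <- call_dominance(matrix(c(0.30, 0.25, 0.25, 0.20), 1, 4,
                                dimnames = list("s", c("t1", "t2", "t3", "t4"))))
  expect_equal(dc30$call, "t1")
})

test_that("rare top labels collapse to 'other' with strict threshold", {
  dom <- data.frame(sample_id = as.character(1:399),
                    top_taxon = rep(c("A", "B"), c(200, 199)),
                    second_taxon = rep(c("B", "A"), c(200, 199)))
  lab <- top2_labels(dom, min_occurrences = 200)
  expect_equal(unique(lab$top_label[1:200]), "A")      # 200 occurrences kept
  expect_equal(unique(lab$top_label[201:399]), "other") # 199 -> other
  expect_equal(unique(lab$second_label[1:200]), "other")
  expect_equal(nrow(lab), nrow(dom))                    # conservation
})

test_that("Shannon diversity has the analytic values", {
  ab <- rbind(uniform = rep(0.25, 4), single = c(1, 0, 0, 0),
              padded = c(0.25, 0.25, 0.25, 0.25))
  colnames(ab) <- paste0("t", 1:4)
  h <- shannon_diversity(ab)
  expect_equal(unname(h["uniform"]), log(4))
  expect_equal(unname(h["single"]), 0)
  # zero-abundance taxa do not contribute
  ab2 <- cbind(ab, t5 = 0)
  expect_equal(unname(shannon_diversity(ab2)), unname(h))
})

test_that("Bray-Curtis matches the formula and its bounds", {
  ab <- relative_abundance(null_cohort(20, 6, seed = 9)$counts)
  d <- as.matrix(bray_curtis(ab))
  expect_equal(unname(diag(d)), rep(0, 20))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  # brute-force formula oracle on one pair
  x <- ab[3, ]; y <- ab[11, ]
  expect_equal(d[3, 11], sum(abs(x - y)) / sum(x + y))
  # identical and disjoint profiles
  two <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  colnames(two) <- c("t1", "t2")
  d2 <- as.matrix(bray_curtis(two))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
})

test_that("embeddings are deterministic and preserve block structure", {
  set.seed(99)
  blocks <- rbind(matrix(rep(c(90, 5, 5), each = 10), 10, 3),
                  matrix(rep(c(5, 5, 90), each = 10), 10, 3)) +
    matrix(rpois(60, 2), 20, 3)
  dimnames(blocks) <- list(paste0("s", 1:20), paste0("t", 1:3))
  ab <- relative_abundance(blocks)
  d <- bray_curtis(ab)
  xy <- embed_2d(d, "pcoa")
  expect_equal(dim(xy), c(20L, 2L))
  # axis 1 separates the two blocks with no overlap
  expect_true(max(xy[1:10, 1]) < min(xy[11:20, 1]) ||
              min(xy[1:10, 1]) > max(xy[11:20, 1]))
  expect_error(embed_2d(as.dist(matrix(0, 2, 2))), "at least 3")
  skip_if_not_installed("Rtsne")
  co <- null_cohort(49, 8, seed = 13)
  ab2 <- relative_abundance(co$counts)
  ab2 <- rbind(ab2, dup = ab2[1, ])       # duplicated profile pair
  d2 <- bray_curtis(ab2)
  t1 <- embed_2d(d2, "tsne", seed = 5, perplexity = 10)
  t2 <- embed_2d(d2, "tsne", seed = 5, perplexity = 10)
  expect_identical(t1, t2)                # determinism contract
  emb_d <- as.matrix(dist(t1))
  pair <- emb_d[1, nrow(t1)]
  expect_lt(pair, quantile(emb_d[upper.tri(emb_d)], 0.01))
})

test_that("CST assignment is nearest-centroid under Yue-Clayton theta", {
  cent <- rbind(I = c(0.9, 0.05, 0.05, 0), III = c(0.05, 0.9, 0.05, 0),
                IV = c(0.1, 0.1, 0.4, 0.4))
  colnames(cent) <- c("Lc", "Li", "Ga", "Pr")
  ab <- rbind(exact = cent["I", ], ortho = c(0, 0, 0, 1),
              mid = c(0.5, 0.45, 0.05, 0))
  colnames(ab) <- colnames(cent)
  res <- assign_cst(ab, cent)
  expect_equal(res$cst[1], "I")
  expect_equal(res$similarity[1], 1)
  # orthogonal profile: theta = 0 against centroid I
  theta <- sum(ab["ortho", ] * cent["I", ]) /
    (sum(ab["ortho", ]^2) + sum(cent["I", ]^2) - sum(ab["ortho", ] * cent["I", ]))
  expect_equal(theta, 0)
  # permutation invariance in taxon order
  perm <- c(3, 1, 4, 2)
  res_p <- assign_cst(ab[, perm], cent)
  expect_equal(res_p$cst, res$cst)
  expect_equal(res_p$similarity, res$similarity)
  # tie between two identical centroids: first label wins, tie flagged
  cent2 <- rbind(B = cent["I", ], A = cent["I", ])
  res_t <- assign_cst(ab["exact", , drop = FALSE], cent2)
  expect_equal(res_t$cst, "A")
  expect_true(res_t$tie)
  expect_error(assign_cst(ab, cent[0, , drop = FALSE]), "empty centroid")
})

test_that("paired-platform concordance is per-taxon Spearman", {
  co <- null_cohort(15, 6, seed = 17)
  ab <- relative_abundance(co$counts)
  same <- paired_platform_concordance(ab, ab)
  expect_equal(same$rho, rep(1, 6))
  # rank-reversing one platform gives rho = -1 (monotone reversal)
  flip <- apply(ab, 2, function(x) max(x) + min(x) - x)
  rownames(flip) <- rownames(ab)
  expect_equal(paired_platform_concordance(ab, flip)$rho, rep(-1, 6))
  const <- ab; const[, 1] <- 0.5
  expect_true(is.na(paired_platform_concordance(ab, const)$rho[1]))
  expect_error(paired_platform_concordance(ab[1:2, ], ab[1:2, ]), "fewer than 3")
})

test_that("beta-diversity distributions enumerate pairs exhaustively", {
  m <- matrix(runif(25), 5, 5); m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:5)
  g <- c("A", "A", "A", "B", "B")
  bd <- beta_group_distributions(m, g)
  expect_equal(sum(bd$type == "within" & bd$group1 == "A"), 3)
  expect_equal(sum(bd$type == "within" & bd$group1 == "B"), 1)
  expect_equal(sum(bd$type == "between"), 6)
  expect_equal(nrow(bd), 5 * 4 / 2)
  bd_one <- beta_group_distributions(m, rep("A", 5))
  expect_equal(sum(bd_one$type == "between"), 0)
})
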