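test_that("mae behaves as a metric on the upper triangle", {
  a <- random_scores(5, 20)
  b <- random_scores(5, 21)
  expect_identical(mae(a, a), 0)
  shifted <- a + 0.25
  diag(shifted) <- 0
  expect_equal(mae(a, shifted), 0.25, tolerance = 1e-12)
  expect_equal(mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
  expect_equal(mae(a, b), mae(b, a))
  # triangle inequality on random triples
  for (s in 1:5) {
    x <- random_scores(4, 100 + s)
    y <- random_scores(4, 200 + s)
    z <- random_scores(4, 300 + s)
    expect_lte(mae(x, z), mae(x, y) + mae(y, z) + 1e-12)
  }
  c2 <- random_scores(5, 22, genes = paste0("h", 1:5))
  expect_error(mae(a, c2), "gene sets differ")
})

test_that("pr_curve geometry is right for perfect and uninformative rankings", {
  genes <- paste0("g", 1:5)
  std <- edge_standard(as_pair_mat(c("g1", "g2"), c("g2", "g3")),
                       as_pair_mat(c("g1", "g3", "g4"),
                                   c("g4", "g5", "g5")), genes)
  perfect <- matrix(0, 5, 5, dimnames = list(genes, genes))
  perfect["g1", "g2"] <- perfect["g2", "g1"] <- 0.9
  perfect["g2", "g3"] <- perfect["g3", "g2"] <- 0.8
  curve <- pr_curve(perfect, std)
  expect_equal(curve$precision[1], 1)
  expect_equal(curve$recall[nrow(curve)], 1)
  expect_equal(curve$precision[nrow(curve)], prevalence(std))
  expect_equal(aupr(perfect, std), 1.0)

  tied <- matrix(0.5, 5, 5, dimnames = list(genes, genes))
  diag(tied) <- 0
  curve <- pr_curve(tied, std)
  expect_identical(nrow(curve), 1L)
  expect_equal(curve$precision, prevalence(std))
  expect_equal(curve$recall, 1)
  expect_equal(aupr(tied, std), prevalence(std))
})

test_that("pr_curve and aupr match exhaustive threshold enumeration", {
  genes <- paste0("g", 1:4)
  std <- edge_standard(as_pair_mat(c("g1", "g2"), c("g2", "g3")),
                       as_pair_mat(c("g1", "g3", "g4", "g2"),
                                   c("g3", "g4", "g1", "g4")), genes)
  set.seed(31)
  s <- random_scores(4, 31, genes = genes)
  ss <- bclr:::standard_scores(s, std)
  ref <- oracle_pr(ss$score, ss$label)
  curve <- pr_curve(s, std)
  expect_equal(curve$threshold, ref$threshold, tolerance = 1e-12)
  expect_equal(curve$precision, ref$precision, tolerance = 1e-12)
  expect_equal(curve$recall, ref$recall, tolerance = 1e-12)
  expect_equal(aupr(s, std), oracle_aupr(ss$score, ss$label),
               tolerance = 1e-12)
})

test_that("aupr requires both labels and is invariant to monotone transforms", {
  genes <- paste0("g", 1:6)
  scores <- random_scores(6, 32, genes = genes)
  only_pos <- edge_standard(as_pair_mat("g1", "g2"), NULL, genes)
  expect_error(aupr(scores, only_pos), "positive and one negative")

  std <- random_standard(genes, 4, 10, seed = 33)
  ref <- aupr(scores, std)
  expect_equal(aupr(scores^3, std), ref, tolerance = 1e-12)
  logt <- log1p(scores); diag(logt) <- 0
  expect_equal(aupr(logt, std), ref, tolerance = 1e-12)
})

test_that("random rankings score near the prevalence", {
  genes <- paste0("g", 1:10)
  std <- random_standard(genes, 8, 30, seed = 34)
  scores <- random_scores(10, 35, genes = genes)
  set.seed(35)
  vals <- replicate(200, {
    shuffled <- scores
    shuffled[upper.tri(shuffled)] <- sample(scores[upper.tri(scores)])
    shuffled[lower.tri(shuffled)] <- t(shuffled)[lower.tri(shuffled)]
    aupr(shuffled, std)
  })
  # average precision has a small positive finite-sample bias of order
  # (1 - prevalence) * H(n_pos) / n_evaluated, so the shuffle mean sits
  # slightly above the prevalence; it must stay within the shuffle
  # distribution's own spread of it
  expect_lt(abs(mean(vals) - prevalence(std)), 3 * sd(vals))
  expect_gt(min(vals), 0)
})

test_that("feo_ratio counts shared-category edges among annotated pairs", {
  ann <- list(a = "K1", b = "K1", c = "K2", d = c("K1", "K2"))
  one_cat <- rbind(c("a", "b"), c("b", "d"))
  expect_equal(feo_ratio(one_cat, ann), 1.0)
  expect_equal(feo_ratio(rbind(c("a", "c")), ann), 0)
  # 5 edges, one with an unannotated endpoint, 2 of remaining 4 share
  edges <- rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"),
                 c("a", "zz"))
  expect_equal(feo_ratio(edges, ann), 0.5)
  expect_equal(feo_ratio(edges, ann),
               oracle_feo(edges, ann))
  # undefined, not zero
  expect_identical(feo_ratio(rbind(c("zz", "yy")), ann), NA_real_)
  expect_error(feo_ratio(NULL, ann), "empty")
})

test_that("adding a same-category edge never decreases the FEO ratio", {
  set.seed(36)
  ann <- generate_annotations(generate_regulatory_network(4, 16, 0.2,
                                                          seed = 37),
                              n_categories = 3, seed = 38)
  genes <- names(ann)
  edges <- cbind(sample(genes, 10, TRUE), sample(genes, 10, TRUE))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  base <- feo_ratio(edges, ann)
  same_cat <- t(combn(names(which(vapply(ann, function(x)
    "K1" %in% x, logical(1)))), 2))
  grown <- feo_ratio(rbind(edges, same_cat[1, ]), ann)
  expect_gte(grown, base)
})

test_that("welch_ttest matches the Welch formulas and guards sample size", {
  xs <- c(1, 2, 3)
  expect_error(welch_ttest(xs, 5), "at least 2")
  same <- welch_ttest(xs, xs)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_lt(welch_ttest(xs, xs + 100)$p_value, 0.01)

  set.seed(39)
  a <- rnorm(5); b <- rnorm(5, mean = 1, sd = 2)
  got <- welch_ttest(a, b)
  ref <- oracle_welch(a, b)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-10)
  expect_equal(got$df, ref$df, tolerance = 1e-10)
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-8)
})

test_that("mean_ci builds nested Student-t intervals", {
  const <- mean_ci(rep(2.5, 4))
  expect_equal(const$ci_lo, 2.5)
  expect_equal(const$ci_hi, 2.5)

  set.seed(40)
  x <- rnorm(10)
  ci <- mean_ci(x, 0.99)
  half <- qt(0.995, 9) * sd(x) / sqrt(10)
  expect_equal(ci$ci_lo, mean(x) - half, tolerance = 1e-9)
  expect_equal(ci$ci_hi, mean(x) + half, tolerance = 1e-9)

  narrow <- mean_ci(x, 0.5)
  expect_gt(narrow$ci_lo, ci$ci_lo)
  expect_lt(narrow$ci_hi, ci$ci_hi)
  expect_error(mean_ci(1), "at least 2")
})
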