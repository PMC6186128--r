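test_that("B-spline weights are a proper fuzzy partition", {
  set.seed(3)
  for (case in list(c(10, 3), c(3, 2), c(5, 1), c(4, 4))) {
    w <- bspline_weights(rnorm(60), case[1], case[2])
    expect_equal(rowSums(w), rep(1, 60), tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("mutual information is symmetric and handles degenerate input", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(mutual_information(x, y), mutual_information(y, x),
               tolerance = 1e-12)
  expect_warning(mi0 <- mutual_information(rep(1, 30), y), "constant")
  expect_identical(mi0, 0)
  expect_error(mutual_information(x, y[-1]), "same length")
})

test_that("MI matches the brute-force estimator on small instances", {
  set.seed(5)
  x <- rnorm(8); y <- x + rnorm(8)
  expect_equal(mutual_information(x, y, clr_config(3, 2)),
               oracle_mi(x, y, 3, 2), tolerance = 1e-10)
  # a batch of random shapes
  for (i in 1:10) {
    n <- sample(6:20, 1)
    bins <- sample(3:6, 1)
    ord <- sample(seq_len(min(bins, 3)), 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(mutual_information(x, y, clr_config(bins, ord)),
                 oracle_mi(x, y, bins, ord), tolerance = 1e-10)
  }
})

test_that("hard binning recovers the identity MI(x,x) = H(x)", {
  # with order-1 (boxcar) splines the joint of x with itself is diagonal, so
  # self-MI equals the marginal entropy; soft splines spread the joint over
  # adjacent bins and self-MI drops to 2 H(x) - H(x,x)
  set.seed(6)
  x <- rnorm(100)
  cfg <- clr_config(10, 1)
  expect_equal(mutual_information(x, x, cfg),
               bclr:::bspline_entropy(x, cfg), tolerance = 1e-12)
  cfg3 <- clr_config(10, 3)
  w <- bspline_weights(x, 10, 3)
  h <- bclr:::bspline_entropy(x, cfg3)
  pxy <- crossprod(w, w) / nrow(w)
  h_joint <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  expect_equal(mutual_information(x, x, cfg3), 2 * h - h_joint,
               tolerance = 1e-10)
})

test_that("MI of independent variables vanishes at large n", {
  set.seed(7)
  expect_lt(mutual_information(rnorm(10000), rnorm(10000)), 0.05)
})

test_that("MI is invariant under increasing affine transforms", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  ref <- mutual_information(x, y)
  expect_equal(mutual_information(3 * x + 7, y), ref, tolerance = 1e-9)
  expect_equal(mutual_information(x, 0.1 * y - 2), ref, tolerance = 1e-9)
})

test_that("mi_matrix composes pairwise MI and is permutation-equivariant", {
  expr <- random_expr(5, 25, seed = 9)
  m <- mi_matrix(expr)
  expect_true(isSymmetric(m))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(m[i, j], mutual_information(expr[i, ], expr[j, ]),
                   tolerance = 1e-12)
    }
  }
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(mi_matrix(expr[perm, ]), m[perm, perm], tolerance = 1e-12)
})

test_that("clr_transform matches a hand computation of mu, sigma, z", {
  mi <- matrix(c(0, .5, .1, .2,
                 .5, 0, .3, .4,
                 .1, .3, 0, .6,
                 .2, .4, .6, 0), 4, 4,
               dimnames = rep(list(paste0("g", 1:4)), 2))
  expect_equal(clr_transform(mi), oracle_clr(mi), tolerance = 1e-10)
  set.seed(10)
  mi2 <- random_scores(6, 11)
  diag(mi2) <- runif(6)  # self-MI on the diagonal must be ignored
  expect_equal(clr_transform(mi2), oracle_clr(mi2), tolerance = 1e-10)
})

test_that("clr_transform degenerate and error cases", {
  flat <- matrix(0.3, 4, 4, dimnames = rep(list(paste0("g", 1:4)), 2))
  diag(flat) <- 0
  expect_true(all(clr_transform(flat) == 0))
  bad <- flat; bad[1, 2] <- 9
  expect_error(clr_transform(bad), "symmetric")
})

test_that("CLR scores are invariant to positive rescaling of MI", {
  expr <- random_expr(8, 30, seed = 12)
  mi <- mi_matrix(expr)
  ref <- clr_transform(mi)
  for (k in c(0.5, 3)) {
    expect_equal(clr_transform(k * mi), ref, tolerance = 1e-9)
  }
  # changing the MI log base is such a rescaling
  nat <- clr_transform(mi_matrix(expr, clr_config(log_base = exp(1))))
  expect_equal(nat, ref, tolerance = 1e-9)
})

test_that("infer_clr is deterministic and satisfies network invariants", {
  expr <- random_expr(6, 20, seed = 13)
  net <- infer_clr(expr)
  expect_identical(net, infer_clr(expr))
  expect_silent(validate_scores(net))
})

test_that("CLR recovers strong edges on synthetic data", {
  # 10 genes, 3 strong regulator-target edges, low noise
  truth <- structure(list(regulators = paste0("TF", 1:3),
                          targets = paste0("G", 1:7),
                          edges = data.frame(
                            regulator = c("TF1", "TF2", "TF3"),
                            target = c("G1", "G2", "G3"),
                            weight = c(2, -2, 1.5)),
                          seed = 1L),
                     class = "synthetic_truth")
  expr <- simulate_expression(truth, 100, noise_sd = 0.1, seed = 42)
  net <- infer_clr(expr)
  ut <- which(upper.tri(net), arr.ind = TRUE)
  ord <- order(net[ut], decreasing = TRUE)
  # regulators precede targets in the gene ordering, so an undirected truth
  # pair is (regulator, target) in upper-triangle orientation
  top5 <- paste(rownames(net)[ut[ord[1:5], 1]],
                rownames(net)[ut[ord[1:5], 2]])
  expect_true(all(paste(truth$edges$regulator, truth$edges$target) %in% top5))
})

test_that("infer_pearson implements absolute product-moment correlation", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.1, -1.4)
  expr <- expression_matrix(rbind(x, 2 * x + 1, -x),
                            gene_ids = c("a", "b", "c"))
  net <- infer_pearson(expr)
  expect_equal(net["a", "b"], 1.0)
  expect_equal(net["a", "c"], 1.0)

  expr2 <- random_expr(2, 6, seed = 14)
  r <- infer_pearson(expr2)[1, 2]
  u <- expr2[1, ]; v <- expr2[2, ]
  manual <- abs(sum((u - mean(u)) * (v - mean(v))) /
                  sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2)))
  expect_equal(r, manual, tolerance = 1e-12)
})

test_that("constant genes correlate to nothing, with a warning", {
  expr <- expression_matrix(rbind(rnorm(5), rep(2, 5), rnorm(5)),
                            gene_ids = c("a", "flat", "c"))
  expect_warning(net <- infer_pearson(expr), "flat")
  expect_true(all(net["flat", ] == 0))
  expect_silent(validate_scores(net))
})

test_that("tiny-sample regimes shrink the binning instead of failing", {
  expr <- random_expr(4, 2, seed = 15)
  w <- capture_warnings(net <- infer_clr(expr))
  expect_match(w, "reducing num_bins", all = FALSE)
  expect_match(w, "reducing spline_order", all = FALSE)
  expect_silent(validate_scores(net))
})
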