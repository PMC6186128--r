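#' Configuration for CLR network inference
#'
#' The mutual information estimator soft-bins each expression profile with
#' B-spline basis functions: `num_bins` basis functions of order
#' `spline_order` (order 3 = quadratic). A sample therefore has fractional
#' membership in up to `spline_order` adjacent bins, which smooths the
#' histogram estimate at the small sample sizes typical of expression
#' compendia. Defaults are 10 bins and order 3.
#'
#' @param num_bins number of B-spline bins (>= 2).
#' @param spline_order B-spline order (1 = hard binning boxcar, 2 = linear,
#'   3 = quadratic); must not exceed `num_bins`.
#' @param log_base base of the MI logarithm; base 2 gives bits. CLR scores
#'   are provably invariant to this choice (z-scoring absorbs the constant
#'   factor), so it only affects raw MI values.
#' @return an object of class `clr_config`.
#' @export
clr_config <- function(num_bins = 10L, spline_order = 3L, log_base = 2) {
  num_bins <- as.integer(num_bins)
  spline_order <- as.integer(spline_order)
  if (num_bins < 2) stop("num_bins must be >= 2", call. = FALSE)
  if (spline_order < 1) stop("spline_order must be >= 1", call. = FALSE)
  if (spline_order > num_bins) {
    stop("spline_order (", spline_order, ") must not exceed num_bins (",
         num_bins, ")", call. = FALSE)
  }
  if (!is.numeric(log_base) || log_base <= 1) {
    stop("log_base must be > 1", call. = FALSE)
  }
  structure(list(num_bins = num_bins, spline_order = spline_order,
                 log_base = log_base),
            class = "clr_config")
}

# Shrink a config to fit n samples: fewer conditions than bins is a regime
# the method must survive (subsampling fractions down to a handful of
# conditions), so bins are capped at the sample count and the spline order
# capped at the bin count, each with a one-time warning.
resolve_config <- function(config, n_samples) {
  stopifnot(inherits(config, "clr_config"))
  bins <- config$num_bins
  ord <- config$spline_order
  if (n_samples < bins) {
    warning("reducing num_bins from ", bins, " to the sample count ",
            n_samples, call. = FALSE)
    bins <- max(2L, as.integer(n_samples))
  }
  if (ord > bins) {
    warning("reducing spline_order from ", ord, " to num_bins = ", bins,
            call. = FALSE)
    ord <- bins
  }
  clr_config(bins, ord, config$log_base)
}

#' B-spline soft-binning weights for one sample vector
#'
#' Affinely rescales `x` onto the B-spline domain and evaluates the
#' `num_bins` basis functions of order `spline_order` at each sample (the
#' Cox-de Boor recursion, on a knot vector clamped at both ends). Each row
#' is one sample's fractional bin membership and sums to 1.
#'
#' @param x numeric vector (non-constant).
#' @param num_bins number of basis functions.
#' @param spline_order B-spline order.
#' @return a `length(x)` x `num_bins` weight matrix with unit row sums.
#' @export
bspline_weights <- function(x, num_bins, spline_order) {
  n <- length(x)
  M <- as.integer(num_bins)
  k <- as.integer(spline_order)
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[2] <= rng[1]) {
    stop("input vector is constant or non-finite", call. = FALSE)
  }
  tmax <- M - k + 1
  z <- (x - rng[1]) / (rng[2] - rng[1]) * tmax
  z <- pmin(pmax(z, 0), tmax)
  # clamped uniform knot vector: k repeats at each end
  knots <- c(rep(0, k), seq_len(M - k), rep(tmax, k))
  # order-1 (boxcar) basis over the M + k - 1 knot intervals
  B <- matrix(0, n, M + k - 1)
  for (i in seq_len(M + k - 1)) {
    if (knots[i + 1] > knots[i]) {
      B[, i] <- as.numeric(z >= knots[i] & z < knots[i + 1])
    }
  }
  # samples at the right edge belong to the last non-degenerate interval
  B[z >= tmax, M] <- 1
  if (k > 1) {
    for (ord in 2:k) {
      ncols <- M + k - ord
      Bn <- matrix(0, n, ncols)
      for (i in seq_len(ncols)) {
        d1 <- knots[i + ord - 1] - knots[i]
        d2 <- knots[i + ord] - knots[i + 1]
        left <- if (d1 > 0) (z - knots[i]) / d1 * B[, i] else 0
        right <- if (d2 > 0) (knots[i + ord] - z) / d2 * B[, i + 1] else 0
        Bn[, i] <- left + right
      }
      B <- Bn
    }
  }
  B
}

#' B-spline mutual information between two expression profiles
#'
#' Estimates MI by soft binning: both vectors are rescaled to the spline
#' domain, each sample gets fractional bin memberships from the B-spline
#' basis, marginal bin probabilities are the sample means of the weights and
#' the joint distribution is the sample mean of the weight outer products.
#' Then `MI = sum p(a,b) * log(p(a,b) / (p(a) p(b)))` over bins with
#' positive joint mass, in units set by `log_base` (bits by default).
#' Because each sample's weights sum to 1 the joint's marginals coincide
#' with the marginal estimates, so the estimate is a true KL divergence and
#' nonnegative up to floating point (tiny negatives are clamped to 0).
#'
#' A constant vector has no binning and contributes no information: the
#' function returns 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 2), one value per
#'   condition.
#' @param config a [clr_config()].
#' @return a single nonnegative MI estimate.
#' @export
mutual_information <- function(x, y, config = clr_config()) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  config <- resolve_config(config, length(x))
  if (max(x) <= min(x) || max(y) <= min(y)) {
    warning("constant input vector: MI set to 0", call. = FALSE)
    return(0)
  }
  wx <- bspline_weights(x, config$num_bins, config$spline_order)
  wy <- bspline_weights(y, config$num_bins, config$spline_order)
  mi_from_weights(wx, wy, config$log_base)
}

mi_from_weights <- function(wx, wy, log_base = 2) {
  n <- nrow(wx)
  pxy <- crossprod(wx, wy) / n
  px <- colMeans(wx)
  py <- colMeans(wy)
  pos <- pxy > 0
  prod_p <- outer(px, py)
  mi <- sum(pxy[pos] * log(pxy[pos] / prod_p[pos], base = log_base))
  max(mi, 0)
}

# Marginal entropy under the same weight machinery (used by diagnostics and
# tests): H(X) = -sum p(a) log p(a) with p(a) the mean basis weights.
bspline_entropy <- function(x, config = clr_config()) {
  config <- resolve_config(config, length(x))
  w <- bspline_weights(x, config$num_bins, config$spline_order)
  p <- colMeans(w)
  p <- p[p > 0]
  -sum(p * log(p, base = config$log_base))
}

#' All-pairs mutual information matrix
#'
#' Computes [mutual_information()] for every gene pair; per-gene weight
#' matrices are computed once and reused. The diagonal holds the MI of each
#' profile with itself (retained for diagnostics; the CLR background
#' statistics downstream exclude it).
#'
#' @param expr genes x conditions expression matrix.
#' @param config a [clr_config()].
#' @return a symmetric gene x gene MI matrix.
#' @export
mi_matrix <- function(expr, config = clr_config()) {
  validate_expression(expr)
  config <- resolve_config(config, ncol(expr))
  g <- nrow(expr)
  genes <- rownames(expr)
  constant <- apply(expr, 1, function(v) max(v) <= min(v))
  if (any(constant)) {
    warning("constant gene profile(s): ",
            paste(genes[constant], collapse = ", "),
            "; their MI is 0", call. = FALSE)
  }
  weights <- vector("list", g)
  for (i in seq_len(g)) {
    if (!constant[i]) {
      weights[[i]] <- bspline_weights(expr[i, ], config$num_bins,
                                      config$spline_order)
    }
  }
  mi <- matrix(0, g, g, dimnames = list(genes, genes))
  for (i in seq_len(g)) {
    if (constant[i]) next
    for (j in i:g) {
      if (constant[j]) next
      mi[i, j] <- mi[j, i] <- mi_from_weights(weights[[i]], weights[[j]],
                                              config$log_base)
    }
  }
  mi
}

#' Context likelihood of relatedness (CLR) background correction
#'
#' Converts a raw mutual information matrix into edge confidences: for each
#' gene i the background mean and standard deviation of its MI values to all
#' other genes are computed, each MI(i, j) becomes a one-sided z-score
#' against gene i's background (negative z clipped to 0), and the pair score
#' combines both directions as `sqrt(z_i^2 + z_j^2)`. The score measures how
#' exceptional an interaction is within the contextual neighbourhood of the
#' two genes, which suppresses indirect correlations shared across a hub's
#' partners.
#'
#' The background uses the population (divide-by-n) standard deviation over
#' the n - 1 partners, excluding the self-pair; a zero background spread
#' yields z = 0 for that gene.
#'
#' @param mi symmetric gene x gene MI matrix (e.g. from [mi_matrix()]).
#' @param tol symmetry tolerance.
#' @return a score matrix (symmetric, nonnegative, zero diagonal).
#' @export
clr_transform <- function(mi, tol = 1e-8) {
  if (!is.matrix(mi) || nrow(mi) != ncol(mi) ||
      max(abs(mi - t(mi))) > tol) {
    stop("CLR requires a symmetric square MI matrix", call. = FALSE)
  }
  g <- nrow(mi)
  if (g < 3) {
    stop("CLR background needs at least 3 genes", call. = FALSE)
  }
  off <- mi
  diag(off) <- NA_real_
  mu <- rowMeans(off, na.rm = TRUE)
  # population sd over the n-1 partners
  sigma <- sqrt(rowMeans((off - mu)^2, na.rm = TRUE))
  z <- (mi - mu) / ifelse(sigma > 0, sigma, Inf)
  z[z < 0] <- 0
  scores <- sqrt(z^2 + t(z)^2)
  diag(scores) <- 0
  dimnames(scores) <- dimnames(mi)
  scores
}

#' Infer a co-expression network by CLR
#'
#' Runs the full pipeline: B-spline mutual information for all gene pairs
#' followed by the CLR background correction. Deterministic for a fixed
#' input.
#'
#' @param expr genes x conditions expression matrix (>= 3 genes,
#'   >= 2 conditions).
#' @param config a [clr_config()]; defaults to 10 bins, order-3 splines.
#' @return a score matrix of CLR z-score-derived confidences.
#' @export
#' @examples
#' expr <- simulate_expression(
#'   generate_regulatory_network(2, 8, density = 0.3, seed = 1),
#'   n_conditions = 40, noise_sd = 0.3, seed = 2)
#' net <- infer_clr(expr)
infer_clr <- function(expr, config = clr_config()) {
  clr_transform(mi_matrix(expr, config))
}

#' Infer a co-expression network by absolute Pearson correlation
#'
#' Scores each gene pair by the absolute value of the Pearson correlation of
#' their profiles across conditions. Absolute value is used because edge
#' weights are nonnegative confidences that get averaged across bagging
#' iterations; signed averaging would let anticorrelated evidence cancel.
#' Constant genes (zero variance) get score 0 to all partners, with a
#' warning.
#'
#' @param expr genes x conditions expression matrix (>= 2 conditions).
#' @return a score matrix with entries |r| and zero diagonal.
#' @export
infer_pearson <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2) stop("need at least 2 conditions", call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant gene profile(s): ",
            paste(rownames(expr)[sds == 0], collapse = ", "),
            "; their correlations are set to 0", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(t(expr)))
  r[!is.finite(r)] <- 0
  scores <- abs(r)
  # guard against |r| marginally above 1 from floating point
  scores[scores > 1] <- 1
  diag(scores) <- 0
  scores
}
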