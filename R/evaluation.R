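#' Mean absolute error between two networks
#'
#' Stability metric: the mean of |a(i,j) - b(i,j)| over all distinct gene
#' pairs (upper triangle, diagonal excluded). A network inferred from
#' reduced data is called stable when its MAE to the parent network (the one
#' inferred from the complete condition set) is small.
#'
#' @param a,b score matrices over identical gene sets in identical order.
#' @return a nonnegative scalar.
#' @export
mae <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    d <- c(setdiff(rownames(a), rownames(b)),
           setdiff(rownames(b), rownames(a)))
    stop("gene sets differ",
         if (length(d) > 0) paste0(": ", paste(unique(d), collapse = ", "))
         else " in order", call. = FALSE)
  }
  mean(abs(a[upper.tri(a)] - b[upper.tri(b)]))
}

# Look up the undirected score of each directed standard pair and return the
# parallel label vector. Masked pairs (absent from the standard) never enter.
standard_scores <- function(scores, standard) {
  stopifnot(inherits(standard, "edge_standard"))
  genes <- rownames(scores)
  pm <- rbind(standard$positives, standard$negatives)
  labels <- c(rep(1L, nrow(standard$positives)),
              rep(0L, nrow(standard$negatives)))
  ri <- match(pm[, 1], genes)
  ti <- match(pm[, 2], genes)
  if (anyNA(ri) || anyNA(ti)) {
    bad <- unique(c(pm[, 1][is.na(ri)], pm[, 2][is.na(ti)]))
    stop("standard references gene(s) absent from the network: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(score = scores[cbind(ri, ti)], label = labels)
}

#' Precision-recall curve against a partial directed standard
#'
#' Each directed standard pair (regulator, target) is assigned the
#' undirected score of that gene pair; pairs the standard does not list are
#' masked and never evaluated. Pairs are ranked by descending score and all
#' pairs sharing a tied score enter together at a single threshold, so the
#' curve is invariant to the order of tied pairs. Precision and recall are
#' recorded at every distinct threshold.
#'
#' @param scores a symmetric score matrix.
#' @param standard an [edge_standard()] with at least one positive and one
#'   negative inside the network's gene set.
#' @return an object of class `pr_curve`: a data.frame with columns
#'   `threshold`, `precision`, `recall`, plus attributes `n_positives` and
#'   `n_evaluated`.
#' @export
pr_curve <- function(scores, standard) {
  ss <- standard_scores(scores, standard)
  n_pos <- sum(ss$label == 1)
  n_neg <- sum(ss$label == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("standard must contain at least one positive and one negative ",
         "pair (has ", n_pos, " positives, ", n_neg, " negatives)",
         call. = FALSE)
  }
  ord <- order(ss$score, decreasing = TRUE)
  s <- ss$score[ord]
  lab <- ss$label[ord]
  # indices where a block of tied scores ends
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(lab)[block_end]
  n_at <- block_end
  curve <- data.frame(threshold = s[block_end],
                      precision = tp / n_at,
                      recall = tp / n_pos)
  structure(curve, class = c("pr_curve", "data.frame"),
            n_positives = n_pos, n_evaluated = length(s))
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("Precision-recall curve: %d thresholds, %d positives / %d evaluated pairs, AUPR = %.4f\n",
              nrow(x), attr(x, "n_positives"), attr(x, "n_evaluated"),
              aupr_from_curve(x)))
  invisible(x)
}

aupr_from_curve <- function(curve) {
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Area under the precision-recall curve
#'
#' Step-wise (rectangular) integration over distinct thresholds:
#' `sum (recall_k - recall_{k-1}) * precision_k` with recall_0 = 0. No
#' interpolation between thresholds, which avoids the optimistic bias of
#' trapezoidal PR areas; tie-grouping (see [pr_curve()]) makes the value
#' independent of tie ordering. An uninformative (all-tied or shuffled)
#' ranking scores the prevalence, positives / evaluated pairs.
#'
#' @inheritParams pr_curve
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, standard) {
  aupr_from_curve(pr_curve(scores, standard))
}

#' Prevalence of positives in a standard
#'
#' The AUPR of an uninformative ranking: positives divided by evaluated
#' (positive + negative) pairs.
#'
#' @param standard an [edge_standard()].
#' @return a scalar in [0, 1].
#' @export
prevalence <- function(standard) {
  stopifnot(inherits(standard, "edge_standard"))
  n_pos <- nrow(standard$positives)
  n_pos / (n_pos + nrow(standard$negatives))
}

#' Functional edge overlap ratio
#'
#' Among the edges whose both endpoints carry functional annotations, the
#' fraction whose endpoint category sets share at least one category. Edges
#' touching an unannotated gene are ignored. Ranges from 0 (no edge links
#' annotated genes in the same category) to 1 (all edges link annotated
#' genes in the same category); returns `NA` when no edge links two
#' annotated genes (the ratio is undefined, which is distinct from 0).
#'
#' @param edges two-column character matrix or data.frame of undirected gene
#'   pairs (e.g. the first two columns of [read_edge_list()] output).
#' @param annotations named list mapping gene id to a character vector of
#'   categories (see [read_annotations()]).
#' @return a scalar in [0, 1], or `NA_real_` if undefined.
#' @export
feo_ratio <- function(edges, annotations) {
  edges <- as_pair_matrix(edges)
  if (nrow(edges) == 0) stop("edge set is empty", call. = FALSE)
  ann_a <- annotations[edges[, 1]]
  ann_b <- annotations[edges[, 2]]
  annotated <- lengths(ann_a) > 0 & lengths(ann_b) > 0
  if (!any(annotated)) return(NA_real_)
  shared <- mapply(function(a, b) length(intersect(a, b)) > 0,
                   ann_a[annotated], ann_b[annotated])
  sum(shared) / sum(annotated)
}

#' Welch's two-sample t-test
#'
#' Two-sided test of equal means with unequal population variances assumed
#' (Welch-Satterthwaite degrees of freedom), used to compare replicate AUPR
#' or MAE values between methods. P-values are reported raw, without
#' multiple-testing correction.
#'
#' @param xs,ys numeric replicate vectors, each of length >= 2.
#' @return a list with `statistic`, `p_value`, and `df`.
#' @export
welch_ttest <- function(xs, ys) {
  if (length(xs) < 2 || length(ys) < 2) {
    stop("each sample needs at least 2 values (got ", length(xs), " and ",
         length(ys), "); significance cannot be assessed on a single ",
         "replicate", call. = FALSE)
  }
  ht <- stats::t.test(xs, ys, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Mean with a Student-t confidence interval
#'
#' Summarises replicate metric values as mean +/- t-quantile * sd / sqrt(n).
#' The t interval is used because experiment curves rest on few replicates
#' per setting (10 by default), too few for a normal interval.
#'
#' @param samples numeric vector of replicate values (>= 2).
#' @param level confidence level in (0, 1); default 0.99.
#' @return an object of class `metric_sample`: a list with `mean`, `ci_lo`,
#'   `ci_hi`, `level`, `n`, and the raw `values`.
#' @export
mean_ci <- function(samples, level = 0.99) {
  if (length(samples) < 2) {
    stop("need at least 2 samples for a confidence interval", call. = FALSE)
  }
  if (!all(is.finite(samples))) stop("non-finite sample", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  n <- length(samples)
  m <- mean(samples)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(samples) / sqrt(n)
  structure(list(mean = m, ci_lo = m - half, ci_hi = m + half,
                 level = level, n = n, values = samples),
            class = "metric_sample")
}

#' @export
print.metric_sample <- function(x, ...) {
  cat(sprintf("%.6g  [%.6g, %.6g]  (%d%% CI, n = %d)\n", x$mean, x$ci_lo,
              x$ci_hi, round(100 * x$level), x$n))
  invisible(x)
}
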