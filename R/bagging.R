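#' Subsample conditions without replacement
#'
#' Draws `max(2, floor(fraction * n_conditions))` distinct conditions
#' uniformly at random without replacement, preserving their original
#' relative order, keeping all genes. The floor of 2 lets fraction sweeps
#' reach down to 0.01 without ever producing a degenerate (empty or
#' single-condition) set.
#'
#' @param expr genes x conditions expression matrix.
#' @param fraction subsampling fraction in (0, 1].
#' @param seed optional integer seed; if `NULL`, uses the current RNG state.
#' @return an expression matrix over the sampled condition subset.
#' @export
subsample_conditions <- function(expr, fraction, seed = NULL) {
  validate_expression(expr)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- ncol(expr)
  size <- max(2L, as.integer(floor(fraction * n)))
  draw <- function() sort(sample.int(n, size, replace = FALSE))
  idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  expr[, idx, drop = FALSE]
}

infer_by_method <- function(expr, method, config) {
  switch(method,
         clr = infer_clr(expr, config),
         pearson = infer_pearson(expr),
         stop("unknown method: ", method, call. = FALSE))
}

#' Bootstrap-aggregated network inference (BCLR / bagged Pearson)
#'
#' Repeatedly subsamples a fraction of the conditions without replacement
#' (the random subspace method over the condition axis — "feature
#' bootstrapping", though no draw repeats a condition within an iteration),
#' infers a constituent network from each subset, and averages constituent
#' edge weights into a consensus network. Constituent scores are used
#' as-generated: no per-constituent rank normalisation. Convergence of the
#' running consensus is tracked per iteration as the MAE between consecutive
#' running means (first entry: MAE to the zero matrix) and, when a standard
#' is supplied, as the AUPR of the running mean.
#'
#' The run is fully reproducible from `seed`: per-iteration substreams are
#' derived up front, so results do not depend on any execution schedule. An
#' iteration whose subsample fails inference (e.g. all-constant draw) is
#' retried with a fresh draw up to 10 times before erroring.
#'
#' @param expr genes x conditions expression matrix.
#' @param fraction subsampling fraction in (0, 1]; `floor(fraction * n)`
#'   (minimum 2) conditions per iteration.
#' @param iterations number of bagging iterations (default 200, which is
#'   ample for the running mean to converge).
#' @param method `"clr"` or `"pearson"`.
#' @param config a [clr_config()] for the CLR method.
#' @param seed integer master seed.
#' @param standard optional [edge_standard()]; when given, the per-iteration
#'   AUPR of the running consensus is recorded.
#' @return an object of class `bagging_result`: list with `consensus` (score
#'   matrix), `mae_trace`, `aupr_trace` (or `NULL`), `iterations_run`, and
#'   `config` (echo of the call parameters).
#' @export
#' @examples
#' expr <- simulate_expression(
#'   generate_regulatory_network(2, 8, density = 0.3, seed = 1),
#'   n_conditions = 40, noise_sd = 0.3, seed = 2)
#' res <- bag_network(expr, fraction = 0.5, iterations = 10,
#'                    method = "pearson", seed = 7)
bag_network <- function(expr, fraction, iterations = 200L,
                        method = c("clr", "pearson"),
                        config = clr_config(), seed = 1L,
                        standard = NULL) {
  method <- match.arg(method)
  validate_expression(expr)
  iterations <- as.integer(iterations)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  g <- nrow(expr)
  running <- matrix(0, g, g, dimnames = list(rownames(expr), rownames(expr)))
  mae_trace <- numeric(iterations)
  aupr_trace <- if (!is.null(standard)) numeric(iterations) else NULL
  for (t in seq_len(iterations)) {
    constituent <- NULL
    for (attempt in seq_len(10L)) {
      sub <- subsample_conditions(expr, fraction,
                                  seed = derive_seed(seed, t, attempt))
      constituent <- tryCatch(
        suppressWarnings(infer_by_method(sub, method, config)),
        error = function(e) NULL)
      if (!is.null(constituent)) break
    }
    if (is.null(constituent)) {
      stop("inference failed on 10 consecutive subsamples at iteration ", t,
           call. = FALSE)
    }
    updated <- running + (constituent - running) / t
    mae_trace[t] <- mean(abs(updated[upper.tri(updated)] -
                               running[upper.tri(running)]))
    running <- updated
    if (!is.null(standard)) aupr_trace[t] <- aupr(running, standard)
  }
  structure(list(consensus = running,
                 mae_trace = mae_trace,
                 aupr_trace = aupr_trace,
                 iterations_run = iterations,
                 config = list(fraction = fraction, iterations = iterations,
                               method = method, seed = seed,
                               clr_config = config)),
            class = "bagging_result")
}

#' @export
print.bagging_result <- function(x, ...) {
  cat(sprintf("Bagged %s consensus network: %d genes, %d iterations at fraction %.3g\n",
              x$config$method, nrow(x$consensus), x$iterations_run,
              x$config$fraction))
  cat(sprintf("  final consensus-update MAE: %.3g\n",
              x$mae_trace[x$iterations_run]))
  invisible(x)
}

#' Summarise bagging convergence
#'
#' The running-mean consensus changes by O(1/t) per iteration; the run is
#' declared converged when the mean of the last `window` consensus-update
#' MAE values falls below `tol_factor` times the mean consensus edge weight.
#'
#' @param result a [bag_network()] result.
#' @param window number of trailing iterations to average (>= 2).
#' @param tol_factor relative tolerance (default 1e-3).
#' @return a list with `converged`, `tail_mean`, `tolerance`, and the
#'   trailing `tail` of the MAE trace.
#' @export
convergence_summary <- function(result, window = 10L, tol_factor = 1e-3) {
  stopifnot(inherits(result, "bagging_result"))
  window <- as.integer(window)
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  if (window > result$iterations_run) {
    stop("window (", window, ") exceeds iterations run (",
         result$iterations_run, ")", call. = FALSE)
  }
  tail_vals <- utils::tail(result$mae_trace, window)
  cons <- result$consensus
  tol <- tol_factor * mean(cons[upper.tri(cons)])
  list(converged = mean(tail_vals) < tol,
       tail_mean = mean(tail_vals),
       tolerance = tol,
       tail = tail_vals)
}
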