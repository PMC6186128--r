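#' Condition-removal stability experiment
#'
#' Quantifies how sensitive an inference procedure is to the amount of input
#' data. A parent network is inferred from the complete condition set; then,
#' for each fraction of data remaining and each repeat, a random condition
#' subset of that size is drawn without replacement, a constituent network
#' is inferred from it, and its MAE to the parent (and, if a standard is
#' supplied, its AUPR) is recorded. Each (fraction, repeat) uses one
#' condition subset for all metrics, so MAE and AUPR are paired.
#'
#' All interfaces use the fraction of data REMAINING (e.g. 0.9 = 10%
#' removed); one canonical axis avoids off-by-complement mistakes. Repeat
#' seeds derive from (seed, fraction index, repeat index), so adding
#' fractions does not perturb existing replicates.
#'
#' @param expr genes x conditions expression matrix.
#' @param fractions_remaining increasing vector of fractions in (0, 1].
#' @param repeats random subsets per fraction (default 10).
#' @param method `"clr"` or `"pearson"`.
#' @param config a [clr_config()].
#' @param bag_fraction if non-`NULL`, the procedure under test is the bagged
#'   variant: both parent and constituents are consensus networks from
#'   [bag_network()] at this subsampling fraction.
#' @param bag_iterations bagging iterations for the bagged variant.
#' @param standard optional [edge_standard()] for paired AUPR tracking.
#' @param seed master seed.
#' @param ci_level confidence level for the per-setting interval.
#' @return an object of class `experiment_curve` (see
#'   [summary.experiment_curve()]): list with `samples` (long data.frame:
#'   setting, rep, metric, value), `summary` (setting, metric, mean, ci_lo,
#'   ci_hi), and `metadata`.
#' @export
condition_removal_experiment <- function(expr, fractions_remaining,
                                         repeats = 10L,
                                         method = c("clr", "pearson"),
                                         config = clr_config(),
                                         bag_fraction = NULL,
                                         bag_iterations = 200L,
                                         standard = NULL, seed = 1L,
                                         ci_level = 0.99) {
  method <- match.arg(method)
  validate_expression(expr)
  fractions_remaining <- sort(unique(fractions_remaining))
  if (any(fractions_remaining <= 0 | fractions_remaining > 1)) {
    stop("fractions_remaining must lie in (0, 1]", call. = FALSE)
  }
  if (any(floor(fractions_remaining * ncol(expr)) < 2)) {
    stop("every fraction must leave at least 2 conditions", call. = FALSE)
  }
  infer_once <- function(e, sub_seed) {
    if (is.null(bag_fraction)) {
      suppressWarnings(infer_by_method(e, method, config))
    } else {
      bag_network(e, bag_fraction, bag_iterations, method, config,
                  seed = sub_seed)$consensus
    }
  }
  parent <- infer_once(expr, derive_seed(seed, 0, 0))
  rows <- list()
  for (i in seq_along(fractions_remaining)) {
    f <- fractions_remaining[i]
    for (r in seq_len(repeats)) {
      sub_seed <- derive_seed(seed, i, r)
      sub <- subsample_conditions(expr, f, seed = sub_seed)
      net <- infer_once(sub, derive_seed(seed, i, r, 1))
      rec <- data.frame(setting = f, rep = r, metric = "mae",
                        value = mae(net, parent))
      if (!is.null(standard)) {
        rec <- rbind(rec, data.frame(setting = f, rep = r, metric = "aupr",
                                     value = aupr(net, standard)))
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  samples <- do.call(rbind, rows)
  new_experiment_curve(samples, ci_level,
                       metadata = list(kind = "condition_removal",
                                       method = method,
                                       bag_fraction = bag_fraction,
                                       repeats = repeats, seed = seed))
}

new_experiment_curve <- function(samples, ci_level, metadata) {
  summ <- do.call(rbind, lapply(split(samples,
                                      samples[c("setting", "metric")],
                                      drop = TRUE), function(d) {
    ci <- mean_ci(d$value, ci_level)
    data.frame(setting = d$setting[1], metric = d$metric[1], mean = ci$mean,
               ci_lo = ci$ci_lo, ci_hi = ci$ci_hi)
  }))
  summ <- summ[order(summ$metric, summ$setting), ]
  rownames(summ) <- NULL
  structure(list(samples = samples, summary = summ,
                 ci_level = ci_level, metadata = metadata),
            class = "experiment_curve")
}

#' @export
print.experiment_curve <- function(x, ...) {
  cat(sprintf("Experiment curve (%s): %d settings x %d repeats\n",
              x$metadata$kind, length(unique(x$samples$setting)),
              x$metadata$repeats %||% NA_integer_))
  print(x$summary)
  invisible(x)
}

#' Summarise an experiment curve
#'
#' @param object an `experiment_curve`.
#' @param ... unused.
#' @return the per-setting summary data.frame (mean with CI bounds).
#' @export
summary.experiment_curve <- function(object, ...) object$summary

#' Subsampling-fraction accuracy sweep
#'
#' Runs bootstrap aggregation across a grid of subsampling fractions on the
#' full condition set and records the consensus AUPR at each fraction,
#' together with the non-bagged baseline AUPR as a horizontal reference. No
#' stability axis exists here: each consensus is its own parent.
#'
#' @param expr genes x conditions expression matrix.
#' @param standard an [edge_standard()].
#' @param fractions subsampling fractions in (0, 1].
#' @param iterations bagging iterations per fraction.
#' @param method `"clr"` or `"pearson"`.
#' @param config a [clr_config()].
#' @param seed master seed.
#' @return a list of class `sweep_curve`: data.frame `curve` (fraction,
#'   aupr), scalar `baseline_aupr`, and `metadata`.
#' @export
subsample_sweep <- function(expr, standard, fractions, iterations = 200L,
                            method = c("clr", "pearson"),
                            config = clr_config(), seed = 1L) {
  method <- match.arg(method)
  validate_expression(expr)
  fractions <- sort(unique(fractions))
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  baseline <- aupr(suppressWarnings(infer_by_method(expr, method, config)),
                   standard)
  vals <- vapply(seq_along(fractions), function(i) {
    res <- bag_network(expr, fractions[i], iterations, method, config,
                       seed = derive_seed(seed, i))
    aupr(res$consensus, standard)
  }, numeric(1))
  structure(list(curve = data.frame(fraction = fractions, aupr = vals),
                 baseline_aupr = baseline,
                 metadata = list(method = method, iterations = iterations,
                                 seed = seed)),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("Subsampling-fraction sweep (%s, %d iterations); baseline AUPR %.4f\n",
              x$metadata$method, x$metadata$iterations, x$baseline_aupr))
  print(x$curve)
  invisible(x)
}

#' Select a subsampling fraction by network stability
#'
#' Implements the stability-selection procedure for studies without a
#' usable standard: (i) build a bagged parent network at each candidate
#' subsampling fraction from the full data; (ii) for each candidate,
#' repeatedly remove conditions and rerun bagging on the reduced set,
#' comparing each consensus to the candidate's parent by MAE; (iii) pick
#' the candidate whose condition-removal curve is most stable — smallest
#' mean MAE across the curve by default (`objective = "mean"`; `"max"` and
#' `"auc"`, the trapezoidal area over the removal axis, are alternatives),
#' ties going to the smaller fraction; (iv) the returned consensus network
#' is the selected candidate's parent, i.e. bagging at the chosen fraction
#' on all available data.
#'
#' @param expr genes x conditions expression matrix.
#' @param candidate_fractions candidate subsampling fractions in (0, 1].
#' @param fractions_remaining condition-removal grid (fractions of data
#'   remaining, in (0, 1]).
#' @param repeats repeats per removal fraction.
#' @param iterations bagging iterations.
#' @param method `"clr"` or `"pearson"`.
#' @param config a [clr_config()].
#' @param objective stability objective over the removal curve.
#' @param seed master seed.
#' @return a list of class `fraction_selection`: `selected_fraction`,
#'   `stability_scores` (named numeric), `curves` (long data.frame:
#'   candidate, setting, rep, value), and `consensus` (the final network).
#' @export
select_fraction_by_stability <- function(expr, candidate_fractions,
                                         fractions_remaining,
                                         repeats = 10L, iterations = 200L,
                                         method = c("clr", "pearson"),
                                         config = clr_config(),
                                         objective = c("mean", "max", "auc"),
                                         seed = 1L) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  validate_expression(expr)
  candidate_fractions <- sort(unique(candidate_fractions))
  fractions_remaining <- sort(unique(fractions_remaining))
  parents <- vector("list", length(candidate_fractions))
  rows <- list()
  for (ci in seq_along(candidate_fractions)) {
    f <- candidate_fractions[ci]
    parents[[ci]] <- bag_network(expr, f, iterations, method, config,
                                 seed = derive_seed(seed, ci, 0))$consensus
    for (ri in seq_along(fractions_remaining)) {
      rho <- fractions_remaining[ri]
      for (r in seq_len(repeats)) {
        sub <- subsample_conditions(expr, rho,
                                    seed = derive_seed(seed, ci, ri, r))
        cons <- bag_network(sub, f, iterations, method, config,
                            seed = derive_seed(seed, ci, ri, r, 1))$consensus
        rows[[length(rows) + 1]] <-
          data.frame(candidate = f, setting = rho, rep = r,
                     value = mae(cons, parents[[ci]]))
      }
    }
  }
  curves <- do.call(rbind, rows)
  score_curve <- function(d) {
    per_setting <- tapply(d$value, d$setting, mean)
    switch(objective,
           mean = mean(d$value),
           max = max(per_setting),
           auc = {
             xs <- as.numeric(names(per_setting))
             if (length(xs) < 2) mean(per_setting)
             else sum(diff(xs) * (utils::head(per_setting, -1) +
                                    utils::tail(per_setting, -1)) / 2) /
               (max(xs) - min(xs))
           })
  }
  scores <- vapply(candidate_fractions, function(f) {
    score_curve(curves[curves$candidate == f, , drop = FALSE])
  }, numeric(1))
  names(scores) <- candidate_fractions
  # argmin; ties resolved toward the smaller fraction (candidates sorted)
  best <- which(scores <= min(scores) + 1e-15)[1]
  structure(list(selected_fraction = candidate_fractions[best],
                 stability_scores = scores,
                 curves = curves,
                 consensus = parents[[best]],
                 metadata = list(method = method, objective = objective,
                                 repeats = repeats, iterations = iterations,
                                 seed = seed)),
            class = "fraction_selection")
}

#' @export
print.fraction_selection <- function(x, ...) {
  cat(sprintf("Stability-selected subsampling fraction: %.3g (objective: %s MAE)\n",
              x$selected_fraction, x$metadata$objective))
  print(x$stability_scores)
  invisible(x)
}
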