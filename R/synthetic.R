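#' Generate a random ground-truth regulatory network
#'
#' Draws a directed bipartite regulator-to-target network: each
#' (regulator, target) pair is an edge independently with probability
#' `density`, with weight magnitude uniform over `weight_range` and random
#' sign. Random signs keep the evaluation honest for absolute-correlation
#' scoring: anticorrelated true edges must be recoverable too. Targets with
#' no parent are allowed (they become pure-noise genes in the simulated
#' compendium).
#'
#' @param n_regulators number of regulator genes (ids `TF1..`).
#' @param n_targets number of target genes (ids `G1..`).
#' @param density edge probability per (regulator, target) pair, in [0, 1].
#' @param weight_range length-2 positive numeric: range of |weight|.
#' @param seed integer seed.
#' @return an object of class `synthetic_truth`: list with `regulators`,
#'   `targets`, `edges` (data.frame regulator/target/weight), and `seed`.
#' @export
generate_regulatory_network <- function(n_regulators, n_targets,
                                        density = 0.05,
                                        weight_range = c(0.5, 2),
                                        seed = 1L) {
  if (n_regulators < 1 || n_targets < 1) {
    stop("need at least 1 regulator and 1 target", call. = FALSE)
  }
  if (density < 0 || density > 1) stop("density must be in [0, 1]",
                                       call. = FALSE)
  if (length(weight_range) != 2 || any(weight_range <= 0) ||
      weight_range[1] > weight_range[2]) {
    stop("weight_range must be a positive increasing interval",
         call. = FALSE)
  }
  regulators <- paste0("TF", seq_len(n_regulators))
  targets <- paste0("G", seq_len(n_targets))
  edges <- with_seed(seed, {
    all_pairs <- expand.grid(regulator = regulators, target = targets,
                             stringsAsFactors = FALSE)
    on <- stats::runif(nrow(all_pairs)) < density
    e <- all_pairs[on, , drop = FALSE]
    magnitude <- stats::runif(nrow(e), weight_range[1], weight_range[2])
    sign <- sample(c(-1, 1), nrow(e), replace = TRUE)
    e$weight <- magnitude * sign
    rownames(e) <- NULL
    e
  })
  structure(list(regulators = regulators, targets = targets, edges = edges,
                 seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic regulatory network: %d regulators, %d targets, %d edges\n",
              length(x$regulators), length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Simulate an expression compendium from a ground-truth network
#'
#' Linear-Gaussian model of a perturbation compendium: every condition is an
#' independent perturbation in which each regulator's expression is drawn
#' standard normal, each regulated target is the weighted sum of its
#' parents' values plus Gaussian observation noise, and parentless targets
#' are pure standard-normal noise. This is deliberately simpler than
#' ODE-based simulators: it is sufficient to exercise ranking, bagging and
#' all evaluation metrics at desk scale, but it has no dynamics, no
#' saturation, and no indirect-effect structure beyond what the linear
#' combination induces.
#'
#' @param truth a [generate_regulatory_network()] result.
#' @param n_conditions number of independent conditions (>= 2).
#' @param noise_sd standard deviation of target observation noise (>= 0).
#' @param seed integer seed.
#' @return a genes x conditions expression matrix containing regulators and
#'   targets.
#' @export
simulate_expression <- function(truth, n_conditions, noise_sd = 0.5,
                                seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_conditions < 2) stop("need at least 2 conditions", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  nr <- length(truth$regulators)
  nt <- length(truth$targets)
  vals <- with_seed(seed, {
    reg <- matrix(stats::rnorm(nr * n_conditions), nr, n_conditions,
                  dimnames = list(truth$regulators, NULL))
    # weight matrix W: targets x regulators
    W <- matrix(0, nt, nr, dimnames = list(truth$targets, truth$regulators))
    if (nrow(truth$edges) > 0) {
      W[cbind(match(truth$edges$target, truth$targets),
              match(truth$edges$regulator, truth$regulators))] <-
        truth$edges$weight
    }
    tgt <- W %*% reg
    has_parent <- rowSums(W != 0) > 0
    tgt[has_parent, ] <- tgt[has_parent, , drop = FALSE] +
      stats::rnorm(sum(has_parent) * n_conditions, sd = noise_sd)
    tgt[!has_parent, ] <- stats::rnorm(sum(!has_parent) * n_conditions)
    rbind(reg, tgt)
  })
  expression_matrix(vals, gene_ids = c(truth$regulators, truth$targets),
                    condition_ids = paste0("C", seq_len(n_conditions)))
}

#' Build a partial (silver) standard from a ground-truth network
#'
#' All true edges become positives; a random `negative_fraction` of the
#' regulator-target pairs that are not edges become negatives; every other
#' pair is masked. With `negative_fraction < 1` the standard is incomplete,
#' as real silver standards are, so the masking path of the evaluation code
#' is always exercised.
#'
#' @param truth a [generate_regulatory_network()] result with >= 1 edge.
#' @param negative_fraction fraction in (0, 1] of non-edges to label
#'   negative.
#' @param seed integer seed.
#' @return an [edge_standard()] over the regulator and target genes.
#' @export
make_standard <- function(truth, negative_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (nrow(truth$edges) == 0) {
    stop("truth has no edges; a standard needs at least one positive",
         call. = FALSE)
  }
  if (negative_fraction <= 0 || negative_fraction > 1) {
    stop("negative_fraction must be in (0, 1]", call. = FALSE)
  }
  universe <- c(truth$regulators, truth$targets)
  all_pairs <- expand.grid(regulator = truth$regulators,
                           target = truth$targets,
                           stringsAsFactors = FALSE)
  pos_key <- paste(truth$edges$regulator, truth$edges$target, sep = "\r")
  is_edge <- paste(all_pairs$regulator, all_pairs$target, sep = "\r") %in%
    pos_key
  non_edges <- all_pairs[!is_edge, , drop = FALSE]
  if (nrow(non_edges) == 0) {
    stop("no non-edges available to draw negatives from", call. = FALSE)
  }
  neg <- with_seed(seed, {
    keep <- stats::runif(nrow(non_edges)) < negative_fraction
    non_edges[keep, , drop = FALSE]
  })
  edge_standard(as.matrix(truth$edges[, c("regulator", "target")]),
                as.matrix(neg), universe)
}

#' Generate functional-category annotations consistent with a network
#'
#' Emulates pathway-style annotations: each regulator is assigned one of
#' `n_categories` categories; each target inherits the category of one of
#' its parents with probability `inherit_prob` (default 0.8) and otherwise
#' draws a random category, so genuinely interacting genes tend to share a
#' category, as pathway co-membership does in real annotation databases.
#' Only a random `annotated_fraction` of genes appear in the returned map,
#' exercising the unannotated-endpoint rule of [feo_ratio()].
#'
#' @param truth a [generate_regulatory_network()] result.
#' @param n_categories number of functional categories (>= 1).
#' @param annotated_fraction probability that a gene is annotated, in
#'   (0, 1].
#' @param inherit_prob probability a target inherits a parent's category.
#' @param seed integer seed.
#' @return a named list mapping gene id to a character vector of categories.
#' @export
generate_annotations <- function(truth, n_categories = 5,
                                 annotated_fraction = 1.0,
                                 inherit_prob = 0.8, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_categories < 1) stop("need at least 1 category", call. = FALSE)
  if (annotated_fraction <= 0 || annotated_fraction > 1) {
    stop("annotated_fraction must be in (0, 1]", call. = FALSE)
  }
  cats <- paste0("K", seq_len(n_categories))
  with_seed(seed, {
    reg_cat <- sample(cats, length(truth$regulators), replace = TRUE)
    names(reg_cat) <- truth$regulators
    tgt_cat <- character(length(truth$targets))
    names(tgt_cat) <- truth$targets
    parents <- split(truth$edges$regulator, truth$edges$target)
    for (g in truth$targets) {
      p <- parents[[g]]
      tgt_cat[g] <- if (length(p) > 0 && stats::runif(1) < inherit_prob) {
        reg_cat[[sample(p, 1)]]
      } else {
        sample(cats, 1)
      }
    }
    all_cat <- c(reg_cat, tgt_cat)
    keep <- stats::runif(length(all_cat)) < annotated_fraction
    ann <- lapply(all_cat[keep], function(x) x)
    ann[order(names(ann))]
  })
}

#' Write a complete synthetic dataset in the supported file dialects
#'
#' Convenience wrapper producing expression, standard, annotation, and
#' ground-truth edge files in one call, mirroring the layout of a DREAM5
#' style benchmark directory at desk scale.
#'
#' @param outdir output directory (created if missing).
#' @param n_regulators,n_targets,density network shape parameters.
#' @param n_conditions,noise_sd compendium parameters.
#' @param negative_fraction standard completeness.
#' @param n_categories,annotated_fraction annotation parameters.
#' @param seed master seed; sub-seeds for each generation step derive from
#'   it.
#' @return invisibly, a list with the file paths and the in-memory objects.
#' @export
simulate_dataset <- function(outdir, n_regulators = 10, n_targets = 90,
                             density = 0.05, n_conditions = 200,
                             noise_sd = 0.5, negative_fraction = 0.3,
                             n_categories = 5, annotated_fraction = 0.8,
                             seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_regulatory_network(n_regulators, n_targets, density,
                                       seed = derive_seed(seed, 1))
  expr <- simulate_expression(truth, n_conditions, noise_sd,
                              seed = derive_seed(seed, 2))
  standard <- make_standard(truth, negative_fraction,
                            seed = derive_seed(seed, 3))
  annotations <- generate_annotations(truth, n_categories,
                                      annotated_fraction,
                                      seed = derive_seed(seed, 4))
  paths <- list(expression = file.path(outdir, "expression.tsv"),
                standard = file.path(outdir, "standard.tsv"),
                annotations = file.path(outdir, "annotations.tsv"),
                truth = file.path(outdir, "truth.tsv"))
  write_expression(expr, paths$expression)
  write_standard(standard, paths$standard)
  write_annotations(annotations, paths$annotations)
  data.table::fwrite(truth$edges, paths$truth, sep = "\t")
  invisible(list(paths = paths, truth = truth, expr = expr,
                 standard = standard, annotations = annotations))
}
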