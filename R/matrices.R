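#' Construct a genes-by-conditions expression matrix
#'
#' The package's canonical expression container is a plain numeric matrix
#' with genes as rows and conditions as columns; row names are gene
#' identifiers and column names are condition identifiers. A "condition" is
#' one expression profile arising from one perturbation (growth condition,
#' genotype, time point) and is the unit resampled by bagging.
#'
#' @param values numeric matrix, genes x conditions.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   existing row names).
#' @param condition_ids character vector of unique condition identifiers
#'   (defaults to existing column names, else `C1..Cn`).
#' @return a validated numeric matrix with `dimnames = list(gene_ids,
#'   condition_ids)`.
#' @export
#' @examples
#' expression_matrix(matrix(rnorm(6), 2, 3), c("g1", "g2"))
expression_matrix <- function(values, gene_ids = rownames(values),
                              condition_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(condition_ids)) {
    condition_ids <- paste0("C", seq_len(ncol(values)))
  }
  if (is.null(gene_ids)) {
    stop("gene identifiers are required", call. = FALSE)
  }
  dimnames(values) <- list(as.character(gene_ids),
                           as.character(condition_ids))
  validate_expression(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique gene and condition identifiers,
#' all entries finite, at least 2 genes and 2 conditions.
#'
#' @param expr matrix as returned by [expression_matrix()].
#' @return `expr`, invisibly; errors describe the violated invariant.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(expr)
  conds <- colnames(expr)
  if (is.null(genes) || is.null(conds)) {
    stop("expression matrix must carry gene row names and condition column names",
         call. = FALSE)
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(conds[duplicated(conds)])
  if (length(dup) > 0) {
    stop("duplicate condition identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(expr) < 2) stop("need at least 2 genes", call. = FALSE)
  if (ncol(expr) < 2) stop("need at least 2 conditions", call. = FALSE)
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', condition '%s'",
                 genes[bad[1]], conds[bad[2]]), call. = FALSE)
  }
  invisible(expr)
}

#' Validate an edge-score matrix
#'
#' A score matrix ("network") is a symmetric nonnegative gene x gene matrix
#' of edge confidences with a zero diagonal, row and column names being the
#' gene identifiers.
#'
#' @param scores numeric matrix.
#' @param tol numeric tolerance for the symmetry check.
#' @return `scores`, invisibly; errors describe the violated invariant.
#' @export
validate_scores <- function(scores, tol = 1e-8) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("scores must be a numeric matrix", call. = FALSE)
  }
  if (nrow(scores) != ncol(scores)) {
    stop("score matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(scores)) ||
      !identical(rownames(scores), colnames(scores))) {
    stop("score matrix must have identical gene row and column names",
         call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("non-finite score", call. = FALSE)
  if (any(scores < 0)) stop("negative score", call. = FALSE)
  if (any(abs(diag(scores)) > tol)) {
    stop("score matrix diagonal must be zero", call. = FALSE)
  }
  if (max(abs(scores - t(scores))) > tol) {
    stop("score matrix must be symmetric", call. = FALSE)
  }
  invisible(scores)
}

#' Construct a partial directed edge standard
#'
#' An edge standard is an incomplete ("silver") set of directed
#' regulator-to-target pairs labelled positive or negative against a declared
#' gene universe. Every pair listed in neither set is masked: evaluation
#' ignores it entirely.
#'
#' @param positives two-column character matrix (regulator, target) of known
#'   interactions.
#' @param negatives two-column character matrix of known non-interactions.
#' @param gene_universe character vector of all gene identifiers in the run
#'   (typically the expression matrix's genes).
#' @return an object of class `edge_standard`.
#' @export
edge_standard <- function(positives, negatives, gene_universe) {
  positives <- as_pair_matrix(positives)
  negatives <- as_pair_matrix(negatives)
  gene_universe <- as.character(gene_universe)
  for (pm in list(positives, negatives)) {
    if (nrow(pm) == 0) next
    if (any(pm[, 1] == pm[, 2])) {
      bad <- pm[pm[, 1] == pm[, 2], 1][1]
      stop("self-pair in standard: (", bad, ", ", bad, ")", call. = FALSE)
    }
    unknown <- setdiff(c(pm), gene_universe)
    if (length(unknown) > 0) {
      stop("standard references gene(s) outside the universe: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
  }
  pos_key <- pair_key(positives)
  neg_key <- pair_key(negatives)
  clash <- intersect(pos_key, neg_key)
  if (length(clash) > 0) {
    stop("pair(s) labelled both positive and negative: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  positives <- positives[!duplicated(pos_key), , drop = FALSE]
  negatives <- negatives[!duplicated(neg_key), , drop = FALSE]
  structure(list(positives = positives, negatives = negatives,
                 gene_universe = gene_universe),
            class = "edge_standard")
}

as_pair_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || length(x) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("regulator", "target"))))
  }
  m <- matrix(as.character(x), ncol = 2)
  colnames(m) <- c("regulator", "target")
  m
}

pair_key <- function(pm) {
  if (nrow(pm) == 0) return(character(0))
  paste(pm[, 1], pm[, 2], sep = "\r")
}

#' @export
print.edge_standard <- function(x, ...) {
  cat("Partial directed edge standard\n")
  cat(sprintf("  %d positives, %d negatives over %d genes (%d pairs masked)\n",
              nrow(x$positives), nrow(x$negatives), length(x$gene_universe),
              length(x$gene_universe) * (length(x$gene_universe) - 1) -
                nrow(x$positives) - nrow(x$negatives)))
  invisible(x)
}
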