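#' Read a tab-delimited expression matrix
#'
#' Supports the two layouts found in the wild for perturbation compendia.
#' The canonical dialect (as in the DREAM5 files) is
#' `orientation = "conditions-by-genes"`: a single header row of gene
#' identifiers followed by one numeric row per condition, with no condition
#' identifiers on disk (they are synthesized as `C1..Cn`). The transposed
#' layout, `orientation = "genes-by-conditions"`, is the classic expression
#' table: a header row of condition identifiers and one row per gene whose
#' first field is the gene identifier (an optional corner cell in the header
#' is ignored). The orientation must be given explicitly; guessing it
#' silently is a classic source of inverted analyses.
#'
#' @param path path to a tab-delimited UTF-8 text file.
#' @param orientation `"conditions-by-genes"` (default, DREAM5 dialect) or
#'   `"genes-by-conditions"`.
#' @return an expression matrix in canonical genes x conditions orientation
#'   (see [expression_matrix()]).
#' @export
read_expression <- function(path,
                            orientation = c("conditions-by-genes",
                                            "genes-by-conditions")) {
  orientation <- match.arg(orientation)
  if (orientation == "conditions-by-genes") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    genes <- colnames(dt)
    for (j in seq_along(dt)) {
      if (!is.numeric(dt[[j]])) {
        bad_row <- which(is.na(suppressWarnings(as.numeric(dt[[j]]))))[1]
        bad_row <- if (is.na(bad_row)) 1L else bad_row
        stop(sprintf("non-numeric or missing cell at condition 'C%d', gene '%s'",
                     bad_row, genes[j]), call. = FALSE)
      }
    }
    vals <- as.matrix(dt)
    check_numeric_cells(vals, genes, paste0("C", seq_len(nrow(vals))))
    expression_matrix(t(vals), gene_ids = genes,
                      condition_ids = paste0("C", seq_len(nrow(vals))))
  } else {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    dt <- data.table::fread(path, sep = "\t", header = FALSE, skip = 1L,
                            data.table = FALSE, check.names = FALSE)
    genes <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(vals) <- "numeric"
    conds <- if (length(header) == ncol(vals) + 1) header[-1] else header
    if (length(conds) != ncol(vals)) {
      stop("header has ", length(conds), " condition identifiers but rows have ",
           ncol(vals), " value columns", call. = FALSE)
    }
    check_numeric_cells(t(vals), genes = genes, conds = conds,
                        transposed = TRUE)
    expression_matrix(vals, gene_ids = genes, condition_ids = conds)
  }
}

# Locate the first non-finite cell of a conditions-x-genes value block and
# report it by row/column identifier.
check_numeric_cells <- function(vals, genes, conds, transposed = FALSE) {
  if (all(is.finite(vals))) return(invisible())
  bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
  stop(sprintf("non-numeric or missing cell at condition '%s', gene '%s'",
               conds[bad[1]], genes[bad[2]]), call. = FALSE)
}

#' Write an expression matrix to a tab-delimited file
#'
#' Inverse of [read_expression()]; the same `orientation` value round-trips.
#'
#' @inheritParams read_expression
#' @param expr genes x conditions expression matrix.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             orientation = c("conditions-by-genes",
                                             "genes-by-conditions")) {
  orientation <- match.arg(orientation)
  validate_expression(expr)
  if (orientation == "conditions-by-genes") {
    dt <- data.table::as.data.table(t(expr))
    data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  } else {
    dt <- data.table::as.data.table(expr, keep.rownames = "gene")
    data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  }
  invisible(path)
}

#' Read a partial directed edge standard
#'
#' Rows are `regulator<TAB>target<TAB>label` with label 1 (known interaction)
#' or 0 (known non-interaction). Any regulator-target pair not listed is
#' masked: downstream precision-recall evaluation never sees it. Identifiers
#' must belong to `gene_universe` (normally the genes of the expression
#' matrix); silent identifier mismatch is the dominant failure mode in
#' network benchmarking, so foreign identifiers are a hard error unless
#' `allow_extra = TRUE`, which drops those rows with a message.
#'
#' @param path path to a 3-column tab-delimited file (no header).
#' @param gene_universe character vector of valid gene identifiers.
#' @param allow_extra drop (rather than reject) rows mentioning genes outside
#'   the universe.
#' @return an [edge_standard()] object.
#' @export
read_standard <- function(path, gene_universe, allow_extra = FALSE) {
  if (file.size(path) == 0) {
    return(edge_standard(NULL, NULL, gene_universe))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE,
                          colClasses = list(character = 1:2))
  if (nrow(dt) == 0) {
    return(edge_standard(NULL, NULL, gene_universe))
  }
  if (ncol(dt) != 3) {
    stop("standard file must have 3 tab-delimited columns, found ", ncol(dt),
         call. = FALSE)
  }
  lab <- dt[[3]]
  if (!is.numeric(lab) || !all(lab %in% c(0, 1))) {
    stop("standard labels must be 0 or 1; offending value: ",
         lab[which(!(lab %in% c(0, 1)))[1]], call. = FALSE)
  }
  pairs <- cbind(dt[[1]], dt[[2]])
  foreign <- !(pairs[, 1] %in% gene_universe) |
    !(pairs[, 2] %in% gene_universe)
  if (any(foreign)) {
    if (allow_extra) {
      message("dropping ", sum(foreign),
              " standard row(s) with genes outside the universe")
      pairs <- pairs[!foreign, , drop = FALSE]
      lab <- lab[!foreign]
    } else {
      bad <- setdiff(unique(c(pairs[foreign, ])), gene_universe)
      stop("standard references gene(s) outside the universe: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  edge_standard(pairs[lab == 1, , drop = FALSE],
                pairs[lab == 0, , drop = FALSE],
                gene_universe)
}

#' Write an edge standard to a 3-column tab-delimited file
#'
#' @param standard an [edge_standard()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standard <- function(standard, path) {
  stopifnot(inherits(standard, "edge_standard"))
  dt <- data.table::data.table(
    regulator = c(standard$positives[, 1], standard$negatives[, 1]),
    target = c(standard$positives[, 2], standard$negatives[, 2]),
    label = c(rep(1L, nrow(standard$positives)),
              rep(0L, nrow(standard$negatives))))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-functional-category annotation map
#'
#' Rows are `gene<TAB>category`; a gene may repeat with different categories
#' and accumulates a category set. Genes absent from the file are treated as
#' unannotated by [feo_ratio()].
#'
#' @param path path to a 2-column tab-delimited file (no header).
#' @return a named list mapping gene id to a character vector of categories.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    stop("malformed annotation row at line ", which(nf != 2)[1],
         ": expected 2 tab-delimited fields, found ", nf[nf != 2][1],
         call. = FALSE)
  }
  genes <- vapply(fields, `[`, character(1), 1)
  cats <- vapply(fields, `[`, character(1), 2)
  lapply(split(cats, genes), function(x) sort(unique(x)))
}

#' Write an annotation map to a 2-column tab-delimited file
#'
#' @param annotations named list as returned by [read_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  genes <- rep(names(annotations), lengths(annotations))
  cats <- unlist(annotations, use.names = FALSE)
  writeLines(paste(genes, cats, sep = "\t"), path)
  invisible(path)
}

#' Write the top-scoring edges of a network as an edge list
#'
#' Emits the `top_n` strongest undirected edges, one per line as
#' `geneA<TAB>geneB<TAB>score` with scores printed to 6 significant digits,
#' in descending score order. Ties are broken deterministically by
#' lexicographic (geneA, geneB). Networks are written as edge lists, never
#' dense matrix dumps: at compendium scale (thousands of genes, millions of
#' pairs) dense text matrices are impractical.
#'
#' @param scores a symmetric score matrix (see [validate_scores()]).
#' @param path output path.
#' @param top_n number of edges to keep; must not exceed the number of
#'   distinct gene pairs.
#' @return the number of edges written, invisibly.
#' @export
write_edge_list <- function(scores, path, top_n) {
  validate_scores(scores)
  genes <- rownames(scores)
  ut <- which(upper.tri(scores), arr.ind = TRUE)
  n_avail <- nrow(ut)
  if (top_n < 1 || top_n > n_avail) {
    stop("top_n = ", top_n, " but the network has ", n_avail,
         " distinct gene pairs", call. = FALSE)
  }
  a <- genes[ut[, 1]]
  b <- genes[ut[, 2]]
  s <- scores[ut]
  ord <- order(-s, a, b)
  keep <- ord[seq_len(top_n)]
  dt <- data.table::data.table(geneA = a[keep], geneB = b[keep],
                               score = formatC(s[keep], digits = 6,
                                               format = "g"))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(top_n)
}

#' Read a 3-column edge list
#'
#' @param path path to a `geneA<TAB>geneB<TAB>score` file as written by
#'   [write_edge_list()].
#' @return a data.frame with columns `geneA`, `geneB`, `score`.
#' @export
read_edge_list <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE,
                          colClasses = list(character = 1:2))
  names(dt) <- c("geneA", "geneB", "score")
  dt
}
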