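#' Labelled cell-by-gene expression matrix
#'
#' The central container of the package: a cells x genes matrix of finite,
#' non-negative expression values (counts or normalized, on whatever scale the
#' data arrive in) together with unique cell and gene identifiers and one
#' categorical cell-type label per cell. All attack, evaluation and defense
#' functions consume and produce this class.
#'
#' The *sequencing depth* of a cell is the row sum of its expression values;
#' the trigger-embedding attack conserves it exactly (see
#' [embed_trigger()]).
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, cells in rows, genes in
#'   columns. All entries must be finite and `>= 0`.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param gene_ids character vector of unique gene identifiers, one per column.
#' @param labels character vector of per-cell cell-type labels. At least two
#'   distinct labels must be present (otherwise classification is undefined).
#'
#' @return An object of class `cell_matrix`: a list with elements `values`,
#'   `cell_ids`, `gene_ids`, `labels`.
#' @examples
#' m <- cell_matrix(matrix(0:5, 2, 3), c("c1", "c2"),
#'                  c("g1", "g2", "g3"), c("alpha", "beta"))
#' n_cells(m)
#' sequencing_depth(m)
#' @export
cell_matrix <- function(values, cell_ids, gene_ids, labels) {
  if (inherits(values, "sparseMatrix")) {
    values <- methods::as(values, "CsparseMatrix")
  } else {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
  }
  m <- structure(
    list(
      values = values,
      cell_ids = as.character(cell_ids),
      gene_ids = as.character(gene_ids),
      labels = as.character(labels)
    ),
    class = "cell_matrix"
  )
  validate_cell_matrix(m)
}

#' Validate a cell_matrix
#'
#' Checks every structural invariant: finite non-negative values, dimension
#' agreement between values, ids and labels, id uniqueness, and the presence of
#' at least two label classes. Called by [cell_matrix()]; exposed so that
#' readers and external constructors can re-validate.
#'
#' @param m a `cell_matrix`.
#' @return `m`, invisibly unchanged, or an error describing the first violated
#'   invariant (for value violations, up to the first 10 offending
#'   coordinates).
#' @export
validate_cell_matrix <- function(m) {
  stopifnot(inherits(m, "cell_matrix"))
  v <- m$values
  nr <- nrow(v)
  nc <- ncol(v)
  if (length(m$cell_ids) != nr || length(m$labels) != nr) {
    stop("cell_ids (", length(m$cell_ids), ") and labels (", length(m$labels),
         ") must both match the number of rows (", nr, ")", call. = FALSE)
  }
  if (length(m$gene_ids) != nc) {
    stop("gene_ids (", length(m$gene_ids), ") must match the number of ",
         "columns (", nc, ")", call. = FALSE)
  }
  if (anyDuplicated(m$cell_ids)) {
    stop("cell_ids must be unique; duplicated: ",
         paste(utils::head(m$cell_ids[duplicated(m$cell_ids)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(m$gene_ids)) {
    stop("gene_ids must be unique; duplicated: ",
         paste(utils::head(m$gene_ids[duplicated(m$gene_ids)], 5),
               collapse = ", "), call. = FALSE)
  }
  x <- if (inherits(v, "sparseMatrix")) v@x else v
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    coords <- .offending_coords(v, n = 10)
    stop("expression values must be finite and >= 0; offending [cell, gene] ",
         "coordinates (first ", nrow(coords), "): ",
         paste(sprintf("[%d,%d]", coords[, 1], coords[, 2]), collapse = " "),
         call. = FALSE)
  }
  if (length(unique(m$labels)) < 2) {
    stop("at least 2 distinct cell-type labels are required, found ",
         length(unique(m$labels)), call. = FALSE)
  }
  invisible(m)
}

.offending_coords <- function(v, n = 10) {
  if (inherits(v, "sparseMatrix")) v <- as.matrix(v)
  idx <- which(!is.finite(v) | v < 0, arr.ind = TRUE)
  utils::head(idx, n)
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes (", if (inherits(x$values, "sparseMatrix")) "sparse" else "dense",
      ")\n", sep = "")
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("labels: ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of cells / genes
#' @param m a `cell_matrix`.
#' @return integer count.
#' @export
n_cells <- function(m) nrow(m$values)

#' @rdname n_cells
#' @export
n_genes <- function(m) ncol(m$values)

#' Per-cell sequencing depth
#'
#' The sequencing depth of cell *i* is the sum of row *i* of the expression
#' matrix — the quantity that the trigger embedding keeps constant so that
#' poisoned cells stay concealed among benign cells.
#'
#' @param m a `cell_matrix`.
#' @return named numeric vector, one non-negative depth per cell.
#' @export
sequencing_depth <- function(m) {
  d <- Matrix::rowSums(m$values)
  names(d) <- m$cell_ids
  d
}

#' Subset cells of a cell_matrix
#'
#' Row subsetting keeps values, ids and labels aligned. Genes are never
#' subset: the gene universe is part of the classifier contract.
#'
#' @param x a `cell_matrix`.
#' @param i integer or logical cell index.
#' @param ... ignored.
#' @return a `cell_matrix` with the selected cells. Validation is not re-run:
#'   a subset may legitimately contain a single label class (e.g. one class'
#'   poisoned cells).
#' @export
`[.cell_matrix` <- function(x, i, ...) {
  structure(
    list(
      values = x$values[i, , drop = FALSE],
      cell_ids = x$cell_ids[i],
      gene_ids = x$gene_ids,
      labels = x$labels[i]
    ),
    class = "cell_matrix"
  )
}

#' Convert a cell_matrix to a tibble
#'
#' One row per cell: `cell_id`, one column per gene, then `label` — the same
#' column layout the CSV reader and writer use. Mainly for interactive
#' inspection; large matrices are better kept in matrix form.
#'
#' @param x a `cell_matrix`.
#' @param ... ignored.
#' @return a tibble with `2 + n_genes(x)` columns.
#' @export
as_tibble.cell_matrix <- function(x, ...) {
  v <- as.matrix(x$values)
  colnames(v) <- x$gene_ids
  dplyr::bind_cols(
    tibble::tibble(cell_id = x$cell_ids),
    tibble::as_tibble(v),
    tibble::tibble(label = x$labels)
  )
}

# dense numeric row of a cell (internal)
.cell_row <- function(m, i) {
  x <- m$values[i, ]
  if (inherits(x, "sparseVector") || inherits(x, "Matrix")) x <- as.numeric(x)
  as.numeric(x)
}

# TRUE when every value of the matrix is a whole number ("integer mode":
# count matrices stay count matrices through the attack)
.is_integer_mode <- function(values) {
  x <- if (inherits(values, "sparseMatrix")) values@x else values
  all(x == floor(x))
}
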