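#' Read a labelled expression matrix
#'
#' Reads a cells x genes labelled expression matrix from one of three on-disk
#' encodings:
#'
#' * `"csv"` — one file: cells as rows, first column `cell_id`, last column
#'   the label, every column in between one gene.
#' * `"mtx_dir"` — a directory in the CellRanger convention: `matrix.mtx`
#'   (MatrixMarket coordinate, genes x cells — transposed on read),
#'   `barcodes.tsv`, `features.tsv`, and a `labels.tsv` sidecar with one label
#'   per barcode in the same order.
#' * `"h5ad"` — an AnnData HDF5 file with cells as observations; the label is
#'   taken from the `obs` column named by `label_key`.
#'
#' @param path file (csv, h5ad) or directory (mtx_dir) path.
#' @param format one of `"h5ad"`, `"mtx_dir"`, `"csv"`. Defaults to a guess
#'   from the path (directory -> mtx_dir, extension otherwise).
#' @param label_key name of the per-cell annotation column holding the
#'   cell-type label (h5ad only; default `"celltype"`).
#' @return a validated [cell_matrix()]. MatrixMarket input stays sparse
#'   internally.
#' @seealso [write_cells()]
#' @export
read_cells <- function(path, format = NULL, label_key = "celltype") {
  format <- format %||% .guess_format(path)
  format <- match.arg(format, c("h5ad", "mtx_dir", "csv"))
  switch(format,
    csv = .read_cells_csv(path),
    mtx_dir = .read_cells_mtx(path),
    h5ad = .read_cells_h5ad(path, label_key)
  )
}

#' Write a labelled expression matrix
#'
#' Inverse of [read_cells()]: `read_cells(write_cells(m, p, f), f)` returns a
#' matrix equal to `m` (bit-equal values for integer counts, within 1e-9
#' relative for floats).
#'
#' @param m a [cell_matrix()].
#' @param path destination file (csv, h5ad) or directory (mtx_dir).
#' @param format one of `"h5ad"`, `"mtx_dir"`, `"csv"`.
#' @param label_key obs column name to store labels under (h5ad only).
#' @return `path`, invisibly.
#' @export
write_cells <- function(m, path, format = NULL, label_key = "celltype") {
  validate_cell_matrix(m)
  format <- format %||% .guess_format(path)
  format <- match.arg(format, c("h5ad", "mtx_dir", "csv"))
  parent <- dirname(path)
  if (!dir.exists(parent)) {
    stop("cannot write '", path, "': directory '", parent, "' does not exist",
         call. = FALSE)
  }
  switch(format,
    csv = .write_cells_csv(m, path),
    mtx_dir = .write_cells_mtx(m, path),
    h5ad = .write_cells_h5ad(m, path, label_key)
  )
  invisible(path)
}

.guess_format <- function(path) {
  if (dir.exists(path) || !nzchar(tools::file_ext(path))) return("mtx_dir")
  switch(tolower(tools::file_ext(path)),
    csv = "csv",
    h5ad = "h5ad",
    stop("cannot guess format of '", path,
         "'; pass format = \"csv\", \"mtx_dir\" or \"h5ad\"", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- CSV ----

.read_cells_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 4) {
    stop("CSV must have cell_id, >= 2 gene columns, and a final label column",
         call. = FALSE)
  }
  gene_cols <- 2:(ncol(df) - 1)
  values <- as.matrix(df[, gene_cols])
  cell_matrix(values,
              cell_ids = df[[1]],
              gene_ids = names(df)[gene_cols],
              labels = df[[ncol(df)]])
}

.write_cells_csv <- function(m, path) {
  readr::write_csv(as_tibble.cell_matrix(m), path, progress = FALSE)
}

## ---- MTX directory ----

.read_cells_mtx <- function(path) {
  files <- file.path(path, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                             "labels.tsv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("MTX directory is missing: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  mm <- Matrix::readMM(files[1])      # genes x cells on disk
  barcodes <- readr::read_tsv(files[2], col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)[[1]]
  features <- readr::read_tsv(files[3], col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)[[1]]
  labels <- readr::read_tsv(files[4], col_names = FALSE,
                            show_col_types = FALSE, progress = FALSE)[[1]]
  if (length(labels) != length(barcodes)) {
    stop("labels.tsv has ", length(labels), " rows but barcodes.tsv has ",
         length(barcodes), call. = FALSE)
  }
  cell_matrix(Matrix::t(mm), cell_ids = barcodes, gene_ids = features,
              labels = labels)
}

.write_cells_mtx <- function(m, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  sp <- methods::as(methods::as(m$values, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(Matrix::t(sp), file.path(path, "matrix.mtx"))
  writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  writeLines(m$gene_ids, file.path(path, "features.tsv"))
  writeLines(m$labels, file.path(path, "labels.tsv"))
}

## ---- H5AD ----
## Minimal AnnData-on-HDF5 encoding: dense X (cells x genes), obs/var groups
## with _index and (for obs) the label column as an HDF5 string dataset.
## anndata stores X row-major; rhdf5 writes column-major, so X is written
## transposed (genes x cells on disk reads back cells x genes in anndata's
## row-major view).

.read_cells_h5ad <- function(path, label_key) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::H5close(), add = TRUE)
  x <- rhdf5::h5read(path, "X")
  obs_names <- as.character(rhdf5::h5read(path, "obs/_index"))
  var_names <- as.character(rhdf5::h5read(path, "var/_index"))
  contents <- rhdf5::h5ls(path)
  obs_cols <- contents$name[contents$group == "/obs" & contents$name != "_index"]
  if (!label_key %in% obs_cols) {
    stop("label column '", label_key, "' not found in obs; available: ",
         paste(obs_cols, collapse = ", "), call. = FALSE)
  }
  labels <- rhdf5::h5read(path, paste0("obs/", label_key), read.attributes = TRUE)
  if (is.list(labels) && !is.null(labels$categories)) {
    labels <- as.character(labels$categories)[as.integer(labels$codes) + 1L]
  }
  labels <- as.character(labels)
  # X on disk is genes x cells (see writer); transpose back
  if (nrow(x) == length(var_names) && ncol(x) == length(obs_names)) {
    x <- t(x)
  }
  cell_matrix(x, cell_ids = obs_names, gene_ids = var_names, labels = labels)
}

.write_cells_h5ad <- function(m, path, label_key) {
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE, after = FALSE)

  # transposed so anndata's row-major read sees cells x genes
  rhdf5::h5write(t(as.matrix(m$values)), h5, "X")
  .h5_attr(h5, "X", "encoding-type", "array")
  .h5_attr(h5, "X", "encoding-version", "0.2.0")

  for (grp in c("obs", "var")) rhdf5::h5createGroup(h5, grp)
  rhdf5::h5write(m$cell_ids, h5, "obs/_index")
  rhdf5::h5write(m$labels, h5, paste0("obs/", label_key))
  rhdf5::h5write(m$gene_ids, h5, "var/_index")
  for (ds in c("obs/_index", paste0("obs/", label_key), "var/_index")) {
    .h5_attr(h5, ds, "encoding-type", "string-array")
    .h5_attr(h5, ds, "encoding-version", "0.2.0")
  }
  for (grp in c("obs", "var")) {
    .h5_attr(h5, grp, "encoding-type", "dataframe")
    .h5_attr(h5, grp, "encoding-version", "0.2.0")
    .h5_attr(h5, grp, "_index", "_index")
  }
  # column-order must be a string *array*, not a scalar
  .h5_attr(h5, "obs", "column-order", label_key, scalar = FALSE)
  .h5_attr(h5, "var", "column-order", "_index", scalar = FALSE)
}

.h5_attr <- function(h5, name, attr, value, scalar = TRUE) {
  obj <- rhdf5::H5Oopen(h5, name)
  on.exit(rhdf5::H5Oclose(obj))
  rhdf5::h5writeAttribute(value, obj, attr, asScalar = scalar)
}
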