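# Domain types. Value-level contracts: matrices may be dense base matrices
# or Matrix sparse matrices; all invariants are checked on construction.

#' Construct a labeled single-cell expression dataset
#'
#' The in-memory stand-in for an annotated scRNA-seq corpus: a cells x genes
#' count matrix with per-cell type labels, unique uppercase gene symbols,
#' unique cell identifiers, and optional spatial coordinates.
#'
#' @param counts non-negative cells x genes matrix of transcript counts.
#' @param gene_symbols character vector of gene symbols (uppercased and
#'   required unique after uppercasing).
#' @param cell_types character vector of per-cell labels, length `nrow(counts)`.
#' @param cell_ids optional unique cell identifiers; defaults to
#'   `cell_1 ... cell_n`.
#' @param coords optional n x 2 matrix of (x, y) positions in micrometres.
#' @return an object of class `sc_dataset`.
#' @export
sc_dataset <- function(counts, gene_symbols, cell_types,
                       cell_ids = NULL, coords = NULL) {
  counts <- if (inherits(counts, "Matrix")) counts else as.matrix(counts)
  n <- nrow(counts); g <- ncol(counts)
  gene_symbols <- toupper(as.character(gene_symbols))
  if (length(gene_symbols) != g)
    abort("gene_symbols length does not match gene axis", "cellmixr_type_error")
  if (anyDuplicated(gene_symbols))
    abort("duplicate gene symbols after uppercase normalization",
          "cellmixr_type_error")
  if (length(cell_types) != n)
    abort("cell_types length does not match cell axis", "cellmixr_type_error")
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  if (length(vals) && (any(!is.finite(vals)) || min(vals) < 0))
    abort("counts must be finite and non-negative", "cellmixr_type_error")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n || anyDuplicated(cell_ids))
    abort("cell_ids must be unique and match the cell axis",
          "cellmixr_type_error")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2L || any(!is.finite(coords)))
      abort("coords must be a finite n x 2 matrix", "cellmixr_type_error")
    colnames(coords) <- c("x", "y")
  }
  dimnames(counts) <- list(cell_ids, gene_symbols)
  structure(
    list(counts = counts, gene_symbols = gene_symbols,
         cell_types = as.character(cell_types), cell_ids = cell_ids,
         coords = coords),
    class = "sc_dataset"
  )
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("<sc_dataset> %d cells x %d genes, %d cell types%s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types)),
              if (is.null(x$coords)) "" else ", spatial"))
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

#' Construct the catalog of model output cell types
#'
#' The ordered, unique list of cell-type names defining the network's output
#' axis. The order is canonical and is persisted with every checkpoint.
#'
#' @param type_names character vector of unique cell-type names.
#' @return an object of class `cell_type_catalog`.
#' @export
cell_type_catalog <- function(type_names) {
  type_names <- as.character(type_names)
  if (length(type_names) == 0L || anyDuplicated(type_names))
    abort("catalog names must be non-empty and unique", "cellmixr_type_error")
  structure(list(type_names = type_names,
                 index = stats::setNames(seq_along(type_names), type_names)),
            class = "cell_type_catalog")
}

#' @export
length.cell_type_catalog <- function(x) length(x$type_names)

#' @export
print.cell_type_catalog <- function(x, ...) {
  cat(sprintf("<cell_type_catalog> %d types: %s%s\n", length(x),
              paste(head(x$type_names, 5), collapse = ", "),
              if (length(x) > 5) ", ..." else ""))
  invisible(x)
}

#' Construct a mixture specification
#'
#' One pseudobulk draw plan: total cell count `T`, number of distinct types
#' `N`, the chosen catalog types and their target fraction ratios (summing
#' to 1).
#'
#' @param total_cells integer total cells in the mixture (the draw `T`).
#' @param types character vector of `N` catalog names.
#' @param fractions numeric vector of target fraction ratios, same length.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(total_cells, types, fractions) {
  total_cells <- as.integer(total_cells)
  if (total_cells < 1L) abort("total_cells must be >= 1", "cellmixr_type_error")
  if (length(types) != length(fractions) || length(types) < 1L)
    abort("types and fractions must have equal positive length",
          "cellmixr_type_error")
  if (anyDuplicated(types)) abort("types must be unique", "cellmixr_type_error")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-12)
    abort("fractions must be >= 0 and sum to 1 within 1e-12",
          "cellmixr_type_error")
  structure(list(total_cells = total_cells, n_types = length(types),
                 types = as.character(types), fractions = as.numeric(fractions)),
            class = "mixture_spec")
}

#' Construct a batch of realized pseudobulk mixtures
#'
#' @param X mixtures x genes expression matrix (mean of depth-log-normalized
#'   member profiles).
#' @param Y mixtures x catalog realized ground-truth fraction matrix; rows on
#'   the simplex.
#' @param catalog the [cell_type_catalog] defining `Y`'s column order.
#' @param specs list of the [mixture_spec]s that produced each row.
#' @return an object of class `mixture_batch`.
#' @export
mixture_batch <- function(X, Y, catalog, specs) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y row mismatch", "cellmixr_type_error")
  if (ncol(Y) != length(catalog))
    abort("Y width must equal catalog size", "cellmixr_type_error")
  if (any(!is.finite(X))) abort("X must be finite", "cellmixr_type_error")
  if (any(Y < 0) || any(abs(rowSums(Y) - 1) > 1e-9))
    abort("Y rows must be non-negative and sum to 1 within 1e-9",
          "cellmixr_type_error")
  colnames(Y) <- catalog$type_names
  structure(list(X = X, Y = Y, catalog = catalog, specs = specs),
            class = "mixture_batch")
}

#' @export
print.mixture_batch <- function(x, ...) {
  cat(sprintf("<mixture_batch> %d mixtures x %d genes, %d catalog types\n",
              nrow(x$X), ncol(x$X), length(x$catalog)))
  invisible(x)
}

#' Construct a deconvolution result
#'
#' @param fractions samples x catalog matrix of predicted fractions; every
#'   row lies on the simplex (entries in `[0, 1]`, summing to 1 within 1e-5).
#' @param catalog the [cell_type_catalog] for the columns.
#' @param sample_ids character sample identifiers.
#' @return an object of class `deconvolution_result`.
#' @export
deconvolution_result <- function(fractions, catalog, sample_ids = NULL) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != length(catalog))
    abort("fraction width must equal catalog size", "cellmixr_type_error")
  if (any(fractions < -1e-9) || any(fractions > 1 + 1e-9) ||
      any(abs(rowSums(fractions) - 1) > 1e-5))
    abort("fraction rows must lie on the simplex (sum 1 within 1e-5)",
          "cellmixr_type_error")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(fractions)))
  dimnames(fractions) <- list(sample_ids, catalog$type_names)
  structure(list(fractions = fractions, catalog = catalog,
                 sample_ids = as.character(sample_ids)),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> %d samples x %d cell types\n",
              nrow(x$fractions), length(x$catalog)))
  invisible(x)
}
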