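# Readers and writers for the standard matrix formats (dense CSV/TSV,
# 10x-style MTX triplet, minimal H5AD), the ontology edge list, and model
# checkpoints. Gene identity throughout is the uppercase symbol string;
# duplicates after uppercasing collapse by sum with a warning.

collapse_duplicate_genes <- function(counts, gene_symbols) {
  gene_symbols <- toupper(gene_symbols)
  if (!anyDuplicated(gene_symbols)) {
    return(list(counts = counts, gene_symbols = gene_symbols))
  }
  warning("duplicate gene symbols after uppercasing; collapsing by sum",
          call. = FALSE)
  f <- factor(gene_symbols, levels = unique(gene_symbols))
  # rowsum on the transposed matrix sums cells of duplicated genes
  collapsed <- t(rowsum(t(as_dense(counts)), group = f))
  list(counts = collapsed, gene_symbols = levels(f))
}

#' Read a labeled expression matrix from disk
#'
#' Supports dense CSV/TSV (one header row, one index column), the 10x-style
#' MatrixMarket triplet (`matrix.mtx` + `features.tsv` + `barcodes.tsv`),
#' and a minimal H5AD layout (dense or CSR `X`, `obs`/`var` index, labels
#' under an observation key). Orientation is corrected to cells x genes;
#' gene symbols are uppercased, duplicates collapsed by sum.
#'
#' @param path file path (for `mtx`, the `.mtx` file; sibling TSVs are
#'   discovered next to it).
#' @param format one of `"csv"`, `"mtx"`, `"h5ad"`.
#' @param label_key for H5AD, the `obs` column holding cell-type labels
#'   (default `"cell_type"`); for CSV/MTX, labels come from `labels` or a
#'   second barcode column.
#' @param genes_as for CSV: `"columns"`, `"rows"`, or `"auto"`; auto follows
#'   the tidy convention (rows are cells, columns are genes).
#' @param labels optional character vector of per-cell labels overriding any
#'   labels found in the file.
#' @param require_labels error if no labels can be found.
#' @return an [sc_dataset].
#' @export
read_expression <- function(path, format = c("csv", "mtx", "h5ad"),
                            label_key = "cell_type",
                            genes_as = c("auto", "columns", "rows"),
                            labels = NULL, require_labels = FALSE) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       sprintf("unknown expression format '%s'", format[1]),
                       "cellmixr_format_error"))
  genes_as <- match.arg(genes_as)
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "cellmixr_io_error")
  out <- switch(format,
    csv = read_expression_csv(path, genes_as),
    mtx = read_expression_mtx(path),
    h5ad = read_expression_h5ad(path, label_key))
  if (!is.null(labels)) out$labels <- as.character(labels)
  if (require_labels && is.null(out$labels))
    abort("cell-type labels required but none found (set label_key/labels)",
          "cellmixr_label_error")
  cg <- collapse_duplicate_genes(out$counts, out$genes)
  sc_dataset(cg$counts, cg$gene_symbols,
             cell_types = out$labels %||% rep(NA_character_, nrow(cg$counts)),
             cell_ids = out$cells, coords = out$coords)
}

read_expression_csv <- function(path, genes_as) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (genes_as == "auto") genes_as <- "columns"
  if (genes_as == "rows") m <- t(m)
  list(counts = m, genes = colnames(m), cells = rownames(m),
       labels = NULL, coords = NULL)
}

find_sibling <- function(mtx_path, stems) {
  dir <- dirname(mtx_path)
  for (s in stems) {
    for (ext in c(".tsv", ".txt", ".csv")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

read_expression_mtx <- function(path) {
  gpath <- find_sibling(path, c("features", "genes"))
  bpath <- find_sibling(path, c("barcodes", "cells"))
  if (is.null(gpath) || is.null(bpath))
    abort("mtx requires sibling features/genes and barcodes/cells TSVs",
          "cellmixr_io_error")
  m <- Matrix::readMM(path)
  gtab <- read.delim(gpath, header = FALSE, stringsAsFactors = FALSE)
  btab <- read.delim(bpath, header = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(gtab[[min(2L, ncol(gtab))]])  # 10x: id, symbol
  if (nrow(gtab) != nrow(m) && nrow(gtab) == ncol(m)) {
    # already cells x genes
  } else {
    m <- Matrix::t(m)  # 10x writes genes x cells
  }
  if (nrow(gtab) != ncol(m) || nrow(btab) != nrow(m))
    abort("mtx dimensions do not match features/barcodes", "cellmixr_io_error")
  labels <- if (ncol(btab) >= 2L) as.character(btab[[2L]]) else NULL
  list(counts = as_dense(m), genes = genes, cells = as.character(btab[[1L]]),
       labels = labels, coords = NULL)
}

h5_exists <- function(path, name) {
  contents <- rhdf5::h5ls(path)
  full <- file.path(contents$group, contents$name)
  full <- sub("^//", "/", full)
  name %in% full
}

h5_read_frame_column <- function(path, name) {
  # AnnData encodes string columns either directly or as categorical groups
  obj <- rhdf5::h5read(path, name)
  if (is.list(obj) && all(c("categories", "codes") %in% names(obj))) {
    codes <- as.integer(obj$codes)
    out <- as.character(obj$categories)[codes + 1L]
    out[codes < 0L] <- NA_character_
    return(out)
  }
  as.character(obj)
}

read_expression_h5ad <- function(path, label_key) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_tab <- rhdf5::h5ls(path)
  full <- sub("^//", "/", file.path(ls_tab$group, ls_tab$name))
  x_is_group <- any(full == "/X/data")
  if (x_is_group) {
    data <- as.numeric(rhdf5::h5read(path, "/X/data"))
    indices <- as.integer(rhdf5::h5read(path, "/X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "/X/indptr"))
    attrs <- rhdf5::h5readAttributes(path, "/X")
    shape <- as.integer(attrs[["shape"]])
    enc <- as.character(attrs[["encoding-type"]] %||% "csr_matrix")
    if (grepl("csr", enc)) {
      m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                                dims = rev(shape))
      m <- Matrix::t(m)  # build as transpose then flip: rows are cells
    } else {
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = shape)
    }
    m <- as_dense(m)
  } else {
    m <- rhdf5::h5read(path, "/X")
    # HDF5 is row-major; rhdf5 returns the transposed array for C-written files
    m <- t(as_dense(m))
  }
  var_idx <- as.character(rhdf5::h5read(path, "/var/_index"))
  obs_idx <- as.character(rhdf5::h5read(path, "/obs/_index"))
  if (nrow(m) == length(var_idx) && ncol(m) == length(obs_idx)) m <- t(m)
  labels <- NULL
  key <- paste0("/obs/", label_key)
  if (any(full == key) || any(full == paste0(key, "/codes")))
    labels <- h5_read_frame_column(path, key)
  coords <- NULL
  if (any(full == "/obsm/spatial")) {
    coords <- t(as_dense(rhdf5::h5read(path, "/obsm/spatial")))
    if (ncol(coords) != 2L) coords <- t(coords)
  }
  list(counts = m, genes = var_idx, cells = obs_idx, labels = labels,
       coords = coords)
}

#' Write a dataset to a minimal H5AD file
#'
#' Dense `X` (cells x genes), `obs` with the cell index and a `cell_type`
#' column, `var` with the gene index, and `obsm/spatial` when coordinates
#' are present. Round-trips exactly through [read_expression].
#'
#' @param ds an [sc_dataset].
#' @param path output path; overwritten if present.
#' @param label_key name of the obs column to store labels under.
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(ds, path, label_key = "cell_type") {
  stopifnot(inherits(ds, "sc_dataset"))
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  # store transposed so that C-order readers see cells x genes
  rhdf5::h5write(t(as_dense(ds$counts)), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(ds$cell_ids, path, "obs/_index")
  rhdf5::h5write(ds$cell_types, path, paste0("obs/", label_key))
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(ds$gene_symbols, path, "var/_index")
  if (!is.null(ds$coords)) {
    rhdf5::h5createGroup(path, "obsm")
    rhdf5::h5write(t(ds$coords), path, "obsm/spatial")
  }
  invisible(path)
}

#' Write a dataset as an MTX triplet
#'
#' @param ds an [sc_dataset].
#' @param dir output directory (created if needed); writes `matrix.mtx`
#'   (genes x cells, 10x convention), `features.tsv`, `barcodes.tsv` (with
#'   labels in the second column).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(ds, dir) {
  stopifnot(inherits(ds, "sc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(as_dense(ds$counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = ds$gene_symbols, symbol = ds$gene_symbols),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(ds$cell_ids, ds$cell_types),
              file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

# ---- ontology ----------------------------------------------------------

#' Read a cell-type ontology from a child-parent edge list
#'
#' Input is a two-column TSV of `child<TAB>parent` lines describing is-a
#' relationships (a Cell Ontology subset, user-supplied). The graph must be
#' a DAG; duplicate edges are dropped with a warning, self-loops and cycles
#' are errors.
#'
#' @param path TSV path, or a two-column data frame of edges.
#' @return an object of class `ontology_graph` with fields `nodes`, `edges`
#'   (data frame child/parent), and the backing igraph object.
#' @export
read_ontology <- function(path) {
  edges <- if (is.data.frame(path)) {
    stats::setNames(path[, 1:2], c("child", "parent"))
  } else {
    if (!file.exists(path))
      abort(sprintf("file not found: %s", path), "cellmixr_io_error")
    read.delim(path, header = FALSE, col.names = c("child", "parent"),
               stringsAsFactors = FALSE)
  }
  edges$child <- trimws(as.character(edges$child))
  edges$parent <- trimws(as.character(edges$parent))
  if (any(!nzchar(edges$child)) || any(!nzchar(edges$parent)))
    abort("ontology names must be non-empty", "cellmixr_ontology_error")
  if (any(edges$child == edges$parent))
    abort(sprintf("self-loop on node '%s'",
                  edges$child[edges$child == edges$parent][1]),
          "cellmixr_ontology_error")
  dup <- duplicated(paste(edges$child, edges$parent, sep = "\r"))
  if (any(dup)) {
    warning("duplicate ontology edges deduplicated", call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    # name one member of a cycle for the error message
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)][1]
    if (is.na(bad)) bad <- edges$child[1]
    abort(sprintf("ontology contains a cycle through '%s'", bad),
          "cellmixr_ontology_error")
  }
  structure(list(nodes = igraph::V(g)$name, edges = edges, graph = g),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Topological order of an ontology (children before parents)
#'
#' @param g an `ontology_graph`.
#' @return character vector of node names in a valid topological order of
#'   the child-to-parent edges.
#' @export
topological_order <- function(g) {
  stopifnot(inherits(g, "ontology_graph"))
  igraph::V(g$graph)$name[igraph::topo_sort(g$graph, mode = "out")]
}

# ---- checkpoints -------------------------------------------------------

#' Save a deconvolution model checkpoint
#'
#' A checkpoint is a directory holding `weights.h5` (one HDF5 dataset per
#' layer weight/bias, float64 so the round trip is bit-identical) and
#' `config.json` (layer sizes, catalog, normalization settings, seed;
#' schema versioned).
#'
#' @param model a `deconv_model`.
#' @param path checkpoint directory (created).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "deconv_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wpath <- file.path(path, "weights.h5")
  if (file.exists(wpath)) unlink(wpath)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(wpath)
  for (i in seq_along(model$weights)) {
    rhdf5::h5write(model$weights[[i]]$W, wpath, sprintf("W%d", i))
    rhdf5::h5write(model$weights[[i]]$b, wpath, sprintf("b%d", i))
  }
  cfg <- model$config
  doc <- list(schema = 1L,
              n_genes = cfg$n_genes, hidden = cfg$hidden,
              n_outputs = cfg$n_outputs, activation = cfg$activation,
              noise_sigma = cfg$noise_sigma,
              input_dropout = cfg$input_dropout,
              seed = cfg$seed,
              gene_symbols = model$gene_symbols,
              catalog = model$catalog$type_names)
  jsonlite::write_json(doc, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a deconvolution model checkpoint
#'
#' @param path checkpoint directory written by [save_checkpoint].
#' @return a `deconv_model` whose predictions on any probe input are
#'   bit-identical to the saved model's.
#' @export
load_checkpoint <- function(path) {
  cpath <- file.path(path, "config.json")
  wpath <- file.path(path, "weights.h5")
  if (!file.exists(cpath) || !file.exists(wpath))
    abort("checkpoint directory must contain config.json and weights.h5",
          "cellmixr_checkpoint_error")
  doc <- tryCatch(jsonlite::read_json(cpath, simplifyVector = TRUE),
                  error = function(e) abort("unreadable checkpoint config",
                                            "cellmixr_checkpoint_error"))
  cfg <- model_config(n_genes = doc$n_genes, hidden = doc$hidden,
                      n_outputs = doc$n_outputs,
                      noise_sigma = doc$noise_sigma,
                      input_dropout = doc$input_dropout, seed = doc$seed)
  model <- build_model(cfg, catalog = cell_type_catalog(doc$catalog),
                       gene_symbols = doc$gene_symbols)
  sizes <- c(cfg$n_genes, cfg$hidden, cfg$n_outputs)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (i in seq_along(model$weights)) {
    W <- tryCatch(as_dense(rhdf5::h5read(wpath, sprintf("W%d", i))),
                  error = function(e) abort(
                    "checkpoint weights unreadable or truncated",
                    "cellmixr_checkpoint_error"))
    b <- tryCatch(as.numeric(rhdf5::h5read(wpath, sprintf("b%d", i))),
                  error = function(e) abort(
                    "checkpoint weights unreadable or truncated",
                    "cellmixr_checkpoint_error"))
    if (!all(dim(W) == c(sizes[i], sizes[i + 1])) ||
        length(b) != sizes[i + 1])
      abort(sprintf("checkpoint weight shape mismatch in layer %d", i),
            "cellmixr_checkpoint_error")
    model$weights[[i]] <- list(W = W, b = b)
  }
  model
}
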