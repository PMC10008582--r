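# Quality control, depth-log normalization of single cells, the model's
# per-input 4-step normalization, and the training-time corruption operator.

#' Quality-control thresholds for single-cell filtering
#'
#' @param min_counts minimum total counts per cell (cells below are removed).
#' @param min_cells_per_gene minimum number of cells a gene must be
#'   expressed in.
#' @param max_mito_frac maximum mitochondrial read fraction per cell.
#' @param depth_sd_mult cells whose log total counts exceed the mean by more
#'   than this many standard deviations of log total counts are removed as
#'   damaged outliers.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return a `qc_params` list.
#' @export
qc_params <- function(min_counts = 200, min_cells_per_gene = 3,
                      max_mito_frac = 0.20, depth_sd_mult = 2.0,
                      mito_prefix = "MT-") {
  if (min_counts <= 0 || min_cells_per_gene <= 0 || depth_sd_mult <= 0)
    abort("QC thresholds must be positive", "cellmixr_config_error")
  if (max_mito_frac <= 0 || max_mito_frac > 1)
    abort("max_mito_frac must lie in (0, 1]", "cellmixr_config_error")
  structure(list(min_counts = min_counts,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 max_mito_frac = max_mito_frac,
                 depth_sd_mult = depth_sd_mult,
                 mito_prefix = toupper(mito_prefix)),
            class = "qc_params")
}

#' Filter cells and genes on quality control rules
#'
#' Applies, in order: (1) cells with total counts below `min_counts`;
#' (2) genes expressed in fewer than `min_cells_per_gene` remaining cells;
#' (3) cells whose mitochondrial read fraction exceeds `max_mito_frac`;
#' (4) depth outliers, cells with `log(total) > mean + depth_sd_mult * SD`
#' of log total counts across remaining cells. Idempotent.
#'
#' @param ds an [sc_dataset] of raw counts.
#' @param qc a [qc_params].
#' @return the filtered [sc_dataset].
#' @export
qc_filter <- function(ds, qc = qc_params()) {
  stopifnot(inherits(ds, "sc_dataset"), inherits(qc, "qc_params"))
  counts <- as_dense(ds$counts)
  removed <- c(low_count = 0L, gene = 0L, mito = 0L, depth = 0L)

  keep_cells <- rowSums(counts) >= qc$min_counts
  removed["low_count"] <- sum(!keep_cells)
  counts <- counts[keep_cells, , drop = FALSE]

  keep_genes <- colSums(counts > 0) >= qc$min_cells_per_gene
  removed["gene"] <- sum(!keep_genes)
  counts <- counts[, keep_genes, drop = FALSE]

  genes <- ds$gene_symbols[keep_genes]
  mito <- startsWith(genes, qc$mito_prefix)
  tot <- rowSums(counts)
  mfrac <- if (any(mito)) rowSums(counts[, mito, drop = FALSE]) /
    pmax(tot, 1) else rep(0, nrow(counts))
  keep_mito <- mfrac <= qc$max_mito_frac
  removed["mito"] <- sum(!keep_mito)
  counts <- counts[keep_mito, , drop = FALSE]

  tot <- rowSums(counts)
  if (nrow(counts) > 1 && all(tot > 0)) {
    lt <- log(tot)
    keep_depth <- lt <= mean(lt) + qc$depth_sd_mult * stats::sd(lt)
  } else keep_depth <- rep(TRUE, nrow(counts))
  removed["depth"] <- sum(!keep_depth)
  counts <- counts[keep_depth, , drop = FALSE]

  if (nrow(counts) == 0L || ncol(counts) == 0L)
    abort(paste0("QC removed everything (removed: ",
                 paste(names(removed), removed, sep = "=", collapse = ", "),
                 ")"), "cellmixr_qc_error")

  kept <- ds$cell_ids %in% rownames(counts)
  sc_dataset(counts, genes, ds$cell_types[kept],
             cell_ids = ds$cell_ids[kept],
             coords = if (is.null(ds$coords)) NULL else
               ds$coords[kept, , drop = FALSE])
}

#' Depth-normalize and log-transform a count matrix
#'
#' Every cell's counts are scaled to `target` total counts and transformed
#' with `log(1 + x)`. This is the representation in which single-cell
#' profiles are averaged into pseudobulk mixtures.
#'
#' @param counts non-negative cells x genes matrix; all row totals must be
#'   positive.
#' @param target per-cell total after scaling (default 10,000).
#' @return the normalized matrix (same shape, finite).
#' @export
depth_log_normalize <- function(counts, target = 10000) {
  counts <- as_dense(counts)
  tot <- rowSums(counts)
  if (any(tot <= 0)) {
    bad <- rownames(counts)[which(tot <= 0)[1]] %||% which(tot <= 0)[1]
    abort(sprintf("cell '%s' has zero total counts", bad),
          "cellmixr_normalize_error")
  }
  log1p(counts * (target / tot))
}

#' Depth-log-normalize a dataset in place
#'
#' @param ds an [sc_dataset] of raw counts.
#' @param target per-cell total after scaling.
#' @return the dataset with `counts` replaced by normalized values.
#' @export
normalize_dataset <- function(ds, target = 10000) {
  stopifnot(inherits(ds, "sc_dataset"))
  ds$counts <- depth_log_normalize(ds$counts, target)
  ds
}

#' Per-input model normalization (4 steps)
#'
#' The normalization applied to every vector entering the network: counts
#' are scaled to 10,000, log2(1 + x)-transformed, z-scored across genes
#' (population SD), and min-max rescaled to `[0, 1]`. Constant vectors map
#' to all zeros. Because the z-score removes any linear rescaling, inputs
#' already log-transformed in any base normalize identically.
#'
#' @param x numeric vector (length G) or samples x genes matrix.
#' @param already_log `TRUE` if `x` is already depth-normalized log
#'   expression (skips the first two steps).
#' @return object of the same shape with values in `[0, 1]`.
#' @export
model_normalize <- function(x, already_log = FALSE) {
  if (is.matrix(x)) {
    if (any(!is.finite(x)))
      abort("input contains NaN or infinite values", "cellmixr_input_error")
    return(t(apply(x, 1L, model_normalize_vec, already_log = already_log)))
  }
  model_normalize_vec(x, already_log)
}

model_normalize_vec <- function(x, already_log) {
  if (any(!is.finite(x)))
    abort("input contains NaN or infinite values", "cellmixr_input_error")
  if (!already_log) {
    if (any(x < 0))
      abort("raw counts must be non-negative", "cellmixr_input_error")
    s <- sum(x)
    if (s > 0) x <- x * (10000 / s)
    x <- log2(1 + x)
  }
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))  # population SD
  if (sdev == 0) return(rep(0, length(x)))
  z <- (x - mu) / sdev
  (z - min(z)) / (max(z) - min(z))
}

#' Training-time input corruption
#'
#' Adds i.i.d. zero-mean Gaussian noise (SD `noise_sigma` on the unit
#' scale) to every entry, then masks each entry to zero independently with
#' probability `dropout`. No inverse rescaling is applied to survivors
#' unless `inverted = TRUE`.
#'
#' @param x unit-scaled numeric vector or matrix.
#' @param noise_sigma Gaussian noise SD (default 0.05 of full scale).
#' @param dropout masking probability in `[0, 1)`.
#' @param inverted rescale survivors by `1 / (1 - dropout)` (off by
#'   default).
#' @param seed optional integer seed for reproducible corruption.
#' @return corrupted object of the same shape.
#' @export
corrupt <- function(x, noise_sigma = 0.05, dropout = 0.20,
                    inverted = FALSE, seed = NULL) {
  if (dropout < 0 || dropout >= 1)
    abort("dropout must lie in [0, 1)", "cellmixr_config_error")
  with_rng(seed, {
    n <- length(x)
    if (noise_sigma > 0) x <- x + rnorm(n, 0, noise_sigma)
    if (dropout > 0) {
      mask <- runif(n) >= dropout
      x <- x * mask
      if (inverted) x <- x / (1 - dropout)
    }
    x
  })
}
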