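# Scoring with Lin's concordance correlation coefficient, per-type
# benchmark tables, sensitivity sweeps over mixing hyperparameters and
# input gene dropout, and spatial downsampling with known ground truth.

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Unlike Pearson's r it penalizes location and
#' scale shifts, so a biased predictor cannot score 1. Degenerate inputs:
#' both constant with equal means gives 1 (defined limit); constant on
#' exactly one side (or constant with unequal means the formula handles)
#' gives 0 when the denominator vanishes.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param sample_moments use 1/(n-1) moments instead (differences vanish
#'   at benchmark n).
#' @return scalar in `[-1, 1]`.
#' @export
ccc <- function(x, y, sample_moments = FALSE) {
  if (length(x) != length(y) || length(x) < 2L)
    abort("ccc needs two equal-length vectors of length >= 2",
          "cellmixr_argument_error")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("ccc inputs must be finite", "cellmixr_argument_error")
  n <- length(x)
  denom_n <- if (sample_moments) n - 1 else n
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / denom_n
  vy <- sum((y - my)^2) / denom_n
  cxy <- sum((x - mx) * (y - my)) / denom_n
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(1)  # both constant, equal means: perfect concordance
  2 * cxy / den
}

#' Per-cell-type benchmark table
#'
#' Computes Lin's CCC across samples between predicted and true fraction
#' columns for every cell type present in both. Degenerate columns (zero
#' variance on both sides with equal means report 1; zero variance on one
#' side reports the formula value, typically 0) are flagged.
#'
#' @param pred a [deconvolution_result] or samples x types matrix with
#'   column names.
#' @param truth samples x types true fraction matrix with column names.
#' @return data frame with columns `cell_type`, `ccc`, `degenerate`;
#'   attribute `mean_ccc` holds the summary mean.
#' @export
benchmark_fractions <- function(pred, truth) {
  P <- if (inherits(pred, "deconvolution_result")) pred$fractions
       else as.matrix(pred)
  truth <- as.matrix(truth)
  if (nrow(P) != nrow(truth))
    abort("prediction and truth sample counts differ",
          "cellmixr_argument_error")
  if (nrow(P) < 2L)
    abort("benchmark needs at least 2 samples", "cellmixr_argument_error")
  common <- intersect(colnames(P), colnames(truth))
  if (length(common) < ncol(truth))
    warning("cell types missing from prediction or truth were skipped",
            call. = FALSE)
  rows <- lapply(common, function(ct) {
    x <- truth[, ct]; y <- P[, ct]
    degen <- (stats::sd(x) == 0) || (stats::sd(y) == 0)
    data.frame(cell_type = ct, ccc = ccc(x, y), degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_ccc") <- mean(out$ccc)
  out
}

#' Mean CCC of a benchmark table
#'
#' @param table result of [benchmark_fractions].
#' @param drop_degenerate exclude flagged degenerate cell types.
#' @return scalar mean CCC.
#' @export
mean_ccc <- function(table, drop_degenerate = FALSE) {
  if (drop_degenerate) table <- table[!table$degenerate, , drop = FALSE]
  mean(table$ccc)
}

#' Sensitivity sweep over mixing hyperparameters
#'
#' Holds the baseline mixing conditions (100 total cells, 5 types per
#' mixture, 0% gene dropout) and varies one axis at a time: total cells,
#' number of unique types, or the fraction of expressed genes randomly
#' removed from each mixture at the input stage. Each grid point generates
#' fresh mixtures, deconvolves them, and reports the mean per-type CCC.
#'
#' @param ds a depth-log-normalized, labeled [sc_dataset].
#' @param model a trained `deconv_model`.
#' @param axis one of `"total_cells"`, `"n_types"`, `"gene_dropout"`.
#' @param values numeric grid values (dropout values must lie in `[0, 1]`).
#' @param replicates mixtures generated per grid point (default 50; the
#'   full-scale recipe uses 500).
#' @param baseline named list with `total_cells`, `n_types`, `gene_dropout`.
#' @param dropout_stage where gene dropout is applied: `"model_input"`
#'   masks the unit-scaled vector entering the network (the same stage as
#'   the training corruption layer); `"expression"` removes genes from the
#'   log-normalized mixture before per-input normalization.
#' @param seed integer seed.
#' @return data frame with columns `axis`, `value`, `mean_ccc`.
#' @export
sensitivity_sweep <- function(ds, model,
                              axis = c("gene_dropout", "total_cells",
                                       "n_types"),
                              values, replicates = 50,
                              baseline = list(total_cells = 100, n_types = 5,
                                              gene_dropout = 0),
                              dropout_stage = c("model_input", "expression"),
                              seed = 0L) {
  axis <- match.arg(axis)
  dropout_stage <- match.arg(dropout_stage)
  values <- as.numeric(values)
  if (axis == "gene_dropout" && any(values < 0 | values > 1))
    abort("gene_dropout values must lie in [0, 1]", "cellmixr_grid_error")
  if (axis != "gene_dropout" && any(values < 1 | !is.finite(values)))
    abort(sprintf("%s values must be finite and >= 1", axis),
          "cellmixr_grid_error")
  catalog <- cell_type_catalog(sort(unique(ds$cell_types)))
  out <- lapply(seq_along(values), function(i) {
    v <- values[i]
    tt <- if (axis == "total_cells") v else baseline$total_cells
    nn <- if (axis == "n_types") v else baseline$n_types
    drop_frac <- if (axis == "gene_dropout") v else baseline$gene_dropout
    nn <- min(nn, length(catalog))
    mp <- mixer_params(t_range = c(tt, tt), n_range = c(nn, nn),
                       seed = substream_seed(seed, paste0("sweep", i)))
    b <- build_training_set(ds, replicates, mp, catalog = catalog)
    mask_genes <- function(X) {
      with_rng(substream_seed(seed, paste0("drop", i)), {
        t(apply(X, 1L, function(row) {
          expressed <- which(row > 0)
          k <- floor(drop_frac * length(expressed))
          if (k > 0) row[sample(expressed, k)] <- 0
          row
        }))
      })
    }
    if (drop_frac > 0 && dropout_stage == "expression") {
      pred <- predict_fractions(model, mask_genes(b$X),
                                gene_symbols = colnames(b$X),
                                already_log = TRUE)
    } else {
      Xa <- align_genes(model, b$X, colnames(b$X))
      Xn <- model_normalize(Xa, already_log = TRUE)
      if (drop_frac > 0) Xn <- mask_genes(Xn)
      pred <- deconvolution_result(net_forward(model, Xn)$output,
                                   model$catalog)
    }
    tab <- benchmark_fractions(pred, b$Y)
    data.frame(axis = axis, value = v, mean_ccc = mean_ccc(tab))
  })
  do.call(rbind, out)
}

#' Downsample a spatial field into pseudo-spots with known fractions
#'
#' Cells are assigned to square bins of side `bin_size` by
#' `floor(coord / bin_size)`; every cell lands in exactly one bin. Each
#' non-empty bin becomes a spot whose expression is the arithmetic mean of
#' its members' depth-log-normalized profiles and whose ground truth is
#' the member type counts divided by the bin total. Spot coordinates are
#' bin centers.
#'
#' @param ds an [sc_dataset] with `coords` (raw counts; normalized
#'   internally unless `already_log = TRUE`).
#' @param bin_size bin side length in the coordinate units.
#' @param already_log set `TRUE` if `ds$counts` already hold
#'   depth-log-normalized values.
#' @return list with `X` (spots x genes), `Y` (spots x types, rows on the
#'   simplex), `coords` (spots x 2 bin centers), and `n_cells` (members
#'   per spot).
#' @export
downsample_spatial <- function(ds, bin_size, already_log = FALSE) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (is.null(ds$coords))
    abort("dataset has no spatial coordinates", "cellmixr_argument_error")
  if (bin_size <= 0)
    abort("bin_size must be positive", "cellmixr_argument_error")
  expr <- if (already_log) as_dense(ds$counts)
          else depth_log_normalize(ds$counts)
  bx <- floor(ds$coords[, 1] / bin_size)
  by <- floor(ds$coords[, 2] / bin_size)
  key <- paste(bx, by, sep = ":")
  bins <- split(seq_along(key), key)
  types <- sort(unique(ds$cell_types))
  X <- matrix(0, length(bins), ncol(expr),
              dimnames = list(names(bins), ds$gene_symbols))
  Y <- matrix(0, length(bins), length(types),
              dimnames = list(names(bins), types))
  coords <- matrix(0, length(bins), 2,
                   dimnames = list(names(bins), c("x", "y")))
  for (i in seq_along(bins)) {
    rows <- bins[[i]]
    X[i, ] <- colMeans(expr[rows, , drop = FALSE])
    tc <- table(factor(ds$cell_types[rows], levels = types))
    Y[i, ] <- as.numeric(tc) / length(rows)
    coords[i, ] <- (c(bx[rows[1]], by[rows[1]]) + 0.5) * bin_size
  }
  list(X = X, Y = Y, coords = coords,
       n_cells = vapply(bins, length, integer(1)))
}
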