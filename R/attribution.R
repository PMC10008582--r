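# Integrated-gradients feature attribution: accumulate input gradients of
# one target class along the linear path from the zero baseline to the
# sample, by trapezoidal summation, and scale by the input itself. The
# randomized mode additionally masks genes at each step with probability
# descending from 100% to 0% as the interpolation coordinate rises,
# roughly emulating low read depth; the deterministic mode (dropout off)
# is exact for linear maps and satisfies the completeness axiom in the
# refinement limit.

#' Integrated-gradients parameters
#'
#' @param steps number of interpolation steps (>= 2; default 50).
#' @param randomized_dropout mask genes per step with descending
#'   probability `1 - alpha` (default on, matching the training-corruption
#'   philosophy); disable for axiomatically exact attributions.
#' @param target catalog cell-type name or output index.
#' @param seed integer seed for the dropout masks.
#' @return an `ig_params` list.
#' @export
ig_params <- function(steps = 50, randomized_dropout = TRUE, target = 1L,
                      seed = 0L) {
  if (steps < 2) abort("steps must be >= 2", "cellmixr_config_error")
  structure(list(steps = as.integer(steps),
                 randomized_dropout = isTRUE(randomized_dropout),
                 target = target, seed = as.integer(seed)),
            class = "ig_params")
}

#' Linear probe model for attribution diagnostics
#'
#' Builds a `deconv_model` computing exactly `F(x) = t(W) %*% x` on
#' non-negative inputs (identity-weight hidden layers stay in the ELU
#' identity region, and the head is linear). Used to verify attribution
#' axioms in closed form.
#'
#' @param W genes x outputs coefficient matrix.
#' @return a `deconv_model` with a linear head.
#' @export
linear_probe_model <- function(W) {
  W <- as.matrix(W)
  n <- nrow(W)
  m <- build_model(model_config(n_genes = n, hidden = c(n, n),
                                n_outputs = ncol(W), seed = 0L),
                   head = "linear")
  m$weights <- list(list(W = diag(n), b = numeric(n)),
                    list(W = diag(n), b = numeric(n)),
                    list(W = W, b = numeric(ncol(W))))
  m
}

resolve_target <- function(model, target) {
  if (is.character(target)) {
    idx <- model$catalog$index[target]
    if (is.na(idx))
      abort(sprintf("unknown target cell type '%s'", target),
            "cellmixr_argument_error")
    return(as.integer(idx))
  }
  target <- as.integer(target)
  if (target < 1L || target > model$config$n_outputs)
    abort("target index out of range", "cellmixr_argument_error")
  target
}

#' Integrated-gradient attributions for one target cell type
#'
#' For steps `k = 0 .. m-1` with `alpha_k = k/(m-1)`, the input is scaled
#' to `alpha_k * x` (zero baseline); in randomized mode each gene is
#' independently zeroed with probability `1 - alpha_k`. Gradients of the
#' target output with respect to the (masked) interpolated input are
#' accumulated with trapezoidal weights and multiplied by `x`, so genes
#' absent from a sample always receive attribution zero. Gradients are
#' taken on the inference graph (the training corruption front-end is
#' inactive).
#'
#' @param model a `deconv_model`.
#' @param X samples x genes matrix, already unit-scaled (output of
#'   [model_normalize]).
#' @param p an [ig_params].
#' @return an `attribution_matrix`: list with `weights` (samples x genes),
#'   `target` (resolved index), and `params`.
#' @export
integrated_gradients <- function(model, X, p = ig_params()) {
  stopifnot(inherits(model, "deconv_model"))
  X <- as_dense(X)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  target <- resolve_target(model, p$target)
  m <- p$steps
  alphas <- seq(0, 1, length.out = m)
  w <- rep(1 / (m - 1), m)
  w[c(1, m)] <- w[c(1, m)] / 2  # trapezoid weights
  acc <- matrix(0, nrow(X), ncol(X))
  with_rng(if (p$randomized_dropout) substream_seed(p$seed, "ig") else NULL, {
    for (k in seq_len(m)) {
      xk <- alphas[k] * X
      if (p$randomized_dropout) {
        keep <- matrix(runif(length(X)) >= (1 - alphas[k]),
                       nrow(X), ncol(X))
        xk <- xk * keep
      }
      g <- net_input_gradient(model, xk, target)
      if (any(!is.finite(g)))
        abort("non-finite gradient during integration",
              "cellmixr_numeric_error")
      acc <- acc + w[k] * g
    }
  })
  weights <- acc * X  # scale by (x - baseline), baseline = 0
  dimnames(weights) <- dimnames(X)
  structure(list(weights = weights, target = target, params = p),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d samples x %d genes, target %d\n",
              nrow(x$weights), ncol(x$weights), x$target))
  invisible(x)
}

#' Relative completeness gap of deterministic integrated gradients
#'
#' The completeness axiom states that attributions sum to
#' `F(x) - F(baseline)`. Returns
#' `|sum(attributions) - (F(x) - F(0))| / max(|F(x) - F(0)|, eps)` for one
#' sample, using deterministic (non-randomized) integration. The trapezoid
#' rule is exact for linear maps (gap ~ 0 at any step count) and converges
#' under step refinement otherwise.
#'
#' @param model a `deconv_model`.
#' @param x unit-scaled input vector (length `n_genes`).
#' @param target catalog name or output index.
#' @param steps interpolation steps.
#' @param eps guard for the vanishing-difference case.
#' @return scalar relative gap.
#' @export
completeness_gap <- function(model, x, target, steps = 200, eps = 1e-12) {
  x <- as.numeric(x)
  target <- resolve_target(model, target)
  A <- integrated_gradients(model, matrix(x, nrow = 1),
                            ig_params(steps = steps,
                                      randomized_dropout = FALSE,
                                      target = target))
  fx <- net_forward(model, matrix(x, nrow = 1))$output[1, target]
  f0 <- net_forward(model, matrix(0, 1, length(x)))$output[1, target]
  diff <- fx - f0
  abs(sum(A$weights) - diff) / max(abs(diff), eps)
}

#' Rank genes by mean attribution over selected samples
#'
#' @param A an `attribution_matrix`.
#' @param mask logical or integer sample selector (default all samples).
#' @param n number of top genes to return.
#' @return data frame with columns `gene` and `mean_attribution`, in
#'   descending order (ties broken by symbol).
#' @export
top_attributed_genes <- function(A, mask = NULL, n = 10) {
  stopifnot(inherits(A, "attribution_matrix"))
  if (n < 1) abort("n must be >= 1", "cellmixr_argument_error")
  W <- A$weights
  if (!is.null(mask)) W <- W[mask, , drop = FALSE]
  if (nrow(W) == 0)
    abort("sample mask selects no samples", "cellmixr_selection_error")
  mw <- colMeans(W)
  genes <- colnames(W) %||% as.character(seq_along(mw))
  ord <- order(-mw, genes)[seq_len(min(n, length(mw)))]
  data.frame(gene = genes[ord], mean_attribution = mw[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
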