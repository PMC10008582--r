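# Reference-guided transfer deconvolution: average a labeled reference
# into per-type signatures, extract network embeddings (middle two dense
# layers) and feature-selected gene values for reference and mixtures,
# factorize each block with NMF fit on the reference, align the two
# batches per component, and regress fractions with a bagged linear
# nu-SVR ensemble (CIBERSORT-style orientation: components are the
# observations, per-type component signatures the predictors).

#' Transfer-deconvolution parameters
#'
#' @param n_components NMF components per feature block; default (`NULL`)
#'   is the number of reference cell types (one factor per state).
#' @param n_hvg genes kept for the gene block, ranked by across-type
#'   signature variance.
#' @param n_bags number of bootstrap nu-SVR estimators.
#' @param nu nu-SVR `nu` in (0, 1].
#' @param cost nu-SVR cost parameter.
#' @param use_blocks feature blocks to use: `"both"`, `"genes"`, or
#'   `"embeddings"`.
#' @param clip_mode how negative embedding values are made non-negative
#'   before NMF: `"clip"` (set to 0) or `"shift"` (subtract the minimum).
#' @param seed integer seed (drives NMF init and bootstrap draws).
#' @return a `select_params` list.
#' @export
select_params <- function(n_components = NULL, n_hvg = 2000, n_bags = 48,
                          nu = 0.5, cost = 1,
                          use_blocks = c("both", "genes", "embeddings"),
                          clip_mode = c("clip", "shift"), seed = 0L) {
  if (!is.null(n_components) && n_components < 1)
    abort("n_components must be >= 1", "cellmixr_config_error")
  if (n_bags < 1) abort("n_bags must be >= 1", "cellmixr_config_error")
  if (nu <= 0 || nu > 1) abort("nu must lie in (0, 1]", "cellmixr_config_error")
  structure(list(n_components = n_components, n_hvg = as.integer(n_hvg),
                 n_bags = as.integer(n_bags), nu = nu, cost = cost,
                 use_blocks = match.arg(use_blocks),
                 clip_mode = match.arg(clip_mode), seed = as.integer(seed)),
            class = "select_params")
}

#' Average a labeled reference into per-type mean signatures
#'
#' @param reference a labeled, depth-log-normalized [sc_dataset].
#' @return a `reference_signature`: list with `type_names` (label-sorted)
#'   and `values` (types x genes matrix of arithmetic means).
#' @export
build_signature <- function(reference) {
  stopifnot(inherits(reference, "sc_dataset"))
  labels <- reference$cell_types
  if (length(unique(labels)) < 2L)
    abort("reference must contain at least two cell states",
          "cellmixr_signature_error")
  f <- factor(labels, levels = sort(unique(labels)))
  sums <- rowsum(as_dense(reference$counts), f)
  values <- sums / as.vector(table(f))
  colnames(values) <- reference$gene_symbols
  structure(list(type_names = levels(f), values = values),
            class = "reference_signature")
}

#' Select highly variable genes from a signature
#'
#' Top-`n` genes by across-type variance of the signature rows; ties break
#' by symbol order for determinism. Constant genes (variance 0) are only
#' included once all varying genes are exhausted.
#'
#' @param signature a `reference_signature` (or types x genes matrix with
#'   column names).
#' @param n genes to keep; clipped to the number available with a warning.
#' @return integer vector of gene column indices, in rank order.
#' @export
select_hvg <- function(signature, n = 2000) {
  values <- if (inherits(signature, "reference_signature")) signature$values
            else as.matrix(signature)
  if (n > ncol(values)) {
    warning("n exceeds the number of genes; clipped", call. = FALSE)
    n <- ncol(values)
  }
  v <- apply(values, 2L, stats::var)
  order(-v, colnames(values))[seq_len(n)]
}

# ---- NMF ---------------------------------------------------------------

# NNDSVD initialization (Boutsidis & Gallopoulos): deterministic SVD-based
# seeding of W (rows x k) and H (k x cols) for non-negative factorization.
nndsvd_init <- function(A, k) {
  s <- svd(A, nu = k, nv = k)
  W <- matrix(0, nrow(A), k); H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    np_ <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nn_ <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (np_ >= nn_ && np_ > 0) {
      W[, j] <- sqrt(s$d[j] * np_) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(s$d[j] * np_) * vp / sqrt(sum(vp^2))
    } else if (nn_ > 0) {
      W[, j] <- sqrt(s$d[j] * nn_) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(s$d[j] * nn_) * vn / sqrt(sum(vn^2))
    }
  }
  eps <- 1e-9 * mean(A)
  W[W <= 0] <- eps; H[H <= 0] <- eps
  list(W = W, H = H)
}

# Frobenius NMF by alternating non-negative least squares (Lawson-Hanson
# per row/column), NNDSVD-seeded; deterministic for fixed input.
nmf_fit <- function(A, k, max_iter = 200, tol = 1e-10) {
  if (k > min(dim(A)))
    abort("k exceeds the feasible factorization rank",
          "cellmixr_argument_error")
  if (all(A == 0))
    abort("cannot factorize an all-zero block", "cellmixr_factorization_error")
  init <- nndsvd_init(A, k)
  W <- init$W; H <- init$H
  prev <- Inf
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nrow(A)))
      W[i, ] <- pracma::lsqnonneg(t(H), A[i, ])$x
    for (j in seq_len(ncol(A)))
      H[, j] <- pracma::lsqnonneg(W, A[, j])$x
    err <- sum((A - W %*% H)^2)
    if (prev - err < tol * max(err, 1)) break
    prev <- err
  }
  list(W = W, H = H, err = err)
}

# Project rows of B onto a fixed dictionary H (k x d): per-sample NNLS.
nmf_transform <- function(B, H) {
  t(apply(B, 1L, function(row) pracma::lsqnonneg(t(H), row)$x))
}

# Two-batch alignment applied independently per component: the batch-
# effect adjustment model with per-feature estimates (no empirical-Bayes
# pooling across components), so batch means agree exactly after
# alignment. Location adjustment is the default; the full location/scale
# variant additionally equalizes batch variances, but is destructive when
# a batch is biologically homogeneous (e.g. spots of one cell state, whose
# tiny spread would be inflated to the pooled spread), so it is opt-in and
# skipped for batches with < 3 samples or vanishing spread.
#
# Identifiability guard: a batch-mean estimate is only meaningful when the
# mixture batch spans some compositional spread. When the mixture samples
# are (near-)homogeneous — spread below `min_mix_spread` of the pooled
# spread, e.g. a field of pure same-state spots — the batch mean is fully
# confounded with biology and shifting it would move every sample off its
# true signature, so that component is left unadjusted.
combat_align <- function(ref, mix, scale_adjust = FALSE,
                         min_mix_spread = 0.25) {
  stopifnot(ncol(ref) == ncol(mix))
  combined <- rbind(ref, mix)
  batch <- rep(c(1L, 2L), c(nrow(ref), nrow(mix)))
  for (j in seq_len(ncol(combined))) {
    x <- combined[, j]
    gm <- mean(x); gs <- stats::sd(x)
    if (!is.finite(gs) || gs == 0) next
    if (nrow(mix) > 1 && stats::sd(x[batch == 2L]) < min_mix_spread * gs)
      next
    z <- (x - gm) / gs
    for (b in 1:2) {
      rows <- batch == b
      bm <- mean(z[rows]); bs <- stats::sd(z[rows])
      if (scale_adjust && sum(rows) >= 3L && is.finite(bs) && bs > 1e-8) {
        z[rows] <- (z[rows] - bm) / bs
      } else {
        z[rows] <- z[rows] - bm
      }
    }
    combined[, j] <- z * gs + gm
  }
  list(ref = combined[batch == 1L, , drop = FALSE],
       mix = combined[batch == 2L, , drop = FALSE])
}

#' Factorize a feature block on the reference and align the mixture batch
#'
#' Negative entries (ELU embeddings can be negative) are clipped to zero
#' (or shifted, see [select_params]); NMF with deterministic NNDSVD
#' seeding is fit on the reference block; the mixture block is projected
#' onto the fixed dictionary by per-sample non-negative least squares;
#' finally the two batches are location/scale aligned per component.
#'
#' @param ref_block types x d reference feature matrix.
#' @param mix_block samples x d mixture feature matrix.
#' @param k number of NMF components.
#' @param clip_mode `"clip"` or `"shift"` (see [select_params]).
#' @param align apply the two-batch component alignment (default `TRUE`).
#' @return list with `ref` (types x k) and `mix` (samples x k) aligned
#'   component matrices.
#' @export
factorize_align <- function(ref_block, mix_block, k,
                            clip_mode = c("clip", "shift"), align = TRUE) {
  clip_mode <- match.arg(clip_mode)
  ref_block <- as.matrix(ref_block); mix_block <- as.matrix(mix_block)
  if (ncol(ref_block) != ncol(mix_block))
    abort("reference and mixture blocks must share the feature axis",
          "cellmixr_argument_error")
  if (any(!is.finite(ref_block)) || any(!is.finite(mix_block)))
    abort("blocks must be finite", "cellmixr_argument_error")
  nonneg <- function(m) {
    if (clip_mode == "clip") pmax(m, 0) else m - min(m, 0)
  }
  ref_block <- nonneg(ref_block); mix_block <- nonneg(mix_block)
  fit <- nmf_fit(ref_block, k)
  ref_comp <- fit$W
  mix_comp <- nmf_transform(mix_block, fit$H)
  if (align) {
    al <- combat_align(ref_comp, mix_comp)
    ref_comp <- al$ref; mix_comp <- al$mix
  }
  list(ref = ref_comp, mix = mix_comp)
}

#' Bagged linear nu-SVR fraction regression
#'
#' For each mixture sample, the sample's component vector (observations =
#' components) is regressed on the transposed reference component matrix
#' (predictors = cell types) by an ensemble of `n_bags` linear nu-SVRs,
#' each fit on a bootstrap of the component observations. Primal
#' coefficients are averaged across bags, negatives clipped to zero, and
#' the result renormalized to the simplex (uniform fallback when every
#' coefficient is non-positive).
#'
#' @param mix_components samples x k_total matrix.
#' @param ref_components types x k_total matrix.
#' @param p a [select_params].
#' @param seed optional seed overriding `p$seed`.
#' @return samples x types fraction matrix, rows on the simplex.
#' @export
svr_deconvolve <- function(mix_components, ref_components,
                           p = select_params(), seed = NULL) {
  mix_components <- as.matrix(mix_components)
  ref_components <- as.matrix(ref_components)
  k_total <- ncol(mix_components)
  n_types <- nrow(ref_components)
  if (ncol(ref_components) != k_total)
    abort("component axes of mixture and reference differ",
          "cellmixr_argument_error")
  if (k_total < n_types)
    abort("need at least as many components as cell types",
          "cellmixr_argument_error")
  design <- t(ref_components)  # k_total observations x n_types predictors
  with_rng(substream_seed(seed %||% p$seed, "svr_bagging"), {
    out <- matrix(0, nrow(mix_components), n_types)
    for (s in seq_len(nrow(mix_components))) {
      yv <- mix_components[s, ]
      coefs <- matrix(0, p$n_bags, n_types)
      fit_svr <- function(rows) {
        tryCatch({
          fit <- e1071::svm(x = design[rows, , drop = FALSE], y = yv[rows],
                            type = "nu-regression", kernel = "linear",
                            nu = p$nu, cost = p$cost, scale = FALSE)
          as.numeric(crossprod(fit$coefs, fit$SV))  # primal weights
        }, error = function(e) NULL)
      }
      for (b in seq_len(p$n_bags)) {
        rows <- sample.int(k_total, k_total, replace = TRUE)
        if (length(unique(rows)) < 2L) rows <- seq_len(k_total)
        w <- fit_svr(rows)
        # a degenerate bootstrap (e.g. constant response) can leave the
        # solver without support vectors; refit on the full observations
        if (is.null(w)) w <- fit_svr(seq_len(k_total))
        if (is.null(w)) w <- pracma::lsqnonneg(design, yv)$x
        coefs[b, ] <- w
      }
      w_bar <- colMeans(coefs)
      if (any(!is.finite(w_bar)))
        abort("non-finite SVR coefficients", "cellmixr_regression_error")
      w_bar[w_bar < 0] <- 0
      if (sum(w_bar) <= 0) w_bar <- rep(1 / n_types, n_types)
      out[s, ] <- w_bar / sum(w_bar)
    }
    out
  })
}

#' Reference-guided transfer deconvolution
#'
#' Pipeline: average the reference into per-type signatures; run signature
#' rows and mixture rows through the trained network, taking the middle
#' two dense layers as embedding blocks; factorize and align each
#' embedding block and (after HVG selection) the gene block; concatenate
#' the aligned components selected by `use_blocks`; regress fractions with
#' the bagged linear nu-SVR ensemble.
#'
#' @param model a trained `deconv_model` (the feature extractor).
#' @param mixtures samples x genes matrix in depth-log-normalized space.
#' @param reference a labeled [sc_dataset]; raw counts are depth-log-
#'   normalized internally unless `reference_already_log = TRUE`.
#' @param p a [select_params].
#' @param gene_symbols mixture column symbols (default `colnames(mixtures)`).
#' @param reference_already_log set `TRUE` if the reference counts are
#'   already depth-log-normalized.
#' @return a [deconvolution_result] over the reference cell states.
#' @export
run_select <- function(model, mixtures, reference, p = select_params(),
                       gene_symbols = colnames(mixtures),
                       reference_already_log = FALSE) {
  stopifnot(inherits(model, "deconv_model"), inherits(reference, "sc_dataset"))
  mixtures <- as_dense(mixtures)
  if (!reference_already_log) reference <- normalize_dataset(reference)
  sig <- build_signature(reference)
  k <- p$n_components %||% length(sig$type_names)

  # shared gene space: align both sides to the model vocabulary
  mix_aligned <- align_genes(model, mixtures, gene_symbols %||% character(0))
  ref_aligned <- align_genes(model, sig$values, colnames(sig$values))
  colnames(ref_aligned) <- colnames(mix_aligned) <-
    model$gene_symbols %||% colnames(mix_aligned)

  mix_norm <- model_normalize(mix_aligned, already_log = TRUE)
  ref_norm <- model_normalize(ref_aligned, already_log = TRUE)

  blocks <- list()
  if (p$use_blocks %in% c("both", "embeddings")) {
    emb_ref <- extract_embeddings(model, ref_norm, already_normalized = TRUE)
    emb_mix <- extract_embeddings(model, mix_norm, already_normalized = TRUE)
    for (nm in names(emb_ref)) {
      fa <- tryCatch(
        factorize_align(emb_ref[[nm]], emb_mix[[nm]], k, p$clip_mode),
        error = function(e) abort(
          sprintf("embedding block %s: %s", nm, conditionMessage(e)),
          "cellmixr_stage_error"))
      blocks[[paste0("emb_", nm)]] <- fa
    }
  }
  if (p$use_blocks %in% c("both", "genes")) {
    hvg <- select_hvg(ref_aligned, min(p$n_hvg, ncol(ref_aligned)))
    fa <- tryCatch(
      factorize_align(ref_aligned[, hvg, drop = FALSE],
                      mix_aligned[, hvg, drop = FALSE], k, p$clip_mode),
      error = function(e) abort(
        sprintf("gene block: %s", conditionMessage(e)),
        "cellmixr_stage_error"))
    blocks[["genes"]] <- fa
  }

  ref_comp <- do.call(cbind, lapply(blocks, `[[`, "ref"))
  mix_comp <- do.call(cbind, lapply(blocks, `[[`, "mix"))
  fractions <- svr_deconvolve(mix_comp, ref_comp, p)
  deconvolution_result(fractions, cell_type_catalog(sig$type_names),
                       sample_ids = rownames(mixtures))
}
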