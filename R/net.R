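# The deconvolution network: a dense ELU stack with softmax head, a
# corruption front-end active only during training, masked mean-squared-
# error loss, Adam optimization with plateau learning-rate decay and
# train-loss early stopping, prediction, and embedding extraction.
# Written directly on base matrix algebra: forward, backward and the
# optimizer are all in this file.

#' Network architecture configuration
#'
#' The published full-scale architecture is 28,867 input genes, hidden
#' layers of 8192/4096/2048/1024 ELU units, and an 840-way softmax output;
#' the tiny preset used throughout the test fixtures is 200 genes,
#' 256/128/64/32 hidden, 8 outputs.
#'
#' @param n_genes input width (number of genes).
#' @param hidden integer vector of hidden-layer widths; at least 2 layers
#'   (embedding extraction uses the middle two).
#' @param n_outputs number of catalog cell types (softmax width).
#' @param activation hidden activation; only `"elu"` is provided.
#' @param noise_sigma training-time Gaussian corruption SD on the unit
#'   input scale.
#' @param input_dropout training-time input masking probability.
#' @param seed integer seed for weight initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(n_genes, hidden = c(256, 128, 64, 32), n_outputs,
                         activation = "elu", noise_sigma = 0.05,
                         input_dropout = 0.20, seed = 0L) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 2L)
    abort("hidden must have at least 2 layers", "cellmixr_config_error")
  if (any(c(n_genes, hidden, n_outputs) < 1))
    abort("all layer sizes must be >= 1", "cellmixr_config_error")
  activation <- match.arg(activation, "elu")
  structure(list(n_genes = as.integer(n_genes), hidden = hidden,
                 n_outputs = as.integer(n_outputs), activation = activation,
                 noise_sigma = noise_sigma, input_dropout = input_dropout,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Closed-form trainable parameter count
#'
#' Sum over dense layers of `(fan_in + 1) * fan_out`. For the full-scale
#' configuration this evaluates to 281,395,016.
#'
#' @param cfg a [model_config] (or a `deconv_model`).
#' @return numeric parameter count.
#' @export
count_params <- function(cfg) {
  if (inherits(cfg, "deconv_model")) cfg <- cfg$config
  sizes <- c(cfg$n_genes, cfg$hidden, cfg$n_outputs)
  sum((sizes[-length(sizes)] + 1) * sizes[-1])
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Build an untrained deconvolution model
#'
#' Layers: corruption front-end (noise then dropout, training mode only),
#' `length(hidden)` dense+ELU layers, and a dense softmax output head.
#' Weights use Glorot-uniform initialization under the config seed.
#'
#' @param cfg a [model_config].
#' @param catalog optional [cell_type_catalog] naming the outputs
#'   (defaults to `type_01 ...`); its length must equal `n_outputs`.
#' @param gene_symbols optional input gene vocabulary (length `n_genes`),
#'   used for symbol alignment at prediction time.
#' @param head `"softmax"` (fractions) or `"linear"` (raw scores; used for
#'   attribution diagnostics).
#' @return a `deconv_model`.
#' @export
build_model <- function(cfg, catalog = NULL, gene_symbols = NULL,
                        head = c("softmax", "linear")) {
  stopifnot(inherits(cfg, "model_config"))
  head <- match.arg(head)
  if (is.null(catalog))
    catalog <- cell_type_catalog(sprintf("type_%02d", seq_len(cfg$n_outputs)))
  if (length(catalog) != cfg$n_outputs)
    abort("catalog length must equal n_outputs", "cellmixr_config_error")
  if (!is.null(gene_symbols)) {
    gene_symbols <- toupper(gene_symbols)
    if (length(gene_symbols) != cfg$n_genes)
      abort("gene_symbols length must equal n_genes", "cellmixr_config_error")
  }
  sizes <- c(cfg$n_genes, cfg$hidden, cfg$n_outputs)
  weights <- with_rng(substream_seed(cfg$seed, "init"), {
    lapply(seq_len(length(sizes) - 1L), function(i)
      list(W = glorot_uniform(sizes[i], sizes[i + 1]),
           b = numeric(sizes[i + 1])))
  })
  structure(list(config = cfg, weights = weights, catalog = catalog,
                 gene_symbols = gene_symbols, head = head),
            class = "deconv_model")
}

#' @export
print.deconv_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<deconv_model> %d -> [%s] -> %d (%s head), %s parameters\n",
              cfg$n_genes, paste(cfg$hidden, collapse = ", "),
              cfg$n_outputs, x$head,
              format(count_params(cfg), big.mark = ",")))
  invisible(x)
}

elu <- function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
elu_grad <- function(z) ifelse(z > 0, 1, exp(pmin(z, 0)))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass keeping intermediate activations for backprop.
# X is assumed unit-scaled; corruption is the caller's responsibility
# (training loop applies it, inference never does).
net_forward <- function(model, X) {
  L <- length(model$config$hidden)
  a <- vector("list", L + 1L)
  z <- vector("list", L + 1L)
  cur <- X
  for (l in seq_len(L)) {
    w <- model$weights[[l]]
    z[[l]] <- sweep(cur %*% w$W, 2L, w$b, "+")
    a[[l]] <- elu(z[[l]])
    cur <- a[[l]]
  }
  w <- model$weights[[L + 1L]]
  z[[L + 1L]] <- sweep(cur %*% w$W, 2L, w$b, "+")
  a[[L + 1L]] <- if (model$head == "softmax") softmax_rows(z[[L + 1L]])
                 else z[[L + 1L]]
  list(z = z, a = a, input = X, output = a[[L + 1L]])
}

#' Masked (sparse) mean-squared-error loss
#'
#' Per sample, squared errors are averaged only over cell types whose true
#' proportion is non-zero; the batch loss is the mean over samples. This
#' prevents the abundant structural zeros of mixture truth vectors from
#' diluting the loss.
#'
#' @param y_true samples x types true fraction matrix (rows on the simplex).
#' @param y_pred samples x types predicted fractions, same shape.
#' @return scalar loss.
#' @export
sparse_mse <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred)))
    abort("shape mismatch between truth and prediction",
          "cellmixr_loss_error")
  mask <- y_true > 0
  m <- rowSums(mask)
  if (any(m == 0))
    abort("a sample has all-zero truth; cannot mask the loss",
          "cellmixr_loss_error")
  mean(rowSums(((y_pred - y_true)^2) * mask) / m)
}

# Gradient of sparse_mse wrt predictions.
sparse_mse_grad <- function(y_true, y_pred) {
  mask <- y_true > 0
  m <- rowSums(mask)
  2 * (y_pred - y_true) * mask / (m * nrow(y_true))
}

# Backward pass: returns gradients for every W and b given dL/d(output).
net_backward <- function(model, fwd, g_out) {
  L <- length(model$config$hidden)
  grads <- vector("list", L + 1L)
  dz <- if (model$head == "softmax") {
    p <- fwd$a[[L + 1L]]
    p * (g_out - rowSums(g_out * p))
  } else g_out
  for (l in (L + 1L):1L) {
    a_prev <- if (l == 1L) fwd$input else fwd$a[[l - 1L]]
    grads[[l]] <- list(W = crossprod(a_prev, dz), b = colSums(dz))
    if (l > 1L) {
      da <- dz %*% t(model$weights[[l]]$W)
      dz <- da * elu_grad(fwd$z[[l - 1L]])
    }
  }
  grads
}

# Gradient of one output unit (post-head) with respect to the input matrix.
net_input_gradient <- function(model, X, target_idx) {
  fwd <- net_forward(model, X)
  K <- model$config$n_outputs
  g_out <- matrix(0, nrow(X), K)
  g_out[, target_idx] <- 1
  L <- length(model$config$hidden)
  dz <- if (model$head == "softmax") {
    p <- fwd$a[[L + 1L]]
    p * (g_out - rowSums(g_out * p))
  } else g_out
  for (l in (L + 1L):1L) {
    if (l > 1L) {
      da <- dz %*% t(model$weights[[l]]$W)
      dz <- da * elu_grad(fwd$z[[l - 1L]])
    } else {
      dz <- dz %*% t(model$weights[[l]]$W)
    }
  }
  dz
}

#' Training schedule parameters
#'
#' Defaults follow the published schedule: Adam at learning rate 1e-4,
#' batch size 256, up to 50 epochs with an 80/20 train/validation split,
#' early stopping on training loss (patience 4 epochs, delta 1.25e-5), and
#' a 50% learning-rate drop when training loss fails to improve by 1e-4
#' within 5 epochs. Validation loss is evaluated every `eval_every` epochs.
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param val_frac held-out validation fraction in (0, 1).
#' @param early_stop_patience epochs without improvement before stopping.
#' @param early_stop_delta minimum loss improvement that resets patience.
#' @param lr_drop_factor multiplicative LR decay on plateau, in (0, 1).
#' @param lr_drop_patience plateau length (epochs) triggering an LR drop.
#' @param lr_drop_delta minimum improvement that resets the LR plateau.
#' @param eval_every validation evaluation interval in epochs.
#' @param monitor loss the early-stop rule watches (`"train"` or `"val"`).
#' @param seed integer seed for the split, shuffling and corruption.
#' @return a `train_params` list.
#' @export
train_params <- function(lr = 1e-4, batch_size = 256, max_epochs = 50,
                         val_frac = 0.2, early_stop_patience = 4,
                         early_stop_delta = 1.25e-5, lr_drop_factor = 0.5,
                         lr_drop_patience = 5, lr_drop_delta = 1e-4,
                         eval_every = 5, monitor = c("train", "val"),
                         seed = 0L) {
  if (val_frac <= 0 || val_frac >= 1)
    abort("val_frac must lie in (0, 1)", "cellmixr_config_error")
  if (lr_drop_factor <= 0 || lr_drop_factor >= 1)
    abort("lr_drop_factor must lie in (0, 1)", "cellmixr_config_error")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), val_frac = val_frac,
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_delta = early_stop_delta,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_patience = as.integer(lr_drop_patience),
                 lr_drop_delta = lr_drop_delta,
                 eval_every = as.integer(eval_every),
                 monitor = match.arg(monitor), seed = as.integer(seed)),
            class = "train_params")
}

adam_init <- function(weights) {
  lapply(weights, function(w)
    list(mW = w$W * 0, vW = w$W * 0, mb = w$b * 0, vb = w$b * 0))
}

adam_step <- function(weights, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (l in seq_along(weights)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    weights[[l]]$W <- weights[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    weights[[l]]$b <- weights[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(weights = weights, state = state)
}

#' Train the deconvolution network on a mixture batch
#'
#' Inputs pass the 4-step per-input normalization once up front (it is
#' deterministic per row and sits outside the differentiated graph); the
#' corruption front-end (Gaussian noise then input masking) is re-drawn
#' inside every training step and never applied to validation or
#' inference inputs.
#'
#' @param model an untrained (or partially trained) `deconv_model`.
#' @param batch a [mixture_batch]; `X` in depth-log-normalized space.
#' @param p a [train_params].
#' @param already_normalized set `TRUE` if `batch$X` is already unit-scaled.
#' @return list with `model` (trained) and `history` (data frame of epoch,
#'   train_loss, val_loss, lr, plus a `stop_reason` attribute of
#'   `"early_stop"` or `"max_epochs"`).
#' @export
train_model <- function(model, batch, p = train_params(),
                        already_normalized = FALSE) {
  stopifnot(inherits(model, "deconv_model"), inherits(batch, "mixture_batch"))
  if (ncol(batch$X) != model$config$n_genes)
    abort("batch gene width does not match the model input",
          "cellmixr_config_error")
  Xn <- if (already_normalized) batch$X else
    model_normalize(batch$X, already_log = TRUE)
  Y <- batch$Y
  n <- nrow(Xn)
  cfg <- model$config

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  stop_reason <- "max_epochs"

  with_rng(substream_seed(p$seed, "train"), {
    idx <- sample.int(n)
    n_val <- max(1L, floor(n * p$val_frac))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    if (length(tr_idx) < 1L)
      abort("no training rows after validation split",
            "cellmixr_training_error")

    state <- adam_init(model$weights)
    lr <- p$lr
    t_step <- 0L
    best_es <- Inf; wait_es <- 0L
    best_lr <- Inf; wait_lr <- 0L

    for (epoch in seq_len(p$max_epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      batch_losses <- numeric(0)
      for (start in seq(1L, length(ord), by = p$batch_size)) {
        rows <- ord[start:min(start + p$batch_size - 1L, length(ord))]
        xb <- corrupt(Xn[rows, , drop = FALSE],
                      noise_sigma = cfg$noise_sigma,
                      dropout = cfg$input_dropout)
        yb <- Y[rows, , drop = FALSE]
        fwd <- net_forward(model, xb)
        loss <- sparse_mse(yb, fwd$output)
        if (!is.finite(loss))
          abort("non-finite training loss; last good weights retained",
                "cellmixr_training_error")
        grads <- net_backward(model, fwd, sparse_mse_grad(yb, fwd$output))
        t_step <- t_step + 1L
        upd <- adam_step(model$weights, grads, state, lr, t_step)
        model$weights <- upd$weights
        state <- upd$state
        batch_losses <- c(batch_losses, loss)
      }
      train_loss <- mean(batch_losses)

      val_loss <- NA_real_
      if (epoch %% p$eval_every == 0L || epoch == p$max_epochs) {
        vf <- net_forward(model, Xn[val_idx, , drop = FALSE])
        val_loss <- sparse_mse(Y[val_idx, , drop = FALSE], vf$output)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        lr = lr))

      monitored <- if (p$monitor == "train" || is.na(val_loss)) train_loss
                   else val_loss

      # plateau LR decay on train loss
      if (best_lr - train_loss > p$lr_drop_delta) {
        best_lr <- train_loss; wait_lr <- 0L
      } else {
        wait_lr <- wait_lr + 1L
        if (wait_lr >= p$lr_drop_patience) {
          lr <- lr * p$lr_drop_factor
          wait_lr <- 0L
        }
      }
      # early stopping
      if (best_es - monitored > p$early_stop_delta) {
        best_es <- monitored; wait_es <- 0L
      } else {
        wait_es <- wait_es + 1L
        if (wait_es >= p$early_stop_patience) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
  })
  attr(history, "stop_reason") <- stop_reason
  list(model = model, history = history)
}

# Align a sample x gene matrix to the model vocabulary by uppercase symbol:
# missing model genes zero-filled, unknown input genes dropped.
align_genes <- function(model, X, gene_symbols) {
  if (is.null(model$gene_symbols)) {
    if (ncol(X) != model$config$n_genes)
      abort("model has no gene vocabulary and input width differs",
            "cellmixr_alignment_error")
    return(X)
  }
  if (length(gene_symbols) == 0L) {
    if (ncol(X) != model$config$n_genes)
      abort("input has no gene symbols and its width differs from the model",
            "cellmixr_alignment_error")
    return(X)
  }
  gene_symbols <- toupper(gene_symbols)
  pos <- match(model$gene_symbols, gene_symbols)
  overlap <- mean(!is.na(pos))
  if (overlap < 0.10)
    abort(sprintf("only %.1f%% of model genes found in input", 100 * overlap),
          "cellmixr_alignment_error")
  if (overlap < 1)
    log_msg(sprintf("gene alignment: %d/%d model genes present",
                    sum(!is.na(pos)), length(pos)))
  out <- matrix(0, nrow(X), length(model$gene_symbols))
  hit <- !is.na(pos)
  out[, hit] <- X[, pos[hit], drop = FALSE]
  colnames(out) <- model$gene_symbols
  out
}

#' Predict cell-type fractions for bulk or spot profiles
#'
#' Gene columns are aligned to the model vocabulary by uppercase symbol
#' (missing genes zero-filled, unknown genes dropped; under 10% overlap is
#' an error), each row passes the 4-step normalization, and the network
#' runs in inference mode (no corruption).
#'
#' @param model a trained `deconv_model`.
#' @param X samples x genes expression matrix.
#' @param gene_symbols column gene symbols (defaults to `colnames(X)`).
#' @param already_log `TRUE` if `X` is already depth-log-normalized.
#' @param sample_ids optional sample identifiers.
#' @return a [deconvolution_result].
#' @export
predict_fractions <- function(model, X, gene_symbols = colnames(X),
                              already_log = FALSE, sample_ids = rownames(X)) {
  stopifnot(inherits(model, "deconv_model"))
  X <- as_dense(X)
  if (is.null(gene_symbols) && is.null(model$gene_symbols))
    gene_symbols <- NULL
  X <- align_genes(model, X, gene_symbols %||% colnames(X) %||% character(0))
  Xn <- model_normalize(X, already_log = already_log)
  out <- net_forward(model, Xn)$output
  deconvolution_result(out, model$catalog, sample_ids)
}

#' Extract embedding-layer activations
#'
#' Returns the post-activation values of designated hidden layers for each
#' input row, in inference mode. The default is the middle two hidden
#' layers (for the full-scale stack: widths 4096 and 2048; for the tiny
#' preset 256/128/64/32: widths 128 and 64).
#'
#' @param model a `deconv_model`.
#' @param X samples x genes matrix (aligned or alignable as in
#'   [predict_fractions]).
#' @param layers integer indices of hidden layers (1-based); default the
#'   middle two.
#' @param gene_symbols column symbols for alignment.
#' @param already_log `TRUE` if `X` is depth-log-normalized.
#' @param already_normalized `TRUE` if `X` is already unit-scaled (skips
#'   normalization and alignment).
#' @return named list of samples x width activation matrices, one per layer.
#' @export
extract_embeddings <- function(model, X, layers = NULL,
                               gene_symbols = colnames(X),
                               already_log = TRUE,
                               already_normalized = FALSE) {
  stopifnot(inherits(model, "deconv_model"))
  L <- length(model$config$hidden)
  if (is.null(layers)) layers <- c(floor(L / 2), floor(L / 2) + 1L)
  if (any(layers < 1L | layers > L))
    abort("requested embedding layer out of range", "cellmixr_argument_error")
  X <- as_dense(X)
  if (!already_normalized) {
    X <- align_genes(model, X, gene_symbols %||% colnames(X) %||% character(0))
    X <- model_normalize(X, already_log = already_log)
  }
  fwd <- net_forward(model, X)
  out <- lapply(layers, function(l) fwd$a[[l]])
  names(out) <- sprintf("layer_%d", layers)
  out
}
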