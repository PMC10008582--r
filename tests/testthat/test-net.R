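test_that("parameter counting matches the dense closed form", {
  full <- model_config(n_genes = 28867, hidden = c(8192, 4096, 2048, 1024),
                       n_outputs = 840)
  expect_equal(count_params(full), 281395016)
  tiny <- model_config(n_genes = 200, hidden = c(256, 128, 64, 32),
                       n_outputs = 8)
  expect_equal(count_params(tiny), 94952)
  # the closed form equals the number of weight elements actually allocated
  m <- build_model(model_config(n_genes = 20, hidden = c(7, 5), n_outputs = 3,
                                seed = 1))
  expect_equal(sum(vapply(m$weights,
                          function(w) length(w$W) + length(w$b), numeric(1))),
               count_params(m))
  expect_error(model_config(n_genes = 10, hidden = 5, n_outputs = 2),
               "at least 2")
})

test_that("every prediction row lies on the simplex", {
  m <- build_model(model_config(n_genes = 30, hidden = c(16, 8),
                                n_outputs = 5, seed = 2))
  set.seed(4)
  for (i in 1:20) {
    X <- matrix(runif(4 * 30), 4, 30)
    p <- predict_fractions(m, X)
    expect_true(all(p$fractions >= 0))
    expect_true(all(abs(rowSums(p$fractions) - 1) < 1e-5))
  }
  # all-zero input degrades gracefully through the all-zero profile path
  pz <- predict_fractions(m, matrix(0, 1, 30))
  expect_lt(abs(sum(pz$fractions) - 1), 1e-5)
})

test_that("masked loss matches hand arithmetic and a brute-force loop", {
  y_true <- rbind(c(0.5, 0.5, 0))
  y_pred <- rbind(c(0.4, 0.4, 0.2))
  expect_equal(sparse_mse(y_true, y_pred), 0.01, tolerance = 1e-12)
  expect_equal(sparse_mse(y_true, y_true), 0)

  brute <- function(yt, yp) {
    per_sample <- numeric(nrow(yt))
    for (i in seq_len(nrow(yt))) {
      errs <- c()
      for (j in seq_len(ncol(yt)))
        if (yt[i, j] > 0) errs <- c(errs, (yp[i, j] - yt[i, j])^2)
      per_sample[i] <- mean(errs)
    }
    mean(per_sample)
  }
  set.seed(5)
  for (i in 1:25) {
    yt <- random_simplex_rows(6, 5)
    yt[yt < 0.15] <- 0
    yt <- yt / rowSums(yt)
    yp <- random_simplex_rows(6, 5)
    expect_equal(sparse_mse(yt, yp), brute(yt, yp), tolerance = 1e-12)
  }
  # with fully dense truth the masked loss is plain MSE
  yt <- random_simplex_rows(8, 4) + 0.01
  yt <- yt / rowSums(yt)
  yp <- random_simplex_rows(8, 4)
  expect_equal(sparse_mse(yt, yp), mean((yt - yp)^2), tolerance = 1e-12)
  expect_error(sparse_mse(matrix(0, 1, 3), matrix(1 / 3, 1, 3)), "all-zero")
})

test_that("backpropagation agrees with central-difference gradients", {
  m <- build_model(model_config(n_genes = 6, hidden = c(5, 4), n_outputs = 3,
                                seed = 1))
  set.seed(6)
  X <- matrix(runif(12), 2, 6)
  Y <- random_simplex_rows(2, 3)
  Y[1, 2] <- 0; Y[1, ] <- Y[1, ] / sum(Y[1, ])
  fwd <- cellmixr:::net_forward(m, X)
  g <- cellmixr:::net_backward(m, fwd, cellmixr:::sparse_mse_grad(Y, fwd$output))
  numgrad <- function(l, i, j, field = "W") {
    eps <- 1e-6
    m2 <- m; m2$weights[[l]][[field]][i, j] <- m2$weights[[l]][[field]][i, j] + eps
    f1 <- sparse_mse(Y, cellmixr:::net_forward(m2, X)$output)
    m2$weights[[l]][[field]][i, j] <- m2$weights[[l]][[field]][i, j] - 2 * eps
    f0 <- sparse_mse(Y, cellmixr:::net_forward(m2, X)$output)
    (f1 - f0) / (2 * eps)
  }
  for (probe in list(c(1, 2, 3), c(2, 1, 2), c(3, 4, 1)))
    expect_equal(g[[probe[1]]]$W[probe[2], probe[3]],
                 numgrad(probe[1], probe[2], probe[3]), tolerance = 1e-6)
  # input gradients (used by integrated gradients) also check out
  gi <- cellmixr:::net_input_gradient(m, X, 2L)
  eps <- 1e-6
  X2 <- X; X2[1, 3] <- X2[1, 3] + eps
  num <- (cellmixr:::net_forward(m, X2)$output[1, 2] - fwd$output[1, 2]) / eps
  expect_equal(gi[1, 3], num, tolerance = 1e-5)
})

test_that("training schedule: early stop and LR decay fire on plateaus", {
  ds <- fixture_norm()
  b <- build_training_set(ds, 80, mixer_params(t_range = c(10, 10),
                                               n_range = c(1, 4), seed = 2))
  # corruption off so the frozen-weight loss is exactly constant per epoch
  m <- build_model(model_config(n_genes = 200, hidden = c(8, 4),
                                n_outputs = 8, noise_sigma = 0,
                                input_dropout = 0, seed = 3),
                   catalog = fixture_catalog())
  # lr = 0 freezes the weights, so the loss never improves: early stopping
  # must fire after exactly `patience` stagnant epochs
  fit <- train_model(m, b, train_params(lr = 0, batch_size = 16,
                                        max_epochs = 50,
                                        early_stop_patience = 4, seed = 1))
  expect_identical(attr(fit$history, "stop_reason"), "early_stop")
  expect_equal(nrow(fit$history), 5L)  # 1 improving (from Inf) + 4 stagnant
  # with early stopping disabled, the LR halves after each 5-epoch plateau
  fit2 <- train_model(m, b, train_params(lr = 0, batch_size = 16,
                                         max_epochs = 12,
                                         early_stop_patience = 100, seed = 1))
  expect_equal(fit2$history$lr, rep(0, 12))  # lr 0 stays 0 but trace exists
  fit3 <- train_model(m, b, train_params(lr = 1e-12, batch_size = 16,
                                         max_epochs = 12,
                                         early_stop_patience = 100,
                                         lr_drop_patience = 5, seed = 1))
  expect_equal(fit3$history$lr[12] / fit3$history$lr[1], 0.25,
               tolerance = 1e-9)  # two 50% drops by epoch 12
})

test_that("the tiny network can memorize a small fixed batch", {
  ds <- fixture_norm()
  b <- build_training_set(ds, 64, mixer_params(t_range = c(50, 50),
                                               n_range = c(2, 6), seed = 8))
  # capacity check: corruption off, higher lr, 200 epochs on 64 mixtures
  m <- build_model(model_config(n_genes = 200, hidden = c(256, 128, 64, 32),
                                n_outputs = 8, noise_sigma = 0,
                                input_dropout = 0, seed = 0),
                   catalog = fixture_catalog(),
                   gene_symbols = ds$gene_symbols)
  fit <- train_model(m, b, train_params(lr = 3e-3, batch_size = 16,
                                        max_epochs = 200, val_frac = 0.05,
                                        early_stop_patience = 1e6,
                                        lr_drop_patience = 1e6, seed = 0))
  expect_lt(min(fit$history$train_loss), 1e-3)
})

test_that("inference is deterministic and alignment is symbol-based", {
  m <- fixture_model()
  b <- fixture_heldout()
  X <- b$X[1:5, , drop = FALSE]
  p1 <- predict_fractions(m, X, already_log = TRUE)
  p2 <- predict_fractions(m, X, already_log = TRUE)
  expect_identical(p1$fractions, p2$fractions)
  # identical rows give identical outputs
  Xr <- rbind(X[1, ], X[1, ])
  pr <- predict_fractions(m, Xr, gene_symbols = colnames(b$X),
                          already_log = TRUE)
  expect_equal(pr$fractions[1, ], pr$fractions[2, ], tolerance = 0)
  # permuting gene columns (with symbols) leaves predictions unchanged
  perm <- sample(ncol(X))
  pp <- predict_fractions(m, X[, perm, drop = FALSE],
                          gene_symbols = colnames(b$X)[perm],
                          already_log = TRUE)
  expect_equal(pp$fractions, p1$fractions, tolerance = 1e-12)
  # insufficient vocabulary overlap is an alignment error
  expect_error(predict_fractions(m, X[, 1:10, drop = FALSE],
                                 gene_symbols = paste0("ZZZ", 1:10)),
               class = "cellmixr_alignment_error")
})

test_that("embedding extraction follows the middle-two rule deterministically", {
  m <- fixture_model()
  b <- fixture_heldout()
  emb <- extract_embeddings(m, b$X[1:4, ], gene_symbols = colnames(b$X))
  expect_named(emb, c("layer_2", "layer_3"))
  expect_equal(ncol(emb$layer_2), 128L)
  expect_equal(ncol(emb$layer_3), 64L)
  emb2 <- extract_embeddings(m, b$X[1:4, ], gene_symbols = colnames(b$X))
  expect_identical(emb, emb2)
  expect_error(extract_embeddings(m, b$X[1:4, ], layers = 9),
               class = "cellmixr_argument_error")
})
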