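test_that("signatures are per-label means, order-invariant, need two states", {
  counts <- rbind(c(1, 3), c(3, 1), c(10, 10))
  ds <- sc_dataset(counts, c("G1", "G2"), c("A", "A", "B"))
  sig <- build_signature(ds)
  expect_equal(unname(sig$values["A", ]), c(2, 2))
  expect_equal(sig$type_names, c("A", "B"))
  # shuffling cells leaves the signature unchanged
  perm <- c(3, 1, 2)
  ds2 <- sc_dataset(counts[perm, ], c("G1", "G2"), c("A", "A", "B")[perm])
  expect_equal(build_signature(ds2)$values, sig$values)
  expect_error(build_signature(sc_dataset(counts, c("G1", "G2"),
                                          rep("A", 3))),
               class = "cellmixr_signature_error")
})

test_that("HVG selection ranks by signature variance with stable ties", {
  sig <- build_signature(normalize_dataset(fixture_corpus()))
  cfg <- fixture_corpus_cfg()
  n_markers <- cfg$n_types * cfg$markers_per_type
  top <- select_hvg(sig, n_markers)
  expect_gte(mean(colnames(sig$values)[top] %in% planted_markers(cfg)$gene),
             0.9)
  # identity at n = n_genes; constant genes excluded below that
  expect_setequal(select_hvg(sig, ncol(sig$values)),
                  seq_len(ncol(sig$values)))
  m <- matrix(c(1, 1, 2, 2, 1, 9), 2, 3,
              dimnames = list(NULL, c("C1", "C2", "V")))
  expect_equal(select_hvg(m, 2), c(3L, 1L))  # constant cols only as filler
  expect_warning(sel <- select_hvg(m, 10), "clipped")
  expect_equal(length(sel), 3L)
})

test_that("NMF recovers an exact low-rank non-negative factorization", {
  set.seed(13)
  W <- matrix(rgamma(6 * 3, 2), 6, 3)
  H <- matrix(rgamma(3 * 40, 2), 3, 40)
  A <- W %*% H
  fit <- cellmixr:::nmf_fit(A, 3)
  rel <- sqrt(sum((A - fit$W %*% fit$H)^2)) / sqrt(sum(A^2))
  expect_lt(rel, 1e-6)
  # a mixture row equal to a reference row projects to the same components
  mix <- A[c(2, 5), , drop = FALSE]
  comp <- cellmixr:::nmf_transform(mix, fit$H)
  expect_equal(comp[1, ], fit$W[2, ], tolerance = 1e-6)
  expect_equal(comp[2, ], fit$W[5, ], tolerance = 1e-6)
})

test_that("two-batch alignment equalizes per-component batch means", {
  set.seed(14)
  ref <- matrix(rgamma(5 * 30, 2), 5, 30)
  mix <- matrix(rgamma(40 * 30, 2), 40, 30) + 1.5  # shifted batch
  fa <- factorize_align(ref, mix, k = 4)
  for (j in seq_len(4)) {
    expect_lt(abs(mean(fa$ref[, j]) - mean(fa$mix[, j])), 1e-6)
  }
  # independent location oracle: limma's batch-effect removal also drives
  # the two batch means of every component to a common value (it centers
  # on the unweighted mean of batch means rather than the pooled mean, so
  # only the equalization property is compared, not absolute positions)
  skip_if_not_installed("limma")
  fa0 <- factorize_align(ref, mix, k = 4, align = FALSE)
  combined <- rbind(fa0$ref, fa0$mix)
  batch <- rep(c("r", "m"), c(nrow(fa0$ref), nrow(fa0$mix)))
  lb <- t(limma::removeBatchEffect(t(combined), batch = batch))
  for (j in seq_len(4)) {
    expect_lt(abs(mean(lb[batch == "r", j]) - mean(lb[batch == "m", j])),
              1e-6)
  }
})

test_that("bagged nu-SVR recovers known mixing weights", {
  set.seed(15)
  # near-orthogonal signatures in component space
  ref <- rbind(c(10, 0, 0, 1, 0, 0.5, 0, 0),
               c(0, 10, 0, 0, 1, 0, 0.5, 0))
  w_true <- c(0.3, 0.7)
  mix <- rbind(w_true %*% ref)
  p <- select_params(n_bags = 48, seed = 1)
  est <- svr_deconvolve(mix, ref, p)
  expect_equal(dim(est), c(1L, 2L))
  expect_lt(max(abs(est[1, ] - w_true)), 0.05)
  # non-negative least-squares oracle on the same inputs
  nn <- pracma::lsqnonneg(t(ref), as.numeric(mix))$x
  expect_lt(max(abs(est[1, ] - nn / sum(nn))), 0.05)
  # a pure signature maps to a near-one-hot fraction
  pure <- svr_deconvolve(ref[2, , drop = FALSE], ref, p)
  expect_gte(pure[1, 2], 0.95)
  # simplex contract and determinism on random inputs
  rmix <- matrix(rgamma(3 * 8, 1), 3, 8)
  e1 <- svr_deconvolve(rmix, ref, p)
  e2 <- svr_deconvolve(rmix, ref, p)
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0))
  expect_true(all(abs(rowSums(e1) - 1) < 1e-9))
})

test_that("transfer deconvolution recovers fractions with a matched reference", {
  model <- fixture_model()
  split <- fixture_select_split()
  b <- fixture_select_mixtures()
  res <- run_select(model, b$X[1:40, , drop = FALSE], split$ref,
                    select_params(use_blocks = "both", seed = 0))
  expect_true(all(abs(rowSums(res$fractions) - 1) < 1e-5))
  expect_identical(colnames(res$fractions), fixture_catalog()$type_names)
  tab <- benchmark_fractions(res, b$Y[1:40, , drop = FALSE])
  expect_gt(mean_ccc(tab), 0.6)
  # a two-state reference with pure single-type pseudo-spots: every spot
  # is assigned to its own state
  ref2 <- subset_cells(split$ref,
                       which(split$ref$cell_types %in%
                               c("type_01", "type_02")))
  pure_X <- t(vapply(1:6, function(i)
    realize_mixture(split$mix, mixture_spec(20, "type_01", 1),
                    seed = 100 + i)$x, numeric(200)))
  colnames(pure_X) <- split$mix$gene_symbols
  pres <- suppressWarnings(
    run_select(model, pure_X, ref2, select_params(seed = 0)))
  expect_true(all(pres$fractions[, "type_01"] >= 0.9))
})
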