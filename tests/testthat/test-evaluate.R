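ccc_brute <- function(x, y) {
  # explicit moment loops, independent of the package implementation
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + x[i] / n; my <- my + y[i] / n }
  vx <- 0; vy <- 0; cxy <- 0
  for (i in seq_len(n)) {
    vx <- vx + (x[i] - mx)^2 / n
    vy <- vy + (y[i] - my)^2 / n
    cxy <- cxy + (x[i] - mx) * (y[i] - my) / n
  }
  2 * cxy / (vx + vy + (mx - my)^2)
}

test_that("concordance matches hand computations and the brute oracle", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  set.seed(17)
  for (i in 1:100) {
    x <- rnorm(sample(5:50, 1))
    y <- rnorm(length(x))
    expect_equal(ccc(x, y), ccc_brute(x, y), tolerance = 1e-12)
  }
  expect_error(ccc(1, 1), "length")
})

test_that("concordance penalizes location shifts, unlike Pearson", {
  set.seed(18)
  x <- rnorm(30)
  expect_equal(ccc(x, x), 1)
  expect_lt(ccc(x, x + 0.5), 1)
  expect_equal(stats::cor(x, x + 0.5), 1)
  # degenerate pairs: both constant equal means -> 1; one-sided constant -> 0
  expect_equal(ccc(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(ccc(c(2, 2, 2), c(1, 2, 3)), 0)
})

test_that("benchmark tables score per type and flag degenerate columns", {
  truth <- random_simplex_rows(30, 4)
  colnames(truth) <- paste0("t", 1:4)
  cat_ <- cell_type_catalog(paste0("t", 1:4))
  perfect <- deconvolution_result(truth, cat_)
  tab <- benchmark_fractions(perfect, truth)
  expect_true(all(abs(tab$ccc - 1) < 1e-12))
  expect_equal(mean_ccc(tab), 1)

  # constant-zero truth and prediction: defined limit, flagged
  t0 <- cbind(truth[, 1:3] / rowSums(truth[, 1:3]), t4 = 0)
  colnames(t0) <- paste0("t", 1:4)
  p0 <- deconvolution_result(t0, cat_)
  tab0 <- benchmark_fractions(p0, t0)
  expect_true(tab0$degenerate[tab0$cell_type == "t4"])
  expect_equal(tab0$ccc[tab0$cell_type == "t4"], 1)

  expect_error(benchmark_fractions(perfect, truth[1, , drop = FALSE]),
               "sample counts")
})

test_that("unrelated predictions score near zero concordance", {
  set.seed(19)
  truth <- random_simplex_rows(500, 6)
  pred <- random_simplex_rows(500, 6)
  colnames(truth) <- colnames(pred) <- paste0("t", 1:6)
  tab <- benchmark_fractions(pred, truth)
  expect_lt(mean(abs(tab$ccc)), 0.2)
})

test_that("sensitivity sweeps degrade with gene dropout and validate grids", {
  ds <- fixture_norm()
  m <- fixture_model()
  sw <- sensitivity_sweep(ds, m, axis = "gene_dropout",
                          values = c(0, 0.95), replicates = 25, seed = 6)
  expect_equal(nrow(sw), 2L)
  expect_gt(sw$mean_ccc[1], sw$mean_ccc[2])  # strict degradation
  expect_error(sensitivity_sweep(ds, m, axis = "gene_dropout", values = 1.5),
               class = "cellmixr_grid_error")
  expect_error(sensitivity_sweep(ds, m, axis = "total_cells", values = 0),
               class = "cellmixr_grid_error")
  # degenerate single-type axis point still scores
  sw1 <- sensitivity_sweep(ds, m, axis = "n_types", values = 1,
                           replicates = 20, seed = 7)
  expect_true(is.finite(sw1$mean_ccc))
})

test_that("spatial binning partitions cells and matches count arithmetic", {
  cfg <- corpus_config(n_types = 3, n_genes = 30, markers_per_type = 3,
                       seed = 23)
  ds <- make_spatial(spatial_config(corpus = cfg, field_size = c(200, 200),
                                    n_niches = 2, cell_spacing = 10,
                                    seed = 23))
  res <- downsample_spatial(ds, bin_size = 50)
  expect_equal(sum(res$n_cells), nrow(ds$counts))  # exact partition
  expect_true(all(abs(rowSums(res$Y) - 1) < 1e-12))
  expect_true(all(res$Y >= 0))

  # per-bin truth equals member-type counts / bin size, recomputed directly
  bx <- floor(ds$coords[, 1] / 50); by <- floor(ds$coords[, 2] / 50)
  key <- paste(bx, by, sep = ":")
  types <- sort(unique(ds$cell_types))
  for (k in sample(rownames(res$Y), 5)) {
    members <- which(key == k)
    expect_equal(unname(res$Y[k, ]),
                 as.numeric(table(factor(ds$cell_types[members],
                                         levels = types))) / length(members))
  }
  # spot expression is the mean of member log-normalized profiles
  expr <- depth_log_normalize(ds$counts)
  k1 <- rownames(res$X)[1]
  expect_equal(res$X[k1, ], colMeans(expr[key == k1, , drop = FALSE]),
               tolerance = 1e-12)

  # tiny bins isolate single cells: one-hot truths
  res1 <- downsample_spatial(ds, bin_size = 3)
  expect_true(all(res1$n_cells == 1))
  expect_true(all(apply(res1$Y, 1, max) == 1))

  # determinism: same input, same output
  expect_identical(downsample_spatial(ds, 50)$X, res$X)
  expect_error(downsample_spatial(fixture_corpus(), 50),
               class = "cellmixr_argument_error")
})
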