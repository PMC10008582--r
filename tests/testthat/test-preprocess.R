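make_qc_dataset <- function() {
  # 6 cells x 4 genes engineered to trip individual QC rules
  genes <- c("ACTB", "CD3E", "MT-CO1", "GAPDH")
  counts <- rbind(
    c(100, 30, 10, 10),    # 150 total: below the 200-count floor
    c(150, 100, 30, 20),   # 300 total, ~11% mito: kept
    c(120, 100, 110, 0),   # 33% mito: removed
    c(200, 100, 60, 40),   # ~17% mito: kept
    c(170, 100, 30, 0),    # 300 total: kept
    c(150, 120, 30, 0))    # 300 total: kept
  sc_dataset(counts, genes, rep("a", 6), cell_ids = paste0("c", 1:6))
}

test_that("QC applies the four filters in order with the stated thresholds", {
  ds <- make_qc_dataset()
  out <- qc_filter(ds, qc_params())
  expect_false("c1" %in% out$cell_ids)  # <200 counts
  expect_false("c3" %in% out$cell_ids)  # 33% mitochondrial
  expect_true(all(c("c2", "c4") %in% out$cell_ids))  # ~11% / ~17% kept
  # GAPDH expressed in only 2 of the surviving cells at gene-filter time
  expect_false("GAPDH" %in% out$gene_symbols)
  # idempotent: filtering twice equals filtering once
  expect_identical(as.matrix(qc_filter(out, qc_params())$counts),
                   as.matrix(out$counts))
})

test_that("depth outliers above mean + 2 SD of log totals are removed", {
  set.seed(1)
  counts <- matrix(rpois(40 * 20, 50), 40, 20)
  counts[40, ] <- counts[40, ] * 100  # one extreme-depth cell
  ds <- sc_dataset(counts, sprintf("G%02d", 1:20), rep("a", 40))
  out <- qc_filter(ds, qc_params(min_counts = 1, min_cells_per_gene = 1))
  expect_false("cell_40" %in% out$cell_ids)
  lt <- log(rowSums(counts[-40, ]))
  expect_true(all(log(rowSums(as.matrix(out$counts))) <=
                    mean(log(rowSums(counts))) +
                    2 * sd(log(rowSums(counts)))))
})

test_that("QC that empties the dataset reports per-rule removals", {
  ds <- tiny_dataset()
  err <- tryCatch(qc_filter(ds, qc_params(min_counts = 1e6)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "low_count=4")
})

test_that("depth-log normalization matches direct arithmetic", {
  out <- depth_log_normalize(matrix(c(0, 10, 30), 1))
  expect_equal(as.numeric(out), log1p(c(0, 2500, 7500)), tolerance = 1e-12)
  # symmetry and depth invariance
  eq <- depth_log_normalize(matrix(c(5, 5), 1))
  expect_equal(eq[1, 1], eq[1, 2])
  expect_equal(eq[1, 1], log1p(5000))
  a <- depth_log_normalize(matrix(c(3, 7, 9), 1))
  b <- depth_log_normalize(matrix(2 * c(3, 7, 9), 1))
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(depth_log_normalize(matrix(c(0, 0), 1)), "zero total")
})

test_that("model normalization follows the 4 steps and their edge rules", {
  # independent stepwise oracle
  oracle <- function(x) {
    x <- x * 10000 / sum(x)
    x <- log2(1 + x)
    z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    (z - min(z)) / (max(z) - min(z))
  }
  x <- c(0, 10, 30)
  expect_equal(model_normalize(x), oracle(x), tolerance = 1e-12)
  expect_equal(round(model_normalize(x), 3), c(0, 0.877, 1))
  expect_equal(model_normalize(c(7, 7, 7)), c(0, 0, 0))
  set.seed(2)
  for (i in 1:20) {
    r <- rpois(50, 20)
    n <- model_normalize(r)
    expect_equal(min(n), 0)
    expect_equal(max(n), 1)
  }
  expect_error(model_normalize(c(1, NA, 2)), "NaN|infinite")
})

test_that("z-scoring makes the normalization log-base invariant", {
  set.seed(3)
  raw <- rpois(100, 30)
  cpm <- raw * 10000 / sum(raw)
  a <- model_normalize(log2(1 + cpm), already_log = TRUE)
  b <- model_normalize(log1p(cpm), already_log = TRUE)
  expect_false(isTRUE(all.equal(log2(1 + cpm), log1p(cpm))))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("corruption has the stated noise scale and masking rate", {
  x <- rep(0.8, 1e5)
  y <- corrupt(x, noise_sigma = 0.05, dropout = 0, seed = 1)
  expect_equal(mean(y), 0.8, tolerance = 1e-3)
  expect_equal(sd(y), 0.05, tolerance = 1e-2)
  expect_equal(mean(y > 0.70 & y < 0.90), 0.954, tolerance = 0.01)

  z <- corrupt(rep(1, 1e5), noise_sigma = 0, dropout = 0.2, seed = 2)
  expect_equal(mean(z == 0), 0.2, tolerance = 0.01)

  # sigma = 0, dropout = 0 is the identity; near-total dropout zeroes all
  expect_identical(corrupt(x[1:100], 0, 0), x[1:100])
  expect_gt(mean(corrupt(rep(1, 1e4), 0, 0.999, seed = 3) == 0), 0.99)
  # masked survivors are not rescaled unless asked
  zi <- corrupt(rep(1, 1e4), 0, 0.2, inverted = TRUE, seed = 4)
  expect_equal(max(zi), 1.25, tolerance = 1e-9)
  expect_error(corrupt(x, dropout = 1), "dropout")
})
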