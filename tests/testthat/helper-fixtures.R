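# Shared fixtures, built lazily once per test session. The expensive ones
# (the trained tiny model and its 5,000-mixture training set) are reused by
# several files; everything is deterministic under fixed seeds.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fixture_corpus_cfg <- function() corpus_config(seed = 7)

fixture_corpus <- function() memo("corpus", make_corpus(fixture_corpus_cfg()))

fixture_norm <- function() memo("norm", normalize_dataset(fixture_corpus()))

fixture_catalog <- function() {
  memo("catalog", cell_type_catalog(sort(unique(fixture_corpus()$cell_types))))
}

# the study-condition training set: 5,000 mixtures, T in [1, 1000], seed 0
fixture_train_batch <- function() {
  memo("train_batch", build_training_set(
    fixture_norm(), 5000,
    mixer_params(t_range = c(1, 1000), n_range = c(1, 8), seed = 0L),
    catalog = fixture_catalog()))
}

# the trained tiny-preset model (200 genes; 256/128/64/32; 8 types)
fixture_model <- function() {
  memo("model", {
    ds <- fixture_norm()
    m <- build_model(
      model_config(n_genes = 200, hidden = c(256, 128, 64, 32),
                   n_outputs = 8, seed = 0L),
      catalog = fixture_catalog(), gene_symbols = ds$gene_symbols)
    train_model(m, fixture_train_batch(), train_params(seed = 0L))$model
  })
}

# held-out evaluation mixtures from the same generating law as training
fixture_heldout <- function() {
  memo("heldout", build_training_set(
    fixture_norm(), 500,
    mixer_params(t_range = c(1, 1000), n_range = c(1, 8), seed = 777L),
    catalog = fixture_catalog()))
}

subset_cells <- function(ds, rows) {
  sc_dataset(as.matrix(ds$counts)[rows, , drop = FALSE], ds$gene_symbols,
             ds$cell_types[rows], cell_ids = ds$cell_ids[rows],
             coords = if (is.null(ds$coords)) NULL
                      else ds$coords[rows, , drop = FALSE])
}

# disjoint split of the corpus for the transfer benchmark: odd cells form
# the mixture pool, even cells the reference
fixture_select_split <- function() {
  memo("select_split", {
    ds <- fixture_corpus()
    idx <- seq_len(nrow(ds$counts))
    list(mix = normalize_dataset(subset_cells(ds, idx[idx %% 2 == 1])),
         ref = subset_cells(ds, idx[idx %% 2 == 0]))
  })
}

fixture_select_mixtures <- function() {
  memo("select_mixtures", build_training_set(
    fixture_select_split()$mix, 200,
    mixer_params(t_range = c(100, 100), n_range = c(2, 8), seed = 5L),
    catalog = fixture_catalog()))
}

random_simplex_rows <- function(n, k) {
  m <- matrix(rgamma(n * k, 1), n, k)
  m / rowSums(m)
}

# small labeled dataset with hand-set counts, for IO and QC tests
tiny_dataset <- function() {
  counts <- matrix(c(5, 0, 3,
                     1, 2, 0,
                     4, 4, 4,
                     0, 7, 2), nrow = 4, byrow = TRUE)
  sc_dataset(counts, c("ACTB", "CD3E", "MT-CO1"),
             c("a", "a", "b", "b"), cell_ids = paste0("c", 1:4))
}
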