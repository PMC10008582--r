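# Synthetic annotated single-cell corpora with planted, recoverable
# cell-type structure. These are first-class study fixtures: every
# downstream stage (QC, mixing, training, transfer, attribution) is
# exercised against corpora whose ground truth is known by construction.

#' Configuration for a synthetic single-cell corpus
#'
#' Each cell type owns a disjoint block of marker genes whose negative-
#' binomial mean is `marker_fold` times the background `base_mean`; counts
#' are then rescaled to a per-cell sequencing depth drawn uniformly from
#' `depth_range`, so depth and type are independent by construction.
#'
#' @param n_types number of cell types.
#' @param n_genes number of genes; must accommodate all marker blocks.
#' @param cells_per_type cells simulated per type.
#' @param markers_per_type genes in each type's marker block.
#' @param marker_fold mean fold-change of a marker in its owning type (> 1).
#' @param base_mean background negative-binomial mean (> 0).
#' @param dispersion negative-binomial overdispersion (size = 1/dispersion).
#' @param depth_range length-2 target total counts per cell (min, max).
#' @param leakage fraction of the marker elevation shared with all other
#'   types (0 = fully disjoint signatures).
#' @param seed integer RNG seed.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(n_types = 8, n_genes = 200, cells_per_type = 100,
                          markers_per_type = 5, marker_fold = 8,
                          base_mean = 4, dispersion = 0.5,
                          depth_range = c(1000, 5000), leakage = 0,
                          seed = 1L) {
  if (markers_per_type * n_types > n_genes)
    abort("marker blocks exceed n_genes", "cellmixr_config_error")
  if (marker_fold <= 1 || base_mean <= 0 || dispersion <= 0)
    abort("marker_fold must exceed 1; base_mean, dispersion must be positive",
          "cellmixr_config_error")
  if (length(depth_range) != 2L || any(depth_range <= 0) ||
      depth_range[1] > depth_range[2])
    abort("depth_range must be positive with min <= max",
          "cellmixr_config_error")
  structure(list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
                 cells_per_type = as.integer(cells_per_type),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold, base_mean = base_mean,
                 dispersion = dispersion, depth_range = depth_range,
                 leakage = leakage, seed = as.integer(seed)),
            class = "corpus_config")
}

corpus_type_names <- function(n) sprintf("type_%02d", seq_len(n))

corpus_mean_matrix <- function(cfg) {
  mu <- matrix(cfg$base_mean, nrow = cfg$n_types, ncol = cfg$n_genes)
  lift <- cfg$base_mean * (cfg$marker_fold - 1)
  for (t in seq_len(cfg$n_types)) {
    block <- ((t - 1) * cfg$markers_per_type + 1):(t * cfg$markers_per_type)
    mu[t, block] <- mu[t, block] + lift
    if (cfg$leakage > 0) {
      others <- setdiff(seq_len(cfg$n_types), t)
      mu[others, block] <- mu[others, block] + cfg$leakage * lift
    }
  }
  mu
}

#' Marker gene assignments planted in a corpus
#'
#' @param cfg a [corpus_config].
#' @return data frame with columns `gene` (symbol) and `type` (owning type).
#' @export
planted_markers <- function(cfg) {
  idx <- seq_len(cfg$markers_per_type * cfg$n_types)
  data.frame(gene = sprintf("GENE%04d", idx),
             type = rep(corpus_type_names(cfg$n_types),
                        each = cfg$markers_per_type),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated single-cell corpus
#'
#' @param cfg a [corpus_config].
#' @return an [sc_dataset] with `n_types * cells_per_type` cells; marker
#'   structure and depths as documented in [corpus_config]. Deterministic
#'   under `cfg$seed`.
#' @export
make_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "corpus_config"))
  with_rng(cfg$seed, {
    mu <- corpus_mean_matrix(cfg)
    n <- cfg$n_types * cfg$cells_per_type
    counts <- matrix(0, nrow = n, ncol = cfg$n_genes)
    types <- rep(corpus_type_names(cfg$n_types), each = cfg$cells_per_type)
    size <- 1 / cfg$dispersion
    for (t in seq_len(cfg$n_types)) {
      rows <- ((t - 1) * cfg$cells_per_type + 1):(t * cfg$cells_per_type)
      draw <- matrix(rnbinom(length(rows) * cfg$n_genes, size = size,
                             mu = rep(mu[t, ], each = length(rows))),
                     nrow = length(rows))
      counts[rows, ] <- draw
    }
    depth <- runif(n, cfg$depth_range[1], cfg$depth_range[2])
    tot <- rowSums(counts)
    tot[tot == 0] <- 1
    counts <- round(counts * depth / tot)
    sc_dataset(counts, sprintf("GENE%04d", seq_len(cfg$n_genes)), types)
  })
}

#' Configuration for a synthetic spatial field
#'
#' Extends [corpus_config] with a rectangular field partitioned into
#' Voronoi niches of random centers; each niche draws its own cell-type
#' composition from a symmetric Dirichlet, emulating the spatially coherent
#' type domains of high-resolution spatial data.
#'
#' @param corpus a [corpus_config] providing the expression model.
#' @param field_size length-2 field (width, height) in micrometres.
#' @param n_niches number of Voronoi niches (>= 1).
#' @param niche_concentration Dirichlet concentration of per-niche type
#'   composition; small values give near-pure niches.
#' @param cell_spacing grid spacing between cells in micrometres.
#' @param seed integer RNG seed.
#' @return a `spatial_config` list.
#' @export
spatial_config <- function(corpus = corpus_config(), field_size = c(1000, 1000),
                           n_niches = 4, niche_concentration = 1,
                           cell_spacing = 10, seed = 1L) {
  if (length(field_size) != 2L || any(field_size <= 0))
    abort("field_size must be positive (width, height)",
          "cellmixr_config_error")
  if (n_niches < 1) abort("n_niches must be >= 1", "cellmixr_config_error")
  if (cell_spacing <= 0) abort("cell_spacing must be positive",
                               "cellmixr_config_error")
  structure(list(corpus = corpus, field_size = field_size,
                 n_niches = as.integer(n_niches),
                 niche_concentration = niche_concentration,
                 cell_spacing = cell_spacing, seed = as.integer(seed)),
            class = "spatial_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic spatial single-cell field
#'
#' Cells sit on a jittered grid with spacing `cell_spacing`; each cell's
#' type is drawn from the Dirichlet-sampled composition of the Voronoi
#' niche (nearest of `n_niches` random centers) containing it. Expression
#' is drawn from the corpus model for the assigned type.
#'
#' @param cfg a [spatial_config].
#' @return an [sc_dataset] with `coords`; attributes `niche` (per-cell
#'   niche index) and `niche_centers` record the generating layout.
#' @export
make_spatial <- function(cfg) {
  stopifnot(inherits(cfg, "spatial_config"))
  cc <- cfg$corpus
  with_rng(cfg$seed, {
    gx <- seq(cfg$cell_spacing / 2, cfg$field_size[1], by = cfg$cell_spacing)
    gy <- seq(cfg$cell_spacing / 2, cfg$field_size[2], by = cfg$cell_spacing)
    pts <- as.matrix(expand.grid(x = gx, y = gy))
    jit <- cfg$cell_spacing * 0.25
    pts <- pts + matrix(runif(length(pts), -jit, jit), ncol = 2)
    pts[, 1] <- pmin(pmax(pts[, 1], 0), cfg$field_size[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 0), cfg$field_size[2])
    n <- nrow(pts)
    centers <- cbind(runif(cfg$n_niches, 0, cfg$field_size[1]),
                     runif(cfg$n_niches, 0, cfg$field_size[2]))
    d2 <- outer(pts[, 1], centers[, 1], "-")^2 +
      outer(pts[, 2], centers[, 2], "-")^2
    niche <- max.col(-d2)
    comp <- t(vapply(seq_len(cfg$n_niches), function(i)
      rdirichlet1(rep(cfg$niche_concentration, cc$n_types)),
      numeric(cc$n_types)))
    tnames <- corpus_type_names(cc$n_types)
    type_idx <- vapply(seq_len(n), function(i)
      sample.int(cc$n_types, 1L, prob = comp[niche[i], ]), integer(1))
    mu <- corpus_mean_matrix(cc)
    size <- 1 / cc$dispersion
    counts <- matrix(rnbinom(n * cc$n_genes, size = size,
                             mu = mu[type_idx, ]), nrow = n)
    depth <- runif(n, cc$depth_range[1], cc$depth_range[2])
    tot <- rowSums(counts); tot[tot == 0] <- 1
    counts <- round(counts * depth / tot)
    ds <- sc_dataset(counts, sprintf("GENE%04d", seq_len(cc$n_genes)),
                     tnames[type_idx], coords = pts)
    attr(ds, "niche") <- niche
    attr(ds, "niche_centers") <- centers
    ds
  })
}
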