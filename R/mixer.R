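# Pseudobulk mixture simulation with known cell-type fractions, following
# the four-step scheme: draw total cells T, draw number of types N, assign
# fraction ratios F on the simplex, then sample and average real cells.

#' Mixture-drawing hyperparameters
#'
#' @param t_range integer range (min, max) for the total cell count `T`;
#'   the full-scale default is 1 to 10,000.
#' @param n_range integer range for the number of distinct types `N`
#'   (default 1 to 32; clipped to the catalog size at draw time).
#' @param fraction_law law for the fraction ratios; currently the flat
#'   Dirichlet (maximum entropy on the simplex).
#' @param seed integer seed.
#' @return a `mixer_params` list.
#' @export
mixer_params <- function(t_range = c(1, 10000), n_range = c(1, 32),
                         fraction_law = "flat_dirichlet", seed = 0L) {
  if (length(t_range) != 2 || t_range[1] < 1 || t_range[1] > t_range[2])
    abort("t_range must be positive and ordered", "cellmixr_config_error")
  if (length(n_range) != 2 || n_range[1] < 1 || n_range[1] > n_range[2])
    abort("n_range must be positive and ordered", "cellmixr_config_error")
  fraction_law <- match.arg(fraction_law, "flat_dirichlet")
  structure(list(t_range = as.integer(t_range), n_range = as.integer(n_range),
                 fraction_law = fraction_law, seed = as.integer(seed)),
            class = "mixer_params")
}

#' Draw one mixture specification
#'
#' `T ~ Uniform{t_range}`; `N ~ Uniform{n_range}` clipped to the catalog
#' size; `N` types sampled uniformly **without replacement** over the
#' catalog (not frequency-weighted, which oversamples rare types relative
#' to their corpus abundance); `F` flat-Dirichlet over the `N` types.
#'
#' @param catalog a [cell_type_catalog].
#' @param p a [mixer_params].
#' @param seed optional seed (used via [with_rng]); `NULL` draws from the
#'   current stream.
#' @return a [mixture_spec].
#' @export
draw_mixture_spec <- function(catalog, p = mixer_params(), seed = NULL) {
  stopifnot(inherits(catalog, "cell_type_catalog"))
  with_rng(seed, {
    tt <- sample(p$t_range[1]:p$t_range[2], 1L)
    n_hi <- min(p$n_range[2], length(catalog))
    n_lo <- min(p$n_range[1], n_hi)
    nn <- sample(n_lo:n_hi, 1L)
    types <- catalog$type_names[sample.int(length(catalog), nn)]
    f <- rdirichlet1(rep(1, nn))
    f <- f / sum(f)
    mixture_spec(tt, types, f)
  })
}

#' Largest-remainder apportionment of T cells to fractions
#'
#' Rounds `total * fractions` to integers summing exactly to `total`:
#' floors first, then distributes the remainder by descending fractional
#' part, ties broken by position (catalog order).
#'
#' @param total integer total to apportion.
#' @param fractions non-negative weights summing to 1.
#' @return integer vector summing to `total`.
#' @export
apportion_counts <- function(total, fractions) {
  total <- as.integer(total)
  raw <- total * fractions
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- raw - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Realize one pseudobulk mixture from a labeled dataset
#'
#' Per-type cell counts come from [apportion_counts]; cells are sampled
#' without replacement within each type. If a type's pool is exhausted, the
#' maximum number available is used without duplication. The expression
#' vector is the arithmetic mean of the selected cells' (depth-log-
#' normalized) profiles; the returned ground truth is the **realized**
#' fraction vector (selected counts / total selected), which is what the
#' averaged profile actually contains.
#'
#' @param ds an [sc_dataset] whose `counts` hold depth-log-normalized
#'   values.
#' @param spec a [mixture_spec].
#' @param type_index optional precomputed list mapping type name to row
#'   indices (see [build_training_set]).
#' @param seed optional seed.
#' @return list with `x` (mean expression vector), `y` (named realized
#'   fractions over `spec$types`), and `cells` (selected row indices).
#' @export
realize_mixture <- function(ds, spec, type_index = NULL, seed = NULL) {
  stopifnot(inherits(ds, "sc_dataset"), inherits(spec, "mixture_spec"))
  if (is.null(type_index))
    type_index <- split(seq_along(ds$cell_types), ds$cell_types)
  with_rng(seed, {
    target <- apportion_counts(spec$total_cells, spec$fractions)
    chosen <- integer(0)
    realized <- integer(length(spec$types))
    for (i in seq_along(spec$types)) {
      pool <- type_index[[spec$types[i]]] %||% integer(0)
      k <- min(target[i], length(pool))
      realized[i] <- k
      if (k > 0) chosen <- c(chosen, pool[sample.int(length(pool), k)])
    }
    if (sum(realized) == 0)
      abort("no cells available for any requested type",
            "cellmixr_mixture_error")
    x <- colMeans(as_dense(ds$counts)[chosen, , drop = FALSE])
    y <- realized / sum(realized)
    names(y) <- spec$types
    list(x = x, y = y, cells = chosen)
  })
}

#' Build a batch of pseudobulk training mixtures
#'
#' Draws `n_mixtures` specifications and realizes each against the dataset.
#' Type row indices are pre-indexed once. The catalog defaults to the
#' sorted unique labels of the dataset.
#'
#' @param ds a depth-log-normalized, labeled [sc_dataset].
#' @param n_mixtures number of mixtures to generate.
#' @param p a [mixer_params]; its `seed` drives all draws.
#' @param catalog optional [cell_type_catalog] (columns of `Y`).
#' @return a [mixture_batch].
#' @export
build_training_set <- function(ds, n_mixtures, p = mixer_params(),
                               catalog = NULL) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (n_mixtures <= 0)
    abort("n_mixtures must be positive", "cellmixr_argument_error")
  if (is.null(catalog))
    catalog <- cell_type_catalog(sort(unique(ds$cell_types)))
  type_index <- split(seq_along(ds$cell_types), ds$cell_types)
  g <- ncol(ds$counts)
  X <- matrix(0, n_mixtures, g)
  Y <- matrix(0, n_mixtures, length(catalog))
  specs <- vector("list", n_mixtures)
  with_rng(substream_seed(p$seed, "mixer"), {
    for (i in seq_len(n_mixtures)) {
      spec <- draw_mixture_spec(catalog, p)
      rm_ <- realize_mixture(ds, spec, type_index = type_index)
      X[i, ] <- rm_$x
      Y[i, catalog$index[names(rm_$y)]] <- rm_$y
      specs[[i]] <- spec
    }
  })
  colnames(X) <- ds$gene_symbols
  mixture_batch(X, Y, catalog, specs)
}
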