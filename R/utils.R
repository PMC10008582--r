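#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rnbinom rgamma sd var cov quantile predict
#' @importFrom utils read.csv write.csv head
NULL

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "cellmixr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream. All stochastic operations in the package funnel
#' through this helper (or accept an explicit seed that does).
#'
#' @param seed integer seed; `NULL` leaves the current stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed from a global seed
#'
#' A global seed fans out to independent named substreams (mixer, corruption,
#' integrated gradients, SVR bagging, ...) so that components can be re-run
#' in isolation with reproducible draws. Result is always in `[0, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param name character substream label.
#' @return integer seed for the substream.
#' @export
#' @examples
#' substream_seed(1L, "mixer")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% (2^31 - 1))
}

log_msg <- function(..., level = "INFO") {
  if (isTRUE(getOption("cellmixr.quiet", TRUE)) && level == "INFO") {
    return(invisible(NULL))
  }
  message(sprintf("[cellmixr %s] %s", level, paste0(...)))
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}
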