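# Belief propagation of predicted fractions over a cell-type ontology:
# each node accumulates the raw mass of itself and all of its distinct
# descendants. Defined on DAGs (each descendant counted once); on trees
# this reduces to plain subtree sums. Propagated values are "at-or-below"
# masses and deliberately NOT a simplex: ancestors double-count by design.

#' Propagate predicted fractions up a cell-type ontology
#'
#' Catalog cell types map to ontology nodes by name; internal nodes carry
#' raw mass 0. For every node `v`, the propagated value is the sum of raw
#' mass over the distinct set `{v} + descendants(v)` (descendants along
#' child-to-parent edges). On a tree whose leaves cover the catalog, any
#' root accumulates total mass 1.
#'
#' @param fractions a [deconvolution_result] (or a samples x types matrix
#'   with column names).
#' @param g an `ontology_graph` from [read_ontology].
#' @return object of class `propagated_fractions`: list with `values`
#'   (nodes x samples matrix, rows in topological order), `raw` (the input
#'   fractions), and `order` (the node order used).
#' @export
propagate <- function(fractions, g) {
  stopifnot(inherits(g, "ontology_graph"))
  fr <- if (inherits(fractions, "deconvolution_result")) fractions$fractions
        else as.matrix(fractions)
  if (is.null(colnames(fr)))
    abort("fractions must carry cell-type column names",
          "cellmixr_mapping_error")
  missing <- setdiff(colnames(fr), g$nodes)
  if (length(missing))
    abort(paste0("catalog names not in the ontology: ",
                 paste(missing, collapse = ", ")),
          "cellmixr_mapping_error")
  ord <- topological_order(g)
  raw <- matrix(0, length(ord), nrow(fr),
                dimnames = list(ord, rownames(fr)))
  raw[colnames(fr), ] <- t(fr)
  vals <- raw
  # children before parents in ord; descendant sets deduplicated via
  # explicit reachability (DAG-safe: a diamond counts its apex once)
  for (v in ord) {
    below <- igraph::subcomponent(g$graph, v, mode = "in")$name
    vals[v, ] <- colSums(raw[below, , drop = FALSE])
  }
  structure(list(values = vals, raw = fr, order = ord),
            class = "propagated_fractions")
}

#' @export
print.propagated_fractions <- function(x, ...) {
  cat(sprintf("<propagated_fractions> %d nodes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Diagnostic validation of an ontology against a catalog
#'
#' @param g an `ontology_graph`.
#' @param catalog a [cell_type_catalog] (or character vector of names).
#' @return list with `issues` (data frame of `node`/`issue`, zero rows
#'   when clean: unmapped catalog names, multi-parent nodes in DAG mode,
#'   isolated nodes) and `roots` (character vector of nodes without
#'   parents, informational).
#' @export
validate_graph <- function(g, catalog) {
  stopifnot(inherits(g, "ontology_graph"))
  names_ <- if (inherits(catalog, "cell_type_catalog")) catalog$type_names
            else as.character(catalog)
  issues <- data.frame(node = character(), issue = character(),
                       stringsAsFactors = FALSE)
  add <- function(issues, node, issue)
    rbind(issues, data.frame(node = node, issue = issue,
                             stringsAsFactors = FALSE))
  for (nm in setdiff(names_, g$nodes))
    issues <- add(issues, nm, "catalog name not in graph")
  outdeg <- igraph::degree(g$graph, mode = "out")
  for (nm in names(outdeg)[outdeg > 1])
    issues <- add(issues, nm, "multi-parent (DAG mode)")
  deg <- igraph::degree(g$graph, mode = "all")
  for (nm in names(deg)[deg == 0])
    issues <- add(issues, nm, "isolated")
  list(issues = issues, roots = names(outdeg)[outdeg == 0])
}
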