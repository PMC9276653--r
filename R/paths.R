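# Path-pattern search: bounded-depth DFS over alternating node and edge
# constraints, with lexicographic tie-breaking so results are deterministic.

#' Build a path pattern
#'
#' A pattern alternates node constraints and edge constraints and must
#' start and end with a node constraint. A node constraint is a list with
#' `label` (optional) and `props` (named list of required property values,
#' optional). An edge constraint has `type` (exact string, optional),
#' `type_pattern` (regex, optional) and `direction` (`"out"`, `"in"` or
#' `"any"`; direction is read along the path: `"out"` means the edge points
#' from the current node to the next).
#'
#' @param nodes list of node constraints (length k)
#' @param edges list of edge constraints (length k - 1)
#' @return object of class `path_pattern`
#' @export
path_pattern <- function(nodes, edges) {
  if (length(nodes) != length(edges) + 1) {
    stop("pattern must start and end with a node constraint (k nodes, k-1 edges)")
  }
  structure(list(nodes = nodes, edges = edges), class = "path_pattern")
}

node_matches <- function(store, id, constraint) {
  node <- store$nodes[[id]]
  if (!is.null(constraint$label) && !(constraint$label %in% node$labels)) return(FALSE)
  for (nm in names(constraint$props %||% list())) {
    if (!(as.character(constraint$props[[nm]]) %in% prop_values(node, nm))) return(FALSE)
  }
  TRUE
}

edge_matches <- function(edge, from_id, constraint) {
  dir <- constraint$direction %||% "any"
  along <- if (identical(edge$source, from_id)) "out"
           else if (identical(edge$target, from_id)) "in"
           else return(NULL)
  if (identical(edge$source, edge$target)) along <- dir  # self-loop matches either
  if (dir != "any" && !identical(along, dir)) return(NULL)
  if (!is.null(constraint$type) && !identical(edge$type, constraint$type)) return(NULL)
  if (!is.null(constraint$type_pattern) && !grepl(constraint$type_pattern, edge$type)) return(NULL)
  if (identical(edge$source, from_id)) edge$target else edge$source
}

sort_key <- function(store, id) {
  n <- store$nodes[[id]]
  paste0(node_identifier(n) %||% "", "\x1f", id)
}

#' Find paths matching a pattern
#'
#' Bounded-depth DFS (depth = pattern length). Returned walks satisfy every
#' constraint in order; node repetition along a walk is allowed. Results
#' are ordered lexicographically by the identifiers of the nodes along the
#' path.
#'
#' @param store a `graph_store`
#' @param pattern a [path_pattern()]
#' @param max_results cap on number of returned paths (default unlimited)
#' @return list of paths; each path is a list with `nodes` (node id vector)
#'   and `edges` (edge id vector)
#' @export
find_paths <- function(store, pattern, max_results = Inf) {
  results <- list()
  k <- length(pattern$nodes)
  starts <- gs_node_ids(store)
  starts <- starts[vapply(starts, function(i) node_matches(store, i, pattern$nodes[[1]]), logical(1))]
  starts <- starts[order(vapply(starts, function(i) sort_key(store, i), ""), method = "radix")]

  recurse <- function(node_path, edge_path) {
    if (length(results) >= max_results) return(invisible(NULL))
    depth <- length(node_path)
    if (depth == k) {
      results[[length(results) + 1L]] <<- list(nodes = node_path, edges = edge_path)
      return(invisible(NULL))
    }
    cur <- node_path[[depth]]
    cand <- list()
    for (eid in gs_incident_edges(store, cur)) {
      nxt <- edge_matches(store$edges[[eid]], cur, pattern$edges[[depth]])
      if (is.null(nxt)) next
      if (!node_matches(store, nxt, pattern$nodes[[depth + 1L]])) next
      cand[[length(cand) + 1L]] <- list(edge = eid, node = nxt)
    }
    if (length(cand) > 0) {
      ord <- order(vapply(cand, function(c) paste0(sort_key(store, c$node), "\x1f", c$edge), ""),
                   method = "radix")
      for (c in cand[ord]) {
        recurse(c(node_path, c$node), c(edge_path, c$edge))
        if (length(results) >= max_results) break
      }
    }
    invisible(NULL)
  }
  for (s in starts) {
    recurse(s, character(0))
    if (length(results) >= max_results) break
  }
  results
}
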