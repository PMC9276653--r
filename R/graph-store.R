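# In-memory labelled property graph. Nodes and edges live in environments
# keyed by surrogate ids ("n<k>"/"e<k>") so renames and replacements never
# break edges. A (label, "identifier") index is maintained eagerly; indices
# on other properties are built lazily and invalidated by a version counter.

#' Create an empty property-graph store
#'
#' The store is a mutable environment holding labelled nodes, typed edges,
#' an incidence map, and per-(label, property) value indices. Node identity
#' for lookups is (primary label, `identifier` property); internally every
#' node carries an opaque surrogate id.
#'
#' @return an object of class `graph_store`
#' @export
graph_store <- function() {
  s <- new.env(parent = emptyenv())
  s$nodes <- new.env(parent = emptyenv())
  s$edges <- new.env(parent = emptyenv())
  s$incidence <- new.env(parent = emptyenv())  # node id -> character vector of edge ids
  s$id_index <- new.env(parent = emptyenv())   # label -> env(identifier value -> node ids)
  s$node_seq <- 0L
  s$edge_seq <- 0L
  s$version <- 0L
  s$index_cache <- new.env(parent = emptyenv())
  s$log <- list()
  class(s) <- "graph_store"
  s
}

#' @export
print.graph_store <- function(x, ...) {
  cat(sprintf("<graph_store: %d nodes, %d edges>\n",
              length(ls(x$nodes)), length(ls(x$edges))))
  invisible(x)
}

gs_log <- function(store, event, ...) {
  store$log[[length(store$log) + 1L]] <- c(list(event = event), list(...))
  invisible(NULL)
}

#' Retrieve the store's skip/warning log
#' @param store a `graph_store`
#' @return list of log entries
#' @export
store_log <- function(store) store$log

touch <- function(store) store$version <- store$version + 1L

id_index_add <- function(store, label, value, node_id) {
  if (is.null(value) || is.na(value) || !nzchar(value)) return(invisible(NULL))
  env <- store$id_index[[label]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    store$id_index[[label]] <- env
  }
  env[[value]] <- unique(c(env[[value]], node_id))
  invisible(NULL)
}

id_index_drop <- function(store, label, value, node_id) {
  env <- store$id_index[[label]]
  if (is.null(env) || is.null(value) || is.na(value) || !nzchar(value)) return(invisible(NULL))
  cur <- setdiff(env[[value]] %||% character(0), node_id)
  if (length(cur) == 0) rm(list = value, envir = env) else env[[value]] <- cur
  invisible(NULL)
}

node_identifier <- function(node) {
  v <- node$properties[["identifier"]]
  if (is.null(v)) NA_character_ else as.character(v[[1]])
}

#' Add a node to the store
#'
#' @param store a `graph_store`
#' @param labels character vector of labels; the first is the primary label
#' @param properties named list; must include `identifier` for indexed lookup
#' @return the new node's surrogate id
#' @export
gs_add_node <- function(store, labels, properties = list()) {
  stopifnot(length(labels) >= 1)
  store$node_seq <- store$node_seq + 1L
  id <- paste0("n", store$node_seq)
  node <- list(id = id, labels = unique(as.character(labels)), properties = properties)
  store$nodes[[id]] <- node
  store$incidence[[id]] <- character(0)
  ident <- node_identifier(node)
  if (!is.na(ident)) for (lb in node$labels) id_index_add(store, lb, ident, id)
  touch(store)
  id
}

#' Fetch a node record by surrogate id
#' @param store a `graph_store`
#' @param id node surrogate id
#' @return list with `id`, `labels`, `properties` (NULL if absent)
#' @export
gs_get_node <- function(store, id) store$nodes[[id]]

#' Replace a node record (labels and/or properties), keeping its id
#' @param store a `graph_store`
#' @param id node surrogate id
#' @param labels new label vector (NULL keeps current)
#' @param properties new property list (NULL keeps current)
#' @export
gs_set_node <- function(store, id, labels = NULL, properties = NULL) {
  node <- store$nodes[[id]]
  if (is.null(node)) stop("no such node: ", id)
  old_ident <- node_identifier(node)
  old_labels <- node$labels
  if (!is.null(labels)) node$labels <- unique(as.character(labels))
  if (!is.null(properties)) node$properties <- properties
  store$nodes[[id]] <- node
  new_ident <- node_identifier(node)
  if (!identical(old_ident, new_ident) || !identical(old_labels, node$labels)) {
    if (!is.na(old_ident)) for (lb in old_labels) id_index_drop(store, lb, old_ident, id)
    if (!is.na(new_ident)) for (lb in node$labels) id_index_add(store, lb, new_ident, id)
  }
  touch(store)
  invisible(id)
}

#' Remove a node and all incident edges
#' @param store a `graph_store`
#' @param id node surrogate id
#' @return number of incident edges removed
#' @export
gs_remove_node <- function(store, id) {
  node <- store$nodes[[id]]
  if (is.null(node)) return(0L)
  eids <- store$incidence[[id]] %||% character(0)
  for (e in eids) gs_remove_edge(store, e)
  ident <- node_identifier(node)
  if (!is.na(ident)) for (lb in node$labels) id_index_drop(store, lb, ident, id)
  rm(list = id, envir = store$nodes)
  rm(list = id, envir = store$incidence)
  touch(store)
  length(eids)
}

#' Add a directed typed edge
#' @param store a `graph_store`
#' @param type edge type string
#' @param source_id,target_id node surrogate ids (must exist)
#' @param properties named list of edge properties
#' @return the new edge's surrogate id
#' @export
gs_add_edge <- function(store, type, source_id, target_id, properties = list()) {
  if (is.null(store$nodes[[source_id]])) stop("dangling source: ", source_id)
  if (is.null(store$nodes[[target_id]])) stop("dangling target: ", target_id)
  store$edge_seq <- store$edge_seq + 1L
  id <- paste0("e", store$edge_seq)
  store$edges[[id]] <- list(id = id, type = type, source = source_id,
                            target = target_id, properties = properties)
  store$incidence[[source_id]] <- c(store$incidence[[source_id]], id)
  if (!identical(source_id, target_id)) {
    store$incidence[[target_id]] <- c(store$incidence[[target_id]], id)
  }
  touch(store)
  id
}

#' Fetch an edge record by surrogate id
#' @param store a `graph_store`
#' @param id edge surrogate id
#' @return list with `id`, `type`, `source`, `target`, `properties`
#' @export
gs_get_edge <- function(store, id) store$edges[[id]]

#' Replace an edge record (type and/or properties)
#' @param store a `graph_store`
#' @param id edge id
#' @param type new type (NULL keeps)
#' @param properties new property list (NULL keeps)
#' @export
gs_set_edge <- function(store, id, type = NULL, properties = NULL) {
  e <- store$edges[[id]]
  if (is.null(e)) stop("no such edge: ", id)
  if (!is.null(type)) e$type <- type
  if (!is.null(properties)) e$properties <- properties
  store$edges[[id]] <- e
  touch(store)
  invisible(id)
}

#' Remove an edge
#' @param store a `graph_store`
#' @param id edge id
#' @export
gs_remove_edge <- function(store, id) {
  e <- store$edges[[id]]
  if (is.null(e)) return(invisible(FALSE))
  for (nid in unique(c(e$source, e$target))) {
    inc <- store$incidence[[nid]]
    if (!is.null(inc)) store$incidence[[nid]] <- setdiff(inc, id)
  }
  rm(list = id, envir = store$edges)
  touch(store)
  invisible(TRUE)
}

#' All node surrogate ids (deterministic order)
#' @param store a `graph_store`
#' @export
gs_node_ids <- function(store) lex_sort(ls(store$nodes))

#' All edge surrogate ids (deterministic order)
#' @param store a `graph_store`
#' @export
gs_edge_ids <- function(store) lex_sort(ls(store$edges))

#' Node ids carrying a given label
#' @param store a `graph_store`
#' @param label label string
#' @export
gs_nodes_with_label <- function(store, label) {
  ids <- gs_node_ids(store)
  ids[vapply(ids, function(i) label %in% store$nodes[[i]]$labels, logical(1))]
}

#' Edge ids of a given type
#' @param store a `graph_store`
#' @param type edge type string
#' @export
gs_edges_with_type <- function(store, type) {
  ids <- gs_edge_ids(store)
  ids[vapply(ids, function(i) identical(store$edges[[i]]$type, type), logical(1))]
}

#' Incident edge ids of a node
#' @param store a `graph_store`
#' @param id node id
#' @export
gs_incident_edges <- function(store, id) lex_sort(store$incidence[[id]] %||% character(0))

#' Degree of a node (incident edge count; self-loops count once)
#' @param store a `graph_store`
#' @param id node id
#' @export
gs_degree <- function(store, id) length(store$incidence[[id]] %||% character(0))

#' Node and edge counts
#' @param store a `graph_store`
#' @return list with `nodes` and `edges`
#' @export
gs_counts <- function(store) {
  list(nodes = length(ls(store$nodes)), edges = length(ls(store$edges)))
}

# value of a property as character vector (scalar or list)
prop_values <- function(node, prop) {
  v <- node$properties[[prop]]
  if (is.null(v)) return(character(0))
  as.character(unlist(v, use.names = FALSE))
}

#' Indexed lookup of nodes by (label, property, value)
#'
#' `identifier` lookups hit the eagerly maintained index; other properties
#' use a lazily built index invalidated whenever the store mutates. Lookups
#' always agree with a linear scan.
#'
#' @param store a `graph_store`
#' @param label label string
#' @param prop property name
#' @param value value to look up
#' @return character vector of node ids (sorted)
#' @export
gs_lookup <- function(store, label, prop, value) {
  value <- as.character(value)
  if (identical(prop, "identifier")) {
    env <- store$id_index[[label]]
    if (is.null(env)) return(character(0))
    return(lex_sort(env[[value]] %||% character(0)))
  }
  idx <- gs_property_index(store, label, prop)
  lex_sort(idx[[value]] %||% character(0))
}

#' Build (or fetch the cached) index value -> node ids for (label, property)
#'
#' Multi-valued properties index every element.
#'
#' @param store a `graph_store`
#' @param label label string
#' @param prop property name
#' @return named list mapping value to node id vector
#' @export
gs_property_index <- function(store, label, prop) {
  key <- paste(label, prop, sep = "\x1f")
  cached <- store$index_cache[[key]]
  if (!is.null(cached) && identical(cached$version, store$version)) return(cached$map)
  map <- list()
  for (id in gs_nodes_with_label(store, label)) {
    for (v in prop_values(store$nodes[[id]], prop)) {
      if (!nzchar(v)) next
      map[[v]] <- c(map[[v]], id)
    }
  }
  store$index_cache[[key]] <- list(version = store$version, map = map)
  map
}

#' Load a node table into the store
#'
#' One node per row under `label`; all columns become properties; columns
#' listed in `list_columns` are split on the list delimiter. The
#' (label, identifier) index is updated. Duplicate identifiers within the
#' table are rejected by default or merged property-wise under
#' `on_duplicate = "merge"` (list-valued properties are unioned, scalar
#' conflicts keep the first row's value).
#'
#' @param table data.frame with an `identifier` column
#' @param label node label to assign
#' @param store a `graph_store`
#' @param list_columns character vector of list-valued column names
#' @param list_delim delimiter for list cells
#' @param on_duplicate `"reject"` (default) or `"merge"`
#' @param extra_labels additional labels appended after `label`
#' @param extra_properties named list added to every node (e.g. `source`)
#' @return number of nodes created
#' @export
load_node_table <- function(table, label, store,
                            list_columns = character(0),
                            list_delim = DEFAULT_LIST_DELIM,
                            on_duplicate = c("reject", "merge"),
                            extra_labels = character(0),
                            extra_properties = list()) {
  on_duplicate <- match.arg(on_duplicate)
  if (!"identifier" %in% names(table)) {
    stop("node table lacks an 'identifier' column (label ", label, ")")
  }
  created <- 0L
  seen <- new.env(parent = emptyenv())  # identifier -> node id
  for (i in seq_len(nrow(table))) {
    props <- list()
    for (col in names(table)) {
      cell <- table[[col]][[i]]
      if (is.na(cell) || !nzchar(cell)) next
      props[[col]] <- if (col %in% list_columns) {
        split_list_cell(cell, list_delim)
      } else cell
    }
    for (nm in names(extra_properties)) props[[nm]] <- extra_properties[[nm]]
    ident <- as.character(table[["identifier"]][[i]])
    prior <- seen[[ident]]
    if (is.null(prior) && length(gs_lookup(store, label, "identifier", ident)) > 0) {
      prior <- gs_lookup(store, label, "identifier", ident)[[1]]
    }
    if (!is.null(prior)) {
      if (on_duplicate == "reject") {
        stop("duplicate identifier '", ident, "' in node table for label ", label)
      }
      node <- gs_get_node(store, prior)
      for (nm in names(props)) {
        cur <- node$properties[[nm]]
        if (is.null(cur)) {
          node$properties[[nm]] <- props[[nm]]
        } else if (nm %in% list_columns) {
          node$properties[[nm]] <- unique(c(cur, props[[nm]]))
        }  # scalar conflict: first occurrence wins
      }
      gs_set_node(store, prior, properties = node$properties)
      next
    }
    nid <- gs_add_node(store, c(label, extra_labels), props)
    seen[[ident]] <- nid
    created <- created + 1L
  }
  created
}

#' Load an edge table into the store
#'
#' One edge per row whose endpoints resolve via the (label, identifier)
#' index. Rows with an unresolvable endpoint are skipped and logged on the
#' store (observable via [store_log()]), never fatal. Extra columns become
#' edge properties.
#'
#' @param table data.frame with source and target identifier columns
#' @param type_name edge type string to assign
#' @param store a `graph_store`
#' @param source_label,target_label labels used to resolve endpoints
#' @param source_column,target_column identifier column names
#' @param list_columns list-valued edge property columns
#' @param extra_properties named list added to every edge
#' @return number of edges created
#' @export
load_edge_table <- function(table, type_name, store,
                            source_label, target_label,
                            source_column = "source_id",
                            target_column = "target_id",
                            list_columns = character(0),
                            extra_properties = list()) {
  for (col in c(source_column, target_column)) {
    if (!col %in% names(table)) stop("edge table lacks column '", col, "'")
  }
  created <- 0L
  for (i in seq_len(nrow(table))) {
    src <- gs_lookup(store, source_label, "identifier", table[[source_column]][[i]])
    dst <- gs_lookup(store, target_label, "identifier", table[[target_column]][[i]])
    if (length(src) == 0 || length(dst) == 0) {
      gs_log(store, "edge_row_skipped", type = type_name, row = i,
             reason = if (length(src) == 0) {
               paste0("unresolved source '", table[[source_column]][[i]], "'")
             } else {
               paste0("unresolved target '", table[[target_column]][[i]], "'")
             })
      next
    }
    props <- list()
    for (col in setdiff(names(table), c(source_column, target_column))) {
      cell <- table[[col]][[i]]
      if (is.na(cell) || !nzchar(cell)) next
      props[[col]] <- if (col %in% list_columns) split_list_cell(cell) else cell
    }
    for (nm in names(extra_properties)) props[[nm]] <- extra_properties[[nm]]
    gs_add_edge(store, type_name, src[[1]], dst[[1]], props)
    created <- created + 1L
  }
  created
}
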