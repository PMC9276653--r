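# Technical validation of the merged graph and final subgraph extraction.
# Validators return reports (never raise) so callers can emit
# machine-readable output and choose their own exit semantics.

validation_report <- function(violations, checked) {
  structure(list(violations = violations, checked = checked),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %d checked, %d violations>\n",
              sum(unlist(x$checked)), nrow(x$violations)))
  invisible(x)
}

violations_df <- function(rows) {
  if (length(rows) == 0) return(empty_df(c("entity_id", "rule", "message")))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("entity_id", "rule", "message")
  df
}

#' Validate edge-type names against the naming grammar and node labels
#'
#' An edge is a violation iff its type does not parse under the grammar or
#' the parsed source/target abbreviations are not abbreviations of labels
#' carried by the incident nodes.
#'
#' @param store a `graph_store`
#' @param registry abbreviation registry
#' @return a `validation_report`
#' @export
validate_edge_names <- function(store, registry = abbreviation_registry()) {
  rows <- list()
  checked <- 0L
  for (eid in gs_edge_ids(store)) {
    e <- store$edges[[eid]]
    checked <- checked + 1L
    p <- parse_edge_type(e$type, registry)
    if (!isTRUE(p$ok)) {
      rows[[length(rows) + 1L]] <- c(eid, "edge_name_grammar",
                                     paste0(e$type, ": ", p$reason))
      next
    }
    if (!(p$src_label %in% store$nodes[[e$source]]$labels)) {
      rows[[length(rows) + 1L]] <- c(eid, "edge_name_source_label",
        paste0(e$type, ": source node lacks label ", p$src_label))
    }
    if (!(p$dst_label %in% store$nodes[[e$target]]$labels)) {
      rows[[length(rows) + 1L]] <- c(eid, "edge_name_target_label",
        paste0(e$type, ": target node lacks label ", p$dst_label))
    }
  }
  validation_report(violations_df(rows), list(edges = checked))
}

#' Validate the resource/tag contract
#'
#' For every data-source name in an entity's `resource` property a tag
#' property whose name starts with the lowercased source name must exist
#' on that entity.
#'
#' @param store a `graph_store`
#' @return a `validation_report`
#' @export
validate_resource_tags <- function(store) {
  rows <- list()
  checked <- 0L
  check_entity <- function(id, props) {
    resources <- as.character(unlist(props[["resource"]] %||% character(0)))
    for (res in resources) {
      checked <<- checked + 1L
      prefix <- tolower(gsub("[^A-Za-z0-9]", "", res))
      has_tag <- any(startsWith(tolower(names(props)), prefix))
      if (!has_tag) {
        rows[[length(rows) + 1L]] <<- c(id, "resource_tag",
          paste0("resource '", res, "' without a '", prefix, "*' tag property"))
      }
    }
  }
  for (nid in gs_node_ids(store)) check_entity(nid, store$nodes[[nid]]$properties)
  for (eid in gs_edge_ids(store)) check_entity(eid, store$edges[[eid]]$properties)
  validation_report(violations_df(rows), list(resources = checked))
}

#' Check that biological entities are human data
#'
#' A node of one of the listed labels whose taxon property exists and
#' differs from the configured human taxonomy id is a violation.
#'
#' @param store a `graph_store`
#' @param labels labels subject to the check
#' @param taxon_property property holding the NCBI taxonomy id
#' @param human_taxon the human taxonomy id (default 9606)
#' @return a `validation_report`
#' @export
check_human_only <- function(store,
                             labels = c("Gene", "Protein", "Pathway", "Variant",
                                        "SideEffect", "Symptom", "Phenotype"),
                             taxon_property = "taxon", human_taxon = 9606L) {
  rows <- list()
  checked <- 0L
  ids <- unique(unlist(lapply(labels, function(lb) gs_nodes_with_label(store, lb))))
  for (nid in ids) {
    node <- store$nodes[[nid]]
    tx <- prop_values(node, taxon_property)
    if (length(tx) == 0) next
    checked <- checked + 1L
    if (!all(suppressWarnings(as.integer(tx)) == as.integer(human_taxon), na.rm = FALSE) ||
        any(is.na(suppressWarnings(as.integer(tx))))) {
      rows[[length(rows) + 1L]] <- c(nid, "human_only",
        paste0("taxon ", paste(tx, collapse = ","), " != ", human_taxon))
    }
  }
  validation_report(violations_df(rows), list(nodes = checked))
}

#' Extract the merged subgraph (drop all source subgraphs)
#'
#' Returns a new store containing exactly the entities without a
#' source-subgraph marker (`source` property). No dangling edges are
#' produced; the input store is untouched. Idempotent.
#'
#' @param store a `graph_store`
#' @return a new `graph_store`
#' @export
extract_merged_subgraph <- function(store) {
  out <- graph_store()
  id_map <- new.env(parent = emptyenv())
  for (nid in gs_node_ids(store)) {
    node <- store$nodes[[nid]]
    if (!is.null(node$properties[["source"]])) next
    id_map[[nid]] <- gs_add_node(out, node$labels, node$properties)
  }
  for (eid in gs_edge_ids(store)) {
    e <- store$edges[[eid]]
    if (!is.null(e$properties[["source"]])) next
    src <- id_map[[e$source]]; dst <- id_map[[e$target]]
    if (is.null(src) || is.null(dst)) next  # edge touching a source subgraph
    gs_add_edge(out, e$type, src, dst, e$properties)
  }
  out
}

#' Extract live index definitions for the merged graph
#'
#' One definition per (label, property) index whose label survives
#' extraction (i.e. is carried by at least one merged-schema node).
#'
#' @param store a `graph_store` (pre-extraction)
#' @return data.frame with columns `label` and `property`
#' @export
extract_indices <- function(store) {
  merged <- extract_merged_subgraph(store)
  live_labels <- unique(unlist(lapply(gs_node_ids(merged), function(i) {
    merged$nodes[[i]]$labels
  })))
  labels <- lex_sort(intersect(ls(store$id_index), live_labels))
  out <- empty_df(c("label", "property"))
  for (i in seq_along(labels)) out[i, ] <- c(labels[[i]], "identifier")
  out
}
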