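# End-to-end orchestration: corpus -> prepare -> integrate -> merge ->
# validate -> extract. Mirrors the construction method's four stages.

#' Run the full forging pipeline over a corpus
#'
#' Prepares every source with the bundled adapter registry, loads the
#' hetnet seed graph, integrates the prepared sources as disconnected
#' subgraphs, executes the merge plan, validates, and extracts the merged
#' subgraph.
#'
#' @param corpus_dir corpus directory (from [generate_corpus()])
#' @param work_dir working directory for prepared outputs (default: a
#'   subdirectory `prepared/` of `corpus_dir`'s parent is NOT used; a
#'   temporary directory is created)
#' @param plan merge plan (default [default_merge_plan()])
#' @return list with `store` (full graph incl. source subgraphs), `merged`
#'   (extracted merged graph), `prepare_report`, `integrate_report`,
#'   `merge_report`, `validation` (edge-name, resource-tag and human-only
#'   reports on the merged graph), `indices`
#' @export
forge_pipeline <- function(corpus_dir, work_dir = tempfile("prepared"),
                           plan = default_merge_plan()) {
  prepare_report <- forge_prepare(corpus_dir, work_dir)
  seed_path <- file.path(corpus_dir, "hetionet", "seed.graphml")
  store <- if (file.exists(seed_path)) read_graphml(seed_path) else graph_store()
  integrate_report <- integrate_sources(store, work_dir)
  xrefs <- load_xref_tables(file.path(corpus_dir, "xrefs"))
  merge_report <- run_merge(store, work_dir, plan = plan, xrefs = xrefs)
  merged <- extract_merged_subgraph(store)
  validation <- list(
    edge_names = validate_edge_names(merged),
    resource_tags = validate_resource_tags(merged),
    human_only = check_human_only(merged))
  list(store = store, merged = merged,
       prepare_report = prepare_report,
       integrate_report = integrate_report,
       merge_report = merge_report,
       validation = validation,
       indices = extract_indices(store))
}

# canonical signatures for graph comparison (identifier + sorted labels /
# type + endpoint identifiers)
node_signatures <- function(store) {
  ids <- gs_node_ids(store)
  sort(vapply(ids, function(i) {
    node <- store$nodes[[i]]
    paste0(node_identifier(node), "\x1f",
           join_list_cell(lex_sort(node$labels)))
  }, "", USE.NAMES = FALSE))
}

edge_signatures <- function(store) {
  ids <- gs_edge_ids(store)
  sort(vapply(ids, function(i) {
    e <- store$edges[[i]]
    paste0(e$type, "\x1f", node_identifier(store$nodes[[e$source]]), "\x1f",
           node_identifier(store$nodes[[e$target]]))
  }, "", USE.NAMES = FALSE))
}

#' Compare a merged graph against ground-truth tables
#'
#' @param merged a `graph_store`
#' @param truth result of [read_truth()]
#' @return list with `nodes_equal`, `edges_equal`, and the differing
#'   signatures (`missing_*` expected but absent, `extra_*` present but
#'   unexpected)
#' @export
compare_to_truth <- function(merged, truth) {
  got_nodes <- node_signatures(merged)
  want_nodes <- sort(paste0(truth$nodes$identifier, "\x1f",
                            vapply(truth$nodes$labels, function(l) {
                              join_list_cell(lex_sort(split_list_cell(l)))
                            }, "", USE.NAMES = FALSE)))
  got_edges <- edge_signatures(merged)
  want_edges <- sort(paste0(truth$edges$type, "\x1f", truth$edges$source_id,
                            "\x1f", truth$edges$target_id))
  list(nodes_equal = identical(got_nodes, want_nodes),
       edges_equal = identical(got_edges, want_edges),
       missing_nodes = setdiff(want_nodes, got_nodes),
       extra_nodes = setdiff(got_nodes, want_nodes),
       missing_edges = setdiff(want_edges, got_edges),
       extra_edges = setdiff(got_edges, want_edges))
}
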