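# Integration: load every prepared source into one store as disconnected
# subgraphs. Source-subgraph nodes get the label "<source>.<Label>" and a
# "source" marker property; source edges get type "<source>.<TYPE>".
# Cross-source link tables (emitted as plain tables by adapters) are not
# integrated -- merge routines consume them during mapping.

LIST_PROPERTY_COLUMNS <- c("synonyms", "synonym_scopes", "xrefs", "pubmed_ids",
                           "members", "resource", "symbols")

source_label <- function(source, label) paste(source, label, sep = ".")

#' Integrate all prepared sources into a store as disconnected subgraphs
#'
#' @param store a `graph_store` (typically already holding the hetnet seed)
#' @param prepared_dir output directory of [forge_prepare()]
#' @return named list per source with node/edge load counts
#' @export
integrate_sources <- function(store, prepared_dir) {
  reports <- list()
  for (src in lex_sort(list.dirs(prepared_dir, recursive = FALSE, full.names = FALSE))) {
    dir <- file.path(prepared_dir, src)
    nodes_loaded <- 0L; edges_loaded <- 0L
    node_files <- lex_sort(list.files(dir, pattern = "^nodes_.*\\.tsv$"))
    for (f in node_files) {
      label <- sub("^nodes_(.*)\\.tsv$", "\\1", f)
      df <- read_table_file(file.path(dir, f))
      nodes_loaded <- nodes_loaded + load_node_table(
        df, source_label(src, label), store,
        list_columns = intersect(LIST_PROPERTY_COLUMNS, names(df)),
        on_duplicate = "merge",
        extra_properties = list(source = src))
    }
    edge_files <- lex_sort(list.files(dir, pattern = "^edges_.*\\.tsv$"))
    for (f in edge_files) {
      parts <- strsplit(sub("^edges_(.*)\\.tsv$", "\\1", f), "__", fixed = TRUE)[[1]]
      if (length(parts) != 3) stop("bad edge file name: ", f)
      df <- read_table_file(file.path(dir, f))
      edges_loaded <- edges_loaded + load_edge_table(
        df, source_label(src, parts[[1]]), store,
        source_label(src, parts[[2]]), source_label(src, parts[[3]]),
        list_columns = intersect(LIST_PROPERTY_COLUMNS, names(df)),
        extra_properties = list(source = src))
    }
    for (f in lex_sort(list.files(dir, pattern = "\\.graphml$"))) {
      sub_store <- read_graphml(file.path(dir, f))
      id_map <- list()
      for (nid in gs_node_ids(sub_store)) {
        node <- sub_store$nodes[[nid]]
        props <- node$properties
        props$source <- src
        id_map[[nid]] <- gs_add_node(store,
                                     vapply(node$labels, function(l) source_label(src, l), ""),
                                     props)
        nodes_loaded <- nodes_loaded + 1L
      }
      for (eid in gs_edge_ids(sub_store)) {
        e <- sub_store$edges[[eid]]
        props <- e$properties
        props$source <- src
        gs_add_edge(store, source_label(src, e$type),
                    id_map[[e$source]], id_map[[e$target]], props)
        edges_loaded <- edges_loaded + 1L
      }
    }
    reports[[src]] <- list(nodes = nodes_loaded, edges = edges_loaded)
  }
  reports
}

# convenience accessors for merge routines
src_nodes <- function(store, source, label) {
  gs_nodes_with_label(store, source_label(source, label))
}

src_edges <- function(store, source, type) {
  gs_edges_with_type(store, source_label(source, type))
}

# read a prepared link table, returning an empty frame when absent
prepared_table <- function(prepared_dir, source, file, required_cols = character(0)) {
  path <- file.path(prepared_dir, source, file)
  if (!file.exists(path)) return(empty_df(required_cols))
  read_table_file(path)
}
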