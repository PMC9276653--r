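# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: the path oracle enumerates walks over the raw
# edge list, the index oracle scans nodes linearly, the similarity oracle
# recomputes scores from logical vectors.

random_store <- function(seed, n_nodes = 8, n_edges = 10,
                         labels = c("Gene", "Disease", "Chemical")) {
  set.seed(seed)
  s <- graph_store()
  ids <- character(n_nodes)
  for (i in seq_len(n_nodes)) {
    props <- list(identifier = sprintf("N%03d", i),
                  name = paste0("entity ", i),
                  score = as.numeric(round(stats::runif(1), 3)))
    if (stats::runif(1) < 0.5) {
      props$synonyms <- paste0("syn", sample(1:4, sample(1:3, 1)))
    }
    ids[[i]] <- gs_add_node(s, sample(labels, 1), props)
  }
  types <- c("RELATES_TO", "LINKS_WITH", "AFFECTS")
  for (i in seq_len(n_edges)) {
    pair <- sample(ids, 2)
    gs_add_edge(s, sample(types, 1), pair[[1]], pair[[2]],
                list(weight = as.numeric(round(stats::runif(1), 3))))
  }
  s
}

# exhaustive walk enumeration over the raw edge list (no incidence index,
# no DFS ordering logic)
brute_force_paths <- function(store, pattern) {
  node_ok <- function(id, c) {
    node <- gs_get_node(store, id)
    if (!is.null(c$label) && !(c$label %in% node$labels)) return(FALSE)
    for (nm in names(c$props %||% list())) {
      vals <- as.character(unlist(node$properties[[nm]]))
      if (!(as.character(c$props[[nm]]) %in% vals)) return(FALSE)
    }
    TRUE
  }
  edges <- lapply(gs_edge_ids(store), function(i) gs_get_edge(store, i))
  k <- length(pattern$nodes)
  results <- list()
  extend <- function(path) {
    depth <- length(path)
    if (depth == k) {
      results[[length(results) + 1L]] <<- path
      return(invisible(NULL))
    }
    c_edge <- pattern$edges[[depth]]
    cur <- path[[depth]]
    for (e in edges) {
      nxts <- character(0)
      dir <- c_edge$direction %||% "any"
      if (identical(e$source, cur) && dir %in% c("out", "any")) nxts <- c(nxts, e$target)
      if (identical(e$target, cur) && dir %in% c("in", "any")) nxts <- c(nxts, e$source)
      if (!is.null(c_edge$type) && !identical(e$type, c_edge$type)) next
      if (!is.null(c_edge$type_pattern) && !grepl(c_edge$type_pattern, e$type)) next
      for (nxt in unique(nxts)) {
        if (node_ok(nxt, pattern$nodes[[depth + 1L]])) extend(c(path, nxt))
      }
    }
  }
  for (id in gs_node_ids(store)) {
    if (node_ok(id, pattern$nodes[[1]])) extend(id)
  }
  results
}

path_key <- function(p) paste(p, collapse = ">")

# linear-scan lookup oracle
scan_lookup <- function(store, label, prop, value) {
  hits <- character(0)
  for (id in gs_node_ids(store)) {
    node <- gs_get_node(store, id)
    if (!(label %in% node$labels)) next
    vals <- as.character(unlist(node$properties[[prop]]))
    if (as.character(value) %in% vals) hits <- c(hits, id)
  }
  sort(hits)
}

random_fingerprint <- function(bits = 256L, density = 0.2, gid = "test") {
  on <- which(stats::runif(bits) < density)
  if (length(on) == 0) on <- sample.int(bits, 1)
  make_fingerprint(on, bits, gid)
}

# similarity scores from dense logical vectors (independent of the set
# representation the implementation uses)
logical_tanimoto <- function(a, b) {
  va <- rep(FALSE, a$length); va[a$on] <- TRUE
  vb <- rep(FALSE, b$length); vb[b$on] <- TRUE
  u <- sum(va | vb)
  if (u == 0) return(0)
  sum(va & vb) / u
}

make_test_corpus <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("kgforge-corpus-", seed))
      if (!dir.exists(dir)) generate_corpus(dir, fixture_manifest(seed = seed))
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})

run_test_pipeline <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      corpus <- make_test_corpus(seed)
      cache[[key]] <- forge_pipeline(corpus,
                                     work_dir = file.path(tempdir(),
                                                          paste0("kgforge-prep-", seed)))
    }
    cache[[key]]
  }
})
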