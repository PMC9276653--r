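# Property-graph store: table loading, indexed lookup, GraphML
# round-trips, and path search.

test_that("node tables load row-per-node with duplicate policies", {
  s <- graph_store()
  tab <- data.frame(identifier = c("MONDO:1", "MONDO:2"),
                    name = c("a", "b"), stringsAsFactors = FALSE)
  expect_equal(load_node_table(tab, "Disease", s), 2L)
  expect_length(gs_nodes_with_label(s, "Disease"), 2L)

  # empty table: header only, no nodes, no error
  s2 <- graph_store()
  expect_equal(load_node_table(tab[0, ], "Disease", s2), 0L)
  expect_equal(gs_counts(s2)$nodes, 0L)

  # duplicates: reject by default, merge-properties keeps distinct count
  dup <- data.frame(identifier = c("g1", "g2", "g1"),
                    synonyms = c("a", "x", "b"), stringsAsFactors = FALSE)
  expect_error(load_node_table(dup, "Gene", graph_store()), "duplicate identifier")
  s3 <- graph_store()
  n <- load_node_table(dup, "Gene", s3, list_columns = "synonyms",
                       on_duplicate = "merge")
  expect_equal(n, length(unique(dup$identifier)))
  merged <- gs_get_node(s3, gs_lookup(s3, "Gene", "identifier", "g1"))
  expect_setequal(merged$properties$synonyms, c("a", "b"))

  expect_error(load_node_table(data.frame(x = 1), "Gene", graph_store()),
               "identifier")
})

test_that("duplicate-merge count equals distinct identifiers on generated tables", {
  set.seed(7)
  for (rep in 1:5) {
    ids <- sample(sprintf("g%02d", 1:12), 20, replace = TRUE)
    tab <- data.frame(identifier = ids, v = as.character(seq_along(ids)),
                      stringsAsFactors = FALSE)
    s <- graph_store()
    expect_equal(load_node_table(tab, "Gene", s, on_duplicate = "merge"),
                 length(unique(ids)))
  }
})

test_that("edge tables resolve endpoints and log skipped rows", {
  s <- graph_store()
  load_node_table(data.frame(identifier = c("a", "b", "c")), "Gene", s)
  tab <- data.frame(source_id = c("a", "b", "a"), target_id = c("b", "c", "zz"),
                    weight = c("1", "2", "3"), stringsAsFactors = FALSE)
  expect_equal(load_edge_table(tab, "RELATES_TO", s, "Gene", "Gene"), 2L)
  skips <- Filter(function(x) identical(x$event, "edge_row_skipped"), store_log(s))
  expect_length(skips, 1L)
  expect_match(skips[[1]]$reason, "zz")
  # no dangling edges ever
  for (eid in gs_edge_ids(s)) {
    e <- gs_get_edge(s, eid)
    expect_false(is.null(gs_get_node(s, e$source)))
    expect_false(is.null(gs_get_node(s, e$target)))
  }
})

test_that("created edge count equals rows minus unresolvable rows (join oracle)", {
  set.seed(11)
  for (rep in 1:5) {
    present <- sprintf("n%02d", 1:10)
    s <- graph_store()
    load_node_table(data.frame(identifier = present), "Gene", s)
    src <- sample(c(present, "missing1", "missing2"), 25, replace = TRUE)
    dst <- sample(c(present, "missing3"), 25, replace = TRUE)
    tab <- data.frame(source_id = src, target_id = dst, stringsAsFactors = FALSE)
    expected <- sum(src %in% present & dst %in% present)
    expect_equal(load_edge_table(tab, "R", s, "Gene", "Gene"), expected)
  }
})

test_that("index lookups agree with linear scan on every triple", {
  for (seed in 1:6) {
    s <- random_store(seed, n_nodes = 12, n_edges = 15)
    for (label in c("Gene", "Disease", "Chemical")) {
      for (prop in c("identifier", "name", "synonyms")) {
        vals <- unique(unlist(lapply(gs_node_ids(s), function(i) {
          as.character(unlist(gs_get_node(s, i)$properties[[prop]]))
        })))
        for (v in vals) {
          expect_equal(gs_lookup(s, label, prop, v), scan_lookup(s, label, prop, v))
        }
      }
    }
  }
})

test_that("node removal cascades incident edges and degree bookkeeping holds", {
  s <- graph_store()
  a <- gs_add_node(s, "Gene", list(identifier = "a"))
  b <- gs_add_node(s, "Gene", list(identifier = "b"))
  c <- gs_add_node(s, "Gene", list(identifier = "c"))
  gs_add_edge(s, "R", a, b)
  gs_add_edge(s, "R", b, c)
  gs_add_edge(s, "R", a, c)
  expect_equal(gs_degree(s, b), 2L)
  expect_equal(gs_remove_node(s, b), 2L)
  expect_equal(gs_counts(s), list(nodes = 2L, edges = 1L))
  expect_equal(gs_degree(s, a), 1L)
})

test_that("GraphML write-then-read is the identity", {
  s <- random_store(3, n_nodes = 10, n_edges = 12)
  path <- tempfile(fileext = ".graphml")
  write_graphml(s, path)
  r <- read_graphml(path)
  expect_identical(kgforge:::node_signatures(r), kgforge:::node_signatures(s))
  expect_identical(kgforge:::edge_signatures(r), kgforge:::edge_signatures(s))
  # element-wise property equality (numbers and list values included)
  for (id in gs_node_ids(s)) {
    ident <- gs_get_node(s, id)$properties$identifier
    rid <- gs_lookup(r, gs_get_node(s, id)$labels[[1]], "identifier", ident)
    got <- gs_get_node(r, rid)$properties
    want <- gs_get_node(s, id)$properties
    expect_equal(got[order(names(got))], want[order(names(want))])
  }

  # empty graph round-trips to a valid zero-node document
  empty_path <- tempfile(fileext = ".graphml")
  write_graphml(graph_store(), empty_path)
  r0 <- read_graphml(empty_path)
  expect_equal(gs_counts(r0), list(nodes = 0L, edges = 0L))
})

test_that("malformed GraphML and unknown keys raise format errors", {
  bad <- tempfile(fileext = ".graphml")
  writeLines("<graphml><node id=", bad)
  expect_error(read_graphml(bad), "malformed")
  unk <- tempfile(fileext = ".graphml")
  writeLines(paste0('<graphml><graph><node id="n1">',
                    '<data key="nope">x</data></node></graph></graphml>'), unk)
  expect_error(read_graphml(unk), "unknown attribute key")
})

test_that("path search equals exhaustive walk enumeration on random graphs", {
  for (seed in 1:8) {
    s <- random_store(seed, n_nodes = 10, n_edges = 14)
    pattern <- path_pattern(
      nodes = list(list(label = "Gene"), list(), list(label = "Disease")),
      edges = list(list(direction = "any"), list(type = "RELATES_TO",
                                                 direction = "any")))
    got <- find_paths(s, pattern)
    want <- brute_force_paths(s, pattern)
    expect_setequal(vapply(got, function(p) path_key(p$nodes), ""),
                    vapply(want, path_key, ""))
  }
})

test_that("path results are deterministically ordered and respect max_results", {
  s <- random_store(5, n_nodes = 10, n_edges = 16)
  pattern <- path_pattern(nodes = list(list(), list()),
                          edges = list(list(direction = "out")))
  a <- find_paths(s, pattern)
  b <- find_paths(s, pattern)
  expect_identical(a, b)
  expect_length(find_paths(s, pattern, max_results = 3), 3L)
  expect_identical(find_paths(graph_store(), pattern), list())
})
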