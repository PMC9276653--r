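# Validators and final-graph extraction.

test_that("edge-name validation flags grammar and label mismatches", {
  s <- graph_store()
  ch <- gs_add_node(s, c("Compound", "Chemical"), list(identifier = "c"))
  d <- gs_add_node(s, "Disease", list(identifier = "d"))
  gs_add_edge(s, "TREATS_CHtD", ch, d)
  expect_equal(nrow(validate_edge_names(s)$violations), 0L)
  # source abbreviation names a label the node does not carry
  gs_add_edge(s, "TREATS_GtD", ch, d)
  rep <- validate_edge_names(s)
  expect_equal(nrow(rep$violations), 1L)
  expect_match(rep$violations$message, "lacks label Gene")
  gs_add_edge(s, "not_a_type", ch, d)
  expect_equal(nrow(validate_edge_names(s)$violations), 2L)
})

test_that("randomized type corruption yields exactly k violations", {
  set.seed(89)
  pipeline <- run_test_pipeline(42L)
  for (k in c(1L, 3L, 5L)) {
    merged <- extract_merged_subgraph(pipeline$store)
    eids <- sample(gs_edge_ids(merged), k)
    for (eid in eids) gs_set_edge(merged, eid, type = "BROKEN_XXxxYY")
    rep <- validate_edge_names(merged)
    expect_equal(nrow(rep$violations), k)
  }
})

test_that("resource names require a matching tag property", {
  s <- graph_store()
  ok <- gs_add_node(s, "Gene", list(identifier = "g1", resource = "CTD",
                                    ctd_id = "123"))
  expect_equal(nrow(validate_resource_tags(s)$violations), 0L)
  gs_add_node(s, "Gene", list(identifier = "g2", resource = "CTD"))
  rep <- validate_resource_tags(s)
  expect_equal(nrow(rep$violations), 1L)
  expect_match(rep$violations$message, "CTD")
  # planted k missing tags -> k violations (nodes and edges both checked)
  gs_add_edge(s, "R_GrG", ok, ok, list(resource = "SIDER"))
  expect_equal(nrow(validate_resource_tags(s)$violations), 2L)
})

test_that("human-only check flags non-human taxa on guarded labels", {
  s <- graph_store()
  gs_add_node(s, "Gene", list(identifier = "g1", taxon = "9606"))
  expect_equal(nrow(check_human_only(s)$violations), 0L)
  gs_add_node(s, "Gene", list(identifier = "g2", taxon = "10090"))
  gs_add_node(s, "Chemical", list(identifier = "c1", taxon = "10090"))  # not guarded
  rep <- check_human_only(s)
  expect_equal(nrow(rep$violations), 1L)
  # random taxa equal the non-human count oracle
  set.seed(97)
  s2 <- graph_store()
  taxa <- sample(c("9606", "10090", "63221"), 30, replace = TRUE)
  for (i in seq_along(taxa)) {
    gs_add_node(s2, "Protein", list(identifier = paste0("p", i), taxon = taxa[[i]]))
  }
  expect_equal(nrow(check_human_only(s2)$violations), sum(taxa != "9606"))
})

test_that("extraction keeps exactly the unmarked entities, no dangling edges", {
  s <- graph_store()
  m1 <- gs_add_node(s, "Gene", list(identifier = "g1"))
  m2 <- gs_add_node(s, "Gene", list(identifier = "g2"))
  src <- gs_add_node(s, "mondo.Term", list(identifier = "t1", source = "mondo"))
  gs_add_edge(s, "R_GrG", m1, m2)
  gs_add_edge(s, "mondo.is_a", src, src, list(source = "mondo"))
  out <- extract_merged_subgraph(s)
  expect_equal(gs_counts(out), list(nodes = 2L, edges = 1L))
  # input untouched; extraction idempotent
  expect_equal(gs_counts(s), list(nodes = 3L, edges = 2L))
  again <- extract_merged_subgraph(out)
  expect_identical(kgforge:::node_signatures(again), kgforge:::node_signatures(out))

  # all-merged graph extracts to an identity copy
  s2 <- random_store(7)
  out2 <- extract_merged_subgraph(s2)
  expect_identical(kgforge:::node_signatures(out2), kgforge:::node_signatures(s2))
  expect_identical(kgforge:::edge_signatures(out2), kgforge:::edge_signatures(s2))
})

test_that("random partitions extract per the predicate-filter oracle", {
  set.seed(101)
  for (rep in 1:10) {
    s <- random_store(rep + 200, n_nodes = 12, n_edges = 16)
    marked <- sample(gs_node_ids(s), 5)
    for (id in marked) {
      node <- gs_get_node(s, id)
      node$properties$source <- "src"
      gs_set_node(s, id, properties = node$properties)
    }
    out <- extract_merged_subgraph(s)
    keep <- setdiff(gs_node_ids(s), marked)
    expect_equal(gs_counts(out)$nodes, length(keep))
    want_edges <- sum(vapply(gs_edge_ids(s), function(eid) {
      e <- gs_get_edge(s, eid)
      e$source %in% keep && e$target %in% keep && is.null(e$properties$source)
    }, logical(1)))
    expect_equal(gs_counts(out)$edges, want_edges)
  }
})

test_that("index extraction reports only labels surviving extraction", {
  s <- graph_store()
  gs_add_node(s, "Chemical", list(identifier = "c"))
  gs_add_node(s, "Gene", list(identifier = "g"))
  gs_add_node(s, "mondo.Term", list(identifier = "t", source = "mondo"))
  idx <- extract_indices(s)
  expect_setequal(idx$label, c("Chemical", "Gene"))
  expect_true(all(idx$property == "identifier"))
})
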