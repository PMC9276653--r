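# Merge-engine primitives: renames, node replacement, edge match-or-create,
# edge nodes, label hierarchy, EQUAL and allele edges.

test_that("bulk renames retype exactly the mapped edges", {
  s <- graph_store()
  a <- gs_add_node(s, "Compound", list(identifier = "c1"))
  b <- gs_add_node(s, "SideEffect", list(identifier = "se1"))
  for (i in 1:3) gs_add_edge(s, "CAUSES_CcSE", a, b)
  gs_add_edge(s, "OTHER_CoC", a, a)
  expect_equal(apply_renames(s, default_rename_map()), 3L)
  expect_length(gs_edges_with_type(s, "CAUSES_CHcSE"), 3L)
  expect_length(gs_edges_with_type(s, "CAUSES_CcSE"), 0L)
  expect_length(gs_edges_with_type(s, "OTHER_CoC"), 1L)
  expect_equal(apply_renames(s, c()), 0L)
})

test_that("per-type counts are conserved under a rename permutation", {
  s <- random_store(61, n_nodes = 10, n_edges = 30)
  before <- table(vapply(gs_edge_ids(s), function(i) gs_get_edge(s, i)$type, ""))
  map <- c(RELATES_TO = "LINKED_A", LINKS_WITH = "LINKED_B", AFFECTS = "LINKED_C")
  apply_renames(s, map)
  after <- table(vapply(gs_edge_ids(s), function(i) gs_get_edge(s, i)$type, ""))
  for (old in names(map)) {
    expect_equal(unname(after[map[[old]]]),
                 unname(before[old]))
  }
})

replacement_fixture <- function() {
  s <- graph_store()
  d1 <- gs_add_node(s, "Disease", list(identifier = "DOID:1", name = "one"))
  d2 <- gs_add_node(s, "Disease", list(identifier = "DOID:2", name = "two"))
  g <- gs_add_node(s, "Gene", list(identifier = "g1"))
  gs_add_edge(s, "ASSOCIATES_DaG", d1, g)
  gs_add_edge(s, "ASSOCIATES_DaG", d2, g)
  list(store = s, d1 = d1, d2 = d2, g = g)
}

test_that("replacement preserves edges of matched nodes and removes the rest", {
  fx <- replacement_fixture()
  repl <- data.frame(identifier = c("NEW:1", "NEW:3"),
                     do_id = c("DOID:1", ""), name = c("one prime", "three"),
                     stringsAsFactors = FALSE)
  res <- replace_or_remove_nodes(fx$store, "Disease", repl, match_key = "do_id",
                                 source = "TestSrc")
  expect_equal(res, list(replaced = 1L, removed = 1L, created = 1L))
  # the replaced node kept its surrogate id, hence its edge
  expect_equal(gs_degree(fx$store, fx$d1), 1L)
  expect_identical(gs_get_node(fx$store, fx$d1)$properties$identifier, "NEW:1")
  expect_null(gs_get_node(fx$store, fx$d2))
  expect_length(gs_edge_ids(fx$store), 1L)

  # replacement equal to the existing set: (n, 0, 0), edges untouched
  fx2 <- replacement_fixture()
  same <- data.frame(identifier = c("DOID:1", "DOID:2"),
                     do_id = c("DOID:1", "DOID:2"), stringsAsFactors = FALSE)
  res2 <- replace_or_remove_nodes(fx2$store, "Disease", same, match_key = "do_id",
                                  source = "TestSrc")
  expect_equal(res2, list(replaced = 2L, removed = 0L, created = 0L))
  expect_length(gs_edge_ids(fx2$store), 2L)
  expect_error(replace_or_remove_nodes(fx2$store, "Disease",
                                       same[c(1, 1), ], match_key = "do_id",
                                       source = "TestSrc"),
               "duplicate match keys")
})

test_that("replacement final node set equals the replacement keys (set oracle)", {
  set.seed(67)
  for (rep in 1:20) {
    s <- graph_store()
    old_ids <- sprintf("OLD:%d", 1:6)
    nodes <- vapply(old_ids, function(i) {
      gs_add_node(s, "Disease", list(identifier = i))
    }, "")
    anchor <- gs_add_node(s, "Gene", list(identifier = "g"))
    for (n in nodes) if (stats::runif(1) < 0.7) gs_add_edge(s, "ASSOCIATES_DaG", n, anchor)
    matched <- sample(old_ids, sample(0:6, 1))
    fresh <- sprintf("NEW:%d", seq_len(sample(0:3, 1)))
    repl <- data.frame(identifier = c(paste0("R_", matched), fresh),
                       do_id = c(matched, rep("", length(fresh))),
                       stringsAsFactors = FALSE)
    degrees_before <- vapply(nodes[old_ids %in% matched],
                             function(n) gs_degree(s, n), 0L)
    replace_or_remove_nodes(s, "Disease", repl, match_key = "do_id",
                            source = "TestSrc")
    final <- vapply(gs_nodes_with_label(s, "Disease"), function(i) {
      gs_get_node(s, i)$properties$identifier
    }, "")
    expect_setequal(final, repl$identifier)
    # replaced nodes keep their degree
    degrees_after <- vapply(nodes[old_ids %in% matched],
                            function(n) gs_degree(s, n), 0L)
    expect_equal(degrees_after, degrees_before)
    # surviving edges are those whose endpoints survive
    for (eid in gs_edge_ids(s)) {
      e <- gs_get_edge(s, eid)
      expect_false(is.null(gs_get_node(s, e$source)))
      expect_false(is.null(gs_get_node(s, e$target)))
    }
  }
})

test_that("merge_edge is an idempotent match-or-create", {
  s <- graph_store()
  a <- gs_add_node(s, "Chemical", list(identifier = "c"))
  b <- gs_add_node(s, "Disease", list(identifier = "d"))
  expect_equal(merge_edge(s, a, b, "TREATS_CHtD", source = "S1"), "created")
  expect_equal(merge_edge(s, a, b, "TREATS_CHtD", source = "S2"), "updated")
  expect_length(gs_edge_ids(s), 1L)
  e <- gs_get_edge(s, gs_edge_ids(s))
  expect_setequal(e$properties$resource, c("S1", "S2"))
  # same endpoints, different type: a new edge
  expect_equal(merge_edge(s, a, b, "PALLIATES_CHpD", source = "S1"), "created")
  expect_length(gs_edge_ids(s), 2L)
  # match_on distinguishes otherwise-identical edges
  expect_equal(merge_edge(s, a, b, "TREATS_CHtD", list(phase = "2"),
                          match_on = "phase", source = "S1"), "created")
  expect_equal(merge_edge(s, a, b, "TREATS_CHtD", list(phase = "2"),
                          match_on = "phase", source = "S1"), "updated")
})

test_that("candidate edge batches split into created and updated per pair-set oracle", {
  set.seed(71)
  s <- graph_store()
  nodes <- vapply(1:6, function(i) {
    gs_add_node(s, "Chemical", list(identifier = paste0("c", i)))
  }, "")
  seen <- character(0)
  created <- 0L; updated <- 0L
  for (i in 1:40) {
    pair <- sample(nodes, 2)
    key <- paste(pair, collapse = ">")
    out <- merge_edge(s, pair[[1]], pair[[2]], "INTERACTS_CiC", source = "X")
    if (key %in% seen) {
      expect_equal(out, "updated"); updated <- updated + 1L
    } else {
      expect_equal(out, "created"); created <- created + 1L
      seen <- c(seen, key)
    }
  }
  expect_equal(length(gs_edge_ids(s)), created)
})

test_that("edge nodes reify n-ary connections with one edge per participant", {
  s <- graph_store()
  p1 <- gs_add_node(s, "Protein", list(identifier = "P1"))
  p2 <- gs_add_node(s, "Protein", list(identifier = "P2"))
  nid <- create_edge_node(s, "Interaction", "I1",
                          list(list(node = p1, relation = "INTERACTS",
                                    label = "Protein", direction = "out"),
                               list(node = p2, relation = "INTERACTS",
                                    label = "Protein", direction = "in")),
                          source = "IID")
  expect_length(gs_edges_with_type(s, "INTERACTS_IiP"), 1L)
  expect_length(gs_edges_with_type(s, "INTERACTS_PiI"), 1L)
  expect_equal(gs_get_edge(s, gs_edges_with_type(s, "INTERACTS_IiP"))$source, nid)

  ch <- gs_add_node(s, c("Compound", "Chemical"), list(identifier = "c"))
  d <- gs_add_node(s, "Disease", list(identifier = "d"))
  cc <- gs_add_node(s, "CellularComponent", list(identifier = "g"))
  create_edge_node(s, "Treatment", "T1",
                   list(list(node = ch, relation = "TREATS", label = "Chemical",
                             direction = "in"),
                        list(node = d, relation = "TREATS", label = "Disease",
                             direction = "out"),
                        list(node = cc, relation = "IS_LOCALIZED_IN",
                             label = "CellularComponent", direction = "out")),
                   source = "Reactome")
  for (t in c("TREATS_CHtT", "TREATS_TtD", "IS_LOCALIZED_IN_TiliCC")) {
    expect_length(gs_edges_with_type(s, t), 1L)
  }
  expect_error(create_edge_node(s, "Interaction", "I2",
                                list(list(node = p1, relation = "INTERACTS",
                                          label = "Protein")),
                                source = "IID"),
               "at least 2")
})

test_that("n interactions add n nodes and 2n edges", {
  s <- graph_store()
  prots <- vapply(1:8, function(i) {
    gs_add_node(s, "Protein", list(identifier = sprintf("P%02d", i)))
  }, "")
  before <- gs_counts(s)
  n <- 6L
  for (i in seq_len(n)) {
    create_edge_node(s, "Interaction", paste0("I", i),
                     list(list(node = prots[[i]], relation = "INTERACTS",
                               label = "Protein", direction = "out"),
                          list(node = prots[[i + 1]], relation = "INTERACTS",
                               label = "Protein", direction = "in")),
                     source = "IID")
  }
  after <- gs_counts(s)
  expect_equal(after$nodes - before$nodes, n)
  expect_equal(after$edges - before$edges, 2L * n)
})

test_that("label hierarchy closure is complete and idempotent", {
  s <- graph_store()
  gs_add_node(s, "Salt", list(identifier = "s1"))
  gs_add_node(s, "SideEffect", list(identifier = "se1"))
  gs_add_node(s, "Reaction", list(identifier = "r1"))
  expect_gt(apply_label_hierarchy(s), 0L)
  salt <- gs_get_node(s, gs_lookup(s, "Salt", "identifier", "s1"))
  expect_setequal(salt$labels, c("Salt", "Compound", "Chemical"))
  expect_equal(salt$labels[[1]], "Salt")  # primary label survives
  se <- gs_get_node(s, gs_lookup(s, "SideEffect", "identifier", "se1"))
  expect_setequal(se$labels, c("SideEffect", "Phenotype"))
  rle <- gs_get_node(s, gs_lookup(s, "Reaction", "identifier", "r1"))
  expect_setequal(rle$labels, c("Reaction", "ReactionLikeEvent"))
  expect_equal(apply_label_hierarchy(s), 0L)  # second application adds nothing
})

test_that("hierarchy closure equals a transitive-closure oracle", {
  hier <- default_label_hierarchy()
  closure_oracle <- function(labels) {
    out <- labels
    repeat {
      nxt <- unique(c(out, unlist(hier[intersect(out, names(hier))],
                                  use.names = FALSE)))
      if (setequal(nxt, out)) return(sort(out))
      out <- nxt
    }
  }
  set.seed(73)
  pool <- c(names(hier), "Gene", "Disease", "Pathway")
  for (i in 1:30) {
    s <- graph_store()
    labels <- sample(pool, sample(1:3, 1))
    gs_add_node(s, labels, list(identifier = "x"))
    apply_label_hierarchy(s)
    got <- gs_get_node(s, gs_node_ids(s))$labels
    expect_setequal(got, closure_oracle(labels))
  }
})

equal_fixture <- function() {
  s <- graph_store()
  gs_add_node(s, c("Disease", "Phenotype"),
              list(identifier = "D1", name = "migraine", umls = "C1"))
  gs_add_node(s, c("SideEffect", "Phenotype"),
              list(identifier = "SE1", name = "Migraine", umls = "C1"))
  gs_add_node(s, c("Symptom", "Phenotype"),
              list(identifier = "S1", name = "migraine"))
  gs_add_node(s, "Phenotype", list(identifier = "PT1", name = "odd pheno"))
  gs_add_node(s, c("SideEffect", "Phenotype"),
              list(identifier = "SE2", name = "odd pheno"))
  s
}

test_that("EQUAL edges link equal-meaning phenotype-class nodes once", {
  s <- equal_fixture()
  n <- generate_equal_edges(s)
  expect_equal(n, 4L)
  expect_length(gs_edges_with_type(s, "EQUAL_DeSE"), 1L)
  expect_length(gs_edges_with_type(s, "EQUAL_DeS"), 1L)
  expect_length(gs_edges_with_type(s, "EQUAL_SeSE"), 1L)
  expect_length(gs_edges_with_type(s, "EQUAL_PTeSE"), 1L)
  # direction follows the type: EQUAL_DeSE runs Disease -> SideEffect
  e <- gs_get_edge(s, gs_edges_with_type(s, "EQUAL_DeSE"))
  expect_equal(gs_get_node(s, e$source)$labels[[1]], "Disease")
  # rerun creates nothing new
  expect_equal(generate_equal_edges(s), 0L)
  # no shared keys, no edges
  s2 <- graph_store()
  gs_add_node(s2, "Disease", list(identifier = "D", name = "a"))
  gs_add_node(s2, "SideEffect", list(identifier = "S", name = "b"))
  expect_equal(generate_equal_edges(s2), 0L)
})

test_that("EQUAL edge set equals a pairwise key-intersection oracle", {
  set.seed(79)
  for (rep in 1:10) {
    s <- graph_store()
    classes <- c("Disease", "Symptom", "SideEffect", "Phenotype")
    keys <- sprintf("K%d", 1:4)
    planted <- list()
    for (i in 1:10) {
      cl <- sample(classes, 1)
      k <- sample(keys, 1)
      id <- sprintf("%s_%d", cl, i)
      gs_add_node(s, cl, list(identifier = id, name = k))
      planted[[i]] <- list(cl = cl, key = k, id = id)
    }
    got <- generate_equal_edges(s)
    pairs <- 0L
    typed <- list(c("Disease", "SideEffect"), c("Disease", "Symptom"),
                  c("Phenotype", "SideEffect"), c("Symptom", "SideEffect"))
    for (i in 1:9) {
      for (j in (i + 1):10) {
        a <- planted[[i]]; b <- planted[[j]]
        if (identical(a$cl, b$cl) || !identical(a$key, b$key)) next
        if (any(vapply(typed, function(p) setequal(p, c(a$cl, b$cl)), logical(1)))) {
          pairs <- pairs + 1L
        }
      }
    }
    expect_equal(got, pairs)
  }
})

test_that("allele edges pair variants sharing an rs identifier", {
  s <- graph_store()
  for (i in 1:3) {
    gs_add_node(s, c("GeneVariant", "Variant"),
                list(identifier = paste0("V", i), rs_id = "rs123"))
  }
  gs_add_node(s, c("GeneVariant", "Variant"),
              list(identifier = "V9", rs_id = "rs999"))
  expect_equal(generate_allele_edges(s), choose(3, 2))
  expect_length(gs_edges_with_type(s, "IS_ALLEL_OF_ViaoV"), 3L)
  expect_equal(generate_allele_edges(s), 0L)  # dedup on rerun
  # random rs assignment equals the union of per-group pair counts
  set.seed(83)
  s2 <- graph_store()
  rs <- sample(sprintf("rs%d", 1:4), 12, replace = TRUE)
  for (i in seq_along(rs)) {
    gs_add_node(s2, c("GeneVariant", "Variant"),
                list(identifier = sprintf("W%02d", i), rs_id = rs[[i]]))
  }
  expect_equal(generate_allele_edges(s2),
               sum(choose(table(rs), 2)))
})

test_that("merged node properties keep existing values on conflict", {
  s <- graph_store()
  nid <- gs_add_node(s, "Disease", list(identifier = "D1", name = "one",
                                        resource = "Hetionet",
                                        hetionet_id = "D1"))
  merge_node_properties(s, nid, list(name = "uno", extra = "x"), "Mondo",
                        source_identifier = "MONDO:1")
  node <- gs_get_node(s, nid)
  expect_equal(node$properties$name, "one")
  expect_equal(node$properties$name_mondo, "uno")
  expect_equal(node$properties$extra, "x")
  expect_setequal(node$properties$resource, c("Hetionet", "Mondo"))
  expect_equal(node$properties$mondo_id, "MONDO:1")
  # idempotent on repeat
  before <- gs_get_node(s, nid)$properties
  merge_node_properties(s, nid, list(name = "uno", extra = "x"), "Mondo",
                        source_identifier = "MONDO:1")
  expect_equal(gs_get_node(s, nid)$properties, before)
})

test_that("a two-source plan shows order dependence: B updates what A created", {
  corpus <- make_test_corpus(42L)
  prepared <- file.path(tempdir(), "order-dep")
  unlink(prepared, recursive = TRUE)
  forge_prepare(corpus, prepared)
  store <- read_graphml(file.path(corpus, "hetionet", "seed.graphml"))
  integrate_sources(store, prepared)
  rep <- run_merge(store, prepared, plan = c("mondo", "do"))
  expect_gt(rep$created[rep$source == "mondo"], 0L)
  expect_gt(rep$updated[rep$source == "do"], 0L)   # DO lands on Mondo's nodes
  expect_equal(rep$created[rep$source == "do"], 0L)
})
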