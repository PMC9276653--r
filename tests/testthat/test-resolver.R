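# Entity resolution: normalization, cascades, xref bridging, reports.

test_that("name normalization lowercases, trims, and strips punctuation", {
  expect_equal(normalize_name("  Aspirin "), "aspirin")
  expect_equal(normalize_name("Warfarin"), normalize_name("warfarin"))
  expect_equal(normalize_name("Crohn's   disease;"), "crohns disease")
})

test_that("normalization is idempotent on random strings", {
  set.seed(41)
  pool <- c(letters, LETTERS, " ", ".", ",", ";", ":", "'", "-", "0":"9")
  for (i in 1:1000) {
    s <- paste(sample(pool, sample(1:25, 1), replace = TRUE), collapse = "")
    expect_identical(normalize_name(normalize_name(s)), normalize_name(s))
  }
})

resolver_store <- function() {
  s <- graph_store()
  gs_add_node(s, "Compound", list(identifier = "DB1", name = "Aspirin",
                                  cas = "50-78-2"))
  gs_add_node(s, "Compound", list(identifier = "DB2", name = "Warfarin",
                                  synonyms = c("Coumadin", "Jantoven")))
  gs_add_node(s, "Compound", list(identifier = "DB3", name = "Othermed",
                                  cas = "1-1-1", synonyms = "Coumadin"))
  s
}

test_that("identifier index is complete, exact, and preserves ambiguity", {
  s <- resolver_store()
  idx <- build_identifier_index(s, "Compound", "cas")
  expect_length(idx, 2L)
  expect_length(idx[["50-78-2"]], 1L)
  # two nodes sharing one value keep both ids
  gs_add_node(s, "Compound", list(identifier = "DB4", cas = "1-1-1"))
  idx2 <- build_identifier_index(s, "Compound", "cas")
  expect_length(idx2[["1-1-1"]], 2L)
  # random graph: index equals a scan-built map
  r <- random_store(19, n_nodes = 15)
  idx3 <- build_identifier_index(r, "Gene", "name")
  for (v in names(idx3)) {
    expect_setequal(idx3[[v]], scan_lookup(r, "Gene", "name", v))
  }
})

test_that("the first strategy producing candidates wins; later ones are ignored", {
  s <- resolver_store()
  # entity whose identifier points at DB1 but whose name matches DB2
  ent <- list(identifier = "x", cas = "50-78-2", name = "Warfarin")
  cascade <- mapping_cascade("chem", "Compound",
                             list(mapping_strategy("identifier", "cas"),
                                  mapping_strategy("name")))
  res <- resolve(ent, cascade, s)
  expect_equal(res$status, "unique")
  expect_equal(gs_get_node(s, res$matched)$properties$identifier, "DB1")
  expect_equal(res$strategy, "identifier:cas")
})

test_that("a name matching two synonyms is ambiguous, never auto-resolved", {
  s <- resolver_store()
  cascade <- mapping_cascade("chem", "Compound", list(mapping_strategy("name")))
  res <- resolve(list(identifier = "x", name = "Coumadin"), cascade, s)
  expect_equal(res$status, "ambiguous")
  expect_length(res$matched, 2L)
  expect_true(res$via_synonym)
  # entity with no keyed property at all is simply unmatched
  none <- resolve(list(identifier = "x"), cascade, s)
  expect_equal(none$status, "unmatched")
  expect_length(none$matched, 0L)
})

test_that("identifier-only cascades agree with a brute-force scan", {
  for (seed in 1:5) {
    s <- random_store(seed, n_nodes = 40)
    cascade <- mapping_cascade("x", "Gene",
                               list(mapping_strategy("identifier", "name")))
    for (probe in c("entity 3", "entity 11", "entity 99")) {
      res <- resolve(list(identifier = "q", name = probe), cascade, s)
      hits <- scan_lookup(s, "Gene", "name", probe)
      if (length(hits) == 0) expect_equal(res$status, "unmatched")
      else expect_setequal(res$matched, hits)
    }
  }
})

test_that("removing a later strategy never changes earlier-resolved entities", {
  s <- resolver_store()
  full <- mapping_cascade("chem", "Compound",
                          list(mapping_strategy("identifier", "cas"),
                               mapping_strategy("name")))
  short <- mapping_cascade("chem", "Compound",
                           list(mapping_strategy("identifier", "cas")))
  ent <- list(identifier = "x", cas = "50-78-2", name = "Warfarin")
  expect_identical(resolve(ent, full, s)$matched, resolve(ent, short, s)$matched)
})

test_that("xref bridging equals a two-step relational join", {
  s <- graph_store()
  n1 <- gs_add_node(s, "SideEffect", list(identifier = "C1", umls = "C1"))
  n2 <- gs_add_node(s, "SideEffect", list(identifier = "C2", umls = "C2"))
  tab <- data.frame(meddra = c("M1", "M1", "M2", "M3"),
                    umls = c("C1", "C2", "C2", "C9"), stringsAsFactors = FALSE)
  idx <- build_identifier_index(s, "SideEffect", "umls")
  expect_setequal(resolve_via_xref("M1", tab, idx), c(n1, n2))
  expect_equal(resolve_via_xref("M2", tab, idx), n2)
  expect_equal(resolve_via_xref("M3", tab, idx), character(0))  # bridge to nothing
  expect_equal(resolve_via_xref("MX", tab, idx), character(0))
  # random bipartite table equals merge() join oracle
  set.seed(29)
  rnd <- data.frame(a = sample(sprintf("A%d", 1:6), 20, TRUE),
                    b = sample(c("C1", "C2", "C9"), 20, TRUE))
  for (a in unique(rnd$a)) {
    bridged <- unique(rnd$b[rnd$a == a])
    want <- sort(unique(unlist(idx[bridged])))
    expect_equal(resolve_via_xref(a, rnd, idx), as.character(want %||% character(0)))
  }
})

test_that("cascades reject duplicate strategies and empty strategy lists", {
  expect_error(mapping_cascade("x", "Gene", list()), "at least one")
  expect_error(mapping_cascade("x", "Gene",
                               list(mapping_strategy("identifier", "cas"),
                                    mapping_strategy("identifier", "cas"))),
               "duplicate")
})

test_that("structure strategies match chemicals above the similarity threshold", {
  s <- graph_store()
  structs <- kgforge:::toy_structures()
  hex <- gs_add_node(s, "Compound", list(identifier = "HEX", name = "hexane"))
  benz <- gs_add_node(s, "Compound", list(identifier = "BENZ", name = "benzene"))
  fps <- fingerprint_set(c(structs$DB002, structs$DB001), ids = c(hex, benz))
  cascade <- mapping_cascade("chem", "Compound",
                             list(mapping_strategy("structure", key = "structure",
                                                   threshold = 0.75)))
  res <- resolve(list(identifier = "q", structure = structs$DB005), cascade, s,
                 fingerprints = fps)
  expect_equal(res$status, "unique")
  expect_equal(res$matched, hex)
})

test_that("mapping reports count outcomes and flag suspicious matches", {
  s <- resolver_store()
  cascade <- mapping_cascade("chem", "Compound",
                             list(mapping_strategy("identifier", "cas"),
                                  mapping_strategy("name")))
  ents <- list(list(identifier = "e1", cas = "50-78-2", name = "Acetylsalicylate"),
               list(identifier = "e2", name = "Coumadin"),
               list(identifier = "e3", name = "nothing here"))
  results <- lapply(ents, resolve, cascade = cascade, store = s)
  rep <- mapping_report(results, ents, s)
  expect_equal(sum(rep$counts$unique, rep$counts$ambiguous, rep$counts$unmatched),
               length(ents))
  # e1 matched by identifier but the names differ -> review list
  expect_equal(nrow(rep$review), 1L)
  expect_equal(rep$review$flag, "name_mismatch")
  # all-unmatched input gives zero-filled counts and an empty review list
  empty_rep <- mapping_report(list(resolve(list(identifier = "q"), cascade, s)))
  expect_equal(sum(empty_rep$counts$unique), 0L)
  expect_equal(nrow(empty_rep$review), 0L)
})
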