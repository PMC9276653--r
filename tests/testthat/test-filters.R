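# Per-source filter catalogue and the adapter engine.

test_that("taxon filter keeps only the configured organism", {
  rows <- data.frame(taxon = c("9606", "63221", "741158", "9606"),
                     g = letters[1:4], stringsAsFactors = FALSE)
  out <- filter_by_taxon(rows)
  expect_equal(out$g, c("a", "d"))
  # already-clean input is the identity
  clean <- rows[rows$taxon == "9606", ]
  expect_equal(filter_by_taxon(clean)$g, clean$g)
  # derived: surviving count equals the column-count oracle
  set.seed(3)
  mixed <- data.frame(taxon = sample(c("9606", "10090", "x"), 50, replace = TRUE))
  expect_equal(nrow(filter_by_taxon(mixed)), sum(mixed$taxon == "9606"))
})

test_that("direct-evidence filter drops empty and whitespace cells", {
  rows <- data.frame(DirectEvidence = c("therapeutic", "", "marker", "  "),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(filter_direct_evidence(rows)), 2L)
  full <- rows[rows$DirectEvidence == "therapeutic", , drop = FALSE]
  expect_equal(nrow(filter_direct_evidence(full)), 1L)
})

test_that("outcome-pair filter uses inclusive frequency and count bounds", {
  pairs <- data.frame(frequency = c("0.2", "0.2", "0.05", "0.1"),
                      count = c("150", "50", "150", "100"),
                      stringsAsFactors = FALSE)
  out <- filter_outcome_pairs(pairs)
  expect_equal(nrow(out), 2L)
  expect_true(all(as.numeric(out$frequency) >= 0.1 & as.numeric(out$count) >= 100))
  # boundary pair (exactly 0.1%, exactly 100) is retained
  expect_equal(nrow(filter_outcome_pairs(pairs[4, , drop = FALSE])), 1L)
  # grid of pairs equals brute-force predicate evaluation
  grid <- expand.grid(frequency = c(0.05, 0.09, 0.1, 0.2, 0.5),
                      count = c(10, 99, 100, 150))
  grid[] <- lapply(grid, as.character)
  keep <- as.numeric(grid$frequency) >= 0.1 & as.numeric(grid$count) >= 100
  expect_equal(nrow(filter_outcome_pairs(grid)), sum(keep))
  neg <- data.frame(frequency = "-1", count = "200")
  expect_equal(nrow(filter_outcome_pairs(neg)), 0L)
})

test_that("annotation evidence filter retains levels 1-3 and significant rows", {
  rows <- data.frame(evidence_level = c("1", "2", "3", "4", "", ""),
                     significance = c("", "", "", "", "yes", "no"),
                     stringsAsFactors = FALSE)
  out <- filter_annotation_evidence(rows)
  expect_equal(out$evidence_level, c("1", "2", "3", ""))
  expect_equal(out$significance[[4]], "yes")
  # random table equals set-membership oracle
  set.seed(9)
  rnd <- data.frame(evidence_level = sample(c("", as.character(1:5)), 40, TRUE),
                    significance = sample(c("yes", "no", "Yes"), 40, TRUE),
                    stringsAsFactors = FALSE)
  keep <- ifelse(nzchar(rnd$evidence_level),
                 rnd$evidence_level %in% c("1", "2", "3"),
                 tolower(rnd$significance) == "yes")
  expect_equal(nrow(filter_annotation_evidence(rnd)), sum(keep))
})

test_that("reference filter removes rows with empty reference lists", {
  rows <- data.frame(pubmed_ids = c("1|2", "", "3"), stringsAsFactors = FALSE)
  expect_equal(nrow(filter_requires_reference(rows)), 2L)
  set.seed(5)
  rnd <- data.frame(pubmed_ids = sample(c("", "1", "1|2"), 30, TRUE),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(filter_requires_reference(rnd)), sum(nzchar(rnd$pubmed_ids)))
})

test_that("evidence codes translate via the bundled table", {
  expect_equal(translate_evidence_code("EXP"), "Inferred from Experiment")
  expect_warning(out <- translate_evidence_code("ZZZ"), "ZZZ")
  expect_equal(out, "ZZZ")
  tab <- kgforge:::go_evidence_table()
  expect_false(anyDuplicated(tab$code) > 0)
  expect_false(anyDuplicated(tab$description) > 0)
  expect_true(all(nzchar(tab$description)))
})

test_that("disconnected nodes are pruned except protected labels", {
  nodes <- list(Gene = data.frame(identifier = c("g1", "g2", "g3"),
                                  stringsAsFactors = FALSE),
                Chemical = data.frame(identifier = "c_disjoint",
                                      stringsAsFactors = FALSE))
  edges <- list(data.frame(source_id = "g1", target_id = "g2",
                           stringsAsFactors = FALSE))
  out <- prune_disconnected(nodes, edges, prune_labels = c("Gene", "Chemical"),
                            keep_labels = "Chemical")
  expect_equal(out$Gene$identifier, c("g1", "g2"))
  expect_equal(out$Chemical$identifier, "c_disjoint")
  # removed set equals the zero-degree oracle on a random bipartite fixture
  set.seed(21)
  g <- sprintf("g%d", 1:10); d <- sprintf("d%d", 1:6)
  e <- data.frame(source_id = sample(g, 12, TRUE), target_id = sample(d, 12, TRUE))
  out2 <- prune_disconnected(list(Gene = data.frame(identifier = g)), list(e),
                             prune_labels = "Gene")
  expect_setequal(out2$Gene$identifier, intersect(g, unique(e$source_id)))
})

test_that("entity dedup keeps first occurrence and unions list columns", {
  rows <- data.frame(key = c("k1", "k2", "k1"),
                     synonyms = c("a", "x", "b"), stringsAsFactors = FALSE)
  out <- dedupe_entities(rows, "key", list_columns = "synonyms")
  expect_equal(nrow(out), 2L)
  expect_equal(out$synonyms[[1]], "a|b")
  nodup <- rows[1:2, ]
  expect_equal(dedupe_entities(nodup, "key")$key, nodup$key)
  set.seed(17)
  rnd <- data.frame(key = sample(sprintf("k%d", 1:8), 30, TRUE),
                    v = as.character(1:30), stringsAsFactors = FALSE)
  expect_equal(nrow(dedupe_entities(rnd, "key")), length(unique(rnd$key)))
})

test_that("filters are idempotent and order-insensitive on disjoint columns", {
  set.seed(23)
  rows <- data.frame(taxon = sample(c("9606", "10090"), 40, TRUE),
                     DirectEvidence = sample(c("", "marker"), 40, TRUE),
                     stringsAsFactors = FALSE)
  strip <- function(df) { attr(df, "filter_log") <- NULL; df }
  f1 <- filter_by_taxon(rows)
  expect_equal(strip(filter_by_taxon(f1)), strip(f1))
  ab <- filter_direct_evidence(filter_by_taxon(rows))
  ba <- filter_by_taxon(filter_direct_evidence(rows))
  expect_equal(strip(ab), strip(ba))
})

test_that("the bundled adapter registry covers the nineteen emulated sources", {
  reg <- adapter_registry()
  expect_length(reg, 19L)
  expect_setequal(names(reg),
                  c("mondo", "do", "entrez", "omim", "pathwaycommons",
                    "wikipathways", "uniprot", "go", "iid", "reactome",
                    "clinvar", "drugbank", "hpo", "ctd", "ndfrt", "sider",
                    "aeolus", "pharmgkb", "dbsnp"))
})

test_that("adapter run reports telescope input - removed = output", {
  corpus <- make_test_corpus(42L)
  out <- file.path(tempdir(), "adapter-telescope")
  unlink(out, recursive = TRUE)
  spec <- adapter_registry()[["ctd"]]
  report <- run_adapter(spec, file.path(corpus, "ctd"), out)
  for (lg in report$filters) {
    expect_equal(lg$input - lg$removed, lg$kept)
  }
  # applying the two chem_disease filters independently gives the same count
  raw <- read_table_file(file.path(corpus, "ctd", "chem_disease.tsv"))
  manual <- filter_requires_reference(filter_direct_evidence(raw))
  emitted <- read_table_file(file.path(out, "ctd", "chem_disease.tsv"))
  expect_equal(nrow(emitted), nrow(manual))
})

test_that("an adapter with no filter chain passes parsed rows through", {
  corpus <- make_test_corpus(42L)
  out <- file.path(tempdir(), "adapter-passthrough")
  unlink(out, recursive = TRUE)
  spec <- adapter_registry()[["sider"]]
  run_adapter(spec, file.path(corpus, "sider"), out)
  raw <- read_table_file(file.path(corpus, "sider", "side_effects.tsv"))
  emitted <- read_table_file(file.path(out, "sider", "side_effects.tsv"))
  expect_equal(emitted, raw)
})

test_that("a missing adapter input is a configuration error before any work", {
  spec <- adapter_spec("broken",
                       inputs = list(x = list(path = "nope.tsv", format = "tsv")))
  expect_error(run_adapter(spec, tempdir(), tempdir()), "missing")
})
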