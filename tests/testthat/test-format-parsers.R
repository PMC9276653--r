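# Format converters: OBO, SDF, FASTA, GMT, GAF.

obo_fixture <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: X:1", "name: root", "",
    "[Term]", "id: X:2", "name: two", "is_a: X:1", "xref: UMLS:C1",
    "synonym: \"deux\" EXACT []", "",
    "[Term]", "id: X:3", "name: three", "is_a: X:1",
    "relationship: part_of X:2", "",
    "[Term]", "id: X:4", "name: four", "is_a: X:2", "",
    "[Term]", "id: X:5", "name: five", "is_a: X:2", "",
    "[Term]", "id: X:9", "name: gone", "is_a: X:1", "is_obsolete: true", "",
    "[Typedef]", "id: part_of", "")
}

test_that("OBO terms become node rows and per-relation edge tables", {
  parsed <- parse_obo(lines = obo_fixture())
  expect_equal(nrow(parsed$nodes), 6L)  # every [Term] stanza, obsolete included
  expect_setequal(names(parsed$edges), c("is_a", "part_of"))
  expect_equal(nrow(parsed$edges$is_a), 4L)  # obsolete term emits no edges
  expect_equal(nrow(parsed$edges$part_of), 1L)
  obs <- parsed$nodes[parsed$nodes$identifier == "X:9", ]
  expect_equal(obs$is_obsolete, "true")
  two <- parsed$nodes[parsed$nodes$identifier == "X:2", ]
  expect_equal(two$synonyms, "deux")
  expect_equal(two$synonym_scopes, "EXACT")
  expect_equal(two$xrefs, "UMLS:C1")
})

test_that("OBO edge-table row counts match a line-grep oracle", {
  lines <- obo_fixture()
  parsed <- parse_obo(lines = lines)
  # grep oracle: count tag lines outside obsolete stanzas
  stanzas <- split(lines, cumsum(grepl("^\\[", lines)))
  live <- Filter(function(s) s[[1]] == "[Term]" && !any(s == "is_obsolete: true"),
                 stanzas)
  expect_equal(nrow(parsed$edges$is_a),
               sum(vapply(live, function(s) sum(startsWith(s, "is_a:")), 0L)))
  expect_equal(nrow(parsed$edges$part_of),
               sum(vapply(live, function(s) sum(startsWith(s, "relationship: part_of")), 0L)))
  expect_equal(nrow(parsed$nodes), sum(lines == "[Term]"))
})

test_that("OBO stanza without id is a format error naming the stanza", {
  expect_error(parse_obo(lines = c("[Term]", "name: anonymous")), "stanza #1")
})

test_that("SDF records become rows under the union of property keys", {
  lines <- c("mol1", "  prog", "", "  0  0  0  0  0  0  0  0  0  0999 V2000",
             "M  END", "> <ID>", "DB1", "", "> <SMILES>", "CCO", "", "$$$$",
             "mol2", "  prog", "", "  0  0  0  0  0  0  0  0  0  0999 V2000",
             "M  END", "> <ID>", "DB2", "", "> <CAS>", "1-2-3", "", "$$$$")
  df <- parse_sdf(lines = lines)
  expect_equal(nrow(df), 2L)
  expect_setequal(names(df), c("ID", "SMILES", "CAS", "structure"))
  expect_equal(df$SMILES, c("CCO", ""))
  expect_equal(df$CAS, c("", "1-2-3"))
  expect_match(df$structure[[1]], "^mol1")
  expect_match(df$structure[[1]], "M  END$")

  expect_equal(nrow(parse_sdf(lines = character(0))), 0L)
  expect_error(parse_sdf(lines = lines[1:8]), "truncated")
})

test_that("SDF cell values equal an independent stanza-splitter oracle", {
  structs <- kgforge:::toy_structures()
  lines <- character(0)
  for (id in names(structs)) {
    lines <- c(lines, strsplit(structs[[id]], "\n")[[1]], "> <ID>", id, "", "$$$$")
  }
  df <- parse_sdf(lines = lines)
  # oracle: split raw text on terminator lines, take line after "> <ID>"
  recs <- split(lines, cumsum(c(0, head(lines == "$$$$", -1))))
  oracle_ids <- vapply(recs, function(r) r[[which(r == "> <ID>") + 1L]], "",
                       USE.NAMES = FALSE)
  expect_equal(df$ID, oracle_ids)
  expect_equal(nrow(df), length(structs))
})

test_that("FASTA parsing concatenates wrapped sequences", {
  lines <- c(">seq1 first", "ACGT", "TTGA", ">seq2", "MKV")
  recs <- parse_fasta(lines = lines)
  expect_equal(recs$header, c("seq1 first", "seq2"))
  expect_equal(recs$sequence, c("ACGTTTGA", "MKV"))
  wrapped <- parse_fasta(lines = c(">s", "AA", "CC", "GG"))
  expect_equal(wrapped$sequence, "AACCGG")
  expect_error(parse_fasta(lines = c("ACGT", ">s")), "before any FASTA header")
  expect_equal(nrow(parse_fasta(lines = character(0))), 0L)
})

test_that("FASTA parsing agrees with Biostrings on randomly wrapped records", {
  skip_if_not_installed("Biostrings")
  set.seed(31)
  n <- 8
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), replace = TRUE),
          collapse = "")
  }, "")
  lines <- character(0)
  for (i in seq_len(n)) {
    width <- sample(5:15, 1)
    chunks <- substring(seqs[[i]], seq(1, nchar(seqs[[i]]), width),
                        pmin(seq(1, nchar(seqs[[i]]), width) + width - 1,
                             nchar(seqs[[i]])))
    lines <- c(lines, paste0(">rec", i), chunks)
  }
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  mine <- parse_fasta(path)
  ref <- Biostrings::readBStringSet(path)
  expect_equal(mine$sequence, unname(as.character(ref)))
  expect_equal(mine$sequence, seqs)  # generator ground truth
  expect_equal(mine$header, names(ref))
})

test_that("GMT lines yield deduplicated member lists in input order", {
  df <- parse_gmt(lines = "pw1\tdesc\tG1\tG2\tG1")
  expect_equal(df$members, "G1|G2")
  expect_equal(nrow(parse_gmt(lines = character(0))), 0L)
  expect_error(parse_gmt(lines = c("pw1\tdesc\tG1", "lonely")), "line 2")
})

test_that("GMT member multisets equal a field-split oracle after dedup", {
  set.seed(13)
  lines <- vapply(1:6, function(i) {
    members <- sample(sprintf("G%d", 1:8), sample(2:10, 1), replace = TRUE)
    paste(c(sprintf("pw%d", i), "desc", members), collapse = "\t")
  }, "")
  df <- parse_gmt(lines = lines)
  expect_equal(nrow(df), length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    expect_equal(split_list_cell(df$members[[i]]), unique(fields[-(1:2)]))
  }
})

test_that("GAF-style files skip comment lines and keep column structure", {
  path <- tempfile()
  writeLines(c("!gaf-version: 2.2", "!generated", "db\tid1\tEXP",
               "db\tid2\tIEA"), path)
  df <- read_gaf(path, c("db", "id", "code"))
  expect_equal(nrow(df), 2L)
  expect_equal(df$code, c("EXP", "IEA"))
})

test_that("parsers preserve record order", {
  recs <- parse_fasta(lines = c(">b", "AA", ">a", "CC", ">c", "GG"))
  expect_equal(recs$header, c("b", "a", "c"))
  df <- parse_gmt(lines = c("z\td\tG1", "a\td\tG2"))
  expect_equal(df$set_name, c("z", "a"))
})
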