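# Deterministic miniature multi-source corpus with constructive ground
# truth. The cross-source core (which entities exist, which overlap, what
# every filter drops) is a fixed design; the seed drives decoy rows
# (non-human taxa, empty evidence, sub-threshold reporting signals, stale
# rs-ids), name-case jitter and extra obsolete ontology terms. The ground
# truth tables are enumerated from the design by set arithmetic and never
# produced by running the pipeline.

#' Build a fixture manifest
#'
#' @param seed integer seed controlling decoys and jitter
#' @param decoys named list of decoy row counts per source
#' @param empty if TRUE, generate structurally valid but empty files
#' @return a `fixture_manifest`
#' @export
fixture_manifest <- function(seed = 42L,
                             decoys = list(entrez = 4L, mondo = 3L, iid = 3L,
                                           aeolus = 4L, ctd = 3L, dbsnp = 5L),
                             empty = FALSE) {
  stopifnot(all(unlist(decoys) >= 0))
  structure(list(seed = as.integer(seed), decoys = decoys, empty = isTRUE(empty)),
            class = "fixture_manifest")
}

jitter_case <- function(x) {
  vapply(x, function(s) sample(c(s, toupper(s), tolower(s)), 1), "",
         USE.NAMES = FALSE)
}

# --- tiny V2000 molecules ----------------------------------------------

v2000_block <- function(title, atoms, bonds) {
  n_a <- nrow(atoms); n_b <- nrow(bonds)
  lines <- c(title, "  kgforge", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b))
  for (i in seq_len(n_a)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              atoms$x[[i]], atoms$y[[i]], 0, atoms$el[[i]]))
  }
  for (i in seq_len(n_b)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", bonds$a[[i]], bonds$b[[i]],
                              bonds$order[[i]]))
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

ring6 <- function(alternating = FALSE) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  atoms <- data.frame(el = "C", x = cos(ang), y = sin(ang))
  bonds <- data.frame(a = 1:6, b = c(2:6, 1),
                      order = if (alternating) rep(c(2L, 1L), 3) else 1L)
  list(atoms = atoms, bonds = bonds)
}

toy_structures <- function() {
  benzene <- ring6(alternating = TRUE)
  hexane <- list(atoms = data.frame(el = "C", x = 0:5, y = 0),
                 bonds = data.frame(a = 1:5, b = 2:6, order = 1L))
  isobutane <- list(atoms = data.frame(el = "C", x = c(0, 1, 2, 1), y = c(0, 0, 0, 1)),
                    bonds = data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = 1L))
  # hexane with atoms listed in a different order: same molecule, so its
  # fingerprint must equal hexane's (similarity 1.0)
  perm <- c(6, 4, 2, 1, 3, 5)
  hex_atoms <- hexane$atoms[perm, , drop = FALSE]
  inv <- match(seq_len(6), perm)
  hex_bonds <- data.frame(a = inv[hexane$bonds$a], b = inv[hexane$bonds$b], order = 1L)
  list(
    DB001 = v2000_block("benzene", benzene$atoms, benzene$bonds),
    DB002 = v2000_block("hexane", hexane$atoms, hexane$bonds),
    DB003 = v2000_block("isobutane", isobutane$atoms, isobutane$bonds),
    DB005 = v2000_block("hexane-renumbered", hex_atoms, hex_bonds)
  )
}

# --- writers for the simple text formats --------------------------------

obo_lines <- function(terms, typedefs = "is_a") {
  lines <- c("format-version: 1.2", "")
  for (t in terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.null(t$namespace)) lines <- c(lines, paste0("namespace: ", t$namespace))
    if (!is.null(t$def)) lines <- c(lines, paste0("def: \"", t$def, "\" []"))
    for (s in t$synonyms %||% character(0)) {
      lines <- c(lines, paste0("synonym: \"", s, "\" EXACT []"))
    }
    for (x in t$xrefs %||% character(0)) lines <- c(lines, paste0("xref: ", x))
    for (p in t$is_a %||% character(0)) lines <- c(lines, paste0("is_a: ", p))
    if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, "")
  }
  for (td in typedefs) lines <- c(lines, "[Typedef]", paste0("id: ", td), "")
  lines
}

write_obo <- function(path, terms, typedefs = "is_a") {
  writeLines(obo_lines(terms, typedefs), path)
}

df_rows <- function(cols, rows) {
  out <- empty_df(cols)
  for (i in seq_along(rows)) out[i, ] <- rows[[i]]
  out
}

# --- the hetnet seed graph ----------------------------------------------

seed_node <- function(store, labels, identifier, props) {
  props$identifier <- identifier
  props$resource <- "Hetionet"
  props$hetionet_id <- identifier
  gs_add_node(store, labels, props)
}

seed_edge <- function(store, type, a, b) {
  gs_add_edge(store, type, a, b,
              list(resource = "Hetionet", hetionet_id = paste0(type, ":", a, ":", b)))
}

#' Build the hetnet-like seed graph the merge starts from
#'
#' @return a `graph_store`
#' @export
build_seed_store <- function() {
  s <- graph_store()
  c1 <- seed_node(s, "Compound", "DB001", list(name = "Aspirin", cas = "50-78-2"))
  c2 <- seed_node(s, "Compound", "DB002", list(name = "Warfarin", cas = "81-81-2",
                                               synonyms = "Coumadin"))
  c3 <- seed_node(s, "Compound", "DB003", list(name = "Metformin", cas = "657-24-9"))
  seed_node(s, "Compound", "DB004", list(name = "Oldrugol"))
  d1 <- seed_node(s, "Disease", "DOID:001", list(name = "hypertension"))
  d2 <- seed_node(s, "Disease", "DOID:002", list(name = "diabetes mellitus"))
  d3 <- seed_node(s, "Disease", "DOID:003", list(name = "bleeding disorder"))
  seed_node(s, "Disease", "DOID:004", list(name = "olddisease"))
  g1 <- seed_node(s, "Gene", "1001", list(symbol = "CYP2C9",
                                          name = "cytochrome P450 2C9", taxon = "9606"))
  g2 <- seed_node(s, "Gene", "1002", list(symbol = "VKORC1",
                                          name = "vitamin K epoxide reductase subunit 1",
                                          taxon = "9606"))
  g3 <- seed_node(s, "Gene", "1003", list(symbol = "MTOR",
                                          name = "mechanistic target of rapamycin",
                                          taxon = "9606"))
  seed_node(s, "Gene", "1004", list(symbol = "OLDG", name = "retired gene",
                                    taxon = "9606"))
  se1 <- seed_node(s, "SideEffect", "C0027497", list(name = "nausea", umls = "C0027497"))
  sy1 <- seed_node(s, "Symptom", "D001", list(name = "headache", mesh = "D001"))
  seed_node(s, "Symptom", "D002", list(name = "fever", mesh = "D002"))
  pw <- seed_node(s, "Pathway", "PWOLD1", list(name = "old pathway"))
  seed_node(s, "BiologicalProcess", "GO:0001", list(name = "coagulation"))
  seed_node(s, "CellularComponent", "GO:0002", list(name = "membrane"))
  seed_node(s, "MolecularFunction", "GO:0003", list(name = "oxidoreductase activity"))
  pc <- seed_node(s, "PharmacologicalClass", "N0000000", list(name = "old class"))
  seed_edge(s, "TREATS_CtD", c1, d1)
  seed_edge(s, "CAUSES_CcSE", c1, se1)
  seed_edge(s, "BINDS_CbG", c2, g2)
  seed_edge(s, "DOWNREGULATES_CdG", c3, g3)
  seed_edge(s, "PALLIATES_CpD", c2, d3)
  seed_edge(s, "PRESENTS_DpS", d1, sy1)
  seed_edge(s, "ASSOCIATES_DaG", d2, g3)
  seed_edge(s, "INCLUDES_CiPC", c2, pc)
  seed_edge(s, "PARTICIPATES_IN_GpiPW", g3, pw)
  seed_edge(s, "RESEMBLES_CrC", c1, c2)
  s
}

# --- corpus generation --------------------------------------------------

write_corpus_source <- function(dir, source, files) {
  d <- file.path(dir, source)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Generate the fixture corpus
#'
#' Writes one directory per emulated source (19 sources plus the hetnet
#' seed graph and generic xref tables) in the formats the adapters parse,
#' together with ground-truth tables under `truth/`. Identical seeds give
#' byte-identical corpora.
#'
#' @param out_dir output directory
#' @param manifest a [fixture_manifest()]
#' @return invisibly, `out_dir`
#' @export
generate_corpus <- function(out_dir, manifest = fixture_manifest()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(manifest$seed)
  empty <- manifest$empty
  dec <- function(nm) if (empty) 0L else as.integer(manifest$decoys[[nm]] %||% 0L)

  # hetionet seed
  d <- write_corpus_source(out_dir, "hetionet")
  seed_store <- if (empty) graph_store() else build_seed_store()
  write_graphml(seed_store, file.path(d, "seed.graphml"))

  # mondo
  d <- write_corpus_source(out_dir, "mondo")
  terms <- if (empty) list() else c(list(
    list(id = "MONDO:0001", name = "hypertension", xrefs = "DOID:001",
         synonyms = "high blood pressure"),
    list(id = "MONDO:0002", name = "diabetes mellitus",
         xrefs = c("DOID:002", "OMIM:600003"), is_a = "MONDO:0001"),
    list(id = "MONDO:0003", name = "bleeding disorder",
         xrefs = c("DOID:003", "OMIM:600004"), is_a = "MONDO:0001"),
    list(id = "MONDO:0005", name = "migraine", xrefs = "UMLS:C0149931",
         is_a = "MONDO:0001")),
    lapply(seq_len(dec("mondo")), function(i) {
      list(id = sprintf("MONDO:09%02d", i), name = paste0("obsolete term ", i),
           is_a = "MONDO:0001", obsolete = TRUE)
    }))
  write_obo(file.path(d, "mondo.obo"), terms)

  # do
  d <- write_corpus_source(out_dir, "do")
  terms <- if (empty) list() else list(
    list(id = "DOID:001", name = "hypertension", def = "elevated blood pressure"),
    list(id = "DOID:002", name = "diabetes mellitus",
         def = "impaired glucose regulation", is_a = "DOID:003"),
    list(id = "DOID:003", name = "bleeding disorder", def = "impaired coagulation"))
  write_obo(file.path(d, "doid.obo"), terms)

  # entrez
  d <- write_corpus_source(out_dir, "entrez")
  core <- list(
    c("9606", "1001", "CYP2C9", "cytochrome P450 2C9", "protein-coding"),
    c("9606", "1002", "VKORC1", "vitamin K epoxide reductase subunit 1", "protein-coding"),
    c("9606", "1003", "MTOR", "mechanistic target of rapamycin", "protein-coding"),
    c("9606", "1005", "ABCB1", "ATP binding cassette subfamily B member 1",
      "protein-coding"))
  decoy_taxa <- c("63221", "741158", "10090")
  decoys <- lapply(seq_len(dec("entrez")), function(i) {
    c(sample(decoy_taxa, 1), as.character(9000 + i), paste0("DECOY", i),
      paste0("non-human gene ", i), "protein-coding")
  })
  rows <- if (empty) list() else c(core, decoys)
  if (length(rows) > 0) rows <- sample(rows)  # shuffle row order
  write_table_file(df_rows(c("taxon", "identifier", "symbol", "name", "type_of_gene"),
                           rows),
                   file.path(d, "gene_info.tsv"))

  # omim
  d <- write_corpus_source(out_dir, "omim")
  write_table_file(df_rows(c("identifier", "type", "name"), if (empty) list() else list(
    c("OMIM:600001", "phenotype", "warfarin sensitivity"),
    c("OMIM:600003", "phenotype", "diabetes mellitus"),
    c("OMIM:600004", "phenotype", "bleeding disorder"))),
    file.path(d, "mim_entries.tsv"))
  write_table_file(df_rows(c("mim_id", "gene_id"), if (empty) list() else list(
    c("OMIM:600001", "1001"), c("OMIM:600001", "1002"), c("OMIM:600003", "1003"))),
    file.path(d, "gene_phenotype.tsv"))

  # pathway gene sets
  d <- write_corpus_source(out_dir, "pathwaycommons")
  writeLines(if (empty) character(0) else c(
    "wnt_signaling\tReactome\tCYP2C9\tMTOR\tFAKEGENE",
    "licensed_pw\tKEGG\tCYP2C9"), file.path(d, "pc.gmt"))
  d <- write_corpus_source(out_dir, "wikipathways")
  writeLines(if (empty) character(0) else
    "vitamin_k_cycle\tWikiPathways\tVKORC1\tCYP2C9\tFAKEGENE2",
    file.path(d, "wp.gmt"))

  # uniprot
  d <- write_corpus_source(out_dir, "uniprot")
  write_table_file(df_rows(c("identifier", "name", "gene_symbol", "synonyms"),
    if (empty) list() else list(
      c("P1001", "Cytochrome P450 2C9", "CYP2C9", "CYPIIC9"),
      c("P1001", "Cytochrome P450 2C9", "CYP2C9", "S-mephenytoin 4-hydroxylase"),
      c("P1002", "Vitamin K epoxide reductase complex subunit 1", "VKORC1", ""),
      c("P1003", "Serine/threonine-protein kinase mTOR", "MTOR", ""))),
    file.path(d, "proteins.tsv"))
  writeLines(if (empty) character(0) else c(
    ">P1001 CYP2C9_HUMAN", "MDSLVVLVLCLSCLLLLSLW", "HKRNFS",
    ">P1002 VKOR1_HUMAN", "MGSTWGSPGWVRLALCLTG",
    ">P1003 MTOR_HUMAN", "MLGTGPAAATTAATTSSN"),
    file.path(d, "sequences.fasta"))
  write_table_file(df_rows(c("a_id", "b_id", "pubmed_ids"),
    if (empty) list() else list(c("P1001", "P1002", "99001"))),
    file.path(d, "interactions.tsv"))
  write_table_file(df_rows(c("gene_symbol", "omim_id", "pubmed_ids"),
    if (empty) list() else list(
      c("MTOR", "OMIM:600003", "12345"),
      c("CYP2C9", "OMIM:600004", ""))),
    file.path(d, "gene_disease.tsv"))

  # go
  d <- write_corpus_source(out_dir, "go")
  terms <- if (empty) list() else list(
    list(id = "GO:0001", name = "coagulation", namespace = "biological_process"),
    list(id = "GO:0002", name = "membrane", namespace = "cellular_component"),
    list(id = "GO:0004", name = "cytosol", namespace = "cellular_component",
         is_a = "GO:0002"),
    list(id = "GO:0003", name = "oxidoreductase activity",
         namespace = "molecular_function"))
  write_obo(file.path(d, "go.obo"), terms)
  gaf <- c("!gaf-version: 2.2",
           if (!empty) c(
             "UniProtKB\tP1001\tCYP2C9\tenables\tGO:0003\tPMID:201\tEXP\tF",
             "UniProtKB\tP1001\tCYP2C9\tlocated_in\tGO:0002\tPMID:202\tIDA\tC",
             "EntrezGene\t1001\tCYP2C9\tinvolved_in\tGO:0001\tPMID:203\tTAS\tP"))
  writeLines(gaf, file.path(d, "goa.gaf"))

  # iid
  d <- write_corpus_source(out_dir, "iid")
  core <- list(c("P1002", "P1003", "exp;ortho", "membrane"))
  decoys <- lapply(seq_len(dec("iid")), function(i) {
    pair <- sample(c("P1001", "P1002", "P1003"), 2)
    c(pair[[1]], pair[[2]], "pred", "")
  })
  write_table_file(df_rows(c("a_id", "b_id", "evidence_type", "cc_name"),
                           if (empty) list() else c(core, decoys)),
                   file.path(d, "ppis.tsv"))

  # reactome (GraphML)
  d <- write_corpus_source(out_dir, "reactome")
  rs <- graph_store()
  if (!empty) {
    p1 <- gs_add_node(rs, "Pathway", list(identifier = "R-HSA-1",
                                          name = "vitamin_k_cycle",
                                          species = "Homo sapiens",
                                          bp_go = "GO:0001"))
    p2 <- gs_add_node(rs, "Pathway", list(identifier = "R-HSA-2", name = "hemostasis",
                                          species = "Homo sapiens"))
    r10 <- gs_add_node(rs, "Reaction", list(identifier = "R-HSA-10",
                                            name = "vitamin K epoxide reduction",
                                            species = "Homo sapiens",
                                            pubmed_ids = "111",
                                            compartment_go = "GO:0002",
                                            disease_do = "DOID:003",
                                            input_chemical_name = "Warfarin",
                                            output_chemical_name = "Aspirin",
                                            input_protein = "P1002"))
    gs_add_node(rs, "BlackBoxEvent", list(identifier = "R-HSA-11",
                                          name = "unreferenced event",
                                          species = "Homo sapiens"))
    gs_add_node(rs, "Reaction", list(identifier = "R-HSA-12", name = "mouse reaction",
                                     species = "Mus musculus", pubmed_ids = "112"))
    gs_add_node(rs, "Treatment", list(identifier = "RT-TREAT-1",
                                      chemical_name = "Warfarin",
                                      disease_name = "bleeding disorder",
                                      cc_go = "GO:0002"))
    gs_add_edge(rs, "hasEncapsulatedEvent", p2, p1, list())
    gs_add_edge(rs, "hasEvent", p1, r10, list())
  }
  write_graphml(rs, file.path(d, "reactome.graphml"))

  # clinvar
  d <- write_corpus_source(out_dir, "clinvar")
  var_cols <- c("identifier", "vtype", "name", "rs_id", "clinical_significance")
  write_table_file(df_rows(var_cols, if (empty) list() else list(
    c("VCV001", "GeneVariant", "NM_000771.3(CYP2C9):c.1075A>C (p.Ile359Leu)",
      "rs1057910", ""),
    c("VCV002", "GeneVariant", "NM_000771.3(CYP2C9):c.430C>T (p.Arg144Cys)",
      "rs1799853", ""),
    c("VCV003", "GeneVariant", "NM_024006.4(VKORC1):c.-1639G>A", "rs9923231", ""),
    c("VCV007", "GeneVariant", "NM_000771.3(CYP2C9):c.1075A>T", "rs1057910", ""),
    c("VCV004", "Haplotype", "CYP2C9*3 haplotype", "", ""),
    c("VCV005", "Genotype", "CYP2C9*3/*3", "", ""))),
    file.path(d, "variation_release.tsv"))
  write_table_file(df_rows(var_cols, if (empty) list() else list(
    c("VCV001", "GeneVariant", "NM_000771.3(CYP2C9):c.1075A>C (p.Ile359Leu)",
      "rs1057910", "drug response"),
    c("VCV006", "GeneVariant", "NC_000007.14:g.87531302A>G", "rs999999", ""))),
    file.path(d, "full_release.tsv"))
  write_table_file(df_rows(c("rel", "source_id", "target_id"),
    if (empty) list() else list(
      c("gene_variant", "1001", "VCV001"), c("gene_variant", "1001", "VCV002"),
      c("gene_variant", "1002", "VCV003"), c("gene_variant", "1001", "VCV007"),
      c("gene_variant", "1005", "VCV006"),
      c("haplotype_gv", "VCV004", "VCV001"),
      c("genotype_h", "VCV005", "VCV004"), c("genotype_gv", "VCV005", "VCV001"))),
    file.path(d, "relationships.tsv"))
  write_table_file(df_rows(c("variant_id", "drug_name", "association"),
    if (empty) list() else list(
      c("VCV001", "Warfarin", "TOXICITY_ADR"),
      c("VCV003", "Warfarin", "DOSAGE"),
      c("VCV002", "Warfarin", ""))),
    file.path(d, "drug_links.tsv"))

  # drugbank
  d <- write_corpus_source(out_dir, "drugbank")
  write_table_file(df_rows(c("identifier", "name", "cas", "synonyms"),
    if (empty) list() else list(
      c("DB001", "Aspirin", "50-78-2", "acetylsalicylic acid"),
      c("DB002", "Warfarin", "81-81-2", "Coumadin"),
      c("DB003", "Metformin", "657-24-9", ""),
      c("DB005", "Novodrug", "", ""))),
    file.path(d, "drugs.tsv"))
  structs <- toy_structures()
  sdf_lines <- character(0)
  if (!empty) {
    for (id in names(structs)) {
      sdf_lines <- c(sdf_lines, strsplit(structs[[id]], "\n")[[1]],
                     "> <ID>", id, "", "$$$$")
    }
  }
  writeLines(sdf_lines, file.path(d, "structures.sdf"))
  write_table_file(df_rows(c("identifier", "name", "parent"),
    if (empty) list() else list(c("DBSALT001", "Warfarin sodium", "DB002"))),
    file.path(d, "salts.tsv"))
  write_table_file(df_rows(c("identifier", "name", "drug"),
    if (empty) list() else list(c("PR001", "Coumadin 5 mg tablet", "DB002"))),
    file.path(d, "products.tsv"))
  write_table_file(df_rows(c("a_id", "b_id"),
    if (empty) list() else list(c("DB001", "DB002"))),
    file.path(d, "interactions.tsv"))
  write_table_file(df_rows(c("rs_id", "drug"),
    if (empty) list() else list(c("rs1057910", "DB002"), c("rs999999", "DB005"))),
    file.path(d, "snp_adr.tsv"))
  write_table_file(df_rows(c("drug", "uniprot", "relation", "pubmed_ids"),
    if (empty) list() else list(
      c("DB002", "P1001", "IS_ACTIVE_IN_METABOLISM", "5001"),
      c("DB002", "P1002", "INHIBITS", "5002"),
      c("DB001", "P9999", "BINDS", "5003"),
      c("DB003", "P1003", "BINDS", ""))),
    file.path(d, "targets.tsv"))
  write_table_file(df_rows(c("code", "name", "parent", "drug"),
    if (empty) list() else list(
      c("B01", "ANTITHROMBOTIC AGENTS", "", "DB002"),
      c("B01AA", "Vitamin K antagonists", "B01", "DB002"))),
    file.path(d, "atc.tsv"))

  # hpo
  d <- write_corpus_source(out_dir, "hpo")
  terms <- if (empty) list() else list(
    list(id = "HP:0001", name = "Headache", xrefs = "UMLS:C0018681"),
    list(id = "HP:0002", name = "Epistaxis", xrefs = "UMLS:C0014591"),
    list(id = "HP:0003", name = "Migraine", xrefs = "UMLS:C0149931"))
  write_obo(file.path(d, "hp.obo"), terms)
  writeLines(c("!hpoa-version: 2",
               "disease_id\thp_id",
               if (!empty) c("OMIM:600003\tHP:0001", "OMIM:600004\tHP:0002")),
             file.path(d, "phenotype.hpoa"))

  # ctd
  d <- write_corpus_source(out_dir, "ctd")
  write_table_file(df_rows(c("identifier", "name", "cas"),
    if (empty) list() else list(
      c("MESH:D010", jitter_case("Aspirin"), "50-78-2"),
      c("MESH:D011", "Lead acetate", ""),
      c("MESH:D012", "Quartz", ""))),
    file.path(d, "chemicals.tsv"))
  write_table_file(df_rows("identifier",
    if (empty) list() else list("1001", "1003", "9999")),
    file.path(d, "genes.tsv"))
  write_table_file(df_rows(c("chemical_id", "gene_id", "relation", "target_type",
                             "taxon", "pubmed_ids"),
    if (empty) list() else list(
      c("MESH:D011", "1003", "UPREGULATES", "gene", "9606", "7001"),
      c("MESH:D010", "1001", "BINDS", "protein", "9606", "7003"),
      c("MESH:D010", "1001", "BINDS", "gene", "10090", "7002"),
      c("MESH:D010", "1003", "BINDS", "gene", "9606", ""))),
    file.path(d, "chem_gene.tsv"))
  cd_core <- list(
    c("MESH:D010", "DOID:001", "therapeutic", "7101"),
    c("MESH:D011", "OMIM:600003", "marker/mechanism", "7102"))
  cd_decoys <- lapply(seq_len(dec("ctd")), function(i) {
    c("MESH:D010", sample(c("DOID:002", "DOID:003"), 1), "", as.character(7900 + i))
  })
  write_table_file(df_rows(c("chemical_id", "disease_id", "DirectEvidence", "pubmed_ids"),
    if (empty) list() else c(cd_core, cd_decoys)),
    file.path(d, "chem_disease.tsv"))
  write_table_file(df_rows(c("gene_id", "disease_id", "DirectEvidence", "pubmed_ids"),
    if (empty) list() else list(
      c("1001", "DOID:001", "marker/mechanism", "7201"),
      c("1003", "DOID:002", "", "7202"))),
    file.path(d, "gene_disease.tsv"))
  write_table_file(df_rows(c("chemical_id", "go_id", "relation", "pubmed_ids"),
    if (empty) list() else list(c("MESH:D011", "GO:0001", "ASSOCIATES", "7301"))),
    file.path(d, "chem_go.tsv"))

  # ndfrt
  d <- write_corpus_source(out_dir, "ndfrt")
  write_table_file(df_rows(c("identifier", "name", "kind"),
    if (empty) list() else list(
      c("N001", "anticoagulants", "mechanism_of_action"),
      c("N002", "antithrombotic agents", "therapeutic_category"))),
    file.path(d, "classes.tsv"))
  write_table_file(df_rows(c("source_id", "target_id"),
    if (empty) list() else list(c("N002", "N001"))),
    file.path(d, "class_hierarchy.tsv"))
  write_table_file(df_rows(c("drug_name", "class_id"),
    if (empty) list() else list(c(jitter_case("Warfarin"), "N001"))),
    file.path(d, "drug_class.tsv"))
  write_table_file(df_rows(c("subject_kind", "subject", "disease_name", "relation"),
    if (empty) list() else list(
      c("class", "N001", "bleeding disorder", "TREATS"),
      c("chem", jitter_case("Aspirin"), "bleeding disorder", "CONTRAINDICATES"))),
    file.path(d, "drug_disease.tsv"))

  # sider
  d <- write_corpus_source(out_dir, "sider")
  write_table_file(df_rows(c("drug_name", "se_umls", "se_name"),
    if (empty) list() else list(
      c(jitter_case("Aspirin"), "C0027497", "Nausea"),
      c(jitter_case("Aspirin"), "C0000737", "Abdominal pain"),
      c(jitter_case("Warfarin"), "C0019080", "Haemorrhage"),
      c(jitter_case("Warfarin"), "C0149931", "Migraine"))),
    file.path(d, "side_effects.tsv"))

  # aeolus
  d <- write_corpus_source(out_dir, "aeolus")
  write_table_file(df_rows(c("concept_id", "name", "kind"),
    if (empty) list() else list(
      c("MDR001", jitter_case("Nausea"), "outcome"),
      c("MDR002", "Dizziness", "outcome"),
      c("MDR003", jitter_case("Diabetes mellitus"), "outcome"),
      c("MDR004", "Warfarin sensitivity", "outcome"),
      c("MDR005", jitter_case("Headache"), "outcome"),
      c("AEO-D1", jitter_case("Aspirin"), "drug"),
      c("AEO-D2", jitter_case("Warfarin"), "drug"))),
    file.path(d, "concepts.tsv"))
  ao_core <- list(
    c("AEO-D1", "MDR001", "0.5", "500"),
    c("AEO-D2", "MDR002", "0.15", "120"),
    c("AEO-D1", "MDR003", "0.2", "200"),
    c("AEO-D1", "MDR005", "0.3", "300"),
    c("AEO-D2", "MDR004", "0.12", "150"))
  ao_decoys <- lapply(seq_len(dec("aeolus")), function(i) {
    drug <- sample(c("AEO-D1", "AEO-D2"), 1)
    outcome <- sample(paste0("MDR00", 1:5), 1)
    if (i %% 2 == 0) {
      c(drug, outcome, sprintf("%.3f", stats::runif(1, 0, 0.099)),
        as.character(sample(100:500, 1)))
    } else {
      c(drug, outcome, sprintf("%.3f", stats::runif(1, 0.1, 0.9)),
        as.character(sample(0:99, 1)))
    }
  })
  write_table_file(df_rows(c("drug_id", "outcome_id", "frequency", "count"),
    if (empty) list() else c(ao_core, ao_decoys)),
    file.path(d, "drug_outcome.tsv"))

  # pharmgkb (GraphML)
  d <- write_corpus_source(out_dir, "pharmgkb")
  ps <- graph_store()
  if (!empty) {
    ch <- gs_add_node(ps, "Chemical", list(identifier = "PA-CH1", name = "Warfarin",
                                           drugbank_id = "DB002"))
    gn <- gs_add_node(ps, "Gene", list(identifier = "PA-G1", symbol = "CYP2C9",
                                       name = "CYP2C9"))
    ph <- gs_add_node(ps, "Phenotype", list(identifier = "PA-PH1",
                                            name = "Toxic liver disease"))
    v1 <- gs_add_node(ps, "Variant", list(identifier = "PA-V1",
                                          name = "CYP2C9 promoter variant",
                                          rs_id = "rs777777"))
    v2 <- gs_add_node(ps, "Variant", list(identifier = "PA-V2",
                                          name = "VKORC1 -1639 variant",
                                          rs_id = "rs9923231"))
    ca1 <- gs_add_node(ps, "ClinicalAnnotation",
                       list(identifier = "CA-PA1", evidence_level = "2"))
    ca2 <- gs_add_node(ps, "ClinicalAnnotation",
                       list(identifier = "CA-PA2", evidence_level = "4"))
    va1 <- gs_add_node(ps, "VariantAnnotation",
                       list(identifier = "VA-PA1", significance = "yes"))
    va2 <- gs_add_node(ps, "VariantAnnotation",
                       list(identifier = "VA-PA2", significance = "no"))
    for (t in list(v2, ch, gn, ph)) gs_add_edge(ps, "associated_with", ca1, t, list())
    gs_add_edge(ps, "associated_with", ca2, ch, list())
    gs_add_edge(ps, "associated_with", ca2, gn, list())
    for (t in list(v1, ch)) gs_add_edge(ps, "associated_with", va1, t, list())
    gs_add_edge(ps, "associated_with", va2, ch, list())
    gs_add_edge(ps, "associated_with", va2, v1, list())
    gs_add_edge(ps, "has_evidence", ca1, va1, list())
    gs_add_edge(ps, "has_variant", gn, v1, list())
  }
  write_graphml(ps, file.path(d, "pharmgkb.graphml"))

  # dbsnp
  d <- write_corpus_source(out_dir, "dbsnp")
  current <- c("rs1057910", "rs1799853", "rs9923231", "rs777777",
               if (dec("dbsnp") > 0) paste0("rs88", sprintf("%04d", seq_len(dec("dbsnp")))))
  write_table_file(df_rows("rs_id", if (empty) list() else as.list(current)),
                   file.path(d, "rs_current.tsv"))
  write_table_file(df_rows(c("rs_id", "alleles"), if (empty) list() else list(
    c("rs1057910", "A/C"), c("rs1799853", "C/T"), c("rs9923231", "G/A"),
    c("rs777777", "C/G"))),
    file.path(d, "rs_info.tsv"))
  write_table_file(df_rows(c("rs_id", "gene_id"),
    if (empty) list() else list(c("rs777777", "1001"))),
    file.path(d, "rs_gene.tsv"))

  # generic xref tables (licensed mapping systems emulated)
  d <- write_corpus_source(out_dir, "xrefs")
  write_table_file(df_rows(c("meddra", "umls"), if (empty) list() else list(
    c("MDR001", "C0027497"), c("MDR002", "C0012833"), c("MDR005", "C0018681"))),
    file.path(d, "meddra_umls.tsv"))

  write_truth(out_dir, empty)
  yaml::write_yaml(list(seed = manifest$seed, decoys = manifest$decoys,
                        empty = manifest$empty),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

# ground truth: enumerated from the corpus design by hand, one row per
# expected merged node/edge
write_truth <- function(out_dir, empty) {
  d <- file.path(out_dir, "truth")
  dir.create(d, showWarnings = FALSE)
  tn <- function(id, ...) c(id, join_list_cell(lex_sort(c(...))))
  nodes <- if (empty) list() else list(
    tn("DB001", "Compound", "Chemical"), tn("DB002", "Compound", "Chemical"),
    tn("DB003", "Compound", "Chemical"), tn("DB005", "Compound", "Chemical"),
    tn("DBSALT001", "Salt", "Compound", "Chemical"),
    tn("PR001", "Product"),
    tn("MESH:D011", "Chemical"), tn("MESH:D012", "Chemical"),
    tn("MONDO:0001", "Disease", "Phenotype"), tn("MONDO:0002", "Disease", "Phenotype"),
    tn("MONDO:0003", "Disease", "Phenotype"), tn("MONDO:0005", "Disease", "Phenotype"),
    tn("1001", "Gene"), tn("1002", "Gene"), tn("1003", "Gene"), tn("1005", "Gene"),
    tn("P1001", "Protein", "Target"), tn("P1002", "Protein", "Target"),
    tn("P1003", "Protein"),
    tn("wnt_signaling", "Pathway"), tn("vitamin_k_cycle", "Pathway"),
    tn("R-HSA-2", "Pathway"),
    tn("GO:0001", "BiologicalProcess"), tn("GO:0002", "CellularComponent"),
    tn("GO:0004", "CellularComponent"), tn("GO:0003", "MolecularFunction"),
    tn("R-HSA-10", "Reaction", "ReactionLikeEvent"),
    tn("VCV001", "GeneVariant", "Variant"), tn("VCV002", "GeneVariant", "Variant"),
    tn("VCV003", "GeneVariant", "Variant"), tn("VCV007", "GeneVariant", "Variant"),
    tn("VCV004", "Haplotype", "Variant"), tn("VCV005", "Genotype", "Variant"),
    tn("PA-V1", "GeneVariant", "Variant"),
    tn("C0027497", "SideEffect", "Phenotype"), tn("C0000737", "SideEffect", "Phenotype"),
    tn("C0019080", "SideEffect", "Phenotype"), tn("C0149931", "SideEffect", "Phenotype"),
    tn("C0012833", "SideEffect", "Phenotype"), tn("C0018681", "SideEffect", "Phenotype"),
    tn("MDR004", "SideEffect", "Phenotype"),
    tn("D001", "Symptom", "Phenotype"), tn("D002", "Symptom", "Phenotype"),
    tn("HP:0002", "Symptom", "Phenotype"), tn("HP:0003", "Symptom", "Phenotype"),
    tn("OMIM:600001", "Phenotype"), tn("PA-PH1", "Phenotype"),
    tn("N001", "PharmacologicalClass"), tn("N002", "PharmacologicalClass"),
    tn("B01AA", "PharmacologicalClass"),
    tn("UPI:P1001_P1002", "Interaction"), tn("IID:P1002_P1003", "Interaction"),
    tn("RT-TREAT-1", "Treatment"),
    tn("CA-PA1", "ClinicalAnnotation"), tn("VA-PA1", "VariantAnnotation"))
  write_table_file(df_rows(c("identifier", "labels"), nodes),
                   file.path(d, "nodes.tsv"))

  te <- function(type, a, b) c(type, a, b)
  edges <- if (empty) list() else list(
    te("TREATS_CHtD", "DB001", "MONDO:0001"),
    te("CAUSES_CHcSE", "DB001", "C0027497"),
    te("BINDS_CHbG", "DB002", "1002"),
    te("DOWNREGULATES_CHdG", "DB003", "1003"),
    te("PALLIATES_CHpD", "DB002", "MONDO:0003"),
    te("PRESENTS_DpS", "MONDO:0001", "D001"),
    te("ASSOCIATES_DaG", "MONDO:0002", "1003"),
    te("IS_A_DiaD", "MONDO:0002", "MONDO:0001"),
    te("IS_A_DiaD", "MONDO:0003", "MONDO:0001"),
    te("IS_A_DiaD", "MONDO:0005", "MONDO:0001"),
    te("IS_A_DiaD", "MONDO:0002", "MONDO:0003"),
    te("ASSOCIATES_PTaG", "OMIM:600001", "1001"),
    te("ASSOCIATES_PTaG", "OMIM:600001", "1002"),
    te("PARTICIPATES_IN_GpiPW", "1001", "wnt_signaling"),
    te("PARTICIPATES_IN_GpiPW", "1003", "wnt_signaling"),
    te("PARTICIPATES_IN_GpiPW", "1002", "vitamin_k_cycle"),
    te("PARTICIPATES_IN_GpiPW", "1001", "vitamin_k_cycle"),
    te("PRODUCES_GpP", "1001", "P1001"),
    te("PRODUCES_GpP", "1002", "P1002"),
    te("PRODUCES_GpP", "1003", "P1003"),
    te("INTERACTS_IiP", "UPI:P1001_P1002", "P1001"),
    te("INTERACTS_PiI", "P1002", "UPI:P1001_P1002"),
    te("IS_A_CCiaCC", "GO:0004", "GO:0002"),
    te("ENABLES_PeMF", "P1001", "GO:0003"),
    te("LOCATED_IN_PliCC", "P1001", "GO:0002"),
    te("INVOLVED_IN_GiiBP", "1001", "GO:0001"),
    te("INTERACTS_IiP", "IID:P1002_P1003", "P1002"),
    te("INTERACTS_PiI", "P1003", "IID:P1002_P1003"),
    te("MIGHT_SUBCELLULAR_LOCATES_ImslCC", "IID:P1002_P1003", "GO:0002"),
    te("HAS_ENCAPSULATED_EVENT_PWheePW", "R-HSA-2", "vitamin_k_cycle"),
    te("PARTICIPATES_IN_PWpiRLE", "vitamin_k_cycle", "R-HSA-10"),
    te("IN_COMPARTMENT_RLEicCC", "R-HSA-10", "GO:0002"),
    te("LEADS_TO_DISEASE_RLEltdD", "R-HSA-10", "MONDO:0003"),
    te("OCCURS_IN_PWoiBP", "vitamin_k_cycle", "GO:0001"),
    te("HAS_GhV", "1001", "VCV001"),
    te("HAS_GhV", "1001", "VCV002"),
    te("HAS_GhV", "1002", "VCV003"),
    te("HAS_GhV", "1001", "VCV007"),
    te("HAS_HhGV", "VCV004", "VCV001"),
    te("HAS_GThH", "VCV005", "VCV004"),
    te("HAS_GThGV", "VCV005", "VCV001"),
    te("PART_OF_CpoSA", "DB002", "DBSALT001"),
    te("HAS_ChPR", "DB002", "PR001"),
    te("INTERACTS_CiC", "DB001", "DB002"),
    te("COMBINATION_CAUSES_ADR_VccaCH", "VCV001", "DB002"),
    te("RESEMBLES_CrC", "DB002", "DB005"),
    te("IS_ACTIVE_IN_METABOLISM_CHiaimP", "DB002", "P1001"),
    te("INHIBITS_CHiP", "DB002", "P1002"),
    te("PRESENTS_DpS", "MONDO:0002", "D001"),
    te("PRESENTS_DpS", "MONDO:0003", "HP:0002"),
    te("UPREGULATES_CHuG", "MESH:D011", "1003"),
    te("BINDS_CHbP", "DB001", "P1001"),
    te("INDUCES_CHiD", "MESH:D011", "MONDO:0002"),
    te("ASSOCIATES_DaG", "MONDO:0001", "1001"),
    te("ASSOCIATES_CHaBP", "MESH:D011", "GO:0001"),
    te("INCLUDES_PCiPC", "N002", "N001"),
    te("INCLUDES_PCiCH", "N001", "DB002"),
    te("TREATS_PCtD", "N001", "MONDO:0003"),
    te("CONTRAINDICATES_CHcD", "DB001", "MONDO:0003"),
    te("TREATS_CHtT", "DB002", "RT-TREAT-1"),
    te("TREATS_TtD", "RT-TREAT-1", "MONDO:0003"),
    te("IS_LOCALIZED_IN_TiliCC", "RT-TREAT-1", "GO:0002"),
    te("HAS_INPUT_RLEhiCH", "R-HSA-10", "DB002"),
    te("HAS_OUTPUT_RLEhoCH", "R-HSA-10", "DB001"),
    te("IS_INPUT_OF_PiioRLE", "P1002", "R-HSA-10"),
    te("ASSOCIATES_TO_TOXICITY_ADR_VattaCH", "VCV001", "DB002"),
    te("ASSOCIATES_TO_DOSAGE_VatdCH", "VCV003", "DB002"),
    te("ASSOCIATES_VaCH", "VCV002", "DB002"),
    te("BELONGS_TO_CHbtPC", "DB002", "N002"),
    te("BELONGS_TO_CHbtPC", "DB002", "B01AA"),
    te("BELONGS_TO_PCbtPC", "B01AA", "N002"),
    te("CAUSES_CHcSE", "DB001", "C0000737"),
    te("CAUSES_CHcSE", "DB002", "C0019080"),
    te("CAUSES_CHcSE", "DB002", "C0149931"),
    te("MIGHT_CAUSES_CHmcSE", "DB001", "C0027497"),
    te("MIGHT_CAUSES_CHmcSE", "DB002", "C0012833"),
    te("MIGHT_CAUSES_CHmcSE", "DB001", "C0018681"),
    te("MIGHT_CAUSES_CHmcSE", "DB002", "MDR004"),
    te("MIGHT_INDUCES_CHmiD", "DB001", "MONDO:0002"),
    te("HAS_GhV", "1001", "PA-V1"),
    te("ASSOCIATES_CAaV", "CA-PA1", "VCV003"),
    te("ASSOCIATES_CAaCH", "CA-PA1", "DB002"),
    te("ASSOCIATES_CAaG", "CA-PA1", "1001"),
    te("ASSOCIATES_CAaPT", "CA-PA1", "PA-PH1"),
    te("ASSOCIATES_VAaV", "VA-PA1", "PA-V1"),
    te("ASSOCIATES_VAaCH", "VA-PA1", "DB002"),
    te("HAS_EVIDENCE_CAheVA", "CA-PA1", "VA-PA1"),
    te("EQUAL_DeSE", "MONDO:0005", "C0149931"),
    te("EQUAL_DeS", "MONDO:0005", "HP:0003"),
    te("EQUAL_SeSE", "HP:0003", "C0149931"),
    te("EQUAL_SeSE", "D001", "C0018681"),
    te("EQUAL_PTeSE", "OMIM:600001", "MDR004"),
    te("IS_ALLEL_OF_ViaoV", "VCV001", "VCV007"))
  write_table_file(df_rows(c("type", "source_id", "target_id"), edges),
                   file.path(d, "edges.tsv"))

  links <- if (empty) list() else list(
    c("CTD", "MESH:D010", "DB001", "identifier:cas"),
    c("SIDER", "Aspirin", "DB001", "name"),
    c("SIDER", "Warfarin", "DB002", "name"),
    c("AEOLUS", "MDR001", "C0027497", "xref:meddra_umls"),
    c("PharmGKB", "PA-CH1", "DB002", "identifier:drugbank_id"),
    c("PharmGKB", "PA-V2", "VCV003", "identifier:rs_id"),
    c("HPO", "HP:0001", "D001", "name"),
    c("Reactome", "R-HSA-1", "vitamin_k_cycle", "name"),
    c("NDFRT", "Warfarin", "DB002", "name"))
  write_table_file(df_rows(c("source", "entity_id", "target_identifier", "strategy"),
                           links),
                   file.path(d, "mapping_links.tsv"))

  counts <- if (empty) list() else list(
    c("entrez", "gene_info", "4"),
    c("aeolus", "drug_outcome", "5"),
    c("ctd", "chem_disease", "2"),
    c("ctd", "chem_gene", "2"),
    c("ctd", "gene_disease", "1"),
    c("ctd", "genes", "2"),
    c("iid", "ppis", "1"),
    c("uniprot", "gene_disease", "1"),
    c("drugbank", "targets", "2"))
  write_table_file(df_rows(c("source", "table", "kept"), counts),
                   file.path(d, "filter_counts.tsv"))
}

#' Read a corpus's ground-truth tables
#' @param corpus_dir corpus directory
#' @return list with `nodes`, `edges`, `mapping_links`, `filter_counts`
#' @export
read_truth <- function(corpus_dir) {
  d <- file.path(corpus_dir, "truth")
  list(nodes = read_table_file(file.path(d, "nodes.tsv")),
       edges = read_table_file(file.path(d, "edges.tsv")),
       mapping_links = read_table_file(file.path(d, "mapping_links.tsv")),
       filter_counts = read_table_file(file.path(d, "filter_counts.tsv")))
}

#' Generate bitvector pairs with prescribed Tanimoto similarities
#'
#' For each target t the generator picks equal-cardinality bit sets whose
#' overlap i satisfies i/(2k - i) within 0.01 of t (searching over k). A
#' target unreachable at the given bit length is an error.
#'
#' @param seed integer seed for bit placement
#' @param targets numeric vector of target Tanimoto values in \[0, 1\]
#' @param bits bitvector length (default 1024)
#' @return list of pairs: each has `a`, `b` (fingerprints), `target`,
#'   `achieved`
#' @export
generate_fingerprint_panel <- function(seed, targets, bits = 1024L) {
  stopifnot(all(targets >= 0 & targets <= 1))
  set.seed(seed)
  out <- list()
  for (t in targets) {
    best <- NULL
    k_max <- min(400L, bits %/% 2)
    for (k in seq_len(k_max)[-1]) {
      i <- round(2 * k * t / (1 + t))
      if (i < 0 || i > k) next
      achieved <- if (2 * k - i == 0) 0 else i / (2 * k - i)
      if (is.null(best) || abs(achieved - t) < abs(best$achieved - t)) {
        best <- list(k = k, i = i, achieved = achieved)
      }
    }
    if (is.null(best) || abs(best$achieved - t) > 0.01) {
      stop("target similarity ", t, " unreachable at bit length ", bits)
    }
    total <- 2 * best$k - best$i
    pos <- sample.int(bits, total)
    shared <- pos[seq_len(best$i)]
    only_a <- pos[best$i + seq_len(best$k - best$i)]
    only_b <- pos[best$k + seq_len(best$k - best$i)]
    gid <- paste0("panel-", bits)
    out[[length(out) + 1L]] <- list(
      a = make_fingerprint(c(shared, only_a), bits, gid),
      b = make_fingerprint(c(shared, only_b), bits, gid),
      target = t, achieved = best$achieved)
  }
  out
}

#' Build the warfarin pharmacogenomics worked-example graph
#'
#' Encodes the drug warfarin, the genes CYP2C9 and VKORC1 with their
#' proteins, and the three gene variants CYP2C9*2, CYP2C9*3 and
#' VKORC1 -1639G>A: each variant connects to warfarin through its gene and
#' protein, the classic pharmacogenomic dosing triangle.
#'
#' @return a `graph_store`
#' @export
fig_example_store <- function() {
  s <- graph_store()
  add <- function(labels, id, props) {
    props$identifier <- id
    props$resource <- "Example"
    props$example_id <- id
    gs_add_node(s, labels, props)
  }
  wf <- add(c("Compound", "Chemical"), "DB00682", list(name = "Warfarin"))
  cyp <- add("Gene", "1559", list(name = "CYP2C9", symbol = "CYP2C9"))
  vko <- add("Gene", "79001", list(name = "VKORC1", symbol = "VKORC1"))
  pc <- add("Protein", "P11712", list(name = "Cytochrome P450 2C9"))
  pv <- add("Protein", "Q9BQB6", list(name = "Vitamin K epoxide reductase 1"))
  v1 <- add(c("GeneVariant", "Variant"), "VCV000634919",
            list(name = "NM_000771.3(CYP2C9):c.430C>T (p.Arg144Cys)",
                 rs_id = "rs1799853"))
  v2 <- add(c("GeneVariant", "Variant"), "VCV000017793",
            list(name = "NM_000771.3(CYP2C9):c.1075A>C (p.Ile359Leu)",
                 rs_id = "rs1057910"))
  v3 <- add(c("GeneVariant", "Variant"), "VCV000017796",
            list(name = "NM_024006.4(VKORC1):c.-1639G>A", rs_id = "rs9923231"))
  e <- function(type, a, b) gs_add_edge(s, type, a, b,
                                        list(resource = "Example", example_id = type))
  e("HAS_GhV", cyp, v1)
  e("HAS_GhV", cyp, v2)
  e("HAS_GhV", vko, v3)
  e("PRODUCES_GpP", cyp, pc)
  e("PRODUCES_GpP", vko, pv)
  e("IS_ACTIVE_IN_METABOLISM_CHiaimP", wf, pc)
  e("INHIBITS_CHiP", wf, pv)
  s
}

#' The variant-to-drug path pattern of the worked example
#'
#' Variant <- gene -> protein <- drug: one path per variant connected to
#' the given chemical through its gene's protein.
#'
#' @param chemical_id identifier of the target chemical node
#' @return a [path_pattern()]
#' @export
variant_drug_pattern <- function(chemical_id) {
  path_pattern(
    nodes = list(list(label = "Variant"),
                 list(label = "Gene"),
                 list(label = "Protein"),
                 list(label = "Chemical", props = list(identifier = chemical_id))),
    edges = list(list(type = "HAS_GhV", direction = "in"),
                 list(type = "PRODUCES_GpP", direction = "out"),
                 list(direction = "in")))
}
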