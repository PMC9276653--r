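# Per-source merge routines. Each routine pulls its integrated source
# subgraph (and prepared link tables), resolves entities onto the merged
# schema through mapping cascades, and applies the node/edge merge
# primitives. Routines are written to be idempotent: every creation is a
# match-or-create keyed on (label, identifier), so re-running the plan on
# its own output changes nothing.

merge_context <- function(prepared_dir, xrefs = list()) {
  ctx <- new.env(parent = emptyenv())
  ctx$prepared_dir <- prepared_dir
  ctx$xrefs <- xrefs
  ctx$mappings <- new.env(parent = emptyenv())
  ctx$registry <- abbreviation_registry()
  ctx
}

#' Load cross-reference tables from a directory of two-column TSVs
#'
#' Each `<name>.tsv` becomes a deduplicated, self-loop-free xref table
#' available to mapping cascades under `<name>`.
#'
#' @param dir directory of xref TSVs
#' @return named list of data.frames
#' @export
load_xref_tables <- function(dir) {
  out <- list()
  if (!dir.exists(dir)) return(out)
  for (f in lex_sort(list.files(dir, pattern = "\\.tsv$"))) {
    df <- read_table_file(file.path(dir, f))
    df <- df[df[[1]] != df[[2]], , drop = FALSE]
    df <- df[!duplicated(paste(df[[1]], df[[2]], sep = "\x1f")), , drop = FALSE]
    rownames(df) <- NULL
    out[[tools::file_path_sans_ext(f)]] <- df
  }
  out
}

# match-or-create a merged node by (primary label, identifier)
match_or_create_node <- function(store, labels, identifier, props, source) {
  hit <- gs_lookup(store, labels[[1]], "identifier", identifier)
  if (length(hit) > 0) {
    merge_node_properties(store, hit[[1]], props, source, source_identifier = identifier)
    return(list(id = hit[[1]], created = FALSE))
  }
  list(id = create_merged_node(store, labels, identifier, props, source), created = TRUE)
}

# properties of a source node as a resolver entity
node_entity <- function(store, id) {
  node <- gs_get_node(store, id)
  ent <- node$properties
  ent$labels <- node$labels
  ent
}

# pull CURIE-prefixed ids out of an xref list ("DOID:1" under prefix DOID)
xref_with_prefix <- function(xrefs, prefix, strip = FALSE) {
  hits <- xrefs[startsWith(xrefs, paste0(prefix, ":"))]
  if (strip) sub("^[^:]+:", "", hits) else hits
}

id_strategy <- function(key) mapping_strategy("identifier", key = key)

# deterministic pick among candidate node ids: smallest primary identifier
pick_by_identifier <- function(store, ids) {
  if (length(ids) == 0) return(NULL)
  idents <- vapply(ids, function(i) node_identifier(gs_get_node(store, i)), "")
  ids[[order(idents, method = "radix")[[1]]]]
}
name_strategy <- function() mapping_strategy("name")

resolve_first <- function(entity, cascades, store, xrefs = list()) {
  # try several cascades (different target labels) in order
  for (cascade in cascades) {
    res <- resolve(entity, cascade, store, xrefs = xrefs)
    if (identical(res$status, "unique")) return(list(result = res, cascade = cascade))
  }
  NULL
}

unique_match <- function(entity, target_label, strategies, store, xrefs = list()) {
  res <- resolve(entity, mapping_cascade("adhoc", target_label, strategies),
                 store, xrefs = xrefs)
  if (identical(res$status, "unique")) res$matched[[1]] else NULL
}

# mark removal counts in routine reports
report_row <- function(created = 0L, updated = 0L, removed = 0L, edges = 0L) {
  list(created = created, updated = updated, removed = removed, edges = edges)
}

# derive disease-ish external ids from an ontology term's xref list
term_ids <- function(xrefs) {
  list(do_id = xref_with_prefix(xrefs, "DOID")[1] %||% NA_character_,
       omim = xref_with_prefix(xrefs, "OMIM")[1] %||% NA_character_,
       umls = xref_with_prefix(xrefs, "UMLS", strip = TRUE)[1] %||% NA_character_,
       mesh = xref_with_prefix(xrefs, "MSH", strip = TRUE)[1] %||% NA_character_)
}

first_or_empty <- function(x) if (length(x) == 0 || is.na(x[1])) "" else x[1]

# --- routines -----------------------------------------------------------

routine_hetionet_renames <- function(store, ctx) {
  n <- apply_renames(store, default_rename_map())
  report_row(edges = n)
}

ontology_replacement_frame <- function(store, source) {
  rows <- list()
  for (id in src_nodes(store, source, "Term")) {
    node <- gs_get_node(store, id)
    if (identical(first_or_empty(prop_values(node, "is_obsolete")), "true")) next
    ids <- term_ids(prop_values(node, "xrefs"))
    rows[[length(rows) + 1L]] <- c(
      identifier = node_identifier(node),
      name = first_or_empty(prop_values(node, "name")),
      definition = first_or_empty(prop_values(node, "definition")),
      synonyms = join_list_cell(prop_values(node, "synonyms")),
      do_id = ids$do_id %||% "", omim = ids$omim %||% "",
      umls = ids$umls %||% "", mesh = ids$mesh %||% "")
  }
  if (length(rows) == 0) {
    return(empty_df(c("identifier", "name", "definition", "synonyms",
                      "do_id", "omim", "umls", "mesh")))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  df[is.na(df)] <- ""
  df
}

merge_ontology_isa <- function(store, ctx, source, target_label, source_name) {
  n <- 0L
  type <- generate_edge_type("IS_A", target_label, target_label, ctx$registry)
  for (eid in src_edges(store, source, "is_a")) {
    e <- gs_get_edge(store, eid)
    src_ident <- node_identifier(gs_get_node(store, e$source))
    dst_ident <- node_identifier(gs_get_node(store, e$target))
    a <- gs_lookup(store, target_label, "identifier", src_ident)
    b <- gs_lookup(store, target_label, "identifier", dst_ident)
    if (length(a) == 0 || length(b) == 0) next
    if (identical(merge_edge(store, a[[1]], b[[1]], type, source = source_name), "created")) {
      n <- n + 1L
    }
  }
  n
}

routine_mondo <- function(store, ctx) {
  df <- ontology_replacement_frame(store, "mondo")
  res <- replace_or_remove_nodes(store, "Disease", df, match_key = "do_id",
                                 source = "Mondo",
                                 list_columns = c("synonyms"))
  n <- merge_ontology_isa(store, ctx, "mondo", "Disease", "Mondo")
  report_row(created = res$created, updated = res$replaced, removed = res$removed,
             edges = n)
}

routine_do <- function(store, ctx) {
  updated <- 0L
  for (id in src_nodes(store, "do", "Term")) {
    node <- gs_get_node(store, id)
    if (identical(first_or_empty(prop_values(node, "is_obsolete")), "true")) next
    ids <- term_ids(prop_values(node, "xrefs"))
    ent <- list(do_id = node_identifier(node), omim = ids$omim,
                name = first_or_empty(prop_values(node, "name")))
    hit <- unique_match(ent, "Disease",
                        list(id_strategy("do_id"), id_strategy("omim"), name_strategy()),
                        store)
    if (is.null(hit)) next
    merge_node_properties(store, hit, list(
      definition = first_or_empty(prop_values(node, "definition")),
      synonyms = prop_values(node, "synonyms")), "DO",
      source_identifier = node_identifier(node))
    updated <- updated + 1L
  }
  # DO ids live on merged diseases under do_id, so is_a endpoints resolve
  # through that property rather than the Mondo identifier
  n <- 0L
  for (eid in src_edges(store, "do", "is_a")) {
    e <- gs_get_edge(store, eid)
    a <- gs_lookup(store, "Disease", "do_id",
                   node_identifier(gs_get_node(store, e$source)))
    b <- gs_lookup(store, "Disease", "do_id",
                   node_identifier(gs_get_node(store, e$target)))
    if (length(a) == 0 || length(b) == 0) next
    if (identical(merge_edge(store, a[[1]], b[[1]], "IS_A_DiaD", source = "DO"), "created")) {
      n <- n + 1L
    }
  }
  report_row(updated = updated, edges = n)
}

routine_entrez <- function(store, ctx) {
  rows <- list()
  for (id in src_nodes(store, "entrez", "Gene")) {
    node <- gs_get_node(store, id)
    rows[[length(rows) + 1L]] <- c(
      identifier = node_identifier(node),
      symbol = first_or_empty(prop_values(node, "symbol")),
      name = first_or_empty(prop_values(node, "name")),
      taxon = first_or_empty(prop_values(node, "taxon")),
      type_of_gene = first_or_empty(prop_values(node, "type_of_gene")))
  }
  df <- if (length(rows)) as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        else empty_df(c("identifier", "symbol", "name", "taxon", "type_of_gene"))
  res <- replace_or_remove_nodes(store, "Gene", df, match_key = "identifier",
                                 source = "Entrez")
  report_row(created = res$created, updated = res$replaced, removed = res$removed)
}

routine_omim <- function(store, ctx) {
  created <- 0L; updated <- 0L; edges <- 0L
  mim_map <- list()
  for (id in src_nodes(store, "omim", "MimEntry")) {
    node <- gs_get_node(store, id)
    mim <- node_identifier(node)
    nm <- first_or_empty(prop_values(node, "name"))
    hit <- unique_match(list(omim = mim), "Disease", list(id_strategy("omim")), store)
    if (is.null(hit)) {
      hit <- gs_lookup(store, "Phenotype", "identifier", mim)
      hit <- if (length(hit) > 0) hit[[1]] else NULL
    }
    if (is.null(hit)) {
      hit <- create_merged_node(store, "Phenotype", mim, list(name = nm), "OMIM")
      created <- created + 1L
    } else {
      merge_node_properties(store, hit, list(name = nm), "OMIM",
                            source_identifier = mim)
      updated <- updated + 1L
    }
    mim_map[[mim]] <- hit
  }
  links <- prepared_table(ctx$prepared_dir, "omim", "gene_phenotype.tsv",
                          c("mim_id", "gene_id"))
  for (i in seq_len(nrow(links))) {
    g <- gs_lookup(store, "Gene", "identifier", links$gene_id[[i]])
    d <- mim_map[[links$mim_id[[i]]]]
    if (length(g) == 0 || is.null(d)) next
    d_labels <- gs_get_node(store, d)$labels
    type <- if ("Disease" %in% d_labels) "ASSOCIATES_DaG" else "ASSOCIATES_PTaG"
    if (identical(merge_edge(store, d, g[[1]], type, source = "OMIM"), "created")) {
      edges <- edges + 1L
    }
  }
  report_row(created = created, updated = updated, edges = edges)
}

routine_pathways <- function(store, ctx) {
  removed <- 0L
  for (id in gs_nodes_with_label(store, "Pathway")) {
    node <- gs_get_node(store, id)
    if (identical(node$labels[[1]], "Pathway") && is.null(node$properties$source)) {
      gs_remove_node(store, id)
      removed <- removed + 1L
    }
  }
  created <- 0L; edges <- 0L
  for (src in c("pathwaycommons", "wikipathways")) {
    source_name <- if (identical(src, "pathwaycommons")) "PathwayCommons" else "WikiPathways"
    tab <- prepared_table(ctx$prepared_dir, src, "pathway_genes.tsv",
                          c("set_name", "description", "member"))
    for (pw in unique(tab$set_name)) {
      r <- match_or_create_node(store, "Pathway", pw, list(name = pw), source_name)
      if (r$created) created <- created + 1L
    }
    for (i in seq_len(nrow(tab))) {
      g <- gs_lookup(store, "Gene", "symbol", tab$member[[i]])
      p <- gs_lookup(store, "Pathway", "identifier", tab$set_name[[i]])
      if (length(g) == 0 || length(p) == 0) next
      if (identical(merge_edge(store, g[[1]], p[[1]], "PARTICIPATES_IN_GpiPW",
                               source = source_name), "created")) {
        edges <- edges + 1L
      }
    }
  }
  report_row(created = created, removed = removed, edges = edges)
}

interaction_edge_node <- function(store, ctx, prefix, a, b, props, source) {
  # deterministic direction: lexicographically smaller protein identifier
  # gets the INTERACTS_IiP edge (node -> protein), the larger INTERACTS_PiI
  pa <- gs_get_node(store, a); pb <- gs_get_node(store, b)
  if (node_identifier(pa) > node_identifier(pb)) { tmp <- a; a <- b; b <- tmp }
  ident <- paste0(prefix, ":", node_identifier(gs_get_node(store, a)), "_",
                  node_identifier(gs_get_node(store, b)))
  hit <- gs_lookup(store, "Interaction", "identifier", ident)
  if (length(hit) > 0) {
    merge_node_properties(store, hit[[1]], props, source, source_identifier = ident)
    nid <- hit[[1]]
  } else {
    nid <- create_merged_node(store, "Interaction", ident, props, source)
  }
  merge_edge(store, nid, a, "INTERACTS_IiP", source = source)
  merge_edge(store, b, nid, "INTERACTS_PiI", source = source)
  nid
}

routine_uniprot <- function(store, ctx) {
  created <- 0L; edges <- 0L
  for (id in src_nodes(store, "uniprot", "Protein")) {
    node <- gs_get_node(store, id)
    props <- node$properties[setdiff(names(node$properties), c("source"))]
    r <- match_or_create_node(store, "Protein", node_identifier(node), props, "UniProt")
    if (r$created) created <- created + 1L
    g <- gs_lookup(store, "Gene", "symbol", first_or_empty(prop_values(node, "gene_symbol")))
    if (length(g) > 0) {
      if (identical(merge_edge(store, g[[1]], r$id, "PRODUCES_GpP", source = "UniProt"),
                    "created")) edges <- edges + 1L
    }
  }
  ints <- prepared_table(ctx$prepared_dir, "uniprot", "interactions.tsv",
                         c("a_id", "b_id", "pubmed_ids"))
  for (i in seq_len(nrow(ints))) {
    a <- gs_lookup(store, "Protein", "identifier", ints$a_id[[i]])
    b <- gs_lookup(store, "Protein", "identifier", ints$b_id[[i]])
    if (length(a) == 0 || length(b) == 0) next
    interaction_edge_node(store, ctx, "UPI", a[[1]], b[[1]],
                          list(pubmed_ids = split_list_cell(ints$pubmed_ids[[i]])),
                          "UniProt")
  }
  gd <- prepared_table(ctx$prepared_dir, "uniprot", "gene_disease.tsv",
                       c("gene_symbol", "omim_id", "pubmed_ids"))
  for (i in seq_len(nrow(gd))) {
    g <- gs_lookup(store, "Gene", "symbol", gd$gene_symbol[[i]])
    d <- gs_lookup(store, "Disease", "omim", gd$omim_id[[i]])
    if (length(g) == 0 || length(d) == 0) next
    merge_edge(store, d[[1]], g[[1]], "ASSOCIATES_DaG",
               list(pubmed_ids = split_list_cell(gd$pubmed_ids[[i]])),
               source = "UniProt")
  }
  report_row(created = created, edges = edges)
}

GO_NAMESPACE_LABELS <- c(biological_process = "BiologicalProcess",
                         cellular_component = "CellularComponent",
                         molecular_function = "MolecularFunction")

go_term_lookup <- function(store, go_id) {
  for (lb in unname(GO_NAMESPACE_LABELS)) {
    hit <- gs_lookup(store, lb, "identifier", go_id)
    if (length(hit) > 0) return(list(id = hit[[1]], label = lb))
  }
  NULL
}

routine_go <- function(store, ctx) {
  removed <- 0L
  for (lb in unname(GO_NAMESPACE_LABELS)) {
    for (id in gs_nodes_with_label(store, lb)) {
      node <- gs_get_node(store, id)
      if (is.null(node$properties$source)) {
        gs_remove_node(store, id)
        removed <- removed + 1L
      }
    }
  }
  created <- 0L; edges <- 0L
  for (id in src_nodes(store, "go", "Term")) {
    node <- gs_get_node(store, id)
    if (identical(first_or_empty(prop_values(node, "is_obsolete")), "true")) next
    lb <- GO_NAMESPACE_LABELS[[first_or_empty(prop_values(node, "namespace"))]] %||% NULL
    if (is.null(lb)) next
    r <- match_or_create_node(store, lb, node_identifier(node),
                              list(name = first_or_empty(prop_values(node, "name")),
                                   namespace = first_or_empty(prop_values(node, "namespace"))),
                              "GO")
    if (r$created) created <- created + 1L
  }
  for (eid in src_edges(store, "go", "is_a")) {
    e <- gs_get_edge(store, eid)
    a <- go_term_lookup(store, node_identifier(gs_get_node(store, e$source)))
    b <- go_term_lookup(store, node_identifier(gs_get_node(store, e$target)))
    if (is.null(a) || is.null(b)) next
    type <- generate_edge_type("IS_A", a$label, b$label, ctx$registry)
    if (identical(merge_edge(store, a$id, b$id, type, source = "GO"), "created")) {
      edges <- edges + 1L
    }
  }
  ann <- prepared_table(ctx$prepared_dir, "go", "annotations.tsv",
                        c("db", "subject_id", "symbol", "qualifier", "go_id",
                          "reference", "evidence_code", "evidence"))
  for (i in seq_len(nrow(ann))) {
    subject <- if (identical(ann$db[[i]], "UniProtKB")) {
      hit <- gs_lookup(store, "Protein", "identifier", ann$subject_id[[i]])
      if (length(hit)) list(id = hit[[1]], label = "Protein") else NULL
    } else {
      hit <- gs_lookup(store, "Gene", "identifier", ann$subject_id[[i]])
      if (length(hit)) list(id = hit[[1]], label = "Gene") else NULL
    }
    term <- go_term_lookup(store, ann$go_id[[i]])
    if (is.null(subject) || is.null(term)) next
    type <- generate_edge_type(toupper(ann$qualifier[[i]]), subject$label,
                               term$label, ctx$registry)
    if (identical(merge_edge(store, subject$id, term$id, type,
                             list(evidence = ann$evidence[[i]],
                                  pubmed_ids = sub("^PMID:", "", ann$reference[[i]])),
                             source = "GO"), "created")) edges <- edges + 1L
  }
  report_row(created = created, removed = removed, edges = edges)
}

routine_iid <- function(store, ctx) {
  ppis <- prepared_table(ctx$prepared_dir, "iid", "ppis.tsv",
                         c("a_id", "b_id", "evidence_type", "cc_name"))
  edges <- 0L
  for (i in seq_len(nrow(ppis))) {
    a <- gs_lookup(store, "Protein", "identifier", ppis$a_id[[i]])
    b <- gs_lookup(store, "Protein", "identifier", ppis$b_id[[i]])
    if (length(a) == 0 || length(b) == 0) next
    nid <- interaction_edge_node(store, ctx, "IID", a[[1]], b[[1]],
                                 list(evidence_type = ppis$evidence_type[[i]]), "IID")
    cc <- ppis$cc_name[[i]]
    if (nzchar(cc)) {
      hit <- unique_match(list(name = cc), "CellularComponent",
                          list(name_strategy()), store)
      if (!is.null(hit)) {
        if (identical(merge_edge(store, nid, hit, "MIGHT_SUBCELLULAR_LOCATES_ImslCC",
                                 source = "IID"), "created")) edges <- edges + 1L
      }
    }
  }
  report_row(edges = edges)
}

RLE_LABELS <- c("Reaction", "FailedReaction", "BlackBoxEvent",
                "Polymerisation", "Depolymerisation")

is_human <- function(node) {
  sp <- first_or_empty(prop_values(node, "species"))
  !nzchar(sp) || identical(sp, "Homo sapiens")
}

routine_reactome <- function(store, ctx) {
  created <- 0L; edges <- 0L
  pw_map <- list()
  for (id in src_nodes(store, "reactome", "Pathway")) {
    node <- gs_get_node(store, id)
    if (!is_human(node)) next
    ent <- list(reactome_id = node_identifier(node),
                name = first_or_empty(prop_values(node, "name")))
    hit <- unique_match(ent, "Pathway",
                        list(id_strategy("reactome_id"), name_strategy()), store)
    if (is.null(hit)) {
      hit <- create_merged_node(store, "Pathway", node_identifier(node),
                                list(name = ent$name, reactome_id = ent$reactome_id),
                                "Reactome")
      created <- created + 1L
    } else {
      merge_node_properties(store, hit, list(reactome_id = ent$reactome_id), "Reactome",
                            source_identifier = ent$reactome_id)
    }
    pw_map[[id]] <- hit
    bp <- first_or_empty(prop_values(node, "bp_go"))
    if (nzchar(bp)) {
      term <- go_term_lookup(store, bp)
      if (!is.null(term)) {
        type <- generate_edge_type("OCCURS_IN", "Pathway", term$label, ctx$registry)
        if (identical(merge_edge(store, hit, term$id, type, source = "Reactome"),
                      "created")) edges <- edges + 1L
      }
    }
  }
  rle_map <- list()
  for (lb in RLE_LABELS) {
    for (id in src_nodes(store, "reactome", lb)) {
      node <- gs_get_node(store, id)
      if (!is_human(node)) next
      if (length(prop_values(node, "pubmed_ids")) == 0) next
      r <- match_or_create_node(store, lb, node_identifier(node),
                                list(name = first_or_empty(prop_values(node, "name")),
                                     pubmed_ids = prop_values(node, "pubmed_ids")),
                                "Reactome")
      if (r$created) created <- created + 1L
      rle_map[[id]] <- r$id
      cc <- first_or_empty(prop_values(node, "compartment_go"))
      if (nzchar(cc)) {
        term <- go_term_lookup(store, cc)
        if (!is.null(term)) {
          if (identical(merge_edge(store, r$id, term$id, "IN_COMPARTMENT_RLEicCC",
                                   source = "Reactome"), "created")) edges <- edges + 1L
        }
      }
      dd <- first_or_empty(prop_values(node, "disease_do"))
      if (nzchar(dd)) {
        d <- gs_lookup(store, "Disease", "do_id", dd)
        if (length(d) > 0) {
          if (identical(merge_edge(store, r$id, d[[1]], "LEADS_TO_DISEASE_RLEltdD",
                                   source = "Reactome"), "created")) edges <- edges + 1L
        }
      }
    }
  }
  for (eid in src_edges(store, "reactome", "hasEncapsulatedEvent")) {
    e <- gs_get_edge(store, eid)
    a <- pw_map[[e$source]]; b <- pw_map[[e$target]]
    if (is.null(a) || is.null(b)) next
    if (identical(merge_edge(store, a, b, "HAS_ENCAPSULATED_EVENT_PWheePW",
                             source = "Reactome"), "created")) edges <- edges + 1L
  }
  for (eid in src_edges(store, "reactome", "hasEvent")) {
    e <- gs_get_edge(store, eid)
    a <- pw_map[[e$source]]; b <- rle_map[[e$target]]
    if (is.null(a) || is.null(b)) next
    if (identical(merge_edge(store, a, b, "PARTICIPATES_IN_PWpiRLE",
                             source = "Reactome"), "created")) edges <- edges + 1L
  }
  ctx$mappings$reactome_rle <- rle_map
  report_row(created = created, edges = edges)
}

routine_clinvar <- function(store, ctx) {
  created <- 0L; edges <- 0L
  for (lb in c("GeneVariant", "Haplotype", "Genotype")) {
    for (id in src_nodes(store, "clinvar", lb)) {
      node <- gs_get_node(store, id)
      props <- list(name = first_or_empty(prop_values(node, "name")),
                    rs_id = first_or_empty(prop_values(node, "rs_id")),
                    clinical_significance = first_or_empty(
                      prop_values(node, "clinical_significance")))
      r <- match_or_create_node(store, lb, node_identifier(node), props, "ClinVar")
      if (r$created) created <- created + 1L
    }
  }
  rel_types <- c(gene_variant = "HAS_GhV", haplotype_gv = "HAS_HhGV",
                 genotype_h = "HAS_GThH", genotype_gv = "HAS_GThGV")
  rel_labels <- list(gene_variant = c("Gene", "GeneVariant"),
                     haplotype_gv = c("Haplotype", "GeneVariant"),
                     genotype_h = c("Genotype", "Haplotype"),
                     genotype_gv = c("Genotype", "GeneVariant"))
  rel <- prepared_table(ctx$prepared_dir, "clinvar", "relationships.tsv",
                        c("rel", "source_id", "target_id"))
  for (i in seq_len(nrow(rel))) {
    kind <- rel$rel[[i]]
    type <- rel_types[[kind]] %||% NULL
    if (is.null(type)) next
    a <- gs_lookup(store, rel_labels[[kind]][[1]], "identifier", rel$source_id[[i]])
    b <- gs_lookup(store, rel_labels[[kind]][[2]], "identifier", rel$target_id[[i]])
    if (length(a) == 0 || length(b) == 0) next
    if (identical(merge_edge(store, a[[1]], b[[1]], type, source = "ClinVar"),
                  "created")) edges <- edges + 1L
  }
  report_row(created = created, edges = edges)
}

routine_drugbank <- function(store, ctx) {
  rows <- list()
  for (id in src_nodes(store, "drugbank", "Drug")) {
    node <- gs_get_node(store, id)
    rows[[length(rows) + 1L]] <- c(
      identifier = node_identifier(node),
      name = first_or_empty(prop_values(node, "name")),
      cas = first_or_empty(prop_values(node, "cas")),
      synonyms = join_list_cell(prop_values(node, "synonyms")),
      structure = first_or_empty(prop_values(node, "structure")))
  }
  df <- if (length(rows)) as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        else empty_df(c("identifier", "name", "cas", "synonyms", "structure"))
  res <- replace_or_remove_nodes(store, "Compound", df, match_key = "identifier",
                                 source = "DrugBank")
  edges <- 0L; created <- res$created
  for (id in src_nodes(store, "drugbank", "Salt")) {
    node <- gs_get_node(store, id)
    r <- match_or_create_node(store, "Salt", node_identifier(node),
                              list(name = first_or_empty(prop_values(node, "name"))),
                              "DrugBank")
    if (r$created) created <- created + 1L
    parent <- gs_lookup(store, "Compound", "identifier",
                        first_or_empty(prop_values(node, "parent")))
    if (length(parent) > 0) {
      if (identical(merge_edge(store, parent[[1]], r$id, "PART_OF_CpoSA",
                               source = "DrugBank"), "created")) edges <- edges + 1L
    }
  }
  for (id in src_nodes(store, "drugbank", "Product")) {
    node <- gs_get_node(store, id)
    r <- match_or_create_node(store, "Product", node_identifier(node),
                              list(name = first_or_empty(prop_values(node, "name"))),
                              "DrugBank")
    if (r$created) created <- created + 1L
    drug <- gs_lookup(store, "Compound", "identifier",
                      first_or_empty(prop_values(node, "drug")))
    if (length(drug) > 0) {
      if (identical(merge_edge(store, drug[[1]], r$id, "HAS_ChPR",
                               source = "DrugBank"), "created")) edges <- edges + 1L
    }
  }
  ints <- prepared_table(ctx$prepared_dir, "drugbank", "interactions.tsv",
                         c("a_id", "b_id"))
  for (i in seq_len(nrow(ints))) {
    a <- gs_lookup(store, "Compound", "identifier", ints$a_id[[i]])
    b <- gs_lookup(store, "Compound", "identifier", ints$b_id[[i]])
    if (length(a) == 0 || length(b) == 0) next
    if (identical(merge_edge(store, a[[1]], b[[1]], "INTERACTS_CiC",
                             source = "DrugBank"), "created")) edges <- edges + 1L
  }
  snps <- prepared_table(ctx$prepared_dir, "drugbank", "snp_adr.tsv",
                         c("rs_id", "drug"))
  for (i in seq_len(nrow(snps))) {
    v <- pick_by_identifier(store, gs_lookup(store, "GeneVariant", "rs_id",
                                             snps$rs_id[[i]]))
    d <- gs_lookup(store, "Compound", "identifier", snps$drug[[i]])
    if (is.null(v) || length(d) == 0) next
    if (identical(merge_edge(store, v, d[[1]], "COMBINATION_CAUSES_ADR_VccaCH",
                             source = "DrugBank"), "created")) edges <- edges + 1L
  }
  targets <- prepared_table(ctx$prepared_dir, "drugbank", "targets.tsv",
                            c("drug", "uniprot", "relation", "pubmed_ids"))
  for (i in seq_len(nrow(targets))) {
    d <- gs_lookup(store, "Compound", "identifier", targets$drug[[i]])
    p <- gs_lookup(store, "Protein", "identifier", targets$uniprot[[i]])
    if (length(d) == 0 || length(p) == 0) next
    pn <- gs_get_node(store, p[[1]])
    if (!"Target" %in% pn$labels) gs_set_node(store, p[[1]], labels = c(pn$labels, "Target"))
    type <- generate_edge_type(targets$relation[[i]], "Chemical", "Protein", ctx$registry)
    if (identical(merge_edge(store, d[[1]], p[[1]], type,
                             list(pubmed_ids = split_list_cell(targets$pubmed_ids[[i]])),
                             source = "DrugBank"), "created")) edges <- edges + 1L
  }
  # structure similarity refresh: drop and recompute resemblance edges
  for (eid in gs_edges_with_type(store, "RESEMBLES_CrC")) gs_remove_edge(store, eid)
  comp_ids <- gs_nodes_with_label(store, "Compound")
  comp_ids <- comp_ids[vapply(comp_ids, function(i) {
    nzchar(first_or_empty(prop_values(gs_get_node(store, i), "structure")))
  }, logical(1))]
  if (length(comp_ids) >= 2) {
    structures <- vapply(comp_ids, function(i) {
      first_or_empty(prop_values(gs_get_node(store, i), "structure"))
    }, "")
    idents <- vapply(comp_ids, function(i) node_identifier(gs_get_node(store, i)), "")
    fps <- fingerprint_set(structures, ids = idents)
    sim <- resemblance_edges(fps, threshold = 0.75)
    for (i in seq_len(nrow(sim))) {
      a <- gs_lookup(store, "Compound", "identifier", sim$source[[i]])
      b <- gs_lookup(store, "Compound", "identifier", sim$target[[i]])
      gs_add_edge(store, "RESEMBLES_CrC", a[[1]], b[[1]],
                  list(origin = "derived", tanimoto = sim$tanimoto[[i]],
                       dice = sim$dice[[i]], score = sim$score[[i]]))
      edges <- edges + 1L
    }
  }
  report_row(created = created, updated = res$replaced, removed = res$removed,
             edges = edges)
}

routine_hpo <- function(store, ctx) {
  created <- 0L; updated <- 0L; edges <- 0L
  hp_map <- list()
  for (id in src_nodes(store, "hpo", "Term")) {
    node <- gs_get_node(store, id)
    if (identical(first_or_empty(prop_values(node, "is_obsolete")), "true")) next
    ids <- term_ids(prop_values(node, "xrefs"))
    ent <- list(mesh = ids$mesh, umls = ids$umls,
                name = first_or_empty(prop_values(node, "name")))
    hit <- unique_match(ent, "Symptom",
                        list(id_strategy("mesh"), id_strategy("umls"), name_strategy()),
                        store)
    if (is.null(hit)) {
      hit <- gs_lookup(store, "Symptom", "identifier", node_identifier(node))
      hit <- if (length(hit) > 0) hit[[1]] else NULL
    }
    if (is.null(hit)) {
      props <- list(name = ent$name)
      if (!is.na(ids$umls)) props$umls <- ids$umls
      hit <- create_merged_node(store, "Symptom", node_identifier(node), props, "HPO")
      created <- created + 1L
    } else {
      props <- list()
      if (!is.na(ids$umls)) props$umls <- ids$umls
      merge_node_properties(store, hit, props, "HPO",
                            source_identifier = node_identifier(node))
      updated <- updated + 1L
    }
    hp_map[[node_identifier(node)]] <- hit
  }
  hpoa <- prepared_table(ctx$prepared_dir, "hpo", "phenotype_annotations.tsv",
                         c("disease_id", "hp_id"))
  for (i in seq_len(nrow(hpoa))) {
    did <- hpoa$disease_id[[i]]
    ent <- if (startsWith(did, "OMIM:")) list(omim = did) else list(do_id = did)
    d <- unique_match(ent, "Disease",
                      list(id_strategy("omim"), id_strategy("do_id")), store)
    s <- hp_map[[hpoa$hp_id[[i]]]]
    if (is.null(d) || is.null(s)) next
    merge_node_properties(store, d, list(), "HPO", source_identifier = did)
    if (identical(merge_edge(store, d, s, "PRESENTS_DpS", source = "HPO"),
                  "created")) edges <- edges + 1L
  }
  report_row(created = created, updated = updated, edges = edges)
}

ctd_chemical_cascade <- function() {
  list(id_strategy("cas"), id_strategy("rxnorm"), id_strategy("unii"),
       id_strategy("inchikey"), id_strategy("mesh"), name_strategy())
}

# protein reached through the subject gene's PRODUCES_GpP edge
gene_protein <- function(store, gene_id) {
  for (eid in gs_incident_edges(store, gene_id)) {
    e <- gs_get_edge(store, eid)
    if (identical(e$type, "PRODUCES_GpP") && identical(e$source, gene_id)) {
      return(e$target)
    }
  }
  NULL
}

routine_ctd <- function(store, ctx) {
  created <- 0L; updated <- 0L; edges <- 0L
  chem_map <- list()
  for (id in src_nodes(store, "ctd", "Chemical")) {
    node <- gs_get_node(store, id)
    mesh <- node_identifier(node)
    ent <- list(cas = first_or_empty(prop_values(node, "cas")), mesh = mesh,
                name = first_or_empty(prop_values(node, "name")))
    hit <- unique_match(ent, "Chemical", ctd_chemical_cascade(), store)
    if (is.null(hit)) {
      props <- list(name = ent$name, mesh = mesh)
      if (nzchar(ent$cas)) props$cas <- ent$cas
      hit <- create_merged_node(store, "Chemical", mesh, props, "CTD")
      created <- created + 1L
    } else {
      merge_node_properties(store, hit, list(mesh = mesh), "CTD",
                            source_identifier = mesh)
      updated <- updated + 1L
    }
    chem_map[[mesh]] <- hit
  }
  for (id in src_nodes(store, "ctd", "Gene")) {
    g <- gs_lookup(store, "Gene", "identifier", node_identifier(gs_get_node(store, id)))
    if (length(g) > 0) {
      merge_node_properties(store, g[[1]], list(), "CTD",
                            source_identifier = node_identifier(gs_get_node(store, id)))
      updated <- updated + 1L
    }
  }
  resolve_ctd_disease <- function(did) {
    ent <- if (startsWith(did, "DOID:")) list(do_id = did)
           else if (startsWith(did, "OMIM:")) list(omim = did)
           else if (startsWith(did, "MESH:")) list(mesh = sub("^MESH:", "", did))
           else list(name = did)
    unique_match(ent, "Disease",
                 list(id_strategy("do_id"), id_strategy("omim"),
                      id_strategy("mesh"), name_strategy()), store)
  }
  cg <- prepared_table(ctx$prepared_dir, "ctd", "chem_gene.tsv",
                       c("chemical_id", "gene_id", "relation", "target_type",
                         "taxon", "pubmed_ids"))
  for (i in seq_len(nrow(cg))) {
    ch <- chem_map[[cg$chemical_id[[i]]]]
    g <- gs_lookup(store, "Gene", "identifier", cg$gene_id[[i]])
    if (is.null(ch) || length(g) == 0) next
    props <- list(pubmed_ids = split_list_cell(cg$pubmed_ids[[i]]))
    if (identical(cg$target_type[[i]], "protein")) {
      p <- gene_protein(store, g[[1]])
      if (is.null(p)) next
      type <- generate_edge_type(cg$relation[[i]], "Chemical", "Protein", ctx$registry)
      if (identical(merge_edge(store, ch, p, type, props, source = "CTD"),
                    "created")) edges <- edges + 1L
    } else {
      type <- generate_edge_type(cg$relation[[i]], "Chemical", "Gene", ctx$registry)
      if (identical(merge_edge(store, ch, g[[1]], type, props, source = "CTD"),
                    "created")) edges <- edges + 1L
    }
  }
  cd <- prepared_table(ctx$prepared_dir, "ctd", "chem_disease.tsv",
                       c("chemical_id", "disease_id", "DirectEvidence", "pubmed_ids"))
  for (i in seq_len(nrow(cd))) {
    ch <- chem_map[[cd$chemical_id[[i]]]]
    d <- resolve_ctd_disease(cd$disease_id[[i]])
    if (is.null(ch) || is.null(d)) next
    type <- if (identical(cd$DirectEvidence[[i]], "therapeutic")) "TREATS_CHtD"
            else "INDUCES_CHiD"
    if (identical(merge_edge(store, ch, d, type,
                             list(pubmed_ids = split_list_cell(cd$pubmed_ids[[i]])),
                             source = "CTD"), "created")) edges <- edges + 1L
  }
  gd <- prepared_table(ctx$prepared_dir, "ctd", "gene_disease.tsv",
                       c("gene_id", "disease_id", "DirectEvidence", "pubmed_ids"))
  for (i in seq_len(nrow(gd))) {
    g <- gs_lookup(store, "Gene", "identifier", gd$gene_id[[i]])
    d <- resolve_ctd_disease(gd$disease_id[[i]])
    if (length(g) == 0 || is.null(d)) next
    if (identical(merge_edge(store, d, g[[1]], "ASSOCIATES_DaG",
                             list(pubmed_ids = split_list_cell(gd$pubmed_ids[[i]])),
                             source = "CTD"), "created")) edges <- edges + 1L
  }
  cgo <- prepared_table(ctx$prepared_dir, "ctd", "chem_go.tsv",
                        c("chemical_id", "go_id", "relation", "pubmed_ids"))
  for (i in seq_len(nrow(cgo))) {
    ch <- chem_map[[cgo$chemical_id[[i]]]]
    term <- go_term_lookup(store, cgo$go_id[[i]])
    if (is.null(ch) || is.null(term)) next
    type <- generate_edge_type(cgo$relation[[i]], "Chemical", term$label, ctx$registry)
    if (identical(merge_edge(store, ch, term$id, type,
                             list(pubmed_ids = split_list_cell(cgo$pubmed_ids[[i]])),
                             source = "CTD"), "created")) edges <- edges + 1L
  }
  report_row(created = created, updated = updated, edges = edges)
}

routine_ndfrt <- function(store, ctx) {
  removed <- 0L
  for (id in gs_nodes_with_label(store, "PharmacologicalClass")) {
    node <- gs_get_node(store, id)
    if (identical(node$labels[[1]], "PharmacologicalClass") &&
        is.null(node$properties$source)) {
      gs_remove_node(store, id)
      removed <- removed + 1L
    }
  }
  created <- 0L; edges <- 0L
  for (id in src_nodes(store, "ndfrt", "Class")) {
    node <- gs_get_node(store, id)
    r <- match_or_create_node(store, "PharmacologicalClass", node_identifier(node),
                              list(name = first_or_empty(prop_values(node, "name")),
                                   class_kind = first_or_empty(prop_values(node, "kind"))),
                              "NDFRT")
    if (r$created) created <- created + 1L
  }
  hier <- prepared_table(ctx$prepared_dir, "ndfrt", "class_hierarchy.tsv",
                         c("source_id", "target_id"))
  for (i in seq_len(nrow(hier))) {
    a <- gs_lookup(store, "PharmacologicalClass", "identifier", hier$source_id[[i]])
    b <- gs_lookup(store, "PharmacologicalClass", "identifier", hier$target_id[[i]])
    if (length(a) == 0 || length(b) == 0) next
    if (identical(merge_edge(store, a[[1]], b[[1]], "INCLUDES_PCiPC",
                             source = "NDFRT"), "created")) edges <- edges + 1L
  }
  chem_cascade <- list(id_strategy("rxnorm"), id_strategy("umls"),
                       id_strategy("inchikey"), id_strategy("unii"), name_strategy())
  dc <- prepared_table(ctx$prepared_dir, "ndfrt", "drug_class.tsv",
                       c("drug_name", "class_id"))
  for (i in seq_len(nrow(dc))) {
    ch <- unique_match(list(name = dc$drug_name[[i]]), "Chemical", chem_cascade, store)
    cl <- gs_lookup(store, "PharmacologicalClass", "identifier", dc$class_id[[i]])
    if (is.null(ch) || length(cl) == 0) next
    merge_node_properties(store, ch, list(), "NDFRT",
                          source_identifier = dc$drug_name[[i]])
    if (identical(merge_edge(store, cl[[1]], ch, "INCLUDES_PCiCH",
                             source = "NDFRT"), "created")) edges <- edges + 1L
  }
  dd <- prepared_table(ctx$prepared_dir, "ndfrt", "drug_disease.tsv",
                       c("subject_kind", "subject", "disease_name", "relation"))
  disease_cascade <- list(id_strategy("umls"), id_strategy("mesh"), name_strategy())
  for (i in seq_len(nrow(dd))) {
    d <- unique_match(list(name = dd$disease_name[[i]]), "Disease", disease_cascade, store)
    if (is.null(d)) next
    if (identical(dd$subject_kind[[i]], "class")) {
      s <- gs_lookup(store, "PharmacologicalClass", "identifier", dd$subject[[i]])
      if (length(s) == 0) next
      type <- generate_edge_type(dd$relation[[i]], "PharmacologicalClass", "Disease",
                                 ctx$registry)
      s <- s[[1]]
    } else {
      s <- unique_match(list(name = dd$subject[[i]]), "Chemical", chem_cascade, store)
      if (is.null(s)) next
      type <- generate_edge_type(dd$relation[[i]], "Chemical", "Disease", ctx$registry)
    }
    if (identical(merge_edge(store, s, d, type, source = "NDFRT"), "created")) {
      edges <- edges + 1L
    }
  }
  report_row(created = created, removed = removed, edges = edges)
}

reactome_chem_cascade <- function() {
  list(id_strategy("chebi"), id_strategy("kegg"), id_strategy("pubchem"),
       id_strategy("inchi"), id_strategy("iuphar"), name_strategy())
}

routine_reactome_chemicals <- function(store, ctx) {
  created <- 0L; edges <- 0L
  for (id in src_nodes(store, "reactome", "Treatment")) {
    node <- gs_get_node(store, id)
    ch <- unique_match(list(chebi = first_or_empty(prop_values(node, "chebi")),
                            name = first_or_empty(prop_values(node, "chemical_name"))),
                       "Chemical", reactome_chem_cascade(), store)
    d <- unique_match(list(name = first_or_empty(prop_values(node, "disease_name"))),
                      "Disease", list(id_strategy("do_id"), name_strategy()), store)
    cc <- go_term_lookup(store, first_or_empty(prop_values(node, "cc_go")))
    participants <- list()
    if (!is.null(ch)) participants <- c(participants, list(list(
      node = ch, relation = "TREATS", label = "Chemical", direction = "in")))
    if (!is.null(d)) participants <- c(participants, list(list(
      node = d, relation = "TREATS", label = "Disease", direction = "out")))
    if (!is.null(cc)) participants <- c(participants, list(list(
      node = cc$id, relation = "IS_LOCALIZED_IN", label = "CellularComponent",
      direction = "out")))
    if (length(participants) < 2) next
    r <- merge_edge_node(store, "Treatment", node_identifier(node), participants,
                         list(), "Reactome", ctx$registry)
    if (r$created) {
      created <- created + 1L
      edges <- edges + length(participants)
    }
  }
  for (src_id in names(ctx$mappings$reactome_rle %||% list())) {
    node <- gs_get_node(store, src_id)
    rle <- ctx$mappings$reactome_rle[[src_id]]
    if (is.null(node) || is.null(gs_get_node(store, rle))) next
    input_ch <- first_or_empty(prop_values(node, "input_chemical_name"))
    if (nzchar(input_ch)) {
      ch <- unique_match(list(name = input_ch), "Chemical", reactome_chem_cascade(), store)
      if (!is.null(ch) && identical(merge_edge(store, rle, ch, "HAS_INPUT_RLEhiCH",
                                               source = "Reactome"), "created")) {
        edges <- edges + 1L
      }
    }
    output_ch <- first_or_empty(prop_values(node, "output_chemical_name"))
    if (nzchar(output_ch)) {
      ch <- unique_match(list(name = output_ch), "Chemical", reactome_chem_cascade(), store)
      if (!is.null(ch) && identical(merge_edge(store, rle, ch, "HAS_OUTPUT_RLEhoCH",
                                               source = "Reactome"), "created")) {
        edges <- edges + 1L
      }
    }
    input_p <- first_or_empty(prop_values(node, "input_protein"))
    if (nzchar(input_p)) {
      p <- gs_lookup(store, "Protein", "identifier", input_p)
      if (length(p) > 0 && identical(merge_edge(store, p[[1]], rle, "IS_INPUT_OF_PiioRLE",
                                                source = "Reactome"), "created")) {
        edges <- edges + 1L
      }
    }
  }
  report_row(created = created, edges = edges)
}

routine_clinvar_chemicals <- function(store, ctx) {
  edges <- 0L
  links <- prepared_table(ctx$prepared_dir, "clinvar", "drug_links.tsv",
                          c("variant_id", "drug_name", "association"))
  for (i in seq_len(nrow(links))) {
    v <- gs_lookup(store, "GeneVariant", "identifier", links$variant_id[[i]])
    ch <- unique_match(list(name = links$drug_name[[i]]), "Chemical",
                       list(name_strategy()), store)
    if (length(v) == 0 || is.null(ch)) next
    assoc <- links$association[[i]]
    relation <- if (nzchar(assoc)) paste0("ASSOCIATES_TO_", assoc) else "ASSOCIATES"
    type <- generate_edge_type(relation, "Variant", "Chemical", ctx$registry)
    if (identical(merge_edge(store, v[[1]], ch, type, source = "ClinVar"),
                  "created")) edges <- edges + 1L
  }
  report_row(edges = edges)
}

routine_drugbank_remainder <- function(store, ctx) {
  created <- 0L; edges <- 0L
  atc <- prepared_table(ctx$prepared_dir, "drugbank", "atc.tsv",
                        c("code", "name", "parent", "drug"))
  code_map <- list()
  for (code in unique(atc$code)) {
    row <- atc[atc$code == code, , drop = FALSE][1, ]
    hit <- unique_match(list(name = row$name), "PharmacologicalClass",
                        list(name_strategy()), store)
    if (is.null(hit)) {
      hit <- gs_lookup(store, "PharmacologicalClass", "identifier", code)
      hit <- if (length(hit) > 0) hit[[1]] else NULL
    }
    if (is.null(hit)) {
      hit <- create_merged_node(store, "PharmacologicalClass", code,
                                list(name = row$name, atc = code), "DrugBank")
      created <- created + 1L
    } else {
      merge_node_properties(store, hit, list(atc = code), "DrugBank",
                            source_identifier = code)
    }
    code_map[[code]] <- hit
  }
  for (i in seq_len(nrow(atc))) {
    cl <- code_map[[atc$code[[i]]]]
    if (nzchar(atc$drug[[i]])) {
      d <- gs_lookup(store, "Compound", "identifier", atc$drug[[i]])
      if (length(d) > 0 && identical(merge_edge(store, d[[1]], cl, "BELONGS_TO_CHbtPC",
                                                source = "DrugBank"), "created")) {
        edges <- edges + 1L
      }
    }
    if (nzchar(atc$parent[[i]])) {
      parent <- code_map[[atc$parent[[i]]]]
      if (is.null(parent)) {
        hit <- unique_match(list(name = atc$parent[[i]]), "PharmacologicalClass",
                            list(name_strategy()), store)
        parent <- hit
      }
      if (!is.null(parent) && identical(merge_edge(store, cl, parent, "BELONGS_TO_PCbtPC",
                                                   source = "DrugBank"), "created")) {
        edges <- edges + 1L
      }
    }
  }
  report_row(created = created, edges = edges)
}

routine_sider <- function(store, ctx) {
  removed <- 0L
  for (id in gs_nodes_with_label(store, "SideEffect")) {
    node <- gs_get_node(store, id)
    if (identical(node$labels[[1]], "SideEffect") && is.null(node$properties$source)) {
      gs_remove_node(store, id)
      removed <- removed + 1L
    }
  }
  created <- 0L; edges <- 0L
  tab <- prepared_table(ctx$prepared_dir, "sider", "side_effects.tsv",
                        c("drug_name", "se_umls", "se_name"))
  chem_cascade <- list(id_strategy("pubchem"), id_strategy("inchikey"),
                       id_strategy("drugbank_id"), name_strategy())
  for (i in seq_len(nrow(tab))) {
    r <- match_or_create_node(store, "SideEffect", tab$se_umls[[i]],
                              list(name = tab$se_name[[i]], umls = tab$se_umls[[i]]),
                              "SIDER")
    if (r$created) created <- created + 1L
    ch <- unique_match(list(name = tab$drug_name[[i]]), "Chemical", chem_cascade, store)
    if (!is.null(ch)) {
      merge_node_properties(store, ch, list(), "SIDER",
                            source_identifier = tab$drug_name[[i]])
      if (identical(merge_edge(store, ch, r$id, "CAUSES_CHcSE", source = "SIDER"),
                    "created")) edges <- edges + 1L
    }
  }
  report_row(created = created, removed = removed, edges = edges)
}

routine_aeolus <- function(store, ctx) {
  created <- 0L; edges <- 0L
  concepts <- prepared_table(ctx$prepared_dir, "aeolus", "concepts.tsv",
                             c("concept_id", "name", "kind"))
  pairs <- prepared_table(ctx$prepared_dir, "aeolus", "drug_outcome.tsv",
                          c("drug_id", "outcome_id", "frequency", "count"))
  cmap <- stats::setNames(concepts$name, concepts$concept_id)
  meddra_umls <- ctx$xrefs$meddra_umls %||% empty_df(c("meddra", "umls"))
  outcome_cascade <- mapping_cascade("outcome", "SideEffect", list(
    mapping_strategy("xref", key = "meddra_umls", entity_key = "meddra",
                     node_key = "umls"),
    name_strategy()))
  drug_cascade <- list(id_strategy("rxnorm"), id_strategy("unii"),
                       id_strategy("inchikey"), id_strategy("mesh"), name_strategy())
  for (i in seq_len(nrow(pairs))) {
    drug_name <- cmap[[pairs$drug_id[[i]]]] %||% NA_character_
    if (is.na(drug_name)) next
    ch <- unique_match(list(name = drug_name), "Chemical", drug_cascade, store)
    if (is.null(ch)) next
    oid <- pairs$outcome_id[[i]]
    oname <- cmap[[oid]] %||% ""
    props <- list(frequency = pairs$frequency[[i]], count = pairs$count[[i]])
    res <- resolve(list(meddra = oid, name = oname), outcome_cascade, store,
                   xrefs = ctx$xrefs)
    if (identical(res$status, "unique")) {
      merge_node_properties(store, res$matched[[1]], list(), "AEOLUS",
                            source_identifier = oid)
      if (identical(merge_edge(store, ch, res$matched[[1]], "MIGHT_CAUSES_CHmcSE",
                               props, source = "AEOLUS"), "created")) edges <- edges + 1L
      next
    }
    d <- unique_match(list(name = oname), "Disease", list(name_strategy()), store)
    if (!is.null(d)) {
      if (identical(merge_edge(store, ch, d, "MIGHT_INDUCES_CHmiD", props,
                               source = "AEOLUS"), "created")) edges <- edges + 1L
      next
    }
    bridged <- meddra_umls$umls[meddra_umls$meddra == oid]
    ident <- if (length(bridged) > 0) bridged[[1]] else oid
    r <- match_or_create_node(store, "SideEffect", ident,
                              list(name = oname,
                                   umls = if (length(bridged) > 0) bridged[[1]] else NULL),
                              "AEOLUS")
    if (r$created) created <- created + 1L
    if (identical(merge_edge(store, ch, r$id, "MIGHT_CAUSES_CHmcSE", props,
                             source = "AEOLUS"), "created")) edges <- edges + 1L
  }
  report_row(created = created, edges = edges)
}

pgkb_participant_label <- function(node) {
  if ("Chemical" %in% node$labels) return("Chemical")
  if ("Gene" %in% node$labels) return("Gene")
  if (identical(node$labels[[1]], "Haplotype")) return("Haplotype")
  if ("Variant" %in% node$labels) return("Variant")
  if ("PharmacologicalClass" %in% node$labels) return("PharmacologicalClass")
  "Phenotype"
}

routine_pharmgkb_entities <- function(store, ctx) {
  created <- 0L; updated <- 0L
  pmap <- list()
  note <- function(src_id, merged_id) pmap[[src_id]] <<- merged_id
  for (id in src_nodes(store, "pharmgkb", "Chemical")) {
    node <- gs_get_node(store, id)
    hit <- unique_match(list(drugbank_id = first_or_empty(prop_values(node, "drugbank_id")),
                             rxnorm = first_or_empty(prop_values(node, "rxnorm")),
                             name = first_or_empty(prop_values(node, "name"))),
                        "Chemical",
                        list(id_strategy("drugbank_id"), id_strategy("rxnorm"),
                             name_strategy()), store)
    if (!is.null(hit)) {
      merge_node_properties(store, hit, list(), "PharmGKB",
                            source_identifier = node_identifier(node))
      updated <- updated + 1L
      note(id, hit)
    }
  }
  for (id in src_nodes(store, "pharmgkb", "Gene")) {
    node <- gs_get_node(store, id)
    hit <- unique_match(list(symbol = first_or_empty(prop_values(node, "symbol")),
                             name = first_or_empty(prop_values(node, "name"))),
                        "Gene", list(id_strategy("symbol"), name_strategy()), store)
    if (!is.null(hit)) {
      merge_node_properties(store, hit, list(), "PharmGKB",
                            source_identifier = node_identifier(node))
      updated <- updated + 1L
      note(id, hit)
    }
  }
  for (id in src_nodes(store, "pharmgkb", "Phenotype")) {
    node <- gs_get_node(store, id)
    ent <- list(umls = first_or_empty(prop_values(node, "umls")),
                name = first_or_empty(prop_values(node, "name")))
    strategies <- list(id_strategy("umls"), name_strategy())
    hit <- NULL
    for (lb in c("Disease", "Symptom", "SideEffect")) {
      hit <- unique_match(ent, lb, strategies, store)
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      r <- match_or_create_node(store, "Phenotype", node_identifier(node),
                                list(name = ent$name), "PharmGKB")
      if (r$created) created <- created + 1L
      hit <- r$id
    } else {
      merge_node_properties(store, hit, list(), "PharmGKB",
                            source_identifier = node_identifier(node))
      updated <- updated + 1L
    }
    note(id, hit)
  }
  for (id in src_nodes(store, "pharmgkb", "Variant")) {
    node <- gs_get_node(store, id)
    rs <- first_or_empty(prop_values(node, "rs_id"))
    hit <- unique_match(list(rs_id = rs,
                             name = first_or_empty(prop_values(node, "name"))),
                        "GeneVariant",
                        list(id_strategy("rs_id"), name_strategy()), store)
    if (is.null(hit)) {
      r <- match_or_create_node(store, "GeneVariant", node_identifier(node),
                                list(name = first_or_empty(prop_values(node, "name")),
                                     rs_id = rs), "PharmGKB")
      if (r$created) created <- created + 1L
      hit <- r$id
    } else {
      merge_node_properties(store, hit, list(), "PharmGKB",
                            source_identifier = node_identifier(node))
      updated <- updated + 1L
    }
    note(id, hit)
  }
  ctx$mappings$pharmgkb <- pmap
  report_row(created = created, updated = updated)
}

routine_dbsnp <- function(store, ctx) {
  current <- prepared_table(ctx$prepared_dir, "dbsnp", "rs_current.tsv", "rs_id")
  info <- prepared_table(ctx$prepared_dir, "dbsnp", "rs_info.tsv", c("rs_id", "alleles"))
  rs_gene <- prepared_table(ctx$prepared_dir, "dbsnp", "rs_gene.tsv", c("rs_id", "gene_id"))
  removed <- 0L; updated <- 0L; edges <- 0L
  for (id in gs_nodes_with_label(store, "GeneVariant")) {
    node <- gs_get_node(store, id)
    if (!is.null(node$properties$source)) next
    rs <- first_or_empty(prop_values(node, "rs_id"))
    if (!nzchar(rs)) next
    if (!(rs %in% current$rs_id)) {
      gs_remove_node(store, id)  # stale variant: incident edges cascade away
      removed <- removed + 1L
      next
    }
    alleles <- info$alleles[info$rs_id == rs]
    props <- if (length(alleles) > 0) list(alleles = alleles[[1]]) else list()
    merge_node_properties(store, id, props, "dbSNP", source_identifier = rs)
    updated <- updated + 1L
  }
  for (i in seq_len(nrow(rs_gene))) {
    g <- gs_lookup(store, "Gene", "identifier", rs_gene$gene_id[[i]])
    vs <- gs_lookup(store, "GeneVariant", "rs_id", rs_gene$rs_id[[i]])
    if (length(g) == 0) next
    for (v in vs) {
      if (!is.null(gs_get_node(store, v)$properties$source)) next
      if (identical(merge_edge(store, g[[1]], v, "HAS_GhV", source = "dbSNP"),
                    "created")) edges <- edges + 1L
    }
  }
  report_row(updated = updated, removed = removed, edges = edges)
}

routine_pharmgkb_edges <- function(store, ctx) {
  pmap <- ctx$mappings$pharmgkb %||% list()
  created <- 0L; edges <- 0L
  ann_nodes <- list()
  annotation_kept <- function(node, kind) {
    df <- data.frame(
      evidence_level = if (identical(kind, "ClinicalAnnotation")) {
        first_or_empty(prop_values(node, "evidence_level"))
      } else "",
      significance = first_or_empty(prop_values(node, "significance")),
      stringsAsFactors = FALSE)
    nrow(filter_annotation_evidence(df)) == 1
  }
  for (kind in c("ClinicalAnnotation", "VariantAnnotation")) {
    for (id in src_nodes(store, "pharmgkb", kind)) {
      node <- gs_get_node(store, id)
      if (!annotation_kept(node, kind)) next
      participants <- list()
      for (eid in gs_incident_edges(store, id)) {
        e <- gs_get_edge(store, eid)
        if (!identical(e$type, source_label("pharmgkb", "associated_with")) ||
            !identical(e$source, id)) next
        target <- pmap[[e$target]]
        if (is.null(target) || is.null(gs_get_node(store, target))) next
        participants <- c(participants, list(list(
          node = target, relation = "ASSOCIATES",
          label = pgkb_participant_label(gs_get_node(store, target)),
          direction = "out")))
      }
      if (length(participants) < 2) next
      props <- list()
      lvl <- first_or_empty(prop_values(node, "evidence_level"))
      if (nzchar(lvl)) props$evidence_level <- lvl
      sig <- first_or_empty(prop_values(node, "significance"))
      if (nzchar(sig)) props$significance <- sig
      r <- merge_edge_node(store, kind, node_identifier(node), participants,
                           props, "PharmGKB", ctx$registry)
      ann_nodes[[id]] <- r$id
      if (r$created) {
        created <- created + 1L
        edges <- edges + length(participants)
      }
    }
  }
  for (eid in src_edges(store, "pharmgkb", "has_evidence")) {
    e <- gs_get_edge(store, eid)
    a <- ann_nodes[[e$source]]; b <- ann_nodes[[e$target]]
    if (is.null(a) || is.null(b)) next
    if (identical(merge_edge(store, a, b, "HAS_EVIDENCE_CAheVA", source = "PharmGKB"),
                  "created")) edges <- edges + 1L
  }
  for (eid in src_edges(store, "pharmgkb", "has_variant")) {
    e <- gs_get_edge(store, eid)
    g <- pmap[[e$source]]; v <- pmap[[e$target]]
    if (is.null(g) || is.null(v)) next
    if (identical(merge_edge(store, g, v, "HAS_GhV", source = "PharmGKB"),
                  "created")) edges <- edges + 1L
  }
  report_row(created = created, edges = edges)
}

routine_equal_allele <- function(store, ctx) {
  eq <- generate_equal_edges(store)
  al <- generate_allele_edges(store)
  report_row(edges = eq + al)
}

merge_routines <- function() {
  list(
    hetionet_renames = routine_hetionet_renames,
    mondo = routine_mondo,
    do = routine_do,
    entrez = routine_entrez,
    omim = routine_omim,
    pathways = routine_pathways,
    uniprot = routine_uniprot,
    go = routine_go,
    iid = routine_iid,
    reactome = routine_reactome,
    clinvar = routine_clinvar,
    drugbank = routine_drugbank,
    hpo = routine_hpo,
    ctd = routine_ctd,
    ndfrt = routine_ndfrt,
    reactome_chemicals = routine_reactome_chemicals,
    clinvar_chemicals = routine_clinvar_chemicals,
    drugbank_remainder = routine_drugbank_remainder,
    sider = routine_sider,
    aeolus = routine_aeolus,
    pharmgkb_entities = routine_pharmgkb_entities,
    dbsnp = routine_dbsnp,
    pharmgkb_edges = routine_pharmgkb_edges,
    equal_allele = routine_equal_allele
  )
}

#' The default merge plan (source order of the construction method)
#'
#' Disease ontologies first, then genes, annotations, proteins, pathways,
#' variants, drugs, phenotype vocabularies, drug classes, deferred
#' chemical link steps, adverse events, pharmacogenomics, variant pruning,
#' and finally cross-label equivalence and allele edges.
#'
#' @return character vector of routine names, in execution order
#' @export
default_merge_plan <- function() {
  names(merge_routines())
}

#' Execute a merge plan
#'
#' Runs the named routines in order, applying the label-hierarchy closure
#' after each, and collects a per-source report of created/updated/removed
#' node and edge counts. A routine failure aborts with the plan position.
#'
#' @param store a `graph_store` holding the seed graph plus integrated
#'   source subgraphs
#' @param prepared_dir prepared-source directory ([forge_prepare()] output)
#' @param plan character vector of routine names (default: full plan)
#' @param xrefs named list of cross-reference tables ([load_xref_tables()])
#' @return data.frame report (one row per executed routine)
#' @export
run_merge <- function(store, prepared_dir, plan = default_merge_plan(),
                      xrefs = list()) {
  routines <- merge_routines()
  ctx <- merge_context(prepared_dir, xrefs)
  rows <- list()
  for (pos in seq_along(plan)) {
    nm <- plan[[pos]]
    fn <- routines[[nm]]
    if (is.null(fn)) stop("unknown merge routine at plan position ", pos, ": ", nm)
    rep <- tryCatch(fn(store, ctx), error = function(e) {
      stop("merge routine '", nm, "' (plan position ", pos, ") failed: ",
           conditionMessage(e))
    })
    apply_label_hierarchy(store)
    rows[[length(rows) + 1L]] <- data.frame(
      source = nm, created = rep$created, updated = rep$updated,
      removed = rep$removed, edges = rep$edges, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
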