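# Merge-engine primitives: edge-type renames, node replacement preserving
# edges, edge match-or-create, edge nodes, label hierarchy closure, and
# the EQUAL / allele edge generators. Conventions: merged nodes carry a
# "resource" list naming contributing sources and, for each source s, a
# tag property named "<s>_id" (lowercased source name); property conflicts
# on update keep the existing value and store the incoming one under
# "<name>_<source>".

#' Default label hierarchy (subsumption plus grouping labels)
#'
#' Salt is a Compound is a Chemical; Phenotype groups Disease, Symptom and
#' SideEffect; Variant groups GeneVariant, Haplotype and Genotype;
#' ReactionLikeEvent groups the five reaction-event labels.
#'
#' @return named list label -> character vector of labels it implies
#' @export
default_label_hierarchy <- function() {
  list(
    Salt = "Compound", Compound = "Chemical",
    Disease = "Phenotype", Symptom = "Phenotype", SideEffect = "Phenotype",
    GeneVariant = "Variant", Haplotype = "Variant", Genotype = "Variant",
    Reaction = "ReactionLikeEvent", FailedReaction = "ReactionLikeEvent",
    BlackBoxEvent = "ReactionLikeEvent", Polymerisation = "ReactionLikeEvent",
    Depolymerisation = "ReactionLikeEvent"
  )
}

hierarchy_closure <- function(labels, hierarchy) {
  out <- labels
  repeat {
    added <- unlist(hierarchy[intersect(out, names(hierarchy))], use.names = FALSE)
    new <- setdiff(added, out)
    if (length(new) == 0) break
    out <- c(out, new)
  }
  out
}

#' Apply the label hierarchy to every node (idempotent closure)
#'
#' Every node with a subsumed label receives all ancestor and grouping
#' labels; the primary (first) label is never changed.
#'
#' @param store a `graph_store`
#' @param hierarchy label hierarchy (see [default_label_hierarchy()])
#' @return count of labels added
#' @export
apply_label_hierarchy <- function(store, hierarchy = default_label_hierarchy()) {
  added <- 0L
  for (id in gs_node_ids(store)) {
    node <- store$nodes[[id]]
    closed <- hierarchy_closure(node$labels, hierarchy)
    if (length(closed) > length(node$labels)) {
      added <- added + length(closed) - length(node$labels)
      gs_set_node(store, id, labels = closed)
    }
  }
  added
}

#' Rename edge types in bulk
#'
#' Every edge of an old type receives the new type; no other edge is
#' touched. Per-type edge counts are conserved under the mapping.
#'
#' @param store a `graph_store`
#' @param rename_map named character vector old type -> new type
#' @return count of edges renamed
#' @export
apply_renames <- function(store, rename_map) {
  n <- 0L
  for (id in gs_edge_ids(store)) {
    e <- store$edges[[id]]
    new <- if (e$type %in% names(rename_map)) rename_map[[e$type]] else NULL
    if (!is.null(new) && !is.na(new)) {
      gs_set_edge(store, id, type = new)
      n <- n + 1L
    }
  }
  n
}

#' The hetnet seed edge-type rename list
#'
#' Exposes the Chemical label in edge types that predate the
#' Chemical > Compound > Salt hierarchy.
#'
#' @return named character vector old -> new
#' @export
default_rename_map <- function() {
  c(CAUSES_CcSE = "CAUSES_CHcSE",
    PALLIATES_CpD = "PALLIATES_CHpD",
    TREATS_CtD = "TREATS_CHtD",
    BINDS_CbG = "BINDS_CHbG",
    DOWNREGULATES_CdG = "DOWNREGULATES_CHdG")
}

# --- merged-node property bookkeeping -----------------------------------

tag_property <- function(source) paste0(tolower(gsub("[^A-Za-z0-9]", "", source)), "_id")

#' Update a merged node's properties from a source record
#'
#' Adds `source` to the node's resource list, guarantees the source tag
#' property (`<source>_id`, set to `source_identifier` when given), fills
#' missing properties, unions list properties, and stores conflicting
#' scalar values under `<name>_<source>` (the existing value wins).
#'
#' @param store a `graph_store`
#' @param node_id node surrogate id
#' @param props named list of incoming properties
#' @param source contributing source name
#' @param source_identifier the entity's identifier in the source
#' @param list_properties names treated as list-valued
#' @export
merge_node_properties <- function(store, node_id, props, source,
                                  source_identifier = NULL,
                                  list_properties = c("synonyms", "xrefs", "pubmed_ids")) {
  node <- gs_get_node(store, node_id)
  p <- node$properties
  p$resource <- unique(c(prop_values(node, "resource"), source))
  tag <- tag_property(source)
  if (!is.null(source_identifier) && nzchar(source_identifier)) {
    p[[tag]] <- unique(c(as.character(p[[tag]] %||% character(0)), source_identifier))
  } else if (is.null(p[[tag]])) {
    p[[tag]] <- "true"
  }
  for (nm in setdiff(names(props), c("resource", "source"))) {
    val <- props[[nm]]
    if (is.null(val) || length(val) == 0 ||
        (length(val) == 1 && (is.na(val) || !nzchar(as.character(val))))) next
    cur <- p[[nm]]
    if (is.null(cur)) {
      p[[nm]] <- val
    } else if (nm %in% list_properties || length(cur) > 1 || length(val) > 1) {
      p[[nm]] <- unique(c(as.character(cur), as.character(val)))
    } else if (!identical(as.character(cur), as.character(val))) {
      p[[paste0(nm, "_", tolower(source))]] <- val
    }
  }
  gs_set_node(store, node_id, properties = p)
}

#' Create a merged-schema node from a source record
#'
#' @param store a `graph_store`
#' @param labels label vector (primary first)
#' @param identifier primary identifier
#' @param props named list of properties
#' @param source contributing source name
#' @return new node id
#' @export
create_merged_node <- function(store, labels, identifier, props = list(), source) {
  props[["identifier"]] <- identifier
  props[["resource"]] <- unique(c(as.character(props[["resource"]] %||% character(0)), source))
  tag <- tag_property(source)
  if (is.null(props[[tag]])) props[[tag]] <- identifier
  props <- props[!vapply(props, function(v) {
    length(v) == 0 || (length(v) == 1 && (is.na(v) || !nzchar(as.character(v))))
  }, logical(1))]
  gs_add_node(store, labels, props)
}

#' Replace, remove, or create nodes of one label from a replacement table
#'
#' Matched nodes keep their surrogate id (all incident edges survive);
#' their identifier becomes the replacement row's identifier and their
#' properties are updated from the row. Existing nodes with no matching
#' row are removed together with their incident edges. Replacement rows
#' matching no existing node become new nodes.
#'
#' @param store a `graph_store`
#' @param label node label to replace
#' @param replacement data.frame with an `identifier` column
#' @param match_key column in `replacement` whose value identifies the
#'   existing node (compared against `node_property`)
#' @param node_property property on existing nodes compared to `match_key`
#'   values (default `"identifier"`)
#' @param source contributing source name
#' @param list_columns list-valued columns of `replacement`
#' @param extra_labels labels added to newly created nodes (after `label`)
#' @return list with `replaced`, `removed`, `created` counts
#' @export
replace_or_remove_nodes <- function(store, label, replacement, match_key,
                                    node_property = "identifier", source,
                                    list_columns = c("synonyms", "xrefs"),
                                    extra_labels = character(0)) {
  if (anyDuplicated(replacement[[match_key]][nzchar(replacement[[match_key]])])) {
    stop("duplicate match keys in replacement table")
  }
  # only nodes whose PRIMARY label matches are replaced/removed; nodes that
  # merely carry the label through the hierarchy (e.g. Salt under Compound)
  # belong to other sources and are left alone
  existing <- gs_nodes_with_label(store, label)
  existing <- existing[vapply(existing, function(i) {
    identical(store$nodes[[i]]$labels[[1]], label)
  }, logical(1))]
  matched_nodes <- character(0)
  replaced <- 0L; created <- 0L
  for (i in seq_len(nrow(replacement))) {
    row <- as.list(replacement[i, , drop = FALSE])
    row <- lapply(row, as.character)
    props <- list()
    for (nm in names(row)) {
      if (is.na(row[[nm]]) || !nzchar(row[[nm]])) next
      props[[nm]] <- if (nm %in% list_columns) split_list_cell(row[[nm]]) else row[[nm]]
    }
    # a node already replaced in an earlier run carries the replacement
    # identifier, so try that before the match key (keeps re-runs stable)
    hit <- intersect(gs_lookup(store, label, "identifier", props[["identifier"]]),
                     existing)
    key <- row[[match_key]]
    if (length(hit) == 0 && !is.na(key) && nzchar(key)) {
      hit <- intersect(gs_lookup(store, label, node_property, key), existing)
    }
    if (length(hit) > 0) {
      nid <- hit[[1]]
      matched_nodes <- c(matched_nodes, nid)
      node <- gs_get_node(store, nid)
      p <- node$properties
      p[["identifier"]] <- props[["identifier"]]
      gs_set_node(store, nid, properties = p)
      merge_node_properties(store, nid, props, source,
                            source_identifier = props[["identifier"]])
      replaced <- replaced + 1L
    } else {
      create_merged_node(store, c(label, extra_labels), props[["identifier"]],
                         props, source)
      created <- created + 1L
    }
  }
  to_remove <- setdiff(existing, matched_nodes)
  for (nid in to_remove) gs_remove_node(store, nid)
  list(replaced = replaced, removed = length(to_remove), created = created)
}

#' Match-or-create a merged edge
#'
#' If an edge of the same type between the same endpoints (and with equal
#' values on `match_on` properties) exists, its properties are unioned,
#' its resource list extended, and `"updated"` is returned; otherwise the
#' edge is created.
#'
#' @param store a `graph_store`
#' @param src,dst node surrogate ids
#' @param type edge type string
#' @param properties named list of edge properties
#' @param match_on property names that must also agree for a match
#' @param source contributing source name (extends the edge resource list)
#' @return `"created"` or `"updated"`
#' @export
merge_edge <- function(store, src, dst, type, properties = list(),
                       match_on = character(0), source = NULL) {
  for (eid in gs_incident_edges(store, src)) {
    e <- store$edges[[eid]]
    if (!identical(e$type, type) || !identical(e$source, src) ||
        !identical(e$target, dst)) next
    match_ok <- all(vapply(match_on, function(nm) {
      identical(as.character(e$properties[[nm]] %||% ""),
                as.character(properties[[nm]] %||% ""))
    }, logical(1)))
    if (!match_ok) next
    p <- e$properties
    if (!is.null(source)) {
      p$resource <- unique(c(as.character(p$resource %||% character(0)), source))
      tag <- tag_property(source)
      if (is.null(p[[tag]])) p[[tag]] <- "true"
    }
    for (nm in names(properties)) {
      if (length(properties[[nm]]) == 0) next
      cur <- p[[nm]]
      if (is.null(cur)) p[[nm]] <- properties[[nm]]
      else if (length(cur) > 1 || length(properties[[nm]]) > 1 ||
               nm %in% c("pubmed_ids", "resource")) {
        p[[nm]] <- unique(c(as.character(cur), as.character(properties[[nm]])))
      } else if (!identical(as.character(cur), as.character(properties[[nm]])) &&
                 !is.null(source)) {
        p[[paste0(nm, "_", tolower(source))]] <- properties[[nm]]
      }
    }
    gs_set_edge(store, eid, properties = p)
    return("updated")
  }
  props <- Filter(length, properties)
  if (!is.null(source)) {
    props$resource <- unique(c(as.character(props$resource %||% character(0)), source))
    tag <- tag_property(source)
    if (is.null(props[[tag]])) props[[tag]] <- "true"
  }
  gs_add_edge(store, type, src, dst, props)
  "created"
}

#' Create an edge node connecting two or more participants
#'
#' Reifies a many-ary connection (Interaction, Treatment,
#' ClinicalAnnotation, VariantAnnotation) as a node plus one typed edge
#' per participant. Each participant names its relation, the label whose
#' abbreviation appears in the edge type, and the edge direction relative
#' to the edge node (`"out"`: edge node -> participant; `"in"`:
#' participant -> edge node).
#'
#' @param store a `graph_store`
#' @param label edge-node label
#' @param identifier edge-node identifier
#' @param participants list of lists with `node` (id), `relation`,
#'   `label`, `direction`
#' @param properties edge-node properties
#' @param source contributing source name
#' @param registry abbreviation registry
#' @return the edge node's surrogate id
#' @export
create_edge_node <- function(store, label, identifier, participants,
                             properties = list(), source,
                             registry = abbreviation_registry()) {
  if (length(participants) < 2) stop("an edge node needs at least 2 participants")
  nid <- create_merged_node(store, label, identifier, properties, source)
  edge_node_participant_edges(store, nid, label, participants, source, registry)
  nid
}

edge_node_participant_edges <- function(store, nid, label, participants, source,
                                        registry) {
  for (p in participants) {
    if (identical(p$direction %||% "out", "out")) {
      type <- generate_edge_type(p$relation, label, p$label, registry)
      merge_edge(store, nid, p$node, type, source = source)
    } else {
      type <- generate_edge_type(p$relation, p$label, label, registry)
      merge_edge(store, p$node, nid, type, source = source)
    }
  }
  invisible(NULL)
}

#' Match-or-create an edge node with its participant edges
#'
#' Like [create_edge_node()], but if a node of the label and identifier
#' already exists its properties are merged and any missing participant
#' edges are re-established (so repeated merges repair edges whose
#' endpoints were refreshed by other sources).
#'
#' @inheritParams create_edge_node
#' @return list with `id` (node id) and `created` flag
#' @export
merge_edge_node <- function(store, label, identifier, participants,
                            properties = list(), source,
                            registry = abbreviation_registry()) {
  if (length(participants) < 2) stop("an edge node needs at least 2 participants")
  hit <- gs_lookup(store, label, "identifier", identifier)
  if (length(hit) > 0) {
    merge_node_properties(store, hit[[1]], properties, source,
                          source_identifier = identifier)
    edge_node_participant_edges(store, hit[[1]], label, participants, source, registry)
    return(list(id = hit[[1]], created = FALSE))
  }
  list(id = create_edge_node(store, label, identifier, participants, properties,
                             source, registry),
       created = TRUE)
}

# --- cross-label equivalence and allele edges ---------------------------

edge_exists <- function(store, src, dst, type) {
  for (eid in gs_incident_edges(store, src)) {
    e <- store$edges[[eid]]
    if (identical(e$type, type) && identical(e$source, src) &&
        identical(e$target, dst)) return(TRUE)
  }
  FALSE
}

equal_edge_types <- function() {
  # label pairs the schema links; the first label of each pair is the edge
  # source (the type fixes the direction, e.g. EQUAL_DeSE runs D -> SE)
  list(
    c("Disease", "SideEffect"), c("Disease", "Symptom"),
    c("Phenotype", "SideEffect"), c("Symptom", "SideEffect")
  )
}

#' Generate EQUAL edges between phenotype-class nodes of equal meaning
#'
#' For each cross-label pair among Disease, Symptom, SideEffect and pure
#' Phenotype nodes sharing a UMLS identifier or a normalized name, one
#' EQUAL edge of the matching type (EQUAL_DeSE, EQUAL_DeS, EQUAL_PTeSE,
#' EQUAL_SeSE) is created, deduplicated; the edge direction follows the
#' type (the node carrying the type's source label is the source). Labels
#' are read as primary labels so the Phenotype grouping label does not
#' duplicate pairs.
#'
#' @param store a `graph_store`
#' @param umls_property node property holding the UMLS id (default "umls")
#' @param registry abbreviation registry
#' @return count of EQUAL edges created
#' @export
generate_equal_edges <- function(store, umls_property = "umls",
                                 registry = abbreviation_registry()) {
  classes <- c("Disease", "Symptom", "SideEffect", "Phenotype")
  members <- list()
  for (id in gs_node_ids(store)) {
    node <- store$nodes[[id]]
    primary <- node$labels[[1]]
    if (!primary %in% classes) next
    keys <- c(prop_values(node, umls_property),
              normalize_name(prop_values(node, "name")))
    keys <- unique(keys[nzchar(keys)])
    members[[id]] <- list(label = primary, keys = keys,
                          ident = node_identifier(node))
  }
  pair_types <- equal_edge_types()
  created <- 0L
  ids <- names(members)
  if (length(ids) < 2) return(created)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      a <- members[[ids[[i]]]]; b <- members[[ids[[j]]]]
      if (identical(a$label, b$label)) next
      hit <- NULL
      for (pt in pair_types) if (setequal(pt, c(a$label, b$label))) { hit <- pt; break }
      if (is.null(hit)) next
      if (length(intersect(a$keys, b$keys)) == 0) next
      ordered <- if (identical(a$label, hit[[1]])) c(ids[[i]], ids[[j]]) else c(ids[[j]], ids[[i]])
      key <- paste(ordered, collapse = "\x1f")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      type <- generate_edge_type("EQUAL", hit[[1]], hit[[2]], registry)
      if (edge_exists(store, ordered[[1]], ordered[[2]], type)) next
      gs_add_edge(store, type, ordered[[1]], ordered[[2]], list(origin = "derived"))
      created <- created + 1L
    }
  }
  created
}

#' Generate allele edges between variants sharing an rs-identifier
#'
#' Variant-labelled nodes sharing a dbSNP rs-identifier are pairwise
#' linked by IS_ALLEL_OF_ViaoV edges (no duplicates, no self-loops,
#' lexicographically smaller identifier as source).
#'
#' @param store a `graph_store`
#' @param rs_property property holding the rs-identifier (default "rs_id")
#' @return count of edges created
#' @export
generate_allele_edges <- function(store, rs_property = "rs_id") {
  groups <- list()
  for (id in gs_nodes_with_label(store, "Variant")) {
    for (rs in prop_values(store$nodes[[id]], rs_property)) {
      if (nzchar(rs)) groups[[rs]] <- unique(c(groups[[rs]], id))
    }
  }
  created <- 0L
  seen <- new.env(parent = emptyenv())
  for (rs in lex_sort(names(groups))) {
    g <- groups[[rs]]
    if (length(g) < 2) next
    idents <- vapply(g, function(i) node_identifier(store$nodes[[i]]), "")
    g <- g[order(idents, method = "radix")]
    for (i in seq_len(length(g) - 1L)) {
      for (j in (i + 1L):length(g)) {
        key <- paste(g[[i]], g[[j]], sep = "\x1f")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        if (edge_exists(store, g[[i]], g[[j]], "IS_ALLEL_OF_ViaoV")) next
        gs_add_edge(store, "IS_ALLEL_OF_ViaoV", g[[i]], g[[j]],
                    list(origin = "derived", rs_id = rs))
        created <- created + 1L
      }
    }
  }
  created
}
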