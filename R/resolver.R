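# Entity resolution: ordered cascades of identifier, cross-reference,
# name, and structure strategies mapping incoming source entities onto
# existing graph nodes. The first strategy producing at least one
# candidate wins; ambiguous results are reported, never auto-merged.

#' Normalize a name for matching
#'
#' Lowercases, trims, collapses internal whitespace and strips a fixed
#' punctuation set. Deterministic and idempotent; spelling variation across
#' databases makes raw name equality unreliable, so all name strategies
#' compare normalized forms.
#'
#' @param raw character vector
#' @return canonical character vector
#' @export
normalize_name <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("[.,;:–—'’]", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Define a mapping strategy
#'
#' @param kind one of `"identifier"`, `"xref"`, `"name"`, `"structure"`
#' @param key property/namespace used: for `identifier`, the shared entity
#'   field and node property name (e.g. `"cas"`, `"inchikey"`); for
#'   `xref`, the name of the cross-reference table; for `name`, ignored;
#'   for `structure`, the entity field holding the structure block
#' @param normalize normalize values before comparison (names always are)
#' @param threshold structure-similarity threshold (structure kind only)
#' @param entity_key for `xref`: entity field holding the bridged id
#' @param node_key for `xref`: node property holding the target namespace id
#' @return a `mapping_strategy` object
#' @export
mapping_strategy <- function(kind = c("identifier", "xref", "name", "structure"),
                             key = NULL, normalize = FALSE, threshold = 0.75,
                             entity_key = NULL, node_key = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, key = key, normalize = normalize,
                 threshold = threshold, entity_key = entity_key,
                 node_key = node_key), class = "mapping_strategy")
}

#' Define a mapping cascade for one entity class / target label pair
#'
#' @param source_class name of the incoming entity class (informative)
#' @param target_label graph label the cascade resolves against
#' @param strategies non-empty ordered list of [mapping_strategy()]s;
#'   duplicate (kind, key) pairs are rejected
#' @return a `mapping_cascade` object
#' @export
mapping_cascade <- function(source_class, target_label, strategies) {
  if (length(strategies) == 0) stop("cascade needs at least one strategy")
  sig <- vapply(strategies, function(s) paste(s$kind, s$key %||% ""), "")
  if (anyDuplicated(sig)) stop("duplicate (kind, key) strategy in cascade")
  structure(list(source_class = source_class, target_label = target_label,
                 strategies = strategies), class = "mapping_cascade")
}

#' Build an index value -> node ids for (label, key property)
#'
#' Complete and exact: every node under `label` carrying the key property
#' appears; lookups agree with a linear scan. Multi-valued properties index
#' each element.
#'
#' @param store a `graph_store`
#' @param label node label
#' @param key_property property name
#' @return named list value -> character vector of node ids
#' @export
build_identifier_index <- function(store, label, key_property) {
  gs_property_index(store, label, key_property)
}

#' Bridge an identifier through a cross-reference table into an index
#'
#' Candidates are the index hits of every identifier the table bridges
#' `entity_id` to, deduplicated. Cross-reference tables are plain
#' two-column data.frames and stand in for licensed mapping systems.
#'
#' @param entity_id identifier in the table's first namespace
#' @param table data.frame whose first column is the entity namespace and
#'   second column the index namespace
#' @param index value -> node ids map (from [build_identifier_index()])
#' @return character vector of candidate node ids
#' @export
resolve_via_xref <- function(entity_id, table, index) {
  bridged <- table[[2]][table[[1]] == entity_id]
  out <- character(0)
  for (b in unique(bridged)) out <- c(out, index[[b]] %||% character(0))
  lex_sort(unique(out))
}

entity_values <- function(entity, key) {
  v <- entity[[key]]
  if (is.null(v)) return(character(0))
  v <- as.character(unlist(v, use.names = FALSE))
  v[!is.na(v) & nzchar(v)]
}

#' Resolve one entity against the graph through a mapping cascade
#'
#' Strategies are tried in order; the first one producing at least one
#' candidate wins and later strategies are not consulted. Name strategies
#' compare the normalized entity name against normalized node names and
#' synonyms; structure strategies delegate to the chemical-similarity
#' module at the strategy's threshold. An entity lacking every keyed
#' property is simply unmatched (not an error).
#'
#' @param entity named list (or single data.frame row as list) of fields
#' @param cascade a [mapping_cascade()]
#' @param store a `graph_store`
#' @param xrefs named list of cross-reference tables (for `xref` strategies)
#' @param fingerprints named list of [fingerprint()]s by node id (for
#'   `structure` strategies)
#' @return a `mapping_result`: list with `source_id`, `matched` (node ids),
#'   `strategy` (winning strategy label or NA), `status` (`"unique"`,
#'   `"ambiguous"` or `"unmatched"`), `via_synonym` flag
#' @export
resolve <- function(entity, cascade, store, xrefs = list(), fingerprints = list()) {
  label <- cascade$target_label
  via_synonym <- FALSE
  for (strat in cascade$strategies) {
    cand <- character(0)
    if (strat$kind == "identifier") {
      for (v in entity_values(entity, strat$key)) {
        v2 <- if (isTRUE(strat$normalize)) normalize_name(v) else v
        cand <- c(cand, gs_lookup(store, label, strat$key, v2))
      }
    } else if (strat$kind == "xref") {
      table <- xrefs[[strat$key]]
      if (!is.null(table)) {
        idx <- build_identifier_index(store, label, strat$node_key %||% names(table)[[2]])
        for (v in entity_values(entity, strat$entity_key %||% names(table)[[1]])) {
          cand <- c(cand, resolve_via_xref(v, table, idx))
        }
      }
    } else if (strat$kind == "name") {
      targets <- normalize_name(c(entity_values(entity, "name"),
                                  entity_values(entity, "synonyms")))
      targets <- unique(targets[nzchar(targets)])
      if (length(targets) > 0) {
        name_idx <- normalized_name_index(store, label)
        direct <- unlist(name_idx$names[targets], use.names = FALSE)
        synonym_hits <- unlist(name_idx$synonyms[targets], use.names = FALSE)
        cand <- c(cand, direct, synonym_hits)
        if (length(direct %||% character(0)) == 0 &&
            length(synonym_hits %||% character(0)) > 0) via_synonym <- TRUE
      }
    } else if (strat$kind == "structure") {
      sv <- entity_values(entity, strat$key %||% "structure")
      if (length(sv) > 0) {
        fp <- tryCatch(fingerprint(sv[[1]]), error = function(e) NULL)
        if (!is.null(fp)) {
          for (nid in names(fingerprints)) {
            node <- gs_get_node(store, nid)
            if (is.null(node) || !(label %in% node$labels)) next
            if (tanimoto(fp, fingerprints[[nid]]) >= strat$threshold) cand <- c(cand, nid)
          }
        }
      }
    }
    cand <- lex_sort(unique(cand))
    if (length(cand) > 0) {
      return(structure(list(
        source_id = as.character(entity[["identifier"]] %||% NA_character_),
        matched = cand,
        strategy = paste(strat$kind, strat$key %||% "", sep = ":"),
        status = if (length(cand) == 1) "unique" else "ambiguous",
        via_synonym = via_synonym
      ), class = "mapping_result"))
    }
  }
  structure(list(source_id = as.character(entity[["identifier"]] %||% NA_character_),
                 matched = character(0), strategy = NA_character_,
                 status = "unmatched", via_synonym = FALSE),
            class = "mapping_result")
}

# normalized name and synonym indices for a label (lazy, version-guarded)
normalized_name_index <- function(store, label) {
  key <- paste0("nameidx\x1f", label)
  cached <- store$index_cache[[key]]
  if (!is.null(cached) && identical(cached$version, store$version)) return(cached$map)
  names_map <- list(); syn_map <- list()
  for (id in gs_nodes_with_label(store, label)) {
    node <- store$nodes[[id]]
    for (v in unique(normalize_name(prop_values(node, "name")))) {
      if (nzchar(v)) names_map[[v]] <- c(names_map[[v]], id)
    }
    for (v in unique(normalize_name(prop_values(node, "synonyms")))) {
      if (nzchar(v)) syn_map[[v]] <- c(syn_map[[v]], id)
    }
  }
  map <- list(names = names_map, synonyms = syn_map)
  store$index_cache[[key]] <- list(version = store$version, map = map)
  map
}

#' Summarize a list of mapping results
#'
#' Per-strategy counts of unique/ambiguous/unmatched outcomes plus a
#' review list of unique matches whose normalized names differ between the
#' entity and the matched node (supporting the semi-manual mapping check),
#' and matches made via synonym only.
#'
#' @param results list of `mapping_result`s
#' @param entities optional list of the entities, parallel to `results`
#' @param store optional store (for the name-difference review list)
#' @return list with `counts` (data.frame strategy x status) and `review`
#'   (data.frame of suspicious unique matches)
#' @export
mapping_report <- function(results, entities = NULL, store = NULL) {
  strat <- vapply(results, function(r) r$strategy %||% NA_character_, "")
  strat[is.na(strat)] <- "(none)"
  status <- vapply(results, function(r) r$status, "")
  tab <- table(strategy = strat, status = factor(status, levels = c("unique", "ambiguous", "unmatched")))
  counts <- as.data.frame.matrix(tab)
  counts <- cbind(strategy = rownames(counts), counts)
  rownames(counts) <- NULL
  review <- empty_df(c("source_id", "node_id", "entity_name", "node_name", "flag"))
  if (!is.null(entities) && !is.null(store)) {
    r_i <- 0L
    for (i in seq_along(results)) {
      res <- results[[i]]
      if (!identical(res$status, "unique")) next
      ent_name <- as.character(entities[[i]][["name"]] %||% "")
      node <- gs_get_node(store, res$matched[[1]])
      node_name <- as.character(node$properties[["name"]] %||% "")
      differs <- nzchar(ent_name) && nzchar(node_name) &&
        !identical(normalize_name(ent_name), normalize_name(node_name))
      if (differs || isTRUE(res$via_synonym)) {
        r_i <- r_i + 1L
        review[r_i, ] <- c(res$source_id, res$matched[[1]], ent_name, node_name,
                           if (differs) "name_mismatch" else "via_synonym")
      }
    }
  }
  list(counts = counts, review = review)
}
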