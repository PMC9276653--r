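# Per-source quality filters. Every filter is a pure, idempotent,
# order-preserving function of its table; removed rows are recorded in the
# "filter_log" attribute so run reports can telescope counts.

filter_result <- function(df, rule, kept_idx, reasons = NULL) {
  out <- df[kept_idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- list(rule = rule, input = nrow(df),
                                  kept = nrow(out), removed = nrow(df) - nrow(out),
                                  reasons = reasons %||% character(0))
  out
}

#' Keep only rows of one NCBI taxon
#'
#' Retains rows whose taxon column equals `taxon_id` (default 9606, human);
#' rows with a non-integer taxon cell are rejected and logged. Order is
#' preserved.
#'
#' @param rows data.frame
#' @param taxon_column column holding NCBI taxonomy ids
#' @param taxon_id taxon to keep (integer; default 9606)
#' @return filtered data.frame with a `filter_log` attribute
#' @export
filter_by_taxon <- function(rows, taxon_column = "taxon", taxon_id = 9606L) {
  if (!taxon_column %in% names(rows)) stop("missing taxon column '", taxon_column, "'")
  vals <- rows[[taxon_column]]
  parsed <- suppressWarnings(as.integer(vals))
  bad <- is.na(parsed) & !is.na(vals)
  keep <- !bad & !is.na(parsed) & parsed == as.integer(taxon_id)
  reasons <- if (any(bad)) paste0("non-integer taxon in row ", which(bad)) else character(0)
  filter_result(rows, "taxon", which(keep), reasons)
}

#' Drop rows with empty direct-evidence cells
#'
#' Rows whose evidence cell is empty or whitespace-only are removed.
#'
#' @param rows data.frame
#' @param evidence_column evidence column name (default `"DirectEvidence"`)
#' @return filtered data.frame
#' @export
filter_direct_evidence <- function(rows, evidence_column = "DirectEvidence") {
  if (!evidence_column %in% names(rows)) stop("missing evidence column '", evidence_column, "'")
  keep <- !is_blank(rows[[evidence_column]])
  filter_result(rows, "direct_evidence", which(keep))
}

#' Drug-outcome signal filter (reporting frequency and count)
#'
#' A drug-outcome pair survives iff its reporting frequency is at least
#' `min_frequency_percent` (in percent) AND its report count is at least
#' `min_count`; bounds are inclusive. Defaults retain pairs reported at
#' >= 0.1% frequency and >= 100 times, dropping pairs likely to be
#' uncorrelated noise. Rows with negative values are rejected and logged.
#'
#' @param pairs data.frame
#' @param frequency_column column with frequency in percent
#' @param count_column column with report counts
#' @param min_frequency_percent minimum frequency in percent (default 0.1)
#' @param min_count minimum report count (default 100)
#' @return filtered data.frame
#' @export
filter_outcome_pairs <- function(pairs, frequency_column = "frequency",
                                 count_column = "count",
                                 min_frequency_percent = 0.1, min_count = 100L) {
  for (col in c(frequency_column, count_column)) {
    if (!col %in% names(pairs)) stop("missing column '", col, "'")
  }
  freq <- suppressWarnings(as.numeric(pairs[[frequency_column]]))
  cnt <- suppressWarnings(as.numeric(pairs[[count_column]]))
  neg <- (!is.na(freq) & freq < 0) | (!is.na(cnt) & cnt < 0)
  keep <- !neg & !is.na(freq) & !is.na(cnt) &
    freq >= min_frequency_percent & cnt >= min_count
  reasons <- if (any(neg)) paste0("negative value in row ", which(neg)) else character(0)
  filter_result(pairs, "outcome_pairs", which(keep), reasons)
}

#' Annotation evidence filter (clinical levels / variant significance)
#'
#' Clinical annotation rows survive iff their evidence level is 1, 2 or 3;
#' variant annotation rows survive iff their significance equals `"yes"`.
#' A row is treated as a clinical annotation when the level column is
#' non-empty, as a variant annotation otherwise. Unparseable levels are
#' rejected and logged.
#'
#' @param rows data.frame
#' @param level_column evidence level column
#' @param significance_column significance column
#' @param levels_retained retained evidence levels (default 1:3)
#' @return filtered data.frame
#' @export
filter_annotation_evidence <- function(rows, level_column = "evidence_level",
                                       significance_column = "significance",
                                       levels_retained = c(1L, 2L, 3L)) {
  for (col in c(level_column, significance_column)) {
    if (!col %in% names(rows)) stop("missing column '", col, "'")
  }
  lvl_raw <- rows[[level_column]]
  has_level <- !is_blank(lvl_raw)
  lvl <- suppressWarnings(as.integer(lvl_raw))
  bad <- has_level & is.na(lvl)
  keep_clinical <- has_level & !bad & lvl %in% as.integer(levels_retained)
  keep_variant <- !has_level & tolower(trimws(rows[[significance_column]])) == "yes"
  reasons <- if (any(bad)) paste0("unparseable evidence level in row ", which(bad)) else character(0)
  filter_result(rows, "annotation_evidence", which(keep_clinical | keep_variant), reasons)
}

#' Keep only edge rows with at least one literature reference
#'
#' @param rows data.frame
#' @param reference_column list-cell column of reference ids (e.g. PubMed)
#' @return filtered data.frame
#' @export
filter_requires_reference <- function(rows, reference_column = "pubmed_ids") {
  if (!reference_column %in% names(rows)) stop("missing column '", reference_column, "'")
  keep <- vapply(rows[[reference_column]],
                 function(x) length(split_list_cell(x)) > 0, logical(1),
                 USE.NAMES = FALSE)
  filter_result(rows, "requires_reference", which(keep))
}

#' Keep rows whose source column is in a whitelist
#'
#' Used e.g. to retain pathways only from license-compatible providers.
#'
#' @param rows data.frame
#' @param source_column column naming the upstream provider
#' @param whitelist allowed provider names
#' @return filtered data.frame
#' @export
filter_source_whitelist <- function(rows, source_column = "source",
                                    whitelist = c("WikiPathways", "Reactome",
                                                  "Panther", "NetPath", "PathBank")) {
  if (!source_column %in% names(rows)) stop("missing column '", source_column, "'")
  keep <- rows[[source_column]] %in% whitelist
  filter_result(rows, "source_whitelist", which(keep))
}

#' Keep rows whose evidence-type cell contains a marker substring
#'
#' Membership rule used for the protein-interaction experimental-evidence
#' filter (evidence type contains `"exp"`).
#'
#' @param rows data.frame
#' @param evidence_column evidence-type column (list cell or free text)
#' @param marker substring that must occur (default `"exp"`)
#' @return filtered data.frame
#' @export
filter_evidence_contains <- function(rows, evidence_column = "evidence_type",
                                     marker = "exp") {
  if (!evidence_column %in% names(rows)) stop("missing column '", evidence_column, "'")
  keep <- grepl(marker, rows[[evidence_column]], fixed = TRUE)
  filter_result(rows, "evidence_contains", which(keep))
}

#' Semi-join filter against a reference identifier list
#'
#' Retains rows whose key occurs in `reference_ids`. Used to reconcile
#' protein identifiers against the current curated protein list and to
#' prune variants whose rs-identifier is no longer current.
#'
#' @param rows data.frame
#' @param key_column column to test
#' @param reference_ids character vector of allowed identifiers
#' @return filtered data.frame
#' @export
filter_semi_join <- function(rows, key_column, reference_ids) {
  if (!key_column %in% names(rows)) stop("missing column '", key_column, "'")
  keep <- rows[[key_column]] %in% reference_ids
  filter_result(rows, "semi_join", which(keep))
}

go_evidence_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "go_evidence_codes.tsv", package = "kgforge")
      cache <<- read_table_file(path)
    }
    cache
  }
})

#' Translate an annotation evidence abbreviation to its long form
#'
#' Uses the bundled GO evidence-code table. Unknown codes pass through
#' unchanged with a warning.
#'
#' @param code character vector of evidence abbreviations
#' @return character vector of descriptive texts
#' @export
translate_evidence_code <- function(code) {
  tab <- go_evidence_table()
  idx <- match(code, tab$code)
  out <- tab$description[idx]
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning("unknown evidence code(s): ", paste(unique(code[unknown]), collapse = ", "))
    out[unknown] <- code[unknown]
  }
  out
}

#' Remove listed-label nodes without any incident edge rows
#'
#' Table-level pruning used during source preparation: node rows (from the
#' tables named in `node_tables`, a named list label -> data.frame with an
#' `identifier` column) are dropped when no edge row references them.
#' Labels in `keep_labels` are never pruned (disjoint chemicals stay, as
#' they remain useful for later mapping).
#'
#' @param node_tables named list (label -> node data.frame)
#' @param edge_tables list of edge data.frames with source_id/target_id
#' @param prune_labels labels to prune
#' @param keep_labels labels never pruned
#' @return named list of pruned node data.frames
#' @export
prune_disconnected <- function(node_tables, edge_tables,
                               prune_labels, keep_labels = character(0)) {
  touched <- unique(unlist(lapply(edge_tables, function(df) {
    c(df$source_id, df$target_id)
  }), use.names = FALSE))
  out <- node_tables
  for (lb in names(node_tables)) {
    if (!(lb %in% prune_labels) || lb %in% keep_labels) next
    df <- node_tables[[lb]]
    keep <- df$identifier %in% touched
    res <- df[keep, , drop = FALSE]
    rownames(res) <- NULL
    out[[lb]] <- res
  }
  out
}

#' Deduplicate rows by key columns, unioning list-valued columns
#'
#' The first occurrence per key is kept; values in `list_columns` are
#' unioned across duplicates (order of first appearance).
#'
#' @param rows data.frame
#' @param key_columns character vector of key column names
#' @param list_columns list-cell columns to union across duplicates
#' @return deduplicated data.frame
#' @export
dedupe_entities <- function(rows, key_columns, list_columns = character(0)) {
  for (col in key_columns) {
    if (!col %in% names(rows)) stop("missing key column '", col, "'")
  }
  if (nrow(rows) == 0) return(rows)
  key <- do.call(paste, c(rows[key_columns], sep = "\x1f"))
  first <- !duplicated(key)
  out <- rows[first, , drop = FALSE]
  rownames(out) <- NULL
  if (length(list_columns) > 0 && any(!first)) {
    out_key <- key[first]
    for (i in which(!first)) {
      j <- match(key[[i]], out_key)
      for (col in list_columns) {
        merged <- unique(c(split_list_cell(out[[col]][[j]]),
                           split_list_cell(rows[[col]][[i]])))
        out[[col]][[j]] <- join_list_cell(merged)
      }
    }
  }
  attr(out, "filter_log") <- list(rule = "dedupe", input = nrow(rows),
                                  kept = nrow(out), removed = nrow(rows) - nrow(out),
                                  reasons = character(0))
  out
}
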