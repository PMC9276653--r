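# Converters for the heterogeneous source formats: OBO flat files, SDF
# V2000 records, FASTA, GMT gene sets, and GAF-style annotation TSVs.
# Each parser emits normalized tables (character data.frames with "|"
# list cells) and never reorders records relative to its input.

#' Parse an OBO flat file into node and edge tables
#'
#' One node row per `[Term]` stanza; one edge table per distinct relation
#' (`is_a` plus each `relationship:` tag). Synonyms and their scope
#' qualifiers are kept as parallel list columns; `xref` and `alt_id`
#' values are both emitted in the `xrefs` list column. Obsolete terms are
#' flagged and emit no edge rows. `[Typedef]` stanzas register relation
#' names but emit no rows.
#'
#' @param path OBO file path (or a character vector of lines via `lines`)
#' @param lines optional character vector of lines (overrides `path`)
#' @return list with `nodes` (data.frame: identifier, name, namespace,
#'   definition, synonyms, synonym_scopes, xrefs, is_obsolete) and `edges`
#'   (named list of data.frames with source_id/target_id per relation)
#' @export
parse_obo <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  # split into stanzas
  stanza_starts <- grep("^\\[", lines)
  relations <- character(0)
  rows <- list()
  edge_rows <- list()  # relation -> list of c(src, dst)
  stanza_index <- 0L
  for (si in seq_along(stanza_starts)) {
    from <- stanza_starts[[si]]
    to <- if (si < length(stanza_starts)) stanza_starts[[si + 1]] - 1L else length(lines)
    header <- lines[[from]]
    body <- lines[(from + 1L):to]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    if (identical(header, "[Typedef]")) {
      idl <- body[startsWith(body, "id:")]
      if (length(idl)) relations <- union(relations, trimws(sub("^id:", "", idl[[1]])))
      next
    }
    if (!identical(header, "[Term]")) next
    stanza_index <- stanza_index + 1L
    tag <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    term_id <- val[tag == "id"]
    if (length(term_id) == 0 || !nzchar(term_id[[1]])) {
      stop("OBO [Term] stanza #", stanza_index, " has no id")
    }
    term_id <- term_id[[1]]
    syn_raw <- val[tag == "synonym"]
    syn_text <- sub('^"(.*)".*$', "\\1", syn_raw)
    syn_scope <- vapply(syn_raw, function(s) {
      m <- regmatches(s, regexec('"\\s+([A-Z]+)', s))[[1]]
      if (length(m) == 2) m[[2]] else "RELATED"
    }, "", USE.NAMES = FALSE)
    xrefs <- c(val[tag == "xref"], val[tag == "alt_id"])
    xrefs <- vapply(xrefs, function(x) strsplit(x, " ", fixed = TRUE)[[1]][[1]], "",
                    USE.NAMES = FALSE)
    obsolete <- any(tag == "is_obsolete" & val == "true")
    defn <- val[tag == "def"]
    defn <- if (length(defn)) sub('^"(.*)".*$', "\\1", defn[[1]]) else ""
    nm <- val[tag == "name"]
    ns <- val[tag == "namespace"]
    rows[[length(rows) + 1L]] <- c(
      identifier = term_id,
      name = if (length(nm)) nm[[1]] else "",
      namespace = if (length(ns)) ns[[1]] else "",
      definition = defn,
      synonyms = join_list_cell(syn_text),
      synonym_scopes = join_list_cell(syn_scope),
      xrefs = join_list_cell(unique(xrefs)),
      is_obsolete = if (obsolete) "true" else "false"
    )
    if (!obsolete) {
      for (parent in val[tag == "is_a"]) {
        dst <- strsplit(parent, " ", fixed = TRUE)[[1]][[1]]
        edge_rows[["is_a"]] <- c(edge_rows[["is_a"]], list(c(term_id, dst)))
      }
      for (rel in val[tag == "relationship"]) {
        parts <- strsplit(rel, " ", fixed = TRUE)[[1]]
        if (length(parts) >= 2) {
          edge_rows[[parts[[1]]]] <- c(edge_rows[[parts[[1]]]], list(c(term_id, parts[[2]])))
        }
      }
    }
  }
  node_cols <- c("identifier", "name", "namespace", "definition", "synonyms",
                 "synonym_scopes", "xrefs", "is_obsolete")
  nodes <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else empty_df(node_cols)
  edges <- lapply(edge_rows, function(rs) {
    df <- as.data.frame(do.call(rbind, rs), stringsAsFactors = FALSE)
    names(df) <- c("source_id", "target_id")
    df
  })
  for (rel in setdiff(relations, names(edges))) {
    edges[[rel]] <- empty_df(c("source_id", "target_id"))
  }
  list(nodes = nodes, edges = edges)
}

#' Parse an SDF (V2000) file into tabular rows
#'
#' One row per `$$$$`-terminated record. The union of all `> <key>`
#' property names forms the columns (absent keys yield empty cells); the
#' structure block (title through `M  END`) is preserved verbatim in a
#' dedicated `structure` column. A record cut off before its terminator is
#' a format error.
#'
#' @param path SDF file path
#' @param lines optional character vector of lines (overrides `path`)
#' @return data.frame with a `structure` column plus one column per
#'   property key (input key order)
#' @export
parse_sdf <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    return(empty_df(character(0)))
  }
  terms <- which(lines == "$$$$")
  if (length(terms) == 0 || max(terms) < max(which(nzchar(trimws(lines))))) {
    stop("truncated SDF record: EOF before '$$$$' terminator")
  }
  records <- list()
  structures <- character(0)
  start <- 1L
  key_order <- character(0)
  for (t in terms) {
    block <- lines[start:(t - 1L)]
    start <- t + 1L
    mend <- which(trimws(block) == "M  END" | trimws(block) == "M END")
    if (length(mend) == 0) stop("SDF record missing 'M  END' line")
    structures <- c(structures, paste(block[1:mend[[1]]], collapse = "\n"))
    props <- list()
    i <- mend[[1]] + 1L
    while (i <= length(block)) {
      ln <- block[[i]]
      if (grepl("^>", ln)) {
        key <- sub("^>\\s*<([^>]*)>.*$", "\\1", ln)
        vals <- character(0)
        i <- i + 1L
        while (i <= length(block) && nzchar(trimws(block[[i]]))) {
          vals <- c(vals, block[[i]])
          i <- i + 1L
        }
        if (key %in% names(props)) stop("duplicate SDF property key '", key, "'")
        props[[key]] <- paste(vals, collapse = "\n")
        key_order <- union(key_order, key)
      }
      i <- i + 1L
    }
    records[[length(records) + 1L]] <- props
  }
  cols <- c(key_order, "structure")
  mat <- matrix("", nrow = length(records), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (r in seq_along(records)) {
    for (k in key_order) mat[r, k] <- records[[r]][[k]] %||% ""
    mat[r, "structure"] <- structures[[r]]
  }
  as.data.frame(mat, stringsAsFactors = FALSE)
}

#' Parse a FASTA file
#'
#' Headers are the full line after `>`; wrapped sequence lines are
#' concatenated. A sequence line before any header is a format error.
#'
#' @param path FASTA file path
#' @param lines optional character vector of lines (overrides `path`)
#' @return data.frame with columns `header` and `sequence`
#' @export
parse_fasta <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_df(c("header", "sequence")))
  if (!startsWith(lines[[1]], ">")) stop("sequence line before any FASTA header")
  headers <- character(0); seqs <- character(0); buf <- character(0)
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (length(headers) > 0) seqs <- c(seqs, paste(buf, collapse = ""))
      headers <- c(headers, sub("^>", "", ln))
      buf <- character(0)
    } else {
      buf <- c(buf, gsub("\\s", "", ln))
    }
  }
  seqs <- c(seqs, paste(buf, collapse = ""))
  data.frame(header = headers, sequence = seqs, stringsAsFactors = FALSE)
}

#' Parse a GMT gene-set file
#'
#' Fields 1 and 2 of each tab-separated line are the set name and
#' description; remaining fields are members, deduplicated with input
#' order preserved. A line with fewer than two fields is a format error
#' naming the line number.
#'
#' @param path GMT file path
#' @param lines optional character vector of lines (overrides `path`)
#' @return data.frame with columns `set_name`, `description`, `members`
#'   (a `"|"` list cell)
#' @export
parse_gmt <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  out <- empty_df(c("set_name", "description", "members"))
  r <- 0L
  for (i in seq_along(lines)) {
    if (!keep[[i]]) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) stop("GMT line ", i, " has fewer than 2 fields")
    r <- r + 1L
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    out[r, ] <- c(fields[[1]], fields[[2]], join_list_cell(members))
  }
  out
}

#' Read a GAF-style annotation file
#'
#' GAF is tab-separated with `!`-prefixed comment lines and no header row;
#' column names must be supplied.
#'
#' @param path file path
#' @param col_names character vector of column names
#' @return data.frame of character columns
#' @export
read_gaf <- function(path, col_names) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  out <- empty_df(col_names)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    length(fields) <- length(col_names)
    fields[is.na(fields)] <- ""
    out[i, ] <- fields
  }
  out
}
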