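# Shared helpers: TSV reading/writing with the "|" list convention, cell
# escaping for embedded newlines/tabs, and small misc utilities.

DEFAULT_LIST_DELIM <- "|"

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) {
  is.na(x) | !nzchar(trimws(as.character(x)))
}

#' Split a delimited list cell into a character vector
#'
#' Empty cells yield `character(0)`. Used everywhere a TSV cell carries a
#' list value (synonyms, xrefs, PubMed ids).
#'
#' @param x character scalar cell value
#' @param delim list delimiter, `"|"` by default
#' @return character vector of elements
#' @export
split_list_cell <- function(x, delim = DEFAULT_LIST_DELIM) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, delim, fixed = TRUE)[[1]]
}

#' Join a character vector into a delimited list cell
#' @param x character vector
#' @param delim list delimiter
#' @return character scalar
#' @export
join_list_cell <- function(x, delim = DEFAULT_LIST_DELIM) {
  paste(x, collapse = delim)
}

# escape/unescape embedded newlines and tabs so multi-line values (SDF
# structure blocks) survive TSV round-trips
escape_cell <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_cell <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s) || !grepl("\\", s, fixed = TRUE)) { out[[i]] <- s; next }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    buf <- character(0); j <- 1
    while (j <= length(chars)) {
      if (chars[[j]] == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1]]
        buf <- c(buf, switch(nxt, n = "\n", t = "\t", "\\" = "\\", nxt))
        j <- j + 2
      } else {
        buf <- c(buf, chars[[j]]); j <- j + 1
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

#' Read a TSV table (UTF-8, header row, escaped cells)
#'
#' The toolkit's table convention: tab-separated, first row is the header,
#' all columns character, `"|"` delimits list cells, embedded newlines and
#' tabs are backslash-escaped. Lines starting with `comment_prefix` are
#' skipped (GAF-style annotation files use `"!"`).
#'
#' @param path file path
#' @param comment_prefix optional comment line prefix to skip (e.g. `"!"`)
#' @return data.frame of character columns
#' @export
read_table_file <- function(path, comment_prefix = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!is.null(comment_prefix) && nzchar(comment_prefix)) {
    lines <- lines[!startsWith(lines, comment_prefix)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty table (no header row): ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol <- length(header)
  rows <- cells[-1]
  out <- as.data.frame(
    do.call(rbind, c(list(matrix(character(0), 0, ncol)), lapply(rows, function(r) {
      length(r) <- ncol
      r[is.na(r)] <- ""
      r
    }))),
    stringsAsFactors = FALSE
  )
  names(out) <- header
  for (j in seq_along(out)) out[[j]] <- unescape_cell(out[[j]])
  out
}

#' Write a TSV table (UTF-8, header row, escaped cells)
#' @param df data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_table_file <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  lines <- paste(vapply(names(df), escape_cell, ""), collapse = "\t")
  if (nrow(df) > 0) {
    body <- apply(df, 1, function(r) paste(escape_cell(as.character(r)), collapse = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

empty_df <- function(cols) {
  out <- as.data.frame(matrix(character(0), 0, length(cols)), stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

# stable deterministic order helper
lex_sort <- function(x) {
  if (is.null(x) || length(x) == 0) return(character(0))
  x[order(x, method = "radix")]
}
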