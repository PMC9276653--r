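# GraphML interchange. Dialect: node labels in a node attribute "labels"
# as ":"-prefixed concatenation (":Chemical:Compound"), edge type in an
# edge attribute "label"; every other property is declared as a <key>.
# List-valued properties are declared with attr.list="string" and encoded
# "|"-joined. write_graphml %then% read_graphml is the identity on any
# graph the toolkit produces.

graphml_type_of <- function(values) {
  # values: list of property values across entities
  values <- Filter(length, values)
  if (length(values) == 0) return("string")
  if (all(vapply(values, is.integer, logical(1)))) return("long")
  if (all(vapply(values, is.numeric, logical(1)))) return("double")
  if (any(vapply(values, function(v) length(v) > 1, logical(1)))) return("list")
  "string"
}

collect_keys <- function(records) {
  # records: list of property lists; returns named chr type per property
  types <- list()
  for (rec in records) {
    for (nm in names(rec)) types[[nm]] <- c(types[[nm]], list(rec[[nm]]))
  }
  vapply(types, graphml_type_of, "")
}

encode_value <- function(v) {
  if (length(v) > 1) join_list_cell(as.character(v)) else as.character(v)
}

#' Write a graph store to GraphML
#'
#' @param store a `graph_store`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_graphml <- function(store, path) {
  nids <- gs_node_ids(store)
  eids <- gs_edge_ids(store)
  node_keys <- collect_keys(lapply(nids, function(i) store$nodes[[i]]$properties))
  edge_keys <- collect_keys(lapply(eids, function(i) store$edges[[i]]$properties))

  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  add_key <- function(id, dom, name, type) {
    k <- xml2::xml_add_child(doc, "key", id = id, "for" = dom, "attr.name" = name)
    if (type == "list") {
      xml2::xml_set_attr(k, "attr.type", "string")
      xml2::xml_set_attr(k, "attr.list", "string")
    } else {
      xml2::xml_set_attr(k, "attr.type", type)
    }
  }
  add_key("labels", "node", "labels", "string")
  for (nm in lex_sort(names(node_keys))) add_key(paste0("n_", nm), "node", nm, node_keys[[nm]])
  add_key("label", "edge", "label", "string")
  for (nm in lex_sort(names(edge_keys))) add_key(paste0("e_", nm), "edge", nm, edge_keys[[nm]])

  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  for (i in nids) {
    node <- store$nodes[[i]]
    xn <- xml2::xml_add_child(g, "node", id = i)
    d <- xml2::xml_add_child(xn, "data", key = "labels")
    xml2::xml_set_text(d, paste0(":", paste(node$labels, collapse = ":")))
    for (nm in lex_sort(names(node$properties))) {
      if (length(node$properties[[nm]]) == 0) next
      d <- xml2::xml_add_child(xn, "data", key = paste0("n_", nm))
      xml2::xml_set_text(d, encode_value(node$properties[[nm]]))
    }
  }
  for (i in eids) {
    e <- store$edges[[i]]
    xe <- xml2::xml_add_child(g, "edge", id = i, source = e$source, target = e$target)
    d <- xml2::xml_add_child(xe, "data", key = "label")
    xml2::xml_set_text(d, e$type)
    for (nm in lex_sort(names(e$properties))) {
      if (length(e$properties[[nm]]) == 0) next
      d <- xml2::xml_add_child(xe, "data", key = paste0("e_", nm))
      xml2::xml_set_text(d, encode_value(e$properties[[nm]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

decode_value <- function(text, type, is_list) {
  if (is_list) return(split_list_cell(text))
  switch(type,
    long = as.integer(text),
    double = as.numeric(text),
    int = as.integer(text),
    float = as.numeric(text),
    boolean = identical(text, "true"),
    text)
}

#' Read a GraphML file into a new graph store
#'
#' Accepts the dialect written by [write_graphml()]: node labels in the
#' "labels" attribute (":"-prefixed concatenation), edge type in "label".
#' Malformed XML raises a parse error (with line information from the XML
#' parser); a `<data>` element referencing an undeclared key is a format
#' error.
#'
#' @param path GraphML file path
#' @return a `graph_store`
#' @export
read_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GraphML: ", conditionMessage(e)))
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  has_ns <- length(xml2::xml_ns(doc)) > 0 &&
    any(grepl("graphml", unlist(xml2::xml_ns(doc))))
  xp <- function(node, q) {
    if (has_ns) xml2::xml_find_all(node, gsub("\\bX:", "g:", q), ns)
    else xml2::xml_find_all(node, gsub("\\bX:", "", q))
  }
  keys <- xp(doc, ".//X:key")
  key_info <- list()
  for (k in keys) {
    kid <- xml2::xml_attr(k, "id")
    tp <- xml2::xml_attr(k, "attr.type") %||% "string"
    if (is.na(tp)) tp <- "string"
    key_info[[kid]] <- list(
      name = xml2::xml_attr(k, "attr.name") %||% kid,
      type = tp,
      list = !is.na(xml2::xml_attr(k, "attr.list"))
    )
  }
  store <- graph_store()
  id_map <- new.env(parent = emptyenv())
  for (xn in xp(doc, ".//X:node")) {
    raw_id <- xml2::xml_attr(xn, "id")
    labels <- character(0)
    props <- list()
    for (d in xp(xn, "./X:data")) {
      kid <- xml2::xml_attr(d, "key")
      info <- key_info[[kid]]
      if (is.null(info)) stop("unknown attribute key in GraphML: ", kid)
      txt <- xml2::xml_text(d)
      if (identical(info$name, "labels")) {
        labels <- strsplit(sub("^:", "", txt), ":", fixed = TRUE)[[1]]
      } else {
        props[[info$name]] <- decode_value(txt, info$type, info$list)
      }
    }
    if (length(labels) == 0) labels <- "Node"
    id_map[[raw_id]] <- gs_add_node(store, labels, props)
  }
  for (xe in xp(doc, ".//X:edge")) {
    src <- id_map[[xml2::xml_attr(xe, "source")]]
    dst <- id_map[[xml2::xml_attr(xe, "target")]]
    if (is.null(src) || is.null(dst)) stop("GraphML edge references unknown node")
    type <- NA_character_
    props <- list()
    for (d in xp(xe, "./X:data")) {
      kid <- xml2::xml_attr(d, "key")
      info <- key_info[[kid]]
      if (is.null(info)) stop("unknown attribute key in GraphML: ", kid)
      txt <- xml2::xml_text(d)
      if (identical(info$name, "label")) type <- txt
      else props[[info$name]] <- decode_value(txt, info$type, info$list)
    }
    if (is.na(type)) type <- "RELATED_TO"
    gs_add_edge(store, type, src, dst, props)
  }
  store
}
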