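# Edge-type naming grammar (hetnet convention): the rendered type is
# RELATION + "_" + <src abbrev> + <relation initials, lowercased> +
# <dst abbrev>, e.g. TREATS + Chemical(CH) + Disease(D) -> "TREATS_CHtD".

#' Default label abbreviation registry
#'
#' Maps every merged-schema label to its uppercase abbreviation used in
#' edge-type names. Abbreviations are unique.
#'
#' @return named character vector (label -> abbreviation)
#' @export
abbreviation_registry <- function() {
  c(Chemical = "CH", Compound = "C", Salt = "SA", Product = "PR",
    Disease = "D", Gene = "G", Protein = "P", Pathway = "PW",
    SideEffect = "SE", Symptom = "S", Phenotype = "PT",
    PharmacologicalClass = "PC", Variant = "V", GeneVariant = "GV",
    Haplotype = "H", Genotype = "GT", BiologicalProcess = "BP",
    CellularComponent = "CC", MolecularFunction = "MF",
    Interaction = "I", ReactionLikeEvent = "RLE", Treatment = "T",
    ClinicalAnnotation = "CA", VariantAnnotation = "VA")
}

#' Lowercased initials of an underscore-separated relation name
#' @param relation e.g. `"MIGHT_SUBCELLULAR_LOCATES"`
#' @return e.g. `"msl"`
#' @export
relation_initials <- function(relation) {
  words <- strsplit(relation, "_", fixed = TRUE)[[1]]
  tolower(paste(substr(words, 1, 1), collapse = ""))
}

#' Generate a grammar-conformant edge-type string
#'
#' @param relation uppercase underscore-separated relation name
#' @param src_label,dst_label labels present in the registry
#' @param registry label abbreviation registry
#' @return edge-type string, e.g. `"TREATS_CHtD"`
#' @export
generate_edge_type <- function(relation, src_label, dst_label,
                               registry = abbreviation_registry()) {
  if (!grepl("^[A-Z][A-Z_]*$", relation)) {
    stop("relation must be uppercase underscore-separated: ", relation)
  }
  for (lb in c(src_label, dst_label)) {
    if (!lb %in% names(registry)) stop("label not in abbreviation registry: ", lb)
  }
  paste0(relation, "_", registry[[src_label]], relation_initials(relation),
         registry[[dst_label]])
}

#' Parse an edge-type string under the naming grammar
#'
#' Inverse of [generate_edge_type()] on its image. Failure is returned as a
#' value (`ok = FALSE` with a `reason`), never thrown.
#'
#' @param type edge-type string
#' @param registry label abbreviation registry
#' @return list with `ok`; on success also `relation`, `src_label`,
#'   `dst_label`, `src_abbrev`, `rel_abbrev`, `dst_abbrev`
#' @export
parse_edge_type <- function(type, registry = abbreviation_registry()) {
  fail <- function(reason) list(ok = FALSE, reason = reason, type = type)
  parts <- strsplit(type, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(fail("no underscore separating relation and abbreviations"))
  blob <- parts[[length(parts)]]
  relation <- paste(parts[-length(parts)], collapse = "_")
  if (!grepl("^[A-Z][A-Z_]*$", relation)) return(fail("relation is not uppercase underscore-separated"))
  m <- regmatches(blob, regexec("^([A-Z]+)([a-z]+)([A-Z]+)$", blob))[[1]]
  if (length(m) != 4) return(fail("abbreviation block does not match <SRC><rel><DST>"))
  src_abbrev <- m[[2]]; rel_abbrev <- m[[3]]; dst_abbrev <- m[[4]]
  rev <- stats::setNames(names(registry), registry)
  if (!src_abbrev %in% names(rev)) return(fail(paste0("unknown source abbreviation '", src_abbrev, "'")))
  if (!dst_abbrev %in% names(rev)) return(fail(paste0("unknown target abbreviation '", dst_abbrev, "'")))
  if (!identical(rel_abbrev, relation_initials(relation))) {
    return(fail(paste0("relation abbreviation '", rel_abbrev,
                       "' does not match initials of '", relation, "'")))
  }
  list(ok = TRUE, relation = relation,
       src_label = rev[[src_abbrev]], dst_label = rev[[dst_abbrev]],
       src_abbrev = src_abbrev, rel_abbrev = rel_abbrev, dst_abbrev = dst_abbrev)
}

#' The edge-type corpus bundled with the package
#'
#' All merged-schema edge-type strings the toolkit targets (as used by the
#' naming-grammar regression suite).
#'
#' @return character vector of edge-type strings
#' @export
edge_type_corpus <- function() {
  path <- system.file("extdata", "edge_type_corpus.txt", package = "kgforge")
  lines <- readLines(path, encoding = "UTF-8")
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
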