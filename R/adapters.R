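# Per-source preparation: an AdapterSpec binds raw source files to parsed
# inputs, applies an ordered filter/transform chain from the rule
# catalogue, and emits normalized node/edge/link tables (or passes GraphML
# through) for integration. Configs are YAML; the bundled registry holds
# one adapter per emulated source.

#' Construct an adapter specification
#'
#' @param source_name unique source name
#' @param inputs named list of input bindings: each a list with `path`
#'   (relative to the source's corpus directory, or `@prepared/...` to
#'   reference another source's prepared output), `format` (one of tsv,
#'   gaf, obo, sdf, fasta, gmt, graphml) and format options
#' @param steps ordered list of filter/transform steps; each a list with
#'   `op` (`"filter"` or a transform name), `input` (the bound input it
#'   mutates) and parameters
#' @param emitters list of emitters: `kind` is `"nodes"`, `"edges"`,
#'   `"table"` or `"graphml"` plus kind-specific fields
#' @return an `adapter_spec`
#' @export
adapter_spec <- function(source_name, inputs, steps = list(), emitters = list()) {
  structure(list(source_name = source_name, inputs = inputs,
                 steps = steps, emitters = emitters),
            class = "adapter_spec")
}

#' Load the adapter registry from a YAML config directory or file
#'
#' @param config path to a YAML file (or directory containing
#'   `adapters.yaml`); defaults to the bundled registry
#' @return named list of `adapter_spec`s
#' @export
adapter_registry <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "adapters.yaml", package = "kgforge")
  }
  if (dir.exists(config)) config <- file.path(config, "adapters.yaml")
  raw <- yaml::read_yaml(config)
  out <- list()
  for (nm in names(raw)) {
    spec <- raw[[nm]]
    out[[nm]] <- adapter_spec(nm, spec$inputs %||% list(),
                              spec$steps %||% list(),
                              spec$emitters %||% list())
  }
  out
}

resolve_input_path <- function(path, source_dir, prepared_dir) {
  if (startsWith(path, "@prepared/")) {
    file.path(prepared_dir, sub("^@prepared/", "", path))
  } else {
    file.path(source_dir, path)
  }
}

parse_input <- function(binding, source_dir, prepared_dir) {
  path <- resolve_input_path(binding$path, source_dir, prepared_dir)
  if (!file.exists(path)) stop("adapter input missing: ", path)
  fmt <- binding$format %||% "tsv"
  switch(fmt,
    tsv = read_table_file(path, comment_prefix = binding$comment_prefix %||% NULL),
    gaf = read_gaf(path, col_names = unlist(binding$col_names)),
    obo = parse_obo(path),
    sdf = parse_sdf(path),
    fasta = parse_fasta(path),
    gmt = parse_gmt(path),
    graphml = path,  # passed through by the graphml emitter
    stop("unknown input format: ", fmt))
}

# address a (possibly nested) parsed input like "mondo/nodes" or
# "mondo/edges/is_a"
get_parsed <- function(parsed, ref) {
  parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
  cur <- parsed[[parts[[1]]]]
  for (p in parts[-1]) cur <- cur[[p]]
  if (is.null(cur)) stop("no parsed input at '", ref, "'")
  cur
}

set_parsed <- function(parsed, ref, value) {
  parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    parsed[[parts[[1]]]] <- value
  } else if (length(parts) == 2) {
    parsed[[parts[[1]]]][[parts[[2]]]] <- value
  } else {
    parsed[[parts[[1]]]][[parts[[2]]]][[parts[[3]]]] <- value
  }
  parsed
}

filter_catalogue <- function() {
  list(
    taxon = function(df, p, parsed) {
      filter_by_taxon(df, p$taxon_column %||% "taxon",
                      as.integer(p$taxon_id %||% 9606L))
    },
    direct_evidence = function(df, p, parsed) {
      filter_direct_evidence(df, p$evidence_column %||% "DirectEvidence")
    },
    outcome_pairs = function(df, p, parsed) {
      filter_outcome_pairs(df, p$frequency_column %||% "frequency",
                           p$count_column %||% "count",
                           as.numeric(p$min_frequency_percent %||% 0.1),
                           as.numeric(p$min_count %||% 100))
    },
    annotation_evidence = function(df, p, parsed) {
      filter_annotation_evidence(df, p$level_column %||% "evidence_level",
                                 p$significance_column %||% "significance")
    },
    requires_reference = function(df, p, parsed) {
      filter_requires_reference(df, p$reference_column %||% "pubmed_ids")
    },
    source_whitelist = function(df, p, parsed) {
      wl <- unlist(p$whitelist) %||% c("WikiPathways", "Reactome", "Panther",
                                       "NetPath", "PathBank")
      filter_source_whitelist(df, p$source_column %||% "source", wl)
    },
    evidence_contains = function(df, p, parsed) {
      filter_evidence_contains(df, p$evidence_column %||% "evidence_type",
                               p$marker %||% "exp")
    },
    semi_join = function(df, p, parsed) {
      ref <- get_parsed(parsed, p$reference)
      filter_semi_join(df, p$key_column, ref[[p$reference_column]])
    }
  )
}

apply_step <- function(parsed, step) {
  op <- step$op
  input <- step$input
  if (identical(op, "filter")) {
    df <- get_parsed(parsed, input)
    fn <- filter_catalogue()[[step$rule]]
    if (is.null(fn)) stop("unknown filter rule: ", step$rule)
    out <- fn(df, step, parsed)
    log <- attr(out, "filter_log")
    parsed <- set_parsed(parsed, input, out)
    attr(parsed, "logs") <- c(attr(parsed, "logs"),
                              list(c(list(table = input), log)))
    return(parsed)
  }
  if (identical(op, "prune")) return(apply_prune_step(parsed, step))
  df <- if (!identical(op, "noop")) get_parsed(parsed, input) else NULL
  out <- switch(op,
    dedupe = dedupe_entities(df, unlist(step$keys),
                             unlist(step$list_columns) %||% character(0)),
    explode = {  # one row per element of a list cell
      col <- step$column
      rows <- list()
      for (i in seq_len(nrow(df))) {
        for (v in split_list_cell(df[[col]][[i]])) {
          r <- df[i, , drop = FALSE]
          r[[col]] <- v
          rows[[length(rows) + 1L]] <- r
        }
      }
      res <- if (length(rows)) do.call(rbind, rows) else df[0, , drop = FALSE]
      rownames(res) <- NULL
      res
    },
    union = {  # union-by-identifier; rows of `other` win on conflict
      other <- get_parsed(parsed, step$other)
      key <- step$key %||% "identifier"
      add <- df[!(df[[key]] %in% other[[key]]), , drop = FALSE]
      cols <- union(names(other), names(df))
      for (c in setdiff(cols, names(other))) other[[c]] <- ""
      for (c in setdiff(cols, names(add))) add[[c]] <- ""
      res <- rbind(other[cols], add[cols])
      rownames(res) <- NULL
      res
    },
    join_fasta = {  # attach sequences by identifier parsed from headers
      fa <- get_parsed(parsed, step$fasta)
      acc <- vapply(fa$header, function(h) strsplit(h, "[| ]")[[1]][[1]], "",
                    USE.NAMES = FALSE)
      df$sequence <- fa$sequence[match(df[[step$key %||% "identifier"]], acc)]
      df$sequence[is.na(df$sequence)] <- ""
      df
    },
    left_join = {
      other <- get_parsed(parsed, step$other)
      by <- step$by
      idx <- match(df[[by]], other[[by]])
      for (c in setdiff(names(other), by)) {
        vals <- other[[c]][idx]
        vals[is.na(vals)] <- ""
        df[[c]] <- vals
      }
      df
    },
    translate_evidence = {
      df[[step$out_column %||% "evidence"]] <-
        suppressWarnings(translate_evidence_code(df[[step$column]]))
      df
    },
    rename = {
      map <- step$columns
      for (old in names(map)) names(df)[names(df) == old] <- map[[old]]
      df
    },
    constant = { df[[step$column]] <- step$value; df },
    stop("unknown adapter op: ", op))
  set_parsed(parsed, input, out)
}

# node/edge pruning needs several tables at once, so it is handled apart
# from the single-input ops
apply_prune_step <- function(parsed, step) {
  touched <- character(0)
  for (ref in names(step$edges)) {
    df <- get_parsed(parsed, ref)
    for (col in unlist(step$edges[[ref]])) touched <- c(touched, df[[col]])
  }
  touched <- unique(touched)
  keep_inputs <- unlist(step$keep) %||% character(0)
  for (ref in names(step$nodes)) {
    if (ref %in% keep_inputs) next
    df <- get_parsed(parsed, ref)
    idcol <- step$nodes[[ref]]
    res <- df[df[[idcol]] %in% touched, , drop = FALSE]
    rownames(res) <- NULL
    parsed <- set_parsed(parsed, ref, res)
  }
  parsed
}

#' Run one source adapter
#'
#' Parses the bound inputs, applies the filter/transform chain in order,
#' and writes the emitted tables to `out_dir/<source>/`. The run report
#' records per-filter row counts (input, kept, removed), which telescope:
#' input rows minus total removed equals emitted rows for each chain.
#'
#' @param spec an [adapter_spec()]
#' @param source_dir directory holding the source's raw files
#' @param out_dir prepared-output root directory
#' @return run report: list with `source`, `filters` (per-step counts) and
#'   `emitted` (per-emitter row counts)
#' @export
run_adapter <- function(spec, source_dir, out_dir) {
  parsed <- list()
  for (nm in names(spec$inputs)) {
    parsed[[nm]] <- parse_input(spec$inputs[[nm]], source_dir, out_dir)
  }
  for (step in spec$steps) parsed <- apply_step(parsed, step)
  dest <- file.path(out_dir, spec$source_name)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  emitted <- list()
  for (em in spec$emitters) {
    kind <- em$kind
    if (identical(kind, "graphml")) {
      src_path <- parsed[[em$input]]
      file.copy(src_path, file.path(dest, em$file %||% basename(src_path)),
                overwrite = TRUE)
      emitted[[length(emitted) + 1L]] <- list(kind = kind, file = em$file %||% basename(src_path))
      next
    }
    df <- get_parsed(parsed, em$input)
    if (!is.null(em$columns)) {
      keep <- unlist(em$columns)
      df2 <- df[, intersect(names(keep) %||% keep, names(df)), drop = FALSE]
      if (!is.null(names(keep))) {
        df2 <- df[, names(keep), drop = FALSE]
        names(df2) <- unname(keep)
      }
      df <- df2
    }
    if (identical(kind, "nodes")) {
      if (!is.null(em$label_column)) {
        for (lb in unique(df[[em$label_column]])) {
          sub <- df[df[[em$label_column]] == lb, , drop = FALSE]
          file <- file.path(dest, paste0("nodes_", lb, ".tsv"))
          write_table_file(sub, file)
          emitted[[length(emitted) + 1L]] <- list(kind = "nodes", label = lb, rows = nrow(sub))
        }
      } else {
        file <- file.path(dest, paste0("nodes_", em$label, ".tsv"))
        write_table_file(df, file)
        emitted[[length(emitted) + 1L]] <- list(kind = "nodes", label = em$label, rows = nrow(df))
      }
    } else if (identical(kind, "edges")) {
      file <- file.path(dest, paste0("edges_", em$type, "__", em$src_label,
                                     "__", em$dst_label, ".tsv"))
      write_table_file(df, file)
      emitted[[length(emitted) + 1L]] <- list(kind = "edges", type = em$type, rows = nrow(df))
    } else if (identical(kind, "table")) {
      write_table_file(df, file.path(dest, em$file))
      emitted[[length(emitted) + 1L]] <- list(kind = "table", file = em$file, rows = nrow(df))
    } else {
      stop("unknown emitter kind: ", kind)
    }
  }
  list(source = spec$source_name,
       filters = attr(parsed, "logs") %||% list(),
       emitted = emitted)
}

#' Run all adapters of a registry over a corpus directory
#'
#' Adapters run in registry order (so later adapters may bind
#' `@prepared/...` outputs of earlier ones). Missing inputs are a
#' configuration error before any work is done for that source.
#'
#' @param corpus_dir corpus root (one subdirectory per source)
#' @param out_dir prepared-output root
#' @param registry adapter registry (default: bundled)
#' @return list of per-source run reports
#' @export
forge_prepare <- function(corpus_dir, out_dir, registry = adapter_registry()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (nm in names(registry)) {
    spec <- registry[[nm]]
    src_dir <- file.path(corpus_dir, nm)
    for (binding in spec$inputs) {
      p <- resolve_input_path(binding$path, src_dir, out_dir)
      if (!file.exists(p)) stop("adapter '", nm, "' input missing: ", p)
    }
    reports[[nm]] <- run_adapter(spec, src_dir, out_dir)
  }
  reports
}
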