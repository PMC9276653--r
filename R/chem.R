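# Compound fingerprints and structure similarity. Fingerprinting delegates
# to ChemmineR's canonical atom-pair descriptors folded to a fixed-length
# bitvector (invariant under atom renumbering); Tanimoto/Dice and the
# resemblance-edge rule are implemented here.

#' Construct a fingerprint object from on-bit positions
#' @param on sorted integer vector of set bit positions (1-based)
#' @param length bitvector length
#' @param generator_id string naming the scheme and parameters
#' @return a `fingerprint` object
#' @export
make_fingerprint <- function(on, length, generator_id) {
  on <- sort(unique(as.integer(on)))
  if (any(on < 1L) || any(on > length)) stop("bit positions out of range")
  structure(list(on = on, length = as.integer(length), generator_id = generator_id),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d/%d bits set>\n", x$generator_id,
              length(x$on), x$length))
  invisible(x)
}

#' Compute fingerprints for a set of SDF structure blocks
#'
#' Structures are V2000 SDF record blocks (title through `M  END`, as
#' produced by [parse_sdf()]'s `structure` column). Unparseable structures
#' are skipped with a log entry in the `skipped` attribute of the result.
#'
#' @param structures character vector of SDF structure blocks
#' @param ids names for the result (defaults to indices)
#' @param bits folded bitvector length (default 1024)
#' @return named list of `fingerprint` objects (parseable structures only),
#'   with a `skipped` attribute naming failures
#' @export
fingerprint_set <- function(structures, ids = NULL, bits = 1024L) {
  if (is.null(ids)) ids <- as.character(seq_along(structures))
  stopifnot(length(ids) == length(structures))
  ok <- vapply(structures, function(s) {
    is.character(s) && length(s) == 1 && !is.na(s) && nzchar(trimws(s)) &&
      grepl("V2000", s, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  out <- list()
  skipped <- ids[!ok]
  if (any(ok)) {
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(paste0(structures[ok], "\n$$$$"), tmp)
    sdfset <- ChemmineR::read.SDFset(tmp)
    ap <- ChemmineR::sdf2ap(sdfset)
    # resolve the most-frequent atom-pair descriptor names ourselves so the
    # package works without ChemmineR attached on the search path
    denv <- new.env(parent = emptyenv())
    utils::data("apfp", package = "ChemmineR", envir = denv)
    descnames <- as.character(denv$apfp$AP)[seq_len(bits)]
    fps <- ChemmineR::desc2fp(ap, descnames = descnames, type = "FPset")
    mat <- fps@fpma
    gid <- paste0("chemmine-ap-", bits)
    kept_ids <- ids[ok]
    for (i in seq_len(nrow(mat))) {
      out[[kept_ids[[i]]]] <- make_fingerprint(which(mat[i, ] != 0), bits, gid)
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Compute a single structure fingerprint
#'
#' Deterministic for identical input and invariant under atom renumbering.
#' An unparseable or empty structure is an error (callers batching many
#' compounds use [fingerprint_set()], which skips and logs instead).
#'
#' @param structure SDF structure block (V2000)
#' @param bits folded bitvector length
#' @return a `fingerprint`
#' @export
fingerprint <- function(structure, bits = 1024L) {
  res <- fingerprint_set(structure, ids = "x", bits = bits)
  if (length(res) == 0) stop("unparseable structure")
  res[["x"]]
}

check_comparable <- function(a, b) {
  if (!identical(a$length, b$length) || !identical(a$generator_id, b$generator_id)) {
    stop("fingerprints are not comparable (length or generator mismatch)")
  }
}

#' Tanimoto coefficient of two fingerprints
#'
#' |A intersect B| / |A union B|; two empty fingerprints score 0 (a missing
#' structure never counts as similar).
#'
#' @param a,b `fingerprint` objects with equal length and generator
#' @return numeric in \[0, 1\]
#' @export
tanimoto <- function(a, b) {
  check_comparable(a, b)
  i <- length(intersect(a$on, b$on))
  u <- length(union(a$on, b$on))
  if (u == 0) return(0)
  i / u
}

#' Dice coefficient of two fingerprints
#'
#' 2 |A intersect B| / (|A| + |B|); two empty fingerprints score 0.
#'
#' @param a,b `fingerprint` objects with equal length and generator
#' @return numeric in \[0, 1\]
#' @export
dice <- function(a, b) {
  check_comparable(a, b)
  denom <- length(a$on) + length(b$on)
  if (denom == 0) return(0)
  2 * length(intersect(a$on, b$on)) / denom
}

#' Compute structure-resemblance edges above a similarity threshold
#'
#' Scores every unordered compound pair with the configured measures and
#' retains a pair iff its maximum score reaches `threshold` (default 0.75,
#' keeping only significant similarities). All scores are returned so they
#' can be stored as edge properties. The pair direction is deterministic:
#' the lexicographically smaller identifier is the source.
#'
#' @param fingerprints named list of `fingerprint`s (names are compound ids)
#' @param threshold retention threshold on the maximum score (default 0.75)
#' @param measures similarity measures to compute
#' @return data.frame with columns source, target, tanimoto, dice, score
#' @export
resemblance_edges <- function(fingerprints, threshold = 0.75,
                              measures = c("tanimoto", "dice")) {
  measures <- match.arg(measures, several.ok = TRUE)
  ids <- lex_sort(names(fingerprints))
  out <- data.frame(source = character(0), target = character(0),
                    tanimoto = numeric(0), dice = numeric(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(ids) < 2) return(out)
  r <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      a <- fingerprints[[ids[[i]]]]; b <- fingerprints[[ids[[j]]]]
      t_val <- if ("tanimoto" %in% measures) tanimoto(a, b) else NA_real_
      d_val <- if ("dice" %in% measures) dice(a, b) else NA_real_
      score <- max(c(t_val, d_val), na.rm = TRUE)
      if (score >= threshold) {
        r <- r + 1L
        out[r, ] <- list(ids[[i]], ids[[j]], t_val, d_val, score)
      }
    }
  }
  out
}
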