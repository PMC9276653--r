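# Fingerprints and structure similarity.

test_that("tanimoto and dice follow their set definitions", {
  a <- make_fingerprint(c(1, 2, 3), 16, "t")
  b <- make_fingerprint(c(2, 3, 4), 16, "t")
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(dice(a, b), 2 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(dice(a, a), 1)
  disjoint <- make_fingerprint(c(9, 10), 16, "t")
  expect_equal(tanimoto(a, disjoint), 0)
  expect_equal(dice(a, disjoint), 0)
  empty <- make_fingerprint(integer(0), 16, "t")
  expect_equal(tanimoto(empty, empty), 0)  # both-empty convention
  expect_equal(dice(empty, empty), 0)
  other <- make_fingerprint(1, 32, "t")
  expect_error(tanimoto(a, other), "not comparable")
})

test_that("tanimoto <= dice, both symmetric, equal 1 iff identical nonzero", {
  set.seed(47)
  for (i in 1:60) {
    a <- random_fingerprint()
    b <- random_fingerprint()
    t_ab <- tanimoto(a, b)
    expect_lte(t_ab, dice(a, b) + 1e-12)
    expect_equal(t_ab, tanimoto(b, a))
    expect_equal(dice(a, b), dice(b, a))
    if (t_ab == 1) expect_identical(a$on, b$on)
  }
})

test_that("fingerprints are deterministic and renumbering-invariant", {
  structs <- kgforge:::toy_structures()
  f1 <- fingerprint(structs$DB002)
  f2 <- fingerprint(structs$DB002)
  expect_identical(f1, f2)
  # same molecule with permuted atom numbering
  f3 <- fingerprint(structs$DB005)
  expect_identical(f1$on, f3$on)
  expect_equal(tanimoto(f1, f3), 1)
  expect_error(fingerprint(""), "unparseable")
  batch <- fingerprint_set(c(structs$DB001, "garbage"), ids = c("ok", "bad"))
  expect_named(batch, "ok")
  expect_equal(attr(batch, "skipped"), "bad")
})

test_that("package similarity agrees with the ChemmineR reference on toys", {
  structs <- kgforge:::toy_structures()
  fps <- fingerprint_set(unlist(structs), ids = names(structs))
  tmp <- tempfile(fileext = ".sdf")
  writeLines(paste0(unlist(structs), "\n$$$$"), tmp)
  sdfset <- ChemmineR::read.SDFset(tmp)
  denv <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = denv)
  ref_fp <- ChemmineR::desc2fp(ChemmineR::sdf2ap(sdfset),
                               descnames = as.character(denv$apfp$AP)[1:1024],
                               type = "FPset")
  pairs <- list(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(1L, 3L))
  for (p in pairs) {
    mine <- tanimoto(fps[[p[[1]]]], fps[[p[[2]]]])
    ref <- ChemmineR::fpSim(ref_fp[p[[1]]], ref_fp[p[[2]]], method = "Tanimoto",
                            addone = 0)
    expect_equal(unname(mine), unname(ref))
  }
  # the renumbered-hexane pair is identical by construction
  expect_equal(tanimoto(fps$DB002, fps$DB005), 1)
})

test_that("resemblance edges honor the retention threshold boundary", {
  panel <- generate_fingerprint_panel(1L, c(0.70, 0.74, 0.75, 0.76, 1.0, 0.0))
  for (p in panel) {
    expect_lte(abs(tanimoto(p$a, p$b) - p$target), 0.01)
  }
  for (p in panel) {
    fps <- list(a = p$a, b = p$b)
    edges <- resemblance_edges(fps, threshold = 0.75, measures = "tanimoto")
    if (p$achieved >= 0.75) expect_equal(nrow(edges), 1L, info = p$target)
    else expect_equal(nrow(edges), 0L, info = p$target)
  }
  expect_equal(nrow(resemblance_edges(list(a = random_fingerprint()))), 0L)
})

test_that("resemblance edges equal exhaustive pair rescoring", {
  set.seed(53)
  fps <- stats::setNames(lapply(1:40, function(i) random_fingerprint(density = 0.4)),
                         sprintf("c%02d", 1:40))
  threshold <- 0.6
  got <- resemblance_edges(fps, threshold = threshold, measures = "tanimoto")
  want <- character(0)
  ids <- sort(names(fps))
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      if (logical_tanimoto(fps[[ids[i]]], fps[[ids[j]]]) >= threshold) {
        want <- c(want, paste(ids[i], ids[j]))
      }
    }
  }
  expect_setequal(paste(got$source, got$target), want)
})

test_that("lowering the threshold never removes edges", {
  set.seed(59)
  fps <- stats::setNames(lapply(1:15, function(i) random_fingerprint(density = 0.5)),
                         letters[1:15])
  hi <- resemblance_edges(fps, threshold = 0.7)
  lo <- resemblance_edges(fps, threshold = 0.4)
  expect_true(all(paste(hi$source, hi$target) %in% paste(lo$source, lo$target)))
})

test_that("the similarity panel generator hits its targets or errors", {
  p1 <- generate_fingerprint_panel(3L, 1.0)[[1]]
  expect_identical(p1$a$on, p1$b$on)
  p0 <- generate_fingerprint_panel(3L, 0.0)[[1]]
  expect_length(intersect(p0$a$on, p0$b$on), 0L)
  expect_error(generate_fingerprint_panel(3L, 0.5, bits = 4L), "unreachable")
})
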