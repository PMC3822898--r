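make_segments <- function(n, labels = NULL) {
  lapply(seq_len(n) - 1L, function(i) {
    ann <- if (!is.null(labels))
      list(stimulus = labels[(i %% length(labels)) + 1L]) else list()
    new_segment(sprintf("s%d", i), annotations = ann)
  })
}

test_that("item predicates keep order: blocks with at least 10 segments", {
  blocks <- lapply(c(3, 10, 12), function(n) {
    b <- new_block(sprintf("b%d", n))
    for (i in seq_len(n)) attach_child(b, new_segment())
    b
  })
  ch <- filter_chain(list(filter_def(
    "at least 10 segments", "block", "item_predicate",
    "function(block) length(block$segments) >= 10")))
  kept <- apply_chain(ch, blocks)
  expect_equal(vapply(kept, function(b) b$name, character(1)), c("b10", "b12"))
})

test_that("list transforms reorder; chains are order-sensitive", {
  segs <- make_segments(8)
  nm <- function(x) vapply(x, function(s) s$name, character(1))
  every3 <- filter_def("every third", "segment", "list_transform",
                       "function(items) items[seq(1, length(items), 3)]")
  reverse <- filter_def("reverse", "segment", "list_transform",
                        "function(items) rev(items)")
  expect_equal(nm(apply_chain(filter_chain(list(every3)), segs[1:7])),
               c("s0", "s3", "s6"))
  rev_then_third <- apply_chain(filter_chain(list(reverse, every3)), segs)
  third_then_rev <- apply_chain(filter_chain(list(every3, reverse)), segs)
  expect_equal(nm(rev_then_third), c("s7", "s4", "s1"))
  expect_equal(nm(third_then_rev), c("s6", "s3", "s0"))
  expect_false(identical(nm(rev_then_third), nm(third_then_rev)))
})

test_that("exclusive groups keep at most one member active", {
  g <- filter_group("Stimulus", exclusive = TRUE, members = list(
    annotation_predicate("stimulus", "A", name = "A"),
    annotation_predicate("stimulus", "B", name = "B", active = FALSE)))
  ch <- filter_chain(list(g))
  actives <- function() {
    fs <- Filter(function(f) f$active, ch$entries[[1]]$members)
    vapply(fs, function(f) f$name, character(1))
  }
  expect_equal(actives(), "A")
  set_active(ch, "B", TRUE)
  expect_equal(actives(), "B")
  set_active(ch, "A", TRUE)
  expect_equal(actives(), "A")
  set_active(ch, "A", FALSE) # zero active members is allowed
  expect_length(actives(), 0)
  expect_error(set_active(ch, "no such filter"), "lookup error")
})

test_that("activation in non-exclusive groups leaves siblings untouched", {
  g <- filter_group("extras", exclusive = FALSE, members = list(
    annotation_predicate("stimulus", "A", name = "A"),
    annotation_predicate("stimulus", "B", name = "B")))
  ch <- filter_chain(list(g))
  set_active(ch, "B", TRUE)
  expect_true(all(vapply(ch$entries[[1]]$members, function(f) f$active,
                         logical(1))))
})

test_that("exclusivity survives random activation sequences", {
  ch <- filter_chain(list(filter_group("G", exclusive = TRUE, members = list(
    annotation_predicate("k", 1, name = "f1"),
    annotation_predicate("k", 2, name = "f2", active = FALSE),
    annotation_predicate("k", 3, name = "f3", active = FALSE)))))
  set.seed(4)
  for (i in 1:50) {
    set_active(ch, sample(c("f1", "f2", "f3"), 1), sample(c(TRUE, FALSE), 1))
    n_active <- sum(vapply(ch$entries[[1]]$members, function(f) f$active,
                           logical(1)))
    expect_lte(n_active, 1L)
  }
})

test_that("annotation predicates use strict typed equality", {
  segs <- make_segments(3, labels = c("A", "A", "B"))
  ch <- filter_chain(list(annotation_predicate("stimulus", "A")))
  expect_length(apply_chain(ch, segs), 2)
  expect_length(apply_chain(filter_chain(list(annotation_predicate("absent", 1))),
                            segs), 0)
  one <- new_segment("x", annotations = list(v = 1))
  expect_length(apply_chain(filter_chain(list(annotation_predicate("v", "1"))),
                            list(one)), 0) # "1" != 1: type-sensitive
  expect_length(apply_chain(filter_chain(list(annotation_predicate("v", 1L))),
                            list(one)), 1) # integer vs double both numeric
})

test_that("erroring filter bodies are skipped with a warning, list unchanged", {
  segs <- make_segments(4)
  boom <- filter_def("boom", "segment", "item_predicate",
                     "function(s) stop('broken')")
  fabricate <- filter_def("fabricate", "segment", "list_transform",
                          "function(items) c(items, items[1])")
  expect_warning(out <- apply_chain(filter_chain(list(boom)), segs),
                 "skipped")
  expect_identical(out, segs)
  expect_warning(out2 <- apply_chain(filter_chain(list(fabricate)), segs),
                 "not drawn from its input")
  expect_identical(out2, segs)
})

test_that("definition errors surface at construction and activation", {
  expect_error(filter_def("bad", "segment", "item_predicate",
                          "function(a, b) TRUE"), "exactly one argument")
  expect_error(filter_def("bad", "segment", "item_predicate", "42"),
               "not a function")
  expect_error(filter_def("bad", "segment", "item_predicate", "function(x) {"),
               "does not parse")
})

test_that("filter bodies cannot reach the filesystem", {
  f <- filter_def("sneaky", "segment", "item_predicate",
                  "function(s) is.null(readLines('/etc/hostname'))")
  expect_warning(out <- apply_chain(filter_chain(list(f)), make_segments(2)),
                 "skipped")
  expect_length(out, 2)
})

test_that("inactive chains are the identity; predicate chains keep subsequence order", {
  segs <- make_segments(6, labels = c("A", "B"))
  ch <- filter_chain(list(
    annotation_predicate("stimulus", "A", name = "A", active = FALSE),
    filter_def("reverse", "segment", "list_transform",
               "function(items) rev(items)", active = FALSE)))
  expect_identical(apply_chain(ch, segs), segs)
  ch2 <- filter_chain(list(
    annotation_predicate("stimulus", "A", name = "A"),
    filter_def("not s0", "segment", "item_predicate",
               "function(s) s$name != 's0'")))
  out <- apply_chain(ch2, segs)
  nm <- vapply(out, function(s) s$name, character(1))
  expect_equal(nm, c("s2", "s4")) # subsequence of the input order
})

test_that("filter files round trip through save and load", {
  chain <- filter_chain(list(
    filter_group("Stimulus", exclusive = TRUE, members = list(
      annotation_predicate("stimulus", "A", name = "Stimulus A"),
      annotation_predicate("stimulus", "B", name = "Stimulus B",
                           active = FALSE))),
    filter_def("Reverse segments", "segment", "list_transform",
               "function(items) rev(items)", active = FALSE),
    filter_def("Every third", "segment", "list_transform",
               "function(items) items[seq(1, length(items), 3)]")))
  f <- withr::local_tempfile(fileext = ".filters")
  save_filters(chain, f)
  loaded <- load_filters(f)
  expect_true(chains_equal(chain, loaded))
  expect_true(loaded$entries[[1]]$exclusive)
  # behavioral equality on the fixture
  segs <- make_segments(9, labels = c("A", "B", "C"))
  expect_equal(
    vapply(apply_chain(loaded, segs), function(s) s$name, character(1)),
    vapply(apply_chain(chain, segs), function(s) s$name, character(1)))
})

test_that("filter file loading rejects headerless functions, accepts empty files", {
  f <- withr::local_tempfile(fileext = ".filters")
  writeLines("function(x) TRUE", f)
  expect_error(load_filters(f), "before the first '#@ filter' header")
  writeLines(character(0), f)
  expect_length(load_filters(f)$entries, 0)
  writeLines(c("#@ filter", "#@ name only half a header", "function(x) TRUE"), f)
  expect_error(load_filters(f), "malformed metadata|missing metadata")
})
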