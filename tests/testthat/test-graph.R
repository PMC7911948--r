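test_that("the reference backbone has the epsilon-node shape", {
  g <- build_reference_graph(reference_sequence("ACG"))
  expect_equal(sum(g$nodes$kind == "base"), 3L)
  expect_equal(sum(g$nodes$kind == "epsilon"), 4L)
  expect_equal(length(g$edges$from), 8L)
  expect_identical(enumerate_generated(g)$sequences, "ACG")
  expect_equal(count_generated(g), 1)
  validate_graph(g)

  g1 <- build_reference_graph(reference_sequence("A"))
  expect_setequal(g1$nodes$id, c("source", "sink", "e:0", "e:1", "b:1:A"))
  expect_error(reference_sequence(""), "non-empty")
})

test_that("substitutions put parallel allele nodes behind the bottleneck", {
  ref <- reference_sequence("AACCT")
  g <- apply_substitution(build_reference_graph(ref),
                          call_substitution(3, c("T", "C")))
  expect_setequal(g$nodes$id[startsWith(g$nodes$id, "b:3:")],
                  c("b:3:T", "b:3:C"))
  expect_setequal(enumerate_generated(g)$sequences, c("AACCT", "AATCT"))
  validate_graph(g)

  # self-substitution (allele set = reference base) leaves the graph alone
  g0 <- build_reference_graph(ref)
  gs <- apply_substitution(g0, call_substitution(3, "C"))
  expect_setequal(gs$nodes$id, g0$nodes$id)
  expect_identical(enumerate_generated(gs)$sequences, "AACCT")

  # a non-reference-only call removes the reference allele everywhere
  gg <- build_mixture_graph(parse_variants("2G", ref))
  expect_false(any(grepl("^AA", enumerate_generated(gg)$sequences)))
  expect_identical(enumerate_generated(gg)$sequences, "AGCCT")

  expect_error(apply_substitution(gs, call_substitution(3, "G")),
               "already been modified")
})

test_that("insertions add a chain plus closing epsilon, skippable unless fixed", {
  ref <- reference_sequence("AACT")
  g <- build_mixture_graph(mixture_profile(ref, call_insertion(3, "C")))
  expect_setequal(enumerate_generated(g)$sequences, c("AACT", "AACCT"))
  expect_true("ei:3" %in% g$nodes$id)
  validate_graph(g)

  gf <- build_mixture_graph(mixture_profile(ref,
                                            call_insertion(3, "C", fixed = TRUE)))
  expect_identical(enumerate_generated(gf)$sequences, "AACCT")

  # same decoded insertion at either end of a homopolymer: same generated set
  ref2 <- reference_sequence("AACAAGT")
  ga <- build_mixture_graph(mixture_profile(ref2, call_insertion(3, "A")))
  gb <- build_mixture_graph(mixture_profile(ref2, call_insertion(5, "A")))
  expect_identical(enumerate_generated(ga)$sequences,
                   enumerate_generated(gb)$sequences)
})

test_that("deletions bypass the span; equivalent placements generate alike", {
  ref <- reference_sequence("AACAAGT")
  g4 <- build_mixture_graph(mixture_profile(ref, call_deletion(4)))
  g5 <- build_mixture_graph(mixture_profile(ref, call_deletion(5)))
  expect_identical(enumerate_generated(g4)$sequences,
                   enumerate_generated(g5)$sequences)
  expect_true("AACAGT" %in% enumerate_generated(g4)$sequences)
  validate_graph(g4)

  gfix <- build_mixture_graph(mixture_profile(ref,
                                              call_deletion(4, fixed = TRUE)))
  expect_identical(enumerate_generated(gfix)$sequences, "AACAGT")
  expect_false("b:4:A" %in% gfix$nodes$id)
})

test_that("an insertion and a following deletion coexist independently", {
  # insertion after 4 plus deletion of 5..6 on AACAAGT: all four
  # combinations of taking/skipping each indel are spellable
  ref <- reference_sequence("AACAAGT")
  prof <- mixture_profile(ref, dplyr::bind_rows(call_insertion(4, "T"),
                                                call_deletion(5, 6)))
  g <- build_mixture_graph(prof)
  validate_graph(g)
  expect_true(all(c("ei:4", "bi:4.1:T") %in% g$nodes$id))
  # bypass leaves from the insertion's closing epsilon (the node now
  # preceding base 5) so deletion and insertion choices are independent
  expect_true(any(graph_edges(g)$from == "ei:4" & graph_edges(g)$to == "e:6"))
  expect_setequal(
    enumerate_generated(g)$sequences,
    c("AACAAGT",    # neither indel
      "AACATAGT",   # insertion only
      "AACAT",      # deletion only
      "AACATT")     # both
  )
})

test_that("fixed deletions spanning an insertion anchor are rejected", {
  ref <- reference_sequence("AACAAGT")
  prof <- mixture_profile(ref, dplyr::bind_rows(call_insertion(5, "T"),
                                                call_deletion(5, 6, fixed = TRUE)))
  expect_error(build_mixture_graph(prof), "contradictory")
})

test_that("mixture graphs are deterministic and enumerable", {
  ref <- reference_sequence("AACCT")
  p <- parse_variants("3Y 4Y", ref)
  g1 <- build_mixture_graph(p)
  g2 <- build_mixture_graph(parse_variants("4Y 3Y", ref))
  expect_identical(g1, g2)
  expect_setequal(enumerate_generated(g1)$sequences,
                  c("AATTT", "AATCT", "AACTT", "AACCT"))
  expect_equal(count_generated(g1), 4)

  trunc <- enumerate_generated(g1, cap = 2)
  expect_true(trunc$truncated)

  we <- worked_example()
  gw <- build_mixture_graph(we$profile)
  expect_equal(enumerate_generated(gw)$count, 4L)
  expect_equal(count_generated(gw), 4)
})

test_that("path counting matches exhaustive enumeration up to 2^12", {
  for (k in c(1L, 5L, 12L)) {
    g <- build_mixture_graph(biallelic_profile(k))
    expect_equal(count_generated(g), 2^k)
    expect_equal(enumerate_generated(g, cap = 2^13)$count, 2^k)
  }
})

test_that("every construction keeps the epsilon bottleneck and acyclicity", {
  ref <- reference_sequence("AACAAGTTACG")
  profiles <- list(
    parse_variants("2R 5Y 7.1AC 9-", ref),
    parse_variants("3W 4.1T 5- 6-", ref),
    parse_variants("2G 3- 4-! 7K", ref)
  )
  # a profile may legally pair a retained deletion with others; fixed
  # deletions remove their span outright
  for (p in profiles) {
    g <- build_mixture_graph(p)
    expect_true(validate_graph(g))
  }
})

test_that("graphs round-trip through JSON and export to DOT", {
  ref <- reference_sequence("AACCT")
  g <- build_mixture_graph(parse_variants("3Y 4.1G", ref))
  json <- withr::local_tempfile(fileext = ".json")
  graph_to_json(g, json)
  g2 <- graph_from_json(json)
  expect_setequal(g2$nodes$id, g$nodes$id)
  expect_setequal(paste(g2$edges$from, g2$edges$to),
                  paste(g$edges$from, g$edges$to))
  expect_identical(g2$reference$bases, g$reference$bases)
  expect_identical(enumerate_generated(g2)$sequences,
                   enumerate_generated(g)$sequences)

  dot <- withr::local_tempfile(fileext = ".dot")
  graph_to_dot(g, dot)
  expect_true(any(grepl("digraph", readLines(dot))))
})

test_that("study plots and graph autoplot build without error", {
  ref <- reference_sequence("AACCT")
  g <- build_mixture_graph(parse_variants("3Y 4.1G", ref))
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
  model <- population_model(reference_length = 150, n_haplotypes = 30,
                            substitution_rate = 0.02)
  st <- run_study(simulate_database(model, seed = 3), 10, seed = 4)
  expect_s3_class(ggplot2::autoplot(st, "pairs"), "ggplot")
  expect_s3_class(ggplot2::autoplot(st, "consistent"), "ggplot")
  expect_s3_class(ggplot2::autoplot(st, "stats"), "ggplot")
})
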