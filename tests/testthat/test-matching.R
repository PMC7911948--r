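test_that("consistency agrees with the printed two-site examples", {
  g <- build_mixture_graph(parse_variants("3Y 4Y", reference_sequence("AACCT")))
  expect_true(all(is_consistent(g, c("AATCT", "AACCT", "AATTT", "AACTT"))))
  expect_false(any(is_consistent(g, c("AAGCT", "AACCA", "AACC", "AACCTT"))))

  ref <- reference_sequence("AACAAGT")
  gr <- build_reference_graph(ref)
  expect_true(is_consistent(gr, "AACAAGT"))
  expect_false(is_consistent(gr, "AACAAGA"))

  # either deletion encoding accepts the deleted string
  for (p in 4:5) {
    gd <- build_mixture_graph(mixture_profile(ref, call_deletion(p)))
    expect_true(is_consistent(gd, "AACAGT"))
    expect_true(is_consistent(gd, "AACAAGT"))
    expect_false(is_consistent(gd, "AACGT"))
  }
})

test_that("consistency equals membership in the generated set (oracle)", {
  set.seed(20)
  refs <- list(
    reference_sequence("AACAAGTTACGCA"),
    reference_sequence("TTGACCAATGGA")
  )
  profs <- c("2R 5Y 9.1C", "3W 6- 10K", "1Y 2- 3- 8M", "4.1AA 7S")
  for (ref in refs) {
    for (pv in profs) {
      g <- build_mixture_graph(parse_variants(pv, ref))
      gen <- enumerate_generated(g)$sequences
      for (s in gen) expect_true(is_consistent(g, s))
      # mutate members: mostly non-members, verdicts must match membership
      for (s in gen[seq_len(min(3, length(gen)))]) {
        chars <- strsplit(s, "")[[1]]
        i <- sample(length(chars), 1)
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
        mut <- paste(chars, collapse = "")
        expect_identical(as.logical(is_consistent(g, mut)), mut %in% gen)
      }
    }
  }
})

test_that("accepting paths enumerate spelling multiplicity", {
  g <- build_mixture_graph(parse_variants("3Y 4Y", reference_sequence("AACCT")))
  expect_length(accepting_paths(g, "AATCT")$paths, 1L)
  expect_length(accepting_paths(g, "AAGGT")$paths, 0L)

  # two independently-applied equivalent deletions: two accepting paths
  ref <- reference_sequence("AACAAGT")
  gd <- apply_deletion(apply_deletion(build_reference_graph(ref),
                                      call_deletion(4)),
                       call_deletion(5))
  ap <- accepting_paths(gd, "AACAGT")
  expect_length(ap$paths, 2L)
  expect_false(ap$truncated)
  # each path spells the haplotype: its base labels concatenate to it
  kind <- stats::setNames(gd$nodes$kind, gd$nodes$id)
  lab <- stats::setNames(gd$nodes$label, gd$nodes$id)
  for (p in ap$paths) {
    expect_identical(paste(lab[p][kind[p] == "base"], collapse = ""), "AACAGT")
  }
  ap1 <- accepting_paths(gd, "AACAGT", cap = 1)
  expect_length(ap1$paths, 1L)
  expect_true(ap1$truncated)
})

test_that("explanation requires joint node and edge coverage", {
  g <- build_mixture_graph(parse_variants("3Y 4Y", reference_sequence("AACCT")))
  # consistent individually, but nobody carries 4T
  r <- explains(g, c("AATCT", "AACCT"))
  expect_false(r$explained)
  expect_true(all(r$consistent))
  expect_true("b:4:T" %in% r$uncovered_nodes)
  # complementary pairs cover everything
  expect_true(explains(g, c("AATTT", "AACCT"))$explained)
  expect_true(explains(g, c("AATCT", "AACTT"))$explained)
  # order of haplotypes is irrelevant
  expect_true(explains(g, c("AACCT", "AATTT"))$explained)
  # an inconsistent haplotype sinks the set
  r2 <- explains(g, c("AATTT", "AAGGT"))
  expect_false(r2$explained)
  expect_equal(as.logical(r2$consistent), c(TRUE, FALSE))
})

test_that("two insertion carriers cannot explain an insertion mixture", {
  # mixture of AACT (reference) and AACCT (insertion): two copies of the
  # insertion haplotype cover all nodes but miss the skip edge
  g <- build_mixture_graph(mixture_profile(reference_sequence("AACT"),
                                           call_insertion(3, "C")))
  r <- explains(g, c("AACCT", "AACCT"))
  expect_false(r$explained)
  expect_length(r$uncovered_nodes, 0L)
  expect_true(any(grepl("^e:3 -> ei:3$", r$uncovered_edges)))
  expect_true(explains(g, c("AACCT", "AACT"))$explained)
})

test_that("a mixture with no ambiguity is explained by twin contributors", {
  ref <- reference_sequence("AACCT")
  g <- build_mixture_graph(parse_variants("3G", ref))
  s <- enumerate_generated(g)$sequences
  expect_length(s, 1L)
  expect_true(explains(g, c(s, s))$explained)
  fp <- feasible_pairs(g)
  expect_equal(nrow(fp), 1L)
  expect_identical(fp$hap1, fp$hap2)
})

test_that("feasible pairs match the brute-force explanation oracle", {
  for (k in 1:4) {
    g <- build_mixture_graph(biallelic_profile(k))
    fp <- feasible_pairs(g)
    got <- lapply(seq_len(nrow(fp)),
                  function(i) sort(c(fp$hap1[i], fp$hap2[i])))
    expected <- brute_force_pairs(g)
    expect_setequal(
      vapply(got, paste, character(1), collapse = "|"),
      vapply(expected, paste, character(1), collapse = "|")
    )
  }
  # indel mixture: oracle agreement where the closed form does not apply
  ref <- reference_sequence("AACAAGT")
  g <- build_mixture_graph(parse_variants("3W 5-", ref))
  fp <- feasible_pairs(g)
  got <- lapply(seq_len(nrow(fp)), function(i) sort(c(fp$hap1[i], fp$hap2[i])))
  expected <- brute_force_pairs(g)
  expect_setequal(
    vapply(got, paste, character(1), collapse = "|"),
    vapply(expected, paste, character(1), collapse = "|")
  )
})

test_that("pair counts follow the 2^(k-1) law for biallelic sites", {
  for (k in 1:8) {
    g <- build_mixture_graph(biallelic_profile(k))
    expect_equal(nrow(feasible_pairs(g)), 2^(k - 1))
    expect_equal(n_feasible_pairs(g), 2^(k - 1))
  }
})

test_that("widening an allele set never excludes a consistent haplotype", {
  set.seed(33)
  ref <- reference_sequence("AACAAGTTACGCA")
  base_prof <- parse_variants("2R 5Y 9M", ref)
  g <- build_mixture_graph(base_prof)
  gen <- enumerate_generated(g)$sequences
  wider <- mixture_profile(ref, dplyr::bind_rows(
    call_substitution(2, c("A", "G", "T")),
    call_substitution(5, c("A", "C", "T")),
    call_substitution(9, c("A", "C", "G"))
  ))
  gw <- build_mixture_graph(wider)
  expect_true(all(is_consistent(gw, gen)))
})

test_that("every simulated mixture is explained by its generating pair", {
  model <- population_model(reference_length = 200, n_haplotypes = 40,
                            substitution_rate = 0.02, indel_rate = 2e-3)
  db <- simulate_database(model, seed = 9)
  ref <- attr(db, "reference")
  set.seed(14)
  done <- 0
  while (done < 15) {
    ij <- sample(nrow(db), 2)
    mm <- make_mixture(db[ij[1], ], db[ij[2], ], ref)
    if (mm$status != "ok") next
    g <- build_mixture_graph(mm$profile)
    expect_true(explains(g, mm$sequences)$explained)
    done <- done + 1
  }
})
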