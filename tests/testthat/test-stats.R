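test_that("Clopper-Pearson upper limits match the closed form and oracle", {
  # zero successes: 1 - (alpha/2)^(1/n)
  for (n in c(1, 10, 100, 1e4)) {
    expect_equal(clopper_pearson_upper(0, n), 1 - 0.025^(1 / n),
                 tolerance = 1e-12)
  }
  # general cases against independent tail-inversion bisection
  for (case in list(c(1, 10), c(5, 10), c(3, 50), c(49, 50), c(17, 1000))) {
    expect_equal(clopper_pearson_upper(case[1], case[2]),
                 cp_upper_oracle(case[1], case[2]), tolerance = 1e-9)
  }
  # and against the exact binomial test's interval
  expect_equal(clopper_pearson_upper(7, 20),
               stats::binom.test(7, 20)$conf.int[2], tolerance = 1e-12)
  expect_equal(clopper_pearson_upper(12, 12), 1)
  # other confidence levels
  expect_equal(clopper_pearson_upper(0, 20, conf = 0.99),
               1 - 0.005^(1 / 20), tolerance = 1e-12)
  expect_error(clopper_pearson_upper(1, 0), "trials")
  expect_error(clopper_pearson_upper(5, 3), "successes")
})

test_that("the upper bound tightens with database size at fixed proportion", {
  ns <- c(10, 100, 1000, 10000)
  ub <- clopper_pearson_upper(ns / 10, ns)
  expect_true(all(diff(ub) < 0))
  expect_true(all(ub >= 0.1))
})

test_that("RMNE counts consistent records with its exact upper bound", {
  we <- worked_example()
  g <- build_mixture_graph(we$profile)
  db <- toy_db(we$ref, c("73G 154T 178A", "73G 154A 178C", "150T"))
  r <- rmne(db, g)
  expect_equal(r$n_consistent, 2L)
  expect_equal(r$p_rmne, 2 / 3)
  expect_equal(r$p_rmne_upper, cp_upper_oracle(2, 3), tolerance = 1e-9)
  expect_true(r$p_rmne <= r$p_rmne_upper)

  # nobody consistent (all keep the reference A at 73): closed-form bound
  db0 <- toy_db(we$ref, c("150T", "151G", "152C", "74T"))
  r0 <- rmne(db0, g)
  expect_equal(r0$p_rmne, 0)
  expect_equal(r0$p_rmne_upper, 1 - 0.025^(1 / 4), tolerance = 1e-12)

  # everyone equals the single generated haplotype of a fixed profile
  g1 <- build_mixture_graph(parse_variants("73G", we$ref))
  db1 <- toy_db(we$ref, rep("73G", 3))
  expect_equal(rmne(db1, g1)$p_rmne, 1)

  expect_error(rmne(db, g, population = "AF"), "available")
  expect_equal(tidy(r)$p_rmne, 2 / 3)
})

test_that("a single-source profile's RMNE is its database frequency", {
  we <- worked_example()
  g <- build_mixture_graph(parse_variants("73G 154T", we$ref))
  db <- toy_db(we$ref, c("73G 154T", "73G 154T", "73G", "152C", "73G 154T 178C"))
  target <- decode_haplotype(we$ref, parse_variants("73G 154T", we$ref))
  expect_equal(rmne(db, g)$p_rmne, mean(db$sequence == target))
})

test_that("masking the discriminating sites stops excluding anybody", {
  we <- worked_example()
  m <- mask_intervals(60, 190)  # covers all three variant sites
  prof <- mask_profile(we$profile, m)
  g <- build_mixture_graph(prof)
  db <- toy_db(we$ref, c("73G 154T 178A", "150T", "73A"))
  r <- rmne(db, g, mask = m)
  expect_equal(r$p_rmne, 1)
})

test_that("the naive likelihood is |U|! times the frequency product", {
  expect_equal(naive_likelihood(0.3), 0.3)
  expect_equal(naive_likelihood(c(0.1, 0.2)), 0.04)
  expect_equal(naive_likelihood(c(0.5, 0.5, 0.5)), 0.75)
  expect_error(naive_likelihood(1.2), "frequencies")
})

test_that("the total likelihood sums naive terms over explaining sets", {
  we <- worked_example()
  g <- build_mixture_graph(we$profile)
  # db frequencies: A and B are the generating pair (1/4 each)
  db <- toy_db(we$ref, c("73G 154T 178A", "73G 154A 178C",
                         "73G 154T 178C", "150T"))
  tl <- total_likelihood(db, g, u = 2)
  expect_equal(tl$likelihood, 2 * (1 / 4) * (1 / 4))
  expect_false(tl$empty_T)

  # one known: remaining unknown must be the complementary haplotype
  known <- db$sequence[1]
  tl1 <- total_likelihood(db, g, u = 1, knowns = known)
  expect_equal(tl1$likelihood, 1 / 4)

  # contributors absent from the database: empty sum
  db_miss <- toy_db(we$ref, c("150T", "151G"))
  tl0 <- total_likelihood(db_miss, g, u = 2)
  expect_equal(tl0$likelihood, 0)
  expect_true(tl0$empty_T)

  # duplicated records raise the haplotype frequency, not the set count
  db_dup <- toy_db(we$ref, c("73G 154T 178A", "73G 154T 178A",
                             "73G 154A 178C", "150T"))
  tl_dup <- total_likelihood(db_dup, g, u = 2)
  expect_equal(tl_dup$likelihood, 2 * (2 / 4) * (1 / 4))
})

test_that("GBC counts explaining combinations out of n choose u", {
  we <- worked_example()
  g <- build_mixture_graph(we$profile)
  db <- toy_db(we$ref, c("73G 154T 178A", "73G 154A 178C",
                         "73G 154T 178C", "150T"))
  gbc <- gbc_likelihood(db, g, u = 2)
  expect_equal(gbc$denominator, choose(4, 2))        # n(n-1)/2
  expect_equal(gbc$n_explaining, 1)                  # only the generating pair
  expect_equal(gbc$proportion, 1 / 6)
  expect_equal(gbc$upper_bound, cp_upper_oracle(1, 6), tolerance = 1e-9)

  # no explaining combination: zero-success bound over C(n, u) trials
  db_miss <- toy_db(we$ref, c("150T", "151G", "73G"))
  gbc0 <- gbc_likelihood(db_miss, g, u = 2)
  expect_equal(gbc0$proportion, 0)
  expect_equal(gbc0$upper_bound, 1 - 0.025^(1 / choose(3, 2)),
               tolerance = 1e-12)

  # one known contributor, one unknown drawn from the records
  gbc1 <- gbc_likelihood(db, g, u = 1, knowns = db$sequence[1])
  expect_equal(gbc1$denominator, 4)
  expect_equal(gbc1$n_explaining, 1)

  expect_error(gbc_likelihood(db, g, u = 5), "exceeds")
})

test_that("GBC denominator switches cover the sampling-design ambiguity", {
  we <- worked_example()
  g <- build_mixture_graph(we$profile)
  db <- toy_db(we$ref, c("73G 154T 178A", "73G 154A 178C", "150T"))
  wr <- gbc_likelihood(db, g, u = 2, with_replacement = TRUE)
  expect_equal(wr$denominator, choose(3 + 1, 2))
  expect_equal(wr$n_explaining, 1)

  ik <- gbc_likelihood(db, g, u = 1, knowns = db$sequence[1],
                       include_knowns = TRUE)
  expect_equal(ik$denominator, 4)  # known appended to the records
})

test_that("restricting the scan to non-excluded haplotypes changes nothing", {
  we <- worked_example()
  g <- build_mixture_graph(we$profile)
  db <- toy_db(we$ref, c("73G 154T 178A", "73G 154A 178C",
                         "73G 154T 178C", "150T", "73G"))
  gbc <- gbc_likelihood(db, g, u = 2)
  # unrestricted oracle: scan every pair of records
  cnt <- 0
  for (i in 1:(nrow(db) - 1)) {
    for (j in (i + 1):nrow(db)) {
      if (explains(g, db$sequence[c(i, j)])$explained) cnt <- cnt + 1
    }
  }
  expect_equal(gbc$n_explaining, cnt)
  # and the total likelihood is 0 exactly when the GBC numerator is 0
  tl <- total_likelihood(db, g, u = 2)
  expect_identical(tl$likelihood == 0, gbc$n_explaining == 0)
})
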