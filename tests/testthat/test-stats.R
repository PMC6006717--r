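test_that("identical samples are never significant; degenerate ties warn", {
  x <- c(1, 2, 3, 4, 5)
  rep0 <- two_sample_tests(x, x)
  expect_false(rep0$significant)
  expect_warning(
    repd <- two_sample_tests(rep(2, 5), rep(2, 6)),
    "degenerate"
  )
  expect_equal(repd$p_mannwhitney, 1)
  expect_equal(repd$p_ks, 1)
})

test_that("exact Mann-Whitney p on disjoint samples matches full enumeration", {
  a <- 1:10
  b <- 11:20
  rep1 <- two_sample_tests(a, b, tail = "less", exact = TRUE)
  expect_equal(rep1$p_mannwhitney, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(rep1$p_mannwhitney, oracle_mw_exact_less(a, b), tolerance = 1e-12)
  # the same enumeration oracle agrees on a non-extreme case
  set.seed(501)
  a2 <- rnorm(6)
  b2 <- rnorm(6) + 0.5
  rep2 <- two_sample_tests(a2, b2, tail = "less", exact = TRUE)
  expect_equal(rep2$p_mannwhitney, oracle_mw_exact_less(a2, b2), tolerance = 1e-12)
})

test_that("clearly shifted samples are significant by both tests", {
  set.seed(502)
  a <- rnorm(100, 1, 1)
  b <- rnorm(100, 0, 1)
  rep1 <- two_sample_tests(a, b, tail = "two")
  expect_true(rep1$significant)
  expect_lt(rep1$p_mannwhitney, 0.05)
  expect_lt(rep1$p_ks, 0.05)
  expect_equal(rep1$direction, "a_greater")
})

test_that("rank-based p-values are invariant under monotone transforms and swap", {
  set.seed(503)
  a <- rlnorm(30)
  b <- rlnorm(30) * 1.5
  r1 <- two_sample_tests(a, b)
  r2 <- two_sample_tests(log(a), log(b))
  expect_equal(r1$p_mannwhitney, r2$p_mannwhitney, tolerance = 1e-12)
  expect_equal(r1$p_ks, r2$p_ks, tolerance = 1e-12)
  r3 <- two_sample_tests(b, a)
  expect_equal(r1$p_mannwhitney, r3$p_mannwhitney, tolerance = 1e-12)
  expect_equal(r1$p_ks, r3$p_ks, tolerance = 1e-12)
})

test_that("the dual criterion requires both tests and records discrepancies", {
  base <- structure(
    list(
      p_mannwhitney = NA_real_, p_ks = NA_real_, tail = "two", alpha = 0.05,
      significant = NA, direction = "none", note = NA_character_,
      n_a = 10L, n_b = 10L, mw_exact = FALSE
    ),
    class = "stoich_test"
  )
  # the published discrepancy pattern: MW 0.20 vs KS 0.004 -> not significant
  r <- base
  r$p_mannwhitney <- 0.20
  r$p_ks <- 0.004
  r <- dual_criterion(r, alpha = 0.05)
  expect_false(r$significant)
  expect_match(r$note, "believing Mann-Whitney")

  r2 <- base
  r2$p_mannwhitney <- 0.001
  r2$p_ks <- 0.001
  expect_true(dual_criterion(r2, 0.05)$significant)

  r3 <- base
  r3$p_mannwhitney <- 0.049
  r3$p_ks <- 0.051
  expect_false(dual_criterion(r3, 0.05)$significant)

  td <- tidy(r)
  expect_equal(nrow(td), 1)
  expect_false(td$significant)
  expect_equal(glance(r), td)
})

test_that("location screens flag injected enrichment and skip tiny groups", {
  set.seed(504)
  n <- 60
  vals <- tibble::tibble(
    location = rep(c("cytoskeleton", "cytoplasm", "nucleus"), each = n),
    characteristic = "acidic",
    value = c(rnorm(n, 0.15, 0.02), rnorm(n, 0.10, 0.02), rnorm(n, 0.10, 0.02))
  )
  out <- screen_locations(vals, alpha = 0.01, characteristics = "acidic")
  # the enriched location is the only one significantly ELEVATED over the
  # pooled rest (unenriched locations read as lower, their rest being a
  # mixture that contains the enriched cell)
  elevated <- out %>% dplyr::filter(significant, direction == "a_greater")
  expect_equal(elevated$location, "cytoskeleton")
  # a single location yields an empty screen
  one <- vals %>% dplyr::filter(location == "nucleus")
  expect_equal(nrow(screen_locations(one)), 0)
  # undersized locations are skipped with a warning
  small <- dplyr::bind_rows(vals, tibble::tibble(
    location = "golgi", characteristic = "acidic", value = 0.1
  ))
  expect_warning(out2 <- screen_locations(small, characteristics = "acidic"), "golgi")
  expect_false("golgi" %in% out2$location)
})

test_that("screens accept records and all-pairs mode", {
  spec <- synthetic_spec(
    locations = c("cytoskeleton", "cytoplasm", "nucleus"),
    n_per_cell = 25, dual_fraction = 0
  )
  prot <- generate_proteomes(spec, seed = 505)
  out <- screen_locations(prot$records,
    alpha = 0.01,
    characteristics = c("acidic", "basic"), mode = "all_pairs"
  )
  expect_equal(nrow(out), 2 * choose(3, 2))
  expect_true(all(c("location", "other") %in% names(out)))
})

test_that("Tukey comparisons resolve which group is shifted", {
  set.seed(506)
  groups <- list(
    g1 = rnorm(50, 0, 1),
    g2 = rnorm(50, 0, 1),
    g3 = rnorm(50, 3, 1) # shifted by 3 sigma
  )
  out <- tukey_multigroup(groups)
  expect_equal(nrow(out), choose(3, 2)) # C(k,2) rows
  hit3 <- out %>% dplyr::filter(group_1 == "g3" | group_2 == "g3")
  expect_true(all(hit3$p_adj < 0.05))
  other <- out %>% dplyr::filter(group_1 != "g3" & group_2 != "g3")
  expect_true(all(other$p_adj > 0.05))
  # identical groups: nothing significant
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_true(all(tukey_multigroup(same)$p_adj > 0.99))
  expect_error(tukey_multigroup(same[1:2]), "two_sample_tests")
})

test_that("relation tallies count categories with 1-decimal percentages", {
  path <- system.file("extdata", "relations_synthetic.tsv", package = "stoichioprot")
  out <- tally_relations(path)
  expect_equal(sum(out$n), 25)
  expect_equal(sum(out$percentage), 100, tolerance = 0.1)
  expect_equal(out$relation[1], "binding/association") # largest category first
  expect_equal(out$percentage, round(100 * out$n / sum(out$n), 1))
  # single-row table is 100%
  single <- tally_relations(tibble::tibble(
    protein = "ACT1", partner = "PFN1", relation = "activation"
  ))
  expect_equal(single$percentage, 100.0)
  # unknown types go to "other" with a warning
  expect_warning(
    odd <- tally_relations(tibble::tibble(
      protein = "A", partner = "B", relation = c("activation", "teleportation")
    )),
    "teleportation"
  )
  expect_true("other" %in% odd$relation)
  # per-protein breakdown
  per <- tally_relations(path, by = "protein")
  act1 <- per %>% dplyr::filter(protein == "ACT1")
  expect_equal(sum(act1$percentage), 100, tolerance = 0.1)
})
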