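test_that("side-chain table matches free-amino-acid formulas minus water and backbone", {
  tbl <- side_chain_counts()
  for (aa in AA_STANDARD) {
    expected <- oracle_side_chain(aa)
    row <- tbl[tbl$aa == aa, c("C", "H", "N", "O", "S")]
    expect_equal(unlist(row), expected, info = aa)
  }
  # counts bounded by 0..10, glycine and sulfur carriers as expected
  expect_true(all(as.matrix(tbl[, -1]) >= 0 & as.matrix(tbl[, -1]) <= 10))
  expect_equal(unlist(side_chain_counts("G")[, -1]), c(C = 0, H = 1, N = 0, O = 0, S = 0))
  expect_equal(side_chain_counts("K")$H, 10)
  s_carriers <- tbl$aa[tbl$S > 0]
  expect_setequal(s_carriers, c("C", "M"))
  expect_error(side_chain_counts("X"), "Nonstandard")
})

test_that("shipped side-chain TSV matches the in-code table", {
  path <- system.file("extdata", "side_chain_elements.tsv", package = "stoichioprot")
  shipped <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(shipped), as.data.frame(side_chain_counts()))
})

test_that("element content equals the per-residue weighted sum", {
  expect_equal(element_content("GGGG", "H"), 1.0)
  expect_equal(element_content("AG", "S"), 0.0)
  expect_equal(element_content("CM", "S"), 1.0)
  expect_error(element_content("XXB", "C"), "no standard residues")
})

test_that("element content times length equals brute-force atom counting", {
  set.seed(101)
  seqs <- random_protein(50)
  for (el in c("C", "H", "N", "O", "S")) {
    got <- element_content(seqs, el) * nchar(seqs)
    want <- vapply(seqs, oracle_atom_count, numeric(1), element = el)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("charged content is the class fraction", {
  expect_equal(charged_content("DE", "acidic"), 1.0)
  expect_equal(charged_content("DEKRH", "basic"), 0.6)
  expect_equal(charged_content("GGGG", "acidic"), 0.0)
  set.seed(102)
  seqs <- random_protein(30)
  expect_equal(
    charged_content(seqs, "acidic") * nchar(seqs),
    unname(vapply(seqs, oracle_charged_count, numeric(1), which = "acidic"))
  )
})

test_that("characteristics are invariant under sequence duplication and bounded", {
  set.seed(103)
  seqs <- random_protein(20)
  once <- sequence_characteristics(seqs)
  twice <- sequence_characteristics(paste0(seqs, seqs))
  for (ch in c("C", "H", "O", "N", "S", "acidic", "basic")) {
    expect_equal(once[[ch]], twice[[ch]], tolerance = 1e-12)
  }
  expect_true(all(once$acidic + once$basic <= 1))
  expect_true(all(as.matrix(once[c("C", "H", "O", "N", "S")]) >= 0 &
    as.matrix(once[c("C", "H", "O", "N", "S")]) <= 10))
})

test_that("sequences with many nonstandard residues are dropped with a warning", {
  expect_warning(
    out <- sequence_characteristics(c(ok = "MKLVDE", bad = "XXXXXXMK")),
    "nonstandard"
  )
  expect_equal(out$id, "ok")
  # a tolerable fraction is excluded from numerator and denominator
  quiet <- sequence_characteristics(c(s = paste0(strrep("G", 39), "X")))
  expect_equal(quiet$L, 39L)
  expect_equal(quiet$H, 1.0)
})

test_that("group profiles are unweighted means, order-invariant", {
  records <- make_records(
    accession = c("A1", "A2"),
    species = "Homo sapiens",
    sequence = c("DGGGG", "DDGGG"), # acidic 0.2 and 0.4
    location = "nucleus",
    experimental = TRUE
  )
  prof <- proteome_profile(records)
  acidic <- prof$mean[prof$characteristic == "acidic"]
  expect_equal(acidic, 0.3)
  expect_equal(unique(prof$n), 2L)
  # singleton group returns its own value; permutation leaves means unchanged
  single <- proteome_profile(records[1, ])
  expect_equal(single$mean[single$characteristic == "acidic"], 0.2)
  expect_equal(proteome_profile(records[2:1, ]), prof)
  expect_error(proteome_profile(records[0, ]), "No located records")
})

test_that("nitrogen content rises as an affine function of basic content when N/Q/W are fixed", {
  base <- setNames(rep(0.05, 20), AA_STANDARD)
  deltas <- seq(0, 0.06, by = 0.02)
  rows <- lapply(deltas, function(d) {
    freq <- base
    freq[c("K", "R", "H")] <- freq[c("K", "R", "H")] + d / 3
    freq[c("A", "G", "L")] <- freq[c("A", "G", "L")] - d / 3
    expected_characteristics(freq)
  })
  rows <- dplyr::bind_rows(rows)
  # strictly increasing and exactly affine in the basic content
  expect_true(all(diff(rows$N) > 0))
  fit <- lm(N ~ basic, data = rows)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
})

test_that("reference normalization classifies ratios around 1", {
  out <- normalize_to_reference(c(0.229911306, 0.114955653, 0.103), 0.114955653)
  expect_equal(out$ratio[1], 2.0)
  expect_equal(out$ratio[2], 1.0)
  expect_equal(out$label, c("higher", "equal", "lower"))
  expect_error(normalize_to_reference(0.1, 0), "reference")
})

test_that("single-dual profile correlation recovers known relationships", {
  cells <- tidyr::expand_grid(
    species = c("s1", "s2"),
    location = c("l1", "l2", "l3")
  )
  base <- cells %>%
    dplyr::mutate(characteristic = "acidic", mean = c(.10, .12, .14, .11, .13, .15), n = 5L)
  # identical profiles: r = 1
  expect_equal(correlate_single_dual(base, base)$r, 1.0)
  # exactly negated deviations from the mean: r = -1
  negated <- base %>% dplyr::mutate(mean = 2 * mean(mean) - mean)
  expect_equal(correlate_single_dual(base, negated)$r, -1.0)
  # shared signal plus independent noise, checked against the closed form
  set.seed(104)
  signal <- rnorm(20, 0.12, 0.02)
  x <- signal + rnorm(20, 0, 0.005)
  y <- signal + rnorm(20, 0, 0.005)
  grid <- tidyr::expand_grid(species = sprintf("s%02d", 1:20), location = "l1")
  px <- grid %>% dplyr::mutate(characteristic = "acidic", mean = x, n = 5L)
  py <- grid %>% dplyr::mutate(characteristic = "acidic", mean = y, n = 5L)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_single_dual(px, py)$r, direct, tolerance = 1e-12)
  # too few matched cells is flagged, not an error
  few <- correlate_single_dual(base[1:2, ], base[1:2, ])
  expect_false(few$computable)
  expect_true(is.na(few$r))
})
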