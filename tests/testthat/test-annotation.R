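test_that("FASTA + annotation table parse into one record per protein", {
  fasta <- tempfile(fileext = ".fasta")
  ann <- tempfile(fileext = ".tsv")
  writeLines(c(
    ">P00001 some description", "MKLVDE",
    ">P00002", "GGGGCC", ">P00003", "DDEEKK"
  ), fasta)
  readr::write_tsv(tibble::tibble(
    accession = c("P00001", "P00002"),
    species = "Homo sapiens",
    location = c("Nucleus", "Cytoskeleton"),
    experimental = c(TRUE, FALSE)
  ), ann)

  records <- read_protein_records(fasta, ann)
  expect_equal(dplyr::n_distinct(records$accession), 3)
  # evidence flag passes through verbatim
  expect_true(records$experimental[records$accession == "P00001"])
  expect_false(records$experimental[records$accession == "P00002"])
  # the unannotated protein is kept with an empty location
  p3 <- records[records$accession == "P00003", ]
  expect_true(is.na(p3$location))
  expect_equal(p3$sequence, "DDEEKK")
})

test_that("annotation rows referencing missing accessions raise a named error", {
  fasta <- tempfile(fileext = ".fasta")
  writeLines(c(">P00001", "MKLV"), fasta)
  ann <- tibble::tibble(
    accession = "Q99999", species = "Homo sapiens",
    location = "nucleus", experimental = TRUE
  )
  expect_error(read_protein_records(fasta, ann), "Q99999")
})

test_that("duplicate accessions are rejected", {
  expect_error(
    protein_records(c(A1 = "MK", A1 = "ML")),
    "Duplicate accession"
  )
})

test_that("records round-trip through FASTA + TSV unchanged", {
  records <- make_records(
    accession = c("A1", "A2", "A2", "A3"),
    species = c("Homo sapiens", "Mus musculus", "Mus musculus", "Homo sapiens"),
    sequence = c("MKLVDE", "GGGGCC", "GGGGCC", "DDEEKK"),
    location = c("nucleus", "golgi", "membrane", NA),
    experimental = c(TRUE, TRUE, FALSE, NA)
  )
  fasta <- tempfile(fileext = ".fasta")
  ann <- tempfile(fileext = ".tsv")
  write_protein_records(records, fasta, ann)
  back <- read_protein_records(fasta, ann)
  expect_equal(
    dplyr::arrange(back, accession, location),
    dplyr::arrange(records, accession, location)
  )
})

test_that("evidence filter keeps only experimentally located proteins", {
  records <- make_records(
    accession = c("A1", "A1", "A2", "A3"),
    species = "Homo sapiens",
    sequence = c("MKLV", "MKLV", "GGGG", "DDEE"),
    location = c("nucleus", "golgi", "membrane", NA),
    experimental = c(TRUE, FALSE, FALSE, NA)
  )
  out <- select_experimental(records)
  # A1 keeps only its experimental label; A2 (predicted only) and A3 drop out
  expect_equal(out$accession, "A1")
  expect_equal(out$location, "nucleus")
  # idempotent; empty input gives empty output
  expect_equal(select_experimental(out), out)
  expect_equal(nrow(select_experimental(records[0, ])), 0)
})

test_that("location labels normalize to the canonical nine-name set", {
  expect_equal(normalize_location_labels("Nucleus"), "nucleus")
  expect_equal(normalize_location_labels("  cell   membrane "), "membrane")
  expect_equal(
    normalize_location_labels("Multi-pass membrane protein"),
    "transmembrane"
  )
  expect_true(is.na(normalize_location_labels("flagellum")))
})

test_that("cytoskeleton co-annotations collapse to cytoskeleton", {
  records <- make_records(
    accession = c("A1", "A1", "A2", "A3", "A3", "A4", "A4"),
    species = "Homo sapiens",
    sequence = c("MK", "MK", "ML", "MM", "MM", "MN", "MN"),
    location = c(
      "cytoskeleton", "nucleus", "nucleus",
      "golgi", "membrane", "cytoskeleton", "cytoplasm"
    ),
    experimental = TRUE
  )
  out <- normalize_locations(records)
  locs <- function(acc) sort(out$location[out$accession == acc])
  expect_equal(locs("A1"), "cytoskeleton")
  expect_equal(locs("A2"), "nucleus")
  expect_equal(locs("A3"), c("golgi", "membrane")) # dual preserved
  expect_equal(locs("A4"), "cytoskeleton")
  # idempotent
  expect_equal(normalize_locations(out), out)
})

test_that("unmapped labels drop with a warning; fully unmapped records persist as NA", {
  records <- make_records(
    accession = c("A1", "A2", "A2"),
    species = "Homo sapiens",
    sequence = c("MK", "ML", "ML"),
    location = c("flagellum", "nucleus", "vacuole"),
    experimental = TRUE
  )
  expect_warning(out <- normalize_locations(records), "flagellum")
  expect_true(is.na(out$location[out$accession == "A1"]))
  expect_equal(out$location[out$accession == "A2"], "nucleus")
})

test_that("single/dual partition conserves every protein exactly once", {
  records <- make_records(
    accession = c("A1", "A2", "A2", "A3", "A4", "A4"),
    species = "Homo sapiens",
    sequence = c("MK", "ML", "ML", "MM", "MN", "MN"),
    location = c("nucleus", "golgi", "membrane", NA, "cytoskeleton", "cytoplasm"),
    experimental = c(TRUE, TRUE, TRUE, NA, TRUE, TRUE)
  )
  part <- partition_single_dual(normalize_locations(records))
  cls <- part %>%
    dplyr::distinct(accession, location_class)
  expect_equal(nrow(cls), 4) # each accession in exactly one class
  expect_equal(cls$location_class[cls$accession == "A1"], "single")
  expect_equal(cls$location_class[cls$accession == "A2"], "dual")
  expect_equal(cls$location_class[cls$accession == "A3"], "excluded")
  # collapses to cytoskeleton, hence single
  expect_equal(cls$location_class[cls$accession == "A4"], "single")
  # dual records appear under every carried location
  expect_equal(sort(part$location[part$accession == "A2"]), c("golgi", "membrane"))
})

test_that("partition conservation holds on generated proteomes", {
  spec <- synthetic_spec(n_per_cell = 8, dual_fraction = 0.3)
  prot <- generate_proteomes(spec, seed = 11)
  part <- partition_single_dual(normalize_locations(select_experimental(prot$records)))
  cls <- part %>% dplyr::distinct(accession, location_class)
  expect_equal(nrow(cls), dplyr::n_distinct(prot$records$accession))
  expect_true(all(table(cls$accession) == 1))
})

test_that("species filter applies a strict count threshold", {
  records <- make_records(
    accession = sprintf("A%03d", 1:601),
    species = c(rep("Homo sapiens", 301), rep("Bos taurus", 300)),
    sequence = "MKLV",
    location = "nucleus",
    experimental = TRUE
  )
  kept <- select_species(records, min_count = 300)
  expect_equal(unique(kept$species), "Homo sapiens") # 301 > 300, 300 is dropped
  all_kept <- select_species(records, min_count = 0)
  expect_setequal(unique(all_kept$species), c("Homo sapiens", "Bos taurus"))
})
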