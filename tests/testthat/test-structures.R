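cpx_spec <- synthetic_spec(complexes = list(
  n = 4, chain_length = 25, interface_size = 6, glu_delta = 0.04,
  spacing = 3.8, offset = 4.0
))

test_that("generated complexes re-parse losslessly", {
  cpx <- generate_complexes(cpx_spec, seed = 401)
  st <- read_structure(cpx$files[1])
  expect_setequal(unique(st$chain), c("A", "B"))
  expect_equal(sort(unique(st$resno)), 1:25)
  # residue types round-trip through the PDB writer/reader
  designated <- cpx$interface %>% dplyr::filter(complex_id == st$complex_id[1])
  merged <- dplyr::inner_join(designated, st, by = c("chain", "resno"))
  expect_equal(merged$aa.x, merged$aa.y)
})

test_that("interface extraction equals brute-force distance checking", {
  cpx <- generate_complexes(cpx_spec, seed = 402)
  for (f in cpx$files[1:2]) {
    st <- read_structure(f)
    for (cutoff in c(4.0, 4.5, 6.0)) {
      got <- extract_interface_residues(st, "A", "B", cutoff)
      want <- oracle_interface(st, "A", "B", cutoff)
      expect_equal(nrow(got), nrow(want))
      expect_setequal(
        paste(got$chain, got$resno),
        paste(want$chain, want$resno)
      )
    }
  }
})

test_that("extraction is symmetric in chain order and monotone in the cutoff", {
  cpx <- generate_complexes(cpx_spec, seed = 403)
  st <- read_structure(cpx$files[1])
  ab <- extract_interface_residues(st, "A", "B", 4.5)
  ba <- extract_interface_residues(st, "B", "A", 4.5)
  expect_equal(
    dplyr::arrange(ab, chain, resno),
    dplyr::arrange(ba, chain, resno)
  )
  narrow <- extract_interface_residues(st, "A", "B", 4.0)
  wide <- extract_interface_residues(st, "A", "B", 6.0)
  expect_true(all(paste(narrow$chain, narrow$resno) %in% paste(ab$chain, ab$resno)))
  expect_true(all(paste(ab$chain, ab$resno) %in% paste(wide$chain, wide$resno)))
  expect_error(extract_interface_residues(st, "A", "Z", 4.5), "Chain Z")
})

test_that("far-apart chains have empty interfaces", {
  cpx <- generate_complexes(cpx_spec, seed = 404)
  st <- read_structure(cpx$files[1])
  st_moved <- st %>% dplyr::mutate(y = ifelse(chain == "B", y + 100, y))
  out <- extract_interface_residues(st_moved, "A", "B", 4.5)
  expect_equal(nrow(out), 0)
})

test_that("interface composition reports the Table-style categories", {
  iface <- tibble::tibble(
    complex_id = "c1", chain_pair = "A:B",
    chain = c("A", "A", "B", "B"), resno = c(1, 2, 1, 2),
    aa = c("E", "E", "K", "G")
  )
  comp <- interface_composition(iface)
  expect_equal(comp$per_interface$glu, 0.5)
  expect_equal(comp$per_interface$basic, 0.25)
  expect_equal(comp$per_interface$acidic, 0.5)
  gly <- iface %>% dplyr::mutate(aa = "G")
  comp0 <- interface_composition(gly)
  expect_equal(comp0$per_interface$glu, 0)
  expect_equal(comp0$per_interface$acidic + comp0$per_interface$basic, 0)
})

test_that("interface vs non-interface split conserves residues", {
  cpx <- generate_complexes(cpx_spec, seed = 405)
  structures <- lapply(cpx$files, read_structure)
  interfaces <- extract_all_interfaces(structures, 4.5)
  paired <- interface_vs_noninterface(structures, interfaces)
  totals <- paired %>%
    dplyr::group_by(complex_id) %>%
    dplyr::summarise(n = sum(n_residues))
  expect_true(all(totals$n == 50)) # 2 chains x 25 residues
  # constructed contrast: Glu-only interface vs Gly-only remainder
  toy <- tibble::tibble(
    complex_id = "t1",
    chain = rep(c("A", "B"), each = 3),
    resno = rep(1:3, 2),
    resid = "GLY", aa = c("E", "G", "G", "E", "G", "G"),
    atom = "CA",
    x = c(0, 50, 100, 0, 50, 100), y = c(0, 0, 0, 3, 100, 100), z = 0
  )
  ifc <- extract_interface_residues(toy, "A", "B", 4.5)
  expect_equal(sort(unique(ifc$aa)), "E")
  pv <- interface_vs_noninterface(list(toy), ifc)
  expect_equal(pv$glu[pv$region == "interface"], 1.0)
  expect_equal(pv$glu[pv$region == "non_interface"], 0.0)
  # empty interfaces: non-interface content equals whole-complex content
  pv0 <- interface_vs_noninterface(list(toy), ifc[0, ])
  expect_equal(
    pv0$glu[pv0$region == "non_interface"],
    mean(toy$aa == "E")
  )
})

test_that("random complex sampling excludes labels and is uniform", {
  pool <- paste0("c", 1:8)
  out <- sample_random_complexes(pool, 3, seed = 9, exclude = c("c1", "c2"))
  expect_false(any(out %in% c("c1", "c2")))
  expect_identical(out, sample_random_complexes(pool, 3, seed = 9, exclude = c("c1", "c2")))
  expect_error(sample_random_complexes(pool, 9, seed = 1), "admissible")
  # frequencies over many singleton draws from a 5-complex pool: multinomial 3-sigma
  pool5 <- paste0("p", 1:5)
  draws <- vapply(1:10000, function(i) sample_random_complexes(pool5, 1, seed = i), character(1))
  freq <- table(factor(draws, levels = pool5))
  expected <- 10000 / 5
  sigma <- sqrt(10000 * 0.2 * 0.8)
  expect_true(all(abs(freq - expected) <= 3 * sigma))
})

test_that("query mapping labels complexes through the search engine", {
  cpx <- generate_complexes(cpx_spec, seed = 406)
  structures <- lapply(cpx$files, read_structure)
  chains <- chain_sequences(structures[[1]])
  queries <- c(q1 = unname(chains[1]))
  labelled <- map_queries_to_structures(queries, structures, max_evalue = 1e-10)
  expect_true(structures[[1]]$complex_id[1] %in% labelled)
  set.seed(407)
  unrelated <- c(qx = random_protein(1, c(40, 40)))
  expect_length(
    map_queries_to_structures(unrelated, structures, max_evalue = 1e-10), 0
  )
})

test_that("precomputed interface tables are accepted as direct input", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    complex_id = "1abc", chain = c("A", "B"), resno = c(10L, 20L), aa = c("E", "K")
  ), path)
  tbl <- read_interface_table(path)
  comp <- interface_composition(tbl %>% dplyr::mutate(chain_pair = "A:B"))
  expect_equal(comp$pooled$glu, 0.5)
})
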