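# Synthetic datasets with the statistical structure the pipeline assumes.
#
# Sequences are i.i.d. draws from per-location amino-acid frequency vectors:
# a documented uniform baseline (0.05 per amino acid) plus named additive
# biases. Boost mass is taken proportionally from the amino acids that are
# neither charged nor cysteine, so an acidic boost leaves the expected basic
# content untouched (and vice versa) -- that orthogonality is what makes
# parameter recovery a clean acceptance surface. Every generator is a pure
# function of (spec, seed), and each emits a truth manifest from which the
# expected pipeline outputs are computable in closed form.

# amino acids that absorb compensation mass (non-charged, non-cysteine)
.COMPENSATION_POOL <- setdiff(AA_STANDARD, c(AA_ACIDIC, AA_BASIC, "C"))

#' Build a synthetic-data specification
#'
#' @param species Character vector of species names.
#' @param locations Character vector of location labels.
#' @param n_per_cell Single-location sequences per (species, location) cell.
#' @param biases Named list: location -> named numeric vector of additive
#'   frequency boosts (`acidic` split over D/E, `basic` over K/R/H, `cys`
#'   on C, `glu` on E). Locations absent from the list use the baseline.
#' @param baseline Baseline amino-acid frequency vector (20 values, named by
#'   one-letter code, summing to 1). Default: uniform 0.05.
#' @param length_meanlog,length_sdlog Log-normal sequence-length parameters.
#' @param length_range Lengths are clamped to this range.
#' @param dual_fraction Fraction (of `n_per_cell`, per location) of
#'   additional dual-location proteins per species.
#' @param ppi List: `n_pairs`, `complementary_fraction`, `boost` (frequency
#'   boost of the acidic/basic members of a complementary pair).
#' @param complexes List: `n`, `chain_length`, `interface_size`, `glu_delta`,
#'   `spacing` (A between consecutive CA atoms), `offset` (A between paired
#'   interface residues; must be below the extraction cutoff).
#' @return A validated `stoich_spec` list.
#' @export
synthetic_spec <- function(species = "Synthetic sapiens",
                           locations = c(
                             "cytoskeleton", "cytoplasm",
                             "nucleus", "extracellular"
                           ),
                           n_per_cell = 40,
                           biases = list(
                             cytoskeleton = c(acidic = 0.05),
                             nucleus = c(basic = 0.05),
                             extracellular = c(cys = 0.03)
                           ),
                           baseline = NULL,
                           length_meanlog = 5.5, length_sdlog = 0.4,
                           length_range = c(50, 5000),
                           dual_fraction = 0.2,
                           ppi = list(
                             n_pairs = 250,
                             complementary_fraction = 0.5,
                             boost = 0.10
                           ),
                           complexes = list(
                             n = 40, chain_length = 60,
                             interface_size = 15, glu_delta = 0.04,
                             spacing = 3.8, offset = 4.0
                           )) {
  if (is.null(baseline)) {
    baseline <- setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (missing(biases)) {
    # default biases apply only where their location was kept
    biases <- biases[intersect(names(biases), locations)]
  }
  spec <- structure(
    list(
      species = species, locations = locations, n_per_cell = n_per_cell,
      biases = biases, baseline = baseline,
      length_meanlog = length_meanlog, length_sdlog = length_sdlog,
      length_range = length_range, dual_fraction = dual_fraction,
      ppi = ppi, complexes = complexes
    ),
    class = "stoich_spec"
  )
  validate_spec(spec)
  spec
}

#' Validate a synthetic-data specification
#'
#' @param spec A `stoich_spec` list.
#' @return The spec, invisibly; errors list every violation found.
#' @export
validate_spec <- function(spec) {
  problems <- character()
  bl <- spec$baseline
  if (!setequal(names(bl), AA_STANDARD)) {
    problems <- c(problems, "baseline must be named by the 20 standard amino acids")
  } else {
    if (any(bl < 0)) problems <- c(problems, "baseline frequencies must be nonnegative")
    if (abs(sum(bl) - 1) > 1e-9) problems <- c(problems, "baseline must sum to 1 (within 1e-9)")
  }
  if (spec$n_per_cell < 0) problems <- c(problems, "n_per_cell must be >= 0")
  if (spec$dual_fraction < 0 || spec$dual_fraction > 1) {
    problems <- c(problems, "dual_fraction must lie in [0, 1]")
  }
  bad_bias_loc <- setdiff(names(spec$biases), spec$locations)
  if (length(bad_bias_loc) > 0) {
    problems <- c(problems, paste0(
      "biases refer to unknown location(s): ", paste(bad_bias_loc, collapse = ", ")
    ))
  }
  for (loc in spec$locations) {
    freq <- try(location_frequencies(spec, loc), silent = TRUE)
    if (inherits(freq, "try-error")) {
      problems <- c(problems, paste0("frequency vector for ", loc, " is invalid"))
    }
  }
  cf <- spec$ppi$complementary_fraction
  if (is.null(cf) || cf < 0 || cf > 1) {
    problems <- c(problems, "ppi$complementary_fraction must lie in [0, 1]")
  }
  cx <- spec$complexes
  if (!is.null(cx) && cx$interface_size > cx$chain_length) {
    problems <- c(problems, "complexes$interface_size exceeds chain_length")
  }
  if (length(problems) > 0) {
    abort(paste0(
      "Invalid synthetic spec:\n",
      paste0("  - ", problems, collapse = "\n")
    ))
  }
  invisible(spec)
}

# apply named additive boosts to a frequency vector; compensation mass is
# removed proportionally from the non-charged, non-cysteine pool
.boost_frequencies <- function(freq, boosts) {
  if (length(boosts) == 0) {
    return(freq)
  }
  known <- c("acidic", "basic", "cys", "glu")
  bad <- setdiff(names(boosts), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown bias name(s): ", paste(bad, collapse = ", ")))
  }
  add <- setNames(rep(0, 20), AA_STANDARD)
  if (!is.null(boosts["acidic"]) && !is.na(boosts["acidic"])) {
    add[AA_ACIDIC] <- add[AA_ACIDIC] + boosts[["acidic"]] / length(AA_ACIDIC)
  }
  if (!is.na(boosts["basic"])) {
    add[AA_BASIC] <- add[AA_BASIC] + boosts[["basic"]] / length(AA_BASIC)
  }
  if (!is.na(boosts["cys"])) add["C"] <- add["C"] + boosts[["cys"]]
  if (!is.na(boosts["glu"])) add["E"] <- add["E"] + boosts[["glu"]]
  total <- sum(add)
  pool_mass <- sum(freq[.COMPENSATION_POOL])
  if (total > pool_mass) {
    abort("Boosts exceed the available compensation mass.")
  }
  out <- freq + add
  out[.COMPENSATION_POOL] <- out[.COMPENSATION_POOL] * (pool_mass - total) / pool_mass
  if (any(out < 0) || abs(sum(out) - 1) > 1e-9) {
    abort("Boosted frequency vector is invalid.")
  }
  out
}

#' Amino-acid frequency vector of one location under a spec
#'
#' @param spec A `stoich_spec`.
#' @param location Location label.
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
location_frequencies <- function(spec, location) {
  boosts <- spec$biases[[location]]
  .boost_frequencies(spec$baseline, boosts %||% numeric())
}

#' Closed-form expected characteristics of a frequency vector
#'
#' Expected per-residue element and charged contents of i.i.d. sequences
#' drawn from `freq`: `sum(freq * w)` per element, and the summed class
#' frequencies for acidic/basic.
#'
#' @param freq Named frequency vector over the 20 standard amino acids.
#' @return One-row tibble with columns `C`, `H`, `O`, `N`, `S`, `acidic`,
#'   `basic`.
#' @export
expected_characteristics <- function(freq) {
  freq <- freq[AA_STANDARD]
  tibble(
    C = sum(freq * .element_weights("C")),
    H = sum(freq * .element_weights("H")),
    O = sum(freq * .element_weights("O")),
    N = sum(freq * .element_weights("N")),
    S = sum(freq * .element_weights("S")),
    acidic = sum(freq[AA_ACIDIC]),
    basic = sum(freq[AA_BASIC])
  )
}

# one random sequence from a frequency vector
.random_lengths <- function(n, spec) {
  len <- round(rlnorm(n, spec$length_meanlog, spec$length_sdlog))
  pmin(pmax(len, spec$length_range[1]), spec$length_range[2])
}

.random_sequences <- function(n, freq, spec) {
  lens <- .random_lengths(n, spec)
  vapply(lens, function(L) {
    paste(sample(AA_STANDARD, L, replace = TRUE, prob = freq), collapse = "")
  }, character(1))
}

#' Generate a synthetic proteome with location annotations
#'
#' Draws `n_per_cell` single-location proteins per (species, location) cell
#' plus `round(dual_fraction * n_per_cell)` dual-location proteins per
#' species and location pair budget, each dual protein carrying two distinct
#' locations and residues drawn from the mean of the two locations'
#' frequency vectors. All annotations are experimentally flagged.
#'
#' @param spec A `stoich_spec`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `records` (records tibble), `annotations` (the
#'   annotation table), `sequences` (named vector) and `manifest` (per-cell
#'   truth: frequency-vector expectations, one row per (species, location)).
#' @export
generate_proteomes <- function(spec, seed = 1) {
  validate_spec(spec)
  withr::with_seed(seed, {
    seq_list <- list()
    ann_list <- list()
    counter <- 0
    for (sp in spec$species) {
      for (loc in spec$locations) {
        freq <- location_frequencies(spec, loc)
        seqs <- .random_sequences(spec$n_per_cell, freq, spec)
        acc <- sprintf("SYN%06d", counter + seq_along(seqs))
        counter <- counter + length(seqs)
        seq_list[[length(seq_list) + 1]] <- setNames(seqs, acc)
        ann_list[[length(ann_list) + 1]] <- tibble(
          accession = acc, species = sp, location = loc, experimental = TRUE
        )
      }
      # dual-location proteins
      if (length(spec$locations) >= 2 && spec$dual_fraction > 0) {
        n_dual <- round(spec$dual_fraction * spec$n_per_cell * length(spec$locations))
        if (n_dual > 0) {
          for (i in seq_len(n_dual)) {
            locs <- sample(spec$locations, 2)
            freq <- (location_frequencies(spec, locs[1]) +
              location_frequencies(spec, locs[2])) / 2
            s <- .random_sequences(1, freq, spec)
            counter <- counter + 1
            acc <- sprintf("SYN%06d", counter)
            seq_list[[length(seq_list) + 1]] <- setNames(s, acc)
            ann_list[[length(ann_list) + 1]] <- tibble(
              accession = acc, species = sp, location = locs, experimental = TRUE
            )
          }
        }
      }
    }
    sequences <- unlist(seq_list)
    annotations <- bind_rows(ann_list)
    cells <- tidyr::expand_grid(
      species = spec$species, location = spec$locations
    )
    manifest <- bind_cols(
      cells,
      purrr::map(cells$location, function(l) {
        expected_characteristics(location_frequencies(spec, l))
      }) %>% bind_rows()
    ) %>% mutate(n = spec$n_per_cell)
    list(
      records = protein_records(sequences, annotations),
      annotations = annotations,
      sequences = sequences,
      manifest = manifest
    )
  })
}

#' Generate synthetic protein-protein interaction pairs
#'
#' Complementary pairs couple an acidic-biased sequence (expected
#' isoelectric point below 7) with a basic-biased one (above 7); background
#' pairs couple two baseline sequences. The class counts follow the spec
#' exactly (`round(complementary_fraction * n_pairs)` complementary pairs).
#'
#' @param spec A `stoich_spec` (fields under `spec$ppi`).
#' @param seed Integer seed.
#' @return List with `sequences` (named vector), `pairs` (tibble `a`, `b`,
#'   `class`) and `manifest` (per-class counts).
#' @export
generate_ppi_pairs <- function(spec, seed = 1) {
  validate_spec(spec)
  n_pairs <- spec$ppi$n_pairs
  n_comp <- round(spec$ppi$complementary_fraction * n_pairs)
  boost <- spec$ppi$boost
  acidic_freq <- .boost_frequencies(spec$baseline, c(acidic = boost))
  basic_freq <- .boost_frequencies(spec$baseline, c(basic = boost))
  withr::with_seed(seed, {
    cls <- c(rep("complementary", n_comp), rep("background", n_pairs - n_comp))
    a_id <- sprintf("PPA%05d", seq_len(n_pairs))
    b_id <- sprintf("PPB%05d", seq_len(n_pairs))
    a_seq <- character(n_pairs)
    b_seq <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      if (cls[i] == "complementary") {
        a_seq[i] <- .random_sequences(1, acidic_freq, spec)
        b_seq[i] <- .random_sequences(1, basic_freq, spec)
      } else {
        a_seq[i] <- .random_sequences(1, spec$baseline, spec)
        b_seq[i] <- .random_sequences(1, spec$baseline, spec)
      }
    }
    sequences <- c(setNames(a_seq, a_id), setNames(b_seq, b_id))
    pairs <- tibble(a = a_id, b = b_id, class = cls)
    list(
      sequences = sequences,
      pairs = pairs,
      manifest = pairs %>% count(.data$class, name = "n")
    )
  })
}

# one fixed-width PDB ATOM line (CA only)
.pdb_atom_line <- function(serial, resname, chain, resno, x, y, z) {
  sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    serial, resname, chain, resno, x, y, z, 1, 0
  )
}

#' Generate toy two-chain complexes with designed interfaces
#'
#' Writes CA-only PDB files of two-chain complexes: chain A runs along the
#' x-axis with `spacing` Angstroms between consecutive residues; the first
#' `interface_size` residues of chain B sit `offset` Angstroms from their
#' chain-A counterparts (so exactly residues `1..interface_size` of both
#' chains are interfacial at any cutoff in `(offset, sqrt(spacing^2 +
#' offset^2))`), and the remaining chain-B residues are displaced far away.
#' Interface residue types are drawn with Glu frequency boosted by
#' `glu_delta`; all other residues use the baseline vector.
#'
#' @param spec A `stoich_spec` (fields under `spec$complexes`).
#' @param seed Integer seed.
#' @param dir Directory for the PDB files (created if needed).
#' @return List with `files` (paths), `interface` (designated interface
#'   residue tibble: `complex_id`, `chain`, `resno`, `aa`) and `manifest`
#'   (per-complex realized Glu content of interface and non-interface
#'   residues, plus the configured delta).
#' @export
generate_complexes <- function(spec, seed = 1, dir = tempfile("complexes")) {
  validate_spec(spec)
  cx <- spec$complexes
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iface_freq <- .boost_frequencies(spec$baseline, c(glu = cx$glu_delta))
  aa_to_3 <- setNames(names(AA_3TO1), AA_3TO1)
  withr::with_seed(seed, {
    files <- character(cx$n)
    iface_list <- list()
    manifest_list <- list()
    for (i in seq_len(cx$n)) {
      id <- sprintf("CPX%04d", i)
      L <- cx$chain_length
      k <- cx$interface_size
      draw <- function(n, freq) sample(AA_STANDARD, n, replace = TRUE, prob = freq)
      aa_a <- c(draw(k, iface_freq), draw(L - k, spec$baseline))
      aa_b <- c(draw(k, iface_freq), draw(L - k, spec$baseline))
      lines <- character(0)
      serial <- 0
      for (j in seq_len(L)) {
        serial <- serial + 1
        lines <- c(lines, .pdb_atom_line(
          serial, aa_to_3[aa_a[j]], "A", j, cx$spacing * j, 0, 0
        ))
      }
      lines <- c(lines, "TER")
      for (j in seq_len(L)) {
        serial <- serial + 1
        y <- if (j <= k) cx$offset else cx$offset + 100
        lines <- c(lines, .pdb_atom_line(
          serial, aa_to_3[aa_b[j]], "B", j, cx$spacing * j, y, 0
        ))
      }
      lines <- c(lines, "TER", "END")
      path <- file.path(dir, paste0(id, ".pdb"))
      writeLines(lines, path)
      files[i] <- path
      iface_list[[i]] <- tibble(
        complex_id = id,
        chain = rep(c("A", "B"), each = k),
        resno = rep(seq_len(k), 2),
        aa = c(aa_a[seq_len(k)], aa_b[seq_len(k)])
      )
      iface_aa <- c(aa_a[seq_len(k)], aa_b[seq_len(k)])
      non_aa <- c(aa_a[-seq_len(k)], aa_b[-seq_len(k)])
      manifest_list[[i]] <- tibble(
        complex_id = id,
        interface_glu = mean(iface_aa == "E"),
        noninterface_glu = mean(non_aa == "E"),
        glu_delta = cx$glu_delta
      )
    }
    list(
      files = files,
      interface = bind_rows(iface_list),
      manifest = bind_rows(manifest_list)
    )
  })
}
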