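# Protein-protein interaction interfaces from 3D structures.
#
# A residue of chain A is interfacial (with respect to chain B) iff one of
# its heavy atoms lies within a distance cutoff (default 4.5 A) of any heavy
# atom of chain B, and symmetrically. This is a geometric stand-in for
# curated interface lists (which mix hydrogen-bond and non-bonded contact
# criteria); precomputed interface residue tables are accepted as direct
# input to bypass the geometric definition.

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Read a structure file into a tidy atom table
#'
#' Parses ATOM records of a PDB file (via bio3d), keeping heavy atoms of
#' standard residues only: HETATM, waters, hydrogens and alternate locations
#' other than '' / 'A' are dropped; the first model of a multi-model file is
#' used.
#'
#' @param path Path to a PDB file.
#' @param complex_id Identifier for the complex (default: file name without
#'   extension).
#' @return Tibble with columns `complex_id`, `chain`, `resno`, `resid`
#'   (3-letter), `aa` (1-letter), `atom`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, complex_id = NULL) {
  if (is.null(complex_id)) {
    complex_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- as_tibble(pdb$atom)
  atoms <- atoms %>%
    filter(
      .data$type == "ATOM",
      .data$resid %in% names(AA_3TO1),
      is.na(.data$alt) | .data$alt %in% c("", "A"),
      !grepl("^H", .data$elety)
    )
  if (nrow(atoms) == 0) abort(paste0("No standard ATOM records in ", path))
  atoms %>%
    mutate(
      complex_id = complex_id,
      aa = unname(AA_3TO1[.data$resid])
    ) %>%
    select("complex_id",
      chain = "chain", resno = "resno", resid = "resid",
      aa = "aa", atom = "elety", x = "x", y = "y", z = "z"
    )
}

#' Sequences of each chain in a structure
#'
#' @param structure Atom tibble from [read_structure()].
#' @return Named character vector, one sequence per chain, names
#'   `complexid_chain`.
#' @export
chain_sequences <- function(structure) {
  seqs <- structure %>%
    distinct(.data$complex_id, .data$chain, .data$resno, .data$aa) %>%
    arrange(.data$complex_id, .data$chain, .data$resno) %>%
    group_by(.data$complex_id, .data$chain) %>%
    summarise(sequence = paste(.data$aa, collapse = ""), .groups = "drop")
  setNames(seqs$sequence, paste(seqs$complex_id, seqs$chain, sep = "_"))
}

#' Label complexes whose chains match query sequences
#'
#' A complex is labelled (e.g. as cytoskeletal) when at least one of its
#' chains hits a query at `E <= max_evalue`, using the same pluggable search
#' engine as the orthology stage (stringent default cutoff 1e-10).
#'
#' @param queries Named character vector of query sequences.
#' @param structures List of atom tibbles (or one combined tibble) from
#'   [read_structure()].
#' @param max_evalue E-value cutoff.
#' @param engine Search engine, see [best_hits()].
#' @return Character vector of labelled complex ids.
#' @export
map_queries_to_structures <- function(queries, structures, max_evalue = 1e-10,
                                      engine = c("builtin", "blastp")) {
  if (is.data.frame(structures)) structures <- list(structures)
  combined <- bind_rows(structures)
  chains <- chain_sequences(combined)
  hits <- .search_hits(queries, chains, engine) %>%
    filter(.data$evalue <= max_evalue)
  if (nrow(hits) == 0) {
    return(character())
  }
  chain_map <- combined %>%
    distinct(.data$complex_id, .data$chain) %>%
    mutate(key = paste(.data$complex_id, .data$chain, sep = "_"))
  sort(unique(chain_map$complex_id[chain_map$key %in% hits$target]))
}

#' Extract interface residues between two chains
#'
#' @param structure Atom tibble from [read_structure()].
#' @param chain_a,chain_b Chain identifiers (order-insensitive).
#' @param cutoff Heavy-atom contact distance in Angstroms (> 0, default 4.5).
#' @return Tibble with columns `complex_id`, `chain_pair`, `chain`, `resno`,
#'   `aa`: the interfacial residues of both chains.
#' @export
extract_interface_residues <- function(structure, chain_a, chain_b, cutoff = 4.5) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  chains <- unique(structure$chain)
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% chains) {
      abort(paste0("Chain ", ch, " not present in the structure."))
    }
  }
  a <- structure %>% filter(.data$chain == chain_a)
  b <- structure %>% filter(.data$chain == chain_b)
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  # squared distances, atoms of A x atoms of B
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  contact <- d2 <= cutoff^2 + 1e-9
  pair <- paste(sort(c(chain_a, chain_b)), collapse = ":")
  res_a <- a %>%
    mutate(.hit = apply(contact, 1, any)) %>%
    filter(.data$.hit) %>%
    distinct(.data$complex_id, .data$chain, .data$resno, .data$aa)
  res_b <- b %>%
    mutate(.hit = apply(contact, 2, any)) %>%
    filter(.data$.hit) %>%
    distinct(.data$complex_id, .data$chain, .data$resno, .data$aa)
  bind_rows(res_a, res_b) %>%
    mutate(chain_pair = pair) %>%
    select("complex_id", "chain_pair", "chain", "resno", "aa") %>%
    arrange(.data$chain, .data$resno)
}

#' Extract all pairwise-chain interfaces of a set of structures
#'
#' @param structures List of atom tibbles from [read_structure()].
#' @param cutoff Contact distance in Angstroms.
#' @return Combined interface-residue tibble over all chain pairs.
#' @export
extract_all_interfaces <- function(structures, cutoff = 4.5) {
  if (is.data.frame(structures)) structures <- list(structures)
  purrr::map(structures, function(st) {
    chains <- sort(unique(st$chain))
    if (length(chains) < 2) {
      return(NULL)
    }
    pairs <- combn(chains, 2, simplify = FALSE)
    purrr::map(pairs, function(pr) {
      extract_interface_residues(st, pr[1], pr[2], cutoff)
    }) %>% bind_rows()
  }) %>% bind_rows()
}

# residue-level composition of one residue set
.residue_fractions <- function(aa) {
  n <- length(aa)
  if (n == 0) {
    return(tibble(
      n_residues = 0L, glu = NA_real_, asp = NA_real_, lys = NA_real_,
      arg = NA_real_, his = NA_real_, acidic = NA_real_, basic = NA_real_
    ))
  }
  tibble(
    n_residues = n,
    glu = sum(aa == "E") / n,
    asp = sum(aa == "D") / n,
    lys = sum(aa == "K") / n,
    arg = sum(aa == "R") / n,
    his = sum(aa == "H") / n,
    acidic = sum(aa %in% AA_ACIDIC) / n,
    basic = sum(aa %in% AA_BASIC) / n
  )
}

#' Charged amino-acid composition of interfaces
#'
#' Per interface (complex x chain pair): fractions of Glu, Asp, Lys, Arg,
#' His, acidic (D+E) and basic (K+R+H) residues, plus the mean across
#' interfaces and the pooled residue fractions.
#'
#' @param interfaces Interface-residue tibble from
#'   [extract_interface_residues()] / [extract_all_interfaces()] (or a
#'   precomputed table with columns `complex_id`, `chain_pair`, `chain`,
#'   `resno`, `aa`).
#' @return List with `per_interface` (tibble, one row per interface),
#'   `mean` (per-interface averages) and `pooled` (fractions over all
#'   interface residues pooled).
#' @export
interface_composition <- function(interfaces) {
  if (nrow(interfaces) == 0) abort("No interface residues supplied.")
  per <- interfaces %>%
    group_by(.data$complex_id, .data$chain_pair) %>%
    summarise(.residue_fractions(.data$aa), .groups = "drop")
  cats <- c("glu", "asp", "lys", "arg", "his", "acidic", "basic")
  list(
    per_interface = per,
    mean = per %>% summarise(
      n_interfaces = dplyr::n(),
      across(dplyr::all_of(cats), mean)
    ),
    pooled = .residue_fractions(interfaces$aa)
  )
}

#' Charged content of interface vs non-interface regions
#'
#' For each complex, computes the charged-residue fractions over its
#' interface residues and over all remaining residues, as paired rows for
#' downstream testing. A complex whose every residue is interfacial gets an
#' NA non-interface row.
#'
#' @param structures List of atom tibbles from [read_structure()].
#' @param interfaces Interface-residue tibble for the same complexes.
#' @return Tibble with one row per (complex, region), region in
#'   `"interface"` / `"non_interface"`, plus the fraction columns of
#'   [interface_composition()].
#' @export
interface_vs_noninterface <- function(structures, interfaces) {
  if (is.data.frame(structures)) structures <- list(structures)
  purrr::map(structures, function(st) {
    id <- st$complex_id[1]
    residues <- st %>% distinct(.data$complex_id, .data$chain, .data$resno, .data$aa)
    iface <- interfaces %>%
      filter(.data$complex_id == id) %>%
      distinct(.data$complex_id, .data$chain, .data$resno, .data$aa)
    non <- residues %>% anti_join(iface, by = c("chain", "resno"))
    iface_row <- .residue_fractions(iface$aa)
    non_row <- .residue_fractions(non$aa)
    bind_rows(
      iface_row %>% mutate(complex_id = id, region = "interface"),
      non_row %>% mutate(complex_id = id, region = "non_interface")
    ) %>% select("complex_id", "region", dplyr::everything())
  }) %>% bind_rows()
}

#' Sample random complexes from a pool
#'
#' Uniform sample without replacement of `n` complex ids, excluding labelled
#' (e.g. cytoskeletal) complexes; reproducible under `seed`.
#'
#' @param pool Character vector of complex ids.
#' @param n Number to draw.
#' @param seed Integer seed.
#' @param exclude Complex ids to exclude (e.g. labelled cytoskeletal ones).
#' @return Character vector of sampled ids.
#' @export
sample_random_complexes <- function(pool, n, seed = 1, exclude = character()) {
  admissible <- sort(setdiff(unique(pool), exclude))
  if (n > length(admissible)) {
    abort(paste0(
      "Requested ", n, " complexes but only ", length(admissible),
      " are admissible."
    ))
  }
  withr::with_seed(seed, sample(admissible, n))
}

#' Read a precomputed interface-residue table
#'
#' Accepts curated interface lists (4-column TSV: `complex_id`, `chain`,
#' `resno`, `aa`, optional `chain_pair`) so the geometric interface
#' definition can be bypassed.
#'
#' @param path Path to the TSV.
#' @return Interface-residue tibble compatible with
#'   [interface_composition()].
#' @export
read_interface_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    complex_id = "c", chain = "c", resno = "i", aa = "c", .default = "c"
  ))
  needed <- c("complex_id", "chain", "resno", "aa")
  if (!all(needed %in% names(tbl))) {
    abort(paste0("Interface table must have columns ", paste(needed, collapse = ", ")))
  }
  if (!"chain_pair" %in% names(tbl)) tbl$chain_pair <- NA_character_
  tbl %>% select("complex_id", "chain_pair", "chain", "resno", "aa")
}
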