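# Protein records with subcellular-location annotations.
#
# The canonical in-memory representation is a long tibble with one row per
# (accession, location annotation):
#   accession    chr  unique per protein within a dataset
#   species      chr  e.g. "Homo sapiens" (NA when unannotated)
#   sequence     chr  one-letter amino-acid codes
#   location     chr  raw or canonical label; NA when the protein carries
#                     no (remaining) location annotation
#   experimental lgl  evidence flag for that location; NA when location is NA

.check_records <- function(records, arg = "records") {
  needed <- c("accession", "species", "sequence", "location", "experimental")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0(
      arg, " must have columns ", paste(needed, collapse = ", "),
      "; missing: ", paste(missing, collapse = ", ")
    ))
  }
  invisible(records)
}

#' Assemble protein records from sequences and an annotation table
#'
#' @param sequences Named character vector (names = accessions) or an
#'   `AAStringSet`.
#' @param annotations Data frame with columns `accession`, `species`,
#'   `location`, `experimental`. Empty-string locations are treated as
#'   missing (a protein known to the dataset but carrying no location).
#' @return A records tibble, one row per (accession, location); proteins
#'   absent from the annotation table get a single row with `location = NA`.
#' @export
protein_records <- function(sequences, annotations = NULL) {
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("Every sequence must be named by its accession.")
  }
  if (anyDuplicated(names(sequences))) {
    dup <- unique(names(sequences)[duplicated(names(sequences))])
    abort(paste0("Duplicate accession(s) in sequences: ", paste(dup, collapse = ", ")))
  }
  if (any(nchar(sequences) < 1)) {
    abort("Sequences must have length >= 1.")
  }
  seq_tbl <- tibble(accession = names(sequences), sequence = unname(sequences))

  if (is.null(annotations) || nrow(annotations) == 0) {
    return(seq_tbl %>%
      mutate(species = NA_character_, location = NA_character_, experimental = NA) %>%
      select("accession", "species", "sequence", "location", "experimental"))
  }
  annotations <- as_tibble(annotations)
  needed <- c("accession", "species", "location", "experimental")
  if (!all(needed %in% names(annotations))) {
    abort(paste0("annotations must have columns ", paste(needed, collapse = ", ")))
  }
  orphan <- setdiff(annotations$accession, seq_tbl$accession)
  if (length(orphan) > 0) {
    abort(paste0(
      "Annotation rows reference accession(s) absent from the sequences: ",
      paste(unique(orphan), collapse = ", ")
    ))
  }
  annotations <- annotations %>%
    mutate(
      location = if_else(is.na(.data$location) | .data$location == "",
        NA_character_, .data$location
      ),
      experimental = if_else(is.na(.data$location), NA, as.logical(.data$experimental))
    )
  annotated <- seq_tbl %>%
    inner_join(annotations, by = "accession") %>%
    select("accession", "species", "sequence", "location", "experimental")
  unannotated <- seq_tbl %>%
    anti_join(annotations, by = "accession") %>%
    mutate(species = NA_character_, location = NA_character_, experimental = NA) %>%
    select("accession", "species", "sequence", "location", "experimental")
  bind_rows(annotated, unannotated) %>% arrange(.data$accession)
}

#' Read protein records from FASTA plus a TSV annotation table
#'
#' The annotation table is a 4-column TSV with a header row: `accession`,
#' `species`, `location` (raw label string), `experimental` (logical). Every
#' annotated accession must be present in the FASTA; a missing one is an
#' error naming the accession.
#'
#' @param fasta Path to a FASTA file of protein sequences (record ids up to
#'   the first whitespace are taken as accessions).
#' @param annotations Path to the annotation TSV, or a data frame.
#' @return A records tibble (see [protein_records()]).
#' @export
read_protein_records <- function(fasta, annotations = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(annotations) && length(annotations) == 1) {
    annotations <- readr::read_tsv(
      annotations,
      col_types = readr::cols(
        accession = readr::col_character(),
        species = readr::col_character(),
        location = readr::col_character(),
        experimental = readr::col_logical()
      ),
      na = c("", "NA")
    )
  }
  protein_records(seqs, annotations)
}

#' Write protein records back to FASTA + annotation TSV
#'
#' Inverse of [read_protein_records()]: records written and re-read compare
#' identical.
#'
#' @param records A records tibble.
#' @param fasta,annotations Output paths.
#' @return Invisibly, the paths.
#' @export
write_protein_records <- function(records, fasta, annotations) {
  .check_records(records)
  seq_tbl <- records %>% distinct(.data$accession, .data$sequence)
  set <- Biostrings::AAStringSet(setNames(seq_tbl$sequence, seq_tbl$accession))
  Biostrings::writeXStringSet(set, fasta)
  records %>%
    select("accession", "species", "location", "experimental") %>%
    readr::write_tsv(annotations, na = "")
  invisible(c(fasta = fasta, annotations = annotations))
}

#' Keep experimentally evidenced locations only
#'
#' Retains proteins that carry at least one experimentally evidenced
#' location, dropping their non-experimental location rows; proteins whose
#' every location is predicted (or that have no location) are excluded.
#' Idempotent.
#'
#' @param records A records tibble.
#' @return The filtered records tibble.
#' @export
select_experimental <- function(records) {
  .check_records(records)
  records %>% filter(!is.na(.data$experimental) & .data$experimental)
}

#' Map raw location labels onto the canonical nine-category vocabulary
#'
#' @param labels Character vector of raw annotation phrases.
#' @param map Mapping table with columns `raw`, `canonical`
#'   (default [default_location_map()]); matching is case-insensitive after
#'   trimming and whitespace collapsing.
#' @return Character vector of canonical labels, `NA` where unmapped.
#' @export
normalize_location_labels <- function(labels, map = default_location_map()) {
  key <- tolower(stringr::str_squish(labels))
  map_key <- tolower(stringr::str_squish(map$raw))
  out <- map$canonical[match(key, map_key)]
  # raw phrases mentioning transmembrane topology override to transmembrane
  tm <- !is.na(labels) & grepl("transmembrane|multi-pass|single-pass", key)
  out[tm] <- "transmembrane"
  out
}

#' Normalize location annotations of a records table
#'
#' Maps raw labels to canonical ones, deduplicates, and applies the
#' cytoskeleton co-annotation rule: a protein annotated with cytoskeleton
#' together with nucleus and/or cytoplasm is recorded as cytoskeleton only
#' (so "cytoskeleton, nucleus" and "cytoskeleton, cytoplasm" each collapse
#' to the single label "cytoskeleton"). Unmapped labels are dropped with a
#' warning; a protein whose whole location set is unmapped is kept with
#' `location = NA` so downstream partitioning can report it as excluded.
#' Idempotent.
#'
#' @param records A records tibble.
#' @param map Label mapping table, see [normalize_location_labels()].
#' @return Records tibble with canonical `location` values.
#' @export
normalize_locations <- function(records, map = default_location_map()) {
  .check_records(records)
  records <- records %>%
    mutate(.canonical = normalize_location_labels(.data$location, map))
  unmapped <- records %>% filter(!is.na(.data$location) & is.na(.data$.canonical))
  if (nrow(unmapped) > 0) {
    warn(paste0(
      "Dropping unmapped location label(s): ",
      paste(unique(unmapped$location), collapse = ", ")
    ))
  }
  kept <- records %>%
    filter(!is.na(.data$.canonical)) %>%
    mutate(location = .data$.canonical) %>%
    select(-".canonical") %>%
    group_by(.data$accession, .data$species, .data$sequence, .data$location) %>%
    summarise(experimental = any(.data$experimental), .groups = "drop")
  # cytoskeleton co-annotation rule
  cyto_acc <- kept %>%
    filter(.data$location == "cytoskeleton") %>%
    pull("accession")
  kept <- kept %>%
    filter(!(.data$accession %in% cyto_acc &
      .data$location %in% c("nucleus", "cytoplasm")))
  # re-attach proteins left with no mapped location
  lost <- records %>%
    distinct(.data$accession, .data$species, .data$sequence) %>%
    anti_join(kept, by = "accession") %>%
    mutate(location = NA_character_, experimental = NA)
  bind_rows(kept, lost) %>%
    select("accession", "species", "sequence", "location", "experimental") %>%
    arrange(.data$accession, .data$location)
}

#' Partition records into single- and dual-location proteins
#'
#' A protein with exactly one canonical location is "single"; one with two
#' or more is "dual" (and appears under each of its locations); one with no
#' location is "excluded". Every protein lands in exactly one class.
#'
#' @param records A normalized records tibble (see [normalize_locations()]).
#' @return Records tibble with an added `location_class` column
#'   (`"single"`, `"dual"` or `"excluded"`).
#' @export
partition_single_dual <- function(records) {
  .check_records(records)
  counts <- records %>%
    group_by(.data$accession) %>%
    summarise(.n_loc = sum(!is.na(.data$location)), .groups = "drop")
  records %>%
    left_join(counts, by = "accession") %>%
    mutate(location_class = dplyr::case_when(
      .data$.n_loc == 0 ~ "excluded",
      .data$.n_loc == 1 ~ "single",
      TRUE ~ "dual"
    )) %>%
    select(-".n_loc")
}

#' Summarise a partition as per-cell protein counts
#'
#' @param partition Output of [partition_single_dual()].
#' @return Tibble with columns `species`, `location`, `location_class`, `n`.
#' @export
partition_counts <- function(partition) {
  partition %>%
    filter(.data$location_class != "excluded") %>%
    count(.data$species, .data$location, .data$location_class, name = "n") %>%
    arrange(.data$species, .data$location, .data$location_class)
}

#' Keep species with more than `min_count` proteins
#'
#' Species whose total (distinct-protein) count is strictly greater than
#' `min_count` are retained; the default reproduces the "more than 300
#' sequences per species" rule.
#'
#' @param records A records tibble.
#' @param min_count Strict lower bound on distinct proteins per species.
#' @return The filtered records tibble.
#' @export
select_species <- function(records, min_count = 300) {
  .check_records(records)
  if (min_count < 0) abort("min_count must be >= 0")
  keep <- records %>%
    distinct(.data$accession, .data$species) %>%
    count(.data$species, name = "n") %>%
    filter(.data$n > min_count) %>%
    pull("species")
  records %>% filter(.data$species %in% keep)
}
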