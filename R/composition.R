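# Stoichiogenomic composition: element and charged amino-acid content.
#
# The seven characteristics of a sequence are the per-residue contents of
# C, H, O, N, S (sum over residues of side-chain atom counts, divided by
# the number of standard residues L) plus the acidic (D+E) and basic
# (K+R+H) amino-acid fractions. Ambiguity / nonstandard codes (B, Z, X, U,
# O, J, ...) are excluded from both the numerator and L.

CHARACTERISTICS <- c("C", "H", "O", "N", "S", "acidic", "basic")

# counts of the 20 standard residues per sequence (matrix, rows = sequences)
.standard_counts <- function(sequences) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::letterFrequency(set, letters = AA_STANDARD)
}

#' Flag sequences with too many nonstandard residues
#'
#' @param sequences Character vector of sequences.
#' @param max_frac Maximum tolerated fraction of nonstandard residues.
#' @return Logical vector, TRUE where the sequence should be kept.
#' @keywords internal
.keep_standard <- function(sequences, max_frac = 0.05) {
  std <- rowSums(.standard_counts(sequences))
  total <- nchar(sequences)
  std >= (1 - max_frac) * total & std > 0
}

#' Per-residue element content of protein sequences
#'
#' Computes `sum_i(w_i * p_i) / L`, where `w_i` is the side-chain atom count
#' of the element for amino acid i, `p_i` the residue count of that amino
#' acid in the sequence, and `L` the number of standard residues.
#'
#' @param sequences Character vector of protein sequences.
#' @param element One of `"C"`, `"H"`, `"O"`, `"N"`, `"S"`.
#' @return Numeric vector of per-residue contents.
#' @examples
#' element_content("GGGG", "H") # 1
#' element_content("CM", "S") # 1
#' @export
element_content <- function(sequences, element) {
  element <- match.arg(element, c("C", "H", "N", "O", "S"))
  counts <- .standard_counts(sequences)
  L <- rowSums(counts)
  if (any(L == 0)) {
    abort("Sequence with no standard residues: element content undefined.")
  }
  as.numeric(counts %*% .element_weights(element)) / L
}

#' Charged amino-acid content of protein sequences
#'
#' Fraction of acidic (D, E) or basic (K, R, H) residues among the standard
#' residues of each sequence.
#'
#' @param sequences Character vector of protein sequences.
#' @param which `"acidic"` or `"basic"`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' charged_content("DEKRH", "basic") # 0.6
#' @export
charged_content <- function(sequences, which = c("acidic", "basic")) {
  which <- match.arg(which)
  counts <- .standard_counts(sequences)
  L <- rowSums(counts)
  if (any(L == 0)) {
    abort("Sequence with no standard residues: charged content undefined.")
  }
  class_aas <- if (which == "acidic") AA_ACIDIC else AA_BASIC
  rowSums(counts[, class_aas, drop = FALSE]) / L
}

#' All seven stoichiogenomic characteristics per sequence
#'
#' @param sequences Character vector (optionally named) of protein sequences.
#' @param max_nonstandard Sequences with a larger fraction of nonstandard
#'   residues are dropped with a warning.
#' @return Tibble with columns `id`, `L` (standard-residue length), and one
#'   column per characteristic: `C`, `H`, `O`, `N`, `S`, `acidic`, `basic`.
#' @export
sequence_characteristics <- function(sequences, max_nonstandard = 0.05) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  keep <- .keep_standard(sequences, max_nonstandard)
  if (any(!keep)) {
    warn(paste0(
      sum(!keep), " sequence(s) dropped: > ", max_nonstandard * 100,
      "% nonstandard residues (", paste(head(ids[!keep], 5), collapse = ", "), ")"
    ))
    sequences <- sequences[keep]
    ids <- ids[keep]
  }
  counts <- .standard_counts(sequences)
  L <- rowSums(counts)
  out <- tibble(
    id = ids,
    L = as.integer(L),
    C = as.numeric(counts %*% .element_weights("C")) / L,
    H = as.numeric(counts %*% .element_weights("H")) / L,
    O = as.numeric(counts %*% .element_weights("O")) / L,
    N = as.numeric(counts %*% .element_weights("N")) / L,
    S = as.numeric(counts %*% .element_weights("S")) / L,
    acidic = rowSums(counts[, AA_ACIDIC, drop = FALSE]) / L,
    basic = rowSums(counts[, AA_BASIC, drop = FALSE]) / L
  )
  out
}

#' Group-mean composition profiles per (species, location)
#'
#' Unweighted mean of per-sequence characteristic values over the proteins
#' in each (species, location) cell, with the number of sequences averaged.
#'
#' @param records A records tibble (see [protein_records()]); rows with
#'   `location = NA` are ignored.
#' @param max_nonstandard Passed to [sequence_characteristics()].
#' @return Long tibble with columns `species`, `location`, `characteristic`,
#'   `mean`, `n`.
#' @export
proteome_profile <- function(records, max_nonstandard = 0.05) {
  .check_records(records)
  records <- records %>% filter(!is.na(.data$location))
  if (nrow(records) == 0) {
    abort("No located records: cannot compute a proteome profile.")
  }
  uniq <- records %>% distinct(.data$accession, .data$sequence)
  chars <- sequence_characteristics(
    setNames(uniq$sequence, uniq$accession), max_nonstandard
  )
  records %>%
    mutate(id = .data$accession) %>%
    inner_join(chars, by = "id") %>%
    tidyr::pivot_longer(
      dplyr::all_of(CHARACTERISTICS),
      names_to = "characteristic", values_to = "value"
    ) %>%
    group_by(.data$species, .data$location, .data$characteristic) %>%
    summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop") %>%
    mutate(characteristic = factor(.data$characteristic, levels = CHARACTERISTICS)) %>%
    arrange(.data$species, .data$location, .data$characteristic) %>%
    mutate(characteristic = as.character(.data$characteristic))
}

#' Normalize a content value to a reference average
#'
#' Divides a content by a reference (e.g. the eukaryote-wide average acidic
#' or basic content), so values above 1 read as "higher than the reference"
#' and below 1 as "lower".
#'
#' @param content Numeric vector of contents.
#' @param reference Positive reference content (scalar or vector).
#' @return Tibble with columns `content`, `reference`, `ratio`, `label`
#'   (`"higher"`, `"lower"` or `"equal"`).
#' @examples
#' normalize_to_reference(0.229911306, 0.114955653) # ratio 2, "higher"
#' @export
normalize_to_reference <- function(content, reference) {
  if (any(reference <= 0)) abort("reference must be > 0")
  ratio <- content / reference
  tibble(
    content = content, reference = reference, ratio = ratio,
    label = dplyr::case_when(
      ratio > 1 ~ "higher",
      ratio < 1 ~ "lower",
      TRUE ~ "equal"
    )
  )
}

#' Default reference contents for ratio normalization
#'
#' Eukaryote-wide average acidic and basic amino-acid contents used as the
#' default denominators of [normalize_to_reference()].
#' @export
REFERENCE_CONTENTS <- c(acidic = 0.114955653, basic = 0.142665842)

#' Correlate single- vs dual-location composition profiles
#'
#' Pearson correlation, per characteristic, of the (species, location) group
#' means computed from single-location proteins against those from
#' dual-location proteins, over the matched cells.
#'
#' @param single_profiles,dual_profiles Long profile tibbles from
#'   [proteome_profile()].
#' @param min_cells Minimum matched cells required; below it the
#'   characteristic is flagged not computable (`r = NA`).
#' @return Tibble with columns `characteristic`, `r`, `n_cells`, `computable`.
#' @export
correlate_single_dual <- function(single_profiles, dual_profiles, min_cells = 3) {
  matched <- inner_join(
    single_profiles, dual_profiles,
    by = c("species", "location", "characteristic"),
    suffix = c("_single", "_dual")
  )
  matched %>%
    group_by(.data$characteristic) %>%
    summarise(
      n_cells = dplyr::n(),
      r = if (dplyr::n() >= min_cells) {
        cor(.data$mean_single, .data$mean_dual)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) %>%
    mutate(computable = .data$n_cells >= min_cells) %>%
    select("characteristic", "r", "n_cells", "computable")
}
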