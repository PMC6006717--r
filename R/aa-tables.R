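# Chemical reference tables used across the package.
#
# Side-chain atom counts are derived mechanically: residue formula
# (free amino acid minus H2O) minus the backbone unit C2H2NO, neutral
# (un-ionized) forms, no terminal atoms. A TSV copy ships in
# inst/extdata/side_chain_elements.tsv so the table can be audited.

#' The 20 standard amino acids, one-letter codes
#' @export
AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Acidic and basic amino-acid classes
#'
#' Acidic: aspartate (D) and glutamate (E). Basic: lysine (K), arginine (R)
#' and histidine (H). These class definitions drive every charged-content
#' statistic in the package; note they are distinct from the ionizable set
#' used for isoelectric points (which additionally includes C and Y).
#' @export
AA_ACIDIC <- c("D", "E")

#' @rdname AA_ACIDIC
#' @export
AA_BASIC <- c("K", "R", "H")

# side-chain atom counts, rows in AA_STANDARD order, columns C,H,N,O,S
.side_chain_matrix <- matrix(
  c(
    # C  H  N  O  S
    1, 3, 0, 0, 0, # A
    4, 10, 3, 0, 0, # R
    2, 4, 1, 1, 0, # N
    2, 3, 0, 2, 0, # D
    1, 3, 0, 0, 1, # C
    3, 6, 1, 1, 0, # Q
    3, 5, 0, 2, 0, # E
    0, 1, 0, 0, 0, # G
    4, 5, 2, 0, 0, # H
    4, 9, 0, 0, 0, # I
    4, 9, 0, 0, 0, # L
    4, 10, 1, 0, 0, # K
    3, 7, 0, 0, 1, # M
    7, 7, 0, 0, 0, # F
    3, 5, 0, 0, 0, # P
    1, 3, 0, 1, 0, # S
    2, 5, 0, 1, 0, # T
    9, 8, 1, 0, 0, # W
    7, 7, 0, 1, 0, # Y
    3, 7, 0, 0, 0 # V
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(AA_STANDARD, c("C", "H", "N", "O", "S"))
)

#' Side-chain element counts
#'
#' Returns the number of C, H, N, O and S atoms on the side chain (R group)
#' of each standard amino acid: the residue formula (free amino acid minus
#' H2O) minus the peptide-backbone unit C2H2NO, neutral forms. Counts range
#' from 0 (e.g. glycine's carbon) to 10 (lysine/arginine hydrogen).
#'
#' @param aa Optional character vector of one-letter codes. When supplied,
#'   returns the corresponding rows; a nonstandard code is an error.
#' @return A tibble with columns `aa`, `C`, `H`, `N`, `O`, `S`.
#' @examples
#' side_chain_counts("G") # 1 hydrogen, nothing else
#' side_chain_counts(c("K", "C"))
#' @export
side_chain_counts <- function(aa = NULL) {
  tbl <- tibble::as_tibble(.side_chain_matrix, rownames = "aa")
  if (is.null(aa)) {
    return(tbl)
  }
  bad <- setdiff(aa, AA_STANDARD)
  if (length(bad) > 0) {
    abort(paste0(
      "Nonstandard amino-acid code(s): ", paste(unique(bad), collapse = ", "),
      ". side_chain_counts() is defined for the 20 standard residues only."
    ))
  }
  tbl[match(aa, tbl$aa), ]
}

# internal: element weight vector for one element, named by AA
.element_weights <- function(element) {
  element <- match.arg(element, c("C", "H", "N", "O", "S"))
  .side_chain_matrix[, element]
}

#' Ionization constants for isoelectric-point computation
#'
#' The default set (`"bjellqvist"`) holds the pKa values used by the ExPASy
#' Compute pI tool: side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98,
#' K 10.0, R 12.0; C-terminus 3.55; N-terminus 7.5 with residue-dependent
#' overrides (A 7.59, M 7.0, S 6.93, P 8.36, T 6.82, V 7.44, E 7.7).
#' Positional side-chain adjustments for terminal residues are not applied.
#'
#' @param name Name of the set; only `"bjellqvist"` is built in.
#' @return A list with elements `side` (named numeric), `cterm`,
#'   `nterm_default`, `nterm` (named numeric overrides) and `name`.
#' @examples
#' pka_set()$side[["D"]]
#' @export
pka_set <- function(name = "bjellqvist") {
  name <- match.arg(name, "bjellqvist")
  list(
    name = "bjellqvist",
    side = c(
      D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
      H = 5.98, K = 10.00, R = 12.00
    ),
    cterm = 3.55,
    nterm_default = 7.50,
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.70)
  )
}

#' Canonical subcellular location labels
#'
#' The closed set of nine location categories retained for subcellular
#' composition analysis.
#' @export
LOCATION_LABELS <- c(
  "cytoplasm", "cytoskeleton", "endoplasmic reticulum", "extracellular",
  "golgi", "membrane", "mitochondria", "nucleus", "transmembrane"
)

#' Default mapping of raw location phrases to canonical labels
#'
#' Maps common Swiss-Prot-style annotation phrases onto the nine canonical
#' labels. A raw phrase containing a transmembrane topology term maps to
#' `transmembrane`; other membrane phrases map to `membrane`. Users can
#' extend or replace the table (columns `raw`, `canonical`); matching is
#' case-insensitive after whitespace normalization. A TSV copy ships in
#' inst/extdata/location_map.tsv.
#'
#' @return A tibble with columns `raw` and `canonical`.
#' @export
default_location_map <- function() {
  tibble::tribble(
    ~raw, ~canonical,
    "cytoplasm", "cytoplasm",
    "cytosol", "cytoplasm",
    "cytoskeleton", "cytoskeleton",
    "endoplasmic reticulum", "endoplasmic reticulum",
    "endoplasmic reticulum membrane", "endoplasmic reticulum",
    "extracellular", "extracellular",
    "secreted", "extracellular",
    "extracellular space", "extracellular",
    "golgi", "golgi",
    "golgi apparatus", "golgi",
    "membrane", "membrane",
    "cell membrane", "membrane",
    "plasma membrane", "membrane",
    "mitochondria", "mitochondria",
    "mitochondrion", "mitochondria",
    "nucleus", "nucleus",
    "nuclear", "nucleus",
    "transmembrane", "transmembrane",
    "single-pass membrane protein", "transmembrane",
    "multi-pass membrane protein", "transmembrane"
  )
}
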