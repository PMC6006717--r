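# Isoelectric points and electrostatic complementarity of protein pairs.
#
# Net charge follows the Henderson-Hasselbalch model: positively ionizable
# groups (N-terminus, H, K, R) contribute n / (1 + 10^(pH - pKa)), negatively
# ionizable groups (C-terminus, D, E, C, Y) contribute -n / (1 + 10^(pKa - pH)).
# The charge is continuous and strictly decreasing in pH whenever both kinds
# of group are present, so the isoelectric point is the unique root on [0, 14],
# found by bisection.

# ionizable-group counts of one sequence (standard residues only)
.ionizable_counts <- function(sequence) {
  counts <- .standard_counts(sequence)[1, ]
  if (sum(counts) == 0) {
    abort("Sequence with no standard residues: charge undefined.")
  }
  # the terminal residue identities matter for the N-terminal pKa
  residues <- strsplit(sequence, "")[[1]]
  residues <- residues[residues %in% AA_STANDARD]
  list(counts = counts, nterm_res = residues[1])
}

# precompute the ionizable groups of one sequence
.charge_groups <- function(sequence, pka) {
  ion <- .ionizable_counts(sequence)
  counts <- ion$counts
  nterm_pka <- unname(pka$nterm[ion$nterm_res])
  if (is.na(nterm_pka)) nterm_pka <- pka$nterm_default
  list(
    pos_pka = c(nterm_pka, pka$side[["H"]], pka$side[["K"]], pka$side[["R"]]),
    pos_n = c(1, counts[["H"]], counts[["K"]], counts[["R"]]),
    neg_pka = c(
      pka$cterm, pka$side[["D"]], pka$side[["E"]],
      pka$side[["C"]], pka$side[["Y"]]
    ),
    neg_n = c(1, counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]])
  )
}

.charge_at <- function(groups, p) {
  sum(groups$pos_n / (1 + 10^(p - groups$pos_pka))) -
    sum(groups$neg_n / (1 + 10^(groups$neg_pka - p)))
}

#' Net charge of a protein sequence at a given pH
#'
#' @param sequence A single protein sequence (nonstandard residues are
#'   ignored, mirroring the composition module's exclusion policy).
#' @param pH Numeric vector of pH values in `[0, 14]`.
#' @param pka A pKa set from [pka_set()].
#' @return Numeric vector of signed net charges, one per pH.
#' @examples
#' net_charge("KKKK", 1) # strongly positive
#' net_charge("DDDD", 13) # strongly negative
#' @export
net_charge <- function(sequence, pH, pka = pka_set()) {
  if (any(pH < 0 | pH > 14)) abort("pH must lie in [0, 14]")
  groups <- .charge_groups(sequence, pka)
  vapply(pH, function(p) .charge_at(groups, p), numeric(1))
}

#' Isoelectric point of protein sequences
#'
#' Bisection on `[0, 14]`, stopping when the bracketing interval is narrower
#' than `tol` or the absolute net charge falls below `charge_tol`.
#' Deterministic: repeated calls return the same value.
#'
#' @param sequences Character vector of protein sequences.
#' @param pka A pKa set from [pka_set()].
#' @param tol Interval-width tolerance (pH units).
#' @param charge_tol Absolute-charge tolerance.
#' @return Numeric vector of isoelectric points.
#' @export
isoelectric_point <- function(sequences, pka = pka_set(),
                              tol = 1e-3, charge_tol = 1e-4) {
  vapply(sequences, function(s) {
    groups <- .charge_groups(s, pka)
    lo <- 0
    hi <- 14
    # termini guarantee charge(0) > 0 > charge(14)
    repeat {
      mid <- (lo + hi) / 2
      q <- .charge_at(groups, mid)
      if (abs(q) < charge_tol || (hi - lo) < tol) {
        return(mid)
      }
      if (q > 0) lo <- mid else hi <- mid
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Isoelectric-point difference of protein pairs
#'
#' For each pair, computes both isoelectric points and the complementarity
#' statistic `delta = PImax - PImin` (symmetric in the two proteins, >= 0).
#'
#' @param pairs Tibble with columns `a`, `b` (accessions), plus optional
#'   extra columns carried through (e.g. an evidence tag).
#' @param sequences Named character vector mapping accessions to sequences.
#' @param pka,tol,charge_tol Passed to [isoelectric_point()].
#' @return The input tibble with added columns `pi_a`, `pi_b`, `pi_min`,
#'   `pi_max`, `delta`.
#' @export
pi_difference <- function(pairs, sequences, pka = pka_set(),
                          tol = 1e-3, charge_tol = 1e-4) {
  pairs <- as_tibble(pairs)
  if (!all(c("a", "b") %in% names(pairs))) {
    abort("pairs must have columns a and b")
  }
  missing <- setdiff(unique(c(pairs$a, pairs$b)), names(sequences))
  if (length(missing) > 0) {
    abort(paste0(
      "Pair member(s) without a sequence: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  ids <- unique(c(pairs$a, pairs$b))
  pis <- setNames(
    isoelectric_point(sequences[ids], pka, tol, charge_tol), ids
  )
  pairs %>%
    mutate(
      pi_a = unname(pis[.data$a]),
      pi_b = unname(pis[.data$b]),
      pi_min = pmin(.data$pi_a, .data$pi_b),
      pi_max = pmax(.data$pi_a, .data$pi_b),
      delta = .data$pi_max - .data$pi_min
    )
}

#' Read a protein-protein interaction pair list
#'
#' Two-column TSV of accessions with an optional `evidence` column; pass
#' `evidence = "in vivo"` to keep in-vivo-evidenced pairs only.
#'
#' @param path Path to the TSV (header row: `a`, `b`, optionally `evidence`).
#' @param evidence Optional evidence tag to filter on (case-insensitive).
#' @return Tibble of pairs.
#' @export
read_ppi_pairs <- function(path, evidence = NULL) {
  pairs <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("a", "b") %in% names(pairs))) {
    abort("PPI pair table must have columns a and b")
  }
  if (!is.null(evidence)) {
    if (!"evidence" %in% names(pairs)) {
      abort("evidence filter requested but table has no evidence column")
    }
    pairs <- pairs %>%
      filter(tolower(.data$evidence) == tolower(!!evidence))
  }
  pairs
}

# canonical unordered key of a pair
.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Sample non-interacting protein pairs
#'
#' Draws `n` distinct unordered pairs of distinct proteins, none of which is
#' present in `known_pairs` (order-insensitive membership), uniformly without
#' replacement. Reproducible under `seed`.
#'
#' @param proteins Character vector of protein ids.
#' @param known_pairs Tibble with columns `a`, `b` of known interactions.
#' @param n Number of pairs to draw.
#' @param seed Integer seed.
#' @return Tibble with columns `a`, `b`.
#' @export
sample_noninteracting_pairs <- function(proteins, known_pairs, n, seed = 1) {
  proteins <- sort(unique(proteins))
  if (length(proteins) < 2) abort("Need at least two proteins.")
  all_pairs <- combn(proteins, 2)
  keys <- .pair_key(all_pairs[1, ], all_pairs[2, ])
  known <- if (nrow(known_pairs) > 0) .pair_key(known_pairs$a, known_pairs$b) else character()
  admissible <- which(!(keys %in% known))
  if (n > length(admissible)) {
    abort(paste0(
      "Requested ", n, " pairs but only ", length(admissible),
      " non-interacting pairs exist."
    ))
  }
  idx <- withr::with_seed(seed, sample(admissible, n))
  tibble(a = all_pairs[1, idx], b = all_pairs[2, idx])
}

#' Compare isoelectric-point differences of two pair sets
#'
#' Runs the dual-criterion nonparametric comparison (Mann-Whitney +
#' Kolmogorov-Smirnov, both must pass) on the `delta = PImax - PImin`
#' distributions of two sets of protein pairs.
#'
#' @param set_a,set_b Tibbles with a `delta` column (see [pi_difference()]),
#'   or bare numeric vectors of deltas.
#' @param tail `"two"` for two-sided, `"greater"` to test whether set A's
#'   deltas tend larger, `"less"` for the reverse.
#' @param alpha Significance level for the dual criterion.
#' @return A `stoich_test` report, see [two_sample_tests()].
#' @export
compare_delta_distributions <- function(set_a, set_b, tail = "two", alpha = 0.05) {
  delta_a <- if (is.numeric(set_a)) set_a else set_a$delta
  delta_b <- if (is.numeric(set_b)) set_b else set_b$delta
  if (is.null(delta_a) || is.null(delta_b)) {
    abort("Pair sets must carry a delta column (run pi_difference() first).")
  }
  two_sample_tests(delta_a, delta_b, tail = tail, alpha = alpha)
}
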