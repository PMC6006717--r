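# Independent oracles and fixture builders. Everything here is deliberately
# naive (brute force, enumeration, dense grids) and shares no code path with
# the package implementation it checks.

# --- fixtures ---------------------------------------------------------------

random_protein <- function(n, length_range = c(20, 120)) {
  vapply(seq_len(n), function(i) {
    L <- sample(length_range[1]:length_range[2], 1)
    paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
  }, character(1))
}

# records tibble built directly
make_records <- function(accession, species, sequence, location, experimental) {
  tibble::tibble(
    accession = accession, species = species, sequence = sequence,
    location = location, experimental = experimental
  )
}

# --- composition oracle -----------------------------------------------------

# independently encoded molecular formulas of the free amino acids;
# side chain = free - H2O - backbone C2H2NO
FREE_AA_FORMULAS <- list(
  A = c(C = 3, H = 7, N = 1, O = 2, S = 0),
  R = c(C = 6, H = 14, N = 4, O = 2, S = 0),
  N = c(C = 4, H = 8, N = 2, O = 3, S = 0),
  D = c(C = 4, H = 7, N = 1, O = 4, S = 0),
  C = c(C = 3, H = 7, N = 1, O = 2, S = 1),
  Q = c(C = 5, H = 10, N = 2, O = 3, S = 0),
  E = c(C = 5, H = 9, N = 1, O = 4, S = 0),
  G = c(C = 2, H = 5, N = 1, O = 2, S = 0),
  H = c(C = 6, H = 9, N = 3, O = 2, S = 0),
  I = c(C = 6, H = 13, N = 1, O = 2, S = 0),
  L = c(C = 6, H = 13, N = 1, O = 2, S = 0),
  K = c(C = 6, H = 14, N = 2, O = 2, S = 0),
  M = c(C = 5, H = 11, N = 1, O = 2, S = 1),
  F = c(C = 9, H = 11, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 9, N = 1, O = 2, S = 0),
  S = c(C = 3, H = 7, N = 1, O = 3, S = 0),
  T = c(C = 4, H = 9, N = 1, O = 3, S = 0),
  W = c(C = 11, H = 12, N = 2, O = 2, S = 0),
  Y = c(C = 9, H = 11, N = 1, O = 3, S = 0),
  V = c(C = 5, H = 11, N = 1, O = 2, S = 0)
)

oracle_side_chain <- function(aa) {
  water <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
  backbone <- c(C = 2, H = 2, N = 1, O = 1, S = 0)
  FREE_AA_FORMULAS[[aa]] - water - backbone
}

# atom-by-atom counting over the concatenated side-chain formulas
oracle_atom_count <- function(sequence, element) {
  residues <- strsplit(sequence, "")[[1]]
  residues <- residues[residues %in% AA_STANDARD]
  sum(vapply(residues, function(r) oracle_side_chain(r)[[element]], numeric(1)))
}

oracle_charged_count <- function(sequence, which) {
  residues <- strsplit(sequence, "")[[1]]
  class_aas <- if (which == "acidic") c("D", "E") else c("K", "R", "H")
  sum(residues %in% class_aas)
}

# --- isoelectric-point oracle -----------------------------------------------

# dense grid scan: vectorized Henderson-Hasselbalch charge over a pH grid,
# root taken at the sign change
oracle_pi_grid <- function(sequence, pka = pka_set(), step = 1e-4) {
  residues <- strsplit(sequence, "")[[1]]
  residues <- residues[residues %in% AA_STANDARD]
  counts <- table(factor(residues, levels = AA_STANDARD))
  nterm <- residues[1]
  nterm_pka <- if (nterm %in% names(pka$nterm)) pka$nterm[[nterm]] else pka$nterm_default
  grid <- seq(0, 14, by = step)
  charge <- rep(0, length(grid))
  pos <- rbind(
    c(1, nterm_pka),
    c(counts[["H"]], pka$side[["H"]]),
    c(counts[["K"]], pka$side[["K"]]),
    c(counts[["R"]], pka$side[["R"]])
  )
  neg <- rbind(
    c(1, pka$cterm),
    c(counts[["D"]], pka$side[["D"]]),
    c(counts[["E"]], pka$side[["E"]]),
    c(counts[["C"]], pka$side[["C"]]),
    c(counts[["Y"]], pka$side[["Y"]])
  )
  for (i in seq_len(nrow(pos))) {
    charge <- charge + pos[i, 1] / (1 + 10^(grid - pos[i, 2]))
  }
  for (i in seq_len(nrow(neg))) {
    charge <- charge - neg[i, 1] / (1 + 10^(neg[i, 2] - grid))
  }
  below <- which(charge < 0)
  if (length(below) == 0) {
    return(14)
  }
  k <- below[1]
  if (k == 1) {
    return(0)
  }
  (grid[k - 1] + grid[k]) / 2
}

# --- Smith-Waterman oracle --------------------------------------------------

# textbook affine-gap local alignment (gap of length L costs open + L * ext)
oracle_sw_score <- function(a, b, open = 11, ext = 1) {
  blosum <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
      M[i, j] <- max(
        0,
        M[i - 1, j - 1] + blosum[a[i - 1], b[j - 1]],
        X[i, j], Y[i, j]
      )
      best <- max(best, M[i, j])
    }
  }
  best
}

# exhaustive best-hit construction from the score matrix, mirroring the
# package's tie-break (higher score, then smaller target id) independently
oracle_best_hits <- function(queries, targets) {
  out <- lapply(names(queries), function(q) {
    scores <- vapply(names(targets), function(t) {
      oracle_sw_score(queries[[q]], targets[[t]])
    }, numeric(1))
    ord <- order(-scores, names(targets))
    data.frame(query = q, target = names(targets)[ord[1]], score = scores[ord[1]])
  })
  do.call(rbind, out)
}

# --- interface oracle -------------------------------------------------------

# residue-level brute force: all atom pairs, plain loops
oracle_interface <- function(structure, chain_a, chain_b, cutoff) {
  a <- structure[structure$chain == chain_a, ]
  b <- structure[structure$chain == chain_b, ]
  hit_a <- logical(nrow(a))
  hit_b <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      if (d <= cutoff) {
        hit_a[i] <- TRUE
        hit_b[j] <- TRUE
      }
    }
  }
  rbind(
    unique(data.frame(chain = a$chain[hit_a], resno = a$resno[hit_a])),
    unique(data.frame(chain = b$chain[hit_b], resno = b$resno[hit_b]))
  )
}

# --- Mann-Whitney enumeration oracle ----------------------------------------

# exact one-tailed p by enumerating every assignment of pooled ranks
oracle_mw_exact_less <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  ranks <- rank(pooled)
  n_a <- length(a)
  obs_w <- sum(ranks[seq_len(n_a)])
  combos <- combn(length(pooled), n_a)
  w_all <- colSums(matrix(ranks[combos], nrow = n_a))
  mean(w_all <= obs_w)
}
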