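# Putative 1:1 orthologs ("prokaryotic analogs") via bidirectional best hits.
#
# The sequence-search engine is pluggable. The built-in engine scores every
# query-target pair by Smith-Waterman local alignment (BLOSUM62, affine gap
# open 11 / extend 1, via Biostrings) and converts raw scores to bit scores
# and E-values with Karlin-Altschul statistics using the standard gapped
# BLOSUM62 11/1 parameters (lambda = 0.267, K = 0.041):
#   bits = (lambda * S - ln K) / ln 2,  E = m * n * 2^(-bits)
# with m the query length and n the summed target-database length. An
# external blastp adapter is available for real-scale runs; desk-scale
# results must not depend on the engine.

KA_LAMBDA <- 0.267
KA_K <- 0.041

# score matrix: queries x targets, Smith-Waterman local alignment scores
.sw_scores <- function(queries, targets) {
  q <- Biostrings::AAStringSet(queries)
  t <- Biostrings::AAStringSet(targets)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- matrix(0, length(q), length(t), dimnames = list(names(q), names(t)))
  for (j in seq_along(t)) {
    mat[, j] <- Biostrings::pairwiseAlignment(
      pattern = q, subject = t[[j]], type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE
    )
  }
  mat
}

# all-vs-all hit table from the built-in engine
.engine_builtin <- function(queries, targets) {
  scores <- .sw_scores(queries, targets)
  db_len <- sum(nchar(targets))
  tibble(
    query = rep(rownames(scores), times = ncol(scores)),
    target = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores)
  ) %>%
    mutate(
      bitscore = (KA_LAMBDA * .data$score - log(KA_K)) / log(2),
      evalue = nchar(queries[.data$query]) * db_len * 2^(-.data$bitscore)
    )
}

# external blastp adapter (requires makeblastdb/blastp on PATH)
.engine_blastp <- function(queries, targets) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    abort("blastp/makeblastdb not found on PATH; use engine = \"builtin\".")
  }
  dir <- tempfile("blastdb")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fasta")
  tf <- file.path(dir, "target.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(queries), qf)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(targets), tf)
  system2("makeblastdb",
    c("-in", tf, "-dbtype", "prot"),
    stdout = FALSE, stderr = FALSE
  )
  out <- system2("blastp",
    c(
      "-query", qf, "-db", tf, "-outfmt", "'6 qseqid sseqid bitscore evalue'",
      "-max_target_seqs", "500"
    ),
    stdout = TRUE, stderr = FALSE
  )
  if (length(out) == 0) {
    return(tibble(
      query = character(), target = character(),
      score = numeric(), bitscore = numeric(), evalue = numeric()
    ))
  }
  parts <- strsplit(out, "\t", fixed = TRUE)
  tibble(
    query = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    score = NA_real_,
    bitscore = as.numeric(vapply(parts, `[`, character(1), 3)),
    evalue = as.numeric(vapply(parts, `[`, character(1), 4))
  )
}

.search_hits <- function(queries, targets, engine = c("builtin", "blastp")) {
  engine <- match.arg(engine)
  if (length(queries) == 0 || length(targets) == 0) {
    abort("Both proteomes must be nonempty.")
  }
  if (is.null(names(queries)) || is.null(names(targets))) {
    abort("Proteome sequences must be named by accession.")
  }
  switch(engine,
    builtin = .engine_builtin(queries, targets),
    blastp = .engine_blastp(queries, targets)
  )
}

#' Best hit of each query in a target proteome
#'
#' For every query with at least one hit at `E <= max_evalue`, returns its
#' single best hit under the ordering: higher bit score, then lower E-value,
#' then lexicographically smaller target accession.
#'
#' @param queries,targets Named character vectors of protein sequences.
#' @param max_evalue E-value cutoff (default 1e-5).
#' @param engine `"builtin"` (Smith-Waterman + Karlin-Altschul E-values) or
#'   `"blastp"` (external BLAST+ adapter).
#' @return Tibble with columns `query`, `target`, `bitscore`, `evalue`;
#'   queries with no admissible hit are absent.
#' @export
best_hits <- function(queries, targets, max_evalue = 1e-5,
                      engine = c("builtin", "blastp")) {
  hits <- .search_hits(queries, targets, engine) %>%
    filter(.data$evalue <= max_evalue)
  hits %>%
    group_by(.data$query) %>%
    arrange(
      dplyr::desc(.data$bitscore), .data$evalue, .data$target,
      .by_group = TRUE
    ) %>%
    slice(1) %>%
    ungroup() %>%
    select("query", "target", "bitscore", "evalue") %>%
    arrange(.data$query)
}

#' Bidirectional best hits between two proteomes
#'
#' A pair (a, b) is kept iff b is a's best hit in B and a is b's best hit in
#' A; such pairs are treated as putative 1:1 orthologs. The output is a
#' partial matching (no accession occurs twice) and is invariant under
#' swapping A and B, up to pair orientation.
#'
#' @param a,b Named character vectors of protein sequences.
#' @inheritParams best_hits
#' @return Tibble with columns `query` (from `a`), `target` (from `b`),
#'   `bitscore`, `evalue` (forward direction's values).
#' @export
bidirectional_best_hits <- function(a, b, max_evalue = 1e-5,
                                    engine = c("builtin", "blastp")) {
  fwd <- best_hits(a, b, max_evalue, engine)
  rev <- best_hits(b, a, max_evalue, engine)
  fwd %>%
    inner_join(rev, by = c("query" = "target", "target" = "query"),
      suffix = c("", "_rev")
    ) %>%
    select("query", "target", "bitscore", "evalue") %>%
    arrange(.data$query)
}

#' Keep mesophilic genomes
#'
#' Retains genomes with growth temperature in `[t_min, t_max]` (inclusive,
#' default 15-50 degrees C); genomes lacking a temperature are dropped with
#' a warning.
#'
#' @param genomes Tibble with columns `genome_id` and `temperature`
#'   (degrees C, may be NA).
#' @param t_min,t_max Inclusive bounds.
#' @return The filtered tibble.
#' @export
filter_mesophiles <- function(genomes, t_min = 15, t_max = 50) {
  if (!all(c("genome_id", "temperature") %in% names(genomes))) {
    abort("genomes must have columns genome_id and temperature")
  }
  no_temp <- genomes %>% filter(is.na(.data$temperature))
  if (nrow(no_temp) > 0) {
    warn(paste0(
      "Dropping genome(s) without growth temperature: ",
      paste(no_temp$genome_id, collapse = ", ")
    ))
  }
  genomes %>%
    filter(
      !is.na(.data$temperature),
      .data$temperature >= t_min, .data$temperature <= t_max
    )
}

#' Compare charged-AA content of subcellular proteomes and their analogs
#'
#' For each subcellular location, averages the acidic and basic amino-acid
#' contents of (i) the location's proteins that have at least one analog and
#' (ii) their analog partners. By default analogs are pooled per occurrence
#' (a protein matched in k genomes contributes k analog sequences);
#' `pooling = "per_genome"` first averages within each genome and then
#' across genomes.
#'
#' @param records Records tibble of the subcellular proteomes (non-NA
#'   locations).
#' @param analogs Tibble of ortholog pairs with columns `query` (accession
#'   in `records`), `target` (analog accession) and `genome_id`.
#' @param analog_sequences Named character vector of analog sequences.
#' @param pooling `"per_occurrence"` (default) or `"per_genome"`.
#' @return Tibble with one row per location: `location`, `n_query`,
#'   `n_analog`, `query_acidic`, `query_basic`, `analog_acidic`,
#'   `analog_basic` (NA rows for locations without analogs).
#' @export
analog_charge_comparison <- function(records, analogs, analog_sequences,
                                     pooling = c("per_occurrence", "per_genome")) {
  pooling <- match.arg(pooling)
  .check_records(records)
  if (!all(c("query", "target", "genome_id") %in% names(analogs))) {
    abort("analogs must have columns query, target, genome_id")
  }
  located <- records %>% filter(!is.na(.data$location))
  locations <- sort(unique(located$location))

  purrr::map(locations, function(loc) {
    members <- located %>%
      filter(.data$location == loc) %>%
      distinct(.data$accession, .data$sequence)
    hits <- analogs %>% filter(.data$query %in% members$accession)
    if (nrow(hits) == 0) {
      return(tibble(
        location = loc, n_query = 0L, n_analog = 0L,
        query_acidic = NA_real_, query_basic = NA_real_,
        analog_acidic = NA_real_, analog_basic = NA_real_
      ))
    }
    matched <- members %>% filter(.data$accession %in% hits$query)
    missing_seq <- setdiff(hits$target, names(analog_sequences))
    if (length(missing_seq) > 0) {
      abort(paste0(
        "Analog(s) without a sequence: ",
        paste(head(missing_seq, 5), collapse = ", ")
      ))
    }
    analog_vals <- hits %>%
      mutate(
        acidic = charged_content(analog_sequences[.data$target], "acidic"),
        basic = charged_content(analog_sequences[.data$target], "basic")
      )
    if (pooling == "per_genome") {
      analog_vals <- analog_vals %>%
        group_by(.data$genome_id) %>%
        summarise(
          acidic = mean(.data$acidic), basic = mean(.data$basic),
          .groups = "drop"
        )
    }
    tibble(
      location = loc,
      n_query = nrow(matched),
      n_analog = nrow(hits),
      query_acidic = mean(charged_content(matched$sequence, "acidic")),
      query_basic = mean(charged_content(matched$sequence, "basic")),
      analog_acidic = mean(analog_vals$acidic),
      analog_basic = mean(analog_vals$basic)
    )
  }) %>% bind_rows()
}
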