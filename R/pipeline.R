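# End-to-end orchestration: run the analysis stages from one configuration.
#
# Stage outputs are pure functions of (inputs, config): every report is a
# TSV written under the configured output directory, reruns with an
# identical config are byte-identical, and enabling one stage never changes
# another stage's outputs.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory for reports.
#' @param stages Stages to run, any of `"simulate"`, `"partition"`,
#'   `"composition"`, `"pi_pairs"`, `"orthology"`, `"interfaces"`,
#'   `"tally"`.
#' @param fasta,annotations Protein input paths (filled automatically by the
#'   simulate stage).
#' @param pairs Path to a PPI pair TSV (columns `a`, `b`, optional
#'   `evidence`, `class`).
#' @param structures_dir Directory of PDB files.
#' @param relations Path to a relation TSV (`protein`, `partner`,
#'   `relation`).
#' @param genome_fastas Named character vector of prokaryotic proteome FASTA
#'   paths (names = genome ids), for the orthology stage.
#' @param genome_metadata Path to a genome metadata TSV (`genome_id`,
#'   `temperature`).
#' @param seed Integer seed used by every stochastic step.
#' @param min_species_count Species filter threshold (strict).
#' @param evalue,evalue_structures E-value cutoffs for orthology / structure
#'   mapping.
#' @param contact_cutoff Interface contact distance (Angstroms).
#' @param alpha,screen_alpha Significance levels (pair tests / screens).
#' @param tail Tail for pair-set comparisons.
#' @param reference Named reference contents for ratio normalization.
#' @param synthetic A `stoich_spec` for the simulate stage.
#' @return A `stoich_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("stoichio_run"),
                            stages = c(
                              "simulate", "partition", "composition",
                              "pi_pairs", "interfaces"
                            ),
                            fasta = NULL, annotations = NULL, pairs = NULL,
                            structures_dir = NULL, relations = NULL,
                            genome_fastas = NULL, genome_metadata = NULL,
                            seed = 1,
                            min_species_count = 0,
                            evalue = 1e-5, evalue_structures = 1e-10,
                            contact_cutoff = 4.5,
                            alpha = 0.05, screen_alpha = 0.01,
                            tail = "two",
                            reference = REFERENCE_CONTENTS,
                            synthetic = synthetic_spec()) {
  structure(
    list(
      out_dir = out_dir, stages = stages, fasta = fasta,
      annotations = annotations, pairs = pairs,
      structures_dir = structures_dir, relations = relations,
      genome_fastas = genome_fastas, genome_metadata = genome_metadata,
      seed = seed, min_species_count = min_species_count,
      evalue = evalue, evalue_structures = evalue_structures,
      contact_cutoff = contact_cutoff, alpha = alpha,
      screen_alpha = screen_alpha, tail = tail, reference = reference,
      synthetic = synthetic
    ),
    class = "stoich_config"
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip unchanged (the synthetic spec included).
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()]: a `stoich_config`;
#'   [write_pipeline_config()]: the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- raw$synthetic
  if (!is.null(syn)) {
    syn$baseline <- unlist(syn$baseline)
    syn$biases <- lapply(syn$biases, unlist)
    raw$synthetic <- do.call(synthetic_spec, syn[setdiff(
      names(syn),
      setdiff(names(syn), names(formals(synthetic_spec)))
    )])
  }
  raw$reference <- unlist(raw$reference)
  raw$genome_fastas <- unlist(raw$genome_fastas)
  do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
}

#' @rdname read_pipeline_config
#' @param config A `stoich_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$synthetic <- unclass(out$synthetic)
  out$synthetic$baseline <- as.list(out$synthetic$baseline)
  out$synthetic$biases <- lapply(out$synthetic$biases, as.list)
  out$reference <- as.list(out$reference)
  yaml::write_yaml(out, path)
  invisible(path)
}

.stage_requirements <- function(config) {
  req <- list(
    partition = c("fasta", "annotations"),
    composition = c("fasta", "annotations"),
    pi_pairs = c("fasta", "pairs"),
    orthology = c("fasta", "annotations", "genome_metadata"),
    interfaces = c("structures_dir"),
    tally = c("relations")
  )
  simulated <- "simulate" %in% config$stages
  for (stage in intersect(config$stages, names(req))) {
    for (field in req[[stage]]) {
      # simulate fills sequence-side inputs at run time
      if (simulated && field %in% c("fasta", "annotations", "pairs", "structures_dir")) next
      value <- config[[field]]
      if (is.null(value)) {
        abort(paste0("Stage '", stage, "' needs config field '", field, "'."))
      }
      if (!all(file.exists(value))) {
        abort(paste0(
          "Stage '", stage, "': input path does not exist: ",
          paste(value[!file.exists(value)], collapse = ", ")
        ))
      }
    }
  }
  if ("orthology" %in% config$stages &&
    (is.null(config$genome_fastas) || is.null(names(config$genome_fastas)))) {
    abort("Stage 'orthology' needs named genome_fastas paths.")
  }
  invisible(config)
}

.write_report <- function(tbl, config, name) {
  path <- file.path(config$out_dir, paste0(name, ".tsv"))
  readr::write_tsv(tbl, path)
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writing one TSV report per result
#' under `config$out_dir` plus a `run_log.txt` recording version, seed and
#' parameters. Missing inputs for an enabled stage raise an error before any
#' computation; reruns with an identical config are byte-identical.
#'
#' @param config A `stoich_config` from [pipeline_config()].
#' @return Invisibly, a named list of the result tibbles.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "stoich_config"))
  .stage_requirements(config)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  results <- list()

  if ("simulate" %in% config$stages) {
    input_dir <- file.path(config$out_dir, "input")
    if (!dir.exists(input_dir)) dir.create(input_dir)
    prot <- generate_proteomes(config$synthetic, config$seed)
    config$fasta <- file.path(input_dir, "proteins.fasta")
    config$annotations <- file.path(input_dir, "annotations.tsv")
    write_protein_records(prot$records, config$fasta, config$annotations)
    .write_report(prot$manifest, config, "truth_proteomes")

    ppi <- generate_ppi_pairs(config$synthetic, config$seed + 1)
    ppi_fasta <- file.path(input_dir, "ppi_proteins.fasta")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(ppi$sequences), ppi_fasta)
    config$pairs <- file.path(input_dir, "ppi_pairs.tsv")
    readr::write_tsv(ppi$pairs, config$pairs)
    config$ppi_fasta <- ppi_fasta
    .write_report(ppi$manifest, config, "truth_ppi")

    cpx <- generate_complexes(
      config$synthetic, config$seed + 2,
      dir = file.path(input_dir, "structures")
    )
    config$structures_dir <- file.path(input_dir, "structures")
    .write_report(cpx$manifest, config, "truth_complexes")
    results$truth <- list(
      proteomes = prot$manifest, ppi = ppi$manifest, complexes = cpx$manifest
    )
  }

  partition <- NULL
  if (any(c("partition", "composition", "orthology") %in% config$stages)) {
    records <- read_protein_records(config$fasta, config$annotations)
    records <- records %>%
      select_experimental() %>%
      normalize_locations() %>%
      select_species(min_count = config$min_species_count)
    partition <- partition_single_dual(records)
  }

  if ("partition" %in% config$stages) {
    counts <- partition_counts(partition)
    .write_report(counts, config, "partition_counts")
    results$partition <- counts
  }

  if ("composition" %in% config$stages) {
    single <- partition %>% filter(.data$location_class == "single")
    profiles <- proteome_profile(single)
    .write_report(profiles, config, "profiles_single")
    results$profiles_single <- profiles
    dual <- partition %>% filter(.data$location_class == "dual")
    if (nrow(dual) > 0) {
      dual_profiles <- proteome_profile(dual)
      .write_report(dual_profiles, config, "profiles_dual")
      results$profiles_dual <- dual_profiles
      results$single_dual_correlation <-
        correlate_single_dual(profiles, dual_profiles)
      .write_report(results$single_dual_correlation, config, "single_dual_correlation")
    }
    ratios <- profiles %>%
      filter(.data$characteristic %in% names(config$reference)) %>%
      mutate(normalize_to_reference(
        .data$mean, unname(config$reference[.data$characteristic])
      ) %>% select("ratio", "label"))
    .write_report(ratios, config, "normalized_ratios")
    results$normalized_ratios <- ratios
    screen <- screen_locations(single, alpha = config$screen_alpha)
    .write_report(screen, config, "location_screen")
    results$location_screen <- screen
  }

  if ("pi_pairs" %in% config$stages) {
    pair_fasta <- config$ppi_fasta %||% config$fasta
    seqs <- Biostrings::readAAStringSet(pair_fasta)
    seqs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
    pairs <- read_ppi_pairs(config$pairs)
    deltas <- pi_difference(pairs, seqs)
    .write_report(deltas, config, "pi_pairs")
    results$pi_pairs <- deltas
    if ("class" %in% names(deltas) && dplyr::n_distinct(deltas$class) == 2) {
      cls <- sort(unique(deltas$class))
      rep <- compare_delta_distributions(
        deltas %>% filter(.data$class == cls[1]),
        deltas %>% filter(.data$class == cls[2]),
        tail = config$tail, alpha = config$alpha
      )
      test_tbl <- tidy(rep) %>%
        mutate(set_a = cls[1], set_b = cls[2], statistic = "pi_delta")
      .write_report(test_tbl, config, "pi_delta_tests")
      results$pi_delta_tests <- test_tbl
    }
  }

  if ("orthology" %in% config$stages) {
    meta <- readr::read_tsv(config$genome_metadata, col_types = readr::cols(
      genome_id = "c", temperature = "d"
    ))
    meso <- filter_mesophiles(meta)
    queries <- partition %>%
      filter(.data$location_class %in% c("single", "dual")) %>%
      distinct(.data$accession, .data$sequence)
    qseqs <- setNames(queries$sequence, queries$accession)
    analog_list <- list()
    analog_seqs <- character()
    for (gid in intersect(names(config$genome_fastas), meso$genome_id)) {
      gset <- Biostrings::readAAStringSet(config$genome_fastas[[gid]])
      gseqs <- setNames(as.character(gset), sub("\\s.*$", "", names(gset)))
      bbh <- bidirectional_best_hits(qseqs, gseqs, max_evalue = config$evalue)
      if (nrow(bbh) > 0) {
        analog_list[[gid]] <- bbh %>% mutate(genome_id = gid)
        analog_seqs <- c(analog_seqs, gseqs[unique(bbh$target)])
      }
    }
    analogs <- bind_rows(analog_list)
    .write_report(analogs, config, "bbh_pairs")
    results$bbh_pairs <- analogs
    located <- partition %>% filter(!is.na(.data$location))
    comparison <- analog_charge_comparison(located, analogs, analog_seqs)
    .write_report(comparison, config, "analog_comparison")
    results$analog_comparison <- comparison
  }

  if ("interfaces" %in% config$stages) {
    files <- sort(list.files(config$structures_dir,
      pattern = "\\.pdb$",
      full.names = TRUE
    ))
    structures <- purrr::map(files, read_structure)
    interfaces <- extract_all_interfaces(structures, config$contact_cutoff)
    .write_report(interfaces, config, "interface_residues")
    comp <- interface_composition(interfaces)
    .write_report(comp$per_interface, config, "interface_composition")
    paired <- interface_vs_noninterface(structures, interfaces)
    .write_report(paired, config, "interface_vs_noninterface")
    results$interface_residues <- interfaces
    results$interface_composition <- comp
    results$interface_vs_noninterface <- paired
  }

  if ("tally" %in% config$stages) {
    tally <- tally_relations(config$relations)
    .write_report(tally, config, "relation_tally")
    results$relation_tally <- tally
  }

  log_lines <- c(
    paste0("stoichioprot version: ", as.character(utils::packageVersion("stoichioprot"))),
    paste0("seed: ", config$seed),
    paste0("stages: ", paste(config$stages, collapse = ", ")),
    paste0("min_species_count: ", config$min_species_count),
    paste0("evalue: ", config$evalue),
    paste0("evalue_structures: ", config$evalue_structures),
    paste0("contact_cutoff: ", config$contact_cutoff),
    paste0("alpha: ", config$alpha),
    paste0("screen_alpha: ", config$screen_alpha),
    paste0("tail: ", config$tail),
    paste0(
      "reference: ",
      paste(names(config$reference), unname(config$reference),
        sep = "=", collapse = ", "
      )
    )
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(results)
}
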