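# Nonparametric comparison with a dual criterion.
#
# Two-sample comparisons run both a Mann-Whitney U test and a
# Kolmogorov-Smirnov test; a difference is called significant only when BOTH
# p-values fall below alpha. When the two tests disagree, the believed
# interpretation follows Mann-Whitney (the more robust of the two), and the
# discrepancy is recorded in the report. No multiple-testing correction is
# applied in proteome-wide screens; screens tighten alpha (default 0.01)
# instead.

#' Mann-Whitney + Kolmogorov-Smirnov two-sample comparison
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param tail `"two"` (default), `"greater"` (a tends larger than b) or
#'   `"less"`.
#' @param alpha Significance level of the dual criterion.
#' @param exact Force the exact Mann-Whitney p-value (`TRUE`/`FALSE`);
#'   `NULL` (default) uses the exact distribution when
#'   `min(n) <= exact_max_n` and there are no ties, otherwise the normal
#'   approximation with tie correction.
#' @param exact_max_n Sample-size bound for the automatic exact switch.
#' @return A `stoich_test` object: list with `p_mannwhitney`, `p_ks`,
#'   `tail`, `alpha`, `significant`, `direction` (believed direction, from
#'   Mann-Whitney), `note` (discrepancy/degeneracy notes), `n_a`, `n_b`,
#'   `mw_exact`. Has [tidy()]/[glance()] methods.
#' @examples
#' two_sample_tests(1:10, 11:20, tail = "greater", exact = TRUE)
#' @export
two_sample_tests <- function(a, b, tail = c("two", "greater", "less"),
                             alpha = 0.05, exact = NULL, exact_max_n = 8) {
  tail <- match.arg(tail)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort("Both samples must have size >= 2.")

  note <- character()
  if (length(unique(c(a, b))) == 1) {
    warn("All values identical across both samples; tests are degenerate.")
    report <- structure(
      list(
        p_mannwhitney = 1, p_ks = 1, tail = tail, alpha = alpha,
        significant = FALSE, direction = "none",
        note = "degenerate: all values tied", n_a = length(a), n_b = length(b),
        mw_exact = FALSE
      ),
      class = "stoich_test"
    )
    return(report)
  }

  has_ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) {
    exact <- min(length(a), length(b)) <= exact_max_n && !has_ties
  }
  mw_alt <- switch(tail,
    two = "two.sided",
    greater = "greater",
    less = "less"
  )
  # ks.test's alternative refers to CDF ordering, the reverse of location
  ks_alt <- switch(tail,
    two = "two.sided",
    greater = "less",
    less = "greater"
  )
  mw <- suppressWarnings(
    wilcox.test(a, b, alternative = mw_alt, exact = exact, correct = TRUE)
  )
  ks <- suppressWarnings(ks.test(a, b, alternative = ks_alt))

  u <- unname(mw$statistic)
  direction <- if (u > length(a) * length(b) / 2) {
    "a_greater"
  } else if (u < length(a) * length(b) / 2) {
    "b_greater"
  } else {
    "none"
  }
  report <- structure(
    list(
      p_mannwhitney = unname(mw$p.value), p_ks = unname(ks$p.value),
      tail = tail, alpha = alpha, significant = NA, direction = direction,
      note = NA_character_, n_a = length(a), n_b = length(b), mw_exact = exact
    ),
    class = "stoich_test"
  )
  dual_criterion(report, alpha)
}

#' Apply the dual significance criterion to a test report
#'
#' Significance requires both the Mann-Whitney and the Kolmogorov-Smirnov
#' p-value below `alpha`. When exactly one test passes, the verdict is "not
#' significant" and the discrepancy is recorded, with interpretation
#' following Mann-Whitney.
#'
#' @param report A `stoich_test` object.
#' @param alpha Significance level.
#' @return The report with `significant`, `alpha` and `note` updated.
#' @export
dual_criterion <- function(report, alpha = report$alpha) {
  stopifnot(inherits(report, "stoich_test"))
  mw_sig <- report$p_mannwhitney < alpha
  ks_sig <- report$p_ks < alpha
  report$alpha <- alpha
  report$significant <- mw_sig && ks_sig
  if (xor(mw_sig, ks_sig)) {
    report$note <- paste0(
      "discrepancy: Mann-Whitney ", if (mw_sig) "significant" else "not significant",
      " vs Kolmogorov-Smirnov ", if (ks_sig) "significant" else "not significant",
      "; believing Mann-Whitney"
    )
  }
  report
}

#' @export
print.stoich_test <- function(x, ...) {
  cat(
    "Two-sample comparison (", x$tail, "-tailed, n = ", x$n_a, " vs ", x$n_b, ")\n",
    "  Mann-Whitney p = ", format(x$p_mannwhitney, digits = 4),
    if (x$mw_exact) " (exact)" else " (approximate)", "\n",
    "  Kolmogorov-Smirnov p = ", format(x$p_ks, digits = 4), "\n",
    "  dual criterion at alpha = ", x$alpha, ": ",
    if (isTRUE(x$significant)) "significant" else "not significant", "\n",
    sep = ""
  )
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @rdname two_sample_tests
#' @param x A `stoich_test` object.
#' @param ... Unused.
#' @export
tidy.stoich_test <- function(x, ...) {
  tibble(
    p_mannwhitney = x$p_mannwhitney, p_ks = x$p_ks, tail = x$tail,
    alpha = x$alpha, significant = x$significant, direction = x$direction,
    note = x$note, n_a = x$n_a, n_b = x$n_b, mw_exact = x$mw_exact
  )
}

#' @rdname two_sample_tests
#' @export
glance.stoich_test <- function(x, ...) tidy(x)

#' Screen locations for composition differences
#'
#' For each stoichiogenomic characteristic, tests each location's
#' per-sequence values against the pooled remaining locations (or against
#' every other location with `mode = "all_pairs"`), applying the dual
#' criterion. No multiple-testing correction is applied; the screen uses a
#' tightened default alpha of 0.01 instead.
#'
#' @param x Either a records tibble (sequences with non-NA locations) or a
#'   long tibble with columns `location`, `characteristic`, `value`.
#' @param alpha Significance level (default 0.01).
#' @param characteristics Characteristics to screen (default: all seven).
#' @param mode `"one_vs_rest"` (default) or `"all_pairs"`.
#' @param min_n Locations with fewer sequences are skipped with a warning.
#' @return Tibble with columns `characteristic`, `location` (and `other` in
#'   all-pairs mode), `n`, `n_rest`, `p_mannwhitney`, `p_ks`, `significant`,
#'   `direction`.
#' @export
screen_locations <- function(x, alpha = 0.01, characteristics = NULL,
                             mode = c("one_vs_rest", "all_pairs"), min_n = 2) {
  mode <- match.arg(mode)
  if ("sequence" %in% names(x)) {
    .check_records(x)
    located <- x %>% filter(!is.na(.data$location))
    uniq <- located %>% distinct(.data$accession, .data$sequence)
    chars <- sequence_characteristics(setNames(uniq$sequence, uniq$accession))
    long <- located %>%
      mutate(id = .data$accession) %>%
      inner_join(chars, by = "id") %>%
      tidyr::pivot_longer(
        dplyr::all_of(CHARACTERISTICS),
        names_to = "characteristic", values_to = "value"
      ) %>%
      select("location", "characteristic", "value")
  } else {
    if (!all(c("location", "characteristic", "value") %in% names(x))) {
      abort("x must be a records tibble or have columns location, characteristic, value")
    }
    long <- as_tibble(x)
  }
  if (is.null(characteristics)) {
    characteristics <- intersect(CHARACTERISTICS, unique(long$characteristic))
  }
  long <- long %>% filter(.data$characteristic %in% characteristics)

  loc_n <- long %>%
    filter(.data$characteristic == characteristics[1]) %>%
    count(.data$location, name = "n")
  small <- loc_n %>% filter(.data$n < min_n)
  if (nrow(small) > 0) {
    warn(paste0(
      "Skipping location(s) with < ", min_n, " sequences: ",
      paste(small$location, collapse = ", ")
    ))
  }
  locations <- loc_n %>%
    filter(.data$n >= min_n) %>%
    pull("location")
  if (length(locations) < 2) {
    return(tibble(
      characteristic = character(), location = character(),
      n = integer(), n_rest = integer(), p_mannwhitney = numeric(),
      p_ks = numeric(), significant = logical(), direction = character()
    ))
  }

  run_one <- function(char, loc, other = NULL) {
    vals <- long %>% filter(.data$characteristic == char)
    in_loc <- vals %>%
      filter(.data$location == loc) %>%
      pull("value")
    rest <- if (is.null(other)) {
      vals %>%
        filter(.data$location != loc, .data$location %in% locations) %>%
        pull("value")
    } else {
      vals %>%
        filter(.data$location == other) %>%
        pull("value")
    }
    rep <- two_sample_tests(in_loc, rest, tail = "two", alpha = alpha)
    tibble(
      characteristic = char, location = loc,
      other = other %||% "rest",
      n = length(in_loc), n_rest = length(rest),
      p_mannwhitney = rep$p_mannwhitney, p_ks = rep$p_ks,
      significant = rep$significant, direction = rep$direction
    )
  }

  out <- if (mode == "one_vs_rest") {
    purrr::map(characteristics, function(char) {
      purrr::map(locations, function(loc) run_one(char, loc))
    })
  } else {
    pairs <- combn(locations, 2, simplify = FALSE)
    purrr::map(characteristics, function(char) {
      purrr::map(pairs, function(pr) run_one(char, pr[1], pr[2]))
    })
  }
  out <- bind_rows(purrr::flatten(out))
  if (mode == "one_vs_rest") out <- out %>% select(-"other")
  out
}

#' Tukey HSD multi-group comparison
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference
#' adjusted pairwise comparisons.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each size >= 2),
#'   or a data frame with columns `group` and `value`.
#' @return Tibble with one row per group pair: `group_1`, `group_2`, `diff`,
#'   `conf_low`, `conf_high`, `p_adj`.
#' @export
tukey_multigroup <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups))) {
      abort("Data-frame input must have columns group and value")
    }
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 3) {
    abort("Tukey comparison needs >= 3 groups; use two_sample_tests() for 2.")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) abort("Every group must have size >= 2.")
  df <- tibble(
    group = factor(rep(names(groups), sizes)),
    value = unlist(groups, use.names = FALSE)
  )
  fit <- aov(value ~ group, data = df)
  hsd <- TukeyHSD(fit)$group
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tibble(
    group_1 = vapply(pairs, `[`, character(1), 1),
    group_2 = vapply(pairs, `[`, character(1), 2),
    diff = hsd[, "diff"], conf_low = hsd[, "lwr"],
    conf_high = hsd[, "upr"], p_adj = hsd[, "p adj"]
  )
}

#' KEGG-style relation vocabulary
#' @export
RELATION_TYPES <- c(
  "activation", "binding/association", "complex", "indirect effect",
  "inhibition", "phosphorylation", "dissociation", "dephosphorylation",
  "state change"
)

#' Tally functional-relationship categories
#'
#' Counts and percentages (1 decimal, denominator = total rows) of relation
#' types between proteins and their upstream/downstream partners. Unknown
#' relation types are tallied under `"other"` with a warning.
#'
#' @param relations Tibble with columns `protein`, `partner`, `relation`
#'   (or a path to a 3-column TSV with that header).
#' @param by Optional grouping column (e.g. `"protein"`) for per-protein
#'   breakdowns.
#' @return Tibble with columns (`by`,) `relation`, `n`, `percentage`,
#'   ordered by decreasing count within group.
#' @export
tally_relations <- function(relations, by = NULL) {
  if (is.character(relations) && length(relations) == 1) {
    relations <- readr::read_tsv(relations, col_types = readr::cols(.default = "c"))
  }
  relations <- as_tibble(relations)
  if (!all(c("protein", "partner", "relation") %in% names(relations))) {
    abort("relations must have columns protein, partner, relation")
  }
  if (nrow(relations) == 0) abort("relations table is empty")
  rel <- tolower(stringr::str_squish(relations$relation))
  unknown <- setdiff(unique(rel), RELATION_TYPES)
  if (length(unknown) > 0) {
    warn(paste0(
      "Unknown relation type(s) counted as 'other': ",
      paste(unknown, collapse = ", ")
    ))
    rel[rel %in% unknown] <- "other"
  }
  relations$relation <- rel
  grouping <- c(by, "relation")
  relations %>%
    group_by(across(dplyr::all_of(grouping))) %>%
    summarise(n = dplyr::n(), .groups = "drop_last") %>%
    mutate(percentage = round(100 * .data$n / sum(.data$n), 1)) %>%
    arrange(dplyr::desc(.data$n), .by_group = TRUE) %>%
    ungroup()
}
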