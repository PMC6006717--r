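# Numeric summaries are the primary output; these plots are quick visual
# checks of the main result types.

#' Plot group-mean composition profiles
#'
#' Bar chart of per-location characteristic means, faceted by
#' characteristic.
#'
#' @param profiles Long profile tibble from [proteome_profile()].
#' @return A ggplot object.
#' @export
plot_composition_profiles <- function(profiles) {
  ggplot2::ggplot(
    profiles,
    ggplot2::aes(x = .data$location, y = .data$mean, fill = .data$species)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~characteristic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean content (per residue)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the isoelectric-point distribution of protein pairs
#'
#' Overlaid histograms of the lower (PImin) and higher (PImax) isoelectric
#' point of each pair; complementary pair sets show two modes separated
#' near pH 7.
#'
#' @param pairs Tibble from [pi_difference()].
#' @param binwidth Histogram bin width (pH units).
#' @return A ggplot object.
#' @export
plot_pi_distribution <- function(pairs, binwidth = 0.25) {
  long <- pairs %>%
    select("pi_min", "pi_max") %>%
    tidyr::pivot_longer(dplyr::everything(),
      names_to = "member", values_to = "pi"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pi, fill = .data$member)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = 7, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(pi_min = "#c0392b", pi_max = "#27ae60")) +
    ggplot2::labs(x = "isoelectric point", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot content ratios relative to a reference
#'
#' @param ratios Tibble with columns `location`, `characteristic`, `ratio`
#'   (e.g. the pipeline's normalized-ratios report).
#' @return A ggplot object.
#' @export
plot_normalized_ratios <- function(ratios) {
  ggplot2::ggplot(
    ratios,
    ggplot2::aes(
      x = .data$location, y = .data$ratio,
      fill = .data$ratio > 1
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~characteristic) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#e78ac3", `FALSE` = "#8da0cb"),
      labels = c(`TRUE` = "higher", `FALSE` = "lower"), name = NULL
    ) +
    ggplot2::labs(x = NULL, y = "content / reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
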