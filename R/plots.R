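#' Plot the TM-count distribution of protein sets
#'
#' @param dist Tibble from [tm_count_distribution()].
#' @return A ggplot object (grouped bars of the fraction of proteins per
#'   TM-segment count).
#' @export
plot_tm_count_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(
    x = factor(.data$tm_count), y = .data$fraction, fill = .data$set
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "TM segments", y = "fraction of proteins",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-residue variant frequency by topological label
#'
#' @param freqs Tibble from [region_frequency()].
#' @return A ggplot object.
#' @export
plot_region_frequency <- function(freqs) {
  ggplot2::ggplot(freqs, ggplot2::aes(
    x = .data$label, y = .data$frequency, fill = .data$classification
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "variants per residue", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot center-distance histograms
#'
#' @param hist Tibble from [center_distance_histogram()].
#' @return A ggplot object (relative frequency vs. normalized distance
#'   from the TM-segment center, one panel colour per source).
#' @export
plot_center_distance <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(
    x = .data$bin_start, y = .data$frequency, fill = .data$source
  )) +
    ggplot2::geom_col(position = "dodge",
                      width = min(hist$bin_end - hist$bin_start)) +
    ggplot2::labs(x = "normalized distance from TM center",
                  y = "relative frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a slice profile along the membrane normal
#'
#' @param profile A [slice_profile()] result.
#' @param min_residues Hide slices supported by fewer residues (default
#'   1; sparse outer slices give noisy ratios).
#' @return A ggplot object of per-class relative frequency vs. z.
#' @export
plot_slice_profile <- function(profile, min_residues = 1L) {
  df <- tibble::as_tibble(profile) |>
    dplyr::filter(.data$residues >= min_residues) |>
    tidyr::pivot_longer(c("f_disease", "f_polymorphism"),
                        names_to = "class", names_prefix = "f_",
                        values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$z_low + .data$z_high) / 2, y = .data$frequency,
    colour = .data$class
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Angstrom, membrane normal)",
                  y = "variants per residue", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of permutation z-scores for one stratum
#'
#' @param perm A [permutation_null()] result.
#' @param label Region label (default `"M"`).
#' @param classification Variant class (default `"Disease"`).
#' @return A ggplot object (mutated residue rows, mutant residue
#'   columns, tile fill = z).
#' @export
plot_permutation_z <- function(perm, label = "M",
                               classification = "Disease") {
  df <- tidy(perm) |>
    dplyr::filter(.data$label == !!label,
                  .data$classification == !!classification) |>
    dplyr::mutate(
      ref_aa = factor(.data$ref_aa, rev(aa_order)),
      alt_aa = factor(.data$alt_aa, aa_order)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$alt_aa, .data$ref_aa,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::labs(x = "mutant residue", y = "mutated residue",
                  fill = "z") +
    ggplot2::theme_minimal()
}
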