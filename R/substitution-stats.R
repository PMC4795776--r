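#' Count amino-acid substitutions per stratum
#'
#' Tallies the (reference residue, mutant residue) pairs of the mapped
#' variants within each (topological label, variant class) stratum. The
#' result is a long table over the complete 20x20 grid with the diagonal
#' structurally absent.
#'
#' @param assignments Tibble from [assign_regions()].
#' @param stratify_by `"region"` (I/M/O) or `"subregion"`
#'   (N-terminal/TM/loop/C-terminal).
#' @return Tibble with columns `label`, `classification`, `ref_aa`,
#'   `alt_aa`, `n` (one row per off-diagonal cell per observed stratum).
#' @export
count_substitutions <- function(assignments,
                                stratify_by = c("region", "subregion")) {
  stratify_by <- match.arg(stratify_by)
  a <- assignments |>
    dplyr::filter(!is.na(.data[[stratify_by]])) |>
    dplyr::mutate(label = .data[[stratify_by]])
  strata <- dplyr::distinct(a, .data$label, .data$classification)
  grid <- tidyr::expand_grid(
    strata,
    ref_aa = aa_order, alt_aa = aa_order
  ) |>
    dplyr::filter(.data$ref_aa != .data$alt_aa)
  counts <- a |>
    dplyr::count(.data$label, .data$classification, .data$ref_aa,
                 .data$alt_aa, name = "n")
  grid |>
    dplyr::left_join(counts,
                     by = c("label", "classification", "ref_aa", "alt_aa")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Cast one stratum of a long substitution table to a 20x20 matrix
#'
#' @param counts Output of [count_substitutions()].
#' @param label,classification Stratum selectors.
#' @param value Column to spread (default `"n"`).
#' @return 20x20 matrix in [aa_order] with zero diagonal.
#' @export
substitution_matrix <- function(counts, label, classification, value = "n") {
  sub <- counts[counts$label == label &
                  counts$classification == classification, ]
  m <- matrix(0, 20, 20, dimnames = list(aa_order, aa_order))
  m[cbind(sub$ref_aa, sub$alt_aa)] <- sub[[value]]
  m
}

#' Convert substitution counts to percentages of the stratum total
#'
#' Each cell becomes `100 * count / total` so a stratum's cells sum to
#' 100. Errors if the total is zero.
#'
#' @param x A count matrix, or a long count tibble from
#'   [count_substitutions()] (percentages then computed per stratum).
#' @return Same shape as the input with a `percent` value.
#' @export
to_percent <- function(x) {
  if (is.matrix(x)) {
    total <- sum(x)
    if (total <= 0) stop("cannot convert an empty matrix to percentages",
                         call. = FALSE)
    return(100 * x / total)
  }
  x |>
    dplyr::group_by(.data$label, .data$classification) |>
    dplyr::mutate(percent = {
      total <- sum(.data$n)
      if (total <= 0) stop("empty stratum: ", .data$label[[1]], "/",
                           .data$classification[[1]], call. = FALSE)
      100 * .data$n / total
    }) |>
    dplyr::ungroup()
}

#' Aggregate a substitution matrix into polarity classes
#'
#' Collapses the 20x20 substitution counts into a 3x3 table over the
#' charged / non-polar / polar side-chain groups (see
#' [polarity_classes()]). Unlike the residue-level matrix, the diagonal
#' may be non-zero (e.g. Val->Leu is non-polar to non-polar). The total
#' equals the parent matrix total.
#'
#' @param matrix 20x20 count (or percent) matrix.
#' @param percent Also return the percent form (default `TRUE`).
#' @return A list with `counts` (3x3) and, if requested, `percent` (3x3
#'   summing to 100 when the input is non-empty).
#' @export
polarity_matrix <- function(matrix, percent = TRUE) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == 20))
  matrix <- matrix[aa_order, aa_order]
  cls <- unname(.polarity_map[aa_order])
  m3 <- matrix(0, 3, 3, dimnames = list(.polarity_order, .polarity_order))
  for (i in .polarity_order) {
    for (j in .polarity_order) {
      m3[i, j] <- sum(matrix[cls == i, cls == j])
    }
  }
  out <- list(counts = m3)
  if (percent) {
    out$percent <- if (sum(m3) > 0) 100 * m3 / sum(m3) else m3
  }
  out
}

#' Per-residue variant frequency by topological label
#'
#' Divides the number of mapped variants of each class within a label by
#' the total number of residues carrying that label across the proteome,
#' giving variants per residue (the normalization used to compare regions
#' of different total size).
#'
#' @param assignments Tibble from [assign_regions()].
#' @param lengths Tibble from [region_lengths()]; its stratification must
#'   match `stratify_by`.
#' @param stratify_by `"region"` or `"subregion"`.
#' @return Tibble with `label`, `classification`, `n`, `residues`,
#'   `frequency`.
#' @export
region_frequency <- function(assignments, lengths,
                             stratify_by = c("region", "subregion")) {
  stratify_by <- match.arg(stratify_by)
  lengths <- lengths[lengths$residues > 0, ]
  assignments |>
    dplyr::filter(!is.na(.data[[stratify_by]])) |>
    dplyr::count(label = .data[[stratify_by]], .data$classification) |>
    dplyr::inner_join(lengths, by = "label") |>
    dplyr::mutate(frequency = .data$n / .data$residues)
}

#' Predictive value of frequent transmembrane substitutions
#'
#' For every substitution type observed in the membrane region, the
#' predictive value is the number of disease-associated occurrences
#' divided by the total (disease + polymorphism) occurrences, reported
#' only for substitutions whose total exceeds the threshold.
#'
#' @param disease_matrix,polymorphism_matrix 20x20 count matrices for the
#'   same stratum (typically TM).
#' @param threshold Minimum combined count (exclusive; default 100).
#' @return Tibble with `ref_aa`, `alt_aa`, `disease`, `polymorphism`,
#'   `total`, `predictive_value`, sorted by decreasing predictive value.
#' @export
predictive_values <- function(disease_matrix, polymorphism_matrix,
                              threshold = 100) {
  stopifnot(all(dim(disease_matrix) == 20),
            all(dim(polymorphism_matrix) == 20))
  d <- disease_matrix[aa_order, aa_order]
  p <- polymorphism_matrix[aa_order, aa_order]
  grid <- tidyr::expand_grid(ref_aa = aa_order, alt_aa = aa_order) |>
    dplyr::filter(.data$ref_aa != .data$alt_aa) |>
    dplyr::mutate(
      disease = d[cbind(.data$ref_aa, .data$alt_aa)],
      polymorphism = p[cbind(.data$ref_aa, .data$alt_aa)],
      total = .data$disease + .data$polymorphism
    ) |>
    dplyr::filter(.data$total > threshold) |>
    dplyr::mutate(predictive_value = .data$disease / .data$total) |>
    dplyr::arrange(dplyr::desc(.data$predictive_value),
                   dplyr::desc(.data$total))
  grid
}
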