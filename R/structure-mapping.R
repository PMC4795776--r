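#' Variant and residue density in slices along the membrane normal
#'
#' Cuts the structure(s) into slices of `slice_width` Angstrom parallel
#' to the membrane plane (slice k covers the half-open interval
#' `[k*w, (k+1)*w)`; a residue at depth z falls in slice `floor(z/w)`),
#' counts all residues with coordinates as well as the disease and
#' polymorphism variants mapped onto them, and reports per-class
#' relative frequencies `class count / residue count` per slice.
#' Variants on residues without coordinates are excluded and reported in
#' the `unmapped` attribute; slices containing no residues are omitted.
#'
#' @param z_map Tibble with columns `protein_id`, `position`, `z` from
#'   [read_structure_frame()] or [generate_structures()] (membrane frame
#'   already applied: z along the membrane normal, origin at the bilayer
#'   center).
#' @param assignments Tibble from [assign_regions()].
#' @param slice_width Slice width in Angstrom (default 1.0).
#' @return Tibble of class `tmvar_slice_profile` with columns `slice`,
#'   `z_low`, `z_high`, `residues`, `disease`, `polymorphism`,
#'   `f_disease`, `f_polymorphism`; attributes `slice_width` and
#'   `unmapped`.
#' @export
slice_profile <- function(z_map, assignments, slice_width = 1.0) {
  if (slice_width <= 0) stop("slice_width must be positive", call. = FALSE)
  z_map <- tibble::as_tibble(z_map)
  res_counts <- z_map |>
    dplyr::mutate(slice = floor(.data$z / slice_width)) |>
    dplyr::count(.data$slice, name = "residues")

  mapped <- assignments |>
    dplyr::inner_join(z_map, by = c("protein_id", "position"))
  unmapped <- nrow(assignments) - nrow(mapped)
  var_counts <- mapped |>
    dplyr::mutate(slice = floor(.data$z / slice_width)) |>
    dplyr::count(.data$slice, .data$classification) |>
    tidyr::pivot_wider(names_from = "classification", values_from = "n",
                       values_fill = 0L)
  for (cl in c("Disease", "Polymorphism")) {
    if (!cl %in% names(var_counts)) var_counts[[cl]] <- 0L
  }

  out <- res_counts |>
    dplyr::left_join(
      dplyr::select(var_counts, "slice", disease = "Disease",
                    polymorphism = "Polymorphism"),
      by = "slice"
    ) |>
    dplyr::mutate(
      disease = tidyr::replace_na(.data$disease, 0L),
      polymorphism = tidyr::replace_na(.data$polymorphism, 0L),
      z_low = .data$slice * slice_width,
      z_high = (.data$slice + 1) * slice_width,
      f_disease = .data$disease / .data$residues,
      f_polymorphism = .data$polymorphism / .data$residues
    ) |>
    dplyr::arrange(.data$slice) |>
    dplyr::select("slice", "z_low", "z_high", "residues", "disease",
                  "polymorphism", "f_disease", "f_polymorphism")
  structure(out, class = c("tmvar_slice_profile", class(out)),
            slice_width = slice_width, unmapped = unmapped)
}

#' Pool slice profiles across proteins
#'
#' Sums residue and variant counts slice-wise across profiles before
#' re-taking the ratio (ratio of sums, not mean of ratios), which is the
#' pooled relative frequency of the combined structure set. All profiles
#' must share the same slice width.
#'
#' @param profiles A list of [slice_profile()] results.
#' @return A pooled `tmvar_slice_profile`.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  widths <- purrr::map_dbl(profiles, ~ attr(.x, "slice_width"))
  if (length(unique(widths)) != 1) {
    stop("profiles have different slice widths", call. = FALSE)
  }
  w <- widths[[1]]
  out <- purrr::list_rbind(purrr::map(profiles, tibble::as_tibble)) |>
    dplyr::group_by(.data$slice) |>
    dplyr::summarise(
      residues = sum(.data$residues),
      disease = sum(.data$disease),
      polymorphism = sum(.data$polymorphism),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      z_low = .data$slice * w,
      z_high = (.data$slice + 1) * w,
      f_disease = .data$disease / .data$residues,
      f_polymorphism = .data$polymorphism / .data$residues
    ) |>
    dplyr::arrange(.data$slice) |>
    dplyr::select("slice", "z_low", "z_high", "residues", "disease",
                  "polymorphism", "f_disease", "f_polymorphism")
  structure(out, class = c("tmvar_slice_profile", class(out)),
            slice_width = w,
            unmapped = sum(purrr::map_int(profiles,
                                          ~ attr(.x, "unmapped") %||% 0L)))
}
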