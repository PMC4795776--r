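#' Assign variants to topological segments
#'
#' Intersects each variant's residue position with the protein's topology
#' segments (a point position falls in exactly one segment of the tiling)
#' and attaches the region, subregion, segment ordinal and 0-based offset
#' from the segment start. Before assignment the analysis filters are
#' applied: unclassified variants are excluded, disease variants
#' associated with more than one distinct disease name ("ambiguous") are
#' removed, variants whose reference residue disagrees with the sequence
#' are dropped, and variants on unknown proteins or beyond the sequence
#' length are skipped. All drop counts are conserved in the `drop_report`
#' attribute (see [parse_report()]).
#'
#' @param variants Variant tibble from [read_variants()] or
#'   [generate_variants()].
#' @param proteome A [tm_proteome()].
#' @param drop_unclassified,drop_ambiguous Apply the corresponding filter
#'   (default `TRUE`).
#' @param check_ref Verify `ref_aa` against the sequence (default `TRUE`).
#' @return Tibble of assignments: the variant columns plus `region`,
#'   `subregion`, `segment_index`, `offset`, `is_tmp`, with attribute
#'   `drop_report`.
#' @export
assign_regions <- function(variants, proteome, drop_unclassified = TRUE,
                           drop_ambiguous = TRUE, check_ref = TRUE) {
  stopifnot(inherits(proteome, "tm_proteome"))
  v <- tibble::as_tibble(variants)
  n_input <- nrow(v)

  n_unclassified <- 0L
  if (drop_unclassified) {
    keep <- v$classification != "Unclassified"
    n_unclassified <- sum(!keep)
    v <- v[keep, ]
  }
  n_ambiguous <- 0L
  if (drop_ambiguous && "disease_names" %in% names(v)) {
    multi <- v$classification == "Disease" &
      purrr::map_int(v$disease_names, ~ length(unique(.x))) > 1
    n_ambiguous <- sum(multi)
    v <- v[!multi, ]
  }
  known <- v$protein_id %in% names(proteome$sequences)
  n_unknown <- sum(!known)
  v <- v[known, ]
  lens <- proteome$proteins$length[match(v$protein_id,
                                         proteome$proteins$protein_id)]
  inside <- v$position >= 1 & v$position <= lens
  n_range <- sum(!inside)
  v <- v[inside, ]
  n_mismatch <- 0L
  if (check_ref && nrow(v) > 0) {
    seq_res <- substr(proteome$sequences[v$protein_id], v$position,
                      v$position)
    ok <- seq_res == v$ref_aa
    n_mismatch <- sum(!ok)
    v <- v[ok, ]
  }

  assigned <- v |>
    dplyr::inner_join(
      proteome$segments,
      by = dplyr::join_by("protein_id",
                          between(x$position, y$start, y$end))
    ) |>
    dplyr::mutate(offset = .data$position - .data$start) |>
    dplyr::select(-"start", -"end") |>
    dplyr::left_join(
      dplyr::select(proteome$proteins, "protein_id", "is_tmp"),
      by = "protein_id"
    )

  attr(assigned, "drop_report") <- tibble::tibble(
    input = n_input,
    assigned = nrow(assigned),
    dropped_unclassified = n_unclassified,
    dropped_ambiguous = n_ambiguous,
    dropped_unknown_protein = n_unknown,
    dropped_out_of_range = n_range,
    dropped_ref_mismatch = n_mismatch
  )
  assigned
}
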