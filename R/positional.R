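#' Normalized distance from the center of a TM segment
#'
#' The center is the most central residue, `floor((start + end) / 2)`
#' (the lower median for even-length segments), and the distance is the
#' signed residue offset from it divided by the segment length, so
#' values lie in [-0.5, 0.5].
#'
#' @param position Residue position(s), 1-based.
#' @param start,end Segment bounds, 1-based inclusive.
#' @return Numeric vector of normalized distances.
#' @examples
#' center_distance(21, 11, 31)  # 0 at the central residue
#' center_distance(31, 11, 31)  # 10/21 at the segment edge
#' @export
center_distance <- function(position, start, end) {
  if (any(position < start | position > end)) {
    stop("position outside the segment", call. = FALSE)
  }
  center <- floor((start + end) / 2)
  (position - center) / (end - start + 1)
}

#' Center distances of TM-mapped variants
#'
#' Computes the normalized distance from the TM-segment center for every
#' assignment that falls in a membrane segment, optionally restricted to
#' one substitution type (e.g. Gly->Arg disease mutations).
#'
#' @param assignments Tibble from [assign_regions()].
#' @param proteome The matching [tm_proteome()].
#' @param ref_aa,alt_aa Optional residue filters.
#' @return Tibble with `source` (classification), `protein_id`,
#'   `position`, `ref_aa`, `alt_aa`, `d` (signed normalized distance).
#' @export
variant_center_distances <- function(assignments, proteome,
                                     ref_aa = NULL, alt_aa = NULL) {
  a <- assignments[assignments$region == "M", ]
  if (!is.null(ref_aa)) a <- a[a$ref_aa %in% ref_aa, ]
  if (!is.null(alt_aa)) a <- a[a$alt_aa %in% alt_aa, ]
  a |>
    dplyr::inner_join(
      dplyr::select(proteome$segments, "protein_id", "segment_index",
                    "start", "end"),
      by = c("protein_id", "segment_index")
    ) |>
    dplyr::mutate(
      d = center_distance(.data$position, .data$start, .data$end),
      source = paste0(tolower(.data$classification), "_variant")
    ) |>
    dplyr::select("source", "protein_id", "position", "ref_aa", "alt_aa",
                  "d")
}

#' Naturally occurring residues within TM segments
#'
#' Scans the membrane segments of every TMP for a given residue (arginine
#' by default), records its normalized distance from the segment center,
#' and tallies the host proteins over TM-segment-count categories --
#' e.g. to ask whether membrane arginines cluster in 7-TM receptors.
#'
#' @param proteome A [tm_proteome()].
#' @param residue One-letter residue code (default `"R"`).
#' @return List with `records` (tibble `source`, `protein_id`,
#'   `position`, `residue`, `d`, `tm_count`) and `hosts` (tibble
#'   `tm_count`, `n_proteins` over proteins with >= 1 occurrence).
#' @export
natural_residue_positions <- function(proteome, residue = "R") {
  stopifnot(residue %in% aa_order)
  m <- proteome$segments[proteome$segments$region == "M", ]
  recs <- purrr::pmap(
    list(m$protein_id, m$start, m$end),
    function(pid, a, b) {
      seg <- substr(proteome$sequences[[pid]], a, b)
      hits <- which(strsplit(seg, "")[[1]] == residue)
      if (length(hits) == 0) return(NULL)
      pos <- a + hits - 1L
      tibble::tibble(
        source = "natural_residue", protein_id = pid, position = pos,
        residue = residue, d = center_distance(pos, a, b)
      )
    }
  ) |>
    purrr::compact() |>
    purrr::list_rbind()
  if (is.null(recs) || nrow(recs) == 0) {
    recs <- tibble::tibble(source = character(), protein_id = character(),
                           position = integer(), residue = character(),
                           d = numeric())
  }
  recs <- dplyr::left_join(
    recs,
    dplyr::select(proteome$proteins, "protein_id", "tm_count"),
    by = "protein_id"
  )
  hosts <- recs |>
    dplyr::distinct(.data$protein_id, .data$tm_count) |>
    dplyr::count(.data$tm_count, name = "n_proteins")
  list(records = recs, hosts = hosts)
}

#' Relative-frequency histogram of center distances
#'
#' Bins normalized center distances into half-open intervals
#' `[k*w, (k+1)*w)` and normalizes counts to relative frequencies within
#' each source. By default distances are folded to |d| (distance from
#' the central residue, non-negative); signed histograms are available
#' with `absolute = FALSE`.
#'
#' @param records Tibble with columns `source` and `d` (e.g. from
#'   [variant_center_distances()] or
#'   `natural_residue_positions()$records`).
#' @param bin_width Bin width on the normalized scale (default 0.05).
#' @param absolute Fold to |d| first (default `TRUE`).
#' @return Tibble with `source`, `bin_start`, `bin_end`, `n`,
#'   `frequency` (summing to 1 per source).
#' @export
center_distance_histogram <- function(records, bin_width = 0.05,
                                      absolute = TRUE) {
  stopifnot(bin_width > 0)
  v <- if (absolute) abs(records$d) else records$d
  records |>
    dplyr::mutate(bin = floor(v / bin_width)) |>
    dplyr::count(.data$source, .data$bin, name = "n") |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      bin_start = .data$bin * bin_width,
      bin_end = (.data$bin + 1) * bin_width
    ) |>
    dplyr::select("source", "bin_start", "bin_end", "n", "frequency")
}
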