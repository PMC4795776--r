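#' Build a proteome object from sequences and topology segments
#'
#' Binds protein sequences to their membrane topology. Every protein's
#' segments must tile the sequence exactly (start at 1, end at the sequence
#' length, no gaps or overlaps) and consecutive segments must differ in
#' region; a membrane (M) segment always separates an inside (I) from an
#' outside (O) segment. Subregions (N-terminal, TM, loop, C-terminal) are
#' labelled on construction for all transmembrane proteins.
#'
#' @param sequences Named character vector of amino-acid sequences
#'   (names are protein accessions), or the output of [read_fasta()].
#' @param segments Tibble of topology segments with columns `protein_id`,
#'   `region` (one of `"I"`, `"M"`, `"O"`), `start`, `end` (1-based,
#'   inclusive), e.g. from [read_topology()].
#' @return An object of class `tm_proteome`: a list with elements
#'   `sequences` (named character), `segments` (tibble with
#'   `segment_index` and `subregion` added) and `proteins` (tibble with
#'   `protein_id`, `length`, `tm_count`, `is_tmp`).
#' @examples
#' seqs <- c(P1 = strrep("A", 60))
#' segs <- tibble::tibble(
#'   protein_id = "P1", region = c("I", "M", "O"),
#'   start = c(1, 11, 31), end = c(10, 30, 60)
#' )
#' tm_proteome(seqs, segs)
#' @export
tm_proteome <- function(sequences, segments) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sequences <- toupper(sequences)
  segments <- tibble::as_tibble(segments)
  req <- c("protein_id", "region", "start", "end")
  if (!all(req %in% names(segments))) {
    stop("segments must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  missing_seq <- setdiff(unique(segments$protein_id), names(sequences))
  if (length(missing_seq) > 0) {
    stop("no sequence for protein(s): ",
         paste(utils::head(missing_seq, 5), collapse = ", "), call. = FALSE)
  }

  segments <- segments |>
    dplyr::arrange(.data$protein_id, .data$start) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(segment_index = dplyr::row_number()) |>
    dplyr::ungroup()

  lens <- nchar(sequences)
  for (pid in unique(segments$protein_id)) {
    seg <- segments[segments$protein_id == pid, ]
    reason <- validate_segments(seg$region, seg$start, seg$end, lens[[pid]])
    if (!is.null(reason)) {
      stop("invalid topology for ", pid, ": ", reason, call. = FALSE)
    }
  }

  segments <- segments |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(subregion = subregion_labels(.data$region)) |>
    dplyr::ungroup()

  proteins <- segments |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(tm_count = sum(.data$region == "M"), .groups = "drop") |>
    dplyr::mutate(
      length = unname(lens[.data$protein_id]),
      is_tmp = .data$tm_count >= 1
    ) |>
    dplyr::select("protein_id", "length", "tm_count", "is_tmp")

  structure(
    list(
      sequences = sequences[proteins$protein_id],
      segments = segments,
      proteins = proteins
    ),
    class = "tm_proteome"
  )
}

# returns NULL if valid, otherwise a one-word-ish reason string
validate_segments <- function(region, start, end, seq_len = NULL) {
  if (length(region) == 0) return("no segments")
  if (!all(region %in% c("I", "M", "O"))) return("unknown region letter")
  if (any(start > end)) return("segment with start > end")
  o <- order(start)
  start <- start[o]; end <- end[o]; region <- region[o]
  if (start[1] != 1) return("does not start at residue 1")
  if (length(start) > 1) {
    d <- start[-1] - end[-length(end)]
    if (any(d < 1)) return("overlapping segments")
    if (any(d > 1)) return("gap between segments")
  }
  if (any(region[-1] == region[-length(region)])) {
    return("consecutive segments share a region")
  }
  # topology alternation: never I adjacent to O without an M between
  adj <- paste0(region[-length(region)], region[-1])
  if (any(adj %in% c("IO", "OI"))) return("I/O segments adjacent without M")
  if (!is.null(seq_len) && end[length(end)] != seq_len) {
    return("segments do not cover the sequence")
  }
  NULL
}

#' Label topological subregions of a single protein's segments
#'
#' For a transmembrane protein, the segment before the first membrane
#' segment is the N-terminal, the segment after the last membrane segment
#' is the C-terminal, membrane segments are TM, and every other
#' inside/outside segment is a loop. Single-pass proteins therefore have
#' no loops. [tm_proteome()] applies this labelling automatically.
#'
#' @param segments Tibble of one protein's segments ordered by `start`,
#'   with a `region` column.
#' @return The tibble with a `subregion` column
#'   (`"N_TERMINAL"`, `"TM"`, `"LOOP"`, `"C_TERMINAL"`).
#' @export
label_subregions <- function(segments) {
  if (!any(segments$region == "M")) {
    stop("not a transmembrane protein: no M segment", call. = FALSE)
  }
  segments$subregion <- subregion_labels(segments$region)
  segments
}

subregion_labels <- function(region) {
  m <- which(region == "M")
  if (length(m) == 0) return(rep(NA_character_, length(region)))
  out <- rep("LOOP", length(region))
  out[region == "M"] <- "TM"
  if (m[1] > 1) out[seq_len(m[1] - 1)] <- "N_TERMINAL"
  last <- m[length(m)]
  if (last < length(region)) out[(last + 1):length(region)] <- "C_TERMINAL"
  out
}

#' @export
print.tm_proteome <- function(x, ...) {
  n <- nrow(x$proteins)
  ntmp <- sum(x$proteins$is_tmp)
  cat("<tm_proteome> ", n, " proteins (", ntmp, " TMPs, ",
      n - ntmp, " non-TMPs), ", sum(x$proteins$length),
      " residues\n", sep = "")
  invisible(x)
}

#' Total residue counts per topological label
#'
#' Sums segment lengths across the proteome, stratified either by region
#' (I/M/O) or by subregion (N-terminal/TM/loop/C-terminal). These totals
#' are the denominators for per-residue variant rates.
#'
#' @param proteome A [tm_proteome()].
#' @param stratify_by `"region"` or `"subregion"`.
#' @param tmp_only Restrict to transmembrane proteins (default `TRUE`;
#'   non-TMPs have no subregion labels).
#' @return Tibble with columns `label` and `residues`.
#' @export
region_lengths <- function(proteome, stratify_by = c("region", "subregion"),
                           tmp_only = TRUE) {
  stratify_by <- match.arg(stratify_by)
  segs <- proteome$segments
  if (tmp_only) {
    tmps <- proteome$proteins$protein_id[proteome$proteins$is_tmp]
    segs <- segs[segs$protein_id %in% tmps, ]
  }
  if (nrow(segs) == 0) {
    return(tibble::tibble(label = character(), residues = integer()))
  }
  segs |>
    dplyr::mutate(label = .data[[stratify_by]]) |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(residues = sum(.data$end - .data$start + 1L),
                     .groups = "drop")
}

#' Distribution of proteins over TM-segment counts
#'
#' For each named set of proteins, the fraction having k membrane segments,
#' k = 1..`max_k`. Proteins with more than `max_k` TM segments stay in the
#' denominator but are not reported, so fractions may sum to less than 1.
#'
#' @param proteome A [tm_proteome()].
#' @param protein_sets Named list of character vectors of protein ids.
#' @param max_k Largest TM count reported (default 12).
#' @return Tibble with columns `set`, `tm_count`, `n`, `fraction`.
#' @export
tm_count_distribution <- function(proteome, protein_sets, max_k = 12L) {
  stopifnot(is.list(protein_sets), !is.null(names(protein_sets)))
  purrr::imap(protein_sets, function(ids, nm) {
    info <- proteome$proteins[proteome$proteins$protein_id %in% ids &
                                proteome$proteins$is_tmp, ]
    denom <- nrow(info)
    tibble::tibble(set = nm, tm_count = seq_len(max_k)) |>
      dplyr::mutate(
        n = purrr::map_int(.data$tm_count, ~ sum(info$tm_count == .x)),
        fraction = if (denom > 0) .data$n / denom else 0
      )
  }) |>
    purrr::list_rbind()
}
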