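#' Read per-protein membrane topology annotations
#'
#' Two dialects. `"tsv"`: one header line with columns `protein_id`,
#' `region` (I/M/O), `start`, `end` (1-based inclusive). `"htp_xml"`: an
#' XML document of the form
#' `<proteins><protein id="..."><segment region="M" from="11" to="30"/>...`
#' with one ordered `segment` element per topology stretch (a documented
#' stand-in dialect for topology-database exports; adapt real exports to
#' it upstream).
#'
#' Each protein's segments are validated: regions must be I/M/O, segments
#' must start at residue 1 and tile without gaps or overlaps, consecutive
#' segments must differ in region, and inside may not touch outside
#' without a membrane segment between. Proteins failing validation are
#' rejected with a named reason, available via [parse_report()].
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` (default) or `"htp_xml"`.
#' @return Tibble of accepted segments (`protein_id`, `region`, `start`,
#'   `end`) with a `rejected` attribute
#'   (tibble `protein_id`, `reason`).
#' @export
read_topology <- function(path, dialect = c("tsv", "htp_xml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("protein_id", "region", "start", "end")
    if (!all(req %in% names(df))) {
      stop("malformed topology tsv; need columns ",
           paste(req, collapse = ", "), call. = FALSE)
    }
    segs <- tibble::as_tibble(df[req])
  } else {
    doc <- xml2::read_xml(path)
    prots <- xml2::xml_find_all(doc, ".//protein")
    segs <- purrr::map(prots, function(p) {
      ss <- xml2::xml_find_all(p, "./segment")
      tibble::tibble(
        protein_id = xml2::xml_attr(p, "id"),
        region = xml2::xml_attr(ss, "region"),
        start = as.integer(xml2::xml_attr(ss, "from")),
        end = as.integer(xml2::xml_attr(ss, "to"))
      )
    }) |> purrr::list_rbind()
  }

  segs$start <- as.integer(segs$start)
  segs$end <- as.integer(segs$end)
  keep <- character(0)
  rejected <- tibble::tibble(protein_id = character(), reason = character())
  for (pid in unique(segs$protein_id)) {
    s <- segs[segs$protein_id == pid, ]
    reason <- validate_segments(s$region, s$start, s$end)
    if (is.null(reason)) {
      keep <- c(keep, pid)
    } else {
      rejected <- dplyr::bind_rows(
        rejected, tibble::tibble(protein_id = pid, reason = reason)
      )
    }
  }
  out <- segs[segs$protein_id %in% keep, ]
  out <- dplyr::arrange(out, .data$protein_id, .data$start)
  attr(out, "rejected") <- rejected
  out
}

#' Write topology segments in the tsv or htp_xml dialect
#'
#' @param segments Segment tibble (`protein_id`, `region`, `start`, `end`).
#' @param path Output path.
#' @param dialect `"tsv"` or `"htp_xml"`.
#' @return `path`, invisibly.
#' @export
write_topology <- function(segments, path, dialect = c("tsv", "htp_xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- c(
      "protein_id\tregion\tstart\tend",
      sprintf("%s\t%s\t%d\t%d", segments$protein_id, segments$region,
              as.integer(segments$start), as.integer(segments$end))
    )
    writeLines(lines, path)
  } else {
    doc <- xml2::xml_new_root("proteins")
    for (pid in unique(segments$protein_id)) {
      s <- segments[segments$protein_id == pid, ]
      p <- xml2::xml_add_child(doc, "protein", id = pid)
      for (i in seq_len(nrow(s))) {
        xml2::xml_add_child(p, "segment", region = s$region[[i]],
                            from = as.character(s$start[[i]]),
                            to = as.character(s$end[[i]]))
      }
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Record ids are normalized to the bare accession (the first `|`- or
#' whitespace-delimited token; UniProt-style `sp|P12345|NAME` headers
#' yield `P12345`) and sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) return(stats::setNames(character(0), character(0)))
  ids <- purrr::map_chr(names(set), function(h) {
    tok <- strsplit(h, "\\s+")[[1]][[1]]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[[1]] %in% c("sp", "tr")) parts[[2]]
    else parts[[1]]
  })
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
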