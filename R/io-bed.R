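#' Convert segments or variants to BED lines
#'
#' Internal coordinates are 1-based inclusive (the UniProt feature
#' convention); BED is 0-based half-open, so residue i maps to
#' `[i-1, i)` and a segment `[s, e]` to `[s-1, e)`. The chrom column
#' carries the protein accession.
#'
#' For segment tibbles the name field is the region (or
#' `region|subregion` when subregions are labelled); for variant or
#' assignment tibbles it is `ref>alt|classification`, extended to
#' `region|subregion|ref>alt|classification` for region assignments.
#'
#' @param x A segment tibble (columns `protein_id`, `start`, `end`) or a
#'   variant/assignment tibble (columns `protein_id`, `position`).
#' @return Character vector of tab-separated BED lines.
#' @export
to_bed <- function(x) {
  if (all(c("start", "end") %in% names(x))) {
    name <- if ("subregion" %in% names(x) && !all(is.na(x$subregion))) {
      paste(x$region, x$subregion, sep = "|")
    } else {
      x$region
    }
    sprintf("%s\t%d\t%d\t%s", x$protein_id, as.integer(x$start) - 1L,
            as.integer(x$end), name)
  } else if ("position" %in% names(x)) {
    name <- paste0(x$ref_aa, ">", x$alt_aa, "|", x$classification)
    if (all(c("region", "subregion") %in% names(x))) {
      name <- paste(x$region, x$subregion, name, sep = "|")
    }
    sprintf("%s\t%d\t%d\t%s", x$protein_id, as.integer(x$position) - 1L,
            as.integer(x$position), name)
  } else {
    stop("x must have start/end or position columns", call. = FALSE)
  }
}

#' Read BED intervals back to 1-based inclusive coordinates
#'
#' Inverse of [to_bed()] for segment-style records: a BED interval
#' `[a, b)` becomes `start = a + 1`, `end = b`.
#'
#' @param path Path to a BED file (3+name columns).
#' @return Tibble with `protein_id`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  tibble::tibble(
    protein_id = as.character(df[[1]]),
    start = as.integer(df[[2]]) + 1L,
    end = as.integer(df[[3]]),
    name = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  )
}

#' Write or read a 20x20 substitution matrix
#'
#' Rows and columns follow the fixed order [aa_order] (mutated residue in
#' rows, mutant residue in columns). The tsv format writes counts as
#' integers and percentages with two decimals; json nests rows as objects.
#'
#' @param matrix A 20x20 numeric matrix with residue dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly (`write_matrix`); a 20x20 matrix
#'   (`read_matrix`).
#' @export
write_matrix <- function(matrix, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.matrix(matrix), all(dim(matrix) == 20))
  matrix <- matrix[aa_order, aa_order]
  fmt1 <- function(v) {
    if (all(v == round(v))) format(as.integer(round(v)))
    else sprintf("%.2f", v)
  }
  if (format == "tsv") {
    lines <- c(
      paste(c("ref", aa_order), collapse = "\t"),
      purrr::map_chr(seq_len(20), function(i) {
        paste(c(aa_order[[i]], fmt1(matrix[i, ])), collapse = "\t")
      })
    )
    writeLines(lines, path)
  } else {
    rows <- purrr::map(seq_len(20), function(i) {
      as.list(stats::setNames(unname(matrix[i, ]), aa_order))
    })
    names(rows) <- aa_order
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
  } else {
    rows <- jsonlite::read_json(path)
    m <- do.call(rbind, purrr::map(rows, ~ unlist(.x)[aa_order]))
    rownames(m) <- names(rows)
    colnames(m) <- aa_order
  }
  m[aa_order, aa_order]
}
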