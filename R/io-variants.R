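#' Read a missense-variant table
#'
#' Two dialects are supported. `"tsv"` is the package's plain format: one
#' header line with columns `protein_id`, `variant_id`, `substitution`
#' (HGVS-style `p.Gly380Arg`), `classification`
#' (Disease/Polymorphism/Unclassified) and `disease` (possibly several
#' names separated by `|`, or `-` for none). `"humsavar"` is the UniProt
#' humsavar flat file: free-text banner lines, a column-header line whose
#' first field is `Main`/`Gene` and which names the `FTId` column, then
#' whitespace-separated records (gene, accession, FTId, substitution,
#' classification, dbSNP id, disease name).
#'
#' Lines whose substitution cannot be decoded to two standard residues and
#' a position, or whose classification is unknown, are skipped and counted
#' in the parse report (see [parse_report()]).
#'
#' @param path Path to the variant table.
#' @param dialect `"tsv"` (default) or `"humsavar"`.
#' @return A tibble of variants with columns `protein_id`, `variant_id`,
#'   `position`, `ref_aa`, `alt_aa`, `classification` and `disease_names`
#'   (a list column of character vectors), with a `parse_report` attribute.
#' @export
read_variants <- function(path, dialect = c("tsv", "humsavar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  if (dialect == "tsv") {
    if (length(lines) == 0) stop("empty variant file: ", path, call. = FALSE)
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    req <- c("protein_id", "variant_id", "substitution", "classification",
             "disease")
    if (!all(req %in% header)) {
      stop("malformed tsv header; need columns ",
           paste(req, collapse = ", "), call. = FALSE)
    }
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    fields <- strsplit(body, "\t", fixed = TRUE)
    recs <- purrr::map(fields, function(f) {
      if (length(f) < length(header)) return(NULL)
      names(f) <- header[seq_along(f)]
      parse_variant_fields(f[["protein_id"]], f[["variant_id"]],
                           f[["substitution"]], f[["classification"]],
                           f[["disease"]])
    })
  } else {
    hdr <- grep("^\\s*(Main|Gene)\\b.*FTId", lines)
    if (length(hdr) == 0) {
      stop("humsavar header line not found in ", path, call. = FALSE)
    }
    body <- lines[-seq_len(hdr[[1]])]
    # footer banners (copyright etc.) and separators carry no VAR_ FTId
    recs <- purrr::map(body, function(ln) {
      if (!nzchar(trimws(ln))) return(NULL)
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tok) < 6 || !grepl("^VAR_", tok[[3]])) {
        if (grepl("^[-_=]+$", tok[[1]])) return(NULL)  # rule lines
        return(list(skip = TRUE))
      }
      disease <- if (length(tok) > 6) paste(tok[-(1:6)], collapse = " ") else "-"
      parse_variant_fields(tok[[2]], tok[[3]], tok[[4]], tok[[5]], disease)
    })
  }

  recs <- purrr::compact(recs)
  skipped <- sum(purrr::map_lgl(recs, ~ isTRUE(.x$skip)))
  recs <- purrr::keep(recs, ~ !isTRUE(.x$skip))
  out <- if (length(recs) == 0) {
    tibble::tibble(
      protein_id = character(), variant_id = character(),
      position = integer(), ref_aa = character(), alt_aa = character(),
      classification = character(), disease_names = list()
    )
  } else {
    tibble::tibble(
      protein_id = purrr::map_chr(recs, "protein_id"),
      variant_id = purrr::map_chr(recs, "variant_id"),
      position = purrr::map_int(recs, "position"),
      ref_aa = purrr::map_chr(recs, "ref_aa"),
      alt_aa = purrr::map_chr(recs, "alt_aa"),
      classification = purrr::map_chr(recs, "classification"),
      disease_names = purrr::map(recs, "disease_names")
    )
  }
  attr(out, "parse_report") <- tibble::tibble(
    records = nrow(out), skipped = skipped
  )
  out
}

parse_variant_fields <- function(protein_id, variant_id, substitution,
                                 classification, disease) {
  sub <- parse_substitution(substitution)
  if (is.null(sub)) return(list(skip = TRUE))
  if (!classification %in% .variant_classes) return(list(skip = TRUE))
  dn <- character(0)
  if (!is.na(disease) && nzchar(disease) && trimws(disease) != "-") {
    dn <- trimws(strsplit(disease, "|", fixed = TRUE)[[1]])
    dn <- dn[nzchar(dn)]
  }
  list(protein_id = protein_id, variant_id = variant_id,
       position = sub$position, ref_aa = sub$ref_aa, alt_aa = sub$alt_aa,
       classification = classification, disease_names = dn)
}

# "p.Gly380Arg" -> list(ref_aa = "G", position = 380L, alt_aa = "R"),
# or NULL when the residues are not among the 20 standard ones
parse_substitution <- function(x) {
  m <- regmatches(x, regexec("^p\\.([A-Za-z]{3})(\\d+)([A-Za-z]{3})$", x))[[1]]
  if (length(m) != 4) return(NULL)
  ref <- .aa3to1[m[[2]]]
  alt <- .aa3to1[m[[4]]]
  pos <- suppressWarnings(as.integer(m[[3]]))
  if (is.na(ref) || is.na(alt) || is.na(pos) || pos < 1) return(NULL)
  if (ref == alt) return(NULL)  # synonymous: not a missense substitution
  list(ref_aa = unname(ref), position = pos, alt_aa = unname(alt))
}

#' Parse or drop report of a reader/mapper result
#'
#' @param x A tibble returned by [read_variants()], [read_topology()] or
#'   [assign_regions()].
#' @return The report tibble stored alongside the result, or `NULL`.
#' @export
parse_report <- function(x) {
  attr(x, "parse_report") %||% attr(x, "drop_report") %||%
    attr(x, "rejected")
}

#' Write variants in the package's tsv dialect
#'
#' @param variants Tibble from [read_variants()] or [generate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  aa1to3 <- stats::setNames(names(.aa3to1), .aa3to1)
  lines <- c(
    "protein_id\tvariant_id\tsubstitution\tclassification\tdisease",
    sprintf(
      "%s\t%s\tp.%s%d%s\t%s\t%s",
      variants$protein_id, variants$variant_id,
      aa1to3[variants$ref_aa], variants$position, aa1to3[variants$alt_aa],
      variants$classification,
      purrr::map_chr(variants$disease_names,
                     ~ if (length(.x) == 0) "-" else paste(.x, collapse = "|"))
    )
  )
  writeLines(lines, path)
  invisible(path)
}
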