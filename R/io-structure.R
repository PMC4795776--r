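#' Residue depths along the membrane normal from a PDB structure
#'
#' Reads C-alpha coordinates from a (minimal) PDB file and applies a
#' rigid-body membrane-frame transformation so the membrane normal lies
#' along z with the origin at the bilayer center: `z = (R x + t)[3]`.
#' Membrane-structure databases distribute such rotation/translation pairs
#' alongside embedded structures. Residues without a C-alpha atom are
#' absent from the result; for alternate locations the first occurrence of
#' a residue number is kept.
#'
#' @param pdb_path Path to a PDB file containing ATOM records with CA atoms.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Numeric length-3 translation (default zero).
#' @param protein_id Accession to attach; defaults to the file name
#'   without extension.
#' @return Tibble with columns `protein_id`, `position` (PDB residue
#'   number) and `z` (Angstrom).
#' @export
read_structure_frame <- function(pdb_path, rotation = diag(3),
                                 translation = c(0, 0, 0),
                                 protein_id = NULL) {
  if (!file.exists(pdb_path)) stop("file not found: ", pdb_path, call. = FALSE)
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(pdb_path))
  }
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0) stop("no CA atoms in ", pdb_path, call. = FALSE)
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  xyz <- t(as.matrix(ca[, c("x", "y", "z")]))
  z <- (rotation %*% xyz + translation)[3, ]
  tibble::tibble(
    protein_id = protein_id,
    position = as.integer(ca$resno),
    z = as.numeric(z)
  )
}

#' Write C-alpha traces as minimal PDB files
#'
#' One file per protein, containing only CA ATOM records in the membrane
#' frame produced by [generate_structures()]. The companion identity
#' frame makes [read_structure_frame()] recover the same z values.
#'
#' @param coords Tibble with columns `protein_id`, `position`, `residue`
#'   (one-letter), `x`, `y`, `z`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_structure_pdb <- function(coords, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa1to3 <- stats::setNames(toupper(names(.aa3to1)), .aa3to1)
  paths <- character(0)
  for (pid in unique(coords$protein_id)) {
    cc <- coords[coords$protein_id == pid, ]
    cc <- cc[order(cc$position), ]
    lines <- sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(cc)), aa1to3[cc$residue], cc$position,
      cc$x, cc$y, cc$z
    )
    p <- file.path(dir, paste0(pid, ".pdb"))
    writeLines(c(lines, "END"), p)
    paths[[pid]] <- p
  }
  invisible(paths)
}
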