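#' Standard amino-acid order used by all substitution matrices
#'
#' The fixed one-letter ordering (A R N D C Q E G H I L K M F P S T W Y V)
#' used for the rows and columns of every 20x20 substitution matrix the
#' package reads, writes or computes.
#'
#' @format A character vector of length 20.
#' @export
aa_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# side-chain polarity partition: 5 polar / 10 non-polar / 5 charged
.polarity_map <- c(
  N = "polar", Q = "polar", S = "polar", T = "polar", Y = "polar",
  A = "non-polar", C = "non-polar", G = "non-polar", I = "non-polar",
  L = "non-polar", M = "non-polar", F = "non-polar", P = "non-polar",
  W = "non-polar", V = "non-polar",
  R = "charged", D = "charged", E = "charged", H = "charged", K = "charged"
)

#' Polarity classes of the 20 standard amino acids
#'
#' Classifies residues into the three side-chain property groups used to
#' aggregate substitution matrices: polar (N, Q, S, T, Y), non-polar
#' (A, C, G, I, L, M, F, P, W, V) and charged (R, D, E, H, K).
#'
#' @param ref_aa,alt_aa Character vectors of one-letter residue codes.
#'   `alt_aa` may be omitted to classify a single set of residues.
#' @return If `alt_aa` is missing, a character vector of classes. Otherwise
#'   a tibble with columns `ref_aa`, `alt_aa`, `class_from`, `class_to`.
#' @examples
#' polarity_classes("G", "R")  # non-polar -> charged
#' polarity_classes(c("V", "S"), c("L", "Y"))
#' @export
polarity_classes <- function(ref_aa, alt_aa = NULL) {
  classify <- function(x) {
    bad <- !(x %in% names(.polarity_map))
    if (any(bad)) {
      stop("non-standard residue(s): ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
    unname(.polarity_map[x])
  }
  if (is.null(alt_aa)) {
    return(classify(ref_aa))
  }
  tibble::tibble(
    ref_aa = ref_aa, alt_aa = alt_aa,
    class_from = classify(ref_aa), class_to = classify(alt_aa)
  )
}

.polarity_order <- c("charged", "non-polar", "polar")

# three-letter -> one-letter lookup for p.Xaa123Xaa substitution strings
.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

.variant_classes <- c("Disease", "Polymorphism", "Unclassified")
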