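#' Default transmembrane substitution spectrum for a variant class
#'
#' The package ships the characteristic 20x20 relative-frequency spectra
#' of amino-acid substitutions observed in transmembrane regions of human
#' TMPs for disease-associated mutations (dominated by Gly->Arg and
#' Leu->Pro) and for polymorphisms (dominated by symmetric non-polar
#' exchanges such as Val<->Ile). They are the default class spectra of the
#' synthetic variant generator. Rows are the mutated residue, columns the
#' mutant residue; the diagonal is structurally zero and entries sum to 1.
#'
#' @param class `"Disease"` or `"Polymorphism"`.
#' @return A 20x20 row/column-named probability matrix.
#' @export
default_spectrum <- function(class = c("Disease", "Polymorphism")) {
  class <- match.arg(class)
  f <- system.file(
    "extdata",
    paste0("tm_spectrum_", tolower(class), ".tsv"),
    package = "tmvar", mustWork = TRUE
  )
  m <- read_matrix(f, format = "tsv")
  m / sum(m)
}

# region residue compositions; TM is hydrophobic-enriched (74% of mass on
# the ten non-polar residues), I/O use a generic soluble-domain profile
default_compositions <- function() {
  tm <- c(A = 0.10, R = 0.02, N = 0.02, D = 0.015, C = 0.02, Q = 0.02,
          E = 0.015, G = 0.07, H = 0.01, I = 0.11, L = 0.16, K = 0.01,
          M = 0.03, F = 0.09, P = 0.03, S = 0.06, T = 0.05, W = 0.02,
          Y = 0.04, V = 0.11)
  sol <- c(A = 0.08, R = 0.06, N = 0.04, D = 0.05, C = 0.02, Q = 0.04,
           E = 0.07, G = 0.07, H = 0.02, I = 0.05, L = 0.09, K = 0.06,
           M = 0.02, F = 0.04, P = 0.05, S = 0.07, T = 0.06, W = 0.01,
           Y = 0.03, V = 0.07)
  stopifnot(abs(sum(tm) - 1) < 1e-9, abs(sum(sol) - 1) < 1e-9)
  list(I = sol[aa_order], M = tm[aa_order], O = sol[aa_order])
}

#' Configuration of the synthetic proteome/variant/structure generator
#'
#' Collects every tunable of the generator with defaults that mirror the
#' human transmembrane proteome and its variant landscape: a TM-count
#' distribution with single-pass, 7-TM and 10/12-TM peaks; 17-25 residue
#' hydrophobic TM helices; per-residue variant rates of 2.57e-2
#' (disease) and 8.76e-3 (polymorphism); and class substitution spectra
#' from [default_spectrum()] applied to every region.
#'
#' @param n_proteins Number of proteins to generate.
#' @param tm_count_weights Probability weights over 0..14 membrane
#'   segments (0 = soluble protein); normalized internally to sum 1.
#' @param segment_length_ranges Named list of `c(min, max)` residue counts
#'   for `TM`, `N_TERMINAL`, `C_TERMINAL`, `LOOP` and `NON_TMP` stretches.
#' @param composition Named list (`I`, `M`, `O`) of 20-residue frequency
#'   vectors; each must sum to 1 and the `M` vector must place at least
#'   60 percent of its mass on the ten non-polar residues.
#' @param class_spectra Named list (`Disease`, `Polymorphism`) of either a
#'   single 20x20 probability matrix (used for every region) or a named
#'   list of per-region (`I`, `M`, `O`) matrices.
#' @param variant_rates Expected variants per residue for `Disease` and
#'   `Polymorphism`: a named numeric vector of per-class rates, or a
#'   named list whose elements are either a scalar rate or a per-region
#'   rate vector `c(I = , M = , O = )`.
#' @param unclassified_rate Per-residue rate of unclassified variants
#'   (uniform random substitutions), exercising the exclusion filter.
#' @param ambiguous_fraction Fraction of disease variants annotated with
#'   two distinct disease names, exercising the multi-disease filter.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A list of class `tmvar_config`.
#' @export
synthetic_config <- function(
    n_proteins = 500L,
    tm_count_weights = c(0.20, 0.22, 0.05, 0.03, 0.04, 0.03, 0.03, 0.17,
                         0.02, 0.02, 0.06, 0.03, 0.06, 0.02, 0.02),
    segment_length_ranges = list(
      TM = c(17L, 25L), N_TERMINAL = c(5L, 60L), C_TERMINAL = c(5L, 60L),
      LOOP = c(3L, 40L), NON_TMP = c(100L, 400L)
    ),
    composition = default_compositions(),
    class_spectra = list(
      Disease = default_spectrum("Disease"),
      Polymorphism = default_spectrum("Polymorphism")
    ),
    variant_rates = c(Disease = 2.57e-2, Polymorphism = 8.76e-3),
    unclassified_rate = 1e-3,
    ambiguous_fraction = 0.1,
    seed = 1L) {
  if (length(tm_count_weights) != 15 || any(tm_count_weights < 0)) {
    stop("tm_count_weights must be 15 non-negative weights (0..14 TMs)",
         call. = FALSE)
  }
  tm_count_weights <- tm_count_weights / sum(tm_count_weights)
  for (r in names(segment_length_ranges)) {
    rng <- segment_length_ranges[[r]]
    if (length(rng) != 2 || rng[[1]] > rng[[2]] || rng[[1]] < 1) {
      stop("infeasible length range for ", r, call. = FALSE)
    }
  }
  for (r in c("I", "M", "O")) {
    v <- composition[[r]]
    if (is.null(v) || abs(sum(v) - 1) > 1e-9 ||
        !setequal(names(v), aa_order)) {
      stop("composition[['", r, "']] must be a 20-residue vector summing to 1",
           call. = FALSE)
    }
    composition[[r]] <- v[aa_order]
  }
  nonpolar <- names(.polarity_map)[.polarity_map == "non-polar"]
  if (sum(composition$M[nonpolar]) < 0.6) {
    stop("TM composition must place >= 60% mass on non-polar residues",
         call. = FALSE)
  }
  class_spectra <- purrr::map(class_spectra, function(sp) {
    if (is.matrix(sp)) sp <- list(I = sp, M = sp, O = sp)
    purrr::map(sp, function(m) {
      stopifnot(is.matrix(m), all(dim(m) == 20))
      m <- m[aa_order, aa_order]
      diag(m) <- 0
      m / sum(m)
    })
  })
  stopifnot(all(unlist(variant_rates) >= 0), unclassified_rate >= 0,
            ambiguous_fraction >= 0, ambiguous_fraction <= 1)
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      tm_count_weights = tm_count_weights,
      segment_length_ranges = segment_length_ranges,
      composition = composition,
      class_spectra = class_spectra,
      variant_rates = variant_rates,
      unclassified_rate = unclassified_rate,
      ambiguous_fraction = ambiguous_fraction,
      seed = as.integer(seed)
    ),
    class = "tmvar_config"
  )
}

#' @export
print.tmvar_config <- function(x, ...) {
  cat("<tmvar_config> ", x$n_proteins, " proteins, seed ", x$seed, "\n",
      "  rates/residue: ",
      paste(names(x$variant_rates), signif(x$variant_rates, 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# stable per-entity RNG substream: independent of generation order
stream_seed <- function(master, index, salt = 0L) {
  (as.double(master) * 2654435761 + as.double(index) * 40503 +
     as.double(salt) * 97911) %% 2147483647
}
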