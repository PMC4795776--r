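#' Run the full variant-topology analysis
#'
#' Orchestrates every stage on in-memory inputs: filters and maps
#' variants onto topology, computes region- and subregion-stratified
#' substitution matrices (counts and percentages), polarity-class
#' tables, per-residue variant frequencies, bootstrap dispersions, the
#' permutation null with z-scores, predictive values of frequent TM
#' substitutions, center-distance records, and (when structures are
#' supplied) the slice profile along the membrane normal. Deterministic
#' given `seed`. With `out_dir` set, every table is written as TSV/JSON
#' with a manifest.
#'
#' @param variants Variant tibble ([read_variants()] /
#'   [generate_variants()]).
#' @param proteome A [tm_proteome()].
#' @param structures Optional z-coordinate tibble
#'   ([generate_structures()] / [read_structure_frame()] rows).
#' @param out_dir Optional output directory.
#' @param bootstrap_reps,perm_reps Replicate counts (defaults 10 / 100).
#' @param predictive_threshold Minimum combined TM count for predictive
#'   values (default 100).
#' @param slice_width Slice width in Angstrom (default 1).
#' @param seed Master seed for bootstrap and permutation streams.
#' @return A list of class `tmvar_report`; see Details. Key elements:
#'   `counts` (drop/mapping accounting), `rates` (per-residue variant
#'   rates in TMPs and non-TMPs), `tables` (all computed tables),
#'   `manifest` (written files), `seed`.
#' @export
run_pipeline <- function(variants, proteome, structures = NULL,
                         out_dir = NULL, bootstrap_reps = 10L,
                         perm_reps = 100L, predictive_threshold = 100,
                         slice_width = 1.0, seed = 1L) {
  seed <- as.integer(seed)
  assignments <- assign_regions(variants, proteome)
  drop <- attr(assignments, "drop_report")

  tmp_assign <- assignments[assignments$is_tmp, ]
  class_counts <- assignments |>
    dplyr::count(.data$classification, .data$is_tmp, name = "n") |>
    tidyr::pivot_wider(names_from = "is_tmp", values_from = "n",
                       values_fill = 0L,
                       names_prefix = "tmp_")
  protein_counts <- assignments |>
    dplyr::distinct(.data$classification, .data$protein_id, .data$is_tmp) |>
    dplyr::count(.data$classification, .data$is_tmp,
                 name = "n_proteins")

  residues <- proteome$proteins |>
    dplyr::group_by(.data$is_tmp) |>
    dplyr::summarise(residues = sum(.data$length), .groups = "drop")
  rates <- assignments |>
    dplyr::count(.data$classification, .data$is_tmp, name = "n") |>
    dplyr::inner_join(residues, by = "is_tmp") |>
    dplyr::mutate(rate = .data$n / .data$residues)

  counts_region <- count_substitutions(tmp_assign, "region")
  counts_subregion <- count_substitutions(tmp_assign, "subregion")
  percent_region <- to_percent(counts_region)

  tm_mats <- purrr::map(
    c(Disease = "Disease", Polymorphism = "Polymorphism"),
    function(cl) substitution_matrix(counts_region, "M", cl)
  )
  polarity <- purrr::map(tm_mats, polarity_matrix)

  freqs <- region_frequency(
    tmp_assign, region_lengths(proteome, "subregion"), "subregion"
  )
  boot <- bootstrap_sd(tmp_assign, n_reps = bootstrap_reps,
                       seed = stream_seed(seed, 1L, salt = 11L))
  perm <- permutation_null(tmp_assign, proteome, n_reps = perm_reps,
                           seed = stream_seed(seed, 2L, salt = 12L))
  pred <- predictive_values(tm_mats$Disease, tm_mats$Polymorphism,
                            threshold = predictive_threshold)

  centers <- dplyr::bind_rows(
    natural_residue_positions(proteome, "R")$records,
    variant_center_distances(tmp_assign, proteome, ref_aa = "G",
                             alt_aa = "R") |>
      dplyr::filter(.data$source == "disease_variant") |>
      dplyr::mutate(source = "disease_gly_arg"),
    variant_center_distances(
      tmp_assign[tmp_assign$classification == "Polymorphism", ], proteome
    )
  )
  center_hist <- if (nrow(centers) > 0) {
    center_distance_histogram(centers)
  } else {
    tibble::tibble(source = character(), bin_start = numeric(),
                   bin_end = numeric(), n = integer(),
                   frequency = numeric())
  }

  profile <- NULL
  if (!is.null(structures)) {
    profile <- slice_profile(structures, tmp_assign,
                             slice_width = slice_width)
  }

  report <- structure(
    list(
      counts = list(
        drop_report = drop,
        by_class = class_counts,
        proteins_by_class = protein_counts
      ),
      rates = rates,
      tables = list(
        counts_region = counts_region,
        counts_subregion = counts_subregion,
        percent_region = percent_region,
        polarity = polarity,
        region_frequency = freqs,
        bootstrap = boot,
        permutation = perm,
        predictive_values = pred,
        center_distances = centers,
        center_distance_histogram = center_hist,
        slice_profile = profile
      ),
      structures_used = !is.null(structures),
      seed = seed,
      version = as.character(utils::packageVersion("tmvar")),
      manifest = character(0)
    ),
    class = "tmvar_report"
  )

  if (!is.null(out_dir)) {
    report$manifest <- write_report(report, out_dir)
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(tibble::as_tibble(df), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <<- c(manifest, p)
  }
  t <- report$tables
  put(t$counts_region, "substitution_counts_region")
  put(t$counts_subregion, "substitution_counts_subregion")
  put(t$percent_region, "substitution_percent_region")
  put(t$region_frequency, "region_frequency")
  put(tidy(t$bootstrap), "bootstrap")
  put(tidy(t$permutation), "permutation")
  put(t$predictive_values, "predictive_values")
  put(t$center_distance_histogram, "center_distance_histogram")
  if (!is.null(t$slice_profile)) put(t$slice_profile, "slice_profile")
  put(report$rates, "rates")
  jp <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(
    list(
      counts = report$counts, rates = report$rates, seed = report$seed,
      version = report$version, structures_used = report$structures_used
    ),
    jp, auto_unbox = TRUE, digits = NA, force = TRUE
  )
  c(manifest, jp)
}

#' @export
print.tmvar_report <- function(x, ...) {
  d <- x$counts$drop_report
  cat("<tmvar_report> seed ", x$seed, "\n", sep = "")
  cat(sprintf(
    "  variants: %d in; %d mapped (dropped: %d unclassified, %d ambiguous, %d unknown protein, %d out of range, %d ref mismatch)\n",
    d$input, d$assigned, d$dropped_unclassified, d$dropped_ambiguous,
    d$dropped_unknown_protein, d$dropped_out_of_range,
    d$dropped_ref_mismatch
  ))
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    cat(sprintf("  %s rate (%s): %.3g per residue (%d / %d)\n",
                r$classification, if (r$is_tmp) "TMPs" else "non-TMPs",
                r$rate, r$n, r$residues))
  }
  pv <- utils::head(x$tables$predictive_values, 5)
  if (nrow(pv) > 0) {
    cat("  top predictive values (TM):\n")
    for (i in seq_len(nrow(pv))) {
      cat(sprintf("    %s->%s: %.2f (D=%d, P=%d)\n", pv$ref_aa[[i]],
                  pv$alt_aa[[i]], pv$predictive_value[[i]],
                  as.integer(pv$disease[[i]]),
                  as.integer(pv$polymorphism[[i]])))
    }
  }
  z <- tidy(x$tables$permutation) |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::arrange(dplyr::desc(.data$z)) |>
    utils::head(5)
  if (nrow(z) > 0) {
    cat("  top permutation z-scores:\n")
    for (i in seq_len(nrow(z))) {
      cat(sprintf("    %s/%s %s->%s: z = %.1f (obs %d, avg %.1f)\n",
                  z$label[[i]], z$classification[[i]], z$ref_aa[[i]],
                  z$alt_aa[[i]], z$z[[i]], as.integer(z$obs[[i]]),
                  z$avg[[i]]))
    }
  }
  if (!x$structures_used) {
    cat("  structures: none supplied; slice profile skipped\n")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `tmvar_report`.
#' @param ... Unused.
#' @method glance tmvar_report
#' @export
glance.tmvar_report <- function(x, ...) {
  d <- x$counts$drop_report
  tm_rates <- x$rates[x$rates$is_tmp, ]
  tibble::tibble(
    variants_in = d$input,
    variants_mapped = d$assigned,
    dropped = d$input - d$assigned,
    rate_disease_tmp = with(tm_rates,
                            rate[classification == "Disease"][1]),
    rate_polymorphism_tmp = with(tm_rates,
                                 rate[classification == "Polymorphism"][1]),
    seed = x$seed
  )
}

#' @rdname run_pipeline
#' @param object A `tmvar_report`.
#' @export
summary.tmvar_report <- function(object, ...) {
  print(object)
}
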