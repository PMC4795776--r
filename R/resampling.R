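#' Bootstrap dispersion of a substitution statistic
#'
#' Estimates the sampling variability of a matrix-valued statistic by
#' repeatedly subsampling a fixed fraction of the mapped variants (90
#' percent by default, drawn without replacement and stratified by
#' variant class, ten times by default) and recomputing the statistic;
#' the per-cell mean and standard deviation over replicates are
#' returned. With `replace = TRUE` a classical bootstrap (resampling n
#' of n with replacement) is performed instead; with `fraction = 1` and
#' no replacement every replicate is the full data and all standard
#' deviations are exactly zero.
#'
#' @param assignments Tibble from [assign_regions()].
#' @param statistic Function mapping an assignment tibble to a long
#'   tibble with a `value` column keyed by the remaining columns.
#'   Defaults to the per-(region, class) percent substitution matrices.
#' @param fraction Subsample fraction in (0, 1].
#' @param n_reps Number of replicates (>= 2).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @param replace Sample with replacement (classical bootstrap).
#' @return A tibble of class `tmvar_bootstrap` with the statistic's key
#'   columns plus `mean` and `sd`; attributes `n_reps`, `fraction`,
#'   `seed`.
#' @export
bootstrap_sd <- function(assignments, statistic = NULL, fraction = 0.9,
                         n_reps = 10L, seed = 1L, replace = FALSE) {
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  stopifnot(n_reps >= 2)
  if (is.null(statistic)) {
    statistic <- function(a) {
      count_substitutions(a, "region") |>
        to_percent() |>
        dplyr::select("label", "classification", "ref_aa", "alt_aa",
                      value = "percent")
    }
  }
  set.seed(as.integer(seed))
  reps <- purrr::map(seq_len(n_reps), function(r) {
    idx <- assignments |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$classification) |>
      dplyr::group_map(function(g, key) {
        k <- if (replace) nrow(g) else floor(fraction * nrow(g))
        sample(g$.row, k, replace = replace)
      }) |>
      unlist()
    statistic(assignments[idx, ]) |>
      dplyr::mutate(.rep = r)
  }) |>
    purrr::list_rbind()
  keys <- setdiff(names(reps), c("value", ".rep"))
  out <- reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
  structure(out, class = c("tmvar_bootstrap", class(out)),
            n_reps = n_reps, fraction = fraction, seed = seed,
            replace = replace)
}

#' Permutation null for region-stratified substitution matrices
#'
#' Tests which cells of the observed substitution matrices exceed what
#' positional chance predicts. For each (region, class) stratum with n
#' observed mutation events, each of `n_reps` replicates draws n residue
#' positions uniformly from the pooled sequences of all segments of that
#' region across the transmembrane proteome; the wild-type residue at a
#' drawn position is the null reference, and the null mutant residue is
#' drawn from the observed mutant-residue marginal of the stratum
#' (redrawn on collision with the reference). The per-cell average (AVG)
#' and standard deviation (STD) of the null count matrices give
#' `z = (OBS - AVG) / STD`; cells with zero STD are reported with `z = NA`.
#'
#' @param assignments Tibble from [assign_regions()].
#' @param proteome The [tm_proteome()] the assignments refer to.
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed.
#' @param alt_model `"marginal"` (default; null mutant residue
#'   independent of the null reference) or `"conditional"` (drawn from
#'   the observed mutant distribution given the sampled reference, with
#'   marginal fallback for references never observed mutated).
#' @param pool `"proteome"` (default; positions pooled over all TMPs) or
#'   `"protein"` (positions drawn within the protein of each observed
#'   event).
#' @return Tibble of class `tmvar_permutation` with columns `label`
#'   (region), `classification`, `ref_aa`, `alt_aa`, `obs`, `avg`,
#'   `std`, `z`; attributes `n_reps`, `seed`, `n_cells_tested`.
#' @export
permutation_null <- function(assignments, proteome, n_reps = 100L,
                             seed = 1L,
                             alt_model = c("marginal", "conditional"),
                             pool = c("proteome", "protein")) {
  alt_model <- match.arg(alt_model)
  pool <- match.arg(pool)
  stopifnot(inherits(proteome, "tm_proteome"))
  set.seed(as.integer(seed))

  tmp_ids <- proteome$proteins$protein_id[proteome$proteins$is_tmp]
  segs <- proteome$segments[proteome$segments$protein_id %in% tmp_ids, ]
  region_pool <- purrr::map(c(I = "I", M = "M", O = "O"), function(r) {
    s <- segs[segs$region == r, ]
    chars <- purrr::pmap(list(s$protein_id, s$start, s$end),
                         function(pid, a, b) {
                           strsplit(substr(proteome$sequences[[pid]], a, b),
                                    "")[[1]]
                         })
    list(residues = unlist(chars),
         protein = rep(s$protein_id, s$end - s$start + 1L))
  })

  strata <- assignments |>
    dplyr::filter(.data$is_tmp, .data$classification != "Unclassified") |>
    dplyr::group_by(.data$region, .data$classification)
  keys <- dplyr::group_keys(strata)
  groups <- dplyr::group_split(strata)

  out <- purrr::map2(groups, seq_len(nrow(keys)), function(g, i) {
    r <- keys$region[[i]]
    cl <- keys$classification[[i]]
    n <- nrow(g)
    pool_r <- region_pool[[r]]
    if (length(pool_r$residues) == 0) {
      stop("empty residue pool for region ", r, call. = FALSE)
    }
    obs <- matrix(0, 20, 20, dimnames = list(aa_order, aa_order))
    tab <- table(factor(g$ref_aa, aa_order), factor(g$alt_aa, aa_order))
    obs[] <- as.numeric(tab)

    alt_marginal <- colSums(obs)
    # resampling-until-different is equivalent to drawing from the
    # marginal with the reference residue zeroed out; done directly
    draw_alt <- function(null_ref) {
      alt <- character(length(null_ref))
      for (rr in unique(null_ref)) {
        idx <- which(null_ref == rr)
        row <- alt_marginal
        row[rr] <- 0
        if (sum(row) <= 0) {
          stop("observed mutant-residue marginal for region ", r,
               " has no mass off residue ", rr, call. = FALSE)
        }
        alt[idx] <- sample(aa_order, length(idx), replace = TRUE, prob = row)
      }
      alt
    }
    draw_alt_conditional <- function(null_ref) {
      purrr::map_chr(null_ref, function(rr) {
        row <- obs[rr, ]
        row[rr] <- 0
        if (sum(row) <= 0) {
          row <- alt_marginal
          row[rr] <- 0
        }
        sample(aa_order, 1, prob = row)
      })
    }

    null_sum <- matrix(0, 20, 20)
    null_sq <- matrix(0, 20, 20)
    for (rep in seq_len(n_reps)) {
      if (pool == "proteome") {
        null_ref <- sample(pool_r$residues, n, replace = TRUE)
      } else {
        null_ref <- purrr::map_chr(g$protein_id, function(pid) {
          res <- pool_r$residues[pool_r$protein == pid]
          if (length(res) == 0) sample(pool_r$residues, 1)
          else sample(res, 1)
        })
      }
      keep <- null_ref %in% aa_order  # non-standard residues excluded
      null_ref <- null_ref[keep]
      null_alt <- if (alt_model == "marginal") draw_alt(null_ref)
                  else draw_alt_conditional(null_ref)
      nm <- table(factor(null_ref, aa_order), factor(null_alt, aa_order))
      null_sum <- null_sum + as.numeric(nm)
      null_sq <- null_sq + as.numeric(nm)^2
    }
    avg <- null_sum / n_reps
    std <- sqrt(pmax(null_sq / n_reps - avg^2, 0) * n_reps / (n_reps - 1))
    grid <- tidyr::expand_grid(ref_aa = aa_order, alt_aa = aa_order) |>
      dplyr::filter(.data$ref_aa != .data$alt_aa)
    dim(avg) <- dim(std) <- c(20, 20)
    dimnames(avg) <- dimnames(std) <- list(aa_order, aa_order)
    grid |>
      dplyr::mutate(
        label = r, classification = cl,
        obs = obs[cbind(.data$ref_aa, .data$alt_aa)],
        avg = avg[cbind(.data$ref_aa, .data$alt_aa)],
        std = std[cbind(.data$ref_aa, .data$alt_aa)],
        z = dplyr::if_else(.data$std > 0,
                           (.data$obs - .data$avg) / .data$std,
                           NA_real_)
      ) |>
      dplyr::relocate("label", "classification")
  }) |>
    purrr::list_rbind()

  structure(out, class = c("tmvar_permutation", class(out)),
            n_reps = n_reps, seed = seed, alt_model = alt_model,
            pool = pool, n_cells_tested = sum(!is.na(out$z)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname permutation_null
#' @param x A `tmvar_permutation` object.
#' @param ... Unused.
#' @method tidy tmvar_permutation
#' @export
tidy.tmvar_permutation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname permutation_null
#' @method glance tmvar_permutation
#' @export
glance.tmvar_permutation <- function(x, ...) {
  tibble::tibble(
    n_reps = attr(x, "n_reps"),
    n_cells_tested = attr(x, "n_cells_tested"),
    n_cells_zero_std = sum(x$std == 0),
    max_z = max(x$z, na.rm = TRUE),
    alt_model = attr(x, "alt_model")
  )
}

#' @rdname bootstrap_sd
#' @param x A `tmvar_bootstrap` object.
#' @param ... Unused.
#' @method tidy tmvar_bootstrap
#' @export
tidy.tmvar_bootstrap <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname bootstrap_sd
#' @method glance tmvar_bootstrap
#' @export
glance.tmvar_bootstrap <- function(x, ...) {
  tibble::tibble(
    n_reps = attr(x, "n_reps"),
    fraction = attr(x, "fraction"),
    replace = attr(x, "replace"),
    max_sd = max(x$sd)
  )
}
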