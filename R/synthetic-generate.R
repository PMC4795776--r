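#' Generate a synthetic proteome with membrane topologies
#'
#' Draws, for each protein, a number of membrane segments from the
#' configured TM-count distribution, alternating inside/outside flanking
#' segments (a membrane segment always separates inside from outside),
#' segment lengths uniform within the configured ranges, and residues
#' i.i.d. from the per-region compositions. Proteins with zero membrane
#' segments are soluble (non-TMP) controls. Deterministic given the
#' config seed; each protein uses its own RNG substream so results do not
#' depend on generation order.
#'
#' @param config A [synthetic_config()].
#' @return A [tm_proteome()].
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "tmvar_config"))
  rng <- function(r) {
    as.integer(round(stats::runif(1, r[[1]], r[[2]])))
  }
  records <- purrr::map(seq_len(config$n_proteins), function(i) {
    set.seed(stream_seed(config$seed, i, salt = 1L))
    pid <- sprintf("SYN%05d", i)
    k <- sample(0:14, 1, prob = config$tm_count_weights)
    lr <- config$segment_length_ranges
    if (k == 0) {
      regions <- sample(c("I", "O"), 1)
      lens <- rng(lr$NON_TMP)
    } else {
      side <- sample(c("I", "O"), 1)
      other <- if (side == "I") "O" else "I"
      regions <- character(2 * k + 1)
      regions[seq(1, 2 * k + 1, by = 2)] <- rep(c(side, other),
                                                length.out = k + 1)
      regions[seq(2, 2 * k, by = 2)] <- "M"
      lens <- integer(2 * k + 1)
      lens[[1]] <- rng(lr$N_TERMINAL)
      lens[[2 * k + 1]] <- rng(lr$C_TERMINAL)
      for (j in seq(2, 2 * k, by = 2)) lens[[j]] <- rng(lr$TM)
      if (k > 1) {
        for (j in seq(3, 2 * k - 1, by = 2)) lens[[j]] <- rng(lr$LOOP)
      }
    }
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    seq_chars <- purrr::map2(regions, lens, function(r, l) {
      sample(aa_order, l, replace = TRUE, prob = config$composition[[r]])
    })
    list(
      protein_id = pid,
      sequence = paste(unlist(seq_chars), collapse = ""),
      segments = tibble::tibble(
        protein_id = pid, region = regions,
        start = as.integer(starts), end = as.integer(ends)
      )
    )
  })
  sequences <- stats::setNames(
    purrr::map_chr(records, "sequence"),
    purrr::map_chr(records, "protein_id")
  )
  segments <- purrr::list_rbind(purrr::map(records, "segments"))
  tm_proteome(sequences, segments)
}

.disease_vocabulary <- c(
  "Synthetic channelopathy 1", "Synthetic channelopathy 2",
  "Synthetic transport disorder", "Synthetic receptor dysplasia",
  "Synthetic storage disease", "Synthetic neuropathy"
)

#' Generate synthetic missense variants on a proteome
#'
#' For every protein, topological region and variant class, the number of
#' variants is Poisson with mean `rate x region length`. Each variant
#' picks a residue position uniformly within the region (several variants
#' may hit one residue), takes the sequence residue there as the
#' reference, and draws the mutant residue from the class spectrum row of
#' the reference (diagonal zeroed and the row renormalized). Disease
#' variants receive one disease name from a fixed synthetic vocabulary,
#' or two distinct names with probability `ambiguous_fraction` so the
#' multi-disease exclusion filter can be exercised; unclassified variants
#' (uniform mutant residue) are emitted at `unclassified_rate`.
#' Deterministic given the config seed.
#'
#' @param proteome A [tm_proteome()] from [generate_proteome()].
#' @param config The same [synthetic_config()].
#' @return A variant tibble as returned by [read_variants()].
#' @export
generate_variants <- function(proteome, config) {
  stopifnot(inherits(proteome, "tm_proteome"),
            inherits(config, "tmvar_config"))
  classes <- c(names(config$variant_rates),
               if (config$unclassified_rate > 0) "Unclassified")
  rows <- purrr::imap(proteome$sequences, function(seqstr, pid) {
    i <- match(pid, names(proteome$sequences))
    set.seed(stream_seed(config$seed, i, salt = 2L))
    segs <- proteome$segments[proteome$segments$protein_id == pid, ]
    res <- strsplit(seqstr, "")[[1]]
    out <- list()
    for (cl in classes) {
      rate_spec <- if (cl == "Unclassified") config$unclassified_rate
                   else config$variant_rates[[cl]]
      if (all(rate_spec <= 0)) next
      for (si in seq_len(nrow(segs))) {
        reg <- segs$region[[si]]
        rate <- if (length(rate_spec) > 1) rate_spec[[reg]] else rate_spec
        if (rate <= 0) next
        pos_range <- segs$start[[si]]:segs$end[[si]]
        n <- stats::rpois(1, rate * length(pos_range))
        if (n == 0) next
        pos <- sample(pos_range, n, replace = TRUE)
        ref <- res[pos]
        if (cl == "Unclassified") {
          alt <- purrr::map_chr(ref, function(r) {
            sample(setdiff(aa_order, r), 1)
          })
        } else {
          sp <- config$class_spectra[[cl]][[reg]]
          alt <- purrr::map_chr(ref, function(r) {
            row <- sp[r, ]
            row[r] <- 0
            if (sum(row) <= 0) {
              stop("class spectrum row for residue ", r, " (", cl, ", ",
                   reg, ") is all zero", call. = FALSE)
            }
            sample(aa_order, 1, prob = row)
          })
        }
        disease <- purrr::map(seq_len(n), function(j) {
          if (cl != "Disease") return(character(0))
          if (stats::runif(1) < config$ambiguous_fraction) {
            sample(.disease_vocabulary, 2)
          } else {
            sample(.disease_vocabulary, 1)
          }
        })
        out[[length(out) + 1]] <- tibble::tibble(
          protein_id = pid, position = as.integer(pos),
          ref_aa = ref, alt_aa = alt, classification = cl,
          disease_names = disease
        )
      }
    }
    if (length(out) == 0) NULL else purrr::list_rbind(out)
  })
  out <- purrr::list_rbind(purrr::compact(unname(rows)))
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      protein_id = character(), position = integer(), ref_aa = character(),
      alt_aa = character(), classification = character(),
      disease_names = list()
    )
  }
  out |>
    dplyr::mutate(variant_id = sprintf("SVAR%06d", dplyr::row_number())) |>
    dplyr::relocate("protein_id", "variant_id")
}

#' Generate idealized membrane-frame structures for a proteome
#'
#' Lays every TM segment on an ideal helix along the membrane normal
#' (rise 1.5 Angstrom per residue, helical radius 2.3 Angstrom, 100
#' degrees per residue) so that a 21-residue helix spans the ~30 Angstrom
#' hydrophobic core and its central residue sits at z ~ 0. Successive TM
#' segments alternate crossing direction. Flanking residues are placed
#' beyond the +/-15 Angstrom membrane boundary on the side given by the
#' topology, with |z| growing 1 Angstrom per residue away from the
#' nearest membrane segment up to `z_cap`; the inside (cytosolic) face is
#' mapped to positive z. The frame is the identity: coordinates are
#' already in the membrane frame.
#'
#' @param proteome A [tm_proteome()].
#' @param config A [synthetic_config()] (seed, kept for interface
#'   symmetry; the construction is deterministic).
#' @param z_cap Maximum |z| for flanking residues (default 50).
#' @return Tibble with columns `protein_id`, `position`, `residue`,
#'   `x`, `y`, `z`; attribute `frame` holds the identity rotation and
#'   zero translation. Soluble proteins contribute no rows.
#' @export
generate_structures <- function(proteome, config = NULL, z_cap = 50) {
  stopifnot(inherits(proteome, "tm_proteome"))
  tmps <- proteome$proteins$protein_id[proteome$proteins$is_tmp]
  rows <- purrr::map(tmps, function(pid) {
    segs <- proteome$segments[proteome$segments$protein_id == pid, ]
    res <- strsplit(proteome$sequences[[pid]], "")[[1]]
    n <- length(res)
    z <- numeric(n)
    m_idx <- which(segs$region == "M")
    # inside face -> positive z; direction of each crossing alternates
    for (j in seq_along(m_idx)) {
      s <- segs[m_idx[[j]], ]
      positions <- s$start:s$end
      len <- length(positions)
      from_sign <- if (m_idx[[j]] > 1) {
        if (segs$region[[m_idx[[j]] - 1]] == "I") 1 else -1
      } else if (m_idx[[j]] < nrow(segs)) {
        # topology starts in the membrane: infer the entry side from the exit
        if (segs$region[[m_idx[[j]] + 1]] == "I") -1 else 1
      } else 1
      t0 <- (len - 1) / 2
      z[positions] <- from_sign * 1.5 * (t0 - (seq_len(len) - 1))
    }
    # flanking residues: walk away from the nearest membrane boundary
    for (si in seq_len(nrow(segs))) {
      if (segs$region[[si]] == "M") next
      side_sign <- if (segs$region[[si]] == "I") 1 else -1
      positions <- segs$start[[si]]:segs$end[[si]]
      prev_m <- if (si > 1) segs$end[[si - 1]] else NA_integer_
      next_m <- if (si < nrow(segs)) segs$start[[si + 1]] else NA_integer_
      dist <- pmin(
        if (is.na(prev_m)) Inf else positions - prev_m,
        if (is.na(next_m)) Inf else next_m - positions
      )
      z[positions] <- side_sign * pmin(15 + dist, z_cap)
    }
    theta <- (seq_len(n) - 1) * 100 * pi / 180
    tibble::tibble(
      protein_id = pid, position = seq_len(n), residue = res,
      x = 2.3 * cos(theta), y = 2.3 * sin(theta), z = z
    )
  })
  out <- purrr::list_rbind(rows)
  if (length(rows) == 0) {
    out <- tibble::tibble(protein_id = character(), position = integer(),
                          residue = character(), x = numeric(),
                          y = numeric(), z = numeric())
  }
  attr(out, "frame") <- list(rotation = diag(3), translation = c(0, 0, 0))
  out
}

#' Write a synthetic data set to files
#'
#' Emits the formats the readers consume: variants (tsv dialect),
#' topology (tsv or htp_xml), sequences (FASTA) and, when structures are
#' given, one minimal PDB per TMP plus a JSON identity frame.
#'
#' @param proteome,variants,structures Generator outputs (`structures`
#'   may be `NULL`).
#' @param dir Output directory.
#' @param topology_dialect `"tsv"` or `"htp_xml"`.
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_set <- function(proteome, variants, dir,
                                structures = NULL,
                                topology_dialect = "tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    variants = file.path(dir, "variants.tsv"),
    topology = file.path(
      dir, paste0("topology.",
                  if (topology_dialect == "tsv") "tsv" else "xml")
    ),
    fasta = file.path(dir, "sequences.fasta")
  )
  write_variants(variants, paths$variants)
  write_topology(proteome$segments, paths$topology,
                 dialect = topology_dialect)
  write_fasta(proteome$sequences, paths$fasta)
  if (!is.null(structures)) {
    paths$structures <- write_structure_pdb(structures,
                                            file.path(dir, "structures"))
    frame <- attr(structures, "frame")
    paths$frame <- file.path(dir, "frame.json")
    jsonlite::write_json(
      list(rotation = frame$rotation, translation = frame$translation),
      paths$frame, digits = NA
    )
  }
  invisible(paths)
}
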