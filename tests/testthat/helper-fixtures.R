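# Hand-built three-protein proteome: a single-pass TMP, a 2-TM TMP and a
# soluble protein. Sequences are deterministic repeats so residue
# identities at given positions are easy to reason about.
toy_proteome <- function() {
  seqs <- c(
    P1 = paste0(strrep("S", 10), strrep("L", 20), strrep("E", 30)),
    P2 = paste0(strrep("K", 5), strrep("G", 20), strrep("T", 10),
                strrep("V", 18), strrep("D", 7)),
    P3 = strrep("A", 40)
  )
  segs <- tibble::tibble(
    protein_id = c(rep("P1", 3), rep("P2", 5), "P3"),
    region = c("I", "M", "O", "I", "M", "O", "M", "I", "O"),
    start = c(1L, 11L, 31L, 1L, 6L, 26L, 36L, 54L, 1L),
    end = c(10L, 30L, 60L, 5L, 25L, 35L, 53L, 60L, 40L)
  )
  tm_proteome(seqs, segs)
}

toy_variant <- function(protein_id, position, ref_aa, alt_aa,
                        classification = "Disease",
                        disease_names = list("Synthetic storage disease"),
                        variant_id = "V1") {
  tibble::tibble(
    protein_id = protein_id, variant_id = variant_id,
    position = as.integer(position), ref_aa = ref_aa, alt_aa = alt_aa,
    classification = classification, disease_names = disease_names
  )
}

# independent per-residue oracle: expands every protein into a residue ->
# (region, subregion, segment_index, offset) lookup table
oracle_residue_table <- function(proteome) {
  out <- list()
  for (pid in names(proteome$sequences)) {
    n <- nchar(proteome$sequences[[pid]])
    region <- character(n); subregion <- character(n)
    seg_idx <- integer(n); offset <- integer(n)
    segs <- proteome$segments[proteome$segments$protein_id == pid, ]
    for (i in seq_len(nrow(segs))) {
      for (pos in segs$start[[i]]:segs$end[[i]]) {
        region[[pos]] <- segs$region[[i]]
        subregion[[pos]] <- if (is.na(segs$subregion[[i]])) NA_character_
                            else segs$subregion[[i]]
        seg_idx[[pos]] <- segs$segment_index[[i]]
        offset[[pos]] <- pos - segs$start[[i]]
      }
    }
    out[[pid]] <- list(region = region, subregion = subregion,
                       segment_index = seg_idx, offset = offset)
  }
  out
}

# small fast generator configuration shared by several tests
quick_config <- function(seed = 11, n_proteins = 40, ...) {
  synthetic_config(n_proteins = n_proteins, seed = seed, ...)
}
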