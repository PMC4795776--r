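test_that("point positions land in the unique covering segment", {
  p <- toy_proteome()
  v <- dplyr::bind_rows(
    toy_variant("P1", 15, "L", "P", variant_id = "V1"),
    toy_variant("P1", 10, "S", "A", variant_id = "V2"),
    toy_variant("P1", 31, "E", "K", variant_id = "V3")
  )
  a <- assign_regions(v, p)
  expect_equal(nrow(a), 3)
  expect_equal(a$region[a$variant_id == "V1"], "M")
  expect_equal(a$offset[a$variant_id == "V1"], 4)       # 15 - 11
  expect_equal(a$region[a$variant_id == "V2"], "I")     # inclusive end
  expect_equal(a$region[a$variant_id == "V3"], "O")
  expect_equal(a$subregion[a$variant_id == "V3"], "C_TERMINAL")
})

test_that("assignment equals the brute-force per-residue oracle", {
  cfg <- quick_config(seed = 23, n_proteins = 60)
  p <- generate_proteome(cfg)
  lookup <- oracle_residue_table(p)
  set.seed(99)
  n <- 1200
  pids <- sample(names(p$sequences), n, replace = TRUE)
  pos <- purrr::map_int(pids, ~ sample(nchar(p$sequences[[.x]]), 1))
  v <- tibble::tibble(
    protein_id = pids,
    variant_id = sprintf("T%04d", seq_len(n)),
    position = pos,
    ref_aa = substr(p$sequences[pids], pos, pos),
    alt_aa = purrr::map_chr(substr(p$sequences[pids], pos, pos),
                            ~ sample(setdiff(aa_order, .x), 1)),
    classification = sample(c("Disease", "Polymorphism"), n, replace = TRUE),
    disease_names = purrr::map(seq_len(n), ~ character(0))
  )
  a <- assign_regions(v, p)
  expect_equal(nrow(a), n)
  for (col in c("region", "subregion", "segment_index", "offset")) {
    expected <- purrr::map2(a$protein_id, a$position,
                            function(pid, q) lookup[[pid]][[col]][[q]])
    expect_equal(as.vector(a[[col]]),
                 unlist(purrr::map(expected, ~ .x %||% NA)),
                 label = col)
  }
})

test_that("drop accounting is conserved across all filters", {
  p <- toy_proteome()
  v <- dplyr::bind_rows(
    toy_variant("P1", 15, "L", "P"),                            # kept
    toy_variant("P1", 20, "L", "V", classification = "Unclassified",
                disease_names = list(character(0))),            # unclassified
    toy_variant("P1", 16, "L", "R",
                disease_names = list(c("Dis A", "Dis B"))),     # ambiguous
    toy_variant("PX", 5, "A", "V"),                             # unknown
    toy_variant("P1", 99, "L", "P"),                            # out of range
    toy_variant("P1", 15, "W", "P")                             # ref mismatch
  )
  a <- assign_regions(v, p)
  rep <- parse_report(a)
  expect_equal(rep$input, 6)
  expect_equal(rep$assigned, 1)
  expect_equal(rep$dropped_unclassified, 1)
  expect_equal(rep$dropped_ambiguous, 1)
  expect_equal(rep$dropped_unknown_protein, 1)
  expect_equal(rep$dropped_out_of_range, 1)
  expect_equal(rep$dropped_ref_mismatch, 1)
  expect_equal(
    rep$input,
    rep$assigned + rep$dropped_unclassified + rep$dropped_ambiguous +
      rep$dropped_unknown_protein + rep$dropped_out_of_range +
      rep$dropped_ref_mismatch
  )
  # a duplicated single disease name is not ambiguous
  v2 <- toy_variant("P1", 15, "L", "P",
                    disease_names = list(c("Dis A", "Dis A")))
  expect_equal(nrow(assign_regions(v2, p)), 1)
})

test_that("subregion labelling distinguishes terminals from loops", {
  simple <- tibble::tibble(
    protein_id = "X", region = c("I", "M", "O"),
    start = c(1L, 11L, 31L), end = c(10L, 30L, 60L)
  )
  expect_equal(label_subregions(simple)$subregion,
               c("N_TERMINAL", "TM", "C_TERMINAL"))

  multi <- tibble::tibble(
    protein_id = "Y", region = c("I", "M", "O", "M", "I"),
    start = c(1L, 6L, 26L, 36L, 54L), end = c(5L, 25L, 35L, 53L, 60L)
  )
  expect_equal(label_subregions(multi)$subregion,
               c("N_TERMINAL", "TM", "LOOP", "TM", "C_TERMINAL"))

  soluble <- tibble::tibble(protein_id = "Z", region = "O",
                            start = 1L, end = 40L)
  expect_error(label_subregions(soluble), "not a transmembrane")
})

test_that("region lengths sum segment sizes and match brute force", {
  p <- toy_proteome()
  rl <- region_lengths(p, "region")
  # P1: I 10 / M 20 / O 30; P2: I 12 / M 38 / O 10; P3 is soluble
  expect_equal(rl$residues[rl$label == "I"], 10 + 12)
  expect_equal(rl$residues[rl$label == "M"], 20 + 38)
  expect_equal(rl$residues[rl$label == "O"], 30 + 10)

  cfg <- quick_config(seed = 31)
  ps <- generate_proteome(cfg)
  lookup <- oracle_residue_table(ps)
  tmp_ids <- ps$proteins$protein_id[ps$proteins$is_tmp]
  brute <- table(unlist(purrr::map(lookup[tmp_ids], "region")))
  rl2 <- region_lengths(ps, "region")
  expect_equal(rl2$residues[match(names(brute), rl2$label)],
               as.integer(brute))
  brute_sub <- table(unlist(purrr::map(lookup[tmp_ids], "subregion")))
  rl3 <- region_lengths(ps, "subregion")
  expect_equal(rl3$residues[match(names(brute_sub), rl3$label)],
               as.integer(brute_sub))

  empty <- tm_proteome(c(E1 = "MKL"),
                       tibble::tibble(protein_id = "E1", region = "I",
                                      start = 1L, end = 3L))
  expect_equal(nrow(region_lengths(empty, "region")), 0)
})

test_that("TM-count distributions keep high-count proteins in denominators", {
  seqs <- c(A = strrep("L", 100), B = strrep("L", 400), C = strrep("L", 400))
  mk <- function(pid, k, len, seg = 10L) {
    n <- 2 * k + 1
    regions <- rep(c("I", "M"), length.out = n)
    regions[seq(1, n, 2)] <- rep(c("I", "O"), length.out = k + 1)
    ends <- cumsum(rep(seg, n))
    ends[n] <- len
    tibble::tibble(protein_id = pid, region = regions,
                   start = c(1L, utils::head(ends, -1) + 1L),
                   end = as.integer(ends))
  }
  p <- tm_proteome(seqs, dplyr::bind_rows(mk("A", 1, 100), mk("B", 7, 400),
                                          mk("C", 7, 400)))
  d <- tm_count_distribution(p, list(all = c("A", "B", "C")))
  expect_equal(d$fraction[d$tm_count == 1], 1 / 3)
  expect_equal(d$fraction[d$tm_count == 7], 2 / 3)
  expect_equal(sum(d$fraction), 1)

  # a 14-TM protein stays in the denominator but not in the rows
  seqs2 <- c(seqs, D = strrep("L", 400))
  p2 <- tm_proteome(seqs2, dplyr::bind_rows(mk("A", 1, 100), mk("B", 7, 400),
                                            mk("C", 7, 400), mk("D", 14, 400)))
  d2 <- tm_count_distribution(p2, list(all = c("A", "B", "C", "D")))
  expect_equal(d2$fraction[d2$tm_count == 7], 2 / 4)
  expect_lt(sum(d2$fraction), 1)
  expect_true(all(d2$tm_count <= 12))
})

test_that("generated TM-count fractions recover the configured weights", {
  w <- c(0.3, 0.3, rep(0, 5), 0.4, rep(0, 7))
  cfg <- synthetic_config(n_proteins = 400, seed = 41,
                          tm_count_weights = w)
  p <- generate_proteome(cfg)
  d <- tm_count_distribution(p, list(all = p$proteins$protein_id))
  n_tmp <- sum(p$proteins$is_tmp)
  for (k in c(1, 7)) {
    # conditional weight among TMPs
    pk <- w[k + 1] / sum(w[-1])
    phat <- d$fraction[d$tm_count == k]
    expect_lt(abs(phat - pk), 3 * sqrt(pk * (1 - pk) / n_tmp))
  }
})
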