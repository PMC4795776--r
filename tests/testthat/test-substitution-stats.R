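tm_assign <- function(...) {
  assign_regions(dplyr::bind_rows(...), toy_proteome())
}

test_that("substitution counting tallies cells per stratum", {
  a <- tm_assign(toy_variant("P1", 15, "L", "P"))
  counts <- count_substitutions(a, "region")
  m <- substitution_matrix(counts, "M", "Disease")
  expect_equal(sum(m), 1)
  expect_equal(m["L", "P"], 1)
  expect_true(all(diag(m) == 0))

  # equals a brute-force tally over raw records on synthetic data
  cfg <- quick_config(seed = 51)
  p <- generate_proteome(cfg)
  v <- generate_variants(p, cfg)
  a2 <- assign_regions(v, p)
  a2 <- a2[a2$is_tmp, ]
  counts2 <- count_substitutions(a2, "region")
  lookup <- oracle_residue_table(p)
  for (cl in c("Disease", "Polymorphism")) {
    for (r in c("I", "M", "O")) {
      sel <- a2[a2$classification == cl, ]
      brute <- matrix(0, 20, 20, dimnames = list(aa_order, aa_order))
      for (i in seq_len(nrow(sel))) {
        reg <- lookup[[sel$protein_id[[i]]]]$region[[sel$position[[i]]]]
        if (reg == r) {
          brute[sel$ref_aa[[i]], sel$alt_aa[[i]]] <-
            brute[sel$ref_aa[[i]], sel$alt_aa[[i]]] + 1
        }
      }
      expect_equal(substitution_matrix(counts2, r, cl), brute)
    }
  }

  # empty input gives an empty long table
  empty <- count_substitutions(a2[0, ], "region")
  expect_equal(nrow(empty), 0)
})

test_that("percent conversion normalizes each stratum to 100", {
  a <- tm_assign(toy_variant("P1", 15, "L", "P"))
  m <- substitution_matrix(count_substitutions(a, "region"), "M", "Disease")
  expect_equal(to_percent(m)["L", "P"], 100)

  a2 <- tm_assign(
    toy_variant("P1", 15, "L", "P", variant_id = "Va"),
    toy_variant("P1", 16, "L", "V", variant_id = "Vb")
  )
  m2 <- substitution_matrix(count_substitutions(a2, "region"),
                            "M", "Disease")
  pm <- to_percent(m2)
  expect_equal(pm["L", "P"], 50)
  expect_equal(pm["L", "V"], 50)

  expect_error(to_percent(matrix(0, 20, 20,
                                 dimnames = list(aa_order, aa_order))),
               "empty")

  cfg <- quick_config(seed = 53)
  p <- generate_proteome(cfg)
  a3 <- assign_regions(generate_variants(p, cfg), p)
  pc <- to_percent(count_substitutions(a3[a3$is_tmp, ], "region"))
  sums <- pc |>
    dplyr::summarise(s = sum(percent), .by = c(label, classification))
  expect_true(all(abs(sums$s - 100) < 1e-6))
})

test_that("polarity partition is the fixed 5/10/5 split", {
  expect_equal(unname(unlist(polarity_classes("G", "R")[c("class_from",
                                                          "class_to")])),
               c("non-polar", "charged"))
  expect_equal(polarity_classes(c("V", "L")), c("non-polar", "non-polar"))
  expect_equal(polarity_classes(c("S", "Y")), c("polar", "polar"))
  expect_equal(polarity_classes(c("R", "D", "E", "H", "K")),
               rep("charged", 5))
  expect_equal(polarity_classes(c("N", "Q", "S", "T", "Y")),
               rep("polar", 5))
  expect_error(polarity_classes("X"), "non-standard")
})

test_that("polarity aggregation conserves totals", {
  a <- tm_assign(toy_variant("P1", 15, "L", "R"))
  m <- substitution_matrix(count_substitutions(a, "region"), "M", "Disease")
  pol <- polarity_matrix(m)
  expect_equal(pol$counts["non-polar", "charged"], 1)
  expect_equal(pol$percent["non-polar", "charged"], 100)
  expect_equal(sum(pol$counts), sum(m))

  z <- polarity_matrix(matrix(0, 20, 20,
                              dimnames = list(aa_order, aa_order)))
  expect_true(all(z$counts == 0))

  cfg <- quick_config(seed = 57)
  p <- generate_proteome(cfg)
  a2 <- assign_regions(generate_variants(p, cfg), p)
  counts <- count_substitutions(a2[a2$is_tmp, ], "region")
  for (cl in unique(counts$classification)) {
    m2 <- substitution_matrix(counts, "M", cl)
    pol2 <- polarity_matrix(m2)
    expect_equal(sum(pol2$counts), sum(m2))
    # brute force via per-variant classification
    sel <- a2[a2$is_tmp & a2$region == "M" & a2$classification == cl, ]
    pc <- polarity_classes(sel$ref_aa, sel$alt_aa)
    brute <- table(factor(pc$class_from, c("charged", "non-polar", "polar")),
                   factor(pc$class_to, c("charged", "non-polar", "polar")))
    expect_equal(as.vector(pol2$counts), as.vector(brute))
    if (sum(m2) > 0) expect_equal(sum(pol2$percent), 100, tolerance = 1e-9)
  }
})

test_that("per-residue frequencies are count over region size", {
  lengths <- tibble::tibble(label = c("M", "I"), residues = c(1000L, 10L))
  a <- tibble::tibble(
    region = rep("M", 5), subregion = rep("TM", 5),
    classification = "Disease"
  )
  f <- region_frequency(a, lengths, "region")
  expect_equal(f$frequency, 5 / 1000)
  expect_equal(nrow(region_frequency(a[0, ], lengths, "region")), 0)
  # zero-length labels are excluded rather than dividing by zero
  lengths0 <- tibble::tibble(label = "M", residues = 0L)
  expect_equal(nrow(region_frequency(a, lengths0, "region")), 0)
})

test_that("predictive values apply the frequency threshold", {
  d <- matrix(0, 20, 20, dimnames = list(aa_order, aa_order))
  p <- matrix(0, 20, 20, dimnames = list(aa_order, aa_order))
  d["G", "R"] <- 150; p["G", "R"] <- 50    # reported: 200 > 100
  d["L", "P"] <- 60;  p["L", "P"] <- 30    # omitted: 90 <= 100
  d["V", "I"] <- 70;  p["V", "I"] <- 31    # reported: 101 > 100
  pv <- predictive_values(d, p, threshold = 100)
  expect_equal(nrow(pv), 2)
  expect_equal(pv$predictive_value[pv$ref_aa == "G"], 0.75)
  expect_false(any(pv$ref_aa == "L"))
  expect_true(all(pv$predictive_value >= 0 & pv$predictive_value <= 1))
})

test_that("symmetric polymorphism spectra are recovered symmetrically", {
  sym <- default_spectrum("Polymorphism")
  sym <- (sym + t(sym)) / 2
  sym <- sym / sum(sym)
  # residue frequencies proportional to the spectrum's row sums make the
  # induced (ref, alt) joint equal to the symmetric spectrum itself
  comp <- synthetic_config()$composition
  comp$M <- rowSums(sym) / sum(sym)
  cfg <- synthetic_config(
    n_proteins = 150, seed = 61,
    composition = comp,
    class_spectra = list(Disease = default_spectrum("Disease"),
                         Polymorphism = sym),
    variant_rates = c(Disease = 0, Polymorphism = 0.05),
    unclassified_rate = 0
  )
  p <- generate_proteome(cfg)
  a <- assign_regions(generate_variants(p, cfg), p)
  counts <- count_substitutions(a[a$is_tmp, ], "region")
  m <- substitution_matrix(counts, "M", "Polymorphism")
  n <- sum(m)
  # every off-diagonal pair (a,b)/(b,a) should agree within binomial error
  for (i in 1:19) {
    for (j in (i + 1):20) {
      pij <- sym[i, j]  # = sym[j, i]
      if (pij < 0.005) next
      se <- sqrt(2 * n * pij)
      expect_lt(abs(m[i, j] - m[j, i]), 4 * se + 1)
    }
  }
})

test_that("bootstrap dispersion behaves at its degenerate settings", {
  cfg <- quick_config(seed = 63)
  p <- generate_proteome(cfg)
  a <- assign_regions(generate_variants(p, cfg), p)
  a <- a[a$is_tmp, ]

  # full-fraction subsampling is the identity: SD exactly zero
  b1 <- bootstrap_sd(a, fraction = 1, n_reps = 5, seed = 1)
  expect_true(all(b1$sd == 0))

  # a statistic constant in the data has SD zero for any fraction
  const_stat <- function(x) tibble::tibble(key = "k", value = 42)
  b2 <- bootstrap_sd(a, statistic = const_stat, fraction = 0.5,
                     n_reps = 8, seed = 2)
  expect_equal(b2$sd, 0)
  expect_equal(b2$mean, 42)

  expect_error(bootstrap_sd(a, fraction = 0), "fraction")
  expect_error(bootstrap_sd(a, fraction = 1.2), "fraction")

  # two seeds agree within the dispersion they report
  bA <- bootstrap_sd(a, seed = 101)
  bB <- bootstrap_sd(a, seed = 202)
  j <- dplyr::inner_join(
    tibble::as_tibble(bA), tibble::as_tibble(bB),
    by = c("label", "classification", "ref_aa", "alt_aa")
  )
  big <- j[j$mean.x > 1, ]  # cells with appreciable mass
  expect_gt(nrow(big), 0)
  tol <- pmax(big$sd.x + big$sd.y, 0.2)
  expect_true(all(abs(big$mean.x - big$mean.y) <= 3 * tol))

  # determinism: same seed, same result
  expect_identical(tibble::as_tibble(bootstrap_sd(a, seed = 7)),
                   tibble::as_tibble(bootstrap_sd(a, seed = 7)))
})

test_that("permutation null is deterministic and flags zero-STD cells", {
  cfg <- quick_config(seed = 67)
  p <- generate_proteome(cfg)
  a <- assign_regions(generate_variants(p, cfg), p)
  perm1 <- permutation_null(a, p, n_reps = 25, seed = 5)
  perm2 <- permutation_null(a, p, n_reps = 25, seed = 5)
  expect_identical(tibble::as_tibble(perm1), tibble::as_tibble(perm2))
  expect_true(all(is.na(perm1$z[perm1$std == 0])))
  expect_true(all(!is.na(perm1$z[perm1$std > 0])))
  g <- glance(perm1)
  expect_equal(g$n_cells_tested, sum(perm1$std > 0))

  # no observed events -> no strata in the output
  expect_equal(nrow(permutation_null(a[0, ], p, n_reps = 5, seed = 1)), 0)

  # the alt-model and pooling flags change the null but keep the layout
  permC <- permutation_null(a, p, n_reps = 10, seed = 5,
                            alt_model = "conditional")
  expect_equal(names(permC), names(perm1))
  expect_equal(nrow(permC), nrow(perm1))
  expect_equal(permC$obs, perm1$obs)
})
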