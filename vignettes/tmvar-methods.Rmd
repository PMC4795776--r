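---
title: "Methods: topology-aware analysis of transmembrane missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology-aware analysis of transmembrane missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmvar)
library(dplyr)
```

## The analysis

Missense variants in transmembrane proteins (TMPs) have sharply different
consequences depending on where they fall relative to the lipid bilayer. A
polymorphism that swaps one hydrophobic residue for another inside a
membrane-spanning helix is usually tolerated; a mutation that places a
charged side chain in the middle of the bilayer is not. `tmvar` implements
a pipeline that quantifies this contrast:

1. **Topology mapping.** Every variant (a `p.RefPosAlt` substitution on a
   protein) is intersected with the protein's ordered
   inside/membrane/outside (I/M/O) segments. Because the segments tile the
   sequence, a residue position falls in exactly one segment. Terminals
   (the segments before the first and after the last membrane segment) are
   distinguished from inter-helix loops. Unclassified variants, disease
   variants annotated with more than one distinct disease (ambiguous
   records), variants whose stated reference residue disagrees with the
   sequence, and variants on unknown proteins are removed, and every drop
   is counted so that input = assigned + dropped holds exactly.
2. **Substitution spectra.** Within each (region, class) stratum the
   20x20 matrix of (mutated residue, mutant residue) counts is tallied and
   expressed as percentages of the stratum total, so each table sums
   to 100. A 3x3 aggregation over side-chain polarity classes — polar
   (N, Q, S, T, Y), non-polar (A, C, G, I, L, M, F, P, W, V) and charged
   (R, D, E, H, K) — summarizes the chemistry of the changes.
3. **Uncertainty and significance.** Dispersion of the percentage tables
   is estimated by subsampling 90% of each class ten times and taking the
   per-cell mean and standard deviation. Significance of individual cells
   is assessed against a positional permutation null: for each observed
   event in a region, a random residue position is drawn from the pooled
   sequences of that region across all TMPs, its wild-type residue becomes
   the null reference, and the null mutant residue is drawn from the
   observed mutant-residue marginal of the stratum (redrawn on collision).
   One hundred replicate null matrices give per-cell AVG and STD, and
   `z = (OBS - AVG)/STD`.
4. **Positional profiles.** For membrane variants, the distance from the
   most central residue of the TM segment, normalized by segment length,
   locates events within the helix; the same scan over the native
   sequences locates naturally occurring residues (arginine by default).
   With 3D coordinates in the membrane frame (z along the membrane normal,
   origin at the bilayer center), the structure is cut into 1 Angstrom
   slices and per-slice relative frequencies `variants / residues` are
   computed, pooling counts before taking ratios.

## The permutation null in detail

The null hypothesis is positional: *given* the set of observed mutation
events in a region, are specific substitutions more frequent than expected
if the mutated sites were random positions of that region? Drawing the
null mutant residue from the observed mutant marginal, independently of
the sampled null reference, keeps reference and mutant independent under
the null — which is exactly what a positional randomization should test.
Drawing the mutant conditionally on the sampled reference instead
(available via `alt_model = "conditional"`) makes the null reproduce the
observed row conditionals and only tests the reference composition;
we keep it as a sensitivity switch, not the default. Position pools are
pooled across the proteome by default (`pool = "proteome"`); a
per-protein variant is available, which constrains null positions to the
protein carrying each event.

Cells whose null standard deviation is zero (substitutions never produced
by the null) are reported with `z = NA` rather than infinity and counted
separately in `glance()`. Raw z ratios are reported without
multiple-testing correction; the number of tested cells is available so
users can apply one.

Resampling until the mutant differs from the reference is implemented
directly as a draw from the marginal with the reference's mass zeroed —
the two procedures define the same distribution, and the direct draw
cannot stall when the marginal is concentrated on a single residue.

## The synthetic data generator

The generator exists so every downstream stage is testable without
external downloads, and its defaults are the study conditions the
analysis assumes:

* **Class spectra.** The default 20x20 substitution spectra for disease
  mutations and polymorphisms in membrane regions ship with the package
  (`default_spectrum()`): the disease spectrum is dominated by Gly->Arg
  (6.91%) and Leu->Pro (5.47%), the polymorphism spectrum by the
  symmetric non-polar exchanges Val->Ile (7.01%) and Ile->Val (6.09%).
  By default the same spectrum is applied in all three regions; per-region
  matrices can be supplied.
* **Rates.** Default per-residue rates are 2.57e-2 (disease) and
  8.76e-3 (polymorphism), applied uniformly across regions. Variant
  counts per (protein, region, class) are Poisson with mean
  `rate x region length`, making rate-per-residue the natural parameter.
  Per-region rates (e.g. membrane-only disease variants) are supported
  and used in tests that need spatial contrast.
* **Topology.** TM counts 0–14 are drawn from a weight vector shaped like
  the human TM proteome (large single-pass and 7-TM classes, smaller
  10/12-TM classes; weight on 0 yields soluble control proteins). TM
  helices are 17–25 residues, drawn from a composition placing 74% of
  its mass on the ten non-polar residues; flanking segments use a generic
  soluble-domain composition.
* **Structures.** TM segments lie on an ideal helix with 1.5 Angstrom
  rise per residue crossing the +/-15 Angstrom hydrophobic core, with
  successive helices alternating direction; flanking residues extend
  beyond the membrane at 1 Angstrom per residue up to a +/-50 Angstrom
  cap, the inside (cytosolic) face on positive z. The accompanying frame
  is the identity, so files written as minimal PDBs read back through
  `read_structure_frame()` unchanged.
* **Determinism.** All randomness derives from one master seed; each
  protein uses a hashed substream so results do not depend on generation
  order, and identical configurations produce byte-identical outputs.

Because variant positions are uniform within a region, the *joint*
(reference, mutant) frequencies produced by the generator are the
configured spectrum's row conditionals weighted by the realized residue
composition of that region; the row conditionals themselves are recovered
exactly (within multinomial error). Parameter-recovery tests check both.
What the generator deliberately does not emulate: codon-level mutability
(the single-nucleotide accessibility of Gly->Arg), CpG deamination
hot-spots, isoform/offset annotation noise beyond a configurable
reference-mismatch drop, signal peptides and re-entrant loops. Passing
tests therefore demonstrate correctness of the computations under the
three-state topology model, not robustness to every artefact of real
release files.

## Numerical and design choices

* **Coordinates** are 1-based inclusive internally (the UniProt feature
  convention); BED export is 0-based half-open with the conversion
  localized in `to_bed()`/`read_bed()`.
* **Center of a TM segment** is `floor((start + end)/2)` — the lower
  median — so the "most central amino acid" is an actual residue and
  even-length segments break ties deterministically. Signed distances are
  kept internally; histograms fold to |d| by default.
* **Slices** are half-open `[k*w, (k+1)*w)`, so a residue at z = 3.4 with
  1 Angstrom slices falls in slice 3 and translating all coordinates by
  one width shifts every index by exactly one.
* **Bootstrap subsampling** is without replacement (a 90% subsample),
  stratified by class; classical with-replacement resampling is behind
  `replace = TRUE`. `fraction = 1` with no replacement yields SD exactly 0,
  which is tested.
* **Ambiguity** means a disease variant with more than one *distinct*
  disease name; a repeated identical name is not ambiguous.
* **Non-standard residues** (U, X, B, Z) are kept in sequences for
  coordinate bookkeeping but never enter substitution counts; variant
  records containing them are skipped at parse time and counted.
* **Empty strata** raise errors on percentage conversion rather than
  producing NaN tables; zero-length region labels are excluded from
  frequency denominators with the exclusion logged.
* **TM-count histograms** report k = 1..12 but keep proteins with more
  segments in the denominator, so displayed fractions need not sum to 1.

## Problem sizes

The shipped tests exercise the pipeline on synthetic proteomes of 25–500
proteins (most at 40–150), with the full parameter-recovery and
permutation-calibration checks at 250–500 proteins, 100 permutation
replicates and 10 bootstrap replicates — the generator's default scale.
The end-to-end acceptance run uses 500 proteins (~4,500 mapped variants).

## A worked example

```{r example}
cfg <- synthetic_config(n_proteins = 150, seed = 42)
proteome <- generate_proteome(cfg)
variants <- generate_variants(proteome, cfg)
structures <- generate_structures(proteome, cfg)
report <- run_pipeline(variants, proteome, structures = structures,
                       perm_reps = 50, seed = 42)
report
```

The permutation table is a tidy tibble:

```{r tidy}
tidy(report$tables$permutation) |>
  filter(label == "M", classification == "Disease", !is.na(z)) |>
  arrange(desc(z)) |>
  head(5)
glance(report$tables$permutation)
```

Plot builders return ggplot objects:

```{r plots, eval = FALSE}
plot_region_frequency(report$tables$region_frequency)
plot_permutation_z(report$tables$permutation)
plot_slice_profile(report$tables$slice_profile)
```

## Known limitations

* The three-state I/M/O model has no signal peptides, re-entrant loops or
  interfacial half-helices; variants in such elements are assigned to the
  enclosing I/M/O stretch.
* Mapping variants onto structures requires an explicit residue-position
  to coordinate correspondence; no homology search or alignment is
  performed for proteins without their own structure.
* The humsavar-dialect reader targets the whitespace-separated layout of
  release-era files; radically different column layouts need a thin
  adapter to the package's tsv dialect.
* Percentages are reported per stratum total; comparisons across strata
  of very different sizes should use the per-residue frequencies instead.
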