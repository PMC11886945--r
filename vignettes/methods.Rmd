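---
title: "Methods: molecular networking, dereplication and scaffold chemotaxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular networking, dereplication and scaffold chemotaxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytonet)
```

This vignette documents the methods phytonet implements, the assumptions
behind them, every tunable parameter with its unit and default, what the
synthetic-data generators do and do not emulate, and the numerical decisions
that make results deterministic.

## 1. Spectral preprocessing

An MS/MS spectrum is a list of (m/z, intensity) fragment peaks plus a
precursor m/z. Before networking, `preprocess_spectrum()` applies two
standard filters:

- **Precursor removal** — peaks within `precursor_window` (half-width, Da;
  default **17**) of the precursor m/z are removed. Rationale: residual
  precursor and isotope/adduct signals near the precursor carry no
  fragmentation information but dominate intensity, inflating cosine scores
  between unrelated spectra.
- **Window thinning** — a peak survives only if it ranks among the `top_k`
  (default **6**) most intense peaks within the window of full width
  `window_size` (Da; default **50**) centred on it. This caps per-region peak
  density so noise peaks cannot accumulate score. Ranking ties are broken by
  m/z order, so the result is deterministic.

A spectrum whose peaks are all removed is *flagged* empty
(`is_empty_spectrum()`) rather than erroring, and is skipped by networking —
an empty spectrum is an expected outcome of aggressive filtering, not a user
mistake.

Replicate spectra of one feature can be merged with
`merge_replicate_spectra()` (tolerance `mz_tol`, default **0.02 Da**):
pooled peaks are grouped by consecutive gaps ≤ tolerance; a merged peak's
intensity is the **sum** of members (total intensity is conserved) and its
m/z the intensity-weighted mean.

## 2. Feature-table filtering

`filter_feature_table()` retains a feature iff

1. its maximal biological-sample area is at least `blank_fold` (default
   **3**) times its maximal extraction-blank area — features absent from all
   blanks pass automatically; and
2. it is detected (area > 0) in at least `min_samples` (default **3**)
   biological samples.

Both rules are inclusive (≥), and every removal is recorded with its
reason(s) in the `removals` attribute. `organ_abundance()` reports log10 of
the mean area per organ, with `NA` (never `-Inf`) for organs where the
feature is absent.

## 3. Modified cosine similarity

For spectra *a*, *b* with precursor delta Δ = prec(a) − prec(b):

1. Drop zero-intensity peaks; error on empty spectra (scoring an empty
   spectrum is a contract violation, unlike *flagging* one during
   preprocessing).
2. Weight peaks by √intensity (`intensity_weighting = "sqrt"`, the
   networking convention; `"raw"` gives the plain cosine weights) and scale
   each spectrum to unit Euclidean norm.
3. Candidate pairs: |mz_i − mz_j| ≤ `frag_tol` (**0.01 Da** default) —
   *direct* — or |mz_i − mz_j − Δ| ≤ `frag_tol` — *shifted* (a shared
   neutral loss). A pair satisfying both windows counts as direct.
4. Score = maximum over one-to-one pairings of Σ w_i·w_j, solved **exactly**
   as a maximum-weight bipartite assignment.

### Numerical decisions

- **Exact assignment, not greedy.** Greedy peak pairing can under- or
  over-count matched peaks when one peak has several candidates. The solver
  is an O(n³) Hungarian algorithm (potentials + shortest augmenting paths)
  on the zero-padded square weight matrix; non-candidate cells have weight
  0, so the optimal perfect matching restricted to candidate cells is the
  optimal partial matching. Correctness is tested against a brute-force
  enumeration oracle on ≥ 1000 random pairs.
- **Deterministic tie-breaks.** Equal-weight pairings are disambiguated by
  an infinitesimal perturbation, `w − 1e-12·(effective m/z difference +
  1e-6·mz)`, preferring smaller m/z deviation, then lower m/z. The reported
  score is computed from the *unperturbed* weights, so the perturbation can
  only select among optima, never change the score (weight gaps below 1e-12
  are beneath the 1e-9 acceptance tolerance).
- The score is clipped into [0, 1] to absorb floating-point drift; symmetry
  holds to 1e-9 (Δ changes sign when arguments swap).

## 4. Molecular networks

`build_network()` scores all pairs and keeps an edge when score ≥
`min_cosine` (**0.7**) *and* matched peaks ≥ `min_matched` (**6**). A
*molecular family* is a connected component with ≥ 2 nodes; smaller
components are singletons. Two optional topology filters mirror the hosted
networking tools and default to **off** because the underlying workflow
documents only the cosine/peak thresholds:

- `top_k` — an edge survives only if each endpoint ranks the other within
  its `top_k` best-scoring neighbours (mutual rank).
- `max_component` — repeatedly remove the globally lowest-scoring edge (ties
  by node-id order, for determinism) from any component larger than the
  bound.

Whether a published "number of networks" counts singletons, and whether
hosted topology filters were active, cannot be decided from thresholds
alone; both knobs are exposed so users can replay deposited datasets and
report sensitivity.

## 5. Dereplication

`library_search()` has two contracts:

- **exact** — only records with |precursor delta| ≤ `prec_tol` (**0.01 Da**)
  are scored, with the *plain* cosine (no shift): an exact hit claims
  identity, so a neutral-loss offset would be evidence against it.
- **analog** — records within `max_delta` (**100 Da**) are scored with the
  modified cosine, so a library compound differing by one modification can
  reach full score. Exact hits are a subset of analog hits (tested as a
  property).

`masst_search()` wraps the exact contract with repository-search defaults
(precursor and fragment tolerance **0.05 Da**, cosine **0.7**, minimum **3**
matched peaks, analog **off**) and aggregates hits into per-species, genus,
and family counts. An empty result is the dereplication "green light"
(potential novelty). The index is a local MGF + metadata CSV; no network
calls are made.

`propagate_delta_annotations()` extends confirmed annotations one hop to
unannotated neighbours, labelling each edge's precursor delta with the
nearest entry of `mass_delta_table()` within `delta_tol` (**0.01 Da**; empty
label when nothing matches — a wrong label is worse than none). The delta
table is *computed* from monoisotopic atomic masses (H = 1.00782503207,
C = 12, N = 14.0030740048, O = 15.9949146196), not stored as rounded
constants. Propagation is single-hop by design: provisional annotations
never seed further propagation and never overwrite confirmed ones.

## 6. Scaffold mining and curation

A `scaffold_query` bundles an inclusion substructure, exclusion
substructures, and a curation blocklist. The five shipped queries
(`inst/extdata/scaffolds.yaml`): benzylisoquinoline, aporphine,
piperolactam, piperidine, seco-benzylisoquinoline. Patterns were validated
against known alkaloids in two independent toolkits (OpenBabel and RDKit):
piperine contains piperidine; quinolizidine and indolizidine contain a
piperidine ring but are rejected by exclusions; the aporphine core is
excluded from the benzylisoquinoline query; the tetrahydroisoquinoline core
is excluded from the seco-benzylisoquinoline query. The piperolactam
inclusion is written as an aromaticity-agnostic SMARTS (`[#6]`/`[#7]`
atoms) because toolkits disagree on whether the fused lactam ring is
aromatic; a plain-SMILES pattern matches in one aromaticity model and not
the other.

`generate_sparql()` emits a byte-stable substructure + taxon occurrence
query (Wikidata/IDSM dialect) — text only, no network call.
`load_reports()` canonicalizes structures (OpenBabel canonical SMILES),
**quarantines** unparsable rows (kept in an attribute and optionally a
reject file — never silently dropped), collapses duplicate
(structure, species) pairs with merged references, and derives a missing
genus from the species name's first token. `curate_reports()` applies the
blocklists (species + compound regex, case-insensitive) and removes reports
flagged `lacks-NMR`; every removal lands in an `audit` attribute with a
reason. `build_presence_matrix()` aggregates to genus level (logical OR),
keeping per-cell supporting references and per-scaffold genus/family/order
counts.

## 7. Phylogeny mapping

`load_tree()` reads Newick; the genus is the first `_`/space-delimited leaf
token. `annotate_tree()` attaches each genus's scaffold vector to its leaves
(all-false for genera without curated reports — absence of evidence is shown
as absence), and returns matrix genera missing from the tree as `unmapped` —
conservation (mapped ∪ unmapped = matrix genera) is a tested invariant.
Genus matching is **case-sensitive and exact**: silently case-folding taxon
names invites false merges, so case-insensitive hits are reported separately
as `near_misses` for manual curation. With `prune = TRUE` (requires a
genus → order backbone covering the tree), all leaves of orders without a
single positive genus are dropped. `export_itol()` writes one iTOL
`DATASET_BINARY` text file per scaffold with a fixed colour/shape palette,
so re-exports are byte-identical.

## 8. Synthetic data: what is emulated, and what guarantees recovery

The generators produce fixtures with known ground truth for every stage in
the same file formats the pipeline reads (MGF, CSV, Newick), so tests
exercise the real parsers. They emulate the *information structure* of a
plant-metabolomics study — analog families related by modification deltas
(CH2, H2, O, H2O, C2H4 monoisotopic masses), blank-dominated artifact
features, literature tables with look-alike decoys, a genus tree with a
taxonomy backbone — **not** fragmentation chemistry, isotope envelopes, or
realistic taxon sampling.

`simulate_spectra()` plants `n_families` (**5**) analog families of
`family_size` (**3–4**) spectra with `n_fragments` (**8–10**) peaks each.
Members copy the family base, shift the precursor and a random half of the
peaks by one modification delta, and add noise. Exact recovery of the
planted families at the default thresholds is a *construction*, not luck:

- **Disjoint bands.** Family *i* lives in its own 50-Da m/z band
  (`[50 + 50(i−1), 50 + 50(i−1) + 45]`), so cross-family peak positions —
  including all delta-shifted variants — are separated by ≥ 5 Da and can
  never produce a candidate pair.
- **Decoy rejection sampling.** Decoy singletons are resampled until no
  peak comes within 0.2 Da of any other spectrum's peaks, either directly or
  offset by the precursor delta; their modified cosine against everything is
  exactly 0 (tested with `expect_identical`).
- **Ratio-separated intensity tiers.** Base intensities are
  `sample(1e4 · cumprod(runif(n, 1.4, 2.2)))`: consecutive sorted
  intensities differ by ≥ 1.4×. Intensity log-noise (sd **0.05**) is
  truncated at 3 sd, so the maximal distortion ratio is exp(0.3) ≈ 1.35 <
  1.4 and the intensity ranking — which the top-6 window thinning keys on —
  can never flip. Every spectrum therefore retains its global top-6
  fragments.
- **Truncated m/z jitter.** Jitter (sd **0.002 Da**) is truncated at 2.4 sd,
  so two jittered copies of one fragment differ by at most 0.0096 Da <
  the 0.01 Da tolerance: shared fragments always remain candidates. (With
  unbounded Gaussian jitter, a ≈3.5σ event breaks a family edge roughly
  once per several hundred spectra — observed in practice before the
  truncation.)
- **Hub topology.** Each member matches the *base* on all fragments
  (unshifted → direct, shifted → shifted at exactly the precursor delta),
  giving ≥ 6 matched peaks and score ≥ 0.7 even in the worst allowed noise
  configuration; the family is connected through the base.

`simulate_reports()` builds positives by prefixing small substituents
(methyl, ethyl, methoxy, propyl or none) to a scaffold core, and decoys from
exclusion substructures (retrieved-but-unrelated look-alikes that exercise
the exclusion logic) or scaffold-free fillers; the truth table is returned
alongside. `simulate_tree()` grows a random genus-level tree with a
family/order backbone. Seeding: the global `seed` drives
`simulate_spectra()`; `simulate_reports()` and `simulate_tree()` use fixed
offsets (+1, +2) so each generator is individually reproducible and
`simulate_reports()` stays consistent with the tree it samples genera from.

## 9. Pipeline and problem sizes

`run_pipeline()` executes the requested stages in fixed order (simulate →
filter → network → annotate → scaffold → tree → itol), validating **all**
inputs and cross-stage dependencies before any work starts (a validation
failure raises `phytonet_validation_error`; the CLI maps it to exit code 2,
runtime failures to 1). Every stage writes its artifacts plus a JSON run
report (inputs, outputs, parameters, removals with reasons).

Default desk-scale problem sizes: ~22 spectra of 8–10 peaks (pairwise
scoring is O(n²) in spectra and O(k³) in candidate peaks — the exact solver
is comfortably fast up to hundreds of peaks), 40 literature reports, a
20-genus tree. The acceptance evidence (`scripts/acceptance.R`) runs 1000
oracle comparisons plus 20 full simulate/recover cycles in well under a
minute on one CPU.

## 10. Open questions inherited from the domain

- Whether a published network count includes singleton nodes; phytonet
  reports families (≥ 2 nodes) and singletons separately.
- Whether hosted networking deployments apply mutual-rank (`top_k`) or
  component-size (`max_component`) topology filters; both are exposed,
  default-off.
- Whether an analog library hit's precursor delta should be required to
  match a known modification mass; phytonet reports the delta and leaves
  thresholding to the caller (`propagate_delta_annotations` labels deltas
  but never discards a hit for lacking a label).
- How family/order labels should be assigned to genera retrieved from a
  knowledge base; the backbone-table contract externalizes this choice.
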