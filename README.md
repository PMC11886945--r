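# phytonet

Feature-based molecular networking and scaffold chemotaxonomy for plant
metabolomics, in R.

## The scientific problem

Untargeted LC-MS/MS experiments on plant extracts yield hundreds of
fragmentation spectra, most of which belong to unknown compounds. Two
complementary questions arise:

1. **Which features are structurally related, and which are already known?**
   Structurally similar metabolites produce similar fragmentation spectra, so
   features can be organized into a *molecular network* whose connected
   components ("molecular families") group analogs — e.g. a methylated and a
   hydroxylated variant of the same alkaloid. Comparing spectra against
   reference libraries and public repositories (*dereplication*) then rules
   out known compounds before any isolation effort.
2. **How taxonomically unusual is a compound class?** Literature occurrence
   reports, retrieved by substructure queries over a knowledge base, can be
   curated into a genus-by-scaffold presence matrix and mapped onto a
   genus-level phylogeny to show where in the plant kingdom each alkaloid
   scaffold has been found.

phytonet implements this full workflow: MGF/feature-table IO, blank and
replication filtering, a modified-cosine spectral similarity with an exact
assignment solver, network construction and export, exact/analog library
search with taxon-aggregated repository search, substructure-based scaffold
mining with curation audit trails, phylogeny annotation with iTOL export, and
seeded synthetic-data generators with known ground truth so the entire
pipeline runs and is tested offline.

## The model: modified cosine with exact peak assignment

Spectra are compared with the molecular-networking convention. For spectra
*a*, *b* with precursor difference Δ = prec(a) − prec(b), intensities are
square-root transformed and each spectrum scaled to unit norm, giving peak
weights *w*. A peak pair (i, j) is a *candidate* if

- |mz_i − mz_j| ≤ tol (direct match), or
- |mz_i − mz_j − Δ| ≤ tol (neutral-loss / shifted match).

The score is

```
S(a, b) = max over one-to-one pairings M of candidate pairs of
          Σ_{(i,j) ∈ M} w_i · w_j            ∈ [0, 1]
```

The maximization is solved **exactly** as a maximum-weight bipartite
assignment (an O(n³) Hungarian solver), not greedily; ties are broken toward
pairs with smaller effective m/z difference. An edge enters the network when
S ≥ 0.7 **and** at least 6 peaks are matched (the workflow defaults, exposed
as parameters). Analog library matching and delta-mass annotation propagation
reuse the same similarity.

## Worked example

Simulate five planted analog families plus five decoy singletons, preprocess,
and build the network (all numbers below are actual output, seed 1):

```r
library(phytonet)

sim <- simulate_spectra(simulation_config(seed = 1))
length(sim$spectra)
#> [1] 22

pre <- lapply(sim$spectra, preprocess_spectrum)   # precursor +/-17 Da removal,
net <- build_network(pre, min_cosine = 0.7,       # top-6 per 50 Da window
                     min_matched = 6, frag_tol = 0.01)
net
#> <molecular_network> 22 nodes, 12 edges, 5 molecular families

fam <- molecular_families(net)
fam$families[[1]]
#> [1] "F01_01" "F01_02" "F01_03" "F01_04"
fam$singletons
#> [1] "D01" "D02" "D03" "D04" "D05"
```

The recovered families equal the planted labels exactly. Zooming in on one
pair — a water-loss analog (precursors 593.7111 vs 611.7217):

```r
ids <- vapply(sim$spectra, `[[`, character(1), "feature_id")
r <- modified_cosine(pre[[which(ids == "F01_01")]],
                     pre[[which(ids == "F01_02")]])
r
#> <similarity_result> score 0.9999  6 matched peaks  delta -18.0106 Da
r$pairs
#>   index_a index_b shifted
#> 1       1       1   FALSE
#> 2       2       3    TRUE
#> 3       3       4    TRUE
#> 4       4       5    TRUE
#> 5       5       2   FALSE
#> 6       6       6    TRUE
```

Four peaks matched only after offsetting by the 18.011 Da precursor delta
(a shared H2O loss) — a plain cosine would have missed them.

Scaffold mining on a two-row literature table (piperine contains a piperidine
ring; quinolizidine contains one too but is rejected by the exclusion
filter):

```r
queries <- default_scaffold_queries()
df <- data.frame(
  structure = c("O=C(N1CCCCC1)/C=C/C=C/c1ccc2OCOc2c1",  # piperine
                "C1CCC2CCCCN2C1"),                       # quinolizidine
  species = c("Piper nigrum", "Lupinus albus"),
  reference = c("doi:x", "doi:y"))
write.csv(df, "reports.csv", row.names = FALSE)
out <- assign_scaffolds(load_reports("reports.csv"), queries)
out[, c("species", "piperidine", "benzylisoquinoline")]
#>         species piperidine benzylisoquinoline
#> 1 Lupinus albus      FALSE              FALSE
#> 2  Piper nigrum       TRUE              FALSE

build_presence_matrix(out)
#> <presence_matrix> 1 genera x 5 scaffolds
#>                  scaffold n_genera n_families n_orders
#> 1      benzylisoquinoline        0          0        0
#> 2               aporphine        0          0        0
#> 3            piperolactam        0          0        0
#> 4              piperidine        1          0        0
#> 5 seco-benzylisoquinoline        0          0        0
```

The whole pipeline (simulate → filter → network → scaffold → tree → iTOL)
runs from one call or from the CLI:

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 7))
```

```sh
Rscript inst/cli/phytonet run-all --out-dir out --seed 7
```

Artifacts land in `out/` (MGF, GraphML, edge list, presence matrix, curation
audit, iTOL datasets) with a JSON run report per stage under `out/reports/`.

## Package layout

| Area | Functions |
|---|---|
| Spectra IO | `read_mgf`, `write_mgf`, `msms_spectrum`, `preprocess_spectrum`, `merge_replicate_spectra` |
| Feature tables | `feature_table`, `read/write_feature_table`, `filter_feature_table`, `organ_abundance` |
| Similarity | `modified_cosine` |
| Networking | `build_network`, `molecular_families`, `export_graphml`, `export_edgelist` |
| Dereplication | `library_search`, `masst_search`, `mass_delta_table`, `propagate_delta_annotations` |
| Scaffold mining | `default_scaffold_queries`, `generate_sparql`, `load_reports`, `assign_scaffolds`, `curate_reports`, `build_presence_matrix` |
| Phylogeny | `load_tree`, `annotate_tree`, `export_itol` |
| Synthetic data | `simulation_config`, `simulate_spectra`, `simulate_reports`, `simulate_tree` |
| Pipeline | `pipeline_config`, `run_pipeline`, CLI at `inst/cli/phytonet` |

See `vignettes/methods.Rmd` for the underlying methods, parameter rationale,
and numerical design decisions.
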