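#' Pipeline configuration
#'
#' Bundles all file paths and stage parameters. The defaults are the study
#' parameters of the workflow this package implements: fragment tolerance
#' 0.01 Da, minimum cosine 0.7 and minimum 6 matched peaks for networking;
#' 0.05 Da precursor/fragment tolerance, cosine 0.7 and 3 matched peaks for
#' repository searches; 3x blank fold change, detection in at least 3
#' biological samples, and 0.02 Da replicate-merge tolerance for the feature
#' filters.
#'
#' @param spectra_mgf,feature_csv,sample_metadata_csv,library_mgf,library_csv
#'   Input paths (may be `NULL` when the stage is not run or `simulate`
#'   creates them).
#' @param reports_csv,tree_newick,backbone_csv,scaffolds_yaml More input
#'   paths; `scaffolds_yaml` defaults to the shipped scaffold definitions.
#' @param out_dir Output directory.
#' @param frag_tol_network Fragment tolerance (Da) for networking.
#' @param min_cosine,min_matched Networking edge thresholds.
#' @param masst_prec_tol,masst_frag_tol,masst_min_cosine,masst_min_matched
#'   Repository-search parameters.
#' @param blank_fold,min_samples,mz_tol_merge Feature-table filter and
#'   replicate-merge parameters.
#' @param precursor_window,window_size,top_k_peaks Spectrum preprocessing
#'   parameters.
#' @param top_k_edges,max_component Optional network topology filters
#'   (disabled by default).
#' @param prune_tree Prune orders without any positive genus (default `TRUE`).
#' @param seed Seed for the `simulate` stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra_mgf = NULL, feature_csv = NULL,
                            sample_metadata_csv = NULL, library_mgf = NULL,
                            library_csv = NULL, reports_csv = NULL,
                            tree_newick = NULL, backbone_csv = NULL,
                            scaffolds_yaml = NULL,
                            out_dir = "phytonet_out",
                            frag_tol_network = 0.01, min_cosine = 0.7,
                            min_matched = 6, masst_prec_tol = 0.05,
                            masst_frag_tol = 0.05, masst_min_cosine = 0.7,
                            masst_min_matched = 3, blank_fold = 3,
                            min_samples = 3, mz_tol_merge = 0.02,
                            precursor_window = 17, window_size = 50,
                            top_k_peaks = 6, top_k_edges = NULL,
                            max_component = NULL, prune_tree = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; keys absent from the file keep the package
#' defaults. Every overridden default is logged to stderr.
#'
#' @param path YAML config path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(raw)) {
    if (!identical(defaults[[k]], raw[[k]])) {
      message("config override: ", k, " = ", paste(raw[[k]], collapse = ","))
    }
    defaults[[k]] <- raw[[k]]
  }
  defaults
}

pipeline_stages <- c("simulate", "filter", "network", "annotate",
                     "scaffold", "tree", "itol")

validation_error <- function(msg) {
  stop(structure(class = c("phytonet_validation_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Run the analysis pipeline
#'
#' Runs the requested stages in the fixed order simulate -> filter ->
#' network -> annotate -> scaffold -> tree -> itol. Every stage writes its
#' artifact files plus a machine-readable JSON run report (input counts,
#' output counts, parameters, removals with reasons) under
#' `out_dir/reports/`. All inputs are validated before any work starts; a
#' validation failure raises a condition of class
#' `phytonet_validation_error`.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("simulate", "filter", "network", "annotate",
#'   "scaffold", "tree", "itol")`.
#' @return Invisibly, a named list of run reports.
#' @export
run_pipeline <- function(config, stages = c("simulate", "filter", "network",
                                            "scaffold", "tree", "itol")) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0L) {
    validation_error(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out <- config$out_dir
  dir.create(file.path(out, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  simulate_first <- "simulate" %in% stages
  if (simulate_first) {
    config$spectra_mgf <- file.path(out, "spectra.mgf")
    config$feature_csv <- file.path(out, "feature_table.csv")
    config$sample_metadata_csv <- file.path(out, "sample_metadata.csv")
    config$reports_csv <- file.path(out, "reports.csv")
    config$tree_newick <- file.path(out, "tree.nwk")
    config$backbone_csv <- file.path(out, "backbone.csv")
  }
  # validate all requested inputs before any stage runs
  need <- list(
    filter = c("feature_csv", "sample_metadata_csv"),
    network = "spectra_mgf",
    annotate = c("spectra_mgf", "library_mgf", "library_csv"),
    scaffold = "reports_csv",
    tree = c("tree_newick", "backbone_csv"),
    itol = c("tree_newick", "backbone_csv")
  )
  for (st in setdiff(stages, "simulate")) {
    for (key in need[[st]]) {
      if (is.null(config[[key]])) {
        validation_error(sprintf("stage '%s' requires config key '%s'",
                                 st, key))
      }
      if (!simulate_first && !file.exists(config[[key]])) {
        validation_error(sprintf("stage '%s': input file not found: %s",
                                 st, config[[key]]))
      }
    }
  }
  if ("tree" %in% stages && !"scaffold" %in% stages) {
    validation_error("stage 'tree' requires stage 'scaffold' in the same run")
  }
  if ("itol" %in% stages && !"tree" %in% stages) {
    validation_error("stage 'itol' requires stage 'tree' in the same run")
  }
  reports <- list()
  state <- new.env(parent = emptyenv())
  for (st in stages) {
    message("[phytonet] stage: ", st)
    reports[[st]] <- switch(st,
      simulate = stage_simulate(config, state),
      filter = stage_filter(config, state),
      network = stage_network(config, state),
      annotate = stage_annotate(config, state),
      scaffold = stage_scaffold(config, state),
      tree = stage_tree(config, state),
      itol = stage_itol(config, state))
    jsonlite::write_json(reports[[st]],
                         file.path(out, "reports", paste0(st, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(reports)
}

stage_simulate <- function(config, state) {
  sim_cfg <- simulation_config(seed = config$seed)
  sim <- simulate_spectra(sim_cfg)
  write_mgf(sim$spectra, config$spectra_mgf)
  state$truth_labels <- sim$labels
  # feature table: triplicates of three organs plus two extraction blanks;
  # simulated features are detected in all biological samples, plus a few
  # blank-dominated artifact features that the blank filter must remove
  ids <- vapply(sim$spectra, function(s) s$feature_id, character(1))
  organs <- rep(c("leaf", "stem", "root"), each = 3)
  samples <- data.frame(
    sample_id = c(paste0(organs, rep(1:3, times = 3)), "blank1", "blank2"),
    role = c(rep("biological", 9), "blank", "blank"),
    organ = c(organs, "none", "none"), stringsAsFactors = FALSE)
  n_art <- 3L
  all_ids <- c(ids, paste0("BLANKART", seq_len(n_art)))
  areas <- matrix(stats::rlnorm(length(all_ids) * 11, log(1e6), 0.3),
                  nrow = length(all_ids))
  areas[seq_along(ids), 10:11] <- 0
  areas[-seq_along(ids), 1:9] <- areas[-seq_along(ids), 1:9] / 10
  feats <- data.frame(
    feature_id = all_ids,
    mz = c(vapply(sim$spectra, function(s) s$precursor_mz, numeric(1)),
           stats::runif(n_art, 100, 900)),
    rt = c(vapply(sim$spectra, function(s) s$rt, numeric(1)),
           stats::runif(n_art, 0.5, 20)))
  ft <- feature_table(areas, feats, samples)
  write_feature_table(ft, config$feature_csv, config$sample_metadata_csv)
  rep_sim <- simulate_reports(sim_cfg, load_scaffolds(config))
  utils::write.csv(rep_sim$reports, config$reports_csv, row.names = FALSE)
  state$report_truth <- rep_sim$truth
  tree_sim <- simulate_tree(sim_cfg)
  writeLines(tree_sim$newick, config$tree_newick)
  utils::write.csv(tree_sim$backbone, config$backbone_csv,
                   row.names = FALSE)
  list(stage = "simulate", seed = config$seed,
       n_spectra = length(sim$spectra),
       n_families = length(unique(sim$labels[grepl("^family",
                                                   sim$labels)])),
       n_features = length(all_ids), n_reports = nrow(rep_sim$reports),
       tree_size = nrow(tree_sim$backbone))
}

stage_filter <- function(config, state) {
  ft <- read_feature_table(config$feature_csv, config$sample_metadata_csv)
  filt <- filter_feature_table(ft, blank_fold = config$blank_fold,
                               min_samples = config$min_samples)
  removals <- attr(filt, "removals")
  write_feature_table(filt, file.path(config$out_dir,
                                      "filtered_features.csv"),
                      file.path(config$out_dir,
                                "filtered_sample_metadata.csv"))
  state$retained_features <- filt$features$feature_id
  list(stage = "filter",
       params = list(blank_fold = config$blank_fold,
                     min_samples = config$min_samples),
       n_in = nrow(ft$areas), n_out = nrow(filt$areas),
       removals = removals)
}

stage_network <- function(config, state) {
  spectra <- read_mgf(config$spectra_mgf)
  if (!is.null(state$retained_features)) {
    spectra <- Filter(function(s) s$feature_id %in% state$retained_features,
                      spectra)
  }
  pre <- lapply(spectra, preprocess_spectrum,
                precursor_window = config$precursor_window,
                window_size = config$window_size,
                top_k = config$top_k_peaks)
  n_empty <- sum(vapply(pre, is_empty_spectrum, logical(1)))
  net <- build_network(pre, min_cosine = config$min_cosine,
                       min_matched = config$min_matched,
                       frag_tol = config$frag_tol_network,
                       top_k = config$top_k_edges,
                       max_component = config$max_component)
  export_graphml(net, file.path(config$out_dir, "network.graphml"))
  export_edgelist(net, file.path(config$out_dir, "network_edges.csv"))
  fam <- molecular_families(net)
  state$network <- net
  list(stage = "network",
       params = list(frag_tol = config$frag_tol_network,
                     min_cosine = config$min_cosine,
                     min_matched = config$min_matched),
       n_in = length(spectra), n_empty_after_preprocess = n_empty,
       n_nodes = igraph::vcount(net$graph), n_edges = nrow(net$edges),
       n_families = length(fam$families),
       n_singletons = length(fam$singletons),
       family_sizes = vapply(fam$families, length, integer(1)))
}

stage_annotate <- function(config, state) {
  spectra <- read_mgf(config$spectra_mgf)
  lib <- read_library(config$library_mgf, config$library_csv)
  exact <- library_search(spectra, lib, min_cosine = config$min_cosine,
                          min_matched = config$min_matched,
                          frag_tol = config$frag_tol_network,
                          mode = "exact")
  analog <- library_search(spectra, lib, min_cosine = config$min_cosine,
                           min_matched = config$min_matched,
                           frag_tol = config$frag_tol_network,
                           mode = "analog")
  utils::write.csv(exact, file.path(config$out_dir, "hits_exact.csv"),
                   row.names = FALSE)
  utils::write.csv(analog, file.path(config$out_dir, "hits_analog.csv"),
                   row.names = FALSE)
  if (!is.null(state$network) && nrow(exact) > 0L) {
    prop <- propagate_delta_annotations(state$network, exact,
                                        mass_delta_table())
    utils::write.csv(prop, file.path(config$out_dir,
                                     "propagated_annotations.csv"),
                     row.names = FALSE)
  }
  list(stage = "annotate", n_queries = length(spectra),
       n_exact_hits = nrow(exact), n_analog_hits = nrow(analog))
}

load_scaffolds <- function(config) {
  if (is.null(config$scaffolds_yaml)) {
    default_scaffold_queries()
  } else {
    load_scaffold_queries(config$scaffolds_yaml)
  }
}

stage_scaffold <- function(config, state) {
  queries <- load_scaffolds(config)
  reports <- load_reports(config$reports_csv,
                          reject_path = file.path(config$out_dir,
                                                  "rejected_structures.csv"))
  assigned <- assign_scaffolds(reports, queries)
  curated <- curate_reports(assigned, queries)
  m <- build_presence_matrix(curated)
  utils::write.csv(data.frame(genus = rownames(m$matrix), m$matrix,
                              check.names = FALSE),
                   file.path(config$out_dir, "presence_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(curated, "audit"),
                   file.path(config$out_dir, "curation_audit.csv"),
                   row.names = FALSE)
  utils::write.csv(m$summary,
                   file.path(config$out_dir, "scaffold_summary.csv"),
                   row.names = FALSE)
  state$presence <- m
  list(stage = "scaffold", n_in = nrow(reports),
       n_quarantined = nrow(attr(reports, "quarantine")),
       n_curated_out = nrow(attr(curated, "audit")),
       n_out = nrow(curated), n_genera = nrow(m$matrix),
       summary = m$summary)
}

stage_tree <- function(config, state) {
  tree <- load_tree(config$tree_newick)
  backbone <- utils::read.csv(config$backbone_csv, stringsAsFactors = FALSE)
  if (is.null(state$presence)) {
    validation_error("tree stage needs the scaffold stage's presence matrix")
  }
  at <- annotate_tree(tree, state$presence, backbone = backbone,
                      prune = config$prune_tree)
  writeLines(at$unmapped, file.path(config$out_dir, "unmapped_genera.txt"))
  state$annotated_tree <- at
  list(stage = "tree", n_tree_leaves = nrow(tree$leaves),
       n_matrix_genera = nrow(state$presence$matrix),
       n_mapped = nrow(state$presence$matrix) - length(at$unmapped),
       n_unmapped = length(at$unmapped),
       retained_orders = at$retained_orders,
       n_leaves_after_prune = nrow(at$leaf_data))
}

stage_itol <- function(config, state) {
  if (is.null(state$annotated_tree)) {
    validation_error("itol stage needs the tree stage's annotated tree")
  }
  files <- export_itol(state$annotated_tree,
                       file.path(config$out_dir, "itol"))
  list(stage = "itol", n_files = length(files), files = basename(files))
}
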