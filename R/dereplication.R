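#' Construct a spectral library record
#'
#' @param library_id Unique record identifier within the library.
#' @param name Compound name.
#' @param spectrum An [msms_spectrum()].
#' @param smiles Optional structure SMILES.
#' @param adduct Optional adduct label (e.g. `"[M+H]+"`).
#' @param species,genus,family Optional source taxonomy (used by repository
#'   searches).
#' @param dataset Optional dataset tag.
#' @return An object of class `library_record`.
#' @export
library_record <- function(library_id, name, spectrum, smiles = NA_character_,
                           adduct = NA_character_, species = NA_character_,
                           genus = NA_character_, family = NA_character_,
                           dataset = NA_character_) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  structure(list(library_id = as.character(library_id),
                 name = as.character(name), spectrum = spectrum,
                 smiles = smiles, adduct = adduct, species = species,
                 genus = genus, family = family, dataset = dataset),
            class = "library_record")
}

#' Read a spectral library from MGF plus a metadata CSV
#'
#' The MGF supplies the reference spectra (feature ids become library ids);
#' the CSV carries columns `library_id`, `name` and optionally `smiles`,
#' `adduct`, `species`, `genus`, `family`, `dataset`.
#'
#' @param mgf_path Library MGF path.
#' @param metadata_path Metadata CSV path.
#' @return A list of [library_record()] objects.
#' @export
read_library <- function(mgf_path, metadata_path) {
  spectra <- read_mgf(mgf_path)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("library_id", "name") %in% names(meta))) {
    stop("library metadata needs columns library_id and name")
  }
  meta$library_id <- as.character(meta$library_id)
  if (anyDuplicated(meta$library_id)) stop("duplicate library ids")
  get <- function(col, i) if (col %in% names(meta)) meta[[col]][i] else NA
  lapply(spectra, function(s) {
    i <- match(s$feature_id, meta$library_id)
    if (is.na(i)) stop("library spectrum without metadata: ", s$feature_id)
    library_record(meta$library_id[i], meta$name[i], s,
                   smiles = get("smiles", i), adduct = get("adduct", i),
                   species = get("species", i), genus = get("genus", i),
                   family = get("family", i), dataset = get("dataset", i))
  })
}

#' Spectral library search (exact or analog)
#'
#' Exact mode scores only records whose precursor m/z is within `prec_tol` of
#' the query, using the plain cosine (no shift). Analog mode scores records
#' within `max_delta` using the modified cosine with neutral-loss shifts, so a
#' library compound differing by one modification can still match at full
#' score. Hits below `min_cosine` or `min_matched` are discarded.
#'
#' @param queries List of [msms_spectrum()] query spectra.
#' @param library List of [library_record()] objects.
#' @param prec_tol Precursor tolerance in Da for exact matches (default 0.01).
#' @param frag_tol Fragment tolerance in Da (default 0.01).
#' @param min_cosine Minimum cosine score (default 0.7).
#' @param min_matched Minimum matched peaks (default 6).
#' @param mode `"exact"` or `"analog"`.
#' @param max_delta Maximum |precursor delta| in Da scored in analog mode
#'   (default 100).
#' @return Data frame of annotation hits: `feature_id`, `library_id`, `name`,
#'   `score`, `matched_peaks`, `match_type`, `precursor_delta`, plus source
#'   metadata columns; sorted by score descending within each query.
#' @export
library_search <- function(queries, library, prec_tol = 0.01,
                           frag_tol = 0.01, min_cosine = 0.7,
                           min_matched = 6, mode = c("exact", "analog"),
                           max_delta = 100) {
  mode <- match.arg(mode)
  stopifnot(prec_tol > 0, frag_tol > 0, min_cosine > 0, min_matched >= 1)
  if (mode == "analog" && max_delta <= 0) {
    stop("analog mode requires max_delta > 0")
  }
  if (length(library) == 0L) {
    warning("empty library; returning no hits")
    return(empty_hits())
  }
  lib_prec <- vapply(library, function(r) r$spectrum$precursor_mz, numeric(1))
  out <- list()
  for (q in queries) {
    deltas <- q$precursor_mz - lib_prec
    in_window <- if (mode == "exact") abs(deltas) <= prec_tol else
      abs(deltas) <= max_delta
    hits <- list()
    for (i in which(in_window)) {
      r <- modified_cosine(q, library[[i]]$spectrum, frag_tol = frag_tol,
                           allow_shift = (mode == "analog"))
      if (r$score >= min_cosine && r$matched_peaks >= min_matched) {
        rec <- library[[i]]
        hits[[length(hits) + 1L]] <- data.frame(
          feature_id = q$feature_id, library_id = rec$library_id,
          name = rec$name, score = r$score,
          matched_peaks = r$matched_peaks, match_type = mode,
          precursor_delta = deltas[i], smiles = rec$smiles,
          species = rec$species, genus = rec$genus, family = rec$family,
          stringsAsFactors = FALSE)
      }
    }
    if (length(hits) > 0L) {
      h <- do.call(rbind, hits)
      out[[length(out) + 1L]] <- h[order(-h$score, h$library_id), ]
    }
  }
  if (length(out) == 0L) return(empty_hits())
  rownames2null(do.call(rbind, out))
}

empty_hits <- function() {
  data.frame(feature_id = character(0), library_id = character(0),
             name = character(0), score = numeric(0),
             matched_peaks = integer(0), match_type = character(0),
             precursor_delta = numeric(0), smiles = character(0),
             species = character(0), genus = character(0),
             family = character(0), stringsAsFactors = FALSE)
}

rownames2null <- function(df) { rownames(df) <- NULL; df }

#' Repository-style MS/MS search with taxon aggregation
#'
#' Searches one query spectrum against a local repository index (MGF plus
#' metadata, see [read_library()]) under the repository-search defaults
#' (precursor and fragment tolerance 0.05 Da, cosine threshold 0.7, minimum 3
#' matched peaks, analog search off) and aggregates the hit metadata into
#' per-species/genus/family match counts, the output shape of the plant
#' repository search tools. An empty result is the dereplication "green
#' light": no similar public spectrum is known.
#'
#' @param query An [msms_spectrum()].
#' @param index List of [library_record()] objects.
#' @param prec_tol,frag_tol Tolerances in Da (defaults 0.05).
#' @param min_cosine Cosine threshold (default 0.7).
#' @param min_matched Minimum matched peaks (default 3).
#' @param analog Enable analog (shifted) search (default `FALSE`).
#' @return An object of class `masst_result`: list with `hits` (data frame as
#'   in [library_search()]) and `species`, `genus`, `family` count data
#'   frames.
#' @export
masst_search <- function(query, index, prec_tol = 0.05, frag_tol = 0.05,
                         min_cosine = 0.7, min_matched = 3, analog = FALSE) {
  hits <- library_search(list(query), index, prec_tol = prec_tol,
                         frag_tol = frag_tol, min_cosine = min_cosine,
                         min_matched = min_matched,
                         mode = if (analog) "analog" else "exact",
                         max_delta = if (analog) 100 else prec_tol)
  agg <- function(col) {
    vals <- hits[[col]][!is.na(hits[[col]])]
    if (length(vals) == 0L) {
      return(data.frame(value = character(0), n = integer(0)))
    }
    tab <- sort(table(vals), decreasing = TRUE)
    data.frame(value = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  structure(list(hits = hits, species = agg("species"),
                 genus = agg("genus"), family = agg("family")),
            class = "masst_result")
}

#' @export
print.masst_result <- function(x, ...) {
  if (nrow(x$hits) == 0L) {
    cat("<masst_result> no match (novelty signal)\n")
  } else {
    cat(sprintf("<masst_result> %d hits across %d species / %d genera / %d families\n",
                nrow(x$hits), nrow(x$species), nrow(x$genus),
                nrow(x$family)))
  }
  invisible(x)
}

#' Table of common mass deltas recomputed from atomic masses
#'
#' Monoisotopic masses of frequently observed structural modifications
#' (methylation, (de)hydrogenation, oxidation, ...), computed from the CODATA
#' monoisotopic atomic masses rather than stored as constants.
#'
#' @return Data frame with columns `label` and `delta_da`.
#' @export
mass_delta_table <- function() {
  H <- 1.00782503207
  C <- 12
  N <- 14.0030740048
  O <- 15.9949146196
  deltas <- c(
    "CH2" = C + 2 * H,
    "H2" = 2 * H,
    "O" = O,
    "OCH2" = O + C + 2 * H,
    "H2O" = 2 * H + O,
    "CO" = C + O,
    "CO2" = C + 2 * O,
    "NH" = N + H,
    "C2H2" = 2 * C + 2 * H,
    "C2H2O" = 2 * C + 2 * H + O,
    "CH2O2" = C + 2 * H + 2 * O
  )
  data.frame(label = names(deltas), delta_da = as.numeric(deltas),
             stringsAsFactors = FALSE)
}

#' Propagate annotations to network neighbours by delta mass
#'
#' For every unannotated neighbour of a confirmed node, emits a provisional
#' annotation carrying the parent compound, the edge precursor delta, the
#' best-matching mass-delta label within `delta_tol` (empty when none), and
#' the edge score. Neighbours with multiple confirmed parents get one
#' candidate per parent, ranked by edge score. Single hop only: provisional
#' annotations never seed further propagation and never overwrite confirmed
#' ones.
#'
#' @param net A [build_network()] result.
#' @param confirmed Data frame of confirmed hits with at least `feature_id`
#'   and `name` columns (e.g. rows of a [library_search()] result).
#' @param mass_deltas Data frame with `label`, `delta_da` (see
#'   [mass_delta_table()]).
#' @param delta_tol Matching tolerance for delta labels in Da (default 0.01).
#' @return Data frame: `feature_id` (the neighbour), `parent_feature_id`,
#'   `parent_compound`, `precursor_delta`, `delta_label`, `edge_score`.
#' @export
propagate_delta_annotations <- function(net, confirmed, mass_deltas,
                                        delta_tol = 0.01) {
  stopifnot(inherits(net, "molecular_network"), nrow(mass_deltas) > 0L)
  nodes <- igraph::V(net$graph)$name
  conf_ids <- unique(as.character(confirmed$feature_id))
  absent <- setdiff(conf_ids, nodes)
  if (length(absent) > 0L) {
    stop("confirmed hit(s) for node(s) absent from the network: ",
         paste(absent, collapse = ", "))
  }
  prec <- stats::setNames(igraph::V(net$graph)$precursor_mz, nodes)
  rows <- list()
  for (k in seq_len(nrow(confirmed))) {
    parent <- as.character(confirmed$feature_id[k])
    nb <- igraph::neighbors(net$graph, parent)$name
    nb <- setdiff(nb, conf_ids)
    for (child in nb) {
      e <- igraph::get_edge_ids(net$graph, c(parent, child))
      d <- prec[child] - prec[parent]
      gap <- abs(mass_deltas$delta_da - abs(d))
      label <- if (min(gap) <= delta_tol) {
        mass_deltas$label[which.min(gap)]
      } else {
        ""
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = child, parent_feature_id = parent,
        parent_compound = as.character(confirmed$name[k]),
        precursor_delta = unname(d), delta_label = label,
        edge_score = igraph::E(net$graph)$score[e],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(feature_id = character(0),
                      parent_feature_id = character(0),
                      parent_compound = character(0),
                      precursor_delta = numeric(0),
                      delta_label = character(0),
                      edge_score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # rank candidates per neighbour by edge score
  out <- out[order(out$feature_id, -out$edge_score, out$parent_feature_id), ]
  rownames2null(out)
}
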