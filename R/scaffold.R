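#' Construct a scaffold substructure query
#'
#' Bundles a named core substructure (the inclusion pattern), the exclusion
#' substructures that flag retrieved-but-unrelated compounds, and a curation
#' blocklist of known-bad literature reports.
#'
#' @param name Scaffold name (used as a column name in the presence matrix).
#' @param inclusion Inclusion substructure as SMILES or SMARTS; must be
#'   nonempty.
#' @param exclusions Character vector of exclusion SMILES/SMARTS (may be
#'   empty).
#' @param blocklist Data frame with columns `species`, `compound` (regular
#'   expressions, matched case-insensitively against the species name and the
#'   canonical structure) and `reason`.
#' @param core_smiles Plain SMILES of the scaffold core used by the
#'   synthetic-report generator to build positives (defaults to `inclusion`).
#' @return An object of class `scaffold_query`.
#' @export
scaffold_query <- function(name, inclusion, exclusions = character(0),
                           blocklist = NULL, core_smiles = inclusion) {
  if (!nzchar(trimws(inclusion))) {
    stop("scaffold '", name, "': inclusion pattern must be nonempty")
  }
  if (is.null(blocklist)) {
    blocklist <- data.frame(species = character(0), compound = character(0),
                            reason = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("species", "compound", "reason") %in% names(blocklist)))
  structure(list(name = as.character(name), inclusion = inclusion,
                 exclusions = as.character(exclusions),
                 blocklist = blocklist, core_smiles = core_smiles),
            class = "scaffold_query")
}

#' Default alkaloid scaffold queries
#'
#' Loads the five scaffold definitions shipped with the package
#' (benzylisoquinoline, aporphine, piperolactam, piperidine,
#' seco-benzylisoquinoline) from `inst/extdata/scaffolds.yaml`. The patterns
#' are package defaults validated against known alkaloids; replace the YAML
#' file to run other scaffolds.
#'
#' @return List of [scaffold_query()] objects.
#' @export
default_scaffold_queries <- function() {
  path <- system.file("extdata", "scaffolds.yaml", package = "phytonet")
  load_scaffold_queries(path)
}

#' Load scaffold queries from a YAML file
#' @param path YAML file with fields `name`, `inclusion`, optional
#'   `core_smiles`, `exclusions` and `blocklist` per entry.
#' @return List of [scaffold_query()] objects.
#' @export
load_scaffold_queries <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(q) {
    bl <- NULL
    if (!is.null(q$blocklist)) {
      bl <- do.call(rbind, lapply(q$blocklist, function(b) {
        data.frame(species = b$species, compound = b$compound,
                   reason = b$reason, stringsAsFactors = FALSE)
      }))
    }
    scaffold_query(q$name, q$inclusion,
                   exclusions = unlist(q$exclusions) %||% character(0),
                   blocklist = bl,
                   core_smiles = q$core_smiles %||% q$inclusion)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit the SPARQL query text for a scaffold occurrence search
#'
#' Instantiates a parameterized SPARQL query asking a knowledge base for
#' natural products containing the scaffold substructure together with the
#' taxa they were reported from. The text is emitted only; no network call is
#' made. Output is byte-stable for fixed inputs.
#'
#' @param q A [scaffold_query()].
#' @param endpoint_dialect Currently only `"wikidata"` (substructure search
#'   via the IDSM/Sachem SPARQL service).
#' @return The query text (single character string).
#' @export
generate_sparql <- function(q, endpoint_dialect = "wikidata") {
  stopifnot(inherits(q, "scaffold_query"))
  supported <- "wikidata"
  if (!endpoint_dialect %in% supported) {
    stop("unknown SPARQL dialect '", endpoint_dialect,
         "'; supported: ", paste(supported, collapse = ", "))
  }
  template <- paste(
    "# Occurrence query for scaffold: %NAME%",
    "PREFIX wdt: <http://www.wikidata.org/prop/direct/>",
    "PREFIX wd: <http://www.wikidata.org/entity/>",
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>",
    "PREFIX p: <http://www.wikidata.org/prop/>",
    "PREFIX ps: <http://www.wikidata.org/prop/statement/>",
    "PREFIX pr: <http://www.wikidata.org/prop/reference/>",
    "PREFIX prov: <http://www.w3.org/ns/prov#>",
    "PREFIX wikibase: <http://wikiba.se/ontology#>",
    "PREFIX bd: <http://www.bigdata.com/rdf#>",
    "PREFIX sachem: <http://bioinfo.uochb.cas.cz/rdf/v1.0/sachem#>",
    "PREFIX idsm: <https://idsm.elixir-czech.cz/sparql/endpoint/>",
    "SELECT DISTINCT ?compound ?compoundLabel ?smiles ?taxon ?taxonName ?reference WHERE {",
    "  SERVICE idsm:wikidata {",
    "    ?compound sachem:substructureSearch [",
    "      sachem:query \"%SMILES%\"",
    "    ] .",
    "  }",
    "  ?compound wdt:P233 ?smiles .",
    "  ?compound p:P703 ?stmt .",
    "  ?stmt ps:P703 ?taxon .",
    "  OPTIONAL { ?stmt prov:wasDerivedFrom/pr:P248 ?reference . }",
    "  ?taxon wdt:P225 ?taxonName .",
    "  SERVICE wikibase:label { bd:serviceParam wikibase:language \"en\" . }",
    "}",
    sep = "\n")
  gsub("%SMILES%", q$core_smiles, gsub("%NAME%", q$name, template,
                                       fixed = TRUE), fixed = TRUE)
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to its OpenBabel canonical form; unparsable strings
#' yield `NA`.
#'
#' @param x Character vector of SMILES.
#' @return Character vector of canonical SMILES (`NA` where parsing failed).
#' @export
canonical_smiles <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- trimws(sub("[\t\n].*", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Load literature occurrence reports from CSV
#'
#' Requires columns `structure` (SMILES), `species` and `reference`; columns
#' `genus`, `family`, `order` and `flags` are optional. Structures are
#' canonicalized; rows whose structure does not parse are quarantined (kept in
#' the `quarantine` attribute and optionally written to a reject file), never
#' dropped silently. Duplicate (canonical structure, species) pairs are
#' collapsed into one report with merged references. A missing genus is
#' derived as the first whitespace/underscore-delimited token of the species
#' name.
#'
#' @param path CSV path.
#' @param reject_path Optional path to write quarantined rows as CSV.
#' @return Data frame of class `occurrence_reports` with columns `structure`,
#'   `structure_canonical`, `species`, `genus`, `family`, `order`,
#'   `reference`, `flags`; attribute `quarantine` holds the rejected rows.
#' @export
load_reports <- function(path, reject_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("structure", "species", "reference")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("reports CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("genus", "family", "order", "flags")) {
    if (!col %in% names(df)) df[[col]] <- ""
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$reference <- as.character(df$reference)
  df$species <- as.character(df$species)
  df$species[is.na(df$species)] <- ""
  df$species <- trimws(df$species)
  if (any(!nzchar(df$species))) stop("reports with empty species name")
  no_genus <- !nzchar(trimws(df$genus))
  df$genus[no_genus] <- vapply(strsplit(df$species[no_genus], "[_ ]+"),
                               `[`, character(1), 1L)
  df$structure_canonical <- canonical_smiles(df$structure)
  bad <- is.na(df$structure_canonical)
  quarantine <- df[bad, setdiff(names(df), "structure_canonical")]
  if (!is.null(reject_path) && nrow(quarantine) > 0L) {
    utils::write.csv(quarantine, reject_path, row.names = FALSE)
  }
  df <- df[!bad, , drop = FALSE]
  key <- paste(df$structure_canonical, df$species, sep = "\r")
  merged <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    r <- df[ix[1L], , drop = FALSE]
    r$reference <- paste(sort(unique(df$reference[ix])), collapse = ";")
    fl <- unique(unlist(strsplit(df$flags[ix], ";")))
    r$flags <- paste(fl[nzchar(fl)], collapse = ";")
    r
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$species, out$structure_canonical), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_reports", "data.frame")
  attr(out, "quarantine") <- quarantine
  out
}

#' Assign scaffolds to occurrence reports by substructure matching
#'
#' A report carries a scaffold iff its structure contains the scaffold's
#' inclusion substructure and none of its exclusion substructures, using
#' standard subgraph matching on the molecular graph (OpenBabel SMARTS).
#' Assignment is deterministic and independent of report order.
#'
#' @param reports An [load_reports()] result (or data frame with a
#'   `structure_canonical` column).
#' @param queries List of [scaffold_query()] objects.
#' @return `reports` with one added logical column per scaffold name.
#' @export
assign_scaffolds <- function(reports, queries) {
  if (!"structure_canonical" %in% names(reports)) {
    reports$structure_canonical <- canonical_smiles(reports$structure)
  }
  if (anyNA(reports$structure_canonical)) {
    stop("all structures must be parsed; quarantine unparsable rows first")
  }
  uniq <- unique(reports$structure_canonical)
  hits <- substructure_match(uniq, queries)
  for (q in queries) {
    reports[[q$name]] <- hits[match(reports$structure_canonical, uniq),
                              q$name]
  }
  reports
}

# match unique SMILES against every query; returns a logical matrix
# (structures x scaffold names)
substructure_match <- function(smiles, queries) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles,
                                               paste0("m", seq_along(smiles))))
  count_matches <- function(pattern, scaffold) {
    res <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = TRUE),
      error = function(e) {
        stop("scaffold '", scaffold, "': pattern failed to compile: ",
             pattern, call. = FALSE)
      })
    as.integer(res) > 0L
  }
  out <- matrix(FALSE, length(smiles), length(queries),
                dimnames = list(NULL,
                                vapply(queries, `[[`, character(1), "name")))
  for (q in queries) {
    inc <- count_matches(q$inclusion, q$name)
    exc <- rep(FALSE, length(smiles))
    for (ex in q$exclusions) {
      exc <- exc | count_matches(ex, q$name)
    }
    out[, q$name] <- inc & !exc
  }
  out
}

#' Curate annotated reports with blocklists and flags
#'
#' Removes reports matching any (species pattern, compound pattern) blocklist
#' entry of any query, and reports flagged `lacks-NMR`. Every removal is
#' recorded with its reason in the `audit` attribute.
#'
#' @param reports An [assign_scaffolds()] result.
#' @param queries List of [scaffold_query()] objects (their blocklists are
#'   applied).
#' @return The curated reports, with attribute `audit`: data frame of
#'   `structure`, `species`, `reason`.
#' @export
curate_reports <- function(reports, queries) {
  drop <- rep(FALSE, nrow(reports))
  reason <- character(nrow(reports))
  for (q in queries) {
    bl <- q$blocklist
    for (k in seq_len(nrow(bl))) {
      hit <- grepl(bl$species[k], reports$species, ignore.case = TRUE) &
        (grepl(bl$compound[k], reports$structure_canonical,
               ignore.case = TRUE) |
           grepl(bl$compound[k], reports$structure, ignore.case = TRUE))
      reason[hit & !drop] <- bl$reason[k]
      drop <- drop | hit
    }
  }
  nmr <- grepl("lacks-NMR", reports$flags, fixed = TRUE)
  reason[nmr & !drop] <- "lack of NMR data in the original publication"
  drop <- drop | nmr
  audit <- data.frame(structure = reports$structure[drop],
                      species = reports$species[drop],
                      reason = reason[drop], stringsAsFactors = FALSE)
  out <- reports[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  attr(out, "quarantine") <- attr(reports, "quarantine")
  out
}

#' Build the genus-by-scaffold presence matrix
#'
#' Aggregates curated, scaffold-annotated reports to the genus level (logical
#' OR over reports), keeping the supporting reference ids per cell and a
#' per-scaffold summary of distinct genus/family/order counts. Genera where
#' every scaffold is present are flagged as "all-scaffold" genera.
#'
#' @param reports A [curate_reports()] result with scaffold columns.
#' @param scaffold_names Character vector of scaffold column names; defaults
#'   to all logical columns of `reports`.
#' @return An object of class `presence_matrix`: list with `matrix` (logical,
#'   genus x scaffold), `support` (named list: per true cell the supporting
#'   reference ids), `summary` (data frame with `scaffold`, `n_genera`,
#'   `n_families`, `n_orders`), `all_scaffold_genera`.
#' @export
build_presence_matrix <- function(reports, scaffold_names = NULL) {
  if (is.null(scaffold_names)) {
    scaffold_names <- names(reports)[vapply(reports, is.logical, logical(1))]
  }
  if (length(scaffold_names) == 0L) stop("no scaffold columns found")
  pos <- reports[rowSums(reports[, scaffold_names, drop = FALSE]) > 0L, ,
                 drop = FALSE]
  genera <- sort(unique(pos$genus))
  m <- matrix(FALSE, length(genera), length(scaffold_names),
              dimnames = list(genera, scaffold_names))
  support <- list()
  for (s in scaffold_names) {
    rows <- pos[pos[[s]], , drop = FALSE]
    for (g in unique(rows$genus)) {
      m[g, s] <- TRUE
      support[[paste(g, s, sep = "|")]] <-
        sort(unique(unlist(strsplit(rows$reference[rows$genus == g], ";"))))
    }
  }
  summary <- do.call(rbind, lapply(scaffold_names, function(s) {
    rows <- pos[pos[[s]], , drop = FALSE]
    data.frame(scaffold = s,
               n_genera = length(unique(rows$genus)),
               n_families = length(unique(rows$family[nzchar(rows$family)])),
               n_orders = length(unique(rows$order[nzchar(rows$order)])),
               stringsAsFactors = FALSE)
  }))
  structure(list(matrix = m, support = support, summary = summary,
                 all_scaffold_genera = genera[rowSums(m) ==
                                                length(scaffold_names)]),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d genera x %d scaffolds\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(x$summary)
  if (length(x$all_scaffold_genera) > 0L) {
    cat("all-scaffold genera:",
        paste(x$all_scaffold_genera, collapse = ", "), "\n")
  }
  invisible(x)
}
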