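#' Load a genus-level phylogeny from a Newick file
#'
#' Leaves are expected to be one representative species per genus; the genus
#' token is the first underscore- or space-delimited token of each leaf label.
#' Polytomies and branch lengths are allowed.
#'
#' @param path Newick file path.
#' @return An object of class `genus_tree`: list with `phylo` (an \pkg{ape}
#'   tree) and `leaves` (data frame with `label`, `genus`).
#' @export
load_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("failed to parse Newick file: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  genus <- vapply(strsplit(tree$tip.label, "[_ ]+"), `[`, character(1), 1L)
  if (any(!nzchar(genus))) stop("leaf with empty genus token")
  structure(list(phylo = tree,
                 leaves = data.frame(label = tree$tip.label, genus = genus,
                                     stringsAsFactors = FALSE)),
            class = "genus_tree")
}

#' @export
print.genus_tree <- function(x, ...) {
  cat(sprintf("<genus_tree> %d leaves, %d distinct genera\n",
              nrow(x$leaves), length(unique(x$leaves$genus))))
  invisible(x)
}

#' Annotate a genus tree with a scaffold presence matrix
#'
#' Attaches to each leaf the boolean scaffold vector of its genus (all-false
#' when the genus has no curated report). Matrix genera absent from the tree
#' are returned in the unmapped list, never silently dropped; genus matching
#' is case-sensitive and exact, and near misses (case-insensitive matches)
#' are reported to help curation. With `prune = TRUE`, all leaves belonging to
#' orders in which no genus has a positive vector are removed and the tree is
#' cleaned of degree-one internal nodes.
#'
#' @param tree A [load_tree()] result.
#' @param m A [build_presence_matrix()] result.
#' @param backbone Data frame with columns `genus`, `order` (optionally
#'   `family`); required when `prune = TRUE`, where it must cover every tree
#'   genus.
#' @param prune Remove orders with no positive genus (default `FALSE`).
#' @return An object of class `annotated_tree`: list with `phylo`,
#'   `leaf_data` (label, genus, one logical column per scaffold), `unmapped`
#'   (matrix genera not on the tree), `near_misses`, and `retained_orders`
#'   (`NULL` when not pruning).
#' @export
annotate_tree <- function(tree, m, backbone = NULL, prune = FALSE) {
  stopifnot(inherits(tree, "genus_tree"), inherits(m, "presence_matrix"))
  if (prune && is.null(backbone)) {
    stop("pruning requires a genus->order backbone table")
  }
  scaffolds <- colnames(m$matrix)
  leaf <- tree$leaves
  pres <- matrix(FALSE, nrow(leaf), length(scaffolds),
                 dimnames = list(leaf$label, scaffolds))
  mapped <- intersect(rownames(m$matrix), leaf$genus)
  for (g in mapped) {
    pres[leaf$genus == g, ] <- rep(m$matrix[g, ], each = sum(leaf$genus == g))
  }
  unmapped <- setdiff(rownames(m$matrix), leaf$genus)
  near <- unmapped[tolower(unmapped) %in% tolower(leaf$genus)]
  leaf_data <- cbind(leaf, as.data.frame(pres, check.names = FALSE),
                     row.names = NULL)
  phylo <- tree$phylo
  retained_orders <- NULL
  if (prune) {
    backbone$genus <- as.character(backbone$genus)
    not_covered <- setdiff(leaf$genus, backbone$genus)
    if (length(not_covered) > 0L) {
      stop("backbone does not cover tree genera: ",
           paste(utils::head(not_covered, 5), collapse = ", "))
    }
    leaf_order <- backbone$order[match(leaf_data$genus, backbone$genus)]
    genus_pos <- rowSums(pres) > 0L
    retained_orders <- sort(unique(leaf_order[genus_pos]))
    keep <- leaf_order %in% retained_orders
    if (!any(keep)) stop("pruning removed every leaf")
    drop <- leaf_data$label[!keep]
    if (length(drop) > 0L) {
      phylo <- ape::drop.tip(phylo, drop, collapse.singles = TRUE)
    }
    leaf_data <- leaf_data[keep, , drop = FALSE]
    leaf_data <- leaf_data[match(phylo$tip.label, leaf_data$label), ,
                           drop = FALSE]
    rownames(leaf_data) <- NULL
  }
  structure(list(phylo = phylo, leaf_data = leaf_data, unmapped = unmapped,
                 near_misses = near, retained_orders = retained_orders,
                 scaffolds = scaffolds),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("<annotated_tree> %d leaves, %d scaffolds, %d unmapped genera\n",
              nrow(x$leaf_data), length(x$scaffolds), length(x$unmapped)))
  invisible(x)
}

# fixed palette so that re-exports are byte-identical
itol_palette <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                  "#a65628", "#f781bf", "#999999")

#' Export iTOL binary datasets for an annotated tree
#'
#' Writes one iTOL `DATASET_BINARY` plain-text annotation file per scaffold
#' (leaves with a positive presence appear in the `DATA` block) plus the
#' (possibly pruned) tree as Newick. Re-exporting identical inputs yields
#' byte-identical files.
#'
#' @param at An [annotate_tree()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, character vector of the files written.
#' @export
export_itol <- function(at, out_dir) {
  stopifnot(inherits(at, "annotated_tree"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  files <- character(0)
  for (i in seq_along(at$scaffolds)) {
    s <- at$scaffolds[i]
    color <- itol_palette[(i - 1L) %% length(itol_palette) + 1L]
    shape <- (i - 1L) %% 6L + 1L
    safe <- gsub("[^A-Za-z0-9_.-]", "_", s)
    path <- file.path(out_dir, paste0("itol_", safe, ".txt"))
    pos <- at$leaf_data$label[at$leaf_data[[s]]]
    lines <- c(
      "DATASET_BINARY",
      "SEPARATOR COMMA",
      paste0("DATASET_LABEL,", s),
      paste0("COLOR,", color),
      paste0("FIELD_SHAPES,", shape),
      paste0("FIELD_LABELS,", s),
      paste0("FIELD_COLORS,", color),
      "DATA",
      if (length(pos) > 0L) paste0(sort(pos), ",1")
    )
    writeLines(lines, path)
    files <- c(files, path)
  }
  tree_path <- file.path(out_dir, "annotated_tree.nwk")
  ape::write.tree(at$phylo, tree_path)
  invisible(c(files, tree_path))
}
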