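#' Construct a feature quantification table
#'
#' Holds the feature-by-sample peak-area matrix together with feature
#' coordinates (m/z, rt) and sample metadata (role and organ). A peak area of
#' 0 means "not detected".
#'
#' @param areas Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). All values must be >= 0.
#' @param features Data frame with columns `feature_id`, `mz`, `rt`.
#' @param samples Data frame with columns `sample_id`,
#'   `role` (one of `"blank"`, `"biological"`) and
#'   `organ` (one of `"leaf"`, `"stem"`, `"root"`, `"none"`).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(areas, features, samples) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (anyNA(areas) || any(areas < 0)) stop("peak areas must be >= 0")
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(features)),
            all(c("sample_id", "role", "organ") %in% names(samples)))
  features$feature_id <- as.character(features$feature_id)
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(features$feature_id)) stop("duplicate feature ids")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (!all(samples$role %in% c("blank", "biological"))) {
    stop("sample role must be 'blank' or 'biological'")
  }
  if (!all(samples$organ %in% c("leaf", "stem", "root", "none"))) {
    stop("sample organ must be one of leaf, stem, root, none")
  }
  if (nrow(areas) != nrow(features) || ncol(areas) != nrow(samples)) {
    stop("areas dimensions must match features and samples")
  }
  rownames(areas) <- features$feature_id
  colnames(areas) <- samples$sample_id
  structure(list(areas = areas, features = features, samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%d blank, %d biological)\n",
              nrow(x$areas), ncol(x$areas),
              sum(x$samples$role == "blank"),
              sum(x$samples$role == "biological")))
  invisible(x)
}

#' Read a feature table from CSV with a sample-metadata sidecar
#'
#' The main CSV carries columns `feature_id`, `mz`, `rt` followed by one
#' column per sample; the sidecar CSV carries `sample_id`, `role`, `organ`.
#'
#' @param path Feature CSV path.
#' @param metadata_path Sample metadata CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, metadata_path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  meta <- utils::read.csv(metadata_path)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(tab))) {
    stop("feature CSV must have columns: ", paste(need, collapse = ", "))
  }
  sample_cols <- setdiff(names(tab), need)
  if (!setequal(sample_cols, meta$sample_id)) {
    stop("sample columns do not match the metadata sidecar")
  }
  meta <- meta[match(sample_cols, meta$sample_id), ]
  feature_table(as.matrix(tab[, sample_cols, drop = FALSE]),
                tab[, need], meta)
}

#' Write a feature table to CSV plus metadata sidecar
#' @param t A [feature_table()].
#' @param path Feature CSV path.
#' @param metadata_path Sample metadata CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(t, path, metadata_path) {
  out <- cbind(t$features, as.data.frame(t$areas, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  utils::write.csv(t$samples, metadata_path, row.names = FALSE)
  invisible(path)
}

#' Blank and replication filtering of a feature table
#'
#' A feature is retained iff both rules hold:
#' \itemize{
#'   \item blank rule: its maximal biological-sample area is at least
#'     `blank_fold` times its maximal blank area. Features absent from all
#'     blanks (blank max 0) always pass.
#'   \item replication rule: it is detected (area strictly > 0) in at least
#'     `min_samples` biological samples.
#' }
#'
#' @param t A [feature_table()].
#' @param blank_fold Required fold change over the blank (default 3).
#' @param min_samples Minimum number of biological samples with detection
#'   (default 3).
#' @return The filtered [feature_table()], with attribute `removals`: a data
#'   frame of removed feature ids and the reason(s).
#' @export
filter_feature_table <- function(t, blank_fold = 3, min_samples = 3) {
  stopifnot(inherits(t, "feature_table"))
  if (blank_fold <= 0) stop("blank_fold must be > 0")
  if (min_samples < 1) stop("min_samples must be >= 1")
  bio <- t$samples$role == "biological"
  if (!any(bio)) stop("feature table has no biological samples")
  blank <- !bio
  bio_area <- t$areas[, bio, drop = FALSE]
  max_bio <- apply(bio_area, 1L, max)
  max_blank <- if (any(blank)) {
    apply(t$areas[, blank, drop = FALSE], 1L, max)
  } else {
    rep(0, nrow(t$areas))
  }
  pass_blank <- max_blank == 0 | max_bio >= blank_fold * max_blank
  n_det <- rowSums(bio_area > 0)
  pass_rep <- n_det >= min_samples
  keep <- pass_blank & pass_rep
  reasons <- character(sum(!keep))
  if (any(!keep)) {
    reasons <- mapply(function(b, r) {
      paste(c(if (!b) sprintf("below %gx blank fold change", blank_fold),
              if (!r) sprintf("detected in fewer than %d biological samples",
                              min_samples)),
            collapse = "; ")
    }, pass_blank[!keep], pass_rep[!keep])
  }
  removals <- data.frame(feature_id = t$features$feature_id[!keep],
                         reason = as.character(reasons),
                         stringsAsFactors = FALSE)
  out <- feature_table(t$areas[keep, , drop = FALSE],
                       t$features[keep, , drop = FALSE], t$samples)
  attr(out, "removals") <- removals
  out
}

#' Organ-level abundance matrix
#'
#' For the requested features, computes log10 of the mean peak area across the
#' biological replicates of each organ. Organs with zero mean area yield `NA`
#' (missing), never `-Inf`.
#'
#' @param t A [feature_table()].
#' @param feature_ids Character vector of features to include.
#' @return Numeric matrix, features x organs.
#' @export
organ_abundance <- function(t, feature_ids) {
  stopifnot(inherits(t, "feature_table"))
  feature_ids <- as.character(feature_ids)
  missing_ids <- setdiff(feature_ids, t$features$feature_id)
  if (length(missing_ids) > 0L) {
    stop("unknown feature id(s): ", paste(missing_ids, collapse = ", "))
  }
  bio <- t$samples$role == "biological" & t$samples$organ != "none"
  organs <- intersect(c("leaf", "stem", "root"),
                      unique(t$samples$organ[bio]))
  out <- matrix(NA_real_, length(feature_ids), length(organs),
                dimnames = list(feature_ids, organs))
  for (org in organs) {
    cols <- bio & t$samples$organ == org
    mu <- rowMeans(t$areas[feature_ids, cols, drop = FALSE])
    out[, org] <- ifelse(mu > 0, log10(mu), NA_real_)
  }
  out
}
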