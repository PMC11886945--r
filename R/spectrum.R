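#' Construct an MS/MS spectrum
#'
#' Container for one LC-MS feature's fragmentation spectrum. Peaks are stored
#' as a two-column matrix (`mz`, `intensity`), sorted strictly ascending by
#' m/z. Retention time is stored in minutes.
#'
#' @param feature_id Opaque feature identifier (coerced to character).
#' @param precursor_mz Precursor m/z in Da; must be positive.
#' @param peaks Two-column numeric matrix or data frame with columns
#'   `mz` and `intensity`, or a list of `c(mz, intensity)` pairs.
#' @param rt Retention time in minutes (`NA` if unknown).
#' @param charge Precursor charge state (small positive integer, default 1).
#' @param provenance Free-text sample/source tag.
#' @return An object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(feature_id, precursor_mz, peaks, rt = NA_real_,
                          charge = 1L, provenance = "") {
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      is.na(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be a single positive number")
  }
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, peaks)
  }
  peaks <- as.matrix(peaks)
  if (length(peaks) == 0L) {
    peaks <- matrix(numeric(0), ncol = 2)
  }
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)")
  colnames(peaks) <- c("mz", "intensity")
  storage.mode(peaks) <- "double"
  if (anyNA(peaks)) stop("peaks must not contain NA")
  if (any(peaks[, "intensity"] < 0)) stop("peak intensities must be >= 0")
  if (any(peaks[, "mz"] <= 0)) stop("peak m/z values must be positive")
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  if (nrow(peaks) > 1L && any(diff(peaks[, "mz"]) == 0)) {
    stop("duplicate peak m/z values; merge peaks before constructing")
  }
  if (!is.na(rt) && rt < 0) stop("rt must be nonnegative (minutes)")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  structure(
    list(
      feature_id = as.character(feature_id),
      precursor_mz = as.numeric(precursor_mz),
      rt = as.numeric(rt),
      charge = charge,
      peaks = peaks,
      provenance = as.character(provenance)
    ),
    class = "msms_spectrum"
  )
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<msms_spectrum> feature %s  precursor m/z %.4f  charge %d  %d peaks\n",
    x$feature_id, x$precursor_mz, x$charge, nrow(x$peaks)
  ))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s An `msms_spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(s) nrow(s$peaks)

#' Whether a spectrum was flagged empty by preprocessing
#' @param s An `msms_spectrum`.
#' @return Logical.
#' @export
is_empty_spectrum <- function(s) {
  nrow(s$peaks) == 0L || isTRUE(attr(s, "flagged_empty"))
}

#' Preprocess an MS/MS spectrum for networking
#'
#' Removes peaks close to the precursor m/z and thins dense regions: a peak is
#' retained only if it ranks within the `top_k` most intense peaks inside the
#' window of full width `window_size` centred on it.
#'
#' @param s An `msms_spectrum`.
#' @param precursor_window Half-width in Da of the exclusion zone around the
#'   precursor m/z (default 17). `0` disables precursor removal of nothing
#'   beyond exact precursor peaks; use `NULL` to disable entirely.
#' @param window_size Full width in Da of the sliding intensity-rank window
#'   (default 50). `NULL` or `Inf` disables window thinning.
#' @param top_k Number of most intense peaks kept per window (default 6).
#'   `Inf` disables window thinning.
#' @return The filtered `msms_spectrum`. If no peaks survive, the spectrum is
#'   returned with zero peaks and attribute `flagged_empty = TRUE` rather than
#'   raising an error; such spectra are excluded from networking.
#' @export
preprocess_spectrum <- function(s, precursor_window = 17, window_size = 50,
                                top_k = 6) {
  stopifnot(inherits(s, "msms_spectrum"))
  if (!is.null(precursor_window) && precursor_window < 0) {
    stop("precursor_window must be >= 0")
  }
  if (!is.infinite(top_k) && (!is.numeric(top_k) || top_k < 1)) {
    stop("top_k must be >= 1")
  }
  pk <- s$peaks
  if (!is.null(precursor_window) && nrow(pk) > 0L) {
    keep <- abs(pk[, "mz"] - s$precursor_mz) > precursor_window
    pk <- pk[keep, , drop = FALSE]
  }
  if (!is.null(window_size) && is.finite(window_size) && is.finite(top_k) &&
      nrow(pk) > 0L) {
    half <- window_size / 2
    mz <- pk[, "mz"]
    inten <- pk[, "intensity"]
    keep <- vapply(seq_along(mz), function(i) {
      in_win <- abs(mz - mz[i]) <= half
      # rank by intensity, ties by m/z order (stable, deterministic)
      sum(inten[in_win] > inten[i] |
            (inten[in_win] == inten[i] & mz[in_win] < mz[i])) < top_k
    }, logical(1))
    pk <- pk[keep, , drop = FALSE]
  }
  out <- s
  out$peaks <- pk
  if (nrow(pk) == 0L) attr(out, "flagged_empty") <- TRUE
  out
}

#' Merge replicate MS/MS spectra of one feature
#'
#' Pools the peaks of all spectra and merges peaks whose consecutive m/z gaps
#' are within `mz_tol`. Merged intensity is the sum of member intensities
#' (intensity merge mode "sum"); merged m/z is the intensity-weighted mean of
#' member m/z values. Total intensity is conserved.
#'
#' @param spectra List of `msms_spectrum` objects sharing one `feature_id`.
#' @param mz_tol Merge tolerance in Da (default 0.02).
#' @return A single merged `msms_spectrum`. The precursor m/z is the
#'   intensity-weighted mean of the member precursors (weights = total ion
#'   current); rt likewise, ignoring missing values.
#' @export
merge_replicate_spectra <- function(spectra, mz_tol = 0.02) {
  stopifnot(length(spectra) >= 1L, mz_tol > 0)
  ids <- unique(vapply(spectra, function(s) s$feature_id, character(1)))
  if (length(ids) != 1L) {
    stop("all spectra must share one feature_id; got: ",
         paste(ids, collapse = ", "))
  }
  if (length(spectra) == 1L) return(spectra[[1L]])
  pooled <- do.call(rbind, lapply(spectra, function(s) s$peaks))
  pooled <- pooled[order(pooled[, "mz"]), , drop = FALSE]
  gaps <- diff(pooled[, "mz"])
  grp <- cumsum(c(1, as.integer(gaps > mz_tol)))
  mz <- tapply(pooled[, "mz"] * pooled[, "intensity"], grp, sum) /
    tapply(pooled[, "intensity"], grp, sum)
  inten <- tapply(pooled[, "intensity"], grp, sum)
  tic <- vapply(spectra, function(s) sum(s$peaks[, "intensity"]), numeric(1))
  w <- if (sum(tic) > 0) tic / sum(tic) else rep(1 / length(tic), length(tic))
  prec <- sum(w * vapply(spectra, function(s) s$precursor_mz, numeric(1)))
  rts <- vapply(spectra, function(s) s$rt, numeric(1))
  rt <- if (all(is.na(rts))) NA_real_ else mean(rts, na.rm = TRUE)
  msms_spectrum(
    feature_id = ids,
    precursor_mz = prec,
    peaks = cbind(mz = as.numeric(mz), intensity = as.numeric(inten)),
    rt = rt,
    charge = spectra[[1L]]$charge,
    provenance = paste(unique(vapply(spectra, function(s) s$provenance,
                                     character(1))), collapse = ";")
  )
}
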