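#' Modified cosine similarity between two MS/MS spectra
#'
#' Scores two fragmentation spectra under the molecular-networking convention:
#' intensities are square-root transformed (optionally left raw) and each
#' spectrum scaled to unit Euclidean norm. A peak pair (i, j) is a candidate
#' if the m/z values agree within `frag_tol` (direct match) or, when
#' `allow_shift = TRUE`, agree after offsetting by the precursor mass
#' difference Delta = precursor(a) - precursor(b) (a shared neutral loss).
#' The score is the maximum, over all one-to-one pairings of candidate pairs,
#' of the sum of products of normalized intensities; the pairing is solved
#' exactly as a maximum-weight bipartite assignment. With
#' `allow_shift = FALSE` this is the plain cosine similarity.
#'
#' Ties between equal-weight pairings are broken toward pairs with smaller
#' effective m/z difference, then lower m/z, by an infinitesimal perturbation
#' of the assignment weights; the reported score is computed from the
#' unperturbed weights. Zero-intensity peaks are dropped before scoring. Each
#' peak participates in at most one pair, direct or shifted, never both.
#'
#' @param a,b [msms_spectrum()] objects; must be nonempty.
#' @param frag_tol Fragment m/z tolerance in Da (default 0.01).
#' @param allow_shift Allow precursor-delta-shifted (neutral-loss) matches
#'   (default `TRUE`).
#' @param intensity_weighting `"sqrt"` (networking convention, default) or
#'   `"raw"`.
#' @return An object of class `similarity_result`: a list with `score` (in
#'   \[0, 1\]), `matched_peaks`, `precursor_delta` (Da, signed, a - b) and
#'   `pairs` (data frame with `index_a`, `index_b`, `shifted`).
#' @export
modified_cosine <- function(a, b, frag_tol = 0.01, allow_shift = TRUE,
                            intensity_weighting = c("sqrt", "raw")) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  if (frag_tol <= 0) stop("frag_tol must be > 0")
  intensity_weighting <- match.arg(intensity_weighting)
  pa <- a$peaks[a$peaks[, "intensity"] > 0, , drop = FALSE]
  pb <- b$peaks[b$peaks[, "intensity"] > 0, , drop = FALSE]
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop("modified_cosine requires nonempty spectra")
  }
  delta <- a$precursor_mz - b$precursor_mz
  wa <- if (intensity_weighting == "sqrt") sqrt(pa[, "intensity"]) else
    pa[, "intensity"]
  wb <- if (intensity_weighting == "sqrt") sqrt(pb[, "intensity"]) else
    pb[, "intensity"]
  wa <- wa / sqrt(sum(wa^2))
  wb <- wb / sqrt(sum(wb^2))

  # candidate pairs: direct and (optionally) precursor-delta shifted
  dmat <- outer(pa[, "mz"], pb[, "mz"], "-")
  direct <- abs(dmat) <= frag_tol
  shifted <- if (allow_shift) abs(dmat - delta) <= frag_tol else
    matrix(FALSE, nrow(pa), nrow(pb))
  cand <- direct | shifted
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(similarity_result(0, 0L, delta,
                             data.frame(index_a = integer(0),
                                        index_b = integer(0),
                                        shifted = logical(0))))
  }
  ia <- idx[, 1L]
  ib <- idx[, 2L]
  w <- wa[ia] * wb[ib]
  # a pair satisfying both windows counts as direct
  is_shift <- !direct[cand]
  eff <- ifelse(is_shift, abs(dmat[cand] - delta), abs(dmat[cand]))
  # infinitesimal tie-break: smaller effective m/z difference, then lower m/z
  w_tb <- w - 1e-12 * (eff + 1e-6 * pa[ia, "mz"])

  sel <- max_weight_pairing(ia, ib, w_tb, nrow(pa), nrow(pb))
  score <- min(sum(w[sel]), 1)
  ord <- order(ia[sel], ib[sel])
  pairs <- data.frame(index_a = ia[sel][ord], index_b = ib[sel][ord],
                      shifted = is_shift[sel][ord])
  similarity_result(score, nrow(pairs), delta, pairs)
}

similarity_result <- function(score, matched_peaks, precursor_delta, pairs) {
  structure(list(score = score, matched_peaks = as.integer(matched_peaks),
                 precursor_delta = precursor_delta, pairs = pairs),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> score %.4f  %d matched peaks  delta %+.4f Da\n",
              x$score, x$matched_peaks, x$precursor_delta))
  invisible(x)
}

# Exact maximum-weight one-to-one pairing over the candidate pairs
# (ia[k], ib[k]) with weights w[k] > 0. Returns the indices k of selected
# pairs. Solved as an assignment problem on the (padded) dense matrix via the
# Hungarian algorithm; non-candidate cells carry weight 0, so the optimal
# perfect matching on the padded square matrix restricted to candidate cells
# is the optimal (possibly partial) matching.
max_weight_pairing <- function(ia, ib, w, na, nb) {
  n <- max(na, nb)
  W <- matrix(0, n, n)
  W[cbind(ia, ib)] <- w
  assign_cols <- hungarian_solve(-W)  # minimize negated weight
  key <- paste(ia, ib)
  sel_key <- paste(seq_len(n), assign_cols)
  which(key %in% sel_key)
}

# O(n^3) Hungarian algorithm (potentials + shortest augmenting paths) for the
# square min-cost assignment problem. Returns, for each row i, the assigned
# column.
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  V <- n + 1L  # virtual column
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)  # row matched to each column (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[V] <- i
    j0 <- V
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      j1 <- 0L
      cur <- cost[i0, ] - u[i0] - v[seq_len(n)]
      upd <- !used[seq_len(n)] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free_cols <- which(!used[seq_len(n)])
      j1 <- free_cols[which.min(minv[free_cols])]
      delta <- minv[j1]
      used_cols <- which(used)
      rows_upd <- p[used_cols]
      u[rows_upd] <- u[rows_upd] + delta
      v[used_cols] <- v[used_cols] - delta
      minv[!used[seq_len(n)]] <- minv[!used[seq_len(n)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == V) break
    }
  }
  ans <- integer(n)
  ans[p[seq_len(n)]] <- seq_len(n)
  ans
}
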