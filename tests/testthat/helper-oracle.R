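# Independent brute-force oracle for the modified cosine: enumerates all
# one-to-one pairings over the candidate peak pairs (branch and bound on the
# remaining weight) and returns the maximum achievable score. Shares no code
# with the package's assignment solver.
bf_modified_cosine <- function(a, b, frag_tol = 0.01, allow_shift = TRUE) {
  pa <- a$peaks[a$peaks[, 2] > 0, , drop = FALSE]
  pb <- b$peaks[b$peaks[, 2] > 0, , drop = FALSE]
  wa <- sqrt(pa[, 2]); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(pb[, 2]); wb <- wb / sqrt(sum(wb^2))
  delta <- a$precursor_mz - b$precursor_mz
  d <- outer(pa[, 1], pb[, 1], "-")
  cand <- abs(d) <= frag_tol
  if (allow_shift) cand <- cand | abs(d - delta) <= frag_tol
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(score = 0, matched = 0L))
  w <- wa[idx[, 1]] * wb[idx[, 2]]
  ord <- order(-w)
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]
  n <- length(w)
  suffix <- rev(cumsum(rev(w)))
  best <- 0
  best_m <- 0L
  rec <- function(k, used_a, used_b, acc, m) {
    if (acc > best) { best <<- acc; best_m <<- m }
    if (k > n || acc + suffix[k] <= best) return(invisible(NULL))
    if (!(idx[k, 1] %in% used_a) && !(idx[k, 2] %in% used_b)) {
      rec(k + 1L, c(used_a, idx[k, 1]), c(used_b, idx[k, 2]), acc + w[k],
          m + 1L)
    }
    rec(k + 1L, used_a, used_b, acc, m)
  }
  rec(1L, integer(0), integer(0), 0, 0L)
  list(score = min(best, 1), matched = best_m)
}

# random spectrum pair with deliberate direct and shifted peak coincidences:
# m/z values live on a coarse grid so that candidate pairs are common
random_spectrum_pair <- function(max_peaks = 8) {
  na <- sample(2:max_peaks, 1)
  nb <- sample(2:max_peaks, 1)
  grid <- seq(100, 300, by = 10)
  prec_a <- 400
  prec_b <- 400 + sample(c(0, 10, 20), 1)
  mza <- sort(sample(grid, na)) + round(stats::runif(na, -0.004, 0.004), 4)
  mzb <- sort(sample(grid, nb)) + round(stats::runif(nb, -0.004, 0.004), 4)
  a <- msms_spectrum("a", prec_a, cbind(mza, stats::runif(na, 1, 100)))
  b <- msms_spectrum("b", prec_b, cbind(mzb, stats::runif(nb, 1, 100)))
  list(a = a, b = b)
}

# an n-peak spectrum with distinct m/z and intensities
toy_spectrum <- function(id, precursor, mz, intensity = NULL) {
  if (is.null(intensity)) intensity <- seq(10, by = 10,
                                           length.out = length(mz))
  msms_spectrum(id, precursor, cbind(mz, intensity))
}

# ten-feature toy table with hand-set areas exercising both filter rules:
# 9 biological samples (3 organs x 3 replicates) and 2 blanks
toy_feature_table <- function() {
  samples <- data.frame(
    sample_id = c(paste0("bio", 1:9), "blank1", "blank2"),
    role = c(rep("biological", 9), "blank", "blank"),
    organ = c(rep(c("leaf", "stem", "root"), each = 3), "none", "none"))
  areas <- matrix(0, 10, 11)
  areas[1, 1:9] <- 1e6                 # clean, everywhere -> keep
  areas[2, 1:3] <- 5e5                 # 3 samples, no blank -> keep
  areas[3, 1:2] <- 5e5                 # only 2 samples -> drop
  areas[4, 1:9] <- 2e5; areas[4, 10] <- 1e5  # fold 2 < 3 -> drop
  areas[5, 1:9] <- 3e5; areas[5, 10] <- 1e5  # fold 3 >= 3 -> keep
  areas[6, 1:9] <- 9e5; areas[6, 10:11] <- 1e5  # fold 9 -> keep
  areas[7, 10:11] <- 1e6               # blank only -> drop (both rules)
  areas[8, 1:4] <- 4e5; areas[8, 11] <- 2e5  # fold 2 -> drop
  areas[9, c(1, 4, 7)] <- 1e6          # one per organ, no blank -> keep
  areas[10, 1] <- 1e7                  # single sample -> drop
  features <- data.frame(feature_id = paste0("feat", 1:10),
                         mz = seq(150, 600, length.out = 10),
                         rt = seq(1, 10))
  feature_table(areas, features, samples)
}

toy_feature_table_expected_kept <- paste0("feat", c(1, 2, 5, 6, 9))
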