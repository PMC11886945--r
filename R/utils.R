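#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table (Hubert & Arabie). 1 means identical
#' partitions, 0 is the expected value under random labeling.
#'
#' @param x,y Vectors of cluster labels (equal length).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(1)
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- comb2(length(x))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# clustering induced by a network's families + singletons, as a named label
# vector over feature ids
network_partition <- function(net) {
  fam <- molecular_families(net, min_size = 2)
  labs <- character(0)
  for (i in seq_along(fam$families)) {
    labs[fam$families[[i]]] <- sprintf("family%03d", i)
  }
  labs[fam$singletons] <- paste0("singleton_", fam$singletons)
  labs
}
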