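#' Configuration for the synthetic-data generators
#'
#' One config object drives all three generators ([simulate_spectra()],
#' [simulate_reports()], [simulate_tree()]). Identical config and seed yield
#' identical outputs; the generators derive fixed per-stage seeds from the
#' global seed so each can also be called standalone.
#'
#' Spectral families are placed in disjoint m/z bands so that all fragment
#' positions and their modification-shifted variants are separated by at
#' least 5 Da across families; decoy singleton spectra are additionally
#' rejection-sampled until no direct or precursor-delta-shifted peak
#' coincidence with any other spectrum is possible.
#'
#' @param seed Integer seed.
#' @param n_families Number of planted analog families (default 5).
#' @param family_size Integer range `c(min, max)` of spectra per family,
#'   including the base spectrum (default `c(3, 4)`).
#' @param n_fragments Integer range of fragment peaks per base spectrum
#'   (default `c(8, 10)`).
#' @param precursor_range Precursor m/z range in Da (default `c(420, 800)`;
#'   wide enough that every family band respects the fragment ceiling
#'   `precursor - 20`).
#' @param modification_deltas Candidate precursor/fragment modification
#'   masses in Da (defaults: CH2, H2, O, H2O, C2H4 monoisotopic deltas).
#' @param intensity_noise_sd Relative (multiplicative log-normal) intensity
#'   noise (default 0.05).
#' @param mz_jitter_sd Gaussian m/z jitter in Da (default 0.002).
#' @param n_decoy_singletons Decoy spectra sharing no peaks with any family
#'   (default 5).
#' @param n_reports Literature-report rows to simulate (default 40).
#' @param decoy_fraction Fraction of decoy report structures (default 0.4).
#' @param tree_size Number of genera (= leaves) in the simulated tree
#'   (default 20).
#' @param unmapped_fraction Fraction of report genera drawn outside the tree
#'   (default 0).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_families = 5L,
                              family_size = c(3L, 4L),
                              n_fragments = c(8L, 10L),
                              precursor_range = c(420, 800),
                              modification_deltas = c(14.01565006,
                                                      2.01565006,
                                                      15.9949146196,
                                                      18.01056468,
                                                      28.03130013),
                              intensity_noise_sd = 0.05,
                              mz_jitter_sd = 0.002,
                              n_decoy_singletons = 5L, n_reports = 40L,
                              decoy_fraction = 0.4, tree_size = 20L,
                              unmapped_fraction = 0) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              n_fragments = as.integer(n_fragments),
              precursor_range = as.numeric(precursor_range),
              modification_deltas = as.numeric(modification_deltas),
              intensity_noise_sd = intensity_noise_sd,
              mz_jitter_sd = mz_jitter_sd,
              n_decoy_singletons = as.integer(n_decoy_singletons),
              n_reports = as.integer(n_reports),
              decoy_fraction = decoy_fraction,
              tree_size = as.integer(tree_size),
              unmapped_fraction = unmapped_fraction)
  if (cfg$n_families < 0 || cfg$n_decoy_singletons < 0 || cfg$n_reports < 0 ||
      cfg$tree_size < 0) {
    stop("counts must be >= 0")
  }
  if (cfg$n_families == 0 && max(cfg$family_size) > 0 &&
      cfg$n_decoy_singletons == 0) {
    stop("infeasible config: family members requested but no families")
  }
  if (cfg$intensity_noise_sd < 0 || cfg$mz_jitter_sd < 0) {
    stop("noise parameters must be >= 0")
  }
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction > 1 ||
      cfg$unmapped_fraction < 0 || cfg$unmapped_fraction > 1) {
    stop("fractions must be in [0, 1]")
  }
  if (diff(cfg$precursor_range) < 0 || cfg$precursor_range[1] <= 0) {
    stop("invalid precursor_range")
  }
  structure(cfg, class = "simulation_config")
}

# truncated Gaussian noise (clamped at b standard deviations): real
# instruments have bounded mass and intensity error, and the truncation is
# what makes exact family recovery a guarantee rather than a high-probability
# event -- jitter clamped at 2.4 sd keeps any pairwise m/z gap below
# 2 * 2.4 * 0.002 = 0.0096 Da < the 0.01 Da fragment tolerance, and intensity
# log-noise clamped at 3 sd (factor <= exp(0.3) < 1.4) can never reorder the
# ratio-separated intensity tiers that window thinning relies on
clamped_noise <- function(n, sd, bound_sd) {
  if (sd == 0) return(rep(0, n))
  b <- bound_sd * sd
  pmax(pmin(stats::rnorm(n, 0, sd), b), -b)
}

# disjoint m/z band layout: 50-Da band per family plus one decoy band,
# cross-band gap >= 5 Da by construction
band_width <- 50
band_lo <- function(i) 50 + (i - 1L) * band_width
band_hi <- function(i) band_lo(i) + band_width - 5

#' Simulate analog spectral families with known network ground truth
#'
#' Each family has a base spectrum with random fragment m/z (drawn inside the
#' family's private m/z band) and log-normal intensities. Members copy the
#' base, shift the precursor and a random subset of peaks by one modification
#' delta, and add multiplicative intensity noise and Gaussian m/z jitter.
#' Both noise terms are truncated (jitter at 2.4 sd, intensity log-noise at
#' 3 sd) so that, at the default parameters, shared fragments always stay
#' within the 0.01 Da networking tolerance and the intensity ranking that
#' window thinning keys on can never flip: exact recovery of the planted
#' families at the default thresholds is guaranteed, not merely likely.
#' Decoy singletons are rejection-sampled so that no direct or shifted peak
#' match with any other spectrum is possible (their modified cosine against
#' anything is exactly 0).
#'
#' @param config A [simulation_config()].
#' @return List with `spectra` (list of [msms_spectrum()]) and `labels`
#'   (named character vector: feature id -> planted family, decoys get unique
#'   singleton labels).
#' @export
simulate_spectra <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  deltas <- config$modification_deltas
  max_delta <- max(abs(deltas))
  needed_top <- band_lo(config$n_families + 1L) + band_width
  if (config$precursor_range[1] - 20 < needed_top) {
    stop("precursor_range too low for ", config$n_families,
         " family bands; raise the lower bound above ", needed_top + 20)
  }
  spectra <- list()
  labels <- character(0)
  # family spectra
  for (f in seq_len(config$n_families)) {
    nfrag <- sample(seq(config$n_fragments[1], config$n_fragments[2]), 1L)
    size <- sample(seq(config$family_size[1], config$family_size[2]), 1L)
    lo <- band_lo(f)
    hi <- band_hi(f) - max_delta
    frags <- numeric(0)
    while (length(frags) < nfrag) {
      x <- stats::runif(1, lo, hi)
      if (length(frags) == 0L || min(abs(frags - x)) >= 1) {
        frags <- c(frags, x)
      }
    }
    frags <- sort(frags)
    # intensity tiers with a guaranteed ratio between consecutive ranks, so
    # that multiplicative noise cannot reorder which peaks a window-based
    # top-k filter retains (real spectra span a similar dynamic range)
    base_int <- sample(1e4 * cumprod(stats::runif(nfrag, 1.4, 2.2)))
    prec <- stats::runif(1, config$precursor_range[1],
                         config$precursor_range[2] - max_delta)
    member_delta <- c(0, sample(deltas, size - 1L, replace = TRUE))
    for (m in seq_len(size)) {
      d <- member_delta[m]
      shift_set <- if (d == 0) rep(FALSE, nfrag) else
        stats::runif(nfrag) < 0.5
      mz <- frags + ifelse(shift_set, d, 0) +
        clamped_noise(nfrag, config$mz_jitter_sd, 2.4)
      inten <- base_int *
        exp(clamped_noise(nfrag, config$intensity_noise_sd, 3))
      fid <- sprintf("F%02d_%02d", f, m)
      spectra[[fid]] <- msms_spectrum(fid, prec + d,
                                      cbind(mz = mz, intensity = inten),
                                      rt = stats::runif(1, 0.5, 20),
                                      provenance = "synthetic")
      labels[fid] <- sprintf("family%02d", f)
    }
  }
  # decoy singletons: exhaustive clash check (direct and shifted) against
  # everything accepted so far
  dec_lo <- band_lo(config$n_families + 1L)
  dec_hi <- band_hi(config$n_families + 1L)
  guard <- 0.2
  clashes <- function(mz, prec) {
    for (s in spectra) {
      d <- prec - s$precursor_mz
      gaps <- outer(mz, s$peaks[, "mz"], "-")
      if (any(abs(gaps) < guard) || any(abs(gaps - d) < guard)) {
        return(TRUE)
      }
    }
    FALSE
  }
  for (k in seq_len(config$n_decoy_singletons)) {
    repeat {
      nfrag <- sample(seq(config$n_fragments[1], config$n_fragments[2]), 1L)
      mz <- sort(stats::runif(nfrag, dec_lo, dec_hi))
      if (nfrag > 1L && min(diff(mz)) < 1) next
      prec <- stats::runif(1, config$precursor_range[1],
                           config$precursor_range[2])
      if (!clashes(mz, prec)) break
    }
    inten <- stats::rlnorm(nfrag, meanlog = log(1e5), sdlog = 1)
    fid <- sprintf("D%02d", k)
    spectra[[fid]] <- msms_spectrum(fid, prec,
                                    cbind(mz = mz, intensity = inten),
                                    rt = stats::runif(1, 0.5, 20),
                                    provenance = "synthetic-decoy")
    labels[fid] <- paste0("singleton_", fid)
  }
  ord <- order(names(spectra))
  list(spectra = unname(spectra[ord]), labels = labels[names(spectra)[ord]])
}

# structure pools for report simulation ------------------------------------

# decoys built from exclusion substructures (match an inclusion or look like
# one, but are filtered out) and scaffold-free fillers
exclusion_decoy_cores <- c("C1CCC2CCCCN2C1",  # quinolizidine
                           "C1CCN2CCCC2C1",   # indolizidine
                           "C1NCCc2ccccc21")  # bare tetrahydroisoquinoline
scaffold_free_pool <- c("CCCCCCC", "CCCCO", "COc1ccccc1", "CC(=O)OCC",
                        "OC(=O)c1ccccc1", "CCCC(=O)OC", "OCC(O)CO",
                        "CC(C)Cc1ccccc1")
substituent_pool <- c("", "C", "CC", "OC", "CCC")

decorate <- function(core, sub) paste0(sub, core)

#' Simulate literature occurrence reports with known scaffold truth
#'
#' Positive structures are scaffold cores carrying small random substituents
#' (methyl, ethyl, methoxy, ...); decoys are either exclusion-substructure
#' compounds (retrieved-but-unrelated look-alikes) or scaffold-free fillers.
#' Species are sampled from the genera of the simulated tree (see
#' [simulate_tree()]), plus a configurable fraction of genera absent from the
#' tree.
#'
#' @param config A [simulation_config()].
#' @param queries List of [scaffold_query()] objects (defaults to the shipped
#'   five).
#' @return List with `reports` (data frame with `structure`, `species`,
#'   `genus`, `family`, `order`, `reference`, `flags`) and `truth` (data
#'   frame: one logical column per scaffold, rows aligned with `reports`).
#' @export
simulate_reports <- function(config, queries = default_scaffold_queries()) {
  stopifnot(inherits(config, "simulation_config"))
  tree_sim <- simulate_tree(config)
  backbone <- tree_sim$backbone
  set.seed(config$seed + 1L)
  n <- config$n_reports
  qnames <- vapply(queries, `[[`, character(1), "name")
  rows <- vector("list", n)
  truth <- matrix(FALSE, n, length(qnames), dimnames = list(NULL, qnames))
  for (i in seq_len(n)) {
    if (stats::runif(1) < config$decoy_fraction) {
      pool <- c(exclusion_decoy_cores, scaffold_free_pool)
      structure_smiles <- decorate(sample(pool, 1L),
                                   sample(substituent_pool, 1L))
      # all-false truth row
    } else {
      qi <- sample(seq_along(queries), 1L)
      structure_smiles <- decorate(queries[[qi]]$core_smiles,
                                   sample(substituent_pool, 1L))
      truth[i, qi] <- TRUE
    }
    if (stats::runif(1) < config$unmapped_fraction) {
      genus <- sprintf("Offtree%02d", sample(9L, 1L))
      fam <- "OfftreeFamily"; ord <- "OfftreeOrder"
    } else {
      j <- sample(nrow(backbone), 1L)
      genus <- backbone$genus[j]
      fam <- backbone$family[j]
      ord <- backbone$order[j]
    }
    rows[[i]] <- data.frame(
      structure = structure_smiles,
      species = paste0(genus, " simulated", i),
      genus = genus, family = fam, order = ord,
      reference = sprintf("ref%03d", i), flags = "",
      stringsAsFactors = FALSE)
  }
  list(reports = do.call(rbind, rows),
       truth = as.data.frame(truth))
}

#' Simulate a genus-level phylogeny with a taxonomy backbone
#'
#' Random rooted tree whose leaves are `Genus_species` labels, with genera
#' partitioned into synthetic families and orders (contiguous blocks of the
#' alphabetical genus list).
#'
#' @param config A [simulation_config()].
#' @return List with `newick` (tree text), `backbone` (data frame `genus`,
#'   `family`, `order`) and `phylo` (the \pkg{ape} tree).
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$tree_size < 2L) stop("tree_size must be >= 2")
  set.seed(config$seed + 2L)
  n <- config$tree_size
  genera <- sprintf("Genus%02d", seq_len(n))
  phylo <- ape::rtree(n, tip.label = paste0(genera, "_typespecies"))
  backbone <- data.frame(
    genus = genera,
    family = sprintf("Family%02d", ceiling(seq_len(n) / 3)),
    order = sprintf("Order%02d", ceiling(seq_len(n) / 5)),
    stringsAsFactors = FALSE)
  list(newick = ape::write.tree(phylo), backbone = backbone, phylo = phylo)
}
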