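lib_mz <- c(100, 120, 141, 163, 188, 210)

make_library <- function() {
  rec <- function(id, name, prec, mz, species = NA, genus = NA,
                  family = NA) {
    library_record(id, name,
                   toy_spectrum(id, prec, mz, rep(100, length(mz))),
                   species = species, genus = genus, family = family)
  }
  list(
    rec("L1", "compoundA", 500, lib_mz,
        species = "Piper nigrum", genus = "Piper", family = "Piperaceae"),
    rec("L2", "compoundB", 700, lib_mz + 250,
        species = "Piper betle", genus = "Piper", family = "Piperaceae"),
    rec("L3", "compoundC", 500.2, lib_mz + 77,
        species = "Punica granatum", genus = "Punica",
        family = "Lythraceae"))
}

test_that("exact search finds identical spectra at full score", {
  lib <- make_library()
  q <- toy_spectrum("q1", 500, lib_mz, rep(100, 6))
  hits <- library_search(list(q), lib, mode = "exact")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$library_id, "L1")
  expect_equal(hits$score, 1)
  expect_equal(hits$matched_peaks, 6L)
  expect_equal(hits$match_type, "exact")
})

test_that("exact search never scores records outside the precursor window", {
  lib <- make_library()
  # L3 sits 0.2 Da away: same peaks as L1 shifted by 77, query matches L3's
  # peaks but the precursor gate (0.01 Da) excludes it
  q <- toy_spectrum("q1", 500, lib_mz + 77, rep(100, 6))
  hits <- library_search(list(q), lib, mode = "exact", prec_tol = 0.01)
  expect_equal(nrow(hits), 0L)
  wide <- library_search(list(q), lib, mode = "exact", prec_tol = 0.5)
  expect_equal(wide$library_id, "L3")
})

test_that("analog search matches a methylated analog that exact misses", {
  lib <- make_library()
  # query = compoundA + CH2: precursor and half the peaks shifted by 14.0157
  d <- 14.0157
  q <- toy_spectrum("q1", 500 + d, lib_mz + c(0, d, 0, d, 0, d), rep(100, 6))
  exact <- library_search(list(q), lib, mode = "exact")
  expect_equal(nrow(exact), 0L)
  analog <- library_search(list(q), lib, mode = "analog")
  expect_equal(analog$library_id, "L1")
  expect_equal(analog$score, 1)
  expect_equal(analog$precursor_delta, d)
})

test_that("exact hits are a subset of analog hits", {
  lib <- make_library()
  set.seed(77)
  for (i in 1:20) {
    keep <- runif(6) < 0.8
    if (sum(keep) < 3) keep[1:3] <- TRUE
    q <- toy_spectrum("q", 500 + rnorm(1, 0, 0.004),
                      lib_mz[keep] + rnorm(sum(keep), 0, 0.002),
                      runif(sum(keep), 10, 100))
    ex <- library_search(list(q), lib, min_cosine = 0.2, min_matched = 2)
    an <- library_search(list(q), lib, min_cosine = 0.2, min_matched = 2,
                         mode = "analog")
    expect_true(all(ex$library_id %in% an$library_id))
  }
})

test_that("an empty library warns and returns an empty hit table", {
  q <- toy_spectrum("q1", 500, lib_mz, rep(100, 6))
  expect_warning(hits <- library_search(list(q), list()), "empty library")
  expect_equal(nrow(hits), 0L)
})

test_that("repository search aggregates hits per taxon", {
  lib <- make_library()
  # query identical to L1; L2 has the same peak pattern shifted +250 at
  # precursor 700, far outside the exact window -> only L1 hits
  q <- toy_spectrum("q1", 500, lib_mz, rep(100, 6))
  res <- masst_search(q, lib)
  expect_s3_class(res, "masst_result")
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$species$value, "Piper nigrum")
  expect_equal(res$genus$value, "Piper")
  # two same-genus records within the window aggregate to one genus row
  lib2 <- c(lib, list(library_record(
    "L4", "compoundA-iso",
    toy_spectrum("L4", 500.01, lib_mz, rep(100, 6)),
    species = "Piper longum", genus = "Piper", family = "Piperaceae")))
  res2 <- masst_search(q, lib2)
  expect_equal(nrow(res2$hits), 2L)
  expect_equal(nrow(res2$species), 2L)
  expect_equal(nrow(res2$genus), 1L)
  expect_equal(res2$genus$n, 2L)
  # no hit is the novelty signal
  novel <- toy_spectrum("qx", 999, c(400, 450, 480), c(10, 10, 10))
  res3 <- masst_search(novel, lib)
  expect_equal(nrow(res3$hits), 0L)
  expect_equal(nrow(res3$species), 0L)
})

test_that("mass deltas are recomputed from atomic masses", {
  md <- mass_delta_table()
  expect_equal(md$delta_da[md$label == "H2"], 2.01565006, tolerance = 1e-7)
  expect_equal(md$delta_da[md$label == "CH2"], 14.01565006,
               tolerance = 1e-7)
  expect_equal(md$delta_da[md$label == "O"], 15.9949146196,
               tolerance = 1e-9)
  expect_equal(md$delta_da[md$label == "H2O"],
               md$delta_da[md$label == "H2"] + md$delta_da[md$label == "O"])
})

test_that("annotations propagate one hop with delta labels", {
  d <- 2.0156
  a <- toy_spectrum("a", 500, lib_mz, rep(100, 6))
  b <- toy_spectrum("b", 500 + d, lib_mz + c(0, 0, 0, d, d, d), rep(100, 6))
  far <- toy_spectrum("c", 800, lib_mz + 400, rep(100, 6))
  net <- build_network(list(a, b, far))
  confirmed <- data.frame(feature_id = "a", name = "compoundA")
  prop <- propagate_delta_annotations(net, confirmed, mass_delta_table())
  expect_equal(nrow(prop), 1L)
  expect_equal(prop$feature_id, "b")
  expect_equal(prop$parent_compound, "compoundA")
  expect_equal(prop$delta_label, "H2")
  expect_equal(prop$precursor_delta, d)
  # an unmatched delta yields an empty label, not a wrong one
  tiny <- data.frame(label = "CH2", delta_da = 14.01565006)
  prop2 <- propagate_delta_annotations(net, confirmed, tiny)
  expect_equal(prop2$delta_label, "")
  # nodes without confirmed neighbours produce no rows
  conf_far <- data.frame(feature_id = "c", name = "compoundC")
  prop3 <- propagate_delta_annotations(net, conf_far, mass_delta_table())
  expect_equal(nrow(prop3), 0L)
  # confirmed ids must exist in the network
  expect_error(propagate_delta_annotations(
    net, data.frame(feature_id = "ghost", name = "x"), mass_delta_table()),
    "absent from the network.*ghost")
})

test_that("propagation never overwrites confirmed annotations", {
  a <- toy_spectrum("a", 500, lib_mz, rep(100, 6))
  b <- toy_spectrum("b", 500, lib_mz, rep(100, 6))
  net <- build_network(list(a, b))
  confirmed <- data.frame(feature_id = c("a", "b"),
                          name = c("compoundA", "compoundB"))
  prop <- propagate_delta_annotations(net, confirmed, mass_delta_table())
  expect_equal(nrow(prop), 0L)
})

test_that("library round trip via MGF + metadata CSV works", {
  lib <- make_library()
  mgf <- withr::local_tempfile(fileext = ".mgf")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mgf(lapply(lib, `[[`, "spectrum"), mgf)
  write.csv(data.frame(
    library_id = c("L1", "L2", "L3"),
    name = c("compoundA", "compoundB", "compoundC"),
    species = c("Piper nigrum", "Piper betle", "Punica granatum"),
    genus = c("Piper", "Piper", "Punica"),
    family = c("Piperaceae", "Piperaceae", "Lythraceae")), csv,
    row.names = FALSE)
  back <- read_library(mgf, csv)
  expect_length(back, 3L)
  expect_equal(back[[1]]$name, "compoundA")
  expect_equal(back[[3]]$genus, "Punica")
  q <- toy_spectrum("q1", 500, lib_mz, rep(100, 6))
  hits <- library_search(list(q), back)
  expect_equal(hits$name, "compoundA")
})
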