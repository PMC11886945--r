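test_that("msms_spectrum validates and normalizes its inputs", {
  s <- msms_spectrum("f1", 300.1, cbind(c(150, 120), c(10, 20)), rt = 5)
  expect_s3_class(s, "msms_spectrum")
  expect_equal(s$peaks[, "mz"], c(120, 150))  # sorted ascending
  expect_equal(n_peaks(s), 2L)
  expect_false(is_empty_spectrum(s))
  expect_error(msms_spectrum("f", -1, cbind(100, 10)), "positive")
  expect_error(msms_spectrum("f", 300, cbind(c(100, 100), c(1, 2))),
               "duplicate")
  expect_error(msms_spectrum("f", 300, cbind(100, -5)), ">= 0")
  expect_error(msms_spectrum("f", 300, cbind(100, NA)), "NA")
})

test_that("MGF read/write round trip preserves spectra exactly", {
  set.seed(42)
  spectra <- lapply(1:5, function(i) {
    n <- sample(3:8, 1)
    msms_spectrum(paste0("feat", i), runif(1, 200, 900),
                  cbind(sort(runif(n, 50, 190)), runif(n, 1, 1e6)),
                  rt = runif(1, 0.5, 20), charge = sample(1:2, 1),
                  provenance = paste0("sample", i))
  })
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_equal(back[[i]]$feature_id, spectra[[i]]$feature_id)
    expect_equal(back[[i]]$precursor_mz, spectra[[i]]$precursor_mz)
    expect_equal(back[[i]]$rt, spectra[[i]]$rt)
    expect_equal(back[[i]]$charge, spectra[[i]]$charge)
    expect_equal(unname(back[[i]]$peaks), unname(spectra[[i]]$peaks))
  }
})

test_that("read_mgf parses the mzmine dialect headers", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS",
               "FEATURE_ID=17",
               "PEPMASS=318.1341 12345.0",
               "RTINSECONDS=90",
               "CHARGE=1+",
               "TITLE=run1",
               "120.0808 1000",
               "188.0706\t2500",
               "END IONS"), path)
  s <- read_mgf(path)
  expect_length(s, 1L)
  expect_equal(s[[1]]$feature_id, "17")
  expect_equal(s[[1]]$precursor_mz, 318.1341)
  expect_equal(s[[1]]$rt, 1.5)  # 90 s -> minutes
  expect_equal(unname(s[[1]]$peaks),
               cbind(c(120.0808, 188.0706), c(1000, 2500)),
               ignore_attr = TRUE)
})

test_that("read_mgf reports malformed input precisely", {
  p1 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "CHARGE=1+", "100 1", "END IONS"), p1)
  expect_error(read_mgf(p1), "block 1 is missing a PEPMASS")
  p2 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=300", "100 1", "oops peak", "END IONS"),
             p2)
  expect_error(read_mgf(p2), "non-numeric peak line at line 4")
  p3 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=300", "100 1"), p3)
  expect_error(read_mgf(p3), "unbalanced")
  expect_error(read_mgf(file.path(tempdir(), "absent.mgf")), "not found")
})

test_that("preprocessing removes the precursor region", {
  s <- msms_spectrum("f", 300, cbind(c(100, 150, 299, 284), c(10, 20, 30, 5)))
  out <- preprocess_spectrum(s, precursor_window = 17, window_size = NULL,
                             top_k = Inf)
  # 299 (1 Da below precursor) and 284 (16 Da below) fall in the +/-17 zone
  expect_equal(out$peaks[, "mz"], c(100, 150))
})

test_that("window thinning keeps the top-k peaks per 50 Da window", {
  # 7 peaks within one 50 Da span; with top_k = 6 only the least intense dies
  mz <- seq(100, 130, by = 5)
  inten <- c(70, 10, 60, 50, 40, 30, 20)  # the 10 is the weakest
  s <- msms_spectrum("f", 500, cbind(mz, inten))
  out <- preprocess_spectrum(s, precursor_window = 17, window_size = 50,
                             top_k = 6)
  expect_equal(out$peaks[, "mz"], mz[inten != 10])
  # a far-away peak is unaffected by the crowded window
  s2 <- msms_spectrum("f", 500, cbind(c(mz, 250), c(inten, 1)))
  out2 <- preprocess_spectrum(s2, precursor_window = 17, window_size = 50,
                              top_k = 6)
  expect_true(250 %in% out2$peaks[, "mz"])
})

test_that("preprocessing flags fully-removed spectra instead of erroring", {
  s <- msms_spectrum("f", 300, cbind(295, 10))
  out <- preprocess_spectrum(s)
  expect_equal(n_peaks(out), 0L)
  expect_true(is_empty_spectrum(out))
})

test_that("preprocessing is idempotent", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    s <- msms_spectrum("f", 500,
                       cbind(sort(runif(n, 50, 480)), runif(n, 1, 1e5)))
    once <- preprocess_spectrum(s)
    twice <- preprocess_spectrum(once)
    expect_equal(unname(twice$peaks), unname(once$peaks))
  }
})

test_that("replicate merging follows the weighted-mean arithmetic", {
  # two peaks 0.01 Da apart (within tol 0.02), intensities 1 and 3:
  # merged m/z = (100.000*1 + 100.010*3) / 4 = 100.0075, intensity = 4
  a <- msms_spectrum("f", 300, cbind(100.000, 1))
  b <- msms_spectrum("f", 300, cbind(100.010, 3))
  m <- merge_replicate_spectra(list(a, b), mz_tol = 0.02)
  expect_equal(unname(m$peaks[, "mz"]), 100.0075)
  expect_equal(unname(m$peaks[, "intensity"]), 4)
  # beyond tolerance the peaks stay separate
  b2 <- msms_spectrum("f", 300, cbind(100.05, 3))
  m2 <- merge_replicate_spectra(list(a, b2), mz_tol = 0.02)
  expect_equal(n_peaks(m2), 2L)
})

test_that("replicate merging conserves total intensity", {
  set.seed(11)
  for (i in 1:15) {
    reps <- lapply(1:3, function(k) {
      n <- sample(4:10, 1)
      msms_spectrum("f", 400 + rnorm(1, 0, 0.005),
                    cbind(sort(runif(n, 100, 380)), runif(n, 10, 1e5)))
    })
    total_in <- sum(vapply(reps, function(s) sum(s$peaks[, "intensity"]),
                           numeric(1)))
    m <- merge_replicate_spectra(reps, mz_tol = 0.02)
    expect_equal(sum(m$peaks[, "intensity"]), total_in)
    expect_lte(n_peaks(m), sum(vapply(reps, n_peaks, integer(1))))
  }
})

test_that("replicate merging rejects mixed feature ids", {
  a <- msms_spectrum("f1", 300, cbind(100, 1))
  b <- msms_spectrum("f2", 300, cbind(100, 1))
  expect_error(merge_replicate_spectra(list(a, b)), "one feature_id")
})
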