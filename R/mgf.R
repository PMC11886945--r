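#' Read feature-linked MS/MS spectra from an MGF file
#'
#' Parses the mzmine/FBMN export dialect of the Mascot Generic Format: one
#' `BEGIN IONS`/`END IONS` block per feature, with `PEPMASS` (precursor m/z,
#' optionally followed by an intensity), `RTINSECONDS`, `CHARGE` (e.g. `1+`)
#' and `FEATURE_ID` headers. Retention time is converted to minutes. The
#' feature id is taken from `FEATURE_ID`, else `SCANS`, else the block
#' ordinal.
#'
#' @param path Path to an MGF file.
#' @return A list of [msms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    line_nos <- (begins[b] + 1L):(ends[b] - 1L)
    is_header <- grepl("=", block, fixed = TRUE)
    headers <- block[is_header]
    keys <- toupper(sub("=.*", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    names(vals) <- keys
    if (!"PEPMASS" %in% keys) {
      stop(sprintf("MGF block %d is missing a PEPMASS (precursor mass) field",
                   b))
    }
    prec <- suppressWarnings(as.numeric(strsplit(trimws(vals[["PEPMASS"]]),
                                                 "[ \t]+")[[1L]][1L]))
    if (is.na(prec)) {
      stop(sprintf("MGF block %d has a non-numeric PEPMASS", b))
    }
    rt <- NA_real_
    if ("RTINSECONDS" %in% keys) {
      rt <- suppressWarnings(as.numeric(vals[["RTINSECONDS"]])) / 60
    }
    charge <- 1L
    if ("CHARGE" %in% keys) {
      charge <- suppressWarnings(as.integer(gsub("[+-]", "",
                                                 vals[["CHARGE"]])))
      if (is.na(charge) || charge < 1L) charge <- 1L
    }
    fid <- if ("FEATURE_ID" %in% keys) {
      trimws(vals[["FEATURE_ID"]])
    } else if ("SCANS" %in% keys) {
      trimws(vals[["SCANS"]])
    } else {
      as.character(b)
    }
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    peak_nos <- line_nos[!is_header & nzchar(trimws(block))]
    if (length(peak_lines) > 0L) {
      parts <- strsplit(trimws(peak_lines), "[ \t]+")
      bad <- vapply(parts, function(p) {
        length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2])))
      }, logical(1))
      if (any(bad)) {
        stop(sprintf("non-numeric peak line at line %d of %s",
                     peak_nos[which(bad)[1L]], path))
      }
      mz <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
      inten <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
      peaks <- cbind(mz = mz, intensity = inten)
    } else {
      peaks <- matrix(numeric(0), ncol = 2)
    }
    spectra[[b]] <- msms_spectrum(
      feature_id = fid, precursor_mz = prec, peaks = peaks, rt = rt,
      charge = charge,
      provenance = if ("TITLE" %in% keys) vals[["TITLE"]] else ""
    )
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: writes the mzmine/FBMN dialect with `FEATURE_ID`,
#' `PEPMASS`, `RTINSECONDS` and `CHARGE` headers. Peak m/z and intensities are
#' written with full precision so that a read/write round trip preserves peak
#' lists exactly.
#'
#' @param spectra List of [msms_spectrum()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) formatC(x, digits = 15, format = "g")
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("FEATURE_ID=", s$feature_id), con)
    writeLines(paste0("PEPMASS=", num(s$precursor_mz)), con)
    if (!is.na(s$rt)) {
      writeLines(paste0("RTINSECONDS=", num(s$rt * 60)), con)
    }
    writeLines(paste0("CHARGE=", s$charge, "+"), con)
    if (nzchar(s$provenance)) {
      writeLines(paste0("TITLE=", s$provenance), con)
    }
    if (nrow(s$peaks) > 0L) {
      writeLines(paste(num(s$peaks[, "mz"]), num(s$peaks[, "intensity"])),
                 con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
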