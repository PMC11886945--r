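queries <- default_scaffold_queries()
qnames <- vapply(queries, `[[`, character(1), "name")

write_reports_csv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  write.csv(df, path, row.names = FALSE)
  path
}

report_row <- function(structure, species, reference = "ref1", genus = "",
                       family = "", order = "", flags = "") {
  data.frame(structure = structure, species = species, genus = genus,
             family = family, order = order, reference = reference,
             flags = flags, stringsAsFactors = FALSE)
}

test_that("the shipped scaffold queries load with their curation rules", {
  expect_length(queries, 5L)
  expect_setequal(qnames, c("benzylisoquinoline", "aporphine",
                            "piperolactam", "piperidine",
                            "seco-benzylisoquinoline"))
  pip <- queries[[which(qnames == "piperidine")]]
  expect_gt(nrow(pip$blocklist), 0L)
  expect_true(any(grepl("database error", pip$blocklist$reason)))
  expect_error(scaffold_query("x", "  "), "nonempty")
})

test_that("SPARQL generation is deterministic and validates its dialect", {
  q <- queries[[1]]
  txt1 <- generate_sparql(q)
  txt2 <- generate_sparql(q)
  expect_identical(txt1, txt2)
  expect_match(txt1, "substructureSearch", fixed = TRUE)
  expect_match(txt1, q$core_smiles, fixed = TRUE)
  expect_match(txt1, "PREFIX sachem:", fixed = TRUE)
  # every prefix used in the body is declared
  used <- unique(regmatches(txt1, gregexpr("\\b[a-z]+:(?=[A-Za-z?])",
                                           txt1, perl = TRUE))[[1]])
  declared <- regmatches(txt1, gregexpr("PREFIX ([a-z]+):", txt1))[[1]]
  declared <- sub("PREFIX ", "", declared)
  expect_true(all(setdiff(used, "http:") %in% c(declared, "https:")))
  expect_error(generate_sparql(q, "neo4j"), "unknown SPARQL dialect.*wikidata")
})

test_that("SMILES canonicalization maps variants together, NA on failure", {
  can <- canonical_smiles(c("C1CCNCC1", "N1CCCCC1", "not_a_smiles((", "",
                            NA))
  expect_equal(can[1], can[2])  # same molecule, different atom order
  expect_true(is.na(can[3]))
  expect_true(is.na(can[4]))
  expect_true(is.na(can[5]))
})

test_that("load_reports quarantines bad structures and merges duplicates", {
  df <- rbind(
    report_row("N1CCCCC1", "Piper nigrum", reference = "refA"),
    report_row("C1CCNCC1", "Piper nigrum", reference = "refB"),  # same cpd
    report_row("))broken((", "Piper nigrum", reference = "refC"),
    report_row("CCO", "Punica granatum", reference = "refD"))
  path <- write_reports_csv(df)
  reports <- load_reports(path)
  expect_s3_class(reports, "occurrence_reports")
  # the two piperidine rows collapse into one with merged references
  expect_equal(nrow(reports), 2L)
  pip <- reports[reports$species == "Piper nigrum", ]
  expect_equal(nrow(pip), 1L)
  expect_setequal(strsplit(pip$reference, ";")[[1]], c("refA", "refB"))
  q <- attr(reports, "quarantine")
  expect_equal(nrow(q), 1L)
  expect_equal(q$reference, "refC")
  # genus falls back to the first species token
  expect_equal(sort(reports$genus), c("Piper", "Punica"))
  # reject file is written when requested
  rp <- withr::local_tempfile(fileext = ".csv")
  load_reports(path, reject_path = rp)
  expect_true(file.exists(rp))
  expect_equal(nrow(read.csv(rp)), 1L)
})

test_that("load_reports rejects structurally invalid input", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(structure = "CCO", species = "X y"), p,
            row.names = FALSE)
  expect_error(load_reports(p), "missing required column.*reference")
  p2 <- write_reports_csv(report_row("CCO", "  "))
  expect_error(load_reports(p2), "empty species")
})

test_that("scaffold assignment matches known alkaloids", {
  piperine <- "O=C(N1CCCCC1)/C=C/C=C/c1ccc2OCOc2c1"
  higenamine <- "Oc1ccc(CC2NCCc3cc(O)c(O)cc23)cc1"
  apomorphine <- "CN1CCc2cccc3c2C1Cc1ccc(O)c(O)c1-3"
  aristolactam_aII <- "COc1cc2ccc3cccc4c3c2c(c1O)C(=O)N4"
  cuspidatin_like <- "COc1cc(CCN(C)C)c(Cc2ccc(O)cc2)cc1O"
  df <- rbind(
    report_row(piperine, "Piper nigrum"),
    report_row(higenamine, "Nelumbo nucifera"),
    report_row(apomorphine, "Papaver somniferum"),
    report_row(aristolactam_aII, "Aristolochia indica"),
    report_row(cuspidatin_like, "Piper fimbriulatum"),
    report_row("c1ccccc1", "Punica granatum"))  # benzene: no scaffold
  reports <- load_reports(write_reports_csv(df))
  out <- assign_scaffolds(reports, queries)
  get <- function(species, scaffold) {
    out[[scaffold]][out$species == species]
  }
  expect_true(get("Piper nigrum", "piperidine"))
  expect_false(get("Piper nigrum", "benzylisoquinoline"))
  expect_true(get("Nelumbo nucifera", "benzylisoquinoline"))
  expect_false(get("Nelumbo nucifera", "aporphine"))
  expect_true(get("Papaver somniferum", "aporphine"))
  # the aporphine core is excluded from the benzylisoquinoline query
  expect_false(get("Papaver somniferum", "benzylisoquinoline"))
  expect_true(get("Aristolochia indica", "piperolactam"))
  expect_true(get("Piper fimbriulatum", "seco-benzylisoquinoline"))
  expect_false(get("Piper fimbriulatum", "benzylisoquinoline"))
  expect_false(any(unlist(out[out$species == "Punica granatum", qnames])))
})

test_that("exclusion substructures reject retrieved look-alikes", {
  # quinolizidine and indolizidine both contain a piperidine ring but are
  # excluded from the piperidine scaffold; THIQ is excluded from the
  # seco-benzylisoquinoline scaffold
  df <- rbind(
    report_row("C1CCC2CCCCN2C1", "Lupinus albus"),        # quinolizidine
    report_row("C1CCN2CCCC2C1", "Tylophora indica"),      # indolizidine
    report_row("C1NCCc2ccccc21", "Cryptostylis fulva"),   # bare THIQ
    report_row("N1CCCCC1", "Piper nigrum"))               # piperidine
  out <- assign_scaffolds(load_reports(write_reports_csv(df)), queries)
  expect_false(out$piperidine[out$species == "Lupinus albus"])
  expect_false(out$piperidine[out$species == "Tylophora indica"])
  expect_false(out$`seco-benzylisoquinoline`[out$species ==
                                               "Cryptostylis fulva"])
  expect_true(out$piperidine[out$species == "Piper nigrum"])
})

test_that("assignment is independent of report order", {
  df <- rbind(
    report_row("N1CCCCC1", "Piper nigrum"),
    report_row("C1CCC2CCCCN2C1", "Lupinus albus"),
    report_row("CCO", "Punica granatum"))
  r1 <- assign_scaffolds(load_reports(write_reports_csv(df)), queries)
  r2 <- assign_scaffolds(load_reports(write_reports_csv(df[3:1, ])),
                         queries)
  r2 <- r2[match(r1$species, r2$species), ]
  for (s in qnames) expect_equal(r1[[s]], r2[[s]])
})

test_that("broken patterns fail loudly, naming the scaffold", {
  bad <- scaffold_query("badpat", "[#6")
  df <- report_row("CCO", "Punica granatum")
  reports <- load_reports(write_reports_csv(df))
  expect_error(assign_scaffolds(reports, list(bad)),
               "badpat.*failed to compile")
})

test_that("curation removes blocklisted and unverified reports with audit", {
  piperine <- "O=C(N1CCCCC1)/C=C/C=C/c1ccc2OCOc2c1"
  df <- rbind(
    report_row(piperine, "Capsicum annuum"),   # blocklisted database error
    report_row(piperine, "Piper nigrum"),      # legitimate
    report_row("N1CCCCC1", "Aglaia perviridis"),
    report_row("CC1CCCCN1", "Withania somnifera", flags = "lacks-NMR"))
  assigned <- assign_scaffolds(load_reports(write_reports_csv(df)), queries)
  curated <- curate_reports(assigned, queries)
  expect_equal(nrow(curated), 1L)
  expect_equal(curated$species, "Piper nigrum")
  audit <- attr(curated, "audit")
  expect_equal(nrow(audit), 3L)
  expect_equal(audit$reason[audit$species == "Capsicum annuum"],
               "database error")
  expect_match(audit$reason[audit$species == "Aglaia perviridis"],
               "lack of NMR data")
  expect_match(audit$reason[audit$species == "Withania somnifera"],
               "lack of NMR data")
  # empty blocklists leave reports untouched
  bare <- lapply(queries, function(q) {
    scaffold_query(q$name, q$inclusion, q$exclusions,
                   core_smiles = q$core_smiles)
  })
  untouched <- curate_reports(assigned, bare)
  expect_equal(nrow(untouched), nrow(assigned) - 1L)  # only lacks-NMR goes
})

test_that("curation only ever removes reports", {
  df <- rbind(report_row("N1CCCCC1", "Piper nigrum"),
              report_row("CCO", "Punica granatum"))
  assigned <- assign_scaffolds(load_reports(write_reports_csv(df)), queries)
  curated <- curate_reports(assigned, queries)
  expect_true(all(curated$species %in% assigned$species))
  expect_equal(nrow(curated) + nrow(attr(curated, "audit")),
               nrow(assigned))
})

test_that("the presence matrix aggregates genera with support and summary", {
  df <- rbind(
    report_row("N1CCCCC1", "Piper nigrum", reference = "r1",
               family = "Piperaceae", order = "Piperales"),
    report_row("CN1CCCCC1", "Piper betle", reference = "r2",
               family = "Piperaceae", order = "Piperales"),
    report_row("N1CCCCC1", "Punica granatum", reference = "r3",
               family = "Lythraceae", order = "Myrtales"),
    report_row("CCO", "Nelumbo nucifera", reference = "r4",
               family = "Nelumbonaceae", order = "Proteales"))
  assigned <- assign_scaffolds(load_reports(write_reports_csv(df)), queries)
  m <- build_presence_matrix(assigned)
  expect_true(m$matrix["Piper", "piperidine"])
  expect_true(m$matrix["Punica", "piperidine"])
  # the scaffold-free genus contributes nothing and is absent entirely
  expect_false("Nelumbo" %in% rownames(m$matrix))
  # two species of one genus both support the cell
  expect_setequal(m$support[["Piper|piperidine"]], c("r1", "r2"))
  smry <- m$summary[m$summary$scaffold == "piperidine", ]
  expect_equal(smry$n_genera, 2L)
  expect_equal(smry$n_families, 2L)
  expect_equal(smry$n_orders, 2L)
  expect_length(m$all_scaffold_genera, 0L)
})

test_that("genera positive for every scaffold are flagged", {
  cores <- vapply(queries, `[[`, character(1), "core_smiles")
  df <- do.call(rbind, lapply(seq_along(cores), function(i) {
    report_row(cores[i], paste0("Piper species", i),
               reference = paste0("r", i))
  }))
  assigned <- assign_scaffolds(load_reports(write_reports_csv(df)), queries)
  m <- build_presence_matrix(assigned)
  expect_equal(m$all_scaffold_genera, "Piper")
  expect_true(all(m$matrix["Piper", ]))
})
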