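test_that("verify_term distinguishes name, synonym, and unverified outcomes", {
  ont <- doid_fixture()
  v1 <- verify_term("hypertension", ont, "disease")
  expect_equal(v1$status, "VERIFIED_NAME")
  expect_equal(v1$matched_ids[[1]], "DOID:10763")

  v2 <- verify_term("HTN", ont)
  expect_equal(v2$status, "VERIFIED_SYNONYM")
  expect_equal(v2$matched_ids[[1]], "DOID:10763")

  # layman phrasing that the ontology lacks stays unverified
  symp <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: SYMP:1", "name: blister"), symp)
  v3 <- verify_term("itchy blisters", load_obo(symp, "SYMP"), "symptom")
  expect_equal(v3$status, "UNVERIFIED")
  expect_length(v3$matched_ids[[1]], 0)
})

test_that("status is UNVERIFIED exactly when matched_ids is empty", {
  cfg <- fixture_config(seed = 11, n_terms = 40, synonym_rate = 0.5,
                        n_pairs = 120, valid_fraction = 0.5)
  src <- gen_ontology(cfg, "DOID")
  tgt <- gen_ontology(cfg, "SYMP")
  a <- gen_association_set(src, tgt, cfg, "disease_symptom")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(src$obo, path)
  ont <- load_obo(path, "DOID")
  verdicts <- assocverify:::verify_terms(a$pairs$source_label, ont)
  n_ids <- lengths(verdicts$matched_ids)
  expect_identical(verdicts$status == "UNVERIFIED", n_ids == 0L)
})

test_that("verify_association_terms is order-preserving and enforces ontology prefixes", {
  dd <- read_associations(
    system.file("extdata", "disease_drug_examples.json", package = "assocverify"),
    "disease_drug"
  )$pairs
  src_obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: DOID:1612", "name: breast cancer", "",
               "[Term]", "id: DOID:2841", "name: asthma", "",
               "[Term]", "id: DOID:2487", "name: hypercholesterolemia"), src_obo)
  tgt_obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: CHEBI:3387", "name: carbamazepine", "",
               "[Term]", "id: CHEBI:10110", "name: zidovudine", "",
               "[Term]", "id: CHEBI:5118", "name: fluoxetine"), tgt_obo)
  doid <- load_obo(src_obo, "DOID")
  chebi <- load_obo(tgt_obo, "CHEBI")

  res <- verify_association_terms(dd, doid, chebi)
  expect_equal(res$source_label, dd$source_label)
  expect_true(all(res$source_status == "VERIFIED_NAME"))
  expect_true(all(res$target_status == "VERIFIED_NAME"))

  expect_equal(nrow(verify_association_terms(dd[0, ], doid, chebi)), 0)
  expect_error(verify_association_terms(dd, chebi, doid), "configuration error")
})

test_that("planted source-validity is recovered pair for pair from the fixture log", {
  cfg <- fixture_config(seed = 11, n_terms = 60, synonym_rate = 0.5,
                        n_pairs = 200, valid_fraction = 0.8)
  src <- gen_ontology(cfg, "DOID")
  tgt <- gen_ontology(cfg, "CHEBI")
  a <- gen_association_set(src, tgt, cfg, "disease_drug")
  p1 <- withr::local_tempfile(fileext = ".obo"); writeLines(src$obo, p1)
  p2 <- withr::local_tempfile(fileext = ".obo"); writeLines(tgt$obo, p2)
  res <- verify_association_terms(a$pairs, load_obo(p1, "DOID"),
                                  load_obo(p2, "CHEBI"))
  expect_identical(res$source_status != "UNVERIFIED", a$log$is_valid_source)
  expect_identical(res$target_status != "UNVERIFIED", a$log$is_valid_target)
  expect_equal(sum(res$source_status != "UNVERIFIED"), sum(a$log$is_valid_source))
})

test_that("accuracy_report counts components over the same denominator", {
  mk <- function(status, name_match, synonym_match) {
    data.frame(status = status, name_match = name_match,
               synonym_match = synonym_match, stringsAsFactors = FALSE)
  }
  v <- mk(c(rep("VERIFIED_NAME", 2), "VERIFIED_SYNONYM", "UNVERIFIED"),
          c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, FALSE))
  rep_ <- accuracy_report(v)
  expect_equal(rep_$combined_pct, 75)
  expect_equal(rep_$name_pct, 50)
  expect_equal(rep_$synonym_pct, 50)

  v10 <- mk(c(rep("VERIFIED_NAME", 9), "UNVERIFIED"),
            c(rep(TRUE, 9), FALSE), rep(FALSE, 10))
  expect_equal(accuracy_report(v10)$combined_pct, 90)

  expect_error(accuracy_report(v[0, ]), "at least one verdict")
})

test_that("combined count equals n minus unverified on fixture runs", {
  for (seed in c(2, 5, 8)) {
    cfg <- fixture_config(seed = seed, n_terms = 40, n_pairs = 80,
                          valid_fraction = 0.6, synonym_rate = 0.5)
    src <- gen_ontology(cfg, "DOID")
    tgt <- gen_ontology(cfg, "SYMP")
    a <- gen_association_set(src, tgt, cfg, "disease_symptom")
    p1 <- withr::local_tempfile(fileext = ".obo"); writeLines(src$obo, p1)
    res <- verify_association_terms(
      a$pairs, load_obo(p1, "DOID"),
      { p2 <- withr::local_tempfile(fileext = ".obo"); writeLines(tgt$obo, p2)
        load_obo(p2, "SYMP") }
    )
    rep_ <- accuracy_report(res, "source")
    n_unv <- sum(res$source_status == "UNVERIFIED")
    expect_equal(rep_$combined_pct, 100 * (nrow(res) - n_unv) / nrow(res))
    expect_gte(rep_$combined_pct, rep_$name_pct)
    expect_gte(rep_$combined_pct, rep_$synonym_pct)
  }
})

test_that("verify_term agrees with the brute-force scan oracle on small ontologies", {
  for (seed in c(1, 4, 9)) {
    cfg <- fixture_config(seed = seed, n_terms = 50, synonym_rate = 0.5,
                          n_pairs = 60, valid_fraction = 0.5)
    src <- gen_ontology(cfg, "GO")
    tgt <- gen_ontology(cfg, "GO")
    a <- gen_association_set(src, tgt, cfg, "process_gene")
    path <- withr::local_tempfile(fileext = ".obo")
    writeLines(src$obo, path)
    ont <- load_obo(path, "GO")
    probes <- c(a$pairs$source_label, src$terms$name,
                src$terms$synonym[!is.na(src$terms$synonym)],
                "no such label at all", "")
    for (pr in probes) {
      expect_equal(verify_term(pr, ont)$status, oracle_verify_term(pr, ont),
                   info = sprintf("seed %d probe '%s'", seed, pr))
    }
  }
})
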