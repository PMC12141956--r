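mk_corpus <- function(texts, years = 2020) {
  corpus(data.frame(record_id = sprintf("A%03d", seq_along(texts)),
                    year = years, text = texts, stringsAsFactors = FALSE))
}

one_pair <- function(src = "alpha syndrome", tgt = "betaxol") {
  association_pairs("DOID:1", src, "CHEBI:2", tgt, "disease_drug")
}

test_that("assign_period buckets the three five-year spans", {
  expect_equal(assign_period(c(2009, 2014)), c("2009-2014", "2009-2014"))
  expect_equal(assign_period(2015), "2015-2019")
  expect_equal(assign_period(c(2019, 2020, 2024)),
               c("2015-2019", "2020-2024", "2020-2024"))
  expect_true(is.na(assign_period(2008)))
  expect_true(is.na(assign_period(2025)))
  expect_true(is.na(assign_period(NA)))
})

test_that("count_cooccurrence counts abstracts containing both terms once each", {
  p <- one_pair()
  cc <- mk_corpus(c("alpha syndrome and betaxol", "only alpha syndrome here",
                    "betaxol then alpha syndrome; betaxol again"))
  expect_equal(count_cooccurrence(p, cc), 2)

  # whole-token matching: "rash" does not hit "rashes"
  p2 <- association_pairs("DOID:3", "rash", "CHEBI:4", "aspirin", "disease_drug")
  expect_equal(count_cooccurrence(p2, mk_corpus("rashes treated with aspirin")), 0)
  expect_equal(count_cooccurrence(p2, mk_corpus("a rash treated with Aspirin.")), 1)

  # symmetry under endpoint swap
  swapped <- association_pairs("DOID:1", p$target_label, "CHEBI:2",
                               p$source_label, "disease_drug")
  expect_equal(count_cooccurrence(swapped, cc), count_cooccurrence(p, cc))
})

test_that("synonym expansion widens containment only when enabled", {
  p <- association_pairs("DOID:10763", "HTN", "CHEBI:2", "betaxol", "disease_drug")
  cc <- mk_corpus("patients with hypertension received betaxol")
  expect_equal(count_cooccurrence(p, cc), 0)  # off by default
  expect_equal(count_cooccurrence(p, cc,
               synonym_expansion = list(source = doid_fixture())), 1)
})

test_that("verify_associations keeps zero-count pairs, in input order", {
  pairs <- rbind(one_pair(), one_pair("gamma fever", "deltaxin"))
  cc <- mk_corpus("alpha syndrome improved on betaxol")
  cov <- verify_associations(pairs, cc)
  expect_equal(cov$counter, c(1L, 0L))
  expect_equal(cov$verified, c(TRUE, FALSE))

  none <- verify_associations(pairs, mk_corpus("nothing relevant at all"))
  expect_true(all(!none$verified))
  expect_equal(coverage_report(none)$verified_pct, 0)
})

test_that("planted fixtures are recovered count for count from the plant log", {
  cfg <- fixture_config(seed = 17, n_terms = 40, n_pairs = 50,
                        valid_fraction = 1, plant_fraction = 0.4,
                        n_abstracts = 120)
  a <- gen_association_set(gen_ontology(cfg, "DOID"), gen_ontology(cfg, "CHEBI"),
                           cfg, "disease_drug")
  corp <- gen_corpus(a$pairs, cfg)
  cov <- verify_associations(a$pairs, corp$corpus)
  expect_identical(cov$counter, corp$log$counter)
  expect_identical(which(cov$verified), which(corp$log$counter > 0))
})

test_that("adding abstracts never decreases a counter", {
  cfg <- fixture_config(seed = 13, n_terms = 30, n_pairs = 30,
                        valid_fraction = 1, plant_fraction = 0.5,
                        n_abstracts = 60)
  a <- gen_association_set(gen_ontology(cfg, "DOID"), gen_ontology(cfg, "SYMP"),
                           cfg, "disease_symptom")
  corp <- gen_corpus(a$pairs, cfg)
  half <- corpus(corp$corpus$records[1:30, ], "half")
  cov_half <- verify_associations(a$pairs, half)
  cov_full <- verify_associations(a$pairs, corp$corpus)
  expect_true(all(cov_full$counter >= cov_half$counter))
})

test_that("coverage_report: percentages, averaging over verified pairs, accounting", {
  pairs <- do.call(rbind, lapply(1:4, function(i) {
    association_pairs(paste0("DOID:", i), paste0("dis ", i),
                      paste0("CHEBI:", i), paste0("drug ", i), "disease_drug")
  }))
  cov <- pairs
  cov$counter <- c(3L, 1L, 0L, 0L)
  cov$verified <- cov$counter > 0
  rep_ <- coverage_report(cov)
  expect_equal(rep_$avg_frequency, 2)  # zero-counter pairs excluded
  expect_equal(rep_$verified_pct + rep_$unverified_pct, 100)
  expect_error(coverage_report(cov[0, ]), "at least one")
})

test_that("period-stratified coverage uses only dated abstracts in span", {
  pairs <- one_pair()
  recs <- data.frame(
    record_id = c("a", "b", "c", "d"),
    year = c(2010, 2016, 2022, NA),
    text = rep("alpha syndrome with betaxol", 4),
    stringsAsFactors = FALSE
  )
  expect_message(cov <- verify_by_period(pairs, corpus(recs)), "excluded")
  expect_equal(nrow(cov), 3)
  expect_equal(cov$counter, rep(1L, 3))
  expect_setequal(cov$period, period_labels())
})

test_that("consistency_report reports count and half-up percentage per model x type", {
  pairs <- rbind(one_pair(), one_pair("gamma fever", "deltaxin"),
                 one_pair("zeta flu", "omegazol"))
  m1 <- mk_corpus(c("alpha syndrome improved on betaxol",
                    "gamma fever and deltaxin"))
  m2 <- mk_corpus("unrelated text only")
  rep_ <- consistency_report(list(disease_drug = pairs),
                             list(model_a = m1, model_b = m2))
  expect_equal(rep_$count[rep_$model == "model_a"], 2)
  expect_equal(rep_$percentage[rep_$model == "model_a"], 66.67)
  expect_equal(rep_$percentage[rep_$model == "model_b"], 0)
  expect_error(consistency_report(list(disease_drug = pairs),
                                  list(model_a = m1, model_b = NULL)),
               "configuration error")
})

test_that("count_cooccurrence agrees with the naive scan oracle on fixture corpora", {
  for (seed in c(13, 23)) {
    cfg <- fixture_config(seed = seed, n_terms = 25, n_pairs = 30,
                          valid_fraction = 0.7, plant_fraction = 0.5,
                          n_abstracts = 100)
    a <- gen_association_set(gen_ontology(cfg, "DOID"), gen_ontology(cfg, "CHEBI"),
                             cfg, "disease_drug")
    corp <- gen_corpus(a$pairs, cfg)
    for (i in seq_len(nrow(a$pairs))) {
      expect_equal(count_cooccurrence(a$pairs[i, ], corp$corpus),
                   oracle_count_cooccurrence(a$pairs[i, ], corp$corpus),
                   info = sprintf("seed %d pair %d", seed, i))
    }
  }
})

test_that("JSONL and MEDLINE corpus readers reconstruct equivalent records", {
  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id": "p1", "year": 2015, "title": "Alpha syndrome", "abstract": "treated with betaxol."}',
    '{"id": "p2", "year": null, "title": "No year", "abstract": "text"}'
  ), jl)
  cj <- read_corpus_jsonl(jl)
  expect_equal(nrow(cj$records), 2)
  expect_true(is.na(cj$records$year[2]))
  expect_equal(count_cooccurrence(one_pair(), cj), 1)

  ml <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "PMID- 100",
    "DP  - 2015 Jan 10",
    "TI  - Alpha syndrome case",
    "AB  - The patient improved after",
    "      betaxol was given.",
    "",
    "PMID- 101",
    "DP  - 2021",
    "TI  - Unrelated",
    "AB  - Nothing here."
  ), ml)
  cm <- read_corpus_medline(ml)
  expect_equal(cm$records$record_id, c("100", "101"))
  expect_equal(cm$records$year, c(2015L, 2021L))
  expect_equal(count_cooccurrence(one_pair(), cm), 1)  # across continuation line
  expect_error(corpus(data.frame(record_id = c("x", "x"), year = 1,
                                 text = "t", stringsAsFactors = FALSE)),
               "duplicate")
})
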