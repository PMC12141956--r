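# assocverify

Large language models will happily emit lists of biomedical "facts" —
disease–drug, disease–symptom and disease–gene term associations — in
machine-readable form. Before such output can seed a knowledge graph or an
annotation pipeline, two questions need answering for every generated
association `(s, t)`:

1. **Are the terms real?** Is `s` (and `t`) an actual entry of the relevant
   domain ontology — DOID for diseases, ChEBI for drugs, SYMP for symptoms,
   GO for genes and genetic processes — either as a primary name or as a
   synonym of any scope?
2. **Is the association attested?** Does any abstract in a literature corpus
   mention both terms together? The number of abstracts containing both
   terms of a pair (its *co-occurrence counter*) is the pair's coverage;
   a pair with counter > 0 is *verified*, one with counter = 0 is merely
   *yet to be verified* — absence of evidence, not evidence of error.

`assocverify` implements both stages for R users working with
LLM-generated association sets, plus the reporting around them:
per-ontology term-accuracy tables (name %, synonym %, name/synonym %),
period-stratified coverage tables over 2009–2014 / 2015–2019 / 2020–2024,
and cross-model consistency tables (how many of a pair set's associations
reappear in abstract corpora produced by different generator models).

## Method sketch

Term verification matches labels, not ids. A label is reduced to a
canonical form — NFKC, case-folded, every punctuation run replaced by one
space, whitespace collapsed — and compared against the same canonical form
of every non-obsolete name and synonym in the ontology:

```
verify(t, O):  t ~ name(O)     -> VERIFIED_NAME
               t ~ synonym(O)  -> VERIFIED_SYNONYM
               otherwise       -> UNVERIFIED
```

Association verification is whole-token co-occurrence counting. For a pair
`P = (s, t)` and corpus `D`:

```
counter(P) = |{ B in D : s ⊑ B and t ⊑ B }|
```

where `⊑` means the term's normalized token sequence occurs contiguously at
word boundaries in the normalized abstract text (so "rash" never matches
inside "rashes"), and each abstract counts at most once per pair. Generated
CURIE ids are validated separately (`validate_curie()`), since generated
ids and generated labels fail independently.

Every statistic the package reports can be rehearsed on synthetic data: the
seeded generators (`gen_ontology()`, `gen_association_set()`,
`gen_corpus()`) plant a known valid fraction of labels and a known set of
co-occurrences, and return ground-truth logs that downstream reports must
reproduce exactly.

## Worked example

```r
library(assocverify)

# Stage 1: is "HTN" a real disease term?
ont <- load_obo(system.file("extdata", "doid_hypertension.obo",
                            package = "assocverify"), "DOID")
verify_term("HTN", ont)[, c("term_text", "status")]
#>   term_text           status
#> 1       HTN VERIFIED_SYNONYM

# A synthetic study: 100 disease-symptom pairs, 80% valid labels,
# 60% of pairs planted into a 200-abstract corpus
cfg <- fixture_config(seed = 7, n_terms = 50, synonym_rate = 0.5,
                      n_pairs = 100, valid_fraction = 0.8,
                      n_abstracts = 200, plant_fraction = 0.6)
disease <- gen_ontology(cfg, "DOID"); symptom <- gen_ontology(cfg, "SYMP")
assoc <- gen_association_set(disease, symptom, cfg, "disease_symptom")
corp  <- gen_corpus(assoc$pairs, cfg)

# Stage 1 over all pairs: accuracy of the disease endpoint
obo <- tempfile(fileext = ".obo"); writeLines(disease$obo, obo)
t2  <- tempfile(fileext = ".obo"); writeLines(symptom$obo, t2)
verdicts <- verify_association_terms(assoc$pairs, load_obo(obo, "DOID"),
                                     load_obo(t2, "SYMP"))
accuracy_report(verdicts, "source")
#> <verification_report> n = 100
#>   name           53.00 %
#>   synonym        31.00 %
#>   name/synonym   84.00 %

# Stage 2: period-stratified literature coverage
cov <- coverage_report(verify_by_period(assoc$pairs, corp$corpus))
cov[, c("period", "n_verified", "verified_pct")]
#>      period n_verified verified_pct
#> 1 2009-2014         24           24
#> 2 2015-2019         25           25
#> 3 2020-2024         24           24
```

The name rate (53%) counts pairs whose disease label equals an ontology
primary name; the synonym rate (31%) counts synonym matches whether or not
a name also matched; name/synonym (84%) counts either — with 80% of labels
planted valid, 84/100 is within sampling noise of the planted fraction.
Per period, roughly a third of the 60% planted pairs land in each 5-year
bucket, giving the ~24% per-period coverage shown.

A command-line front end covers the same flows
(`validate`, `verify-terms`, `cover`, `consistency`, `fixtures`, `report`):

```sh
inst/bin/assoc-verify fixtures --seed 7 --type disease_symptom --out fx
inst/bin/assoc-verify cover --type disease_symptom \
    --pairs fx/pairs.json --corpus fx/corpus.jsonl --by-period --out out
```

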