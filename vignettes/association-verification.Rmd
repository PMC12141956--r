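---
title: "Verifying generated biomedical associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying generated biomedical associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The verification problem

A text generator asked for disease-centric associations returns typed term
pairs — a disease with a drug, a symptom, or a gene/genetic process —
usually as two-key JSON records mapping a CURIE to a label. Two failure
modes need separating. The *terms* may not exist: a generated label may be
a layman's paraphrase ("sad mood" where the ontology says "depression"), an
over-verbose variant ("rapid weight loss" for "weight loss"), or pure
invention. And the *association* may be unattested: both terms can be real
while their pairing has no support in the literature.

`assocverify` treats these as two independent stages with independent
evidence sources: term verification against a domain ontology, and
association verification by co-occurrence counting in an abstract corpus.
Crucially, the second stage is a coverage notion, not a truth notion: a
pair no abstract mentions is *unverified*, which means "yet to be
verified", never "wrong".

## Stage 1: term verification

### The matching model

Matching is by label, never by id. Each ontology (an OBO 1.2/1.4 flat
file) is indexed under a fixed normalization policy, `normalize_label()`:

1. Unicode compatibility normalization (NFKC),
2. case-folding,
3. every maximal run of non-letter, non-digit characters (punctuation,
   hyphens, apostrophes, symbols, whitespace) replaced by a single space,
4. trimming.

The transform is deterministic and idempotent, which the test suite checks
property-style over random strings. The policy is deliberately aggressive:
the common causes of spurious mismatch between generated terms and
ontology labels are exactly casing, hyphenation, quoting and stray
punctuation, and all of those are erased here without introducing any
fuzzy (edit-distance or embedding) matching, which would make verdicts
non-deterministic to audit. Accent marks survive (they are letters);
inflection does not fold ("rashes" never matches "rash") — a deliberate
boundary, see Limitations.

A term is `VERIFIED_NAME` when its normalized form equals the normalized
primary name of any non-obsolete term, `VERIFIED_SYNONYM` when it equals a
synonym but no name, `UNVERIFIED` otherwise. Three policy decisions that
were genuinely open:

* **All synonym scopes count.** OBO distinguishes EXACT, RELATED, NARROW
  and BROAD synonyms. Restricting to EXACT would be defensible, but the
  canonical worked example in this area — hypertension, DOID:10763, whose
  synonym list is "HTN" (EXACT), "hyperpiesia" (EXACT), "hypertensive
  disease" (RELATED), "vascular hypertensive disorder" (EXACT) — is only
  fully recovered when RELATED counts too. The scope is retained on every
  parsed synonym, so a stricter filter is a one-line change downstream.
* **Obsolete terms are indexed but never matched.** OBO files carry
  retired vocabulary; verifying a generated term against it would bless
  terminology the ontology maintainers have withdrawn. They are kept in
  the loaded object for audit.
* **Ambiguity is data.** Several terms may share a label; `lookup()`
  returns all of them and never errors. A term matching both by name and
  by synonym is reported once, as NAME.

### Accuracy accounting

Term-accuracy tables report three rates per endpoint: *name*, *synonym*
and *name/synonym*. Their relationship is not self-evident — published
tables of this shape show synonym rates below name rates with the combined
rate above both — so the package fixes the one convention consistent with
that ordering: `name_pct` counts terms matching any primary name,
`synonym_pct` counts terms matching any synonym *regardless of whether a
name also matched*, and `combined_pct` counts terms matching either. Under
this convention `combined >= max(name, synonym)` holds identically, which
the acceptance suite asserts on every fixture run. Percentages are kept
unrounded internally and rounded half-up to two decimals only for display
(`round_half_up()`), so accounting identities hold exactly before
rounding.

Generated CURIEs are validated separately (`validate_curie()`: strict
`PREFIX:digits`, case-sensitive prefix, 7-digit GO local ids), because id
hallucination and label hallucination occur independently — a correct
label often arrives with a wrong or redundant id. A small prefix alias
table (default `SYMPTOM -> SYMP`) is applied at parse time, since
generator output mixes the colloquial and registered prefixes for the
Symptom Ontology.

## Stage 2: association verification

For each pair, the counter is the number of abstracts whose text contains
both terms, where *contains* means: the term's normalized token sequence
occurs contiguously, at word boundaries, in the normalized abstract text.
An abstract contributes at most one count per pair however often it
repeats the terms. The choice of strict whole-token containment (rather
than substring or fuzzy containment) mirrors the stage-1 philosophy: the
documented failure modes of generated terms are wording variants, so the
counter should be a faithful, reproducible string instrument, with any
semantic widening made explicit.

That explicit widening is `synonym_expansion`: when enabled, a term is
contained if its label *or any name/synonym of the ontology terms the
label resolves to* is contained. It is **off by default** — the default
measures what the generator actually wrote, and mixing ontology knowledge
into the corpus search would conflate the two stages.

A pair's raw counter is stored as-is. The per-pair "hit ratio" one might
define by dividing a pair's abstract count by the number of pairs mixes
units (abstracts per pair set) and is not reproduced here; coverage is
derived at report level instead: per association type and period,
`verified_pct = 100·|counter>0|/n`, its exact complement
`unverified_pct`, and `avg_frequency`, the mean counter **over verified
pairs only**. Averaging over verified pairs is the reading consistent with
published average-frequency magnitudes (hundreds of supporting abstracts
per supported association); including the zero-counter pairs would make
the statistic a blend of coverage and support. Groups with no verified
pair report `NA` rather than 0 — there is no supported pair to average.

Period stratification buckets abstracts by publication year into
2009–2014, 2015–2019 and 2020–2024. Abstracts without a usable year are
excluded from stratified runs (with a message) but participate in
unstratified runs.

## Prompt contract and the mock generator

Prompt construction (`prompt_spec()`, `build_prompt()`) interpolates the
requested count and pairing into a fixed one-shot instruction sentence and
appends exactly one example record. The generator itself is a contract —
`generate(prompt) -> text` — so any backend, including a file replay, can
satisfy it; no live API client ships, keeping the test surface free and
hermetic. The packaged `mock_generator()` is seed-deterministic
(byte-identical responses for a fixed seed) and can inject the observed
failure modes at configurable rates: duplicate records, malformed CURIEs,
and truncated (invalid-JSON) responses. Invalid JSON in a response is
*data*, not an exception: `parse_response()` returns an outcome whose
rejected record carries the message "Invalid JSON format in response."

## What the synthetic generators emulate — and what they don't

The fixture generators stand in for three artifacts: a domain ontology, a
generated association set, and an abstract corpus.

* `gen_ontology()` emits pronounceable nonsense labels in real OBO syntax
  (so the production loader is exercised end to end), one synonym per term
  with probability `synonym_rate`, scope uniform over the four OBO scopes.
* `gen_association_set()` makes each endpoint label valid (a real name,
  or its synonym half the time when one exists) with probability
  `valid_fraction`; invalid labels are perturbed by the taxonomy of real
  failure modes — added qualifier words, truncation, off-vocabulary
  paraphrase — and *guaranteed* non-matching by checking against the
  ontology's normalized label set.
* `gen_corpus()` plants each pair with probability `plant_fraction`,
  giving planted pairs `1 + Geometric(0.5)` dedicated abstracts containing
  both labels verbatim amid filler text; filler vocabulary is purged of
  every token occurring in any pair label, so filler alone can never
  complete a co-occurrence. Because labels can share or nest token
  sequences across pairs, the plant log is finalized by a containment
  sweep over the constructed texts: the log records true counts, not just
  sampling intent.

Default condition, used throughout the examples: 50-term ontologies with
synonym rate 0.5, 100 pairs at valid fraction 0.8, 200 abstracts at plant
fraction 0.6 over years 2009–2024. The recovery tests run 500 pairs at
planted fractions 0.2/0.5/0.8 and require the measured combined rate to
fall in the exact binomial 99% interval; the oracle-equivalence suites run
ontologies of ≤ 50 terms and corpora of ≤ 100 abstracts, sizes at which
the brute-force scans are exact and fast. The full-size consistency
reproduction in `scripts/acceptance.R` uses the real pair-set sizes
(2625/5008/5466).

What passing these tests does **not** show about real data: fixture labels
are token-disjoint nonsense, so they never exhibit genuine lexical
ambiguity (one label naming two diseases), cross-lingual synonymy, or the
near-miss morphology ("blister"/"itchy blisters") that dominates real
symptom mismatch; corpora have uniform years, uniform short lengths, and
no MeSH-style indexing structure. The fixtures validate the machinery and
its accounting, not the difficulty of the real matching problem.

## Numerical and I/O choices

* Half-up rounding at two decimals for all displayed percentages, with an
  epsilon guard for binary representation of count ratios; unrounded
  values retained everywhere internally.
* JSON association files: both the array dialect and JSONL are read; the
  array dialect is written, one record per line, deterministically —
  `read(write(p)) == p` and double writes are byte-identical.
* A fatal (top-level) JSON syntax error reports a byte offset recovered
  from the parser's error context; individual bad records are never
  fatal, and the parse outcome partitions the input exactly:
  `records = pairs + rejected + duplicates`.
* Duplicate pairs are defined on the 4-tuple (ids plus *normalized*
  labels), since near-duplicate records differing only in casing or
  punctuation are redundancy, not information.
* All generator randomness flows from one seed; per-artifact streams are
  derived with a fixed affine map so that e.g. the source and target
  fixture ontologies of one configuration do not share label sequences.
  Identical configurations give byte-identical artifacts, and the CLI
  records the seed in each run manifest.

## Limitations

* Matching is literal after normalization: no stemming, no spelling
  correction, no embeddings. Layman paraphrases and inflectional variants
  stay unverified by design; quantifying that gap is an analysis task,
  not something the matcher silently absorbs.
* Co-occurrence is not relation extraction: a counter says two terms
  appear in the same abstract, nothing about the relation asserted there.
* The OBO reader interprets the tags relevant to label matching (`id`,
  `name`, `synonym`, `is_obsolete`) and ignores the rest; it is not a
  general OBO toolchain, and `is_a` traversal is out of scope.
* Coverage against a finite corpus is relative to that corpus; the
  package ships no corpus downloader, so corpora are supplied as JSONL or
  MEDLINE flat files.
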