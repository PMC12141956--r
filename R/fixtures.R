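# Seeded synthetic-data generators. Every generator returns, alongside its
# artifact, a ground-truth log sufficient to recompute from first
# principles any statistic the pipeline later reports on that artifact.

SYLLABLES <- c("ba", "co", "di", "fu", "ga", "he", "ki", "lo", "mu", "ne",
               "po", "ra", "su", "ti", "vo", "za", "xe", "pha", "dro", "sta",
               "cli", "mer", "tol", "vin")

INTENSIFIERS <- c("rapid", "severe", "frequent", "chronic", "mild", "itchy",
                  "persistent", "acute")

FILLER_WORDS <- c(
  "the", "study", "patients", "with", "were", "observed", "clinical",
  "results", "analysis", "group", "treatment", "control", "cohort",
  "significant", "levels", "measured", "during", "followup", "baseline",
  "reported", "outcomes", "compared", "between", "among", "subjects",
  "trial", "randomized", "evidence", "findings", "suggest", "increase",
  "decrease", "after", "before", "period", "years", "months", "data",
  "method", "samples", "tissue", "cells", "expression", "response",
  "therapy", "dose", "effects", "improved", "reduced", "observed"
)

# n pronounceable lowercase words of 2-4 syllables (uses the current RNG).
gen_words <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(SYLLABLES, sample(2:4, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# n multi-word labels (1-3 words), distinct (uses the current RNG).
gen_labels <- function(n, n_words_max = 3) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    fresh <- vapply(seq_len(need), function(i) {
      paste(gen_words(sample(seq_len(n_words_max), 1)), collapse = " ")
    }, character(1))
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

# n distinct CURIEs for a prefix; GO ids are zero-padded to 7 digits.
make_curies <- function(prefix, n) {
  if (prefix == "GO") {
    sprintf("GO:%07d", sample.int(9999999L, n))
  } else {
    sprintf("%s:%d", prefix, sample.int(999999L, n))
  }
}

#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives the whole fixture suite: a miniature
#' ontology, an association set with a controlled fraction of valid
#' labels, and an abstract corpus with planted co-occurrences. Identical
#' configurations produce byte-identical artifacts.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_terms ontology size.
#' @param synonym_rate probability a term carries a synonym.
#' @param n_pairs number of association pairs.
#' @param valid_fraction probability an endpoint label is a real ontology
#'   label (the rest are perturbed: extra qualifier words, truncation, or
#'   an off-vocabulary paraphrase).
#' @param n_abstracts corpus size.
#' @param plant_fraction probability a pair gets at least one abstract
#'   containing both of its labels.
#' @param year_range inclusive year interval for abstract dates.
#' @return object of class `"fixture_config"` (a validated list).
#' @export
fixture_config <- function(seed = 1L, n_terms = 50L, synonym_rate = 0.5,
                           n_pairs = 100L, valid_fraction = 0.8,
                           n_abstracts = 200L, plant_fraction = 0.6,
                           year_range = c(2009L, 2024L)) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_terms >= 0, n_pairs >= 0, n_abstracts >= 0,
    synonym_rate >= 0, synonym_rate <= 1,
    valid_fraction >= 0, valid_fraction <= 1,
    plant_fraction >= 0, plant_fraction <= 1,
    length(year_range) == 2L, year_range[1] <= year_range[2]
  )
  structure(
    list(seed = as.integer(seed), n_terms = as.integer(n_terms),
         synonym_rate = synonym_rate, n_pairs = as.integer(n_pairs),
         valid_fraction = valid_fraction, n_abstracts = as.integer(n_abstracts),
         plant_fraction = plant_fraction, year_range = as.integer(year_range)),
    class = "fixture_config"
  )
}

# Derive a generator-specific seed so e.g. the DOID and CHEBI fixture
# ontologies of one config do not share label streams. Stays < 2^31.
derive_seed <- function(seed, tag) {
  (seed * 1009L + sum(utf8ToInt(tag)) * 31L) %% 2000000011L
}

#' Generate a miniature OBO ontology
#'
#' Emits `n_terms` terms with pronounceable multi-word labels in OBO 1.2
#' flat-file dialect, so the real loader is exercised end to end. Each
#' term gains one synonym with probability `synonym_rate`, with its scope
#' drawn uniformly from EXACT/RELATED/NARROW/BROAD. A GO prefix yields
#' 7-digit local ids.
#'
#' @param config a [fixture_config()].
#' @param prefix CURIE prefix for the generated ontology.
#' @return list with `obo` (single OBO text string) and `terms` (manifest
#'   data.frame: id, name, synonym (NA when none), scope).
#' @export
gen_ontology <- function(config, prefix) {
  stopifnot(inherits(config, "fixture_config"), config$n_terms >= 1)
  local_seed(derive_seed(config$seed, paste0("ontology:", prefix)), {
    n <- config$n_terms
    ids <- make_curies(prefix, n)
    names_ <- gen_labels(n)
    has_syn <- runif(n) < config$synonym_rate
    synonyms <- rep(NA_character_, n)
    synonyms[has_syn] <- gen_labels(sum(has_syn))
    scope <- rep(NA_character_, n)
    scope[has_syn] <- sample(c("EXACT", "RELATED", "NARROW", "BROAD"),
                             sum(has_syn), replace = TRUE)
    stanzas <- vapply(seq_len(n), function(i) {
      s <- c("[Term]", paste0("id: ", ids[i]), paste0("name: ", names_[i]))
      if (has_syn[i]) {
        s <- c(s, sprintf('synonym: "%s" %s []', synonyms[i], scope[i]))
      }
      paste(c(s, ""), collapse = "\n")
    }, character(1))
    header <- "format-version: 1.2\n\n"
    list(
      obo = paste0(header, paste(stanzas, collapse = "\n")),
      terms = data.frame(id = ids, name = names_, synonym = synonyms,
                         scope = scope, stringsAsFactors = FALSE)
    )
  })
}

# Perturb a label so it no longer matches any ontology label, mimicking
# observed generator failure modes: added qualifier words ("rapid weight
# loss" for "weight loss"), truncation ("blister" for "itchy blisters" in
# reverse), and off-vocabulary paraphrase. Guaranteed non-matching by
# checking against the normalized ontology label set.
perturb_label <- function(label, forbidden_normalized) {
  for (attempt in seq_len(50L)) {
    mode <- sample(c("verbose", "truncate", "paraphrase"), 1L)
    cand <- switch(mode,
      verbose = paste(sample(INTENSIFIERS, 1L), label),
      truncate = {
        words <- strsplit(label, " ", fixed = TRUE)[[1]]
        if (length(words) > 1) paste(words[-length(words)], collapse = " ")
        else paste(sample(INTENSIFIERS, 1L), label)
      },
      paraphrase = gen_labels(1L)
    )
    if (!(normalize_label(cand) %in% forbidden_normalized)) return(cand)
  }
  stop("could not perturb label away from the ontology vocabulary", call. = FALSE)
}

#' Generate an association set with a controlled valid fraction
#'
#' Samples pairs of terms from two fixture ontologies. Each endpoint
#' label is, independently with probability `valid_fraction`, a real
#' ontology label (the term's name, or its synonym half the time when one
#' exists); otherwise it is perturbed so that it cannot match any label
#' in that ontology. CURIE ids are always the sampled terms' real ids —
#' validity here is a property of the label, mirroring how generated ids
#' and generated labels fail independently. The log records the ground
#' truth per pair.
#'
#' @param ontology_src,ontology_tgt outputs of [gen_ontology()].
#' @param config a [fixture_config()].
#' @param assoc_type one of [assoc_types()].
#' @return list with `pairs` ([association_pairs()] data.frame) and `log`
#'   (data.frame: pair, is_valid_source, is_valid_target,
#'   source_term_id, target_term_id).
#' @export
gen_association_set <- function(ontology_src, ontology_tgt, config,
                                assoc_type = "disease_symptom") {
  stopifnot(inherits(config, "fixture_config"),
            nrow(ontology_src$terms) >= 1, nrow(ontology_tgt$terms) >= 1)
  assoc_type <- match.arg(assoc_type, names(ASSOC_TYPES))
  local_seed(derive_seed(config$seed, "pairs"), {
    n <- config$n_pairs
    pick_endpoint <- function(manifest) {
      forbidden <- normalize_label(
        c(manifest$name, manifest$synonym[!is.na(manifest$synonym)])
      )
      idx <- sample.int(nrow(manifest), n, replace = TRUE)
      valid <- runif(n) < config$valid_fraction
      label <- character(n)
      for (i in seq_len(n)) {
        row <- manifest[idx[i], ]
        if (valid[i]) {
          use_syn <- !is.na(row$synonym) && runif(1) < 0.5
          label[i] <- if (use_syn) row$synonym else row$name
        } else {
          label[i] <- perturb_label(row$name, forbidden)
        }
      }
      list(id = manifest$id[idx], label = label, valid = valid)
    }
    src <- pick_endpoint(ontology_src$terms)
    tgt <- pick_endpoint(ontology_tgt$terms)
    pairs <- association_pairs(src$id, src$label, tgt$id, tgt$label, assoc_type)
    log <- data.frame(
      pair = seq_len(n),
      is_valid_source = src$valid,
      is_valid_target = tgt$valid,
      source_term_id = src$id,
      target_term_id = tgt$id,
      stringsAsFactors = FALSE
    )
    list(pairs = pairs, log = log)
  })
}

#' Generate a corpus with planted co-occurrences
#'
#' Builds `n_abstracts` abstract records. Each pair is planted with
#' probability `plant_fraction`; a planted pair receives `1 + Geom(0.5)`
#' dedicated abstracts, each containing both of its labels verbatim
#' inside filler sentences. Remaining abstracts are pure filler, drawn
#' from a fixed word list purged of every token occurring in any pair
#' label, so a filler abstract can never complete a co-occurrence. Years
#' are uniform over `year_range`. Because labels may share or nest token
#' sequences across pairs, the returned log is finalized by a containment
#' sweep over the constructed texts: `counter` and `abstract_ids` are the
#' true whole-token co-occurrence counts, and `planted` records the
#' sampling intent.
#'
#' @param pairs association pairs data.frame.
#' @param config a [fixture_config()].
#' @return list with `corpus` (a [corpus()]), `jsonl` (the corpus as JSONL
#'   text), and `log` (data.frame: pair, planted, counter, list-column
#'   abstract_ids).
#' @export
gen_corpus <- function(pairs, config) {
  stopifnot(inherits(config, "fixture_config"), nrow(pairs) >= 1)
  local_seed(derive_seed(config$seed, "corpus"), {
    n_pairs <- nrow(pairs)
    planted <- runif(n_pairs) < config$plant_fraction
    mentions <- integer(n_pairs)
    mentions[planted] <- 1L + rgeom(sum(planted), 0.5)

    label_tokens <- unique(unlist(strsplit(
      normalize_label(c(pairs$source_label, pairs$target_label)), " ",
      fixed = TRUE
    )))
    filler <- setdiff(FILLER_WORDS, label_tokens)

    mk_filler <- function(k) sample(filler, k, replace = TRUE)
    texts <- character(0); owner <- integer(0)
    for (i in which(planted)) {
      for (m in seq_len(mentions[i])) {
        words <- mk_filler(sample(8:14, 1))
        at <- sort(sample(seq_len(length(words) + 1L), 2L))
        body <- append(words, pairs$source_label[i], after = at[1] - 1L)
        body <- append(body, pairs$target_label[i], after = at[2])
        texts <- c(texts, paste(body, collapse = " "))
        owner <- c(owner, i)
      }
    }
    n_planted_abs <- length(texts)
    n_filler <- max(0L, config$n_abstracts - n_planted_abs)
    for (k in seq_len(n_filler)) {
      texts <- c(texts, paste(mk_filler(sample(10:18, 1)), collapse = " "))
      owner <- c(owner, NA_integer_)
    }
    n_abs <- length(texts)
    ord <- sample.int(n_abs)  # shuffle so planted abstracts are not a prefix
    texts <- texts[ord]; owner <- owner[ord]
    ids <- sprintf("SIM%06d", seq_len(n_abs))
    years <- sample(seq(config$year_range[1], config$year_range[2]),
                    n_abs, replace = TRUE)
    title_words <- vapply(texts, function(t) {
      w <- strsplit(t, " ", fixed = TRUE)[[1]]
      paste(w[seq_len(min(3L, length(w)))], collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    abstract_body <- vapply(seq_along(texts), function(i) {
      w <- strsplit(texts[i], " ", fixed = TRUE)[[1]]
      if (length(w) > 3L) paste(w[-seq_len(3L)], collapse = " ") else ""
    }, character(1))
    # readers rebuild text as title + " " + abstract, which restores the
    # exact token sequence even when a label starts inside the title
    records <- data.frame(record_id = ids, year = years,
                          text = texts, stringsAsFactors = FALSE)
    corp <- corpus(records, label = "synthetic")

    jsonl <- vapply(seq_len(n_abs), function(i) {
      as.character(jsonlite::toJSON(
        list(id = ids[i], year = years[i], title = title_words[i],
             abstract = abstract_body[i]),
        auto_unbox = TRUE
      ))
    }, character(1))

    # containment sweep: the definitive per-pair ground truth
    padded <- paste0(" ", normalize_label(texts), " ")
    counter <- integer(n_pairs)
    abstract_ids <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      s <- paste0(" ", normalize_label(pairs$source_label[i]), " ")
      t <- paste0(" ", normalize_label(pairs$target_label[i]), " ")
      hit <- stringi::stri_detect_fixed(padded, s) &
             stringi::stri_detect_fixed(padded, t)
      counter[i] <- sum(hit)
      abstract_ids[[i]] <- ids[hit]
    }
    log <- data.frame(pair = seq_len(n_pairs), planted = planted,
                      counter = counter, stringsAsFactors = FALSE)
    log$abstract_ids <- abstract_ids
    list(corpus = corp, jsonl = paste0(paste(jsonl, collapse = "\n"), "\n"),
         log = log)
  })
}
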