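# Independent oracles, deliberately written as naive scans so they share no
# code path with the implementations they check (only the public
# normalize_label() primitive, which both sides are specified to use).

# Brute-force term verification: scan every (term, name/synonym) string of
# the ontology tables and compare normalized strings one by one.
oracle_verify_term <- function(term_text, ontology) {
  key <- normalize_label(term_text)
  if (!nzchar(key)) return("UNVERIFIED")
  name_hit <- FALSE
  syn_hit <- FALSE
  for (i in seq_len(nrow(ontology$terms))) {
    if (ontology$terms$obsolete[i]) next
    if (normalize_label(ontology$terms$name[i]) == key) name_hit <- TRUE
  }
  for (i in seq_len(nrow(ontology$synonyms))) {
    id <- ontology$synonyms$id[i]
    obs <- ontology$terms$obsolete[match(id, ontology$terms$id)]
    if (isTRUE(obs)) next
    if (normalize_label(ontology$synonyms$text[i]) == key) syn_hit <- TRUE
  }
  if (name_hit) "VERIFIED_NAME" else if (syn_hit) "VERIFIED_SYNONYM" else "UNVERIFIED"
}

# Naive co-occurrence counter: character-level substring search on the
# normalized text, constrained to word boundaries with a regex, one
# abstract at a time.
oracle_count_cooccurrence <- function(pair, corp) {
  contains <- function(text_norm, label) {
    lab <- normalize_label(label)
    if (!nzchar(lab)) return(FALSE)
    grepl(paste0("(^| )", lab, "( |$)"), text_norm)
  }
  n <- 0L
  for (i in seq_len(nrow(corp$records))) {
    tx <- normalize_label(corp$records$text[i])
    if (contains(tx, pair$source_label) && contains(tx, pair$target_label)) {
      n <- n + 1L
    }
  }
  n
}

# Minimal second OBO parser: line-oriented, collects (id, label) rows for
# every name and synonym of non-obsolete terms.
oracle_obo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  id <- NULL; obs <- FALSE; labels <- character(0); ids <- character(0)
  buf_labels <- character(0)
  flush <- function() {
    if (!is.null(id) && !obs && length(buf_labels)) {
      labels <<- c(labels, buf_labels)
      ids <<- c(ids, rep(id, length(buf_labels)))
    }
  }
  for (ln in c(lines, "[Term]")) {
    if (grepl("^\\[", ln)) {
      flush()
      id <- NULL; obs <- FALSE; buf_labels <- character(0)
    } else if (startsWith(ln, "id: ")) {
      id <- trimws(sub("^id: ", "", ln))
    } else if (startsWith(ln, "name: ")) {
      buf_labels <- c(buf_labels, trimws(sub("^name: ", "", ln)))
    } else if (startsWith(ln, "synonym: ")) {
      m <- regmatches(ln, regexec('^synonym: "(.*)" [A-Z]* ?\\[', ln))[[1]]
      if (length(m) == 2) buf_labels <- c(buf_labels, m[2])
    } else if (grepl("^is_obsolete: *true", ln)) {
      obs <- TRUE
    }
  }
  data.frame(id = ids, label = labels, stringsAsFactors = FALSE)
}

# Exact two-sided binomial 99% interval for a count at (n, p).
binom99_count <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)

# Shared miniature DOID fixture (the worked hypertension stanza).
doid_fixture <- function() {
  load_obo(system.file("extdata", "doid_hypertension.obo",
                       package = "assocverify"), "DOID")
}

# Write a fixture suite to files; returns the paths.
write_fixture_suite <- function(dir, config, assoc_type = "disease_symptom") {
  pre <- assocverify:::assoc_prefixes(assoc_type)
  src <- gen_ontology(config, pre[["source"]])
  tgt <- gen_ontology(config, pre[["target"]])
  assoc <- gen_association_set(src, tgt, config, assoc_type)
  corp <- gen_corpus(assoc$pairs, config)
  paths <- list(
    src_obo = file.path(dir, "src.obo"), tgt_obo = file.path(dir, "tgt.obo"),
    pairs = file.path(dir, "pairs.json"), corpus = file.path(dir, "corpus.jsonl")
  )
  writeLines(src$obo, paths$src_obo)
  writeLines(tgt$obo, paths$tgt_obo)
  write_associations(assoc$pairs, paths$pairs)
  cat(corp$jsonl, file = paths$corpus)
  c(paths, list(src = src, tgt = tgt, assoc = assoc, corp = corp))
}
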