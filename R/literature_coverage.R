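#' Construct a corpus of literature abstracts
#'
#' A corpus is a labelled collection of abstract records. Each record has
#' an opaque id, a publication year (may be NA; such records are excluded
#' from period-stratified runs, with a message) and the searchable text
#' (title + abstract concatenated).
#'
#' @param records data.frame with columns `record_id`, `year`, `text`.
#' @param label corpus name (a model name, a period, a source).
#' @return object of class `"corpus"`.
#' @export
corpus <- function(records, label = "corpus") {
  stopifnot(all(c("record_id", "year", "text") %in% names(records)))
  records <- data.frame(
    record_id = as.character(records$record_id),
    year = suppressWarnings(as.integer(records$year)),
    text = as.character(records$text),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(records$record_id)) {
    stop("duplicate record ids in corpus '", label, "'", call. = FALSE)
  }
  empty <- is.na(records$text) | !nzchar(trimws(records$text))
  if (any(empty)) {
    stop(sum(empty), " record(s) with empty text in corpus '", label, "'",
         call. = FALSE)
  }
  structure(list(label = label, records = records), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  yrs <- x$records$year[!is.na(x$records$year)]
  cat(sprintf("<corpus> '%s': %d abstract(s), years %s, %d undated\n",
              x$label, nrow(x$records),
              if (length(yrs)) paste(range(yrs), collapse = "-") else "-",
              sum(is.na(x$records$year))))
  invisible(x)
}

#' Read a corpus from JSONL
#'
#' One JSON object per line with fields `id`, `year`, `title`, `abstract`.
#' Title and abstract are concatenated into the searchable text; a
#' missing/null year becomes NA.
#'
#' @param path path to the JSONL file.
#' @param label corpus label (defaults to the file name).
#' @return object of class `"corpus"`.
#' @export
read_corpus_jsonl <- function(path, label = NULL) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::parse_json)
  grab <- function(r, k) {
    v <- r[[k]]
    if (is.null(v) || length(v) == 0) NA else v
  }
  records <- data.frame(
    record_id = vapply(recs, function(r) as.character(grab(r, "id")), character(1)),
    year = vapply(recs, function(r) {
      y <- grab(r, "year")
      if (is.na(y[[1]])) NA_integer_ else as.integer(y)
    }, integer(1)),
    text = vapply(recs, function(r) {
      paste(c(grab(r, "title"), grab(r, "abstract"))[
        !is.na(c(grab(r, "title"), grab(r, "abstract")))], collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  corpus(records, label)
}

#' Read a corpus from a MEDLINE flat file
#'
#' Minimal reader for the PubMed MEDLINE text format: records separated by
#' blank lines, tags `PMID- `, `DP  - ` (year = first 4-digit run),
#' `TI  - `, `AB  - `, with continuation lines indented by six spaces.
#'
#' @inheritParams read_corpus_jsonl
#' @return object of class `"corpus"`.
#' @export
read_corpus_medline <- function(path, label = NULL) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  blank <- !nzchar(trimws(lines))
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) * !blank
  fields <- list()
  out <- list()
  flush_rec <- function(f) {
    if (is.null(f$PMID)) return(NULL)
    year <- if (is.null(f$DP)) NA_integer_ else {
      y <- stringi::stri_extract_first_regex(f$DP, "\\b[0-9]{4}\\b")
      if (is.na(y)) NA_integer_ else as.integer(y)
    }
    data.frame(record_id = f$PMID, year = year,
               text = paste(c(f$TI, f$AB), collapse = " "),
               stringsAsFactors = FALSE)
  }
  cur <- list(); cur_tag <- NULL
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      r <- flush_rec(cur)
      if (!is.null(r)) out[[length(out) + 1L]] <- r
      cur <- list(); cur_tag <- NULL
      next
    }
    m <- stringi::stri_match_first_regex(ln, "^([A-Z]{2,4})\\s*- (.*)$")
    if (!is.na(m[1, 1])) {
      cur_tag <- m[1, 2]
      cur[[cur_tag]] <- paste(c(cur[[cur_tag]], m[1, 3]), collapse = " ")
    } else if (!is.null(cur_tag) && stringi::stri_detect_regex(ln, "^\\s{4,}")) {
      cur[[cur_tag]] <- paste(cur[[cur_tag]], trimws(ln))
    }
  }
  if (!length(out)) stop("no MEDLINE records found in '", path, "'", call. = FALSE)
  corpus(do.call(rbind, out), label)
}

#' Assign a publication year to a five-year period
#'
#' The three study periods: 2009-2014 (P1), 2015-2019 (P2), 2020-2024
#' (P3). Years outside the span map to NA.
#'
#' @param year integer vector of calendar years.
#' @return character vector of period labels ("2009-2014", "2015-2019",
#'   "2020-2024") or NA.
#' @examples
#' assign_period(c(2014, 2015, 2008))
#' @export
assign_period <- function(year) {
  year <- suppressWarnings(as.integer(year))
  out <- rep(NA_character_, length(year))
  out[!is.na(year) & year >= 2009 & year <= 2014] <- "2009-2014"
  out[!is.na(year) & year >= 2015 & year <= 2019] <- "2015-2019"
  out[!is.na(year) & year >= 2020 & year <= 2024] <- "2020-2024"
  out
}

#' All period labels, in order
#' @return character vector of the three period labels.
#' @export
period_labels <- function() c("2009-2014", "2015-2019", "2020-2024")

# A label (plus optional ontology expansion) -> search patterns: padded
# normalized token sequences, matched as contiguous whole tokens.
term_patterns <- function(label, ontology = NULL) {
  labels <- label
  if (!is.null(ontology)) {
    ids <- lookup(ontology, label)$id
    if (length(ids)) {
      tm <- ontology$terms
      sy <- ontology$synonyms
      labels <- c(labels, tm$name[tm$id %in% ids], sy$text[sy$id %in% ids])
    }
  }
  pats <- unique(normalize_label(labels))
  pats <- pats[nzchar(pats)]
  if (!length(pats)) return(character(0))
  paste0(" ", pats, " ")
}

# Pad normalized corpus texts so a fixed-string search of " tokens " is a
# whole-token contiguous match.
padded_corpus_text <- function(corp) {
  paste0(" ", normalize_label(corp$records$text), " ")
}

# Count abstracts (by index into `padded`) containing any of the patterns.
detect_any <- function(padded, patterns, cache = NULL) {
  if (!length(patterns)) return(rep(FALSE, length(padded)))
  hit <- rep(FALSE, length(padded))
  for (p in patterns) {
    if (!is.null(cache)) {
      key <- p
      if (is.null(cache[[key]])) {
        cache[[key]] <- stringi::stri_detect_fixed(padded, p)
      }
      hit <- hit | cache[[key]]
    } else {
      hit <- hit | stringi::stri_detect_fixed(padded, p)
    }
  }
  hit
}

#' Count co-occurrences of an association pair in a corpus
#'
#' The per-pair counter: the number of abstracts whose text contains both
#' terms of the pair. Containment means the term's normalized token
#' sequence occurs contiguously at word boundaries in the normalized
#' abstract text, so "rash" does not match inside "rashes" but casing,
#' punctuation and extra whitespace are immaterial. Each abstract
#' contributes at most one count regardless of repeated mentions. With
#' `synonym_expansion`, a term is contained when its label or any
#' name/synonym of the ontology terms it resolves to is; by default only
#' the generated strings themselves are searched.
#'
#' @param pair one-row data.frame ([association_pairs()] row).
#' @param corpus object of class `"corpus"`.
#' @param synonym_expansion optional `list(source = <ontology>,
#'   target = <ontology>)` enabling synonym expansion.
#' @return integer count in `[0, corpus size]`.
#' @examples
#' p <- association_pairs("DOID:10763", "hypertension", "CHEBI:6541",
#'                        "losartan", "disease_drug")
#' cc <- corpus(data.frame(record_id = 1:2, year = 2020,
#'   text = c("hypertension treated with losartan", "losartan alone")))
#' count_cooccurrence(p, cc)
#' @export
count_cooccurrence <- function(pair, corpus, synonym_expansion = NULL) {
  stopifnot(inherits(corpus, "corpus"), nrow(pair) == 1L)
  padded <- padded_corpus_text(corpus)
  src <- term_patterns(pair$source_label, synonym_expansion$source)
  tgt <- term_patterns(pair$target_label, synonym_expansion$target)
  sum(detect_any(padded, src) & detect_any(padded, tgt))
}

#' Verify association pairs against a corpus
#'
#' Runs the co-occurrence counter for every pair and flags each pair
#' verified when its counter is positive. Pairs with zero counts are kept
#' (flagged unverified), and input order is preserved; a pair that the
#' corpus never mentions is "yet to be verified", not wrong.
#'
#' @param pairs data.frame of association pairs.
#' @param corpus object of class `"corpus"`.
#' @inheritParams count_cooccurrence
#' @return `pairs` with added integer column `counter` and logical column
#'   `verified`.
#' @export
verify_associations <- function(pairs, corpus, synonym_expansion = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  out <- pairs
  if (nrow(pairs) == 0) {
    out$counter <- integer(0); out$verified <- logical(0)
    return(out)
  }
  padded <- padded_corpus_text(corpus)
  cache <- new.env(parent = emptyenv())
  counter <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    src <- term_patterns(pairs$source_label[i], synonym_expansion$source)
    tgt <- term_patterns(pairs$target_label[i], synonym_expansion$target)
    counter[i] <- sum(detect_any(padded, src, cache) &
                      detect_any(padded, tgt, cache))
  }
  out$counter <- counter
  out$verified <- counter > 0L
  out
}

#' Verify associations per five-year period
#'
#' Splits the corpus by [assign_period()] and runs [verify_associations()]
#' against each period's sub-corpus. Undated abstracts and years outside
#' 2009-2024 are excluded (a message reports how many).
#'
#' @inheritParams verify_associations
#' @return row-bound coverage tables with an extra `period` column.
#' @export
verify_by_period <- function(pairs, corpus, synonym_expansion = NULL) {
  per <- assign_period(corpus$records$year)
  dropped <- sum(is.na(per))
  if (dropped > 0) {
    message(dropped, " abstract(s) without a year in 2009-2024 excluded from period-stratified run")
  }
  out <- list()
  for (p in period_labels()) {
    sub <- corpus(corpus$records[!is.na(per) & per == p, , drop = FALSE],
                  label = paste0(corpus$label, "/", p))
    cov <- verify_associations(pairs, sub, synonym_expansion)
    cov$period <- p
    out[[p]] <- cov
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate pair coverage into a report
#'
#' For each association type x period group: the percentage of pairs with
#' at least one supporting abstract (`verified_pct`), its complement
#' (`unverified_pct`; the two sum to exactly 100 before rounding), and
#' the mean counter over the verified pairs only (`avg_frequency`;
#' zero-counter pairs are excluded from the mean, NA when nothing
#' verified). Unrounded values are returned; round for display with
#' [round_half_up()].
#'
#' @param coverages data.frame from [verify_associations()] /
#'   [verify_by_period()] (columns `assoc_type`, `counter`, `verified`,
#'   optionally `period`).
#' @return data.frame with one row per group: `assoc_type`, `period`,
#'   `n_pairs`, `n_verified`, `verified_pct`, `unverified_pct`,
#'   `avg_frequency`.
#' @export
coverage_report <- function(coverages) {
  if (is.null(coverages) || nrow(coverages) == 0) {
    stop("coverage_report needs at least one pair coverage row", call. = FALSE)
  }
  if (is.null(coverages$period)) coverages$period <- "all"
  key <- interaction(coverages$assoc_type, coverages$period, drop = TRUE)
  groups <- split(coverages, key)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    nv <- sum(g$verified)
    data.frame(
      assoc_type = g$assoc_type[1],
      period = g$period[1],
      n_pairs = n,
      n_verified = nv,
      verified_pct = 100 * nv / n,
      unverified_pct = 100 * (n - nv) / n,
      avg_frequency = if (nv > 0) mean(g$counter[g$verified]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$assoc_type, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-model consistency report
#'
#' Checks each association set against each model's corpus (e.g. corpora
#' of simulated abstracts generated by different models) and reports, per
#' model x association type, the number of pairs with at least one
#' co-occurrence and the percentage of the type's pairs that number
#' represents (rounded half-up to 2 decimals).
#'
#' @param pairs_by_type named list: association type -> pairs data.frame.
#' @param corpora_by_model named list: model label -> `"corpus"`.
#' @inheritParams count_cooccurrence
#' @return data.frame with columns `model`, `assoc_type`, `count`,
#'   `total`, `percentage`.
#' @export
consistency_report <- function(pairs_by_type, corpora_by_model,
                               synonym_expansion = NULL) {
  if (is.null(names(corpora_by_model)) || any(!nzchar(names(corpora_by_model)))) {
    stop("configuration error: corpora_by_model must be a named list", call. = FALSE)
  }
  bad <- !vapply(corpora_by_model, inherits, logical(1), what = "corpus")
  if (any(bad)) {
    stop("configuration error: missing corpus for model(s) ",
         paste(names(corpora_by_model)[bad], collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (model in names(corpora_by_model)) {
    for (ty in names(pairs_by_type)) {
      pairs <- pairs_by_type[[ty]]
      cov <- verify_associations(pairs, corpora_by_model[[model]],
                                 synonym_expansion)
      cnt <- sum(cov$verified)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, assoc_type = ty, count = cnt, total = nrow(pairs),
        percentage = round_half_up(100 * cnt / nrow(pairs), 2),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
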