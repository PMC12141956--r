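TERM_TYPES <- c("disease", "drug", "symptom", "gene", "genetic_process")
VERDICT_LEVELS <- c("VERIFIED_NAME", "VERIFIED_SYNONYM", "UNVERIFIED")

# Vectorized verdicts for many terms against one ontology. Besides the
# three-way status, the raw name/synonym hit flags are kept: the synonym
# accuracy column counts every term with a synonym match even when the
# same term also matches a primary name.
verify_terms <- function(term_text, ontology, term_type = NA_character_) {
  n <- length(term_text)
  status <- character(n)
  name_match <- logical(n)
  synonym_match <- logical(n)
  matched_ids <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- lookup_raw(ontology, term_text[i])
    name_match[i] <- length(hits$name_ids) > 0
    synonym_match[i] <- length(hits$synonym_ids) > 0
    ids <- union(hits$name_ids, hits$synonym_ids)
    matched_ids[[i]] <- sort(ids)
    status[i] <- if (name_match[i]) "VERIFIED_NAME"
                 else if (synonym_match[i]) "VERIFIED_SYNONYM"
                 else "UNVERIFIED"
  }
  out <- data.frame(
    term_text = as.character(term_text),
    term_type = rep_len(as.character(term_type), n),
    status = status,
    name_match = name_match,
    synonym_match = synonym_match,
    stringsAsFactors = FALSE
  )
  out$matched_ids <- matched_ids
  out
}

#' Verify one term against a domain ontology
#'
#' The per-term verification step: a generated term is VERIFIED_NAME when
#' its normalized form equals the primary name of any non-obsolete
#' ontology term, VERIFIED_SYNONYM when it equals a synonym (of any OBO
#' scope) but no primary name, and UNVERIFIED otherwise. All matching ids
#' are reported; `status == "UNVERIFIED"` exactly when `matched_ids` is
#' empty.
#'
#' @param term_text the generated free-text term.
#' @param ontology an `"ontology"` object ([load_obo()]).
#' @param term_type optional term category, one of
#'   `r paste(TERM_TYPES, collapse = ", ")` (recorded in the verdict).
#' @return one-row data.frame with columns `term_text`, `term_type`,
#'   `status`, `name_match`, `synonym_match` and list-column `matched_ids`.
#' @examples
#' ont <- load_obo(system.file("extdata", "doid_hypertension.obo",
#'                             package = "assocverify"), "DOID")
#' verify_term("hypertension", ont)$status  # VERIFIED_NAME
#' verify_term("HTN", ont)$status           # VERIFIED_SYNONYM
#' @export
verify_term <- function(term_text, ontology, term_type = NA_character_) {
  stopifnot(length(term_text) == 1L, inherits(ontology, "ontology"))
  if (!is.na(term_type)) term_type <- match.arg(term_type, TERM_TYPES)
  verify_terms(term_text, ontology, term_type)
}

# term category of each endpoint, per association type
endpoint_term_types <- function(assoc_type) {
  switch(assoc_type,
    disease_drug    = c("disease", "drug"),
    disease_symptom = c("disease", "symptom"),
    disease_gene    = c("disease", "gene"),
    process_gene    = c("genetic_process", "gene")
  )
}

#' Verify both terms of every association pair
#'
#' Runs [verify_term()] on the source label of each pair against the
#' source ontology and on the target label against the target ontology,
#' preserving input order. The ontology prefixes must agree with the
#' pairs' association type (e.g. DOID/CHEBI for disease_drug); a mismatch
#' is a configuration error.
#'
#' @param pairs data.frame as from [association_pairs()] (one assoc_type).
#' @param source_ontology,target_ontology `"ontology"` objects.
#' @return `pairs` with added columns `source_status`, `source_name_match`,
#'   `source_synonym_match`, list-column `source_matched_ids`, and the
#'   same four for `target_`.
#' @export
verify_association_terms <- function(pairs, source_ontology, target_ontology) {
  stopifnot(inherits(source_ontology, "ontology"),
            inherits(target_ontology, "ontology"))
  if (nrow(pairs) == 0) {
    out <- pairs
    for (col in c("source_status", "target_status")) out[[col]] <- character(0)
    return(out)
  }
  assoc_type <- unique(pairs$assoc_type)
  if (length(assoc_type) != 1L) {
    stop("pairs must carry a single association type", call. = FALSE)
  }
  pre <- assoc_prefixes(assoc_type)
  if (!identical(source_ontology$prefix, unname(pre[["source"]])) ||
      !identical(target_ontology$prefix, unname(pre[["target"]]))) {
    stop(sprintf(
      "configuration error: association type '%s' expects ontologies %s -> %s, got %s -> %s",
      assoc_type, pre[["source"]], pre[["target"]],
      source_ontology$prefix, target_ontology$prefix), call. = FALSE)
  }
  tt <- endpoint_term_types(assoc_type)
  src <- verify_terms(pairs$source_label, source_ontology, tt[[1]])
  tgt <- verify_terms(pairs$target_label, target_ontology, tt[[2]])
  out <- pairs
  out$source_status <- src$status
  out$source_name_match <- src$name_match
  out$source_synonym_match <- src$synonym_match
  out$source_matched_ids <- src$matched_ids
  out$target_status <- tgt$status
  out$target_name_match <- tgt$name_match
  out$target_synonym_match <- tgt$synonym_match
  out$target_matched_ids <- tgt$matched_ids
  out
}

#' Aggregate term verdicts into an accuracy report
#'
#' Computes the three headline rates over a set of verdicts:
#' \describe{
#'   \item{name_pct}{share of terms whose label matches any primary name.}
#'   \item{synonym_pct}{share matching any synonym, counted whether or not
#'     the same term also matches a primary name (so the two components
#'     overlap and neither bounds the other).}
#'   \item{combined_pct}{share with status != UNVERIFIED, i.e. matching
#'     either route; always >= each component rate.}
#' }
#' Percentages are kept unrounded in the object; the print method rounds
#' half-up to two decimals.
#'
#' @param verdicts data.frame of verdicts ([verify_term()] rows, or the
#'   `source_`/`target_` columns of [verify_association_terms()] output
#'   via `endpoint`).
#' @param endpoint when `verdicts` comes from [verify_association_terms()],
#'   which endpoint to report: `"source"` or `"target"`.
#' @return an object of class `"verification_report"`: `n_terms`,
#'   `name_pct`, `synonym_pct`, `combined_pct`.
#' @export
accuracy_report <- function(verdicts, endpoint = NULL) {
  if (!is.null(endpoint)) {
    endpoint <- match.arg(endpoint, c("source", "target"))
    verdicts <- data.frame(
      status = verdicts[[paste0(endpoint, "_status")]],
      name_match = verdicts[[paste0(endpoint, "_name_match")]],
      synonym_match = verdicts[[paste0(endpoint, "_synonym_match")]],
      stringsAsFactors = FALSE
    )
  }
  n <- nrow(verdicts)
  if (is.null(n) || n == 0) {
    stop("accuracy_report needs at least one verdict (percentages undefined)",
         call. = FALSE)
  }
  structure(
    list(
      n_terms = n,
      name_pct = 100 * sum(verdicts$name_match) / n,
      synonym_pct = 100 * sum(verdicts$synonym_match) / n,
      combined_pct = 100 * sum(verdicts$status != "UNVERIFIED") / n
    ),
    class = "verification_report"
  )
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> n = %d\n", x$n_terms))
  cat(sprintf("  name          %6.2f %%\n", round_half_up(x$name_pct)))
  cat(sprintf("  synonym       %6.2f %%\n", round_half_up(x$synonym_pct)))
  cat(sprintf("  name/synonym  %6.2f %%\n", round_half_up(x$combined_pct)))
  invisible(x)
}

#' @export
as.data.frame.verification_report <- function(x, ...) {
  data.frame(
    feature = c("name", "synonym", "name/synonym"),
    accuracy_pct = round_half_up(c(x$name_pct, x$synonym_pct, x$combined_pct)),
    n_terms = x$n_terms,
    stringsAsFactors = FALSE
  )
}
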