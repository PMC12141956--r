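#' Construct a table of typed association pairs
#'
#' The in-memory form of an association set: one row per source->target
#' term pair, each endpoint a CURIE id plus its free-text label. The four
#' association types map to fixed ontology prefix pairs:
#' disease_drug DOID->CHEBI, disease_symptom DOID->SYMP,
#' disease_gene DOID->GO, process_gene GO->GO.
#'
#' @param source_id,target_id CURIE vectors.
#' @param source_label,target_label label vectors (non-empty).
#' @param assoc_type one of [assoc_types()].
#' @return data.frame with columns `source_id`, `source_label`,
#'   `target_id`, `target_label`, `assoc_type`.
#' @export
association_pairs <- function(source_id, source_label, target_id, target_label,
                              assoc_type) {
  assoc_type <- match.arg(assoc_type, names(ASSOC_TYPES))
  n <- length(source_id)
  stopifnot(length(source_label) == n, length(target_id) == n,
            length(target_label) == n)
  pre <- assoc_prefixes(assoc_type)
  bad_src <- !validate_curie(source_id, pre[["source"]], aliases = NULL)
  bad_tgt <- !validate_curie(target_id, pre[["target"]], aliases = NULL)
  if (any(bad_src) || any(bad_tgt)) {
    stop("CURIE prefix does not match association type '", assoc_type, "': ",
         paste(head(c(source_id[bad_src], target_id[bad_tgt]), 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(trimws(source_label))) || any(!nzchar(trimws(target_label)))) {
    stop("association labels must be non-empty", call. = FALSE)
  }
  data.frame(
    source_id = as.character(source_id),
    source_label = as.character(source_label),
    target_id = as.character(target_id),
    target_label = as.character(target_label),
    assoc_type = rep(assoc_type, n),
    stringsAsFactors = FALSE
  )
}

empty_pairs <- function(assoc_type) {
  empty_df(source_id = character(0), source_label = character(0),
           target_id = character(0), target_label = character(0),
           assoc_type = character(0))
}

new_parse_outcome <- function(pairs, rejected, duplicates_removed, n_records) {
  structure(
    list(pairs = pairs, rejected = rejected,
         duplicates_removed = duplicates_removed, n_records = n_records),
    class = "parse_outcome"
  )
}

#' @export
print.parse_outcome <- function(x, ...) {
  cat(sprintf(
    "<parse_outcome> %d record(s): %d pair(s), %d rejected, %d duplicate(s) removed\n",
    x$n_records, nrow(x$pairs), nrow(x$rejected), x$duplicates_removed
  ))
  if (nrow(x$rejected)) {
    tab <- sort(table(x$rejected$reason), decreasing = TRUE)
    for (r in names(tab)) cat(sprintf("  %4d x %s\n", tab[[r]], r))
  }
  invisible(x)
}

# Validate one parsed JSON record (named list) -> pair row or rejection reason.
record_to_pair <- function(rec, assoc_type, aliases) {
  if (!is.list(rec) || is.null(names(rec))) {
    return(list(reason = "record is not a key/value object"))
  }
  if (length(rec) != 2L) {
    return(list(reason = "ambiguous pair arity"))
  }
  ids <- apply_aliases(names(rec), aliases)
  labels <- rec
  ok_scalar <- vapply(labels, function(v) is.character(v) && length(v) == 1L &&
                        !is.na(v), logical(1))
  if (!all(ok_scalar)) {
    return(list(reason = "label is not a string"))
  }
  labels <- unlist(labels, use.names = FALSE)
  pre <- assoc_prefixes(assoc_type)
  if (!validate_curie(ids[[1]], pre[["source"]], aliases = NULL)) {
    return(list(reason = sprintf("invalid source CURIE for prefix %s", pre[["source"]])))
  }
  if (!validate_curie(ids[[2]], pre[["target"]], aliases = NULL)) {
    return(list(reason = sprintf("invalid target CURIE for prefix %s", pre[["target"]])))
  }
  if (any(!nzchar(trimws(labels)))) {
    return(list(reason = "empty label"))
  }
  list(pair = data.frame(
    source_id = ids[[1]], source_label = labels[[1]],
    target_id = ids[[2]], target_label = labels[[2]],
    assoc_type = assoc_type, stringsAsFactors = FALSE
  ))
}

# Render a parsed JSON value back to compact JSON for the rejected log.
compact_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null"))
}

#' Parse association records from JSON text
#'
#' The in-memory worker behind [read_associations()]. Accepts either a
#' JSON array of two-key objects (`{"DOID:11734": "Epistaxis",
#' "SYMPTOM:1080": "Nosebleed"}`) or one such object per line (JSONL).
#' Records failing the two-key contract, CURIE syntax (after the prefix
#' alias table), or the non-empty-label rule are collected under
#' machine-readable reasons instead of aborting; exact duplicates (same
#' id pair and same labels after [normalize_label()]) are collapsed and
#' counted. The accounting identity
#' `n_records == nrow(pairs) + nrow(rejected) + duplicates_removed`
#' always holds.
#'
#' @param text JSON text (single string, or character vector of lines).
#' @param assoc_type one of [assoc_types()].
#' @param aliases prefix alias table (see [default_aliases()]).
#' @return an object of class `"parse_outcome"`: `pairs` (data.frame as
#'   [association_pairs()]), `rejected` (data.frame: record, reason),
#'   `duplicates_removed`, `n_records`.
#' @export
parse_associations <- function(text, assoc_type, aliases = default_aliases()) {
  assoc_type <- match.arg(assoc_type, names(ASSOC_TYPES))
  text <- paste(text, collapse = "\n")

  first <- stringi::stri_extract_first_regex(text, "\\S")
  recs <- list()
  rejected_raw <- character(0); rejected_reason <- character(0)

  if (is.na(first)) {
    recs <- list()
  } else if (identical(first, "[")) {
    parsed <- tryCatch(
      jsonlite::parse_json(text, simplifyVector = FALSE),
      error = function(e) e
    )
    if (inherits(parsed, "error")) {
      stop("fatal JSON parse error at byte offset ",
           json_error_offset(text, conditionMessage(parsed)), ": ",
           conditionMessage(parsed), call. = FALSE)
    }
    recs <- parsed
  } else if (!inherits(whole <- tryCatch(jsonlite::parse_json(text, simplifyVector = FALSE),
                                         error = function(e) e), "error") &&
             is.list(whole) && !is.null(names(whole))) {
    # a single (possibly multi-line) object is one record
    recs <- list(whole)
  } else {
    # JSONL: one object per non-blank line; bad lines are record-level errors
    lines <- stringi::stri_split_lines1(text)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      p <- tryCatch(jsonlite::parse_json(ln, simplifyVector = FALSE),
                    error = function(e) e)
      if (inherits(p, "error")) {
        rejected_raw <- c(rejected_raw, ln)
        rejected_reason <- c(rejected_reason, "invalid JSON record")
      } else {
        recs <- c(recs, list(p))
      }
    }
  }

  pair_rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    res <- record_to_pair(recs[[i]], assoc_type, aliases)
    if (is.null(res$pair)) {
      rejected_raw <- c(rejected_raw, compact_json(recs[[i]]))
      rejected_reason <- c(rejected_reason, res$reason)
    } else {
      pair_rows[[i]] <- res$pair
    }
  }
  pair_rows <- pair_rows[!vapply(pair_rows, is.null, logical(1))]
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else empty_pairs(assoc_type)

  n_records <- length(recs) + sum(rejected_reason == "invalid JSON record")

  dup_key <- paste(pairs$source_id, pairs$target_id,
                   normalize_label(pairs$source_label),
                   normalize_label(pairs$target_label), sep = "\r")
  dup <- duplicated(dup_key)
  duplicates_removed <- sum(dup)
  pairs <- pairs[!dup, , drop = FALSE]
  rownames(pairs) <- NULL

  rejected <- if (length(rejected_raw)) {
    data.frame(record = rejected_raw, reason = rejected_reason,
               stringsAsFactors = FALSE)
  } else {
    empty_df(record = character(0), reason = character(0))
  }
  new_parse_outcome(pairs, rejected, duplicates_removed, n_records)
}

# Best-effort byte offset at which JSON parsing failed. The parser's error
# message shows the text immediately before the failure point ("(right
# here) ------^"); locating that snippet in the input recovers the offset.
# Premature end of input (truncation) maps to the final byte.
json_error_offset <- function(text, err_msg) {
  m <- stringi::stri_match_first_regex(err_msg, "\\n\\s*(\\S[^\\n]*)\\n\\s*\\(right here\\)")
  ctx <- m[1, 2]
  if (!is.na(ctx) && nzchar(ctx)) {
    pos <- stringi::stri_locate_last_fixed(text, ctx)[1, 2]
    if (!is.na(pos)) return(as.integer(pos))
  }
  nchar(text, type = "bytes")
}

#' Read an association file
#'
#' Reads and validates a JSON association file (array of two-key objects,
#' or JSONL with one object per line) into a [parse_associations()]
#' outcome. An unparseable top-level JSON array is fatal; individual bad
#' records are not.
#'
#' @param path path to the association file (UTF-8).
#' @inheritParams parse_associations
#' @return an object of class `"parse_outcome"`.
#' @examples
#' f <- system.file("extdata", "disease_drug_examples.json", package = "assocverify")
#' read_associations(f, "disease_drug")
#' @export
read_associations <- function(path, assoc_type, aliases = default_aliases()) {
  parse_associations(read_text(path), assoc_type, aliases)
}

#' Write association pairs to a JSON file
#'
#' Serializes pairs to the array-of-two-key-objects dialect, one record
#' per line, with a deterministic byte layout: writing the same pairs
#' twice produces identical files, and
#' `read_associations(write_associations(p))$pairs` reproduces `p`.
#'
#' @param pairs data.frame as produced by [association_pairs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_associations <- function(pairs, path) {
  j <- function(s) as.character(jsonlite::toJSON(s, auto_unbox = TRUE))
  if (nrow(pairs) == 0) {
    return(write_text("[]\n", path))
  }
  recs <- vapply(seq_len(nrow(pairs)), function(i) {
    sprintf("  {%s: %s, %s: %s}",
            j(pairs$source_id[i]), j(pairs$source_label[i]),
            j(pairs$target_id[i]), j(pairs$target_label[i]))
  }, character(1))
  write_text(paste0("[\n", paste(recs, collapse = ",\n"), "\n]\n"), path)
}
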