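#' Normalize a free-text label for matching
#'
#' The canonical form used everywhere labels are compared: Unicode
#' compatibility normalization (NFKC), case-folding, replacement of every
#' run of characters that is neither letter nor digit (punctuation,
#' hyphens, apostrophes, symbols, whitespace) by a single space, and
#' trimming. Deterministic and idempotent. Generated terms routinely
#' differ from ontology labels only in casing, hyphenation or quoting, so
#' matching on this form recovers those without any fuzzy matching.
#'
#' @param text character vector.
#' @return character vector of normalized labels; `""` for empty/NA input.
#' @examples
#' normalize_label("Bull's-Eye  Rash")  # "bull s eye rash"
#' normalize_label("HTN")               # "htn"
#' @export
normalize_label <- function(text) {
  if (length(text) == 0) return(character(0))
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_nfkc(x)
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "[^\\p{L}\\p{N}]+", " ")
  stringi::stri_trim_both(x)
}

OBO_SCOPES <- c("EXACT", "RELATED", "NARROW", "BROAD", "UNSPECIFIED")

# Construct the ontology object from parsed term/synonym tables.
new_ontology <- function(prefix, terms, synonyms, errors = character(0)) {
  active <- terms[!terms$obsolete, , drop = FALSE]
  name_index <- empty_df(label = character(0), id = character(0))
  if (nrow(active)) {
    name_index <- data.frame(
      label = normalize_label(active$name), id = active$id,
      stringsAsFactors = FALSE
    )
    name_index <- name_index[name_index$label != "", , drop = FALSE]
    name_index <- unique(name_index)
  }
  syn_index <- empty_df(label = character(0), id = character(0))
  if (nrow(synonyms)) {
    keep <- synonyms$id %in% active$id
    syn_index <- data.frame(
      label = normalize_label(synonyms$text[keep]), id = synonyms$id[keep],
      stringsAsFactors = FALSE
    )
    syn_index <- syn_index[syn_index$label != "", , drop = FALSE]
    syn_index <- unique(syn_index)
  }
  label_index <- unique(rbind(name_index, syn_index))
  structure(
    list(
      prefix = prefix,
      terms = terms,
      synonyms = synonyms,
      name_index = name_index,
      synonym_index = syn_index,
      label_index = label_index,
      errors = errors
    ),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> prefix=%s  terms=%d (%d obsolete)  synonyms=%d  labels indexed=%d\n",
    x$prefix, nrow(x$terms), sum(x$terms$obsolete), nrow(x$synonyms),
    length(unique(x$label_index$label))
  ))
  if (length(x$errors)) {
    cat(sprintf("  %d record-level parse error(s); see $errors\n", length(x$errors)))
  }
  invisible(x)
}

# Parse one synonym tag value: "TEXT" SCOPE [xrefs]; scope optional.
parse_synonym_value <- function(value) {
  m <- stringi::stri_match_first_regex(
    value, '^\\s*"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z_]+)?'
  )
  if (is.na(m[1, 1])) return(NULL)
  text <- stringi::stri_replace_all_regex(m[1, 2], "\\\\(.)", "$1")
  scope <- m[1, 3]
  if (is.na(scope) || !scope %in% OBO_SCOPES) scope <- "UNSPECIFIED"
  list(text = text, scope = scope)
}

#' Load an OBO flat-file ontology
#'
#' Reads an OBO 1.2/1.4 flat file into an indexed ontology supporting
#' [lookup()] under the [normalize_label()] policy. Only the tags relevant
#' to label matching are interpreted: `id`, `name`, `synonym` (with its
#' scope keyword `EXACT`/`RELATED`/`NARROW`/`BROAD`), and `is_obsolete`.
#' Obsolete terms are retained in `$terms` but excluded from the match
#' indexes, so retired vocabulary never verifies a generated term.
#' Synonyms duplicated within a term (after normalization) are collapsed.
#'
#' A `[Term]` stanza without an `id` is a record-level error: it is
#' skipped, collected into the returned object's `$errors`, and reported
#' as a warning rather than aborting the load.
#'
#' @param path path to the OBO file.
#' @param prefix expected CURIE prefix of the ontology (e.g. `"DOID"`).
#' @return an object of class `"ontology"` with components `prefix`,
#'   `terms` (data.frame: id, name, obsolete), `synonyms` (data.frame:
#'   id, text, scope), the match indexes, and `errors`.
#' @examples
#' obo <- system.file("extdata", "doid_hypertension.obo", package = "assocverify")
#' ont <- load_obo(obo, "DOID")
#' lookup(ont, "HTN")
#' @export
load_obo <- function(path, prefix) {
  if (!file.exists(path)) {
    stop("cannot read OBO file '", path, "': no such file", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # stanza boundaries: lines like [Term], [Typedef], ...
  stanza_starts <- grep("^\\[[A-Za-z]+\\]\\s*$", lines)
  errors <- character(0)
  ids <- character(0); names_ <- character(0); obsolete <- logical(0)
  syn_id <- character(0); syn_text <- character(0); syn_scope <- character(0)

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (k in seq_along(stanza_starts)) {
    header <- trimws(lines[stanza_starts[k]])
    if (header != "[Term]") next
    body <- lines[seq.int(stanza_starts[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    tags <- stringi::stri_match_first_regex(body, "^([A-Za-z_]+):\\s*(.*)$")
    keys <- tags[, 2]; vals <- tags[, 3]

    id <- vals[which(keys == "id")[1]]
    if (is.na(id) || !nzchar(trimws(id))) {
      errors <- c(errors, sprintf(
        "stanza starting at line %d has no id; skipped", stanza_starts[k]
      ))
      next
    }
    id <- trimws(id)
    name <- vals[which(keys == "name")[1]]
    name <- if (is.na(name)) "" else trimws(name)
    obs <- any(keys == "is_obsolete" &
                 stringi::stri_detect_regex(vals, "^\\s*true\\b"))
    ids <- c(ids, id); names_ <- c(names_, name); obsolete <- c(obsolete, obs)

    seen <- character(0)
    for (v in vals[which(keys == "synonym")]) {
      s <- parse_synonym_value(v)
      if (is.null(s)) {
        errors <- c(errors, sprintf("unparseable synonym line in %s: %s", id, v))
        next
      }
      key <- normalize_label(s$text)
      if (!nzchar(key) || key %in% seen) next  # dedupe within term
      seen <- c(seen, key)
      syn_id <- c(syn_id, id); syn_text <- c(syn_text, s$text)
      syn_scope <- c(syn_scope, s$scope)
    }
  }

  # duplicate stanzas for one id: keep the first, note the rest
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    errors <- c(errors, sprintf("duplicate stanza for %s; kept first", unique(ids[dup])))
    keep_ids <- !dup
    drop_syn <- duplicated(paste(syn_id, normalize_label(syn_text)))
    ids <- ids[keep_ids]; names_ <- names_[keep_ids]; obsolete <- obsolete[keep_ids]
    syn_id <- syn_id[!drop_syn]; syn_text <- syn_text[!drop_syn]
    syn_scope <- syn_scope[!drop_syn]
  }

  terms <- data.frame(id = ids, name = names_, obsolete = obsolete,
                      stringsAsFactors = FALSE)
  synonyms <- data.frame(id = syn_id, text = syn_text, scope = syn_scope,
                         stringsAsFactors = FALSE)
  if (length(errors)) {
    warning(length(errors), " record-level parse error(s) in '", path,
            "'; see $errors", call. = FALSE)
  }
  new_ontology(prefix, terms, synonyms, errors)
}

# Raw index hits for a label: list(name_ids, synonym_ids); synonym_ids may
# overlap name_ids (callers decide the reporting policy).
lookup_raw <- function(ontology, label) {
  key <- normalize_label(label)
  if (!nzchar(key)) return(list(name_ids = character(0), synonym_ids = character(0)))
  ni <- ontology$name_index
  si <- ontology$synonym_index
  list(
    name_ids = unique(ni$id[ni$label == key]),
    synonym_ids = unique(si$id[si$label == key])
  )
}

#' Look up a label in an ontology
#'
#' Returns every non-obsolete term whose normalized primary name equals
#' the normalized label (`match_kind = "NAME"`) and every term with a
#' matching synonym of any scope (`match_kind = "SYNONYM"`). A term
#' matching by both routes is reported once, as `NAME`. Ambiguity is
#' allowed: several terms may share a label, and all are returned.
#'
#' @param ontology an `"ontology"` object from [load_obo()].
#' @param label free-text label to look up.
#' @return data.frame with columns `id` and `match_kind`; zero rows when
#'   nothing matches (including the empty label).
#' @examples
#' obo <- system.file("extdata", "doid_hypertension.obo", package = "assocverify")
#' ont <- load_obo(obo, "DOID")
#' lookup(ont, "hypertension")
#' lookup(ont, "vascular hypertensive disorder")
#' @export
lookup <- function(ontology, label) {
  stopifnot(inherits(ontology, "ontology"))
  hits <- lookup_raw(ontology, label)
  syn_only <- setdiff(hits$synonym_ids, hits$name_ids)
  out <- data.frame(
    id = c(hits$name_ids, syn_only),
    match_kind = c(rep("NAME", length(hits$name_ids)),
                   rep("SYNONYM", length(syn_only))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
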