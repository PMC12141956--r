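# Association type registry: expected CURIE prefixes for each typed pair.
ASSOC_TYPES <- list(
  disease_drug    = c(source = "DOID", target = "CHEBI"),
  disease_symptom = c(source = "DOID", target = "SYMP"),
  disease_gene    = c(source = "DOID", target = "GO"),
  process_gene    = c(source = "GO",   target = "GO")
)

#' Association types understood by the toolkit
#'
#' @return character vector of the four association type names.
#' @export
assoc_types <- function() names(ASSOC_TYPES)

# Expected (source, target) prefixes for an association type.
assoc_prefixes <- function(assoc_type) {
  assoc_type <- match.arg(assoc_type, names(ASSOC_TYPES))
  ASSOC_TYPES[[assoc_type]]
}

#' Default CURIE prefix alias table
#'
#' Generated association records sometimes spell an ontology prefix by the
#' ontology's colloquial name rather than its registered prefix; the one
#' systematic case is `SYMPTOM:` for the Symptom Ontology's `SYMP:`.
#' Aliases are applied to the prefix part of a CURIE at parse time.
#'
#' @return named character vector mapping alias prefix -> canonical prefix.
#' @export
default_aliases <- function() c(SYMPTOM = "SYMP")

# Apply a prefix alias table to CURIE strings ("SYMPTOM:1080" -> "SYMP:1080").
apply_aliases <- function(ids, aliases = default_aliases()) {
  if (length(aliases) == 0 || length(ids) == 0) return(ids)
  parts <- stringi::stri_split_fixed(ids, ":", n = 2L)
  vapply(parts, function(p) {
    if (length(p) == 2L && p[[1]] %in% names(aliases)) {
      paste0(aliases[[p[[1]]]], ":", p[[2]])
    } else {
      paste(p, collapse = ":")
    }
  }, character(1))
}

#' Validate a CURIE against an expected ontology prefix
#'
#' A CURIE is valid when it has the form `<PREFIX>:<digits>`, with a
#' case-sensitive prefix match. GO local identifiers are fixed-width
#' (exactly 7 digits, e.g. `GO:0006915`); DOID, CHEBI and SYMP accept any
#' positive number of digits.
#'
#' @param id character vector of candidate CURIE strings.
#' @param expected_prefix single expected prefix, e.g. `"DOID"`.
#' @param aliases optional prefix alias table applied before validation
#'   (see [default_aliases()]); use `NULL` to disable.
#' @return logical vector, `TRUE` where the CURIE is valid.
#' @examples
#' validate_curie("DOID:10763", "DOID")
#' validate_curie("GO:123", "GO")        # GO needs exactly 7 digits
#' validate_curie("SYMPTOM:1080", "SYMP")
#' @export
validate_curie <- function(id, expected_prefix, aliases = default_aliases()) {
  stopifnot(is.character(expected_prefix), length(expected_prefix) == 1L)
  if (length(id) == 0) return(logical(0))
  id <- apply_aliases(as.character(id), aliases)
  digits <- if (expected_prefix == "GO") "[0-9]{7}" else "[0-9]+"
  pattern <- paste0("^", expected_prefix, ":", digits, "$")
  !is.na(id) & stringi::stri_detect_regex(id, pattern)
}
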