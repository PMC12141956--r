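# Human-readable pairing names used in the instruction sentence.
ASSOC_PROMPT_NAMES <- c(
  disease_drug = "DOID-CHEBI",
  disease_symptom = "DOID-SYMPTOM",
  disease_gene = "DOID-GO",
  process_gene = "GO-GO"
)

#' Specify a one-shot generation prompt
#'
#' Bundles what a one-shot association-generation request needs: the
#' association type, the number of associations to request, exactly one
#' worked example (the "shot") rendered as a two-key JSON object, and an
#' opaque model label. The shot must itself parse as one valid
#' association under the prefix alias table.
#'
#' @param assoc_type one of [assoc_types()].
#' @param n_associations number of associations to request (>= 1).
#' @param shot named character vector of length 2, CURIE -> label, e.g.
#'   `c("DOID:11734" = "Epistaxis", "SYMPTOM:1080" = "Nosebleed")`.
#' @param model_name opaque model label.
#' @param aliases prefix alias table used to validate the shot.
#' @return object of class `"prompt_spec"`.
#' @export
prompt_spec <- function(assoc_type, n_associations, shot,
                        model_name = "mock", aliases = default_aliases()) {
  assoc_type <- match.arg(assoc_type, names(ASSOC_TYPES))
  if (!is.numeric(n_associations) || length(n_associations) != 1L ||
      is.na(n_associations) || n_associations < 1) {
    stop("n_associations must be a single number >= 1", call. = FALSE)
  }
  if (!is.character(shot) || length(shot) != 2L || is.null(names(shot))) {
    stop("shot must be a named character vector of length 2 (CURIE -> label)",
         call. = FALSE)
  }
  shot_json <- render_shot(shot)
  outcome <- parse_associations(shot_json, assoc_type, aliases)
  if (nrow(outcome$pairs) != 1L) {
    stop("shot does not parse as one valid ", assoc_type, " association: ",
         paste(outcome$rejected$reason, collapse = "; "), call. = FALSE)
  }
  structure(
    list(assoc_type = assoc_type,
         n_associations = as.integer(n_associations),
         shot = shot, model_name = model_name, aliases = aliases),
    class = "prompt_spec"
  )
}

# Render a named CURIE->label vector as the two-key JSON object.
render_shot <- function(shot) {
  j <- function(s) as.character(jsonlite::toJSON(unname(s), auto_unbox = TRUE))
  paste0("{\n  ", j(names(shot)[1]), ": ", j(shot[[1]]), ",\n  ",
         j(names(shot)[2]), ": ", j(shot[[2]]), "\n}")
}

#' Build the one-shot prompt text
#'
#' Interpolates the request count and association pairing into the fixed
#' instruction sentence and appends the serialized shot. Deterministic
#' for a fixed spec.
#'
#' @param spec a [prompt_spec()].
#' @return single prompt string.
#' @examples
#' sp <- prompt_spec("disease_symptom", 10,
#'                   c("DOID:11734" = "Epistaxis", "SYMPTOM:1080" = "Nosebleed"))
#' cat(build_prompt(sp))
#' @export
build_prompt <- function(spec) {
  stopifnot(inherits(spec, "prompt_spec"))
  paste0(
    "You are an assistant that generates ", spec$n_associations, " ",
    ASSOC_PROMPT_NAMES[[spec$assoc_type]],
    " term associations in a structured JSON format. ",
    "Ensure the JSON is valid and correctly formatted for parsing. ",
    "Provide one example in the following format:\n",
    render_shot(spec$shot), "\n"
  )
}

#' Parse a generator response
#'
#' Applies the association-file semantics ([parse_associations()]) to an
#' in-memory response. Structurally invalid JSON is not an R error here:
#' it yields an outcome whose single rejected record carries the reason
#' `"Invalid JSON format in response."` and zero pairs, so callers can
#' count failures as data.
#'
#' @param response response text.
#' @inheritParams parse_associations
#' @return object of class `"parse_outcome"`.
#' @export
parse_response <- function(response, assoc_type, aliases = default_aliases()) {
  tryCatch(
    parse_associations(response, assoc_type, aliases),
    error = function(e) {
      new_parse_outcome(
        pairs = empty_pairs(assoc_type),
        rejected = data.frame(record = paste(response, collapse = "\n"),
                              reason = "Invalid JSON format in response.",
                              stringsAsFactors = FALSE),
        duplicates_removed = 0L, n_records = 1L
      )
    }
  )
}

#' Deterministic mock text generator
#'
#' Stands in for a live model behind the generator contract (a single
#' `generate(prompt) -> response text` capability). The mock draws
#' association records from seeded vocabulary (or from supplied
#' ontologies' labels) and can inject, at configurable rates, the failure
#' modes observed in real generator output: duplicate records, malformed
#' CURIEs, and a truncated (invalid-JSON) response. Its internal ground
#' truth (`$truth`) records every emitted record and its defects, so
#' parsing results can be checked record-by-record. For a fixed seed the
#' response is byte-identical across calls and sessions.
#'
#' @param assoc_type one of [assoc_types()].
#' @param n number of records to emit.
#' @param seed integer seed.
#' @param duplicate_rate fraction of records that repeat an earlier record.
#' @param bad_curie_rate fraction of records given a malformed source CURIE.
#' @param invalid_json if `TRUE` the response is truncated mid-record.
#' @param source_labels,target_labels optional label pools; defaults are
#'   generated pronounceable labels.
#' @return object of class `"mock_generator"` with `$generate(prompt)`,
#'   `$truth` (data.frame: source_id, source_label, target_id,
#'   target_label, duplicate, bad_curie) and `$seed`.
#' @export
mock_generator <- function(assoc_type, n, seed, duplicate_rate = 0,
                           bad_curie_rate = 0, invalid_json = FALSE,
                           source_labels = NULL, target_labels = NULL) {
  assoc_type <- match.arg(assoc_type, names(ASSOC_TYPES))
  pre <- assoc_prefixes(assoc_type)
  truth <- local_seed(seed, {
    src_lab <- if (is.null(source_labels)) gen_labels(n) else
      sample(source_labels, n, replace = TRUE)
    tgt_lab <- if (is.null(target_labels)) gen_labels(n) else
      sample(target_labels, n, replace = TRUE)
    df <- data.frame(
      source_id = make_curies(pre[["source"]], n),
      source_label = src_lab,
      target_id = make_curies(pre[["target"]], n),
      target_label = tgt_lab,
      duplicate = FALSE, bad_curie = FALSE,
      stringsAsFactors = FALSE
    )
    bad <- runif(n) < bad_curie_rate
    dup <- runif(n) < duplicate_rate & !bad
    dup[1] <- FALSE
    for (i in which(dup)) {
      clean_earlier <- which(!bad[seq_len(i - 1L)])  # duplicates copy valid records
      if (!length(clean_earlier)) { dup[i] <- FALSE; next }
      src <- clean_earlier[sample.int(length(clean_earlier), 1L)]
      df[i, c("source_id", "source_label", "target_id", "target_label")] <-
        df[src, c("source_id", "source_label", "target_id", "target_label")]
      df$duplicate[i] <- TRUE
    }
    df$source_id[bad] <- paste0(pre[["source"]], ":X",
                                substring(df$source_id[bad], nchar(pre[["source"]]) + 2L))
    df$bad_curie[bad] <- TRUE
    df
  })
  j <- function(s) as.character(jsonlite::toJSON(s, auto_unbox = TRUE))
  recs <- vapply(seq_len(nrow(truth)), function(i) {
    sprintf("  {%s: %s, %s: %s}",
            j(truth$source_id[i]), j(truth$source_label[i]),
            j(truth$target_id[i]), j(truth$target_label[i]))
  }, character(1))
  response <- paste0("[\n", paste(recs, collapse = ",\n"), "\n]\n")
  if (invalid_json) {
    response <- substr(response, 1L, floor(nchar(response) * 0.8))
  }
  structure(
    list(
      generate = function(prompt) response,
      truth = truth,
      seed = seed,
      assoc_type = assoc_type
    ),
    class = "mock_generator"
  )
}
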