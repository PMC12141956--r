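#' Round half away from zero
#'
#' Deterministic half-up rounding for display percentages (so 0.125 -> 0.13
#' at 2 digits), unlike [base::round()]'s round-half-to-even. A tiny epsilon
#' absorbs binary representation error in ratios of integer counts.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(85.715, 2)
#' round_half_up(100 * 375 / 2625, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Read a whole text file as a single UTF-8 string.
read_text <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file", call. = FALSE)
  }
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt
}

# Write text with "\n" line endings and no trailing-newline surprises.
write_text <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(enc2utf8(text), con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

# Zero-row data.frame with the given column name -> prototype value pairs.
empty_df <- function(...) {
  proto <- list(...)
  as.data.frame(lapply(proto, function(x) x[0]), stringsAsFactors = FALSE)
}
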