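#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so that
#' e.g. 78.65 renders as 78.7 rather than the IEEE banker's rounding of
#' [base::round()].
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

## Deterministic combination of two small integers into a valid seed (< 2^31).
mix_seed <- function(a, b) {
  as.integer((as.double(a) * 7919 + as.double(b) * 104729 + 1) %% 2147483647)
}

## Stable non-cryptographic hash (FNV-1a style) used to reference free-text
## snippets in risk events without storing the text itself.
text_hash <- function(x) {
  h <- 216613626
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b %% 256))
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

parse_utc <- function(x) as.POSIXct(x, tz = "UTC")

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

## Strip common Latin diacritics after case-folding; locale-independent.
strip_diacritics <- function(x) {
  chartr(
    "áàâãäéèêëíìîïóòôõöúùûüçñý",
    "aaaaaeeeeiiiiooooouuuucny",
    x
  )
}

normalize_text <- function(x) {
  x <- tolower(enc2utf8(x))
  x <- strip_diacritics(x)
  gsub("[[:space:]]+", " ", trimws(x))
}

stop_checkup <- function(class, message, ...) {
  stop(structure(
    class = c(class, "checkup_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
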