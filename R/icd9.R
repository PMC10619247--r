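#' Normalize raw ICD-9-CM code strings
#'
#' Hospital extracts mix dotted (`"428.0"`) and undotted (`"4280"`) forms and
#' sometimes carry stray whitespace. Normalization strips whitespace, removes
#' the decimal point, and detects the namespace from a leading `V` or `E`
#' (case-insensitive). Numeric codes keep their 3-digit category (so `"428.0"`
#' becomes digits `"4280"`); V codes drop the `V` (`"V45.0"` becomes `"450"`).
#'
#' @param raw character vector of raw code strings.
#' @return A data frame with one row per input code and columns `raw`,
#'   `namespace` (`"numeric"`, `"V"` or `"E"`), `digits` (dot-free digit
#'   string), `valid` (logical) and `reason` (why an invalid code was
#'   rejected; `NA` for valid codes). Invalid codes contribute no comorbidity
#'   flags downstream.
#' @examples
#' normalize_icd9(c("428.0", "V45.0", "2860", "42x"))
#' @export
normalize_icd9 <- function(raw) {
  raw <- as.character(raw)
  trimmed <- toupper(gsub("\\s+", "", raw))
  body <- sub("^[VE]", "", trimmed)
  namespace <- ifelse(startsWith(trimmed, "V"), "V",
                      ifelse(startsWith(trimmed, "E"), "E", "numeric"))
  digits <- gsub(".", "", body, fixed = TRUE)

  valid <- rep(TRUE, length(raw))
  reason <- rep(NA_character_, length(raw))
  flag <- function(bad, why) {
    hit <- bad & valid
    valid[hit] <<- FALSE
    reason[hit] <<- why
  }
  flag(!nzchar(trimmed), "empty code")
  flag(!grepl("^[0-9]*$", digits), "non-digit characters")
  # at most one dot, and only in the expected position
  flag(nchar(body) - nchar(digits) > 1, "multiple decimal points")
  n <- nchar(digits)
  flag(namespace == "numeric" & (n < 3 | n > 5), "numeric code needs 3-5 digits")
  flag(namespace == "V" & (n < 2 | n > 5), "V code needs 2-5 digits")
  flag(namespace == "E" & (n < 3 | n > 5), "E code needs 3-5 digits")
  flag(namespace == "numeric" & n >= 3 & substr(digits, 1, 3) == "000",
       "numeric category below 001")

  data.frame(raw = raw, namespace = namespace, digits = digits,
             valid = valid, reason = reason, stringsAsFactors = FALSE)
}

pad0 <- function(x, width) paste0(x, strrep("0", pmax(0L, width - nchar(x))))
pad9 <- function(x, width) paste0(x, strrep("9", pmax(0L, width - nchar(x))))

#' Compile a code token into a matchable range pattern
#'
#' Tokens come from the condition-definition table and are either a single
#' code (`"428.0"`) or an inclusive range (`"428.0-428.9"`). Endpoints are
#' normalized like recorded codes. When the two endpoints print at different
#' precisions (`"042-044.9"`, `"495.0-505"`) the range is widened to the finer
#' precision: the low endpoint is right-padded with `"0"` and the high endpoint
#' with `"9"`, so the coarser endpoint spans its whole category (e.g. `"505"`
#' in `"495.0-505"` covers 505.0-505.9).
#'
#' @param token single code or `"a-b"` range string (ASCII hyphen or en dash).
#' @return A list of class `icd9_pattern` with elements `namespace`, `low`,
#'   `high`, `precision` and `token`.
#' @examples
#' compile_pattern("428.0-428.9")
#' compile_pattern("042-044.9")
#' @export
compile_pattern <- function(token) {
  stopifnot(length(token) == 1L)
  parts <- strsplit(gsub("–", "-", token), "-", fixed = TRUE)[[1]]
  if (length(parts) > 2L)
    stop("malformed code token: ", token)
  ends <- normalize_icd9(parts)
  if (any(!ends$valid))
    stop("cannot compile token '", token, "': ", ends$reason[!ends$valid][1])
  if (length(unique(ends$namespace)) != 1L)
    stop("cannot compile token '", token, "': endpoints cross namespaces")
  low <- ends$digits[1]
  high <- ends$digits[length(parts)]
  precision <- max(nchar(low), nchar(high))
  low <- pad0(low, precision)
  high <- pad9(high, precision)
  if (low > high)
    stop("cannot compile token '", token, "': endpoints out of order")
  structure(list(namespace = ends$namespace[1], low = low, high = high,
                 precision = precision, token = token),
            class = "icd9_pattern")
}

#' Test normalized codes against a compiled range pattern
#'
#' A code matches when it shares the pattern's namespace and, after being
#' truncated to the pattern's precision (when longer) or right-padded with
#' `"0"` (when shorter), falls lexicographically inside `[low, high]`.
#' Truncation is what lets a 4-digit table entry such as 428.0 capture its
#' 5-digit children (428.00-428.09), the standard convention for
#' administrative-claims comorbidity mapping.
#'
#' @param pattern an `icd9_pattern` from [compile_pattern()].
#' @param codes data frame from [normalize_icd9()] (invalid rows never match).
#' @return logical vector, one element per code.
#' @export
code_matches <- function(pattern, codes) {
  stopifnot(inherits(pattern, "icd9_pattern"))
  d <- codes$digits
  p <- pattern$precision
  key <- ifelse(nchar(d) >= p, substr(d, 1, p), pad0(d, p))
  codes$valid & codes$namespace == pattern$namespace &
    key >= pattern$low & key <= pattern$high
}

#' Enumerate the category prefixes a pattern covers
#'
#' Lists every digit string at the pattern's own precision inside
#' `[low, high]`, rendered with the namespace prefix (`"V"`/`"E"`). Used by
#' the synthetic-record generator to sample concrete codes for a condition.
#'
#' @param pattern an `icd9_pattern`.
#' @return character vector of code strings (undotted).
#' @export
expand_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "icd9_pattern"))
  ints <- seq.int(as.integer(pattern$low), as.integer(pattern$high))
  digits <- formatC(ints, width = pattern$precision, flag = "0", format = "d")
  prefix <- switch(pattern$namespace, numeric = "", V = "V", E = "E")
  paste0(prefix, digits)
}
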