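# Independent oracles and small fixture builders shared across tests.

# --- brute-force ICD-9 range oracle -----------------------------------------
# Expands a definition-table token into the explicit set of all 3/4/5-digit
# code strings it covers, by integer enumeration, and tests membership by set
# lookup. Written against the raw token text, independently of the package's
# interval matcher.
oracle_expand_token <- function(token) {
  parts <- strsplit(gsub("–", "-", token), "-", fixed = TRUE)[[1]]
  strip <- function(x) {
    x <- toupper(trimws(x))
    ns <- if (startsWith(x, "V")) "V" else if (startsWith(x, "E")) "E" else ""
    list(ns = ns, d = gsub("[VE.]", "", x))
  }
  lo <- strip(parts[1])
  hi <- strip(parts[length(parts)])
  p <- max(nchar(lo$d), nchar(hi$d))
  lo_d <- paste0(lo$d, strrep("0", p - nchar(lo$d)))
  hi_d <- paste0(hi$d, strrep("9", p - nchar(hi$d)))
  covered <- formatC(seq.int(as.integer(lo_d), as.integer(hi_d)),
                     width = p, flag = "0", format = "d")
  out <- character(0)
  for (s in covered) {
    # the covered prefix itself, all longer descendants up to 5 digits, and
    # any shorter code whose zero-padding equals the prefix
    ext <- s
    if (p <= 4) ext <- c(ext, paste0(rep(s, each = 10), 0:9))
    if (p <= 3) ext <- c(ext, paste0(rep(s, each = 100),
                                     formatC(0:99, width = 2, flag = "0")))
    for (k in seq_len(p - 1)) {
      t <- substr(s, 1, k)
      if (paste0(t, strrep("0", p - k)) == s) ext <- c(ext, t)
    }
    out <- c(out, ext)
  }
  max_len <- if (lo$ns == "V") 5 else 5
  min_len <- if (lo$ns == "V") 2 else 3
  out <- unique(out[nchar(out) >= min_len & nchar(out) <= max_len])
  paste0(lo$ns, out)
}

# membership sets for every condition, built once per session
oracle_code_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- utils::read.delim(
        system.file("extdata", "elixhauser_icd9.tsv", package = "elixadjust"),
        stringsAsFactors = FALSE, colClasses = "character")
      sets <- lapply(seq_len(nrow(tab)), function(i) {
        tokens <- trimws(strsplit(tab$icd9_codes[i], ",", fixed = TRUE)[[1]])
        unique(unlist(lapply(tokens, oracle_expand_token)))
      })
      names(sets) <- tab$key
      cache <<- sets
    }
    cache
  }
})

# oracle flag assignment for one undotted code string
oracle_flags_for_code <- function(code) {
  sets <- oracle_code_sets()
  vapply(sets, function(s) code %in% s, logical(1))
}

# random syntactically valid undotted codes (numeric and V namespaces)
random_codes <- function(n) {
  len <- sample(3:5, n, replace = TRUE)
  num <- vapply(len, function(l)
    paste(sample(0:9, l, replace = TRUE), collapse = ""), character(1))
  bad <- substr(num, 1, 3) == "000"
  num[bad] <- paste0("001", substr(num[bad], 4, 5))
  is_v <- runif(n) < 0.15
  vlen <- sample(2:4, sum(is_v), replace = TRUE)
  num[is_v] <- vapply(vlen, function(l)
    paste0("V", paste(sample(0:9, l, replace = TRUE), collapse = "")),
    character(1))
  num
}

# --- brute-force concordance oracle -----------------------------------------
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  s1 <- scores[labels]
  s0 <- scores[!labels]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- tiny cohort builder ----------------------------------------------------
# Builds a valid elix_cohort from minimal per-record descriptions.
make_cohort <- function(records, ward_stays = NULL, events = NULL) {
  ts <- function(x) as.POSIXct(x, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d"))
  h <- data.frame(
    hospitalization_id = vapply(records, `[[`, character(1), "id"),
    patient_id = vapply(records, function(r)
      if (is.null(r$patient)) r$id else r$patient, character(1)),
    admit = ts(vapply(records, `[[`, character(1), "admit")),
    discharge = ts(vapply(records, `[[`, character(1), "discharge")),
    age_years = vapply(records, function(r)
      if (is.null(r$age)) 74 else r$age, numeric(1)),
    sex = vapply(records, function(r)
      if (is.null(r$sex)) "female" else r$sex, character(1)),
    admission_source = "emergency",
    died_in_hospital = vapply(records, function(r)
      isTRUE(r$died), logical(1)),
    drg = NA_integer_,
    stringsAsFactors = FALSE)
  h$diagnosis_codes <- lapply(records, function(r)
    if (is.null(r$codes)) character(0) else r$codes)
  ws <- if (is.null(ward_stays)) {
    data.frame(hospitalization_id = character(0), ward_class = character(0),
               start = as.POSIXct(character(0), tz = "UTC"),
               end = as.POSIXct(character(0), tz = "UTC"))
  } else {
    data.frame(hospitalization_id = vapply(ward_stays, `[[`, character(1), "id"),
               ward_class = vapply(ward_stays, `[[`, character(1), "class"),
               start = ts(vapply(ward_stays, `[[`, character(1), "start")),
               end = ts(vapply(ward_stays, `[[`, character(1), "end")),
               stringsAsFactors = FALSE)
  }
  ev <- if (is.null(events)) {
    data.frame(hospitalization_id = character(0), kind = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"),
               drug_name = character(0))
  } else {
    data.frame(hospitalization_id = vapply(events, `[[`, character(1), "id"),
               kind = vapply(events, `[[`, character(1), "kind"),
               timestamp = ts(vapply(events, `[[`, character(1), "time")),
               drug_name = vapply(events, function(e)
                 if (is.null(e$drug)) NA_character_ else e$drug, character(1)),
               stringsAsFactors = FALSE)
  }
  elixadjust:::new_cohort(h, ws, ev)
}

shared_defs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- elix_definitions()
    cache
  }
})
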