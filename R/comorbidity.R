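# Elixhauser condition definitions: loading, compiling, flag assignment,
# severity hierarchies, optional DRG screen, prevalence summaries.

# DRG groups referenced by name in the definition table's screen column.
drg_groups <- list(
  cardiac = c(103:108, 110:112, 115:118, 120:127, 129, 132:133),
  renal = c(302:305, 315:333),
  liver = c(199:202, 205:208),
  leukemia_lymphoma = 400:414,
  cancer = c(10, 11, 64, 82, 172, 173, 199, 203, 239, 257:260, 274, 275,
             303, 318, 319, 338, 344, 346, 347, 354, 366, 367, 406:414)
)

parse_drg_tokens <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(integer(0))
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  out <- integer(0)
  for (tok in tokens) {
    if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else if (grepl("^[0-9]+-[0-9]+$", tok)) {
      ends <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      out <- c(out, seq.int(ends[1], ends[2]))
    } else if (tok %in% names(drg_groups)) {
      out <- c(out, drg_groups[[tok]])
    } else {
      stop("unknown DRG group name in definitions: '", tok, "'")
    }
  }
  sort(unique(out))
}

#' Load and compile Elixhauser condition definitions
#'
#' Reads the condition-definition table (30 conditions, hypertension combined
#' into a single key) and compiles each condition's code tokens into matchable
#' range patterns and its DRG-screen tokens into explicit DRG sets. The
#' shipped table transcribes the original Elixhauser ICD-9-CM specification.
#' Users may supply a replacement file with the same four tab-separated
#' columns (`key`, `display_name`, `icd9_codes`, `drg_screen`).
#'
#' @param file path to a definition table; defaults to the shipped resource.
#' @return An object of class `elix_definitions`: a list with one element per
#'   condition, each holding `key`, `display_name`, `patterns` (list of
#'   [compile_pattern()] results) and `drg_screen` (integer vector).
#' @examples
#' defs <- elix_definitions()
#' names(defs)[1:5]
#' @export
elix_definitions <- function(file = system.file("extdata", "elixhauser_icd9.tsv",
                                                package = "elixadjust")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("key", "display_name", "icd9_codes", "drg_screen")
  if (!all(needed %in% names(tab)))
    stop("definition table must have columns: ", paste(needed, collapse = ", "))
  defs <- lapply(seq_len(nrow(tab)), function(i) {
    tokens <- trimws(strsplit(tab$icd9_codes[i], ",", fixed = TRUE)[[1]])
    list(key = tab$key[i],
         display_name = tab$display_name[i],
         patterns = lapply(tokens, compile_pattern),
         drg_screen = parse_drg_tokens(tab$drg_screen[i]))
  })
  names(defs) <- tab$key
  if (anyDuplicated(names(defs)))
    stop("duplicate condition keys in definition table")
  structure(defs, class = "elix_definitions")
}

#' Condition keys in table order
#'
#' @param definitions compiled definitions from [elix_definitions()].
#' @return character vector of the 30 condition keys.
#' @export
condition_keys <- function(definitions = elix_definitions()) {
  names(definitions)
}

#' Assign comorbidity flags to one code list
#'
#' A condition is flagged when at least one of the hospitalization's own
#' diagnosis codes matches at least one of the condition's patterns. Only
#' codes recorded during that hospitalization are consulted; codes from a
#' patient's other admissions never count. Unparseable codes are skipped.
#' No hierarchy is applied here (see [apply_hierarchy()]).
#'
#' @param codes character vector of raw ICD-9-CM codes (possibly empty).
#' @param definitions compiled definitions.
#' @return named logical vector over all condition keys.
#' @examples
#' flags <- assign_flags(c("4280", "25000"), elix_definitions())
#' names(flags)[flags]
#' @export
assign_flags <- function(codes, definitions = elix_definitions()) {
  flags <- flag_matrix(list(codes), definitions)
  stats::setNames(as.logical(flags[1, ]), colnames(flags))
}

#' Assign comorbidity flags to a whole cohort
#'
#' Vectorized version of [assign_flags()]: normalizes the pooled unique codes
#' once, matches them against every pattern, then distributes matches back to
#' hospitalizations.
#'
#' @param code_lists list of character vectors, one per hospitalization.
#' @param definitions compiled definitions.
#' @return logical matrix, rows = hospitalizations, columns = condition keys.
#' @export
flag_matrix <- function(code_lists, definitions = elix_definitions()) {
  stopifnot(is.list(code_lists))
  keys <- names(definitions)
  n <- length(code_lists)
  out <- matrix(FALSE, nrow = n, ncol = length(keys),
                dimnames = list(NULL, keys))
  all_codes <- unlist(code_lists, use.names = FALSE)
  if (length(all_codes)) {
    uniq <- unique(all_codes)
    norm <- normalize_icd9(uniq)
    # unique code x condition lookup
    hit <- matrix(FALSE, nrow = length(uniq), ncol = length(keys),
                  dimnames = list(uniq, keys))
    for (key in keys) {
      for (pat in definitions[[key]]$patterns) {
        hit[, key] <- hit[, key] | code_matches(pat, norm)
      }
    }
    counts <- lengths(code_lists)
    row_of <- rep.int(seq_len(n), counts)
    idx <- match(all_codes, uniq)
    for (j in seq_along(keys)) {
      matched <- hit[idx, j]
      if (any(matched)) out[unique(row_of[matched]), j] <- TRUE
    }
  }
  out
}

#' Apply the comorbidity severity hierarchies
#'
#' Two condition pairs are mutually graded: when both uncomplicated and
#' complicated diabetes are flagged, only complicated diabetes counts; when
#' both a solid tumor and metastatic cancer are flagged, only metastatic
#' cancer counts. All other flags pass through. Idempotent; only ever turns
#' flags off.
#'
#' @param flags named logical vector or logical matrix from [flag_matrix()].
#' @return same shape as `flags` with the hierarchies resolved.
#' @export
apply_hierarchy <- function(flags) {
  if (is.matrix(flags)) {
    both <- flags[, "diabetes_uncomplicated"] & flags[, "diabetes_complicated"]
    flags[both, "diabetes_uncomplicated"] <- FALSE
    both <- flags[, "solid_tumor"] & flags[, "metastatic_cancer"]
    flags[both, "solid_tumor"] <- FALSE
  } else {
    if (flags[["diabetes_uncomplicated"]] && flags[["diabetes_complicated"]])
      flags[["diabetes_uncomplicated"]] <- FALSE
    if (flags[["solid_tumor"]] && flags[["metastatic_cancer"]])
      flags[["solid_tumor"]] <- FALSE
  }
  flags
}

#' Screen out comorbidities that coincide with the principal DRG
#'
#' In the original Elixhauser scheme a condition does not count as a
#' comorbidity when the hospitalization's diagnosis-related group shows the
#' condition was the principal reason for admission (e.g. congestive heart
#' failure with a cardiac DRG). The screen is optional because many systems
#' (including Israeli records) carry no DRG; with `drg` missing the flags are
#' returned unchanged with a one-time warning.
#'
#' @param flags logical matrix from [flag_matrix()] (or a named vector).
#' @param drg integer vector of DRG codes, one per row; `NA` = unknown.
#' @param definitions compiled definitions.
#' @return flags with screened conditions forced to `FALSE`.
#' @export
apply_drg_screen <- function(flags, drg, definitions = elix_definitions()) {
  vec <- !is.matrix(flags)
  if (vec) flags <- matrix(flags, nrow = 1, dimnames = list(NULL, names(flags)))
  drg <- rep_len(as.integer(drg), nrow(flags))
  if (anyNA(drg))
    warning("DRG missing for ", sum(is.na(drg)),
            " hospitalization(s); their flags were not screened")
  for (key in colnames(flags)) {
    screen <- definitions[[key]]$drg_screen
    if (length(screen)) {
      hit <- !is.na(drg) & drg %in% screen
      flags[hit, key] <- FALSE
    }
  }
  if (vec) stats::setNames(as.logical(flags[1, ]), colnames(flags)) else flags
}

#' Per-condition prevalence table
#'
#' @param flags logical matrix (hospitalizations x conditions).
#' @param definitions compiled definitions, used for display names.
#' @return data frame with `condition`, `display_name`, `count`, `percent`
#'   (to one decimal), in definition-table order.
#' @export
prevalence_table <- function(flags, definitions = elix_definitions()) {
  if (!is.matrix(flags) || nrow(flags) == 0)
    stop("prevalence_table needs a non-empty flag matrix")
  counts <- colSums(flags)
  data.frame(condition = colnames(flags),
             display_name = vapply(definitions[colnames(flags)],
                                   `[[`, character(1), "display_name"),
             count = as.integer(counts),
             percent = round(100 * counts / nrow(flags), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the conditions that enter the models
#'
#' Drops explicitly excluded conditions and any condition rarer than
#' `min_count`. The default exclusion reproduces the 29-condition analysis in
#' which the near-empty blood-loss-anemia category is removed. Order follows
#' the definition table and fixes the design-matrix column order.
#'
#' @param prevalences data frame from [prevalence_table()].
#' @param exclusions character vector of condition keys to drop.
#' @param min_count minimum flag count to keep a condition.
#' @return ordered character vector of included condition keys.
#' @export
select_conditions <- function(prevalences, exclusions = "blood_loss_anemia",
                              min_count = 0) {
  unknown <- setdiff(exclusions, prevalences$condition)
  if (length(unknown))
    stop("unknown condition key(s) in exclusions: ",
         paste(unknown, collapse = ", "))
  keep <- !(prevalences$condition %in% exclusions) &
    prevalences$count >= min_count
  prevalences$condition[keep]
}
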