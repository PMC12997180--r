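# Structured ingestion of per-model diagnostic output: ranked candidates with
# ICD-10 codes and confidences, plus hedging/confidence marker counts scored
# against a declared lexicon. JSONL in, validated response objects out.

dx_statuses <- c("ok", "timeout", "overflow", "error")

#' Default hedging / confidence marker lexicon
#'
#' Marker counts are lexicon-dependent, so the lexicon is explicit data:
#' this default is shipped with the package and fully user-overridable via
#' [read_lexicon()]. Phrases are matched case-insensitively, longest match
#' first, without overlap, at word boundaries.
#'
#' @return A `dx_lexicon`: list with character vectors `uncertainty` and
#'   `confidence`.
#' @export
default_lexicon <- function() {
  validate_lexicon(list(
    uncertainty = c("may", "might", "possibly", "uncertain",
                    "cannot rule out", "unclear", "suspected"),
    confidence = c("clearly", "definitive", "consistent with",
                   "classic", "certain")
  ))
}

validate_lexicon <- function(lex) {
  unc <- tolower(trimws(as.character(lex$uncertainty %||% character(0))))
  conf <- tolower(trimws(as.character(lex$confidence %||% character(0))))
  if (any(!nzchar(c(unc, conf)))) {
    stop_validation("lexicon contains an empty phrase")
  }
  both <- intersect(unc, conf)
  if (length(both) > 0L) {
    stop_validation(sprintf("lexicon term lists are not disjoint: %s",
                            paste(both, collapse = ", ")))
  }
  structure(list(uncertainty = unc, confidence = conf),
            class = "dx_lexicon")
}

#' Read a marker lexicon from YAML
#'
#' Expects a mapping with `uncertainty:` and `confidence:` phrase lists.
#'
#' @param path YAML file path.
#' @return A validated `dx_lexicon`.
#' @export
read_lexicon <- function(path) {
  doc <- yaml::read_yaml(path)
  validate_lexicon(doc)
}

#' Validate and normalize ICD-10(-CM) codes
#'
#' Accepts both ICD-10 and ICD-10-CM shapes: one letter, two digits, and an
#' optional dot followed by one to four alphanumerics (`M04.1`, `F15.959`,
#' `T56.0X1A`, `I30`). Normalization is uppercasing plus whitespace trimming.
#' Invalid codes are reported, never raised: callers decide severity.
#'
#' @param code Character vector of candidate codes.
#' @return A data frame with columns `code` (input), `normalized`, `valid`.
#' @export
#' @examples
#' validate_icd10(c("M04.1", "f15.959", "XYZ"))
validate_icd10 <- function(code) {
  normalized <- toupper(trimws(as.character(code)))
  valid <- grepl("^[A-Z][0-9]{2}(\\.[A-Z0-9]{1,4})?$", normalized)
  data.frame(code = as.character(code), normalized = normalized,
             valid = valid, stringsAsFactors = FALSE)
}

.dx_pattern_cache <- new.env(parent = emptyenv())

marker_pattern <- function(phrases) {
  # escape any regex metacharacter (everything non-alphanumeric)
  escaped <- gsub("([^a-zA-Z0-9 ])", "\\\\\\1",
                  phrases[order(-nchar(phrases))], perl = TRUE)
  escaped <- gsub(" +", "\\\\s+", escaped)
  paste0("(?<![a-zA-Z0-9])(?:", paste(escaped, collapse = "|"),
         ")(?![a-zA-Z0-9])")
}

#' Count uncertainty and confidence markers in text
#'
#' Case-insensitive, non-overlapping, longest-match-first phrase counting:
#' "cannot rule out" is one uncertainty marker, and its "out" is not
#' re-counted. Counts are total occurrences, not distinct terms. Matches are
#' word-bounded so "may" does not fire inside "maybe", and "certain" does
#' not fire inside "uncertain".
#'
#' @param text A single character string (`NA`/`NULL` counts as empty).
#' @param lexicon A `dx_lexicon` (default [default_lexicon()]).
#' @return Named integer vector `c(uncertainty = , confidence = )`.
#' @export
#' @examples
#' count_markers("possibly myocarditis; cannot rule out FMF")
count_markers <- function(text, lexicon = default_lexicon()) {
  if (!inherits(lexicon, "dx_lexicon")) {
    lexicon <- validate_lexicon(unclass(lexicon))
  }
  empty <- c(uncertainty = 0L, confidence = 0L)
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(text)) {
    return(empty)
  }
  phrases <- c(lexicon$uncertainty, lexicon$confidence)
  # compiled pattern cached per lexicon (counting runs per response)
  key <- paste(phrases, collapse = "\r")
  pat <- .dx_pattern_cache[[key]]
  if (is.null(pat)) {
    pat <- marker_pattern(phrases)
    .dx_pattern_cache[[key]] <- pat
  }
  m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  hits <- tolower(regmatches(text, list(m))[[1]])
  hits <- gsub("\\s+", " ", hits)
  c(uncertainty = sum(hits %in% lexicon$uncertainty),
    confidence = sum(hits %in% lexicon$confidence))
}

new_candidate <- function(label, icd10_codes = character(0),
                          confidence = NA_real_, rank = NA_integer_,
                          rationale_text = NULL) {
  list(label = label, icd10_codes = icd10_codes, confidence = confidence,
       rank = rank, rationale_text = rationale_text)
}

validate_candidate <- function(cand, idx = NA_integer_) {
  label <- cand$label
  if (!is_scalar_string(label) || !nzchar(label)) {
    stop_validation(sprintf("candidate %s: missing or empty 'label'", idx))
  }
  conf <- cand$confidence
  if (is.null(conf) || length(conf) != 1L || is.na(suppressWarnings(as.numeric(conf)))) {
    stop_validation(sprintf("candidate %s ('%s'): missing required field 'confidence'",
                            idx, label))
  }
  conf <- as.numeric(conf)
  if (conf < 0 || conf > 100) {
    stop_validation(sprintf("candidate %s ('%s'): confidence %s outside [0, 100]",
                            idx, label, conf))
  }
  # percent inputs auto-detected by value > 1; stored as fraction
  if (conf > 1) conf <- conf / 100
  rank <- cand$rank
  if (is.null(rank) || length(rank) != 1L || is.na(suppressWarnings(as.integer(rank))) ||
      as.integer(rank) < 1L) {
    stop_validation(sprintf("candidate %s ('%s'): rank must be a positive integer",
                            idx, label))
  }
  codes <- as.character(unlist(cand$icd10_codes %||% character(0)))
  if (length(codes) > 0L) {
    chk <- validate_icd10(codes)
    if (any(!chk$valid)) {
      stop_validation(sprintf("candidate %s ('%s'): invalid ICD-10 code(s): %s",
                              idx, label,
                              paste(chk$code[!chk$valid], collapse = ", ")))
    }
    codes <- chk$normalized
  }
  rationale <- cand$rationale_text
  if (!is.null(rationale)) rationale <- as.character(rationale)[1]
  new_candidate(label = label, icd10_codes = codes, confidence = conf,
                rank = as.integer(rank), rationale_text = rationale)
}

new_response <- function(model_id, case_id, status = "ok",
                         candidates = list(), raw_text = NULL,
                         uncertainty_marker_count = 0L,
                         confidence_marker_count = 0L) {
  structure(
    list(model_id = model_id, case_id = case_id, status = status,
         candidates = candidates, raw_text = raw_text,
         uncertainty_marker_count = as.integer(uncertainty_marker_count),
         confidence_marker_count = as.integer(confidence_marker_count)),
    class = "dx_response"
  )
}

#' Parse one model-response record
#'
#' Turns one decoded JSONL record into a validated `dx_response`. Candidates
#' are required when `status == "ok"` (an explicitly empty list is allowed),
#' ranks must be strictly increasing, confidences given as percent (e.g. 75)
#' are normalized to fractions (0.75), and ICD-10 codes are validated and
#' normalized. Marker counts are computed from `raw_text` when present
#' (zero when absent) using the supplied lexicon.
#'
#' @param record A named list (one decoded JSONL line) carrying at least
#'   `model_id`, `case_id`, `status`.
#' @param lexicon A `dx_lexicon` used for marker counting.
#' @return A `dx_response`.
#' @export
parse_response <- function(record, lexicon = default_lexicon()) {
  for (field in c("model_id", "case_id", "status")) {
    if (!is_scalar_string(record[[field]] %||% NA_character_)) {
      stop_validation(sprintf("response record: missing required field '%s'",
                              field))
    }
  }
  status <- record$status
  if (!status %in% dx_statuses) {
    stop_validation(sprintf("response record (%s/%s): unknown status '%s' (valid: %s)",
                            record$model_id, record$case_id, status,
                            paste(dx_statuses, collapse = ", ")))
  }
  if (status == "ok" && is.null(record$candidates)) {
    stop_validation(sprintf(
      "response record (%s/%s): status 'ok' requires a candidates list (may be empty)",
      record$model_id, record$case_id))
  }
  cands <- list()
  if (!is.null(record$candidates) && length(record$candidates) > 0L) {
    cands <- lapply(seq_along(record$candidates), function(i) {
      validate_candidate(record$candidates[[i]], idx = i)
    })
    ranks <- vapply(cands, function(cc) cc$rank, integer(1))
    if (any(diff(ranks) <= 0L)) {
      stop_validation(sprintf(
        "response record (%s/%s): candidate ranks must be strictly increasing (got %s)",
        record$model_id, record$case_id, paste(ranks, collapse = ",")))
    }
  }
  raw_text <- record$raw_text
  if (!is.null(raw_text)) raw_text <- as.character(raw_text)[1]
  if (!is.null(raw_text) && !is.na(raw_text)) {
    counts <- count_markers(raw_text, lexicon)
  } else {
    counts <- c(
      uncertainty = as.integer(record$uncertainty_marker_count %||% 0L),
      confidence = as.integer(record$confidence_marker_count %||% 0L)
    )
    if (any(is.na(counts)) || any(counts < 0L)) {
      stop_validation("marker counts must be non-negative integers")
    }
  }
  new_response(model_id = record$model_id, case_id = record$case_id,
               status = status, candidates = cands, raw_text = raw_text,
               uncertainty_marker_count = counts[["uncertainty"]],
               confidence_marker_count = counts[["confidence"]])
}

response_to_record <- function(resp) {
  rec <- list(model_id = resp$model_id, case_id = resp$case_id,
              status = resp$status)
  rec$candidates <- lapply(resp$candidates, function(cc) {
    r <- list(label = cc$label, icd10_codes = I(cc$icd10_codes),
              confidence = cc$confidence, rank = cc$rank)
    if (!is.null(cc$rationale_text)) r$rationale_text <- cc$rationale_text
    r
  })
  if (!is.null(resp$raw_text)) rec$raw_text <- resp$raw_text
  rec$uncertainty_marker_count <- resp$uncertainty_marker_count
  rec$confidence_marker_count <- resp$confidence_marker_count
  rec
}

#' Write responses to JSONL
#'
#' One response per line; [read_responses()] is a left inverse on valid
#' records.
#'
#' @param responses List of `dx_response` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  lines <- vapply(responses, function(r) {
    as.character(jsonlite::toJSON(response_to_record(r), auto_unbox = TRUE,
                                  digits = NA, null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read responses from JSONL
#'
#' @param path JSONL file, one response record per line.
#' @param lexicon A `dx_lexicon` used to score `raw_text`.
#' @return List of `dx_response` objects.
#' @export
read_responses <- function(path, lexicon = default_lexicon()) {
  if (!file.exists(path)) {
    stop_dependency(sprintf("responses file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parse_response(jsonlite::fromJSON(ln, simplifyVector = FALSE), lexicon)
  })
}

#' Construct a clinical case
#'
#' @param case_id Unique case identifier.
#' @param presentation_text Non-empty free-text presentation.
#' @param demographics Optional named list (age, sex, origin,
#'   social_context).
#' @param truth_label Optional canonical diagnosis label (simulation only).
#' @return A `dx_case`.
#' @export
clinical_case <- function(case_id, presentation_text, demographics = list(),
                          truth_label = NULL) {
  if (!is_scalar_string(case_id) || !nzchar(case_id)) {
    stop_validation("case_id must be a non-empty string")
  }
  if (!is_scalar_string(presentation_text) || !nzchar(presentation_text)) {
    stop_validation(sprintf("case %s: presentation_text must be non-empty",
                            case_id))
  }
  structure(list(case_id = case_id, presentation_text = presentation_text,
                 demographics = demographics, truth_label = truth_label),
            class = "dx_case")
}

#' Read a clinical case set from JSON or YAML
#'
#' @param path File with a list of case mappings.
#' @return List of `dx_case` objects with unique `case_id`s.
#' @export
read_cases <- function(path) {
  docs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  cases <- lapply(docs, function(d) {
    clinical_case(d$case_id, d$presentation_text,
                  d$demographics %||% list(), d$truth_label)
  })
  ids <- vapply(cases, function(cc) cc$case_id, character(1))
  if (anyDuplicated(ids)) {
    stop_validation(sprintf("duplicate case_id in case set: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  cases
}

#' @export
print.dx_response <- function(x, ...) {
  cat(sprintf("<dx_response> %s / %s [%s], %d candidate(s), markers u=%d c=%d\n",
              x$model_id, x$case_id, x$status, length(x$candidates),
              x$uncertainty_marker_count, x$confidence_marker_count))
  invisible(x)
}
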