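# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles deliberately use different mechanisms from the implementation
# (character-level scans, pairwise closure, direct inequality evaluation).

empty_aliases <- structure(list(), class = "dx_alias_table")

make_candidate <- function(label, codes = character(0), confidence = 0.8,
                           rank = 1L, rationale = NULL) {
  list(label = label, icd10_codes = codes, confidence = confidence,
       rank = rank, rationale_text = rationale)
}

make_response <- function(model_id, case_id = "c1", candidates = list(),
                          status = "ok", raw_text = NULL) {
  if (is.character(candidates)) {
    candidates <- lapply(seq_along(candidates), function(i) {
      make_candidate(candidates[i], rank = i,
                     confidence = round(0.9 * 0.95^(i - 1), 4))
    })
  }
  rec <- list(model_id = model_id, case_id = case_id, status = status,
              candidates = candidates, raw_text = raw_text)
  if (status != "ok" && length(candidates) == 0L) rec$candidates <- NULL
  parse_response(rec)
}

make_registry <- function(model_id,
                          origin_region = rep("US", length(model_id)),
                          cost_tier = rep("free", length(model_id)),
                          parameter_class = NA_character_) {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(model_id = model_id, provider = "test",
                   origin_region = origin_region, cost_tier = cost_tier,
                   release_date = "", parameter_class = parameter_class,
                   architecture_family = "", intended_scope = "",
                   stringsAsFactors = FALSE)
  df$parameter_class[is.na(df$parameter_class)] <- ""
  utils::write.csv(df, f, row.names = FALSE)
  reg <- suppressMessages(suppressWarnings(load_registry(f)))
  unlink(f)
  reg
}

# --- independent oracles -------------------------------------------------

# character-position scan, longest phrase first, word-bounded, greedy.
oracle_count_markers <- function(text, lexicon = default_lexicon()) {
  out <- c(uncertainty = 0L, confidence = 0L)
  if (is.null(text) || !nzchar(text)) return(out)
  lo <- tolower(text)
  phrases <- c(lexicon$uncertainty, lexicon$confidence)
  kind <- rep(c("uncertainty", "confidence"),
              c(length(lexicon$uncertainty), length(lexicon$confidence)))
  ord <- order(-nchar(phrases))
  phrases <- phrases[ord]; kind <- kind[ord]
  is_alnum <- function(ch) grepl("[a-z0-9]", ch)
  i <- 1L
  n <- nchar(lo)
  while (i <= n) {
    matched <- FALSE
    for (p in seq_along(phrases)) {
      ph <- phrases[p]
      lp <- nchar(ph)
      if (i + lp - 1L > n) next
      if (substr(lo, i, i + lp - 1L) != ph) next
      before_ok <- i == 1L || !is_alnum(substr(lo, i - 1L, i - 1L))
      after_ok <- i + lp > n || !is_alnum(substr(lo, i + lp, i + lp))
      if (before_ok && after_ok) {
        out[kind[p]] <- out[kind[p]] + 1L
        i <- i + lp
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  out
}

# pairwise merge rules + breadth-first transitive closure over candidates
oracle_components <- function(cands, aliases = empty_aliases) {
  n <- length(cands)
  if (n == 0L) return(list())
  roots <- local({
    r <- character(0)
    for (canon in names(aliases)) {
      r[canon] <- canon
      for (al in aliases[[canon]]) r[al] <- canon
    }
    r
  })
  root_of <- function(x) {
    hit <- roots[x]
    ifelse(is.na(hit), x, hit)
  }
  keyset <- lapply(cands, function(cc) {
    ca <- canonicalize_label(cc$label, return_alias = TRUE)
    ks <- root_of(ca$canonical)
    if (!is.na(ca$alias)) ks <- c(ks, root_of(ca$alias))
    list(concepts = ks, codes = toupper(cc$codes %||% character(0)))
  })
  linked <- function(a, b) {
    length(intersect(keyset[[a]]$concepts, keyset[[b]]$concepts)) > 0L ||
      length(intersect(keyset[[a]]$codes, keyset[[b]]$codes)) > 0L
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      a <- queue[1]; queue <- queue[-1]
      for (b in seq_len(n)) {
        if (is.na(comp[b]) && linked(a, b)) {
          comp[b] <- cid
          queue <- c(queue, b)
        }
      }
    }
  }
  split(seq_len(n), comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct inequality evaluation of the stratum thresholds
oracle_stratum <- function(k, denom, primary = 0.30, alternative = 0.10) {
  rate <- k / denom
  if (rate >= primary) "PRIMARY" else if (rate >= alternative) "ALTERNATIVE" else "MINORITY"
}

oracle_model_category <- function(rate, high = 0.60, moderate = 0.30) {
  if (is.na(rate)) "low" else if (rate >= high) "high" else if (rate >= moderate) "moderate" else "low"
}

# flat map cluster -> stratum from a differential, keyed by canonical label
strata_of <- function(differential) {
  out <- character(0)
  for (s in names(differential$strata)) {
    for (cl in differential$strata[[s]]) {
      out[cl$canonical_label] <- s
    }
  }
  out
}

# case set where model m aligns with the majority on exactly
# aligned_per_model[[m]] of n_cases cases; anchors pin the majority cluster
align_fixture <- function(aligned_per_model, n_cases) {
  anchors <- c("anchor1", "anchor2", "anchor3")
  case_ids <- sprintf("case%02d", seq_len(n_cases))
  case_responses <- list()
  for (ci in seq_len(n_cases)) {
    rs <- lapply(anchors, function(a) {
      make_response(a, case_ids[ci], "Majority Dx")
    })
    for (m in names(aligned_per_model)) {
      lab <- if (ci <= aligned_per_model[[m]]) "Majority Dx" else
        paste("Unique", m)
      rs[[length(rs) + 1L]] <- make_response(m, case_ids[ci], lab)
    }
    case_responses[[case_ids[ci]]] <- rs
  }
  diffs <- lapply(case_responses, stratify_case, aliases = empty_aliases)
  categorize_model_consensus(case_responses, diffs)
}

# small random ensemble of responses for property tests
random_ensemble <- function(n_models, diagnoses, p = 0.5) {
  lapply(seq_len(n_models), function(j) {
    picked <- diagnoses[stats::runif(length(diagnoses)) < p]
    make_response(sprintf("m%02d", j), candidates = picked)
  })
}
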