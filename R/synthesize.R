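# Plurality-preserving report construction with provenance annotations,
# progressive-disclosure rendering, and the failover synthesizer chain.
# Report assembly is template-based and deterministic: the chain abstraction
# still models failover for any pluggable backend, but the shipped
# synthesizer never averages anything away.

#' Summary uncertainty indicator from a consensus rate
#'
#' Bands bracket the consensus range the stratification typically produces:
#' `"high"` at >= 80% consensus, `"moderate"` at 60-79%, `"low"` below 60%,
#' `"unknown"` when no consensus rate exists.
#'
#' @param consensus_pct Consensus rate in percent (may be `NA`).
#' @param high,moderate Band boundaries in percent.
#' @return One of `"high"`, `"moderate"`, `"low"`, `"unknown"`.
#' @export
uncertainty_band <- function(consensus_pct, high = 80, moderate = 60) {
  if (is.null(consensus_pct) || is.na(consensus_pct)) return("unknown")
  if (consensus_pct >= high) "high" else if (consensus_pct >= moderate) "moderate" else "low"
}

provenance_note <- function(ids, registry) {
  if (is.null(registry)) return(ids)
  idx <- match(ids, registry$model_id)
  vapply(seq_along(ids), function(i) {
    if (is.na(idx[i])) return(ids[i])
    sprintf("%s (%s, %s)", ids[i], registry$origin_region[idx[i]],
            registry$cost_tier[idx[i]])
  }, character(1))
}

cluster_entry <- function(cl, registry) {
  list(label = cl$canonical_label,
       codes = cl$icd10_codes,
       agreement_pct = round(100 * cl$agreement_rate, 1),
       mean_confidence = round(cl$mean_confidence, 3),
       supporters = cl$supporting_model_ids,
       provenance = provenance_note(cl$supporting_model_ids, registry))
}

disagreement_notes <- function(differential, registry) {
  if (is.null(registry)) return(list())
  notes <- list()
  for (s in c("ALTERNATIVE", "MINORITY")) {
    for (cl in differential$strata[[s]]) {
      ids <- cl$supporting_model_ids
      idx <- match(ids, registry$model_id)
      regions <- unique(registry$origin_region[idx[!is.na(idx)]])
      tiers <- unique(registry$cost_tier[idx[!is.na(idx)]])
      if (length(regions) == 1L && !is.na(regions)) {
        notes[[length(notes) + 1L]] <- list(
          label = cl$canonical_label, stratum = s,
          characteristic = sprintf("origin_region=%s", regions),
          note = sprintf("'%s' is supported only by %s-origin model(s): %s",
                         cl$canonical_label, regions,
                         paste(ids, collapse = ", ")))
      } else if (length(tiers) == 1L && !is.na(tiers)) {
        notes[[length(notes) + 1L]] <- list(
          label = cl$canonical_label, stratum = s,
          characteristic = sprintf("cost_tier=%s", tiers),
          note = sprintf("'%s' is supported only by %s-tier model(s): %s",
                         cl$canonical_label, tiers,
                         paste(ids, collapse = ", ")))
      }
    }
  }
  notes
}

#' Build a plurality-preserving diagnostic report
#'
#' Full mode carries all three strata with provenance annotations and
#' disagreement notes; nothing is averaged away, and minority entries are
#' never omitted. Summary mode (progressive disclosure) carries only the
#' top PRIMARY entry plus the summary uncertainty indicator, with an
#' explicit pointer to the full report. With an empty PRIMARY stratum the
#' report leads with a no-consensus banner and the highest-rate cluster;
#' with no clusters at all it carries an explicit no-candidates marker
#' rather than raising.
#'
#' @param differential A `dx_differential`.
#' @param registry Optional `dx_registry` for provenance annotations.
#' @param attribution Optional list of `dx_bias_summary` objects to attach.
#' @param mode `"full"` or `"summary"`.
#' @param bands Uncertainty-indicator boundaries in percent,
#'   `c(high = 80, moderate = 60)`.
#' @param generated_at Optional timestamp string. Default `NULL` (omitted)
#'   so that report content is a pure function of its inputs.
#' @param synthesizer_used Identifier of the synthesizer that produced the
#'   report.
#' @return A `dx_report`.
#' @export
build_report <- function(differential, registry = NULL, attribution = NULL,
                         mode = c("full", "summary"),
                         bands = c(high = 80, moderate = 60),
                         generated_at = NULL,
                         synthesizer_used = "deterministic-template") {
  mode <- match.arg(mode)
  cls <- all_clusters(differential)
  consensus_pct <- if (length(cls) > 0L) {
    100 * max(vapply(cls, function(cl) cl$agreement_rate, numeric(1)))
  } else {
    NA_real_
  }
  indicator <- uncertainty_band(consensus_pct, bands[["high"]],
                                bands[["moderate"]])
  banner <- NULL
  no_candidates <- length(cls) == 0L
  primary <- differential$strata$PRIMARY
  if (no_candidates) {
    banner <- "no candidates: no model proposed any diagnosis for this case"
  } else if (length(primary) == 0L) {
    banner <- "no consensus: no diagnosis reached the primary agreement threshold"
  }

  entries <- function(stratum) {
    lapply(differential$strata[[stratum]], cluster_entry, registry = registry)
  }
  if (mode == "full") {
    consensus_section <- entries("PRIMARY")
    if (length(primary) == 0L && !no_candidates) {
      # lead with the highest-rate cluster so the banner is actionable
      top <- majority_cluster(differential)
      consensus_section <- list(cluster_entry(top, registry))
    }
    alternatives_section <- entries("ALTERNATIVE")
    minority_section <- entries("MINORITY")
    notes <- disagreement_notes(differential, registry)
    expansion_note <- NULL
  } else {
    top <- majority_cluster(differential)
    consensus_section <- if (is.null(top)) list() else
      list(cluster_entry(top, registry))
    alternatives_section <- list()
    minority_section <- list()
    notes <- list()
    expansion_note <- "alternatives and minority findings withheld in summary mode; render with mode='full' to expand"
  }

  structure(
    list(case_id = differential$case_id,
         generated_at = generated_at,
         render_mode = mode,
         synthesizer_used = synthesizer_used,
         consensus_rate_pct = consensus_pct,
         uncertainty_indicator = indicator,
         banner = banner,
         no_candidates = no_candidates,
         consensus_section = consensus_section,
         alternatives_section = alternatives_section,
         minority_section = minority_section,
         disagreement_notes = notes,
         expansion_note = expansion_note,
         attribution = attribution,
         total_models = differential$total_models,
         responding_models = differential$responding_models),
    class = "dx_report"
  )
}

render_entry_md <- function(e) {
  codes <- if (length(e$codes) > 0L) {
    sprintf(" (%s)", paste(e$codes, collapse = ", "))
  } else ""
  sprintf("- **%s**%s -- agreement %s%%; supported by: %s",
          e$label, codes, format(e$agreement_pct),
          paste(e$provenance, collapse = "; "))
}

#' Render a report as Markdown or JSON
#'
#' Markdown is human-readable with one heading per stratum (full mode).
#' JSON round-trips losslessly through [read_report()].
#'
#' @param report A `dx_report`.
#' @param format `"markdown"` or `"json"`.
#' @return A character scalar (the document).
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  if (length(format) == 1L && !format %in% c("markdown", "json")) {
    stop_validation(sprintf("unknown render format '%s' (valid formats: markdown, json)",
                            format))
  }
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)))
  }
  lines <- c(sprintf("# Differential diagnosis report -- case %s",
                     report$case_id),
             "",
             sprintf("Uncertainty indicator: **%s** (consensus %s%%); synthesizer: %s; models responding: %s/%s",
                     report$uncertainty_indicator,
                     if (is.na(report$consensus_rate_pct)) "NA" else
                       format(round(report$consensus_rate_pct)),
                     report$synthesizer_used,
                     report$responding_models, report$total_models))
  if (!is.null(report$banner)) {
    lines <- c(lines, "", sprintf("> %s", toupper(report$banner)))
  }
  lines <- c(lines, "", "## Consensus (PRIMARY)", "")
  lines <- c(lines, if (length(report$consensus_section) > 0L) {
    vapply(report$consensus_section, render_entry_md, character(1))
  } else "- none")
  if (report$render_mode == "full") {
    lines <- c(lines, "", "## Alternatives (ALTERNATIVE)", "")
    lines <- c(lines, if (length(report$alternatives_section) > 0L) {
      vapply(report$alternatives_section, render_entry_md, character(1))
    } else "- none")
    lines <- c(lines, "", "## Minority findings (MINORITY)", "")
    lines <- c(lines, if (length(report$minority_section) > 0L) {
      vapply(report$minority_section, render_entry_md, character(1))
    } else "- none")
    if (length(report$disagreement_notes) > 0L) {
      lines <- c(lines, "", "### Disagreement notes", "")
      lines <- c(lines, vapply(report$disagreement_notes,
                               function(nn) sprintf("- %s", nn$note),
                               character(1)))
    }
  } else {
    lines <- c(lines, "", sprintf("_%s_", report$expansion_note))
  }
  paste(lines, collapse = "\n")
}

# canonical plain-list form used for JSON serialization and round-trip
# comparison
report_to_list <- function(report) {
  x <- unclass(report)
  x$consensus_section <- lapply(x$consensus_section, entry_to_list)
  x$alternatives_section <- lapply(x$alternatives_section, entry_to_list)
  x$minority_section <- lapply(x$minority_section, entry_to_list)
  x$attribution <- NULL  # attribution summaries serialize separately
  x[!vapply(x, is.null, logical(1))]
}

entry_to_list <- function(e) {
  list(label = e$label, codes = I(as.character(e$codes)),
       agreement_pct = e$agreement_pct, mean_confidence = e$mean_confidence,
       supporters = I(as.character(e$supporters)),
       provenance = I(as.character(e$provenance)))
}

#' Read a JSON report back into a `dx_report`
#'
#' @param json A JSON string or path to a JSON report file.
#' @return A `dx_report` whose canonical list form equals the one that was
#'   rendered.
#' @export
read_report <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fix_entry <- function(e) {
    list(label = e$label, codes = as.character(unlist(e$codes)),
         agreement_pct = as.numeric(e$agreement_pct),
         mean_confidence = as.numeric(e$mean_confidence),
         supporters = as.character(unlist(e$supporters)),
         provenance = as.character(unlist(e$provenance)))
  }
  x$consensus_section <- lapply(x$consensus_section, fix_entry)
  x$alternatives_section <- lapply(x$alternatives_section, fix_entry)
  x$minority_section <- lapply(x$minority_section, fix_entry)
  x$disagreement_notes <- lapply(x$disagreement_notes, function(nn) {
    lapply(nn, function(v) if (is.list(v)) unlist(v) else v)
  })
  x$consensus_rate_pct <- if (is.null(x$consensus_rate_pct)) NA_real_ else
    as.numeric(x$consensus_rate_pct)
  structure(x, class = "dx_report")
}

#' Define a synthesizer failover chain
#'
#' An ordered list of synthesis backends tried in sequence until one
#' succeeds, each with a per-attempt timeout.
#'
#' @param ids Character vector of unique synthesizer ids, tried in order.
#' @param timeout Per-attempt timeout in seconds (recycled across ids).
#' @return A `dx_synth_chain`.
#' @export
synthesizer_chain <- function(ids, timeout = 30) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop_validation("synthesizer chain must be non-empty")
  if (anyDuplicated(ids)) {
    stop_validation("synthesizer chain ids must be unique")
  }
  structure(list(ids = ids,
                 timeout = rep_len(as.numeric(timeout), length(ids))),
            class = "dx_synth_chain")
}

#' Default three-member synthesizer chain
#'
#' A primary synthesis engine with two backups, mirroring the usual
#' deployment of one preferred backend plus failover options.
#'
#' @param timeout Per-attempt timeout in seconds.
#' @return A `dx_synth_chain` of length 3.
#' @export
default_synthesizer_chain <- function(timeout = 30) {
  synthesizer_chain(c("claude-3.5-sonnet", "gpt-4o", "gemini-2.0-pro"),
                    timeout = timeout)
}

#' Select a synthesizer by walking the failover chain
#'
#' Ids are tried in chain order; the first whose availability check
#' succeeds is chosen. Every failed attempt is logged with its cause. If
#' all attempts fail, a `dx_failover_error` is raised carrying the complete
#' attempt log. Deterministic for a fixed availability pattern.
#'
#' @param chain A `dx_synth_chain`.
#' @param availability Named list or vector keyed by synthesizer id; each
#'   value is `TRUE`/`FALSE` or a zero-argument function returning `TRUE`
#'   on success (a thrown error or non-`TRUE` value counts as failure, with
#'   the error message recorded as the cause). Ids absent from
#'   `availability` count as unavailable.
#' @return List with `chosen` (id) and `attempts` (data frame
#'   `synthesizer_id`, `outcome`, `cause`).
#' @export
select_synthesizer <- function(chain, availability) {
  attempts <- data.frame(synthesizer_id = character(0), outcome = character(0),
                         cause = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(chain$ids)) {
    id <- chain$ids[i]
    av <- if (id %in% names(availability)) availability[[id]] else NULL
    result <- if (is.null(av)) {
      list(ok = FALSE, cause = "availability unknown")
    } else if (is.function(av)) {
      tryCatch({
        v <- av()
        if (isTRUE(v)) list(ok = TRUE, cause = NA_character_)
        else list(ok = FALSE, cause = "availability check returned non-TRUE")
      }, error = function(e) list(ok = FALSE, cause = conditionMessage(e)))
    } else if (isTRUE(av)) {
      list(ok = TRUE, cause = NA_character_)
    } else {
      list(ok = FALSE, cause = "unavailable")
    }
    attempts <- rbind(attempts, data.frame(
      synthesizer_id = id,
      outcome = if (result$ok) "success" else "failed",
      cause = result$cause, stringsAsFactors = FALSE))
    if (result$ok) {
      return(list(chosen = id, attempts = attempts))
    }
  }
  stop_failover(sprintf("all %d synthesizer(s) in the chain failed",
                        length(chain$ids)),
                data = list(attempts = attempts))
}

#' @export
print.dx_report <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}
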