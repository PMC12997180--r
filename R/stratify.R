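# Agreement-rate stratification: the orchestration core. Every unique
# (clustered) diagnosis gets an agreement rate, is classified into
# PRIMARY / ALTERNATIVE / MINORITY strata, and models themselves are
# categorized by how often they align with the per-case majority.

dx_strata <- c("PRIMARY", "ALTERNATIVE", "MINORITY")

#' Stratification thresholds and policies
#'
#' Defaults implement the orchestration boundaries: a diagnosis is PRIMARY
#' at agreement rate >= 0.30, ALTERNATIVE in \[0.10, 0.30), MINORITY below
#' 0.10; a model is high-consensus at majority-alignment >= 0.60, moderate
#' in \[0.30, 0.60), low below 0.30.
#'
#' The agreement-rate denominator defaults to models that actually responded
#' (`status == "ok"`): counting silent timeouts/overflows as disagreement
#' would bias every rate downward. The literal all-queried behaviour is
#' available via `denominator_policy = "all_queried_models"`.
#'
#' @param primary_threshold PRIMARY boundary (inclusive), default 0.30.
#' @param alternative_threshold ALTERNATIVE lower boundary (inclusive),
#'   default 0.10.
#' @param model_high_threshold High-consensus model boundary (inclusive),
#'   default 0.60.
#' @param model_moderate_threshold Moderate-consensus lower boundary
#'   (inclusive), default 0.30.
#' @param denominator_policy `"responding_models"` (default) or
#'   `"all_queried_models"`.
#' @return A `dx_strat_config`.
#' @export
stratification_config <- function(primary_threshold = 0.30,
                                  alternative_threshold = 0.10,
                                  model_high_threshold = 0.60,
                                  model_moderate_threshold = 0.30,
                                  denominator_policy = c("responding_models",
                                                         "all_queried_models")) {
  denominator_policy <- match.arg(denominator_policy)
  if (!(alternative_threshold > 0 && alternative_threshold < primary_threshold &&
        primary_threshold <= 1)) {
    stop_validation("need 0 < alternative_threshold < primary_threshold <= 1")
  }
  if (!(model_moderate_threshold > 0 &&
        model_moderate_threshold < model_high_threshold &&
        model_high_threshold <= 1)) {
    stop_validation("need 0 < model_moderate_threshold < model_high_threshold <= 1")
  }
  structure(list(primary_threshold = primary_threshold,
                 alternative_threshold = alternative_threshold,
                 model_high_threshold = model_high_threshold,
                 model_moderate_threshold = model_moderate_threshold,
                 denominator_policy = denominator_policy),
            class = "dx_strat_config")
}

#' Compute per-cluster agreement rates
#'
#' `agreement_rate = |supporting models| / denominator`, where the
#' denominator follows `config$denominator_policy`. Rates are always in
#' (0, 1].
#'
#' @param clusters List of `dx_cluster` objects.
#' @param total_models Number of models queried.
#' @param responding_models Number of models with `status == "ok"`.
#' @param config A `dx_strat_config`.
#' @return The clusters with `agreement_rate` set.
#' @export
compute_agreement_rates <- function(clusters, total_models,
                                    responding_models,
                                    config = stratification_config()) {
  denom <- switch(config$denominator_policy,
                  responding_models = responding_models,
                  all_queried_models = total_models)
  if (is.null(denom) || is.na(denom) || denom < 1L) {
    stop_validation("agreement-rate denominator must be >= 1")
  }
  lapply(clusters, function(cl) {
    k <- length(cl$supporting_model_ids)
    if (k > denom) {
      stop_validation(sprintf(
        "cluster '%s' has %d supporters but denominator is %d",
        cl$canonical_label, k, denom))
    }
    cl$agreement_rate <- k / denom
    cl
  })
}

classify_rate <- function(rate, config) {
  ifelse(rate >= config$primary_threshold, "PRIMARY",
         ifelse(rate >= config$alternative_threshold, "ALTERNATIVE",
                "MINORITY"))
}

order_clusters <- function(clusters) {
  if (length(clusters) == 0L) return(clusters)
  rate <- vapply(clusters, function(cl) cl$agreement_rate, numeric(1))
  conf <- vapply(clusters, function(cl) cl$mean_confidence, numeric(1))
  lab <- vapply(clusters, function(cl) cl$canonical_label, character(1))
  clusters[order(-rate, -conf, lab)]
}

#' Stratify clustered diagnoses into PRIMARY / ALTERNATIVE / MINORITY
#'
#' Threshold classification with inclusive boundaries: rate >= 0.30 is
#' PRIMARY, 0.10 <= rate < 0.30 is ALTERNATIVE, rate < 0.10 is MINORITY
#' (defaults; see [stratification_config()]). The strata partition the
#' cluster set, and each stratum is ordered by agreement rate descending,
#' then mean confidence descending, then canonical label ascending.
#'
#' @param clusters List of `dx_cluster` objects with `agreement_rate` set.
#' @param case_id Case identifier carried on the result.
#' @param total_models Number of models queried.
#' @param responding_models Number of models with `status == "ok"`.
#' @param config A `dx_strat_config`.
#' @return A `dx_differential`.
#' @export
stratify_differential <- function(clusters, case_id = NA_character_,
                                  total_models = NA_integer_,
                                  responding_models = NA_integer_,
                                  config = stratification_config()) {
  rates <- vapply(clusters, function(cl) cl$agreement_rate %||% NA_real_,
                  numeric(1))
  if (length(clusters) > 0L && any(is.na(rates))) {
    stop_validation("all clusters must carry an agreement_rate; run compute_agreement_rates() first")
  }
  strata <- stats::setNames(vector("list", length(dx_strata)), dx_strata)
  cls <- if (length(clusters) > 0L) classify_rate(rates, config) else character(0)
  for (s in dx_strata) {
    strata[[s]] <- order_clusters(clusters[cls == s])
  }
  structure(list(case_id = case_id, strata = strata,
                 total_models = total_models,
                 responding_models = responding_models,
                 config = config),
            class = "dx_differential")
}

#' Cluster and stratify one case's responses in one call
#'
#' Convenience wrapper: [cluster_candidates()] then
#' [compute_agreement_rates()] then [stratify_differential()].
#'
#' @param responses List of `dx_response` objects for one case.
#' @param total_models Number of models queried; defaults to
#'   `length(responses)`.
#' @param aliases A `dx_alias_table`.
#' @param config A `dx_strat_config`.
#' @param merge_icd10_category Passed to [cluster_candidates()].
#' @return A `dx_differential`.
#' @export
stratify_case <- function(responses, total_models = length(responses),
                          aliases = default_alias_table(),
                          config = stratification_config(),
                          merge_icd10_category = FALSE) {
  responding <- sum(vapply(responses, function(r) r$status == "ok", logical(1)))
  clusters <- cluster_candidates(responses, aliases = aliases,
                                 merge_icd10_category = merge_icd10_category)
  if (length(clusters) > 0L) {
    clusters <- compute_agreement_rates(clusters, total_models, responding,
                                        config)
  }
  case_id <- if (length(responses) > 0L) responses[[1]]$case_id else NA_character_
  stratify_differential(clusters, case_id = case_id,
                        total_models = total_models,
                        responding_models = responding, config = config)
}

all_clusters <- function(differential) {
  c(differential$strata$PRIMARY, differential$strata$ALTERNATIVE,
    differential$strata$MINORITY)
}

# The case's majority cluster: top PRIMARY cluster; if PRIMARY is empty,
# the highest-rate cluster overall. NULL when the case has no clusters.
majority_cluster <- function(differential) {
  if (length(differential$strata$PRIMARY) > 0L) {
    return(differential$strata$PRIMARY[[1]])
  }
  cls <- order_clusters(all_clusters(differential))
  if (length(cls) == 0L) return(NULL)
  cls[[1]]
}

#' Categorize models by majority alignment across a case set
#'
#' A model is "aligned" on a case iff any of its candidates belongs to that
#' case's majority cluster (`mode = "any_candidate"`, the default, since
#' models return ranked lists rather than single answers; `mode = "top1"`
#' counts only the model's rank-1 candidate). The majority alignment rate is
#' aligned cases / cases the model responded to, and the category follows
#' the thresholds: high at >= 0.60, moderate in \[0.30, 0.60), low below.
#'
#' @param case_responses Named list: case_id -> list of `dx_response`.
#' @param differentials Named list: case_id -> `dx_differential` (names must
#'   cover `case_responses`).
#' @param config A `dx_strat_config`.
#' @param mode `"any_candidate"` or `"top1"`.
#' @return A `dx_consensus` data frame: `model_id`, `cases_evaluated`,
#'   `aligned_cases`, `majority_alignment_rate`, `category`.
#' @export
categorize_model_consensus <- function(case_responses, differentials,
                                       config = stratification_config(),
                                       mode = c("any_candidate", "top1")) {
  mode <- match.arg(mode)
  if (length(case_responses) < 1L) {
    stop_validation("need at least one case")
  }
  if (is.null(names(case_responses)) || is.null(names(differentials)) ||
      !all(names(case_responses) %in% names(differentials))) {
    stop_validation("differentials must be named by case_id and cover all cases")
  }
  models <- sort(unique(unlist(lapply(case_responses, function(rs) {
    vapply(rs, function(r) r$model_id, character(1))
  }))))
  evaluated <- stats::setNames(integer(length(models)), models)
  aligned <- stats::setNames(integer(length(models)), models)
  for (cid in names(case_responses)) {
    maj <- majority_cluster(differentials[[cid]])
    if (is.null(maj)) next
    aligned_ids <- if (mode == "any_candidate") {
      maj$supporting_model_ids
    } else {
      unique(maj$members$model_id[maj$members$rank == 1L])
    }
    for (r in case_responses[[cid]]) {
      if (r$status != "ok") next
      evaluated[r$model_id] <- evaluated[r$model_id] + 1L
      if (r$model_id %in% aligned_ids) {
        aligned[r$model_id] <- aligned[r$model_id] + 1L
      }
    }
  }
  rate <- ifelse(evaluated > 0L, aligned / evaluated, NA_real_)
  if (any(evaluated == 0L)) {
    warning(sprintf("model(s) responded to zero cases: %s",
                    paste(models[evaluated == 0L], collapse = ", ")))
  }
  category <- ifelse(is.na(rate), "low",
                     ifelse(rate >= config$model_high_threshold, "high",
                            ifelse(rate >= config$model_moderate_threshold,
                                   "moderate", "low")))
  structure(
    data.frame(model_id = models, cases_evaluated = unname(evaluated),
               aligned_cases = unname(aligned),
               majority_alignment_rate = unname(rate),
               category = unname(category), stringsAsFactors = FALSE),
    class = c("dx_consensus", "data.frame")
  )
}

#' Per-case ensemble summary analytics
#'
#' Consensus rate (top-cluster agreement as percent), diagnostic breadth
#' (number of distinct clusters), alternative count (breadth - 1), and
#' marker totals summed over responses. With no clusters, breadth is 0 and
#' the consensus rate is `NA`.
#'
#' @param differential A `dx_differential`.
#' @param responses The case's `dx_response` list (for marker totals).
#' @return A one-row `dx_analytics` data frame.
#' @export
ensemble_summary <- function(differential, responses = list()) {
  cls <- all_clusters(differential)
  breadth <- length(cls)
  consensus <- if (breadth > 0L) {
    100 * max(vapply(cls, function(cl) cl$agreement_rate, numeric(1)))
  } else {
    NA_real_
  }
  u <- sum(vapply(responses, function(r) r$uncertainty_marker_count, integer(1)))
  cf <- sum(vapply(responses, function(r) r$confidence_marker_count, integer(1)))
  structure(
    data.frame(case_id = differential$case_id, consensus_rate = consensus,
               diagnostic_breadth = breadth,
               alternative_count = max(breadth - 1L, 0L),
               uncertainty_total = u, confidence_total = cf,
               stringsAsFactors = FALSE),
    class = c("dx_analytics", "data.frame")
  )
}

#' @export
print.dx_differential <- function(x, ...) {
  cat(sprintf("<dx_differential> case %s (%s/%s models responding)\n",
              x$case_id, x$responding_models, x$total_models))
  for (s in dx_strata) {
    cls <- x$strata[[s]]
    cat(sprintf("  %s (%d):", s, length(cls)))
    if (length(cls) > 0L) {
      cat(" ", paste(vapply(cls, function(cl) {
        sprintf("%s [%.0f%%]", cl$canonical_label, 100 * cl$agreement_rate)
      }, character(1)), collapse = "; "))
    }
    cat("\n")
  }
  invisible(x)
}
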