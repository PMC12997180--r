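# Bias attribution: map systematic output differences to documented model
# provenance. Mention rates per provenance group, cost-tier alignment with a
# bootstrap interval, hedging-vs-confidence balance, and the
# breadth-consensus association.

dx_bias_axes <- c("geographic", "temporal", "cost", "demographic",
                  "confidence_expression", "diagnostic_diversity")

new_bias_summary <- function(axis, target, group_stats, effect,
                             effect_descriptor, extra = list()) {
  structure(c(list(axis = axis, target = target, group_stats = group_stats,
                   effect = effect, effect_descriptor = effect_descriptor),
              extra),
            class = "dx_bias_summary")
}

#' Mentions per model of a target diagnosis, by provenance group
#'
#' Counts how many times each provenance group's models mention a target
#' diagnosis (candidate labels matched through canonicalization and the
#' alias table; optionally also occurrences in `raw_text`), normalized per
#' responding model in the group. The effect is the max group rate minus the
#' min group rate, with both group labels attached. The normalization base
#' is models that responded (status ok), and the output labels it.
#'
#' @param responses Flat list of `dx_response` objects (may span cases).
#' @param registry A `dx_registry` covering the responding models.
#' @param target Diagnosis label or term to count.
#' @param axis Registry grouping axis (default `"origin_region"`).
#' @param aliases A `dx_alias_table` used to match label variants.
#' @param include_raw_text If `TRUE`, also count word-bounded occurrences of
#'   the target term in `raw_text`.
#' @return A `dx_bias_summary` with a `group_stats` data frame
#'   (`group`, `n_models`, `total_mentions`, `mentions_per_model`).
#' @export
mentions_per_model_by_group <- function(responses, registry, target,
                                        axis = "origin_region",
                                        aliases = default_alias_table(),
                                        include_raw_text = FALSE) {
  roots <- alias_root_map(aliases)
  target_root <- resolve_root(canonicalize_label(target), roots)

  model_ids <- vapply(responses, function(r) r$model_id, character(1))
  ok <- vapply(responses, function(r) r$status == "ok", logical(1))
  responding <- unique(model_ids[ok])
  missing <- setdiff(responding, registry$model_id)
  if (length(missing) > 0L) {
    stop_validation(sprintf("responding model(s) missing from registry: %s",
                            paste(missing, collapse = ", ")))
  }

  mention_count <- stats::setNames(numeric(length(responding)), responding)
  cand_model <- list(); cand_label <- list()
  i <- 0L
  for (r in responses) {
    if (r$status != "ok") next
    for (cand in r$candidates) {
      i <- i + 1L
      cand_model[[i]] <- r$model_id
      cand_label[[i]] <- cand$label
    }
    if (include_raw_text && !is.null(r$raw_text) && nzchar(r$raw_text)) {
      pat <- marker_pattern(tolower(target))
      m <- gregexpr(pat, r$raw_text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] != -1L) {
        mention_count[r$model_id] <- mention_count[r$model_id] + length(m)
      }
    }
  }
  if (i > 0L) {
    ca <- canonicalize_label(unlist(cand_label), return_alias = TRUE)
    hit <- resolve_root(ca$canonical, roots) == target_root |
      (!is.na(ca$alias) & resolve_root(ca$alias, roots) == target_root)
    tl <- table(unlist(cand_model)[hit])
    mention_count[names(tl)] <- mention_count[names(tl)] + as.numeric(tl)
  }

  groups <- registry[[axis]]
  if (is.null(groups)) {
    stop_validation(sprintf("unknown grouping axis '%s'", axis))
  }
  groups[is.na(groups)] <- "unknown"
  names(groups) <- registry$model_id
  glev <- unique(groups[responding])
  stats_df <- do.call(rbind, lapply(glev, function(g) {
    ids <- responding[groups[responding] == g]
    total <- sum(mention_count[ids])
    data.frame(group = g, n_models = length(ids), total_mentions = total,
               mentions_per_model = total / length(ids),
               stringsAsFactors = FALSE)
  }))
  stats_df <- stats_df[order(stats_df$group), , drop = FALSE]
  rownames(stats_df) <- NULL

  if (nrow(stats_df) > 0L) {
    hi <- which.max(stats_df$mentions_per_model)
    lo <- which.min(stats_df$mentions_per_model)
    effect <- stats_df$mentions_per_model[hi] - stats_df$mentions_per_model[lo]
    descriptor <- sprintf(
      "'%s': %s highest (%.1f mentions/model), %s lowest (%.1f mentions/model); rates are per responding model",
      target, stats_df$group[hi], stats_df$mentions_per_model[hi],
      stats_df$group[lo], stats_df$mentions_per_model[lo])
  } else {
    effect <- NA_real_
    descriptor <- "no responding models"
  }
  axis_name <- if (axis == "origin_region") "geographic" else axis
  new_bias_summary(axis = axis_name, target = target,
                   group_stats = stats_df, effect = effect,
                   effect_descriptor = descriptor)
}

#' Consensus alignment by cost tier
#'
#' Mean majority-alignment rate per cost tier, the signed free-minus-paid
#' difference, and (optionally) a percentile bootstrap interval for that
#' difference obtained by resampling models within each tier.
#'
#' @param consensus_records A `dx_consensus` data frame from
#'   [categorize_model_consensus()].
#' @param registry A `dx_registry`; every model must carry a cost tier.
#' @param bootstrap_n Number of bootstrap resamples (0 disables).
#' @param conf Interval coverage (default 0.95).
#' @return A `dx_bias_summary`; `group_stats` has per-tier `n_models`,
#'   `mean_alignment` (fraction) and `alignment_pct` (one-decimal percent);
#'   `effect` is free - paid on the fraction scale (`NA` when a tier is
#'   empty); `ci` is the bootstrap interval when requested.
#' @export
alignment_by_cost_tier <- function(consensus_records, registry,
                                   bootstrap_n = 0L, conf = 0.95) {
  tiers <- stats::setNames(registry$cost_tier, registry$model_id)
  missing <- setdiff(consensus_records$model_id, names(tiers))
  if (length(missing) > 0L || any(is.na(tiers[consensus_records$model_id]))) {
    stop_validation("every model in consensus_records must have a cost_tier in the registry")
  }
  rec <- consensus_records[!is.na(consensus_records$majority_alignment_rate), ,
                           drop = FALSE]
  rates <- split(rec$majority_alignment_rate, tiers[rec$model_id])
  stats_df <- do.call(rbind, lapply(dx_cost_tiers, function(tier) {
    x <- rates[[tier]]
    if (is.null(x) || length(x) == 0L) {
      data.frame(group = tier, n_models = 0L, mean_alignment = NA_real_,
                 alignment_pct = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(group = tier, n_models = length(x), mean_alignment = mean(x),
                 alignment_pct = round(100 * mean(x), 1),
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(stats_df) <- NULL
  free <- rates[["free"]] %||% numeric(0)
  paid <- rates[["paid"]] %||% numeric(0)
  effect <- if (length(free) > 0L && length(paid) > 0L) {
    mean(free) - mean(paid)
  } else {
    NA_real_
  }
  ci <- NULL
  if (bootstrap_n > 0L && length(free) > 0L && length(paid) > 0L) {
    draws <- vapply(seq_len(bootstrap_n), function(b) {
      mean(free[sample.int(length(free), replace = TRUE)]) -
        mean(paid[sample.int(length(paid), replace = TRUE)])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
  }
  descriptor <- if (is.na(effect)) {
    "a cost tier has no models; effect undefined"
  } else {
    sprintf("free %.1f%% vs paid %.1f%% (effect free - paid = %+.1f points)",
            100 * mean(free), 100 * mean(paid), 100 * effect)
  }
  new_bias_summary(axis = "cost", target = "majority alignment",
                   group_stats = stats_df, effect = effect,
                   effect_descriptor = descriptor,
                   extra = list(ci = ci, conf = conf,
                                bootstrap_n = bootstrap_n))
}

#' Uncertainty vs confidence marker balance for a case
#'
#' Sums marker counts across a case's responses and reports which side
#' dominates (strictly greater total; `"neutral"` on a tie).
#'
#' @param responses List of `dx_response` objects for one case.
#' @return List with `uncertainty_total`, `confidence_total`, `dominance`.
#' @export
marker_balance <- function(responses) {
  u <- sum(vapply(responses, function(r) r$uncertainty_marker_count, integer(1)))
  cf <- sum(vapply(responses, function(r) r$confidence_marker_count, integer(1)))
  dominance <- if (u > cf) "uncertainty" else if (cf > u) "confidence" else "neutral"
  list(uncertainty_total = u, confidence_total = cf, dominance = dominance)
}

#' Rank association between consensus and diagnostic breadth
#'
#' Spearman rank correlation between per-case consensus rate and diagnostic
#' breadth. Rank-based by design: breadth is a count with a heavy right
#' tail, so a product-moment correlation would be dominated by extreme
#' cases.
#'
#' @param analytics A data frame of per-case rows as produced by
#'   [ensemble_summary()] (rbind-ed), with columns `consensus_rate` and
#'   `diagnostic_breadth`.
#' @return List with `rho`, `n`, and `direction` (`"negative"`,
#'   `"positive"`, `"none"`, or `"undefined"` for a constant series, where
#'   `rho` is `NA`).
#' @export
breadth_consensus_association <- function(analytics) {
  keep <- !is.na(analytics$consensus_rate)
  x <- analytics$consensus_rate[keep]
  y <- analytics$diagnostic_breadth[keep]
  if (length(x) < 3L) {
    stop_validation("need >= 3 cases with a defined consensus rate")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, n = length(x), direction = "undefined"))
  }
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  direction <- if (is.na(rho)) "undefined"
               else if (rho < 0) "negative"
               else if (rho > 0) "positive" else "none"
  list(rho = rho, n = length(x), direction = direction)
}

#' @export
print.dx_bias_summary <- function(x, ...) {
  cat(sprintf("<dx_bias_summary> axis: %s, target: %s\n", x$axis, x$target))
  print(x$group_stats)
  cat(sprintf("  effect: %s\n", format(x$effect)))
  cat(sprintf("  %s\n", x$effect_descriptor))
  invisible(x)
}

#' Render a bias summary as a Markdown table row set
#'
#' @param summaries List of `dx_bias_summary` objects.
#' @return Character vector of Markdown lines (bias type, manifestation,
#'   example, implication columns).
#' @export
bias_summary_markdown <- function(summaries) {
  lines <- c("| Bias axis | Manifestation | Groups | Effect |",
             "|---|---|---|---|")
  for (s in summaries) {
    groups <- paste(
      sprintf("%s: %s", s$group_stats$group,
              vapply(seq_len(nrow(s$group_stats)), function(i) {
                gs <- s$group_stats[i, ]
                if (!is.null(gs$mentions_per_model)) {
                  sprintf("%.1f/model", gs$mentions_per_model)
                } else if (!is.null(gs$alignment_pct)) {
                  sprintf("%.1f%%", gs$alignment_pct)
                } else ""
              }, character(1))),
      collapse = "; ")
    lines <- c(lines, sprintf("| %s | %s | %s | %s |",
                              s$axis, s$effect_descriptor, groups,
                              format(s$effect, digits = 3)))
  }
  lines
}
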