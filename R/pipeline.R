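# Composable pipeline: simulate/ingest -> stratify -> attribute -> report,
# each stage writing versioned artifacts plus a manifest with a config hash
# and per-file checksums. Output is a pure function of (config, seed, input
# files): re-running an identical seeded config reproduces identical
# checksums.

dx_stages <- c("simulate", "ingest", "stratify", "attribute", "report")

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `seed`; `simulate:` (either `alphas` +
#' `cases_per_alpha` + `n_models` + `pool_size` for an ambiguity sweep, or
#' a `case_specs:` list with `case_id`, `pool` (mapping), optional
#' `regional_target`, `ambiguity`, `hallucination_rate`); `registry`,
#' `responses`, `cases` (input paths for ingest mode); `stratification:`
#' (threshold overrides, see [stratification_config()]); `lexicon`,
#' `aliases` (paths); `render_mode`; `synthesizer_chain` (id list);
#' `attribution_targets` (labels for mention-rate analysis).
#'
#' @param path YAML config path.
#' @return A `dx_pipeline_config` (named list, validated lazily by
#'   [run_pipeline()]).
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("pipeline config not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)
  structure(cfg %||% list(), class = "dx_pipeline_config")
}

config_strat <- function(cfg) {
  sc <- cfg$stratification %||% list()
  do.call(stratification_config, sc)
}

config_lexicon <- function(cfg) {
  if (!is.null(cfg$lexicon)) read_lexicon(cfg$lexicon) else default_lexicon()
}

config_aliases <- function(cfg) {
  if (!is.null(cfg$aliases)) read_alias_table(cfg$aliases) else
    default_alias_table()
}

config_sim <- function(cfg) {
  sim <- cfg$simulate
  if (is.null(sim)) {
    stop_dependency("stage 'simulate': config has no 'simulate:' section")
  }
  if (is.null(cfg$seed)) {
    stop_validation("stage 'simulate': config must carry a seed")
  }
  if (!is.null(sim$case_specs)) {
    specs <- lapply(sim$case_specs, function(s) {
      case_spec(s$case_id, unlist(s$pool),
                regional_target = s$regional_target,
                ambiguity = s$ambiguity %||% 0.3,
                hallucination_rate = s$hallucination_rate %||% 0.05,
                truth_label = s$truth_label)
    })
    simulation_config(specs,
                      n_models = sim$n_models %||% 30,
                      cost_tier_split = sim$cost_tier_split %||% 0.5,
                      anachronism_rate = sim$anachronism_rate %||% 0.05,
                      hedging_scale = sim$hedging_scale %||% 8,
                      seed = cfg$seed)
  } else if (!is.null(sim$alphas)) {
    specs <- list()
    for (a in sim$alphas) {
      pool <- ambiguity_pool(a, k = sim$pool_size %||% 8)
      names(pool) <- sprintf("Condition %02d", seq_along(pool))
      for (j in seq_len(sim$cases_per_alpha %||% 4)) {
        specs[[length(specs) + 1L]] <- case_spec(
          sprintf("amb%03d_c%d", round(100 * a), j), pool, ambiguity = a)
      }
    }
    simulation_config(specs, n_models = sim$n_models %||% 30,
                      seed = cfg$seed)
  } else {
    stop_validation("simulate config needs either 'case_specs' or 'alphas'")
  }
}

artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(stage, path) {
  if (!file.exists(path)) {
    stop_dependency(sprintf("stage '%s': missing upstream artifact '%s'",
                            stage, path))
  }
  path
}

#' Run the orchestration pipeline
#'
#' Executes the requested stages in order, writing versioned artifacts into
#' `out_dir`: `registry.csv` + `responses.jsonl` (+ `truth.json`) from
#' simulate/ingest, `stratified.json` + `analytics.csv` from stratify,
#' `attribution.json` from attribute, `reports/<case>.md|.json` from
#' report, and finally `manifest.json` with the stage order, a config hash,
#' and an md5 checksum per artifact. Stages form a contiguous chain: each
#' stage's inputs must exist on disk or be produced by an earlier requested
#' stage, otherwise a dependency error names the stage and file.
#'
#' @param config A `dx_pipeline_config` (or plain named list).
#' @param stages Ordered subset of
#'   `c("simulate", "ingest", "stratify", "attribute", "report")`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, stages, out_dir) {
  bad <- setdiff(stages, dx_stages)
  if (length(bad) > 0L) {
    stop_validation(sprintf("unknown stage(s): %s (valid: %s)",
                            paste(bad, collapse = ", "),
                            paste(dx_stages, collapse = ", ")))
  }
  if ("simulate" %in% stages && "ingest" %in% stages) {
    stop_validation("stages 'simulate' and 'ingest' are alternative entry points; request one")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  strat_cfg <- config_strat(config)
  lexicon <- config_lexicon(config)
  aliases <- config_aliases(config)
  written <- character(0)
  note <- function(p) written <<- c(written, p)

  for (stage in stages) {
    if (stage == "simulate") {
      sim <- simulate_ensemble(config_sim(config), lexicon = lexicon)
      write_registry(sim$registry, artifact(out_dir, "registry.csv"))
      write_responses(sim$responses, artifact(out_dir, "responses.jsonl"))
      writeLines(as.character(jsonlite::toJSON(
        sim$truth, auto_unbox = TRUE, digits = NA, null = "null",
        pretty = TRUE)), artifact(out_dir, "truth.json"))
      note(artifact(out_dir, "registry.csv"))
      note(artifact(out_dir, "responses.jsonl"))
      note(artifact(out_dir, "truth.json"))
    } else if (stage == "ingest") {
      reg_in <- require_artifact("ingest", config$registry %||% "")
      resp_in <- require_artifact("ingest", config$responses %||% "")
      registry <- suppressMessages(load_registry(reg_in))
      responses <- read_responses(resp_in, lexicon)
      write_registry(registry, artifact(out_dir, "registry.csv"))
      write_responses(responses, artifact(out_dir, "responses.jsonl"))
      note(artifact(out_dir, "registry.csv"))
      note(artifact(out_dir, "responses.jsonl"))
    } else if (stage == "stratify") {
      resp_path <- require_artifact("stratify",
                                    artifact(out_dir, "responses.jsonl"))
      responses <- read_responses(resp_path, lexicon)
      by_case <- split_responses_by_case(responses)
      diffs <- lapply(by_case, stratify_case, aliases = aliases,
                      config = strat_cfg)
      analytics <- do.call(rbind, lapply(names(diffs), function(cid) {
        ensemble_summary(diffs[[cid]], by_case[[cid]])
      }))
      writeLines(as.character(jsonlite::toJSON(
        lapply(diffs, differential_to_list), auto_unbox = TRUE,
        digits = NA, null = "null", pretty = TRUE)),
        artifact(out_dir, "stratified.json"))
      utils::write.csv(analytics, artifact(out_dir, "analytics.csv"),
                       row.names = FALSE)
      note(artifact(out_dir, "stratified.json"))
      note(artifact(out_dir, "analytics.csv"))
    } else if (stage == "attribute") {
      require_artifact("attribute", artifact(out_dir, "stratified.json"))
      resp_path <- require_artifact("attribute",
                                    artifact(out_dir, "responses.jsonl"))
      reg_path <- require_artifact("attribute",
                                   artifact(out_dir, "registry.csv"))
      responses <- read_responses(resp_path, lexicon)
      registry <- suppressMessages(load_registry(reg_path))
      by_case <- split_responses_by_case(responses)
      diffs <- lapply(by_case, stratify_case, aliases = aliases,
                      config = strat_cfg)
      consensus <- suppressWarnings(
        categorize_model_consensus(by_case, diffs, strat_cfg))
      out <- list(
        model_consensus = consensus,
        cost_alignment = unclass(
          alignment_by_cost_tier(consensus, registry)),
        marker_balance = lapply(by_case, marker_balance)
      )
      analytics <- do.call(rbind, lapply(names(diffs), function(cid) {
        ensemble_summary(diffs[[cid]], by_case[[cid]])
      }))
      if (sum(!is.na(analytics$consensus_rate)) >= 3L) {
        out$breadth_consensus <- breadth_consensus_association(analytics)
      }
      targets <- config$attribution_targets %||% character(0)
      if (length(targets) > 0L) {
        out$mention_rates <- lapply(targets, function(tg) {
          unclass(mentions_per_model_by_group(responses, registry, tg,
                                              aliases = aliases))
        })
      }
      writeLines(as.character(jsonlite::toJSON(
        out, auto_unbox = TRUE, digits = NA, null = "null",
        dataframe = "rows", pretty = TRUE)),
        artifact(out_dir, "attribution.json"))
      note(artifact(out_dir, "attribution.json"))
    } else if (stage == "report") {
      resp_path <- require_artifact("report",
                                    artifact(out_dir, "responses.jsonl"))
      require_artifact("report", artifact(out_dir, "stratified.json"))
      reg_path <- artifact(out_dir, "registry.csv")
      registry <- if (file.exists(reg_path)) {
        suppressMessages(load_registry(reg_path))
      } else NULL
      responses <- read_responses(resp_path, lexicon)
      by_case <- split_responses_by_case(responses)
      diffs <- lapply(by_case, stratify_case, aliases = aliases,
                      config = strat_cfg)
      chain <- synthesizer_chain(
        config$synthesizer_chain %||% default_synthesizer_chain()$ids)
      # shipped synthesizers are deterministic templates, always available
      avail <- stats::setNames(as.list(rep(TRUE, length(chain$ids))),
                               chain$ids)
      chosen <- select_synthesizer(chain, avail)$chosen
      rep_dir <- file.path(out_dir, "reports")
      dir.create(rep_dir, showWarnings = FALSE)
      mode <- config$render_mode %||% "full"
      for (cid in names(diffs)) {
        rep <- build_report(diffs[[cid]], registry = registry, mode = mode,
                            synthesizer_used = chosen)
        md_path <- file.path(rep_dir, paste0(cid, ".md"))
        json_path <- file.path(rep_dir, paste0(cid, ".json"))
        writeLines(render_report(rep, "markdown"), md_path)
        writeLines(render_report(rep, "json"), json_path)
        note(md_path)
        note(json_path)
      }
    }
  }

  cfg_json <- as.character(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA,
                                            null = "null"))
  cfg_tmp <- tempfile()
  writeLines(cfg_json, cfg_tmp)
  checks <- tools::md5sum(sort(unique(written)))
  # manifest records out_dir-relative artifact names so reruns in different
  # directories produce identical manifests
  names(checks) <- substring(names(checks), nchar(out_dir) + 2L)
  manifest <- list(
    schema_version = "1",
    stages = stages,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    artifacts = as.list(checks)
  )
  unlink(cfg_tmp)
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             artifact(out_dir, "manifest.json"))
  invisible(manifest)
}

differential_to_list <- function(differential) {
  list(case_id = differential$case_id,
       total_models = differential$total_models,
       responding_models = differential$responding_models,
       strata = lapply(differential$strata, function(cls) {
         lapply(cls, function(cl) {
           list(canonical_label = cl$canonical_label,
                member_labels = I(cl$member_labels),
                icd10_codes = I(cl$icd10_codes),
                icd10_category = cl$icd10_category,
                supporting_model_ids = I(cl$supporting_model_ids),
                agreement_rate = cl$agreement_rate,
                mean_confidence = cl$mean_confidence)
         })
       }))
}
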