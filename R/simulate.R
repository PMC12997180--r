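# Synthetic biased-ensemble generator. Emulates a heterogeneous model
# ensemble with case-dependent consensus, a regional recognition boost,
# temporal anchoring (anachronistic proposals), hallucination, and
# ambiguity-scaled hedging language -- with the ground truth retained so
# attribution and stratification can be checked against injected effects.
# The generative model is deliberately simple: independent Bernoulli
# proposals per (model, diagnosis), which is the minimal mechanism that
# yields the agreement-rate arithmetic downstream.

dx_historical_conditions <- c("HIV/AIDS", "Tuberculosis", "Syphilis",
                              "Rheumatic Fever", "Scurvy")

dx_speculative_pool <- c(
  "Paraneoplastic Syndrome", "Atypical Vasculitis", "Mitochondrial Disorder",
  "Heavy Metal Toxicity", "Occult Malignancy", "Autoinflammatory Syndrome",
  "Mast Cell Activation Syndrome", "Chronic Q Fever", "Amyloidosis",
  "Sarcoid-like Reaction", "Atypical Mycobacterial Infection",
  "IgG4-Related Disease")

# long tail of rare conditions an ambiguous presentation can plausibly pull
# in; idiosyncratic proposals are drawn from here so that ambiguous cases
# spread over many near-singleton clusters (the way real ensembles produce
# dozens of distinct alternatives) rather than over a small fixed pool
dx_rare_pool <- c(
  dx_speculative_pool,
  "Erdheim-Chester Disease", "Fabry Disease", "Gaucher Disease",
  "Pompe Disease", "Niemann-Pick Disease", "Castleman Disease",
  "Whipple Disease", "Adult-Onset Still Disease", "Takayasu Arteritis",
  "Polyarteritis Nodosa", "Eosinophilic Granulomatosis",
  "Goodpasture Syndrome", "Alport Syndrome", "Gitelman Syndrome",
  "Bartter Syndrome", "Addison Disease", "Cushing Syndrome",
  "Pheochromocytoma", "Carcinoid Syndrome", "Zollinger-Ellison Syndrome",
  "Budd-Chiari Syndrome", "Primary Sclerosing Cholangitis",
  "Autoimmune Hepatitis", "Alpha-1 Antitrypsin Deficiency",
  "Cystic Fibrosis", "Kartagener Syndrome", "Sjogren Syndrome",
  "Dermatomyositis", "Polymyositis", "Mixed Connective Tissue Disease",
  "Relapsing Polychondritis", "Ehlers-Danlos Syndrome", "Marfan Syndrome",
  "Loeys-Dietz Syndrome", "Brugada Syndrome", "Long QT Syndrome",
  "Arrhythmogenic Cardiomyopathy", "Constrictive Pericarditis",
  "Lofgren Syndrome", "Henoch-Schonlein Purpura", "Kawasaki Disease",
  "Lyme Disease", "Brucellosis", "Leptospirosis", "Babesiosis",
  "Bartonellosis", "Histoplasmosis", "Coccidioidomycosis")

# Deterministic, valid ICD-style code for a synthetic diagnosis label.
synthetic_icd10 <- function(label) {
  h <- str_hash31(canonicalize_label(label))
  sprintf("%s%02d.%d", LETTERS[(h %% 26L) + 1L], (h %/% 26L) %% 100L,
          (h %/% 2600L) %% 10L)
}

#' Specify one synthetic case
#'
#' @param case_id Case identifier.
#' @param pool Named numeric vector: base diagnosis pool with per-diagnosis
#'   proposal probabilities, each in \[0, 1\] (independent Bernoulli, so
#'   they need not sum to 1).
#' @param regional_target Optional `list(diagnosis =, region =, boost =)`:
#'   models from `region` propose `diagnosis` with probability
#'   `pool[diagnosis] + boost` (must stay <= 1).
#' @param ambiguity Case ambiguity alpha in \[0, 1\]; scales hedging
#'   density (and, via [ambiguity_pool()], pool dispersion).
#' @param hallucination_rate Probability a model adds an out-of-pool
#'   speculative diagnosis.
#' @param truth_label Canonical intended diagnosis; defaults to the
#'   highest-probability pool entry.
#' @return A `dx_case_spec`.
#' @export
case_spec <- function(case_id, pool, regional_target = NULL,
                      ambiguity = 0.3, hallucination_rate = 0.05,
                      truth_label = NULL) {
  if (!is_scalar_string(case_id)) stop_validation("case_id must be a string")
  if (is.null(names(pool)) || any(!nzchar(names(pool))) ||
      anyDuplicated(names(pool))) {
    stop_validation(sprintf("case %s: pool must have unique non-empty names",
                            case_id))
  }
  if (any(pool < 0 | pool > 1)) {
    stop_validation(sprintf("case %s: pool probabilities must lie in [0, 1]",
                            case_id))
  }
  if (!is.null(regional_target)) {
    d <- regional_target$diagnosis
    if (!is_scalar_string(d) || !d %in% names(pool)) {
      stop_validation(sprintf("case %s: regional_target diagnosis must be in the pool",
                              case_id))
    }
    if (!regional_target$region %in% dx_regions) {
      stop_validation(sprintf("case %s: regional_target region must be one of %s",
                              case_id, paste(dx_regions, collapse = ", ")))
    }
    boost <- regional_target$boost
    if (boost < 0 || boost > 1 || pool[[d]] + boost > 1) {
      stop_validation(sprintf(
        "case %s: need boost in [0, 1] and p + boost <= 1 for '%s'",
        case_id, d))
    }
  }
  if (ambiguity < 0 || ambiguity > 1) {
    stop_validation(sprintf("case %s: ambiguity must lie in [0, 1]", case_id))
  }
  if (hallucination_rate < 0 || hallucination_rate > 1) {
    stop_validation(sprintf("case %s: hallucination_rate must lie in [0, 1]",
                            case_id))
  }
  structure(list(case_id = case_id, pool = pool,
                 regional_target = regional_target, ambiguity = ambiguity,
                 hallucination_rate = hallucination_rate,
                 truth_label = truth_label %||%
                   names(pool)[which.max(pool)]),
            class = "dx_case_spec")
}

#' Interpolated proposal-probability pool for a given ambiguity
#'
#' Ambiguity alpha controls pool dispersion: at alpha = 0 the pool is
#' concentrated (one dominant diagnosis, rare alternatives), at alpha = 1 it
#' is flat (every diagnosis proposed by about half the models). Higher
#' alpha therefore means lower consensus and higher diagnostic breadth.
#'
#' @param alpha Ambiguity in \[0, 1\].
#' @param k Pool size.
#' @param top Dominant-diagnosis probability at alpha = 0.
#' @param floor_p Tail probability at alpha = 0. The default is small
#'   enough that an unambiguous case keeps a narrow differential even in a
#'   30-model ensemble (tail diagnoses appear in only a minority of runs),
#'   so high-consensus cases carry few alternatives while ambiguous cases
#'   spread over the whole pool.
#' @param flat Common probability at alpha = 1.
#' @return Unnamed numeric vector of length `k` (assign names via
#'   [case_spec()]'s `pool`).
#' @export
ambiguity_pool <- function(alpha, k = 8, top = 0.92, floor_p = 0.005,
                           flat = 0.5) {
  if (alpha < 0 || alpha > 1) stop_validation("alpha must lie in [0, 1]")
  (1 - alpha) * c(top, rep(floor_p, k - 1)) + alpha * rep(flat, k)
}

#' Configure a synthetic ensemble simulation
#'
#' Defaults describe the emulated population: 30 models with the observed
#' geographic mix (US 65%, Europe 10%, China 16%, Other 9%), an even
#' free/paid split, and a small anachronism rate that occasionally surfaces
#' historical conditions regardless of case relevance.
#'
#' @param case_specs List of `dx_case_spec` objects.
#' @param n_models Ensemble size.
#' @param region_distribution Probability vector over
#'   US/Europe/China/Other (must sum to 1 within 1e-9).
#' @param cost_tier_split Fraction of models in the free tier.
#' @param anachronism_rate Probability a model proposes a historical
#'   condition on a case.
#' @param hedging_scale Expected uncertainty-marker count at ambiguity 1
#'   (hedging density is `Poisson(ambiguity * hedging_scale)`).
#' @param breadth_scale Expected number of idiosyncratic rare-condition
#'   proposals per model at ambiguity 1 (count is
#'   `Poisson(ambiguity * breadth_scale)`, labels drawn from a long rare
#'   -condition tail). This is what lets ambiguous cases fan out into many
#'   near-singleton alternatives instead of saturating a small fixed pool.
#' @param seed Integer seed, required -- simulations are never silently
#'   non-reproducible.
#' @return A `dx_sim_config`.
#' @export
simulation_config <- function(case_specs, n_models = 30,
                              region_distribution = c(US = 0.65,
                                                      Europe = 0.10,
                                                      China = 0.16,
                                                      Other = 0.09),
                              cost_tier_split = 0.5,
                              anachronism_rate = 0.05,
                              hedging_scale = 8,
                              breadth_scale = 0.5,
                              seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_validation("seed is required for simulation (reproducibility is not optional)")
  }
  if (length(case_specs) == 0L) stop_validation("need at least one case spec")
  if (!all(vapply(case_specs, inherits, logical(1), "dx_case_spec"))) {
    stop_validation("case_specs must be dx_case_spec objects (see case_spec())")
  }
  ids <- vapply(case_specs, function(cs) cs$case_id, character(1))
  if (anyDuplicated(ids)) stop_validation("case_spec case_ids must be unique")
  if (!setequal(names(region_distribution), dx_regions)) {
    stop_validation(sprintf("region_distribution must be named over %s",
                            paste(dx_regions, collapse = ", ")))
  }
  if (abs(sum(region_distribution) - 1) > 1e-9) {
    stop_validation("region_distribution must sum to 1 (tolerance 1e-9)")
  }
  if (any(region_distribution < 0)) {
    stop_validation("region_distribution entries must be non-negative")
  }
  if (cost_tier_split < 0 || cost_tier_split > 1) {
    stop_validation("cost_tier_split must lie in [0, 1]")
  }
  if (anachronism_rate < 0 || anachronism_rate > 1) {
    stop_validation("anachronism_rate must lie in [0, 1]")
  }
  names(case_specs) <- ids
  structure(list(case_specs = case_specs, n_models = as.integer(n_models),
                 region_distribution = region_distribution[dx_regions],
                 cost_tier_split = cost_tier_split,
                 anachronism_rate = anachronism_rate,
                 hedging_scale = hedging_scale,
                 breadth_scale = breadth_scale,
                 seed = as.integer(seed)),
            class = "dx_sim_config")
}

sim_profiles <- function(config) {
  n <- config$n_models
  set.seed(config$seed)
  region <- sample(dx_regions, n, replace = TRUE,
                   prob = config$region_distribution)
  tier <- sample(dx_cost_tiers, n, replace = TRUE,
                 prob = c(config$cost_tier_split, 1 - config$cost_tier_split))
  pclass <- sample(dx_parameter_classes, n, replace = TRUE)
  rdate <- format(as.Date("2022-01-01") +
                    sample.int(1400, n, replace = TRUE))
  df <- data.frame(
    model_id = sprintf("sim_m%02d", seq_len(n)),
    provider = "synthetic",
    origin_region = region,
    cost_tier = tier,
    release_date = rdate,
    parameter_class = pclass,
    architecture_family = "synthetic-transformer",
    intended_scope = "synthetic diagnostic ensemble member",
    stringsAsFactors = FALSE)
  new_registry(df)
}

sim_hedging_text <- function(k_unc, k_conf, lexicon) {
  if (k_unc + k_conf == 0L) return("findings noted on review.")
  phrases <- c(
    if (k_unc > 0L) sample(lexicon$uncertainty, k_unc, replace = TRUE),
    if (k_conf > 0L) sample(lexicon$confidence, k_conf, replace = TRUE))
  phrases <- sample(phrases)
  paste0(paste0(phrases, " finding", collapse = "; the picture "), ".")
}

sim_one_response <- function(model_id, region, cs, config, lexicon) {
  pool <- cs$pool
  p_eff <- pool
  rt <- cs$regional_target
  if (!is.null(rt) && region == rt$region) {
    p_eff[[rt$diagnosis]] <- p_eff[[rt$diagnosis]] + rt$boost
  }
  proposed <- names(pool)[stats::runif(length(pool)) < p_eff]
  n_idio <- stats::rpois(1, cs$ambiguity * (config$breadth_scale %||% 0.5))
  if (n_idio > 0L) {
    proposed <- c(proposed,
                  sample(dx_rare_pool, min(n_idio, length(dx_rare_pool))))
  }
  if (stats::runif(1) < cs$hallucination_rate) {
    proposed <- c(proposed, sample(dx_speculative_pool, 1))
  }
  if (stats::runif(1) < config$anachronism_rate) {
    proposed <- c(proposed, sample(dx_historical_conditions, 1))
  }
  proposed <- unique(proposed)
  k <- length(proposed)
  cands <- list()
  if (k > 0L) {
    proposed <- sample(proposed, k)  # order not tied to pool order
    conf <- numeric(k)
    conf[1] <- stats::runif(1, 0.6, 0.95)
    if (k > 1L) {
      for (i in 2:k) conf[i] <- conf[i - 1] * stats::runif(1, 0.7, 0.95)
    }
    cands <- lapply(seq_len(k), function(i) {
      new_candidate(label = proposed[i],
                    icd10_codes = synthetic_icd10(proposed[i]),
                    confidence = round(conf[i], 4), rank = i)
    })
  }
  k_unc <- stats::rpois(1, cs$ambiguity * config$hedging_scale)
  k_conf <- stats::rpois(1, max(0, (1 - cs$ambiguity) * 3))
  raw_text <- sim_hedging_text(k_unc, k_conf, lexicon)
  counts <- count_markers(raw_text, lexicon)
  new_response(model_id = model_id, case_id = cs$case_id, status = "ok",
               candidates = cands, raw_text = raw_text,
               uncertainty_marker_count = counts[["uncertainty"]],
               confidence_marker_count = counts[["confidence"]])
}

#' Simulate a synthetic diagnostic ensemble
#'
#' Draws model profiles from the configured provenance distributions, then
#' for each (model, case) pair independently proposes each pool diagnosis
#' with its probability (plus the regional boost when the model's region
#' matches the case's boosted region), adds a hallucinated out-of-pool
#' diagnosis with the case's hallucination rate, occasionally proposes an
#' anachronistic historical condition, draws per-candidate confidences
#' declining in rank, and writes hedging phrases into `raw_text` with
#' expected count proportional to the case's ambiguity. Every (model, case)
#' pair uses its own RNG substream derived from the seed, so output is
#' reproducible and independent of evaluation order.
#'
#' @param config A `dx_sim_config`.
#' @param lexicon The `dx_lexicon` used both to generate and to score
#'   hedging text.
#' @return A `dx_simulation`: list with `registry` (a `dx_registry`),
#'   `responses` (flat list of `dx_response`, case-major order), and
#'   `truth` (realized profiles plus the per-case generative parameters and
#'   per-(model, case) effective proposal probabilities).
#' @export
simulate_ensemble <- function(config, lexicon = default_lexicon()) {
  if (!inherits(config, "dx_sim_config")) {
    stop_validation("config must be a dx_sim_config (see simulation_config())")
  }
  registry <- sim_profiles(config)
  responses <- vector(
    "list", config$n_models * length(config$case_specs))
  probs <- list()
  k <- 0L
  for (cs in config$case_specs) {
    case_probs <- list()
    for (i in seq_len(config$n_models)) {
      mid <- registry$model_id[i]
      region <- registry$origin_region[i]
      sub_seed <- (config$seed + str_hash31(paste(mid, cs$case_id,
                                                  sep = "::"))) %% 2147483647
      set.seed(as.integer(sub_seed))
      k <- k + 1L
      responses[[k]] <- sim_one_response(mid, region, cs, config, lexicon)
      p_eff <- cs$pool
      rt <- cs$regional_target
      if (!is.null(rt) && region == rt$region) {
        p_eff[[rt$diagnosis]] <- p_eff[[rt$diagnosis]] + rt$boost
      }
      case_probs[[mid]] <- p_eff
    }
    probs[[cs$case_id]] <- case_probs
  }
  truth <- list(
    profiles = as.data.frame(registry, stringsAsFactors = FALSE),
    case_effects = lapply(config$case_specs, function(cs) {
      list(case_id = cs$case_id, pool = cs$pool,
           regional_target = cs$regional_target, ambiguity = cs$ambiguity,
           hallucination_rate = cs$hallucination_rate,
           anachronism_rate = config$anachronism_rate,
           breadth_scale = config$breadth_scale,
           truth_label = cs$truth_label)
    }),
    proposal_probabilities = probs,
    seed = config$seed)
  structure(list(registry = registry, responses = responses, truth = truth,
                 config = config),
            class = "dx_simulation")
}

#' Simulate a case batch across an ambiguity sweep
#'
#' Builds `cases_per_alpha` cases at each ambiguity value, with pools from
#' [ambiguity_pool()], and simulates the full ensemble over the batch.
#' Higher ambiguity flattens proposal probabilities, which lowers consensus
#' and raises diagnostic breadth, and raises hedging density.
#'
#' @param alphas Numeric vector of ambiguity values (the sweep).
#' @param cases_per_alpha Cases per ambiguity value.
#' @param n_models Ensemble size.
#' @param pool_size Diagnoses per case pool.
#' @param seed Integer seed (required).
#' @param hallucination_rate Per-case hallucination rate.
#' @param ... Passed to [simulation_config()].
#' @return A `dx_simulation` whose truth records each case's alpha.
#' @export
simulate_case_set <- function(alphas, cases_per_alpha = 4, n_models = 16,
                              pool_size = 8, seed, hallucination_rate = 0.05,
                              ...) {
  if (length(alphas) == 0L) stop_validation("sweep spec must be non-empty")
  specs <- list()
  for (a in alphas) {
    pool <- ambiguity_pool(a, k = pool_size)
    names(pool) <- sprintf("Condition %02d", seq_len(pool_size))
    for (j in seq_len(cases_per_alpha)) {
      cid <- sprintf("amb%03d_c%d", round(100 * a), j)
      specs[[length(specs) + 1L]] <- case_spec(
        cid, pool, ambiguity = a, hallucination_rate = hallucination_rate)
    }
  }
  config <- simulation_config(specs, n_models = n_models, seed = seed, ...)
  simulate_ensemble(config)
}

# split a flat response list into a named per-case list, case order preserved
split_responses_by_case <- function(responses) {
  ids <- vapply(responses, function(r) r$case_id, character(1))
  split(responses, factor(ids, levels = unique(ids)))
}

#' @export
print.dx_simulation <- function(x, ...) {
  cat(sprintf("<dx_simulation> %d model(s) x %d case(s), seed %d\n",
              x$config$n_models, length(x$config$case_specs),
              x$config$seed))
  invisible(x)
}
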