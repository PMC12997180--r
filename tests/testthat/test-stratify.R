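make_rated_clusters <- function(supports, denom) {
  # build clusters through the public path: model j proposes diagnosis i
  # iff j <= supports[i]
  n <- denom
  diagnoses <- sprintf("Diagnosis %s", LETTERS[seq_along(supports)])
  responses <- lapply(seq_len(n), function(j) {
    picked <- diagnoses[supports >= j]
    make_response(sprintf("m%02d", j), candidates = picked)
  })
  stratify_case(responses, aliases = empty_aliases)
}

test_that("agreement rates follow the supporters/denominator formula", {
  # single model, single diagnosis -> rate 1.0
  d <- make_rated_clusters(1L, 1L)
  expect_equal(d$strata$PRIMARY[[1]]$agreement_rate, 1.0)
  # 6 supporters of 20 responding -> 0.30, lands exactly on PRIMARY edge
  d2 <- make_rated_clusters(6L, 20L)
  cl <- strata_of(d2)
  expect_equal(unname(cl["diagnosis a"]), "PRIMARY")
  expect_equal(d2$strata$PRIMARY[[1]]$agreement_rate, 0.30)
})

test_that("rates equal a brute-force per-diagnosis tally on random ensembles", {
  set.seed(505)
  diagnoses <- sprintf("Cond %s", LETTERS[1:6])
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    responses <- random_ensemble(n, diagnoses, p = 0.4)
    d <- stratify_case(responses, aliases = empty_aliases)
    tally <- table(tolower(unlist(lapply(responses, function(r) {
      unique(vapply(r$candidates, function(cc) cc$label, character(1)))
    }))))
    for (s in names(d$strata)) {
      for (cl in d$strata[[s]]) {
        expect_equal(cl$agreement_rate,
                     unname(tally[[cl$canonical_label]]) / n)
      }
    }
  }
})

test_that("stratum boundaries are inclusive exactly as printed", {
  # rate 0.30 -> PRIMARY; 0.10 -> ALTERNATIVE; 0.0999... -> MINORITY
  d <- make_rated_clusters(c(30L, 10L, 9L), 100L)
  s <- strata_of(d)
  expect_equal(unname(s["diagnosis a"]), "PRIMARY")
  expect_equal(unname(s["diagnosis b"]), "ALTERNATIVE")
  expect_equal(unname(s["diagnosis c"]), "MINORITY")
  # unanimous proposal -> PRIMARY
  d2 <- make_rated_clusters(8L, 8L)
  expect_equal(unname(strata_of(d2)["diagnosis a"]), "PRIMARY")
})

test_that("stratification matches exhaustive inequality evaluation (k, n <= 12)", {
  for (n in 1:12) {
    d <- make_rated_clusters(seq_len(n), n)
    s <- strata_of(d)
    for (k in seq_len(n)) {
      lab <- tolower(sprintf("diagnosis %s", LETTERS[k]))
      expect_equal(unname(s[lab]), oracle_stratum(k, n),
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
})

test_that("strata are internally ordered by rate, confidence, then label", {
  responses <- list(
    make_response("m1", candidates = list(
      make_candidate("Zeta Fever", confidence = 0.9, rank = 1),
      make_candidate("Alpha Fever", confidence = 0.9, rank = 2))),
    make_response("m2", candidates = list(
      make_candidate("Beta Fever", confidence = 0.2, rank = 1))))
  d <- stratify_case(responses, aliases = empty_aliases)
  labs <- vapply(d$strata$PRIMARY, function(cl) cl$canonical_label,
                 character(1))
  # all rate 0.5; zeta/alpha tie on confidence -> alphabetical; beta lowest
  # confidence last
  expect_equal(labs, c("alpha fever", "zeta fever", "beta fever"))
})

test_that("denominator policy switches between responding and queried models", {
  responses <- c(
    lapply(1:3, function(j) make_response(sprintf("m%d", j),
                                          candidates = "Alpha Fever")),
    list(make_response("m4", status = "timeout"),
         make_response("m5", status = "overflow")))
  d_resp <- stratify_case(responses, aliases = empty_aliases)
  expect_equal(d_resp$responding_models, 3L)
  expect_equal(d_resp$strata$PRIMARY[[1]]$agreement_rate, 1.0)

  cfg <- stratification_config(denominator_policy = "all_queried_models")
  d_all <- stratify_case(responses, aliases = empty_aliases, config = cfg)
  expect_equal(d_all$strata$PRIMARY[[1]]$agreement_rate, 3 / 5)

  expect_error(
    compute_agreement_rates(list(), total_models = 0L,
                            responding_models = 0L),
    "denominator", class = "dx_validation_error")
})

test_that("adding a supporter never demotes a cluster (monotonicity)", {
  rank_of <- c(PRIMARY = 3L, ALTERNATIVE = 2L, MINORITY = 1L)
  n <- 10L
  for (k in 1:(n - 1)) {
    s1 <- strata_of(make_rated_clusters(k, n))[["diagnosis a"]]
    s2 <- strata_of(make_rated_clusters(k + 1L, n))[["diagnosis a"]]
    expect_gte(rank_of[[s2]], rank_of[[s1]])
  }
})

test_that("threshold configs reject inverted or out-of-range boundaries", {
  expect_error(stratification_config(primary_threshold = 0.05),
               class = "dx_validation_error")
  expect_error(stratification_config(model_high_threshold = 0.2),
               class = "dx_validation_error")
  expect_silent(stratification_config(primary_threshold = 0.5,
                                      alternative_threshold = 0.2))
})

test_that("model consensus categories respect the printed boundaries", {
  # alignment 5/6 = 0.833 -> high; 0.60 -> high; 0.30 -> moderate;
  # 0.299-ish (3/10 - 1 case short) -> low
  recs <- align_fixture(list(mA = 25L, mB = 18L, mC = 9L, mD = 8L), 30L)
  got <- stats::setNames(recs$category, recs$model_id)
  expect_equal(unname(got["mA"]), "high")      # 25/30 = 0.833
  expect_equal(unname(got["mB"]), "high")      # 18/30 = 0.60 exactly
  expect_equal(unname(got["mC"]), "moderate")  # 9/30 = 0.30 exactly
  expect_equal(unname(got["mD"]), "low")       # 8/30 = 0.267
  rate <- stats::setNames(recs$majority_alignment_rate, recs$model_id)
  expect_equal(unname(rate["mA"]), 25 / 30)
})

test_that("model categories match direct threshold evaluation on a rate grid", {
  n_cases <- 20L
  ks <- 0:20
  recs <- align_fixture(stats::setNames(as.list(ks),
                                        sprintf("g%02d", ks)), n_cases)
  for (i in seq_along(ks)) {
    m <- sprintf("g%02d", ks[i])
    row <- recs[recs$model_id == m, ]
    expect_equal(row$category, oracle_model_category(ks[i] / n_cases),
                 info = m)
  }
})

test_that("a model that responded to zero cases gets a warned low record", {
  case_responses <- list(
    c1 = list(make_response("a1", "c1", "Majority Dx"),
              make_response("a2", "c1", "Majority Dx"),
              make_response("ghost", "c1", status = "timeout")))
  diffs <- lapply(case_responses, stratify_case, aliases = empty_aliases)
  expect_warning(recs <- categorize_model_consensus(case_responses, diffs),
                 "ghost")
  row <- recs[recs$model_id == "ghost", ]
  expect_true(is.na(row$majority_alignment_rate))
  expect_equal(row$category, "low")
})

test_that("ensemble summary arithmetic: consensus, breadth, alternatives", {
  d <- make_rated_clusters(c(19L, 3L, 2L, 1L), 20L)
  responses <- list(make_response("x", raw_text = "possibly viral; clearly"))
  s <- ensemble_summary(d, responses)
  expect_equal(s$consensus_rate, 95)
  expect_equal(s$diagnostic_breadth, 4L)
  expect_equal(s$alternative_count, 3L)
  expect_equal(s$uncertainty_total, 1L)
  expect_equal(s$confidence_total, 1L)

  d1 <- make_rated_clusters(3L, 5L)
  expect_equal(ensemble_summary(d1)$alternative_count, 0L)

  d0 <- stratify_case(list(make_response("m1", candidates = list())),
                      aliases = empty_aliases)
  s0 <- ensemble_summary(d0)
  expect_equal(s0$diagnostic_breadth, 0L)
  expect_true(is.na(s0$consensus_rate))
})

test_that("strata partition the clusters and survive model reordering", {
  set.seed(606)
  diagnoses <- sprintf("Cond %s", LETTERS[1:6])
  for (rep in 1:20) {
    responses <- random_ensemble(sample(3:9, 1), diagnoses, p = 0.4)
    d <- stratify_case(responses, aliases = empty_aliases)
    sizes <- vapply(d$strata, length, integer(1))
    expect_equal(sum(sizes), ensemble_summary(d)$diagnostic_breadth)
    labs <- unlist(lapply(d$strata, function(cls) {
      vapply(cls, function(cl) cl$canonical_label, character(1))
    }))
    expect_false(anyDuplicated(labs) > 0)
    # permutation invariance
    d2 <- stratify_case(sample(responses), aliases = empty_aliases)
    expect_equal(strata_of(d2)[names(strata_of(d))], strata_of(d))
    rates <- vapply(c(d$strata$PRIMARY, d$strata$ALTERNATIVE,
                      d$strata$MINORITY),
                    function(cl) cl$agreement_rate, numeric(1))
    expect_true(all(rates > 0 & rates <= 1))
  }
})
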