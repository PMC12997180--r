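test_that("mentions per model are normalized per responding group member", {
  reg <- make_registry(c("e1", "e2", "u1", "u2"),
                       origin_region = c("Europe", "Europe", "US", "US"))
  fmf <- function(times) {
    lapply(seq_len(times), function(i) {
      make_candidate("Familial Mediterranean Fever", "M04.1", 0.6, i)
    })
  }
  responses <- list(
    make_response("e1", "c1", fmf(3)),
    make_response("e2", "c1", fmf(1)),
    make_response("u1", "c1", list(make_candidate("Pericarditis", "I30"))),
    make_response("u2", "c1", list()))
  s <- mentions_per_model_by_group(responses, reg,
                                   "Familial Mediterranean Fever",
                                   aliases = empty_aliases)
  gs <- s$group_stats
  expect_equal(gs$mentions_per_model[gs$group == "Europe"], 2.0)
  expect_equal(gs$mentions_per_model[gs$group == "US"], 0.0)
  expect_equal(gs$n_models[gs$group == "US"], 2L)
  expect_equal(s$effect, 2.0)
  expect_match(s$effect_descriptor, "Europe")
  expect_match(s$effect_descriptor, "US")
  expect_match(s$effect_descriptor, "per responding model")
})

test_that("alias variants of the target are counted as mentions", {
  reg <- make_registry(c("m1", "m2"), origin_region = c("US", "Europe"))
  responses <- list(
    make_response("m1", "c1", list(make_candidate("FMF"))),
    make_response("m2", "c1", list(make_candidate("Anxiety"))))
  s <- mentions_per_model_by_group(responses, reg,
                                   "Familial Mediterranean Fever",
                                   aliases = default_alias_table())
  gs <- s$group_stats
  expect_equal(gs$total_mentions[gs$group == "US"], 1)
  expect_equal(gs$total_mentions[gs$group == "Europe"], 0)
})

test_that("a never-mentioned target yields an all-zero summary, not an error", {
  reg <- make_registry(c("m1", "m2"), origin_region = c("US", "China"))
  responses <- list(make_response("m1", "c1", "Pericarditis"),
                    make_response("m2", "c1", "Anxiety"))
  s <- mentions_per_model_by_group(responses, reg, "COVID-19",
                                   aliases = empty_aliases)
  expect_true(all(s$group_stats$total_mentions == 0))
  expect_equal(s$effect, 0)
})

test_that("mention effects are antisymmetric under group relabeling", {
  reg1 <- make_registry(c("a", "b"), origin_region = c("US", "Europe"))
  reg2 <- make_registry(c("a", "b"), origin_region = c("Europe", "US"))
  responses <- list(make_response("a", "c1", list(make_candidate("Target Dx"))),
                    make_response("b", "c1", list()))
  s1 <- mentions_per_model_by_group(responses, reg1, "Target Dx",
                                    aliases = empty_aliases)
  s2 <- mentions_per_model_by_group(responses, reg2, "Target Dx",
                                    aliases = empty_aliases)
  r1 <- stats::setNames(s1$group_stats$mentions_per_model,
                        s1$group_stats$group)
  r2 <- stats::setNames(s2$group_stats$mentions_per_model,
                        s2$group_stats$group)
  expect_equal(unname(r1["US"]), unname(r2["Europe"]))
  expect_equal(unname(r1["Europe"]), unname(r2["US"]))
  expect_equal(s1$effect, s2$effect)  # max - min is label-free
})

consensus_fixture <- function(model_id, rate) {
  structure(data.frame(model_id = model_id,
                       cases_evaluated = 10L,
                       aligned_cases = as.integer(round(10 * rate)),
                       majority_alignment_rate = rate,
                       category = "moderate", stringsAsFactors = FALSE),
            class = c("dx_consensus", "data.frame"))
}

test_that("cost-tier alignment averages per tier with one-decimal display", {
  reg <- make_registry(c("f1", "f2", "f3", "f4", "p1", "p2"),
                       cost_tier = c(rep("free", 4), rep("paid", 2)))
  # free tier: 2 of 4 aligned on their single case -> 50.0%
  recs <- consensus_fixture(c("f1", "f2", "f3", "f4", "p1", "p2"),
                            c(1, 1, 0, 0, 1, 1))
  recs$cases_evaluated <- 1L
  s <- alignment_by_cost_tier(recs, reg)
  gs <- s$group_stats
  expect_equal(gs$alignment_pct[gs$group == "free"], 50.0)
  expect_equal(gs$alignment_pct[gs$group == "paid"], 100.0)
  expect_equal(s$effect, -0.5)

  # saturation: everyone aligned -> both tiers 100.0%
  recs2 <- consensus_fixture(c("f1", "f2", "p1"), c(1, 1, 1))
  s2 <- alignment_by_cost_tier(recs2, reg)
  expect_equal(s2$group_stats$alignment_pct,
               c(100.0, 100.0))
  expect_equal(s2$effect, 0)
})

test_that("an empty tier is reported as NA with an undefined effect", {
  reg <- make_registry(c("f1", "f2"), cost_tier = c("free", "free"))
  s <- alignment_by_cost_tier(consensus_fixture(c("f1", "f2"), c(0.5, 0.7)),
                              reg)
  expect_true(is.na(s$group_stats$mean_alignment[s$group_stats$group == "paid"]))
  expect_true(is.na(s$effect))
})

test_that("cost-tier alignment is invariant to record order", {
  reg <- make_registry(sprintf("m%d", 1:6),
                       cost_tier = rep(c("free", "paid"), 3))
  recs <- consensus_fixture(sprintf("m%d", 1:6),
                            c(0.2, 0.9, 0.4, 0.6, 0.8, 0.1))
  s1 <- alignment_by_cost_tier(recs, reg)
  s2 <- alignment_by_cost_tier(recs[sample(1:6), ], reg)
  expect_equal(s1$group_stats, s2$group_stats)
  expect_equal(s1$effect, s2$effect)
})

test_that("marker balance reports totals and strict dominance", {
  mk <- function(u, cf) {
    parse_response(list(model_id = "m", case_id = "c", status = "ok",
                        candidates = list(),
                        uncertainty_marker_count = u,
                        confidence_marker_count = cf))
  }
  # the complex-case shape: 46 uncertainty vs 19 confidence markers
  b <- marker_balance(list(mk(40, 10), mk(6, 9)))
  expect_equal(b$uncertainty_total, 46L)
  expect_equal(b$confidence_total, 19L)
  expect_equal(b$dominance, "uncertainty")
  expect_equal(marker_balance(list(mk(0, 0)))$dominance, "neutral")
  expect_equal(marker_balance(list(mk(3, 3)))$dominance, "neutral")
  expect_equal(marker_balance(list(mk(5, 41)))$dominance, "confidence")
})

test_that("breadth-consensus association is rank-based with correct sign", {
  # high-consensus/narrow vs low-consensus/broad case shapes
  an <- data.frame(consensus_rate = c(95, 53, 75),
                   diagnostic_breadth = c(3, 58, 4))
  a <- breadth_consensus_association(an)
  expect_equal(a$direction, "negative")
  expect_lt(a$rho, 0)

  inc <- data.frame(consensus_rate = c(10, 20, 30, 40),
                    diagnostic_breadth = c(1, 2, 3, 4))
  expect_equal(breadth_consensus_association(inc)$rho, 1)

  const <- data.frame(consensus_rate = c(50, 50, 50),
                      diagnostic_breadth = c(1, 2, 3))
  expect_true(is.na(breadth_consensus_association(const)$rho))
  expect_equal(breadth_consensus_association(const)$direction, "undefined")

  expect_error(breadth_consensus_association(
    data.frame(consensus_rate = c(1, 2), diagnostic_breadth = c(1, 2))),
    class = "dx_validation_error")
})
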