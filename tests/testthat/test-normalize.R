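test_that("label canonicalization folds case, punctuation and whitespace", {
  expect_equal(canonicalize_label("Familial Mediterranean Fever."),
               "familial mediterranean fever")
  expect_equal(canonicalize_label("  IgA   Nephropathy "), "iga nephropathy")
  expect_equal(canonicalize_label("Wilson's Disease"), "wilsons disease")
  ca <- canonicalize_label("McArdle Disease (Glycogen Storage Disease V)",
                           return_alias = TRUE)
  expect_equal(ca$canonical, "mcardle disease")
  expect_equal(ca$alias, "glycogen storage disease v")
  expect_error(canonicalize_label("   "), class = "dx_validation_error")
})

test_that("candidates sharing a full ICD-10 code merge into one cluster", {
  responses <- list(
    make_response("A", candidates = list(make_candidate("FMF", "M04.1"))),
    make_response("B", candidates = list(
      make_candidate("Familial Mediterranean Fever", "M04.1"))))
  cls <- cluster_candidates(responses, aliases = empty_aliases)
  expect_length(cls, 1L)
  expect_setequal(cls[[1]]$supporting_model_ids, c("A", "B"))
  expect_setequal(cls[[1]]$member_labels,
                  c("FMF", "Familial Mediterranean Fever"))
})

test_that("unlinked candidates stay in separate clusters", {
  responses <- list(
    make_response("A", candidates = list(make_candidate("Pericarditis", "I30"))),
    make_response("B", candidates = list(
      make_candidate("Anxiety disorder", "F41.9"))))
  cls <- cluster_candidates(responses, aliases = empty_aliases)
  expect_length(cls, 2L)
})

test_that("alias links merge, and full-code equality does not coarsen to category", {
  aliases <- default_alias_table()
  responses <- list(
    make_response("A", candidates = list(make_candidate("FMF"))),
    make_response("B", candidates = list(
      make_candidate("Familial Mediterranean Fever"))),
    # same E83 category, different diseases: must NOT merge by default
    make_response("C", candidates = list(make_candidate("Copper storage", "E83.01"))),
    make_response("D", candidates = list(make_candidate("Zinc deficiency", "E83.110"))))
  cls <- cluster_candidates(responses, aliases = aliases)
  labs <- vapply(cls, function(cl) cl$canonical_label, character(1))
  expect_length(cls, 3L)
  fmf <- cls[[which(labs == "familial mediterranean fever")]]
  expect_setequal(fmf$supporting_model_ids, c("A", "B"))

  cls_cat <- cluster_candidates(responses, aliases = aliases,
                                merge_icd10_category = TRUE)
  expect_length(cls_cat, 2L)
})

test_that("a model supports a cluster at most once", {
  responses <- list(
    make_response("A", candidates = list(
      make_candidate("FMF", "M04.1", rank = 1),
      make_candidate("Familial Mediterranean Fever", "M04.1", 0.5, rank = 2))),
    make_response("B", candidates = list(make_candidate("FMF", "M04.1"))))
  cls <- cluster_candidates(responses, aliases = empty_aliases)
  expect_length(cls, 1L)
  expect_setequal(cls[[1]]$supporting_model_ids, c("A", "B"))
})

test_that("clustering is invariant to response order and partitions candidates", {
  set.seed(303)
  diagnoses <- c("Alpha Syndrome", "Beta Disease", "Gamma Fever",
                 "Delta Disorder", "Epsilon Deficiency")
  for (rep in 1:20) {
    responses <- random_ensemble(6, diagnoses, p = 0.5)
    cls1 <- cluster_candidates(responses, aliases = empty_aliases)
    cls2 <- cluster_candidates(rev(responses), aliases = empty_aliases)
    sig <- function(cls) {
      lapply(cls, function(cl) list(cl$canonical_label,
                                    cl$supporting_model_ids))
    }
    expect_equal(sig(cls1), sig(cls2))
    n_cands <- sum(vapply(responses, function(r) length(r$candidates),
                          integer(1)))
    expect_equal(sum(vapply(cls1, function(cl) nrow(cl$members), integer(1))),
                 n_cands)
  }
})

test_that("adding an alias pair never increases the number of clusters", {
  responses <- list(
    make_response("A", candidates = list(make_candidate("Bergers disease"))),
    make_response("B", candidates = list(make_candidate("IgA Nephropathy"))),
    make_response("C", candidates = list(make_candidate("Pericarditis"))))
  n_without <- length(cluster_candidates(responses, aliases = empty_aliases))
  aliases <- structure(list("iga nephropathy" = "bergers disease"),
                       class = "dx_alias_table")
  n_with <- length(cluster_candidates(responses, aliases = aliases))
  expect_equal(n_without, 3L)
  expect_equal(n_with, 2L)
  expect_lte(n_with, n_without)
})

test_that("clustering equals brute-force transitive closure on random graphs", {
  set.seed(404)
  labels <- c("Alpha Syndrome", "alpha   syndrome.", "Beta Disease",
              "Gamma Fever (Beta Disease)", "Delta Disorder", "BD")
  codes <- c("A01.1", "B02.2", "C03.3", NA)
  aliases <- structure(list("beta disease" = "bd"),
                       class = "dx_alias_table")
  for (rep in 1:50) {
    n_models <- sample(2:5, 1)
    cands <- list()
    responses <- lapply(seq_len(n_models), function(j) {
      k <- sample(1:3, 1)
      labs <- sample(labels, k)
      cc <- lapply(seq_len(k), function(i) {
        code <- sample(codes, 1)
        make_candidate(labs[i],
                       codes = if (is.na(code)) character(0) else code,
                       confidence = 0.5, rank = i)
      })
      make_response(sprintf("m%d", j), candidates = cc)
    })
    flat <- list()
    for (r in responses) {
      for (cand in r$candidates) {
        flat[[length(flat) + 1L]] <- list(model = r$model_id,
                                          label = cand$label,
                                          codes = cand$icd10_codes)
      }
    }
    expected <- oracle_components(flat, aliases)
    got <- cluster_candidates(responses, aliases = aliases)
    # compare induced partitions of the (model, label) pairs
    pair <- vapply(flat, function(x) paste(x$model, x$label, sep = "@"),
                   character(1))
    expected_sig <- unname(sort(vapply(expected, function(idx) {
      paste(sort(pair[idx]), collapse = "|")
    }, character(1))))
    got_sig <- sort(vapply(got, function(cl) {
      paste(sort(paste(cl$members$model_id, cl$members$label, sep = "@")),
            collapse = "|")
    }, character(1)))
    expect_equal(got_sig, expected_sig)
  }
})

test_that("cluster canonical label is the modal member label, ties lexicographic", {
  responses <- list(
    make_response("A", candidates = list(make_candidate("FMF", "M04.1"))),
    make_response("B", candidates = list(make_candidate("FMF", "M04.1"))),
    make_response("C", candidates = list(
      make_candidate("Familial Mediterranean Fever", "M04.1"))))
  cls <- cluster_candidates(responses, aliases = empty_aliases)
  expect_equal(cls[[1]]$canonical_label, "fmf")
  # tie: 1 vs 1 -> lexicographically smaller canonical wins
  responses2 <- list(
    make_response("A", candidates = list(make_candidate("Zeta Fever", "Q11.1"))),
    make_response("B", candidates = list(make_candidate("Alpha Fever", "Q11.1"))))
  cls2 <- cluster_candidates(responses2, aliases = empty_aliases)
  expect_equal(cls2[[1]]$canonical_label, "alpha fever")
})

test_that("mixed case ids are rejected", {
  responses <- list(make_response("A", "c1", "X disease"),
                    make_response("B", "c2", "X disease"))
  expect_error(cluster_candidates(responses, aliases = empty_aliases),
               "mix", class = "dx_validation_error")
})
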