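---
title: "Methods: agreement-rate stratification, bias attribution, and the synthetic ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement-rate stratification, bias attribution, and the synthetic ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxensemble)
```

## The model

`dxensemble` treats a multi-model differential diagnosis as a set of
independent opinions to be *stratified*, not aggregated. The pipeline has
three stages.

**Stage 1 — parallel inference with provenance.** Every ensemble member is
described by a provenance profile (`origin_region` in the four buckets
US/Europe/China/Other, `cost_tier` free/paid, optional release date,
parameter class, architecture family). Each model is queried independently
per case and returns a ranked list of candidate diagnoses with ICD-10(-CM)
codes and confidences, or a failure status (`timeout`, `overflow`,
`error`). The orchestration contract is exactly-once accounting — one
recorded status per (model, case) pair — and order independence: results
are sorted, and no downstream statistic depends on execution order or
concurrency.

**Stage 2 — clustering and stratification.** Agreement must be counted
over concepts, not strings, so candidates are canonicalized (lowercase,
punctuation stripped, whitespace collapsed, a trailing parenthetical split
off as an alias) and merged transitively when (a) canonical labels are
equal, (b) an alias table links them, or (c) they share an identical full
ICD-10 code. Category-level (3-character) code merging is opt-in only,
because distinct diseases commonly share a category; fuzzy string matching
is off by default, because a silent merge is precisely the failure mode
the package exists to prevent — it would erase minority diagnoses. Each
cluster's agreement rate is `supporters / denominator` and is classified
with inclusive boundaries: PRIMARY at rate >= 0.30, ALTERNATIVE in
[0.10, 0.30), MINORITY below 0.10. Models are categorized by
majority-alignment rate with the same inclusive-edge convention: high at
>= 0.60, moderate in [0.30, 0.60), low otherwise (0.60 itself is high —
the upper band's inclusive edge is explicit, so the moderate band is
half-open).

**Stage 3 — plurality-preserving presentation.** The full report carries
all three strata, each entry citing its supporters with provenance notes,
plus disagreement notes when a non-primary cluster is supported only by
models sharing one region or tier. The summary view (progressive
disclosure) shows the top consensus entry and a summary uncertainty
indicator — high at consensus >= 80%, moderate at 60–79%, low below 60%,
bands chosen to bracket the consensus range the default conditions
produce (roughly 45–95%) — with an explicit pointer to the full report.
Report assembly is a deterministic template; the failover chain
(`select_synthesizer()`) models a primary synthesis backend with ordered
backups and a complete attempt log, for any pluggable backend.

## Design choices that were genuinely open

**Denominator policy.** The agreement-rate denominator defaults to
*responding* models, not all queried models. Ensembles of remote models
lose members to timeouts and token overflows; counting a silent failure as
a disagreement biases every rate downward and can demote a diagnosis a
stratum. The literal behaviour (`all_queried_models`) is one configuration
flag away, and both are tested.

**Majority alignment.** "Agreement with the majority" needs a definition:
the majority cluster is the top PRIMARY cluster (highest-rate cluster if
PRIMARY is empty), and a model is aligned if *any* of its candidates falls
in that cluster (default) — models return ranked differentials, so
punishing a model for ranking the majority diagnosis second would conflate
calibration with recognition. A `top1` mode is provided.

**Cluster naming.** A cluster's canonical label is the modal
*canonicalized* member label (ties broken lexicographically). Using the
modal verbatim string would let an abbreviation ("FMF") name a cluster
whose other members cannot be mapped back to it.

**Association statistic.** The consensus–breadth association uses Spearman
rank correlation: breadth is a count with a heavy right tail (one
ambiguous case can carry dozens of alternatives), so a product-moment
statistic would be dominated by extremes. At least three cases with a
defined consensus are required; constant series return `NA` rather than a
sign.

**Marker lexicon.** Hedging counts are lexicon-dependent, so the lexicon
is explicit, shipped, and overridable (uncertainty: *may, might, possibly,
uncertain, cannot rule out, unclear, suspected*; confidence: *clearly,
definitive, consistent with, classic, certain*). Matching is
case-insensitive, word-bounded, longest-match-first and non-overlapping:
"cannot rule out" counts once, "certain" does not fire inside
"uncertain". Counts are total occurrences. Both per-case totals and
per-model aggregations are available, and outputs label which
normalization they use (mention rates are per *responding* model).

## The synthetic ensemble generator

No public corpus of per-model differential responses exists, and live
commercial APIs are irreproducible, so the simulator is a first-class
module: it generates the registry and response JSONL the real pipeline
consumes (a drop-in Stage 1) and retains the ground truth for recovery
tests.

The generative model, per (model, case):

- **Profiles**: region drawn from (US 0.65, Europe 0.10, China 0.16,
  Other 0.09) — the observed composition of a real 30-model ensemble —
  tier free with probability 0.5, release dates in 2022–2025.
- **Proposals**: each pool diagnosis is an independent Bernoulli with its
  probability `p`; if the case has a regional target and the model's
  region matches, that diagnosis gets `p + delta` (validated
  `p + delta <= 1`). Independence is deliberate: it is the simplest
  mechanism that produces the agreement-rate arithmetic downstream;
  correlated-model variants are future work.
- **Ambiguity** `alpha` in [0, 1] does three things: it flattens the pool
  (`ambiguity_pool()` interpolates between a concentrated pool — one
  diagnosis at 0.92, tail at 0.005 — and a flat pool at 0.5), it adds
  idiosyncratic long-tail proposals (each model proposes
  `Poisson(alpha * 0.5)` conditions from a ~60-entry rare-disease list),
  and it scales hedging density (`Poisson(alpha * 8)` uncertainty phrases
  against `Poisson((1 - alpha) * 3)` confidence phrases, written into
  `raw_text` and re-scored with the same lexicon the ingest path uses).
  The long-tail component exists because a fixed small pool saturates: at
  30 models, any diagnosis with `p >= 0.02` appears almost surely, and
  breadth would stop responding to ambiguity. With it, unambiguous cases
  keep narrow differentials (a handful of clusters) while ambiguous cases
  fan out into many near-singleton alternatives — the regime where an
  inverse consensus–breadth relation emerges.
- **Hallucination**: with per-case probability `h` (default 0.05) a model
  adds one out-of-pool speculative diagnosis; it flows through the
  pipeline as a flagged minority finding, never suppressed.
- **Anachronism**: with probability 0.05 a model proposes a historical
  condition from a fixed list, emulating temporal anchoring; the temporal
  attribution axis is mention-rate analysis of such user-specified terms
  (no release-date regression is attempted — a mention count is what the
  phenomenon is).
- **Confidences** decline in rank (rank 1 uniform on [0.6, 0.95], each
  subsequent multiplied by uniform [0.7, 0.95]); they exist to exercise
  ordering and tie-breaking and carry no clinical meaning.
- **Reproducibility**: the seed is mandatory. Every (model, case) pair
  derives its own RNG substream from a 31-bit string hash of
  `(model_id, case_id)` plus the seed, so output is byte-identical across
  runs and independent of evaluation order.

What the simulator does *not* emulate: correlated model errors, prompt
sensitivity, label noise beyond canonicalization variants, ranked-position
biases, case text with clinical content, or any specific commercial
model's behaviour. Passing recovery tests therefore shows the *pipeline*
is sound — injected effects of the stated size are detected with the
stated reliability — not that real ensembles behave this way.

## Numerical and degenerate-input conventions

- Confidences arriving as percentages (75) are detected by value > 1 and
  stored as fractions; values outside [0, 100] are validation errors.
- Rates live in (0, 1]; a zero denominator (no responding models) is an
  error, not a zero.
- An empty registry file is a warning plus an empty registry; duplicate
  model ids and unknown cost-tier tokens are errors naming the id/token
  and row; unmapped free-text regions fall to "Other" with a warning
  (models rarely ship tidy provenance, and refusing to load a registry
  over geography would discard the transparency the registry exists for).
- No-candidate cases produce breadth 0 and an `NA` consensus (serialized
  as `null`), and reports carry an explicit no-candidates banner instead
  of raising.
- Display rounding is integer percent for consensus and one-decimal
  percent for alignment; all stored values are unrounded.
- Pipeline artifacts contain no timestamps by default, so a seeded rerun
  is byte-identical (manifest checksums are md5, with out-dir-relative
  names).
- The per-query time budget is enforced cooperatively: the orchestrator
  measures elapsed time after the client returns and demotes over-budget
  completions to `timeout`; an in-process R client cannot be preempted.

## Problem sizes used in the tests

The test suite exercises: an exhaustive k/n sweep at n = 100 for the
stratum boundaries; ~7,000 small ensembles (up to 10 models x 6
diagnoses) against brute-force inequality evaluation; 1,000 random
ensembles for partition/permutation invariants; 200 seeded runs of the
regional-boost recovery design (delta = 0.4 on p = 0.3, 30 models, 12
cases); 100 seeded null runs for bootstrap-interval calibration of the
cost-tier effect (1,000 resamples each); and 200 seeded ambiguity sweeps
(alpha in {0.1, 0.5, 0.9}, 4 cases each, 16 models) for the emergent
inverse consensus–breadth relation. These sizes keep each property
estimate's Monte-Carlo error well below the asserted thresholds while the
whole suite stays comfortably runnable on a laptop.

## Known limitations

- Clustering is intentionally conservative; true synonyms absent from the
  alias table and sharing no code stay separate, inflating breadth and
  deflating agreement. The remedy is extending the alias table, not
  enabling fuzzy matching blindly.
- The treatment-approach axis (aggressive vs conservative care) is not
  implemented: there is no operational definition of "aggressive" to
  compute from structured responses.
- Live API clients are out of scope by design; the client contract plus
  the mock and synthetic clients define the tested surface.
- Bias attribution is descriptive. Group differences in a 30-model
  ensemble are hypothesis-generating contrasts, not inference about model
  populations; only the bootstrap interval on the cost-tier effect
  quantifies uncertainty, and it resamples models, not cases.

```{r session}
sessionInfo()
```
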