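# dxensemble

Plurality-preserving orchestration of diagnostic model ensembles.

## The problem

When several AI models produce a differential diagnosis for the same
patient, the standard ensemble move — vote, average, gate — throws away
exactly the information a clinician needs: *which* models disagreed, *how
much*, and *why*. A diagnosis proposed by one regionally-trained model and
ignored by the rest may be a rare endemic disease, not noise. `dxensemble`
implements the opposite discipline: run heterogeneous models in parallel,
keep every output, quantify agreement per diagnosis, and attribute
divergence to each model's documented provenance (origin region, cost
tier, release era).

The package is for people building or studying multi-model clinical
decision support: it supplies the orchestration and analysis machinery,
plus a fully seeded synthetic ensemble simulator, so every stage is
testable offline with no commercial model APIs.

## The core computation

For each clinical case, candidate diagnoses from all responding models are
canonicalized and clustered into concepts (exact canonical-label match,
alias-table link, or identical full ICD-10 code; transitive closure). Each
cluster *D* gets an agreement rate

    agreement_rate(D) = |models supporting D| / n

with `n` the number of responding models by default (all queried models by
configuration), and is stratified

    PRIMARY      if agreement_rate >= 0.30
    ALTERNATIVE  if 0.10 <= agreement_rate < 0.30
    MINORITY     if agreement_rate < 0.10

Models themselves are categorized by how often they align with each case's
majority cluster: high (>= 60%), moderate ([30%, 60%)), low (< 30%).
Attribution analytics compare provenance groups: mentions-per-model of a
target diagnosis by region, mean majority alignment by cost tier (with a
bootstrap interval), uncertainty-vs-confidence hedging marker balance, and
the Spearman association between per-case consensus and diagnostic
breadth. Reports preserve all three strata with provenance notes; a
summary mode (progressive disclosure) shows only the top consensus entry
plus an uncertainty indicator.

## Worked example

```r
library(dxensemble)

# a regional-recognition case: every model proposes the rare febrile
# syndrome with probability 0.3; US-origin models get a +0.4 boost
spec <- case_spec(
  "case_fmf",
  c("Familial Mediterranean Fever" = 0.3, "Viral Myocarditis" = 0.6,
    "Pericarditis" = 0.2),
  regional_target = list(diagnosis = "Familial Mediterranean Fever",
                         region = "US", boost = 0.4),
  ambiguity = 0.5)
sim <- simulate_ensemble(simulation_config(list(spec), n_models = 20,
                                           seed = 42))
d <- stratify_case(sim$responses)
d
#> <dx_differential> case case_fmf (20/20 models responding)
#>   PRIMARY (2):  viral myocarditis [75%]; familial mediterranean fever [45%]
#>   ALTERNATIVE (1):  pericarditis [20%]
#>   MINORITY (5):  mixed connective tissue disease [5%]; mast cell
#>   activation syndrome [5%]; ehlers danlos syndrome [5%]; gaucher disease
#>   [5%]; sarcoid like reaction [5%]
```

The two primary clusters were proposed by 15/20 and 9/20 responding
models; pericarditis sits in the alternative band at 20%; five singleton
proposals (5% each) are preserved as minority findings rather than
discarded. `ensemble_summary(d, sim$responses)` reduces this to per-case
analytics (consensus 75%, breadth 8, 7 alternatives, marker totals), and
`build_report(d, registry = sim$registry)` renders the full
plurality-preserving report — minority entries annotated with their
supporters' origin region and cost tier:

```r
s <- mentions_per_model_by_group(sim$responses, sim$registry,
                                 "Familial Mediterranean Fever")
s$effect_descriptor
#> 'Familial Mediterranean Fever': US highest (0.7 mentions/model),
#> Europe lowest (0.0 mentions/model); rates are per responding model
```

The injected +0.4 regional boost is recovered as a higher
mentions-per-model rate in the boosted region.

`run_pipeline()` chains the stages
(simulate/ingest → stratify → attribute → report) with on-disk artifacts
and a checksummed manifest; the same flow is scriptable via the thin CLI
at `inst/cli/dxensemble`.

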