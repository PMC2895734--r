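# phigold

Building and evaluating de-identification gold standards for clinical text.

Clinical free text cannot be shared for research until spans of protected
health information (PHI) — names, dates, ages, locations, health-care
units, phone numbers — have been found and masked.  Reference corpora for
this task are produced by several human annotators whose span annotations
disagree in boundaries and class labels, so before any tagger can be
trained the annotations must be merged into a single *consensus gold
standard*.  `phigold` implements that whole workflow for Swedish-style
electronic patient record (EPR) text:

* **Automatic consensus** — the union of all annotators' spans, resolved
  per overlap cluster: majority vote on the class, the longest span on
  boundaries, label-specificity as fallback (`First_Name` vs
  `Clinician_First_Name` resolves to the more specific), single-annotator
  instances included, because for de-identification high recall matters
  more than high precision.
* **Manual consensus** — refined annotation guidelines expressed as an
  executable ordered rule set: no sub-token spans (*34-årig* is annotated
  whole), `Street_Address`/`Town`/`Municipality`/`Country`/`Organization`
  merged into `Location`, weekdays stripped from dates, generic health-care
  units ("Geriatriken") deleted, largest-span merging, and deletion of the
  `Relation` and `Ethnicity` classes.
* **Inter-annotator agreement (IAA)** — pairwise F-scores treating one
  annotator as reference (P(a,b) = R(b,a), so F is symmetric), pairwise
  matrices with per-annotator totals, and an agreement table of instance
  clusters × class judgments.
* **Class schemes** — configurable label-space mappings for progressive
  class-merging experiments, from the full 28-class catalog down to a
  single generic `PHI` class.
* **A linear-chain CRF de-identifier** — `crf_deid()` fits a conditional
  random field over BIO-encoded tokens (character n-grams up to size six,
  word shape, context windows; L-BFGS on the exact forward–backward
  gradient, compiled core) and returns a classed model with `predict()`,
  `coef()`, `summary()` methods; `cross_validate()` runs document-level
  k-fold evaluation.
* **Evaluation** — exact (token-level span + label) and partial
  (character-overlap + label) matching with one-to-one credit, per-class
  Annotated/Retrieved/Relevant tables, micro/macro P/R/F, and a
  false-positive audit listing every unmatched prediction with context for
  human re-adjudication (system "errors" are often PHI the annotators
  missed).
* **Synthetic data** — a seeded generator of clinical-style documents with
  gold PHI annotations (fictional Swedish lexicons, Health_Care_Unit
  dominant as in real EPR data) plus simulated imperfect annotators with
  tunable miss/boundary-jitter/confusion/spurious rates, so the entire
  pipeline runs and is tested without access to any confidential corpus.

With counts `annotated` (gold), `retrieved` (system) and `relevant`
(correctly retrieved), scores follow the standard definitions
P = relevant/retrieved, R = relevant/annotated, F = 2PR/(P+R).

## Worked example

```r
library(phigold)

# a 200-document synthetic study with three calibrated imperfect annotators
study <- build_annotation_study(synth_config(n_documents = 200, seed = 7))

attr(pairwise_matrix(study, "exact"), "mean_f")
#> [1] 0.6366784

consensus <- build_automatic_consensus(study)
nrow(consensus)           # annotation instances after union + resolution
#> [1] 2222

manual <- apply_guidelines(consensus, study$corpus)   # refined guidelines

cv <- cross_validate(study$corpus, consensus, k = 4,
                     scheme = "manual_gs", maxit = 60, seed = 7)
cv
#> <crf_cv> 4-fold cross-validation: exact F = 0.774, partial F = 0.936
```

The mean pairwise agreement of 0.64 F-score reflects the calibrated
annotator error models (unequal miss rates, boundary jitter, label
confusion, spurious spans).  The CRF recovers the consensus annotation
with exact-match F ≈ 0.77 — held down mostly by the spurious and
boundary-jittered consensus instances no tagger could learn — while
partial-match F ≈ 0.94 shows that most residual errors are boundary
disagreements, not missed instances.

A thin command-line wrapper over the same stages
(`generate` / `iaa` / `consensus` / `experiment`) ships in
`inst/cli/phigold.R`.

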