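---
title: "Consensus gold standards and CRF de-identification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gold standards and CRF de-identification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures behind `phigold`, the
assumptions they make, the parameters that matter, and the design choices
taken where the problem left the design genuinely open.

## The problem

De-identification of electronic patient records (EPRs) is span labelling:
find every stretch of text that is protected health information (PHI) and
assign it a class (`First_Name`, `Full_Date`, `Health_Care_Unit`, ...).
Reference data comes from multiple human annotators working from evolving
guidelines, so the raw material is several *disagreeing* annotation sets
over the same documents.  The package covers the full path from those raw
sets to a trained, evaluated tagger: agreement statistics, consensus
construction (automatic and guideline-based), label-space coarsening
experiments, CRF training, and exact/partial match evaluation — plus a
synthetic-data module so all of it runs without any confidential corpus.

## Data model and conventions

All offsets are 0-based, half-open, character-level; every format is
converted to this convention on read.  Annotation sets are flat: no nested
or overlapping spans within one source, which makes BIO (IOB2) encoding
well defined.  Annotations that are not aligned to token boundaries are
snapped *outward* to whole tokens at BIO-encoding time (and by the
guideline engine), because the refined guidelines forbid sub-token
annotation; the number of snapped spans is reported.  Ill-formed tag
output (an `I-X` after `O` or after a different label) is repaired
IOB2-style to `B-X`, so the decoder accepts output from any sequence
labeller.

The tokenizer splits on whitespace, then splits punctuation off, with
three exceptions that Swedish clinical text demands: hyphenated words
(`34-årig`) stay whole, multi-part numbers (`2010-05-03`, `3/5`,
`08-517 746 12` chunk-wise) stay whole, and known abbreviations keep
their trailing period (`Univ.`, `Avd.`).  The abbreviation list ships as
plain-text data, not code, so it can be extended per corpus.  The
tokenizer guarantees offset consistency: token substrings are non-empty,
whitespace-free, strictly increasing, and concatenation with the
intervening separators reconstructs the text exactly.

## Automatic consensus

The automatic consensus implements a recall-first merge of all annotators'
sets.  Annotations from any annotator whose character spans intersect —
chained transitively — form one *overlap cluster*; "covering almost the
same instance" is operationalised as *any* character overlap (a minimum
overlap fraction is configurable, default 0), which maximises recall and
keeps the relation simple.  Each cluster yields exactly one consensus
annotation:

* **span**: the longest member span, ties broken by smallest start;
* **label**: one vote per annotator (an annotator chained into a cluster
  with several members votes with its longest member's label).  A strict
  plurality wins.  If the top labels tie and form a chain in the label
  specificity order — e.g. `First_Name` below `Clinician_First_Name` —
  the most specific label wins.  Otherwise a fixed, documented label
  order (the catalog order by default) breaks the tie deterministically.
* single-annotator clusters are included by default
  (`include_singletons`), again because recall is the priority for
  de-identification.

Every decision (members, votes, decision path) is written to a
per-cluster audit log.  Properties that hold by construction and are
tested: the consensus has exactly one annotation per cluster; every input
annotation overlaps some consensus annotation; consensus of identical
sets is the identity; and the whole procedure agrees with an independent
brute-force implementation (explicit graph components, literal rule
transcription) over enumerated and randomised studies.

The historical rule list that resolved class mismatches beyond the
specificity principle was never published; the specificity-plus-tie-break
policy is this package's deterministic stand-in, and the policy object
makes it configurable.

## Manual consensus: the guideline rule engine

The refined annotation guidelines are six declarative rules applied in a
fixed order — boundary fixes before label logic, deletions last so the
change log is complete:

1. snap spans outward to whole tokens;
2. relabel `Street_Address`, `Town`, `Municipality`, `Country`,
   `Organization` to `Location`;
3. merge adjacent same-label annotations separated only by
   punctuation/whitespace (addresses and unit names get their largest
   span);
4. strip leading/trailing weekday words from `Date_Part`/`Full_Date`
   spans, deleting weekday-only dates (the `Date_Part`/`Full_Date`
   division itself is kept);
5. delete `Health_Care_Unit` annotations whose surface is only generic
   unit vocabulary ("Geriatriken") — what counts as *generic* is a
   lexicon decision, configurable, because the underlying guideline
   deliberately left "specific unit" to annotator judgment;
6. delete the `Relation` and `Ethnicity` classes.

Every deletion, relabel, merge and boundary move is logged, giving the
bookkeeping identity `|output| = |input| − |removals logged|`, and the
engine is idempotent.  It accepts either the automatic consensus or raw
annotator sets as input, since the historical procedure ("created
semi-automatically") is compatible with both readings.

## Agreement statistics

Agreement between two annotators is the F-score of one set against the
other under the package's matching rules; since precision of (a, b) is
the recall of (b, a), F is symmetric.  The headline "average IAA" is the
micro-average over all instances; per-class scores are available through
the same report machinery.  Chance-corrected coefficients (kappa, alpha)
are deliberately out of scope — span-level F-score is the convention this
pipeline follows.  Whether historical agreement figures used exact or
partial matching is not recoverable, so both are always computed.

## Evaluation

A prediction is **exactly** correct iff some gold annotation has the same
token-aligned span *and* label; it is **partially** correct iff it
character-overlaps a same-label gold annotation (threshold configurable,
default any overlap; label identity is required in both modes).  Matching
is one-to-one — each gold annotation credits at most one prediction and
vice versa — via a left-to-right sweep that pairs each prediction with
the earliest-ending unmatched overlapping gold span.  Because both sets
are internally non-overlapping, this greedy sweep attains the maximum
matching (verified in tests against an augmenting-path optimal matcher on
thousands of random pairs).  Counts follow the
Annotated/Retrieved/Relevant table convention; zero denominators are
reported as 0 with an `undefined` flag rather than NaN.  Micro-averaging
(pooled counts) is the headline aggregate; macro means are also emitted.

The false-positive audit lists every prediction unmatched in exact mode
with ±40 characters of context, in deterministic order, because in
practice a substantial fraction of a de-identifier's false positives turn
out to be genuine PHI the annotators missed — the audit is the interface
for that human re-adjudication.

## Class schemes

A scheme maps every catalog label to a target label or deletion.  The
shipped series `full_28 → auto_2 … auto_6 → phi_1` reconstructs a
progressive merging experiment: drop infrequent identifier classes, fold
clinician/patient name refinements into `First_Name`/`Last_Name` (16
classes), fold relative names and `Age_Over_89` (13 classes), group first
and last names into `Name`, merge locations and dates, and finally map
everything to one `PHI` class.  The exact membership of the historical
intermediate schemes is unpublished; only the 16- and 13-class sizes and
the guiding principles are anchored, so the intermediate schemes are
explicitly **non-canonical** and fully configurable from YAML files.  The
`manual_gs` scheme reproduces the manually refined label set: generic
`First_Name`/`Last_Name`, one `Age` class, `Full_Date`, `Date_Part`,
`Location`, `Health_Care_Unit`, `Phone_Number`, with `Relation` and
`Ethnicity` deleted.  Scheme application conserves spans and counts minus
deletions and composes functorially.

The default 28-label catalog is likewise a documented reconstruction: the
classes named in the study (name refinements, both age and date classes,
the five pre-merge location classes, `Relation`, `Ethnicity`,
`E-mail_Address`, `Social_Security_Number`) completed with four
conventional HIPAA-style identifier classes (`Medical_Record_Number`,
`Profession`, `URL`, `ID_Number`).

## The CRF de-identifier

`crf_deid()` fits a first-order linear-chain conditional random field
over BIO tags.  Features are deterministic per-token strings: lowercased
identity, word shape (`Xx`, `dd`, run-compressed variants), character
n-grams from the token start and end up to `char_ngram_max = 6` —
the one feature-set fact anchored in the study design — orthographic
flags, and neighbour identities within a `context_window` of 1.
Everything beyond the n-gram order is this package's choice, since the
original experiments used an external tool whose full feature set is not
enumerable.  The engine is deliberately pluggable behind the
train/predict contract.

Training minimises the L2-penalised negative log-likelihood
(`0.5 · c2 · ||w||²`, `c2 = 1` by default) with L-BFGS; the gradient
comes from exact forward–backward marginals computed in scaled
(probability-domain) form in compiled code, which avoids per-cell
`log-sum-exp` calls and was verified against numerical differentiation to
~1e-8.  Training is deterministic given the data.  Decoding is Viterbi;
decoded tags pass through the IOB2 repair, so predictions are always
token-aligned and non-overlapping.

Cross-validation splits by *document* (never by annotation) into k folds
of near-equal size under a seeded shuffle, preventing context leakage
between training and test; the study's four-fold setting on 100 documents
yields four folds of 25.  Reports are produced per fold and
pooled over all held-out predictions.

## The synthetic-data module

The generator emulates the study conditions: ~100–200 records of
clinical-style Swedish text with skewed class frequencies
(`Health_Care_Unit` strictly dominant, as in real EPR data), assembled
from sentence templates whose context words carry class signal the way
section headers and stock phrases do in real records.  PHI surfaces come
from entirely fictional lexicons shipped as plain text (names,
Stockholm-area style towns, multiword unit names embedding locations,
programmatic age/date/phone patterns).  Two deliberate wrinkles make the
guideline rules testable: generic-unit distractors are inserted *without*
gold annotation, and some date insertions are preceded by a weekday word
outside the gold span.  Spurious annotator spans never overlap gold, so
oracle bookkeeping stays exact.

An annotator error model has four tunable components: a miss rate, a
boundary jitter (one-token shrink/extend), a label-confusion matrix, and
a spurious-annotation rate.  The defaults — miss rates 0.05/0.10/0.25
across the three annotators, jitter 0.08, confusion 0.96 on the diagonal
with the off-mass on each label's most plausible confusand, 0.4 spurious
spans per document — were derived analytically before running the
pipeline: with per-annotation survival probability
`p = (1−miss)(1−jitter)·diag`, the expected pairwise exact F between
annotators a and b is approximately `2·N·p_a·p_b / (N_a + N_b)`, which
for these settings gives pairwise values near 0.68/0.62/0.60 (mean
≈ 0.63, in the intended 0.60–0.70 band) and clearly unequal per-annotator
totals.  These defaults *are* the study conditions for every calibrated
test; they are not tuned per test.

What the generator does **not** emulate: real clinical language
(morphology, misspellings, telegraphic style), document structure, class
co-occurrence, or ambiguity between `Location` and `Health_Care_Unit`
readings of the same string.  Passing tests therefore demonstrate the
correctness of the pipeline's algorithms and the learnability of
template-structured data — not expected performance on real EPRs, which
is known to be substantially harder.

## Numerical and scale choices

* Degenerate inputs: empty annotation sets are legal everywhere;
  agreement of two empty sets is reported as NaN with a warning; empty
  training data is an error.
* Tie-breaks are total and documented (longest-then-leftmost spans,
  catalog-order labels), so every stage is deterministic under a fixed
  seed.
* The test suite and the acceptance script run the full rehearsal at 200
  documents (~39k tokens, ~2,000 gold instances, ~2,200 consensus
  instances) with `maxit = 60` L-BFGS iterations — sizes chosen so the
  rehearsal exercises every stage at meaningful scale while a complete
  run stays in the minutes range on one CPU; the optimisation is
  effectively converged well before the cap on this data.
* The exhaustive consensus-oracle check enumerates a structured
  sub-family of annotator configurations (all one-annotation-per-annotator
  pairings over a span grid) and complements it with thousands of seeded
  random configurations of up to five annotations, because the full
  configuration space is combinatorially infeasible.

## Known limitations

* The intermediate class schemes and the 28-class catalog are principled
  reconstructions, not the historical artefacts.
* The guideline engine captures the published guideline changes; the
  unpublished case-by-case adjudication rules are represented only by the
  specificity principle and the configurable lexicons.
* The CRF is a solid baseline engine, not a replica of any specific
  external tagger; absolute scores on real data will depend on the
  engine and feature set.
* Synthetic results overstate real-world performance by design (see
  above); the package's claims are about pipeline correctness, measured
  properties, and reproducibility.
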