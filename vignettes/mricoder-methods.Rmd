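---
title: "Predicting MRI billing codes from scanner logs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MRI billing codes from scanner logs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After an MRI exam, a technologist records the procedure billing codes
(Tarmed-style fee-for-service codes) in the radiology information system.
The task is manual, error-prone, and — because some codes may legitimately
be charged several times per exam — not a plain multi-label problem but a
*multi-output* one: for exam $i$ the target is a labelset
$\mathbf{y}_i = [y_{i,1}, \dots, y_{i,q}]$ with $y_{i,j} \in \{0, \dots, K_j\}$,
where $K_j$ is the maximum chargeable count of code $j$.

`mricoder` predicts these labelsets from MRI modality log events alone:
the executed sequences and their acquisition parameters, scanner-table
movements, contrast administration, and approximate patient age. No image
content, no report text.

```{r, eval = FALSE}
library(mricoder)
ds    <- generate_dataset(generator_config(n_exams = 1000, seed = 1))
exams <- assemble_exams(ds$events) |> merge_billing(ds$truth)
```

## Exam assembly

Raw events arrive as a JSON-lines stream (one event per line;
`registration`, `sequence_start`/`sequence_end`, `table_move`,
`contrast_injection`). A registration opens an exam on its scanner; the
exam spans from registration to the end of its last sequence. Aborted
exams — registrations with no completed sequence — are kept and flagged,
but excluded from model fitting by default, since they carry empty
labelsets. Malformed lines, events before any registration and orphan
sequence ends are never dropped silently: every stage attaches a rejects
report (`side_report()`).

Billing records join either by exam id or by timestamp (record time
within the exam span ± a configurable tolerance, default 30 minutes).
Two scanners operating concurrently make pure-timestamp matching
genuinely ambiguous, so a record may carry a `scanner_id` to restrict
candidates; an irreducibly ambiguous record is an error, not a guess.

## Sequence-name standardization

User-defined sequence names ("t1_tse_tra_fs" vs "t1_tse_fs_tra") encode
the same acquisition under different strings, and names carry site-specific
decoration — body region, slice thickness, post-contrast delay — that says
nothing about the sequence itself. `standardize_names()` therefore derives
a canonical name *from acquisition parameters*, not from the string:

* weighting from b-values (diffusion), inversion time (FLAIR band
  1800–3000 ms, STIR band 100–250 ms), then the TR/TE quadrant
  (t1: TR < 800 & TE < 30 ms; t2: TR ≥ 2000 & TE ≥ 60; pd: TR ≥ 2000 &
  TE < 30; gaps map to no weighting token);
* fixed token order: weighting, technique, `fs`, orientation, `bh`;
* diffusion EPI renders as the fused token `ep2d_diff` with no separate
  weighting token, matching radiological naming convention;
* oblique orientations render as the dominant axis, with `tra` as the
  tie-break;
* the raw name is consulted only as a last-resort keyword scan when the
  structured technique field is unusable.

All thresholds live in `standardizer_rules()` because the TR/TE bands that
separate weightings shift with field strength and sequence family; the
defaults are conventional 1.5–3 T values. The map is deterministic and
idempotent, and can only compress a vocabulary, never grow it.

## Features

`featurize()` turns one exam into a fixed-length numeric row:

* counts per standardized sequence name over a vocabulary fitted on
  training exams only (counts, not presence — repeat acquisitions are
  exactly what surcharge codes bill for); unseen names at prediction time
  land in a reserved overflow bin so the dimension never changes;
* total acquisition time ACQ (sum of sequence durations, seconds), idle
  user-operating time UOP (span − ACQ, clipped at 0), and the UOP/ACQ
  ratio — MR-guided biopsies spend most of the exam *not* scanning, so
  this ratio separates them sharply from diagnostic exams. ACQ = 0
  (aborted) yields ratio 0 by convention; the aborted flag carries the
  signal, avoiding infinities;
* table-movement summaries: total |Δposition|, min/max position, and the
  mean |step| between consecutive sequence starts (start-time order is
  canonical, making every feature invariant to how the sequence list is
  stored) — whole-body sweeps and biopsy in/out cycles have unmistakable
  shapes here;
* contrast flag, approximate age, coarse coil-group indicators
  (head/spine/body/extremity/breast/other via configurable regexes —
  element names are scanner-specific, groups are not), and the sequence
  count.

No scaling happens in `featurize()`; z-scoring is owned by the model so
that cross-validation folds fit it on their own training rows only.

## Label cleaning

Three rules, applied in a fixed idempotent order by `clean_labelsets()`:

1. drop non-imaging-related codes (i.v. access, sedation): they are not
   predictable from modality logs;
2. truncate counts above the per-code maximum $K_j$ (tariff rule
   violations), logging every correction;
3. prune codes charged in fewer than 20 training exams ("instances" are
   exams containing the code, not units): below that there is too little
   signal to learn, and the pruned tail is economically negligible
   (`removed_reimbursement_share()` reports its tariff-point share,
   ~0.2% under the default generator).

Pruning uses training data only; the kept-code list then defines the label
space everywhere. Held-out labels get rules 1–2 (mirroring a manually
ground-truthed test period) via explicit calls, never implicitly.

## Models

Every classifier is a *problem transformation* over a pluggable per-label
base learner (`base_spec()`): a single-hidden-layer MLP (`nnet`), an RBF
SVM (`e1071`), or a random forest (`randomForest`). Each per-label problem
is multi-class over $\{0, \dots, K_j\}$ as observed in training; a label
with one observed value becomes a constant predictor.

* **Binary relevance** (`fit_binary_relevance()`): one independent
  classifier per code. Fast, robust, blind to label dependencies.
* **Classifier chain** (`fit_chain()`): classifiers along a label order;
  position $p$ consumes the features plus the labels at positions
  $< p$ — true values (hard labels) during training, the chain's own
  sequential predictions at inference.
* **Ensemble of classifier chains** (`fit_ecc()`): $n$ chains with
  independently drawn random label orders (duplicates allowed);
  per-label majority vote. Vote ties break toward the *smallest* count:
  when the ensemble is undecided, prefer undercharging — a deterministic,
  deliberately conservative coding policy.

Billing codes are interdependent — an additional-series surcharge exists
only alongside a main procedure code — which is exactly the structure
chains can exploit and binary relevance cannot.

Hyperparameters are tuned by `tune_base_spec()`: exhaustive grid, k-fold
cross-validation (default 10) on training data, winner by mean
micro-averaged F1, fully seeded so the CV table is reproducible.

## Evaluation

Confusion counts for count-valued labels use a unit-expansion convention:
with truth $t$ and prediction $p$ for one code, TP $= \min(t,p)$,
FP $= \max(0, p-t)$, FN $= \max(0, t-p)$, and TN $= K_j - \max(t,p)$ unit
slots. Precision, recall and F1 ignore TN, so the TN convention is inert
for every reported score; it is defined for completeness. Micro averages
pool TP/FP/FN over codes before applying the metric (frequency-weighted;
the standard pooled form — a printed variant with a $1/q$ prefactor would
break the $[0,1]$ semantics of precision and recall and is not used);
macro averages per-code scores with equal weight. Zero denominators yield
0 with a warning.

Dataset descriptors: label cardinality (mean charged units per exam — a
twice-charged code contributes two), density (cardinality over the code
universe size, passed explicitly since conventions differ on the
denominator), and diversity (distinct labelsets). Subset accuracy is the
exact-match fraction — all codes, all counts.

Beyond scores: `prevalence_f1_correlation()` (Spearman, average-rank
ties, restricted to imperfect codes) quantifies whether rare codes are
the badly predicted ones; `reimbursement_delta()` prices under- and
overcoding in tariff points; `paired_comparison()` gives the
both/auto-only/manual-only/neither quadrant fractions of two coders
against ground truth.

## The synthetic generator

No public MRI log corpus exists, so `generate_dataset()` fabricates one
with the statistical structure the pipeline assumes. Eight procedure
templates (head ± contrast, neck, spine, knee, abdomen, whole-body,
MR-guided biopsy) each define a sequence plan over twelve acquisition
archetypes, idle-gap and table-movement behaviour (static / stepped /
whole-body sweep / biopsy cycles), contrast probability, a base labelset
and conditional auxiliary-code rules. Study conditions baked into the
defaults: expected imaging-code cardinality ≈ 4.1 units per exam
(hand-computed from the rule tables; empirically 4.05 at n = 5000), neck
exams averaging ≈ six codes, biopsy idle ratios several times the
diagnostic median, whole-body table movement far above every static
template, and a rare code tail (~1–2% within single templates) that the
pruning rule removes at realistic training sizes.

Two design principles matter for interpretation:

* **Labels first, logs second.** The labelset is drawn from the template
  rules, then the sequence list is emitted *consistently with it*: every
  auxiliary count leaves a deterministic footprint (extra series repeats,
  angiography runs, 2×CM-series post-contrast acquisitions). Labels are
  therefore identifiable from log features with zero label noise — which
  is what lets an end-to-end test demand micro F1 ≥ 0.95 and what makes a
  perfect score on synthetic data *unsurprising*. Passing says the
  pipeline recovers recoverable structure; it says nothing about the
  noise, protocol drift, analogous coding and inter-site variation of
  real hospital data.
* **Auxiliary codes are conditional only.** Surcharges are never drawn
  marginally, so the main→auxiliary dependency that motivates classifier
  chains genuinely exists in the data.

Raw names are decorated with the site-specific token classes the
standardizer removes (region, thickness, post-CM delay, accelerator tags)
at random positions, and the structured technique field is occasionally
degraded to exercise the raw-name fallback. With only twelve archetypes
under heavy decoration, the corpus-level name-reduction fraction (~99%)
is much higher than a real site's, where hundreds of true protocols
remain after standardization; tests assert archetype recovery, not a
specific percentage.

`simulate_technologist()` models manual coding errors: each charged unit
is forgotten independently (auxiliary surcharges at an elevated rate —
they are added by hand to the main service and dominate real coding
errors), and spurious units are added per exam at a lower rate. With
forgetting dominating addition the simulated coder reproduces the
characteristic asymmetry of manual coding: precision above recall.

## The constructed dependency scenario

The test suite proves the chain advantage on a minimal constructed case:
main label A has three interval classes along one feature (masses
0.5/0.25/0.25), auxiliary label B = 1(A ≥ 1). Strict feature-independence
of B together with high chain accuracy is impossible — a chain's
prediction is itself a function of the features — so the scenario encodes
a *learnability* gap instead: a size-1 MLP is monotone in one projection,
which represents A's interval classes exactly but cannot represent B's
two-sided acceptance region. Binary relevance is then pinned near the
best single-threshold rate (~0.75), while a chain ordered (A, B) reaches
≥ 0.95 on B through its predicted A, and the 10-chain ensemble's median
micro F1 beats binary relevance across seeds.

## Reproducibility and numerical conventions

All randomness flows from explicit integer seeds (generator, fold
assignment, chain orders, base learners); two pipeline runs with the same
`pipeline_config()` produce byte-identical evaluation reports, which the
tests assert literally. Timestamps are second-resolution ISO-8601 UTC;
durations are seconds; UOP clips at zero; ratio and rate conventions for
degenerate denominators are 0-with-warning throughout. The temporal
train/test split holds out the final contiguous fraction by registration
time (default 30%), emulating evaluation on a final month of operations;
a random split is available by flag.

Default problem sizes in the test suite (up to 2000 exams, 10 chains,
hidden width 6–8) were chosen as the smallest sizes at which the
end-to-end properties are comfortably stable.

## Limitations

* The generator emulates structure, not a real site: real logs carry
  vendor-specific payloads, protocol drift, inter-technologist variance
  and analogous-coding conventions that no synthetic corpus captures.
  It also emits only completed exams; aborted exams (registration with
  no completed sequence) are handled and tested at the assembly layer
  but not simulated.
* The code-definition table is a structural stand-in (counts, flags,
  points), not the actual tariff catalogue, and encodes no inter-code
  legality rules beyond per-code maxima.
* Non-imaging codes are excluded as unpredictable from logs; a deployed
  coding aid would need another data source for them.
* Chain augmentation uses hard labels; probability-weighted augmentation
  and calibration are out of scope.
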