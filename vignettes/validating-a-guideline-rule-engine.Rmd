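---
title: "Validating a guideline rule engine: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a guideline rule engine: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsrules)
```

`cdsrules` models a knowledge-based clinical decision support (CDS) engine
for type 2 diabetes and packages the analytical-validation protocol such an
engine needs before it can face clinicians. This vignette explains the model
and its assumptions, the tunable parameters, what the synthetic data do and
do not emulate, the numerical choices, and the design decisions taken where
the design was genuinely open.

## The rule model

A knowledge base is organized into four chapters (glycemic management,
dyslipidemia, blood pressure control, anti-platelet therapy), each holding
typed rules over a shared parameter catalogue and a substance → medication
class table. The engine is brand agnostic: only medicinal substances are
recognized, and each maps to exactly one class.

Conditions are finite boolean trees over parameter comparisons
(`<, <=, ==, >=, >, in`), regimen predicates (`takes_class`,
`takes_substance`, regimen size) and — for annotation and inter-chapter
rules — predicates over a draft recommendation. The language deliberately
excludes arithmetic between parameters: every condition is then decidable
over a finite discretization, which is what makes the coverage and ambiguity
checks below exhaustive rather than heuristic.

Evaluation is a fixed pipeline:

1. **Main rules** (per chapter, grouped in clusters) generate drug
   recommendations. A chapter in which no main rule fires yields an explicit
   `no_change` outcome rather than silence, so every single-chapter test
   case carries a label.
2. **Safety rules** withdraw, substitute or annotate recommendations of
   their own chapter (contraindications such as SGLT2 inhibitors below
   eGFR 30).
3. **Inter-chapter rules** act across chapters (e.g. diuretic–SGLT2i volume
   depletion, incretin duplication).
4. **Master rules** run last among the modifying layers because they may
   overrule anything the earlier layers did; the rule set orders types by
   precedence, and "can overrule the others" pins master after safety and
   inter-chapter. Procedural master behaviour that resists a declarative
   condition/action form can be registered as a hook
   (`evaluate_record(..., master_hooks = )`), applied after the declarative
   master rules and audited like a rule.
5. **Annotation rules** mark each add/replace recommendation *by addition*
   or *by replacement* and, where an aim rule matches, *cardiorenal
   protection* or *glycemic control*. Annotation never alters drug content
   and is idempotent; an unmatched add/replace recommendation produces a
   completeness warning in the audit trail, not an error.
6. **Renal dose adjustment** looks the recommended agent up in the dose
   table (substance entry first, then class) and attaches the eGFR band's
   guidance; an eGFR above all bands means standard dosing, a missing eGFR
   withholds guidance with an explicit "not assessed" flag.
7. **Feedback rules** emit hints; they are structurally unable to change
   recommendations.

Within every layer rules apply in `(priority, id)` order — priority is an
explicit integer, ties break lexicographically by rule id — and later rules
see earlier rules' effects. Identical input and knowledge base therefore
give byte-identical serialized output, which the test suite asserts.

## Static verification of a rule set

`validate_knowledge_base()` is the machine analogue of a second expert
reviewing the rule set: duplicate ids, missing references, dangling
parameter or class names, malformed conditions and overlapping dose bands.
With a catalogue it additionally enumerates each chapter's discretized
scenario space — numeric parameters at range endpoints plus midpoint, both
flag states, each referenced medication class present/absent — and reports
clusters in which two main rules are simultaneously satisfiable.
`check_cluster_exhaustiveness()` reports scenarios no main rule covers;
together (no uncovered scenario, no ambiguous cluster) they imply exactly
one main rule fires per scenario, which the suite asserts by enumeration on
the demo knowledge base.

This soundness is relative to the discretization: a rule whose behaviour
changes strictly between two representative values would be missed. With
threshold-only comparisons the representative set can in principle include
every threshold's two sides; the default (endpoints + midpoint) is a
documented compromise between fidelity and scenario-space size, capped at
10^5 scenarios with a refusal above the cap.

## The parameter catalogue

The catalogue is configuration, not code: roughly twenty parameters with
units following Canadian convention (HbA1c in % NGSP, lipids in mmol/L,
eGFR in mL/min/1.73 m², blood pressure in mmHg) and plausible ranges such
as HbA1c 3–20% or eGFR 0–200. Unit conversion is out of scope — a value
supplied in the wrong unit lands outside its range and surfaces as an
`out_of_range` issue. A parameter is `missing` only when a requested
chapter requires it; the demo catalogue requires `sex` in no chapter
because no demo rule references it. Validation is total (bad clinical
values are reported, never thrown) and idempotent; malformed *catalogues*
are configuration errors, kept distinct from clinical-value issues.

## Synthetic case generation

`generate_case_inputs()` draws medically plausible single-chapter records
under explicit constraints: numeric parameters uniform over their
(optionally tightened) catalogue range, rounded to one decimal; boolean
flags Bernoulli with a per-flag prevalence; regimens of 0–3 medication
classes from the chapter's agent list, one random substance per class.

Two defaults deserve justification. Flag prevalence is 0.5 — not an
epidemiological estimate but a scenario-coverage choice: validation cases
should exercise both branches of every comorbidity-gated rule roughly
equally. Pregnancy is the exception at 5%, since an overwhelmingly pregnant
cohort would mask the chapters' ordinary behaviour behind the master
override. The generator draws parameters independently: it does **not**
emulate correlated comorbidity structure (low eGFR co-occurring with CKD
flags, age with ASCVD), so a passing validation says the engine handles
every constraint-respecting combination, not that the case mix resembles a
clinic population. That is the right target for rule validation — the rare
corner combinations are exactly where rule sets break — but it means
observed recommendation frequencies in generated cohorts should not be read
as clinical prevalence.

Randomness is reproducible end to end: one root seed, with each stage
(generation per chapter, PN placement, PN mutation per case, reviewer
assignment) drawing from its own derived stream, so adding cases to one
stage never reshuffles another. `sampler_uniformity_test()` checks the
numeric sampler against its exact expected bin masses (the one-decimal
rounding gives the two endpoints half the interior mass), at the
conventional α = 0.001 for sampler sanity at n = 10,000.

## Predicted negatives

To estimate reviewer error, a fraction of cases (default 5%) is converted
into negative controls whose presented recommendations deliberately do not
match the engine: either by swapping in another case's prediction or by
altering a recommended agent to a different class. In the original
protocol this corruption was a manual expert step; here it is seeded and
automatic, with the human judgment replaced by a mechanical guarantee —
every mutated case is re-evaluated and must differ from the engine's true
output, retrying with a different draw on accidental agreement and failing
after a bounded number of retries (which would indicate a degenerate rule
base). Polarity labels live with the experimenters only; the
reviewer-facing export is generated without the field, and a test
string-scans the export for leaks.

## Study allocation, assignment and adjudication

Integer allocation over chapters uses largest-remainder rounding of the
chapter shares (0.3/0.3/0.3/0.1 by default), and the PN total is
`round(pn_fraction × total)` apportioned the same way — at the reference
design of 1000 cases and 5% this gives 15/15/15/5. The study that motivated
this design reported per-chapter sample-size targets of 271/271/271/101
plus 86 buffer cases described as evenly distributed, yet printed chapter
totals of 297/297/297/109 — an internally inconsistent buffer split
(26/26/26/8). The allocator therefore accepts an explicit per-chapter
buffer vector, defaulting to proportional-to-share largest-remainder; the
published totals are reproduced by passing the explicit vector. The
271/101 targets themselves are accepted as configuration and never
re-derived; the packaged sample-size helper is the standard binomial
normal approximation `⌈z²p(1−p)/d²⌉`, a re-derivation chosen because no
authoritative formula was available to copy.

Reviewers are chapter experts with fixed quotas; assignment shuffles within
chapter under a seeded stream and deals PN cases round-robin so same-chapter
reviewers differ by at most one. Phase-1 answers are yes / no / not-sure,
with comments mandatory for no and not-sure. Phase-2 adjudication may move
only no/not-sure answers (a transition on a phase-1 yes, or on a PN case,
is a protocol error), may land on yes, no, not-sure or missing, and is
idempotent: the output carries the phase-1 answer alongside the final one,
so re-applying the same transitions is a no-op.

Metrics follow the study's definitions. Precision = TP/(TP+FP) over
predicted positives, excluding not-sure and missing from the denominator;
PN cases are excluded from precision entirely. The study labels a "yes" on
a PN case *TN* — idiosyncratically, since it is a reviewer **error** — and
defines reviewer error rate = TN/PN; the implementation keeps that label in
outputs for comparability and additionally reports the PN
correct-rejection count. "Missing" (responses never finalized) is a
first-class answer state excluded from every metric denominator. Accuracy
= (TP+TN)/final-valid-n keeps not-sure in the denominator; this is an
interpretation, flagged here because no reference value exists to calibrate
against. Undefined precision (no yes/no responses) renders as `n/a`, never
0 or 100.

## Numerical and testing choices

* Prediction equality is decided on canonical JSON of the clinical content
  (recommendations, hints, safety notes — not the audit trail); compact
  FNV-1a digests are used only for baseline bookkeeping, where a collision
  could at worst hide a change, never fabricate a PN mismatch.
* The engine's oracle in the test suite is a naive interpreter — flat loops
  in precedence order, its own condition evaluator, no shared engine code —
  compared over exhaustively discretized chapter spaces (about 15,000
  scenarios across the four chapters, including eGFR, potassium and
  pregnancy values that trigger the safety and master layers) and the
  comparison is on order-insensitive content summaries.
* The safety-soundness scan draws 2,500 random valid records per chapter
  (10,000 total) and asserts that no output recommendation matches the
  target of any removing safety rule whose condition the record satisfies.
* The predicted-negative guarantee is exercised over 1,000 seeded mutations
  (125 cases per chapter × two strategies), all of which must fail the
  re-evaluation equality check.
* These problem sizes are the package's test-scale defaults; all scale
  linearly and can be raised in user code.

## Demo knowledge base and limitations

The packaged knowledge base (~40 rules) paraphrases guideline-style
statements that are common knowledge in diabetes care — SGLT2i/GLP-1RA for
cardiorenal protection, statin/ezetimibe lipid management, ACEi/ARB-first
blood-pressure control at the 130/80 mmHg diabetes threshold, antiplatelet
therapy only for established ASCVD, and insulin *without* metformin as
primary therapy in metabolic decompensation (distinct from symptomatic
hyperglycemia, where metformin is co-recommended). It is illustrative: it
carries a "not for clinical use" banner, covers a deliberately small
substance vocabulary, and its dose table holds a handful of agents. A
production rule base would replace these files wholesale; everything in the
package operates on the loaded configuration, not on constants.

Known limitations: ambiguity/coverage checking is sound only over the
finite discretization; the condition language cannot express inter-parameter
arithmetic (by design); generated cohorts have independent, not correlated,
parameters; insulin titration arithmetic beyond dose-table lookup, web/EHR
integration and terminology-server mapping (RxNorm/ATC) are out of scope.

## The bundled external-review dataset

`example_validation_study()` expands packaged count tables — phase-1
answers and phase-2 adjudication transitions per chapter and polarity from
a two-phase external expert review of a four-chapter T2D rule base (18
reviewers, 1000 cases, 950 PP / 50 PN, 4 finally missing) — into per-case
records with synthetic ids. The counts are the dataset's substance; the
expansion merely gives the adjudication and metric functions real rows to
work on. Every number the README or the acceptance script reports
(precision 95.5% overall, 894 TP, 42 FP, 10 final not-sure, reviewer error
12%) is recomputed from these fixtures through the same
`apply_adjudication()` → `compute_study_metrics()` path a live study would
use.
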