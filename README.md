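# cdsrules

A rule-based clinical decision support (CDS) engine for type 2 diabetes and
its cardiorenal comorbidities, together with the full machinery needed to
validate such an engine analytically.

People with type 2 diabetes carry a high burden of cardiovascular and renal
disease, and guidelines now recommend cardiorenal-protective agents (SGLT2
inhibitors, GLP-1 receptor agonists) for many of them — yet most eligible
patients never receive one. Knowledge-based CDS systems address this by
mapping a patient's clinical parameters and current regimen to referenced,
guideline-directed treatment recommendations. Before such a system can be
trusted it must be validated: against itself (regression baselines), against
enumeration (scenario coverage), and against blinded human experts
(precision on randomly generated cases, with deliberately corrupted negative
controls to estimate reviewer error). `cdsrules` implements both halves —
the engine and the validation protocol — for R users building or studying
computable guidelines.

**The packaged knowledge base is demonstration content and not for clinical
use.**

## The engine

A knowledge base is a YAML document with four *chapters* (glycemic
management, dyslipidemia, blood pressure control, anti-platelet therapy) and
seven typed rule kinds:

| Rule type | Role |
|---|---|
| main | generate drug recommendations from clinical parameters + current regimen; grouped in clusters that partition the scenario space |
| safety | withdraw or annotate recommendations within a chapter (contraindications) |
| inter-chapter | cross-chapter modifications (drug–drug interactions) |
| master | highest precedence; may overrule any other rule |
| recommendation type | annotate *by addition* vs *by replacement* |
| treatment aim | annotate *cardiorenal protection* vs *glycemic control* |
| feedback | clinical hints; structurally unable to alter drug content |

Evaluation is a fixed deterministic pipeline — main → safety →
inter-chapter → master → annotation → renal dose adjustment → feedback —
with every effect recorded in an audit trail, and a complete reference list
on every recommendation. The engine recognizes medicinal substances only
(never brands) and classifies them into medication classes.

## The validation protocol

Single-chapter test cases are drawn by a constrained random generator
(`generate_case_inputs()`), paired with the engine's output ("prediction
labels", `build_test_cases()`), and snapshot as regression baselines
(`baseline_snapshot()` / `compare_to_baseline()`). For external review, a
fraction of cases (default 5%) is converted into *predicted negative* (PN)
controls by swapping or altering the recommendations
(`make_predicted_negative()`), with a re-evaluation check guaranteeing the
corrupted labels no longer match the engine. Cases are assigned blind to
chapter-expert reviewers (`assign_cases_to_reviewers()`); phase-1 yes /
no / not-sure answers are revised in a moderated phase-2 interview
(`apply_adjudication()`), and the final metrics are

- precision = TP / (TP + FP) over predicted-positive cases, excluding
  not-sure and missing responses;
- reviewer error rate = (yes answers on PN cases) / PN;
- accuracy = (TP + TN) / final valid n.

The binomial sample size for a target precision CI is
`n = ⌈z² p(1−p)/d²⌉` (`required_sample_size()`).

## Worked example

```r
library(cdsrules)
kb        <- load_demo_knowledge_base()
catalogue <- load_demo_catalogue()

rec <- patient_record(
  params = list(age = 67, hba1c = 8.4, egfr = 38, ascvd = FALSE, hf = TRUE,
                ckd = FALSE, metabolic_decompensation = FALSE,
                symptomatic_hyperglycemia = FALSE, pregnancy = FALSE,
                frailty = FALSE),
  regimen = c("metformin", "gliclazide"))

rs <- evaluate_record(evaluation_request(rec, "glycemic_management"), kb, catalogue)
rs
#> recommendation_set (kb 1.0)
#>   glycemic_management:
#>     - add_class SGLT2i [by_addition; cardiorenal_protection; reduced dose; monitor renal function]
#>   hints: 2
#>   audit entries: 6
```

The patient is above the HbA1c target with heart failure and no SGLT2
inhibitor on board, so the engine adds one *by addition*, *for cardiorenal
protection*; at eGFR 38 the dose table returns the reduced-dose band. The
audit trail names each deciding rule:

```r
audit_trail(rs)[, 1:3]
#>                 layer  rule_id    effect
#> 1                main GLY-M-04     fired
#> 2 recommendation_type    RT-01 annotated
#> 3       treatment_aim    TA-01 annotated
#> 4                dose   SGLT2i annotated
#> 5            feedback GLY-F-01     fired
#> 6            feedback GLY-F-02     fired
```

Scoring the bundled two-phase external review (1000 cases, 950 predicted
positive, 50 predicted negative):

```r
st      <- example_validation_study()
final   <- apply_adjudication(st$responses, st$transitions, st$polarities)
metrics <- compute_study_metrics(final, st$polarities)
metrics
#> study_metrics
#>              chapter  pp pn  tp fp not_sure missing tn precision
#>  glycemic_management 282 15 263 15        0       4  1     94.6%
#>         dyslipidemia 282 15 276  5        1       0  2     98.2%
#>       blood_pressure 282 15 267  9        6       0  1     96.7%
#>         antiplatelet 104  5  88 13        3       0  2     87.1%
#>              overall 950 50 894 42       10       4  6     95.5%
```

So overall precision after adjudication is 95.5% (894 true positives, 42
false positives, 10 final not-sure), and the reviewer error rate on
predicted negatives is 6/50 = 12%.

A command-line front end (`exec/cdsrules`) wires the same functions as
`kb-validate`, `evaluate`, `gencases`, `pipeline`, `score` and
`sample-size` subcommands.

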