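---
title: "The lbpcds clinical model: adaptive items, graded rules, and suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lbpcds clinical model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbpcds)
```

## The problem

Most low back pain (LBP) is not dangerous, but it is also rarely given a
diagnosis more specific than "nonspecific LBP", which leaves clinicians
without a handle for evidence-based, individualised treatment. The
clinical literature does distinguish pain-mechanism categories —
nociceptive, neuropathic and nociplastic pain — and, within them,
specific conditions such as facet joint pain, radicular pain, neurogenic
claudication or piriformis syndrome, each with treatment
recommendations. `lbpcds` implements the inference core of a
clinician-facing decision support tool that operationalises such a
classification: a declarative knowledge base drives an adaptive
interview/examination, Boolean rules turn recorded findings into graded
*working diagnoses* with full traceability, and accepted diagnoses map
to treatments and patient education.

A working diagnosis is deliberately provisional: rather than a
probability, each diagnosis is graded on a small integer *likeliness
scale* anchored at "less likely" (1) and "more likely" (`scale_max`,
default 5), because history-and-examination evidence for these
conditions cannot be definitive.

## The knowledge base

A knowledge base (JSON canonical; YAML accepted 1:1) declares:

* **Items** — interview, examination, or synthesis questions with a
  response domain (default `{present, absent}`) and an optional
  `enabled_when` Boolean condition. Items without a condition are
  enabled for every patient; conditional items belong to
  microdiagnosis-specific clusters and appear only when indicated.
* **Diagnoses** — macro (pain mechanism) or micro (condition) level,
  each with a Boolean `rule`, an ordered list of `evidence_atoms`, a
  `scale_max`, optional `suppressors`, and linked education materials.
  Every rule atom must also appear in the evidence list, so triggering
  and grading draw on the same findings.
* **Treatments** — applying either to an explicit diagnosis list or to
  `ALL` working diagnoses.
* **Education materials** — plain-text patient handouts.

`validate_kb()` checks every cross-reference, detects enabling-graph
cycles (via strongly connected components of the item dependency
graph), flags micro diagnoses without a macro parent, orphan treatments
or education, and rules that can never trigger. `load_kb()` refuses a
KB with any validation error.

The shipped default KB (`default_kb()`) encodes 44 items — 13 interview
items enabled for all patients, 13 conditional interview items, 1
always-enabled examination item, 16 conditional examination items, and
1 synthesis item — and 12 diagnoses (3 macro + 9 micro). The published
sources fix these counts, the category names, the piriformis-syndrome
rule (a 5-way OR), the nerve-root adaptive cluster (recording "sensory
changes in a nerve root distribution" enables 8 further interview and 6
further examination items), and two treatment facts; everything else is
reconstructed from the cited classification framework and carries
`source: reconstructed` metadata. The census and rule constraints are
enforced by the test suite, so the reconstruction cannot drift from the
published structure.

```{r census}
kb <- default_kb()
kb_census(kb)
```

## Rule semantics

Rules are finite Boolean trees over `(item, response)` atoms with
`and`, `or`, `not` connectives. An atom is satisfied **iff the findings
map records exactly the required response**; an unanswered item never
satisfies an atom. Two consequences worth noting:

* "Absence of evidence" never triggers a diagnosis: an empty session
  triggers nothing.
* A negated atom *is* satisfied by an unanswered item. The default KB
  uses no negation, but KB authors adding `not` nodes should be aware
  that they fire on missing data — a modelling caution, not a bug.

Only one default-KB rule uses `and`: radiculopathy requires nerve-root
symptoms *and* at least one objective neurological deficit, which is
how the underlying framework distinguishes it from radicular pain.

## Adaptive enabling and the active-findings fixed point

Recording and retracting findings changes which items are presented.
Inference never reads raw findings; it reads the **active findings**:
the greatest subset *S* of recorded findings such that every item in
*S* is enabled when enabling conditions are evaluated against *S*
itself. This is computed by iterated removal of disabled items, which
terminates because the enabling graph is required to be acyclic.

A finding whose item becomes disabled (say, after retracting its
enabler) is *retained but inactive*: it is excluded from inference and
from the patient summary, and silently restored if the item is
re-enabled. The alternative — destroying the value — was rejected
because it makes exploratory toggling lossy for the user; the
retained-but-inactive policy mirrors common form-UX behaviour. This is
a design decision, not a published fact about the prototype.

`enabled_items()` is therefore a pure function of the active findings:
any record/retract history reaching the same findings map yields the
same enabled set (property-tested over randomized histories). Display
order is contractual: interview before examination before synthesis,
clusters contiguous (in first-declaration order), declaration order
within a cluster.

## Grading, suppression, ranking

For a diagnosis with `n` evidence atoms of which `c` are satisfied:

* untriggered → `scale_value = 0`;
* triggered → `scale_value = max(1, ceiling(scale_max * c / n))`.

The published sources give only the anchors (1 = less likely,
`scale_max` = more likely), not a formula; ceiling-proportional mapping
was chosen because it is monotone in `c`, reaches `scale_max` exactly
when all atoms are satisfied, and never grades a triggered diagnosis
below 1. With `scale_max = 5` and 5-atom rules the scale simply equals
the count.

**Suppression** models the demonstrated rejection of an overlapping
diagnosis by a stronger competitor (piriformis syndrome by neurogenic
claudication). Suppression pairs are *declared in the KB*, keeping
clinical policy out of engine code: diagnosis D with suppressor C is
marked suppressed iff both rules trigger and C's evidence count
**strictly** exceeds D's (equal counts never suppress). Suppression is
a single pass over pre-suppression counts — it never chains
transitively and never alters counts or scales, only the flag and a
human-readable reason naming the dominating diagnosis.

The output ranking is a deterministic total order: unsuppressed before
suppressed, then likeliness descending, evidence count descending, and
finally KB declaration order as the reproducible tie-break.

Clinicians may accept, reject or reset any diagnosis regardless of the
model output; accepting an untriggered diagnosis is recorded with an
override marker rather than refused.

## Care plans and the exported note

Accepted diagnoses pull in every treatment whose `applies_to`
intersects them plus all `ALL` treatments, de-duplicated, each with its
contributing diagnoses. Treatments are ordered by breadth of
contribution (then KB order) — with no published evidence weights,
breadth is the only principled priority, and the ordering is documented
as provisional. All recommended treatments default to selected;
individual toggles persist in the session and the exported note lists
only selected ones. Education materials are the de-duplicated union
across accepted diagnoses and export as one markdown file per material.
The note itself is deterministic plain text — a pure function of
(session, evidences, plan) — so identical encounters export
byte-identical notes.

## Scenario fixtures and the synthetic generator

Four built-in scenarios mirror the usability-test encounters: acute
nociceptive pain, chronic nociceptive pain, chronic nociceptive pain
with symptoms of neurogenic claudication, and radicular pain. The
published descriptions name only the condition labels, so each fixture
script is the minimal finding set consistent with its label (marked
reconstructed in the narrative); the testable surface is rank and
suppression behaviour, not vignette prose. A fifth fixture,
`multifactorial_scenario()`, reproduces the demonstrated complex
encounter: evidence for all three macrodiagnoses, neurogenic
claudication and nociplastic pain on top, piriformis syndrome triggered
but rejected because claudication's evidence is stronger.

`generate_random_scenario(kb, seed, target_dx)` walks enabled items in
declaration order (re-scanning as answers enable new items), answering
`present` with probability 0.3, otherwise `absent` with probability
0.5, otherwise leaving the item unanswered; evidence atoms of a target
diagnosis are answered with their required response with probability
0.9. The 0.3/0.9 defaults are the package's chosen study conditions:
0.3 produces sparse, clinically plausible encounters that exercise the
adaptive logic without triggering everything, and 0.9 makes a targeted
diagnosis trigger in the overwhelming majority of seeds (two of the
five piriformis atoms are always enabled, so the per-seed trigger
probability is at least 1 − 0.1² = 0.99). Scripts are emitted in
recording order and replay cleanly by construction, since answers are
only ever recorded on currently enabled items.

What the generator does **not** emulate: response correlations within a
patient, demographic structure, prevalence of conditions, or answer
noise/contradictions. Passing tests therefore demonstrate engine
correctness under the declared logic, not clinical validity on real
patients.

## SUS scoring

`sus_score()` implements the standard System Usability Scale: odd
(positively worded) items contribute `rating − 1`, even (negatively
worded) items `5 − rating`, summed and multiplied by 2.5 — scores are
exactly the multiples of 2.5 in [0, 100]. `sus_summary()` reports n,
mean, range and the percentage of respondents above the conventional 68
(above average) and 80 (top decile) benchmarks. Input must follow
instrument order; no reverse-scoring auto-detection is attempted.

## Numerical and testing choices

* All determinism is structural (total orders, declaration-order
  tie-breaks); the only randomness is the seeded scenario generator,
  which saves and restores the global RNG state.
* Property scales: Boolean-evaluator equivalence against a brute-force
  truth-table oracle over all 2^6 assignments for random expressions of
  up to 6 atoms; enablement purity and fixed-point soundness over 1,000
  randomized record/retract sequences; scenario replayability over
  1,000 seeds; evidence-count monotonicity along generated finding
  sequences. These sizes keep the full suite under about two minutes on
  one CPU while exhausting the small state spaces involved.
* Degenerate inputs: empty findings trigger nothing; a diagnosis with
  zero evidence atoms but a `true` rule grades at `scale_max` (vacuous
  full evidence); an empty accepted set refuses to build a plan.

## Limitations

The engine does not screen for red-flag pathology (fracture, infection,
malignancy) — that is an explicit non-goal of the underlying model. It
has no probabilistic calibration: likeliness values are evidence
counts, not posterior probabilities. The default KB's unpublished rules
are reconstructions; they honour every published constraint but should
be reviewed clinically before any real-world use. There is no EHR
integration, terminology binding (ICD-10/SNOMED), or web UI; the
package is the inference core such a front end would call.
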