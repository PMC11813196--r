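# lbpcds — rule-based clinical decision support for low back pain

Most low back pain (LBP) never gets a diagnosis more specific than
"nonspecific LBP", even though evidence-based treatments exist for the
specific pain mechanisms and conditions that drive it. `lbpcds` is the
inference core of a clinician-facing decision support tool for LBP: a
declarative clinical knowledge base drives an adaptive
interview/examination, Boolean diagnostic rules grade *working
diagnoses* on a likeliness scale with per-finding traceability, and
accepted diagnoses map to treatment recommendations and patient
education. It is aimed at clinical-informatics developers and
researchers who need a testable, scriptable rule engine behind an LBP
(or similar) decision-support front end.

## The model in brief

A knowledge base declares items, diagnoses, treatments and education.
Each item `i` carries a Boolean enabling condition `E_i` over recorded
findings; the *active findings* are the greatest subset `S` of recorded
findings with `∀i ∈ S: E_i(S)` (an acyclicity-guaranteed fixed point),
and an item is presented iff its condition holds on `S`. Each diagnosis
`D` has a rule `R_D` (a Boolean tree over `(item, response)` atoms) and
an evidence-atom list of size `n_D`; with `c_D` atoms satisfied,

```
scale_value(D) = 0                                if R_D(S) is false
               = max(1, ceiling(scale_max · c_D / n_D))   otherwise
```

on a "less likely" (1) to "more likely" (`scale_max`, default 5) scale.
A diagnosis with a KB-declared suppressor `C` is rejected by the model
iff both rules trigger and `c_C > c_D` (strict dominance, single pass).
Output is a deterministic total order: unsuppressed first, then
likeliness, evidence count, declaration order.

The shipped knowledge base encodes 44 items (13 always-enabled
interview, 13 conditional interview, 1 always-enabled examination, 16
conditional examination, 1 synthesis) and 12 diagnoses (3
macrodiagnoses — nociceptive, neuropathic, nociplastic pain — and 9
microdiagnoses), including the published 5-way OR rule for piriformis
syndrome and the nerve-root cluster that enables 8 interview + 6
examination items when "sensory changes in a nerve root distribution"
is recorded.

## Worked example

Replay the complex multifactorial demonstration encounter and evaluate
all diagnoses:

```r
library(lbpcds)
kb <- default_kb()
s  <- replay_scenario(multifactorial_scenario(), kb)
evaluate_diagnoses(kb, s)
#> Working diagnoses (ranked)
#>   [#####] Nociplastic pain                 5 finding(s)
#>   [#####] Neurogenic claudication          5 finding(s)
#>   [####.] Central sensitization            2 finding(s)
#>   [###..] Myofascial pain                  1 finding(s)
#>   [###..] Sacroiliac joint pain            1 finding(s)
#>   [##...] Nociceptive pain                 2 finding(s)
#>   [##...] Neuropathic pain                 2 finding(s)
#>   [.....] Radiculopathy                    1 finding(s)
#>   [.....] Discogenic pain                  0 finding(s)
#>   [.....] Zygapophyseal (facet) joint pain 0 finding(s)
#>   [.....] Radicular pain                   0 finding(s)
#>   [###..] Piriformis syndrome              3 finding(s)  (rejected by model)
```

Neurogenic claudication and nociplastic pain each have all (5/5, bar
`#####`) of their evidence findings satisfied and rank above everything
else. Piriformis syndrome *triggered* (3 of its 5 findings are
present), but the model rejects it because its symptoms overlap with
neurogenic claudication and claudication's evidence is strictly
stronger (5 vs 3 findings) — the suppression reason is carried on the
row. Accepting the top two diagnoses builds a care plan whose exported
note lists, among others, "Graded exposure and activity training" with
both diagnoses as contributors:

```r
s <- set_dx_selection(s, "dx_neurogenic_claudication", "accepted")
s <- set_dx_selection(s, "dx_nociplastic", "accepted")
plan <- build_care_plan(kb, s)
cat(export_note(s, evaluate_diagnoses(kb, s), plan))
```

A command-line twin of every capability ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lbpcds.R",package="lbpcds"))')" census --json
#> {"total_items":44,"interview_always":13,"interview_conditional":13,
#>  "examination_always":1,"examination_conditional":16,"synthesis":1,
#>  "diagnoses_total":12,"macro":3,"micro":9}
```

Subcommands: `validate`, `census`, `evaluate`, `scenario`, `interview`,
`sus`.

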