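# medcomplexity

Rule-based clinical decision support for **medication-regimen complexity**.

Complex drug regimens — split tablets, inhaler devices, meal-coupled intake,
multiple daily administrations — burden patients and erode adherence. Rather
than condensing this into a single weighted score, `medcomplexity` screens a
structured medication plan against a catalogue of **61 discrete complexity
factors** in six categories (dosage form, dosage scheme, additional
instructions, patient, product, process). **38** of the factors are detected
automatically from the plan; the rest are reached through patient questions.
The workflow mirrors a pharmacist-led medication review:

1. **Analyze** — parse the plan (a simplified dialect of the German
   standardized medication plan, BMP) and run four rule families:
   * *product rules*, joined to a drug reference via the Pharmacy Product
     Number (PZN): dosage-form factors with device subtypes, palatability,
     training needs, self-measurement;
   * *dosage-scheme rules* over the four-slot dose quadruple
     `morning-noon-evening-night` (e.g. `0.5-0-0.5-0` ⇒ tablet splitting;
     more than two non-zero slots ⇒ frequent administration; any slot ≥ 2 ⇒
     stacked doses);
   * *schedule-level rules*: line count ≥ polypharmacy threshold (default 5),
     same ingredient under different PZNs;
   * *keyword rules*: case-insensitive word-boundary matching of free-text
     instructions (meal-dependent intake fires on *meal, food, eat,
     breakfast, lunch, dinner*).
2. **Interview** — every finding gets a key question (device-specific where
   relevant), eight distinct questions cover factors invisible in the plan
   (e.g. swallowing difficulties), and one open question always comes last.
   Answers are scored by per-question problem predicates (mixed yes/no
   polarities, numeric thresholds); only *confirmed* factors move on.
3. **Plan** — confirmed factors map to optimisation measures:
   recommendations for action (aid / explain / review), training-material
   stubs, and **five substitution algorithms** that query curated
   equivalence groups in the drug reference: alternative strength (whole
   units instead of fragments or stacks), alternative dosage form (liquid /
   orodispersible), extended-release frequency reduction, fixed-dose
   combinations, and prefilled injection devices.

Everything is deterministic: identical inputs give byte-identical JSON
reports.

## Worked example

```r
library(medcomplexity)
kb      <- load_knowledge_base()      # packaged 61-factor catalogue
drugref <- read_drug_reference()      # packaged PZN fixture

sch <- medication_schedule(list(
  medication_row(pzn = "30000002", brand_name = "AmloTab 10",
                 scheme_text = "0.5-0-0.5-0", unit = "tablet"),
  medication_row(pzn = "20000002", brand_name = "GastroProt",
                 scheme_text = "1-0-0-0", unit = "tablet",
                 instructions = "take 30 min before breakfast")))

findings_table(detect(sch, drugref, kb))
#>                 factor_id rows   evidence_type                    evidence
#> 1 only_drug_at_time_point    1    slot_pattern                 0.5-0-0.5-0
#> 2        tablet_splitting    1    slot_pattern                 0.5-0-0.5-0
#> 3          meal_dependent    2 matched_keyword 'breakfast' in instructions
```

Half tablets of the 10 mg product and the breakfast-coupled intake are
flagged, each with its evidence; the first row is also the only drug taken
at its time points. The interview then asks, among others,
*"Do you find it difficult to split your tablets consistently into pieces
that have the same size?"* — answering **yes** confirms the factor and
triggers the planning step:

```r
qs  <- build_question_set(detect(sch, drugref, kb), kb, sch)
ans <- answer_template(qs)                  # everything in non-problem polarity
ans[["q_tablet_splitting@1"]] <- "yes"
conf <- resolve_answers(qs, ans, kb)
plan_measures(conf, sch, drugref, kb)
#> <measure_plan> 2 entries
#>   tablet_splitting: m_splitting_alg [algorithm] -> 1 suggestion(s): AmloTab 5
#>   tablet_splitting: m_splitting_train [training_material]
```

The strength-substitution algorithm proposes the 5 mg sibling — one whole
tablet replaces each half — alongside a leaflet on correct splitting.

## Command line

```sh
Rscript inst/cli/medcomplexity.R analyze --schedule plan.xml --out report.json
Rscript inst/cli/medcomplexity.R interview --report report.json --answers answers.json
Rscript inst/cli/medcomplexity.R kb-stats
Rscript inst/cli/medcomplexity.R synth --out schedules/ --n 50 --seed 1
```

`analyze` exits 0 with a JSON report (findings, question set, config echo,
input digests), 2 on input errors.

## Synthetic ground truth

`generate_schedule()` / `generate_suite()` build fictional plans in which
requested factors are *planted by construction* and every planted condition
is returned as ground truth; `detect()` recovers that ground truth exactly
(set equality per schedule) on the default 50-schedule suite. This replaces
iterative testing against unpublished example plans and is the repository's
headline regression test.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline end to end from the installed package: loads and
validates the packaged knowledge base, prints its structure, regenerates the
50-schedule synthetic suite for the given seed and checks exact ground-truth
recovery, runs one interview/planning pass, and writes the results JSON.

## Files

* `inst/extdata/knowledge_base.json` — the 61-factor catalogue, question
  bank, and measure registry (layout documented in
  `inst/extdata/kb_schema.json`)
* `inst/extdata/lexicon_en.json`, `lexicon_de.json` — keyword lexicons with
  per-entry provenance
* `inst/extdata/drug_reference.csv` — synthetic PZN-keyed product fixture
  spanning every form class, device subtype, and equivalence group
* `vignettes/medication-complexity.Rmd` — the methods vignette: model,
  parameters, design decisions, limitations
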