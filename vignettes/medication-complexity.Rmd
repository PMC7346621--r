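---
title: "Assessing and reducing medication-regimen complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and reducing medication-regimen complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medcomplexity)
```

## The model

`medcomplexity` treats regimen complexity not as a score but as a catalogue
of discrete, individually actionable *complexity factors*: characteristics
of the dosage form, the dosage scheme, the additional instructions, the
patient, the product, or the medication process that can encumber drug
administration. The packaged catalogue holds 61 factors in these six
categories (13/14/8/10/5/11). Its structure encodes three nested
populations:

* **38 automated factors** carry a detection mechanism readable from a
  structured medication plan: the product identifier (PZN) joined to a drug
  reference, the four-slot dosage scheme, the number of schedule lines, or
  keywords in free text (one factor, self-performed complex measurements,
  needs both a product flag and a keyword).
* **14 further factors** cannot be read from the plan but are reachable by
  *distinct questions* — eight questions asked in every interview, some
  covering several factors at once (one question about recent prescription
  changes covers six process factors). Together 52 factors are considered
  by the tool.
* **9 factors** (e.g. health literacy, busy lifestyle) are too diffuse for
  a single question and are catalogued as "not considered"; an open-ended
  question at the end of every interview gives them a free-text outlet.

The pipeline is *analyze → interview → plan*. Detection is deliberately
shallow — attribute joins, slot arithmetic, and word-boundary keyword
matching — because every finding is subsequently validated with the patient
before any measure is proposed. A finding is evidence that a factor *could*
be a problem; only the patient's answer makes it one.

## Detection rules and their assumptions

**Dosage schemes** are the quadruple morning–noon–evening–night. The
grammar accepts 2–4 dash-separated decimal tokens (comma decimals and
simple fractions like `1/2` are normalized); shorter schemes are
right-padded with zeros, matching how plans omit trailing slots. Anything
else — ranges, words, empty — is an *unstructured* scheme that keeps its
text. Parsing is total: no input raises.

The seven scheme rules are pure predicates on the slots: fractional dose on
a solid oral form (splitting), more than two non-zero slots, non-zero noon
slot, any slot ≥ 2 (stacked units), ≥ 2 distinct non-zero doses, free-text
scheme on a non-PRN row (variable dosing), and a slot where no other row is
dosed (stand-alone administration time). Two edge decisions:

* the stand-alone-time rule is suppressed for single-row schedules — with
  one drug there is no administration round from which it stands apart;
* variable dosing is suppressed for PRN rows, which are deliberately
  dose-free and already covered by the as-needed factor.

**Keyword matching** is case-insensitive and word-bounded in the Unicode
sense (a phrase does not match inside a longer letter/digit run: *seafood*
never triggers *eat* or *food*). Only the meal-dependent list (*meal, food,
eat, breakfast, lunch, dinner*) is fixed by the tool's published
description; the other twelve keyword factors ship with curated default
phrase lists marked `"repo-default"` in the lexicon file, and a parallel
German lexicon is provided. Frequency-related factors (once weekly, every
two days or less, fixed interval, PRN) also scan the raw scheme text, where
such phrases are printed in practice. The PRN factor additionally fires on
the row's PRN flag, since the national plan format has a dedicated
as-needed section.

**Product rules** require a resolvable PZN; rows without one skip the
product family with a recorded warning rather than failing the analysis.
Nasal and dermatological preparations count as complexity factors only when
prescription-only, per the catalogue's scoping; the fixture encodes that
flag explicitly since no public rule resolves borderline products.

## Tunable parameters

| Parameter | Default | Where | Rationale |
|---|---|---|---|
| `polypharmacy_threshold` | 5 rows | `detection_config()` | the catalogue names the characteristic (schedule line count) but no cut-off; 5 follows the common polypharmacy convention |
| breath-hold threshold | 5 s | KB question predicates | counselling convention for inhalation technique; the question itself states no cut-off |
| injection-site rotation | > 1 injection per site | KB question predicate | the printed question asks "how frequently" without semantics; modelled as injections at the same site before rotating |
| lexicon | `en` | `detection_config()` | German file ships alongside |
| strength equality | `1e-9` mg | `find_alternatives()` | strengths are catalogue values, not measurements; exact matching with rounding guard |

All predicates and thresholds live in the knowledge-base JSON, not in code,
so local conventions can be changed without touching the package.

## The interview

Key questions instantiate per finding *and per row* — two meal-coupled
drugs yield two questions, each prefixed with its brand name — while
distinct questions instantiate once and the open question is always last.
Question polarity is encoded per question because the catalogue mixes
problem-affirming phrasings ("Do you have problems…?" — yes ⇒ problem) with
competence-affirming ones ("Do you always succeed…?" — no ⇒ problem); a
global yes-means-problem rule would mis-score the latter. Multi-part
questions printed as one cell (e.g. the PRN pair "Do you know the medical
condition…? Do you know what dose…?") are one instance whose sub-answers
combine by OR: any problematic part confirms. The screening half of the
prescription-change question ("Have your drugs changed recently?") carries
an `info` predicate that never confirms on its own — change without
perceived difficulty is not a problem.

A distinct question confirms *all* factors it covers: if a patient cannot
tell similar drugs apart, both the name-similarity and appearance-similarity
factors enter the plan. Open-question text is stored verbatim as a note and
never auto-mapped to a factor.

## Measures and the five algorithms

Each in-tool factor maps to at least one measure: a recommendation for
action (topics: suggest an aid, explain administration, review the
regimen), a training-material stub (leaflet/video identifiers only — the
package deliberately ships no educational content, so no total count of
materials is implied), or a substitution algorithm. The registry holds
exactly five algorithms:

* **A1 alternative strength** — splitting and stacked-dose findings; group
  members whose strength equals the administered slot dose.
* **A2 alternative form** — crushing and swallowing problems; liquid or
  orodispersible siblings at equal strength.
* **A3 frequency reduction** — extended-release siblings matching the total
  daily dose, collapsing several administrations into one.
* **A4 fixed-dose combination** — row pairs whose ingredients and strengths
  co-occur in a combination product *with identical dosing schemes* (an
  extra guard: merging rows dosed at different times would change therapy).
* **A5 prefilled device** — prefilled injectors with identical ingredient
  and strength for non-prefilled devices.

The catalogue flags six factors for algorithms; five algorithms cannot map
those six one-to-one and also leave frequency reduction attached to
anything sensible. We therefore share A1 between splitting and stacked
doses, share A2 between crushing and swallowing, and attach A3 to the
more-than-twice-daily factor alongside its recommendation — the one place
where the "less frequent dosing" strategy, named as the canonical example
of an algorithmic measure, has a trigger. This is a documented
reconstruction; the mapping lives in the KB file and is configurable.

Algorithms only ever return members of the product's curated
`equivalence_group`. Equivalence is an explicit fixture field rather than
inferred ATC matching: no public substitution-equivalence rule exists, and
inference would overreach. Suggestions are advisory; the tool never mutates
a schedule (the test suite contains a helper that applies suggestions
purely to verify the reduction property).

## The synthetic generator

Real plans from the original testing are unpublished, so the generator is
the regression corpus: it *plants* requested factors by construction and
returns the exact list of planted conditions. Determinism discipline keeps
the ground truth exact rather than statistical:

* background rows are clean solid-oral products dosed `1-0-1-0`, at least
  two per schedule, so morning and evening slots are never unique;
* the night slot is reserved for the stand-alone-time recipe;
* recipes that necessarily co-fire another rule record the side effect
  (three administrations per day must use the noon slot and therefore also
  plant the lunch-time factor; a palatability-flagged liquid also plants
  the liquid-oral form factor);
* noise text is drawn from a pool verified to contain no lexicon keyword;
* schedules at or above the polypharmacy threshold plant the
  total-number-of-drugs factor and report it as a conflict when it was not
  requested.

The headline test — detection equals ground truth, as set equality, on a
50-schedule suite covering all 38 automated factors — is exact because the
generator and the rules share the plan dialect. A green suite therefore
establishes internal consistency and regression safety, **not** field
performance: it says nothing about misspelled instructions, non-standard
abbreviations, incomplete plans, or products outside the fixture, all of
which the original work names as real-world failure modes.

## Numerical and format choices

* PZNs are opaque zero-padded 8-character strings; leading zeros are
  significant and integer arithmetic is never applied.
* The knowledge base, lexicons, answers, and reports are JSON (the
  environment provides no YAML parser); the KB layout is documented by a
  JSON-Schema file and enforced at load time by `validate_kb()`, which
  returns violations as data naming record and rule.
* Reports are byte-reproducible: timestamps are opt-in, serialization
  options are fixed, and every input is identified by an MD5 digest.
* Orderings are total and documented: findings by first triggering row then
  factor id (schedule-level last); question instances by finding order,
  then the distinct block, then the open question; plan entries by
  catalogue order, then measure type (algorithm, recommendation, training);
  alternatives by strength, then PZN.

## Known limitations

* No spelling correction, abbreviation expansion, or phonetic drug-name
  similarity — keyword lists must match verbatim at word boundaries.
* The drug reference is a ~70-product synthetic fixture standing in for the
  national product database; coverage of form classes and device subtypes
  is complete, coverage of the market is not.
* Twelve of the thirteen keyword factors use curated default phrase lists;
  sites should review them against local prescribing language.
* No clinical appropriateness checking: substitution suggestions ignore
  renal function, interactions, and pricing, and are meant to be reviewed
  by a health-care professional with the patient.
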