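---
title: "Methods: an oncology extension for OMOP-style observational data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an oncology extension for OMOP-style observational data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(scipen = 15)
library(oncomop)
```

`oncomop` implements the data-model and vocabulary machinery that
observational cancer research needs on top of a generic common data model:
precoordinated cancer diagnoses integrated into a disease ontology,
diagnosis-linked modifiers, nested disease/treatment episodes, rule-based
regimen detection, a vocabulary-driven tumor-registry ETL, and first-line
treatment characterization. This vignette describes the methods, the
assumptions behind them, the tunable parameters, and what the synthetic
test harness does and does not demonstrate.

## The vocabulary store

Everything is driven by a `concept_graph`: a concept table, a typed
relationship table, and the ancestor closure of the `"Is a"` hierarchy.
Files use the distributed OMOP vocabulary dialect (tab-delimited, upper-case
column names, `"S"`/empty standard flag) so real vocabulary exports can be
dropped in; concept validity dates and deprecation are deliberately out of
scope — every concept is treated as currently valid, and the lifecycle of a
precoordinated concept after a source remapping is not modeled.

The closure stores minimum and maximum levels of separation, defined as the
shortest and longest `"Is a"` path lengths. Acyclicity and topological order
come from `igraph`; the min/max levels are a dynamic program over the
topological order (no graph library exposes this closure directly). The test
suite checks the closure against an independent matrix-power oracle — path
existence by boolean powers of the adjacency matrix — on random DAGs of up
to 200 nodes, which is exact and cannot share a bug with the DP.

Newly minted concepts (precoordinated diagnoses) take identifiers from
2,000,000,000 upward — the usual convention for site-local concepts — in
sorted concept-code order, so id allocation is deterministic for a given
graph and input set.

## Precoordination and two-step hierarchy integration

A cancer diagnosis is identified by the triple histology/behavior/topography
(`8520/3-C50.9`). Only *observed* combinations are instantiated: the caller
supplies the combination list, and `precoordinate()` creates exactly one
Condition concept per unique combination with `"Has Histology"` /
`"Has Topography"` links to the component concepts. Behavior participates
through the histology axis: each `HHHH/B` pair is treated as a unit with its
own morphology equivalence, which matches how the component equivalence
tables are built.

Integration is two-step:

1. **Attribute resolution** — the component `"Maps to"` equivalences
   translate histology/behavior into a SNOMED associated-morphology concept
   and topography into a finding-site (body structure) concept.
2. **Equivalence or insertion** — if a disorder exists whose two defining
   attributes *exactly* equal the resolved pair, the precoordinated concept
   maps to it and the disorder is the designated standard concept.
   Otherwise the precoordinated concept itself becomes a standard disorder
   at the intersection: it receives the attribute edges and `"Is a"` links
   to the most specific existing disorders that subsume the intersection
   (morphology attribute ancestor-or-equal of the new morphology *and* site
   attribute ancestor-or-equal of the new site, with non-minimal candidates
   pruned).

Design choices worth recording:

- **The equivalence predicate is exact equality on both axes.** A disorder
  sitting at the intersection but carrying a *coarser* morphology is a
  subsumer, not an equivalent — that is exactly how the fixture encodes
  "carcinoma of breast" relative to `8010/3-C50.9`: its morphology
  attribute is the generic malignant-neoplasm morphology, so the carcinoma
  intersection finds no exact match and the new concept is inserted beneath
  it. The general predicate had to be chosen; exact attribute equality is
  the only rule that reproduces both worked outcomes simultaneously and
  never silently merges distinguishable diagnoses.
- **Polyhierarchy is allowed.** When several minimal subsumers exist the
  concept receives all of them as parents, matching SNOMED conventions; ties
  among multiple *exact* equivalents resolve to the lowest concept id with a
  warning (determinism; the model assumes uniqueness).
- **Fallback root.** If no disorder subsumes the intersection at all, the
  concept is parented under a configured root (the fixture's "Neoplastic
  disease") with a warning rather than left orphaned.
- **Backward compatibility** is structural: integration only ever adds
  concepts and edges, so every pre-existing ancestor/descendant pair
  survives; the tests assert this on the closure and the suite checks parent
  selection against a brute-force subsumer-enumeration oracle on random
  attribute fixtures.
- Integration is idempotent: a concept that already maps, or is already
  standard with parents, is returned as-is.

Finally each precoordinated concept is linked to its cancer type by
topography prefix (any `C50.*` topography links to cancer type: breast);
the longest matching prefix wins, and an uncovered prefix warns rather than
errors, since type linkage is an annotation, not a requirement.

## Clinical layer: modifiers, episodes, deaths

Modifiers (stage, grade, biomarkers, tumor size) are measurements with two
extra fields — the id of the diagnosis row they qualify and a concept naming
its table — enforced to resolve within the same person. Episodes are closed
calendar-day intervals; a child episode must be fully contained in its
parent, parent links must form a forest, and any event linked through
`EPISODE_EVENT` must fall inside the episode's interval. These invariants
are checked both at construction and by a whole-store scan
(`validate_cdm()`).

Death reconciliation unions EHR and registry deaths per person. On a date
conflict the *earlier* date is kept and the person flagged — conservative
for survival estimation, where a late-reported death otherwise inflates
follow-up. The augmentation report is
`100 * additional / n_EHR`, with the zero-EHR-deaths case defined as 0 plus
a warning.

## Regimen detection

The algorithm uses ingredient identity and timing; dose is carried through
(`quantity`) but not used for matching — no dosing rule is defined for
matching in this version, and surfacing dose rules as configuration is left
for future work.

Pipeline, per person:

1. **Normalization** — each exposure resolves to an ingredient via
   `"Maps to"` and ingredient-class ancestry; unresolvable exposures are
   dropped with a counted warning; ingredients outside the antineoplastic
   class are kept but flagged `non_oncologic`.
2. **Ingredient starts** — one event per distinct (person, ingredient,
   start date). Cycle grouping works on these per-administration starts
   rather than on merged eras: merged eras would fuse monthly
   administrations of a single agent into one interval and hide the cycle
   structure. Ingredient eras (gap-bridged intervals, default gap 30 days)
   are still built and reported for continuity analyses.
3. **Cycle grouping** — greedy left-to-right: a cycle opens at the earliest
   unconsumed start, every start within the combination window (default 14
   days) joins it, each start is consumed once.
4. **Matching** — exact ingredient-set equality first; otherwise the
   definition that is a *maximal subset* of the cycle's ingredients
   (tolerates co-medication; a definition with a missing component never
   matches). Exact-only behavior is available behind a flag
   (`exact_only = TRUE`) since the deployed rule is not pinned down.
5. **Assembly** — consecutive same-regimen cycles with inter-cycle gaps of
   at most 90 days (default) merge into one regimen episode; regimen end is
   the last cycle start plus cycle length − 1, extended if jitter pushed an
   administration later so that episode containment holds by construction.
   Lines of therapy number regimens per person in start order; with an
   index diagnosis date, numbering starts at the first regimen on or after
   it.

Defaults (era gap 30 d, window 14 d, cycle gap 90 d) follow common
oncology-analytics practice — cycle lengths are typically 14–28 days, so a
14-day window groups one cycle's administrations without bridging two
cycles, and 90 days separates a treatment break from a new line. All three
are configurable per study.

## Tumor-registry ETL

Registry abstracts arrive as item-number-keyed records (one row per tumor,
columns are item numbers: 400 primary site, 522 histology, 523 behavior,
390 date of diagnosis, 1760 vital status, 1750 date of last contact). This
container was chosen over a fixed-width or XML submission format so the
vocabulary-driven semantics stay independent of any particular registry
dialect; a reader for another dialect only has to produce the same keyed
records. The mapping rules are data, not code: each rule binds an item to a
kind (diagnosis component, date, vital status, categorical/numeric
modifier), a measurement concept, and a value map. Dates follow the
`YYYYMMDD` registry convention; a year-only date resolves to July 1 and is
flagged.

Per record the ETL assembles the combined code, looks it up among the
precoordinated concepts, and writes the condition with its designated
standard concept, the mapped modifiers linked to that condition, a Disease
First Occurrence episode, and a registry death record when the vital-status
item says so. The run report conserves records exactly
(`records_in = mapped + unmapped + rejected`) and the coverage fraction is
`mapped / (mapped + unmapped)` — rejected records (missing required items)
are excluded from the denominator, since they carry no diagnosis to map.

## Characterization

Cohorts are defined by an index condition set expanded through the
hierarchy (`descendants_of`), an optional modifier requirement (e.g.
distant metastasis present, expressed as a measurement value rather than a
separate condition concept, consistent with the modifier design), and
optionally the presence of a treatment-regimen episode on or after index.
First-line therapy is the earliest regimen episode on or after the index
date; regimens group into categories through an explicit map with an
`"Other"` fallback, and untreated members are counted when therapy was not
required. Age at index is index year minus birth year (birth is stored at
year resolution); medians use the average-of-two-central-order-statistics
convention.

## The synthetic harness — what it shows and what it does not

`make_fixture_vocab()` emits a deterministic breast-cancer vocabulary
subtree whose five SNOMED identifiers carry their published values;
`simulate_patients()` generates persons, diagnoses (coded to the integrated
standard concepts), modifiers, planted regimen histories (components
administered at cycle-length intervals, optional jitter of up to ±3 days
and unrelated co-medication), registry abstracts for a configurable covered
fraction, and EHR/registry deaths — all from one seeded stream, with full
ground truth.

Default study conditions: 100 persons (tests use 15–200 depending on the
property; the acceptance-scale detection runs use 200), 60/40 split between
the two fixture regimens, 30% second lines, 3–6 cycles per regimen, 60%
metastatic, 80% registry coverage, 20% EHR death rate, 10% registry-only
deaths among covered survivors. Noise controls default to zero so planted
regimens are exactly recoverable; the noisy configuration (jitter 3 days,
10% co-medication) exercises subset matching and window robustness.

Passing these suites shows the algorithms are correct *under the generative
model*: clean component timing, a small closed formulary, co-medication
drawn independently of cycles. Real pharmacy data adds dose fractionation,
mid-cycle substitutions, overlapping regimens and coding noise that the
simulator deliberately does not model, so recovery rates here are upper
bounds, not claims about field accuracy. Likewise the first-line
distributions computed on synthetic cohorts demonstrate the machinery, not
any real-world treatment-pattern estimate, which would require actual EHR
or claims data.

## Numerical and degenerate-input choices

- Dates are whole calendar days; all intervals are closed on both ends, and
  durations count both endpoints (`end - start + 1`).
- Empty inputs are legal wherever a count can be zero (empty cohort, empty
  death lists, empty detections); division guards define the degenerate
  ratios as 0 with a warning where relevant.
- Ties are always broken toward the lowest concept id, with a warning, so
  every pipeline stage is deterministic and independent of input row order
  (the detection suite asserts order invariance under permutation).
- Known limitations: no OWL/description-logic classification of inserted
  concepts; no probabilistic episode derivation; no radiotherapy or surgery
  episodes; no dosing-based matching; the modifier concept set covers the
  fixture's breast-cancer items only.
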