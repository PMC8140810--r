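# oncomop

An R toolkit for harmonizing oncology data under an OMOP-style common data
model, aimed at observational cancer researchers and CDM ETL engineers.
Cancer data resists the usual condition-code treatment: a diagnosis is a
*combination* of histology, behavior and anatomic site; treatments come as
multi-drug regimens delivered in cycles; and the quantities studies actually
need — first occurrence, progression, lines of therapy — are abstractions
over many low-level events. `oncomop` implements the vocabulary and model
machinery for all of this:

- **Precoordinated cancer diagnoses.** ICD-O-3 codes of the form
  `HHHH/B-Cnn.n` (e.g. `8520/3-C50.9`, lobular carcinoma, NOS, of breast,
  NOS) are instantiated as single Condition concepts — only observed
  combinations — and integrated into a SNOMED-style disease hierarchy by a
  two-step algorithm. Step 1 translates the ICD-O-3 histology and topography
  into their SNOMED *associated morphology* and *finding site* equivalents.
  Step 2 looks for an existing disorder at the exact intersection of the two
  attributes: if found, the ICD-O concept **maps** to it and the SNOMED
  disorder is the standard concept (e.g. `8520/3-C50.9` ↦ 278054005,
  infiltrating lobular carcinoma of breast); if not, the ICD-O concept is
  itself **inserted** as a standard disorder, child of the most specific
  subsuming disorder(s) (e.g. `8010/3-C50.9` under 254838004, carcinoma of
  breast, at the intersection of finding site 76752008 and morphology
  68453008). Insertion only adds edges, so pre-existing hierarchy queries
  keep working.
- **Diagnostic modifiers** (stage, grade, biomarkers, tumor size) stored as
  measurements with an explicit link to the diagnosis row they qualify.
- **Episodes.** `EPISODE` / `EPISODE_EVENT` tables for nested disease and
  treatment phases: a Treatment Regimen episode contains its Treatment Cycle
  episodes, which link down to the individual drug exposures.
- **Regimen detection.** A rule-based algorithm groups ingredient
  administrations into cycles (greedy, within a combination window), matches
  each cycle's ingredient set against HemOnc-style regimen definitions
  (exact set first, then maximal subset to tolerate co-medication), merges
  consecutive matching cycles into regimens, and assigns per-person lines of
  therapy.
- **Tumor-registry ETL.** A vocabulary-driven transformation of
  item-number-keyed registry abstracts into CDM rows — condition with its
  standard concept, linked modifiers, a Disease First Occurrence episode,
  registry death records — with a per-run coverage report, plus EHR/registry
  death reconciliation.
- **Characterization.** Cohort identification with hierarchy expansion and
  modifier requirements, and first-line regimen distributions with category
  grouping.
- **Synthetic fixtures.** A deterministic fixture vocabulary (the breast
  subtree above, with the published SNOMED identifiers) and a seeded patient
  simulator that plants regimen histories, registry abstracts and deaths,
  with full ground truth for validation.

## Worked example

```r
options(scipen = 15)
library(oncomop)

# Integrate the two observed combinations into the fixture vocabulary
res <- integrate_all(make_fixture_vocab(),
                     c("8520/3-C50.9", "8010/3-C50.9"),
                     type_rules = fixture_type_rules())
print(res$report, row.names = FALSE)
#>     icdo_code icdo_concept_id       mode standard_concept_id   parents
#>  8010/3-C50.9      2000000148   INSERTED          2000000148 254838004
#>  8520/3-C50.9      2000000149 EQUIVALENT           278054005
```

`8520/3-C50.9` found its exact SNOMED equivalent (mode `EQUIVALENT`,
standard concept 278054005), while `8010/3-C50.9` had no exact match and was
inserted as a new standard concept (id 2000000148, minted in the 2-billion
local range) under carcinoma of breast (254838004).

```r
# Simulate a population, detect regimens, characterize first-line therapy
sim <- simulate_patients(sim_config(n_persons = 80, seed = 105),
                         graph = res$graph)
det <- detect_regimens(sim$store, sim$graph, fixture_regimen_definitions())
regimen_recovery(det$regimens, sim$truth$regimens)
#> [1] 1

coh <- identify_cohort(
  cohort_definition(254838004,
    required_modifier = list(
      measurement_concept_id = fixture_concepts[["meas_metastasis"]],
      value_concept_id = fixture_concepts[["val_met_present"]]),
    require_systemic_therapy = TRUE),
  det$store, sim$graph)
out <- first_line_distribution(coh, det$store,
  c("2000000131" = "Taxane + anti-VEGF",
    "2000000132" = "Platinum combination"))
print(out$distribution, row.names = FALSE)
#>              category  n  percent
#>    Taxane + anti-VEGF 29 55.76923
#>  Platinum combination 23 44.23077
```

Detection recovered every planted regimen episode (fraction 1); of the 52
cohort members (metastatic, treated), 29 received a first-line taxane +
anti-VEGF regimen and 23 a platinum combination. Registry/EHR death
reconciliation reports the augmentation the registry linkage brings:

```r
m <- merge_vital_status(sim$store$death, sim$registry$deaths)
m$report[c("n_ehr_deaths", "additional_deaths", "percent_increase")]
#> $n_ehr_deaths      [1] 16
#> $additional_deaths [1] 4
#> $percent_increase  [1] 25
```

A thin command-line front end over the same functions is installed at
`inst/scripts/oncomop.R` (subcommands `fixtures-vocab`, `vocab-validate`,
`integrate`, `detect-regimens`, `etl-naaccr`, `characterize`).

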