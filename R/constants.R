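# Enumerations and well-known identifiers shared across modules.

#' Vocabulary enumerations
#'
#' Allowed domain labels and typed relationship labels for concepts held in a
#' [concept_graph]. These mirror the OMOP vocabulary conventions used
#' throughout the package: concepts live in a domain, and concepts are tied
#' together by a small set of typed relationships ("Is a" carries the
#' hierarchy, "Maps to" carries source-to-standard equivalence, the
#' "Has ..." relationships carry defining attributes).
#'
#' @format Character vectors.
#' @name oncomop-enums
#' @keywords internal
NULL

onco_domains <- c(
  "Condition", "Measurement", "Drug", "Procedure", "Episode", "Observation",
  "Spec Anatomic Site", "Meas Value", "Regimen", "Modifier"
)

onco_relationships <- c(
  "Maps to", "Is a", "Has finding site", "Has associated morphology",
  "Has Histology", "Has Topography", "Has cancer type",
  "Has regimen component", "Item-value maps to"
)

# Concept ids naming the CDM table a foreign reference points at
# (MEASUREMENT.modifier_of_field_concept_id, EPISODE_EVENT.*_field_concept_id).
field_concepts <- c(
  condition_occurrence = 1147127,
  drug_exposure        = 1147094,
  procedure_occurrence = 1147082,
  episode              = 1147879
)

# OMOP gender concept ids (used in the PERSON table only; gender concepts are
# not part of the oncology vocabulary subset handled here).
gender_concepts <- c(male = 8507, female = 8532)

# Local concept ids are minted from this floor (OMOP convention for
# site-local, 2-billion-range concepts).
LOCAL_CONCEPT_FLOOR <- 2000000000
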