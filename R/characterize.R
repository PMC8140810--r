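# characterization: cohort identification and first-line treatment-pattern
# description (regimen distribution with category grouping, descriptive
# summaries) over a conformant CDM instance.

#' Define a characterization cohort
#'
#' A cohort is defined by an index condition concept set (expanded through
#' the hierarchy with [descendants_of()], so descendant diagnoses qualify),
#' an optional required diagnostic modifier (e.g. distant metastasis
#' present), an optional requirement of at least one detected treatment
#' regimen on or after the index diagnosis, and an observation cutoff date.
#'
#' @param index_condition_concept_ids non-empty numeric vector.
#' @param required_modifier optional list with `measurement_concept_id` and
#'   `value_concept_id`.
#' @param require_systemic_therapy logical.
#' @param cutoff_date optional Date ending every observation window.
#' @return List of class `cohort_definition`.
#' @export
cohort_definition <- function(index_condition_concept_ids,
                              required_modifier = NULL,
                              require_systemic_therapy = FALSE,
                              cutoff_date = NULL) {
  if (!length(index_condition_concept_ids)) stop("empty index concept set")
  structure(list(index_condition_concept_ids = as.numeric(index_condition_concept_ids),
                 required_modifier = required_modifier,
                 require_systemic_therapy = require_systemic_therapy,
                 cutoff_date = if (is.null(cutoff_date)) NULL else as.Date(cutoff_date)),
            class = "cohort_definition")
}

#' Identify a cohort
#'
#' Returns the persons with at least one condition occurrence in the
#' hierarchy-expanded index set, satisfying the modifier requirement (a
#' linked measurement with the required concept and value on a qualifying
#' diagnosis), and — when systemic therapy is required — at least one
#' Treatment Regimen episode starting on or after the index date. The index
#' date is the earliest qualifying diagnosis; the observation window runs
#' from it to the person's last recorded encounter or the cutoff date,
#' whichever is earlier.
#'
#' @param defn a [cohort_definition()].
#' @param store a `cdm_store`.
#' @param graph a [concept_graph].
#' @param regimen_episode_concept_id Episode-domain concept identifying
#'   treatment-regimen episodes.
#' @return data.frame `person_id`, `index_date`, `observation_end`.
#' @export
identify_cohort <- function(defn, store, graph,
                            regimen_episode_concept_id =
                              unname(fixture_concepts[["ep_treatment_regimen"]])) {
  expanded <- sort(unique(unlist(lapply(defn$index_condition_concept_ids,
                                        function(id) descendants_of(graph, id)))))
  co <- store$condition_occurrence
  qual <- co[co$condition_concept_id %in% expanded, , drop = FALSE]
  if (!nrow(qual)) {
    return(data.frame(person_id = numeric(0),
                      index_date = as.Date(character(0)),
                      observation_end = as.Date(character(0))))
  }
  if (!is.null(defn$required_modifier)) {
    mm <- store$measurement
    ok_meas <- mm[mm$measurement_concept_id == defn$required_modifier$measurement_concept_id &
                    !is.na(mm$value_as_concept_id) &
                    mm$value_as_concept_id == defn$required_modifier$value_concept_id &
                    mm$modifier_of_field_concept_id == field_concepts[["condition_occurrence"]], ,
                  drop = FALSE]
    qual <- qual[qual$condition_occurrence_id %in% ok_meas$modifier_of_event_id, ,
                 drop = FALSE]
  }
  if (!nrow(qual)) {
    return(data.frame(person_id = numeric(0),
                      index_date = as.Date(character(0)),
                      observation_end = as.Date(character(0))))
  }
  index <- tapply(qual$condition_start_date, qual$person_id, min)
  out <- data.frame(person_id = as.numeric(names(index)),
                    index_date = as.Date(as.numeric(index), origin = "1970-01-01"))
  if (defn$require_systemic_therapy) {
    ep <- store$episode
    regs <- ep[ep$episode_concept_id == regimen_episode_concept_id, , drop = FALSE]
    has_reg <- vapply(seq_len(nrow(out)), function(i) {
      any(regs$person_id == out$person_id[i] &
            regs$episode_start_date >= out$index_date[i])
    }, logical(1))
    out <- out[has_reg, , drop = FALSE]
  }
  out$observation_end <- vapply(out$person_id, function(p)
    last_encounter(store, p), numeric(1))
  out$observation_end <- as.Date(out$observation_end, origin = "1970-01-01")
  if (!is.null(defn$cutoff_date)) {
    out$observation_end <- pmin(out$observation_end, defn$cutoff_date)
  }
  rownames(out) <- NULL
  out
}

last_encounter <- function(store, person_id) {
  dates <- c(store$condition_occurrence$condition_start_date[
               store$condition_occurrence$person_id == person_id],
             store$measurement$measurement_date[
               store$measurement$person_id == person_id],
             store$drug_exposure$drug_exposure_end_date[
               store$drug_exposure$person_id == person_id],
             store$episode$episode_end_date[
               store$episode$person_id == person_id],
             store$death$death_date[store$death$person_id == person_id])
  as.numeric(max(dates))
}

# average-of-two-central-order-statistics median
midpoint_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (!n) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

#' First-line regimen distribution and cohort summaries
#'
#' For every cohort member, takes the first-line regimen — the earliest
#' Treatment Regimen episode starting on or after the index date — and
#' groups it into a treatment category through `categories` (regimens
#' without an entry fall into `"Other"`; members with no regimen are counted
#' as `"Untreated"`). Percentages are over the whole cohort and sum to 100.
#' Summaries report median age at index (index year minus birth year),
#' percent male, and median first-line duration in days (closed interval,
#' end - start + 1), all medians by the midpoint-of-two convention.
#'
#' @param cohort output of [identify_cohort()].
#' @param store a `cdm_store`.
#' @param categories named character vector: names are regimen concept ids
#'   (as printed numbers), values category labels.
#' @param regimen_episode_concept_id Episode-domain concept identifying
#'   treatment-regimen episodes.
#' @return List with `distribution` (data.frame `category`, `n`, `percent`)
#'   and `summaries` (list `n`, `median_age_at_index`, `percent_male`,
#'   `median_first_line_duration_days`).
#' @export
first_line_distribution <- function(cohort, store, categories,
                                    regimen_episode_concept_id =
                                      unname(fixture_concepts[["ep_treatment_regimen"]])) {
  if (!nrow(cohort)) {
    return(list(distribution = data.frame(category = character(0),
                                          n = numeric(0), percent = numeric(0)),
                summaries = list(n = 0, median_age_at_index = NA_real_,
                                 percent_male = NA_real_,
                                 median_first_line_duration_days = NA_real_)))
  }
  ep <- store$episode
  regs <- ep[ep$episode_concept_id == regimen_episode_concept_id, , drop = FALSE]
  cat_of <- character(nrow(cohort)); dur <- rep(NA_real_, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    r <- regs[regs$person_id == cohort$person_id[i] &
                regs$episode_start_date >= cohort$index_date[i], , drop = FALSE]
    if (!nrow(r)) {
      cat_of[i] <- "Untreated"
      next
    }
    r <- r[order(r$episode_start_date, r$episode_id), , drop = FALSE]
    key <- format_id(r$episode_object_concept_id[1L])
    cat_of[i] <- if (key %in% names(categories)) categories[[key]] else "Other"
    dur[i] <- as.numeric(r$episode_end_date[1L] - r$episode_start_date[1L]) + 1
  }
  tab <- table(cat_of)
  distribution <- data.frame(category = names(tab), n = as.numeric(tab),
                             percent = 100 * as.numeric(tab) / nrow(cohort),
                             stringsAsFactors = FALSE)
  distribution <- distribution[order(-distribution$n, distribution$category), ]
  rownames(distribution) <- NULL
  birth <- store$person$year_of_birth[match(cohort$person_id, store$person$person_id)]
  gender <- store$person$gender_concept_id[match(cohort$person_id,
                                                 store$person$person_id)]
  age <- as.numeric(format(cohort$index_date, "%Y")) - birth
  list(distribution = distribution,
       summaries = list(
         n = nrow(cohort),
         median_age_at_index = midpoint_median(age),
         percent_male = 100 * mean(gender == gender_concepts[["male"]]),
         median_first_line_duration_days = midpoint_median(dur[!is.na(dur)])))
}
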