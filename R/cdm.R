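# cdm_core: clinical-event and episode layers — persons, condition
# occurrences, modifier measurements with explicit diagnosis linkage, drug
# exposures, deaths, and the EPISODE/EPISODE_EVENT model.

cdm_table_cols <- list(
  person = c("person_id", "gender_concept_id", "year_of_birth"),
  condition_occurrence = c("condition_occurrence_id", "person_id",
                           "condition_concept_id", "condition_start_date",
                           "condition_source_value"),
  measurement = c("measurement_id", "person_id", "measurement_concept_id",
                  "measurement_date", "value_as_concept_id", "value_as_number",
                  "unit_source_value", "modifier_of_event_id",
                  "modifier_of_field_concept_id"),
  drug_exposure = c("drug_exposure_id", "person_id", "drug_concept_id",
                    "ingredient_concept_id", "drug_exposure_start_date",
                    "drug_exposure_end_date", "quantity"),
  death = c("person_id", "death_date", "death_source"),
  episode = c("episode_id", "person_id", "episode_concept_id",
              "episode_object_concept_id", "episode_parent_id",
              "episode_number", "episode_start_date", "episode_end_date"),
  episode_event = c("episode_id", "event_id", "episode_event_field_concept_id")
)

cdm_date_cols <- c("condition_start_date", "measurement_date",
                   "drug_exposure_start_date", "drug_exposure_end_date",
                   "death_date", "episode_start_date", "episode_end_date")

empty_cdm_table <- function(name) {
  cols <- cdm_table_cols[[name]]
  out <- lapply(cols, function(cl) {
    if (cl %in% cdm_date_cols) as.Date(character(0))
    else if (cl %in% c("condition_source_value", "unit_source_value", "death_source"))
      character(0)
    else numeric(0)
  })
  as.data.frame(setNames(out, cols), stringsAsFactors = FALSE)
}

#' Construct an empty CDM store
#'
#' A `cdm_store` holds the seven clinical tables used by the oncology
#' module: `person`, `condition_occurrence`, `measurement` (diagnostic
#' modifiers carry an explicit link to their diagnosis), `drug_exposure`,
#' `death`, and the episode layer `episode` / `episode_event`.
#'
#' @return An object of class `cdm_store` (named list of data.frames).
#' @export
new_cdm <- function() {
  structure(lapply(setNames(nm = names(cdm_table_cols)), empty_cdm_table),
            class = "cdm_store")
}

#' @export
print.cdm_store <- function(x, ...) {
  cat("<cdm_store>\n")
  for (nm in names(cdm_table_cols)) {
    cat(sprintf("  %-22s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Read / write a CDM directory
#'
#' The seven tables are stored as comma-separated files with lower-case
#' column names (`person.csv`, `condition_occurrence.csv`, ...); dates are
#' ISO `YYYY-MM-DD`. Missing files read as empty tables.
#'
#' @param directory directory holding (or receiving) the CSV files.
#' @param store a `cdm_store` (for `cdm_write`).
#' @return `cdm_read` returns a validated `cdm_store`; `cdm_write` returns
#'   `directory` invisibly.
#' @export
cdm_read <- function(directory) {
  store <- new_cdm()
  for (nm in names(cdm_table_cols)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) next
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(cdm_table_cols[[nm]], names(df))
    if (length(missing)) {
      stop("table ", nm, " missing columns: ", paste(missing, collapse = ", "))
    }
    df <- df[, cdm_table_cols[[nm]], drop = FALSE]
    proto <- empty_cdm_table(nm)
    for (cl in names(df)) {
      df[[cl]] <- if (cl %in% cdm_date_cols) as.Date(df[[cl]])
      else if (is.character(proto[[cl]])) {
        v <- as.character(df[[cl]]); v[is.na(v)] <- ""; v
      } else as.numeric(df[[cl]])
    }
    store[[nm]] <- df
  }
  validate_cdm(store)
  store
}

#' @rdname cdm_read
#' @export
cdm_write <- function(store, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cdm_table_cols)) {
    df <- store[[nm]]
    for (cl in intersect(names(df), cdm_date_cols)) df[[cl]] <- as.character(df[[cl]])
    write.csv(df, file.path(directory, paste0(nm, ".csv")), row.names = FALSE,
              quote = FALSE, na = "")
  }
  invisible(directory)
}

#' Validate CDM referential integrity
#'
#' Checks that every stored row's references resolve (persons, modifier
#' targets, episode parents and events), that episode parent links form a
#' forest of properly nested intervals, and that every episode event's date
#' lies within its episode interval.
#'
#' @param store a `cdm_store`.
#' @param graph optional [concept_graph] for domain checks on condition
#'   concepts.
#' @return `store`, invisibly; errors on the first violation.
#' @export
validate_cdm <- function(store, graph = NULL) {
  persons <- store$person$person_id
  if (anyDuplicated(persons)) {
    stop("duplicate person_id: ", persons[duplicated(persons)][1L])
  }
  for (nm in c("condition_occurrence", "measurement", "drug_exposure",
               "death", "episode")) {
    bad <- setdiff(store[[nm]]$person_id, persons)
    if (length(bad)) stop(nm, " references unknown person_id: ", bad[1L])
  }
  dx <- store$drug_exposure
  if (any(dx$drug_exposure_end_date < dx$drug_exposure_start_date)) {
    stop("drug_exposure with end date before start date")
  }
  if (!is.null(graph) && nrow(store$condition_occurrence)) {
    dom <- graph$concepts$domain_id[
      match(store$condition_occurrence$condition_concept_id, graph$concepts$concept_id)]
    if (any(is.na(dom) | dom != "Condition")) {
      stop("condition_occurrence with non-Condition concept")
    }
  }
  ep <- store$episode
  if (anyDuplicated(ep$episode_id)) stop("duplicate episode_id")
  has_parent <- !is.na(ep$episode_parent_id)
  if (any(has_parent)) {
    pi <- match(ep$episode_parent_id[has_parent], ep$episode_id)
    if (anyNA(pi)) stop("episode parent not found")
    if (any(ep$person_id[has_parent] != ep$person_id[pi])) {
      stop("episode parent belongs to a different person")
    }
    if (any(ep$episode_start_date[has_parent] < ep$episode_start_date[pi] |
              ep$episode_end_date[has_parent] > ep$episode_end_date[pi])) {
      stop("child episode interval not contained in parent interval")
    }
    for (i in which(has_parent)) {       # forest check: no cycles
      seen <- numeric(0); cur <- ep$episode_id[i]
      while (!is.na(cur)) {
        if (cur %in% seen) stop("cycle in episode parent links at ", cur)
        seen <- c(seen, cur)
        cur <- ep$episode_parent_id[match(cur, ep$episode_id)]
      }
    }
  }
  if (any(!is.na(ep$episode_number) & ep$episode_number < 1)) {
    stop("episode_number must be >= 1")
  }
  ee <- store$episode_event
  if (nrow(ee)) {
    ei <- match(ee$episode_id, ep$episode_id)
    if (anyNA(ei)) stop("episode_event references unknown episode")
    for (i in seq_len(nrow(ee))) {
      ev <- resolve_event(store, ee$event_id[i],
                          ee$episode_event_field_concept_id[i])
      if (ev$person_id != ep$person_id[ei[i]]) {
        stop("episode_event links event of a different person")
      }
      if (ev$date < ep$episode_start_date[ei[i]] ||
            ev$date > ep$episode_end_date[ei[i]]) {
        stop("episode_event date outside episode interval (episode ",
             ee$episode_id[i], ")")
      }
    }
  }
  mm <- store$measurement
  if (nrow(mm)) {
    one_value <- xor(!is.na(mm$value_as_concept_id), !is.na(mm$value_as_number))
    if (any(!one_value)) {
      stop("measurement must carry exactly one of value_as_concept_id / value_as_number")
    }
  }
  invisible(store)
}

resolve_event <- function(store, event_id, field_concept_id) {
  table <- names(field_concepts)[match(field_concept_id, field_concepts)]
  if (is.na(table)) stop("unknown event field concept ", field_concept_id)
  if (table == "condition_occurrence") {
    i <- match(event_id, store$condition_occurrence$condition_occurrence_id)
    if (is.na(i)) stop("unknown condition_occurrence ", event_id)
    list(person_id = store$condition_occurrence$person_id[i],
         date = store$condition_occurrence$condition_start_date[i])
  } else if (table == "drug_exposure") {
    i <- match(event_id, store$drug_exposure$drug_exposure_id)
    if (is.na(i)) stop("unknown drug_exposure ", event_id)
    list(person_id = store$drug_exposure$person_id[i],
         date = store$drug_exposure$drug_exposure_start_date[i])
  } else {
    stop("events of table ", table, " are not stored in this CDM subset")
  }
}

next_id <- function(df, col) if (nrow(df)) max(df[[col]]) + 1 else 1

#' Add rows to the clinical tables
#'
#' Small row-wise builders used by the ETL, the simulator and tests. Each
#' checks referential integrity against the store and returns the updated
#' store (`create_episode` returns the new `episode_id` in an attribute-free
#' list, since callers need it for nesting and event linkage).
#'
#' @param store a `cdm_store`.
#' @param person_id,gender_concept_id,year_of_birth person fields.
#' @return The updated store (`create_episode`: list with `store` and
#'   `episode_id`).
#' @name cdm-builders
NULL

#' @rdname cdm-builders
#' @export
add_person <- function(store, person_id, gender_concept_id, year_of_birth) {
  if (person_id %in% store$person$person_id) {
    stop("duplicate person_id: ", person_id)
  }
  store$person <- rbind(store$person, data.frame(
    person_id = person_id, gender_concept_id = gender_concept_id,
    year_of_birth = year_of_birth))
  store
}

#' @rdname cdm-builders
#' @param condition_concept_id,start_date,source_code condition fields.
#' @export
add_condition <- function(store, person_id, condition_concept_id, start_date,
                          source_code = "") {
  if (!person_id %in% store$person$person_id) {
    stop("unknown person_id: ", person_id)
  }
  store$condition_occurrence <- rbind(store$condition_occurrence, data.frame(
    condition_occurrence_id = next_id(store$condition_occurrence, "condition_occurrence_id"),
    person_id = person_id, condition_concept_id = condition_concept_id,
    condition_start_date = as.Date(start_date),
    condition_source_value = source_code, stringsAsFactors = FALSE))
  store
}

#' @rdname cdm-builders
#' @param drug_concept_id,ingredient_concept_id,end_date,quantity drug-exposure fields.
#' @export
add_drug_exposure <- function(store, person_id, drug_concept_id, start_date,
                              end_date = start_date,
                              ingredient_concept_id = NA_real_,
                              quantity = NA_real_) {
  if (!person_id %in% store$person$person_id) {
    stop("unknown person_id: ", person_id)
  }
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("drug exposure end before start")
  store$drug_exposure <- rbind(store$drug_exposure, data.frame(
    drug_exposure_id = next_id(store$drug_exposure, "drug_exposure_id"),
    person_id = person_id, drug_concept_id = drug_concept_id,
    ingredient_concept_id = ingredient_concept_id,
    drug_exposure_start_date = start_date, drug_exposure_end_date = end_date,
    quantity = quantity))
  store
}

#' Attach a diagnostic modifier measurement to a clinical event
#'
#' Stores a modifier (stage, grade, biomarker, tumor size, ...) as a
#' MEASUREMENT row explicitly linked to the diagnosis (or episode) it
#' qualifies via `modifier_of_event_id` / `modifier_of_field_concept_id`.
#' Exactly one of `value_concept_id` (categorical) or `value_number`
#' (measured, with optional `unit`) must be supplied; the target event must
#' exist and belong to the same person.
#'
#' @param store a `cdm_store`.
#' @param person_id person the measurement belongs to.
#' @param measurement_concept_id concept identifying the modifier.
#' @param target_event_id id of the linked row.
#' @param target_table `"condition_occurrence"` (default) or `"episode"`.
#' @param value_concept_id,value_number,unit the modifier value.
#' @param date measurement date (defaults to the target event's date).
#' @return The updated store.
#' @export
attach_modifier <- function(store, person_id, measurement_concept_id,
                            target_event_id,
                            target_table = "condition_occurrence",
                            value_concept_id = NULL, value_number = NULL,
                            unit = "", date = NULL) {
  if (is.null(value_concept_id) == is.null(value_number)) {
    stop("exactly one of value_concept_id / value_number must be given")
  }
  field_id <- field_concepts[[target_table]]
  if (target_table == "episode") {
    i <- match(target_event_id, store$episode$episode_id)
    if (is.na(i)) stop("modifier target episode ", target_event_id, " not found")
    tperson <- store$episode$person_id[i]
    tdate <- store$episode$episode_start_date[i]
  } else {
    i <- match(target_event_id, store$condition_occurrence$condition_occurrence_id)
    if (is.na(i)) stop("modifier target condition ", target_event_id, " not found")
    tperson <- store$condition_occurrence$person_id[i]
    tdate <- store$condition_occurrence$condition_start_date[i]
  }
  if (tperson != person_id) {
    stop("modifier target belongs to person ", tperson, ", not ", person_id)
  }
  store$measurement <- rbind(store$measurement, data.frame(
    measurement_id = next_id(store$measurement, "measurement_id"),
    person_id = person_id, measurement_concept_id = measurement_concept_id,
    measurement_date = as.Date(if (is.null(date)) tdate else date),
    value_as_concept_id = if (is.null(value_concept_id)) NA_real_ else value_concept_id,
    value_as_number = if (is.null(value_number)) NA_real_ else value_number,
    unit_source_value = unit, modifier_of_event_id = target_event_id,
    modifier_of_field_concept_id = field_id, stringsAsFactors = FALSE))
  store
}

#' Retrieve the modifiers attached to a condition
#'
#' @param store a `cdm_store`.
#' @param condition_occurrence_id the diagnosis row.
#' @return The linked measurement rows.
#' @export
modifiers_of <- function(store, condition_occurrence_id) {
  mm <- store$measurement
  mm[mm$modifier_of_event_id == condition_occurrence_id &
       mm$modifier_of_field_concept_id == field_concepts[["condition_occurrence"]], ,
     drop = FALSE]
}

#' Create an episode / link a clinical event to it
#'
#' Episodes are abstracted, dated disease or treatment phases (disease first
#' occurrence, progression, treatment regimen, treatment cycle). They may
#' nest: a parent episode must belong to the same person and fully contain
#' the child's closed date interval. `link_event` attaches an individual
#' clinical event (condition or drug exposure) to an episode through the
#' EPISODE_EVENT table; the event's date must lie inside the episode.
#'
#' @param store a `cdm_store`.
#' @param person_id person the episode belongs to.
#' @param episode_concept_id Episode-domain concept (the abstracted state).
#' @param object_concept_id the specific diagnosis or regimen concept.
#' @param start_date,end_date closed calendar-day interval.
#' @param parent_id optional parent `episode_id`.
#' @param episode_number optional ordinal (cycle number, line number), >= 1.
#' @return `create_episode`: list with `store` and the new `episode_id`;
#'   `link_event`: the updated store.
#' @export
create_episode <- function(store, person_id, episode_concept_id,
                           object_concept_id, start_date, end_date,
                           parent_id = NA, episode_number = NA) {
  if (!person_id %in% store$person$person_id) {
    stop("unknown person_id: ", person_id)
  }
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("episode end before start")
  if (!is.na(episode_number) && episode_number < 1) {
    stop("episode_number must be >= 1")
  }
  if (!is.na(parent_id)) {
    i <- match(parent_id, store$episode$episode_id)
    if (is.na(i)) stop("parent episode ", parent_id, " not found")
    if (store$episode$person_id[i] != person_id) {
      stop("parent episode belongs to a different person")
    }
    if (start_date < store$episode$episode_start_date[i] ||
          end_date > store$episode$episode_end_date[i]) {
      stop("child episode interval not contained in parent interval")
    }
  }
  episode_id <- next_id(store$episode, "episode_id")
  store$episode <- rbind(store$episode, data.frame(
    episode_id = episode_id, person_id = person_id,
    episode_concept_id = episode_concept_id,
    episode_object_concept_id = object_concept_id,
    episode_parent_id = if (is.na(parent_id)) NA_real_ else parent_id,
    episode_number = if (is.na(episode_number)) NA_real_ else episode_number,
    episode_start_date = start_date, episode_end_date = end_date))
  list(store = store, episode_id = episode_id)
}

#' @rdname create_episode
#' @param episode_id episode to link to.
#' @param event_id row id in the event's table.
#' @param event_table `"condition_occurrence"` or `"drug_exposure"`.
#' @export
link_event <- function(store, episode_id, event_id,
                       event_table = "drug_exposure") {
  i <- match(episode_id, store$episode$episode_id)
  if (is.na(i)) stop("unknown episode ", episode_id)
  field_id <- field_concepts[[event_table]]
  ev <- resolve_event(store, event_id, field_id)
  if (ev$person_id != store$episode$person_id[i]) {
    stop("event belongs to a different person than the episode")
  }
  if (ev$date < store$episode$episode_start_date[i] ||
        ev$date > store$episode$episode_end_date[i]) {
    stop("event date outside episode interval")
  }
  store$episode_event <- rbind(store$episode_event, data.frame(
    episode_id = episode_id, event_id = event_id,
    episode_event_field_concept_id = field_id))
  store
}

#' Reconcile EHR and tumor-registry vital status
#'
#' Unions death records from the EHR and the tumor registry into at most one
#' reconciled death per person. When both sources report a death with
#' different dates, the earlier date is kept (conservative for survival
#' analysis) and the person is flagged as a conflict. The augmentation
#' report counts registry-only deaths and the percent increase they
#' represent over the EHR death count
#' (`100 * additional_deaths / n_ehr_deaths`, defined as 0 with a warning
#' when there are no EHR deaths).
#'
#' @param ehr_deaths,registry_deaths data.frames with columns `person_id`,
#'   `death_date` (Date); empty inputs allowed.
#' @return List with `deaths` (reconciled `person_id`, `death_date`,
#'   `death_source`) and `report` (list: `n_ehr_deaths`, `additional_deaths`,
#'   `percent_increase`, `conflict_person_ids`).
#' @export
merge_vital_status <- function(ehr_deaths, registry_deaths) {
  norm <- function(df, src) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(person_id = numeric(0),
                        death_date = as.Date(character(0)),
                        death_source = character(0), stringsAsFactors = FALSE))
    }
    df <- df[!duplicated(df$person_id), c("person_id", "death_date")]
    df$death_date <- as.Date(df$death_date)
    df$death_source <- src
    df
  }
  ehr <- norm(ehr_deaths, "EHR")
  reg <- norm(registry_deaths, "REGISTRY")
  both <- intersect(ehr$person_id, reg$person_id)
  conflicts <- numeric(0)
  merged <- ehr
  for (p in both) {
    de <- ehr$death_date[ehr$person_id == p]
    dr <- reg$death_date[reg$person_id == p]
    if (dr != de) {
      conflicts <- c(conflicts, p)
      if (dr < de) {
        merged$death_date[merged$person_id == p] <- dr
        merged$death_source[merged$person_id == p] <- "REGISTRY"
      }
    }
  }
  reg_only <- reg[!reg$person_id %in% ehr$person_id, , drop = FALSE]
  merged <- rbind(merged, reg_only)
  merged <- merged[order(merged$person_id), , drop = FALSE]
  rownames(merged) <- NULL
  additional <- nrow(reg_only)
  if (nrow(ehr) == 0 && additional > 0) {
    warning("no EHR deaths; percent_increase reported as 0")
    pct <- 0
  } else if (nrow(ehr) == 0) {
    pct <- 0
  } else {
    pct <- 100 * additional / nrow(ehr)
  }
  list(deaths = merged,
       report = list(n_ehr_deaths = nrow(ehr), additional_deaths = additional,
                     percent_increase = pct,
                     conflict_person_ids = sort(conflicts)))
}
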