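# naaccr_etl: vocabulary-driven transformation of tumor-registry abstracts
# (item-number-keyed records) into CDM rows — precoordinated condition,
# linked modifier measurements, a Disease First Occurrence episode, and
# registry death records.

#' Item mapping rules
#'
#' The ETL is driven entirely by a rule table binding registry item numbers
#' to their meaning: diagnosis components (primary site, histology,
#' behavior), dates (diagnosis, last contact), vital status, and modifier
#' items mapped to measurement concepts — categorical items carry a value
#' map from raw registry values to value concept ids, numeric items carry a
#' unit. `default_mapping_rules()` returns the rule set for the fixture
#' items (400 primary site, 522 histology, 523 behavior, 390 date of
#' diagnosis, 1760 vital status, 1750 date of last contact, 2880 estrogen
#' receptor status, 752 tumor size). Rules round-trip through a CSV in which
#' the value map is encoded `raw=concept;raw=concept`.
#'
#' @return data.frame with columns `item_number`, `kind`, `role`,
#'   `measurement_concept_id`, `units` and a `value_map` list-column.
#' @export
default_mapping_rules <- function() {
  rule <- function(item, kind, role = NA_character_,
                   measurement_concept_id = NA_real_, units = NA_character_,
                   value_map = NULL) {
    out <- data.frame(item_number = item, kind = kind, role = role,
                      measurement_concept_id = measurement_concept_id,
                      units = units, stringsAsFactors = FALSE)
    out$value_map <- list(value_map)
    out
  }
  rbind(
    rule("400", "DIAGNOSIS_COMPONENT", role = "site"),
    rule("522", "DIAGNOSIS_COMPONENT", role = "histology"),
    rule("523", "DIAGNOSIS_COMPONENT", role = "behavior"),
    rule("390", "DATE", role = "diagnosis_date"),
    rule("1760", "VITAL_STATUS",
         value_map = c("0" = "DEAD", "1" = "ALIVE")),
    rule("1750", "DATE", role = "last_contact_date"),
    rule("2880", "MODIFIER_CATEGORICAL",
         measurement_concept_id = unname(fixture_concepts[["meas_er_status"]]),
         value_map = c("010" = unname(fixture_concepts[["val_er_positive"]]),
                       "020" = unname(fixture_concepts[["val_er_negative"]]))),
    rule("752", "MODIFIER_NUMERIC",
         measurement_concept_id = unname(fixture_concepts[["meas_tumor_size"]]),
         units = "mm")
  )
}

#' @rdname default_mapping_rules
#' @param path CSV file path.
#' @export
read_mapping_rules <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df$measurement_concept_id <- suppressWarnings(as.numeric(df$measurement_concept_id))
  df$value_map <- lapply(df$value_map, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    vals <- vapply(kv, `[[`, character(1), 2L)
    num <- suppressWarnings(as.numeric(vals))
    setNames(if (anyNA(num)) vals else num, vapply(kv, `[[`, character(1), 1L))
  })
  df$units[df$units == ""] <- NA_character_
  df$role[df$role == ""] <- NA_character_
  validate_mapping_rules(df)
}

#' @rdname default_mapping_rules
#' @param rules a rule table.
#' @export
write_mapping_rules <- function(rules, path) {
  enc <- vapply(rules$value_map, function(vm) {
    if (is.null(vm)) "" else paste(names(vm), sapply(vm, format_id), sep = "=",
                                   collapse = ";")
  }, character(1))
  out <- data.frame(item_number = rules$item_number, kind = rules$kind,
                    role = ifelse(is.na(rules$role), "", rules$role),
                    measurement_concept_id = ifelse(
                      is.na(rules$measurement_concept_id), "",
                      format_id(rules$measurement_concept_id)),
                    units = ifelse(is.na(rules$units), "", rules$units),
                    value_map = enc, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_mapping_rules <- function(rules) {
  kinds <- c("DIAGNOSIS_COMPONENT", "MODIFIER_CATEGORICAL", "MODIFIER_NUMERIC",
             "VITAL_STATUS", "DATE")
  bad <- setdiff(rules$kind, kinds)
  if (length(bad)) stop("unknown rule kind: ", paste(bad, collapse = ", "))
  cat_no_map <- rules$kind == "MODIFIER_CATEGORICAL" &
    !vapply(rules$value_map, length, integer(1))
  if (any(cat_no_map)) {
    stop("MODIFIER_CATEGORICAL rule without value_map: item ",
         rules$item_number[cat_no_map][1L])
  }
  num_no_unit <- rules$kind == "MODIFIER_NUMERIC" & is.na(rules$units)
  if (any(num_no_unit)) {
    stop("MODIFIER_NUMERIC rule without units: item ",
         rules$item_number[num_no_unit][1L])
  }
  rules
}

#' Parse a registry date
#'
#' Dates follow the `YYYYMMDD` registry convention; a partial year-only
#' value (`YYYY`) resolves to July 1 of that year and is flagged.
#'
#' @param x raw item text.
#' @return List with `date` (Date or `NA`) and `partial` (logical).
#' @export
parse_naaccr_date <- function(x) {
  x <- trimws(x)
  if (grepl("^[0-9]{8}$", x)) {
    return(list(date = as.Date(x, format = "%Y%m%d"), partial = FALSE))
  }
  if (grepl("^[0-9]{4}$", x)) {
    return(list(date = as.Date(paste0(x, "-07-01")), partial = TRUE))
  }
  list(date = as.Date(NA), partial = FALSE)
}

# "C509" -> "C50.9"; 3-character site codes pass through unchanged
normalize_site_code <- function(x) {
  x <- toupper(trimws(x))
  if (grepl("^C[0-9]{3}$", x)) paste0(substr(x, 1, 3), ".", substr(x, 4, 4)) else x
}

item_of <- function(record, item) {
  v <- record[[item]]
  if (is.null(v) || is.na(v)) "" else trimws(as.character(v))
}

#' Transform tumor-registry records into CDM rows
#'
#' For each record: (1) assemble the combined ICD-O-3 code from the
#' diagnosis-component items, look it up among the precoordinated concepts
#' and write a condition occurrence carrying its designated standard
#' concept; (2) write each mapped modifier item as a measurement linked to
#' that condition; (3) write a Disease First Occurrence episode whose object
#' is the diagnosis concept, starting at the date of diagnosis; (4) derive a
#' registry death record from the vital-status and last-contact items.
#' Records missing a required diagnosis item are rejected with a reason; a
#' combined code with no precoordinated/standard concept counts as an
#' unmapped diagnosis; unmapped modifier values are skipped with per-item
#' counts.
#'
#' @param records data.frame with `record_id`, `person_id` and item-number
#'   columns (e.g. `"400"`, `"522"`).
#' @param rules rule table (see [default_mapping_rules()]).
#' @param graph an integrated [concept_graph].
#' @param store a `cdm_store`; missing persons are created.
#' @param episode_concept_id Episode-domain concept for the disease first
#'   occurrence episode.
#' @return List: `store`, `registry_deaths` (data.frame), `report` (list
#'   with per-record data.frame `records`, `counts`, `modifier_skips`,
#'   `partial_dates`).
#' @export
transform_records <- function(records, rules, graph, store,
                              episode_concept_id =
                                unname(fixture_concepts[["ep_disease_first_occurrence"]])) {
  rules <- validate_mapping_rules(rules)
  ritem <- function(kind, role = NULL) {
    i <- rules$kind == kind
    if (!is.null(role)) i <- i & !is.na(rules$role) & rules$role == role
    rules$item_number[i][1L]
  }
  site_item <- ritem("DIAGNOSIS_COMPONENT", "site")
  hist_item <- ritem("DIAGNOSIS_COMPONENT", "histology")
  beh_item <- ritem("DIAGNOSIS_COMPONENT", "behavior")
  dxdate_item <- ritem("DATE", "diagnosis_date")
  vital_item <- ritem("VITAL_STATUS")
  contact_item <- ritem("DATE", "last_contact_date")
  modifier_rules <- rules[rules$kind %in% c("MODIFIER_CATEGORICAL",
                                            "MODIFIER_NUMERIC"), , drop = FALSE]
  rows <- list(); deaths <- list()
  skips <- setNames(rep(0L, nrow(modifier_rules)), modifier_rules$item_number)
  partial_dates <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    rid <- rec$record_id; pid <- rec$person_id
    required <- c(site_item, hist_item, beh_item, dxdate_item)
    vals <- vapply(required, function(it) item_of(rec, it), character(1))
    if (any(!nzchar(vals))) {
      rows[[i]] <- data.frame(record_id = rid, person_id = pid,
                              status = "rejected",
                              reason = paste("missing required item",
                                             paste(required[!nzchar(vals)], collapse = ",")),
                              condition_concept_id = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    dxd <- parse_naaccr_date(vals[[dxdate_item]])
    if (is.na(dxd$date)) {
      rows[[i]] <- data.frame(record_id = rid, person_id = pid,
                              status = "rejected",
                              reason = "unparseable date of diagnosis",
                              condition_concept_id = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    if (dxd$partial) partial_dates <- partial_dates + 1L
    code <- paste0(vals[[hist_item]], "/", vals[[beh_item]], "-",
                   normalize_site_code(vals[[site_item]]))
    std <- tryCatch(diagnosis_standard_concept(graph, code), error = function(e) NA_real_)
    if (is.na(std)) {
      rows[[i]] <- data.frame(record_id = rid, person_id = pid,
                              status = "unmapped",
                              reason = paste("no standard concept for", code),
                              condition_concept_id = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    if (!pid %in% store$person$person_id) {
      store <- add_person(store, pid, 0, NA_real_)
    }
    store <- add_condition(store, pid, std, dxd$date, source_code = code)
    cond_id <- max(store$condition_occurrence$condition_occurrence_id)
    for (j in seq_len(nrow(modifier_rules))) {
      mr <- modifier_rules[j, , drop = FALSE]
      raw <- item_of(rec, mr$item_number)
      if (!nzchar(raw)) next
      if (mr$kind == "MODIFIER_CATEGORICAL") {
        vm <- mr$value_map[[1L]]
        if (!raw %in% names(vm)) {
          skips[mr$item_number] <- skips[mr$item_number] + 1L
          next
        }
        store <- attach_modifier(store, pid, mr$measurement_concept_id, cond_id,
                                 value_concept_id = as.numeric(vm[[raw]]))
      } else {
        num <- suppressWarnings(as.numeric(raw))
        if (is.na(num)) {
          skips[mr$item_number] <- skips[mr$item_number] + 1L
          next
        }
        store <- attach_modifier(store, pid, mr$measurement_concept_id, cond_id,
                                 value_number = num, unit = mr$units)
      }
    }
    res <- create_episode(store, pid, episode_concept_id, std,
                          dxd$date, dxd$date)
    store <- res$store
    store <- link_event(store, res$episode_id, cond_id, "condition_occurrence")
    if (!is.na(vital_item)) {
      vraw <- item_of(rec, vital_item)
      vmap <- rules$value_map[rules$item_number == vital_item][[1L]]
      if (nzchar(vraw) && identical(unname(vmap[vraw]), "DEAD")) {
        dd <- parse_naaccr_date(item_of(rec, contact_item))
        if (dd$partial) partial_dates <- partial_dates + 1L
        if (!is.na(dd$date)) {
          deaths[[length(deaths) + 1L]] <- data.frame(
            person_id = pid, death_date = dd$date, stringsAsFactors = FALSE)
        }
      }
    }
    rows[[i]] <- data.frame(record_id = rid, person_id = pid,
                            status = "mapped", reason = "",
                            condition_concept_id = std, stringsAsFactors = FALSE)
  }
  report_records <- do.call(rbind, rows)
  counts <- list(n_records = nrow(records),
                 mapped = sum(report_records$status == "mapped"),
                 unmapped = sum(report_records$status == "unmapped"),
                 rejected = sum(report_records$status == "rejected"))
  registry_deaths <- if (length(deaths)) do.call(rbind, deaths) else
    data.frame(person_id = numeric(0), death_date = as.Date(character(0)))
  list(store = store, registry_deaths = registry_deaths,
       report = list(records = report_records, counts = counts,
                     modifier_skips = skips, partial_dates = partial_dates))
}

#' Diagnosis mapping coverage
#'
#' Fraction of processed registry records whose diagnosis mapped to a
#' precoordinated/standard concept. The denominator is the records that
#' carried the required diagnosis items (rejected records are excluded);
#' zero such records is an error.
#'
#' @param report the `report` element returned by [transform_records()].
#' @return Coverage fraction in \[0, 1\].
#' @export
coverage_report <- function(report) {
  n <- report$counts$mapped + report$counts$unmapped
  if (report$counts$n_records == 0) stop("no records processed")
  if (n == 0) stop("no records with required diagnosis items")
  report$counts$mapped / n
}
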