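# regimen_detection: rule-based derivation of treatment-regimen and
# treatment-cycle episodes from drug exposures, matched against HemOnc-style
# regimen definitions (ingredient identity + timing; dosing is carried
# through for reporting but not used for matching).

#' Regimen definitions
#'
#' A regimen definition names a regimen concept, its component antineoplastic
#' ingredients (RxNorm-style ingredient concept ids), and the cycle length
#' in days. `regimen_definitions()` builds the table from parallel vectors;
#' `read_regimen_definitions()` / `write_regimen_definitions()` use a CSV
#' with columns `regimen_concept_id`, `regimen_name`,
#' `component_ingredient_ids` (semicolon-separated), `cycle_length_days`.
#'
#' @param regimen_concept_id numeric vector of regimen concept ids.
#' @param regimen_name character vector of names.
#' @param components list of numeric vectors (ingredient concept ids).
#' @param cycle_length_days positive integer vector.
#' @return data.frame with a `components` list-column.
#' @export
regimen_definitions <- function(regimen_concept_id, regimen_name, components,
                                cycle_length_days) {
  components <- lapply(components, function(x) sort(unique(as.numeric(x))))
  if (any(!lengths(components))) stop("regimen with empty component set")
  if (any(cycle_length_days < 1)) stop("cycle_length_days must be >= 1")
  out <- data.frame(regimen_concept_id = as.numeric(regimen_concept_id),
                    regimen_name = regimen_name,
                    cycle_length_days = as.numeric(cycle_length_days),
                    stringsAsFactors = FALSE)
  out$components <- components
  out
}

#' @rdname regimen_definitions
#' @param path CSV file path.
#' @export
read_regimen_definitions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  regimen_definitions(
    as.numeric(df$regimen_concept_id), df$regimen_name,
    lapply(strsplit(df$component_ingredient_ids, ";", fixed = TRUE), as.numeric),
    as.numeric(df$cycle_length_days))
}

#' @rdname regimen_definitions
#' @param definitions a definitions table.
#' @export
write_regimen_definitions <- function(definitions, path) {
  out <- data.frame(
    regimen_concept_id = format_id(definitions$regimen_concept_id),
    regimen_name = definitions$regimen_name,
    component_ingredient_ids = vapply(definitions$components, function(x)
      paste(format_id(x), collapse = ";"), character(1)),
    cycle_length_days = format_id(definitions$cycle_length_days),
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve drug exposures to ingredients
#'
#' Sets `ingredient_concept_id` on each exposure by resolving the exposed
#' drug concept through the vocabulary: an ingredient-class concept resolves
#' to itself; otherwise the drug's `"Maps to"` standard equivalent and its
#' ancestors are searched for an ingredient-class concept. Exposures whose
#' drug cannot be resolved are dropped with a single warning reporting the
#' count. Exposures whose ingredient does not descend from the
#' antineoplastic drug class are kept but flagged `non_oncologic` (regimen
#' definitions never contain them, so subset matching ignores them).
#'
#' @param exposures `drug_exposure` rows.
#' @param graph a [concept_graph].
#' @param antineoplastic_class_id concept id of the antineoplastic drug
#'   class; defaults to the graph's concept named `"Antineoplastic agents"`.
#' @return The exposures with `ingredient_concept_id` and `non_oncologic`
#'   columns; dropped-row count in `attr(, "n_dropped")`.
#' @export
normalize_to_ingredients <- function(exposures, graph,
                                     antineoplastic_class_id = NULL) {
  if (is.null(antineoplastic_class_id)) {
    antineoplastic_class_id <- graph$concepts$concept_id[
      graph$concepts$concept_name == "Antineoplastic agents"][1L]
  }
  resolve_one <- function(drug_id) {
    if (!drug_id %in% graph$concepts$concept_id) return(NA_real_)
    cand <- c(drug_id, related_targets(graph, drug_id, "Maps to"))
    for (cid in cand) {
      if (concept_row(graph, cid)$concept_class_id == "Ingredient") return(cid)
      anc <- ancestors_of(graph, cid)
      ing <- anc[graph$concepts$concept_class_id[
        match(anc, graph$concepts$concept_id)] == "Ingredient"]
      if (length(ing)) return(min(ing))
    }
    NA_real_
  }
  uniq <- unique(exposures$drug_concept_id)
  resolved <- vapply(uniq, resolve_one, numeric(1))
  exposures$ingredient_concept_id <- resolved[match(exposures$drug_concept_id, uniq)]
  dropped <- is.na(exposures$ingredient_concept_id)
  if (any(dropped)) {
    warning(sum(dropped), " exposure(s) dropped: drug concept not resolvable",
            " to an ingredient")
  }
  exposures <- exposures[!dropped, , drop = FALSE]
  if (!is.null(antineoplastic_class_id) && !is.na(antineoplastic_class_id)) {
    onc_ing <- descendants_of(graph, antineoplastic_class_id)
    exposures$non_oncologic <- !exposures$ingredient_concept_id %in% onc_ing
  } else {
    exposures$non_oncologic <- FALSE
  }
  rownames(exposures) <- NULL
  attr(exposures, "n_dropped") <- sum(dropped)
  exposures
}

#' Build ingredient eras
#'
#' Merges, per person and ingredient, consecutive exposures whose
#' inter-exposure gap (next start minus previous end, in days) is at most
#' `gap_days` into one continuous ingredient era — the standard OMOP era
#' construction used to reason about treatment continuity.
#'
#' @param exposures normalized exposures (see [normalize_to_ingredients()]).
#' @param gap_days maximum bridgeable gap in days (default 30).
#' @return data.frame `person_id`, `ingredient_concept_id`, `era_start_date`,
#'   `era_end_date`, `n_exposures`, with an `exposure_ids` list-column.
#' @export
build_eras <- function(exposures, gap_days = 30) {
  if (!nrow(exposures)) {
    out <- data.frame(person_id = numeric(0), ingredient_concept_id = numeric(0),
                      era_start_date = as.Date(character(0)),
                      era_end_date = as.Date(character(0)),
                      n_exposures = numeric(0))
    out$exposure_ids <- list()
    return(out)
  }
  ex <- exposures[order(exposures$person_id, exposures$ingredient_concept_id,
                        exposures$drug_exposure_start_date,
                        exposures$drug_exposure_id), , drop = FALSE]
  key <- paste(ex$person_id, ex$ingredient_concept_id)
  rows <- lapply(split(seq_len(nrow(ex)), key), function(idx) {
    g <- ex[idx, , drop = FALSE]
    era_of <- integer(nrow(g)); era_of[1L] <- 1L
    end <- g$drug_exposure_end_date[1L]
    for (i in seq_len(nrow(g))[-1L]) {
      if (as.numeric(g$drug_exposure_start_date[i] - end) > gap_days) {
        era_of[i] <- era_of[i - 1L] + 1L
      } else {
        era_of[i] <- era_of[i - 1L]
      }
      end <- max(end, g$drug_exposure_end_date[i])
    }
    do.call(rbind, lapply(split(seq_len(nrow(g)), era_of), function(j) {
      out <- data.frame(person_id = g$person_id[1L],
                        ingredient_concept_id = g$ingredient_concept_id[1L],
                        era_start_date = min(g$drug_exposure_start_date[j]),
                        era_end_date = max(g$drug_exposure_end_date[j]),
                        n_exposures = length(j))
      out$exposure_ids <- list(g$drug_exposure_id[j])
      out
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$person_id, out$ingredient_concept_id, out$era_start_date), ]
  rownames(out) <- NULL
  out
}

# One row per distinct (person, ingredient, administration start date); these
# are the "ingredient starts" cycle detection consumes. Same-day exposures to
# one ingredient collapse into a single start carrying all exposure ids.
ingredient_starts <- function(exposures) {
  if (!nrow(exposures)) {
    out <- data.frame(person_id = numeric(0), ingredient_concept_id = numeric(0),
                      start_date = as.Date(character(0)))
    out$exposure_ids <- list()
    return(out)
  }
  key <- paste(exposures$person_id, exposures$ingredient_concept_id,
               exposures$drug_exposure_start_date)
  rows <- lapply(split(seq_len(nrow(exposures)), key), function(idx) {
    out <- data.frame(person_id = exposures$person_id[idx[1L]],
                      ingredient_concept_id = exposures$ingredient_concept_id[idx[1L]],
                      start_date = exposures$drug_exposure_start_date[idx[1L]])
    out$exposure_ids <- list(sort(exposures$drug_exposure_id[idx]))
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$person_id, out$start_date, out$ingredient_concept_id), ]
  rownames(out) <- NULL
  out
}

#' Detect treatment cycles from ingredient administration starts
#'
#' Greedy left-to-right grouping of a person's ingredient administration
#' start dates into candidate treatment cycles: a cycle opens at the
#' earliest unconsumed start; every start within `window_days` of the
#' opening date joins it; each start is consumed exactly once. The cycle's
#' ingredient set is the distinct ingredients of its member starts.
#'
#' @param starts per-person administration starts (internally derived from
#'   normalized exposures: one row per distinct person, ingredient and start
#'   date, with constituent exposure ids).
#' @param window_days combination window in days (default 14).
#' @return data.frame `person_id`, `cycle_start_date` with list-columns
#'   `ingredients` and `exposure_ids`.
#' @export
detect_cycles <- function(starts, window_days = 14) {
  empty <- data.frame(person_id = numeric(0),
                      cycle_start_date = as.Date(character(0)),
                      last_start_date = as.Date(character(0)))
  empty$ingredients <- list(); empty$exposure_ids <- list()
  if (!nrow(starts)) return(empty)
  rows <- lapply(split(seq_len(nrow(starts)), starts$person_id), function(idx) {
    g <- starts[idx, , drop = FALSE]
    g <- g[order(g$start_date, g$ingredient_concept_id), , drop = FALSE]
    consumed <- rep(FALSE, nrow(g))
    cycles <- list()
    while (any(!consumed)) {
      open <- which(!consumed)[1L]
      member <- !consumed &
        as.numeric(g$start_date - g$start_date[open]) <= window_days
      cyc <- data.frame(person_id = g$person_id[1L],
                        cycle_start_date = g$start_date[open],
                        last_start_date = max(g$start_date[member]))
      cyc$ingredients <- list(sort(unique(g$ingredient_concept_id[member])))
      cyc$exposure_ids <- list(sort(unique(unlist(g$exposure_ids[member]))))
      cycles[[length(cycles) + 1L]] <- cyc
      consumed[member] <- TRUE
    }
    do.call(rbind, cycles)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$person_id, out$cycle_start_date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match a cycle's ingredient set to a regimen definition
#'
#' Exact set equality wins. Failing that (unless `exact_only`), the
#' definition whose components are a subset of the observed set with the
#' most components wins — this tolerates co-medications, while a definition
#' with a component the cycle lacks never matches. Ties go to the lowest
#' regimen concept id with a warning.
#'
#' @param cycle_ingredients numeric vector of ingredient concept ids.
#' @param definitions a [regimen_definitions()] table (non-empty).
#' @param exact_only require exact ingredient-set equality (default FALSE).
#' @return The matched `regimen_concept_id`, or `NA` when nothing matches.
#' @export
match_regimen <- function(cycle_ingredients, definitions, exact_only = FALSE) {
  if (!nrow(definitions)) stop("empty regimen definition list")
  ing <- unique(as.numeric(cycle_ingredients))
  exact <- vapply(definitions$components, function(comp)
    setequal(comp, ing), logical(1))
  if (any(exact)) {
    ids <- definitions$regimen_concept_id[exact]
    if (length(ids) > 1L) warning("tied exact regimen matches; choosing lowest id")
    return(min(ids))
  }
  if (exact_only) return(NA_real_)
  subset_ok <- vapply(definitions$components, function(comp)
    all(comp %in% ing), logical(1))
  if (!any(subset_ok)) return(NA_real_)
  sizes <- lengths(definitions$components)
  best <- subset_ok & sizes == max(sizes[subset_ok])
  ids <- definitions$regimen_concept_id[best]
  if (length(ids) > 1L) warning("tied subset regimen matches; choosing lowest id")
  min(ids)
}

#' Assemble matched cycles into detected regimens with lines of therapy
#'
#' Consecutive cycles matched to the same regimen with an inter-cycle gap of
#' at most `max_cycle_gap_days` merge into one detected regimen; a change of
#' regimen concept or an exceeded gap starts a new one. Cycles are numbered
#' 1..k within each regimen; the regimen end date is the last cycle start
#' plus the definition's cycle length minus one (extended if a constituent
#' exposure falls later, so episode containment always holds). Line numbers
#' are assigned per person in regimen start order; when an index diagnosis
#' date is supplied for a person, numbering starts at the first regimen on or
#' after it and earlier regimens carry line `NA`.
#'
#' @param cycles output of [detect_cycles()] with a `regimen_concept_id`
#'   column (`NA` = unmatched; such cycles are ignored).
#' @param definitions a [regimen_definitions()] table.
#' @param max_cycle_gap_days maximum gap between consecutive cycle starts of
#'   one regimen (default 90).
#' @param index_dates optional named Date vector (names = person ids).
#' @return List of data.frames: `regimens` (`detected_regimen_id`,
#'   `person_id`, `regimen_concept_id`, `start_date`, `end_date`,
#'   `n_cycles`, `line_number`) and `cycles` (`detected_regimen_id`,
#'   `person_id`, `cycle_number`, `cycle_start_date`, `cycle_end_date`, plus
#'   `ingredients` / `exposure_ids` list-columns).
#' @export
assemble_regimens <- function(cycles, definitions, max_cycle_gap_days = 90,
                              index_dates = NULL) {
  matched <- cycles[!is.na(cycles$regimen_concept_id), , drop = FALSE]
  reg_rows <- list(); cyc_rows <- list(); reg_id <- 0L
  for (pid in sort(unique(matched$person_id))) {
    g <- matched[matched$person_id == pid, , drop = FALSE]
    g <- g[order(g$cycle_start_date), , drop = FALSE]
    run <- cumsum(c(TRUE, diff_run(g, max_cycle_gap_days)))
    person_regs <- list()
    for (r in unique(run)) {
      h <- g[run == r, , drop = FALSE]
      reg_id <- reg_id + 1L
      len <- definitions$cycle_length_days[
        match(h$regimen_concept_id[1L], definitions$regimen_concept_id)]
      # last_start_date guards containment when jitter pushes a constituent
      # administration past the nominal cycle end
      cyc_end <- pmax(h$cycle_start_date + len - 1, h$last_start_date)
      reg <- data.frame(detected_regimen_id = reg_id, person_id = pid,
                        regimen_concept_id = h$regimen_concept_id[1L],
                        start_date = min(h$cycle_start_date),
                        end_date = max(cyc_end),
                        n_cycles = nrow(h), line_number = NA_real_)
      person_regs[[length(person_regs) + 1L]] <- reg
      cyc <- data.frame(detected_regimen_id = reg_id, person_id = pid,
                        cycle_number = seq_len(nrow(h)),
                        cycle_start_date = h$cycle_start_date,
                        cycle_end_date = cyc_end)
      cyc$ingredients <- h$ingredients
      cyc$exposure_ids <- h$exposure_ids
      cyc_rows[[length(cyc_rows) + 1L]] <- cyc
    }
    pr <- do.call(rbind, person_regs)
    idx <- if (!is.null(index_dates)) index_dates[as.character(pid)] else NA
    eligible <- if (!is.null(index_dates) && !is.na(idx)) {
      pr$start_date >= as.Date(idx)
    } else rep(TRUE, nrow(pr))
    pr$line_number[eligible] <- seq_len(sum(eligible))
    reg_rows[[length(reg_rows) + 1L]] <- pr
  }
  regimens <- if (length(reg_rows)) do.call(rbind, reg_rows) else
    data.frame(detected_regimen_id = numeric(0), person_id = numeric(0),
               regimen_concept_id = numeric(0),
               start_date = as.Date(character(0)),
               end_date = as.Date(character(0)), n_cycles = numeric(0),
               line_number = numeric(0))
  cyc <- if (length(cyc_rows)) do.call(rbind, cyc_rows) else {
    z <- data.frame(detected_regimen_id = numeric(0), person_id = numeric(0),
                    cycle_number = numeric(0),
                    cycle_start_date = as.Date(character(0)),
                    cycle_end_date = as.Date(character(0)))
    z$ingredients <- list(); z$exposure_ids <- list(); z
  }
  rownames(regimens) <- NULL; rownames(cyc) <- NULL
  list(regimens = regimens, cycles = cyc)
}

# TRUE where a new regimen run must start (concept change or gap exceeded)
diff_run <- function(g, max_cycle_gap_days) {
  if (nrow(g) < 2L) return(logical(0))
  gap <- as.numeric(diff(g$cycle_start_date))
  change <- g$regimen_concept_id[-1L] != g$regimen_concept_id[-nrow(g)]
  change | gap > max_cycle_gap_days
}

#' Emit treatment episodes for detected regimens
#'
#' Writes one Treatment Regimen episode per detected regimen (object concept
#' = the regimen concept, episode number = line of therapy) with one child
#' Treatment Cycle episode per cycle (episode number = cycle ordinal), and
#' links every constituent drug exposure to its cycle through EPISODE_EVENT.
#'
#' @param store a `cdm_store`.
#' @param detected output of [assemble_regimens()].
#' @param episode_concepts named numeric vector with entries `regimen` and
#'   `cycle` giving the Episode-domain concept ids (defaults to the fixture
#'   vocabulary's concepts).
#' @return The updated store.
#' @export
emit_episodes <- function(store, detected, episode_concepts = NULL) {
  if (is.null(episode_concepts)) {
    episode_concepts <- c(regimen = unname(fixture_concepts[["ep_treatment_regimen"]]),
                          cycle = unname(fixture_concepts[["ep_treatment_cycle"]]))
  }
  regs <- detected$regimens
  for (i in seq_len(nrow(regs))) {
    res <- create_episode(store, regs$person_id[i], episode_concepts[["regimen"]],
                          regs$regimen_concept_id[i], regs$start_date[i],
                          regs$end_date[i],
                          episode_number = regs$line_number[i])
    store <- res$store
    cyc <- detected$cycles[
      detected$cycles$detected_regimen_id == regs$detected_regimen_id[i], ,
      drop = FALSE]
    for (j in seq_len(nrow(cyc))) {
      cres <- create_episode(store, regs$person_id[i], episode_concepts[["cycle"]],
                             regs$regimen_concept_id[i],
                             cyc$cycle_start_date[j],
                             min(cyc$cycle_end_date[j], regs$end_date[i]),
                             parent_id = res$episode_id,
                             episode_number = cyc$cycle_number[j])
      store <- cres$store
      for (eid in cyc$exposure_ids[[j]]) {
        store <- link_event(store, cres$episode_id, eid, "drug_exposure")
      }
    }
  }
  store
}

#' Detect regimens from a CDM store
#'
#' End-to-end driver for the rule-based regimen-detection algorithm:
#' resolve exposures to ingredients, derive per-administration ingredient
#' starts, group them into cycles, match each cycle's ingredient set to the
#' regimen definitions, assemble consecutive matched cycles into regimens
#' with line-of-therapy numbers, and (optionally) emit the nested Treatment
#' Regimen / Treatment Cycle episodes into the store. Output is independent
#' of input row order.
#'
#' @param store a `cdm_store` with drug exposures.
#' @param graph a [concept_graph] for ingredient resolution.
#' @param definitions a [regimen_definitions()] table.
#' @param era_gap_days,window_days,max_cycle_gap_days algorithm thresholds
#'   (defaults 30 / 14 / 90 days).
#' @param exact_only require exact ingredient-set matches.
#' @param index_dates optional named Date vector of per-person index
#'   diagnosis dates for line numbering.
#' @param emit write episodes into the store (default TRUE).
#' @return List: `store` (updated when `emit`), `regimens`, `cycles`, `eras`,
#'   `n_dropped` (unresolvable exposures).
#' @export
detect_regimens <- function(store, graph, definitions, era_gap_days = 30,
                            window_days = 14, max_cycle_gap_days = 90,
                            exact_only = FALSE, index_dates = NULL,
                            emit = TRUE) {
  ex <- normalize_to_ingredients(store$drug_exposure, graph)
  n_dropped <- attr(ex, "n_dropped")
  eras <- build_eras(ex, gap_days = era_gap_days)
  starts <- ingredient_starts(ex)
  cycles <- detect_cycles(starts, window_days = window_days)
  cycles$regimen_concept_id <- vapply(cycles$ingredients, function(ing)
    match_regimen(ing, definitions, exact_only = exact_only), numeric(1))
  detected <- assemble_regimens(cycles, definitions,
                                max_cycle_gap_days = max_cycle_gap_days,
                                index_dates = index_dates)
  if (emit) store <- emit_episodes(store, detected)
  list(store = store, regimens = detected$regimens, cycles = detected$cycles,
       eras = eras, n_dropped = n_dropped)
}

#' Score recovery of planted regimens
#'
#' Fraction of ground-truth regimen episodes recovered exactly by detection:
#' a truth row counts as recovered when a detected regimen exists for the
#' same person with the same regimen concept, the same cycle count, and the
#' same line number.
#'
#' @param detected `regimens` data.frame from [detect_regimens()].
#' @param truth ground-truth data.frame with columns `person_id`,
#'   `regimen_concept_id`, `n_cycles`, `line_number`.
#' @return Recovery fraction in \[0, 1\].
#' @export
regimen_recovery <- function(detected, truth) {
  if (!nrow(truth)) stop("empty ground truth")
  key <- function(df) paste(df$person_id, df$regimen_concept_id, df$n_cycles,
                            df$line_number)
  mean(key(truth) %in% key(detected))
}
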