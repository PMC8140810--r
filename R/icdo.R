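# icdo_integration: precoordinate ICD-O-3 histology/behavior/topography into
# single Condition concepts and integrate them into the SNOMED-style disease
# hierarchy by the two-step equivalence-or-insertion algorithm.

#' Parse an ICD-O-3 combination code
#'
#' Decomposes a combined ICD-O-3 code of the form `"HHHH/B-Cnn.n"` (histology,
#' behavior, topography — e.g. `"8520/3-C50.9"`, lobular carcinoma, NOS, of
#' breast, NOS) into its three components. Histology must lie in 8000–9999
#' and behavior in 0–3 (benign, uncertain, in situ, malignant).
#'
#' @param code character scalar; surrounding whitespace is ignored.
#' @return An object of class `icdo_code`: list with `histology`, `behavior`,
#'   `topography`, `combined_code`.
#' @examples
#' parse_icdo("8520/3-C50.9")
#' @export
parse_icdo <- function(code) {
  raw <- trimws(code)
  m <- regmatches(raw, regexec("^([0-9]{4})/([0-9])-(C[0-9]{2}(\\.[0-9])?)$", raw))[[1L]]
  if (!length(m)) stop("malformed ICD-O-3 code: \"", code, "\"")
  histology <- as.integer(m[2L]); behavior <- as.integer(m[3L])
  if (histology < 8000 || histology > 9999) {
    stop("malformed ICD-O-3 code: \"", code, "\" (histology out of range)")
  }
  if (behavior > 3) {
    stop("malformed ICD-O-3 code: \"", code, "\" (behavior out of range)")
  }
  structure(list(histology = histology, behavior = behavior,
                 topography = m[4L], combined_code = raw),
            class = "icdo_code")
}

#' @export
print.icdo_code <- function(x, ...) {
  cat("<icdo_code> ", x$combined_code, " (histology ", x$histology,
      ", behavior ", x$behavior, ", topography ", x$topography, ")\n", sep = "")
  invisible(x)
}

histology_code <- function(icdo) paste0(icdo$histology, "/", icdo$behavior)

as_icdo <- function(x) if (inherits(x, "icdo_code")) x else parse_icdo(x)

#' Precoordinate observed ICD-O-3 combinations
#'
#' Creates one Condition-domain concept per unique observed
#' histology/behavior/topography combination (vocabulary `"ICDO3"`,
#' `concept_code` = the combined code), with `"Has Histology"` and
#' `"Has Topography"` relationships to the component ICD-O concepts already
#' in the graph. Only the supplied (observed) combinations are instantiated;
#' combinations already present are left untouched. New concept ids are
#' minted from the 2-billion local range in sorted combined-code order.
#'
#' @param graph a [concept_graph] containing the ICD-O component concepts.
#' @param codes character vector of combined codes (or `icdo_code` objects).
#' @return The updated graph.
#' @export
precoordinate <- function(graph, codes) {
  icdos <- lapply(codes, as_icdo)
  combined <- vapply(icdos, `[[`, character(1), "combined_code")
  icdos <- icdos[!duplicated(combined)]
  icdos <- icdos[order(vapply(icdos, `[[`, character(1), "combined_code"))]
  new <- Filter(function(ic) is.na(concept_by_code(graph, "ICDO3", ic$combined_code)),
                icdos)
  if (!length(new)) return(graph)
  ids <- next_local_id(graph, length(new))
  for (k in seq_along(new)) {
    ic <- new[[k]]
    hist_id <- concept_by_code(graph, "ICDO3", histology_code(ic))
    if (is.na(hist_id)) {
      stop("histology concept missing from graph for code ", ic$combined_code)
    }
    topo_id <- concept_by_code(graph, "ICDO3", ic$topography)
    if (is.na(topo_id)) {
      stop("topography concept missing from graph for code ", ic$combined_code)
    }
    name <- paste(concept_row(graph, hist_id)$concept_name, "of",
                  concept_row(graph, topo_id)$concept_name)
    graph <- add_concepts(graph, data.frame(
      concept_id = ids[k], concept_name = name, domain_id = "Condition",
      vocabulary_id = "ICDO3", concept_class_id = "ICDO Condition",
      standard_concept = FALSE, concept_code = ic$combined_code,
      stringsAsFactors = FALSE))
    graph <- add_relationship(graph, ids[k], hist_id, "Has Histology")
    graph <- add_relationship(graph, ids[k], topo_id, "Has Topography")
  }
  graph <- rebuild_ancestors(graph)
  validate_concept_graph(graph)
}

#' Resolve SNOMED attribute equivalents of an ICD-O-3 code
#'
#' Step 1 of the integration algorithm: translate the ICD-O-3 histology
#' (with behavior) into the equivalent SNOMED associated-morphology concept
#' and the topography into the equivalent SNOMED finding-site (body
#' structure) concept, using the `"Maps to"` equivalences carried by the
#' component ICD-O concepts.
#'
#' @param graph a [concept_graph].
#' @param icdo an `icdo_code` (or combined-code string).
#' @return List with `morphology_concept_id` and `finding_site_concept_id`.
#' @export
resolve_attributes <- function(graph, icdo) {
  icdo <- as_icdo(icdo)
  hist_id <- concept_by_code(graph, "ICDO3", histology_code(icdo))
  if (is.na(hist_id)) {
    stop("no histology concept for ", histology_code(icdo),
         " (histology axis unresolvable)")
  }
  morph <- related_targets(graph, hist_id, "Maps to")
  if (!length(morph)) {
    stop("no morphology equivalence for histology ", histology_code(icdo),
         " (histology axis unresolvable)")
  }
  topo_id <- concept_by_code(graph, "ICDO3", icdo$topography)
  if (is.na(topo_id)) {
    stop("no topography concept for ", icdo$topography,
         " (topography axis unresolvable)")
  }
  site <- related_targets(graph, topo_id, "Maps to")
  if (!length(site)) {
    stop("no finding-site equivalence for topography ", icdo$topography,
         " (topography axis unresolvable)")
  }
  list(morphology_concept_id = morph[1L], finding_site_concept_id = site[1L])
}

# Disorder concepts carrying both defining attributes, as a data.frame of
# (concept_id, morphology, site) rows — one row per attribute pairing.
disorder_attributes <- function(graph, exclude = numeric(0)) {
  re <- graph$relationships
  morph <- re[re$relationship_id == "Has associated morphology", c(1, 2)]
  site <- re[re$relationship_id == "Has finding site", c(1, 2)]
  names(morph) <- c("concept_id", "morphology")
  names(site) <- c("concept_id", "site")
  d <- merge(morph, site, by = "concept_id")
  cond <- graph$concepts$concept_id[graph$concepts$domain_id == "Condition"]
  d[d$concept_id %in% setdiff(cond, exclude), , drop = FALSE]
}

#' Find the SNOMED disorder exactly equivalent to an attribute pair
#'
#' Step 2a of the integration algorithm: look for a disorder whose
#' associated-morphology attribute equals `pair$morphology_concept_id`
#' exactly and whose finding-site attribute equals
#' `pair$finding_site_concept_id` exactly. A disorder with a coarser
#' (ancestral) attribute on either axis is not an equivalent — it is a
#' candidate hierarchy parent for [insert_into_hierarchy()].
#'
#' @param graph a [concept_graph].
#' @param pair attribute pair from [resolve_attributes()].
#' @param exclude concept ids never to return (e.g. the ICD-O concept being
#'   integrated).
#' @return The matching disorder concept id, or `NULL` when none exists.
#'   Multiple exact matches trigger a warning and the lowest id is returned.
#' @export
find_equivalent <- function(graph, pair, exclude = numeric(0)) {
  d <- disorder_attributes(graph, exclude = exclude)
  hit <- unique(d$concept_id[d$morphology == pair$morphology_concept_id &
                               d$site == pair$finding_site_concept_id])
  if (!length(hit)) return(NULL)
  if (length(hit) > 1L) {
    warning("multiple exact attribute matches (", paste(sort(hit), collapse = ", "),
            "); choosing lowest concept_id")
  }
  min(hit)
}

#' Insert a precoordinated concept into the disease hierarchy
#'
#' Step 2b of the integration algorithm, used when no exact equivalent
#' exists: the ICD-O concept is placed at the intersection of its morphology
#' and finding-site attributes — it gains those attribute edges, becomes a
#' standard concept, and is made a child (`"Is a"`) of the most specific
#' existing disorder(s) that subsume the intersection. A disorder subsumes
#' the intersection when its morphology attribute is an ancestor-or-equal of
#' the new morphology and its site attribute an ancestor-or-equal of the new
#' site; non-minimal subsumers are pruned, so pre-existing hierarchy queries
#' keep working unchanged.
#'
#' @param graph a [concept_graph].
#' @param icdo_concept_id the precoordinated concept to insert.
#' @param pair attribute pair from [resolve_attributes()].
#' @param fallback_root parent used (with a warning) when no subsuming
#'   disorder exists; defaults to the graph's `"Neoplastic disease"` concept
#'   if present.
#' @return List with `graph` (updated) and `outcome` (an
#'   `integration_outcome` with mode `"INSERTED"`).
#' @export
insert_into_hierarchy <- function(graph, icdo_concept_id, pair,
                                  fallback_root = NULL) {
  d <- disorder_attributes(graph, exclude = icdo_concept_id)
  subsumes <- vapply(seq_len(nrow(d)), function(i) {
    is_ancestor_or_equal(graph, d$morphology[i], pair$morphology_concept_id) &&
      is_ancestor_or_equal(graph, d$site[i], pair$finding_site_concept_id)
  }, logical(1))
  cand <- unique(d$concept_id[subsumes])
  # keep only minimal (most specific) subsumers
  keep <- vapply(cand, function(x) {
    !any(vapply(setdiff(cand, x), function(y) is_ancestor_or_equal(graph, x, y),
                logical(1)))
  }, logical(1))
  parents <- sort(cand[keep])
  if (!length(parents)) {
    if (is.null(fallback_root)) {
      fallback_root <- graph$concepts$concept_id[
        graph$concepts$concept_name == "Neoplastic disease"][1L]
    }
    if (is.null(fallback_root) || is.na(fallback_root)) {
      stop("no subsuming disorder and no fallback root configured")
    }
    warning("no subsuming disorder for concept ", icdo_concept_id,
            "; parenting under configured root ", fallback_root)
    parents <- fallback_root
  }
  graph <- add_relationship(graph, icdo_concept_id, pair$morphology_concept_id,
                            "Has associated morphology")
  graph <- add_relationship(graph, icdo_concept_id, pair$finding_site_concept_id,
                            "Has finding site")
  for (p in parents) graph <- add_relationship(graph, icdo_concept_id, p, "Is a")
  graph$concepts$standard_concept[
    graph$concepts$concept_id == icdo_concept_id] <- TRUE
  graph <- rebuild_ancestors(graph)
  outcome <- integration_outcome(icdo_concept_id, "INSERTED",
                                 standard_concept_id = icdo_concept_id,
                                 parent_concept_ids = parents)
  list(graph = graph, outcome = outcome)
}

integration_outcome <- function(icdo_concept_id, mode, standard_concept_id,
                                parent_concept_ids = numeric(0)) {
  structure(list(icdo_concept_id = icdo_concept_id, mode = mode,
                 standard_concept_id = standard_concept_id,
                 parent_concept_ids = parent_concept_ids),
            class = "integration_outcome")
}

#' @export
print.integration_outcome <- function(x, ...) {
  cat("<integration_outcome> concept ", format_id(x$icdo_concept_id), ": ",
      x$mode, ", standard = ", format_id(x$standard_concept_id), sep = "")
  if (length(x$parent_concept_ids)) {
    cat(", parents = ", paste(format_id(x$parent_concept_ids), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Integrate a precoordinated diagnosis into the disease hierarchy
#'
#' The two-step integration: resolve the SNOMED attribute equivalents of the
#' ICD-O-3 components ([resolve_attributes()]); if a disorder with exactly
#' those attributes exists ([find_equivalent()]), record a `"Maps to"`
#' equivalence — the SNOMED disorder becomes the designated standard concept
#' for the diagnosis (mode `"EQUIVALENT"`). Otherwise the ICD-O concept is
#' itself inserted into the hierarchy and becomes standard
#' ([insert_into_hierarchy()], mode `"INSERTED"`). Re-running on an already
#' integrated concept is a no-op returning the recorded outcome.
#'
#' @param graph a [concept_graph].
#' @param icdo_concept_id a concept created by [precoordinate()].
#' @param fallback_root see [insert_into_hierarchy()].
#' @return List with `graph` and `outcome`.
#' @export
integrate_diagnosis <- function(graph, icdo_concept_id, fallback_root = NULL) {
  row <- concept_row(graph, icdo_concept_id)
  if (row$vocabulary_id != "ICDO3" || !grepl("-", row$concept_code, fixed = TRUE)) {
    stop("concept ", icdo_concept_id, " is not a precoordinated ICD-O-3 concept")
  }
  existing_map <- related_targets(graph, icdo_concept_id, "Maps to")
  if (length(existing_map)) {
    return(list(graph = graph,
                outcome = integration_outcome(icdo_concept_id, "EQUIVALENT",
                                              standard_concept_id = existing_map[1L])))
  }
  if (row$standard_concept) {
    return(list(graph = graph,
                outcome = integration_outcome(
                  icdo_concept_id, "INSERTED",
                  standard_concept_id = icdo_concept_id,
                  parent_concept_ids = sort(related_targets(graph, icdo_concept_id, "Is a")))))
  }
  pair <- resolve_attributes(graph, row$concept_code)
  eq <- find_equivalent(graph, pair, exclude = icdo_concept_id)
  if (!is.null(eq)) {
    graph <- add_relationship(graph, icdo_concept_id, eq, "Maps to")
    validate_concept_graph(graph)
    return(list(graph = graph,
                outcome = integration_outcome(icdo_concept_id, "EQUIVALENT",
                                              standard_concept_id = eq)))
  }
  insert_into_hierarchy(graph, icdo_concept_id, pair, fallback_root = fallback_root)
}

#' Link a precoordinated diagnosis to its cancer type
#'
#' Adds a `"Has cancer type"` relationship from the precoordinated concept to
#' the cancer-type concept selected by topography prefix (longest matching
#' prefix wins; e.g. any `C50.*` topography links to cancer type: breast).
#' An uncovered prefix produces a warning and no edge.
#'
#' @param graph a [concept_graph].
#' @param icdo_concept_id a precoordinated concept id.
#' @param type_rules named numeric vector: names are topography prefixes
#'   (e.g. `"C50"`), values cancer-type concept ids.
#' @return The updated graph.
#' @export
link_cancer_type <- function(graph, icdo_concept_id, type_rules) {
  if (!length(type_rules)) return(graph)
  code <- concept_row(graph, icdo_concept_id)$concept_code
  topo <- as_icdo(code)$topography
  hits <- names(type_rules)[startsWith(topo, names(type_rules))]
  if (!length(hits)) {
    warning("no cancer-type rule covers topography ", topo)
    return(graph)
  }
  best <- hits[which.max(nchar(hits))]
  add_relationship(graph, icdo_concept_id, unname(type_rules[[best]]),
                   "Has cancer type")
}

#' Precoordinate and integrate a set of observed combinations
#'
#' Convenience driver: [precoordinate()] every observed combination, run
#' [integrate_diagnosis()] on each, and (optionally) link cancer types.
#'
#' @param graph a [concept_graph].
#' @param codes character vector of combined ICD-O-3 codes.
#' @param type_rules optional cancer-type rules (see [link_cancer_type()]).
#' @param fallback_root see [insert_into_hierarchy()].
#' @return List with `graph` and `report`, a data.frame with one row per
#'   code: `icdo_code`, `icdo_concept_id`, `mode`, `standard_concept_id`,
#'   `parents` (semicolon-separated).
#' @export
integrate_all <- function(graph, codes, type_rules = NULL, fallback_root = NULL) {
  codes <- unique(vapply(lapply(codes, as_icdo), `[[`, character(1), "combined_code"))
  graph <- precoordinate(graph, codes)
  rows <- vector("list", length(codes))
  for (k in seq_along(sort(codes))) {
    code <- sort(codes)[k]
    cid <- concept_by_code(graph, "ICDO3", code)
    res <- integrate_diagnosis(graph, cid, fallback_root = fallback_root)
    graph <- res$graph
    if (!is.null(type_rules)) graph <- link_cancer_type(graph, cid, type_rules)
    rows[[k]] <- data.frame(
      icdo_code = code, icdo_concept_id = cid, mode = res$outcome$mode,
      standard_concept_id = res$outcome$standard_concept_id,
      parents = paste(format_id(res$outcome$parent_concept_ids), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(graph = graph, report = do.call(rbind, rows))
}
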