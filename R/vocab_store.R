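# vocab_store: load, hold, query and write the vocabulary layer
# (concepts, typed relationships, hierarchical ancestor closure).

#' Construct a concept graph
#'
#' A `concept_graph` is the in-memory vocabulary store: a table of concepts,
#' a table of typed relationships between them, and the derived ancestor
#' closure of the "Is a" hierarchy. All other modules are driven by it.
#'
#' @param concepts data.frame with columns `concept_id`, `concept_name`,
#'   `domain_id`, `vocabulary_id`, `concept_class_id`, `standard_concept`
#'   (logical), `concept_code`.
#' @param relationships data.frame with columns `concept_id_1`,
#'   `concept_id_2`, `relationship_id`.
#' @param ancestors optional data.frame with columns `ancestor_concept_id`,
#'   `descendant_concept_id`, `min_levels_of_separation`,
#'   `max_levels_of_separation`; rebuilt from the "Is a" edges when `NULL`.
#' @param validate run invariant checks (default `TRUE`).
#'
#' @return An object of class `concept_graph`.
#' @export
concept_graph <- function(concepts = empty_concepts(),
                          relationships = empty_relationships(),
                          ancestors = NULL, validate = TRUE) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  relationships <- as.data.frame(relationships, stringsAsFactors = FALSE)
  g <- structure(list(concepts = concepts, relationships = relationships,
                      ancestors = ancestors), class = "concept_graph")
  if (is.null(ancestors)) g <- rebuild_ancestors(g)
  if (validate) validate_concept_graph(g)
  g
}

empty_concepts <- function() {
  data.frame(concept_id = numeric(0), concept_name = character(0),
             domain_id = character(0), vocabulary_id = character(0),
             concept_class_id = character(0), standard_concept = logical(0),
             concept_code = character(0), stringsAsFactors = FALSE)
}

empty_relationships <- function() {
  data.frame(concept_id_1 = numeric(0), concept_id_2 = numeric(0),
             relationship_id = character(0), stringsAsFactors = FALSE)
}

empty_ancestors <- function() {
  data.frame(ancestor_concept_id = numeric(0), descendant_concept_id = numeric(0),
             min_levels_of_separation = numeric(0),
             max_levels_of_separation = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.concept_graph <- function(x, ...) {
  cat("<concept_graph> ", nrow(x$concepts), " concepts, ",
      nrow(x$relationships), " relationships, ",
      nrow(x$ancestors), " ancestor rows\n", sep = "")
  vocabs <- sort(unique(x$concepts$vocabulary_id))
  if (length(vocabs)) cat("  vocabularies:", paste(vocabs, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a concept graph
#'
#' Checks the store invariants: unique `concept_id`, unique
#' `(vocabulary_id, concept_code)`, non-empty codes, known domains and
#' relationship types, resolvable relationship endpoints, no "Is a"
#' self-loops, and every "Maps to" target flagged standard.
#'
#' @param graph a [concept_graph].
#' @return `graph`, invisibly; errors on the first violated invariant.
#' @export
validate_concept_graph <- function(graph) {
  co <- graph$concepts
  re <- graph$relationships
  dup <- co$concept_id[duplicated(co$concept_id)]
  if (length(dup)) stop("duplicate concept_id: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(co$concept_code))) {
    stop("empty concept_code for concept_id: ",
         paste(co$concept_id[!nzchar(co$concept_code)], collapse = ", "))
  }
  key <- paste(co$vocabulary_id, co$concept_code, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (vocabulary_id, concept_code): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  bad_dom <- setdiff(unique(co$domain_id), onco_domains)
  if (length(bad_dom)) stop("unknown domain_id: ", paste(bad_dom, collapse = ", "))
  bad_rel <- setdiff(unique(re$relationship_id), onco_relationships)
  if (length(bad_rel)) stop("unknown relationship_id: ", paste(bad_rel, collapse = ", "))
  dangling <- setdiff(c(re$concept_id_1, re$concept_id_2), co$concept_id)
  if (length(dangling)) {
    stop("relationship endpoint not in concept table: ",
         paste(dangling, collapse = ", "))
  }
  isa <- re[re$relationship_id == "Is a", , drop = FALSE]
  if (any(isa$concept_id_1 == isa$concept_id_2)) {
    stop("'Is a' self-loop at concept_id: ",
         paste(isa$concept_id_1[isa$concept_id_1 == isa$concept_id_2], collapse = ", "))
  }
  mt <- re[re$relationship_id == "Maps to", , drop = FALSE]
  if (nrow(mt)) {
    std <- co$standard_concept[match(mt$concept_id_2, co$concept_id)]
    if (any(!std)) {
      stop("'Maps to' target is not a standard concept: ",
           paste(mt$concept_id_2[!std], collapse = ", "))
    }
  }
  invisible(graph)
}

# ---- file dialect ----------------------------------------------------------

vocab_file_specs <- list(
  CONCEPT = list(
    file = "CONCEPT.csv",
    cols = c("CONCEPT_ID", "CONCEPT_NAME", "DOMAIN_ID", "VOCABULARY_ID",
             "CONCEPT_CLASS_ID", "STANDARD_CONCEPT", "CONCEPT_CODE")),
  CONCEPT_RELATIONSHIP = list(
    file = "CONCEPT_RELATIONSHIP.csv",
    cols = c("CONCEPT_ID_1", "CONCEPT_ID_2", "RELATIONSHIP_ID")),
  CONCEPT_ANCESTOR = list(
    file = "CONCEPT_ANCESTOR.csv",
    cols = c("ANCESTOR_CONCEPT_ID", "DESCENDANT_CONCEPT_ID",
             "MIN_LEVELS_OF_SEPARATION", "MAX_LEVELS_OF_SEPARATION"))
)

read_vocab_table <- function(path, spec) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty vocabulary file (no header): ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, spec$cols)) {
    stop("unexpected header in ", path, ": ", lines[1L])
  }
  n <- length(spec$cols)
  # strsplit drops a trailing empty field, so allow n - 1 when the last
  # field of a row is blank
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != n & nfield != n - 1L)
  bad <- bad[bad != 1L]
  if (length(bad)) {
    stop("malformed row in ", basename(path), " at line ", bad[1L],
         " (expected ", length(spec$cols), " tab-separated fields)")
  }
  if (length(lines) == 1L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(spec$cols)),
                                  spec$cols), stringsAsFactors = FALSE)
    return(out)
  }
  df <- read.delim(text = lines, sep = "\t", quote = "", comment.char = "",
                   colClasses = "character", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = NULL)
  names(df) <- spec$cols
  df
}

#' Load a vocabulary directory
#'
#' Reads `CONCEPT.csv` and `CONCEPT_RELATIONSHIP.csv` (tab-delimited, upper
#' case OMOP column names, `"S"`/empty standard-concept flag) from
#' `directory`; `CONCEPT_ANCESTOR.csv` is read when present, otherwise the
#' ancestor closure is rebuilt from the "Is a" edges.
#'
#' @param directory path containing the vocabulary files.
#' @return A validated [concept_graph].
#' @export
load_vocab <- function(directory) {
  cpath <- file.path(directory, vocab_file_specs$CONCEPT$file)
  rpath <- file.path(directory, vocab_file_specs$CONCEPT_RELATIONSHIP$file)
  apath <- file.path(directory, vocab_file_specs$CONCEPT_ANCESTOR$file)
  if (!file.exists(cpath)) stop("missing ", cpath)
  if (!file.exists(rpath)) stop("missing ", rpath)
  craw <- read_vocab_table(cpath, vocab_file_specs$CONCEPT)
  rraw <- read_vocab_table(rpath, vocab_file_specs$CONCEPT_RELATIONSHIP)
  concepts <- data.frame(
    concept_id = as.numeric(craw$CONCEPT_ID),
    concept_name = craw$CONCEPT_NAME,
    domain_id = craw$DOMAIN_ID,
    vocabulary_id = craw$VOCABULARY_ID,
    concept_class_id = craw$CONCEPT_CLASS_ID,
    standard_concept = craw$STANDARD_CONCEPT == "S",
    concept_code = craw$CONCEPT_CODE,
    stringsAsFactors = FALSE)
  relationships <- data.frame(
    concept_id_1 = as.numeric(rraw$CONCEPT_ID_1),
    concept_id_2 = as.numeric(rraw$CONCEPT_ID_2),
    relationship_id = rraw$RELATIONSHIP_ID,
    stringsAsFactors = FALSE)
  ancestors <- NULL
  if (file.exists(apath)) {
    araw <- read_vocab_table(apath, vocab_file_specs$CONCEPT_ANCESTOR)
    ancestors <- data.frame(
      ancestor_concept_id = as.numeric(araw$ANCESTOR_CONCEPT_ID),
      descendant_concept_id = as.numeric(araw$DESCENDANT_CONCEPT_ID),
      min_levels_of_separation = as.numeric(araw$MIN_LEVELS_OF_SEPARATION),
      max_levels_of_separation = as.numeric(araw$MAX_LEVELS_OF_SEPARATION),
      stringsAsFactors = FALSE)
  }
  concept_graph(concepts, relationships, ancestors)
}

#' Write a vocabulary directory
#'
#' Writes `CONCEPT.csv`, `CONCEPT_RELATIONSHIP.csv` and
#' `CONCEPT_ANCESTOR.csv` in the tab-delimited dialect read by
#' [load_vocab()], in canonical sort order so output is byte-stable.
#'
#' @param graph a [concept_graph].
#' @param directory output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_vocab <- function(graph, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  co <- graph$concepts[order(graph$concepts$concept_id), , drop = FALSE]
  cdf <- data.frame(
    CONCEPT_ID = format_id(co$concept_id), CONCEPT_NAME = co$concept_name,
    DOMAIN_ID = co$domain_id, VOCABULARY_ID = co$vocabulary_id,
    CONCEPT_CLASS_ID = co$concept_class_id,
    STANDARD_CONCEPT = ifelse(co$standard_concept, "S", ""),
    CONCEPT_CODE = co$concept_code, stringsAsFactors = FALSE)
  re <- graph$relationships
  re <- re[order(re$concept_id_1, re$concept_id_2, re$relationship_id), , drop = FALSE]
  rdf <- data.frame(CONCEPT_ID_1 = format_id(re$concept_id_1),
                    CONCEPT_ID_2 = format_id(re$concept_id_2),
                    RELATIONSHIP_ID = re$relationship_id, stringsAsFactors = FALSE)
  an <- graph$ancestors
  an <- an[order(an$ancestor_concept_id, an$descendant_concept_id), , drop = FALSE]
  adf <- data.frame(ANCESTOR_CONCEPT_ID = format_id(an$ancestor_concept_id),
                    DESCENDANT_CONCEPT_ID = format_id(an$descendant_concept_id),
                    MIN_LEVELS_OF_SEPARATION = format_id(an$min_levels_of_separation),
                    MAX_LEVELS_OF_SEPARATION = format_id(an$max_levels_of_separation),
                    stringsAsFactors = FALSE)
  write_tab <- function(df, file) {
    write.table(df, file.path(directory, file), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tab(cdf, vocab_file_specs$CONCEPT$file)
  write_tab(rdf, vocab_file_specs$CONCEPT_RELATIONSHIP$file)
  write_tab(adf, vocab_file_specs$CONCEPT_ANCESTOR$file)
  invisible(directory)
}

format_id <- function(x) format(x, scientific = FALSE, trim = TRUE)

# ---- ancestor closure ------------------------------------------------------

#' Rebuild the ancestor closure
#'
#' Recomputes the `CONCEPT_ANCESTOR` closure as the transitive closure of the
#' "Is a" edges plus a reflexive row per concept; `min`/`max` levels of
#' separation are the shortest/longest "Is a" path lengths. The "Is a" edges
#' must form a DAG; a cycle is a hard error naming one offending cycle.
#'
#' @param graph a [concept_graph].
#' @return `graph` with its `ancestors` table replaced.
#' @export
rebuild_ancestors <- function(graph) {
  ids <- graph$concepts$concept_id
  isa <- graph$relationships[graph$relationships$relationship_id == "Is a", , drop = FALSE]
  if (!length(ids)) {
    graph$ancestors <- empty_ancestors()
    return(graph)
  }
  reflexive <- data.frame(ancestor_concept_id = ids, descendant_concept_id = ids,
                          min_levels_of_separation = 0, max_levels_of_separation = 0,
                          stringsAsFactors = FALSE)
  if (!nrow(isa)) {
    graph$ancestors <- reflexive
    return(graph)
  }
  vn <- as.character(ids)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(isa$concept_id_1),
               to = as.character(isa$concept_id_2)),
    directed = TRUE, vertices = vn)
  if (!igraph::is_dag(ig)) stop("cycle in 'Is a' hierarchy: ", find_isa_cycle(isa))
  # child -> parent edges: topological order lists children before parents;
  # walk parents-first so each node's ancestor map can extend its parents'.
  topo <- rev(as.character(igraph::topo_sort(ig, mode = "out")$name))
  parents <- split(as.character(isa$concept_id_2), as.character(isa$concept_id_1))
  minmax <- new.env(parent = emptyenv())   # node -> list(anc ids, min, max)
  for (v in topo) {
    anc_min <- numeric(0); anc_max <- numeric(0)
    for (p in parents[[v]]) {
      pm <- get(p, envir = minmax)
      cand_min <- c(setNames(1, p), pm$min + 1)
      cand_max <- c(setNames(1, p), pm$max + 1)
      for (a in names(cand_min)) {
        anc_min[a] <- if (is.na(anc_min[a])) cand_min[[a]] else min(anc_min[[a]], cand_min[[a]])
        anc_max[a] <- if (is.na(anc_max[a])) cand_max[[a]] else max(anc_max[[a]], cand_max[[a]])
      }
    }
    assign(v, list(min = anc_min, max = anc_max), envir = minmax)
  }
  rows <- lapply(vn, function(v) {
    m <- get(v, envir = minmax)
    if (!length(m$min)) return(NULL)
    data.frame(ancestor_concept_id = as.numeric(names(m$min)),
               descendant_concept_id = as.numeric(v),
               min_levels_of_separation = unname(m$min),
               max_levels_of_separation = unname(m$max[names(m$min)]),
               stringsAsFactors = FALSE)
  })
  closure <- rbind(reflexive, do.call(rbind, rows))
  closure <- closure[order(closure$ancestor_concept_id, closure$descendant_concept_id), ]
  rownames(closure) <- NULL
  graph$ancestors <- closure
  graph
}

find_isa_cycle <- function(isa) {
  adj <- split(isa$concept_id_2, isa$concept_id_1)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    s <- mget(v, envir = state, ifnotfound = 0L)[[1L]]
    if (s == 1L) { found <<- c(path[which(path == v)[1L]:length(path)], v); return() }
    if (s == 2L) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (w in as.character(adj[[v]])) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in as.character(unique(isa$concept_id_1))) visit(v)
  paste(found, collapse = " -> ")
}

#' Hierarchy queries
#'
#' `descendants_of()` returns all descendants of a concept (itself included)
#' from the ancestor closure; `ancestors_of()` the converse. Cohort
#' definitions use `descendants_of()` to expand an index concept set so that
#' queries written against a parent disorder keep matching newly inserted,
#' more granular diagnoses.
#'
#' @param graph a [concept_graph].
#' @param concept_id a concept id present in the graph.
#' @return Numeric vector of concept ids (always includes `concept_id`).
#' @export
descendants_of <- function(graph, concept_id) {
  if (!concept_id %in% graph$concepts$concept_id) {
    stop("unknown concept_id: ", concept_id)
  }
  an <- graph$ancestors
  sort(unique(an$descendant_concept_id[an$ancestor_concept_id == concept_id]))
}

#' @rdname descendants_of
#' @export
ancestors_of <- function(graph, concept_id) {
  if (!concept_id %in% graph$concepts$concept_id) {
    stop("unknown concept_id: ", concept_id)
  }
  an <- graph$ancestors
  sort(unique(an$ancestor_concept_id[an$descendant_concept_id == concept_id]))
}

is_ancestor_or_equal <- function(graph, ancestor_id, descendant_id) {
  an <- graph$ancestors
  any(an$ancestor_concept_id == ancestor_id &
        an$descendant_concept_id == descendant_id)
}

# ---- small accessors used across modules -----------------------------------

concept_row <- function(graph, concept_id) {
  i <- match(concept_id, graph$concepts$concept_id)
  if (is.na(i)) stop("unknown concept_id: ", concept_id)
  graph$concepts[i, , drop = FALSE]
}

concept_by_code <- function(graph, vocabulary_id, concept_code) {
  co <- graph$concepts
  hit <- co$concept_id[co$vocabulary_id == vocabulary_id &
                         co$concept_code == concept_code]
  if (length(hit)) hit[1L] else NA_real_
}

related_targets <- function(graph, concept_id, relationship_id) {
  re <- graph$relationships
  re$concept_id_2[re$concept_id_1 == concept_id &
                    re$relationship_id == relationship_id]
}

add_concepts <- function(graph, concepts) {
  graph$concepts <- rbind(graph$concepts, concepts)
  graph
}

add_relationship <- function(graph, id1, id2, relationship_id) {
  re <- graph$relationships
  exists <- any(re$concept_id_1 == id1 & re$concept_id_2 == id2 &
                  re$relationship_id == relationship_id)
  if (!exists) {
    graph$relationships <- rbind(re, data.frame(
      concept_id_1 = id1, concept_id_2 = id2, relationship_id = relationship_id,
      stringsAsFactors = FALSE))
  }
  graph
}

next_local_id <- function(graph, n = 1L) {
  ids <- graph$concepts$concept_id
  base <- max(c(LOCAL_CONCEPT_FLOOR - 1, ids[ids >= LOCAL_CONCEPT_FLOOR]))
  base + seq_len(n)
}
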