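# Shared fixtures and independent oracles.

fig3_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_fixture_vocab()
    g
  }
})

integrated_graph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- integrate_all(make_fixture_vocab(),
                              c("8520/3-C50.9", "8010/3-C50.9"),
                              type_rules = fixture_type_rules())
    }
    cache
  }
})

fxid <- function(name) unname(fixture_concepts[[name]])

# Minimal concept table for synthetic hierarchy-only graphs.
toy_concepts <- function(ids, domain = "Condition", standard = TRUE) {
  data.frame(concept_id = ids, concept_name = paste0("concept ", ids),
             domain_id = domain, vocabulary_id = "SNOMED",
             concept_class_id = "Clinical Finding", standard_concept = standard,
             concept_code = as.character(ids), stringsAsFactors = FALSE)
}

toy_isa <- function(child, parent) {
  data.frame(concept_id_1 = child, concept_id_2 = parent,
             relationship_id = "Is a", stringsAsFactors = FALSE)
}

# Random DAG over 1..n: edges i -> j only for i < j, so acyclic by
# construction. Returns a concept_graph.
random_dag_graph <- function(n, p = 1.5 / n) {
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) {
    hit <- which(runif(n - i) < p)
    from <- c(from, rep(i, length(hit)))
    to <- c(to, i + hit)
  }
  concept_graph(toy_concepts(seq_len(n)),
                if (length(from)) toy_isa(from, to) else NULL)
}

# Independent ancestor-closure oracle: path existence by boolean matrix
# powers. B_k[i, j] = a directed "Is a" path of exactly length k from i to j;
# min/max levels are the first/last k with a path. Nilpotency of a DAG's
# adjacency matrix bounds the loop.
oracle_closure <- function(graph) {
  ids <- graph$concepts$concept_id
  n <- length(ids)
  isa <- graph$relationships[graph$relationships$relationship_id == "Is a", ]
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(isa)) {
    A[cbind(match(isa$concept_id_1, ids), match(isa$concept_id_2, ids))] <- 1
  }
  res <- data.frame(ancestor_concept_id = ids, descendant_concept_id = ids,
                    min_levels_of_separation = 0, max_levels_of_separation = 0)
  B <- A; k <- 1
  minl <- matrix(NA_real_, n, n); maxl <- matrix(NA_real_, n, n)
  while (any(B > 0)) {
    hit <- B > 0
    minl[hit & is.na(minl)] <- k
    maxl[hit] <- k
    B <- (B %*% A > 0) * 1
    k <- k + 1
    if (k > n) stop("not a DAG")
  }
  idx <- which(!is.na(minl), arr.ind = TRUE)
  if (nrow(idx)) {
    res <- rbind(res, data.frame(
      ancestor_concept_id = ids[idx[, 2]], descendant_concept_id = ids[idx[, 1]],
      min_levels_of_separation = minl[idx], max_levels_of_separation = maxl[idx]))
  }
  res <- res[order(res$ancestor_concept_id, res$descendant_concept_id), ]
  rownames(res) <- NULL
  res
}

sorted_closure <- function(graph) {
  an <- graph$ancestors[order(graph$ancestors$ancestor_concept_id,
                              graph$ancestors$descendant_concept_id), ]
  rownames(an) <- NULL
  an
}

# Independent reachability for the insertion-parent oracle: DFS over raw
# "Is a" edges, no use of the package's ancestor closure.
dfs_reaches <- function(isa, from, to) {
  if (from == to) return(TRUE)
  adj <- split(isa$concept_id_2, isa$concept_id_1)
  seen <- numeric(0); stack <- from
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    nxt <- adj[[as.character(v)]]
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt)
  }
  FALSE
}

# Brute-force parent selection: enumerate every disorder subsuming the
# (morphology, site) pair, prune the non-minimal ones.
oracle_insert_parents <- function(graph, pair, exclude) {
  re <- graph$relationships
  isa <- re[re$relationship_id == "Is a", ]
  morph <- re[re$relationship_id == "Has associated morphology", ]
  site <- re[re$relationship_id == "Has finding site", ]
  cond <- graph$concepts$concept_id[graph$concepts$domain_id == "Condition"]
  cand <- numeric(0)
  for (d in setdiff(intersect(morph$concept_id_1, site$concept_id_1), exclude)) {
    if (!d %in% cond) next
    m <- morph$concept_id_2[morph$concept_id_1 == d]
    s <- site$concept_id_2[site$concept_id_1 == d]
    ok <- any(vapply(m, function(x)
      dfs_reaches(isa, pair$morphology_concept_id, x), logical(1))) &&
      any(vapply(s, function(x)
        dfs_reaches(isa, pair$finding_site_concept_id, x), logical(1)))
    if (ok) cand <- c(cand, d)
  }
  cand <- unique(cand)
  keep <- vapply(cand, function(x)
    !any(vapply(setdiff(cand, x), function(y) dfs_reaches(isa, y, x), logical(1))),
    logical(1))
  sort(cand[keep])
}
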