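test_that("combined ICD-O-3 codes parse into their three components", {
  x <- parse_icdo("8520/3-C50.9")
  expect_equal(x$histology, 8520)
  expect_equal(x$behavior, 3)
  expect_equal(x$topography, "C50.9")
  expect_equal(x$combined_code, "8520/3-C50.9")
  y <- parse_icdo("  8010/3-C50.9 ")
  expect_equal(y$histology, 8010)
  expect_equal(parse_icdo("8000/0-C61")$topography, "C61")
  expect_error(parse_icdo("8010/9-C50.9"), "8010/9-C50.9")  # behavior range
  expect_error(parse_icdo("7000/3-C50.9"), "histology")
  expect_error(parse_icdo("8010-C50.9"), "malformed")
})

test_that("precoordination instantiates only observed combinations, once", {
  g <- fig3_graph()
  g2 <- precoordinate(g, c("8520/3-C50.9", "8010/3-C50.9", "8520/3-C50.9"))
  new_ids <- setdiff(g2$concepts$concept_id, g$concepts$concept_id)
  expect_length(new_ids, 2)
  codes <- g2$concepts$concept_code[g2$concepts$concept_id %in% new_ids]
  expect_setequal(codes, c("8520/3-C50.9", "8010/3-C50.9"))
  attr_edges <- g2$relationships[g2$relationships$relationship_id %in%
                                   c("Has Histology", "Has Topography"), ]
  expect_equal(nrow(attr_edges), 4)
  expect_true(all(g2$concepts$domain_id[g2$concepts$concept_id %in% new_ids] ==
                    "Condition"))
  # ids are minted deterministically in sorted code order
  expect_lt(g2$concepts$concept_id[g2$concepts$concept_code == "8010/3-C50.9"],
            g2$concepts$concept_id[g2$concepts$concept_code == "8520/3-C50.9"])
  expect_identical(precoordinate(g2, "8520/3-C50.9"), g2)   # idempotent
  expect_error(precoordinate(g, "9999/3-C50.9"), "9999/3-C50.9")
  expect_error(precoordinate(g, "8010/3-C34.1"), "8010/3-C34.1")
})

test_that("attribute resolution returns the SNOMED morphology and site", {
  g <- fig3_graph()
  pair <- resolve_attributes(g, "8010/3-C50.9")
  expect_equal(pair$finding_site_concept_id, 76752008)
  expect_equal(pair$morphology_concept_id, 68453008)
  pair2 <- resolve_attributes(g, "8520/3-C50.9")
  expect_equal(pair2$morphology_concept_id, fxid("lobular_carcinoma_morph"))
  # missing equivalence names the failing axis
  g3 <- g
  g3$relationships <- g3$relationships[
    !(g3$relationships$concept_id_1 == fxid("hist_8010_3") &
        g3$relationships$relationship_id == "Maps to"), ]
  expect_error(resolve_attributes(g3, "8010/3-C50.9"), "histology axis")
  expect_error(resolve_attributes(g, "8140/3-C50.9"), "histology")
})

test_that("exact equivalence requires equality on both attribute axes", {
  g <- fig3_graph()
  expect_equal(find_equivalent(g, list(morphology_concept_id = fxid("lobular_carcinoma_morph"),
                                       finding_site_concept_id = 76752008)),
               278054005)
  # carcinoma-of-breast subsumes but is not exactly equivalent to the
  # (carcinoma, breast) intersection
  expect_null(find_equivalent(g, list(morphology_concept_id = 68453008,
                                      finding_site_concept_id = 76752008)))
  empty <- concept_graph()
  expect_null(find_equivalent(empty, list(morphology_concept_id = 1,
                                          finding_site_concept_id = 2)))
})

test_that("two-step integration reproduces both worked outcomes", {
  res <- integrated_graph()
  rep <- res$report
  a <- rep[rep$icdo_code == "8520/3-C50.9", ]
  expect_equal(a$mode, "EQUIVALENT")
  expect_equal(a$standard_concept_id, 278054005)
  b <- rep[rep$icdo_code == "8010/3-C50.9", ]
  expect_equal(b$mode, "INSERTED")
  expect_equal(b$standard_concept_id, b$icdo_concept_id)
  expect_equal(b$parents, "254838004")
  g <- res$graph
  # EQUIVALENT: Maps-to edge to the standard concept, not itself standard
  mt <- g$relationships[g$relationships$relationship_id == "Maps to" &
                          g$relationships$concept_id_1 == a$icdo_concept_id, ]
  expect_equal(mt$concept_id_2, 278054005)
  # INSERTED: standard, child of carcinoma of breast, attribute edges set
  expect_true(g$concepts$standard_concept[g$concepts$concept_id == b$icdo_concept_id])
  expect_true(b$icdo_concept_id %in% descendants_of(g, 254838004))
})

test_that("hierarchy insertion is backward compatible and idempotent", {
  before <- fig3_graph()
  res <- integrated_graph()
  g <- res$graph
  # every pre-existing ancestor/descendant pair is preserved
  old <- sorted_closure(before)
  new <- sorted_closure(g)
  oldkey <- paste(old$ancestor_concept_id, old$descendant_concept_id)
  newkey <- paste(new$ancestor_concept_id, new$descendant_concept_id)
  expect_true(all(oldkey %in% newkey))
  # pre-existing leaf still a descendant, inserted concept now one too
  desc <- descendants_of(g, 254838004)
  expect_true(278054005 %in% desc)
  inserted <- res$report$icdo_concept_id[res$report$icdo_code == "8010/3-C50.9"]
  expect_true(inserted %in% desc)
  # integrating again changes nothing
  again <- integrate_all(g, c("8520/3-C50.9", "8010/3-C50.9"),
                         type_rules = fixture_type_rules())
  expect_identical(again$graph, g)
  expect_equal(again$report$mode, res$report$mode)
})

test_that("every integrated concept is standard-with-parent xor mapped", {
  g <- integrated_graph()$graph
  pre <- g$concepts[g$concepts$vocabulary_id == "ICDO3" &
                      grepl("-", g$concepts$concept_code, fixed = TRUE), ]
  for (cid in pre$concept_id) {
    mapped <- g$relationships$concept_id_2[
      g$relationships$concept_id_1 == cid &
        g$relationships$relationship_id == "Maps to"]
    std <- g$concepts$standard_concept[g$concepts$concept_id == cid]
    parents <- g$relationships$concept_id_2[
      g$relationships$concept_id_1 == cid &
        g$relationships$relationship_id == "Is a"]
    if (std) {
      expect_length(mapped, 0)
      expect_gte(length(parents), 1)
    } else {
      expect_length(mapped, 1)
      expect_true(g$concepts$standard_concept[g$concepts$concept_id == mapped])
    }
  }
})

test_that("insertion picks the most specific subsuming disorders", {
  # 6-node fixture: site S; morphologies M0 <- M1; disorders X (coarse) and
  # Y (finer), Y Is-a X; new pair (M1, S) must parent under Y only
  co <- rbind(
    toy_concepts(1:2, domain = "Observation"),          # M0 = 1, M1 = 2
    toy_concepts(3, domain = "Spec Anatomic Site"),     # S = 3
    toy_concepts(4:6))                                  # X = 4, Y = 5, new = 6
  re <- rbind(
    toy_isa(2, 1), toy_isa(5, 4),
    data.frame(concept_id_1 = c(4, 4, 5, 5),
               concept_id_2 = c(1, 3, 1, 3),
               relationship_id = rep(c("Has associated morphology",
                                       "Has finding site"), 2)))
  g <- concept_graph(co, re)
  pair <- list(morphology_concept_id = 2, finding_site_concept_id = 3)
  out <- insert_into_hierarchy(g, 6, pair)
  expect_equal(out$outcome$parent_concept_ids, 5)
  expect_equal(out$outcome$mode, "INSERTED")
  expect_equal(out$outcome$parent_concept_ids,
               oracle_insert_parents(g, pair, exclude = 6))
})

test_that("parent selection matches the brute-force oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:25) {
    n_morph <- sample(3:8, 1); n_site <- sample(2:5, 1)
    n_dis <- sample(3:12, 1)
    morph_ids <- 100 + seq_len(n_morph)
    site_ids <- 200 + seq_len(n_site)
    dis_ids <- 300 + seq_len(n_dis)
    new_id <- 999
    tree <- function(ids) {      # random tree rooted at ids[1]
      if (length(ids) < 2) return(NULL)
      toy_isa(ids[-1], vapply(seq_along(ids)[-1], function(i)
        ids[sample.int(i - 1, 1)], numeric(1)))
    }
    isa <- rbind(tree(morph_ids), tree(site_ids))
    attrs <- do.call(rbind, lapply(dis_ids, function(d) {
      data.frame(concept_id_1 = d,
                 concept_id_2 = c(sample(morph_ids, 1), sample(site_ids, 1)),
                 relationship_id = c("Has associated morphology", "Has finding site"))
    }))
    co <- rbind(toy_concepts(morph_ids, domain = "Observation"),
                toy_concepts(site_ids, domain = "Spec Anatomic Site"),
                toy_concepts(dis_ids), toy_concepts(new_id))
    g <- concept_graph(co, rbind(isa, attrs))
    pair <- list(morphology_concept_id = sample(morph_ids, 1),
                 finding_site_concept_id = sample(site_ids, 1))
    expected <- oracle_insert_parents(g, pair, exclude = new_id)
    if (!length(expected)) next     # fallback-root path tested separately
    out <- insert_into_hierarchy(g, new_id, pair)
    expect_equal(out$outcome$parent_concept_ids, expected)
  }
})

test_that("insertion without any subsumer falls back to the configured root", {
  co <- rbind(toy_concepts(1, domain = "Observation"),
              toy_concepts(2, domain = "Spec Anatomic Site"),
              toy_concepts(3:4))
  co$concept_name[co$concept_id == 3] <- "Neoplastic disease"
  g <- concept_graph(co)
  pair <- list(morphology_concept_id = 1, finding_site_concept_id = 2)
  expect_warning(out <- insert_into_hierarchy(g, 4, pair), "root")
  expect_equal(out$outcome$parent_concept_ids, 3)
})

test_that("cancer-type linkage follows topography prefix rules", {
  res <- integrated_graph()
  g <- res$graph
  cid <- res$report$icdo_concept_id[res$report$icdo_code == "8010/3-C50.9"]
  edges <- g$relationships[g$relationships$relationship_id == "Has cancer type" &
                             g$relationships$concept_id_1 == cid, ]
  expect_equal(edges$concept_id_2, fxid("cancer_type_breast"))
  # uncovered prefix warns and adds nothing
  g2 <- precoordinate(fig3_graph(), "8010/3-C50.9")
  cid2 <- g2$concepts$concept_id[g2$concepts$concept_code == "8010/3-C50.9"]
  expect_warning(g3 <- link_cancer_type(g2, cid2, c(C61 = fxid("cancer_type_breast"))),
                 "C50.9")
  expect_false(any(g3$relationships$relationship_id == "Has cancer type"))
  expect_identical(link_cancer_type(g2, cid2, numeric(0)), g2)
})
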