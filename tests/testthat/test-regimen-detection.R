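defs <- fixture_regimen_definitions()

expo <- function(person, drug, dates) {
  s <- new_cdm()
  s <- add_person(s, person, 8507, 1950)
  for (d in as.character(dates)) s <- add_drug_exposure(s, person, drug, d)
  s
}

test_that("drug exposures resolve to ingredients through the vocabulary", {
  g <- fig3_graph()
  s <- expo(1, fxid("drug_paclitaxel_inj"), "2019-01-01")           # product
  s <- add_drug_exposure(s, 1, fxid("ing_cisplatin"), "2019-01-01")  # already ingredient
  s <- add_drug_exposure(s, 1, fxid("ing_dexamethasone"), "2019-01-01")
  ex <- normalize_to_ingredients(s$drug_exposure, g)
  expect_equal(ex$ingredient_concept_id,
               c(fxid("ing_paclitaxel"), fxid("ing_cisplatin"),
                 fxid("ing_dexamethasone")))
  expect_equal(ex$non_oncologic, c(FALSE, FALSE, TRUE))
  expect_equal(attr(ex, "n_dropped"), 0)
  # unmappable drug concept is dropped with a counted warning
  s <- add_drug_exposure(s, 1, 424242, "2019-01-02")
  expect_warning(ex2 <- normalize_to_ingredients(s$drug_exposure, g), "1 exposure")
  expect_equal(attr(ex2, "n_dropped"), 1)
  expect_equal(nrow(ex2), 3)
})

test_that("ingredient eras merge exposures up to the gap", {
  g <- fig3_graph()
  mk <- function(dates) {
    s <- expo(1, fxid("ing_cisplatin"), dates)
    build_eras(normalize_to_ingredients(s$drug_exposure, g), gap_days = 30)
  }
  one <- mk(c("2019-01-01", "2019-01-11"))    # 10 days apart -> one era
  expect_equal(nrow(one), 1)
  expect_equal(one$era_start_date, as.Date("2019-01-01"))
  expect_equal(one$era_end_date, as.Date("2019-01-11"))
  expect_equal(one$n_exposures, 2)
  two <- mk(c("2019-01-01", "2019-02-10"))    # 40 days apart -> two eras
  expect_equal(nrow(two), 2)
  single <- mk("2019-01-01")                  # era equals the exposure interval
  expect_equal(single$era_start_date, single$era_end_date)
})

test_that("greedy cycle grouping consumes each ingredient start once", {
  g <- fig3_graph()
  s <- new_cdm(); s <- add_person(s, 1, 8507, 1950)
  for (d in c("2019-01-01", "2019-01-22")) {           # paclitaxel day 0 / 21
    s <- add_drug_exposure(s, 1, fxid("ing_paclitaxel"), d)
  }
  for (d in c("2019-01-02", "2019-01-23")) {           # bevacizumab day 1 / 22
    s <- add_drug_exposure(s, 1, fxid("ing_bevacizumab"), d)
  }
  ex <- normalize_to_ingredients(s$drug_exposure, g)
  cyc <- detect_cycles(oncomop:::ingredient_starts(ex), window_days = 14)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$cycle_start_date, as.Date(c("2019-01-01", "2019-01-22")))
  for (i in 1:2) {
    expect_setequal(cyc$ingredients[[i]],
                    c(fxid("ing_paclitaxel"), fxid("ing_bevacizumab")))
  }
  # one ingredient monthly x3 -> three singleton cycles
  s2 <- expo(1, fxid("ing_cisplatin"), c("2019-01-01", "2019-02-01", "2019-03-01"))
  ex2 <- normalize_to_ingredients(s2$drug_exposure, g)
  cyc2 <- detect_cycles(oncomop:::ingredient_starts(ex2), window_days = 14)
  expect_equal(nrow(cyc2), 3)
  expect_true(all(lengths(cyc2$ingredients) == 1))
  # empty input
  expect_equal(nrow(detect_cycles(oncomop:::ingredient_starts(
    new_cdm()$drug_exposure))), 0)
})

test_that("regimen matching prefers exact sets, then maximal subsets", {
  pac_bev <- c(fxid("ing_paclitaxel"), fxid("ing_bevacizumab"))
  expect_equal(match_regimen(pac_bev, defs), fxid("reg_pac_bev"))
  # co-medication tolerated via maximal-subset matching
  gcd <- c(fxid("ing_gemcitabine"), fxid("ing_cisplatin"), fxid("ing_dexamethasone"))
  more <- rbind(defs, regimen_definitions(2000000199, "Gemcitabine monotherapy",
                                          list(fxid("ing_gemcitabine")), 28))
  expect_equal(match_regimen(gcd, more), fxid("reg_gem_cis"))
  # a definition with a missing component never matches
  expect_true(is.na(match_regimen(fxid("ing_gemcitabine"), defs)))
  expect_true(is.na(match_regimen(fxid("ing_dexamethasone"), more)))
  # exact-only mode refuses subset matches
  expect_true(is.na(match_regimen(gcd, more, exact_only = TRUE)))
  expect_error(match_regimen(1, defs[0, ]), "empty")
})

test_that("cycles assemble into regimens with per-person therapy lines", {
  cyc <- function(person, dates, regimen) {
    out <- data.frame(person_id = person, cycle_start_date = as.Date(dates),
                      last_start_date = as.Date(dates))
    out$ingredients <- rep(list(numeric(0)), length(dates))
    out$exposure_ids <- rep(list(numeric(0)), length(dates))
    out$regimen_concept_id <- regimen
    out
  }
  # 3 cycles, 21-day gaps -> one regimen, cycles 1..3, line 1
  a <- assemble_regimens(cyc(1, c("2019-01-01", "2019-01-22", "2019-02-12"),
                             fxid("reg_pac_bev")), defs)
  expect_equal(nrow(a$regimens), 1)
  expect_equal(a$regimens$n_cycles, 3)
  expect_equal(a$regimens$line_number, 1)
  expect_equal(a$cycles$cycle_number, 1:3)
  expect_equal(a$regimens$end_date, as.Date("2019-02-12") + 20)
  # same regimen resuming after 200 days -> two regimens, lines 1 and 2
  b <- assemble_regimens(cyc(1, c("2019-01-01", "2019-07-20"),
                             fxid("reg_pac_bev")), defs)
  expect_equal(b$regimens$line_number, 1:2)
  # regimen A then regimen B -> lines 1 and 2
  cc <- rbind(cyc(1, "2019-01-01", fxid("reg_pac_bev")),
              cyc(1, "2019-02-01", fxid("reg_gem_cis")))
  d <- assemble_regimens(cc, defs)
  expect_equal(d$regimens$regimen_concept_id,
               c(fxid("reg_pac_bev"), fxid("reg_gem_cis")))
  expect_equal(d$regimens$line_number, 1:2)
  # an index date shifts line numbering to on-or-after regimens
  e <- assemble_regimens(cc, defs,
                         index_dates = c("1" = as.Date("2019-01-15")))
  expect_true(is.na(e$regimens$line_number[1]))
  expect_equal(e$regimens$line_number[2], 1)
})

test_that("emitted episodes nest cycles under regimens and link exposures", {
  g <- fig3_graph()
  s <- new_cdm(); s <- add_person(s, 1, 8507, 1950)
  for (k in 0:2) {
    s <- add_drug_exposure(s, 1, fxid("ing_gemcitabine"),
                           as.Date("2019-01-01") + 21 * k)
    s <- add_drug_exposure(s, 1, fxid("ing_cisplatin"),
                           as.Date("2019-01-01") + 21 * k)
  }
  res <- detect_regimens(s, g, defs)
  expect_equal(nrow(res$regimens), 1)
  # 1 regimen + 3 cycles = 4 episode rows; 6 exposure links
  expect_equal(nrow(res$store$episode), 4)
  expect_equal(nrow(res$store$episode_event), 6)
  expect_silent(validate_cdm(res$store))
  ep <- res$store$episode
  reg_row <- ep[ep$episode_concept_id == fxid("ep_treatment_regimen"), ]
  expect_equal(reg_row$episode_object_concept_id, fxid("reg_gem_cis"))
  cycles <- ep[ep$episode_concept_id == fxid("ep_treatment_cycle"), ]
  expect_equal(cycles$episode_number, 1:3)
  expect_true(all(cycles$episode_parent_id == reg_row$episode_id))
  expect_true(all(cycles$episode_start_date >= reg_row$episode_start_date &
                    cycles$episode_end_date <= reg_row$episode_end_date))
  # every exposure consumed by at most one cycle
  expect_false(anyDuplicated(res$store$episode_event$event_id) > 0)
  # empty detection leaves the store unchanged
  s0 <- new_cdm()
  expect_identical(emit_episodes(s0, list(regimens = res$regimens[0, ],
                                          cycles = res$cycles[0, ])), s0)
})

test_that("planted regimens are recovered exactly on noise-free histories", {
  sim <- simulate_patients(sim_config(n_persons = 40, seed = 7))
  res <- detect_regimens(sim$store, sim$graph, defs)
  expect_equal(regimen_recovery(res$regimens, sim$truth$regimens), 1)
  expect_silent(validate_cdm(res$store))
  expect_false(anyDuplicated(res$store$episode_event$event_id[
    res$store$episode_event$episode_event_field_concept_id == 1147094]) > 0)
})

test_that("detection is invariant to input row order", {
  sim <- simulate_patients(sim_config(n_persons = 15, seed = 21,
                                      cycle_jitter_days = 2,
                                      comedication_rate = 0.1))
  res1 <- detect_regimens(sim$store, sim$graph, defs, emit = FALSE)
  shuffled <- sim$store
  set.seed(5)
  shuffled$drug_exposure <- shuffled$drug_exposure[
    sample(nrow(shuffled$drug_exposure)), ]
  res2 <- detect_regimens(shuffled, sim$graph, defs, emit = FALSE)
  expect_equal(res2$regimens, res1$regimens)
})
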