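reg_record <- function(record_id, person_id, site = "C509", hist = "8520",
                       beh = "3", dxdate = "20180301", vital = "1",
                       contact = "20200101", er = "010", size = "23") {
  data.frame(record_id = record_id, person_id = person_id, "400" = site,
             "522" = hist, "523" = beh, "390" = dxdate, "1760" = vital,
             "1750" = contact, "2880" = er, "752" = size,
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("a registry abstract becomes a condition with its standard concept", {
  g <- integrated_graph()$graph
  out <- transform_records(reg_record(1, 10), default_mapping_rules(), g, new_cdm())
  expect_equal(out$report$counts$mapped, 1)
  co <- out$store$condition_occurrence
  expect_equal(co$condition_concept_id, 278054005)      # Fig-3A outcome
  expect_equal(co$condition_source_value, "8520/3-C50.9")
  expect_equal(co$condition_start_date, as.Date("2018-03-01"))
  # mapped modifier items become measurements linked to that condition
  mods <- modifiers_of(out$store, co$condition_occurrence_id)
  expect_equal(nrow(mods), 2)
  er <- mods[mods$measurement_concept_id == fxid("meas_er_status"), ]
  expect_equal(er$value_as_concept_id, fxid("val_er_positive"))
  sz <- mods[mods$measurement_concept_id == fxid("meas_tumor_size"), ]
  expect_equal(sz$value_as_number, 23)
  # disease-first-occurrence episode written with the diagnosis as object
  ep <- out$store$episode
  expect_equal(nrow(ep), 1)
  expect_equal(ep$episode_concept_id, fxid("ep_disease_first_occurrence"))
  expect_equal(ep$episode_object_concept_id, 278054005)
  expect_equal(ep$episode_start_date, as.Date("2018-03-01"))
  expect_silent(validate_cdm(out$store, g))
})

test_that("rejection, unmapped codes and dead records are accounted for", {
  g <- integrated_graph()$graph
  recs <- rbind(
    reg_record(1, 10),                                      # maps (8520/3)
    reg_record(2, 11, hist = "8010"),                       # maps (inserted)
    reg_record(3, 12, hist = ""),                           # missing histology
    reg_record(4, 13, hist = "9140"),                       # not precoordinated
    reg_record(5, 14, vital = "0", contact = "20190615"))   # registry death
  out <- transform_records(recs, default_mapping_rules(), g, new_cdm())
  cts <- out$report$counts
  expect_equal(cts$n_records, 5)
  expect_equal(cts$mapped, 3)
  expect_equal(cts$unmapped, 1)
  expect_equal(cts$rejected, 1)
  # conservation: records_in = mapped + unmapped + rejected
  expect_equal(cts$n_records, cts$mapped + cts$unmapped + cts$rejected)
  rr <- out$report$records
  expect_match(rr$reason[rr$record_id == 3], "missing required item")
  expect_match(rr$reason[rr$record_id == 4], "9140/3-C50.9")
  # the inserted 8010/3 concept is itself the standard concept
  inserted <- integrated_graph()$report
  expect_equal(rr$condition_concept_id[rr$record_id == 2],
               inserted$standard_concept_id[inserted$icdo_code == "8010/3-C50.9"])
  expect_equal(out$registry_deaths$person_id, 14)
  expect_equal(out$registry_deaths$death_date, as.Date("2019-06-15"))
  expect_equal(coverage_report(out$report), 3 / 4)
})

test_that("coverage is mapped over records with required items", {
  g <- integrated_graph()$graph
  ten <- do.call(rbind, lapply(1:10, function(i) reg_record(i, i)))
  out <- transform_records(ten, default_mapping_rules(), g, new_cdm())
  expect_equal(coverage_report(out$report), 1.0)
  ten$`522`[10] <- "9140"                                  # one unmapped code
  out2 <- transform_records(ten, default_mapping_rules(), g, new_cdm())
  expect_equal(coverage_report(out2$report), 0.9)
  allbad <- do.call(rbind, lapply(1:3, function(i) reg_record(i, i, hist = "")))
  out3 <- transform_records(allbad, default_mapping_rules(), g, new_cdm())
  expect_error(coverage_report(out3$report), "required")
})

test_that("partial dates resolve to July 1 and are flagged", {
  expect_equal(parse_naaccr_date("20180301"),
               list(date = as.Date("2018-03-01"), partial = FALSE))
  expect_equal(parse_naaccr_date("2018"),
               list(date = as.Date("2018-07-01"), partial = TRUE))
  expect_true(is.na(parse_naaccr_date("03/01/2018")$date))
  g <- integrated_graph()$graph
  out <- transform_records(reg_record(1, 1, dxdate = "2018"),
                           default_mapping_rules(), g, new_cdm())
  expect_equal(out$report$partial_dates, 1)
  expect_equal(out$store$condition_occurrence$condition_start_date,
               as.Date("2018-07-01"))
})

test_that("unmapped modifier values are skipped with per-item counts", {
  g <- integrated_graph()$graph
  out <- transform_records(reg_record(1, 1, er = "999", size = "n/a"),
                           default_mapping_rules(), g, new_cdm())
  expect_equal(out$report$counts$mapped, 1)
  expect_equal(unname(out$report$modifier_skips["2880"]), 1)
  expect_equal(unname(out$report$modifier_skips["752"]), 1)
  expect_equal(nrow(out$store$measurement), 0)
})

test_that("simulated registries round-trip to the planted diagnoses", {
  sim <- simulate_patients(sim_config(n_persons = 40, seed = 13))
  out <- transform_records(sim$registry$records, default_mapping_rules(),
                           sim$graph, sim$store)
  cts <- out$report$counts
  expect_equal(cts$rejected, 0)
  expect_equal(cts$unmapped, 0)
  expect_equal(coverage_report(out$report), 1.0)
  rr <- out$report$records
  planted <- sim$truth$diagnoses
  expect_equal(rr$condition_concept_id,
               planted$condition_concept_id[match(rr$person_id, planted$person_id)])
  # registry deaths recovered exactly
  expect_setequal(out$registry_deaths$person_id, sim$registry$deaths$person_id)
})

test_that("mapping rules survive the CSV round trip", {
  rules <- default_mapping_rules()
  path <- withr::local_tempfile(fileext = ".csv")
  write_mapping_rules(rules, path)
  back <- read_mapping_rules(path)
  expect_equal(back$item_number, rules$item_number)
  expect_equal(back$kind, rules$kind)
  expect_equal(back$measurement_concept_id, rules$measurement_concept_id)
  expect_equal(back$value_map[[7]], rules$value_map[[7]])
  expect_error(read_mapping_rules({
    p <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(item_number = "1", kind = "MODIFIER_CATEGORICAL",
                         role = "", measurement_concept_id = "5", units = "",
                         value_map = ""), p, row.names = FALSE)
    p
  }), "value_map")
})
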