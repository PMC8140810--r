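# synthetic_fixtures: deterministic fixture vocabulary (the breast-cancer
# subtree with the published SNOMED identifiers) and a seeded patient
# simulator planting regimen histories, registry abstracts and deaths.

#' Fixture concept identifiers
#'
#' Named concept ids used by the fixture vocabulary. The five SNOMED
#' identifiers match their published values (breast structure 76752008,
#' carcinoma morphology 68453008, carcinoma of breast 254838004,
#' infiltrating lobular carcinoma of breast 278054005); every other fixture
#' concept is allocated in the 2,000,000,xxx local range.
#'
#' @format Named numeric vector.
#' @export
fixture_concepts <- c(
  # Fig-3-style breast subtree -------------------------------------------
  body_structure            = 2000000001,
  breast_structure          = 76752008,
  morph_root                = 2000000002,
  malignant_neoplasm_morph  = 2000000003,
  carcinoma_morph           = 68453008,
  lobular_carcinoma_morph   = 2000000004,
  neoplastic_disease        = 2000000005,
  malignant_neoplasm_breast = 2000000006,
  carcinoma_of_breast       = 254838004,
  ilc_breast                = 278054005,
  hist_8010_3               = 2000000007,
  hist_8520_3               = 2000000008,
  topo_c509                 = 2000000009,
  cancer_type_breast        = 2000000010,
  # episode, treatment and modifier extension ----------------------------
  ep_disease_first_occurrence = 2000000101,
  ep_disease_progression      = 2000000102,
  ep_treatment_regimen        = 2000000103,
  ep_treatment_cycle          = 2000000104,
  atc_antineoplastic        = 2000000110,
  ing_paclitaxel            = 2000000111,
  ing_bevacizumab           = 2000000112,
  ing_gemcitabine           = 2000000113,
  ing_cisplatin             = 2000000114,
  ing_dexamethasone         = 2000000115,
  drug_paclitaxel_inj       = 2000000121,
  drug_bevacizumab_inj      = 2000000122,
  reg_pac_bev               = 2000000131,
  reg_gem_cis               = 2000000132,
  meas_metastasis           = 2000000141,
  val_met_present           = 2000000142,
  val_met_absent            = 2000000143,
  meas_er_status            = 2000000144,
  val_er_positive           = 2000000145,
  val_er_negative           = 2000000146,
  meas_tumor_size           = 2000000147
)

fx <- function(name) unname(fixture_concepts[[name]])

#' Build the fixture vocabulary
#'
#' Constructs the deterministic test vocabulary: a breast-cancer SNOMED-style
#' subtree (body/morphology hierarchies, the disorders "Neoplastic disease"
#' > "Malignant neoplasm of breast" > "Carcinoma of breast" (254838004) >
#' "Infiltrating lobular carcinoma of breast" (278054005) with their
#' associated-morphology and finding-site attributes), the ICD-O-3 component
#' concepts 8010/3, 8520/3 and C50.9 with their SNOMED equivalences, and a
#' cancer-type concept for breast. The disorders above the leaf carry the
#' coarser malignant-neoplasm morphology, so "carcinoma of breast" subsumes
#' — but is not exactly equivalent to — the 8010/3-C50.9 intersection.
#'
#' With `include_treatment = TRUE` (default) the Episode-domain concepts,
#' RxNorm-style ingredients, two drug products, HemOnc-style regimen
#' concepts with their component relationships, and the modifier measurement
#' concepts are added. Output is deterministic: identical calls produce
#' byte-identical files.
#'
#' @param out_dir optional directory; when given, the vocabulary files are
#'   written there with [write_vocab()].
#' @param include_treatment include the treatment/episode/modifier layer.
#' @return A validated [concept_graph].
#' @export
make_fixture_vocab <- function(out_dir = NULL, include_treatment = TRUE) {
  cc <- function(name_key, concept_name, domain, vocab, class, standard,
                 code = NULL) {
    data.frame(concept_id = fx(name_key), concept_name = concept_name,
               domain_id = domain, vocabulary_id = vocab,
               concept_class_id = class, standard_concept = standard,
               concept_code = if (is.null(code)) format_id(fx(name_key)) else code,
               stringsAsFactors = FALSE)
  }
  concepts <- rbind(
    cc("body_structure", "Body structure", "Spec Anatomic Site", "SNOMED",
       "Body Structure", TRUE),
    cc("breast_structure", "Breast structure", "Spec Anatomic Site", "SNOMED",
       "Body Structure", TRUE),
    cc("morph_root", "Morphologically abnormal structure", "Observation",
       "SNOMED", "Morph Abnormality", TRUE),
    cc("malignant_neoplasm_morph", "Malignant neoplasm, morphology",
       "Observation", "SNOMED", "Morph Abnormality", TRUE),
    cc("carcinoma_morph", "Carcinoma", "Observation", "SNOMED",
       "Morph Abnormality", TRUE),
    cc("lobular_carcinoma_morph", "Lobular carcinoma, morphology",
       "Observation", "SNOMED", "Morph Abnormality", TRUE),
    cc("neoplastic_disease", "Neoplastic disease", "Condition", "SNOMED",
       "Clinical Finding", TRUE),
    cc("malignant_neoplasm_breast", "Malignant neoplasm of breast",
       "Condition", "SNOMED", "Clinical Finding", TRUE),
    cc("carcinoma_of_breast", "Carcinoma of breast", "Condition", "SNOMED",
       "Clinical Finding", TRUE),
    cc("ilc_breast", "Infiltrating lobular carcinoma of breast", "Condition",
       "SNOMED", "Clinical Finding", TRUE),
    cc("hist_8010_3", "Carcinoma, NOS", "Observation", "ICDO3",
       "ICDO Histology", FALSE, "8010/3"),
    cc("hist_8520_3", "Lobular carcinoma, NOS", "Observation", "ICDO3",
       "ICDO Histology", FALSE, "8520/3"),
    cc("topo_c509", "Breast, NOS", "Spec Anatomic Site", "ICDO3",
       "ICDO Topography", FALSE, "C50.9"),
    cc("cancer_type_breast", "Cancer type: breast", "Condition",
       "OMOP Extension", "Cancer Type", TRUE, "cancer-type-breast")
  )
  rel <- function(a, b, r) data.frame(concept_id_1 = fx(a), concept_id_2 = fx(b),
                                      relationship_id = r, stringsAsFactors = FALSE)
  relationships <- rbind(
    rel("breast_structure", "body_structure", "Is a"),
    rel("malignant_neoplasm_morph", "morph_root", "Is a"),
    rel("carcinoma_morph", "malignant_neoplasm_morph", "Is a"),
    rel("lobular_carcinoma_morph", "carcinoma_morph", "Is a"),
    rel("malignant_neoplasm_breast", "neoplastic_disease", "Is a"),
    rel("carcinoma_of_breast", "malignant_neoplasm_breast", "Is a"),
    rel("ilc_breast", "carcinoma_of_breast", "Is a"),
    rel("malignant_neoplasm_breast", "malignant_neoplasm_morph", "Has associated morphology"),
    rel("malignant_neoplasm_breast", "breast_structure", "Has finding site"),
    rel("carcinoma_of_breast", "malignant_neoplasm_morph", "Has associated morphology"),
    rel("carcinoma_of_breast", "breast_structure", "Has finding site"),
    rel("ilc_breast", "lobular_carcinoma_morph", "Has associated morphology"),
    rel("ilc_breast", "breast_structure", "Has finding site"),
    rel("hist_8010_3", "carcinoma_morph", "Maps to"),
    rel("hist_8520_3", "lobular_carcinoma_morph", "Maps to"),
    rel("topo_c509", "breast_structure", "Maps to")
  )
  if (include_treatment) {
    concepts <- rbind(
      concepts,
      cc("ep_disease_first_occurrence", "Disease First Occurrence", "Episode",
         "OMOP Extension", "Episode of Care", TRUE, "ep-disease-first-occurrence"),
      cc("ep_disease_progression", "Disease Progression", "Episode",
         "OMOP Extension", "Episode of Care", TRUE, "ep-disease-progression"),
      cc("ep_treatment_regimen", "Treatment Regimen", "Episode",
         "OMOP Extension", "Episode of Care", TRUE, "ep-treatment-regimen"),
      cc("ep_treatment_cycle", "Treatment Cycle", "Episode",
         "OMOP Extension", "Episode of Care", TRUE, "ep-treatment-cycle"),
      cc("atc_antineoplastic", "Antineoplastic agents", "Drug", "ATC",
         "Drug Class", TRUE, "L01"),
      cc("ing_paclitaxel", "paclitaxel", "Drug", "RxNorm", "Ingredient",
         TRUE, "56946"),
      cc("ing_bevacizumab", "bevacizumab", "Drug", "RxNorm", "Ingredient",
         TRUE, "253337"),
      cc("ing_gemcitabine", "gemcitabine", "Drug", "RxNorm", "Ingredient",
         TRUE, "12574"),
      cc("ing_cisplatin", "cisplatin", "Drug", "RxNorm", "Ingredient",
         TRUE, "2555"),
      cc("ing_dexamethasone", "dexamethasone", "Drug", "RxNorm", "Ingredient",
         TRUE, "3264"),
      cc("drug_paclitaxel_inj", "paclitaxel 100 MG injection", "Drug",
         "RxNorm", "Clinical Drug", FALSE, "pac-100mg-inj"),
      cc("drug_bevacizumab_inj", "bevacizumab 400 MG injection", "Drug",
         "RxNorm", "Clinical Drug", FALSE, "bev-400mg-inj"),
      cc("reg_pac_bev", "Paclitaxel and Bevacizumab", "Regimen", "HemOnc",
         "Regimen", TRUE, "pac-bev"),
      cc("reg_gem_cis", "Gemcitabine and Cisplatin", "Regimen", "HemOnc",
         "Regimen", TRUE, "gem-cis"),
      cc("meas_metastasis", "Metastasis status", "Measurement",
         "OMOP Extension", "Staging/Grading", TRUE, "metastasis-status"),
      cc("val_met_present", "Distant metastasis present", "Meas Value",
         "OMOP Extension", "Answer", TRUE, "metastasis-present"),
      cc("val_met_absent", "Distant metastasis absent", "Meas Value",
         "OMOP Extension", "Answer", TRUE, "metastasis-absent"),
      cc("meas_er_status", "Estrogen receptor status", "Measurement",
         "OMOP Extension", "Staging/Grading", TRUE, "er-status"),
      cc("val_er_positive", "Estrogen receptor positive", "Meas Value",
         "OMOP Extension", "Answer", TRUE, "er-positive"),
      cc("val_er_negative", "Estrogen receptor negative", "Meas Value",
         "OMOP Extension", "Answer", TRUE, "er-negative"),
      cc("meas_tumor_size", "Tumor size", "Measurement", "OMOP Extension",
         "Measurement", TRUE, "tumor-size")
    )
    relationships <- rbind(
      relationships,
      rel("ing_paclitaxel", "atc_antineoplastic", "Is a"),
      rel("ing_bevacizumab", "atc_antineoplastic", "Is a"),
      rel("ing_gemcitabine", "atc_antineoplastic", "Is a"),
      rel("ing_cisplatin", "atc_antineoplastic", "Is a"),
      rel("drug_paclitaxel_inj", "ing_paclitaxel", "Maps to"),
      rel("drug_bevacizumab_inj", "ing_bevacizumab", "Maps to"),
      rel("reg_pac_bev", "ing_paclitaxel", "Has regimen component"),
      rel("reg_pac_bev", "ing_bevacizumab", "Has regimen component"),
      rel("reg_gem_cis", "ing_gemcitabine", "Has regimen component"),
      rel("reg_gem_cis", "ing_cisplatin", "Has regimen component")
    )
  }
  graph <- concept_graph(concepts, relationships)
  if (!is.null(out_dir)) write_vocab(graph, out_dir)
  graph
}

#' Fixture regimen definitions and cancer-type rules
#'
#' `fixture_regimen_definitions()` returns the two HemOnc-style regimens of
#' the fixture vocabulary (paclitaxel + bevacizumab; gemcitabine +
#' cisplatin), both on 21-day cycles. `fixture_type_rules()` returns the
#' topography-prefix rule linking `C50.*` to cancer type: breast.
#'
#' @return See description.
#' @export
fixture_regimen_definitions <- function() {
  regimen_definitions(
    regimen_concept_id = c(fx("reg_pac_bev"), fx("reg_gem_cis")),
    regimen_name = c("Paclitaxel and Bevacizumab", "Gemcitabine and Cisplatin"),
    components = list(c(fx("ing_paclitaxel"), fx("ing_bevacizumab")),
                      c(fx("ing_gemcitabine"), fx("ing_cisplatin"))),
    cycle_length_days = c(21, 21))
}

#' @rdname fixture_regimen_definitions
#' @export
fixture_type_rules <- function() {
  c(C50 = fx("cancer_type_breast"))
}

#' Simulation configuration
#'
#' Validated settings for [simulate_patients()]. Defaults describe a
#' moderately sized breast-cancer population with planted first- and
#' second-line regimen histories; noise controls (`cycle_jitter_days`,
#' `comedication_rate`) default to zero so that planted regimens are exactly
#' recoverable.
#'
#' @param n_persons number of persons (>= 1).
#' @param seed integer seed driving the single pseudo-random stream.
#' @param regimen_frequencies named probabilities over regimen concept ids.
#' @param p_second_line probability of a second line of therapy.
#' @param cycles_range inclusive range of planted cycles per regimen.
#' @param cycle_jitter_days administrations are shifted by up to this many
#'   days either way.
#' @param comedication_rate expected unrelated (non-antineoplastic)
#'   exposures as a fraction of regimen exposures.
#' @param fraction_metastatic fraction with a distant-metastasis modifier.
#' @param registry_coverage fraction of persons with a registry abstract.
#' @param ehr_death_rate fraction with an EHR-recorded death.
#' @param registry_only_death_rate fraction of remaining covered persons
#'   whose death is known only to the registry.
#' @param diagnosis_frequencies named probabilities over combined ICD-O-3
#'   codes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 100, seed = 1,
                       regimen_frequencies = c("2000000131" = 0.6,
                                               "2000000132" = 0.4),
                       p_second_line = 0.3, cycles_range = c(3, 6),
                       cycle_jitter_days = 0, comedication_rate = 0,
                       fraction_metastatic = 0.6, registry_coverage = 0.8,
                       ehr_death_rate = 0.2, registry_only_death_rate = 0.1,
                       diagnosis_frequencies = c("8520/3-C50.9" = 0.7,
                                                 "8010/3-C50.9" = 0.3)) {
  cfg <- list(n_persons = n_persons, seed = seed,
              regimen_frequencies = regimen_frequencies,
              p_second_line = p_second_line, cycles_range = cycles_range,
              cycle_jitter_days = cycle_jitter_days,
              comedication_rate = comedication_rate,
              fraction_metastatic = fraction_metastatic,
              registry_coverage = registry_coverage,
              ehr_death_rate = ehr_death_rate,
              registry_only_death_rate = registry_only_death_rate,
              diagnosis_frequencies = diagnosis_frequencies)
  if (n_persons < 1) stop("n_persons must be >= 1")
  probs <- c(p_second_line, comedication_rate, fraction_metastatic,
             registry_coverage, ehr_death_rate, registry_only_death_rate,
             regimen_frequencies, diagnosis_frequencies)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(regimen_frequencies) - 1) > 1e-8 ||
        abs(sum(diagnosis_frequencies) - 1) > 1e-8) {
    stop("frequency vectors must sum to 1")
  }
  if (cycles_range[1] < 1 || cycles_range[2] < cycles_range[1]) {
    stop("invalid cycles_range")
  }
  if (cycle_jitter_days < 0) stop("cycle_jitter_days must be >= 0")
  structure(cfg, class = "sim_config")
}

diagnosis_standard_concept <- function(graph, code) {
  cid <- concept_by_code(graph, "ICDO3", code)
  if (is.na(cid)) stop("combination ", code, " not in graph")
  mapped <- related_targets(graph, cid, "Maps to")
  if (length(mapped)) mapped[1L]
  else if (concept_row(graph, cid)$standard_concept) cid
  else stop("combination ", code, " has not been integrated")
}

#' Simulate a synthetic oncology population
#'
#' Generates, from a single seeded random stream, every input the other
#' modules consume: persons with precoordinated breast-cancer diagnoses
#' (conditions carry the integrated standard concepts), metastasis/ER/tumor-
#' size modifier measurements linked to the diagnosis, a Disease First
#' Occurrence episode per person, drug exposures realizing planted regimen
#' histories (component administrations at cycle-length intervals, optional
#' jitter and unrelated co-medication), EHR deaths, tumor-registry abstracts
#' for a configurable fraction of persons (item-number-keyed, consistent
#' with the planted diagnosis and vital status), registry death records, and
#' a ground-truth table of everything planted.
#'
#' @param config a [sim_config()].
#' @param graph an integrated [concept_graph]; defaults to the fixture
#'   vocabulary with the observed combinations integrated.
#' @return List: `store` (a `cdm_store`), `registry` (list `records`,
#'   `deaths`), `truth` (list `diagnoses`, `regimens`,
#'   `n_registry_only_deaths`, `metastatic`), `graph`, `manifest`.
#' @export
simulate_patients <- function(config = sim_config(), graph = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(graph)) {
    graph <- integrate_all(make_fixture_vocab(),
                           codes = names(config$diagnosis_frequencies),
                           type_rules = fixture_type_rules())$graph
  }
  set.seed(config$seed)
  defs <- fixture_regimen_definitions()
  store <- new_cdm()
  truth_dx <- list(); truth_reg <- list(); met_flags <- logical(config$n_persons)
  registry_rows <- list(); registry_deaths <- list()
  exposure_drug_for <- c("2000000111" = fx("drug_paclitaxel_inj"),
                         "2000000112" = fx("drug_bevacizumab_inj"),
                         "2000000113" = fx("ing_gemcitabine"),
                         "2000000114" = fx("ing_cisplatin"))
  n_registry_only <- 0L
  for (p in seq_len(config$n_persons)) {
    gender <- if (runif(1) < 0.5) gender_concepts[["male"]] else gender_concepts[["female"]]
    birth_year <- sample(1935:1975, 1)
    store <- add_person(store, p, gender, birth_year)
    code <- sample(names(config$diagnosis_frequencies), 1,
                   prob = config$diagnosis_frequencies)
    dx_concept <- diagnosis_standard_concept(graph, code)
    dx_date <- as.Date("2016-01-01") + sample(0:1095, 1)
    store <- add_condition(store, p, dx_concept, dx_date, source_code = code)
    cond_id <- max(store$condition_occurrence$condition_occurrence_id)
    truth_dx[[p]] <- data.frame(person_id = p, icdo_code = code,
                                condition_concept_id = dx_concept,
                                diagnosis_date = dx_date,
                                stringsAsFactors = FALSE)
    res <- create_episode(store, p, fx("ep_disease_first_occurrence"),
                          dx_concept, dx_date, dx_date)
    store <- res$store
    store <- link_event(store, res$episode_id, cond_id, "condition_occurrence")
    met <- runif(1) < config$fraction_metastatic
    met_flags[p] <- met
    store <- attach_modifier(store, p, fx("meas_metastasis"), cond_id,
                             value_concept_id = if (met) fx("val_met_present")
                             else fx("val_met_absent"))
    er_positive <- runif(1) < 0.75
    store <- attach_modifier(store, p, fx("meas_er_status"), cond_id,
                             value_concept_id = if (er_positive)
                               fx("val_er_positive") else fx("val_er_negative"))
    tumor_mm <- round(runif(1, 5, 80))
    store <- attach_modifier(store, p, fx("meas_tumor_size"), cond_id,
                             value_number = tumor_mm, unit = "mm")
    # planted regimen lines ------------------------------------------------
    n_lines <- 1L + (runif(1) < config$p_second_line)
    line1 <- sample(names(config$regimen_frequencies), 1,
                    prob = config$regimen_frequencies)
    regs <- as.numeric(line1)
    if (n_lines == 2L) {
      others <- setdiff(defs$regimen_concept_id, regs)
      regs <- c(regs, if (length(others) > 1L) sample(others, 1) else others)
    }
    start <- dx_date + sample(10:60, 1)
    n_reg_expo <- 0L
    for (line in seq_along(regs)) {
      di <- match(regs[line], defs$regimen_concept_id)
      len <- defs$cycle_length_days[di]
      k <- sample(config$cycles_range[1]:config$cycles_range[2], 1)
      cycle_starts <- start + (seq_len(k) - 1L) * len
      for (cs in seq_along(cycle_starts)) {
        for (ing in defs$components[[di]]) {
          jit <- if (config$cycle_jitter_days > 0)
            sample(-config$cycle_jitter_days:config$cycle_jitter_days, 1) else 0L
          d <- cycle_starts[cs] + jit
          store <- add_drug_exposure(store, p,
                                     exposure_drug_for[[as.character(ing)]],
                                     d, d, quantity = 1)
          n_reg_expo <- n_reg_expo + 1L
        }
      }
      end <- cycle_starts[k] + len - 1
      truth_reg[[length(truth_reg) + 1L]] <- data.frame(
        person_id = p, regimen_concept_id = regs[line], n_cycles = k,
        line_number = line, start_date = cycle_starts[1L], end_date = end)
      start <- end + sample(91:180, 1)   # next line well past the cycle gap
    }
    last_treatment_end <- start - 1
    if (config$comedication_rate > 0 && n_reg_expo > 0) {
      n_comed <- rbinom(1, n_reg_expo, config$comedication_rate)
      if (n_comed > 0) {
        span <- as.numeric(last_treatment_end - dx_date)
        comed_dates <- dx_date + sample(0:span, n_comed, replace = TRUE)
        for (ci in seq_len(n_comed)) {
          store <- add_drug_exposure(store, p, fx("ing_dexamethasone"),
                                     comed_dates[ci], comed_dates[ci],
                                     quantity = 1)
        }
      }
    }
    # deaths and registry abstract ----------------------------------------
    ehr_dead <- runif(1) < config$ehr_death_rate
    death_date <- last_treatment_end + sample(60:400, 1)
    if (ehr_dead) {
      store$death <- rbind(store$death, data.frame(
        person_id = p, death_date = death_date, death_source = "EHR",
        stringsAsFactors = FALSE))
    }
    covered <- runif(1) < config$registry_coverage
    registry_only_dead <- FALSE
    if (covered && !ehr_dead && runif(1) < config$registry_only_death_rate) {
      registry_only_dead <- TRUE
      n_registry_only <- n_registry_only + 1L
    }
    if (covered) {
      dead <- ehr_dead || registry_only_dead
      last_contact <- if (dead) death_date else last_treatment_end + sample(30:300, 1)
      parsed <- parse_icdo(code)
      registry_rows[[length(registry_rows) + 1L]] <- data.frame(
        record_id = length(registry_rows) + 1L, person_id = p,
        item_400 = sub(".", "", parsed$topography, fixed = TRUE),
        item_522 = as.character(parsed$histology),
        item_523 = as.character(parsed$behavior),
        item_390 = format(dx_date, "%Y%m%d"),
        item_1760 = if (dead) "0" else "1",
        item_1750 = format(last_contact, "%Y%m%d"),
        item_2880 = if (er_positive) "010" else "020",
        item_752 = as.character(tumor_mm),
        stringsAsFactors = FALSE)
      if (dead) {
        registry_deaths[[length(registry_deaths) + 1L]] <- data.frame(
          person_id = p, death_date = death_date, stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(registry_rows)) do.call(rbind, registry_rows) else
    data.frame(record_id = numeric(0), person_id = numeric(0))
  names(records) <- sub("^item_", "", names(records))
  reg_deaths <- if (length(registry_deaths)) do.call(rbind, registry_deaths) else
    data.frame(person_id = numeric(0), death_date = as.Date(character(0)))
  list(store = store,
       registry = list(records = records, deaths = reg_deaths),
       truth = list(diagnoses = do.call(rbind, truth_dx),
                    regimens = do.call(rbind, truth_reg),
                    n_registry_only_deaths = n_registry_only,
                    metastatic = data.frame(person_id = seq_len(config$n_persons),
                                            metastatic = met_flags)),
       graph = graph,
       manifest = list(seed = config$seed, n_persons = config$n_persons,
                       config = unclass(config)))
}
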