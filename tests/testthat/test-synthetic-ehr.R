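test_that("empty population yields empty mention table and truth", {
  cfg <- sim_config(0, c(htn = 0.3), seed = 1)
  pop <- generate_population(cfg)
  expect_s3_class(pop$mentions, "mention_table")
  expect_identical(nrow(pop$mentions), 0L)
  expect_identical(nrow(pop$truth$true_treatments), 0L)
})

test_that("config validation rejects bad probabilities and dangling ids", {
  expect_error(sim_config(10, c(a = 1.2)), "prevalence")
  expect_error(sim_config(10, c(a = 0.5), recording_prob = 0),
               "recording_prob")
  expect_error(
    sim_config(10, c(a = 0.5),
               treatments = data.frame(medication_id = "m",
                                       condition_id = "b", prob = 0.5)),
    "unknown condition"
  )
  expect_error(
    sim_config(10, c(a = 0.5),
               comorbidity_links = data.frame(parent = "a", child = "a",
                                              odds_multiplier = -1)),
    "multiplier"
  )
})

test_that("noise-free single-visit limit exposes exactly the latent sets", {
  cfg <- sim_config(
    n_patients = 300,
    conditions = c(htn = 0.4, dm = 0.3),
    treatments = data.frame(medication_id = c("hctz", "metformin"),
                            condition_id = c("htn", "dm"),
                            prob = c(0.8, 0.8)),
    visit_count_mean = 1, recording_prob = 1, seed = 9
  )
  pop <- generate_population(cfg)
  m <- pop$mentions
  # every patient has exactly one visit, and no duplicated mention rows
  expect_true(all(m$visit_id == 1))
  expect_false(any(duplicated(m)))
  # a treatment-only medication implies its latent condition is mentioned
  hctz_pat <- m$patient_id[m$concept_id == "hctz"]
  htn_pat <- m$patient_id[m$concept_id == "htn"]
  expect_true(all(hctz_pat %in% htn_pat))
  met_pat <- m$patient_id[m$concept_id == "metformin"]
  dm_pat <- m$patient_id[m$concept_id == "dm"]
  expect_true(all(met_pat %in% dm_pat))
})

test_that("empirical prevalence matches the configured marginal", {
  n <- 10000
  cfg <- sim_config(n, c(htn = 0.3), visit_count_mean = 1,
                    recording_prob = 1, seed = 4)
  pop <- generate_population(cfg)
  phat <- length(unique(pop$mentions$patient_id)) / n
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("generation is deterministic given the config seed", {
  cfg <- confounded_config(500, seed = 12)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$mentions, b$mentions)
  cfg2 <- confounded_config(500, seed = 13)
  expect_false(identical(generate_population(cfg2)$mentions, a$mentions))
})

test_that("raising a prescribing probability does not lower drug use", {
  make <- function(p) {
    sim_config(10000, c(htn = 0.4),
               treatments = data.frame(medication_id = "hctz",
                                       condition_id = "htn", prob = p),
               visit_count_mean = 2, recording_prob = 0.9, seed = 21)
  }
  freq <- function(cfg) {
    m <- generate_population(cfg)$mentions
    with_htn <- unique(m$patient_id[m$concept_id == "htn"])
    with_med <- unique(m$patient_id[m$concept_id == "hctz"])
    mean(with_htn %in% with_med)
  }
  expect_gte(freq(make(0.8)), freq(make(0.5)))
})

test_that("comorbidity links induce a real marginal confounded association", {
  cfg <- sim_config(
    10000,
    conditions = data.frame(condition_id = c("htn", "afib"),
                            prevalence = c(0.3, 0.1)),
    comorbidity_links = data.frame(parent = "htn", child = "afib",
                                   odds_multiplier = 4),
    treatments = data.frame(medication_id = "warfarin",
                            condition_id = "afib", prob = 0.8),
    visit_count_mean = 1, recording_prob = 1, seed = 31
  )
  m <- generate_population(cfg)$mentions
  # tally over the full simulated population: patients with no mentions
  # at all sit in the (no htn, no warfarin) cell
  pats <- seq_len(10000)
  h <- pats %in% m$patient_id[m$concept_id == "htn"]
  w <- pats %in% m$patient_id[m$concept_id == "warfarin"]
  or <- (sum(h & w) * sum(!h & !w)) / (sum(!h & w) * sum(h & !w))
  expect_gt(or, 1)
})

test_that("visit counts are overdispersed around the configured mean", {
  cfg <- sim_config(4000, c(htn = 1), visit_count_mean = 5,
                    recording_prob = 1, seed = 2)
  m <- generate_population(cfg)$mentions
  nv <- tapply(m$visit_id, m$patient_id, max)
  expect_lt(abs(mean(nv) - 5), 0.4)
  expect_gt(sd(nv), mean(nv))  # sd above mean, as in clinic visit data
  expect_true(all(nv >= 1))
})

test_that("summarize_mentions reproduces a hand tally on the fixture", {
  m <- fixture_mentions()
  s <- summarize_mentions(m, "htn", seed = 1)
  expect_identical(s$cases[s$statistic == "Number of patients"], "2")
  expect_identical(s$controls[s$statistic == "Number of patients"], "2")
  # case 1 has 2 visits, case 2 has 1 -> mean 1.5; controls have 1 each
  expect_identical(
    s$cases[s$statistic == "Mean number of visits per patient (sd)"],
    "1.5 (0.7)")
  expect_identical(
    s$controls[s$statistic == "Mean number of visits per patient (sd)"],
    "1.0 (0.0)")
  # unique conditions over all visits: case1 {htn,dm}=2, case2 {htn,dm}=2
  expect_identical(
    s$cases[s$statistic ==
              "Unique conditions per patient, all visits (sd)"],
    "2.0 (0.0)")
})

test_that("a single case with three visits averages three visits", {
  m <- data.frame(
    patient_id = c(1L, 1L, 1L, 2L),
    visit_id = c(1L, 2L, 3L, 1L),
    kind = c("condition", "condition", "condition", "condition"),
    concept_id = c("htn", "x", "y", "x")
  )
  s <- summarize_mentions(m, "htn")
  expect_identical(
    s$cases[s$statistic == "Mean number of visits per patient (sd)"],
    "3.0 (0.0)")
})

test_that("an index condition nobody has yields zero cases", {
  m <- fixture_mentions()
  s <- summarize_mentions(m, "asthma")
  expect_identical(s$cases[s$statistic == "Number of patients"], "0")
  expect_identical(s$controls[s$statistic == "Number of patients"], "4")
  expect_error(summarize_mentions(m, "asthma", strict = TRUE), "not found")
})
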