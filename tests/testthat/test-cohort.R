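test_that("the four-patient fixture produces the hand-computed matrix", {
  ds <- build_case_control(fixture_mentions(), "htn", seed = 1)
  expect_identical(ds$y, c(1L, 1L, 0L, 0L))
  # case 1's only index visit is visit 1; all other patients have 1 visit
  expect_equal(ds$selected_visit, c(1, 1, 1, 1))
  expected <- matrix(
    c(0, 1, 1, 0,   # dm
      1, 0, 0, 0,   # hctz
      0, 1, 1, 0,   # metformin
      0, 0, 0, 1),  # vitamin
    nrow = 4,
    dimnames = list(NULL, c("dm", "hctz", "metformin", "vitamin"))
  )
  expect_identical(as.matrix(ds$x), expected)
  expect_identical(ds$columns$kind,
                   c("condition", "medication", "medication", "medication"))
})

test_that("the index condition never leaks into the feature columns", {
  pop <- generate_population(confounded_config(800, seed = 3))
  ds <- build_case_control(pop$mentions, "htn", seed = 3)
  expect_false("htn" %in% ds$columns$concept_id)
  cc <- build_class_choice(
    pop$mentions, "htn",
    class_map = c(hctz = "Thiazide", atenolol = "Beta_Blocker"), seed = 3)
  expect_false("htn" %in% cc$columns$concept_id)
})

test_that("labels reflect the full history regardless of sampled visit", {
  pop <- generate_population(confounded_config(800, seed = 5))
  m <- pop$mentions
  for (s in c(1, 2)) {
    ds <- build_case_control(m, "htn", seed = s)
    ever <- ds$patient_id %in%
      unique(m$patient_id[m$kind == "condition" & m$concept_id == "htn"])
    expect_identical(ds$y, as.integer(ever))
  }
})

test_that("cohort construction is reproducible given the seed", {
  pop <- generate_population(confounded_config(600, seed = 8))
  a <- build_case_control(pop$mentions, "htn", seed = 42)
  b <- build_case_control(pop$mentions, "htn", seed = 42)
  expect_identical(a$selected_visit, b$selected_visit)
  expect_identical(as.matrix(a$x), as.matrix(b$x))
})

test_that("degenerate designs and unknown conditions error", {
  m <- fixture_mentions()
  expect_error(build_case_control(m, "nothere"), "vocabulary")
  all_cases <- m[m$patient_id %in% c(1, 2), ]
  expect_error(build_case_control(all_cases, "htn"), "degenerate")
})

test_that("a case whose every visit mentions the index can get any visit", {
  m <- data.frame(
    patient_id = c(1L, 1L, 2L),
    visit_id = c(1L, 2L, 1L),
    kind = "condition",
    concept_id = c("htn", "htn", "dm")
  )
  seen <- vapply(1:40, function(s) {
    build_case_control(m, "htn", seed = s)$selected_visit[1]
  }, numeric(1))
  expect_setequal(unique(seen), c(1, 2))
  # the control has one visit: always selected
  expect_true(all(vapply(1:5, function(s) {
    build_case_control(m, "htn", seed = s)$selected_visit[2]
  }, numeric(1)) == 1))
})

test_that("patients without a qualifying visit are excluded from the
           class-choice dataset", {
  m <- rbind(
    fixture_mentions(),
    data.frame(patient_id = 5L, visit_id = 1L, kind = "condition",
               concept_id = "htn")
  )
  cc <- build_class_choice(m, "htn", c(hctz = "Thiazide"), seed = 1)
  # only patient 1 has htn and a mapped medication at the same visit
  expect_identical(cc$patient_id, 1L)
  expect_identical(as.character(cc$class), "Thiazide")
})

test_that("single-class visits are assigned that class with certainty", {
  m <- fixture_mentions()
  for (s in 1:5) {
    cc <- build_class_choice(m, "htn", c(hctz = "Thiazide"), seed = s)
    expect_identical(as.character(cc$class), "Thiazide")
  }
})

test_that("two-class visits split close to half and half", {
  n <- 10000
  m <- data.frame(
    patient_id = rep(seq_len(n), each = 3),
    visit_id = 1L,
    kind = rep(c("condition", "medication", "medication"), n),
    concept_id = rep(c("htn", "medA", "medB"), n)
  )
  cc <- build_class_choice(m, "htn", c(medA = "A", medB = "B"), seed = 9)
  f <- mean(cc$class == "A")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
})

test_that("history feature window unions all visits", {
  ds <- build_case_control(fixture_mentions(), "htn", seed = 1,
                           feature_window = "history")
  # case 1 mentions dm only at the unselected visit 2
  expect_identical(as.numeric(ds$x[1, "dm"]), 1)
})
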