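test_that("reference files round-trip with deduplication", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("medication_id,condition_id",
               "hctz,htn", "lisinopril,htn", "hctz,htn",
               "metformin,dm", "warfarin,afib", "amlodipine,htn"),
             path)
  ref <- load_reference(path)
  expect_identical(nrow(ref$pairs), 5L)
  out <- withr::local_tempfile(fileext = ".csv")
  write_reference(ref, out)
  expect_identical(load_reference(out)$pairs, ref$pairs)
})

test_that("empty and malformed reference files behave per contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("medication_id,condition_id", path)
  expect_identical(nrow(load_reference(path)$pairs), 0L)
  writeLines(c("medication_id,condition_id", "hctz,htn", ",htn"), path)
  expect_error(load_reference(path), "line 3")
})

test_that("precision at k follows the top-30 protocol arithmetic", {
  meds <- sprintf("m%02d", 1:30)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("medication_id,condition_id",
               paste0(meds[1:23], ",htn")), path)
  ref <- load_reference(path)
  expect_equal(precision_at_k(meds, ref, "htn", k = 30), 23 / 30)
  expect_equal(precision_at_k(meds[24:30], ref, "htn", k = 7), 0)
  expect_equal(precision_at_k(meds[1:5], ref, "htn", k = 5), 1)
  expect_warning(p <- precision_at_k(meds[1:5], ref, "htn", k = 10),
                 "depth")
  expect_equal(p, 1)
  # reordering inside the top k leaves precision unchanged
  expect_equal(precision_at_k(rev(meds), ref, "htn", k = 30), 23 / 30)
})

test_that("discovery_report counts drugs only and handles zero discoveries", {
  tab <- data.frame(
    concept_id = c("m1", "m2", "c1", "m3", "m4"),
    kind = c("medication", "medication", "condition", "medication",
             "medication"),
    p_value = c(0.001, 0.002, 0.0001, 0.003, 0.9),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("medication_id,condition_id", "m1,htn", "m3,htn"), path)
  ref <- load_reference(path)
  rep <- discovery_report(tab, ref, "htn", q = 0.05)
  expect_identical(rep$n_discoveries, 3L)
  expect_false("c1" %in% rep$discoveries)
  expect_equal(rep$prop_discoveries_in_reference, 2 / 3)
  none <- discovery_report(tab, ref, "htn", q = 1e-6)
  expect_identical(none$n_discoveries, 0L)
  expect_true(is.na(none$prop_discoveries_in_reference))
})

test_that("the discovery count is monotone in q", {
  set.seed(10)
  tab <- data.frame(
    concept_id = paste0("m", 1:40),
    kind = "medication",
    p_value = runif(40)^3,
    stringsAsFactors = FALSE
  )
  prev <- 0L
  for (q in c(0.01, 0.05, 0.1, 0.3)) {
    cur <- discovery_report(tab, NULL, "htn", q = q)$n_discoveries
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("discoveries equal a direct BH application to the same p-vector", {
  pop <- generate_population(confounded_config(2500, seed = 6))
  fit <- drug_association(pop$mentions, "htn", seed = 6)
  meds <- fit$table[fit$table$kind == "medication", ]
  rep <- discovery_report(fit$table, NULL, "htn", q = 0.05)
  expect_identical(rep$n_discoveries,
                   sum(oracle_bh_reject(meds$p_value, 0.05)))
})

test_that("truth_recovery scores rankings against the planted truth", {
  pop <- generate_population(confounded_config(100, seed = 1))
  truth <- pop$truth
  true_meds <- true_treatment_meds(truth, "htn")
  expect_setequal(true_meds, c("hctz", "lisinopril", "amlodipine",
                               "losartan", "atenolol"))
  expect_setequal(confounder_meds(truth, "htn"),
                  c("epoetin", "warfarin", "statin"))
  perfect <- truth_recovery(true_meds, truth, "htn", k = 5)
  expect_equal(perfect$recall, 1)
  expect_identical(perfect$n_confounders, 0L)
  bad <- truth_recovery(confounder_meds(truth, "htn"), truth, "htn", k = 3)
  expect_equal(bad$recall, 0)
  expect_identical(bad$n_confounders, 3L)
  expect_error(truth_recovery(true_meds, list(), "htn"), "truth_set")
})
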