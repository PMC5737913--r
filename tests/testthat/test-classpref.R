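test_that("the published asthma coefficients yield factor 1.06", {
  cf <- matrix(c(0.018, -0.043), nrow = 1,
               dimnames = list("asthma", c("A2Blocker", "Beta_Blocker")))
  out <- interpret_pair(cf, "asthma", "A2Blocker", "Beta_Blocker")
  expect_equal(out$difference, 0.061, tolerance = 1e-12)
  expect_equal(round(out$odds_factor, 2), 1.06)
})

test_that("interpret_pair is an identity for a class against itself and
           reciprocal across orderings", {
  set.seed(41)
  cf <- matrix(rnorm(15), 3, 5,
               dimnames = list(paste0("c", 1:3), paste0("K", 1:5)))
  expect_equal(interpret_pair(cf, "c1", "K2", "K2")$odds_factor, 1)
  for (i in 1:10) {
    a <- sample(colnames(cf), 2)
    cm <- sample(rownames(cf), 1)
    f1 <- interpret_pair(cf, cm, a[1], a[2])$odds_factor
    f2 <- interpret_pair(cf, cm, a[2], a[1])$odds_factor
    expect_equal(f1 * f2, 1, tolerance = 1e-12)
  }
  expect_error(interpret_pair(cf, "c9", "K1", "K2"), "unknown comorbidity")
  expect_error(interpret_pair(cf, "c1", "K9", "K2"), "unknown class")
})

test_that("reported quantities depend only on pairwise differences", {
  set.seed(6)
  cf <- matrix(rnorm(8), 2, 4,
               dimnames = list(c("a", "b"), paste0("K", 1:4)))
  shifted <- cf
  shifted["a", ] <- shifted["a", ] + 5  # common shift: unidentified part
  for (pair in list(c("K1", "K2"), c("K3", "K4"))) {
    expect_equal(
      interpret_pair(cf, "a", pair[1], pair[2])$odds_factor,
      interpret_pair(shifted, "a", pair[1], pair[2])$odds_factor,
      tolerance = 1e-12
    )
  }
})

test_that("the null multinomial fit reproduces class marginal frequencies", {
  set.seed(14)
  cls <- sample(c("A", "B", "C"), 600, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  x <- cbind(cm = rbinom(600, 1, 0.3), cm2 = rbinom(600, 1, 0.4))
  ds <- manual_class_choice(x, cls, classes = c("A", "B", "C"))
  cv <- prescreg:::cv_lasso_path(ds$x, ds$class, family = "multinomial",
                                 seed = 14)
  # at the top of the path all coefficients are zero: intercept-only model
  p0 <- predict(cv$fit, newx = ds$x[1:2, , drop = FALSE],
                s = cv$lambda[1], type = "response")[1, , 1]
  expect_equal(unname(p0), as.numeric(prop.table(table(cls))[c("A", "B", "C")]),
               tolerance = 1e-4)
})

test_that("fitted class probabilities sum to one", {
  pop <- generate_population(preference_config(3000, seed = 3))
  m <- class_preference(pop$mentions, "htn",
                        c(valsartan = "A2Blocker",
                          atenolol = "Beta_Blocker"), seed = 3)
  pr <- predict(m, as.matrix(m$dataset$x))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-10))
})

test_that("a planted class-preference effect is recovered with the right
           sign", {
  pop <- generate_population(preference_config(10000, seed = 51))
  m <- class_preference(pop$mentions, "htn",
                        c(valsartan = "A2Blocker",
                          atenolol = "Beta_Blocker"), seed = 51)
  out <- interpret_pair(m, "asthma", "A2Blocker", "Beta_Blocker")
  expect_gt(out$difference, 0)
})

test_that("comorbidity ranking follows the drop-out penalty", {
  cf <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("K1", "K2")))
  model <- structure(
    list(coef = cf, intercepts = c(K1 = 0, K2 = 0),
         dropout = c(a = 0.01, b = 0.1),
         pct_patients = c(a = 10, b = 20),
         classes = c("K1", "K2"), lambda_star = 0.01,
         parameterization = "sum-to-zero"),
    class = "class_pref"
  )
  rk <- rank_comorbidities(model, top_n = 2)
  expect_identical(rk$comorbidity, c("b", "a"))
  expect_error(rank_comorbidities(model, top_n = 0), "positive")
})

test_that("ranking is invariant to comorbidity column permutation", {
  pop <- generate_population(preference_config(4000, seed = 23))
  cmap <- c(valsartan = "A2Blocker", atenolol = "Beta_Blocker")
  ds <- build_class_choice(pop$mentions, "htn", cmap, seed = 23)
  ids <- ds$columns$concept_id
  m1 <- fit_multinomial_lasso(ds, ids, seed = 23)
  ds2 <- ds
  perm <- rev(seq_along(ids))
  ds2$x <- ds$x[, perm, drop = FALSE]
  ds2$columns <- ds$columns[perm, , drop = FALSE]
  m2 <- fit_multinomial_lasso(ds2, rev(ids), seed = 23)
  r1 <- rank_comorbidities(m1, top_n = length(ids))
  r2 <- rank_comorbidities(m2, top_n = length(ids))
  expect_identical(r1$comorbidity, r2$comorbidity)
  expect_equal(r1$dropout_penalty, r2$dropout_penalty, tolerance = 1e-10)
})

test_that("sum-to-zero parameterization is enforced and tagged", {
  pop <- generate_population(preference_config(3000, seed = 8))
  m <- class_preference(pop$mentions, "htn",
                        c(valsartan = "A2Blocker",
                          atenolol = "Beta_Blocker"), seed = 8)
  expect_identical(m$parameterization, "sum-to-zero")
  expect_true(all(abs(rowMeans(m$coef)) < 1e-12))
  expect_lt(abs(mean(m$intercepts)), 1e-12)
})
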