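test_that("IDF labelling combines the obesity gate with two criteria", {
  # BMI > 30 gate + diabetes history + raised triglyceride -> positive
  expect_equal(label_mets(base_record(bmi = 31, diabetes = 1,
                                      triglyceride = 1.8)), 1L)
  # gate + a single criterion -> negative
  expect_equal(label_mets(base_record(bmi = 31, diabetes = 1)), 0L)
  # gate fails: waist below cutoff, bmi 24, no criteria
  expect_equal(label_mets(base_record(waist_cm = 85, bmi = 24)), 0L)
  # waist gate alone suffices as gate
  expect_equal(label_mets(base_record(waist_cm = 91, triglyceride = 2.0,
                                      hdl_c = 0.9)), 1L)
  # sex-specific cutoffs and HDL thresholds
  expect_equal(label_mets(base_record(sex = "female", waist_cm = 81,
                                      hdl_c = 1.2, triglyceride = 1.8)), 1L)
  expect_equal(label_mets(base_record(sex = "male", waist_cm = 81,
                                      hdl_c = 1.2, triglyceride = 1.8)), 0L)
  # glucose and blood-pressure criteria
  expect_equal(label_mets(base_record(bmi = 32, fasting_glucose = 5.7,
                                      sbp = 135)), 1L)
  expect_error(label_mets(list(sex = "male", bmi = 31)), "missing fields")
})

test_that("stratified split reproduces per-stratum round-to-nearest counts", {
  tab <- data.frame(subject_id = 1:184,
                    mets_label = rep(c(1L, 0L), times = c(93, 91)))
  sp <- split_cohort(tab, 0.7, seed = 17)
  expect_equal(nrow(sp$train), 129)
  expect_equal(nrow(sp$test), 55)
  expect_equal(sum(sp$train$mets_label), 65)  # round(0.7 * 93)
  expect_equal(sum(sp$test$mets_label), 28)

  small <- data.frame(x = 1:10, mets_label = rep(0L, 10))
  ss <- split_cohort(small, 0.7, seed = 1)
  expect_equal(nrow(ss$train), 7)
  expect_equal(nrow(ss$test), 3)

  # partition + determinism
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_equal(sort(c(sp$train$subject_id, sp$test$subject_id)), 1:184)
  sp2 <- split_cohort(tab, 0.7, seed = 17)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  sp3 <- split_cohort(tab, 0.7, seed = 18)
  expect_false(identical(sp$train$subject_id, sp3$train$subject_id))
})

test_that("univariate screen: closed-form OR, null case, constants", {
  # binary predictor with 2x2 table 30/15 vs 15/30: OR = 900/225 = 4
  tab <- data.frame(x = rep(c(1, 1, 0, 0), times = c(30, 15, 15, 30)),
                    y = rep(c(1, 0, 1, 0), times = c(30, 15, 15, 30)))
  sc <- univariate_screen(tab, "y", predictors = "x")
  expect_equal(sc$or[1], 4.0, tolerance = 1e-6)
  expect_true(sc$retained[1])

  # perfectly balanced independent predictor: OR exactly 1, not retained
  tab2 <- data.frame(x = rep(c(1, 0, 1, 0), each = 20),
                     y = rep(c(1, 1, 0, 0), each = 20))
  sc2 <- univariate_screen(tab2, "y", predictors = "x")
  expect_equal(sc2$or[1], 1.0, tolerance = 1e-9)
  expect_false(sc2$retained[1])

  # constant predictor flagged, not fitted
  tab3 <- data.frame(x = rep(1, 40), y = rep(c(0, 1), 20))
  sc3 <- univariate_screen(tab3, "y", predictors = "x")
  expect_true(sc3$constant[1])
  expect_true(is.na(sc3$or[1]))

  # continuous predictors are standardized: OR is per SD
  set.seed(5)
  tab4 <- data.frame(x = rnorm(300, 100, 25))
  tab4$y <- rbinom(300, 1, plogis(0.8 * (tab4$x - 100) / 25))
  sc4 <- univariate_screen(tab4, "y", predictors = "x")
  fit <- glm(y ~ scale(x), data = tab4, family = binomial())
  expect_equal(log(sc4$or[1]), unname(coef(fit)[2]), tolerance = 1e-6)
})

test_that("VIF closed forms and collinearity flags", {
  set.seed(8)
  n <- 200
  ortho <- data.frame(a = rep(c(1, -1), n / 2),
                      b = rep(c(1, 1, -1, -1), n / 4),
                      c = rnorm(n))
  ortho$c <- resid(lm(c ~ a + b, ortho))  # exactly orthogonal to a, b
  v <- vif_scores(ortho, c("a", "b", "c"))
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)

  pair <- correlated_pair(100, 0.8, seed = 2)
  expect_equal(cor(pair$x1, pair$x2), 0.8, tolerance = 1e-12)
  v2 <- vif_scores(pair, c("x1", "x2"))
  expect_equal(unname(v2), rep(1 / (1 - 0.64), 2), tolerance = 1e-3)

  tri <- pair
  tri$x3 <- tri$x1 + tri$x2
  v3 <- vif_scores(tri, c("x1", "x2", "x3"))
  expect_true(is.infinite(v3[["x3"]]))
})

test_that("collinearity pruning terminates with clean survivors", {
  set.seed(10)
  n <- 150
  clean <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(sort(prune_collinearity(c("a", "b", "c"), clean)),
               c("a", "b", "c"))

  dup <- clean; dup$a2 <- dup$a  # duplicated column: exactly one copy removed
  out <- prune_collinearity(c("a", "a2", "b"), dup)
  expect_length(out, 2)
  expect_true(xor("a" %in% out, "a2" %in% out))
  expect_true("b" %in% out)

  # post-condition on a messy seeded input
  messy <- data.frame(matrix(rnorm(n * 3), n, 3))
  names(messy) <- c("p", "q", "r")
  messy$s <- messy$p + rnorm(n, 0, 0.05)   # |r| ~ 0.999
  messy$t <- messy$q * 0.9 + rnorm(n, 0, 0.1)
  kept <- prune_collinearity(c("p", "q", "r", "s", "t"), messy)
  if (length(kept) >= 2) {
    expect_true(all(vif_scores(messy, kept) <= 10))
    rho <- cor(messy[, kept], method = "spearman")
    diag(rho) <- 0
    expect_true(max(abs(rho)) <= 0.8)
  }
})

test_that("logistic fit matches the saturated closed form and its algebra", {
  tab <- data.frame(x = rep(c(1, 1, 0, 0), times = c(30, 15, 15, 30)),
                    y = rep(c(1, 0, 1, 0), times = c(30, 15, 15, 30)))
  fit <- fit_logistic(tab, "x", "y")
  expect_equal(unname(fit$coefficients["x"]), log(4), tolerance = 1e-6)
  # OR/CI algebra holds row by row
  expect_equal(fit$or, exp(fit$coefficients))
  expect_equal(fit$ci_lo, exp(fit$coefficients - 1.96 * fit$se))
  expect_equal(fit$ci_hi, exp(fit$coefficients + 1.96 * fit$se))

  # standardization round trip: predict_prob on training rows equals fitted
  set.seed(30)
  tab2 <- data.frame(a = rnorm(120, 5, 2), b = rbinom(120, 1, 0.4))
  tab2$y <- rbinom(120, 1, plogis(0.5 * (tab2$a - 5) / 2 + 0.7 * tab2$b))
  fit2 <- fit_logistic(tab2, c("a", "b"), "y")
  expect_equal(predict_prob(fit2, tab2), fit2$fitted, tolerance = 1e-12)

  # perfect separation is an explicit failure
  sep <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                    y = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(sep, "x", "y"))
})

test_that("null model: coefficients small and p-values roughly uniform", {
  set.seed(44)
  n <- 2000
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                    y = rbinom(n, 1, 0.5))
  fit <- fit_logistic(tab, c("a", "b", "c"), "y")
  expect_true(all(abs(fit$coefficients) < 0.15))
  expect_gt(min(fit$p), 1e-4)
})

test_that("predicted probabilities obey the logistic closed forms", {
  tab <- data.frame(x = rnorm(50), y = rep(c(0, 1), 25))
  fit <- fit_logistic(tab, character(0), "y")   # intercept-only
  expect_equal(unname(predict_prob(fit, data.frame(x = 0))),
               plogis(fit$intercept))
  set.seed(2)
  tab2 <- data.frame(x = rnorm(200))
  tab2$y <- rbinom(200, 1, plogis(1.2 * tab2$x))
  fit2 <- fit_logistic(tab2, "x", "y")
  expect_gt(fit2$coefficients[["x"]], 0)
  p1 <- predict_prob(fit2, data.frame(x = 0.5))
  p2 <- predict_prob(fit2, data.frame(x = 1.5))
  expect_gt(p2, p1)  # monotone in a positive-coefficient predictor
  expect_error(predict_prob(fit2, data.frame(z = 1)), "missing predictor")
})

test_that("three-model construction respects the specified feature sets", {
  spec <- default_cohort_spec(n = 300)
  spec$beta <- c(imat_fd = 1.2, imat_mfr = 1.0, imr = 0.8)
  cohort <- synth_cohort(spec, seed = 77)
  sp <- split_cohort(cohort, 0.7, seed = 77)
  models <- build_three_models(sp$train)

  expect_setequal(models$radiological$predictors,
                  c("imr", "imat_fd", "imat_mfr"))
  expect_length(intersect(models$clinical$predictors,
                          models$radiological$predictors), 0)
  expect_setequal(models$combined$predictors,
                  union(models$clinical$predictors,
                        models$radiological$predictors))
  # every multivariable predictor passed the screen (radiological set is
  # entered by specification)
  clin_kept <- models$screen$variable[models$screen$retained %in% TRUE]
  expect_true(all(models$clinical$predictors %in% clin_kept))
})

test_that("IMAT-only signal makes the combined model beat the clinical one", {
  spec <- default_cohort_spec(n = 260)
  spec$beta <- c(imat_fd = 1.3, imat_mfr = 1.1)
  set.seed(99)
  delta <- replicate(20, {
    seed <- sample.int(1e6, 1)
    cohort <- synth_cohort(spec, seed = seed)
    sp <- split_cohort(cohort, 0.7, seed = seed)
    models <- tryCatch(build_three_models(sp$train), error = function(e) NULL)
    if (is.null(models)) return(NA_real_)
    pc <- predict_prob(models$combined, sp$test)
    pk <- predict_prob(models$clinical, sp$test)
    auc(pc, sp$test$mets_label) - auc(pk, sp$test$mets_label)
  })
  expect_gt(mean(delta, na.rm = TRUE), 0)
})
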