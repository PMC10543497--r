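cohort_200 <- function(seed = 1) generate_cohort(seed = seed)

test_that("scan records validate and derive High FLAIR", {
  rec <- tibble::tibble(patient_id = "P1", t_C1D1 = c(0, 30),
                        ce_cm3 = c(5, 6), fluid_cm3 = c(2, 2),
                        edema1_cm3 = c(10, 11), edema2_cm3 = c(3, 3))
  out <- scan_records(rec)
  expect_equal(out$high_flair_cm3, c(13, 14))
  rec$edema1_cm3[1] <- -1
  expect_error(scan_records(rec), ">= 0")
  rec$edema1_cm3[1] <- 10; rec$high_flair_cm3 <- c(99, 14)
  expect_error(scan_records(rec), "high_flair_cm3 must equal")
})

test_that("correlation matrix recovers exact and simulated relationships", {
  base <- tibble::tibble(patient_id = "P1", t_C1D1 = c(1, 2, 3, 4, 5) * 10)
  rec <- dplyr::mutate(base, ce_cm3 = 2 * t_C1D1, fluid_cm3 = 100 - t_C1D1,
                       edema1_cm3 = 1:5, edema2_cm3 = 0,
                       ttp_days = c(3, 1, 4, 1, 5))
  cm <- correlation_matrix(rec, vars = c("t_C1D1", "ce_cm3", "fluid_cm3"))
  expect_equal(cm$r["t_C1D1", "ce_cm3"], 1)          # y = 2x
  expect_equal(cm$r["t_C1D1", "fluid_cm3"], -1)      # y = -x
  expect_equal(diag(cm$r), c(t_C1D1 = 1, ce_cm3 = 1, fluid_cm3 = 1))
  expect_true(all(abs(cm$r) <= 1, na.rm = TRUE))
  # zero-variance variable flagged
  expect_warning(
    cm2 <- correlation_matrix(rec, vars = c("t_C1D1", "edema2_cm3")),
    "zero variance")
  expect_true(is.na(cm2$r["t_C1D1", "edema2_cm3"]))
  # seeded simulation: empirical R near generating correlation
  set.seed(11)
  n <- 2000; x <- rnorm(n); yv <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  sim <- tibble::tibble(patient_id = "P", t_C1D1 = abs(x) * 0,
                        ce_cm3 = x - min(x), fluid_cm3 = yv - min(yv),
                        edema1_cm3 = 0, edema2_cm3 = 0)
  cm3 <- correlation_matrix(sim, vars = c("ce_cm3", "fluid_cm3"))
  expect_equal(cm3$r["ce_cm3", "fluid_cm3"], 0.8, tolerance = 0.05)
  # tidy() gives one row per unordered pair
  td <- tidy(cm)
  expect_equal(nrow(td), 3)
})

test_that("predict_ttp evaluates the linear model", {
  m <- reference_ttp_model()
  z <- tibble::tibble(t_C1D1 = 0, ce_cm3 = 0, fluid_cm3 = 0)
  expect_identical(predict_ttp(m, z), 205.6)
  r <- tibble::tibble(t_C1D1 = 100, ce_cm3 = 10, fluid_cm3 = 5)
  expect_equal(predict_ttp(m, r), 144.6)
  zero <- ttp_model(42, c(t_C1D1 = 0, ce_cm3 = 0))
  expect_equal(predict_ttp(zero, r), 42)
  expect_error(predict_ttp(m, tibble::tibble(t_C1D1 = 1)), "missing model predictor")
})

test_that("horizon accuracy equals the brute-force label count", {
  expect_equal(horizon_accuracy(c(10, 100), c(90, 20), 30), 0)
  expect_equal(horizon_accuracy(c(10, 100), c(25, 95), 30), 1)
  expect_equal(horizon_accuracy(1:10, 1:10, 5), 1)
  brute <- function(tr, pr, n) {
    lt <- ifelse(tr <= n, 1, 0); lp <- ifelse(pr <= n, 1, 0)
    sum(lt == lp) / length(lt)
  }
  set.seed(99)
  for (i in 1:25) {
    tr <- runif(40, -50, 400); pr <- tr + rnorm(40, 0, 60)
    n <- sample(c(30, 60, 90), 1)
    acc <- horizon_accuracy(tr, pr, n)
    expect_identical(acc, brute(tr, pr, n))
    expect_gte(acc, 0); expect_lte(acc, 1)
  }
  expect_error(horizon_accuracy(numeric(0), numeric(0), 30), "empty")
  expect_error(horizon_accuracy(1:3, 1:2, 30), "equal length")
})

test_that("noiseless cohorts are recovered exactly by subset selection", {
  co <- generate_cohort(noise_sigma_days = 0, n_patients = 6,
                        scans_per_patient = 5, seed = 4)
  m <- select_model(co, seed = 4)
  expect_setequal(m$predictors, c("t_C1D1", "ce_cm3", "fluid_cm3"))
  expect_equal(m$intercept, 205.6, tolerance = 1e-8)
  expect_equal(unname(m$coefficients[c("t_C1D1", "ce_cm3", "fluid_cm3")]),
               c(-0.6, -2.5, 4.8), tolerance = 1e-8)
  # single noiseless predictor: y = 100 - x
  rec <- tibble::tibble(patient_id = "P", t_C1D1 = seq(0, 90, 10),
                        ce_cm3 = 0, fluid_cm3 = 0, edema1_cm3 = 0,
                        edema2_cm3 = 0)
  rec$ttp_days <- 100 - rec$t_C1D1
  m2 <- select_model(rec, candidate_vars = "t_C1D1", k_folds = 5, seed = 1)
  expect_equal(m2$intercept, 100, tolerance = 1e-8)
  expect_equal(unname(m2$coefficients[["t_C1D1"]]), -1, tolerance = 1e-8)
})

test_that("selection is deterministic given the seed, including leave-one-out", {
  co <- generate_cohort(n_patients = 4, scans_per_patient = 5, seed = 8)
  m1 <- select_model(co, k_folds = 10, seed = 21)
  m2 <- select_model(co, k_folds = 10, seed = 21)
  expect_identical(m1$predictors, m2$predictors)
  expect_equal(m1$coefficients, m2$coefficients)
  expect_equal(m1$mean_cv_aic, m2$mean_cv_aic)
  loo1 <- select_model(co, k_folds = nrow(co), seed = 5)
  loo2 <- select_model(co, k_folds = nrow(co), seed = 5)
  expect_equal(loo1$mean_cv_aic, loo2$mean_cv_aic)
})

test_that("refit residuals are orthogonal to the design", {
  co <- cohort_200()
  m <- select_model(co, seed = 1)
  X <- cbind(1, as.matrix(co[!is.na(co$ttp_days), m$predictors]))
  res <- stats::residuals(m$fit)
  expect_lt(max(abs(crossprod(X, res))), 1e-6 * nrow(X) * max(abs(co$ttp_days)))
})

test_that("coefficient error shrinks with cohort size", {
  truth <- reference_ttp_model()
  err <- sapply(c(200, 2000), function(n) {
    co <- generate_cohort(n_patients = n / 10, scans_per_patient = 10,
                          noise_sigma_days = 10, seed = 13)
    m <- select_model(co, candidate_vars = c("t_C1D1", "ce_cm3", "fluid_cm3"),
                      seed = 13)
    mean(abs(m$coefficients[names(truth$coefficients)] - truth$coefficients))
  })
  expect_lt(err[2], err[1])
})

test_that("pure-noise outcomes select a minimal model", {
  wins <- sapply(1:5, function(s) {
    co <- generate_cohort(n_patients = 30, scans_per_patient = 10, seed = s)
    set.seed(1000 + s)
    co$ttp_days <- rnorm(nrow(co), 150, 15)
    length(select_model(co, seed = s)$predictors)
  })
  expect_true(median(wins) <= 2)
})

test_that("perfectly collinear subsets are skipped, not fitted", {
  co <- generate_cohort(n_patients = 5, scans_per_patient = 6, seed = 2)
  m <- select_model(co, seed = 2)
  tab <- attr(m, "cv_table")
  collinear <- grepl("edema1_cm3", tab$predictors) &
    grepl("edema2_cm3", tab$predictors) &
    grepl("high_flair_cm3", tab$predictors)
  expect_true(all(is.na(tab$mean_cv_aic[collinear])))
  expect_true(all(!is.na(tab$mean_cv_aic[!collinear])))
})

test_that("model accessors: tidy and glance", {
  co <- cohort_200()
  m <- select_model(co, seed = 1)
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), length(m$predictors) + 1)
  gl <- glance(m)
  expect_gt(gl$r.squared, 0.5)
  expect_equal(gl$nobs, nrow(co))
  td2 <- tidy(reference_ttp_model())
  expect_equal(td2$estimate[td2$term == "(Intercept)"], 205.6)
})
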