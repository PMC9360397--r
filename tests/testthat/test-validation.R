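# Splitting, nested cross-validation and method-comparison statistics.

test_that("stratified split reproduces the 49/21 partition and conserves", {
  s <- make_sample_table(seed = 42)
  plan <- split_calibration(s, 0.7, seed = 1)
  expect_length(plan$calibration_ids, 49)
  expect_length(plan$validation_ids, 21)
  expect_setequal(c(plan$calibration_ids, plan$validation_ids), s$sample_id)
  expect_length(intersect(plan$calibration_ids, plan$validation_ids), 0)
  # per-level proportions within one sample of 70/30
  cal <- s[s$sample_id %in% plan$calibration_ids, ]
  expect_true(all(table(cal$fraction) == 7))
  plan2 <- split_calibration(s, 0.7, seed = 1)
  expect_identical(plan, plan2)
  one_level <- data.frame(sample_id = sprintf("s%02d", 1:10), fraction = 0)
  p <- split_calibration(one_level, 0.7, seed = 2)
  expect_length(p$calibration_ids, 7)
  bad <- data.frame(sample_id = c("a", "b", "c"), fraction = c(0, 0, 0.1))
  expect_error(split_calibration(bad), "at least 2 samples")
})

test_that("nested CV partitions by animal into 10 folds of 7", {
  s <- make_sample_table(seed = 13)
  fit_fn <- function(tr) ols_fit(tr$hb_ref, tr$absorbance540)
  predict_fn <- function(m, te) predict_hb(m, te$absorbance540)
  cv <- nested_cv(s, fit_fn, predict_fn, k = 10)
  expect_length(cv$predictions, 70)
  expect_true(all(table(cv$fold_assignments) == 7))
  # folds are the animals
  expect_equal(length(unique(paste(s$animal_id, cv$fold_assignments))), 10)
  # every sample predicted exactly once
  expect_setequal(names(cv$predictions), s$sample_id)
  expect_equal(anyDuplicated(names(cv$predictions)), 0)
  # identity predictor: pooled RMSE zero
  cv0 <- nested_cv(s, function(tr) NULL, function(m, te) te$hb_ref, k = 10)
  expect_equal(unname(cv0$predictions), s$hb_ref)
  expect_equal(max(cv0$per_fold_rmse), 0)
})

test_that("nested CV falls back to stratified folds when animals != k", {
  s <- make_sample_table(n_animals = 6, seed = 3)
  expect_warning(
    cv <- nested_cv(s, function(tr) NULL, function(m, te) te$hb_ref, k = 10),
    "falling back")
  sizes <- table(cv$fold_assignments)
  expect_equal(sum(sizes), 42)
  expect_lte(diff(range(sizes)), 1)
})

test_that("paired t reproduces the worked example and the t.test oracle", {
  # a difference vector with mean 0.0115 and SD 0.455, n = 21
  set.seed(71)
  z <- rnorm(21); z <- (z - mean(z)) / sd(z)
  ref <- runif(21, 0, 10)
  pred <- ref + 0.0115 + 0.455 * z
  pt <- paired_t(pred, ref)
  expect_equal(pt$mean_diff, 0.0115, tolerance = 1e-12)
  expect_equal(pt$sd_diff, 0.455, tolerance = 1e-12)
  expect_equal(round(pt$t_cal, 3), 0.116)
  expect_true(pt$comparable)
  # degenerate cases
  expect_equal(paired_t(ref, ref)$t_cal, 0)
  expect_equal(paired_t(c(1, -1), c(0, 0))$t_cal, 0)
  expect_equal(paired_t(c(2, 2), c(1, 1))$t_cal, Inf)
  # textbook oracle on random pairs
  set.seed(72)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    pt <- paired_t(a, b)
    oracle <- t.test(a, b, paired = TRUE)
    expect_equal(pt$t_cal, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(pt$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("equality line is predicted-on-reference OLS", {
  ref <- c(0, 1, 2, 5, 10)
  f <- equality_line(ref, ref)
  expect_equal(c(f$intercept, f$slope, f$r), c(0, 1, 1))
  f2 <- equality_line(0.9 * ref + 0.5, ref)
  expect_equal(f2$slope, 0.9, tolerance = 1e-12)
  expect_equal(f2$intercept, 0.5, tolerance = 1e-12)
})

test_that("inverse prediction through a fitted calibration is unbiased", {
  # 200 seeded calibrate-then-validate simulations: the mean equality-line
  # slope sits at 1 (inverse prediction does not attenuate)
  slopes <- vapply(1:200, function(i) {
    design <- generate_design(10, seed = 3000 + i)
    s <- simulate_samples(design, seed = 4000 + i)
    plan <- split_calibration(s, 0.7, seed = i)
    cal <- s[s$sample_id %in% plan$calibration_ids, ]
    val <- s[s$sample_id %in% plan$validation_ids, ]
    fit <- ols_fit(cal$hb_ref, cal$absorbance540)
    equality_line(predict_hb(fit, val$absorbance540), val$hb_ref)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.01)
})

test_that("EJCR decision matches the residual-sum oracle and basic cases", {
  ref <- c(0, 1, 2, 5, 10)
  ex <- ejcr_test(equality_line(ref, ref))
  expect_true(ex$inside)
  expect_equal(ex$statistic, 0)
  set.seed(73)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 10)
    y <- runif(1, 0.7, 1.3) * x + rnorm(1, 0, 0.3) + rnorm(n, 0, 0.5)
    fit <- ols_fit(x, y)
    mine <- ejcr_test(fit, 0, 1)
    expect_identical(mine$inside, oracle_ejcr_inside(x, y, 0, 1))
  }
  tiny <- structure(list(n = 2), class = "linear_fit")
  expect_error(ejcr_test(tiny), "n > 2")
})

test_that("comparison reports assemble and serialize coherently", {
  s <- make_sample_table(seed = 10)
  plan <- split_calibration(s, seed = 10)
  cal <- s[s$sample_id %in% plan$calibration_ids, ]
  val <- s[s$sample_id %in% plan$validation_ids, ]
  fit <- ols_fit(cal$hb_ref, cal$absorbance540)
  rep <- comparison_report(predict_hb(fit, val$absorbance540), val$hb_ref,
                           "uv")
  expect_s3_class(rep$equality_fit, "linear_fit")
  expect_equal(rep$intercept_ci[2] - rep$intercept_ci[1],
               2 * rep$equality_fit$ci_half_intercept)
  p <- tempfile(fileext = ".csv")
  write_comparison_report(rep, p)
  row <- read.csv(p)
  expect_equal(row$slope, rep$equality_fit$slope, tolerance = 1e-12)
  expect_equal(row$t_cal, rep$paired$t_cal, tolerance = 1e-12)
})
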