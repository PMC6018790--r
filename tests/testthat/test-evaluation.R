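test_that("centre-based split follows the <200-case rule and the 3:1 ratio", {
  co <- make_center_cohort(c(A = 300, B = 250, C = 150, D = 100))
  g <- split_dataset(co, split_spec(center_size_threshold = 200, seed = 1))
  expect_equal(nrow(g$external), 250)
  expect_setequal(unique(g$external$center_id), c("C", "D"))
  n_rest <- 550
  expect_equal(nrow(g$train), round(0.75 * n_rest))
  expect_equal(nrow(g$train) + nrow(g$internal) + nrow(g$external), nrow(co))

  # partition exactness: no row lost or duplicated
  ids <- c(rownames(g$train), rownames(g$internal), rownames(g$external))
  expect_setequal(ids, rownames(co))
  expect_equal(anyDuplicated(ids), 0)

  # a 14231-row remainder splits 10673 / 3558
  big <- make_center_cohort(c(Z = 14231))
  expect_warning(gb <- split_dataset(big, split_spec(seed = 2)), "no centre below")
  expect_equal(nrow(gb$train), 10673)
  expect_equal(nrow(gb$internal), 3558)
  expect_equal(nrow(gb$external), 0)
})

test_that("split is seed-reproducible and validates input", {
  co <- make_center_cohort(c(A = 300, B = 100))
  g1 <- split_dataset(co, split_spec(seed = 7))
  g2 <- split_dataset(co, split_spec(seed = 7))
  expect_identical(g1, g2)
  expect_error(split_dataset(data.frame(x = 1)), "center_id")
})

test_that("the 20% band classification handles boundaries as documented", {
  expect_equal(classify_prediction(3.5, 3.0), "ideal")         # 0.5 <= 0.6
  expect_equal(classify_prediction(1.5, 2.0), "underestimate") # 0.5 > 0.4
  expect_equal(classify_prediction(3.0, 2.5), "ideal")         # boundary inclusive
  expect_equal(classify_prediction(2.61, 2.0), "overestimate")
  expect_error(classify_prediction(1, 0), "> 0")
  # scale invariance
  set.seed(1)
  p <- runif(50, 1, 5); a <- runif(50, 1, 5)
  expect_identical(classify_prediction(p, a), classify_prediction(3 * p, 3 * a))
})

test_that("dose subgroups use <2.5 / [2.5, 3.0] / >3.0", {
  expect_equal(dose_subgroup(c(2.4, 2.5, 2.8, 3.0, 3.2)),
               c("low", "intermediate", "intermediate", "intermediate", "high"))
  expect_error(dose_subgroup(-1), "> 0")
})

test_that("accuracy report computes MAE, RMSE and stratified counts", {
  r <- accuracy_report(c(3, 3), c(3, 3))
  expect_equal(r$mae, 0)
  expect_equal(r$rmse, 0)
  expect_equal(unname(r$percentages[["ideal"]]), 100)

  r2 <- accuracy_report(c(2, 4), c(3, 3))
  expect_equal(r2$mae, 1)
  expect_equal(r2$rmse, 1)

  expect_error(accuracy_report(1:3, 1:2), "length mismatch")
})

test_that("percentages reproduce published-table arithmetic at 1 dp", {
  # construct groups with prescribed classification counts
  counts_to_vectors <- function(under, ideal, over) {
    n <- under + ideal + over
    actual <- rep(2.8, n)
    pred <- c(rep(2.8 * 0.7, under), rep(2.8, ideal), rep(2.8 * 1.3, over))
    list(pred = pred, actual = actual)
  }
  iv <- counts_to_vectors(746, 2088, 724)
  riv <- accuracy_report(iv$pred, iv$actual)
  expect_equal(riv$n, 3558)
  expect_equal(unname(riv$counts), c(746, 2088, 724))
  expect_equal(unname(riv$percentages), c(21.0, 58.7, 20.3))

  ev <- counts_to_vectors(257, 920, 286)
  rev <- accuracy_report(ev$pred, ev$actual)
  expect_equal(rev$n, 1463)
  expect_equal(unname(rev$percentages), c(17.6, 62.9, 19.5))

  # counts sum to n in every stratum
  set.seed(2)
  p <- runif(300, 1.5, 4); a <- runif(300, 1.5, 4)
  rr <- accuracy_report(p, a)
  expect_equal(sum(rr$counts), rr$n)
  for (s in rr$subgroups) expect_equal(sum(s$counts), s$n)
  expect_equal(sum(vapply(rr$subgroups, function(s) s$n, numeric(1))), rr$n)
})

test_that("MAE never exceeds RMSE", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    p <- runif(n, 1, 5); a <- runif(n, 1, 5)
    r <- accuracy_report(p, a)
    expect_lte(r$mae, r$rmse)
  }
})

test_that("group comparison reproduces the t and chi-square behaviour", {
  same <- accuracy_report(c(2.0, 1.5, 3.1), c(2.2, 2.5, 3.0))
  cmp0 <- compare_groups(same, same)
  expect_equal(cmp0$t$statistic, 0)
  expect_equal(cmp0$t$p_value, 1)
  expect_equal(unname(cmp0$chisq$statistic), 0)

  # two-proportion z^2 oracle for the chi-square on ideal counts
  z2_oracle <- function(x1, n1, x2, n2) {
    p_pool <- (x1 + x2) / (n1 + n2)
    z <- (x1 / n1 - x2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    z^2
  }
  ra <- list(n = 3558, counts = c(underestimate = 746, ideal = 2088, overestimate = 724),
             abs_errors = NULL)
  rb <- list(n = 1463, counts = c(underestimate = 257, ideal = 920, overestimate = 286),
             abs_errors = NULL)
  set.seed(4)
  cmp <- compare_groups(ra, rb, abs_errors_a = runif(50), abs_errors_b = runif(50))
  expect_equal(unname(cmp$chisq$statistic),
               z2_oracle(2088, 3558, 920, 1463), tolerance = 1e-10)
  expect_lt(cmp$chisq$p_value, 0.05)

  expect_error(compare_groups(ra, rb, abs_errors_a = 1, abs_errors_b = 2),
               "degenerate")
})

test_that("bootstrap MAE interval brackets the point estimate", {
  set.seed(5)
  e <- abs(rnorm(200, 0.4, 0.1))
  ci <- bootstrap_mae_ci(e, seed = 1)
  expect_lt(ci[1], mean(e))
  expect_gt(ci[2], mean(e))
  expect_identical(ci, bootstrap_mae_ci(e, seed = 1))
})
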