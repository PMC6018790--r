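test_that("integrity filter drops strictly-below-threshold columns only", {
  d <- data.frame(full = 1:10,
                  forty = c(rep(1, 4), rep(NA, 6)),
                  fifty = c(rep(1, 5), rep(NA, 5)))
  f <- filter_integrity(d, 0.50)
  expect_named(f$table, c("full", "fifty"))
  expect_equal(f$dropped$name, "forty")
  expect_equal(f$dropped$completeness, 0.4)
  expect_equal(nrow(f$table), 10)

  # identity on complete tables, and idempotence
  clean <- data.frame(a = 1:5, b = 6:10)
  expect_identical(filter_integrity(clean, 0.5)$table, clean)
  again <- filter_integrity(f$table, 0.50)
  expect_identical(again$table, f$table)
  expect_equal(nrow(again$dropped), 0)

  expect_error(filter_integrity(data.frame()), "non-empty")
})

test_that("partial eta-squared matches the projection oracle on a worked dataset", {
  d <- data.frame(y = c(2.1, 3.4, 2.9, 4.2, 3.3, 5.0),
                  a = c(1, 2, 2, 3, 3, 4),
                  b = c(0.5, 0.1, 0.9, 0.4, 0.8, 0.2))
  got <- ancova_partial_eta2(d, "y", c("a", "b"))
  oracle <- seq_ss_oracle(d$y, list(d$a, d$b))
  expect_equal(got$partial_eta2,
               oracle$ss / (oracle$ss + oracle$ss_error),
               tolerance = 1e-10)
  # F-test p-values from the same decomposition
  df_err <- 6 - 3
  f_stat <- oracle$ss / (oracle$ss_error / df_err)
  expect_equal(got$p_value, pf(f_stat, 1, df_err, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("partial eta-squared hits 1 for a perfect first candidate and ~0 under the null", {
  set.seed(42)
  d <- data.frame(y = rnorm(100))
  d$same <- d$y
  d$noise <- rnorm(100)
  # base anova warns that F tests on an exact fit are unreliable; the
  # sequential SS themselves are what the screen uses
  suppressWarnings(got <- ancova_partial_eta2(d, "y", c("same", "noise")))
  expect_equal(got$partial_eta2[1], 1)

  big <- data.frame(y = rnorm(5000), z = rnorm(5000))
  expect_lt(ancova_partial_eta2(big, "y", "z")$partial_eta2, 0.01)
})

test_that("partial eta-squared is invariant to affine rescaling of a candidate", {
  set.seed(7)
  d <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
  base <- ancova_partial_eta2(d, "y", c("a", "b"))
  d$a <- 100 * d$a - 3
  scaled <- ancova_partial_eta2(d, "y", c("a", "b"))
  expect_equal(base$partial_eta2, scaled$partial_eta2, tolerance = 1e-10)
})

test_that("constant or collinear candidates are flagged with eta2 0 and p 1", {
  set.seed(1)
  d <- data.frame(y = rnorm(30), a = rnorm(30))
  d$twice_a <- 2 * d$a
  d$const <- 5
  warns <- capture_warnings(got <- ancova_partial_eta2(d, "y", c("a", "twice_a", "const")))
  expect_length(warns, 2)
  expect_match(warns, "constant or collinear", all = TRUE)
  expect_equal(got$partial_eta2[got$name %in% c("twice_a", "const")], c(0, 0))
  expect_equal(got$p_value[got$name %in% c("twice_a", "const")], c(1, 1))
  expect_true(all(got$flagged[got$name %in% c("twice_a", "const")]))
  expect_false(got$flagged[got$name == "a"])
})

test_that("selection applies thresholds then enrolls mandatory variables", {
  scores <- published_screen_scores()
  sel <- select_variables(scores, selection_config())
  expect_length(sel, 12)
  expect_true(all(c("height", "weight") %in% sel))
  expect_equal(sel[1:10], scores$name)

  strict <- select_variables(scores, selection_config(eta2_threshold = 0.01,
                                                      mandatory = character(0)))
  expect_setequal(strict, c("warfarin_origin", "first_anticoagulant_day"))

  only_mand <- select_variables(scores[0, ], selection_config(mandatory = "height"))
  expect_equal(only_mand, "height")

  # mandatory variables never duplicated
  scores2 <- rbind(scores, data.frame(name = "height", partial_eta2 = 0.02,
                                      p_value = 0.001, flagged = FALSE))
  sel2 <- select_variables(scores2, selection_config())
  expect_equal(sum(sel2 == "height"), 1)

  expect_error(select_variables(scores[0, ], selection_config(mandatory = character(0))),
               "empty|no candidates")
})

test_that("min-max scaler maps endpoints, round-trips, and survives serialization", {
  d <- data.frame(a = c(2, 4, 3), b = c(10, 20, 15), flat = c(7, 7, 7))
  expect_warning(sc <- fit_minmax(d, c("a", "b", "flat")), "zero-range")
  m <- apply_minmax(sc, d)
  expect_equal(m[, "a"], c(0, 1, 0.5))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m[, "flat"], c(0, 0, 0))
  expect_equal(invert_minmax(sc, m[, "b"], "b"), d$b, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  write_scaler(sc, path)
  sc2 <- read_scaler(path)
  expect_equal(apply_minmax(sc2, d), m)
})
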