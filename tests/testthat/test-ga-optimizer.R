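test_that("encode/decode is a lossless bijection across random shapes", {
  expect_equal(chromosome_length(2, 2, 1), 9)
  set.seed(10)
  for (m in 1:5) {
    for (h in sample(1:6, 3)) {
      p <- init_network(m, h, seed = m * 10 + h)
      genes <- encode_network(p)
      expect_length(genes, chromosome_length(m, h))
      expect_equal(decode_network(genes, m, h), p)
      expect_equal(encode_network(decode_network(genes, m, h)), genes)
    }
  }
  expect_error(decode_network(rep(0, 5), 2, 2), "length")
})

test_that("perturbing one gene changes exactly one decoded entry", {
  m <- 2; h <- 3
  genes <- encode_network(init_network(m, h, seed = 1))
  base <- decode_network(genes, m, h)
  flat <- function(p) c(as.vector(p$w_ih), p$b_h, as.vector(p$w_ho), p$b_o)
  for (k in seq_along(genes)) {
    g2 <- genes
    g2[k] <- g2[k] + 1
    expect_equal(sum(flat(decode_network(g2, m, h)) != flat(base)), 1,
                 label = paste("gene", k))
  }
})

test_that("fitness is the reciprocal summed absolute error over samples", {
  # two samples with absolute errors 0.4 and 0.6: F = 1/(1 + eps)
  p <- decode_network(c(rep(0, chromosome_length(1, 1) - 1), 0), 1, 1)
  genes <- encode_network(p)  # predicts 0 everywhere
  x <- matrix(c(1, 2), 2, 1)
  expect_equal(ga_fitness(genes, x, y = c(0.4, -0.6), m = 1, h = 1, epsilon = 1e-8),
               1 / (1 + 1e-8), tolerance = 1e-12)
  # zero error attains the 1/epsilon ceiling
  expect_equal(ga_fitness(genes, x, y = c(0, 0), m = 1, h = 1, epsilon = 1e-8), 1e8)
  # halving every absolute error exactly doubles F in the eps -> 0 limit
  f1 <- ga_fitness(genes, x, y = c(0.4, -0.6), m = 1, h = 1, epsilon = 1e-300)
  f2 <- ga_fitness(genes, x, y = c(0.2, -0.3), m = 1, h = 1, epsilon = 1e-300)
  expect_equal(f2 / f1, 2, tolerance = 1e-12)
  # non-finite prediction culls the individual
  bad <- genes
  bad[length(bad)] <- Inf
  expect_warning(f <- ga_fitness(bad, x, c(0, 0), 1, 1), "non-finite")
  expect_equal(f, 0)
})

test_that("roulette selection is exactly fitness-proportional", {
  probs <- c(3, 1) / 4
  expect_equal(probs, c(0.75, 0.25))
  set.seed(123)
  draws <- roulette_select(c(3, 1), n_draws = 1e5)
  freq <- mean(draws == 1)
  mc_sd <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(freq - 0.75), 3 * mc_sd)

  set.seed(5)
  uniform <- roulette_select(rep(2, 4), n_draws = 4e4)
  expect_true(all(abs(tabulate(uniform, 4) / 4e4 - 0.25) < 0.01))

  expect_warning(roulette_select(c(0, 0), 10), "all fitnesses zero")
  expect_error(roulette_select(numeric(0)), "non-empty")
  # probabilities sum to one for any positive fitness vector
  f <- runif(50)
  expect_equal(sum(f / sum(f)), 1, tolerance = 1e-12)
})

test_that("crossover swaps tails at the cut point", {
  a <- c(1, 1, 1, 1); b <- c(2, 2, 2, 2)
  set.seed(1)
  ch <- ga_crossover(a, b, rate = 1, k = 2)
  expect_equal(ch$child1, c(1, 1, 2, 2))
  expect_equal(ch$child2, c(2, 2, 1, 1))

  none <- ga_crossover(a, b, rate = 0)
  expect_equal(none$child1, a)
  expect_equal(none$child2, b)
  expect_true(is.na(none$k))

  same <- ga_crossover(a, a, rate = 1)
  expect_equal(same$child1, a)
  expect_equal(same$child2, a)

  expect_warning(short <- ga_crossover(1, 2, rate = 1), "too short")
  expect_equal(short$child1, 1)
})

test_that("mutation respects rate, bounds, and seeding", {
  g <- seq(-0.8, 0.8, length.out = 9)
  expect_identical(ga_mutate(g, rate = 0), g)

  set.seed(3)
  m1 <- ga_mutate(g, rate = 1)
  set.seed(3)
  m2 <- ga_mutate(g, rate = 1)
  expect_identical(m1, m2)
  expect_lte(sum(m1 != g), 1)
  expect_true(all(m1 >= -1 & m1 <= 1))

  set.seed(4)
  pg <- ga_mutate(g, rate = 1, mode = "per_gene")
  expect_true(all(pg >= -1 & pg <= 1))
  expect_gt(sum(pg != g), 1)
})

test_that("evolution is monotone under elitism and conserves the population", {
  task <- make_norm_task(n = 40, m = 2, seed = 6)
  cfg <- ga_config(population_size = 20, generations = 15, seed = 9)
  evo <- ga_evolve(task$x, task$y, m = 2, h = 3, config = cfg)
  expect_equal(nrow(evo$trajectory), 16)  # generation 0 plus 15
  expect_true(all(diff(evo$trajectory$best_fitness) >= 0))
  expect_equal(dim(evo$population), c(20, chromosome_length(2, 3)))
  expect_true(all(evo$population >= -1 & evo$population <= 1))
  expect_equal(evo$best_fitness, max(evo$trajectory$best_fitness))

  none <- ga_evolve(task$x, task$y, 2, 3, config = ga_config(population_size = 10,
                                                             generations = 0, seed = 2))
  expect_equal(nrow(none$trajectory), 1)
  expect_equal(none$best_fitness, none$trajectory$best_fitness[1])
})

test_that("evolution improves on the initial population for most seeds", {
  task <- make_norm_task(n = 40, m = 2, seed = 8)
  improved <- vapply(1:20, function(s) {
    evo <- ga_evolve(task$x, task$y, 2, 3,
                     config = ga_config(population_size = 20, generations = 15, seed = s))
    tr <- evo$trajectory$best_fitness
    c(tr[length(tr)] >= tr[1], tr[length(tr)] > tr[1])
  }, logical(2))
  expect_true(all(improved[1, ]))          # never worse than generation 0
  expect_gte(mean(improved[2, ]), 0.9)     # strict improvement in >= 90% of seeds
})

test_that("the full BP-GA fit is deterministic end to end", {
  task <- make_norm_task(n = 50, m = 3, seed = 12)
  cfg_ga <- ga_config(population_size = 12, generations = 8, seed = 4)
  cfg_tr <- train_config(max_epochs = 40)
  m1 <- fit_bpga(task$x, task$y, h = 4, ga = cfg_ga, train = cfg_tr)
  m2 <- fit_bpga(task$x, task$y, h = 4, ga = cfg_ga, train = cfg_tr)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$ga$trajectory, m2$ga$trajectory)
  expect_equal(predict(m1, task$x), forward(m1$params, task$x))
})

test_that("GA-only predictions are no better than the GA+BP pipeline's", {
  task <- make_norm_task(n = 400, m = 3, seed = 13)
  idx <- 1:300
  cfg_ga <- ga_config(population_size = 20, generations = 20, seed = 3)
  model <- fit_bpga(task$x[idx, ], task$y[idx], h = 4, ga = cfg_ga,
                    train = train_config())
  evo <- ga_evolve(task$x[idx, ], task$y[idx], 3, 4, config = cfg_ga)
  ga_only <- decode_network(evo$best, 3, 4)
  test_idx <- 301:400
  mae <- function(p) mean(abs(forward(p, task$x[test_idx, ]) - task$y[test_idx]))
  expect_gte(mae(ga_only), mae(model$params))
})
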