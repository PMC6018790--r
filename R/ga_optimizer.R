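#' @title Real-coded genetic algorithm for network initialisation
#' @description Searches the network's initial weights and thresholds with a
#'   real-coded GA: fitness is the reciprocal of the summed absolute
#'   prediction error of a single forward pass, parents are drawn by
#'   roulette (fitness-proportional) selection, children by single-point
#'   tail-swap crossover and single-gene mutation, with elitism. The best
#'   individual seeds back-propagation training.
#' @name ga_optimizer
NULL

#' GA configuration
#'
#' @param population_size Individuals per generation (default 50).
#' @param generations Number of generations to evolve (default 100).
#' @param crossover_rate Probability a selected pair is recombined (default 0.95).
#' @param mutation_rate Probability an individual mutates (default 0.09).
#' @param elitism_count Best individuals copied unchanged each generation.
#' @param epsilon Small positive constant added to the fitness denominator.
#' @param bounds Search box per gene, `c(lower, upper)`.
#' @param mutation_mode `"individual"` (select the individual, then replace
#'   one uniformly chosen gene) or `"per_gene"` (each gene mutates
#'   independently at `mutation_rate`).
#' @param plateau_patience Optional early stop: halt when the best fitness
#'   has improved by less than `plateau_tol` for this many consecutive
#'   generations (NULL = run all generations).
#' @param plateau_tol Improvement below this counts as a plateau.
#' @param seed Integer seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      crossover_rate = 0.95, mutation_rate = 0.09,
                      elitism_count = 1, epsilon = 1e-8,
                      bounds = c(-1, 1),
                      mutation_mode = c("individual", "per_gene"),
                      plateau_patience = NULL, plateau_tol = 1e-6,
                      seed = 1L) {
  if (population_size < 2) stop_invalid("ga_config: population_size must be >= 2")
  if (generations < 0) stop_invalid("ga_config: generations must be >= 0")
  if (crossover_rate < 0 || crossover_rate > 1 || mutation_rate < 0 || mutation_rate > 1) {
    stop_invalid("ga_config: rates must lie in [0, 1]")
  }
  if (elitism_count < 1) stop_invalid("ga_config: elitism_count must be >= 1")
  if (epsilon <= 0) stop_invalid("ga_config: epsilon must be > 0")
  if (bounds[1] >= bounds[2]) stop_invalid("ga_config: bounds must be increasing")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count), epsilon = epsilon,
                 bounds = bounds, mutation_mode = match.arg(mutation_mode),
                 plateau_patience = plateau_patience, plateau_tol = plateau_tol,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Chromosome length for a network shape
#' @param m,h,n Layer sizes.
#' @return `h*m + h + n*h + n`.
#' @export
chromosome_length <- function(m, h, n = 1) h * m + h + n * h + n

#' Encode network parameters as a flat chromosome
#'
#' Gene order: `w_ih` row-major, `b_h`, `w_ho` row-major, `b_o`. Lossless.
#'
#' @param params `network_parameters`.
#' @return Numeric gene vector.
#' @export
encode_network <- function(params) {
  c(as.vector(t(params$w_ih)), params$b_h, as.vector(t(params$w_ho)), params$b_o)
}

#' Decode a chromosome back into network parameters
#'
#' @param genes Numeric gene vector.
#' @param m,h,n Layer sizes the chromosome must match.
#' @return `network_parameters`.
#' @export
decode_network <- function(genes, m, h, n = 1) {
  L <- chromosome_length(m, h, n)
  if (length(genes) != L) {
    stop_invalid("decode_network: chromosome length ", length(genes),
                 " does not match shape (", m, ", ", h, ", ", n, "): expected ", L)
  }
  i <- 0
  w_ih <- matrix(genes[i + seq_len(h * m)], h, m, byrow = TRUE); i <- i + h * m
  b_h <- genes[i + seq_len(h)]; i <- i + h
  w_ho <- matrix(genes[i + seq_len(n * h)], n, h, byrow = TRUE); i <- i + n * h
  b_o <- genes[i + seq_len(n)]
  structure(list(w_ih = w_ih, b_h = b_h, w_ho = w_ho, b_o = b_o,
                 m = as.integer(m), h = as.integer(h), n = as.integer(n)),
            class = "network_parameters")
}

#' GA fitness of a chromosome
#'
#' `F = 1 / (sum_i |predicted_i - actual_i| + epsilon)`, the sum running
#' over all training samples, predictions from one forward pass of the
#' decoded network (no back-propagation inside the fitness).
#'
#' @param genes Chromosome.
#' @param x Feature matrix, normalized scale.
#' @param y Target vector, normalized scale.
#' @param m,h,n Network shape.
#' @param epsilon Denominator constant.
#' @return Positive fitness value; 0 (with a warning) if the forward pass is
#'   non-finite.
#' @export
ga_fitness <- function(genes, x, y, m, h, n = 1, epsilon = 1e-8) {
  if (length(y) == 0) stop_invalid("ga_fitness: empty data")
  pred <- forward(decode_network(genes, m, h, n), x)
  if (any(!is.finite(pred))) {
    warning("ga_fitness: non-finite prediction; individual assigned fitness 0")
    return(0)
  }
  1 / (sum(abs(pred - y)) + epsilon)
}

#' Roulette (fitness-proportional) selection
#'
#' Draws indices with probability exactly `f_i / sum(f)`. If every fitness
#' is zero, draws uniformly with a warning.
#'
#' @param fitnesses Non-negative fitness vector.
#' @param n_draws Number of indices to draw (with replacement).
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(fitnesses, n_draws = 1) {
  if (length(fitnesses) < 1 || any(fitnesses < 0)) {
    stop_invalid("roulette_select: fitnesses must be a non-empty non-negative vector")
  }
  if (sum(fitnesses) == 0) {
    warning("roulette_select: all fitnesses zero; drawing uniformly")
    fitnesses <- rep(1, length(fitnesses))
  }
  sample.int(length(fitnesses), n_draws, replace = TRUE, prob = fitnesses / sum(fitnesses))
}

#' Single-point tail-swap crossover
#'
#' With probability `rate`, a cut point k (uniform on 1..L-1 unless forced)
#' swaps the tails of the two parents; otherwise the children are copies.
#'
#' @param a,b Parent chromosomes of equal length.
#' @param rate Crossover probability.
#' @param k Optional fixed cut point (mainly for testing).
#' @return List with `child1`, `child2`, `k` (NA when no crossover happened).
#' @export
ga_crossover <- function(a, b, rate = 0.95, k = NULL) {
  if (length(a) != length(b)) stop_invalid("ga_crossover: parents differ in length")
  L <- length(a)
  if (L < 2) {
    warning("ga_crossover: chromosome too short to cross; returning copies")
    return(list(child1 = a, child2 = b, k = NA_integer_))
  }
  if (stats::runif(1) < rate) {
    if (is.null(k)) k <- sample.int(L - 1, 1)
    tail_idx <- (k + 1):L
    c1 <- a; c1[tail_idx] <- b[tail_idx]
    c2 <- b; c2[tail_idx] <- a[tail_idx]
    list(child1 = c1, child2 = c2, k = as.integer(k))
  } else {
    list(child1 = a, child2 = b, k = NA_integer_)
  }
}

#' Mutation
#'
#' In `"individual"` mode the whole individual mutates with probability
#' `rate`: one uniformly chosen gene is replaced by a uniform draw from the
#' bounds. In `"per_gene"` mode each gene independently mutates at `rate`.
#'
#' @param genes Chromosome.
#' @param rate Mutation probability.
#' @param bounds Search box `c(lower, upper)`.
#' @param mode `"individual"` or `"per_gene"`.
#' @return Mutated chromosome.
#' @export
ga_mutate <- function(genes, rate = 0.09, bounds = c(-1, 1),
                      mode = c("individual", "per_gene")) {
  mode <- match.arg(mode)
  if (mode == "individual") {
    if (stats::runif(1) < rate) {
      j <- sample.int(length(genes), 1)
      genes[j] <- stats::runif(1, bounds[1], bounds[2])
    }
  } else {
    hit <- stats::runif(length(genes)) < rate
    genes[hit] <- stats::runif(sum(hit), bounds[1], bounds[2])
  }
  genes
}

#' Evolve a population of network initialisations
#'
#' Initialises `population_size` chromosomes uniformly inside the bounds,
#' then for each generation: copies the `elitism_count` best unchanged,
#' fills the rest by roulette-selected parents, crossover and mutation.
#' Runs exactly `generations` generations (generation 0 is the random
#' initial population) unless the optional plateau rule stops earlier.
#'
#' @param x Feature matrix, normalized scale.
#' @param y Target vector, normalized scale.
#' @param m,h,n Network shape the chromosomes encode.
#' @param config A [ga_config()].
#' @return List with `best` (chromosome), `best_fitness`, `trajectory`
#'   (data.frame generation / best_fitness / mean_fitness), `population`
#'   (final population matrix), `config`.
#' @export
ga_evolve <- function(x, y, m, h, n = 1, config = ga_config()) {
  L <- chromosome_length(m, h, n)
  with_seed(config$seed, {
    pop <- matrix(stats::runif(config$population_size * L,
                               config$bounds[1], config$bounds[2]),
                  config$population_size, L)
    fit <- apply(pop, 1, ga_fitness, x = x, y = y, m = m, h = h, n = n,
                 epsilon = config$epsilon)
    if (all(fit == 0)) stop_invalid("ga_evolve: every individual has divergent fitness")
    traj <- data.frame(generation = 0L, best_fitness = max(fit), mean_fitness = mean(fit))
    best <- pop[which.max(fit), ]
    best_fit <- max(fit)
    stale <- 0L
    for (g in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- matrix(NA_real_, config$population_size, L)
      n_elite <- min(config$elitism_count, config$population_size)
      newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      filled <- n_elite
      while (filled < config$population_size) {
        parents <- roulette_select(fit, 2)
        ch <- ga_crossover(pop[parents[1], ], pop[parents[2], ], config$crossover_rate)
        for (child in list(ch$child1, ch$child2)) {
          if (filled >= config$population_size) break
          filled <- filled + 1
          newpop[filled, ] <- ga_mutate(child, config$mutation_rate,
                                        config$bounds, config$mutation_mode)
        }
      }
      pop <- newpop
      fit <- apply(pop, 1, ga_fitness, x = x, y = y, m = m, h = h, n = n,
                   epsilon = config$epsilon)
      if (all(fit == 0)) stop_invalid("ga_evolve: every individual has divergent fitness")
      gen_best <- max(fit)
      traj <- rbind(traj, data.frame(generation = g, best_fitness = gen_best,
                                     mean_fitness = mean(fit)))
      if (gen_best > best_fit + config$plateau_tol) stale <- 0L else stale <- stale + 1L
      if (gen_best > best_fit) {
        best_fit <- gen_best
        best <- pop[which.max(fit), ]
      }
      if (!is.null(config$plateau_patience) && stale >= config$plateau_patience) break
    }
    list(best = best, best_fitness = best_fit, trajectory = traj,
         population = pop, config = config)
  })
}

#' Fit the full GA-initialised back-propagation model
#'
#' Evolves the GA, decodes the best chromosome into initial weights and
#' thresholds, then trains by back-propagation. The returned model carries
#' full provenance (configs, seeds, GA trajectory, BP loss).
#'
#' @param x Feature matrix, normalized scale.
#' @param y Target vector, normalized scale.
#' @param h Hidden-layer size (e.g. from [hidden_size_search()]).
#' @param ga Config for the GA stage ([ga_config()]); pass `NULL` to skip
#'   the GA and train from a random initialisation (ablation).
#' @param train Config for the BP stage ([train_config()]).
#' @param init_seed Seed for the random initialisation when `ga` is `NULL`.
#' @return Object of class `bpga_model`: `params`, `ga` (trajectory and best
#'   fitness, or NULL), `bp` (loss trajectory, stop reason), `provenance`.
#' @export
fit_bpga <- function(x, y, h, ga = ga_config(), train = train_config(),
                     init_seed = 1L) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (!is.null(ga)) {
    evo <- ga_evolve(x, y, m, h, 1, ga)
    init <- decode_network(evo$best, m, h, 1)
    ga_info <- list(best_fitness = evo$best_fitness, trajectory = evo$trajectory)
  } else {
    init <- init_network(m, h, 1, seed = init_seed)
    ga_info <- NULL
  }
  tr <- train_backprop(init, x, y, train)
  structure(list(params = tr$params, ga = ga_info,
                 bp = list(loss = tr$loss, epochs = tr$epochs,
                           stop_reason = tr$stop_reason),
                 provenance = list(m = m, h = h,
                                   ga_config = if (is.null(ga)) NULL else unclass(ga),
                                   train_config = unclass(train),
                                   init_seed = if (is.null(ga)) init_seed else NULL)),
            class = "bpga_model")
}

#' Predict normalized doses from a fitted model
#' @param object A `bpga_model`. @param x Feature matrix. @param ... Unused.
#' @return Predicted values on the normalized scale.
#' @export
predict.bpga_model <- function(object, x, ...) {
  forward(object$params, x)
}

#' Serialize a fitted model to JSON
#' @param model A `bpga_model`. @param path File to write.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  p <- model$params
  jsonlite::write_json(list(shape = list(m = p$m, h = p$h, n = p$n),
                            genes = encode_network(p),
                            provenance = model$provenance,
                            ga_best_fitness = model$ga$best_fitness,
                            bp_stop_reason = model$bp$stop_reason,
                            bp_final_mse = model$bp$loss[length(model$bp$loss)]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
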