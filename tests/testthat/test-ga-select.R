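# Genetic-algorithm operators and the wrapper fitness: worked bit-string
# examples, formula arithmetic, and search behaviour.

test_that("the fitness formula penalizes the selected-feature fraction", {
  expect_equal(fitness_score(89, 60, 112), 89 - 100 * 60 / 112)
  expect_equal(round(fitness_score(89, 60, 112), 2), 35.43)
  expect_equal(round(fitness_score(64, 1, 28), 2), 60.43)
  expect_equal(fitness_score(77, 112, 112), 77 - 100)
})

test_that("wrapper fitness is bounded by accuracy and is chromosome-deterministic", {
  train <- apply_minmax(small_table(seed = 5), fit_minmax(small_table(seed = 5)))
  L <- length(feature_names(train))
  set.seed(99)
  for (i in 1:5) {
    ch <- as.integer(runif(L) < 0.5)
    if (sum(ch) == 0) ch[1] <- 1L
    rec <- evaluate_fitness(ch, train)
    rec2 <- evaluate_fitness(ch, train)
    expect_identical(rec, rec2)
    expect_lte(rec$fitness, rec$accuracy)
    expect_equal(rec$fitness,
                 fitness_score(rec$accuracy, sum(ch), L))
  }
  expect_error(evaluate_fitness(rep(0L, L), train), "no features")
  expect_error(evaluate_fitness(c(1L, 0L), train), "length")
})

test_that("binary tournament returns the fitter of two and is fair under ties", {
  set.seed(1)
  for (i in 1:50) {
    winner <- tournament_select(c(30, 10))
    expect_equal(winner, 1L)
  }
  expect_equal(tournament_select(c(42)), 1L)
  set.seed(2)
  picks <- vapply(1:10000, function(i) tournament_select(c(5, 5)), 0L)
  expect_gt(mean(picks == 1), 0.45)
  expect_lt(mean(picks == 1), 0.55)
})

test_that("one-point crossover reproduces the printed example and conserves bits", {
  fx <- worked_fixtures()
  p1 <- bandsift:::bits_from_string(fx$crossover_parents[1])
  p2 <- bandsift:::bits_from_string(fx$crossover_parents[2])
  off <- crossover_one_point(p1, p2, cut = fx$crossover_point)
  expect_identical(bandsift:::bits_to_string(off[[1]]), fx$crossover_offspring[1])
  expect_identical(bandsift:::bits_to_string(off[[2]]), fx$crossover_offspring[2])

  same <- crossover_one_point(p1, p1, cut = 3)
  expect_identical(same[[1]], p1)
  expect_identical(same[[2]], p1)

  set.seed(3)
  for (i in 1:20) {
    a <- as.integer(runif(9) < 0.5)
    b <- as.integer(runif(9) < 0.5)
    o <- crossover_one_point(a, b)
    expect_equal(o[[1]] + o[[2]], a + b)  # column-wise bit multiset conserved
  }
  expect_error(crossover_one_point(p1, p2[1:5]), "length")
})

test_that("bit-flip mutation reproduces the printed example and respects limits", {
  fx <- worked_fixtures()
  ch <- bandsift:::bits_from_string(fx$mutation_input)
  out <- mutate_bitflip(ch, prob = 0, flip_loci = fx$mutation_locus)
  expect_identical(bandsift:::bits_to_string(out), fx$mutation_output)

  set.seed(4)
  expect_identical(mutate_bitflip(ch, prob = 0), ch)
  comp <- mutate_bitflip(ch, prob = 1)
  expect_identical(comp, 1L - ch)
  # full complement of an all-ones chromosome is empty and must be repaired
  repaired <- mutate_bitflip(rep(1L, 9), prob = 1)
  expect_equal(sum(repaired), 1)
})

test_that("the GA recovers a hidden mask and behaves deterministically", {
  dummy <- small_table(n_mdd = 3, n_hv = 3, p = 28, seed = 1)
  set.seed(77)
  mask <- as.integer(runif(28) < 0.5)
  hits <- 0
  for (s in 1:5) {
    fit <- run_ga(dummy, ga_config(seed = s),
                  fitness_fn = function(ch) sum(ch == mask))
    if (identical(fit$best_chromosome, mask)) hits <- hits + 1
    expect_true(all(diff(fit$history$best_ever) >= 0))  # elitism monotonicity
  }
  expect_gte(hits, 4)

  f1 <- run_ga(dummy, ga_config(seed = 9), fitness_fn = function(ch) sum(ch))
  f2 <- run_ga(dummy, ga_config(seed = 9), fitness_fn = function(ch) sum(ch))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best_chromosome, f2$best_chromosome)
})

test_that("a uniform population without mutation is a fixed point", {
  dummy <- small_table(n_mdd = 3, n_hv = 3, p = 10, seed = 1)
  ch <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)
  init <- replicate(10, ch, simplify = FALSE)
  fit <- run_ga(dummy,
                ga_config(population_size = 10, generations = 5,
                          mutation_prob = 0, seed = 1),
                fitness_fn = function(x) sum(x),
                init = init)
  expect_identical(fit$best_chromosome, ch)
  expect_true(all(fit$history$best == fit$history$mean))
})

test_that("informative features are preferentially selected on separable data", {
  # uncorrelated noise features: under the single-factor correlation model a
  # "noise" feature shares the common factor with informative ones and can
  # legitimately improve the classifier by cancelling it, so strict exclusion
  # is only expected at zero inter-feature correlation
  informative <- 1:3
  prec <- numeric(5)
  rec <- numeric(5)
  for (s in 1:5) {
    tab <- small_table(n_mdd = 50, n_hv = 50, p = 28, informative = informative,
                       d = 2.5, seed = 600 + s, rho = 0)
    train <- apply_minmax(tab, fit_minmax(tab))
    fit <- run_ga(train, ga_config(population_size = 24, generations = 20,
                                   inner_repeats = 2, seed = s))
    sel <- which(feature_names(train) %in% fit$selected_features)
    prec[s] <- length(intersect(sel, informative)) / max(length(sel), 1)
    rec[s] <- length(intersect(sel, informative)) / length(informative)
  }
  expect_gt(mean(rec), 0.5)   # majority of informative features recovered
  expect_gt(mean(prec), 0.5)  # majority of selections are informative
})

test_that("configuration invariants are enforced", {
  expect_error(ga_config(population_size = 31), "even")
  expect_error(ga_config(elitism = 30, population_size = 30), "elitism")
  expect_error(ga_config(crossover_prob = 1.5), "crossover")
})
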