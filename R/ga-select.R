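# Genetic-algorithm wrapper feature selection. Chromosomes are bit vectors
# over the feature columns (1 = selected); fitness is held-out accuracy of
# the LDA + decision-tree classifier minus a penalty proportional to the
# selected fraction of features.

#' Genetic-algorithm hyperparameters
#'
#' The search itself (binary tournament selection, one-point crossover,
#' per-bit mutation, elitism) is fixed; these knobs size it. Defaults follow
#' common GA practice for feature-selection problems of ~100 bits: population
#' 30, 50 generations, crossover probability 0.9, mutation 1/L per bit,
#' one elite.
#'
#' @param population_size Even number of chromosomes per generation.
#' @param generations Number of generations (fixed stopping rule).
#' @param crossover_prob Probability a selected pair is recombined.
#' @param mutation_prob Per-bit flip probability; `NULL` means `1/L`.
#' @param elitism Number of best chromosomes copied unchanged (must be
#'   smaller than the population).
#' @param inner_split_fraction Training fraction of the fitness-evaluation
#'   split inside the wrapper.
#' @param inner_repeats Number of inner splits averaged per evaluation.
#' @param paper_mode If `TRUE`, fitness uses a single fixed inner split
#'   (`inner_repeats = 1`) shared by all chromosomes.
#' @param shrinkage Diagonal shrinkage for the inner LDA fits.
#' @param seed Integer seed for the whole run.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 30, generations = 50,
                      crossover_prob = 0.9, mutation_prob = NULL,
                      elitism = 1, inner_split_fraction = 0.7,
                      inner_repeats = 3, paper_mode = FALSE,
                      shrinkage = 1e-3, seed = 1L) {
  if (population_size %% 2 != 0) abort("`population_size` must be even (pairing).")
  if (elitism >= population_size) abort("`elitism` must be < population size.")
  if (crossover_prob < 0 || crossover_prob > 1) abort("`crossover_prob` in [0,1].")
  if (!is.null(mutation_prob) && (mutation_prob < 0 || mutation_prob > 1)) {
    abort("`mutation_prob` in [0,1].")
  }
  structure(list(population_size = population_size, generations = generations,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 elitism = elitism, inner_split_fraction = inner_split_fraction,
                 inner_repeats = if (paper_mode) 1L else inner_repeats,
                 paper_mode = paper_mode, shrinkage = shrinkage,
                 seed = as.integer(seed)), class = "ga_config")
}

#' Fitness score from accuracy and feature counts
#'
#' `fitness = accuracy - 100 * (n_selected / n_total)`, with accuracy on the
#' 0-100 scale. The penalty makes chromosomes with fewer features and equal
#' accuracy strictly fitter; with every feature selected the fitness is
#' `accuracy - 100`.
#'
#' @param accuracy Classification accuracy in percent (0-100).
#' @param n_selected Number of selected features.
#' @param n_total Total number of features.
#' @return Fitness value.
#' @examples
#' fitness_score(89, 60, 112)  # 35.43
#' @export
fitness_score <- function(accuracy, n_selected, n_total) {
  accuracy - 100 * (n_selected / n_total)
}

#' Evaluate a chromosome's fitness
#'
#' Restricts the training table to the chromosome's selected features, splits
#' it into inner training/testing partitions (stratified), fits the LDA
#' mapping on inner-train, fits the decision tree on the mapped inner-train,
#' scores accuracy (percent) on the mapped inner-test, averages over
#' `inner_repeats` splits, and applies the feature-count penalty of
#' [fitness_score()]. The inner seed is derived from the chromosome content,
#' so a chromosome's fitness is a pure function of (chromosome, table,
#' config). The outer test partition is never seen here.
#'
#' @param chromosome Integer 0/1 vector over the feature columns.
#' @param train Normalized training feature table.
#' @param config A [ga_config()].
#' @param tree Optional [tree_config()] for the inner classifier.
#' @return A one-row tibble `accuracy`, `fitness`, `n_selected`, `n_total`.
#' @export
evaluate_fitness <- function(chromosome, train, config = ga_config(),
                             tree = tree_config()) {
  assert_feature_table(train)
  feats <- feature_names(train)
  if (length(chromosome) != length(feats)) {
    abort("Chromosome length must equal the number of features.")
  }
  if (sum(chromosome) == 0) abort("Chromosome selects no features.")
  m <- ft_matrix(train)
  labels <- as_label_factor(train$label)
  acc <- eval_chromosome_matrix(chromosome, m, labels, config, tree)
  tibble(accuracy = acc,
         fitness = fitness_score(acc, sum(chromosome), length(chromosome)),
         n_selected = sum(chromosome), n_total = length(chromosome))
}

# Matrix-level fitness accuracy, RNG-isolated from the caller.
eval_chromosome_matrix <- function(chromosome, m, labels, config, tree) {
  sel <- which(chromosome == 1)
  x <- m[, sel, drop = FALSE]
  base_seed <- if (config$paper_mode) {
    derive_seed(config$seed, "inner-split")  # one shared split
  } else {
    derive_seed(config$seed + sum(sel * seq_along(sel)) %% 100000, "inner-split")
  }
  accs <- numeric(config$inner_repeats)
  withr::with_seed(base_seed, {
    for (r in seq_len(config$inner_repeats)) {
      idx <- stratified_indices(labels, config$inner_split_fraction)
      tries <- 0
      while (length(unique(labels[idx])) < 2 || length(unique(labels[-idx])) < 2) {
        idx <- stratified_indices(labels, config$inner_split_fraction)
        tries <- tries + 1
        if (tries > 10) abort("Degenerate inner split: a class is absent.")
      }
      fit <- fit_lda_matrix(x[idx, , drop = FALSE], labels[idx], config$shrinkage)
      z_tr <- x[idx, , drop = FALSE] %*% fit$weights
      z_te <- x[-idx, , drop = FALSE] %*% fit$weights
      tr_tbl <- tibble(sample_id = as.character(idx),
                       label = labels[idx], ld1 = as.vector(z_tr))
      tree_fit <- fit_c45(tr_tbl, tree)
      pred <- predict_c45_matrix(tree_fit, matrix(z_te, ncol = 1))
      accs[r] <- 100 * mean(pred == labels[-idx])
    }
  })
  mean(accs)
}

# plain stratified sample of training indices (uses the current RNG stream)
stratified_indices <- function(labels, fraction) {
  idx <- integer(0)
  for (cl in levels(labels)) {
    ix <- which(labels == cl)
    idx <- c(idx, sample(ix, floor(fraction * length(ix))))
  }
  sort(idx)
}

#' Binary tournament selection
#'
#' Draws two distinct chromosomes uniformly at random and returns the index
#' of the one with the higher fitness; exact ties are resolved by a fair coin.
#'
#' @param fitnesses Numeric fitness of each population member.
#' @return Index of the selected chromosome.
#' @export
tournament_select <- function(fitnesses) {
  n <- length(fitnesses)
  if (n == 0) abort("Empty population.")
  if (n == 1) return(1L)
  pair <- sample.int(n, 2)
  f <- fitnesses[pair]
  if (f[1] == f[2]) pair[sample.int(2, 1)] else pair[which.max(f)]
}

#' One-point crossover
#'
#' Cuts both parents at the same locus `c` (uniform on `1..L-1`, or supplied)
#' and exchanges the tails: offspring are `p1[1..c] + p2[c+1..L]` and
#' `p2[1..c] + p1[c+1..L]`.
#'
#' @param p1,p2 Parent chromosomes (equal-length 0/1 vectors).
#' @param cut Optional fixed cut point for reproducible examples.
#' @return List of two offspring chromosomes.
#' @examples
#' fx <- worked_fixtures()
#' p <- lapply(fx$crossover_parents, function(s) as.integer(strsplit(s, "")[[1]]))
#' crossover_one_point(p[[1]], p[[2]], cut = fx$crossover_point)
#' @export
crossover_one_point <- function(p1, p2, cut = NULL) {
  if (length(p1) != length(p2)) abort("Parent chromosomes differ in length.")
  L <- length(p1)
  cut <- cut %||% sample.int(L - 1, 1)
  if (cut < 1 || cut >= L) abort("`cut` must be in 1..L-1.")
  list(c(p1[1:cut], p2[(cut + 1):L]),
       c(p2[1:cut], p1[(cut + 1):L]))
}

#' Bit-flip mutation
#'
#' Flips every bit independently with probability `prob`. A chromosome left
#' with no selected feature is repaired by setting one uniformly random bit.
#'
#' @param chromosome 0/1 vector.
#' @param prob Per-bit flip probability in `[0, 1]`.
#' @param flip_loci Optional loci to flip deterministically instead of random
#'   flipping (used for worked examples).
#' @return Mutated chromosome.
#' @export
mutate_bitflip <- function(chromosome, prob, flip_loci = NULL) {
  out <- chromosome
  if (!is.null(flip_loci)) {
    out[flip_loci] <- 1L - out[flip_loci]
  } else {
    if (prob < 0 || prob > 1) abort("`prob` must be in [0, 1].")
    flip <- runif(length(out)) < prob
    out[flip] <- 1L - out[flip]
  }
  if (sum(out) == 0) out[sample.int(length(out), 1)] <- 1L
  out
}

#' Run the genetic-algorithm feature search
#'
#' Starts from a random population and iterates: evaluate fitness, carry the
#' elite over unchanged, fill the rest of the next generation with offspring
#' of tournament-selected parents (one-point crossover with probability
#' `crossover_prob`, then per-bit mutation). Fitness values are cached per
#' chromosome, so converged populations cost little. The run is fully
#' deterministic under `config$seed`.
#'
#' @param train Normalized training feature table.
#' @param config A [ga_config()].
#' @param tree A [tree_config()] for the wrapped classifier.
#' @param fitness_fn Optional replacement fitness `function(chromosome)`
#'   returning a scalar, used e.g. for surrogate benchmarks; `NULL` uses the
#'   LDA + tree wrapper fitness.
#' @param init Optional list of chromosomes for the initial population.
#' @return A `ga_fit` with `best_chromosome`, `best_fitness`,
#'   `selected_features`, and a per-generation `history` tibble.
#' @export
run_ga <- function(train, config = ga_config(), tree = tree_config(),
                   fitness_fn = NULL, init = NULL) {
  assert_feature_table(train)
  feats <- feature_names(train)
  L <- length(feats)
  pm <- config$mutation_prob %||% (1 / L)
  m <- ft_matrix(train)
  labels <- as_label_factor(train$label)
  fitness_of <- fitness_fn %||% function(chrom) {
    acc <- eval_chromosome_matrix(chrom, m, labels, config, tree)
    fitness_score(acc, sum(chrom), L)
  }

  cache <- new.env(parent = emptyenv())
  cached_fitness <- function(chrom) {
    key <- bits_to_string(chrom)
    if (is.null(cache[[key]])) cache[[key]] <- fitness_of(chrom)
    cache[[key]]
  }

  withr::with_seed(derive_seed(config$seed, "ga"), {
    pop <- init %||% lapply(seq_len(config$population_size), function(i) {
      ch <- as.integer(runif(L) < 0.5)
      if (sum(ch) == 0) ch[sample.int(L, 1)] <- 1L
      ch
    })
    best_chrom <- NULL
    best_fit <- -Inf
    history <- vector("list", config$generations)
    for (g in seq_len(config$generations)) {
      fits <- vapply(pop, cached_fitness, 0)
      gen_best <- max(fits)
      if (gen_best > best_fit) {
        best_fit <- gen_best
        best_chrom <- pop[[which.max(fits)]]
      }
      history[[g]] <- tibble(generation = g, best = gen_best,
                             mean = mean(fits), best_ever = best_fit)
      elite_ix <- order(-fits)[seq_len(config$elitism)]
      nxt <- pop[elite_ix]
      while (length(nxt) < config$population_size) {
        pa <- pop[[tournament_select(fits)]]
        pb <- pop[[tournament_select(fits)]]
        off <- if (runif(1) < config$crossover_prob) {
          crossover_one_point(pa, pb)
        } else {
          list(pa, pb)
        }
        off <- lapply(off, mutate_bitflip, prob = pm)
        nxt <- c(nxt, off)
      }
      pop <- nxt[seq_len(config$population_size)]
    }
    # final evaluation so the last generation can still improve best-ever
    fits <- vapply(pop, cached_fitness, 0)
    if (max(fits) > best_fit) {
      best_fit <- max(fits)
      best_chrom <- pop[[which.max(fits)]]
    }
  })

  structure(list(
    best_chromosome = best_chrom,
    best_fitness = best_fit,
    selected_features = feats[best_chrom == 1],
    n_total = L,
    history = dplyr::bind_rows(history),
    config = config
  ), class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit> selected %d / %d features; best fitness %.2f after %d generations\n",
              length(x$selected_features), x$n_total, x$best_fitness,
              max(x$history$generation)))
  invisible(x)
}

#' @rdname run_ga
#' @param x A `ga_fit`.
#' @param ... Unused.
#' @export
tidy.ga_fit <- function(x, ...) x$history

#' @rdname run_ga
#' @export
glance.ga_fit <- function(x, ...) {
  tibble(n_selected = length(x$selected_features),
         n_total = x$n_total,
         reduction_percent = 100 * (1 - length(x$selected_features) / x$n_total),
         best_fitness = x$best_fitness,
         generations = max(x$history$generation))
}
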