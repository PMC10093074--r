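# Genetic-algorithm feature selection over fused feature tables.
#
# Chromosomes are feature bitmasks; fitness is the entropy-gated Gaussian
# NB cross-validated accuracy (nb_fitness). One generation: roulette-wheel
# parent selection (probability proportional to fitness, uniform fallback
# when every fitness is zero), uniform crossover, per-bit mutation, merge
# offspring with parents, sort by fitness and keep the top P with B elite
# parents guaranteed to survive unchanged.

#' GA configuration
#'
#' Defaults follow the published search settings: population 100, 500
#' iterations, mutation 0.001, crossover 0.8, elitism B = 6.
#'
#' @param population population size P.
#' @param max_iterations generation cap.
#' @param mutation_rate per-bit flip probability.
#' @param crossover_rate probability a parent pair recombines.
#' @param elitism number of top chromosomes B carried unchanged.
#' @param lambda Laplace smoothing constant for the NB fitness.
#' @param tau entropy gate threshold (nats). Default `log(10)`, the
#'   maximum attainable with 10 quantile bins — i.e. the gate only bites
#'   when lowered.
#' @param folds cross-validation folds in the fitness.
#' @param stagnation stop after this many generations without improvement.
#' @param seed integer seed.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population = 100L, max_iterations = 500L,
                      mutation_rate = 0.001, crossover_rate = 0.8,
                      elitism = 6L, lambda = 1, tau = log(10), folds = 3L,
                      stagnation = 50L, seed = 1L) {
  # B = P is allowed: the GA then produces no offspring and reduces to
  # evaluating the initial population (useful as a regression guard).
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            population >= elitism, elitism >= 0, tau > 0)
  structure(list(population = as.integer(population),
                 max_iterations = as.integer(max_iterations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elitism = as.integer(elitism), lambda = lambda, tau = tau,
                 folds = as.integer(folds),
                 stagnation = as.integer(stagnation),
                 seed = as.integer(seed)),
            class = "ga_config")
}

mask_key <- function(mask) paste(packBits(c(
  mask, rep(FALSE, (8L - length(mask) %% 8L) %% 8L)), "raw"), collapse = "")

ensure_nonempty <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
  mask
}

#' Genetic-algorithm feature selection
#'
#' Runs the GA described above and returns the best chromosome found.
#' When the final population is entirely gated to zero fitness, the mask
#' with the lowest pooled entropy is returned and flagged with a warning
#' attribute.
#'
#' @param table an `scnn_feature_table` with labels (>= 2 classes).
#' @param cfg a [ga_config()].
#' @return list with `best` (list `mask`, `fitness`), `selected` (feature
#'   indices of the best mask, in original table coordinates via
#'   `feature_order`), `history` (best fitness per generation),
#'   `generations`, `all_zero_fitness` flag.
#' @export
ga_select <- function(table, cfg = ga_config()) {
  stopifnot(inherits(table, "scnn_feature_table"))
  if (is.null(table$y) || nlevels(table$y) < 2L)
    scnn_error("scnn_config_error", "ga_select needs labels with >= 2 classes")
  L <- ncol(table$x)
  P <- cfg$population
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(mask) {
    key <- mask_key(mask)
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    f <- if (any(mask)) nb_fitness(table, mask, cfg) else 0
    assign(key, f, envir = cache)
    f
  }

  with_seed(derive_seed(cfg$seed, "ga"), {
    pop <- lapply(seq_len(P), function(i)
      ensure_nonempty(stats::runif(L) < 0.5))
    fit <- vapply(pop, fitness_of, numeric(1))
    history <- numeric(0)
    stagnant <- 0L
    best_so_far <- -Inf
    gen <- 0L
    while (gen < cfg$max_iterations && stagnant < cfg$stagnation) {
      gen <- gen + 1L
      # roulette wheel (uniform fallback when all fitness is zero)
      probs <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / P, P)
      n_off <- P - cfg$elitism
      offspring <- vector("list", n_off)
      i <- 1L
      while (i <= n_off) {
        pid <- sample.int(P, 2L, replace = TRUE, prob = probs)
        a <- pop[[pid[1]]]; b <- pop[[pid[2]]]
        if (stats::runif(1) < cfg$crossover_rate) {
          take_a <- stats::runif(L) < 0.5       # uniform crossover
          c1 <- ifelse(take_a, a, b)
          c2 <- ifelse(take_a, b, a)
        } else {
          c1 <- a; c2 <- b
        }
        for (child in list(c1, c2)) {
          if (i > n_off) break
          flip <- stats::runif(L) < cfg$mutation_rate
          child <- xor(child, flip)
          offspring[[i]] <- ensure_nonempty(child)
          i <- i + 1L
        }
      }
      off_fit <- vapply(offspring, fitness_of, numeric(1))
      # merge parents + offspring, sort by fitness, keep the top P.
      # Duplicate masks carry no information, so the truncation keeps
      # distinct chromosomes first (padding with the best when fewer than
      # P are distinct); parents surviving the merge subsume the B elites.
      merged <- c(pop, offspring)
      merged_fit <- c(fit, off_fit)
      keys <- vapply(merged, mask_key, character(1))
      keep <- order(merged_fit, decreasing = TRUE)
      keep <- keep[!duplicated(keys[keep])]
      if (length(keep) < P) keep <- c(keep, rep(keep[1], P - length(keep)))
      pop <- merged[keep[seq_len(P)]]
      fit <- merged_fit[keep[seq_len(P)]]
      history <- c(history, fit[1])
      if (fit[1] > best_so_far + 1e-12) {
        best_so_far <- fit[1]
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
    }
    all_zero <- all(fit == 0)
    best_idx <- if (all_zero) {
      ent <- vapply(pop, function(m) pooled_feature_entropy(table$x, m),
                    numeric(1))
      which.min(ent)
    } else which.max(fit)
    best <- list(mask = pop[[best_idx]], fitness = fit[best_idx])
    res <- list(best = best,
                selected = sort(table$feature_order[which(best$mask)]),
                history = history, generations = gen,
                all_zero_fitness = all_zero)
    if (all_zero)
      warning("GA: final population entirely entropy-gated; returning lowest-entropy mask")
    res
  })
}
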