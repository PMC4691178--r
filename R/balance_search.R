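#' Configuration for the balance-factor search
#'
#' Bundles the grid step of the greedy coordinate scan, the number of
#' greedy restarts (which is also the default genetic-algorithm population
#' size), and the GA operator rates. The defaults follow the search
#' protocol the pipeline is built around: a 0.01 grid scanned from 0 to 1
#' per coordinate and 50 greedy restarts forming the initial population.
#'
#' @param grid_step Grid step of the coordinate scan (default 0.01).
#' @param init_restarts Number of greedy restarts (default 50).
#' @param population_size GA population (default `init_restarts`).
#' @param generations Maximum GA generations (default 100).
#' @param crossover_rate,mutation_rate,mutation_sd Real-coded GA operator
#'   parameters.
#' @param elitism Number of best individuals copied unchanged (default 1).
#' @param stall Stop after this many generations without improvement
#'   (default 20).
#' @param seed Integer seed governing all randomness of the search.
#' @param fitness Function mapping a balance vector to the fitness error
#'   (1 - overall CV success rate); lower is better. See
#'   [make_cv_fitness()].
#' @return A `search_config` list.
#' @export
search_config <- function(grid_step = 0.01, init_restarts = 50L,
                          population_size = init_restarts,
                          generations = 100L, crossover_rate = 0.8,
                          mutation_rate = 0.1, mutation_sd = 0.05,
                          elitism = 1L, stall = 20L, seed = 1L,
                          fitness = NULL) {
  stopifnot(grid_step > 0, grid_step <= 0.5, init_restarts >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(grid_step = grid_step,
                 init_restarts = as.integer(init_restarts),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd,
                 elitism = as.integer(elitism),
                 stall = as.integer(stall),
                 seed = as.integer(seed),
                 fitness = fitness),
            class = "search_config")
}

#' Cross-validation fitness closure for the balance search
#'
#' Builds the fitness function the balance-factor search minimizes:
#' `1 - overall success rate` of candidate-class fused cosine-KNN under a
#' stratified K-fold partition that is drawn once (from `seed`) and then
#' frozen, so the search optimizes a deterministic function. Block Gram
#' matrices are precomputed once; each evaluation only rescales them, so a
#' fitness call costs O(N^2) arithmetic and never re-encodes.
#'
#' @param A,B Block matrices (rows = samples, aligned).
#' @param y Integer class codes.
#' @param K Folds inside the fitness (default 3; small for speed).
#' @param k KNN neighborhood size inside the fitness (default 1).
#' @param seed Seed for the frozen partition.
#' @param standardize Per-feature z-scoring of each block, fitted on the
#'   training rows of each frozen fold (default `FALSE`: blocks are used on
#'   their natural scales). Standardizing puts the two blocks on comparable
#'   scales, which makes intermediate balance factors effective; see the
#'   package vignette.
#' @param mode `"true-label"` (default): every sample, held-out ones
#'   included, is fused with its own class factor before the cosine — the
#'   weighting the fusion construction defines for labeled data, usable
#'   here because the search operates on a labeled training set.
#'   `"candidate-class"`: held-out samples are weighted label-free, as at
#'   prediction time (see [knn_predict_fused()]).
#' @return Function `f(R) -> fitness error in [0, 1]`.
#' @export
make_cv_fitness <- function(A, B, y, K = 3L, k = 1L, seed = 1L,
                            standardize = FALSE,
                            mode = c("true-label", "candidate-class")) {
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B); y <- as.integer(y)
  stopifnot(nrow(A) == nrow(B), nrow(A) == length(y))
  fold <- suppressWarnings(stratified_kfold(y, K, 1L, seed))[[1L]]
  N <- length(y)
  fold_ids <- sort(unique(fold))
  # per-fold Gram blocks; under standardization the scaling is fitted on
  # that fold's training rows only, so the grams differ per fold
  grams <- lapply(fold_ids, function(f) {
    train <- which(fold != f)
    Af <- if (standardize) zscore_by(A, train) else A
    Bf <- if (standardize) zscore_by(B, train) else B
    GA <- tcrossprod(Af)
    GB <- tcrossprod(Bf)
    list(GA = GA, GB = GB, dA = diag(GA), dB = diag(GB))
  })
  function(R) {
    check_balance(R)
    if (length(R) != max(y)) {
      stop("balance vector length ", length(R),
           " does not match the class count ", max(y))
    }
    correct <- 0L
    for (fi in seq_along(fold_ids)) {
      test <- which(fold == fold_ids[fi])
      train <- which(fold != fold_ids[fi])
      g <- grams[[fi]]
      rc <- R[y[train]]^2
      sc <- (1 - R[y[train]])^2
      tn <- sqrt(g$dA[train] * rc + g$dB[train] * sc)
      if (mode == "candidate-class") {
        # each train column j imposes its class weight on both sides of
        # the comparison
        num <- sweep(g$GA[test, train, drop = FALSE], 2L, rc, "*") +
          sweep(g$GB[test, train, drop = FALSE], 2L, sc, "*")
        qn <- sqrt(outer(g$dA[test], rc) + outer(g$dB[test], sc))
        sims <- num / (qn * rep(tn, each = length(test)))
      } else {
        # every sample weighted by its own class factor
        rq <- R[y[test]]
        sq <- 1 - R[y[test]]
        num <- (rq * g$GA[test, train, drop = FALSE]) %r% R[y[train]] +
          (sq * g$GB[test, train, drop = FALSE]) %r% (1 - R[y[train]])
        qn <- sqrt(rq^2 * g$dA[test] + sq^2 * g$dB[test])
        sims <- num / outer(qn, tn)
      }
      pred <- knn_vote(sims, y[train], min(k, length(train)))
      correct <- correct + sum(pred == y[test])
    }
    1 - correct / N
  }
}

# scale the columns of a matrix by a vector
`%r%` <- function(M, v) sweep(M, 2L, v, "*")

# z-score all rows of X by the mean/sd of the rows indexed by `train`;
# features constant on the training rows keep scale 1
zscore_by <- function(X, train) {
  mu <- colMeans(X[train, , drop = FALSE])
  sd <- apply(X[train, , drop = FALSE], 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sd, "/")
}

#' Greedy initial population for the balance-factor search
#'
#' Produces `config$init_restarts` balance vectors, each by one greedy
#' pass: draw a random permutation of the n coordinates, start every
#' factor at 0.5, then visit the coordinates in that order, scanning each
#' over the grid 0, 0.01, ..., 1 (endpoints clamped to the open interval
#' at 1e-6) and keeping the value with the lowest fitness error (highest
#' prediction accuracy). Deterministic given `config$seed`.
#'
#' @param n Number of classes (length of each balance vector).
#' @param config A [search_config()] whose `fitness` is set.
#' @return List of `init_restarts` numeric balance vectors, each carrying
#'   attributes `fitness` and `provenance = "greedy-init"`.
#' @export
greedy_init <- function(n, config) {
  stopifnot(inherits(config, "search_config"), n >= 2L)
  fitness <- config$fitness
  if (is.null(fitness)) stop("config$fitness must be set")
  eps <- 1e-6
  grid <- seq(0, 1, by = config$grid_step)
  grid <- pmin(pmax(grid, eps), 1 - eps)
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  lapply(seq_len(config$init_restarts), function(rep) {
    ord <- sample.int(n)
    R <- rep(0.5, n)
    f_cur <- fitness(R)
    for (i in ord) {
      vals <- vapply(grid, function(g) {
        Rg <- R
        Rg[i] <- g
        fitness(Rg)
      }, numeric(1))
      best <- which.min(vals)
      R[i] <- grid[best]
      f_cur <- vals[best]
    }
    structure(R, fitness = f_cur, provenance = "greedy-init")
  })
}

#' Genetic-algorithm refinement of balance vectors
#'
#' Real-coded GA over balance vectors: tournament selection (size 2),
#' arithmetic crossover (`child = beta * p1 + (1 - beta) * p2`, beta
#' uniform), additive Gaussian mutation reflected back into the open unit
#' interval, and generational replacement with elitism, stopping at
#' `config$generations` or after `config$stall` generations without
#' improvement. The best-so-far fitness never worsens.
#'
#' @param initial_population List of balance vectors (e.g. from
#'   [greedy_init()]).
#' @param config A [search_config()] with `fitness` set.
#' @return A `search_result` list: `best_R` (with
#'   `provenance = "ga-optimized"`), `best_fitness`, `history` (data frame
#'   generation/best/mean/evaluations) and `evaluations`.
#' @export
ga_optimize <- function(initial_population, config) {
  stopifnot(inherits(config, "search_config"),
            length(initial_population) >= 1L)
  fitness <- config$fitness
  if (is.null(fitness)) stop("config$fitness must be set")
  eps <- 1e-6
  n <- length(initial_population[[1L]])
  pop_size <- max(config$population_size, 2L)
  old <- local_seed(config$seed + 1L)
  on.exit(restore_seed(old))
  # seed the population from the initializer, recycling if undersized
  pop <- lapply(seq_len(pop_size), function(i) {
    as.numeric(initial_population[[((i - 1L) %% length(initial_population)) + 1L]])
  })
  fit <- vapply(pop, fitness, numeric(1))
  evals <- length(pop)
  best_idx <- which.min(fit)
  best_R <- pop[[best_idx]]
  best_fit <- fit[best_idx]
  history <- data.frame(generation = 0L, best = best_fit,
                        mean = mean(fit), evaluations = evals)
  stall <- 0L
  for (gen in seq_len(config$generations)) {
    elite_idx <- order(fit)[seq_len(min(config$elitism, pop_size))]
    children <- pop[elite_idx]
    while (length(children) < pop_size) {
      p1 <- pop[[tournament(fit)]]
      p2 <- pop[[tournament(fit)]]
      child <- if (stats::runif(1) < config$crossover_rate) {
        beta <- stats::runif(1)
        beta * p1 + (1 - beta) * p2
      } else {
        p1
      }
      mut <- stats::runif(n) < config$mutation_rate
      if (any(mut)) {
        child[mut] <- child[mut] + stats::rnorm(sum(mut),
                                                sd = config$mutation_sd)
        child <- reflect_unit(child, eps)
      }
      children[[length(children) + 1L]] <- child
    }
    pop <- children
    fit <- vapply(pop, fitness, numeric(1))
    evals <- evals + pop_size
    gen_best <- min(fit)
    if (gen_best < best_fit) {
      best_fit <- gen_best
      best_R <- pop[[which.min(fit)]]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history <- rbind(history,
                     data.frame(generation = gen, best = best_fit,
                                mean = mean(fit), evaluations = evals))
    if (stall >= config$stall) break
  }
  structure(list(best_R = structure(best_R, fitness = best_fit,
                                    provenance = "ga-optimized"),
                 best_fitness = best_fit, history = history,
                 evaluations = evals),
            class = "search_result")
}

# size-2 tournament on fitness errors (lower wins)
tournament <- function(fit) {
  i <- sample.int(length(fit), 2L, replace = TRUE)
  i[which.min(fit[i])]
}

# reflect into [eps, 1 - eps]; repeated until inside (then clamped for
# pathological magnitudes)
reflect_unit <- function(x, eps) {
  lo <- eps
  hi <- 1 - eps
  for (it in 1:50) {
    below <- x < lo
    above <- x > hi
    if (!any(below | above)) break
    x[below] <- 2 * lo - x[below]
    x[above] <- 2 * hi - x[above]
  }
  pmin(pmax(x, lo), hi)
}

#' Pick the final balance vector from several search results
#'
#' Returns the `best_R` with minimum `best_fitness`; ties are broken by
#' the lower evaluation count, then by the lexicographically smaller
#' vector.
#'
#' @param results List of `search_result` objects.
#' @return The selected balance vector.
#' @export
select_final_R <- function(results) {
  if (length(results) == 0L) stop("no search results supplied")
  fit <- vapply(results, `[[`, numeric(1), "best_fitness")
  evals <- vapply(results, `[[`, numeric(1), "evaluations")
  cand <- which(fit == min(fit))
  if (length(cand) > 1L) cand <- cand[evals[cand] == min(evals[cand])]
  if (length(cand) > 1L) {
    Rs <- lapply(results[cand], function(r) as.numeric(r$best_R))
    ord <- do.call(order, as.data.frame(do.call(rbind, Rs)))
    cand <- cand[ord[1L]]
  }
  results[[cand[1L]]]$best_R
}

#' Full balance-factor optimization
#'
#' Convenience wrapper running the greedy initializer, then the GA seeded
#' with the full greedy population, as one search.
#'
#' @param A,B Block matrices.
#' @param y Integer class codes.
#' @param config A [search_config()]; its `fitness`, if unset, defaults to
#'   [make_cv_fitness()] on `A`, `B`, `y`.
#' @param cv_K,cv_k Folds and neighborhood size of the default fitness.
#' @param standardize,mode Passed to [make_cv_fitness()].
#' @return A `search_result` (see [ga_optimize()]).
#' @export
optimize_balance <- function(A, B, y, config = search_config(),
                             cv_K = 3L, cv_k = 1L, standardize = FALSE,
                             mode = "true-label") {
  if (is.null(config$fitness)) {
    config$fitness <- make_cv_fitness(A, B, y, K = cv_K, k = cv_k,
                                      seed = config$seed,
                                      standardize = standardize,
                                      mode = mode)
  }
  init <- greedy_init(max(y), config)
  ga_optimize(init, config)
}

#' Write a search history as TSV
#'
#' @param result A `search_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_search_trace <- function(result, path) {
  utils::write.table(result$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
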