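# closed-form separable fitness with known optimum (0.8, 0.3)
quad_fitness <- function(R) (R[1] - 0.8)^2 + (R[2] - 0.3)^2

test_that("greedy initializer lands within one grid step of a separable optimum", {
  cfg <- search_config(init_restarts = 6, seed = 4, fitness = quad_fitness)
  pop <- greedy_init(2, cfg)
  expect_length(pop, 6L)
  for (R in pop) {
    expect_lte(abs(R[1] - 0.8), 0.01 + 1e-9)
    expect_lte(abs(R[2] - 0.3), 0.01 + 1e-9)
    expect_true(all(R > 0 & R < 1))
    expect_equal(attr(R, "provenance"), "greedy-init")
  }
  # brute-force the per-coordinate grid optimum as an independent check
  grid <- pmin(pmax(seq(0, 1, 0.01), 1e-6), 1 - 1e-6)
  expect_equal(pop[[1]][1], grid[which.min((grid - 0.8)^2)])
  expect_equal(pop[[1]][2], grid[which.min((grid - 0.3)^2)])
})

test_that("the default configuration emits 50 greedy balance vectors", {
  cfg <- search_config(seed = 1, fitness = quad_fitness)
  expect_equal(cfg$init_restarts, 50L)
  expect_equal(cfg$grid_step, 0.01)
  pop <- greedy_init(2, cfg)
  expect_length(pop, 50L)
})

test_that("greedy scans depend only on the seed", {
  cfg <- search_config(init_restarts = 3, seed = 11, fitness = quad_fitness)
  expect_identical(greedy_init(2, cfg), greedy_init(2, cfg))
  cfg2 <- search_config(init_restarts = 3, seed = 12,
                        fitness = quad_fitness)
  expect_false(identical(attr(greedy_init(3, cfg)[[1]], "fitness"),
                         NULL))
})

test_that("GA refines toward the optimum and never regresses", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- search_config(init_restarts = 8, generations = 30, seed = s,
                         fitness = quad_fitness)
    pop <- greedy_init(2, cfg)
    best_init <- min(vapply(pop, attr, numeric(1), "fitness"))
    res <- ga_optimize(pop, cfg)
    expect_lte(res$best_fitness, best_init + 1e-12)
    expect_true(all(diff(res$history$best) <= 1e-15))
    if (max(abs(as.numeric(res$best_R) - c(0.8, 0.3))) <= 0.02) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)   # >= 95% of the 20 seeded runs
})

test_that("a variation-free GA keeps a uniform population constant", {
  cfg <- search_config(init_restarts = 4, population_size = 4,
                       generations = 10, crossover_rate = 0,
                       mutation_rate = 0, seed = 2,
                       fitness = quad_fitness)
  pop <- replicate(4, c(0.6, 0.4), simplify = FALSE)
  res <- ga_optimize(pop, cfg)
  expect_true(all(res$history$best == res$history$best[1]))
  expect_true(all(res$history$mean == res$history$best[1]))
  expect_equal(as.numeric(res$best_R), c(0.6, 0.4))
})

test_that("GA results are reproducible given the seed", {
  cfg <- search_config(init_restarts = 5, generations = 15, seed = 7,
                       fitness = quad_fitness)
  r1 <- ga_optimize(greedy_init(2, cfg), cfg)
  r2 <- ga_optimize(greedy_init(2, cfg), cfg)
  expect_identical(r1, r2)
})

test_that("final selection uses fitness, then evaluations, then lexicographic order", {
  mk <- function(R, fit, ev) {
    structure(list(best_R = R, best_fitness = fit, evaluations = ev,
                   history = NULL), class = "search_result")
  }
  res <- list(mk(c(0.5, 0.5), 0.3, 10), mk(c(0.2, 0.9), 0.2, 10),
              mk(c(0.4, 0.4), 0.25, 5))
  expect_equal(as.numeric(select_final_R(res)), c(0.2, 0.9))
  expect_equal(as.numeric(select_final_R(res[1])), c(0.5, 0.5))
  tie <- list(mk(c(0.7, 0.1), 0.2, 10), mk(c(0.3, 0.9), 0.2, 10),
              mk(c(0.3, 0.8), 0.2, 20))
  expect_equal(as.numeric(select_final_R(tie)), c(0.3, 0.9))
  expect_error(select_final_R(list()), "no search results")
})

test_that("the CV fitness equals an explicit fold-by-fold reconstruction", {
  ds <- generate_synthetic(n_classes = 3L, per_class = 6L, seed = 30L)
  A <- encode_all(ds, "dipc")
  B <- encode_all(ds, "pssm")
  y <- unname(ds$labels)
  fit <- make_cv_fitness(A, B, y, K = 3, k = 1, seed = 9,
                         mode = "candidate-class")
  R <- c(0.7, 0.4, 0.2)
  # reconstruct with the generic (non-Gram) candidate-class path
  folds <- suppressWarnings(stratified_kfold(y, 3, 1, seed = 9))[[1]]
  correct <- 0L
  for (f in 1:3) {
    te <- which(folds == f); tr <- which(folds != f)
    out <- knn_predict_fused(A[tr, ], B[tr, ], y[tr], A[te, ], B[te, ],
                             R, k = 1)
    correct <- correct + sum(out$pred == y[te])
  }
  expect_equal(fit(R), 1 - correct / length(y), tolerance = 1e-12)
  expect_error(fit(c(0.5, 0.5)), "class count")
})
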