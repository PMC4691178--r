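test_that("metric formulas match hand-computed confusion tables", {
  # perfect 3-class prediction
  y <- rep(1:3, each = 5)
  m <- compute_metrics(y, y, 3)
  expect_equal(m$per_class$SE, rep(1, 3))
  expect_equal(m$per_class$SP, rep(1, 3))
  expect_equal(m$per_class$ACC, rep(1, 3))
  expect_equal(m$per_class$MCC, rep(1, 3))
  expect_equal(m$overall, 1)

  # binary total disagreement: MCC = -1 for both classes
  yb <- rep(1:2, each = 10)
  flip <- 3L - yb
  mf <- compute_metrics(yb, flip, 2)
  expect_equal(mf$per_class$MCC, c(-1, -1))
  expect_equal(mf$overall, 0)

  # balanced random: TP = TN = FP = FN = 25 per class
  tr <- rep(1:2, each = 50)
  pr <- rep(rep(1:2, each = 25), 2)
  mr <- compute_metrics(tr, pr, 2)
  expect_equal(mr$per_class$TP, c(25L, 25L))
  expect_equal(mr$per_class$MCC, c(0, 0))
  expect_equal(mr$per_class$ACC, c(0.5, 0.5))

  # enumerated 3-class table: class 1 has TP=8, FN=2, FP=1, TN=19 (N=30)
  true <- c(rep(1L, 10), rep(2L, 10), rep(3L, 10))
  pred <- c(rep(1L, 8), 2L, 3L,        # 8 hits, 2 misses for class 1
            1L, rep(2L, 9),            # one class-2 sample predicted 1
            rep(3L, 10))
  m3 <- compute_metrics(true, pred, 3)
  expect_equal(m3$per_class$TP[1], 8L)
  expect_equal(m3$per_class$TN[1], 19L)
  expect_equal(m3$per_class$SE[1], 0.8)
  expect_equal(m3$per_class$SP[1], 0.95)
  expect_equal(m3$per_class$ACC[1], 0.9)
  # hand evaluation: (8*19 - 1*2) / sqrt(9 * 10 * 20 * 21)
  expect_equal(m3$per_class$MCC[1], 150 / sqrt(37800), tolerance = 1e-12)
  expect_equal(m3$overall, 27 / 30)
  expect_equal(sum(m3$per_class$TP), 27L)

  expect_error(compute_metrics(c(1, 4), c(1, 1), 3), "1..3")
})

test_that("stratified folds preserve class proportions deterministically", {
  y <- rep(1:2, each = 50)
  folds <- stratified_kfold(y, K = 10, repeats = 1, seed = 3)[[1]]
  for (f in 1:10) {
    expect_equal(sum(folds == f & y == 1), 5L)
    expect_equal(sum(folds == f & y == 2), 5L)
  }
  reps <- stratified_kfold(y, K = 10, repeats = 50, seed = 3)
  expect_length(reps, 50L)
  expect_gt(length(unique(vapply(reps, paste, character(1),
                                 collapse = ","))), 1L)
  expect_identical(stratified_kfold(y, 10, 2, seed = 9),
                   stratified_kfold(y, 10, 2, seed = 9))
  # uneven classes: per-class fold counts differ by at most one
  yu <- rep(1:3, c(7, 11, 23))
  fu <- stratified_kfold(yu, K = 5, seed = 1)[[1]]
  for (cl in 1:3) {
    cnt <- table(factor(fu[yu == cl], levels = 1:5))
    expect_lte(max(cnt) - min(cnt), 1L)
  }
  expect_warning(stratified_kfold(rep(1:2, c(3, 40)), K = 5, seed = 1),
                 "best-effort")
  expect_error(stratified_kfold(y, K = 1), ">= 2")
})

test_that("cross-validation is deterministic and reports the scanned k", {
  ds <- generate_synthetic(n_classes = 3L, per_class = 8L, seed = 20L)
  X <- encode_all(ds, "pssm")
  r1 <- cross_validate(X, ds$labels, K = 4, repeats = 2, k_grid = 1:5,
                       seed = 6)
  r2 <- cross_validate(X, ds$labels, K = 4, repeats = 2, k_grid = 1:5,
                       seed = 6)
  expect_identical(r1, r2)
  expect_true(r1$best_k %in% 1:5)
  expect_equal(dim(r1$overall_by_k), c(2L, 5L))
  expect_equal(r1$overall_mean, mean(r1$overall_by_k[, paste0("k", r1$best_k)]))
  # per-class sensitivity equals the per-class success rate on pooled labels
  expect_equal(r1$metrics$per_class$SE,
               r1$metrics$per_class$TP / (r1$metrics$per_class$TP +
                                          r1$metrics$per_class$FN))
})

test_that("K = N cross-validation equals the jackknife", {
  ds <- generate_synthetic(n_classes = 2L, per_class = 6L, seed = 21L)
  X <- encode_all(ds, "dipc")
  N <- nrow(X)
  jk <- jackknife(X, ds$labels, k_grid = 1:3)
  cv <- suppressWarnings(
    cross_validate(X, ds$labels, K = N, repeats = 1, k_grid = 1:3,
                   seed = 99))
  expect_equal(jk$metrics$per_class[, c("TP", "TN", "FP", "FN")],
               cv$metrics$per_class[, c("TP", "TN", "FP", "FN")])
  expect_identical(jk, jackknife(X, ds$labels, k_grid = 1:3))
  expect_equal(jk$config$K, N)
})

test_that("trainable stages never see held-out rows", {
  ds <- generate_synthetic(n_classes = 3L, per_class = 6L, seed = 22L)
  A <- encode_all(ds, "dipc")
  B <- encode_all(ds, "pssm")
  y <- unname(ds$labels)
  train <- which(seq_along(y) %% 3 != 0)
  test <- setdiff(seq_along(y), train)
  R <- rep(0.5, 3)
  sims1 <- subnucfuse:::fold_similarities(list(A = A, B = B), y, train,
                                          test, R, "max", TRUE, TRUE)
  # corrupt the held-out rows: fitted stages and the training-side geometry
  # must be unchanged, so held-out similarities change only through the
  # corrupted query itself
  A2 <- A; B2 <- B
  A2[test[1], ] <- A2[test[1], ] + 100
  sims2 <- subnucfuse:::fold_similarities(list(A = A2, B = B2), y, train,
                                          test, R, "max", TRUE, TRUE)
  expect_equal(sims1$sims[-1, ], sims2$sims[-1, ])
  expect_false(isTRUE(all.equal(sims1$sims[1, ], sims2$sims[1, ])))
})

test_that("metrics reports serialize as TSV", {
  ds <- generate_synthetic(n_classes = 2L, per_class = 5L, seed = 23L)
  X <- encode_all(ds, "pssm")
  r <- cross_validate(X, ds$labels, K = 2, repeats = 1, k_grid = 1,
                      seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_tsv(r, f)
  lines <- readLines(f)
  expect_match(lines[1], "best_k=1")
  expect_match(lines[length(lines)], "^overall\t")
})
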