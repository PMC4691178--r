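#' Per-class and overall classification metrics
#'
#' From pooled true and predicted class codes, computes one-vs-rest
#' confusion counts per class and the four standard indexes:
#' sensitivity `SE = TP / (TP + FN)` (identical to the per-class success
#' rate `T(i) / N(i)`), specificity `SP = TN / (TN + FP)`, accuracy
#' `ACC = (TP + TN) / (TP + FP + TN + FN)` and the Matthews correlation
#' coefficient
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' reported as 0 when its denominator vanishes. The overall success rate is
#' `sum_i T(i) / sum_i N(i)`.
#'
#' @param true,pred Equal-length integer class codes in 1..n.
#' @param n Number of classes.
#' @return A `snf_metrics` list: `per_class` (data frame with counts and
#'   SE/SP/ACC/MCC), `overall` (overall success rate), `n_samples`.
#' @export
compute_metrics <- function(true, pred, n) {
  true <- as.integer(true); pred <- as.integer(pred)
  stopifnot(length(true) == length(pred))
  if (any(true < 1L | true > n) || any(pred < 1L | pred > n)) {
    stop("labels must lie in 1..", n)
  }
  N <- length(true)
  per <- data.frame(class = seq_len(n), TP = NA_integer_, TN = NA_integer_,
                    FP = NA_integer_, FN = NA_integer_, SE = NA_real_,
                    SP = NA_real_, ACC = NA_real_, MCC = NA_real_)
  for (i in seq_len(n)) {
    tp <- sum(true == i & pred == i)
    fn <- sum(true == i & pred != i)
    fp <- sum(true != i & pred == i)
    tn <- N - tp - fn - fp
    per$TP[i] <- tp; per$TN[i] <- tn; per$FP[i] <- fp; per$FN[i] <- fn
    per$SE[i] <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    per$SP[i] <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
    per$ACC[i] <- (tp + tn) / N
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    per$MCC[i] <- if (den == 0) 0 else ((as.numeric(tp) * tn) - (as.numeric(fp) * fn)) / den
  }
  structure(list(per_class = per,
                 overall = sum(true == pred) / N,
                 n_samples = N),
            class = "snf_metrics")
}

#' @export
print.snf_metrics <- function(x, digits = 4, ...) {
  cat("Per-class metrics (", x$n_samples, " samples):\n", sep = "")
  print(cbind(x$per_class[, 1:5],
              round(x$per_class[, 6:9], digits)), row.names = FALSE)
  cat(sprintf("Overall success rate: %.4f\n", x$overall))
  invisible(x)
}

#' Stratified K-fold partitions
#'
#' Randomly partitions samples into K folds that preserve the class
#' proportions: within every class, fold counts differ by at most one.
#' `repeats` independent partitions are drawn; the whole draw is
#' deterministic given `seed`.
#'
#' @param y Integer class codes.
#' @param K Number of folds (>= 2; classes smaller than K trigger a
#'   warning and best-effort stratification).
#' @param repeats Number of independent partitions.
#' @param seed Integer seed.
#' @return List of `repeats` integer vectors of fold assignments in 1..K.
#' @export
stratified_kfold <- function(y, K, repeats = 1L, seed = 1L) {
  y <- as.integer(y)
  if (K < 2L) stop("K must be >= 2")
  if (K > length(y)) stop("K cannot exceed the sample count")
  sizes <- table(y)
  if (any(sizes < K)) {
    warning("class(es) smaller than K = ", K,
            "; stratification is best-effort")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lapply(seq_len(repeats), function(rep) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(K), length.out = length(idx)))
    }
    fold
  })
}

#' Cross-validated evaluation of a localization pipeline
#'
#' Repeated stratified K-fold cross-validation of the
#' encode-fuse-reduce-classify pipeline. Per repeat and fold, every
#' trainable stage (the LDA projection and, for fused features, the
#' true-label fusion) is fitted on the training folds only; the held-out
#' fold is predicted label-free (candidate-class fusion) and predictions
#' are pooled over folds. The KNN neighborhood size is chosen by scanning
#' `k_grid` and keeping the k with the highest mean overall success rate
#' across repeats.
#'
#' @param features Either a numeric matrix (single representation) or a
#'   list `list(A = , B = )` of two block matrices to be fused with `R`.
#' @param y Integer class codes aligned with the feature rows.
#' @param R Balance vector (required when `features` is a block pair).
#' @param K Folds (default 10).
#' @param repeats Repeated random partitions averaged over (default 5).
#' @param k_grid Candidate KNN neighborhood sizes (default 1..10).
#' @param lda_dim `NULL` for no reduction, `"max"` for C - 1, or an
#'   integer.
#' @param standardize Per-feature z-scoring fitted on the training folds
#'   only (default `FALSE`: natural feature scales).
#' @param seed Integer seed governing the partitions.
#' @return A list: `best_k`, `metrics` (a `snf_metrics` whose per-class
#'   values are averaged over repeats at `best_k`), `overall_by_k`
#'   (repeats x k matrix), `overall_mean`, `overall_se`, `config`.
#' @export
cross_validate <- function(features, y, R = NULL, K = 10L, repeats = 5L,
                           k_grid = 1:10, lda_dim = NULL, seed = 1L,
                           standardize = FALSE) {
  y <- as.integer(y)
  folds <- stratified_kfold(y, K, repeats, seed)
  cv_core(features, y, folds, R, k_grid, lda_dim, standardize,
          config = list(K = K, repeats = repeats, k_grid = k_grid,
                        lda_dim = lda_dim, standardize = standardize,
                        seed = seed))
}

#' Jackknife (leave-one-out) evaluation
#'
#' The K = N case of [cross_validate()]: every sample is held out once, so
#' the result is deterministic for a given dataset.
#'
#' @inheritParams cross_validate
#' @return As [cross_validate()].
#' @export
jackknife <- function(features, y, R = NULL, k_grid = 1:10,
                      lda_dim = NULL, standardize = FALSE) {
  y <- as.integer(y)
  if (length(y) < 3L) stop("jackknife needs N >= 3")
  cv_core(features, y, list(seq_along(y)), R, k_grid, lda_dim, standardize,
          config = list(K = length(y), repeats = 1L, k_grid = k_grid,
                        lda_dim = lda_dim, standardize = standardize,
                        protocol = "jackknife"))
}

# shared fold loop for cross_validate / jackknife
cv_core <- function(features, y, folds, R, k_grid, lda_dim, standardize,
                    config) {
  fused <- is.list(features) && !is.null(features$A)
  if (fused && is.null(R)) stop("fused features require a balance vector R")
  N <- length(y)
  n_class <- max(y)
  k_grid <- as.integer(k_grid)
  overall_by_k <- matrix(NA_real_, length(folds), length(k_grid),
                         dimnames = list(NULL, paste0("k", k_grid)))
  pred_store <- vector("list", length(folds))
  for (repi in seq_along(folds)) {
    fold <- folds[[repi]]
    preds <- matrix(NA_integer_, N, length(k_grid))
    for (f in sort(unique(fold))) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (max(k_grid) > length(train)) {
        stop("fold ", f, ": k = ", max(k_grid),
             " exceeds the training size ", length(train))
      }
      sims_y <- fold_similarities(features, y, train, test, R, lda_dim,
                                  standardize, fused)
      for (j in seq_along(k_grid)) {
        preds[test, j] <- knn_vote(sims_y$sims, sims_y$train_y, k_grid[j])
      }
    }
    for (j in seq_along(k_grid)) {
      overall_by_k[repi, j] <- mean(preds[, j] == y)
    }
    pred_store[[repi]] <- preds
  }
  mean_by_k <- colMeans(overall_by_k)
  best_j <- which.max(mean_by_k)  # ties: smaller k (first index)
  best_k <- k_grid[best_j]
  reports <- lapply(pred_store, function(p) {
    compute_metrics(y, p[, best_j], n_class)
  })
  avg <- reports[[1L]]
  if (length(reports) > 1L) {
    for (col in c("TP", "TN", "FP", "FN", "SE", "SP", "ACC", "MCC")) {
      avg$per_class[[col]] <- rowMeans(
        vapply(reports, function(r) as.numeric(r$per_class[[col]]),
               numeric(n_class)))
    }
    avg$overall <- mean(vapply(reports, `[[`, numeric(1), "overall"))
  }
  se <- if (nrow(overall_by_k) > 1L) {
    stats::sd(overall_by_k[, best_j]) / sqrt(nrow(overall_by_k))
  } else {
    0
  }
  list(best_k = best_k, metrics = avg, overall_by_k = overall_by_k,
       overall_mean = mean_by_k[[best_j]], overall_se = se,
       config = config)
}

# fit trainable stages on the training rows only; return test-vs-train
# similarities
fold_similarities <- function(features, y, train, test, R, lda_dim,
                              standardize, fused) {
  if (fused) {
    A <- features$A; B <- features$B
    if (standardize) {
      A <- zscore_by(A, train)
      B <- zscore_by(B, train)
    }
    lda <- NULL
    if (!is.null(lda_dim)) {
      r_tr <- R[y[train]]
      Ftr <- cbind(A[train, , drop = FALSE] * r_tr,
                   B[train, , drop = FALSE] * (1 - r_tr))
      lda <- lda_fit(Ftr, y[train], m = lda_dim)
    }
    out <- knn_predict_fused(A[train, , drop = FALSE],
                             B[train, , drop = FALSE], y[train],
                             A[test, , drop = FALSE],
                             B[test, , drop = FALSE], R,
                             k = 1L, lda = lda)
    list(sims = out$sims, train_y = y[train])
  } else {
    if (standardize) features <- zscore_by(features, train)
    Xtr <- features[train, , drop = FALSE]
    Xte <- features[test, , drop = FALSE]
    if (!is.null(lda_dim)) {
      lda <- lda_fit(Xtr, y[train], m = lda_dim)
      Xtr <- lda_transform(lda, Xtr)
      Xte <- lda_transform(lda, Xte)
    }
    list(sims = cosine_similarity(Xte, Xtr), train_y = y[train])
  }
}

#' Write a metrics report as TSV
#'
#' @param report Result of [cross_validate()] or [jackknife()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subnucfuse metrics; best_k=%d overall=%.6f",
                     report$best_k, report$metrics$overall), con)
  utils::write.table(report$metrics$per_class, con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("overall\t%.6f", report$metrics$overall), con)
  invisible(path)
}

# seed helpers: run under a fixed seed, then restore the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
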