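#' Cosine similarity between the rows of two matrices
#'
#' `cos(u, v) = u . v / (||u|| ||v||)`, in [-1, 1]; the measure the KNN
#' classifier ranks neighbors by.
#'
#' @param X,Y Numeric matrices with the same column count.
#' @return `nrow(X)` x `nrow(Y)` similarity matrix.
#' @export
cosine_similarity <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  nx <- sqrt(rowSums(X^2))
  ny <- sqrt(rowSums(Y^2))
  if (any(nx == 0) || any(ny == 0)) {
    stop("cosine similarity undefined for zero-norm vectors")
  }
  tcrossprod(X / nx, Y / ny)
}

#' Fit a cosine-KNN model
#'
#' Stores the training table verbatim; prediction ranks training samples by
#' cosine similarity and takes the majority label of the k most similar.
#'
#' @param X Numeric training matrix (no zero-norm rows).
#' @param y Integer class codes, length `nrow(X)`.
#' @param k Neighborhood size, `1 <= k <= nrow(X)`.
#' @return A `knn_model` list.
#' @export
knn_fit <- function(X, y, k = 1L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (k < 1L || k > nrow(X)) {
    stop("k must lie in 1..", nrow(X), "; got ", k)
  }
  zero <- which(rowSums(X^2) == 0)
  if (length(zero) > 0L) {
    stop("zero-norm training vector(s): row ",
         paste(zero, collapse = ", "))
  }
  structure(list(X = X, y = as.integer(y), k = as.integer(k)),
            class = "knn_model")
}

#' Predict labels with a cosine-KNN model
#'
#' @param model A `knn_model` from [knn_fit()].
#' @param Q Query matrix with `ncol(model$X)` columns.
#' @return Integer vector of predicted class codes.
#' @export
knn_predict <- function(model, Q) {
  Q <- as.matrix(Q)
  if (ncol(Q) != ncol(model$X)) {
    stop("query has ", ncol(Q), " features, model expects ", ncol(model$X))
  }
  sims <- cosine_similarity(Q, model$X)
  knn_vote(sims, model$y, model$k)
}

# Majority vote over a precomputed query x train similarity matrix.
# Deterministic tie rules: similarity ties at the k-boundary go to the
# smaller training index (stable order); vote ties go to the class with the
# larger summed similarity among its tied neighbors, then to the smaller
# class code.
knn_vote <- function(sims, train_y, k) {
  n_class <- max(train_y)
  apply(sims, 1L, function(s) {
    nb <- order(s, seq_along(s), decreasing = c(TRUE, FALSE),
                method = "radix")[seq_len(k)]
    votes <- tabulate(train_y[nb], nbins = n_class)
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      simsum <- vapply(top, function(cl) sum(s[nb][train_y[nb] == cl]),
                       numeric(1))
      top <- top[simsum == max(simsum)]
    }
    top[1L]
  })
}

#' Candidate-class fused KNN prediction
#'
#' Label-free prediction under per-class balance factors: when a query is
#' compared with a training sample of class c, both vectors are fused with
#' that class's factor `R[c]` (and, if an LDA model is supplied, projected)
#' before the cosine is taken, so every comparison happens in the candidate
#' class's weighted space. Training samples are fused with their own
#' (known) class factor.
#'
#' @param trainA,trainB Training block matrices.
#' @param train_y Integer training labels.
#' @param queryA,queryB Query block matrices.
#' @param R Balance vector, one factor per class.
#' @param k Neighborhood size.
#' @param lda An optional `lda_model` fitted on the true-label fused
#'   training table; when supplied, all fused vectors are projected through
#'   it before the cosine.
#' @return List with `pred` (integer labels) and `sims` (query x train
#'   similarity matrix).
#' @export
knn_predict_fused <- function(trainA, trainB, train_y, queryA, queryB, R,
                              k = 1L, lda = NULL) {
  stopifnot(nrow(trainA) == length(train_y))
  check_balance(R)
  r_tr <- R[train_y]
  Ftr <- cbind(trainA * r_tr, trainB * (1 - r_tr))
  Ptr <- if (is.null(lda)) Ftr else lda_transform(lda, Ftr)
  sims <- matrix(NA_real_, nrow(queryA), nrow(trainA))
  for (c in seq_along(R)) {
    idx <- which(train_y == c)
    if (length(idx) == 0L) next
    Fq <- cbind(queryA * R[c], queryB * (1 - R[c]))
    Pq <- if (is.null(lda)) Fq else lda_transform(lda, Fq)
    sims[, idx] <- cosine_similarity(Pq, Ptr[idx, , drop = FALSE])
  }
  list(pred = knn_vote(sims, train_y, k), sims = sims)
}

#' Write predictions as TSV
#'
#' @param ids Sample identifiers.
#' @param pred Predicted class codes.
#' @param truth Optional true class codes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(ids, pred, truth = NULL, path) {
  tab <- data.frame(id = ids, predicted = pred)
  if (!is.null(truth)) tab$true <- truth
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
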