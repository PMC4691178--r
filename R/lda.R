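#' Fit linear discriminant analysis by the generalized eigenproblem
#'
#' Maximizes the between-class over within-class scatter ratio
#' `J(W) = |W' S_B W| / |W' S_W W|` where
#' `S_W = sum_i sum_j (x_ij - mu_i)(x_ij - mu_i)'` and
#' `S_B = sum_i N_i (mu_i - mu)(mu_i - mu)'`. The columns of the projection
#' matrix solve `S_B w = lambda S_W w`, so at most C - 1 informative
#' components exist for C classes. The generalized problem is solved on the
#' symmetrized whitened form: eigendecompose the (possibly
#' ridge-regularized) `S_W`, whiten, and take the leading eigenvectors of
#' the whitened `S_B`.
#'
#' When the feature dimension exceeds the sample count — routine for the
#' 630D fused representation — `S_W` is singular; the default ridge policy
#' adds `1e-6 * trace(S_W) / d` to its diagonal before solving, and the
#' ridge actually used is recorded in the model.
#'
#' @param X Numeric N x d feature matrix.
#' @param y Integer class codes 1..C.
#' @param m Requested projection dimension, or `"max"` for
#'   `min(C - 1, rank(S_B))`.
#' @param ridge `"auto"` (default), `"off"`, or a nonnegative number added
#'   to the diagonal of `S_W`.
#' @return An `lda_model` list: `W` (d x m, columns of unit norm ordered by
#'   descending generalized eigenvalue, sign fixed so each column's
#'   largest-magnitude entry is positive), `eigenvalues`, `class_means`,
#'   `total_mean`, `ridge`, `C`, `d`.
#' @export
lda_fit <- function(X, y, m = "max", ridge = "auto") {
  X <- as.matrix(X)
  y <- as.integer(y)
  N <- nrow(X); d <- ncol(X)
  classes <- sort(unique(y))
  C <- length(classes)
  if (C < 2L) stop("LDA needs at least 2 classes")
  if (N < C) stop("LDA needs N >= C samples; got N = ", N, ", C = ", C)
  if (any(tabulate(y) == 1L)) {
    warning("singleton class(es) contribute nothing to the within-class scatter")
  }
  mu <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  class_means <- matrix(NA_real_, C, d)
  for (i in seq_len(C)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    mi <- colMeans(Xi)
    class_means[i, ] <- mi
    Xc <- sweep(Xi, 2L, mi)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  ridge_val <- if (identical(ridge, "auto")) {
    1e-6 * sum(diag(Sw)) / d
  } else if (identical(ridge, "off")) {
    0
  } else {
    stopifnot(is.numeric(ridge), ridge >= 0)
    ridge
  }
  ew <- eigen(Sw + diag(ridge_val, d), symmetric = TRUE)
  tol <- max(ew$values, 0) * d * .Machine$double.eps
  if (any(ew$values <= tol)) {
    stop("within-class scatter S_W is singular; the generalized ",
         "eigenproblem S_B w = lambda S_W w requires nonsingular S_W ",
         "(set ridge = \"auto\" or a positive value)")
  }
  # whitening transform S_W^{-1/2}
  Wi <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  S <- Wi %*% Sb %*% Wi
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  vals <- pmax(es$values, 0)
  rank_b <- sum(vals > max(vals, .Machine$double.eps) * 1e-9)
  m_max <- min(C - 1L, max(rank_b, 1L))
  m_out <- if (identical(m, "max")) m_max else min(as.integer(m), m_max)
  W <- Wi %*% es$vectors[, seq_len(m_out), drop = FALSE]
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(m_out)) {
    peak <- which.max(abs(W[, j]))
    if (W[peak, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(W = W, eigenvalues = vals[seq_len(m_out)],
                 class_means = class_means, total_mean = mu,
                 classes = classes, ridge = ridge_val,
                 C = C, d = d, m = m_out),
            class = "lda_model")
}

#' Project data through a fitted LDA model
#'
#' Applies the exact linear map `Y = W' X` (rows of `X` are samples).
#'
#' @param model An `lda_model` from [lda_fit()].
#' @param X Numeric matrix with `model$d` columns (or a single vector).
#' @return N x m matrix of projected coordinates.
#' @export
lda_transform <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop("input has ", ncol(X), " features, model expects ", model$d)
  }
  X %*% model$W
}

#' Serialize / restore an LDA model as plain text
#'
#' Writes the projection matrix, eigenvalues, means and ridge as a
#' tab-separated text bundle; projected coordinates for external plotting
#' can be produced with [lda_transform()] and [write_features_tsv()].
#'
#' @param model An `lda_model`.
#' @param path Output path.
#' @return `write_lda()` returns `path` invisibly; `read_lda()` the model.
#' @export
write_lda <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subnucfuse lda_model v%s",
                       as.character(utils::packageVersion("subnucfuse"))),
               sprintf("dims\t%d\t%d\t%d", model$d, model$m, model$C),
               sprintf("ridge\t%.17g", model$ridge),
               paste0("eigenvalues\t",
                      paste(sprintf("%.17g", model$eigenvalues),
                            collapse = "\t")),
               paste0("classes\t", paste(model$classes, collapse = "\t")),
               paste0("total_mean\t",
                      paste(sprintf("%.17g", model$total_mean),
                            collapse = "\t"))), con)
  for (i in seq_len(model$C)) {
    writeLines(paste0("class_mean\t",
                      paste(sprintf("%.17g", model$class_means[i, ]),
                            collapse = "\t")), con)
  }
  for (j in seq_len(model$m)) {
    writeLines(paste0("W\t",
                      paste(sprintf("%.17g", model$W[, j]),
                            collapse = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_lda
#' @export
read_lda <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, character(1), 1L)
  num <- function(f) as.numeric(f[-1L])
  dims <- as.integer(fields[[which(key == "dims")]][-1L])
  cm <- do.call(rbind, lapply(fields[key == "class_mean"], num))
  W <- do.call(cbind, lapply(fields[key == "W"], num))
  structure(list(W = W,
                 eigenvalues = num(fields[[which(key == "eigenvalues")]]),
                 class_means = cm,
                 total_mean = num(fields[[which(key == "total_mean")]]),
                 classes = as.integer(fields[[which(key == "classes")]][-1L]),
                 ridge = num(fields[[which(key == "ridge")]]),
                 d = dims[1L], m = dims[2L], C = dims[3L]),
            class = "lda_model")
}
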