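test_that("scatter matrices satisfy the total-scatter decomposition", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- sample(1:3, 40, replace = TRUE)
  model <- lda_fit(X, y, ridge = 0)
  # recompute S_W + S_B independently and compare with total scatter
  mu <- colMeans(X)
  St <- crossprod(sweep(X, 2, mu))
  Sw <- matrix(0, 6, 6); Sb <- matrix(0, 6, 6)
  for (c in 1:3) {
    Xi <- X[y == c, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  expect_lt(norm(Sw + Sb - St, "F") / norm(St, "F"), 1e-8)
  # the fitted projection solves the generalized eigenproblem on these
  for (j in seq_len(model$m)) {
    w <- model$W[, j]
    resid <- Sb %*% w - model$eigenvalues[j] * (Sw %*% w)
    expect_lt(sqrt(sum(resid^2)), 1e-6 * sqrt(sum((Sb %*% w)^2)))
  }
})

test_that("isotropic two-class problem projects onto the mean difference", {
  set.seed(10)
  mu1 <- c(3, -1)
  mu2 <- c(-2, 2)
  # symmetric point clouds => S_W proportional to the identity
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  X <- rbind(sweep(base, 2, mu1, "+"), sweep(base, 2, mu2, "+"))
  y <- rep(1:2, each = 4)
  model <- lda_fit(X, y)
  expect_equal(model$m, 1L)
  dirn <- (mu1 - mu2) / sqrt(sum((mu1 - mu2)^2))
  cosang <- abs(sum(model$W[, 1] * dirn))
  expect_gte(cosang, 0.999)
})

test_that("eigen solution matches an exhaustive 1-degree direction search", {
  set.seed(12)
  for (rep in 1:5) {
    X <- rbind(matrix(rnorm(30, 0, 1), 15, 2),
               sweep(matrix(rnorm(30, 0, 1.5), 15, 2), 2, c(3, 1), "+"))
    X[, 2] <- X[, 2] + 0.5 * X[, 1]   # correlated within-class scatter
    y <- rep(1:2, each = 15)
    model <- lda_fit(X, y)
    # brute force the generalized Rayleigh quotient over unit directions
    mu <- colMeans(X); Sw <- matrix(0, 2, 2); Sb <- matrix(0, 2, 2)
    for (c in 1:2) {
      Xi <- X[y == c, ]
      mi <- colMeans(Xi)
      Sw <- Sw + crossprod(sweep(Xi, 2, mi))
      Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
    }
    Swr <- Sw + diag(model$ridge, 2)
    angles <- seq(0, 179, by = 1) * pi / 180
    ratios <- sapply(angles, function(a) {
      d <- c(cos(a), sin(a))
      (d %*% Sb %*% d) / (d %*% Swr %*% d)
    })
    best <- angles[which.max(ratios)]
    fit_angle <- atan2(model$W[2, 1], model$W[1, 1]) %% pi
    delta <- min(abs(fit_angle - best), pi - abs(fit_angle - best))
    expect_lt(delta, 2 * pi / 180)
  }
})

test_that("projection dimension is capped at C - 1 and transform is linear", {
  ds <- generate_synthetic(n_classes = 9L, per_class = 3L, seed = 5L)
  X <- encode_all(ds, "pssm")
  model <- lda_fit(X, ds$labels, m = "max")
  expect_lte(model$m, 8L)
  expect_equal(model$m, 8L)    # distinct synthetic class means: full rank
  expect_lte(ncol(lda_transform(model, X)), 8L)
  expect_equal(lda_transform(model, rep(0, ncol(X))),
               matrix(0, 1, model$m))
  # requesting more than C - 1 still caps
  expect_equal(lda_fit(X, ds$labels, m = 20)$m, 8L)
})

test_that("singular within-class scatter errors without ridge, fits with it", {
  set.seed(14)
  X <- matrix(rnorm(8 * 30), 8, 30)   # d >> N: S_W singular
  y <- rep(1:2, each = 4)
  expect_error(lda_fit(X, y, ridge = "off"), "nonsingular")
  model <- lda_fit(X, y)              # auto ridge
  expect_gt(model$ridge, 0)
  expect_equal(model$m, 1L)
  # the ridge-regularized residual contract holds in high dimension
  mu <- colMeans(X); Sw <- matrix(0, 30, 30); Sb <- matrix(0, 30, 30)
  for (c in 1:2) {
    Xi <- X[y == c, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  w <- model$W[, 1]
  resid <- Sb %*% w -
    model$eigenvalues[1] * ((Sw + diag(model$ridge, 30)) %*% w)
  expect_lt(sqrt(sum(resid^2)), 1e-6 * sqrt(sum((Sb %*% w)^2)))
})

test_that("refitting on projected data cannot increase separation", {
  # exact (unregularized) fits: the leading generalized eigenvalue over a
  # projected subspace can never exceed the global one
  set.seed(16)
  ds <- generate_synthetic(n_classes = 3L, per_class = 8L, seed = 16L)
  X <- encode_all(ds, "pssm")[, 1:10]   # N > d so S_W is nonsingular
  m1 <- lda_fit(X, ds$labels, ridge = 0)
  Y <- lda_transform(m1, X)
  m2 <- lda_fit(Y, ds$labels, ridge = 0)
  expect_lte(m2$eigenvalues[1], m1$eigenvalues[1] * (1 + 1e-8))
})

test_that("LDA models serialize to text and back", {
  set.seed(18)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rep(1:2, each = 10)
  model <- lda_fit(X, y)
  f <- withr::local_tempfile()
  write_lda(model, f)
  back <- read_lda(f)
  expect_equal(back$W, model$W)
  expect_equal(back$eigenvalues, model$eigenvalues)
  expect_equal(back$ridge, model$ridge)
  expect_equal(lda_transform(back, X), lda_transform(model, X))
})
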