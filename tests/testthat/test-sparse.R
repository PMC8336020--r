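test_that("dense sPCA equals plain SVD and scores are orthogonal", {
  set.seed(31)
  X <- matrix(rnorm(240), 30, 8)
  f <- spca(X, ncomp = 3, keep = 8)
  sv <- svd(scale(X, scale = FALSE))
  for (j in 1:3) {
    expect_lt(min(max(abs(f$loadings[, j] - sv$v[, j])),
                  max(abs(f$loadings[, j] + sv$v[, j]))), 1e-6)
  }
  G <- crossprod(f$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(unname(colSums(f$loadings^2)), rep(1, 3), tolerance = 1e-9)
})

test_that("sPCA recovers a planted sparse support and keep = 1 picks the argmax", {
  set.seed(32)
  u <- rnorm(25)
  v <- numeric(12); v[c(2, 5, 7, 8, 11)] <- rnorm(5) + c(2, -2, 2, 2, -2)
  v <- v / sqrt(sum(v^2))
  X <- 5 * outer(u, v)
  f <- spca(X, ncomp = 1, keep = 5, center = FALSE)
  expect_setequal(which(abs(f$loadings[, 1]) > 0), c(2, 5, 7, 8, 11))
  f1 <- spca(X, ncomp = 1, keep = 1, center = FALSE)
  nz <- which(abs(f1$loadings[, 1]) > 0)
  expect_length(nz, 1)
  expect_equal(unname(nz),
               which.max(abs(crossprod(X, X %*% f1$loadings[, 1] /
                                         sqrt(sum((X %*% f1$loadings[, 1])^2))))))
  expect_error(spca(X, keep = 13), "exceeds")
})

test_that("loading cardinality never exceeds keep and columns stay unit-norm", {
  set.seed(33)
  for (keep in c(3, 7, 12)) {
    X <- matrix(rnorm(20 * 15), 20, 15)
    f <- spca(X, ncomp = 2, keep = keep)
    expect_true(all(colSums(abs(f$loadings) > 0) <= keep))
    expect_equal(unname(colSums(f$loadings^2)), c(1, 1), tolerance = 1e-9)
  }
})

test_that("dense sPLS reproduces the power-iteration PLS oracle and the X = Y identity", {
  set.seed(34)
  X <- matrix(rnorm(40 * 12), 40, 12)
  Y <- matrix(rnorm(40 * 4), 40, 4)
  f <- spls(X, Y, ncomp = 1, keep_x = 12)
  o <- pls_power_oracle(X, Y)
  expect_lt(min(max(abs(f$loadings[, 1] - o$u)), max(abs(f$loadings[, 1] + o$u))),
            1e-6)
  expect_lt(min(max(abs(f$y_loadings[, 1] - o$v)),
                max(abs(f$y_loadings[, 1] + o$v))), 1e-6)
  # X == Y: identical loadings, latent correlation 1
  fxy <- spls(X, X, ncomp = 1, keep_x = 12)
  expect_equal(fxy$loadings[, 1], fxy$y_loadings[, 1], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(abs(cor(fxy$scores[, 1], fxy$y_scores[, 1])), 1, tolerance = 1e-9)
})

test_that("sPLS selects the planted gene support driving a two-column response", {
  set.seed(35)
  n <- 40; p <- 200
  lat <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:5] <- 0.1 * X[, 1:5] + outer(lat, rep(1, 5))
  Y <- cbind(lat + rnorm(n, 0, 0.1), -lat + rnorm(n, 0, 0.1))
  f <- spls(X, Y, ncomp = 2, keep_x = 5)
  supp1 <- which(abs(f$loadings[, 1]) > 0)
  expect_setequal(supp1, 1:5)           # sensitivity 1.0 on component 1
  expect_error(spls(X, Y[1:10, ]), "share rows")
  expect_error(spls(X, Y, keep_x = p + 1), "exceeds")
})

test_that("the selected sPLS support is covariance-optimal on structured instances", {
  # exhaustive search over all cardinality-3 supports, p = 8; the
  # cross-covariance SVD restricted to the selected support must attain the
  # best support's leading singular value
  set.seed(36)
  for (rep in 1:5) {
    n <- 15; p <- 8; q <- 3
    lat <- rnorm(n)
    X <- matrix(rnorm(n * p, 0, 0.3), n, p)
    X[, 1:3] <- X[, 1:3] + outer(lat, c(1, 0.8, 0.9))
    Y <- matrix(rnorm(n * q, 0, 0.3), n, q)
    Y[, 1] <- Y[, 1] + lat
    f <- spls(X, Y, ncomp = 1, keep_x = 3)
    M <- crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE))
    supp <- which(abs(f$loadings[, 1]) > 0)
    best <- max(vapply(combn(p, 3, simplify = FALSE),
                       function(S) svd(M[S, , drop = FALSE])$d[1], numeric(1)))
    expect_gte(svd(M[supp, , drop = FALSE])$d[1], best - 1e-8)
  }
})

test_that("dense components agree with mixOmics canonical sPLS", {
  set.seed(37)
  X <- matrix(rnorm(30 * 10), 30, 10)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  f <- spls(X, Y, ncomp = 1, keep_x = 10, scale = TRUE)
  mo <- mixOmics::spls(X, Y, ncomp = 1, keepX = 10, mode = "canonical",
                       scale = TRUE)
  expect_gt(abs(cor(f$loadings[, 1], mo$loadings$X[, 1])), 1 - 1e-6)
})

test_that("bootstrap consolidation gives frequency 1 to a noiseless support and respects the cutoff", {
  set.seed(38)
  u <- rnorm(30)
  v <- numeric(20); v[c(1, 4, 9, 13, 18)] <- c(1, -1, 1, 1, -1)
  X <- outer(u, v)
  colnames(X) <- paste0("g", 1:20)
  bc <- bootstrap_consolidate(X, ncomp = 1, keep = 5, n_boot = 20, seed = 1)
  act <- paste0("g", c(1, 4, 9, 13, 18))
  expect_equal(bc$selection_freq$freq[bc$selection_freq$variable %in% act],
               rep(1, 5))
  expect_setequal(bc$retained, act)
  # cutoff 0 retains everything ever selected; retained set shrinks with cutoff
  set.seed(39)
  Xn <- matrix(rnorm(25 * 40), 25, 40, dimnames = list(NULL, paste0("n", 1:40)))
  b0 <- bootstrap_consolidate(Xn, ncomp = 1, keep = 5, n_boot = 15,
                              cutoff = 0, seed = 2)
  expect_setequal(b0$retained,
                  b0$selection_freq$variable[b0$selection_freq$freq > 0])
  for (cut in c(0.1, 0.3, 0.6)) {
    bc2 <- suppressWarnings(
      bootstrap_consolidate(Xn, ncomp = 1, keep = 5, n_boot = 15,
                            cutoff = cut, seed = 2))
    expect_true(all(bc2$retained %in% b0$retained))
    expect_lte(length(bc2$retained), length(b0$retained))
    b0 <- bc2
  }
})

test_that("pure-noise bootstrap selection spreads thinly across many variables", {
  set.seed(40)
  X <- matrix(rnorm(30 * 500), 30, 500, dimnames = list(NULL, paste0("g", 1:500)))
  bc <- bootstrap_consolidate(X, ncomp = 2, keep = 50, n_boot = 50,
                              cutoff = 0.1, seed = 3)
  expect_gt(length(bc$retained), 50)    # far more than one fit's cardinality
  # per-iteration selection probability concentrates near keep * ncomp / p
  expect_lt(abs(mean(bc$selection_freq$freq) - 50 * 2 / 500), 0.1)
})

test_that("stratified resampling keeps every subject represented", {
  set.seed(41)
  X <- matrix(rnorm(24 * 30), 24, 30, dimnames = list(NULL, paste0("g", 1:30)))
  strata <- rep(paste0("P", 1:4), each = 6)
  bc <- bootstrap_consolidate(X, ncomp = 1, keep = 5, n_boot = 10,
                              strata = strata, seed = 4)
  expect_s3_class(bc$selection_freq, "tbl_df")
  expect_true(all(bc$selection_freq$freq >= 0 & bc$selection_freq$freq <= 1))
})
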