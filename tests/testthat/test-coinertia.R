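test_that("RV coefficient reproduces hand computations and detects homothety", {
  X <- matrix(c(1, -1, 0, 0), 2, 2)
  Y <- matrix(c(0, 0, 2, -2), 2, 2)
  expect_equal(rv_coefficient(X, Y), 1)          # proportional configurations
  X2 <- matrix(c(1, -1, 0), 3, 1)
  Y2 <- matrix(c(0, 1, -1), 3, 1)
  expect_equal(rv_coefficient(X2, Y2), 0.25)     # trace products 1, 4, 4
  set.seed(51)
  Z <- matrix(rnorm(30), 10, 3)
  expect_equal(rv_coefficient(Z, Z), 1, tolerance = 1e-12)
  expect_error(rv_coefficient(Z, matrix(0, 10, 2)), "zero-inertia")
})

test_that("RV is invariant under orthogonal rotation of a block", {
  set.seed(52)
  X <- matrix(rnorm(40), 10, 4)
  Y <- matrix(rnorm(30), 10, 3)
  base <- rv_coefficient(X, Y)
  for (rep in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    expect_equal(rv_coefficient(X %*% Q, Y), base, tolerance = 1e-12)
  }
})

test_that("coinertia of a block with itself returns its PCA eigenvalues, and the cross-table SVD is exact", {
  set.seed(53)
  X <- matrix(rnorm(40), 8, 5)
  tx <- as_triplet(X)
  coi <- coinertia_fit(tx, tx)
  pca <- pca_triplet(tx)
  expect_equal(coi$singular_values[1:5], pca$eigenvalues[1:5], tolerance = 1e-9)
  expect_equal(coi$rv, 1, tolerance = 1e-12)
  # small two-block example against a direct SVD of the weighted cross table
  A <- matrix(c(1, 2, 3, 0, -1, 1), 3, 2)
  B <- matrix(c(2, 0, 1, 1, 1, -2), 3, 2)
  ta <- as_triplet(A); tb <- as_triplet(B)
  co2 <- coinertia_fit(ta, tb)
  Z <- crossprod(tb$X, (1 / 3) * ta$X)
  expect_equal(co2$singular_values, svd(Z)$d, tolerance = 1e-12)
  expect_equal(sum(co2$singular_values^2), co2$total_coinertia, tolerance = 1e-12)
  expect_error(coinertia_fit(ta, as_triplet(matrix(rnorm(8), 4, 2))), "share rows")
})

test_that("a planted shared latent factor is recovered by the coinertia axes", {
  set.seed(54)
  n <- 30
  f <- rnorm(n)
  X <- outer(f, rnorm(6)) + matrix(rnorm(n * 6, 0, 0.2), n, 6)
  Y <- outer(f, rnorm(10)) + matrix(rnorm(n * 10, 0, 0.2), n, 10)
  coi <- coinertia_fit(as_triplet(X), as_triplet(Y))
  expect_gt(abs(cor(coi$x_row_scores[, 1], f)), 0.9)
  expect_gt(abs(cor(coi$y_row_scores[, 1], f)), 0.9)
  expect_gt(abs(cor(coi$x_row_scores[, 1], coi$y_row_scores[, 1])), 0.9)
})

test_that("RV permutation test hits the attainable extremes", {
  set.seed(55)
  X <- matrix(rnorm(36), 12, 3)
  res <- rv_permutation_test(X, X, n_perm = 999, seed = 1)
  expect_equal(res$rv, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 0.001)
  r1 <- rv_permutation_test(X, matrix(rnorm(24), 12, 2), n_perm = 1, seed = 2)
  expect_true(r1$p_value %in% c(0.5, 1))
})

test_that("variation partitioning recovers forced designs and sums to one", {
  set.seed(56)
  y <- rnorm(30)
  vp <- variation_partition(y, list(A = y, B = rnorm(30)))
  fr <- setNames(vp$fractions$value, vp$fractions$fraction)
  expect_equal(unname(fr["A"] + fr["A&B"]), 1, tolerance = 1e-9)
  expect_equal(vp$combined, 1, tolerance = 1e-9)
  # two orthogonal halves
  a <- rep(c(1, -1), 15); b <- rep(c(1, 1, -1, -1), length.out = 30)
  b <- b - mean(b); a <- a - mean(a)
  b <- b - a * sum(a * b) / sum(a^2)   # force exact orthogonality
  y2 <- a + b * sqrt(sum(a^2) / sum(b^2))
  vp2 <- variation_partition(y2, list(A = a, B = b))
  fr2 <- setNames(vp2$fractions$value, vp2$fractions$fraction)
  expect_equal(unname(fr2["A"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(fr2["B"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(fr2["A&B"]), 0, tolerance = 1e-9)
  expect_equal(sum(vp2$fractions$value), 1, tolerance = 1e-9)
  # independent predictors explain nearly nothing at large n
  set.seed(57)
  y3 <- rnorm(500)
  vp3 <- variation_partition(y3, list(A = rnorm(500), B = rnorm(500)))
  expect_lt(vp3$combined, 0.05)
})

test_that("three-set fractions agree with vegan's varpart", {
  set.seed(58)
  n <- 40
  Y <- matrix(rnorm(n * 3), n, 3)
  A <- matrix(rnorm(n * 2), n, 2)
  B <- matrix(rnorm(n * 2), n, 2)
  C <- matrix(rnorm(n), n, 1)
  vp <- variation_partition(Y, list(A = A, B = B, C = C))
  vg <- vegan::varpart(Y, A, B, C)
  expect_equal(sum(vp$fractions$value), 1, tolerance = 1e-9)
  # vegan reports individual fractions on the adjusted-R2 scale
  vpa <- variation_partition(Y, list(A = A, B = B, C = C), adjust = TRUE)
  ours <- setNames(vpa$fractions$value, vpa$fractions$fraction)
  vg_tab <- vg$part$indfract
  expect_equal(unname(ours[c("A", "B", "C")]),
               unname(vg_tab[1:3, "Adj.R.square"]), tolerance = 1e-9)
  # vegan's pairwise order is [d]=X1&X2, [e]=X2&X3, [f]=X1&X3, [g]=all
  expect_equal(unname(ours[c("A&B", "B&C", "A&C", "A&B&C")]),
               unname(vg_tab[4:7, "Adj.R.square"]), tolerance = 1e-9)
  # and the full-model R2 matches vegan's
  expect_equal(vp$combined,
               vg$part$fract["[a+b+c+d+e+f+g] = All", "R.square"],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("consensus k-means nails separated blobs and returns a valid consensus matrix", {
  set.seed(59)
  X <- rbind(matrix(rnorm(40, 0), 20, 2),
             matrix(rnorm(40, 8), 20, 2),
             matrix(rnorm(40, -8), 20, 2))
  rownames(X) <- paste0("i", 1:60)
  truth <- rep(1:3, each = 20)
  cc <- consensus_kmeans(X, k = 3, n_rep = 30, seed = 1)
  expect_equal(adjusted_rand(cc$labels, truth), 1)
  expect_true(isSymmetric(cc$consensus))
  expect_equal(unname(diag(cc$consensus)), rep(1, 60))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
  # stability: a different master seed gives the same partition here
  cc2 <- consensus_kmeans(X, k = 3, n_rep = 30, seed = 99)
  expect_gt(adjusted_rand(cc$labels, cc2$labels), 0.9)
  # degenerate k
  c1 <- consensus_kmeans(X, k = 1)
  expect_equal(unname(unique(c1$labels)), 1L)
  expect_true(all(c1$consensus == 1))
  expect_error(consensus_kmeans(X[1:2, ], k = 5), "exceeds")
})

test_that("Ward leaf orders are permutations that keep identical rows adjacent and blocks contiguous", {
  X <- rbind(a = c(1, 1, 1), b = c(9, 9, 9), c = c(1, 1, 1), d = c(9.1, 9, 9))
  ord <- ward_heatmap_order(X)
  expect_setequal(ord$rows, 1:4)
  ra <- which(ord$rows == 1); rc <- which(ord$rows == 3)
  expect_equal(abs(ra - rc), 1)   # identical rows end up adjacent
  set.seed(60)
  blocks <- rbind(matrix(rnorm(30, 0, 0.1), 10, 3),
                  matrix(rnorm(30, 10, 0.1), 10, 3))
  ob <- ward_heatmap_order(blocks)
  pos <- match(1:10, ob$rows)
  expect_equal(sort(pos), seq(min(pos), min(pos) + 9))   # block contiguous
})
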