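# Independent oracles, coded from the algorithm definitions and kept free
# of the package's implementation paths.

# Brute-force TMM: reference by 75th-percentile fraction closest to the
# mean, double rank-based trimming of M and A, inverse-asymptotic-variance
# weighted mean, geometric-mean-1 rescaling.
tmm_oracle <- function(m, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(m)
  x <- m[rowSums(m > 0) > 0, , drop = FALSE]
  f75 <- apply(x, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(x))
  for (i in seq_len(ncol(x))) {
    obs <- x[, i]; refv <- x[, ref]
    nO <- lib[i]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) { f[i] <- 1; next }
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f[i] <- 2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

# Exhaustive hypergeometric upper tail P(X >= x) by enumerating every draw
# of size n from a universe of size N with K marked items. N <= 12 only.
hyper_enum_oracle <- function(N, K, n, x) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= x)
}

# Plain PLS component 1 by power iteration on the cross-covariance.
pls_power_oracle <- function(X, Y, iter = 5000) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  M <- crossprod(X, Y)
  u <- svd(M, nu = 1, nv = 0)$u[, 1] * 0 + rnorm(ncol(X))
  u <- u / sqrt(sum(u^2))
  for (i in seq_len(iter)) {
    v <- crossprod(M, u); v <- v / sqrt(sum(v^2))
    u_new <- M %*% v; u_new <- u_new / sqrt(sum(u_new^2))
    if (max(abs(u_new - u)) < 1e-12) { u <- u_new; break }
    u <- u_new
  }
  v <- crossprod(M, u); v <- v / sqrt(sum(v^2))
  list(u = as.numeric(u), v = as.numeric(v))
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Small metabolite-table fixture with an attached CRLB matrix.
make_metab_fixture <- function() {
  metabolite_table(
    data.frame(subject = c("P1", "P1", "P2"),
               side = c("injected", "contralateral", "injected"),
               time_days = c(40, 40, 60),
               NAA = c(8, 7.5, 6), Cr = c(4, 4, 4), PCr = c(4, 4, 4),
               Lac = c(1, 1.4, 2.2)),
    crlb = data.frame(NAA = c(5, 10, 55), Cr = c(5, 5, 5),
                      PCr = c(8, 6, 7), Lac = c(20, 45, 12))
  )
}

# Mixed-species count fixture: deterministic small integers.
make_count_fixture <- function() {
  m <- matrix(c(100, 200, 50, 10,
                300, 600, 150, 30,
                40, 80, 20, 4,
                5, 10, 2, 1,
                900, 1800, 450, 90), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  count_matrix(m, species = c("human", "mouse", "human", "ambiguous", "mouse"),
               sample_meta = tibble::tibble(sample = paste0("s", 1:4),
                                            subject = c("P1", "P1", "P2", "P2"),
                                            type = c("injected", "contralateral",
                                                     "injected", "contralateral")))
}
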