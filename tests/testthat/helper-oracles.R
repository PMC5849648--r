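# Independent oracles used across the suite.  These deliberately avoid
# the package's own computational paths.

# Plain periodogram least-squares slope: regress log power on log
# frequency over the lowest n/4 Fourier frequencies.  Returns the
# spectral exponent alpha (negated regression slope).
oracle_periodogram_slope <- function(x, frac = 1 / 4) {
  v <- as.numeric(x)
  n <- length(v)
  v <- v - mean(v)
  I <- Mod(fft(v))^2 / n
  j <- seq_len(floor(n * frac / 2))
  lam <- 2 * pi * j / n
  -unname(coef(lm(log(I[j + 1]) ~ log(lam)))[2])
}

# Ordinary least squares by explicit normal equations, with classical
# standard errors; independent of lm().
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (nrow(X) - 1) / df
  list(beta = drop(beta), se = se, t = drop(beta) / se,
       r2 = r2, adj_r2 = adj, df = df)
}

# R^2 of y on subsets of {x1, x2} from the sample covariance matrix
# (closed form, no regression call).
oracle_r2_from_cov <- function(y, x1, x2) {
  S <- cov(cbind(y, x1, x2))
  r2_1 <- S[1, 2]^2 / (S[2, 2] * S[1, 1])
  r2_2 <- S[1, 3]^2 / (S[3, 3] * S[1, 1])
  Sxx <- S[2:3, 2:3]
  sxy <- S[2:3, 1]
  r2_full <- drop(t(sxy) %*% solve(Sxx) %*% sxy) / S[1, 1]
  list(x1 = r2_1, x2 = r2_2, full = r2_full)
}

# Naive spatial Laplacian-of-Gaussian edge count with replicate
# borders: the brute-force counterpart of the package's FFT-based
# clutter step.  Slow; use on small frames only.
oracle_log_edge_map <- function(frame, sigma, threshold_frac) {
  h <- ceiling(3 * sigma)
  g <- seq(-h, h)
  xx <- outer(g^2, rep(1, length(g)))
  r2 <- xx + t(xx)
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)
  nr <- nrow(frame); nc <- ncol(frame)
  resp <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in seq_along(g)) {
        ii <- min(max(i + g[a], 1L), nr)
        for (b in seq_along(g)) {
          jj <- min(max(j + g[b], 1L), nc)
          acc <- acc + k[a, b] * frame[ii, jj]
        }
      }
      resp[i, j] <- acc
    }
  }
  thr <- threshold_frac * max(abs(resp))
  sgn <- sign(resp)
  sgn[abs(resp) < 1e-9 * max(abs(resp))] <- 0
  zc <- matrix(FALSE, nr, nc)
  zc[-nr, ] <- zc[-nr, ] | (sgn[-nr, ] * sgn[-1, ] < 0)
  zc[, -nc] <- zc[, -nc] | (sgn[, -nc] * sgn[, -1] < 0)
  zc & (abs(resp) > thr)
}

# mean Whittle d over replicated draws from a generator function
mean_whittle <- function(gen, reps, seed, ...) {
  set.seed(seed)
  mean(vapply(seq_len(reps), function(i) local_whittle(gen(i), ...)$d,
              numeric(1)))
}
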