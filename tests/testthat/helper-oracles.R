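# Independent oracles used to cross-check the package implementations.
# Each one recomputes the target quantity through a different code path
# (normal equations on an explicit basis, dense numerical integration,
# outer-product covariance formulas) and must stay free of the package
# internals it checks.

# least-squares spline classifier via truncated-power bases and normal
# equations; same knot rule (rightmost point) and monotonicity enforcement
oracle_classify <- function(pts) {
  x <- pts[, 1]
  u <- -(pts[, 2] - pts[1, 2])
  if (any(diff(u) <= 0))
    u <- cummax(u) + (max(u) - min(u)) * 1e-9 * seq_along(u)
  m <- which.max(x)[1]
  kn <- u[m]
  B1 <- cbind(1, u, pmax(u - kn, 0))
  B2 <- cbind(1, u, u^2, pmax(u - kn, 0)^2)
  r1 <- sum(qr.resid(qr(B1), x)^2)
  r2 <- sum(qr.resid(qr(B2), x)^2)
  if (r1 < r2) "diamond" else "circle"
}

# area between two curves monotone in y: dense trapezoidal integration of
# |x_a(y) - x_b(y)| over the overlapping vertical range
oracle_area_monotone <- function(A, B, n_grid = 20000) {
  ys <- seq(max(min(A[, 2]), min(B[, 2])), min(max(A[, 2]), max(B[, 2])),
            length.out = n_grid)
  xa <- approx(A[, 2], A[, 1], ys)$y
  xb <- approx(B[, 2], B[, 1], ys)$y
  dy <- diff(ys)
  f <- abs(xa - xb)
  sum((f[-1] + f[-n_grid]) / 2 * dy)
}

# closed-form pooled-covariance discriminant with Ledoit-Wolf shrinkage,
# built from explicit per-sample outer products and a dense p x p solve
oracle_lda_weights <- function(X, y) {
  classes <- sort(unique(y))
  m0 <- colMeans(X[y == classes[1], , drop = FALSE])
  m1 <- colMeans(X[y == classes[2], , drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  S <- matrix(0, p, p)
  phi <- 0
  xs <- vector("list", n)
  for (i in seq_len(n)) {
    mi <- if (y[i] == classes[1]) m0 else m1
    xs[[i]] <- X[i, ] - mi
    S <- S + tcrossprod(xs[[i]]) / n
  }
  for (i in seq_len(n)) phi <- phi + sum((tcrossprod(xs[[i]]) - S)^2) / n^2
  mu <- mean(diag(S))
  delta <- sum((S - diag(mu, p))^2) / p
  beta <- min(phi / p, delta)
  s <- if (delta > 0) min(max(beta / delta, 0), 1) else 0
  a <- s * mu
  if (a <= 0) a <- max(mu, 1) * 1e-10
  Sig <- (1 - s) * S + diag(a, p)
  list(w = solve(Sig, m1 - m0), m0 = m0, m1 = m1, shrinkage = s)
}

# explicit per-bin sample means for the temporal binning
oracle_bin <- function(dat, times, window, n_bins) {
  width <- (window[2] - window[1]) / n_bins
  out <- c()
  for (ch in seq_len(nrow(dat))) for (b in seq_len(n_bins)) {
    inb <- times >= window[1] + (b - 1) * width - 1e-9 &
      times < window[1] + b * width - 1e-9
    out <- c(out, mean(dat[ch, inb]))
  }
  out
}

# Box-Cox profile log-likelihood on a fixed lambda grid
oracle_boxcox_grid <- function(x, grid = seq(-1, 2, by = 0.001)) {
  n <- length(x)
  slog <- sum(log(x))
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-8) log(x) else (x^l - 1) / l
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slog
  }, numeric(1))
  grid[which.max(ll)]
}
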