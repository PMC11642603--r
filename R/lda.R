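#' Ledoit-Wolf shrinkage intensity
#'
#' Computes the optimal shrinkage of a sample covariance matrix toward the
#' scaled identity `mu * I` (`mu` the mean sample variance) from centred
#' data, using the Ledoit-Wolf lemma.  Everything is evaluated through the
#' n x n Gram matrices, so the p x p covariance is never formed; the result
#' is identical to the usual feature-space formula.
#'
#' @param Xc Centred data matrix (rows = samples).  For a pooled class
#'   covariance, centre each row by its class mean first.
#' @return A list with `shrinkage` (in [0, 1]) and `mu`.
#' @export
ledoit_wolf_shrinkage <- function(Xc) {
  Xc <- as.matrix(Xc)
  n <- nrow(Xc)
  p <- ncol(Xc)
  X2 <- Xc^2
  mu <- sum(X2) / (n * p)
  G <- Xc %*% t(Xc)
  delta_raw <- sum(G^2) / n^2            # ||S||_F^2, S = Xc'Xc / n
  beta_raw <- sum(rowSums(X2)^2)         # sum_k ||x_k||^4
  delta <- (delta_raw - p * mu^2) / p    # ||S - mu I||_F^2 / p
  beta <- (beta_raw / n - delta_raw) / (p * n)
  if (delta <= 0) return(list(shrinkage = 0, mu = mu))
  s <- min(max(min(beta, delta) / delta, 0), 1)
  list(shrinkage = s, mu = mu)
}

#' Fit a two-class shrinkage LDA classifier
#'
#' Linear discriminant analysis in its least-squares form: the weight vector
#' solves `Sigma w = m1 - m0`, where `Sigma` is the pooled (class-centred)
#' covariance shrunk toward the scaled identity with the Ledoit-Wolf
#' coefficient, and the threshold is the midpoint between the projected
#' class means (equal priors).  For wide data (more features than samples)
#' the solve goes through the Woodbury identity on the n x n Gram matrix,
#' which is algebraically exact; a direct p x p solve is used otherwise.
#' The fit is deterministic given the input order.
#'
#' @param X Feature matrix (samples x features).
#' @param y Class labels (exactly two distinct values, each with at least
#'   two samples).
#' @return An object of class `lda_shrinkage` with elements `w`, `b`,
#'   `classes`, `shrinkage`, `mu`.
#' @seealso [predict.lda_shrinkage()]
#' @export
fit_lda <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2)
    stop("fit_lda requires exactly two classes; got ", length(classes))
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  n <- nrow(X)
  p <- ncol(X)
  m0 <- colMeans(X[y == classes[1], , drop = FALSE])
  m1 <- colMeans(X[y == classes[2], , drop = FALSE])
  Xc <- X
  Xc[y == classes[1], ] <- sweep(X[y == classes[1], , drop = FALSE], 2, m0)
  Xc[y == classes[2], ] <- sweep(X[y == classes[2], , drop = FALSE], 2, m1)
  lw <- ledoit_wolf_shrinkage(Xc)
  s <- lw$shrinkage
  mu <- lw$mu
  a <- s * mu
  if (a <= 0) a <- max(mu, 1) * 1e-10   # guard: keep the system invertible
  dm <- m1 - m0
  if (p <= n || p <= 64) {
    Sigma <- (1 - s) * crossprod(Xc) / n + diag(a, p)
    w <- solve(Sigma, dm)
  } else {
    B <- sqrt((1 - s) / n) * Xc
    M <- diag(a, n) + B %*% t(B)
    w <- (dm - crossprod(B, solve(M, B %*% dm))) / a
    w <- as.vector(w)
  }
  b <- -sum(w * (m0 + m1)) / 2
  structure(list(w = w, b = b, classes = classes, shrinkage = s, mu = mu),
            class = "lda_shrinkage")
}

#' Predict classes from a fitted shrinkage LDA
#'
#' @param object An `lda_shrinkage` fit.
#' @param newdata Feature matrix (samples x features).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.lda_shrinkage <- function(object, newdata, ...) {
  sc <- as.matrix(newdata) %*% object$w + object$b
  ifelse(sc > 0, object$classes[2], object$classes[1])
}
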