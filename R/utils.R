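# Internal numerical helpers shared across modules.

# Log-density of rows of x under a multivariate normal, via Cholesky.
# x: n x m matrix; mu: length-m; sigma: m x m SPD.
logdmvnorm <- function(x, mu, sigma) {
  x <- as.matrix(x)
  m <- length(mu)
  sigma <- matrix(sigma, m, m) # guard against dropped dims when m = 1
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(ensure_spd(sigma))
  }
  centred <- sweep(x, 2L, mu, "-")
  z <- backsolve(ch, t(centred), transpose = TRUE) # solves t(ch) %*% z = t(centred)
  quad <- colSums(z^2)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
}

# Floor eigenvalues so a symmetric matrix is safely positive definite.
ensure_spd <- function(sigma, eps = NULL) {
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  if (is.null(eps)) eps <- max(abs(e$values), .Machine$double.eps) * 1e-10
  e$values <- pmax(e$values, eps)
  e$vectors %*% (e$values * t(e$vectors))
}

# Wrap an angle (radians) to (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Row-wise log-sum-exp for an n x k matrix of log terms.
row_logsumexp <- function(lw) {
  mx <- apply(lw, 1L, max)
  mx + log(rowSums(exp(lw - mx)))
}

embc_note <- function(...) {
  if (isTRUE(getOption("embclust.verbose", FALSE))) message(...)
  invisible(NULL)
}
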