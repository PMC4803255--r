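# Independent oracles kept deliberately naive: direct formula evaluation,
# double loops and brute-force enumeration, never the package's own code path.

# Haversine great-circle distance, written from the textbook formula.
oracle_haversine <- function(lon1, lat1, lon2, lat2, r = 6371008.8) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlmb <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlmb / 2)^2
  2 * r * asin(sqrt(pmin(1, a)))
}

# Multivariate normal density by direct evaluation of the formula.
oracle_dmvnorm <- function(x, mu, sigma) {
  m <- length(mu)
  d <- as.numeric(x - mu)
  exp(-0.5 * t(d) %*% solve(sigma) %*% d) /
    sqrt((2 * pi)^m * det(sigma))
}

# Posterior weights by naive per-point, per-component loops.
oracle_estep <- function(X, mu, sigma, pi) {
  n <- nrow(X); k <- length(pi)
  W <- matrix(0, n, k)
  for (i in seq_len(n)) {
    dens <- sapply(seq_len(k), function(j)
      pi[j] * oracle_dmvnorm(X[i, ], mu[j, ], sigma[, , j]))
    W[i, ] <- dens / sum(dens)
  }
  W
}

# Unconstrained M step (mixing proportions, means, covariances) as explicit
# double-loop weighted sums.
oracle_emc_mstep <- function(X, W) {
  n <- nrow(X); m <- ncol(X); k <- ncol(W)
  pi <- colSums(W) / n
  mu <- matrix(0, k, m)
  sigma <- array(0, c(m, m, k))
  for (j in seq_len(k)) {
    for (l in seq_len(m)) mu[j, l] <- sum(W[, j] * X[, l]) / sum(W[, j])
    for (r in seq_len(m)) for (s in seq_len(m)) {
      sigma[r, s, j] <- sum(W[, j] * (X[, r] - mu[j, r]) *
                              (X[, s] - mu[j, s])) / sum(W[, j])
    }
  }
  list(pi = pi, mu = mu, sigma = sigma)
}

# Constrained reliability-weighted mean and covariance sums, double loop.
oracle_embc_moments <- function(X, W, U, membership, j) {
  m <- ncol(X)
  rows <- which(membership[, j])
  mu <- numeric(m)
  for (l in seq_len(m)) {
    num <- 0; den <- 0
    for (i in rows) {
      num <- num + U[i, l] * W[i, j] * X[i, l]
      den <- den + U[i, l] * W[i, j]
    }
    mu[l] <- num / den
  }
  sigma <- matrix(0, m, m)
  for (r in seq_len(m)) for (s in seq_len(m)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(X))) {
      u <- sqrt(U[i, r]^2 + U[i, s]^2) / sqrt(2)
      num <- num + u * W[i, j] * (X[i, r] - mu[r]) * (X[i, s] - mu[s])
      den <- den + u * W[i, j]
    }
    sigma[r, s] <- num / den
  }
  list(mu = mu, sigma = sigma)
}

# Dense grid search for the minimum pairwise-posterior difference along the
# segment between two component means.
oracle_delimiter_grid <- function(model, lo, hi, var, n_grid = 20001L) {
  mu_a <- model$mu[lo, ]; mu_b <- model$mu[hi, ]
  tt <- seq(0, 1, length.out = n_grid)
  P <- outer(tt, mu_b - mu_a) + matrix(mu_a, n_grid, length(mu_a), byrow = TRUE)
  da <- sapply(seq_len(n_grid), function(i)
    model$pi[lo] * oracle_dmvnorm(P[i, ], mu_a, model$sigma[, , lo]))
  db <- sapply(seq_len(n_grid), function(i)
    model$pi[hi] * oracle_dmvnorm(P[i, ], mu_b, model$sigma[, , hi]))
  wa <- da / (da + db)
  P[which.min(abs(2 * wa - 1)), var]
}

# Random well-conditioned 2x2 covariance.
random_cov2 <- function() {
  a <- stats::runif(1, 0.3, 1.5)
  b <- stats::runif(1, 0.3, 1.5)
  rho <- stats::runif(1, -0.6, 0.6)
  matrix(c(a^2, rho * a * b, rho * a * b, b^2), 2, 2)
}

# A simple planar trajectory from step lengths and headings.
path_from_steps <- function(len, heading, dt = 1) {
  x <- c(0, cumsum(len * cos(heading)))
  y <- c(0, cumsum(len * sin(heading)))
  trajectory(seq_along(x) * dt, x, y, geodesic = FALSE)
}
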