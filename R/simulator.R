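# Synthetic labelled datasets emulating the benchmark design: four bivariate
# Gaussian behavioural modes on the unit square with a tunable overlap
# parameter, state sequences from a Markov chain or i.i.d. prior sampling,
# and the data-loss / jittering degradation protocols.

#' Benchmark mixture layout
#'
#' The 2^m-component Gaussian mixture used to generate synthetic feature
#' sets: per variable, low clusters are centred at 0.25 and high clusters at
#' 0.75 on the unit interval, with isotropic diagonal covariance of common
#' standard deviation sigma = 0.8 * (0.25 - gamma) and uniform mixing
#' proportions. Lower gamma gives more blurred (overlapping) clusters; as
#' gamma approaches 0.25 the clusters become perfectly separated. With m = 2
#' the variables are interpreted as (velocity, turn).
#'
#' @param gamma overlap parameter in (0, 0.25); the benchmark grid uses
#'   \{0.01, 0.05, 0.1\}.
#' @param m number of variables (default 2).
#' @return a mixture model with codes, as consumed by
#'   \code{\link{embc_estep}} and \code{\link{emit_features}}.
#' @export
gmm_layout <- function(gamma, m = 2L) {
  if (gamma <= 0 || gamma >= 0.25) stop("gamma must lie in (0, 0.25)")
  k <- 2L^m
  codes <- binary_codes(m)
  mu <- matrix(NA_real_, k, m)
  for (j in seq_len(k)) for (l in seq_len(m)) {
    mu[j, l] <- if (code_bit(j, l, m) == 0L) 0.25 else 0.75
  }
  colnames(mu) <- if (m == 2L) c("velocity", "turn") else paste0("x", seq_len(m))
  rownames(mu) <- codes
  s <- 0.8 * (0.25 - gamma)
  sigma <- array(diag(s^2, m), c(m, m, k))
  mixture_model(mu, sigma, rep(1 / k, k), codes = codes)
}

#' Default benchmark transition matrix
#'
#' Row-stochastic k x k matrix with self-transition probability
#' \code{self} and the remainder spread uniformly; its stationary
#' distribution is uniform.
#'
#' @param k number of states.
#' @param self self-transition probability.
#' @return k x k matrix.
#' @export
default_transition <- function(k = 4L, self = 0.85) {
  tm <- matrix((1 - self) / (k - 1L), k, k)
  diag(tm) <- self
  tm
}

#' Sample a behavioural state sequence
#'
#' Either a Markov chain started from a uniform initial state
#' (\code{scheme = "markov"}) or i.i.d. draws from the prior mixture
#' proportions (\code{scheme = "prior"}).
#'
#' @param n sequence length.
#' @param scheme \code{"markov"} or \code{"prior"}.
#' @param transition row-stochastic k x k matrix (markov scheme).
#' @param prior probability vector over states (prior scheme).
#' @param seed integer seed.
#' @return integer state sequence in 1..k.
#' @export
sample_states <- function(n, scheme = c("markov", "prior"),
                          transition = default_transition(),
                          prior = rep(0.25, 4L), seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (scheme == "markov") {
    k <- nrow(transition)
    if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
      stop("transition matrix must be row-stochastic")
    s <- integer(n)
    s[1L] <- sample.int(k, 1L)
    for (i in seq_len(n - 1L)) {
      s[i + 1L] <- sample.int(k, 1L, prob = transition[s[i], ])
    }
    s
  } else {
    if (any(prior < 0) || abs(sum(prior) - 1) > 1e-8)
      stop("prior must be a probability vector")
    sample.int(length(prior), n, replace = TRUE, prob = prior)
  }
}

#' Emit features from a state sequence
#'
#' Draws row i from the Gaussian component of state i and clips the values to
#' the unit interval. Sampling intervals default to 1 s with unit
#' reliability; heterogeneous intervals (occasional gaps of 2 to
#' \code{gap_max} times the nominal interval with probability \code{p_gap})
#' can be requested to exercise the reliability weighting and the jitter
#' protocol.
#'
#' @param states integer state sequence.
#' @param model generating mixture (e.g. \code{\link{gmm_layout}}).
#' @param seed integer seed.
#' @param tau_mode nominal sampling interval (s).
#' @param p_gap probability that a point's interval is a gap.
#' @param gap_max maximum gap length in units of \code{tau_mode}.
#' @return a \code{"synthetic_dataset"}: list with \code{features}
#'   (a \code{\link{feature_matrix}}), \code{states} (integer), and the
#'   generating configuration.
#' @export
emit_features <- function(states, model, seed = 1L, tau_mode = 1,
                          p_gap = 0, gap_max = 5) {
  set.seed(seed)
  n <- length(states)
  m <- ncol(model$mu)
  X <- matrix(NA_real_, n, m)
  for (j in sort(unique(states))) {
    rows <- which(states == j)
    ch <- chol(model$sigma[, , j])
    Z <- matrix(stats::rnorm(length(rows) * m), length(rows), m)
    X[rows, ] <- sweep(Z %*% ch, 2L, model$mu[j, ], "+")
  }
  X <- pmin(pmax(X, 0), 1)
  colnames(X) <- colnames(model$mu)
  tau <- rep(tau_mode, n)
  if (p_gap > 0) {
    gap <- stats::runif(n) < p_gap
    tau[gap] <- tau_mode * stats::runif(sum(gap), 2, gap_max)
  }
  U <- matrix(rep(reliability_from_tau(tau, tau_mode), m), n, m)
  colnames(U) <- colnames(X)
  structure(list(
    features = feature_matrix(X, U = U, tau = tau, tau_mode = tau_mode,
                              valid = rep(TRUE, n)),
    states = states,
    codes = model$codes,
    config = list(seed = seed, tau_mode = tau_mode, p_gap = p_gap,
                  gap_max = gap_max)
  ), class = "synthetic_dataset")
}

#' Generate a labelled synthetic dataset
#'
#' Convenience wrapper: mixture layout for \code{gamma}, state sequence under
#' the chosen sampling scheme, and feature emission, all under one seed.
#'
#' @param n number of points.
#' @param gamma overlap parameter (see \code{\link{gmm_layout}}).
#' @param scheme \code{"markov"} or \code{"prior"}.
#' @param seed integer seed.
#' @param m number of variables.
#' @param transition,prior state-sampling parameters
#'   (see \code{\link{sample_states}}).
#' @param ... passed to \code{\link{emit_features}} (sampling-interval
#'   heterogeneity).
#' @return a \code{"synthetic_dataset"}.
#' @export
simulate_dataset <- function(n, gamma, scheme = "markov", seed = 1L, m = 2L,
                             transition = default_transition(2L^m),
                             prior = rep(1 / 2L^m, 2L^m), ...) {
  model <- gmm_layout(gamma, m)
  states <- sample_states(n, scheme, transition = transition, prior = prior,
                          seed = seed)
  out <- emit_features(states, model, seed = seed + 1L, ...)
  out$config <- c(out$config,
                  list(n = n, gamma = gamma, scheme = scheme, m = m))
  out
}

#' Integrate a synthetic feature set into a planar trajectory
#'
#' Interprets the two variables as (velocity, turn) and integrates positions:
#' each step advances by velocity * v_scale * dt along a heading that rotates
#' by +/- the turn value (random sign per step, seeded). Re-deriving
#' velocity/turn features from the trajectory recovers the generated values
#' on the interior points.
#'
#' @param dataset a bivariate \code{"synthetic_dataset"}.
#' @param dt time step (s).
#' @param v_scale velocity scale (m/s per feature unit).
#' @param seed seed for the turn signs.
#' @return a planar \code{\link{trajectory}}.
#' @export
to_trajectory <- function(dataset, dt = 1, v_scale = 1, seed = 1L) {
  X <- dataset$features$X
  stopifnot(ncol(X) == 2L)
  n <- nrow(X)
  set.seed(seed)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  heading <- numeric(n - 1L)
  heading[1L] <- 0
  for (i in 2:(n - 1L)) heading[i] <- heading[i - 1L] + sgn[i] * X[i, 2L]
  # floor zero (clipped) velocities so step headings stay well defined
  step <- pmax(X[seq_len(n - 1L), 1L], 1e-12) * v_scale * dt
  x <- c(0, cumsum(step * cos(heading)))
  y <- c(0, cumsum(step * sin(heading)))
  trajectory(seq_len(n) * dt, x, y, geodesic = FALSE, id = "synthetic")
}

#' Data-loss degradation
#'
#' Removes points at random while preserving the underlying behavioural
#' distribution: each point receives a uniform random value p_i in [0, 1]
#' and is removed when p_i < k_dl. The number kept is Binomial(n, 1 - k_dl).
#'
#' @param features a \code{\link{feature_matrix}}.
#' @param k_dl data-loss factor in [0, 1].
#' @param seed integer seed.
#' @return list with the subset \code{features} and the \code{kept} indices.
#' @export
degrade_loss <- function(features, k_dl, seed = 1L) {
  stopifnot(k_dl >= 0, k_dl <= 1)
  n <- nrow(features$X)
  set.seed(seed)
  kept <- which(stats::runif(n) >= k_dl)
  sub <- feature_matrix(features$X[kept, , drop = FALSE],
                        U = features$U[kept, , drop = FALSE],
                        tau = features$tau[kept],
                        tau_mode = features$tau_mode,
                        valid = features$valid[kept],
                        units = features$units)
  list(features = sub, kept = kept)
}

#' Jittering degradation
#'
#' Perturbs each point uniformly within a box whose half-width per variable
#' is Delta_i = k_di * max(X) * max(0, (tau_i - tau_mode) / tau_mode): points
#' sampled at the nominal interval are untouched, points after longer gaps
#' may move proportionally further. Jittered values are clamped to the global
#' range of each variable.
#'
#' @param features a \code{\link{feature_matrix}} with sampling intervals.
#' @param k_di data-inaccuracy factor (small, positive).
#' @param seed integer seed.
#' @return a jittered \code{\link{feature_matrix}}.
#' @export
degrade_jitter <- function(features, k_di, seed = 1L) {
  stopifnot(k_di >= 0)
  X <- features$X
  tau <- features$tau
  tmode <- features$tau_mode
  if (!is.finite(tmode) || tmode <= 0) stop("tau_mode must be positive")
  set.seed(seed)
  rel <- pmax(0, (tau - tmode) / tmode)
  rel[!is.finite(rel)] <- 0
  for (l in seq_len(ncol(X))) {
    lo_g <- min(X[, l], na.rm = TRUE)
    hi_g <- max(X[, l], na.rm = TRUE)
    delta <- k_di * hi_g * rel
    lo <- pmax(lo_g, X[, l] - delta)
    hi <- pmin(hi_g, X[, l] + delta)
    idx <- which(delta > 0 & is.finite(lo) & is.finite(hi))
    X[idx, l] <- stats::runif(length(idx), lo[idx], hi[idx])
  }
  out <- features
  out$X <- X
  out
}
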