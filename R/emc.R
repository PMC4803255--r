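# Classic unconstrained Gaussian-mixture EM clustering, used as a comparison
# baseline and as the unconstrained limit of the binary-constrained fit.

# Plain maximum-likelihood M step for a Gaussian mixture: mixing proportions,
# means and covariances as posterior-weighted moments over all points.
emc_mstep <- function(X, W, sigma_min) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  k <- ncol(W)
  nk <- colSums(W)
  pi_new <- nk / n
  mu <- matrix(NA_real_, k, m, dimnames = list(NULL, colnames(X)))
  sigma <- array(NA_real_, c(m, m, k))
  for (j in seq_len(k)) {
    for (l in seq_len(m)) mu[j, l] <- sum(W[, j] * X[, l]) / sum(W[, j])
    sg <- matrix(0, m, m)
    for (r in seq_len(m)) for (s in r:m) {
      sg[r, s] <- sum(W[, j] * (X[, r] - mu[j, r]) * (X[, s] - mu[j, s])) /
        sum(W[, j])
      sg[s, r] <- sg[r, s]
    }
    diag(sg) <- pmax(diag(sg), sigma_min^2)
    sigma[, , j] <- cap_correlation(sg)
  }
  mixture_model(mu, sigma, pi_new)
}

# k-means++-style seeding: the first mean is a uniformly drawn data point,
# each further mean a data point drawn with probability proportional to its
# squared distance to the nearest mean chosen so far.
seed_means <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(X, 1L, function(x)
      min(colSums((t(X[idx, , drop = FALSE]) - x)^2)))
    if (sum(d2) == 0) {
      idx <- c(idx, sample.int(n, 1L))
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2))
    }
  }
  X[idx, , drop = FALSE]
}

#' Unconstrained Gaussian-mixture EM clustering (baseline)
#'
#' Standard EM fit of a k-component Gaussian mixture. Means are seeded from
#' the data points (k-means++-style, under the given seed), mixing
#' proportions start uniform and covariances start from the per-variable data
#' variances. The best of \code{n_starts} runs (by final log-likelihood, ties
#' to the first) is returned. Within a run the log-likelihood is
#' non-decreasing up to numerical tolerance, the standard EM guarantee.
#'
#' @param X a \code{\link{feature_matrix}} or numeric matrix.
#' @param k number of components.
#' @param n_starts number of random restarts.
#' @param seed integer seed governing all restarts.
#' @param sigma_min per-variable minimum standard deviations (as in
#'   \code{\link{embc}}).
#' @param max_iter,delta stopping rule (iteration cap; threshold on the mean
#'   per-point log-likelihood increment).
#' @return An object of class \code{"emc_fit"}: mixture model, posterior
#'   weights, integer labels, log-likelihood trace of the winning run, and
#'   stop status.
#' @export
emc_fit <- function(X, k = 4L, n_starts = 1L, seed = 1L, sigma_min = NULL,
                    max_iter = 200L, delta = 1e-6) {
  feats <- if (inherits(X, "feature_matrix")) X else feature_matrix(X)
  valid <- feats$valid & stats::complete.cases(feats$X)
  Xv <- feats$X[valid, , drop = FALSE]
  n <- nrow(Xv)
  m <- ncol(Xv)
  if (n < k) stop("need at least k = ", k, " valid points")
  sigma_min <- default_sigma_min(sigma_min, colnames(Xv), m)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_starts)
  best <- NULL
  for (s in run_seeds) {
    set.seed(s)
    run <- emc_run(Xv, k, sigma_min, max_iter, delta)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  W <- matrix(NA_real_, nrow(feats$X), k)
  W[valid, ] <- best$W
  lab <- rep(NA_integer_, nrow(feats$X))
  lab[valid] <- best$labels
  structure(list(mixture = best$model, W = W, labels = lab, valid = valid,
                 loglik_trace = best$trace, loglik = best$loglik,
                 status = best$status, k = k),
            class = "emc_fit")
}

emc_run <- function(Xv, k, sigma_min, max_iter, delta) {
  n <- nrow(Xv)
  m <- ncol(Xv)
  mu <- seed_means(Xv, k)
  sg0 <- diag(pmax(apply(Xv, 2L, stats::var), sigma_min^2), m)
  sigma <- array(sg0, c(m, m, k))
  model <- mixture_model(mu, sigma, rep(1 / k, k))
  trace <- numeric(0)
  status <- "max_iter"
  reseeded <- rep(FALSE, k)
  for (it in seq_len(max_iter)) {
    W <- embc_estep(Xv, model)
    # empty components: re-seed once from a random data point, then drop
    nk <- colSums(W)
    for (j in which(model$active & nk < 1e-8 * n)) {
      if (!reseeded[j]) {
        model$mu[j, ] <- Xv[sample.int(n, 1L), ]
        model$sigma[, , j] <- sg0
        reseeded[j] <- TRUE
        W <- embc_estep(Xv, model)
        nk <- colSums(W)
      }
      if (nk[j] < 1e-8 * n) {
        warning("component ", j, " is empty and was dropped")
        model$active[j] <- FALSE
        model$pi[j] <- 0
        model$pi <- model$pi / sum(model$pi)
        W <- embc_estep(Xv, model)
        nk <- colSums(W)
      }
    }
    act <- which(model$active)
    upd <- emc_mstep(Xv, W[, act, drop = FALSE], sigma_min)
    model$mu[act, ] <- upd$mu
    model$sigma[, , act] <- upd$sigma
    model$pi[act] <- upd$pi
    ll <- loglik_mixture(Xv, model)
    trace <- c(trace, ll)
    if (it >= 2L && abs(ll - trace[it - 1L]) < delta) {
      status <- "converged"
      break
    }
  }
  W <- embc_estep(Xv, model)
  Wa <- W
  Wa[, !model$active] <- -Inf
  list(model = model, W = W, labels = max.col(Wa, ties.method = "first"),
       trace = trace, loglik = trace[length(trace)], status = status)
}

#' @export
print.emc_fit <- function(x, ...) {
  cat("Gaussian-mixture EM fit (", x$status, "), k = ", x$k, "\n", sep = "")
  cat("  mean per-point log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}
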