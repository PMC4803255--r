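# Core of the constrained EM optimization: a Gaussian mixture whose component
# means are bounded to binary (low/high) regions of the variable space. The
# regions are delimited, per variable and per low/high context of the other
# variables, by data-driven splitting values recomputed at every iteration
# from the current means ("delimiters").

#' Binary cluster codes
#'
#' The 2^m cluster identities for m variables, as strings over {L, H}
#' ordered lexicographically with L < H (e.g. LL, LH, HL, HH for m = 2);
#' symbol l of code j gives whether variable l takes low or high values in
#' cluster j.
#'
#' @param m number of variables.
#' @return character vector of length 2^m.
#' @export
binary_codes <- function(m) {
  stopifnot(m >= 1)
  g <- do.call(expand.grid, rep(list(c("L", "H")), m))
  # expand.grid varies the first factor fastest; variable 1 must be the
  # most significant symbol for lexicographic L<H order
  apply(g[, rev(seq_len(m)), drop = FALSE], 1L, paste0, collapse = "")
}

# Bit (0 = L, 1 = H) of variable l in cluster j, for k = 2^m clusters.
code_bit <- function(j, l, m) {
  as.integer((j - 1L) %/% 2^(m - l)) %% 2L
}

#' Adjacent cluster pairs per delimiter
#'
#' Enumerates the m * 2^(m-1) delimiters: one per splitting variable and per
#' L/H combination of the remaining variables. Each delimiter separates two
#' adjacent clusters whose codes differ only at the splitting variable.
#'
#' @param m number of variables.
#' @return data frame with columns \code{var} (splitting variable),
#'   \code{lo}, \code{hi} (indices of the adjacent clusters), \code{context}
#'   (code with a dot at the splitting variable), and \code{value}
#'   (initialized \code{NA}).
#' @export
delimiter_pairs <- function(m) {
  codes <- binary_codes(m)
  out <- do.call(rbind, lapply(seq_len(m), function(l) {
    lo <- which(vapply(seq_along(codes), code_bit, integer(1), l = l, m = m) == 0L)
    hi <- lo + 2L^(m - l)
    ctx <- codes[lo]
    substr(ctx, l, l) <- "."
    data.frame(var = l, lo = lo, hi = hi, context = ctx,
               stringsAsFactors = FALSE)
  }))
  out$value <- NA_real_
  out
}

# Construct a mixture-model object.
mixture_model <- function(mu, sigma, pi, active = NULL, codes = NULL) {
  k <- nrow(mu)
  if (is.null(active)) active <- rep(TRUE, k)
  structure(list(mu = mu, sigma = sigma, pi = pi, active = active,
                 codes = codes), class = "embc_mixture")
}

#' Posterior cluster weights (E step)
#'
#' Posterior probability of each point belonging to each active mixture
#' component (Bayes rule over the component densities weighted by the mixing
#' proportions), computed in log space for numerical stability. Columns of
#' inactive components are zero; rows sum to one.
#'
#' @param X numeric n x m matrix of (valid) points.
#' @param model a mixture model (means, covariances, mixing proportions,
#'   active flags).
#' @return n x k matrix of posterior weights.
#' @export
embc_estep <- function(X, model) {
  X <- as.matrix(X)
  act <- which(model$active)
  stopifnot(length(act) >= 1L)
  n <- nrow(X)
  k <- length(model$pi)
  lw <- matrix(-Inf, n, length(act))
  for (a in seq_along(act)) {
    j <- act[a]
    lw[, a] <- log(model$pi[j]) +
      logdmvnorm(X, model$mu[j, ], model$sigma[, , j])
  }
  lse <- row_logsumexp(lw)
  W <- matrix(0, n, k)
  W[, act] <- exp(lw - lse)
  bad <- !is.finite(lse)
  if (any(bad)) {
    warning(sum(bad), " points underflowed all component densities; ",
            "assigned uniform weights")
    W[bad, ] <- 0
    W[bad, act] <- 1 / length(act)
  }
  W
}

# Shannon entropy (bits) of a binary split proportion.
split_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Maximum-entropy initialization
#'
#' Builds the least informative starting partition: variables are selected
#' sequentially, at each step choosing the not-yet-split variable whose
#' median split of the current data subset has maximum entropy (ties go to
#' the lowest variable index); the split recurses into the low and high
#' subsets. Conditional delimiters are the within-subset medians. Initial
#' components are estimated from the resulting regions with uniform
#' per-point weights and uniform mixing proportions 1/k.
#'
#' @param X numeric n x m matrix of valid points (n >= 2^m).
#' @param sigma_min per-variable minimum standard deviations.
#' @return list with elements \code{model} (mixture model) and
#'   \code{delimiters} (as from \code{\link{delimiter_pairs}}, with values).
#' @export
init_max_entropy <- function(X, sigma_min = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  k <- 2L^m
  if (n < k) stop("need at least 2^m = ", k, " valid points")
  sigma_min <- default_sigma_min(sigma_min, colnames(X), m)

  build <- function(rows, vars_left) {
    if (!length(vars_left)) return(list(leaf = TRUE, rows = rows))
    if (!length(rows)) {
      return(list(leaf = FALSE, var = vars_left[1L], value = NA_real_,
                  lo = build(integer(0), setdiff(vars_left, vars_left[1L])),
                  hi = build(integer(0), setdiff(vars_left, vars_left[1L]))))
    }
    best <- NULL
    for (l in vars_left) {
      med <- stats::median(X[rows, l])
      ent <- split_entropy(mean(X[rows, l] <= med))
      if (is.null(best) || ent > best$ent + 1e-12) {
        best <- list(var = l, value = med, ent = ent)
      }
    }
    lo_rows <- rows[X[rows, best$var] <= best$value]
    hi_rows <- setdiff(rows, lo_rows)
    if (!length(hi_rows)) {
      warning("degenerate split: all values of variable ", best$var,
              " equal in a subset; delimiter placed at that value")
    }
    rest <- setdiff(vars_left, best$var)
    list(leaf = FALSE, var = best$var, value = best$value,
         lo = build(lo_rows, rest), hi = build(hi_rows, rest))
  }
  tree <- build(seq_len(n), seq_len(m))

  codes <- binary_codes(m)
  leaf_rows <- function(node, code) {
    if (isTRUE(node$leaf)) return(node$rows)
    side <- substr(code, node$var, node$var)
    leaf_rows(if (side == "L") node$lo else node$hi, code)
  }
  # delimiter for variable l in a given L/H context: the tree's split value
  # of l along the path selected by the context
  delim_value <- function(l, context) {
    node <- tree
    while (!isTRUE(node$leaf)) {
      if (node$var == l) return(node$value)
      side <- substr(context, node$var, node$var)
      node <- if (side == "L") node$lo else node$hi
    }
    NA_real_
  }
  delims <- delimiter_pairs(m)
  full_ctx <- codes[delims$lo] # context with actual L at the split position
  delims$value <- mapply(delim_value, delims$var, full_ctx)

  glob_mu <- colMeans(X)
  glob_sig <- stats::cov(X)
  mu <- matrix(NA_real_, k, m, dimnames = list(codes, colnames(X)))
  sigma <- array(NA_real_, c(m, m, k))
  for (j in seq_len(k)) {
    rows <- leaf_rows(tree, codes[j])
    if (length(rows) >= 1L) {
      mu[j, ] <- colMeans(X[rows, , drop = FALSE])
      sigma[, , j] <- if (length(rows) >= 2L)
        stats::cov(X[rows, , drop = FALSE]) else diag(sigma_min^2, m)
    } else {
      mu[j, ] <- glob_mu
      sigma[, , j] <- glob_sig
    }
    sg <- matrix(sigma[, , j], m, m)
    diag(sg) <- pmax(diag(sg), sigma_min^2)
    sigma[, , j] <- cap_correlation(sg)
  }
  model <- mixture_model(mu, sigma, rep(1 / k, k), codes = codes)
  list(model = model, delimiters = delims)
}

# Resolve the per-variable minimum standard deviation. Velocity and turn get
# physically motivated floors (0.01 m/s, 0.087 rad = 5 degrees); any other
# variable gets sqrt(.Machine$double.eps).
default_sigma_min <- function(sigma_min, varnames, m) {
  if (!is.null(sigma_min)) {
    if (length(sigma_min) == 1L) sigma_min <- rep(sigma_min, m)
    stopifnot(length(sigma_min) == m, all(sigma_min > 0))
    return(sigma_min)
  }
  out <- rep(sqrt(.Machine$double.eps), m)
  if (!is.null(varnames)) {
    out[varnames == "velocity"] <- 0.01
    out[varnames == "turn"] <- 0.087
  }
  out
}

# Keep covariance matrices safely positive definite by capping the implied
# correlations (diagonal is already floored by sigma_min).
cap_correlation <- function(sigma, rho_max = 0.9999) {
  m <- nrow(sigma)
  if (m == 1L) return(sigma)
  s <- sqrt(diag(sigma))
  for (r in seq_len(m - 1L)) for (sdx in (r + 1L):m) {
    cap <- rho_max * s[r] * s[sdx]
    sigma[r, sdx] <- max(min(sigma[r, sdx], cap), -cap)
    sigma[sdx, r] <- sigma[r, sdx]
  }
  sigma
}

#' Delimiter between two adjacent clusters
#'
#' The delimiter is located on the frontier of equal posterior probability
#' between the two adjacent components: all points are orthogonally projected
#' onto the segment joining the two current means, the pairwise posterior
#' weights (restricted to the pair, using the current mixing proportions and
#' covariances) are evaluated at the projected points, and the delimiter is
#' the splitting-variable coordinate of the projected point with minimum
#' absolute weight difference. Projections falling outside the segment are
#' excluded unless none remain; ties go to the point closest to the segment
#' midpoint.
#'
#' @param X numeric n x m matrix of valid points.
#' @param model mixture model.
#' @param lo,hi indices of the adjacent clusters (low/high in \code{var}).
#' @param var the splitting variable.
#' @return scalar delimiter value (units of \code{var}).
#' @export
compute_delimiter <- function(X, model, lo, hi, var) {
  X <- as.matrix(X)
  mu_a <- model$mu[lo, ]
  mu_b <- model$mu[hi, ]
  d <- mu_b - mu_a
  dn2 <- sum(d^2)
  if (dn2 == 0) {
    embc_note("coincident means for adjacent pair (", lo, ",", hi,
              "): absorption candidate")
    return(mu_a[var])
  }
  tt <- as.vector(sweep(X, 2L, mu_a, "-") %*% d) / dn2
  sel <- which(tt >= 0 & tt <= 1)
  if (!length(sel)) sel <- seq_len(nrow(X))
  ts <- tt[sel]
  P <- outer(ts, d) + matrix(mu_a, length(ts), length(mu_a), byrow = TRUE)
  la <- log(model$pi[lo]) + logdmvnorm(P, mu_a, model$sigma[, , lo])
  lb <- log(model$pi[hi]) + logdmvnorm(P, mu_b, model$sigma[, , hi])
  wa <- 1 / (1 + exp(lb - la)) # pairwise posterior of the low cluster
  dif <- abs(2 * wa - 1)
  cand <- which(dif <= min(dif) + 1e-12)
  if (length(cand) > 1L) cand <- cand[which.min(abs(ts[cand] - 0.5))]
  P[cand, var]
}

# Recompute all delimiters for the current model state. Pairs with an
# inactive member are undefined (NA).
compute_delimiters <- function(X, model, delims) {
  for (r in seq_len(nrow(delims))) {
    lo <- delims$lo[r]; hi <- delims$hi[r]
    delims$value[r] <- if (model$active[lo] && model$active[hi]) {
      compute_delimiter(X, model, lo, hi, delims$var[r])
    } else NA_real_
  }
  delims
}

#' Binary region membership
#'
#' A point belongs to region R_j when, for every variable, it lies on the
#' low (<=) or high (>=) side of the applicable delimiter according to
#' cluster j's code; boundary equality counts as membership. Because
#' delimiters generally do not tile the space exactly, a point may belong to
#' several regions (it then contributes to the means of all of them) or to
#' none (it is then assigned to the region of its current maximum-posterior
#' cluster). Constraints whose delimiter is undefined (absorbed neighbour)
#' are skipped.
#'
#' @param X numeric n x m matrix of valid points.
#' @param delims delimiter table with current values.
#' @param model mixture model (for active flags).
#' @param W current posterior weights (fallback assignment).
#' @return n x k logical membership matrix.
#' @export
region_membership <- function(X, delims, model, W) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- length(model$pi)
  mem <- matrix(TRUE, n, k)
  for (r in seq_len(nrow(delims))) {
    v <- delims$value[r]
    if (is.na(v)) next
    mem[, delims$lo[r]] <- mem[, delims$lo[r]] & (X[, delims$var[r]] <= v)
    mem[, delims$hi[r]] <- mem[, delims$hi[r]] & (X[, delims$var[r]] >= v)
  }
  mem[, !model$active] <- FALSE
  none <- rowSums(mem) == 0
  if (any(none)) {
    embc_note(sum(none), " points in no binary region; assigned to their ",
              "max-posterior cluster's region")
    Wact <- W
    Wact[, !model$active] <- -Inf
    jmax <- max.col(Wact, ties.method = "first")
    mem[cbind(which(none), jmax[none])] <- TRUE
  }
  mem
}

#' Constrained, reliability-weighted M step
#'
#' Updates the mixture parameters given posteriors, reliability weights and
#' binary-region membership. Mixing proportions use all points; each mean is
#' a reliability- and posterior-weighted average restricted to the points in
#' the cluster's binary region (and clamped onto the region, which the
#' weighted average can only leave via fallback-assigned points); covariances
#' stay unbounded, computed over all points with pairwise-combined
#' reliability weights and the new means, with diagonals floored at
#' sigma_min^2. Clusters whose region is empty or whose posterior mass
#' vanishes are absorbed: deactivated, with mixing proportions renormalized.
#'
#' @param X numeric n x m matrix of valid points.
#' @param W n x k posterior weights.
#' @param U n x m reliability weights in [0, 1].
#' @param membership n x k logical region membership.
#' @param model current mixture model.
#' @param delims delimiter table with current values (for mean clamping).
#' @param sigma_min per-variable minimum standard deviations.
#' @return updated mixture model.
#' @export
embc_mstep <- function(X, W, U, membership, model, delims, sigma_min) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  k <- length(model$pi)
  active <- model$active
  pi_new <- colSums(W) / n
  mu <- model$mu
  sigma <- model$sigma
  absorbed <- integer(0)

  for (j in which(active)) {
    rows <- which(membership[, j])
    if (!length(rows) || sum(W[, j]) < 1e-8 * n) {
      absorbed <- c(absorbed, j)
      next
    }
    newmu <- rep(NA_real_, m)
    ok <- TRUE
    for (l in seq_len(m)) {
      wgt <- U[rows, l] * W[rows, j]
      den <- sum(wgt)
      if (den <= 0) { ok <- FALSE; break }
      newmu[l] <- sum(wgt * X[rows, l]) / den
    }
    if (!ok) {
      absorbed <- c(absorbed, j)
      next
    }
    # clamp onto the binary region (fallback-assigned points may lie outside)
    for (r in which(delims$lo == j | delims$hi == j)) {
      v <- delims$value[r]
      if (is.na(v)) next
      l <- delims$var[r]
      newmu[l] <- if (delims$lo[r] == j) min(newmu[l], v) else max(newmu[l], v)
    }
    mu[j, ] <- newmu
    sg <- matrix(0, m, m)
    for (r in seq_len(m)) for (s in r:m) {
      urs <- pair_reliability(U[, r], U[, s])
      wu <- urs * W[, j]
      sg[r, s] <- sum(wu * (X[, r] - newmu[r]) * (X[, s] - newmu[s])) / sum(wu)
      sg[s, r] <- sg[r, s]
    }
    diag(sg) <- pmax(diag(sg), sigma_min^2)
    sigma[, , j] <- cap_correlation(sg)
  }
  if (length(absorbed)) {
    warning("cluster(s) ", paste(model$codes[absorbed], collapse = ", "),
            " absorbed")
    active[absorbed] <- FALSE
  }
  pi_new[!active] <- 0
  if (sum(pi_new) <= 0) stop("all clusters absorbed")
  pi_new <- pi_new / sum(pi_new)
  mixture_model(mu, sigma, pi_new, active, model$codes)
}

#' Mean per-point mixture log-likelihood
#'
#' @param X numeric n x m matrix of valid points.
#' @param model mixture model.
#' @return scalar: (1/n) sum_i log sum_j pi_j N(x_i | mu_j, Sigma_j) over
#'   active components.
#' @export
loglik_mixture <- function(X, model) {
  X <- as.matrix(X)
  act <- which(model$active)
  lw <- vapply(act, function(j) {
    log(model$pi[j]) + logdmvnorm(X, model$mu[j, ], model$sigma[, , j])
  }, numeric(nrow(X)))
  lw <- matrix(lw, nrow = nrow(X))
  mean(row_logsumexp(lw))
}

#' Fit the binary-constrained Gaussian mixture
#'
#' Runs the constrained EM loop: posterior weights (E step), delimiter
#' update, binary-region membership, constrained reliability-weighted M step,
#' and the mean per-point log-likelihood. Unlike an unconstrained mixture
#' fit, the constrained update is not a strict likelihood maximization:
#' occasional likelihood drops act as informed restarts, and a persistent
#' oscillation between the binary and the unconstrained optimum is detected
#' as a cycle, upon which the best state seen is restored and the fit stops
#' with a warning. The fit is deterministic: it has no random state and the
#' starting point is the maximum-entropy median partition.
#'
#' @param features a \code{\link{feature_matrix}} or plain numeric matrix.
#' @param sigma_min per-variable minimum standard deviations; defaults to
#'   0.01 m/s for a variable named \code{velocity}, 0.087 rad (5 degrees)
#'   for \code{turn}, and sqrt(machine epsilon) otherwise.
#' @param max_iter maximum EM iterations.
#' @param delta convergence threshold on the change of mean per-point
#'   log-likelihood.
#' @param reliability use the feature matrix's reliability weights
#'   (\code{TRUE}) or unit weights (\code{FALSE}).
#' @return An object of class \code{"embc_fit"}: the mixture model, the
#'   final delimiter set, posterior weights \code{W} (rows of invalid points
#'   are \code{NA}), per-point binary-code \code{labels} (invalid points
#'   inherit the nearest preceding valid label), the log-likelihood trace,
#'   a stop \code{status} (\code{converged}, \code{max_iter} or
#'   \code{cycle_stop}) and the number of active clusters.
#' @export
embc <- function(features, sigma_min = NULL, max_iter = 200L, delta = 1e-6,
                 reliability = TRUE) {
  if (!inherits(features, "feature_matrix")) features <- feature_matrix(features)
  X <- features$X
  valid <- features$valid & stats::complete.cases(X)
  Xv <- X[valid, , drop = FALSE]
  m <- ncol(X)
  k <- 2L^m
  n_v <- nrow(Xv)
  if (n_v < k) stop("need at least 2^m = ", k, " valid points, got ", n_v)
  sigma_min <- default_sigma_min(sigma_min, colnames(X), m)
  Uv <- if (isTRUE(reliability)) features$U[valid, , drop = FALSE]
        else matrix(1, n_v, m)
  Uv[is.na(Uv)] <- 1
  codes <- binary_codes(m)

  if (all(apply(Xv, 2L, function(v) diff(range(v)) == 0))) {
    warning("all valid points are identical; returning a single active cluster")
    mu <- matrix(Xv[1L, ], k, m, byrow = TRUE, dimnames = list(codes, colnames(X)))
    sigma <- array(diag(sigma_min^2, m), c(m, m, k))
    model <- mixture_model(mu, sigma, c(1, rep(0, k - 1L)),
                           active = c(TRUE, rep(FALSE, k - 1L)), codes = codes)
    delims <- delimiter_pairs(m)
    return(finalize_embc(features, valid, Xv, model, delims,
                         loglik_mixture(Xv, model), "converged"))
  }

  init <- init_max_entropy(Xv, sigma_min)
  model <- init$model
  delims <- init$delimiters
  trace <- numeric(0)
  best <- NULL
  status <- "max_iter"

  for (it in seq_len(max_iter)) {
    W <- embc_estep(Xv, model)
    delims <- compute_delimiters(Xv, model, delims)
    mem <- region_membership(Xv, delims, model, W)
    model_new <- embc_mstep(Xv, W, Uv, mem, model, delims, sigma_min)
    ll <- loglik_mixture(Xv, model_new)
    trace <- c(trace, ll)
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, model = model_new)
    }
    if (it >= 2L && abs(ll - trace[it - 1L]) < delta) {
      model <- model_new
      status <- "converged"
      break
    }
    # cycle: the current value re-appears from >= 2 iterations back within
    # the last 20, with a likelihood decrease in between
    if (it >= 3L) {
      lo_w <- max(1L, it - 20L)
      past <- lo_w:(it - 2L)
      hits <- past[abs(trace[past] - ll) < 1e-9]
      if (length(hits) && any(diff(trace[hits[1L]:it]) < 0)) {
        warning("likelihood cycle detected; stopping and restoring the ",
                "best state seen")
        model <- best$model
        status <- "cycle_stop"
        break
      }
    }
    model <- model_new
  }
  delims <- compute_delimiters(Xv, model, delims)
  finalize_embc(features, valid, Xv, model, delims, trace, status)
}

# Assemble the fit object: final posteriors, labels with tie-breaking by
# region membership then lowest code index, and label back-fill for invalid
# rows.
finalize_embc <- function(features, valid, Xv, model, delims, trace, status) {
  n <- nrow(features$X)
  k <- length(model$pi)
  Wv <- embc_estep(Xv, model)
  memv <- region_membership(Xv, delims, model, Wv)
  lab_v <- integer(nrow(Xv))
  for (i in seq_len(nrow(Xv))) {
    w <- Wv[i, ]
    cand <- which(w >= max(w) - 1e-12 & model$active)
    if (length(cand) > 1L) {
      inreg <- cand[memv[i, cand]]
      if (length(inreg)) cand <- inreg
    }
    lab_v[i] <- cand[1L]
  }
  W <- matrix(NA_real_, n, k, dimnames = list(NULL, model$codes))
  W[valid, ] <- Wv
  lab <- rep(NA_integer_, n)
  lab[valid] <- lab_v
  # invalid rows inherit the nearest preceding valid label (leading rows the
  # first valid one) so every location carries an annotation
  if (anyNA(lab)) {
    filled <- lab
    last <- lab[which(valid)[1L]]
    for (i in seq_len(n)) {
      if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
    }
    lab <- filled
  }
  structure(list(
    mixture = model,
    delimiters = delims,
    W = W,
    labels = model$codes[lab],
    label_index = lab,
    valid = valid,
    loglik_trace = trace,
    loglik = if (length(trace)) trace[length(trace)] else NA_real_,
    status = status,
    n_active = sum(model$active),
    features = features
  ), class = "embc_fit")
}

#' @export
print.embc_fit <- function(x, ...) {
  cat("Binary clustering fit (", x$status, ") after ",
      length(x$loglik_trace), " iterations\n", sep = "")
  cat("  active clusters:", x$n_active, "of", length(x$mixture$pi), "\n")
  cat("  mean per-point log-likelihood:", format(x$loglik, digits = 6), "\n")
  tab <- table(factor(x$labels, levels = x$mixture$codes))
  cat("  label counts:\n")
  print(tab)
  invisible(x)
}

#' Cluster statistics of a fit
#'
#' @param fit an \code{"embc_fit"} object.
#' @return data frame with one row per cluster: code, active flag, mixing
#'   proportion, label count and fraction, and per-variable means.
#' @export
cluster_stats <- function(fit) {
  model <- fit$mixture
  cnt <- as.integer(table(factor(fit$labels, levels = model$codes)))
  out <- data.frame(code = model$codes, active = model$active,
                    pi = model$pi, n = cnt, frac = cnt / length(fit$labels))
  cbind(out, stats::setNames(as.data.frame(model$mu),
                             paste0("mean_", colnames(model$mu))))
}

#' Scatter plot of a bivariate fit
#'
#' Points coloured by label (LL orange, LH red, HL cyan, HH blue) with the
#' final delimiters drawn as dashed (low-context) and dot-dashed
#' (high-context) lines.
#'
#' @param x an \code{"embc_fit"} object over two variables.
#' @param ... passed to \code{plot}.
#' @export
plot.embc_fit <- function(x, ...) {
  stopifnot(ncol(x$features$X) == 2L)
  cols <- label_colors()
  Xv <- x$features$X[x$valid, ]
  labv <- x$labels[x$valid]
  graphics::plot(Xv[, 1L], Xv[, 2L], col = cols[labv], pch = 16, cex = 0.6,
                 xlab = colnames(Xv)[1L], ylab = colnames(Xv)[2L], ...)
  for (r in seq_len(nrow(x$delimiters))) {
    v <- x$delimiters$value[r]
    if (is.na(v)) next
    lty <- if (grepl("L", x$delimiters$context[r])) 2L else 4L
    if (x$delimiters$var[r] == 1L) graphics::abline(v = v, lty = lty)
    else graphics::abline(h = v, lty = lty)
  }
  graphics::points(x$mixture$mu[x$mixture$active, 1L],
                   x$mixture$mu[x$mixture$active, 2L], pch = 19)
  invisible(x)
}

label_colors <- function() {
  c(LL = "orange", LH = "red", HL = "cyan3", HH = "blue")
}

#' Population-level fit over several feature sets
#'
#' Stacks the feature matrices of several individuals, fits a single model
#' to the pooled points, and splits the labels back per individual. Useful
#' for defining population-average modes: each individual typically uses
#' only a subset of the population-level clusters.
#'
#' @param feature_sets list of \code{\link{feature_matrix}} objects with
#'   identical variables.
#' @param ... passed to \code{\link{embc}}.
#' @return list with the pooled \code{fit}, per-set \code{labels} (list of
#'   character vectors) and a per-individual cluster \code{usage} count
#'   table.
#' @export
embc_pooled <- function(feature_sets, ...) {
  stopifnot(length(feature_sets) >= 1L)
  vars <- lapply(feature_sets, function(f) colnames(f$X))
  if (!all(vapply(vars, identical, logical(1), y = vars[[1L]])))
    stop("all feature sets must share the same variables")
  X <- do.call(rbind, lapply(feature_sets, `[[`, "X"))
  U <- do.call(rbind, lapply(feature_sets, `[[`, "U"))
  tau <- unlist(lapply(feature_sets, `[[`, "tau"))
  valid <- unlist(lapply(feature_sets, `[[`, "valid"))
  pooled <- feature_matrix(X, U = U, tau = tau,
                           tau_mode = feature_sets[[1L]]$tau_mode,
                           valid = valid, units = feature_sets[[1L]]$units)
  fit <- embc(pooled, ...)
  sizes <- vapply(feature_sets, function(f) nrow(f$X), integer(1))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  labels <- Map(function(a, b) fit$labels[a:b], starts, ends)
  usage <- t(vapply(labels, function(lb)
    as.integer(table(factor(lb, levels = fit$mixture$codes))),
    integer(length(fit$mixture$codes))))
  colnames(usage) <- fit$mixture$codes
  list(fit = fit, labels = labels, usage = usage)
}
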