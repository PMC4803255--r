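test_that("posterior weights match direct density-formula evaluation", {
  set.seed(11)
  # symmetry: identical components, equal mixing -> all weights 0.5
  mu <- rbind(c(0, 0), c(0, 0))
  sigma <- array(diag(2), c(2, 2, 2))
  model <- embclust:::mixture_model(mu, sigma, c(0.5, 0.5))
  X <- matrix(rnorm(20), 10, 2)
  W <- embc_estep(X, model)
  expect_equal(W, matrix(0.5, 10, 2))
  # separation limit
  mu2 <- rbind(c(0, 0), c(100, 0))
  model2 <- embclust:::mixture_model(mu2, sigma, c(0.5, 0.5))
  W2 <- embc_estep(matrix(c(0, 0), 1, 2), model2)
  expect_gt(W2[1, 1], 1 - 1e-10)
  # random instances vs the naive oracle
  for (rep in 1:5) {
    mu3 <- matrix(rnorm(4, sd = 2), 2, 2)
    sigma3 <- array(c(random_cov2(), random_cov2()), c(2, 2, 2))
    p <- runif(1, 0.2, 0.8)
    model3 <- embclust:::mixture_model(mu3, sigma3, c(p, 1 - p))
    X3 <- matrix(rnorm(40, sd = 2), 20, 2)
    expect_equal(embc_estep(X3, model3),
                 oracle_estep(X3, mu3, sigma3, c(p, 1 - p)),
                 tolerance = 1e-12)
    expect_equal(rowSums(embc_estep(X3, model3)), rep(1, 20),
                 tolerance = 1e-12)
  }
})

test_that("max-entropy initialization splits at medians with entropy ties to variable 1", {
  # m = 1: the single delimiter is the sample median
  x <- matrix(c(5, 1, 9, 3, 7), ncol = 1)
  init <- init_max_entropy(x, sigma_min = 0.01)
  expect_equal(init$delimiters$value, 5)
  # m = 2 symmetric data: both splits have 1 bit entropy; variable 1 chosen
  g <- as.matrix(expand.grid(x1 = c(0, 1), x2 = c(0, 1)))
  init2 <- init_max_entropy(rbind(g, g), sigma_min = 0.01)
  d <- init2$delimiters
  expect_equal(nrow(d), 4L) # m * 2^(m-1)
  # variable 1 split first: both its contexts share the global median
  expect_equal(d$value[d$var == 1], rep(median(g[, 1]), 2))
})

test_that("initialization variable order matches exhaustive search over orders", {
  set.seed(23)
  # duplicated values make the median split of x1 unbalanced (low entropy),
  # so the entropy criterion must pick x2 first
  X <- cbind(x1 = c(rep(0, 9), 1, 2, 3),
             x2 = rnorm(12, 0, 3))
  init <- init_max_entropy(X, sigma_min = 0.01)
  # brute force: entropy of each variable's median split of the full set
  ent <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
  first_entropy <- sapply(1:2, function(l) ent(mean(X[, l] <= median(X[, l]))))
  best_first <- which(first_entropy >= max(first_entropy) - 1e-12)[1]
  expect_equal(best_first, 2L)
  # the first-chosen variable has identical delimiters across its contexts
  d <- init$delimiters
  vals_by_var <- split(d$value, d$var)
  chosen_first <- which(sapply(vals_by_var, function(v) length(unique(v)) == 1L))
  expect_true(best_first %in% chosen_first)
  expect_equal(unique(vals_by_var[[best_first]]), median(X[, best_first]))
  # second-level delimiters are within-subset medians
  other <- setdiff(1:2, best_first)
  lo <- X[, best_first] <= median(X[, best_first])
  expect_setequal(round(vals_by_var[[other]], 10),
                  round(c(median(X[lo, other]), median(X[!lo, other])), 10))
})

test_that("delimiters sit at the minimum pairwise-posterior difference", {
  # symmetric 1-D pair with a point projecting exactly to the midpoint
  mu <- rbind(-1, 1)
  sigma <- array(1, c(1, 1, 2))
  model <- embclust:::mixture_model(mu, sigma, c(0.5, 0.5))
  X <- matrix(c(-1.5, -0.5, 0, 0.5, 1.5), ncol = 1)
  expect_equal(compute_delimiter(X, model, 1, 2, 1), 0)

  # random adjacent pairs: within one grid spacing of a dense grid search
  set.seed(31)
  for (rep in 1:10) {
    mu2 <- rbind(c(runif(1, -2, 0), runif(1, -1, 1)),
                 c(runif(1, 0.5, 2.5), runif(1, -1, 1)))
    sigma2 <- array(c(random_cov2(), random_cov2()), c(2, 2, 2))
    p <- runif(1, 0.15, 0.85)
    model2 <- embclust:::mixture_model(mu2, sigma2, c(p, 1 - p))
    X2 <- matrix(runif(400, -3, 3), 200, 2)
    d_pkg <- compute_delimiter(X2, model2, 1, 2, 1)
    d_grid <- oracle_delimiter_grid(model2, 1, 2, 1)
    # the package picks a projected data point; allow the spacing of the
    # projected points around the grid optimum
    tt <- ((sweep(X2, 2, mu2[1, ]) %*% (mu2[2, ] - mu2[1, ])) /
             sum((mu2[2, ] - mu2[1, ])^2))
    proj1 <- sort(mu2[1, 1] + tt[tt >= 0 & tt <= 1] * (mu2[2, 1] - mu2[1, 1]))
    spacing <- max(diff(proj1))
    expect_lt(abs(d_pkg - d_grid), spacing + 1e-9)
  }

  # unequal mixing shifts the delimiter toward the rarer component
  sig <- array(c(diag(0.2, 2), diag(0.2, 2)), c(2, 2, 2))
  mu3 <- rbind(c(-1, 0), c(1, 0))
  model_eq <- embclust:::mixture_model(mu3, sig, c(0.5, 0.5))
  model_uneq <- embclust:::mixture_model(mu3, sig, c(0.95, 0.05))
  X3 <- cbind(seq(-1, 1, length.out = 401), 0)
  d_eq <- compute_delimiter(X3, model_eq, 1, 2, 1)
  d_uneq <- compute_delimiter(X3, model_uneq, 1, 2, 1)
  expect_gt(d_uneq, d_eq) # pushed toward mu_b when pi_a >> pi_b
  expect_equal(d_uneq, oracle_delimiter_grid(model_uneq, 1, 2, 1),
               tolerance = 0.01)
})

test_that("region membership handles exact, overlapping and extended delimiters", {
  codes <- binary_codes(2)
  model <- embclust:::mixture_model(matrix(0, 4, 2),
                                    array(diag(2), c(2, 2, 4)),
                                    rep(0.25, 4), codes = codes)
  W <- matrix(0.25, 5, 4)
  d <- delimiter_pairs(2)
  # aligned delimiters -> exact partition
  d$value <- c(0.5, 0.5, 0.5, 0.5)
  X <- rbind(c(0.2, 0.2), c(0.2, 0.8), c(0.8, 0.2), c(0.8, 0.8), c(0.5, 0.5))
  mem <- region_membership(X, d, model, W)
  expect_equal(mem[1:4, ], diag(4) == 1, ignore_attr = TRUE)
  expect_equal(unname(rowSums(mem[1:4, ])), rep(1, 4))
  expect_equal(unname(mem[5, ]), rep(TRUE, 4)) # boundary point in all

  # overlapping: r_.L > r_.H and r_L. > r_H. -> centre in both LL and HH
  # rows of d: (var1, ctx .L), (var1, ctx .H), (var2, ctx L.), (var2, ctx H.)
  d$value[d$var == 1] <- c(0.7, 0.3) # r_.L = 0.7, r_.H = 0.3
  d$value[d$var == 2] <- c(0.7, 0.3) # r_L. = 0.7, r_H. = 0.3
  mem_ov <- region_membership(matrix(c(0.5, 0.5), 1), d, model, W[1, , drop = FALSE])
  expect_equal(unname(mem_ov[1, ]), c(TRUE, FALSE, FALSE, TRUE))

  # non-overlapping delimiters: the extended middle rectangle belongs to
  # both LH and HL
  d$value[d$var == 1] <- c(0.3, 0.7)
  d$value[d$var == 2] <- c(0.3, 0.7)
  mem_no <- region_membership(matrix(c(0.5, 0.5), 1), d, model, W[1, , drop = FALSE])
  expect_equal(unname(mem_no[1, ]), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("delimiter context bookkeeping matches the code layout", {
  d <- delimiter_pairs(2)
  expect_equal(d$context, c(".L", ".H", "L.", "H."))
  expect_equal(binary_codes(2)[d$lo], c("LL", "LH", "LL", "HL"))
  expect_equal(binary_codes(2)[d$hi], c("HL", "HH", "LH", "HH"))
  for (m in 1:4) expect_equal(nrow(delimiter_pairs(m)), m * 2^(m - 1))
  expect_equal(binary_codes(3)[delimiter_pairs(3)$lo[delimiter_pairs(3)$var == 2]],
               c("LLL", "LLH", "HLL", "HLH"))
})

test_that("constrained M step reduces to the plain M step and matches brute-force sums", {
  set.seed(41)
  X <- matrix(rnorm(80, sd = 2), 40, 2)
  W <- matrix(runif(80), 40, 2)
  W <- W / rowSums(W)
  model <- embclust:::mixture_model(matrix(rnorm(4), 2, 2),
                                    array(diag(2), c(2, 2, 2)),
                                    c(0.5, 0.5), codes = c("L", "H"))
  d <- delimiter_pairs(1)
  d$value <- NA_real_ # no active constraints
  U1 <- matrix(1, 40, 2)
  mem_all <- matrix(TRUE, 40, 2)
  smin <- rep(1e-6, 2)
  constrained <- embc_mstep(X, W, U1, mem_all, model, d, smin)
  plain <- embclust:::emc_mstep(X, W, smin)
  expect_equal(constrained$mu, plain$mu, ignore_attr = TRUE)
  expect_equal(constrained$sigma, plain$sigma, tolerance = 1e-14)
  expect_equal(constrained$pi, plain$pi)
  # plain M step vs the double-loop oracle
  orc <- oracle_emc_mstep(X, W)
  expect_equal(plain$mu, orc$mu, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(plain$sigma, orc$sigma, tolerance = 1e-12)
  expect_equal(plain$pi, orc$pi, tolerance = 1e-12)

  # one-hot weights with disjoint membership give per-class moments
  lab <- rep(1:2, each = 20)
  W1h <- cbind(lab == 1, lab == 2) * 1
  mem <- W1h == 1
  fit1h <- embc_mstep(X, W1h, U1, mem, model, d, smin)
  expect_equal(fit1h$mu[1, ], colMeans(X[lab == 1, ]), ignore_attr = TRUE)
  expect_equal(fit1h$pi, c(0.5, 0.5))

  # non-trivial reliability vs the double-loop oracle
  U <- matrix(runif(80), 40, 2)
  memr <- matrix(runif(80) > 0.2, 40, 2)
  memr[rowSums(memr) == 0, 1] <- TRUE
  res <- embc_mstep(X, W, U, memr, model, d, smin)
  for (j in 1:2) {
    orc_j <- oracle_embc_moments(X, W, U, memr, j)
    expect_equal(res$mu[j, ], orc_j$mu, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(res$sigma[, , j], orc_j$sigma, tolerance = 1e-12)
  }
})

test_that("mean per-point log-likelihood matches closed form and naive sums", {
  sigma <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  model <- embclust:::mixture_model(matrix(c(1, 2), 1, 2),
                                    array(sigma, c(2, 2, 1)), 1)
  ll <- loglik_mixture(matrix(c(1, 2), 1, 2), model)
  expect_equal(ll, -log(2 * pi) - 0.5 * log(det(sigma)))
  set.seed(5)
  mu <- matrix(rnorm(4), 2, 2)
  sig <- array(c(random_cov2(), random_cov2()), c(2, 2, 2))
  model2 <- embclust:::mixture_model(mu, sig, c(0.3, 0.7))
  X <- matrix(rnorm(60), 30, 2)
  naive <- mean(log(sapply(seq_len(30), function(i)
    0.3 * oracle_dmvnorm(X[i, ], mu[1, ], sig[, , 1]) +
      0.7 * oracle_dmvnorm(X[i, ], mu[2, ], sig[, , 2]))))
  expect_equal(loglik_mixture(X, model2), naive, tolerance = 1e-12)
  # duplication leaves the per-point mean unchanged
  expect_equal(loglik_mixture(rbind(X, X), model2), loglik_mixture(X, model2))
})

test_that("well-separated blobs are recovered with all clusters active", {
  set.seed(51)
  mu_true <- rbind(LL = c(0, 0), LH = c(0, 10), HL = c(10, 0), HH = c(10, 10))
  n_per <- 200
  X <- do.call(rbind, lapply(1:4, function(j)
    cbind(rnorm(n_per, mu_true[j, 1], 0.5), rnorm(n_per, mu_true[j, 2], 0.5))))
  fit <- embc(X, sigma_min = 0.01)
  expect_equal(fit$n_active, 4L)
  expect_equal(fit$status, "converged")
  se <- 0.5 / sqrt(n_per)
  for (j in 1:4) {
    expect_true(all(abs(fit$mixture$mu[j, ] - mu_true[j, ]) < 3 * se + 0.05))
  }
  ref <- rep(rownames(mu_true), each = n_per)
  expect_gt(f_measure(ref, fit$labels), 0.999)
})

test_that("single-Gaussian data yields absorption but labels for every point", {
  set.seed(61)
  X <- matrix(rnorm(600), 300, 2)
  fit <- suppressWarnings(embc(X, sigma_min = 0.01))
  expect_lte(fit$n_active, 4L)
  expect_false(anyNA(fit$labels))
  expect_true(all(abs(rowSums(fit$W) - 1) < 1e-12))
  # degenerate identical points: one active cluster
  X1 <- matrix(1, 20, 2)
  fit1 <- suppressWarnings(embc(X1, sigma_min = 0.01))
  expect_equal(fit1$n_active, 1L)
  expect_false(anyNA(fit1$labels))
})

test_that("fitting is deterministic and insensitive to RNG state", {
  ds <- simulate_dataset(200, 0.05, seed = 2)
  set.seed(1); fit1 <- embc(ds$features)
  set.seed(99999); fit2 <- embc(ds$features)
  expect_identical(fit1$mixture, fit2$mixture)
  expect_identical(fit1$labels, fit2$labels)
})

test_that("post-M-step means lie inside their binary regions", {
  for (s in 1:5) {
    ds <- simulate_dataset(300, c(0.01, 0.05, 0.1)[1 + s %% 3], seed = 100 + s)
    Xv <- ds$features$X
    init <- init_max_entropy(Xv, sigma_min = rep(0.01, 2))
    model <- init$model
    delims <- init$delimiters
    U1 <- matrix(1, nrow(Xv), 2)
    for (it in 1:15) {
      W <- embc_estep(Xv, model)
      delims <- embclust:::compute_delimiters(Xv, model, delims)
      mem <- region_membership(Xv, delims, model, W)
      model <- suppressWarnings(
        embc_mstep(Xv, W, U1, mem, model, delims, rep(0.01, 2)))
      for (r in seq_len(nrow(delims))) {
        v <- delims$value[r]
        if (is.na(v)) next
        lo <- delims$lo[r]; hi <- delims$hi[r]; l <- delims$var[r]
        if (model$active[lo]) expect_lte(model$mu[lo, l], v)
        if (model$active[hi]) expect_gte(model$mu[hi, l], v)
      }
      expect_true(all(apply(model$sigma[, , model$active, drop = FALSE],
                            3, diag) >= 0.01^2 - 1e-15))
    }
  }
})

test_that("best-so-far log-likelihood is non-decreasing along the trace", {
  for (s in 1:3) {
    ds <- simulate_dataset(250, 0.05, seed = 200 + s)
    fit <- suppressWarnings(embc(ds$features))
    best <- cummax(fit$loglik_trace)
    expect_true(all(diff(best) >= 0))
    # increasing optimization interspersed with sporadic drops: most
    # increments are non-negative and the fit improves on its start
    expect_gt(mean(diff(fit$loglik_trace) >= -1e-9), 0.5)
    expect_gt(fit$loglik_trace[length(fit$loglik_trace)],
              fit$loglik_trace[1])
  }
})

test_that("pooled fitting stacks datasets and splits labels back", {
  ds <- simulate_dataset(150, 0.1, seed = 9)
  res <- embc_pooled(list(ds$features, ds$features))
  expect_identical(res$labels[[1]], res$labels[[2]])
  expect_equal(nrow(res$usage), 2L)
  expect_identical(unname(res$usage[1, ]), unname(res$usage[2, ]))
  # stacking order: fit depends on data content, not on block order
  ds2 <- simulate_dataset(150, 0.1, seed = 10)
  a <- embc_pooled(list(ds$features, ds2$features))
  b <- embc_pooled(list(ds2$features, ds$features))
  expect_equal(a$fit$mixture$mu, b$fit$mixture$mu, tolerance = 1e-8)
  expect_identical(a$labels[[1]], b$labels[[2]])
  expect_error(embc_pooled(list(ds$features,
                                feature_matrix(matrix(1:10, 5, 2)))),
               "same variables")
})
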