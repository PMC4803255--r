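# Confusion-matrix scoring of a labelling against a reference, plus the
# benchmark and robustness experiment drivers.

#' Confusion matrix
#'
#' Cross-tabulation of reference (rows) against predicted (columns) labels.
#' Pairs with a missing value on either side are dropped.
#'
#' @param ref,pred label vectors of equal length.
#' @param levels optional common label set; defaults to the sorted union.
#' @return an integer c x c matrix of class \code{"confusion_matrix"}.
#' @export
confusion <- function(ref, pred, levels = NULL) {
  if (length(ref) != length(pred)) stop("ref and pred must have equal length")
  keep <- !(is.na(ref) | is.na(pred))
  ref <- as.character(ref)[keep]
  pred <- as.character(pred)[keep]
  if (is.null(levels)) levels <- sort(unique(c(ref, pred)))
  cm <- table(factor(ref, levels = levels), factor(pred, levels = levels))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("reference", "predicted")
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Recall, precision and F-measure from a confusion matrix
#'
#' Per class: recall = diagonal / row sum, precision = diagonal / column sum,
#' F = harmonic mean of the two (0 when both are 0). The overall F-measure is
#' the reference-marginal-weighted mean of the per-class F values.
#'
#' @param cm a square confusion matrix (reference in rows).
#' @return list with \code{per_class} (data frame: marginal, recall,
#'   precision, F) and \code{overall_F}.
#' @export
clustering_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  dg <- diag(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  recall <- ifelse(rs > 0, dg / rs, 0)
  precision <- ifelse(cs > 0, dg / cs, 0)
  f <- ifelse(recall + precision > 0,
              2 * precision * recall / (precision + recall), 0)
  mrg <- rs / total
  cls <- rownames(cm)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(cm)))
  list(per_class = data.frame(class = cls, marginal = mrg,
                              recall = recall, precision = precision,
                              F = f, row.names = NULL),
       overall_F = sum(mrg * f))
}

#' Overall F-measure of a labelling against a reference
#'
#' @param ref,pred label vectors.
#' @param levels optional common label set.
#' @return scalar in [0, 1].
#' @export
f_measure <- function(ref, pred, levels = NULL) {
  clustering_metrics(confusion(ref, pred, levels))$overall_F
}

#' Match arbitrary cluster indices to reference classes
#'
#' Unconstrained clusterings (e.g. the EM baseline) return clusters in
#' arbitrary order; this finds the one-to-one column permutation of the
#' confusion matrix that maximizes the overall F-measure, exhaustively over
#' all permutations (intended for c <= 8). Binary-coded labellings are
#' semantically anchored and do not need this step.
#'
#' @param cm square confusion matrix.
#' @return list with \code{perm} (perm[j] = reference class index matched to
#'   predicted column j), the permuted \code{cm}, and \code{overall_F}.
#' @export
match_clusters <- function(cm) {
  cm <- unclass(cm)
  c_n <- ncol(cm)
  stopifnot(nrow(cm) == c_n)
  if (c_n > 8L) stop("exhaustive matching is limited to 8 classes")
  perms <- permutations(c_n)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    prm <- perms[p, ]
    # prm[j]: reference class that predicted column j is mapped to
    cmp <- cm[, order(prm), drop = FALSE]
    f <- clustering_metrics(cmp)$overall_F
    if (is.null(best) || f > best$overall_F) {
      best <- list(perm = prm, cm = cmp, overall_F = f)
    }
  }
  dimnames(best$cm) <- dimnames(cm)
  best
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
  dimnames(out) <- NULL
  out
}

#' Synthetic benchmark driver
#'
#' Reproduces the synthetic performance experiment: for each combination of
#' trajectory length, overlap parameter and sampling scheme, generates
#' \code{reps} labelled datasets, fits each requested method, and scores the
#' labels against the generating states with the overall F-measure. Binary
#' clustering labels are scored directly through their codes; baseline EM
#' labels are first matched to the reference classes
#' (\code{\link{match_clusters}}).
#'
#' @param ns vector of trajectory lengths.
#' @param gammas vector of overlap parameters.
#' @param scheme \code{"markov"} or \code{"prior"}.
#' @param reps replicates per cell.
#' @param methods subset of \code{c("embc", "emc")}.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param emc_starts restarts for the EM baseline.
#' @return list with \code{runs} (one row per fit: method, n, gamma, rep, F,
#'   failed) and \code{summary} (per cell: mean F, RMSE of F around the mean,
#'   failures).
#' @export
run_benchmark <- function(ns = c(50, 100, 200, 400, 800, 1600),
                          gammas = c(0.01, 0.05, 0.1),
                          scheme = "markov", reps = 10L,
                          methods = c("embc", "emc"), seed = 1L,
                          emc_starts = 5L) {
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^31 - 2, length(ns) * length(gammas) * reps),
                      nrow = reps)
  cell <- 0L
  runs <- list()
  for (n in ns) for (g in gammas) {
    cell <- cell + 1L
    for (r in seq_len(reps)) {
      ds <- simulate_dataset(n, g, scheme = scheme,
                             seed = rep_seeds[r, cell])
      ref <- ds$codes[ds$states]
      for (method in methods) {
        f <- NA_real_
        failed <- FALSE
        res <- tryCatch({
          if (method == "embc") {
            fit <- suppressWarnings(embc(ds$features))
            f_measure(ref, fit$labels, levels = ds$codes)
          } else {
            fit <- suppressWarnings(
              emc_fit(ds$features, k = length(ds$codes),
                      n_starts = emc_starts, seed = rep_seeds[r, cell]))
            # rows = reference codes, columns = arbitrary cluster indices
            cm <- unclass(table(factor(ref, levels = ds$codes),
                                factor(fit$labels,
                                       levels = seq_along(ds$codes))))
            match_clusters(matrix(as.integer(cm), nrow = nrow(cm),
                                  dimnames = dimnames(cm)))$overall_F
          }
        }, error = function(e) NA_real_)
        if (is.na(res)) failed <- TRUE else f <- res
        runs[[length(runs) + 1L]] <- data.frame(
          method = method, n = n, gamma = g, scheme = scheme, rep = r,
          F = f, failed = failed)
      }
    }
  }
  runs <- do.call(rbind, runs)
  agg <- split(runs, interaction(runs$method, runs$n, runs$gamma, drop = TRUE))
  summary <- do.call(rbind, lapply(agg, function(d) {
    f <- d$F[!d$failed]
    data.frame(method = d$method[1L], n = d$n[1L], gamma = d$gamma[1L],
               scheme = d$scheme[1L], reps = nrow(d),
               failures = sum(d$failed),
               mean_F = mean(f),
               rmse_F = sqrt(mean((f - mean(f))^2)))
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

#' Robustness experiment driver
#'
#' Measures the stability of the labelling under data loss or jittering.
#' The fit on the full data provides the reference labels; for each
#' degradation factor and replicate the data are degraded, refitted, and the
#' new labels are scored (overall F) against the reference labels on the
#' surviving points.
#'
#' @param features the full \code{\link{feature_matrix}}.
#' @param kind \code{"loss"} or \code{"jitter"}.
#' @param factors degradation factor grid (k_dl or k_di values).
#' @param reps replicates per factor.
#' @param reliability use reliability weights in the degraded refits.
#' @param seed master seed.
#' @param ... passed to \code{\link{embc}}.
#' @return list with \code{runs} (factor, rep, F, n_used) and \code{summary}
#'   (per factor: mean F over valid replicates).
#' @export
run_robustness <- function(features, kind = c("loss", "jitter"),
                           factors = if (kind[1L] == "loss")
                             seq(0, 0.8, by = 0.2) else seq(0, 0.1, by = 0.02),
                           reps = 10L, reliability = TRUE, seed = 1L, ...) {
  kind <- match.arg(kind)
  ref_fit <- suppressWarnings(embc(features, reliability = reliability, ...))
  ref <- ref_fit$labels
  k_min <- 2L^ncol(features$X)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^31 - 2, length(factors) * reps),
                      nrow = reps)
  runs <- list()
  for (fi in seq_along(factors)) {
    fac <- factors[fi]
    for (r in seq_len(reps)) {
      s <- rep_seeds[r, fi]
      if (kind == "loss") {
        deg <- degrade_loss(features, fac, seed = s)
        sub <- deg$features
        ref_sub <- ref[deg$kept]
      } else {
        sub <- degrade_jitter(features, fac, seed = s)
        ref_sub <- ref
      }
      if (sum(sub$valid) < k_min) {
        runs[[length(runs) + 1L]] <- data.frame(
          factor = fac, rep = r, F = NA_real_, n_used = sum(sub$valid))
        next
      }
      f <- tryCatch({
        fit <- suppressWarnings(embc(sub, reliability = reliability, ...))
        f_measure(ref_sub, fit$labels, levels = ref_fit$mixture$codes)
      }, error = function(e) NA_real_)
      runs[[length(runs) + 1L]] <- data.frame(
        factor = fac, rep = r, F = f, n_used = sum(sub$valid))
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(runs, runs$factor), function(d) {
    data.frame(factor = d$factor[1L], reps = nrow(d),
               invalid = sum(is.na(d$F)),
               mean_F = mean(d$F, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary, reference = ref_fit)
}
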