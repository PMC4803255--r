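#' Movement trajectory container
#'
#' Bundles an ordered sequence of timestamped positions. Positions are either
#' geographic (longitude/latitude, WGS84 degrees) or planar (x/y, metres);
#' the geometry determines how distances and headings are computed downstream.
#'
#' @param t numeric vector of timestamps (seconds since epoch) or POSIXct;
#'   must be strictly increasing.
#' @param x longitude (degrees) when \code{geodesic}, otherwise planar x (m).
#' @param y latitude (degrees) when \code{geodesic}, otherwise planar y (m).
#' @param geodesic logical; \code{TRUE} for lon/lat input.
#' @param id character track identifier.
#' @return An object of class \code{"trajectory"}: a data frame with columns
#'   \code{t}, \code{x}, \code{y} and attributes \code{geodesic} and \code{id}.
#' @export
trajectory <- function(t, x, y, geodesic = TRUE, id = "track") {
  t <- as.numeric(t)
  x <- as.numeric(x)
  y <- as.numeric(y)
  stopifnot(length(t) == length(x), length(t) == length(y))
  keep <- !(is.na(t) | is.na(x) | is.na(y))
  if (!all(keep)) {
    embc_note("dropping ", sum(!keep), " rows with missing coordinates: ",
              paste(which(!keep), collapse = ","))
    t <- t[keep]; x <- x[keep]; y <- y[keep]
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop("timestamps must be strictly increasing (violation at point ", bad, ")")
  }
  if (geodesic) {
    if (any(x < -180 | x > 180) || any(y < -90 | y > 90))
      stop("lon/lat out of range for geodesic trajectory")
  }
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "geodesic") <- isTRUE(geodesic)
  attr(out, "id") <- id
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Read a trajectory from a CSV file
#'
#' Defaults follow the Movebank column dialect
#' (\code{timestamp, location-long, location-lat}); a planar file with columns
#' \code{t, x, y} is read by setting \code{geodesic = FALSE} (then the
#' default columns become \code{t}, \code{x}, \code{y}). Timestamps may be
#' ISO-8601 strings or epoch seconds.
#'
#' @param file path to a CSV file.
#' @param t_col,x_col,y_col column names; \code{NULL} picks the dialect default.
#' @param geodesic logical; lon/lat (default) or planar coordinates.
#' @param id track identifier (defaults to the file name).
#' @return A \code{\link{trajectory}}.
#' @export
read_trajectory_csv <- function(file, t_col = NULL, x_col = NULL, y_col = NULL,
                                geodesic = TRUE, id = NULL) {
  dat <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(t_col)) t_col <- if (geodesic) "timestamp" else "t"
  if (is.null(x_col)) x_col <- if (geodesic) "location-long" else "x"
  if (is.null(y_col)) y_col <- if (geodesic) "location-lat" else "y"
  miss <- setdiff(c(t_col, x_col, y_col), names(dat))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tv <- dat[[t_col]]
  if (is.character(tv)) {
    parsed <- suppressWarnings(as.numeric(tv))
    if (anyNA(parsed)) {
      parsed <- as.numeric(as.POSIXct(tv, tz = "UTC",
                                      tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                     "%Y-%m-%d %H:%M:%OS",
                                                     "%Y-%m-%d")))
    }
    tv <- parsed
  }
  trajectory(tv, dat[[x_col]], dat[[y_col]], geodesic = geodesic,
             id = if (is.null(id)) basename(file) else id)
}

#' Feature matrix with reliability weights
#'
#' The container consumed by the clustering routines: an n x m matrix of
#' movement variables plus, per point and variable, a reliability weight in
#' [0, 1] used to discount inaccurate observations in parameter estimation,
#' the sampling intervals they were derived from, and a validity mask (rows
#' with \code{valid = FALSE} are excluded from fitting but kept for label
#' back-fill).
#'
#' @param X numeric n x m matrix of variables.
#' @param U n x m reliability weights in [0, 1]; default all 1 (disabled).
#' @param tau sampling intervals (s) per row; default \code{NA}.
#' @param tau_mode scalar mode of the sampling interval (s).
#' @param valid logical mask of rows usable for fitting.
#' @param units character vector of variable units.
#' @return An object of class \code{"feature_matrix"}.
#' @export
feature_matrix <- function(X, U = NULL, tau = NULL, tau_mode = NA_real_,
                           valid = NULL, units = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); m <- ncol(X)
  if (is.null(U)) U <- matrix(1, n, m)
  U <- as.matrix(U)
  stopifnot(all(dim(U) == dim(X)))
  if (any(U < 0 | U > 1, na.rm = TRUE)) stop("reliability weights must lie in [0,1]")
  if (is.null(tau)) tau <- rep(NA_real_, n)
  if (is.null(valid)) valid <- stats::complete.cases(X)
  if (is.null(units)) units <- rep("", m)
  structure(list(X = X, U = U, tau = as.numeric(tau),
                 tau_mode = as.numeric(tau_mode),
                 valid = as.logical(valid), units = units),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$X), "points x", ncol(x$X), "variables (",
      paste(colnames(x$X), collapse = ", "), ")\n")
  cat("  valid rows:", sum(x$valid), " tau mode:", format(x$tau_mode), "s\n")
  invisible(x)
}

# Great-circle distance (m) between successive rows, sphere radius 6371008.8 m.
step_distances <- function(traj) {
  n <- nrow(traj)
  p <- cbind(traj$x, traj$y)
  if (attr(traj, "geodesic")) {
    geosphere::distHaversine(p[-n, , drop = FALSE], p[-1L, , drop = FALSE],
                             r = 6371008.8)
  } else {
    sqrt(rowSums((p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  }
}

# Heading (radians) of each successive step. Geodesic headings are initial
# great-circle bearings; planar headings are atan2(dy, dx). Only differences
# of successive headings are used downstream, so the convention is free.
step_headings <- function(traj) {
  n <- nrow(traj)
  p <- cbind(traj$x, traj$y)
  if (attr(traj, "geodesic")) {
    b <- geosphere::bearing(p[-n, , drop = FALSE], p[-1L, , drop = FALSE])
    b * pi / 180
  } else {
    d <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
    atan2(d[, 2L], d[, 1L])
  }
}

#' Mode of the sampling-interval distribution
#'
#' Most frequent sampling interval, estimated as the median of the fullest
#' 1-second histogram bin; falls back to the overall median when no bin holds
#' at least two intervals.
#'
#' @param tau positive numeric vector of sampling intervals (s).
#' @return scalar interval mode (s).
#' @export
tau_mode_estimate <- function(tau) {
  tau <- tau[is.finite(tau)]
  if (!length(tau)) return(NA_real_)
  if (any(tau <= 0)) stop("sampling intervals must be positive")
  bins <- floor(tau)
  counts <- table(bins)
  if (max(counts) >= 2) {
    b <- as.numeric(names(counts)[which.max(counts)])
    stats::median(tau[bins == b])
  } else {
    stats::median(tau)
  }
}

#' Velocity and turning angle features
#'
#' Computes the canonical bivariate feature set for behavioural annotation.
#' The velocity at point i is the distance to point i+1 divided by the
#' sampling interval tau_i; the turn at an interior point is the absolute
#' change in heading between the incoming and outgoing steps, in [0, pi].
#' The first point (no incoming step) and the last point (no outgoing step)
#' are flagged invalid, leaving n - 2 valid rows. Reliability weights
#' discount points with sampling intervals longer than the track's interval
#' mode (see \code{\link{reliability_from_tau}}); a custom reliability
#' function of the interval vector can be supplied instead.
#'
#' @param traj a \code{\link{trajectory}} with at least 3 points.
#' @param reliability \code{TRUE} for the default interval-based weights,
#'   \code{FALSE} for unit weights, or a function \code{f(tau, tau_mode)}
#'   returning weights in [0, 1].
#' @return A \code{\link{feature_matrix}} with variables
#'   \code{velocity} (m/s) and \code{turn} (rad).
#' @export
compute_velocity_turn <- function(traj, reliability = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 3L) stop("at least 3 points are required for velocity/turn features")
  tau <- diff(traj$t)
  if (any(tau <= 0)) stop("zero or negative sampling interval at point ",
                          which(tau <= 0)[1L])
  dist <- step_distances(traj)
  head <- step_headings(traj)
  velocity <- c(dist / tau, NA_real_)          # attributed to the step origin
  turn <- rep(NA_real_, n)
  turn[2:(n - 1L)] <- abs(wrap_angle(head[-1L] - head[-(n - 1L)]))
  tau_full <- c(tau, NA_real_)
  tmode <- tau_mode_estimate(tau)
  u <- rep(1, n)
  if (isTRUE(reliability)) {
    u[seq_len(n - 1L)] <- reliability_from_tau(tau, tmode)
  } else if (is.function(reliability)) {
    u[seq_len(n - 1L)] <- reliability(tau, tmode)
  }
  valid <- rep(TRUE, n)
  valid[c(1L, n)] <- FALSE
  X <- cbind(velocity = velocity, turn = turn)
  feature_matrix(X, U = cbind(velocity = u, turn = u), tau = tau_full,
                 tau_mode = tmode, valid = valid, units = c("m/s", "rad"))
}

#' Interval-based reliability weights
#'
#' Default reliability function for variables estimated from consecutive
#' fixes: points sampled at the track's nominal interval (the interval mode)
#' or faster get full weight; longer gaps are discounted proportionally,
#' \code{u = min(1, tau_mode / tau)}.
#'
#' @param tau positive sampling intervals (s).
#' @param tau_mode positive scalar interval mode (s).
#' @return weights in (0, 1], non-increasing in \code{tau}.
#' @export
reliability_from_tau <- function(tau, tau_mode) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("tau must be positive")
  if (!is.finite(tau_mode) || tau_mode <= 0) stop("tau_mode must be positive")
  pmin(1, tau_mode / tau)
}

#' Combined reliability of a variable pair
#'
#' The weight used for covariance terms mixing two variables: the normalized
#' Euclidean length of the two per-variable weights,
#' \code{sqrt(u_r^2 + u_s^2) / sqrt(2)}, so that (1,1) maps to 1.
#'
#' @param u_r,u_s weights in [0, 1] (vectorized).
#' @return combined weights in [0, 1].
#' @export
pair_reliability <- function(u_r, u_s) {
  if (any(u_r < 0 | u_r > 1 | u_s < 0 | u_s > 1, na.rm = TRUE))
    stop("reliability weights must lie in [0,1]")
  sqrt(u_r^2 + u_s^2) / sqrt(2)
}

#' Windowed path-shape features
#'
#' Aggregates a trajectory into consecutive fixed-duration windows and
#' computes, per window: mean speed (gross path length over elapsed time),
#' net displacement (distance between the first and last fix), and
#' straightness (net displacement over gross path length, in [0, 1], defined
#' as 1 for a degenerate zero-length path). This trivariate window summary
#' suits highly resolved tracks (e.g. video-recorded crawling) where
#' point-wise velocity/turn are too noisy.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param window window length in seconds (> 0).
#' @return A \code{\link{feature_matrix}} with variables \code{mean_speed},
#'   \code{net_displacement}, \code{straightness}; \code{tau} holds the
#'   window length.
#' @export
windowed_features <- function(traj, window) {
  stopifnot(inherits(traj, "trajectory"), window > 0)
  t0 <- traj$t[1L]
  if (traj$t[nrow(traj)] - t0 < window)
    stop("trajectory spans less than one window")
  idx <- floor((traj$t - t0) / window)
  dist <- c(step_distances(traj), NA_real_)
  rows <- lapply(sort(unique(idx)), function(w) {
    sel <- which(idx == w)
    if (length(sel) < 2L) {
      embc_note("window ", w + 1L, " has fewer than 2 fixes; skipped")
      return(NULL)
    }
    first <- sel[1L]; last <- sel[length(sel)]
    gross <- sum(dist[first:(last - 1L)])
    net <- if (attr(traj, "geodesic")) {
      geosphere::distHaversine(c(traj$x[first], traj$y[first]),
                               c(traj$x[last], traj$y[last]), r = 6371008.8)
    } else {
      sqrt((traj$x[last] - traj$x[first])^2 + (traj$y[last] - traj$y[first])^2)
    }
    elapsed <- traj$t[last] - traj$t[first]
    c(mean_speed = gross / elapsed,
      net_displacement = net,
      straightness = if (gross == 0) 1 else net / gross)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no window contained at least 2 fixes")
  feature_matrix(rows, tau = rep(window, nrow(rows)), tau_mode = window,
                 valid = rep(TRUE, nrow(rows)),
                 units = c("m/s", "m", ""))
}

#' Running-mean pre-smoothing of features
#'
#' Centred moving average of each variable over the valid points, a
#' pre-processing alternative for coarse-graining the annotation: the window
#' length expresses the behavioural time scale of interest. Edge windows are
#' truncated to the available points. Reliability weights and the validity
#' mask are propagated unchanged.
#'
#' @param features a \code{\link{feature_matrix}}.
#' @param span odd positive integer window width (in points).
#' @return A smoothed \code{\link{feature_matrix}}.
#' @export
running_mean_presmooth <- function(features, span) {
  stopifnot(inherits(features, "feature_matrix"))
  if (span < 1 || span %% 2 == 0) stop("span must be an odd positive integer")
  vidx <- which(features$valid)
  nv <- length(vidx)
  if (span > nv) {
    warning("span exceeds the number of valid points; using the global mean")
    span <- if (nv %% 2 == 1) nv else nv - 1L
  }
  half <- (span - 1L) %/% 2L
  X <- features$X
  for (l in seq_len(ncol(X))) {
    v <- X[vidx, l]
    sm <- vapply(seq_len(nv), function(i) {
      lo <- max(1L, i - half); hi <- min(nv, i + half)
      mean(v[lo:hi])
    }, numeric(1))
    X[vidx, l] <- sm
  }
  out <- features
  out$X <- X
  out
}

#' Write a feature matrix to CSV
#'
#' Columns: \code{id, t, tau} then one column per variable, per reliability
#' weight (\code{u_} prefix), and \code{valid}.
#'
#' @param features a \code{\link{feature_matrix}}.
#' @param file output path.
#' @param id track identifier; \code{t} optional timestamps.
#' @param t optional timestamps aligned to rows.
#' @return the output path, invisibly.
#' @export
write_features_csv <- function(features, file, id = "track", t = NULL) {
  n <- nrow(features$X)
  if (is.null(t)) t <- rep(NA_real_, n)
  df <- data.frame(id = id, t = t, tau = features$tau,
                   features$X, check.names = FALSE)
  U <- features$U
  colnames(U) <- paste0("u_", colnames(features$X))
  df <- cbind(df, U, valid = features$valid)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
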