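# Burst segmentation and export of annotated trajectories.

#' Burst segmentation of an annotated trajectory
#'
#' Converts a label sequence into maximal runs of consecutive equally
#' labelled locations ("bursts"); adjacent bursts differ in label and the
#' bursts tile the sequence. With a trajectory supplied, each burst also
#' carries its time span, duration and mean position.
#'
#' @param labels label vector aligned to the trajectory points.
#' @param traj optional \code{\link{trajectory}} of the same length.
#' @return data frame with one row per burst: \code{label}, \code{start},
#'   \code{end} (point indices), and with a trajectory \code{t_start},
#'   \code{t_end}, \code{duration} (s), \code{mean_x}, \code{mean_y}.
#' @export
bursts <- function(labels, traj = NULL) {
  r <- rle(as.character(labels))
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  out <- data.frame(label = r$values, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(traj)) {
    stopifnot(nrow(traj) == length(labels))
    out$t_start <- traj$t[start]
    out$t_end <- traj$t[end]
    out$duration <- out$t_end - out$t_start
    out$mean_x <- vapply(seq_len(nrow(out)), function(b)
      mean(traj$x[start[b]:end[b]]), numeric(1))
    out$mean_y <- vapply(seq_len(nrow(out)), function(b)
      mean(traj$y[start[b]:end[b]]), numeric(1))
  }
  out
}

#' Annotated trajectory as a data frame
#'
#' @param fit an \code{"embc_fit"} object.
#' @param traj the \code{\link{trajectory}} the features came from.
#' @return data frame with the trajectory columns, \code{label}, one
#'   posterior-weight column per cluster (\code{w_} prefix) and
#'   \code{active_k}.
#' @export
annotation_frame <- function(fit, traj) {
  stopifnot(nrow(traj) == length(fit$labels))
  W <- fit$W
  colnames(W) <- paste0("w_", fit$mixture$codes)
  data.frame(id = attr(traj, "id"), t = traj$t, x = traj$x, y = traj$y,
             label = fit$labels, W, active_k = fit$n_active,
             check.names = FALSE)
}

#' Export an annotated trajectory
#'
#' Writes the annotation as CSV, KML or GeoJSON. Point mode writes one
#' feature (or row) per location with its label and posterior weights; burst
#' mode writes one line-segment feature per burst with its label and
#' duration. The label colour map is LL orange, LH red, HL cyan, HH blue.
#'
#' @param fit an \code{"embc_fit"} object.
#' @param traj the matching \code{\link{trajectory}}.
#' @param file output path.
#' @param format \code{"csv"}, \code{"kml"} or \code{"geojson"}.
#' @param mode \code{"point"} or \code{"burst"}.
#' @return the output path, invisibly.
#' @export
export_annotation <- function(fit, traj, file,
                              format = c("csv", "kml", "geojson"),
                              mode = c("point", "burst")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  df <- annotation_frame(fit, traj)
  br <- bursts(fit$labels, traj)
  switch(format,
    csv = {
      out <- if (mode == "point") df else br
      utils::write.csv(out, file, row.names = FALSE)
    },
    kml = write_kml(df, br, file, mode),
    geojson = write_geojson(df, br, file, mode)
  )
  invisible(file)
}

kml_colors <- function() {
  # KML uses aabbggrr hex
  c(LL = "ff00a5ff", LH = "ff0000ff", HL = "ffffff00", HH = "ffff0000")
}

write_kml <- function(df, br, file, mode) {
  esc <- function(x) gsub("&", "&amp;", x)
  head <- c('<?xml version="1.0" encoding="UTF-8"?>',
            '<kml xmlns="http://www.opengis.net/kml/2.2">', "<Document>")
  styles <- vapply(names(kml_colors()), function(lb) {
    paste0('<Style id="', lb, '"><IconStyle><color>', kml_colors()[[lb]],
           "</color></IconStyle><LineStyle><color>", kml_colors()[[lb]],
           "</color><width>2</width></LineStyle></Style>")
  }, character(1))
  body <- if (mode == "point") {
    vapply(seq_len(nrow(df)), function(i) {
      paste0("<Placemark><name>", esc(df$label[i]), "</name><styleUrl>#",
             df$label[i], "</styleUrl><description>t=", df$t[i],
             "</description><Point><coordinates>", df$x[i], ",", df$y[i],
             ",0</coordinates></Point></Placemark>")
    }, character(1))
  } else {
    vapply(seq_len(nrow(br)), function(b) {
      sel <- br$start[b]:br$end[b]
      coords <- paste0(df$x[sel], ",", df$y[sel], ",0", collapse = " ")
      paste0("<Placemark><name>", esc(br$label[b]), "</name><styleUrl>#",
             br$label[b], "</styleUrl><description>duration=",
             br$duration[b], "s</description><LineString><coordinates>",
             coords, "</coordinates></LineString></Placemark>")
    }, character(1))
  }
  writeLines(c(head, styles, body, "</Document>", "</kml>"), file)
}

write_geojson <- function(df, br, file, mode) {
  cols <- label_colors()
  feats <- if (mode == "point") {
    lapply(seq_len(nrow(df)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(df$x[i], df$y[i])),
           properties = list(label = df$label[i], t = df$t[i],
                             color = unname(cols[df$label[i]])))
    })
  } else {
    lapply(seq_len(nrow(br)), function(b) {
      sel <- br$start[b]:br$end[b]
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = unname(
                             lapply(sel, function(i) c(df$x[i], df$y[i])))),
           properties = list(label = br$label[b],
                             duration = br$duration[b],
                             color = unname(cols[br$label[b]])))
    })
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Deterministic test fixture bundle
#'
#' Writes small plain-text fixtures used by the examples and tests: a
#' 12-point planar trajectory with hand-checkable velocity/turn values (plus
#' the hand-computed feature table), a well-separated 4-blob feature set, a
#' delimiter-overlap instance, and a labelled synthetic dataset
#' (n = 400, gamma = 0.05).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 7L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  # 12-point planar zig-zag: steps of length 10 m every 10 s alternating
  # heading 0 / pi/2, so velocity is 1 m/s everywhere and every interior
  # turn is pi/2
  n <- 12L
  heading <- rep(c(0, pi / 2), length.out = n - 1L)
  x <- c(0, cumsum(10 * cos(heading)))
  y <- c(0, cumsum(10 * sin(heading)))
  put(data.frame(t = seq(0, by = 10, length.out = n), x = x, y = y),
      "traj12.csv")
  put(data.frame(point = 2:(n - 1L), velocity = 1, turn = pi / 2),
      "traj12_features.csv")

  set.seed(seed)
  blob_mu <- rbind(c(0, 0), c(0, 10), c(10, 0), c(10, 10))
  blobs <- do.call(rbind, lapply(1:4, function(j) {
    cbind(x1 = stats::rnorm(50, blob_mu[j, 1L], 0.3),
          x2 = stats::rnorm(50, blob_mu[j, 2L], 0.3), state = j)
  }))
  put(as.data.frame(blobs), "blobs4.csv")

  # overlapping-delimiter instance: two diagonal clusters so that the LL/HH
  # regions overlap in the middle
  ov <- rbind(cbind(stats::rnorm(60, 0.2, 0.1), stats::rnorm(60, 0.2, 0.1)),
              cbind(stats::rnorm(60, 0.8, 0.1), stats::rnorm(60, 0.8, 0.1)))
  put(data.frame(x1 = ov[, 1L], x2 = ov[, 2L]), "overlap.csv")

  ds <- simulate_dataset(400, 0.05, scheme = "markov", seed = seed)
  put(data.frame(state = ds$states, ds$features$X, tau = ds$features$tau),
      "synthetic400.csv")
  files
}
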