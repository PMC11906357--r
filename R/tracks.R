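# Statistics over fate-labelled 3D cell trajectories: radial dynamics,
# sorting scores, displacement maps, first-passage and fate-switch analysis.

#' Construct a TrackSet
#'
#' @param df `data.frame` with columns `track_id`, `t_min`, `x_um`, `y_um`,
#'   `z_um`, `fate` and optionally `parent_id`, `reporter`.
#' @param frameInterval frame interval in minutes; inferred from the median
#'   time difference when omitted.
#' @return a [TrackSet].
#' @export
trackSet <- function(df, frameInterval = NULL) {
  if (!"parent_id" %in% names(df)) df$parent_id <- NA_integer_
  if (is.null(frameInterval)) {
    dts <- unlist(lapply(split(df$t_min, df$track_id), diff))
    frameInterval <- if (length(dts)) stats::median(dts) else NA_real_
  }
  methods::new("TrackSet", tracks = df, frameInterval = frameInterval)
}

#' Radial coordinates of tracked cells
#'
#' For each frame, the ICM centroid is the average of the x, y and z
#' coordinates of all cells present; each cell's radial distance `r` is its
#' Euclidean distance to that centroid, and the normalized position `d`
#' divides `r` by the largest cell radius at that frame (the geometric
#' centroid is d = 0, the ICM outer surface is d = 1). An optional centered
#' rolling average (window truncated at the track ends) smooths each cell's
#' radial series; `d` is recomputed from the smoothed radii.
#'
#' @param x a [TrackSet]
#' @param smoothingWindow rolling-average width in frames (1 = none;
#'   default 3).
#' @return a [RadialSeries].
#' @export
radialSeries <- function(x, smoothingWindow = 3L) {
  df <- x@tracks
  if (!nrow(df)) stop("empty track set")
  byT <- split(df, df$t_min)
  cent <- do.call(rbind, lapply(byT, function(g)
    data.frame(t_min = g$t_min[1], x_um = mean(g$x_um), y_um = mean(g$y_um),
               z_um = mean(g$z_um))))
  rownames(cent) <- NULL
  m <- match(df$t_min, cent$t_min)
  r <- sqrt((df$x_um - cent$x_um[m])^2 + (df$y_um - cent$y_um[m])^2 +
              (df$z_um - cent$z_um[m])^2)
  out <- data.frame(track_id = df$track_id, fate = df$fate,
                    t_min = df$t_min, r_um = r)
  out <- out[order(out$track_id, out$t_min), ]
  if (smoothingWindow > 1L) {
    out$r_um <- unlist(lapply(split(out$r_um, out$track_id),
                              rollingMean, window = smoothingWindow),
                       use.names = FALSE)
  }
  rmax <- stats::ave(out$r_um, out$t_min, FUN = max)
  out$d <- ifelse(rmax > 0, out$r_um / rmax, 0)
  rownames(out) <- NULL
  methods::new("RadialSeries", data = out, centroids = cent)
}

#' Centered rolling average with truncated edge windows
#'
#' @param x numeric series
#' @param window odd window width in samples
#' @return smoothed series of the same length.
#' @examples
#' rollingMean(c(0, 0, 3, 0, 0), 3)  # 0 1 1 1 0
#' @export
rollingMean <- function(x, window = 3L) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' EPI/PrE sorting score
#'
#' The average over all (PrE, EPI) cell pairs of the sign of the pairwise
#' difference between the PrE and EPI radial distances: +1 when every PrE
#' cell lies strictly outside every EPI cell, -1 in the inverted
#' configuration, and ties contribute 0.
#'
#' @param radii radial distances of the cells at one time point.
#' @param fates matching fate labels (`EPI` / `PRE`; other labels ignored).
#' @return score in [-1, 1].
#' @examples
#' sortingScore(c(1, 3, 2, 4), c("EPI", "EPI", "PRE", "PRE"))  # 0.5
#' @export
sortingScore <- function(radii, fates) {
  rP <- radii[fates == "PRE"]
  rE <- radii[fates == "EPI"]
  if (!length(rP) || !length(rE))
    stop("sorting score needs at least one EPI and one PrE cell")
  mean(sign(outer(rP, rE, "-")))
}

#' Sorting score at every frame of a radial series
#'
#' @param radial a [RadialSeries]
#' @return `data.frame` with columns `t_min` and `sorting_score`.
#' @export
sortingScoreSeries <- function(radial) {
  out <- lapply(split(radial@data, radial@data$t_min), function(g)
    data.frame(t_min = g$t_min[1],
               sorting_score = sortingScore(g$r_um, g$fate)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean radial displacement binned by starting position and time
#'
#' Per-step displacement `r(t+1) - r(t)` (positive = outward movement),
#' assigned to bins by the step's *starting* position and time. Bins are on
#' the normalized position `d` by default (`on = "r"` bins raw radii).
#' Empty bins are kept with `n = 0` and an undefined (`NA`) mean, never a
#' silent zero.
#'
#' @param radial a [RadialSeries]
#' @param rBins bin edges for the starting radial position.
#' @param tBins bin edges for the starting time (minutes).
#' @param on `"d"` (normalized) or `"r"` (um).
#' @return `data.frame`: `fate`, `r_bin`, `t_bin`, `mean_displacement_um`,
#'   `n`.
#' @export
binnedDisplacements <- function(radial, rBins = seq(0, 1, by = 0.25),
                                tBins = NULL, on = c("d", "r")) {
  on <- match.arg(on)
  df <- radial@data
  steps <- do.call(rbind, lapply(split(df, df$track_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    n <- nrow(g)
    data.frame(fate = g$fate[-n], t0 = g$t_min[-n],
               pos0 = if (on == "d") g$d[-n] else g$r_um[-n],
               dr = diff(g$r_um))
  }))
  if (is.null(steps) || !nrow(steps)) stop("need at least two frames")
  if (is.null(tBins)) tBins <- range(steps$t0) + c(-1e-9, 1e-9)
  steps$r_bin <- cut(steps$pos0, rBins, include.lowest = TRUE)
  steps$t_bin <- cut(steps$t0, tBins, include.lowest = TRUE)
  grid <- expand.grid(fate = unique(steps$fate),
                      r_bin = levels(steps$r_bin),
                      t_bin = levels(steps$t_bin),
                      stringsAsFactors = FALSE)
  agg <- aggregate(dr ~ fate + r_bin + t_bin, steps,
                   function(v) c(mean = mean(v), n = length(v)))
  agg <- data.frame(agg[c("fate", "r_bin", "t_bin")],
                    mean_displacement_um = agg$dr[, "mean"],
                    n = agg$dr[, "n"])
  agg$r_bin <- as.character(agg$r_bin); agg$t_bin <- as.character(agg$t_bin)
  out <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  out$n[is.na(out$n)] <- 0L
  out[order(out$fate, out$r_bin, out$t_bin), ]
}

#' First-passage probabilities of motion toward the cavity
#'
#' Scans each distance-to-lumen trajectory for first exits of the
#' `threshold`-um corridor around an initial position X0: the first time
#' the cell has moved by `threshold` um either away from or toward the
#' cavity. Successive X0 samples along one trajectory are separated by at
#' least `minSeparation` minutes to suppress correlations; trajectories
#' that never leave the corridor are censored (counted, never included in
#' the probability). Returns, per X0 bin, the fraction of exits directed
#' toward the lumen.
#'
#' @param distances `data.frame` with columns `track_id`, `t_min`,
#'   `dist_um` (distance to the lumen surface).
#' @param threshold corridor half-width in um (default 3).
#' @param minSeparation minimum time between X0 samples (minutes, default 3).
#' @param x0Bins bin edges for X0 (um); default four equal bins over the
#'   observed range.
#' @return `data.frame`: `x0_bin`, `x0_mid`, `p_toward_lumen`, `n_events`,
#'   `n_censored`.
#' @export
firstPassageProbabilities <- function(distances, threshold = 3,
                                      minSeparation = 3, x0Bins = NULL) {
  stopifnot(all(c("track_id", "t_min", "dist_um") %in% names(distances)))
  ev <- do.call(rbind, lapply(split(distances, distances$track_id),
                              function(g) {
    g <- g[order(g$t_min), ]
    n <- nrow(g)
    lastT <- -Inf
    rows <- list()
    for (i in seq_len(n - 1L)) {
      if (g$t_min[i] - lastT < minSeparation) next
      lastT <- g$t_min[i]
      x0 <- g$dist_um[i]
      rel <- g$dist_um[(i + 1L):n] - x0
      hit <- which(abs(rel) >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        x0 = x0,
        outcome = if (length(hit)) {
          if (rel[hit[1]] <= -threshold) "toward" else "away"
        } else "censored")
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  if (is.null(ev) || !nrow(ev)) stop("no first-passage samples found")
  if (is.null(x0Bins))
    x0Bins <- seq(min(ev$x0), max(ev$x0), length.out = 5L)
  ev$bin <- cut(ev$x0, x0Bins, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(ev$bin), function(b) {
    g <- ev[!is.na(ev$bin) & ev$bin == b, ]
    dec <- g[g$outcome != "censored", ]
    data.frame(x0_bin = b,
               x0_mid = mean(x0Bins[match(b, levels(ev$bin)) + 0:1]),
               p_toward_lumen = if (nrow(dec)) mean(dec$outcome == "toward")
                                else NA_real_,
               n_events = nrow(dec),
               n_censored = sum(g$outcome == "censored"))
  }))
  rownames(out) <- NULL
  out
}

#' Detect reporter-based fate switches with hysteresis
#'
#' A switch to PrE is a crossing of the reporter above `highThreshold`
#' sustained for at least `minPersist` frames, starting from the low state
#' (reporter below `lowThreshold`); switches to EPI are symmetric. When no
#' thresholds are given they default to the midpoint between the two
#' reporter modes (2-class clustering) +/- 10% of the mode separation.
#'
#' @param x a [TrackSet] whose tracks carry a `reporter` column.
#' @param highThreshold,lowThreshold hysteresis band (low < high).
#' @param minPersist frames a crossing must persist (default 2).
#' @return list with `events` (`data.frame`: `track_id`, `t_min`,
#'   `direction`) and `counts` (named totals per direction).
#' @export
fateSwitchEvents <- function(x, highThreshold = NULL, lowThreshold = NULL,
                             minPersist = 2L) {
  df <- x@tracks
  if (!"reporter" %in% names(df) || all(is.na(df$reporter)))
    stop("fate-switch detection needs a reporter series")
  if (is.null(highThreshold) || is.null(lowThreshold)) {
    km <- stats::kmeans(df$reporter, centers = 2L, nstart = 5L)
    modes <- sort(km$centers[, 1])
    mid <- mean(modes)
    sep <- diff(modes)
    if (is.null(lowThreshold)) lowThreshold <- mid - 0.1 * sep
    if (is.null(highThreshold)) highThreshold <- mid + 0.1 * sep
  }
  if (lowThreshold >= highThreshold)
    stop("thresholds inverted: lowThreshold must be below highThreshold")
  events <- do.call(rbind, lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$t_min), ]
    lev <- ifelse(g$reporter > highThreshold, 1L,
                  ifelse(g$reporter < lowThreshold, -1L, 0L))
    state <- 0L
    rows <- list()
    n <- length(lev)
    for (i in seq_len(n)) {
      if (lev[i] == 0L || lev[i] == state) next
      # candidate crossing: must persist minPersist frames
      run <- i
      while (run < n && lev[run + 1L] == lev[i]) run <- run + 1L
      if (run - i + 1L >= minPersist) {
        if (state != 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            track_id = g$track_id[1], t_min = g$t_min[i],
            direction = if (lev[i] > 0L) "to_PRE" else "to_EPI")
        state <- lev[i]
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  if (is.null(events))
    events <- data.frame(track_id = integer(0), t_min = numeric(0),
                         direction = character(0))
  rownames(events) <- NULL
  list(events = events,
       counts = c(to_PRE = sum(events$direction == "to_PRE"),
                  to_EPI = sum(events$direction == "to_EPI")))
}

#' Read / write track tables
#'
#' CSV interchange with the schema of the upstream nuclear detection and
#' tracking pipeline: `track_id, parent_id, t_min, x_um, y_um, z_um, fate`
#' and optional `reporter`, header required.
#'
#' @param path CSV file path.
#' @return [readTracks()]: a [TrackSet]; [writeTracks()]: `path`, invisibly.
#' @export
readTracks <- function(path) {
  df <- readTable(path, required = c("track_id", "t_min", "x_um", "y_um",
                                     "z_um", "fate"))
  trackSet(as.data.frame(df))
}

#' @rdname readTracks
#' @param x a [TrackSet]
#' @export
writeTracks <- function(x, path) {
  cols <- intersect(c("track_id", "parent_id", "t_min", "x_um", "y_um",
                      "z_um", "fate", "reporter"), names(x@tracks))
  writeTable(x@tracks[cols], path)
  invisible(path)
}
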