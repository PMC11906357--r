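# Trajectory statistics: radial series, sorting score, displacement maps,
# first passage, fate switches.

mkTracks <- function(pos, fates, dt = 20) {
  # pos: list per cell of n x 3 matrices
  df <- do.call(rbind, lapply(seq_along(pos), function(i) {
    m <- pos[[i]]
    data.frame(track_id = i, t_min = (seq_len(nrow(m)) - 1) * dt,
               x_um = m[, 1], y_um = m[, 2], z_um = m[, 3],
               fate = fates[i])
  }))
  trackSet(df, frameInterval = dt)
}

test_that("radial series: centroid, normalization and smoothing", {
  # a single cell is its own centroid
  one <- mkTracks(list(cbind(1:5, 0, 0)), "EPI")
  rs <- radialSeries(one, smoothingWindow = 1L)
  expect_equal(rs@data$r_um, rep(0, 5))

  # two cells at (+/-5, 0, 0): centroid at the origin, r = 5, d = 1
  two <- mkTracks(list(cbind(rep(5, 3), 0, 0), cbind(rep(-5, 3), 0, 0)),
                  c("EPI", "PRE"))
  rs2 <- radialSeries(two, smoothingWindow = 1L)
  expect_equal(rs2@data$r_um, rep(5, 6))
  expect_equal(rs2@data$d, rep(1, 6))
  expect_equal(rs2@centroids$x_um, rep(0, 3))

  # rolling window 3 on [0,0,3,0,0] -> [0,1,1,1,0]
  expect_equal(rollingMean(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
})

test_that("sorting score matches hand-computed pair averages", {
  expect_equal(sortingScore(c(1, 2, 3, 4), c("EPI", "EPI", "PRE", "PRE")), 1)
  expect_equal(sortingScore(c(1, 2, 3, 4), c("PRE", "PRE", "EPI", "EPI")), -1)
  # worked example: EPI at r = {1, 3}, PrE at r = {2, 4} -> 0.5
  expect_equal(sortingScore(c(1, 3, 2, 4), c("EPI", "EPI", "PRE", "PRE")),
               0.5)
  expect_error(sortingScore(c(1, 2), c("EPI", "EPI")), "PrE")
})

test_that("sorting score invariances and the +1 criterion", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    r <- runif(n, 0, 30)
    fates <- sample(c("EPI", "PRE"), n, replace = TRUE)
    if (!any(fates == "EPI")) fates[1] <- "EPI"
    if (!any(fates == "PRE")) fates[2] <- "PRE"
    s <- sortingScore(r, fates)
    # antisymmetry under fate exchange
    swapped <- ifelse(fates == "EPI", "PRE", "EPI")
    expect_equal(sortingScore(r, swapped), -s)
    # invariance under common rescaling
    expect_equal(sortingScore(3.7 * r, fates), s)
    # +1 iff min PrE radius exceeds max EPI radius
    expect_identical(s == 1,
                     min(r[fates == "PRE"]) > max(r[fates == "EPI"]))
  }
  # random fate labels on fixed positions: mean score compatible with 0
  set.seed(32)
  r <- runif(20, 0, 30)
  scores <- replicate(1000, {
    f <- sample(rep(c("EPI", "PRE"), 10))
    sortingScore(r, f)
  })
  expect_lt(abs(mean(scores)), 3 * sd(scores) / sqrt(length(scores)))
})

test_that("binned displacements: trivial fields and a brute-force oracle", {
  # static tracks: all means 0
  still <- mkTracks(list(cbind(rep(4, 6), 0, 0), cbind(rep(-2, 6), 0, 0)),
                    c("EPI", "PRE"))
  rsStill <- radialSeries(still, smoothingWindow = 1L)
  bd <- binnedDisplacements(rsStill)
  expect_true(all(abs(bd$mean_displacement_um[bd$n > 0]) < 1e-12))
  # bin counts add up to the number of steps per fate
  expect_equal(sum(bd$n[bd$fate == "EPI"]), 5)
  expect_equal(sum(bd$n[bd$fate == "PRE"]), 5)

  # uniform outward drift v: every populated bin mean is v
  v <- 0.75
  drift <- mkTracks(list(cbind(5 + v * (0:5), 0, 0),
                         cbind(-(5 + v * (0:5)), 0, 0)),
                    c("EPI", "PRE"))
  rsD <- radialSeries(drift, smoothingWindow = 1L)
  bdD <- binnedDisplacements(rsD)
  expect_equal(unique(round(bdD$mean_displacement_um[bdD$n > 0], 12)), v)

  # 10-point toy track against a direct loop
  set.seed(7)
  m <- cbind(cumsum(rnorm(10, 0.3)), cumsum(rnorm(10)), cumsum(rnorm(10)))
  m2 <- -m + rnorm(30, sd = 0.1)
  toy <- mkTracks(list(m, m2), c("PRE", "EPI"))
  rsT <- radialSeries(toy, smoothingWindow = 1L)
  edges <- seq(0, 1, by = 0.5)
  bdT <- binnedDisplacements(rsT, rBins = edges)
  df <- rsT@data
  for (f in c("EPI", "PRE")) {
    g <- df[df$fate == f, ]
    g <- g[order(g$track_id, g$t_min), ]
    for (tid in unique(g$track_id)) {
      gg <- g[g$track_id == tid, ]
      drs <- diff(gg$r_um)
      d0 <- gg$d[-nrow(gg)]
      for (b in 1:2) {
        inBin <- if (b == 1) d0 <= 0.5 else d0 > 0.5
        if (!any(inBin)) next
        lev <- levels(cut(c(0.25, 0.75), edges, include.lowest = TRUE))[b]
        got <- bdT[bdT$fate == f & bdT$r_bin == lev, ]
        expect_equal(got$n, sum(inBin))
        expect_equal(got$mean_displacement_um, mean(drs[inBin]))
      }
    }
  }
})

test_that("first-passage probabilities: trivial and analytic cases", {
  # strictly decreasing distance: probability 1 everywhere populated
  dec <- data.frame(track_id = 1, t_min = seq(0, 200, by = 5),
                    dist_um = seq(50, 10, length.out = 41))
  fp <- firstPassageProbabilities(dec, threshold = 3, minSeparation = 3)
  expect_true(all(fp$p_toward_lumen[fp$n_events > 0] == 1))

  # biased +/-1-um random walk: exact gambler's-ruin absorption
  set.seed(77)
  u <- 0.7  # probability of moving away from the cavity per frame
  n <- 3000
  walks <- do.call(rbind, lapply(seq_len(n), function(i) {
    steps <- sample(c(1, -1), 60, replace = TRUE, prob = c(u, 1 - u))
    data.frame(track_id = i, t_min = seq(0, by = 3, length.out = 61),
               dist_um = 30 + c(0, cumsum(steps)))
  }))
  fp2 <- firstPassageProbabilities(walks, threshold = 3, minSeparation = 3,
                                   x0Bins = c(0, 60))
  expected <- ruinTowardProbability(u, a = 3L)
  se <- sqrt(expected * (1 - expected) / fp2$n_events)
  expect_lt(abs(fp2$p_toward_lumen - expected), 3 * se)
  # censored walks are reported, not silently dropped
  flat <- data.frame(track_id = 1, t_min = seq(0, 60, by = 3),
                     dist_um = rep(10, 21))
  fpc <- firstPassageProbabilities(flat, x0Bins = c(0, 20))
  expect_identical(fpc$n_events, 0L)
  expect_gt(fpc$n_censored, 0)
})

test_that("fate switches require sustained hysteresis crossings", {
  t <- seq(0, 400, by = 20)
  mk <- function(rep) trackSet(data.frame(
    track_id = 1, t_min = t, x_um = 0, y_um = 0, z_um = 0,
    fate = "UNKNOWN", reporter = rep), frameInterval = 20)
  # constant reporter: no events
  ev0 <- fateSwitchEvents(mk(rep(1, 21)), highThreshold = 2,
                          lowThreshold = 0.5, minPersist = 2)
  expect_identical(nrow(ev0$events), 0L)
  # engineered single sustained crossing: exactly one event, to PrE
  rep1 <- c(rep(0.2, 8), rep(3, 13))
  ev1 <- fateSwitchEvents(mk(rep1), highThreshold = 2, lowThreshold = 0.5,
                          minPersist = 2)
  expect_identical(nrow(ev1$events), 1L)
  expect_identical(ev1$events$direction, "to_PRE")
  # a single-frame spike does not persist
  rep2 <- c(rep(0.2, 8), 3, rep(0.2, 12))
  ev2 <- fateSwitchEvents(mk(rep2), highThreshold = 2, lowThreshold = 0.5,
                          minPersist = 2)
  expect_identical(nrow(ev2$events), 0L)
  expect_error(fateSwitchEvents(mk(rep1), highThreshold = 0.5,
                                lowThreshold = 2), "inverted")
})
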