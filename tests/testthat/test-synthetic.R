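# Synthetic-data generators: determinism and designed statistical structure.

test_that("generators are pure functions of their seed", {
  expect_identical(tracks(genTracks(seed = 4)), tracks(genTracks(seed = 4)))
  expect_false(identical(tracks(genTracks(seed = 4)),
                         tracks(genTracks(seed = 5))))
  expect_identical(genEmbryoPopulation(seed = 2),
                   genEmbryoPopulation(seed = 2))
  expect_identical(genAspiration(seed = 3), genAspiration(seed = 3))
  c1 <- genContour(seed = 6, noiseSd = 0.5)
  c2 <- genContour(seed = 6, noiseSd = 0.5)
  expect_identical(c1@points, c2@points)
  expect_identical(genIntensityFates(seed = 7), genIntensityFates(seed = 7))
})

test_that("track generator: static limit and sorting by construction", {
  still <- genTracks(driftPre = 0, driftEpi = 0, diffusion = 0, seed = 1)
  df <- tracks(still)
  expect_equal(length(unique(df$x_um)), length(unique(df$track_id)))
  # outward PrE drift raises the sorting score from start to end
  moving <- genTracks(driftPre = 0.5, driftEpi = 0, diffusion = 0.5,
                      nFrames = 30, seed = 2)
  rs <- radialSeries(moving, smoothingWindow = 1L)
  ss <- sortingScoreSeries(rs)
  expect_gt(ss$sorting_score[nrow(ss)], ss$sorting_score[1])
  # retention keeps cells within the surface radius
  expect_true(all(with(tracks(moving),
                       sqrt(x_um^2 + y_um^2 + z_um^2)) <= 20 + 1e-9))
})

test_that("embryo population scales with size ratio and hits the design p*", {
  pop <- genEmbryoPopulation(sizeRatios = c(1, 2), nPerClass = 150,
                             baseCells = 40, seed = 8)
  m1 <- mean(pop$n_total[pop$size_ratio == 1])
  m2 <- mean(pop$n_total[pop$size_ratio == 2])
  expect_equal(m2 / m1, 2, tolerance = 0.15)
  # designed outcomes match the recomputed classification exactly
  out <- icmAreas(pop, scalingConstants())
  expect_identical(as.character(out$outcome), pop$true_outcome)
  # binomial consistency of the designed monolayer fraction
  pop8 <- genEmbryoPopulation(sizeRatios = 1, nPerClass = 200, pStar = 0.8,
                              seed = 9)
  phat <- mean(pop8$true_outcome == "MONOLAYER")
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / 200))
})

test_that("contour generator: constant curvature without protrusions", {
  circ <- genContour(radius = 40, protrusionAngles = numeric(0))
  k <- attr(circ, "true_curvature")
  expect_equal(k, rep(1 / 40, nrow(circ@points)), tolerance = 1e-6)
  measured <- curvatureProfile(circ, offset = 10L)
  expect_true(all(abs(measured - 1 / 40) / (1 / 40) < 0.02))
  # a bump at the cavity pole lands in the cavity-facing bin
  bumped <- genContour(radius = 50, protrusionAngles = pi)
  out <- boundaryBinOrientation(bumped, k = 6L)
  expect_identical(out$argmax_curvature, 1L)
  expect_warning(genContour(protrusionAngles = c(0, 0.1), width = 0.25),
                 "overlap")
})

test_that("intensity generator: separation limit and z-decay switch", {
  far <- genIntensityFates(nCells = 60, separation = 10, seed = 3)
  cf <- classifyFatesKmeans(far)
  expect_identical(cf$fate, far$true_fate)
  # zDecay = Inf: correction is a no-op up to the removed mean trend
  flat <- genIntensityFates(nCells = 60, zDecay = Inf, seed = 4)
  cc <- classifyFatesKmeans(flat)
  slope <- coef(lm(log(flat$gata6) ~ flat$z_um))[2]
  # the raw slope is already statistically flat
  expect_lt(abs(slope), 0.02)
})

test_that("aspiration generator inverts exactly without noise", {
  clean <- genAspiration(n = 20, gammaTrue = 700, noiseSd = 0, seed = 2)
  expect_equal(laplaceTension(clean), rep(700, 20))
  noisy <- genAspiration(n = 40, gammaTrue = 500, noiseSd = 0.05, seed = 3)
  est <- laplaceTension(noisy)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 500), 3 * se)
})
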