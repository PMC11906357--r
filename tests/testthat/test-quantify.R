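# Image-derived operators.

test_that("Young-Laplace tension: worked values, limits and errors", {
  expect_equal(laplaceTension(300, 4, 12), 900)
  expect_equal(laplaceTension(100, 4, Inf), 200)  # flat-cell limit
  expect_error(laplaceTension(100, 4, 4), "invalid measurement")
  expect_error(laplaceTension(100, 4, 3), "invalid measurement")
  # homogeneous of degree 1 in pressure
  expect_equal(laplaceTension(600, 4, 12), 2 * laplaceTension(300, 4, 12))
  # scaling radii by s and pressure by 1/s leaves gamma unchanged
  s <- 2.5
  expect_equal(laplaceTension(300 / s, 4 * s, 12 * s),
               laplaceTension(300, 4, 12))
  # data-frame interface
  df <- data.frame(P_c_pa = c(300, 100), R_p_um = 4, R_c_um = c(12, Inf))
  expect_equal(laplaceTension(df), c(900, 200))
  expect_error(laplaceTension(data.frame(P_c_pa = 1)), "missing columns")
})

test_that("polarization index: ratio of outer to inner quarter", {
  pos <- seq(0, 1, length.out = 20)
  expect_equal(polarizationIndex(rep(5, 20)), 1)
  prof <- ifelse(pos >= 0.75, 20, ifelse(pos <= 0.25, 10, 15))
  expect_equal(polarizationIndex(prof), 2)
  # reversal inverts the index for strictly positive profiles
  set.seed(3)
  p <- runif(40, 1, 10)
  expect_equal(polarizationIndex(rev(p)), 1 / polarizationIndex(p))
  zeroInner <- ifelse(pos <= 0.25, 0, 1)
  expect_error(polarizationIndex(zeroInner), "undefined")
})

test_that("intensity profiles: binning, normalization, smoothing", {
  # constant input, normalized: all bins 1
  set.seed(5)
  posn <- runif(500)
  pc <- intensityProfile(posn, rep(7, 500), nBins = 10, window = 1L)
  expect_equal(pc@intensities, rep(1, 10))
  # linear ramp: bin means match the analytic ramp within half a bin width
  pr <- intensityProfile(posn, posn, nBins = 20, normalize = FALSE,
                         window = 1L)
  expect_true(all(abs(pr@intensities - pr@positions) < 0.5 / 20))
  # smoothing window 3 on [0,0,3,0,0]
  ps <- intensityProfile(seq(0.1, 0.9, by = 0.2), c(0, 0, 3, 0, 0),
                         nBins = 5, normalize = FALSE, window = 3L)
  expect_equal(ps@intensities, c(0, 1, 1, 1, 0))
  # empty bins are NA-flagged unless interpolation is requested
  pe <- intensityProfile(c(0.05, 0.95), c(1, 3), nBins = 4,
                         normalize = FALSE, window = 1L)
  expect_true(anyNA(pe@intensities))
  pi2 <- intensityProfile(c(0.05, 0.95), c(1, 3), nBins = 4,
                          normalize = FALSE, window = 1L,
                          interpolate = TRUE)
  expect_false(anyNA(pi2@intensities))
})

test_that("curvature: analytic circles, collinearity and mirroring", {
  # smooth circle of radius 50 px
  circ <- circleContour(50, n = 300)
  k <- curvatureProfile(circ, offset = 10L)
  expect_true(all(abs(k - 0.02) / 0.02 < 0.02))
  # circle digitized at ~1-pixel arc spacing
  circD <- circleContour(50, n = round(2 * pi * 50))
  kD <- curvatureProfile(circD, offset = 10L)
  expect_lt(mean(abs(kD - 0.02)) / 0.02, 0.02)
  # unit conversion: pixel size 0.5 um/px doubles the curvature
  circU <- circleContour(50, n = 300, pixelSize = 0.5)
  expect_true(all(abs(curvatureProfile(circU, 10L) - 0.04) < 0.002))
  # straight polyline: exactly zero at interior points
  line <- contour2D(cbind(seq(0, 40), 0.5 * seq(0, 40)), closed = FALSE)
  kl <- curvatureProfile(line, offset = 5L)
  expect_true(all(kl[!is.na(kl)] == 0))
  expect_true(all(is.na(kl[1:5])))
  # mirrored contour: equal magnitude, opposite sign
  bump <- genContour(radius = 40, protrusionAngles = pi / 3)
  kb <- curvatureProfile(bump, offset = 10L)
  mirror <- contour2D(cbind(bump@points[, 1], -bump@points[, 2]))
  km <- curvatureProfile(mirror, offset = 10L)
  expect_equal(km, -kb)
})

test_that("boundary bins are equal-arc and anchored at the cavity pole", {
  cav <- pi / 2
  ct <- genContour(radius = 50, protrusionAngles = cav, amplitude = 8,
                   width = 0.2)
  out <- boundaryBinOrientation(ct, k = 6L)
  # the bump and its co-located intensity hotspot sit in the cavity bin
  expect_identical(out$argmax_curvature, 1L)
  expect_identical(out$argmax_intensity, 1L)
  expect_false(out$tie_intensity)
  # bin arc lengths equal within one point spacing
  spacing <- max(sqrt(rowSums((ct@points[c(2:nrow(ct@points), 1), ] -
                                 ct@points)^2)))
  expect_lt(diff(range(out$bins$arc_length_px)), 2 * spacing)
  # uniform intensity: argmax flagged as a tie
  flat <- circleContour(30, n = 120, intensity = rep(2, 120),
                        cavityDirection = c(0, 1))
  outF <- boundaryBinOrientation(flat, k = 6L)
  expect_true(outF$tie_intensity)
  expect_identical(outF$argmax_intensity, 1L)
  expect_error(boundaryBinOrientation(circleContour(30), k = 6L), "axis")
})

test_that("depth-corrected k-means recovers generated fates", {
  # widely separated clusters: perfect recovery
  far <- genIntensityFates(nCells = 80, separation = 8, zDecay = 50,
                           seed = 2)
  cf <- classifyFatesKmeans(far)
  expect_identical(cf$fate, far$true_fate)
  # default separation: at least 95% recovery
  std <- genIntensityFates(nCells = 200, seed = 3)
  cs <- classifyFatesKmeans(std)
  expect_gte(mean(cs$fate == std$true_fate), 0.95)
  # z-correction flattens a noiseless exponential decay
  z <- seq(0, 40, length.out = 50)
  mode <- rep(c(100, 10), 25)  # alternating bimodal, balanced in z
  noiseless <- data.frame(gata6 = mode * exp(-z / 30),
                          nanog = rev(mode) * exp(-z / 30), z_um = z)
  cc <- classifyFatesKmeans(noiseless)
  slope <- coef(lm(cc$gata6_corrected ~ z))[2]
  expect_lt(abs(slope), 1e-6)
  expect_error(classifyFatesKmeans(data.frame(gata6 = 1, nanog = 1,
                                              z_um = 0)), "fewer cells")
})

test_that("shape metrics: circles, ellipses and protrusion angles", {
  circ <- circleContour(40, n = 200)
  m <- shapeMetrics(circ)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(m$circularity, 1, tolerance = 0.02)
  # 2:1 ellipse: aspect ratio 2; circularity vs Ramanujan perimeter
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  a <- 40; b <- 20
  ell <- contour2D(cbind(a * cos(th), b * sin(th)))
  me <- shapeMetrics(ell)
  expect_equal(me$aspect_ratio, 2, tolerance = 0.01)
  h <- ((a - b) / (a + b))^2
  ramanujan <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(me$circularity, 4 * pi * (pi * a * b) / ramanujan^2,
               tolerance = 0.01)
  # protrusion geometry
  mp <- shapeMetrics(circ, protrusionTip = c(0, 60), cavityPoint = c(0, 99),
                     center = c(0, 0))
  expect_equal(mp$protrusion_angle_deg, 0)
  expect_equal(mp$protrusion_length_um, 60)
  mo <- shapeMetrics(circ, protrusionTip = c(0, -60),
                     cavityPoint = c(0, 99), center = c(0, 0))
  expect_equal(mo$protrusion_angle_deg, 180)
  expect_error(shapeMetrics(contour2D(cbind(c(0, 1, 2), c(0, 1, 2) * 2 + 1),
                                      closed = TRUE)), "degenerate")
})

test_that("colocalization coefficients", {
  set.seed(9)
  A <- matrix(runif(100, 1, 5), 10)
  same <- colocalization(A, A)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$manders_M1, 1)
  expect_equal(same$manders_M2, 1)
  # spatially disjoint signals
  B <- matrix(0, 10, 10); B[1:5, ] <- 3
  C <- matrix(0, 10, 10); C[6:10, ] <- 2
  dj <- colocalization(B, C)
  expect_equal(dj$manders_M1, 0)
  expect_equal(dj$manders_M2, 0)
  # affine relation: r = 1, Manders by direct summation
  D <- 2 * A + 1
  aff <- colocalization(A, D)
  expect_equal(aff$pearson_r, 1)
  expect_equal(aff$manders_M1, sum(A[D > 0]) / sum(A))
  # constant channel is flagged
  flat <- colocalization(matrix(1, 4, 4), matrix(1, 4, 4))
  expect_true(flat$constant_channel)
  expect_true(is.na(flat$pearson_r))
  expect_error(colocalization(A, matrix(1, 3, 3)), "identical shape")
})

test_that("cortical normalization is scale-invariant", {
  set.seed(4)
  cort <- runif(30, 5, 20); nuc <- runif(10, 50, 80)
  r <- normalizedCorticalIntensity(cort, nuc)
  expect_equal(normalizedCorticalIntensity(7.3 * cort, 7.3 * nuc), r)
})
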