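# Spherical-cap geometry and the monolayer scaling model.

test_that("cap geometry closed forms", {
  # flat-disc limit and hemisphere identity
  expect_equal(capGeometry(10, 0), data.frame(volume_um3 = 0,
                                              area_um2 = 100 * pi))
  hemi <- capGeometry(7, 7)
  expect_equal(hemi$volume_um3, 2 / 3 * pi * 343)
  expect_equal(hemi$area_um2, 2 * pi * 49)
  # worked value r = 3, h = 1 vs the integration oracle
  g <- capGeometry(3, 1)
  expect_equal(g$volume_um3, 14 * pi / 3)
  expect_equal(g$area_um2, 10 * pi)
  oracle <- capByIntegration(3, 1)
  expect_equal(g$volume_um3, oracle$volume, tolerance = 1e-8)
  expect_equal(g$area_um2, oracle$area, tolerance = 1e-8)
  expect_error(capGeometry(-1, 1), "r > 0")
})

test_that("icmAreas computes volumes, bounds and inclusive outcomes", {
  k <- scalingConstants()
  g <- data.frame(R_um = 30, H_um = 40, h_um = 10, n_total = 100)
  out <- icmAreas(g, k)
  expect_equal(out$A_interface_um2, 1000 * pi)
  expect_equal(out$V_icm_um3,
               capGeometry(30, 40)$volume_um3 - capGeometry(30, 10)$volume_um3)
  # bounds from the printed constants f = 0.6, q10 = 157, q90 = 376
  expect_equal(out$A_pre_min_um2, 9420)
  expect_equal(out$A_pre_max_um2, 22560)
  # tie at the upper bound is classified MONOLAYER (inclusive interval)
  hTie <- sqrt(22560 / pi - 30^2)
  tie <- icmAreas(data.frame(R_um = 30, H_um = 90, h_um = hTie,
                             n_total = 100), k)
  expect_equal(tie$A_interface_um2, 22560)
  expect_identical(as.character(tie$outcome), "MONOLAYER")
  just <- icmAreas(data.frame(R_um = 30, H_um = 90, h_um = hTie + 1e-6,
                              n_total = 100), k)
  expect_identical(as.character(just$outcome), "GAP")
  expect_error(icmAreas(data.frame(R_um = 30, H_um = 5, h_um = 10,
                                   n_total = 10), k), "invalid geometry")
})

test_that("cap formulas agree with integration over the parameter grid", {
  for (r in c(5, 10, 20, 50, 100)) {
    for (frac in c(0.1, 0.5, 1)) {
      h <- frac * r
      g <- capGeometry(r, h)
      o <- capByIntegration(r, h)
      expect_lt(abs(g$volume_um3 - o$volume) / o$volume, 1e-3)
      expect_lt(abs(g$area_um2 - o$area) / o$area, 1e-3)
    }
  }
})

test_that("hemisphere reference curve: identity and homogeneity", {
  c0 <- 1907
  for (N in c(10, 40, 160)) {
    # two-route computation: the ICM is a sphere of volume V = cN and the
    # hemispherical interface is half its surface: V -> r -> 2 pi r^2
    V <- c0 * N
    r <- (3 * V / (4 * pi))^(1 / 3)
    expect_equal(hemisphereAreaFromCount(N, c0), 2 * pi * r^2,
                 tolerance = 1e-12)
  }
  expect_equal(hemisphereAreaFromCount(80, c0),
               2^(2 / 3) * hemisphereAreaFromCount(40, c0))
})

test_that("monolayer feasibility of a hemispherical ICM is a contiguous size window", {
  k <- scalingConstants()
  N <- 1:2000
  A <- hemisphereAreaFromCount(N, k@c)
  inside <- A >= k@f * N * k@q10 & A <= k@f * N * k@q90
  runs <- rle(inside)
  expect_identical(sum(runs$values), 1L)  # exactly one contiguous window
  expect_true(any(inside) && !inside[1] || inside[1])
  # the window opens and closes within the scanned range
  expect_false(inside[2000])
})

test_that("through-origin scaling fits recover c and f", {
  # exact data
  vol <- data.frame(n_total = c(10, 20, 40), V_icm_um3 = 2000 * c(10, 20, 40))
  fit <- fitScaling(volumes = vol)
  expect_equal(fit$c, 2000)
  expect_equal(fit$c_se, 0)
  frac <- data.frame(n_total = c(10, 20, 50), n_pre = 0.6 * c(10, 20, 50))
  expect_equal(fitScaling(fractions = frac)$f, 0.6)
  # noisy synthetic: recovery within 3 s.e.
  set.seed(12)
  n <- sample(10:80, 50, replace = TRUE)
  noisy <- data.frame(n_total = n,
                      V_icm_um3 = 1900 * n + rnorm(50, sd = 4000))
  f2 <- fitScaling(volumes = noisy)
  expect_lt(abs(f2$c - 1900), 3 * f2$c_se)
  expect_error(fitScaling(), "supply")
})

test_that("outcome probabilities: frequencies, errors, f-monotonicity", {
  k <- scalingConstants()
  # all embryos inside the band
  pop <- genEmbryoPopulation(sizeRatios = 1, nPerClass = 30, pStar = 1,
                             seed = 5)
  pr <- outcomeProbabilities(pop, k)
  expect_equal(pr$p[pr$outcome == "MONOLAYER"], 1)
  expect_equal(pr$se[pr$outcome == "MONOLAYER"], 0)
  expect_equal(sum(pr$p), 1)
  # raising f never decreases the multilayer probability
  pop2 <- genEmbryoPopulation(sizeRatios = c(0.5, 1, 2), nPerClass = 25,
                              pStar = 0.7, seed = 6)
  pm <- vapply(c(0.4, 0.6, 0.8), function(f) {
    pr <- outcomeProbabilities(pop2, k, scenarioF = f, by = "species")
    pr$p[pr$outcome == "MULTILAYER"]
  }, numeric(1))
  expect_true(all(diff(pm) >= 0))
})

test_that("blastocyst volume follows the mean-diameter rule", {
  expect_equal(blastocystVolume(100, 100), 4 / 3 * pi * 50^3)
  expect_equal(blastocystVolume(120, 80), blastocystVolume(100, 100))
  expect_equal(blastocystVolume(120, 80), blastocystVolume(80, 120))
  expect_error(blastocystVolume(0, 10), "positive")
})

test_that("species presets carry the scenario fractions", {
  sp <- speciesPresets()
  expect_identical(sp$f[sp$species == "mouse"], 0.6)
  expect_identical(sp$f[sp$species == "monkey"], 0.7)
  expect_identical(sp$f[sp$species == "human"], 0.55)
})
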