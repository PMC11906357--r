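# Seeded generators emulating the statistical structure of each input the
# analysis stages consume, so the whole pipeline is testable without image
# data. Every generator is a pure function of its arguments and seed, and
# returns the ground truth needed to predict each downstream result.

#' Generate fate-labelled 3D tracks with biased PrE motion
#'
#' PrE cells perform radially biased random walks with outward drift and
#' absorbing retention at the ICM surface radius (once at the surface, a
#' cell's radial excursions are clipped there, emulating the low-tension
#' trapping of PrE at the fluid interface); EPI cells are unbiased (or
#' inward-biased). Positions carry isotropic Gaussian jitter. Frame
#' interval defaults to the 20-min imaging cadence.
#'
#' @param nEpi,nPre cells per fate.
#' @param nFrames frames per track.
#' @param frameInterval minutes between frames.
#' @param driftPre,driftEpi radial drift per frame (um; positive = outward).
#' @param diffusion isotropic jitter s.d. per frame (um).
#' @param surfaceRadius ICM surface radius (um).
#' @param retention clip radial positions at the surface radius.
#' @param startFraction cells start uniformly within this fraction of the
#'   surface radius.
#' @param seed RNG seed.
#' @return a [TrackSet]; fate labels are the ground truth.
#' @export
genTracks <- function(nEpi = 12L, nPre = 18L, nFrames = 25L,
                      frameInterval = 20, driftPre = 0.5, driftEpi = 0,
                      diffusion = 1, surfaceRadius = 20, retention = TRUE,
                      startFraction = 0.6, seed = 1L) {
  set.seed(seed)
  nc <- nEpi + nPre
  fates <- c(rep("EPI", nEpi), rep("PRE", nPre))
  drifts <- c(rep(driftEpi, nEpi), rep(driftPre, nPre))
  # uniform start positions in a central ball
  u <- matrix(stats::rnorm(3 * nc), nc, 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * (surfaceRadius * startFraction * stats::runif(nc)^(1 / 3))
  rows <- vector("list", nFrames)
  for (fidx in seq_len(nFrames)) {
    rows[[fidx]] <- data.frame(track_id = seq_len(nc),
                               parent_id = NA_integer_,
                               t_min = (fidx - 1) * frameInterval,
                               x_um = pos[, 1], y_um = pos[, 2],
                               z_um = pos[, 3], fate = fates)
    # advance: radial drift + isotropic jitter, then surface retention
    r <- sqrt(rowSums(pos^2))
    dir <- pos / ifelse(r > 0, r, 1)
    pos <- pos + dir * drifts +
      matrix(stats::rnorm(3 * nc, sd = diffusion), nc, 3)
    if (retention) {
      r <- sqrt(rowSums(pos^2))
      over <- r > surfaceRadius
      if (any(over))
        pos[over, ] <- pos[over, ] * (surfaceRadius / r[over])
    }
  }
  trackSet(do.call(rbind, rows), frameInterval = frameInterval)
}

#' Generate a population of embryo cap geometries across size classes
#'
#' Cell counts scale linearly with the size ratio (Poisson noise), PrE
#' counts are Binomial(n_total, f), and the cavity-facing cap is drawn so
#' that a configured fraction `pStar` of embryos falls inside the
#' monolayer band (f n q10, f n q90): with probability `pStar` the
#' interface area is uniform inside the band, otherwise it lands outside
#' (half gaps above, half multilayers below). Cap shape (h/R) and ICM
#' height H carry Gaussian variability. The designed outcome is recorded
#' per embryo as ground truth.
#'
#' @param sizeRatios size classes (1 = normal size).
#' @param nPerClass embryos per class.
#' @param baseCells mean total ICM cells of a normal-sized embryo.
#' @param constants a [ScalingConstants] (f, q10, q90).
#' @param pStar designed monolayer probability.
#' @param shapeRatio mean h/R of the cavity-facing cap.
#' @param shapeNoiseSd s.d. of the h/R ratio.
#' @param seed RNG seed.
#' @return `data.frame` with the [icmAreas()] input schema plus
#'   `true_outcome`.
#' @export
genEmbryoPopulation <- function(sizeRatios = c(0.25, 0.375, 0.5, 1, 2, 3, 4),
                                nPerClass = 20L, baseCells = 40,
                                constants = scalingConstants(),
                                pStar = 0.8, shapeRatio = 0.45,
                                shapeNoiseSd = 0.05, seed = 1L) {
  stopifnot(pStar >= 0, pStar <= 1)
  set.seed(seed)
  f <- constants@f; q10 <- constants@q10; q90 <- constants@q90
  rows <- list()
  id <- 0L
  for (sr in sizeRatios) {
    for (i in seq_len(nPerClass)) {
      id <- id + 1L
      n <- stats::rpois(1, baseCells * sr)
      n <- max(n, 4L)
      nPre <- stats::rbinom(1, n, f)
      lo <- f * n * q10
      hi <- f * n * q90
      inBand <- stats::runif(1) < pStar
      A <- if (inBand) {
        stats::runif(1, lo, hi)
      } else if (stats::runif(1) < 0.5) {
        stats::runif(1, hi * 1.001, hi * 1.5)   # gap
      } else {
        stats::runif(1, lo * 0.5, lo * 0.999)   # multilayer
      }
      rho <- max(0.05, stats::rnorm(1, shapeRatio, shapeNoiseSd))
      R <- sqrt(A / (pi * (1 + rho^2)))
      h <- rho * R
      H <- max(h * 1.1, stats::rnorm(1, 1.6, 0.15) * R)
      rows[[id]] <- data.frame(
        embryo_id = id, species = "mouse", size_ratio = sr,
        R_um = R, H_um = H, h_um = h, n_total = n, n_pre = nPre,
        true_outcome = if (inBand) "MONOLAYER"
                       else if (A > hi) "GAP" else "MULTILAYER")
    }
  }
  do.call(rbind, rows)
}

#' Generate a cell contour with localized protrusions
#'
#' A circle of given radius with Gaussian radial bumps at the requested
#' angles, an optional intensity channel with hotspots co-located with (or
#' offset from) the bumps, and the analytic curvature field of the
#' generating polar curve attached as attribute `true_curvature` (um^-1).
#' The cavity direction points at the first protrusion angle.
#'
#' @param radius base circle radius (pixels).
#' @param nPoints contour points (counter-clockwise).
#' @param protrusionAngles bump centres (radians).
#' @param amplitude bump amplitude (pixels).
#' @param width bump s.d. (radians).
#' @param intensityOffset angular offset of the intensity hotspots from
#'   the bumps (radians).
#' @param pixelSize um per pixel.
#' @param seed RNG seed (reserved for noise; the contour itself is
#'   deterministic).
#' @param noiseSd radial jitter s.d. (pixels).
#' @return a [Contour2D].
#' @export
genContour <- function(radius = 50, nPoints = 360L,
                       protrusionAngles = numeric(0), amplitude = 8,
                       width = 0.25, intensityOffset = 0, pixelSize = 1,
                       seed = 1L, noiseSd = 0) {
  set.seed(seed)
  if (length(protrusionAngles) > 1L) {
    gaps <- diff(sort(protrusionAngles))
    if (any(gaps < 2 * width))
      warning("protrusion bumps overlap (angular gap < 2 * width)")
  }
  th <- seq(0, 2 * pi, length.out = nPoints + 1L)[-(nPoints + 1L)]
  wrap <- function(a) (a + pi) %% (2 * pi) - pi
  bump <- function(a, centres) {
    if (!length(centres)) return(rep(0, length(a)))
    Reduce(`+`, lapply(centres, function(c0)
      exp(-wrap(a - c0)^2 / (2 * width^2))))
  }
  g <- bump(th, protrusionAngles)
  r <- radius + amplitude * g
  if (noiseSd > 0) r <- r + stats::rnorm(nPoints, sd = noiseSd)
  pts <- cbind(r * cos(th), r * sin(th))
  intensity <- 1 + 10 * bump(th, protrusionAngles + intensityOffset)
  # curvature of the polar curve r(theta) (noise-free part), via
  # high-accuracy central differences of the generating function
  eps <- 1e-5
  rpNum <- (radius + amplitude * bump(th + eps, protrusionAngles) -
              (radius + amplitude * bump(th - eps, protrusionAngles))) /
    (2 * eps)
  rppNum <- (bump(th + eps, protrusionAngles) - 2 * g +
               bump(th - eps, protrusionAngles)) * amplitude / eps^2
  kappa <- (r^2 + 2 * rpNum^2 - r * rppNum) /
    (r^2 + rpNum^2)^(3 / 2) / pixelSize
  cav <- if (length(protrusionAngles))
    c(cos(protrusionAngles[1]), sin(protrusionAngles[1])) else numeric(0)
  out <- contour2D(pts, pixelSize = pixelSize, closed = TRUE,
                   intensity = intensity, cavityDirection = cav)
  attr(out, "true_curvature") <- kappa
  out
}

#' Generate bimodal fate-marker intensities with depth decay
#'
#' Two log-normal intensity modes per channel, anti-correlated across
#' GATA6 and NANOG (PrE cells: high GATA6 / low NANOG; EPI the reverse),
#' multiplied by an exponential decay exp(-z / zDecay) with imaging depth.
#' `separation` is the distance between the log-modes of one channel in
#' units of the log-normal s.d.; the default of 3 emulates the strongly
#' bimodal marker contrast of GATA6/NANOG immunostaining (per-channel
#' Bayes error below 2%).
#'
#' @param nCells number of cells.
#' @param preFraction PrE fraction.
#' @param separation mode separation in s.d. of the log intensity.
#' @param sdLog s.d. of each log-normal mode.
#' @param zDecay depth decay length (um; `Inf` disables the z effect).
#' @param zMax imaging depth range (um).
#' @param baseIntensity low-mode median intensity (a.u.).
#' @param seed RNG seed.
#' @return `data.frame`: `cell_id`, `gata6`, `nanog`, `z_um`, `true_fate`.
#' @export
genIntensityFates <- function(nCells = 100L, preFraction = 0.6,
                              separation = 3, sdLog = 0.4, zDecay = 60,
                              zMax = 40, baseIntensity = 100, seed = 1L) {
  set.seed(seed)
  nPre <- round(preFraction * nCells)
  fate <- sample(c(rep("PRE", nPre), rep("EPI", nCells - nPre)))
  z <- stats::runif(nCells, 0, zMax)
  hi <- log(baseIntensity) + separation * sdLog
  lo <- log(baseIntensity)
  mkChannel <- function(highFate) {
    mu <- ifelse(fate == highFate, hi, lo)
    exp(stats::rnorm(nCells, mu, sdLog)) * exp(-z / zDecay)
  }
  data.frame(cell_id = seq_len(nCells), gata6 = mkChannel("PRE"),
             nanog = mkChannel("EPI"), z_um = z, true_fate = fate)
}

#' Generate micropipette aspiration measurements
#'
#' Aspiration pressures follow the Young-Laplace law for the configured
#' true tension, with multiplicative Gaussian measurement noise on the
#' pressure; [laplaceTension()] applied to the noise-free records recovers
#' the tension exactly.
#'
#' @param n measurements.
#' @param gammaTrue true interfacial tension (pN/um).
#' @param Rp pipette radius (um).
#' @param RcRange cell curvature-radius range (um), entries > Rp.
#' @param noiseSd fractional pressure noise s.d. (0 = noise-free).
#' @param seed RNG seed.
#' @return `data.frame`: `P_c_pa`, `R_p_um`, `R_c_um`, with attribute
#'   `gamma_true`.
#' @export
genAspiration <- function(n = 40L, gammaTrue = 500, Rp = 4,
                          RcRange = c(8, 15), noiseSd = 0.05, seed = 1L) {
  stopifnot(gammaTrue > 0, all(RcRange > Rp))
  set.seed(seed)
  Rc <- stats::runif(n, RcRange[1], RcRange[2])
  P <- 2 * gammaTrue * (1 / Rp - 1 / Rc)
  P <- P * (1 + stats::rnorm(n, sd = noiseSd))
  out <- data.frame(P_c_pa = P, R_p_um = rep(Rp, n), R_c_um = Rc)
  attr(out, "gamma_true") <- gammaTrue
  out
}
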