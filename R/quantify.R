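# Image-derived scalar operators: interfacial tension, polarity, intensity
# profiles, membrane curvature, boundary-orientation binning, shape
# descriptors, depth-corrected fate classification and colocalization.

#' Construct a Contour2D
#'
#' @param points n x 2 matrix or data.frame of ordered boundary points
#'   (pixel units).
#' @param pixelSize um per pixel.
#' @param closed closed contour (implicit closure; do not repeat the first
#'   point).
#' @param intensity optional per-point intensity.
#' @param cavityDirection optional unit vector toward the cavity.
#' @return a [Contour2D].
#' @export
contour2D <- function(points, pixelSize = 1, closed = TRUE,
                      intensity = numeric(0),
                      cavityDirection = numeric(0)) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (length(cavityDirection) == 2L) {
    nrm <- sqrt(sum(cavityDirection^2))
    if (nrm == 0) stop("cavityDirection must be non-zero")
    cavityDirection <- cavityDirection / nrm
  }
  methods::new("Contour2D", points = points, pixelSize = pixelSize,
               closed = closed, intensity = as.numeric(intensity),
               cavityDirection = cavityDirection)
}

#' Interfacial tension from micropipette aspiration (Young-Laplace)
#'
#' `gamma = P_c / (2 * (1/R_p - 1/R_c))`: the steady-state tension of a
#' cell of surface curvature radius `R_c` aspirated into a pipette of
#' radius `R_p` at pressure `P_c`. With pressures in Pa and radii in um the
#' result is in pN/um (1 Pa um = 1 pN/um). `R_c = Inf` gives the flat-cell
#' limit `gamma = P_c * R_p / 2`.
#'
#' @param P_c aspiration pressure(s), Pa; alternatively a `data.frame` with
#'   columns `P_c_pa`, `R_p_um`, `R_c_um`.
#' @param R_p pipette radius (um).
#' @param R_c cell surface curvature radius (um); must exceed `R_p`.
#' @return tension(s) in pN/um.
#' @examples
#' laplaceTension(300, 4, 12)   # 900 pN/um
#' laplaceTension(100, 4, Inf)  # 200 pN/um
#' @export
laplaceTension <- function(P_c, R_p = NULL, R_c = Inf) {
  if (is.data.frame(P_c)) {
    df <- P_c
    need <- c("P_c_pa", "R_p_um", "R_c_um")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("aspiration table missing columns: ", paste(miss, collapse = ", "))
    return(laplaceTension(df$P_c_pa, df$R_p_um, df$R_c_um))
  }
  if (any(R_p <= 0) || any(P_c <= 0))
    stop("invalid measurement: P_c and R_p must be positive")
  if (any(R_c <= R_p))
    stop("invalid measurement: R_c must exceed R_p (non-positive denominator)")
  P_c / (2 * (1 / R_p - 1 / R_c))
}

#' Polarization index of a radial intensity profile
#'
#' The ratio between the mean intensity over the quarter of the profile
#' nearest the outer edge (positions >= 0.75) and the mean intensity over
#' the quarter nearest the inner edge (positions <= 0.25). Values above 1
#' indicate apical (outward-facing) enrichment of the marker.
#'
#' @param profile an [IntensityProfile], or a numeric intensity vector at
#'   equally spaced positions spanning \[0, 1\].
#' @return the polarization index.
#' @export
polarizationIndex <- function(profile) {
  if (methods::is(profile, "IntensityProfile")) {
    pos <- profile@positions
    int <- profile@intensities
  } else {
    int <- as.numeric(profile)
    pos <- seq(0, 1, length.out = length(int))
  }
  inner <- int[pos <= 0.25]
  outer <- int[pos >= 0.75]
  if (!length(inner) || !length(outer))
    stop("profile must span the inner (0) to outer (1) edge")
  mi <- mean(inner, na.rm = TRUE)
  if (!is.finite(mi) || mi == 0)
    stop("polarization index undefined: inner-quarter mean intensity is zero")
  mean(outer, na.rm = TRUE) / mi
}

#' Bin an intensity line scan into a normalized profile
#'
#' Mean intensity per equal-width positional bin over \[0, 1\] (the fixed
#' number of intervals that normalizes cell or ICM length), optionally
#' divided by the maximum bin value and smoothed by a centered rolling
#' average. Empty bins are flagged `NA` and linearly interpolated only when
#' `interpolate = TRUE`.
#'
#' @param positions fractional positions in \[0, 1\] (0 = inner edge).
#' @param intensities matching non-negative intensities.
#' @param nBins number of bins (>= 2).
#' @param normalize divide by the maximum bin value (max becomes 1).
#' @param window rolling-average width in bins (1 = none).
#' @param interpolate linearly fill empty bins.
#' @param channel channel tag stored in the result.
#' @return an [IntensityProfile] (positions are bin midpoints).
#' @export
intensityProfile <- function(positions, intensities, nBins = 20L,
                             normalize = TRUE, window = 3L,
                             interpolate = FALSE, channel = "") {
  stopifnot(nBins >= 2L, length(positions) == length(intensities))
  edges <- seq(0, 1, length.out = nBins + 1L)
  bin <- cut(positions, edges, include.lowest = TRUE)
  means <- tapply(intensities, bin, mean)
  means <- as.numeric(means)  # empty bins -> NA (flagged, never zero)
  if (interpolate && anyNA(means)) {
    ok <- which(!is.na(means))
    means <- stats::approx(ok, means[ok], xout = seq_along(means),
                           rule = 2)$y
  }
  if (normalize) {
    mx <- max(means, na.rm = TRUE)
    if (mx > 0) means <- means / mx
  }
  if (window > 1L) {
    nas <- is.na(means)
    means[!nas] <- rollingMean(means[!nas], window)
  }
  methods::new("IntensityProfile",
               positions = (edges[-1] + edges[-length(edges)]) / 2,
               intensities = means, normalized = normalize,
               channel = channel)
}

#' Per-point membrane curvature of a traced contour
#'
#' For each contour point, two neighbouring points are taken `offset`
#' points away on either side and the curvature is the inverse of the
#' radius of the circle through the three points (in physical units via
#' the pixel size), exactly zero when the three points are collinear
#' (|cross product| < 1e-9 x scale^2). On closed contours indexing wraps;
#' on open contours the first and last `offset` points get `NA`. The sign
#' convention assumes counter-clockwise traversal: positive curvature is
#' locally convex outward (a protrusion), and mirroring the contour flips
#' the sign.
#'
#' @param contour a [Contour2D]
#' @param offset neighbour distance in points (default 10, i.e. a segment
#'   of 20 pixels on a 1 px-spaced trace).
#' @return numeric vector of curvatures (um^-1), one per contour point.
#' @export
curvatureProfile <- function(contour, offset = 10L) {
  p <- contour@points
  n <- nrow(p)
  if (contour@closed && n <= 2L * offset)
    stop("closed contour needs more than 2*offset points")
  kappa <- rep(NA_real_, n)
  idx <- if (contour@closed) seq_len(n) else seq(offset + 1L, n - offset)
  for (i in idx) {
    ia <- if (contour@closed) ((i - 1L - offset) %% n) + 1L else i - offset
    ic <- if (contour@closed) ((i - 1L + offset) %% n) + 1L else i + offset
    A <- p[ia, ]; B <- p[i, ]; C <- p[ic, ]
    ab <- B - A; ac <- C - A; bc <- C - B
    cross <- ab[1] * ac[2] - ab[2] * ac[1]
    scale2 <- max(sum(ab^2), sum(ac^2), sum(bc^2))
    if (abs(cross) < 1e-9 * scale2) {
      kappa[i] <- 0
      next
    }
    # circumradius R = |AB| |BC| |CA| / (2 |cross|)
    R <- sqrt(sum(ab^2) * sum(bc^2) * sum(ac^2)) / (2 * abs(cross))
    turn <- ab[1] * bc[2] - ab[2] * bc[1]  # left turn = convex (CCW contour)
    kappa[i] <- sign(turn) / (R * contour@pixelSize)
  }
  kappa
}

#' Curvature and intensity binned along the cavity-TE axis
#'
#' Partitions a closed contour into `k` contiguous equal-arc-length
#' intervals anchored to the cavity-trophectoderm axis (bin 1 is centred on
#' the cavity-facing pole) and returns per-bin mean curvature and mean
#' intensity together with the argmax bin of each. Ties for the argmax take
#' the lowest bin index and are flagged.
#'
#' @param contour a closed [Contour2D] carrying per-point intensity.
#' @param axis unit vector toward the cavity; defaults to the contour's
#'   `cavityDirection`.
#' @param k number of bins (default 6).
#' @param offset curvature neighbour distance (see [curvatureProfile()]).
#' @return list: `bins` (`data.frame`: `bin`, `arc_length_px`,
#'   `mean_curvature`, `mean_intensity`), `argmax_curvature`,
#'   `argmax_intensity`, `tie_curvature`, `tie_intensity`.
#' @export
boundaryBinOrientation <- function(contour, axis = NULL, k = 6L,
                                   offset = 10L) {
  if (!contour@closed) stop("boundary binning needs a closed contour")
  if (is.null(axis)) axis <- contour@cavityDirection
  if (length(axis) != 2L || sum(axis^2) == 0)
    stop("need a non-zero cavity-TE axis")
  axis <- axis / sqrt(sum(axis^2))
  p <- contour@points
  n <- nrow(p)
  seg <- sqrt(rowSums((p[c(2:n, 1), ] - p)^2))  # length of edge i -> i+1
  arc <- c(0, cumsum(seg))[seq_len(n)]          # arc position of point i
  L <- sum(seg)
  ctr <- colMeans(p)
  proj <- (p[, 1] - ctr[1]) * axis[1] + (p[, 2] - ctr[2]) * axis[2]
  pole <- which.max(proj)                        # cavity-facing pole point
  s0 <- arc[pole] - L / (2 * k)                  # bin 1 centred on the pole
  rel <- (arc - s0) %% L
  bin <- pmin(floor(rel / (L / k)) + 1L, k)
  kappa <- curvatureProfile(contour, offset = offset)
  intens <- if (length(contour@intensity)) contour@intensity
            else rep(NA_real_, n)
  bins <- data.frame(
    bin = seq_len(k),
    arc_length_px = as.numeric(tapply(seg, bin, sum)[as.character(seq_len(k))]),
    mean_curvature = as.numeric(tapply(kappa, bin, mean)[as.character(seq_len(k))]),
    mean_intensity = as.numeric(tapply(intens, bin, mean)[as.character(seq_len(k))]))
  amax <- function(v) {
    if (all(is.na(v))) return(list(i = NA_integer_, tie = NA))
    mx <- max(v, na.rm = TRUE)
    hits <- which(abs(v - mx) < 1e-12)
    list(i = hits[1], tie = length(hits) > 1L)
  }
  ac <- amax(bins$mean_curvature)
  ai <- amax(bins$mean_intensity)
  list(bins = bins, argmax_curvature = ac$i, argmax_intensity = ai$i,
       tie_curvature = ac$tie, tie_intensity = ai$tie)
}

#' Depth-corrected k-means classification of EPI/PrE fates
#'
#' To compensate for fluorescence decay with imaging depth, channel
#' intensities are log-transformed and a linear regression of log intensity
#' against z-depth is fitted and subtracted per channel; 2-class k-means on
#' the corrected (GATA6, NANOG) values then assigns fates, labelling the
#' cluster with the higher corrected GATA6 mean as PrE. The k-means uses a
#' fixed seed and multiple restarts, so the classification is deterministic.
#'
#' @param cells `data.frame` with columns `gata6`, `nanog` (positive
#'   intensities) and `z_um`.
#' @param k number of clusters (2).
#' @param seed RNG seed for the k-means initialization.
#' @param nstart k-means restarts.
#' @param ... further arguments to [stats::kmeans()] (e.g. `algorithm`).
#' @return the input with added columns `gata6_corrected`,
#'   `nanog_corrected` (z-corrected log intensities) and `fate`.
#' @export
classifyFatesKmeans <- function(cells, k = 2L, seed = 1L, nstart = 10L,
                                ...) {
  stopifnot(all(c("gata6", "nanog", "z_um") %in% names(cells)))
  if (nrow(cells) < k) stop("fewer cells than clusters")
  if (any(cells$gata6 <= 0) || any(cells$nanog <= 0))
    stop("intensities must be positive for the log transform")
  correct <- function(v) {
    lv <- log(v)
    stats::residuals(stats::lm(lv ~ cells$z_um)) + mean(lv)
  }
  cells$gata6_corrected <- correct(cells$gata6)
  cells$nanog_corrected <- correct(cells$nanog)
  old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  km <- stats::kmeans(cbind(cells$gata6_corrected, cells$nanog_corrected),
                      centers = k, nstart = nstart, ...)
  clusterMeans <- tapply(cells$gata6_corrected, km$cluster, mean)
  preId <- as.integer(names(clusterMeans)[which.max(clusterMeans)])
  cells$fate <- ifelse(km$cluster == preId, "PRE", "EPI")
  cells
}

#' Shape descriptors and protrusion geometry of a cell outline
#'
#' Aspect ratio from the ellipse with the same second area moments as the
#' polygon (major/minor axis ratio), circularity `4 pi A / P^2` with the
#' polygonal perimeter (implicit closure), and -- when a protrusion tip and
#' a cavity-normal reference point are given -- the protrusion length
#' (centre to tip, um) and the angle at the centre between the centre-tip
#' and centre-cavity segments (degrees, in \[0, 180\]).
#'
#' @param contour a closed [Contour2D]
#' @param protrusionTip optional (x, y) of the protrusion tip (pixels).
#' @param cavityPoint optional (x, y) of the foot of the normal dropped to
#'   the cavity surface (pixels).
#' @param center optional (x, y) of the cell/nucleus centre; defaults to
#'   the polygon centroid.
#' @return list: `aspect_ratio`, `circularity`, `area_um2`, `perimeter_um`,
#'   and (when tips are given) `protrusion_length_um`,
#'   `protrusion_angle_deg`.
#' @export
shapeMetrics <- function(contour, protrusionTip = NULL, cavityPoint = NULL,
                         center = NULL) {
  p <- contour@points
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  A <- sum(cross) / 2
  if (abs(A) < 1e-9) stop("degenerate (zero-area) contour")
  cx <- sum((x + x2) * cross) / (6 * A)
  cy <- sum((y + y2) * cross) / (6 * A)
  # second area moments about the centroid (Green's theorem)
  sxx <- sum((x^2 + x * x2 + x2^2) * cross) / 12 - A * cx^2
  syy <- sum((y^2 + y * y2 + y2^2) * cross) / 12 - A * cy^2
  sxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cross) / 24 -
    A * cx * cy
  cov <- matrix(c(sxx, sxy, sxy, syy), 2) / A
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  perim <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  out <- list(aspect_ratio = sqrt(ev[1] / ev[2]),
              circularity = 4 * pi * abs(A) / perim^2,
              area_um2 = abs(A) * contour@pixelSize^2,
              perimeter_um = perim * contour@pixelSize)
  if (!is.null(protrusionTip)) {
    ctr <- if (is.null(center)) c(cx, cy) else center
    v1 <- protrusionTip - ctr
    if (sum(v1^2) == 0) stop("protrusion tip coincides with the centre")
    out$protrusion_length_um <- sqrt(sum(v1^2)) * contour@pixelSize
    if (!is.null(cavityPoint)) {
      v2 <- cavityPoint - ctr
      if (sum(v2^2) == 0) stop("cavity reference coincides with the centre")
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      out$protrusion_angle_deg <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
  }
  out
}

#' Pearson and Manders colocalization coefficients
#'
#' Pearson's correlation over the union of above-threshold voxels, and the
#' Manders overlap coefficients: `M1` is the fraction of channel-A signal
#' in B-positive voxels, `M2` the fraction of channel-B signal in
#' A-positive voxels.
#'
#' @param channelA,channelB equal-size non-negative arrays.
#' @param thresholdA,thresholdB positivity thresholds (>= 0).
#' @return list: `pearson_r` (NA with a flag when a channel is constant
#'   over the union), `manders_M1`, `manders_M2`, `constant_channel`.
#' @export
colocalization <- function(channelA, channelB, thresholdA = 0,
                           thresholdB = 0) {
  if (!identical(dim(channelA), dim(channelB)) ||
      length(channelA) != length(channelB))
    stop("channels must have identical shape")
  stopifnot(thresholdA >= 0, thresholdB >= 0)
  a <- channelA > thresholdA
  b <- channelB > thresholdB
  u <- a | b
  constant <- !any(u) || stats::sd(channelA[u]) == 0 ||
    stats::sd(channelB[u]) == 0
  r <- if (constant) NA_real_ else stats::cor(channelA[u], channelB[u])
  sumA <- sum(channelA)
  sumB <- sum(channelB)
  list(pearson_r = r,
       manders_M1 = if (sumA > 0) sum(channelA[b]) / sumA else NA_real_,
       manders_M2 = if (sumB > 0) sum(channelB[a]) / sumB else NA_real_,
       constant_channel = constant)
}

#' Cortical signal normalized by a nuclear reference
#'
#' Mean cortical marker intensity (e.g. ppMRLC along the outer cell
#' surface) divided by the mean nuclear reference intensity (DAPI) of the
#' same cell; invariant to any common scaling of the two channels.
#'
#' @param cortical intensities sampled along the cell cortex.
#' @param nuclear nuclear reference intensities of the same cell.
#' @return the normalized ratio.
#' @export
normalizedCorticalIntensity <- function(cortical, nuclear) {
  mn <- mean(nuclear, na.rm = TRUE)
  if (!is.finite(mn) || mn == 0) stop("nuclear reference mean is zero")
  mean(cortical, na.rm = TRUE) / mn
}
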