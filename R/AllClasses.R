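# S4 classes shared across the package.

#' Voxel types used by the lattice model
#'
#' Integer codes for the four voxel types of the ICM lattice model: `MEDIUM`
#' (0), `EPI` (1), `PRE` (2) and `ECM` (3). The same codes index the contact
#' energy and active-exponent tables of [simParams()].
#'
#' @format Named integer vector of length 4.
#' @export
voxelTypes <- c(MEDIUM = 0L, EPI = 1L, PRE = 2L, ECM = 3L)

.typeNames <- names(voxelTypes)

#' VoxelLattice: a 3D label grid with a cell registry
#'
#' A `VoxelLattice` holds the state of the cellular Potts model: a 3D integer
#' array mapping each voxel (1 voxel = 1 um^3) to a label, plus a registry
#' describing each label. Label 0 is the medium; every non-zero label present
#' in the grid must appear in the registry with a type (`EPI`, `PRE`, `ECM`
#' or `MEDIUM`), a preferred volume and a sampled division target. The
#' outermost one-voxel shell of the array is a frozen boundary: the kinetics
#' never update it (closed-box, isolated-ICM geometry).
#'
#' @slot labels 3D integer array of voxel labels (0 = medium).
#' @slot cells `data.frame` with columns `label`, `type`, `prefVolume`,
#'   `divisionTarget`, `birthTime` (one row per registered label).
#'
#' @seealso [initICM()], [latticeEnergy()], [simulateStep()], [runSimulation()]
#' @export
setClass("VoxelLattice",
  representation(labels = "array", cells = "data.frame"))

setValidity("VoxelLattice", function(object) {
  msgs <- character(0)
  d <- dim(object@labels)
  if (length(d) != 3L)
    msgs <- c(msgs, "labels must be a 3D array")
  if (!is.integer(object@labels))
    msgs <- c(msgs, "labels must be an integer array")
  reg <- object@cells
  need <- c("label", "type", "prefVolume", "divisionTarget", "birthTime")
  if (!all(need %in% names(reg))) {
    msgs <- c(msgs, paste("cell registry must have columns:",
                          paste(need, collapse = ", ")))
  } else {
    if (!all(reg$type %in% .typeNames))
      msgs <- c(msgs, "registry types must be MEDIUM, EPI, PRE or ECM")
    present <- unique(as.vector(object@labels))
    present <- present[present > 0L]
    if (!all(present %in% reg$label))
      msgs <- c(msgs, "every non-zero label in the grid must be registered")
    if (anyDuplicated(reg$label))
      msgs <- c(msgs, "duplicated labels in registry")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimParams: all constants of the Poissonian cellular Potts model
#'
#' Energies are in units of kT (the internal thermal scale, set to 1 at
#' 37 degrees C), volumes in um^3, time in minutes.
#'
#' @slot J 4x4 symmetric matrix of contact energies per Moore voxel pair,
#'   indexed by voxel type (`MEDIUM`, `EPI`, `PRE`, `ECM`); same-label pairs
#'   contribute nothing regardless of `J`.
#' @slot kappa volume-constraint stiffness (kT per um^6).
#' @slot alpha named vector of kinetic action rates (events per minute) per
#'   *target* voxel type.
#' @slot phi 4x4 matrix of active exponents phi(source type, target type),
#'   dimensionless; non-zero entries boost specific conversions (here:
#'   cell-to-ECM transitions at PrE contacts).
#' @slot epsilon energy cost per ECM voxel (kT), driving ECM degradation.
#' @slot kT thermal energy scale (internal unit, 1).
#' @slot dt integration step of the tau-leap kinetics (minutes).
#' @slot growthRate linear growth rate g of the preferred cell volume
#'   (um^3 per minute).
#' @slot divisionVolumes empirical distribution of target division volumes
#'   (um^3) resampled with replacement at each division.
#' @slot seed RNG seed recorded with every simulation.
#'
#' @seealso [simParams()]
#' @export
setClass("SimParams",
  representation(J = "matrix", kappa = "numeric", alpha = "numeric",
                 phi = "matrix", epsilon = "numeric", kT = "numeric",
                 dt = "numeric", growthRate = "numeric",
                 divisionVolumes = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@J), c(4L, 4L)))
    msgs <- c(msgs, "J must be a 4x4 matrix (MEDIUM, EPI, PRE, ECM)")
  else if (!isTRUE(all.equal(object@J, t(object@J))))
    msgs <- c(msgs, "J must be symmetric")
  else if (object@J["MEDIUM", "PRE"] > object@J["MEDIUM", "EPI"])
    msgs <- c(msgs, "tension ordering requires J[MEDIUM,PRE] <= J[MEDIUM,EPI]")
  if (!identical(dim(object@phi), c(4L, 4L)))
    msgs <- c(msgs, "phi must be a 4x4 matrix")
  if (length(object@alpha) != 4L || any(object@alpha < 0))
    msgs <- c(msgs, "alpha must be four non-negative rates")
  if (object@dt <= 0) msgs <- c(msgs, "dt must be positive")
  if (object@kT <= 0) msgs <- c(msgs, "kT must be positive")
  if (length(object@divisionVolumes) == 0 || any(object@divisionVolumes <= 0))
    msgs <- c(msgs, "divisionVolumes must be non-empty and positive")
  if (length(msgs)) msgs else TRUE
})

#' SimTrace: recorded output of a lattice simulation
#'
#' @slot times recording times (minutes).
#' @slot sortingScores EPI/PrE sorting score at each recording time.
#' @slot ecmMeanRadius mean distance of ECM voxels from the aggregate
#'   centroid (um; `NA` while no ECM exists).
#' @slot ecmHistograms list of per-time ECM radial histograms (1-um bins).
#' @slot centroids list of per-time data frames (label, type, volume, x, y, z).
#' @slot snapshots optional stored lattices.
#' @slot params the [SimParams] used.
#' @slot seed the RNG seed used.
#' @export
setClass("SimTrace",
  representation(times = "numeric", sortingScores = "numeric",
                 ecmMeanRadius = "numeric", ecmHistograms = "list",
                 centroids = "list", snapshots = "list", params = "SimParams",
                 seed = "integer"))

setValidity("SimTrace", function(object) {
  n <- length(object@times)
  if (length(object@sortingScores) != n || length(object@ecmMeanRadius) != n ||
      length(object@ecmHistograms) != n || length(object@centroids) != n)
    return("all recorded sequences must share the same length")
  sc <- object@sortingScores
  if (any(!is.na(sc) & (sc < -1 | sc > 1)))
    return("sorting scores must lie in [-1, 1]")
  TRUE
})

#' TrackSet: fate-labelled 3D cell trajectories
#'
#' The consumed interface of the nuclear detection and tracking pipeline:
#' one row per cell per frame with 3D position in um and a fate label.
#'
#' @slot tracks `data.frame` with columns `track_id`, `parent_id`, `t_min`,
#'   `x_um`, `y_um`, `z_um`, `fate` (one of `EPI`, `PRE`, `UNKNOWN`) and
#'   optional `reporter`.
#' @slot frameInterval frame interval in minutes.
#' @seealso [trackSet()], [radialSeries()], [sortingScore()]
#' @export
setClass("TrackSet",
  representation(tracks = "data.frame", frameInterval = "numeric"))

setValidity("TrackSet", function(object) {
  msgs <- character(0)
  df <- object@tracks
  need <- c("track_id", "t_min", "x_um", "y_um", "z_um", "fate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(paste("tracks missing columns:", paste(miss, collapse = ", ")))
  if (!all(df$fate %in% c("EPI", "PRE", "UNKNOWN")))
    msgs <- c(msgs, "fates must be EPI, PRE or UNKNOWN")
  bad <- vapply(split(df$t_min, df$track_id),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    msgs <- c(msgs, "per-cell times must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' RadialSeries: radial coordinates of tracked cells
#'
#' @slot data `data.frame` with columns `track_id`, `fate`, `t_min`, `r_um`
#'   (distance from the ICM centroid) and `d` (normalized position; the
#'   centroid is d = 0, the outermost cell at that frame is d = 1).
#' @slot centroids per-frame ICM centroid (`t_min`, `x_um`, `y_um`, `z_um`).
#' @export
setClass("RadialSeries",
  representation(data = "data.frame", centroids = "data.frame"))

setValidity("RadialSeries", function(object) {
  df <- object@data
  if (any(df$r_um < 0)) return("radial distances must be non-negative")
  if (any(df$d < -1e-9 | df$d > 1 + 1e-9))
    return("normalized positions must lie in [0, 1]")
  TRUE
})

#' Contour2D: an ordered planar cell boundary
#'
#' @slot points n x 2 matrix of boundary points (pixel units).
#' @slot pixelSize physical pixel size (um per pixel).
#' @slot closed whether the contour is closed (first point is implicitly
#'   joined to the last; the first point must not repeat the last).
#' @slot intensity optional per-point intensity (e.g. laminin), length n or 0.
#' @slot cavityDirection optional unit vector pointing towards the cavity,
#'   length 2 or 0.
#' @seealso [contour2D()], [curvatureProfile()], [boundaryBinOrientation()]
#' @export
setClass("Contour2D",
  representation(points = "matrix", pixelSize = "numeric", closed = "logical",
                 intensity = "numeric", cavityDirection = "numeric"))

setValidity("Contour2D", function(object) {
  p <- object@points
  msgs <- character(0)
  if (ncol(p) != 2L) msgs <- c(msgs, "points must be an n x 2 matrix")
  if (nrow(p) < 3L) msgs <- c(msgs, "a contour needs at least 3 points")
  if (nrow(p) >= 2L) {
    dup <- rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2) == 0
    if (any(dup)) msgs <- c(msgs, "duplicated consecutive points")
  }
  if (isTRUE(object@closed) && nrow(p) >= 2L &&
      all(p[1, ] == p[nrow(p), ]))
    msgs <- c(msgs, "closed contours use implicit closure: drop the repeated last point")
  if (object@pixelSize <= 0) msgs <- c(msgs, "pixelSize must be positive")
  il <- length(object@intensity)
  if (il != 0L && il != nrow(p))
    msgs <- c(msgs, "intensity must have one value per point (or be empty)")
  cl <- length(object@cavityDirection)
  if (cl != 0L && cl != 2L)
    msgs <- c(msgs, "cavityDirection must have length 2 (or be empty)")
  if (length(msgs)) msgs else TRUE
})

#' IntensityProfile: a binned intensity series along a normalized axis
#'
#' @slot positions ordered fractional coordinates in [0, 1] (bin midpoints
#'   for binned profiles); position 0 is the inner edge, 1 the outer edge.
#' @slot intensities non-negative intensities, same length as `positions`.
#' @slot normalized whether intensities were divided by their maximum.
#' @slot channel free-text channel tag.
#' @seealso [intensityProfile()], [polarizationIndex()]
#' @export
setClass("IntensityProfile",
  representation(positions = "numeric", intensities = "numeric",
                 normalized = "logical", channel = "character"))

setValidity("IntensityProfile", function(object) {
  if (length(object@positions) != length(object@intensities))
    return("positions and intensities must have the same length")
  if (is.unsorted(object@positions))
    return("positions must be sorted")
  TRUE
})

#' ScalingConstants: constants of the monolayer scaling model
#'
#' @slot f PrE fate fraction (mouse default 0.6).
#' @slot q10,q90 10th and 90th percentiles of the PrE apical cell area
#'   (um^2; defaults 157 and 376).
#' @slot c mean cell volume (um^3; default 1907, the through-origin fit of
#'   ICM volume against total cell number).
#' @seealso [scalingConstants()], [icmAreas()]
#' @export
setClass("ScalingConstants",
  representation(f = "numeric", q10 = "numeric", q90 = "numeric",
                 c = "numeric"))

setValidity("ScalingConstants", function(object) {
  msgs <- character(0)
  if (object@f <= 0 || object@f >= 1) msgs <- c(msgs, "f must be in (0, 1)")
  if (object@q10 <= 0 || object@q90 <= object@q10)
    msgs <- c(msgs, "need 0 < q10 < q90")
  if (object@c <= 0) msgs <- c(msgs, "mean cell volume c must be positive")
  if (length(msgs)) msgs else TRUE
})
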