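# Tau-leap kinetics, growth and division, and the recording run loop.

#' Advance the lattice kinetics by tau-leap steps
#'
#' One step of length `params@dt`: every boundary voxel (a non-frozen voxel
#' with at least one differing Moore neighbour), visited in random order,
#' draws one candidate label uniformly from [candidateLabels()] and executes
#' the copy with probability `1 - exp(-lambda * dt)` where `lambda` is the
#' [transitionRate()]. Moves that would fragment or empty an EPI/PrE cell
#' are rejected (ECM and medium regions may fragment and vanish). Preferred
#' volumes are not grown here; see [growAndDivide()] and [runSimulation()].
#'
#' @param lattice a [VoxelLattice]
#' @param params a [SimParams]
#' @param nSteps number of tau-leap steps.
#' @return the updated [VoxelLattice].
#' @export
simulateStep <- function(lattice, params, nSteps = 1L) {
  .checkJ(lattice, params)
  lab <- as.vector(lattice@labels)
  vbar <- .labelVector(lattice, "prefVolume")
  divT <- numeric(length(vbar))  # no division checks in the bare kinetics
  res <- cpp_advance(lab, dim(lattice@labels), .typeCodes(lattice), vbar,
                     divT, unname(params@J), unname(params@phi),
                     unname(params@alpha), params@kappa, params@epsilon,
                     params@kT, params@dt, 0, .ecmLabel(lattice),
                     as.integer(nSteps))
  lattice@labels <- array(res$labels, dim = dim(lattice@labels))
  lattice
}

#' Grow preferred volumes and divide cells that reached their target
#'
#' Preferred volumes follow `Vbar_c(t) = Vbar_c(0) + g * t`. When a cell's
#' preferred volume reaches its sampled division target, the cell's voxels
#' are partitioned by the plane through the centroid perpendicular to the
#' principal axis of the gyration tensor; daughters inherit the type, their
#' preferred volumes are reset to their actual post-split volumes, and fresh
#' division targets are resampled with replacement from
#' `params@divisionVolumes`.
#'
#' @param lattice a [VoxelLattice]
#' @param params a [SimParams]
#' @param elapsed elapsed time (minutes) over which to grow.
#' @param t current simulation time (minutes), recorded as daughters' birth
#'   time.
#' @return the updated [VoxelLattice].
#' @export
growAndDivide <- function(lattice, params, elapsed, t = elapsed) {
  reg <- lattice@cells
  isCell <- reg$type %in% c("EPI", "PRE")
  reg$prefVolume[isCell] <- reg$prefVolume[isCell] +
    params@growthRate * elapsed
  lattice@cells <- reg
  repeat {
    reg <- lattice@cells
    due <- which(reg$type %in% c("EPI", "PRE") & reg$divisionTarget > 0 &
                   reg$prefVolume >= reg$divisionTarget)
    if (!length(due)) break
    lattice <- .divideCell(lattice, reg$label[due[1]], params, t)
  }
  lattice
}

# Split one cell along the plane perpendicular to the principal gyration
# axis. Ties (voxels exactly on the plane) go to the parent's side. Minor
# disconnected fragments created by the cut are reassigned to the sibling.
.divideCell <- function(lattice, label, params, t) {
  dims <- dim(lattice@labels)
  vox <- cpp_voxels_of_label(as.vector(lattice@labels), dims, label)
  if (nrow(vox) < 2L) {  # nothing to split; just resample a target
    i <- match(label, lattice@cells$label)
    lattice@cells$divisionTarget[i] <- sample(params@divisionVolumes, 1L)
    return(lattice)
  }
  ctr <- colMeans(vox)
  centred <- sweep(vox, 2, ctr)
  gyr <- crossprod(centred) / nrow(vox)
  eig <- eigen(gyr, symmetric = TRUE)
  # principal axis; on degenerate (isotropic) tensors eigen() still returns
  # a deterministic basis and we take its first vector; fix the sign so the
  # first non-zero component is positive
  axis <- eig$vectors[, 1]
  nz <- which(abs(axis) > 1e-12)[1]
  if (!is.na(nz) && axis[nz] < 0) axis <- -axis
  s <- as.vector(centred %*% axis)
  newLabel <- as.integer(max(lattice@cells$label)) + 1L
  side <- s > 1e-9
  lab <- lattice@labels
  idx <- vox[, 1] + dims[1] * ((vox[, 2] - 1L) + dims[2] * (vox[, 3] - 1L))
  lab[idx[side]] <- newLabel

  # registry: daughter inherits the parent's type
  reg <- lattice@cells
  i <- match(label, reg$label)
  daughter <- reg[i, ]
  daughter$label <- newLabel
  reg <- rbind(reg, daughter)
  lattice@labels <- lab
  lattice@cells <- reg
  lattice@labels <- .repairComponents(lattice@labels, c(label, newLabel),
                                      maxIter = 4L)

  vols <- tabulate(lattice@labels, nbins = newLabel)
  reg$prefVolume[match(c(label, newLabel), reg$label)] <-
    vols[c(label, newLabel)]
  reg$divisionTarget[match(c(label, newLabel), reg$label)] <-
    sample(params@divisionVolumes, 2L, replace = TRUE)
  reg$birthTime[match(c(label, newLabel), reg$label)] <- t
  lattice@cells <- reg
  methods::validObject(lattice)
  lattice
}

#' Run a recorded simulation
#'
#' Advances the tau-leap kinetics with growth and division in `params@dt`
#' increments for `duration` minutes, recording at every `recordEvery`
#' minutes: the EPI/PrE sorting score computed on cell centroids (see
#' [sortingScore()]), the radial histogram and mean radial position of ECM
#' voxels around the aggregate centroid (the observable behind the
#' prediction that secreted matrix shifts towards the ICM periphery as
#' sorting proceeds), and all cell centroids.
#'
#' @param params a [SimParams]; `params@seed` seeds the run.
#' @param init initial [VoxelLattice], e.g. from [initICM()].
#' @param duration simulated minutes (>= 0).
#' @param recordEvery recording interval (minutes).
#' @param snapshotEvery optional lattice-snapshot interval (minutes; `Inf`
#'   disables snapshots).
#' @return a [SimTrace].
#' @export
runSimulation <- function(params, init, duration, recordEvery = 30,
                          snapshotEvery = Inf) {
  stopifnot(duration >= 0, recordEvery > 0)
  .checkJ(init, params)
  set.seed(params@seed)
  lattice <- init
  times <- numeric(0); scores <- numeric(0); ecmMean <- numeric(0)
  hists <- list(); cents <- list(); snaps <- list()
  record <- function(t) {
    cc <- cellCentroids(lattice)
    times <<- c(times, t)
    scores <<- c(scores, .latticeSortingScore(cc))
    eh <- .ecmRadialHistogram(lattice, cc)
    hists[[length(hists) + 1L]] <<- eh$hist
    ecmMean <<- c(ecmMean, eh$mean)
    cents[[length(cents) + 1L]] <<- cc
    if (is.finite(snapshotEvery) && (t %% snapshotEvery) < 1e-9)
      snaps[[sprintf("t%g", t)]] <<- lattice
  }
  record(0)
  t <- 0
  nextRec <- recordEvery
  while (t < duration - 1e-9) {
    target <- min(nextRec, duration)
    stepsLeft <- as.integer(round((target - t) / params@dt))
    while (stepsLeft > 0L) {
      lab <- as.vector(lattice@labels)
      vbar <- .labelVector(lattice, "prefVolume")
      divT <- .labelVector(lattice, "divisionTarget")
      res <- cpp_advance(lab, dim(lattice@labels), .typeCodes(lattice), vbar,
                         divT, unname(params@J), unname(params@phi),
                         unname(params@alpha), params@kappa, params@epsilon,
                         params@kT, params@dt, params@growthRate,
                         .ecmLabel(lattice), stepsLeft)
      lattice@labels <- array(res$labels, dim = dim(lattice@labels))
      reg <- lattice@cells
      reg$prefVolume <- res$vbar[reg$label + 1L]
      lattice@cells <- reg
      done <- res$steps_done
      t <- t + done * params@dt
      stepsLeft <- stepsLeft - done
      if (res$divide_label > 0L)
        lattice <- .divideCell(lattice, res$divide_label, params, t)
      if (done == 0L && res$divide_label == 0L) break  # no boundary voxels
    }
    t <- target
    record(t)
    nextRec <- nextRec + recordEvery
  }
  methods::new("SimTrace", times = times, sortingScores = scores,
               ecmMeanRadius = ecmMean, ecmHistograms = hists,
               centroids = cents, snapshots = snaps, params = params,
               seed = params@seed)
}

# sorting score over EPI/PrE cell centroids, centroid = mean cell position
.latticeSortingScore <- function(cc) {
  cc <- cc[cc$type %in% c("EPI", "PRE") & cc$volume > 0, ]
  if (!any(cc$type == "EPI") || !any(cc$type == "PRE")) return(NA_real_)
  ctr <- colMeans(cc[, c("x", "y", "z")])
  r <- sqrt((cc$x - ctr[1])^2 + (cc$y - ctr[2])^2 + (cc$z - ctr[3])^2)
  sortingScore(r, cc$type)
}

.ecmRadialHistogram <- function(lattice, cc, binWidth = 1) {
  ecm <- .ecmLabel(lattice)
  empty <- list(hist = integer(0), mean = NA_real_)
  if (ecm == 0L) return(empty)
  vox <- cpp_voxels_of_label(as.vector(lattice@labels), dim(lattice@labels),
                             ecm)
  if (nrow(vox) == 0L) return(empty)
  cells <- cc[cc$type %in% c("EPI", "PRE") & cc$volume > 0, ]
  ctr <- colMeans(cells[, c("x", "y", "z")])
  r <- sqrt((vox[, 1] - ctr[1])^2 + (vox[, 2] - ctr[2])^2 +
              (vox[, 3] - ctr[3])^2)
  h <- tabulate(pmin(floor(r / binWidth) + 1L, 1000L))
  list(hist = h, mean = mean(r))
}

#' Write lattice snapshots as multi-plane TIFF stacks with a JSON sidecar
#'
#' One 16-bit label image per z-plane per stored snapshot, plus
#' `labels.json` mapping labels to types. Requires the `tiff` package.
#'
#' @param trace a [SimTrace] run with a finite `snapshotEvery`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeLatticeSnapshots <- function(trace, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF snapshots requires the 'tiff' package")
  if (!length(trace@snapshots)) stop("trace holds no snapshots")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(trace@snapshots)) {
    lat <- trace@snapshots[[nm]]
    arr <- lat@labels
    planes <- lapply(seq_len(dim(arr)[3]),
                     function(z) arr[, , z] / 65535)
    p <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(planes, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  reg <- trace@snapshots[[1]]@cells
  sidecar <- file.path(dir, "labels.json")
  jsonlite::write_json(stats::setNames(as.list(reg$type),
                                       as.character(reg$label)),
                       sidecar, auto_unbox = TRUE)
  invisible(c(paths, sidecar))
}
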