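# Generics and simple accessors / show methods.

#' @rdname VoxelLattice-class
#' @param object,x a `VoxelLattice`
#' @export
setGeneric("cellRegistry", function(x) standardGeneric("cellRegistry"))

#' @rdname VoxelLattice-class
#' @export
setMethod("cellRegistry", "VoxelLattice", function(x) x@cells)

#' @rdname VoxelLattice-class
#' @export
setGeneric("latticeLabels", function(x) standardGeneric("latticeLabels"))

#' @rdname VoxelLattice-class
#' @export
setMethod("latticeLabels", "VoxelLattice", function(x) x@labels)

#' @rdname VoxelLattice-class
#' @export
setGeneric("latticeDims", function(x) standardGeneric("latticeDims"))

#' @rdname VoxelLattice-class
#' @export
setMethod("latticeDims", "VoxelLattice", function(x) dim(x@labels))

#' Current cell volumes (exact voxel counts)
#'
#' @param x a `VoxelLattice`
#' @return named numeric vector, one entry per registered label (um^3).
#' @export
setGeneric("cellVolumes", function(x) standardGeneric("cellVolumes"))

#' @rdname cellVolumes
#' @export
setMethod("cellVolumes", "VoxelLattice", function(x) {
  labs <- x@cells$label
  v <- tabulate(x@labels, nbins = max(labs))
  stats::setNames(as.numeric(v[labs]), labs)
})

#' Cell centroids and volumes of a lattice
#'
#' @param x a `VoxelLattice`
#' @return `data.frame` with columns `label`, `type`, `volume`, `x`, `y`, `z`
#'   (voxel coordinates, 1 voxel = 1 um).
#' @export
setGeneric("cellCentroids", function(x) standardGeneric("cellCentroids"))

#' @rdname cellCentroids
#' @export
setMethod("cellCentroids", "VoxelLattice", function(x) {
  reg <- x@cells
  st <- cpp_cell_stats(as.vector(x@labels), dim(x@labels), max(reg$label))
  data.frame(label = reg$label, type = reg$type,
             volume = st[reg$label, 1], x = st[reg$label, 2],
             y = st[reg$label, 3], z = st[reg$label, 4])
})

setMethod("show", "VoxelLattice", function(object) {
  d <- dim(object@labels)
  reg <- object@cells
  tab <- table(factor(reg$type, levels = .typeNames))
  cat(sprintf("VoxelLattice %d x %d x %d voxels (1 um^3 each)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  registered labels: %d (EPI %d, PRE %d, ECM %d)\n",
              nrow(reg), tab[["EPI"]], tab[["PRE"]], tab[["ECM"]]))
  cat(sprintf("  occupied voxels: %d of %d\n",
              sum(object@labels > 0L), prod(d)))
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams (energies in kT, time in min, volumes in um^3)\n")
  cat("  J (contact energies):\n")
  print(object@J)
  cat(sprintf("  kappa = %g, epsilon = %g, kT = %g, dt = %g min\n",
              object@kappa, object@epsilon, object@kT, object@dt))
  cat("  alpha:", paste(sprintf("%s=%g", names(object@alpha), object@alpha),
                        collapse = ", "), "\n")
  cat(sprintf("  growth g = %g um^3/min; %d division volumes; seed = %d\n",
              object@growthRate, length(object@divisionVolumes), object@seed))
})

setMethod("show", "SimTrace", function(object) {
  n <- length(object@times)
  cat(sprintf("SimTrace: %d recordings over %g min (seed %d)\n",
              n, if (n) max(object@times) else 0, object@seed))
  if (n) {
    cat(sprintf("  sorting score: %.3f -> %.3f\n",
                object@sortingScores[1], object@sortingScores[n]))
    fin <- object@ecmMeanRadius[n]
    if (!is.na(fin))
      cat(sprintf("  final ECM mean radius: %.1f um\n", fin))
  }
})

#' Tabular view of a simulation trace
#'
#' @param trace a [SimTrace]
#' @return `data.frame` with columns `time_min`, `sorting_score`,
#'   `ecm_mean_radius_um`, `n_ecm_voxels`.
#' @export
setGeneric("traceTable", function(trace) standardGeneric("traceTable"))

#' @rdname traceTable
#' @export
setMethod("traceTable", "SimTrace", function(trace) {
  data.frame(time_min = trace@times,
             sorting_score = trace@sortingScores,
             ecm_mean_radius_um = trace@ecmMeanRadius,
             n_ecm_voxels = vapply(trace@ecmHistograms, sum, numeric(1)))
})

#' @rdname TrackSet-class
#' @param x a `TrackSet`
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname TrackSet-class
#' @export
setMethod("tracks", "TrackSet", function(x) x@tracks)

#' @rdname TrackSet-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname TrackSet-class
#' @export
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)

setMethod("show", "TrackSet", function(object) {
  df <- object@tracks
  cat(sprintf("TrackSet: %d cells, %d records, frame interval %g min\n",
              length(unique(df$track_id)), nrow(df), object@frameInterval))
  print(table(fate = df$fate[!duplicated(df$track_id)]))
})

setMethod("show", "RadialSeries", function(object) {
  cat(sprintf("RadialSeries: %d cells x %d frames\n",
              length(unique(object@data$track_id)),
              length(unique(object@data$t_min))))
})

setMethod("show", "Contour2D", function(object) {
  cat(sprintf("Contour2D: %d points (%s), pixel size %g um/px\n",
              nrow(object@points),
              if (object@closed) "closed" else "open", object@pixelSize))
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile [%s]: %d bins%s\n",
              if (length(object@channel)) object@channel else "?",
              length(object@positions),
              if (isTRUE(object@normalized)) ", normalized to max = 1" else ""))
})

setMethod("show", "ScalingConstants", function(object) {
  cat(sprintf(
    "ScalingConstants: f = %g, q10 = %g um^2, q90 = %g um^2, c = %g um^3\n",
    object@f, object@q10, object@q90, object@c))
})
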