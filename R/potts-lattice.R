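# Lattice construction: registry helpers, the initial salt-and-pepper ICM.

#' Construct a VoxelLattice from a label array and registry
#'
#' Low-level constructor used by [initICM()] and by tests that craft small
#' lattices by hand. Preferred volumes default to the current voxel counts
#' (cells start unstressed) and division targets are sampled from
#' `params@divisionVolumes`.
#'
#' @param labels 3D integer array of labels (0 = medium).
#' @param types named character vector mapping label (as name) to type, or a
#'   full registry `data.frame` (columns `label`, `type`, `prefVolume`,
#'   `divisionTarget`, `birthTime`).
#' @param params a [SimParams] (used only to sample division targets when
#'   `types` is not a full registry).
#' @return a [VoxelLattice].
#' @export
voxelLattice <- function(labels, types, params = simParams()) {
  storage.mode(labels) <- "integer"
  if (is.data.frame(types)) {
    reg <- types
  } else {
    lab <- as.integer(names(types))
    vol <- tabulate(labels, nbins = max(lab, 1L))
    reg <- data.frame(label = lab,
                      type = unname(types),
                      prefVolume = as.numeric(vol[lab]),
                      divisionTarget = sample(params@divisionVolumes,
                                              length(lab), replace = TRUE),
                      birthTime = 0)
  }
  methods::new("VoxelLattice", labels = labels, cells = reg)
}

#' Initialize a salt-and-pepper ICM aggregate
#'
#' Builds a spherical aggregate of `nCells` Voronoi-seeded, Moore-connected
#' cells inside a medium-filled closed box (one-voxel frozen shell). Exactly
#' `round(preFraction * nCells)` cells are typed PrE, the rest EPI, with the
#' type assignment spatially random (the salt-and-pepper configuration from
#' which EPI/PrE sorting starts). An empty ECM registry entry is created so
#' that PrE cells can deposit matrix during simulation.
#'
#' @param nCells number of cells (>= 1).
#' @param preFraction PrE fate fraction in [0, 1] (mouse default 0.6).
#' @param radius aggregate radius in um; default chosen so cells average
#'   `meanCellVolume` um^3.
#' @param params a [SimParams] (division-target sampling).
#' @param seed RNG seed; the same seed reproduces the lattice exactly.
#' @param meanCellVolume target mean cell volume (um^3) used when `radius`
#'   is not given.
#' @param withEcm register an (initially empty) ECM region so PrE cells
#'   can deposit matrix; set `FALSE` for matrix-free simulations (e.g. a
#'   fully EPI/PrE-symmetric control).
#' @return a [VoxelLattice].
#' @examples
#' lat <- initICM(nCells = 10, preFraction = 0.6, seed = 1,
#'                meanCellVolume = 150)
#' table(cellRegistry(lat)$type)
#' @export
initICM <- function(nCells, preFraction = 0.6, radius = NULL,
                    params = simParams(), seed = params@seed,
                    meanCellVolume = 1000, withEcm = TRUE) {
  stopifnot(nCells >= 1, preFraction >= 0, preFraction <= 1)
  if (is.null(radius))
    radius <- (3 * nCells * meanCellVolume / (4 * pi))^(1 / 3)
  vol <- 4 / 3 * pi * radius^3
  if (vol / nCells < 27)
    stop("infeasible packing: fewer than 27 voxels per cell at this radius")
  set.seed(seed)
  pad <- 3L
  side <- 2L * (as.integer(ceiling(radius)) + pad) + 1L
  ctr <- (side + 1) / 2

  # dart-throwing seeds inside the sphere with a soft minimum separation
  minSep <- 0.6 * (vol / nCells)^(1 / 3)
  seeds <- matrix(NA_real_, nCells, 3)
  placed <- 0L
  tries <- 0L
  while (placed < nCells && tries < 20000L) {
    tries <- tries + 1L
    p <- stats::runif(3, -1, 1) * radius * 0.92
    if (sum(p^2) > (radius * 0.92)^2) next
    if (placed > 0L) {
      d2 <- rowSums((seeds[seq_len(placed), , drop = FALSE] -
                       matrix(p, placed, 3, byrow = TRUE))^2)
      if (min(d2) < minSep^2) next
    }
    placed <- placed + 1L
    seeds[placed, ] <- p
    if (tries > 10000L) minSep <- minSep * 0.95
  }
  if (placed < nCells)
    stop("infeasible packing: could not place ", nCells,
         " cell seeds in a radius-", signif(radius, 3), " um sphere")

  # nearest-seed (Voronoi) assignment of in-sphere voxels
  ax <- seq_len(side) - ctr
  grid <- expand.grid(x = ax, y = ax, z = ax)
  r2 <- grid$x^2 + grid$y^2 + grid$z^2
  inside <- r2 <= radius^2
  pts <- as.matrix(grid[inside, ])
  d2 <- outer(rowSums(pts^2), rep(1, nCells)) -
    2 * pts %*% t(seeds) +
    outer(rep(1, nrow(pts)), rowSums(seeds^2))
  assign <- max.col(-d2)
  labels <- array(0L, dim = c(side, side, side))
  labels[inside] <- as.integer(assign)

  # keep the shell strictly medium
  labels[c(1, side), , ] <- 0L
  labels[, c(1, side), ] <- 0L
  labels[, , c(1, side)] <- 0L

  labels <- .repairComponents(labels, seq_len(nCells))

  nPre <- round(preFraction * nCells)
  preIds <- sample(seq_len(nCells), nPre)
  types <- rep("EPI", nCells)
  types[preIds] <- "PRE"
  vols <- tabulate(labels, nbins = nCells)
  if (any(vols == 0))
    stop("infeasible packing: a seeded cell received no voxels")
  nCells <- as.integer(nCells)
  reg <- data.frame(label = seq_len(nCells),
                    type = types,
                    prefVolume = as.numeric(vols),
                    divisionTarget = sample(params@divisionVolumes, nCells,
                                            replace = TRUE),
                    birthTime = 0)
  if (withEcm)
    reg <- rbind(reg, data.frame(label = nCells + 1L, type = "ECM",
                                 prefVolume = 0, divisionTarget = 0,
                                 birthTime = 0))
  methods::new("VoxelLattice", labels = labels, cells = reg)
}

# Reassign minor connected components of each label to the dominant
# neighbouring label so that every cell is Moore-connected.
.repairComponents <- function(labels, labelIds, maxIter = 6L) {
  dims <- dim(labels)
  for (iter in seq_len(maxIter)) {
    changed <- FALSE
    for (l in labelIds) {
      comp <- cpp_label_components(as.vector(labels), dims, l)
      nComp <- max(comp)
      if (nComp <= 1L) next
      changed <- TRUE
      sizes <- tabulate(comp[comp > 0L], nbins = nComp)
      keep <- which.max(sizes)
      for (cid in setdiff(seq_len(nComp), keep)) {
        vox <- which(comp == cid)
        nb <- .neighbourLabels(labels, vox)
        nb <- nb[nb != l & nb != 0L]
        labels[vox] <- if (length(nb)) as.integer(names(which.max(table(nb))))
                       else 0L
      }
    }
    if (!changed) return(labels)
  }
  labels
}

# labels adjacent (Moore) to a set of linear voxel indices
.neighbourLabels <- function(labels, vox) {
  dims <- dim(labels)
  coords <- arrayInd(vox, dims)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  out <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    idx <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1 + dims[2] * (nb[ok, 3] - 1))
    out <- c(out, labels[idx])
  }
  out
}

#' Audit Moore-connectivity of all EPI/PrE cells
#'
#' @param lattice a [VoxelLattice]
#' @return named logical vector: `TRUE` where the cell's voxel set forms a
#'   single Moore-connected component.
#' @export
auditConnectivity <- function(lattice) {
  reg <- lattice@cells
  ids <- reg$label[reg$type %in% c("EPI", "PRE")]
  dims <- dim(lattice@labels)
  lab <- as.vector(lattice@labels)
  out <- vapply(ids, function(l) {
    comp <- cpp_label_components(lab, dims, l)
    max(comp) == 1L
  }, logical(1))
  stats::setNames(out, ids)
}
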