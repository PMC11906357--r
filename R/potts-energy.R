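# Hamiltonian, incremental energies and Poissonian transition rates.

#' Cellular Potts Hamiltonian of a lattice
#'
#' Total energy in kT: the sum over unordered Moore-neighbour voxel pairs
#' with differing labels of the contact energy `J[type_i, type_j]`, plus the
#' volume constraint `kappa/2 * (V_c - Vbar_c)^2` over EPI and PrE cells
#' (medium and ECM carry no volume constraint and there is no perimeter
#' term), plus `epsilon` per ECM voxel.
#'
#' @param lattice a [VoxelLattice]
#' @param params a [SimParams]
#' @return scalar energy (kT).
#' @examples
#' lat <- voxelLattice(array(0L, c(3, 3, 3)),
#'                     data.frame(label = 1L, type = "EPI", prefVolume = 1,
#'                                divisionTarget = 3000, birthTime = 0))
#' latticeEnergy(lat, simParams())  # all-medium lattice: 0
#' @export
latticeEnergy <- function(lattice, params) {
  .checkJ(lattice, params)
  cpp_lattice_energy(as.vector(lattice@labels), dim(lattice@labels),
                     .typeCodes(lattice), unname(params@J), params@kappa,
                     .labelVector(lattice, "prefVolume"), params@epsilon)
}

#' Incremental energy of a single-voxel flip
#'
#' The energy difference of assigning `newLabel` to the voxel at `voxel`
#' (1-based array coordinates), identical to
#' `latticeEnergy(after) - latticeEnergy(before)` and including the
#' `epsilon` term when the move creates or destroys an ECM voxel.
#'
#' @param lattice a [VoxelLattice]
#' @param params a [SimParams]
#' @param voxel integer vector of length 3 (array coordinates) or a single
#'   linear index.
#' @param newLabel target label (must be registered, or 0 for medium).
#' @return scalar energy difference (kT).
#' @export
deltaEnergy <- function(lattice, params, voxel, newLabel) {
  .checkJ(lattice, params)
  dims <- dim(lattice@labels)
  i0 <- if (length(voxel) == 3L)
    (voxel[1] - 1L) + dims[1] * ((voxel[2] - 1L) + dims[2] * (voxel[3] - 1L))
  else as.integer(voxel) - 1L
  reg <- lattice@cells
  if (newLabel != 0L && !(newLabel %in% reg$label))
    stop("newLabel ", newLabel, " is not registered")
  vols <- numeric(max(reg$label) + 1L)
  vols[reg$label + 1L] <- cellVolumes(lattice)
  cpp_delta_energy(as.vector(lattice@labels), dims, .typeCodes(lattice),
                   unname(params@J), params@kappa,
                   .labelVector(lattice, "prefVolume"), vols, params@epsilon,
                   i0, as.integer(newLabel))
}

.checkJ <- function(lattice, params) {
  present <- unique(lattice@cells$type)
  if (sum(lattice@labels == 0L) > 0) present <- union(present, "MEDIUM")
  if (!all(present %in% rownames(params@J)))
    stop("configuration error: J is missing entries for types ",
         paste(setdiff(present, rownames(params@J)), collapse = ", "))
  invisible(TRUE)
}

#' Poissonian transition rate of a label-copy move
#'
#' `lambda = alpha(target) * exp(phi(source, target)) *
#' min(1, exp(-deltaE / kT))`: a Metropolis-shaped acceptance with per-type
#' kinetic action rates and active exponents. With uniform `alpha` and
#' `phi = 0` the kinetics obey detailed balance with respect to the
#' Boltzmann distribution of the Hamiltonian. `deltaE` must already include
#' the `epsilon` term when ECM voxels are created or destroyed.
#'
#' @param deltaE energy difference(s) of the move (kT); vectorized.
#' @param sourceType,targetType voxel type names (`MEDIUM`, `EPI`, `PRE`,
#'   `ECM`).
#' @param params a [SimParams]
#' @return rate(s) in events per minute (saturating at
#'   `alpha * exp(phi)` for `deltaE <= 0`).
#' @examples
#' transitionRate(0, "EPI", "MEDIUM", simParams())   # alpha(MEDIUM)
#' transitionRate(1e6, "EPI", "MEDIUM", simParams()) # -> 0
#' @export
transitionRate <- function(deltaE, sourceType, targetType, params) {
  a <- params@alpha[targetType]
  if (is.na(a)) stop("alpha is not defined for target type ", targetType)
  ex <- params@phi[sourceType, targetType] - pmax(0, deltaE / params@kT)
  a * exp(pmin(ex, 700))
}

#' Candidate target labels of a voxel
#'
#' The distinct labels present in the voxel's Moore neighbourhood (excluding
#' its own), extended by the ECM label when the voxel belongs to an EPI/PrE
#' cell and a *different* PrE cell touches it -- the rule by which PrE cells
#' deposit matrix at their cell-cell contacts.
#'
#' @inheritParams deltaEnergy
#' @return integer vector of candidate labels (possibly empty).
#' @export
candidateLabels <- function(lattice, voxel) {
  dims <- dim(lattice@labels)
  i0 <- if (length(voxel) == 3L)
    (voxel[1] - 1L) + dims[1] * ((voxel[2] - 1L) + dims[2] * (voxel[3] - 1L))
  else as.integer(voxel) - 1L
  cpp_candidates(as.vector(lattice@labels), dims, .typeCodes(lattice),
                 i0, .ecmLabel(lattice))
}
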