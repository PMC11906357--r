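# Parameter container for the Poissonian cellular Potts model.

.symmetricJ <- function(mediumEpi, mediumPre, epiEpi, prePre, epiPre,
                        mediumEcm, epiEcm, preEcm, ecmEcm = 0) {
  J <- matrix(0, 4, 4, dimnames = list(.typeNames, .typeNames))
  J["MEDIUM", "EPI"] <- J["EPI", "MEDIUM"] <- mediumEpi
  J["MEDIUM", "PRE"] <- J["PRE", "MEDIUM"] <- mediumPre
  J["EPI", "EPI"] <- epiEpi
  J["PRE", "PRE"] <- prePre
  J["EPI", "PRE"] <- J["PRE", "EPI"] <- epiPre
  J["MEDIUM", "ECM"] <- J["ECM", "MEDIUM"] <- mediumEcm
  J["EPI", "ECM"] <- J["ECM", "EPI"] <- epiEcm
  J["PRE", "ECM"] <- J["ECM", "PRE"] <- preEcm
  J["ECM", "ECM"] <- ecmEcm
  J
}

#' Construct simulation parameters
#'
#' Defaults encode the experimentally observed interfacial-tension ordering
#' gamma(PrE:medium) < gamma(PrE:PrE) < gamma(EPI:EPI) < gamma(PrE:EPI) <
#' gamma(EPI:medium) and the kinetic asymmetry alpha(EPI) < alpha(PrE), with
#' ECM surface and kinetic parameters identical to PrE
#' (J[MEDIUM,ECM] = J[MEDIUM,PRE], J[EPI,ECM] = J[EPI,PRE],
#' J[PRE,ECM] = J[PRE,PRE], alpha(ECM) = alpha(PrE)). Under the contact-energy
#' mapping gamma(A:M) = J\[A,M\] - J\[A,A\]/2, gamma(A:B) = J\[A,B\] -
#' (J\[A,A\] + J\[B,B\])/2 and gamma(A:A) = J\[A,A\]/2, the default table gives
#' tensions 0.1 < 0.2 < 0.3 < 0.4 < 0.6 kT per voxel face, satisfying the
#' complete-wetting condition gamma(EPI:M) > gamma(PrE:EPI) + gamma(PrE:M)
#' needed for PrE to envelop EPI.
#'
#' @param J 4x4 symmetric contact-energy matrix (kT per Moore voxel pair),
#'   dimnames `MEDIUM`, `EPI`, `PRE`, `ECM`. See [voxelTypes].
#' @param kappa volume-constraint stiffness (kT um^-6).
#' @param alpha named kinetic action rates (events/min) per target voxel type.
#' @param phiEpiEcm,phiPreEcm active exponents boosting EPI-to-ECM and
#'   PrE-to-ECM conversion at PrE contacts (dimensionless; the rate carries
#'   a factor exp(phi)). The default gives a sparse interfacial ECM
#'   population whose radial distribution shifts peripherally as sorting
#'   proceeds; see the methods vignette.
#' @param epsilon per-ECM-voxel energy cost (kT) promoting ECM degradation.
#' @param kT thermal energy scale (internal unit; 1 = 37 degrees C).
#' @param dt integration time step (minutes).
#' @param growthRate linear preferred-volume growth rate g (um^3/min).
#' @param divisionVolumes empirical division-volume distribution (um^3);
#'   defaults to the ten experimentally measured mitotic volumes.
#' @param seed RNG seed.
#' @return a [SimParams] object.
#' @examples
#' p <- simParams()
#' p@J["MEDIUM", "PRE"] < p@J["MEDIUM", "EPI"]
#' @export
simParams <- function(J = .symmetricJ(mediumEpi = 0.9, mediumPre = 0.3,
                                      epiEpi = 0.6, prePre = 0.4,
                                      epiPre = 0.9, mediumEcm = 0.3,
                                      epiEcm = 0.9, preEcm = 0.4),
                      kappa = 0.05,
                      alpha = c(MEDIUM = 1, EPI = 0.5, PRE = 1, ECM = 1),
                      phiEpiEcm = 3.5, phiPreEcm = 3.5,
                      epsilon = 2, kT = 1, dt = 0.1,
                      growthRate = 2.5,
                      divisionVolumes = c(2406.63, 2428.09, 2455.23, 2517.92,
                                          2994.28, 3002.65, 3110.31, 3116.73,
                                          3294.93, 4133.67),
                      seed = 1L) {
  if (is.null(dimnames(J)))
    dimnames(J) <- list(.typeNames, .typeNames)
  phi <- matrix(0, 4, 4, dimnames = list(.typeNames, .typeNames))
  phi["EPI", "ECM"] <- phiEpiEcm
  phi["PRE", "ECM"] <- phiPreEcm
  alpha <- alpha[.typeNames]
  names(alpha) <- .typeNames
  if (anyNA(alpha))
    stop("alpha must be named MEDIUM, EPI, PRE, ECM")
  methods::new("SimParams", J = J, kappa = kappa, alpha = alpha, phi = phi,
               epsilon = epsilon, kT = kT, dt = dt, growthRate = growthRate,
               divisionVolumes = divisionVolumes, seed = as.integer(seed))
}

# registry lookup vectors used by the C++ layer:
# typeOf[label + 1] = integer type code (index 1 = label 0 = medium)
.typeCodes <- function(lattice) {
  reg <- lattice@cells
  maxLab <- max(reg$label, 0L)
  out <- integer(maxLab + 1L)
  out[reg$label + 1L] <- voxelTypes[reg$type]
  out
}

# preferred volumes / division targets indexed like .typeCodes
.labelVector <- function(lattice, column) {
  reg <- lattice@cells
  maxLab <- max(reg$label, 0L)
  out <- numeric(maxLab + 1L)
  out[reg$label + 1L] <- reg[[column]]
  out
}

# the single registered ECM region label (0 if absent)
.ecmLabel <- function(lattice) {
  reg <- lattice@cells
  l <- reg$label[reg$type == "ECM"]
  if (length(l)) l[1] else 0L
}
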