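# Tau-leap update rules: candidate sets, fragmentation guard, bookkeeping.

# a 5^3 lattice with an EPI cell next to medium, and optionally a PrE cell
craftedLattice <- function(withPre = FALSE) {
  a <- array(0L, c(5, 5, 5))
  a[2:3, 2:4, 2:4] <- 1L          # EPI cell
  if (withPre) a[4, 2:4, 2:4] <- 2L
  reg <- data.frame(label = c(1L, 2L, 3L),
                    type = c("EPI", "PRE", "ECM"),
                    prefVolume = c(sum(a == 1L), sum(a == 2L), 0),
                    divisionTarget = c(3000, 3000, 0), birthTime = 0)
  voxelLattice(a, reg)
}

test_that("ECM only becomes a candidate at contacts with a PrE cell", {
  noPre <- craftedLattice(withPre = FALSE)
  # exhaustive: no voxel of the lattice may offer the ECM label
  d <- latticeDims(noPre)
  for (v in seq_len(prod(d)))
    expect_false(3L %in% candidateLabels(noPre, v))
  withPre <- craftedLattice(withPre = TRUE)
  # an EPI voxel touching the PrE cell now offers ECM
  expect_true(3L %in% candidateLabels(withPre, c(3L, 3L, 3L)))
  # ...but an EPI voxel away from PrE still does not
  expect_false(3L %in% candidateLabels(withPre, c(2L, 2L, 2L)))
  # medium voxels never offer ECM through the deposition rule
  expect_false(3L %in% candidateLabels(withPre, c(1L, 3L, 3L)))
})

test_that("zero kinetic rates freeze the lattice", {
  lat <- craftedLattice(withPre = TRUE)
  p <- simParams(alpha = c(MEDIUM = 0, EPI = 0, PRE = 0, ECM = 0))
  set.seed(5)
  out <- simulateStep(lat, p, nSteps = 50L)
  expect_identical(latticeLabels(out), latticeLabels(lat))
})

test_that("moves that would fragment a cell are rejected", {
  # dumbbell: two 3x3x1 plates joined by a single bridge voxel
  a <- array(0L, c(9, 5, 5))
  a[2:3, 2:4, 2:4] <- 1L
  a[7:8, 2:4, 2:4] <- 1L
  a[4:6, 3, 3] <- 1L  # thin bridge
  reg <- data.frame(label = 1L, type = "EPI", prefVolume = sum(a == 1L),
                    divisionTarget = 5000, birthTime = 0)
  lat <- voxelLattice(a, reg)
  # oracle: removing the middle bridge voxel disconnects the cell
  b <- a; b[5, 3, 3] <- 0L
  expect_false(floodConnected(b, 1L))
  expect_false(icmDynamics:::cpp_connected_after_removal(
    as.vector(a), dim(a), (5 - 1) + 9 * ((3 - 1) + 5 * (3 - 1))))
  # under strongly medium-favouring kinetics the cell must stay connected
  p <- simParams(kappa = 0, alpha = c(MEDIUM = 10, EPI = 10, PRE = 10,
                                      ECM = 0))
  set.seed(11)
  out <- simulateStep(lat, p, nSteps = 30L)
  expect_true(floodConnected(latticeLabels(out), 1L))
  expect_gt(sum(latticeLabels(out) == 1L), 0)
})

test_that("volume bookkeeping is exact and determinism holds", {
  p <- simParams(seed = 3)
  lat <- initICM(nCells = 8, preFraction = 0.5, seed = 3,
                 meanCellVolume = 150)
  set.seed(9)
  out <- simulateStep(lat, p, nSteps = 40L)
  vols <- cellVolumes(out)
  nMedium <- sum(latticeLabels(out) == 0L)
  expect_identical(sum(vols) + nMedium, as.numeric(prod(latticeDims(out))))
  expect_true(all(auditConnectivity(out)))
  # same seed, same trajectory
  set.seed(9)
  out2 <- simulateStep(lat, p, nSteps = 40L)
  expect_identical(latticeLabels(out), latticeLabels(out2))
})

test_that("a short recorded run keeps cells connected and scores in range", {
  p <- simParams(seed = 21)
  lat <- initICM(nCells = 10, preFraction = 0.6, seed = 21,
                 meanCellVolume = 200)
  tr <- runSimulation(p, lat, duration = 10, recordEvery = 5,
                      snapshotEvery = 5)
  tt <- traceTable(tr)
  expect_equal(tt$time_min, c(0, 5, 10))
  expect_true(all(tt$sorting_score >= -1 & tt$sorting_score <= 1))
  for (snap in tr@snapshots)
    expect_true(all(auditConnectivity(snap)))
  # duration 0: a single record of the initial state
  tr0 <- runSimulation(p, lat, duration = 0, recordEvery = 5)
  expect_length(tr0@times, 1L)
  expect_identical(tr0@times, 0)
})
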