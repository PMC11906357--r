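# Independent oracles used across the suite. Everything here is pure R and
# deliberately naive: these implementations never share code with the
# package's computational paths they are used to check.

# all 26 Moore offsets, and the 13 "half" offsets that enumerate each
# unordered neighbour pair exactly once
mooreOffsets <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off[rowSums(abs(off)) > 0, ]
}
halfOffsets <- function() {
  off <- mooreOffsets()
  off[off$dx > 0 | (off$dx == 0 & off$dy > 0) |
        (off$dx == 0 & off$dy == 0 & off$dz > 0), ]
}

# brute-force cellular Potts Hamiltonian (kT): pairwise contact energies
# over unordered Moore pairs with differing labels, volume constraint over
# EPI/PrE cells, epsilon per ECM voxel
bruteEnergy <- function(lattice, params) {
  labels <- latticeLabels(lattice)
  reg <- cellRegistry(lattice)
  d <- dim(labels)
  typeOf <- function(l) ifelse(l == 0L, "MEDIUM",
                               reg$type[match(l, reg$label)])
  E <- 0
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    li <- labels[x, y, z]
    off <- halfOffsets()
    for (k in seq_len(nrow(off))) {
      xx <- x + off$dx[k]; yy <- y + off$dy[k]; zz <- z + off$dz[k]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3])
        next
      lj <- labels[xx, yy, zz]
      if (lj != li)
        E <- E + params@J[typeOf(li), typeOf(lj)]
    }
  }
  vols <- tabulate(labels, nbins = max(reg$label, 1L))
  for (i in seq_len(nrow(reg))) {
    if (reg$type[i] %in% c("EPI", "PRE"))
      E <- E + params@kappa / 2 * (vols[reg$label[i]] - reg$prefVolume[i])^2
  }
  nEcm <- sum(labels %in% reg$label[reg$type == "ECM"])
  E + params@epsilon * nEcm
}

# flood-fill Moore connectivity of one label (pure R, stack-based)
floodConnected <- function(labels, label) {
  idx <- which(labels == label)
  if (length(idx) <= 1L) return(TRUE)
  d <- dim(labels)
  mask <- array(FALSE, d)
  mask[idx] <- TRUE
  visited <- array(FALSE, d)
  off <- as.matrix(mooreOffsets())
  stack <- arrayInd(idx[1], d)
  visited[idx[1]] <- TRUE
  seen <- 1L
  top <- 1L
  stackM <- matrix(0L, length(idx), 3)
  stackM[1, ] <- stack
  while (top > 0L) {
    cur <- stackM[top, ]; top <- top - 1L
    for (k in seq_len(nrow(off))) {
      nb <- cur + off[k, ]
      if (any(nb < 1L) || any(nb > d)) next
      if (mask[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        seen <- seen + 1L
        top <- top + 1L
        stackM[top, ] <- nb
      }
    }
  }
  seen == length(idx)
}

# random small lattice with a handful of registered labels of mixed types
randomLattice <- function(seed, side = 8L, nLabels = 4L) {
  set.seed(seed)
  labels <- array(sample(0:nLabels, side^3, replace = TRUE),
                  dim = rep(side, 3L))
  storage.mode(labels) <- "integer"
  types <- sample(c("EPI", "PRE", "ECM"), nLabels, replace = TRUE)
  reg <- data.frame(label = seq_len(nLabels), type = types,
                    prefVolume = stats::runif(nLabels, 50, 150),
                    divisionTarget = 3000, birthTime = 0)
  voxelLattice(labels, reg)
}

# exact corridor-absorption (gambler's ruin) probability: a +/-1 random
# walk from the corridor centre, P(hit -a before +a), where u is the
# probability of a +1 step
ruinTowardProbability <- function(u, a = 3L) {
  if (abs(u - 0.5) < 1e-12) return(0.5)
  rho <- (1 - u) / u
  pAway <- (1 - rho^a) / (1 - rho^(2 * a))  # hit +a before -a
  1 - pAway
}

# numerical spherical-cap volume and area by integration (solid/surface of
# revolution of the sphere of radius Rs = (r^2 + h^2) / (2 h))
capByIntegration <- function(r, h) {
  if (h == 0) return(list(volume = 0, area = pi * r^2))
  Rs <- (r^2 + h^2) / (2 * h)
  vol <- stats::integrate(function(z) pi * (Rs^2 - z^2), Rs - h, Rs,
                          rel.tol = 1e-10)$value
  area <- stats::integrate(function(z) 2 * pi * sqrt(Rs^2 - z^2) *
                             sqrt(1 + z^2 / (Rs^2 - z^2)), Rs - h, Rs,
                           rel.tol = 1e-10)$value
  list(volume = vol, area = area)
}

# digitized circle contour (counter-clockwise), radius in pixels
circleContour <- function(radius, n = 360L, pixelSize = 1, ...) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(radius * cos(th), radius * sin(th))
  contour2D(pts, pixelSize = pixelSize, closed = TRUE, ...)
}

# equal-tension null parameters: every contact energy identical, equal
# kinetic rates for medium/EPI/PrE, ECM disabled
equalTensionParams <- function(seed, J0 = 0.6) {
  eqJ <- matrix(J0, 4, 4, dimnames = list(names(voxelTypes),
                                          names(voxelTypes)))
  simParams(J = eqJ, alpha = c(MEDIUM = 1, EPI = 1, PRE = 1, ECM = 0),
            phiEpiEcm = 0, phiPreEcm = 0, seed = seed)
}
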