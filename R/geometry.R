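# The cross-species geometric model: spherical-cap ICM measurements,
# PrE-area bounds from the fixed fate fraction, and monolayer / gap /
# multilayer classification across embryo sizes.

#' Construct scaling constants
#'
#' @param f PrE fate fraction (mouse 0.6; monkey 0.7; human 0.55).
#' @param q10,q90 10th / 90th percentiles of the PrE apical area (um^2).
#' @param c mean cell volume (um^3).
#' @return a [ScalingConstants].
#' @export
scalingConstants <- function(f = 0.6, q10 = 157, q90 = 376, c = 1907) {
  methods::new("ScalingConstants", f = f, q10 = q10, q90 = q90, c = c)
}

#' Species scenario presets for the PrE fraction
#'
#' The fixed fate-proportion scenarios used for the cross-species
#' comparison (fitted slopes must be recomputed from measurements with
#' [fitScaling()]).
#'
#' @return `data.frame` with columns `species` and `f`.
#' @export
speciesPresets <- function() {
  data.frame(species = c("mouse", "monkey", "human"),
             f = c(0.6, 0.7, 0.55))
}

#' Volume and surface area of a spherical cap
#'
#' For base radius `r` and height `h`:
#' volume = (1/6) pi h (3 r^2 + h^2), lateral surface area = pi (r^2 + h^2).
#' `h = 0` is the flat-disc limit (zero volume, area `pi r^2`); `h = r` the
#' hemisphere ((2/3) pi r^3 and 2 pi r^2).
#'
#' @param r base radius (um), > 0; vectorized.
#' @param h cap height (um), >= 0.
#' @return `data.frame` with columns `volume_um3`, `area_um2`.
#' @export
capGeometry <- function(r, h) {
  if (any(r <= 0) || any(h < 0))
    stop("need r > 0 and h >= 0")
  data.frame(volume_um3 = pi * h * (3 * r^2 + h^2) / 6,
             area_um2 = pi * (r^2 + h^2))
}

#' ICM volume, interface area, PrE-area bounds and outcome per embryo
#'
#' The ICM is modelled as the region between two spherical caps on the
#' same base circle of radius R: the trophectoderm-facing cap of height H
#' and the cavity-facing cap of height h (the elevation of the ICM-fluid
#' interface). Then `V_icm = capVolume(R, H) - capVolume(R, h)` and
#' `A_interface = capArea(R, h)`. The total PrE apical area available to
#' tile that interface lies between `f * n_total * q10` and
#' `f * n_total * q90`; an embryo is classified `GAP` when the interface
#' strictly exceeds the upper bound (EPI cells exposed to the cavity),
#' `MULTILAYER` when it is strictly below the lower bound (superfluous PrE
#' cells inside the ICM), and `MONOLAYER` otherwise (bounds inclusive).
#' Convex (human-type) interfaces use the same formulas with h measured
#' toward the cavity.
#'
#' @param geometry `data.frame` with columns `R_um`, `H_um`, `h_um`,
#'   `n_total` (and optionally `embryo_id`, `species`, `size_ratio`,
#'   `n_pre`).
#' @param constants a [ScalingConstants].
#' @return the input plus `V_icm_um3`, `A_interface_um2`, `A_pre_min_um2`,
#'   `A_pre_max_um2` and `outcome` (factor GAP / MONOLAYER / MULTILAYER).
#' @examples
#' g <- data.frame(R_um = 30, H_um = 40, h_um = 10, n_total = 100)
#' icmAreas(g, scalingConstants())
#' @export
icmAreas <- function(geometry, constants = scalingConstants()) {
  need <- c("R_um", "H_um", "h_um", "n_total")
  miss <- setdiff(need, names(geometry))
  if (length(miss))
    stop("geometry table missing columns: ", paste(miss, collapse = ", "))
  bad <- geometry$R_um <= 0 | geometry$H_um <= geometry$h_um |
    geometry$h_um < 0 | geometry$n_total < 0
  if (any(bad))
    stop("invalid geometry: need R > 0, H > h >= 0, n_total >= 0 (rows ",
         paste(which(bad), collapse = ", "), ")")
  major <- capGeometry(geometry$R_um, geometry$H_um)
  minor <- capGeometry(geometry$R_um, geometry$h_um)
  geometry$V_icm_um3 <- major$volume_um3 - minor$volume_um3
  geometry$A_interface_um2 <- minor$area_um2
  geometry$A_pre_min_um2 <- constants@f * geometry$n_total * constants@q10
  geometry$A_pre_max_um2 <- constants@f * geometry$n_total * constants@q90
  geometry$outcome <- factor(
    ifelse(geometry$A_interface_um2 > geometry$A_pre_max_um2, "GAP",
           ifelse(geometry$A_interface_um2 < geometry$A_pre_min_um2,
                  "MULTILAYER", "MONOLAYER")),
    levels = c("GAP", "MONOLAYER", "MULTILAYER"))
  geometry
}

#' Interface area of a hemispherical ICM as a function of cell number
#'
#' Assuming each cell contributes an average volume `c` so that the ICM is
#' a sphere of volume `V = c N`, a hemispherical PrE interface covers half
#' of that sphere's surface, giving the reference curve
#' `A = 3^(2/3) (pi/2)^(1/3) (c N)^(2/3)` (equivalently `2 pi r^2` with
#' `(4/3) pi r^3 = c N`). It illustrates how nonlinear surface-to-volume
#' scaling restricts monolayer formation to a window of embryo sizes.
#'
#' @param N total cell number (vectorized).
#' @param c mean cell volume (um^3).
#' @return hemisphere interface area(s) in um^2.
#' @export
hemisphereAreaFromCount <- function(N, c = 1907) {
  stopifnot(all(N >= 1), c > 0)
  3^(2 / 3) * (pi / 2)^(1 / 3) * (c * N)^(2 / 3)
}

#' Through-origin scaling fits for cell volume and PrE fraction
#'
#' Fits `V = c N` across size-manipulated embryos (least-squares slope of
#' ICM volume against total cell number, through the origin) and the PrE
#' fraction `n_pre = f n_total`, with standard errors from the
#' through-origin regressions.
#'
#' @param volumes `data.frame` with columns `n_total`, `V_icm_um3`
#'   (or `NULL`).
#' @param fractions `data.frame` with columns `n_total`, `n_pre`
#'   (or `NULL`).
#' @return list with any of `c`, `c_se`, `f`, `f_se`.
#' @export
fitScaling <- function(volumes = NULL, fractions = NULL) {
  out <- list()
  throughOrigin <- function(xcol, ycol, df) {
    stopifnot(nrow(df) >= 2)
    if (all(df[[xcol]] == 0)) stop("all predictor values are zero")
    fit <- stats::lm(stats::reformulate(paste0("0 + ", xcol), ycol), df)
    s <- suppressWarnings(summary(fit))$coefficients  # exact fits: se = 0
    c(slope = unname(s[1, 1]), se = unname(s[1, 2]))
  }
  if (!is.null(volumes)) {
    v <- throughOrigin("n_total", "V_icm_um3", volumes)
    out$c <- v[["slope"]]; out$c_se <- v[["se"]]
  }
  if (!is.null(fractions)) {
    f <- throughOrigin("n_total", "n_pre", fractions)
    out$f <- f[["slope"]]; out$f_se <- f[["se"]]
  }
  if (!length(out)) stop("supply volumes and/or fractions")
  out
}

#' Monolayer / gap / multilayer probabilities per size class
#'
#' Recomputes each embryo's outcome under a scenario PrE fraction (e.g.
#' 0.4 / 0.6 / 0.8) and estimates, per size class, the probability of each
#' outcome as a relative frequency with binomial standard errors
#' `sqrt(p (1 - p) / n)`. Probabilities within a class sum to 1.
#'
#' @param geometry `data.frame` as for [icmAreas()], with a grouping
#'   column.
#' @param constants a [ScalingConstants]; its `f` is replaced by
#'   `scenarioF` when given.
#' @param scenarioF scenario PrE fraction (default: `constants@f`).
#' @param by grouping column name (default `"size_ratio"`; use a constant
#'   column for a single class).
#' @return `data.frame`: group, `outcome`, `p`, `se`, `n`.
#' @export
outcomeProbabilities <- function(geometry, constants = scalingConstants(),
                                 scenarioF = NULL, by = "size_ratio") {
  if (!is.null(scenarioF))
    constants <- scalingConstants(f = scenarioF, q10 = constants@q10,
                                  q90 = constants@q90, c = constants@c)
  if (!by %in% names(geometry)) geometry[[by]] <- "all"
  res <- icmAreas(geometry, constants)
  groups <- split(res, res[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    grp <- groups[[g]]
    n <- nrow(grp)
    if (!n) return(NULL)
    p <- as.numeric(table(grp$outcome)) / n
    data.frame(group = g, outcome = levels(grp$outcome), p = p,
               se = sqrt(p * (1 - p) / n), n = n)
  }))
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}

#' Blastocyst volume from the fitted ellipse axes
#'
#' The mean of the major and minor axes is taken as the average diameter d
#' and the volume estimated as a sphere of radius d/2.
#'
#' @param major,minor ellipse axes (um), `major >= minor > 0`; vectorized.
#' @return volume(s) in um^3.
#' @examples
#' blastocystVolume(100, 100)  # (4/3) pi 50^3
#' @export
blastocystVolume <- function(major, minor) {
  if (any(major <= 0) || any(minor <= 0))
    stop("axes must be positive")
  d <- (major + minor) / 2
  4 / 3 * pi * (d / 2)^3
}
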