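---
title: "Models and methods behind icmDynamics"
author: "icmDynamics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icmDynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmDynamics)
```

# The biological problem

Between embryonic days E3.5 and E4.5 the mouse blastocyst's inner cell mass
(ICM) resolves a salt-and-pepper mixture of epiblast (EPI) and primitive
endoderm (PrE) precursors into a radially ordered pattern: a PrE monolayer
lining the fluid cavity, enveloping the EPI. Three quantitative ingredients
interact: differential interfacial tensions (polarized PrE cells have a much
lower cell-medium tension than apolar EPI cells), actively directed PrE
migration guided by a self-deposited extracellular-matrix (ECM) gradient,
and a tissue-scale geometric constraint — a fixed fate proportion can tile
the cavity interface with a monolayer only for a window of embryo sizes.
`icmDynamics` implements a simulator and the estimators for all three
levels, plus seeded generators for every input class, so each statistical
claim in the package is testable end to end without image data.

# The Poissonian cellular Potts model

## State and energy

The tissue lives on a cubic voxel lattice (1 voxel = 1 um^3). Each voxel
carries a label: 0 for medium, or an identifier registered as an EPI cell,
a PrE cell, or the ECM region. The energy of a configuration is

$$E = \sum_{\langle i j\rangle} J_{\tau(i)\tau(j)}\,[\ell_i \neq \ell_j]
  \;+\; \frac{\kappa}{2}\sum_{c}(V_c - \bar V_c)^2
  \;+\; \varepsilon\, N_\mathrm{ECM},$$

where the first sum runs over unordered Moore-neighbour voxel pairs with
differing labels, the second over EPI/PrE cells only (medium and ECM carry
no volume constraint, and there is no perimeter/area term — the actomyosin
cortex, not membrane inextensibility, sets cell shape on these timescales),
and each ECM voxel pays a constant cost $\varepsilon$ that drives matrix
turnover. All energies are in units of $k_BT$ (internal scale 1,
temperature 37 °C).

## Kinetics

Unlike Metropolis Monte Carlo, transitions are Poisson events with physical
rates, which gives the simulation a real time axis:

$$\lambda = \alpha_{\tau(\text{target})}\;
  e^{\phi(\tau_\text{source},\,\tau_\text{target})}\;
  \min\!\left(1, e^{-\Delta E/k_BT}\right).$$

The per-type action rates $\alpha$ set the diffusive mobility of each voxel
species; the Metropolis-shaped acceptance factor was chosen because it makes
the chain Boltzmann-stationary when $\alpha$ is uniform and $\phi = 0$ — a
property the test suite verifies empirically on an exactly enumerable
three-voxel system. Time is advanced by tau-leaping: every boundary voxel,
visited in random order, draws one candidate label uniformly from the
distinct labels in its Moore neighbourhood and executes the copy with
probability $1 - e^{-\lambda\,\Delta t}$, with $\Delta t = 0.1$ min. Moves
that would fragment or empty an EPI/PrE cell are rejected outright (the
exact criterion — flood fill with early termination over the cell minus the
flipped voxel — not a local heuristic), while ECM and medium regions may
fragment and vanish freely.

## ECM secretion

When a voxel belonging to a cell has a *different* PrE cell in its
neighbourhood, the ECM label joins its candidate set: PrE cells deposit
matrix at their cell-cell contacts. The deposition bias enters through the
active exponents $\phi(\text{EPI},\text{ECM})$ and
$\phi(\text{PrE},\text{ECM})$; all other $\phi$ entries are zero. ECM
surface and kinetic parameters copy those of PrE
($J_{M:\mathrm{ECM}} = J_{M:\mathrm{PrE}}$,
$J_{\mathrm{EPI}:\mathrm{ECM}} = J_{\mathrm{EPI}:\mathrm{PrE}}$,
$J_{\mathrm{PrE}:\mathrm{ECM}} = J_{\mathrm{PrE}:\mathrm{PrE}}$,
$\alpha_\mathrm{ECM} = \alpha_\mathrm{PrE}$).

## Growth and division

Preferred volumes grow linearly, $\bar V_c(t) = \bar V_c(0) + g\,t$, until a
division target sampled from the empirical distribution of ten measured
mitotic volumes (2,406.63 ... 4,133.67 um^3) is reached. The cell is then cut
by the plane through its centroid perpendicular to the principal axis of its
gyration tensor; daughters inherit the type, take their actual post-split
volumes as new preferred volumes, and resample fresh targets. On an
isotropic gyration tensor the first eigenvector returned by the symmetric
eigensolver is used (deterministic tie-break, sign-normalized); voxels
exactly on the plane go to the parent's side. Rare fragments created by a
cut through a non-convex cell are reassigned to the sibling so both
daughters stay connected.

## Parameter choices

The study's parameter table is not printed in the source material, so the
shipped defaults are the package's own calibration, fixed once:

* **Contact energies.** Under the mapping $\gamma_{A:M} = J_{AM} - J_{AA}/2$,
  $\gamma_{A:B} = J_{AB} - (J_{AA}+J_{BB})/2$ and
  $\gamma_{A:A} = J_{AA}/2$, the defaults
  ($J_{M:\mathrm{PrE}} = 0.3$, $J_{\mathrm{PrE}:\mathrm{PrE}} = 0.4$,
  $J_{\mathrm{EPI}:\mathrm{EPI}} = 0.6$, $J_{\mathrm{EPI}:\mathrm{PrE}} = 0.9$,
  $J_{M:\mathrm{EPI}} = 0.9$) encode the experimentally measured tension
  ordering $\gamma_{\mathrm{PrE}:M} < \gamma_{\mathrm{PrE}:\mathrm{PrE}} <
  \gamma_{\mathrm{EPI}:\mathrm{EPI}} < \gamma_{\mathrm{PrE}:\mathrm{EPI}} <
  \gamma_{\mathrm{EPI}:M}$ (0.1 < 0.2 < 0.3 < 0.4 < 0.6 kT per voxel face)
  and satisfy the complete-wetting condition
  $\gamma_{\mathrm{EPI}:M} > \gamma_{\mathrm{PrE}:\mathrm{EPI}} +
  \gamma_{\mathrm{PrE}:M}$ required for PrE to envelop EPI. The magnitudes
  (tenths of kT per voxel-pair) keep interfaces thermally rough enough to
  rearrange within hours of simulated time.
* **Kinetic rates.** $\alpha_\mathrm{PrE} = 1$, $\alpha_\mathrm{EPI} = 0.5$
  events/min (PrE more motile than EPI, as observed), medium 1, ECM = PrE.
* **ECM energetics.** $\phi(\cdot,\mathrm{ECM}) = 3.5$ and
  $\varepsilon = 2\,k_BT$. These two numbers balance forced deposition at
  PrE contacts against degradation; a small sweep showed this balance
  maintains a sparse interfacial ECM pool (tens of voxels on a 30-cell ICM)
  whose mean radial position shifts outward by ~4-6 um as sorting proceeds —
  the predicted bulk-to-periphery redistribution. Much larger exponents make
  deposition certain at every eligible draw and flood the lattice with
  matrix; both parameters are plain configuration values
  (`simParams(phiPreEcm =, epsilon =)`).
* **Volume constraint and growth.** $\kappa = 0.05$ kT um^-6 (volume s.d.
  of a few voxels around $\bar V$) and $g = 2.5$ um^3/min, which takes a
  ~1,000 um^3 E3.5 cell to the smallest measured division volume in roughly
  one cell cycle.
* **Geometry.** 30-cell ICMs at a mean initial cell volume of 1,000 um^3,
  60% PrE, initialized by Voronoi tessellation of a sphere with spatially
  random fate assignment; a one-voxel frozen medium shell closes the box
  (isolated-ICM boundary condition).

Simulated study conditions in the acceptance suite: ten independent seeds,
8 simulated hours each (4,800 steps), ~1 min wall-clock per run, plus twelve
equal-tension control runs. These sizes were chosen to estimate the sorting
gain and the ECM shift with comfortable Monte-Carlo margins.

# Trajectory statistics

The tracking interface is a CSV of fate-labelled 3D positions (the output
format of the upstream nuclear-detection pipeline; 20-min frame interval by
default). From it the package derives per-frame centroids (mean of all cell
positions), radial distances, and normalized positions $d \in [0,1]$ with
the per-frame outermost cell as $d = 1$ — a parameter-free proxy for the
ICM surface. The **sorting score** is the mean over all (PrE, EPI) pairs of
$\mathrm{sign}(r_\mathrm{PrE} - r_\mathrm{EPI})$; the sign convention makes
the fully sorted state (all PrE outside all EPI) +1. **Displacement maps**
bin per-step radial displacements by starting position and time, flagging
empty bins as undefined rather than zero. **First-passage probabilities**
scan each distance-to-cavity series for the first exit of a +/-3-um corridor
around sampled starting positions X0 (samples at least 3 min apart to damp
autocorrelation); trajectories that never exit are censored — reported but
excluded from the conditional probability, which keeps the estimator
unbiased for the exit direction. **Fate-switch detection** uses a hysteresis
band: a crossing must start below the low threshold, exceed the high
threshold, and persist a minimum number of frames; by default the band is
the midpoint between the two reporter modes (2-class clustering) +/- 10% of
their separation, since no numeric rule is available.

# Image-derived quantification

All operators consume precomputed inputs (traced contours, sampled line
scans, aspiration tables) — the package does no segmentation.

* **Young-Laplace tension**: $\gamma = P_c / (2(1/R_p - 1/R_c))$, in pN/um
  with pressures in Pa and radii in um; $R_c \le R_p$ is rejected as an
  invalid steady-state reading.
* **Polarization index**: outer-quarter over inner-quarter mean intensity of
  a radially oriented profile normalized to [0, 1].
* **Membrane curvature**: for each contour point, the circle through the
  points `offset` = 10 positions away on either side; curvature is its
  inverse radius, exactly zero for collinear triples
  ($|\text{cross}| < 10^{-9}\times\text{scale}^2$). The sign convention
  (counter-clockwise traversal, convex-outward positive) is retained for
  testability even though only magnitudes are interpreted.
* **Boundary-orientation binning**: six equal-arc-length bins anchored with
  bin 1 centred on the cavity-facing pole (the contour point of maximal
  projection on the cavity axis); the anchoring is a documented choice, as
  the source describes only "six equal length intervals oriented along the
  cavity-TE axis". Argmax ties take the lowest bin and are flagged.
* **Fate classification**: per-channel log intensities are detrended by a
  linear fit against imaging depth z, then 2-class k-means (fixed seed, 10
  restarts) on the corrected (GATA6, NANOG) pairs assigns PrE to the
  higher-GATA6 cluster. Detrending by OLS residuals makes the corrected
  slope against z exactly zero.
* **Shape and protrusions**: aspect ratio from the second-area-moment
  ellipse of the traced polygon, circularity $4\pi A/P^2$ with polygonal
  perimeter, protrusion length and cavity angle from centre-tip and
  centre-cavity segments.
* **Colocalization**: Pearson over the union of above-threshold voxels and
  both Manders coefficients; constant channels are flagged rather than
  returning a spurious correlation.

# The spherical-cap scaling model

The ICM cross-section is modelled as two spherical caps on a common base
circle of radius R: the trophectoderm-facing cap of height H and the
cavity-facing cap of height h. Cap formulas
($V = \tfrac{1}{6}\pi h(3r^2+h^2)$, $A = \pi(r^2+h^2)$) give the ICM volume
(cap difference) and the cavity interface area. With a fixed PrE fraction
$f$ and the 10th/90th percentiles of PrE apical area
($q_{10} = 157$, $q_{90} = 376$ um^2), the total PrE area available to tile
the interface lies in $(f n q_{10},\, f n q_{90})$ for an ICM of $n$ cells:
interfaces above the band predict a gap, below it a multilayer, inside it a
monolayer. Boundary ties are classified monolayer — the source states strict
inequalities only for gap and multilayer, so the monolayer interval is
closed. Convex (human-type) interfaces use the same formulas with h measured
toward the cavity. The hemisphere reference curve
$A = 3^{2/3}(\pi/2)^{1/3}(cN)^{2/3}$ treats the ICM as a sphere of volume
$cN$ whose interface is half its surface; with the default
$c = 1907$ um^3/cell it crosses the PrE band on a contiguous window of cell
numbers — the geometric statement that a fixed fate fraction supports a
monolayer only within certain size limits. Scaling fits
($V = cN$, $n_\mathrm{pre} = f\,n_\mathrm{total}$) are through-origin
least squares, as literally specified, not affine fits. Outcome
probabilities are relative frequencies per size class with binomial
standard errors; species presets carry the scenario fractions (mouse 0.6,
monkey 0.7, human 0.55), while fitted slopes always come from user data.

# Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its seed and mirrors one input class:

* `genTracks()` — PrE cells as radially biased random walks (+0.5 um/frame)
  with absorbing retention at the surface radius; EPI unbiased; isotropic
  Gaussian jitter (1 um/frame).
* `genEmbryoPopulation()` — cell counts linear in size ratio with Poisson
  noise around 40 cells at normal size, binomial PrE counts, and cavity-cap
  geometries drawn so a designed fraction p* of embryos (default 0.8) falls
  inside the monolayer band, with Gaussian variability on the cap shape
  h/R; the designed outcome is recorded per embryo, so every downstream
  probability has exact ground truth.
* `genContour()` — circles with Gaussian radial bumps and co-located (or
  offset) intensity hotspots; the analytic curvature of the generating
  polar curve ships with the contour.
* `genIntensityFates()` — two log-normal modes per channel, anti-correlated
  across GATA6/NANOG, attenuated by $e^{-z/\text{decay}}$; the default mode
  separation of 3 log-s.d. emulates the strongly bimodal
  immunostaining contrast of these markers (per-channel Bayes error < 2%,
  so >= 95% recovery is attainable; at 2 s.d. the two-channel Bayes error
  is already 7.9%, which no classifier could beat).
* `genAspiration()` — Young-Laplace pressures with multiplicative 5%
  Gaussian noise.

These generators reproduce the statistical structure each estimator
assumes — not real microscopy. Passing tests demonstrate correctness of the
estimators and the internal consistency of the model chain; they do not
validate the biological parameter values against images, which are not
publicly deposited.

# Numerical choices and degenerate inputs

* Incremental energies are exact: 10^-9 relative agreement with full
  Hamiltonian recomputation is enforced over a thousand random flips.
* The fragmentation guard uses an exact connectivity criterion (all
  same-label neighbours of the removed voxel must be mutually reachable in
  the cell minus that voxel), with early-terminating flood fill so the
  check stays local in practice.
* Rate exponents are capped at e^50 before exponentiation; beyond that the
  execution probability is 1 at any dt.
* Rolling averages use centred windows truncated at the series ends.
* Empty profile bins are NA-flagged and only interpolated on request; empty
  displacement bins report count 0 with undefined mean.
* Collinear curvature triples return exactly 0; open contours skip their
  end points instead of wrapping.
* Division of a single-voxel cell degenerates to a target resample; ties on
  the division plane go to the parent.
* CSV round-trips format doubles as %.17g and parse with base R's exact
  strtod, so written tables read back value-identically.

# Known limitations

* The exact Poisson-rate functional of the companion lattice-kinetics
  method is not public; the Metropolis-shaped form used here is fixed by
  its Boltzmann limit, but other forms with the same limit exist.
* Numeric simulation parameters are calibrated to the printed tension
  ordering and sorting timescale, not to the unpublished parameter table;
  quantitative ECM abundances are therefore indicative only.
* No trophectoderm, cavity pressure, or FGF/GATA6/NANOG gene-network
  dynamics: fates are fixed labels in the simulator.
* Whole-blastocyst distance-to-lumen definitions, polar-plot bin edges and
  profile bin counts are exposed as arguments; defaults are documented
  choices where the source is silent.
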