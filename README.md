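# icmDynamics

Cell sorting, matrix dynamics and geometric scaling in the blastocyst
inner cell mass.

Between E3.5 and E4.5 the mouse blastocyst's inner cell mass (ICM) turns a
salt-and-pepper mixture of epiblast (EPI) and primitive endoderm (PrE)
precursors into a PrE monolayer facing the fluid cavity. `icmDynamics` is
an R toolkit for the quantitative side of that process, aimed at
developmental biologists and tissue biophysicists who want to simulate the
sorting process, analyse cell-tracking data, quantify images of polarized
cells, or ask whether a given embryo geometry can support a PrE monolayer
at all.

## What is inside

**A 3D Poissonian cellular Potts simulator** (`simParams()`, `initICM()`,
`runSimulation()`). Cells are voxel domains on a 1-um lattice evolving by
label-copy moves with explicit Poisson rates,

    lambda = alpha(target) * exp(phi(source, target)) * min(1, exp(-dE/kT)),

under the Hamiltonian

    E = sum_<ij> J[tau_i, tau_j] + (kappa/2) sum_c (V_c - Vbar_c)^2
        + epsilon * N_ECM.

Differential contact energies encode the measured tension ordering
gamma(PrE:medium) < gamma(PrE:PrE) < gamma(EPI:EPI) < gamma(PrE:EPI) <
gamma(EPI:medium); cells grow linearly and divide across their gyration
axis at empirically measured mitotic volumes; PrE cells deposit ECM at
their cell-cell contacts, and the secreted matrix redistributes towards
the ICM periphery as sorting proceeds.

**Trajectory statistics** (`radialSeries()`, `sortingScore()`,
`binnedDisplacements()`, `firstPassageProbabilities()`,
`fateSwitchEvents()`). The sorting score is the mean sign of pairwise
PrE-EPI radial differences (+1 = fully sorted); first-passage analysis
reports the fraction of +/-3-um corridor exits directed toward the cavity.

**Image-derived quantification** (`laplaceTension()`,
`polarizationIndex()`, `intensityProfile()`, `curvatureProfile()`,
`boundaryBinOrientation()`, `classifyFatesKmeans()`, `shapeMetrics()`,
`colocalization()`). Micropipette tensions via Young-Laplace, apical
polarity indices, three-point circumcircle membrane curvature,
depth-corrected k-means fate calls, and more. All operators consume
precomputed CSV inputs; there is no image segmentation here.

**The spherical-cap scaling model** (`capGeometry()`, `icmAreas()`,
`hemisphereAreaFromCount()`, `fitScaling()`, `outcomeProbabilities()`).
The ICM is two spherical caps on a common base; comparing the cavity
interface area with the band (f n q10, f n q90) of feasible total PrE
apical areas classifies each embryo as GAP, MONOLAYER or MULTILAYER and
yields per-size-class probabilities.

**Seeded synthetic-data generators** (`genTracks()`,
`genEmbryoPopulation()`, `genContour()`, `genIntensityFates()`,
`genAspiration()`) that reproduce the statistical structure each estimator
assumes, with ground truth attached — the whole pipeline is testable
without any image download.

## A worked example

Simulate an isolated 30-cell ICM for two hours and watch sorting emerge:

```r
library(icmDynamics)
p   <- simParams(seed = 1)
icm <- initICM(nCells = 30, preFraction = 0.6, seed = 1)
tr  <- runSimulation(p, icm, duration = 120, recordEvery = 60)
traceTable(tr)
#>   time_min sorting_score ecm_mean_radius_um n_ecm_voxels
#> 1        0    -0.2870370                 NA            0
#> 2       60     0.2314815           14.73510           65
#> 3      120     0.4166667           16.17007           49
```

The score starts near zero (salt-and-pepper; here slightly negative by
chance) and rises as the low-tension PrE cells reach the surface — by
eight simulated hours this seed reaches 0.78, and the ten-seed campaign
run by the acceptance script averages 0.91. The ECM column tracks the
mean radial position of secreted matrix: it appears in the ICM bulk
(~15 um from the centroid here) and drifts outward with sorting.

Classify an embryo's geometry:

```r
icmAreas(data.frame(R_um = 30, H_um = 40, h_um = 10, n_total = 100),
         scalingConstants())
#>   R_um H_um h_um n_total V_icm_um3 A_interface_um2 A_pre_min_um2 A_pre_max_um2
#> 1   30   40   10     100  75398.22        3141.593          9420         22560
#>      outcome
#> 1 MULTILAYER
```

A 100-cell ICM with a cavity interface of only ~3,142 um^2 cannot
accommodate 60 PrE cells at 157-376 um^2 apiece in one layer: the model
predicts a multilayer.

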