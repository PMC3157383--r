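# helixmetrics

Geometric analysis of molecular-dynamics trajectories of single-pass
membrane proteins, built around the observables that characterise how a
transmembrane (TM) helix sits in a lipid bilayer. The motivating system
is the thrombopoietin receptor MPL, whose TM-domain mutations
(S505N/A, W515L/K) are implicated in myeloproliferative neoplasms: the
working hypothesis is that these mutations act by changing the helix's
**tilt** and **azimuthal rotation** in the membrane, thereby
repositioning the intracellular Box1 motif that binds JAK2. The package
is for structural bioinformaticians and simulators who need these
measurements as tested, reusable code rather than one-off scripts.

## What it computes

For each frame of a topology (PDB) + trajectory (CHARMM/NAMD DCD, or
multi-model PDB) pair:

* **Membrane frame** — midplane, unit normal n, and the two leaflet
  phosphate-plane offsets, estimated from lipid phosphorus atoms
  (fixed-z or iteratively fitted mode).
* **Tilt angle** — θ = arccos |a · n| ∈ [0°, 90°], where the helix
  axis **a** is fitted to the TM Cα atoms (curvature-based estimator,
  exact on ideal helices; position-SVD available).
* **Azimuthal angle** — the IUPAC torsion χ over four chosen
  intracellular Cα atoms, in (−180°, 180°], with linear *and* circular
  summaries: circular mean, mean resultant length R̄ and circular SD
  √(−2 ln R̄); R̄ < 0.2 flags free rotation.
* **Hydration** — water–Cβ radial distribution functions
  g(r) = ⟨n(r)⟩ / (ρ V_shell), minimum-image periodic distances, and
  hydration-shell coordination numbers.
* **IC-region metrics** — minimum distance of labelled regions (e.g.
  the Box1 loop) to the nearer phosphate plane, and water-contact
  counts as an openness measure.

A fully parameterised synthetic helix-in-bilayer generator
(`syntheticSpec()` / `generateTrajectory()` / `makeVariantPanel()`)
produces systems with known ground truth — von Mises tilt/azimuth
distributions, water layout, rare water-penetration events, open vs
packed Box1 placements — so the whole pipeline is validated by
parameter recovery at desk scale. See the vignette in `vignettes/` for
the methods in detail.

## Worked example

```r
library(helixmetrics)

panelDir <- tempfile("panel")
specs <- list(
  WT    = syntheticSpec(nFrames = 2000, helixResidues = 26,
                        tiltMean = 27.6, tiltSD = 7.0, seed = 1),
  S505N = syntheticSpec(nFrames = 2000, helixResidues = 26,
                        tiltMean = 33.5, tiltSD = 5.8,
                        penetrationResidue = 505,
                        penetrationProb = 0.3, seed = 2),
  W515K = syntheticSpec(nFrames = 2000, helixResidues = 26,
                        tiltMean = 25.1, tiltSD = 7.5,
                        azimuthUniform = TRUE, seed = 3))
makeVariantPanel(specs, panelDir)

cfg <- runConfig(
  variants = lapply(names(specs), function(l)
    list(label = l,
         topology = file.path(panelDir, paste0(l, ".pdb")),
         trajectory = file.path(panelDir, paste0(l, ".dcd")))),
  window = "last 10 ns")
report <- runAnalysis(cfg)
report$tiltTable
```

```
  variant  mean    sd    n
1      WT 27.56 6.580 1000
2   S505N 33.37 5.847 1000
3   W515K 24.64 7.294 1000
```

Each recovered tilt mean/SD sits within sampling error of its generator
set-point (27.6 ± 7.0, 33.5 ± 5.8, 25.1 ± 7.5). The azimuth table shows
what the circular statistics are for:

```
  variant circularMean resultantLength weaklyConcentrated   n
1      WT        1.316          0.9410              FALSE 100
2   S505N        0.474          0.9443              FALSE 100
3   W515K     -106.444          0.0657               TRUE 100
```

The W515K-like variant rotates freely: its azimuth covers the full
circle, the resultant length collapses toward 0 and the summary flags
its circular mean as unreliable. And in the RDF curves, only the
penetration-enabled S505N-like variant has any first-shell
(r < 4 Å) water density at residue 505 — the g(r) sum below 4 Å is 232
for S505N and exactly 0 for WT and W515K, the hydration signature of
waters transiently entering the membrane at a polar residue.

`writeReport(report, dir)` writes the tables as TSV (angles at 1
decimal, g(r) at 4), a full-precision JSON mirror, and a checksummed
file manifest. A thin command-line wrapper is installed at
`inst/scripts/helixmetrics.R` (`run` and `generate-panel` subcommands,
YAML configs).

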