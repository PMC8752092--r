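# glyrPALM

Quantitative single-molecule counting of synaptic receptors from PALM
localization data, with correlative serial-section EM morphometry.

Photoactivated localization microscopy (PALM) of a photoconvertible
fusion protein (e.g. mEos4b fused to the glycine receptor β subunit)
yields a table of single-molecule detections, not a molecule count:
every fluorophore blinks several times before bleaching, a fraction
never becomes fluorescent, and only the two β subunits of the pentameric
GlyR (α₃β₂ stoichiometry) carry a tag. This package implements, for
microscopists and quantitative neurobiologists, the full analysis chain
that converts localization tables into **receptor copy numbers and
packing densities at synapses**, plus the surrounding diagnostics:

- lateral **drift estimation/correction** from five dense anchor
  clusters tracked over sliding 2000-frame windows;
- pointillist **rendering** (10 nm pixels) and density-threshold
  **segmentation** of synaptic clusters (≥ 250 detections, 200–3000 nm)
  and extrasynaptic calibration complexes (≥ 5 detections, 10–120 nm);
- **photophysics calibration** on extrasynaptic two-fluorophore
  complexes: bursts are runs of ≥ 2 detections split at > 1000-frame
  gaps, and the detection probability follows from the one- vs
  two-burst complex tally, *P*<sub>det</sub> = 2N₂/(N₁ + 2N₂),
  embedded in a geometric blink model that corrects singleton
  censoring, burst collisions and the minimum-detection filter;
- **molecular conversion** R = D / (d̄ · *P*<sub>det</sub> · n<sub>β</sub>)
  and density ρ = R / A per cluster;
- **co-localization** (intensity correlation quotient, ±0.5 bounds),
  receptor–scaffold **occupancy**, and **Fourier ring correlation**
  resolution (odd/even frame split, 1/7 threshold);
- **serial-section EM morphometry**: postsynaptic area as cumulative
  profile length × 70 nm section thickness, a segmentation index
  counting in-plane and z-axis interruptions, and PALM-vs-EM area
  comparison under tilt;
- a fully parameterized **synthetic-data generator** (log-normal copy
  numbers, constant ~2000 µm⁻² packing density, blinking bursts over
  25,000 frames, localization noise, drift, perforated shapes, serial
  sections) with complete ground truth, so every stage is verified by
  parameter recovery.

## Worked example

Simulate a dorsal-horn-like population and run the complete pipeline
(drift correction → segmentation → calibration → counting):

```r
library(glyrPALM)
cfg <- simulationConfig("dorsal-2mo", nSynapses = 400, seed = 11,
                        driftPath = linearDriftPath(80, 60, 25000))
res <- runPipeline(cfg)
res$calibration
#> PhotophysicsCalibration (geometric model): N1 = 981, N2 = 667, excluded = 10
#>   raw: P_det = 0.576, detections/burst = 8.45
#>   corrected: P_det = 0.59, detections/fluorophore = 5.94
res$clusters
#> SynapticClusterSet: 383 clusters, median area 0.0573 um^2, median receptors 116.4
```

The calibration line says that of the usable extrasynaptic complexes,
981 showed one burst and 667 showed two; the blink-model corrected
functional-fluorophore fraction is 0.59 and each fluorophore yields on
average 5.94 detections (the raw per-burst mean, 8.45, is inflated by
singleton censoring and must not be used directly — see the vignette).
The recovered population statistics:

```r
s <- res$summary
cat(sprintf("median %.1f [IQR %.1f-%.1f] receptors/synapse, CV %.2f\n",
            s$median, s$q1, s$q3, s$cv))
#> median 116.4 [IQR 83.4-169.9] receptors/synapse, CV 0.56
cat(sprintf("mean density %.0f per um^2; Spearman rho(density, area) = %.3f\n",
            mean(clusterTable(res$clusters)$density),
            res$densityReport$spearman))
#> mean density 2086 per um^2; Spearman rho(density, area) = 0.055
bindingSiteOccupancy(mean(clusterTable(res$clusters)$density), 9000, 2)
#> [1] 0.46
```

The ground truth behind this run had a median of 114 receptors per
synapse at 2000 µm⁻² packing density: the pipeline recovers the median
within a few percent, finds the density unbiased and uncorrelated with
synapse area (constant packing), and — against a scaffold lattice of
9000 binding sites µm⁻² — estimates that close to half the receptor
binding sites are occupied.

EM morphometry works on serial-section stacks, real or synthetic:

```r
stk <- serialSectionStack(list(400, 500, 600), thickness = 70)
emArea(stk)                # 0.105 um^2
segmentationIndex(serialSectionStack(list(500, c(200, 250), 500)))  # 1
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/glyrpalm.R` (subcommands `simulate`, `count`, `report`).

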