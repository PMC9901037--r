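# GrooveFlex

Geometric and statistical analysis of conformational flexibility at the
N-terminus of the MHC class I peptide-binding groove.

## The problem

MHC class I molecules present short peptides to CD8+ T cells in a groove
whose A pocket normally closes around the peptide's N-terminal amino group.
Long N-terminally extended peptides can bind with the extension protruding
out of the groove, forcing the conserved N-terminal elements — Tyr59, the
3<sub>10</sub>-helix (residues 50–55, including Ile52) and the
Gln54–Tyr59 stretch — into unusual, partially disordered conformations.
Characterizing that plasticity takes three kinds of measurement, all
implemented here for crystallographers and MD practitioners working on
peptide–MHC systems:

1. **Crystal-structure comparison** — detection of unmodeled
   (missing-density) residue ranges; rigid-body (Kabsch) superposition on
   the α1α2 domain Cα frame and per-P-position peptide Cα displacements;
   hydrogen-bond and hydrophobic contact networks in the A/B pockets.
2. **Equilibrium-ensemble geometry** — per-residue RMSF,
   `RMSF_i = sqrt(⟨|x_i − ⟨x_i⟩|²⟩)` after removal of global motion; the
   interaction geometry between peptide P1 and Tyr59/Ile52:
   ring-center distances, ring normal–normal angles for π-π stacking
   (T-shaped near 90°, parallel-like near 0°/180°), and the CH-π
   criterion (ring-center–Cδ distance ≤ 6 Å and C–H–X angle ≥ 120°, X the
   ring center).
3. **State tracking and stability** — the terminal-amino-group dihedral
   ω = Cys76:CA–P7:CA–P1:CA–P1:N (≈ −100°: amino group points up out of
   the A pocket; ≈ +100°: canonical pointing-down), with |Δω| < 180°
   unwrapping, 10-ns sliding-window smoothing and rotation-event
   detection; and melting temperatures from thermal-denaturation curves
   (minimum of dF/dT, half-depth centroid refinement).

Peptide positions are labeled P1…P8 from the core N-terminus (extensions
P-1, P-2, …), anchored by the P7 cysteine disulfide-bonded to heavy-chain
Cys76, which the package locates automatically.

A synthetic-data module generates every input kind — harmonic
trajectories with prescribed per-residue amplitudes, ring pairs at
prescribed distance/angle, wrapped dihedral traces with programmed
rotation events, gapped structures, sigmoidal melt curves — with known
ground truth, so the full pipeline is testable without external data.

## Worked example

```r
library(GrooveFlex)

## P1 Phe / Tyr59 stacking on a synthetic equilibrium ensemble
## programmed at 6 A center distance, 150 deg normal-normal angle
rp  <- makeRingPair(6, 150, jitter = 0.15, nFrames = 2000, seed = 42)
ser <- ringRingSeries(rp$trajectory, "P", 1, "H", 59)
estimateDistribution(ser@distance, 0.25)
#> BinnedDistribution: 4 bins, peak at 6.125 , FWHM 0.5
cls <- classifyPiPi(ser@angle)
#> stacking class: parallel-like  (s peak = 31.1 deg)

## terminal amino-group rotation over three replicates
reps <- list(
  makeRotationTrace(data.frame(timeNs = c(0, 120), valueDeg = c(-100, 100)),
                    noiseSd = 15, totalNs = 300, seed = 1)$series,
  makeRotationTrace(data.frame(timeNs = c(0, 200), valueDeg = c(-70, -260)),
                    noiseSd = 15, totalNs = 300, seed = 2)$series,
  makeRotationTrace(data.frame(timeNs = 0, valueDeg = -100),
                    noiseSd = 15, totalNs = 300, seed = 3)$series)
rot <- runRotationReport(reps, tempdir())
rot$summary
#> "2 of 3 replicates rotated"   (events at 123.0 and 202.9 ns)

## melting temperature from a noisy quadruplicate melt curve
mc <- makeMeltCurve(65.8, width = 3, noiseFrac = 0.01, seed = 4,
                    replicates = 4)
meltingTemperature(mc$curve)
#> MeltResult: Tm = 65.76 C ( minimum of dF/dT )
```

The distance peak sits one half-bin above the programmed 6 Å (bin-center
convention); the 150° stacking angle folds to a deviation s ≈ 30°, the
parallel-like/intermediate boundary; the second rotation replicate ends
at −260°, which the detector recognizes as the +100° state via 360°
periodicity; and the Tm of the noisy curve is recovered within 0.05 °C.

A command-line wrapper over the same functions is installed at
`inst/scripts/groove.R` (`structure`, `compare`, `rmsf`, `rotation`,
`tm`, `run --config cfg.yaml`).

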