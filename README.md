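# habind

Analysis toolkit for molecular-dynamics studies of hyaluronan binding to
the CD44 hyaluronan-binding domain (HABD), built around one central idea:
HA does not occupy a single site on the receptor but attaches in **three
mutually exclusive binding modes** — *crystallographic*, *parallel* and
*upright* — each with a characteristic residue-contact fingerprint, ordered
in strength (crystallographic strongest, parallel weakest), with the key
arginine R41 engaged in all three. The package is for computational
structural biologists who have (or simulate) receptor–glycosaminoglycan
trajectories and want the full downstream analysis as tested, reusable
code.

What it computes:

* **Contact fingerprints** — per-residue binding percentages
  `100 · n_frames(min dist ≤ 0.6 nm) / n_frames` with standard errors over
  replicas, per-arginine atom-pair contact profiles, and polymer-residue ×
  time contact contours.
* **Mode classification** — cosine similarity of a window's fingerprint
  against packaged reference fingerprints for the three modes
  (label = argmax mode if best similarity ≥ 0.80, `unbound` for all-zero,
  `ambiguous` otherwise), plus run-length transition detection.
* **A/B-form assignment** — the backbone φ dihedral of the residue after
  the key arginine acts as a bistable switch; a frame is B-form only if φ
  sits in the B basin *and* the arginine side chain hydrogen-bonds the
  ligand.
* **Umbrella energetics** — self-consistent WHAM with analytic
  bin-averaged bias factors and block-bootstrap uncertainties;
  minimum-to-bulk depth ΔG_min, population-integrated ΔG
  (−k_BT ln ∫_bound e^(−G/k_BT) dξ / ∫_unbound e^(−G/k_BT) dξ), thermal-unit
  conversion and Boltzmann preference factors exp(ΔΔG/k_BT).
* **Detachment assays** — in-silico electrophoresis: first frame with zero
  receptor–ligand contacts = detached; fractions and detachment times
  (± SE over detached replicas only) per mode and field.
* **Sliding** — contact-centroid tracks along the polymer with
  gap-tolerant interpolation, net displacement, partial-detachment events
  and 1D mean squared displacement.
* **A coarse-grained Brownian-dynamics generator** that plants known
  binding modes on a GlcUA/GlcNAc bead polymer, so every analysis runs end
  to end with ground truth and no external data.

## Worked example

Classify three synthetic replicas per planted mode and convert the two
characterised binding free energies:

```r
library(habind)

res <- run_fingerprint(n_replicas = 3, n_steps = 50000, seed = 20260927)
table(res$assignments$mode, res$assignments$label)
#>                    crystallographic parallel upright
#>   crystallographic                3        0       0
#>   parallel                        0        3       0
#>   upright                         0        0       3

conv <- run_energetics(dg_inputs = c(crystallographic = -33, parallel = -22))
conv$dg_kbt
#> crystallographic         parallel
#>            -13.2             -8.8
conv$preference
#> [1] 81.45087
```

All nine replicas recover their planted label; the −33 and −22 kJ/mol free
energies convert to −13.2 and −8.8 thermal units (k_BT = 2.5 kJ/mol), a
4.4 k_BT gap, i.e. the crystallographic mode is ~80× more favourable by
Boltzmann weight. The in-silico electrophoresis assay over 20 replicas per
mode under a strong field (analysis/03) prints the detachment table

```
  crystallographic    20%   0.233 +- 0.041 ns
  parallel           100%   0.028 +- 0.007 ns
  upright             90%   0.122 +- 0.019 ns
```

reproducing the qualitative ranking: the parallel mode is the weakest, the
crystallographic the strongest, upright intermediate.

## Analysis workflow

The numbered drivers under `analysis/` run the four standard analyses over
the bundled generator and write tables under `results/`:

| script | analysis | outputs |
|---|---|---|
| `01_fingerprint_and_modes.R` | replica fingerprint table + classification | `results/fingerprint/` |
| `02_energetics.R` | unit conversions, umbrella scans, WHAM, preferences | `results/energetics/` |
| `03_efield_assay.R` | detachment table under strong/weak fields | `results/efield/` |
| `04_sliding.R` | sliding tracks, MSD, weak-vs-deep mobility contrast | `results/sliding/` |

Each writes its resolved settings and a run log next to its outputs;
reruns with the same seed are reproducible.

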