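---
title: "Binding-mode fingerprints and energetics of hyaluronan-receptor complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode fingerprints and energetics of hyaluronan-receptor complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habind)
```

## The problem

Hyaluronan (HA) is a linear polyanionic polysaccharide of alternating
glucuronic acid (GlcUA) and N-acetylglucosamine (GlcNAc) units. Its main
receptor, CD44, binds HA through a globular hyaluronan-binding domain
(HABD, canonical residues 20-169). Molecular-dynamics work on this system
shows that HA does not occupy a single site: it attaches in three
topographically distinct, mutually exclusive binding modes --
*crystallographic* (the groove seen by X-ray), *parallel* and *upright* --
each leaving a characteristic residue-contact signature, with the key
arginine (R41) engaged in all three. The modes differ in strength
(crystallographic strongest, parallel weakest), and the weak modes let the
receptor slide along the polymer, which matters for receptor clustering.

`habind` turns that analysis into a reusable pipeline: contact
fingerprinting with replica errors, mode classification, detection of the
A/B conformational switch, umbrella-sampling energetics through WHAM,
electric-field detachment assays, and sliding tracks. Because no public
trajectories accompany the original study, the package ships a
coarse-grained Brownian-dynamics generator that plants known binding modes,
so every analysis is exercised end to end against ground truth.

## Contact statistics

A residue is *in contact* when any of its atoms (heavy atoms by default --
hydrogen placement is force-field dependent) lies within **0.6 nm** of any
ligand atom. The boundary is inclusive: exactly 0.6 nm counts. Two
estimators are deliberately kept apart, because "number of contacts" is
used for both in the field:

* `residue_contact_series()` / `residue_binding_percent()`: a per-frame
  boolean per residue; the binding percentage is
  100 x (frames in contact)/(frames). This is the fingerprint-table
  estimator. Replica aggregation (`replica_binding_table()`) reports the
  mean over replicas with the standard error sd/sqrt(n); with one replica
  the SE is `NA`, never zero.
* `contact_count_series()` / `contact_count_profile()`: atom-pair counts
  within the cutoff, used for per-arginine profiles, contact contours and
  the detachment criterion.

Under periodic boundaries all distances use the orthorhombic minimum-image
convention; the kernels are tested against a 27-image brute-force
enumeration.

Hydrogen bonds are geometric: donor-acceptor distance <= 0.35 nm and,
when an explicit hydrogen is present, donor-H-acceptor angle >= 150
degrees. Both values are configurable; they are conventional choices, not
derived quantities.

## Fingerprints and mode classification

The packaged reference fingerprints (`reference_fingerprints()`) give the
binding percentage of 39 literature-curated residues in each of the three
modes, with replica standard errors. A trajectory window's fingerprint is
compared against each reference column by **cosine similarity**: run-to-run
contact magnitudes vary with occupancy and window length, but the pattern
across residues is the signature, and cosine is scale-invariant. The label
is the best-scoring mode if its similarity reaches 0.80; an all-zero
fingerprint is `unbound`; anything else is `ambiguous`. The 0.80 default
separates the three reference columns comfortably (their mutual cosines
are 0.57-0.75, self-similarity is 1) while rejecting windows dominated by
nonspecific contacts; it is a package choice -- the original assignment was
done by inspection -- and is configurable. `detect_transitions()`
run-length-encodes window labels with a minimum segment length (default 5
windows) so single-window flicker is not reported as a mode transition.

## The A/B switch

The crystallographic complex occurs in two conformations: in the A form
the key arginine's side chain points away from the ligand, in the B form
it folds over the ligand and hydrogen-bonds it directly. The switch is
carried by the backbone phi dihedral of the following tyrosine (Y42-like),
computed from C(i-1), N(i), CA(i), C(i) with the IUPAC sign convention
(checked against an independent implementation and `bio3d::torsion.xyz`).
`ab_form()` labels a frame **B only when both** conditions hold: phi in
the B basin *and* at least one key-arginine side-chain hydrogen bond to
the ligand. The default basins split at zero (B: [-180, 0); A: [0, 180))
because the literature states bistability without numeric boundaries; the
basins are configurable. The conjunction means a ligand-free frame can
never be B, encoding that the B form is stabilised by the bound ligand.

## Umbrella energetics

`wham()` implements the standard binned self-consistent WHAM iteration
over umbrella windows (reaction coordinate: distance between the receptor
core and the binding-site anchor). Numerical choices that matter:

* **Bias factors are bin-averaged analytically** (Gaussian integrals over
  each bin) rather than evaluated at bin centres. With stiff springs the
  bias varies by more than k_BT across a bin at the window tails, and the
  centre-point approximation visibly tilts the recovered profile.
* The profile is anchored so the **bulk region** (by default the last 20%
  of the grid) averages zero; "bulk" is not defined in the source
  analysis, so it is an explicit, configurable choice.
* **Uncertainties are a Bayesian block bootstrap**: one Dirichlet weight
  per contiguous block of 20 samples. Umbrella time series are
  autocorrelated; an iid bootstrap demonstrably under-covers. For derived
  quantities -- above all the profile minimum, whose pointwise-min
  estimator carries both window-stitching noise and selection bias -- use
  `pmf_boot_ci()`, which propagates the full bootstrap ensemble through
  the estimator instead of quoting a single-bin standard error.
* `delta_g_min()` is min-over-grid minus the bulk mean.
  `delta_g_population()` integrates Boltzmann populations on either side
  of a partition point (trapezoidal quadrature); the default partition is
  the first grid point past the minimum where the profile rises to within
  1 k_BT of bulk. The population route folds basin widths into the
  preference, so a broad shallow well closes the gap on a deep narrow one
  -- the entropic compression seen when comparing point-minimum and
  population preferences.

Two thermal constants are offered (`thermo_params()`). The default
`"arithmetic"` constant is k_BT = 2.5 kJ/mol because the printed
conversions of the source analysis are exactly -22/2.5 = -8.8 and
-33/2.5 = -13.2 thermal units, and the 80-fold preference is
exp(11/2.5) = 81.45; the physical constant at 310 K (about 2.577 kJ/mol)
does not reproduce those printed numbers. Every converted value records
the constant used.

## Detachment assay

In the in-silico electrophoresis assay the receptor is immobilised and a
uniform field pulls the negatively charged polymer away. A replica is
*detached* at the first frame where the receptor-ligand atom-pair contact
count reaches zero; later re-binding is ignored, and there is no
persistence requirement by default (a `persistence` option exists but is
off). The censoring time is a required input, never a default: the
observation window is part of the experiment's definition. Summaries
report the detachment fraction over all replicas and the mean +- SE of the
detachment time over the detached replicas only; with one or zero
detachments the SE (and with zero, the mean) is the `NA` sentinel.

## Sliding along the polymer

`contact_contour()` resolves contacts per polymer monosaccharide per
frame; `contact_centroid()` is the count-weighted mean position
(fractional monosaccharide units), undefined -- not an error -- at
zero-contact frames. `sliding_track()` interpolates across zero-contact
gaps up to 20 frames, reflecting the transient partial detachments that
make sliding possible, and reports net displacement and maximum excursion.
`detect_partial_detachment()` finds stretches where the total contact
count falls below a quarter of the track median while at least one residue
of the retained band (default 108-114, the hydrogen-bond band toward the
reducing end) stays bound throughout; a full detachment is by definition
not a partial one. `msd_1d()` gives the one-dimensional mean squared
displacement over time origins with defined centroids.

## The synthetic generator

`toy_config()` / `simulate_toy()` implement an overdamped Langevin
("Brownian dynamics") model: a rigid cluster of labelled pseudo-residues
(the receptor) and a linear alternating GlcUA/GlcNAc bead polymer with
unit negative charges on the GlcUA beads. Gaussian attraction wells
connect the beads of one planted surface patch (plus a shared key-site
cluster around the R41-like bead) to the polymer beads; a shorter-range
Gaussian repulsion keeps the bound pose at about 0.35 nm, safely inside
the 0.6 nm contact cutoff. The patch-to-residue dictionary is derived from
the packaged reference fingerprints (shared cluster: residues above 60% in
every mode; per-mode patches: residues at or above 50% in that mode), so
the same classifier runs on toy and real data.

Key parameter choices, made once as the package's study conditions:

* **Well depths 28 / 21 / 14 kJ/mol** (crystallographic / upright /
  parallel). The ordering and the gap structure follow the reference
  ranking; the absolute scale is set so that at 310 K (k_BT ~ 2.58
  kJ/mol) bound states persist over analysis windows in the overdamped
  toy -- with shallower wells the weak modes unbind within tens of
  picoseconds and no planted signal survives.
* **Per-mode well widths 0.18 / 0.22 / 0.28 nm**, narrowing with binding
  strength: the crystallographic groove is the most shape-complementary,
  the parallel mode the loosest. Because the sticky beads sit on the 0.5
  nm polymer lattice, the registry corrugation -- the barrier to sliding
  by one monosaccharide -- scales with depth and narrowness (adiabatic
  barriers about 13 / 8 / 4 kJ/mol), which is what makes the
  crystallographic receptor stationary and the parallel receptor mobile.
* **Depth calibration.** The attraction prefactor is root-solved at
  construction so that the *free-energy* depth along the approach
  coordinate -- with the transverse (x, y) motion of the restrained
  receptor integrated out -- equals the nominal depth. A plain
  potential-energy calibration overstates the depth by the transverse
  entropy lost in the bound well (about 1 kJ/mol here), which would make
  the nominal depth unrecoverable by umbrella sampling. A brute-force 2D
  quadrature reproduces the calibrated depth to 0.02 kJ/mol.
* **Timestep and diffusion** (dt = 2 fs equivalents: 0.002 ps, D = 0.015
  nm^2/ps). Construction validates the spec's stability rule (per-step RMS
  displacement below a tenth of the narrowest well width) and keeps the
  Euler-Maruyama stability number D dt U''/k_BT below about 0.1 at the
  stiffest point of the bound well; umbrella scans refine dt to 0.001 ps.
  Larger steps measurably overheat the stiff bound degrees of freedom and
  produce spurious escapes.
* **Scenario presets** freeze one side, mirroring the reference setups:
  binding and sliding runs freeze the polymer (a restrained strand);
  sliding additionally tethers the receptor transverse to the strand and
  leaves it free along it, as in the restrained co-diffusion systems it
  emulates. The field assay freezes the receptor and moves the short
  oligomer as a rigid body with its lateral registry restrained, so
  detachment means crossing the full planted well rather than peeling or
  sliding out of the groove; a flexible chain peels bead by bead and
  collapses the planted ordering. Umbrella scans freeze the polymer and
  tether the receptor laterally above the bound registry (stiffness 2000
  kJ mol^-1 nm^-2), the pulling geometry.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses assume: three planted
modes of ordered strength with distinct residue signatures, a key site
contacted in every mode, field-driven detachment ordered by well depth,
registry-corrugated sliding, and umbrella wells of known depth. It is not
an atomistic model: no solvent, no chain flexibility of the receptor, no
electrostatics beyond the uniform applied field, no absolute-affinity
realism (the reference -22/-33 kJ/mol values enter only as conversion
inputs). Passing the synthetic suites therefore validates the *analysis
machinery and its contracts*, not the biology of any particular real
trajectory.

## Problem sizes used by the tests and the acceptance script

Mode recovery uses 30 trajectories (10 per mode) of 20,000 steps -- long
enough for stable fingerprints, short enough that weak-mode unbinding
stays rare. The detachment assay uses 20 replicas per mode censored at
0.3 ns, with field strengths 0.5 (ordering) and 0.25 vs 2.0 (monotonicity
on the deepest well, where the fraction is far from saturation). Sliding
uses 20 seeds per depth at 300,000 steps on a 64-bead strand; net
displacement of a diffusing tracer is intrinsically high-variance, so the
group size is chosen for adequate one-sided Mann-Whitney power. Umbrella
recovery uses 24 windows 0.1 nm apart with 1.6 million steps each and a
60-bin profile: window overlap and per-window sampling control the
free-energy stitching error, and moderately wide bins keep the
pointwise-minimum estimator from chasing bin noise.

## Known limitations

* The classifier assumes the reference residue set; synthetic systems map
  onto it through the patch dictionary, and a real trajectory must be
  numbered canonically (a scalar offset maps author numbering; no
  per-residue mapping table across species variants is provided).
* Absolute detachment rates in the toy are inflated relative to any real
  system: the contact margin between the bound pose and the 0.6 nm cutoff
  is a few k_BT, so transient zero-contact frames occur at weak planted
  depths even without a field. The assay's claims are comparative
  (ordering in depth, monotonicity in field), not absolute.
* WHAM is 1D; no multistate reweighting. Trajectory I/O covers PDB, DCD
  (read via bio3d; minimal writer for interchange tests) and the
  columnar text format; compressed XTC is not parsed.
* The minimum-segment rule in `detect_transitions()` decides whether brief
  excursions count as transitions; the source analysis labels end states
  only, so this is exposed as a parameter rather than fixed.
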