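---
title: "Methods: structural inference for diamond-like disordered sphere packings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural inference for diamond-like disordered sphere packings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Photonic glasses — disordered assemblies of monodisperse dielectric spheres —
colour the scales of several beetles. The chitin sphere assemblies inside
*Anoplophora graafi* scales are puzzling because their measured volume
fraction (φ ≈ 0.45–0.55) and touching-neighbour count (n_touch ≈ 4–5) are
both far below anything a close-packed or randomly jammed arrangement can
sustain: maximally random jammed (MRJ) packings sit at φ ≈ 0.64 with ≈ 6
contacts, and mechanically stable random packings do not exist below
φ ≈ 0.6. A low-density packing with four tetrahedrally arranged neighbours
is instead the signature of a *diamond-like* network, which can only be
stabilized by directional adhesion between spheres.

`diamondpack` implements the full structural-inference chain needed to make
and test that claim on synthetic data: a tetrahedral patchy-particle
sedimentation model (the generative hypothesis), reference crystal builders
and a jamming generator (the null alternatives), contact-number and
packing-fraction statistics, Steinhardt bond-orientational order parameters
with reference-structure classification, small-angle X-ray scattering (SAXS)
forward models and fits, and a tomogram emulator with a
distance-transform/watershed sphere extractor standing in for FIB-SEM data.

# The patchy-particle model

Spheres of diameter σ (default 210 nm, matching the SAXS diameter of blue
scales) carry four attractive patches at tetrahedral angles. All radial
interactions use the steep 2n–n Lennard-Jones form with n = 24,

U(r) = 4ε [ (σ/r)^2n − (σ/r)^n ],

whose minimum lies at r = 2^(1/n) σ ≈ 1.03 σ. Three channels are active:
patch–patch attraction with ε_p = 8 kT, a body–body channel with
ε_b = 3 kT (repulsive-only at contact by default; see below), and a purely
repulsive Weeks–Chandler–Andersen (WCA) channel with ε = 10 kT used for the
confining wall. σ is interpreted throughout as the centre–centre *contact
distance* (the particle diameter): the quoted 1.03 σ minimum and the LJ
convention itself only cohere with that reading.

The patch–patch channel acts between particle centres and is modulated by a
continuous Kern–Frenkel-style alignment factor: each particle contributes
f = exp(−θ²/2δ²), where θ is the angle between its best-aligned patch axis
and the centre line and δ is the patch half-width. The pair energy is
U_p(r)·f_i·f_j, so a perfectly bonded pair at the minimum has energy
−ε_p = −8 kT under the default repulsive body channel (−11 kT when the
body channel is the attractive LJ variant, whose minimum coincides by
construction). The "best-aligned patch" selection makes the energy
landscape piecewise smooth; the switching set is measure-zero and never
encountered by the integrator in practice.

**The body channel decides the structure.** The decisive modelling choice is
whether non-patch contacts attract. With an isotropic 3 kT attraction at
contact (`body_mode = "lj"`), any two touching spheres stick regardless of
orientation and the sediment collapses into a dense amorphous bed with
n_touch ≈ 7–8 at every patch width we scanned (δ = 15–30°) — nothing like a
tetravalent network. With non-patch contacts purely repulsive
(`body_mode = "wca"`, the default), the only cohesion is directional and the
bed is an open tetrahedral gel whose coordination rises smoothly with
gravity, passing through n_touch ≈ 4.5 at φ ≈ 0.46. "Directional adhesion
only" is therefore the physical statement of the model, and the default.
The patch half-width keeps its natural default δ = 30°; within the
repulsive-body model the sediment coordination is insensitive to it, so it
is not used as a tuning knob.

# Langevin dynamics and sedimentation

Rigid-body dynamics uses the BAOAB Langevin splitting for translations and
its rotational analogue on unit quaternions (isotropic inertia I = 2/5 m r²;
reduced units σ = m = kT = 1 internally, nm and kT at every interface).
The standard time step dt = 0.003 (0.002 for microcanonical checks) was
chosen for the stiff n = 24 potential and is validated by an
energy-conservation precondition: before a production run, a short
frictionless (NVE) integration must conserve total energy to better than
1 %. The bottom wall is a WCA potential; a reflective guard makes it
strictly impenetrable at finite dt, and runaway velocities abort the run
with an instability error naming the step. Initial gas configurations use
a jitter truncated at two standard deviations so no seed can start two
particles deeply overlapped in the stiff potential.

Sedimentation runs start from a dilute jittered-grid gas in a laterally
periodic box with a walled z axis. The bed density is controlled by the
gravity strength g (kT/nm): `equilibrate_to_density()` bisects g
(geometrically, since the useful range spans decades) until the *bulk*
packing fraction of the settled bed is within ±0.02 of the target. Bulk
means: slabs more than 1.5 diameters above the wall and below the free
surface, the surface being the highest slab at half the peak slab density —
boundary layering is thereby excluded from all bed statistics, which is also
how the bed's contact statistics are evaluated.

Run length (93 000 steps, i.e. 280 reduced time units) and system size
(N = 1080) were fixed as the package's standard sedimentation protocol:
long enough for the gas to settle, gel and stop compacting under weak
gravity, small enough to iterate on a workstation. The default gravity
bracket of the bisection (0.4-1.5 kT per diameter) spans the
disordered-sediment regime, where bed densities run from about 0.40 to
0.55.

# Contacts, packing fraction, jamming

Two particles are touching neighbours when d_ij ≤ r_i + r_j + gap, with
gap = 15 nm by default — one voxel side of the emulated tomograms, which is
the convention used when the criterion is applied to segmented imaging data.
The histogram of the integer n_touch values is summarized by mean ± sd *and*
mode: a histogram of integers cannot peak at 4.5, so a quoted "peak at 4.5"
is read as the mean of the distribution, and both statistics are always
reported.

Packing fractions are computed analytically (cap-corrected sphere–region
clipping; exact for fully periodic boxes, per-face cap corrections
otherwise — keep sub-region faces a radius away from sphere-crossing
corners) and by seeded Monte-Carlo point sampling with a standard error;
the two must agree within 3 standard errors, which is a standing test.

The MRJ reference packings come from a growth-and-quench protocol: particles
grow stepwise in a periodic box, the harmonic overlap energy is minimized
with FIRE after each step, and the packing fraction is bisected until the
residual energy per particle sits in a narrow just-jammed window
(10⁻⁸–10⁻⁷ per particle). Rattlers (< 4 contacts at force balance, pruned
iteratively) are excluded from the contact statistic and included in φ.
Monodisperse quenches land at φ ≈ 0.639 with ≈ 6.1 backbone contacts —
the known MRJ/isostaticity benchmarks.

# Bond-orientational order

Steinhardt's q_l are computed from orthonormal spherical harmonics
(Condon–Shortley phase, stable Legendre recurrences): q_lm(i) is the mean of
Y_lm over the bonds of particle i, and q_l = sqrt(4π/(2l+1) Σ_m |q_lm|²).
The neighbourhood is the *same* distance criterion as the contact count.
Two variants are always reported: the plain per-particle invariant and the
neighbourhood-averaged (Lechner–Dellago) variant, in which q_lm is averaged
over {i} ∪ neighbours(i) before the invariant is taken.

Classification against reference structures uses the *ensemble mean of the
plain per-particle invariants* (mean of invariants, not invariant of means).
The choice matters and was made on the data. For perfect lattices the two
variants coincide. For a disordered tetrahedral network they diverge
sharply: a particle with four tetrahedrally arranged bonds sits at the
diamond fingerprint (q4, q6) ≈ (0.509, 0.628) regardless of what its
neighbours do, so the plain ensemble mean of a diamond-like *glass* stays
near the diamond reference — which is precisely the structural claim the
classification is meant to test. The Lechner–Dellago average, by contrast,
adds neighbouring q_lm tensors that are mutually rotated by the random
dihedral angles of the network; they add incoherently, the averaged point
collapses toward the disordered region, and the same sediment would
misclassify as MRJ. Averaging over particles is therefore the convention
that carries the local-symmetry signal for this class of structures, and it
is what "averaged bond-orientational order parameters" means here.

Reference (q4, q6) points for HCP, BCC, FCC and diamond are regenerated
deterministically from the lattice builders, and the MRJ point from the
jamming generator with a fixed seed, all under the same neighbour criterion
— with one deliberate exception. The 8 cube-corner neighbours of BCC are two
interpenetrating tetrahedra, and every even-l Steinhardt invariant is blind
to inversion, so an 8-neighbour BCC reference would coincide *exactly* with
the diamond point. The BCC reference therefore uses the merged first+second
shell (14 neighbours, only 15 % apart in BCC), the standard convention for
BCC bond-order fingerprints, which reproduces the published
(q4, q6) = (0.036, 0.511) and keeps the five references distinct.
Classification is nearest-reference by Euclidean distance in the (q4, q6)
plane, with exact ties reported as ties.

# SAXS models

The forward model is I(q) = scale · ⟨P(q; R)⟩ · S(q) + background with the
normalized sphere form factor P and a Gaussian diameter distribution
averaged by Gauss–Legendre quadrature (truncated at ±4 sd and R > 0,
R⁶-weighted so each size contributes its scattering power). The structure
factor is evaluated at the effective hard-sphere radius (local-monodisperse
approximation, recorded in the output metadata): the analytic
Ashcroft–Lekner Percus–Yevick solution for hard spheres, or the Baxter
sticky-hard-sphere factor computed from the Wiener–Hopf factor function,
whose τ → ∞ limit reproduces Percus–Yevick to 10⁻³ (a standing test).
"Guinier" language in SAXS reports of sphere assemblies is read as the
standard sphere form factor, whose low-q limit *is* the Guinier law with
R_g² = (3/5)R²; a literal Guinier-only model cannot produce form-factor
oscillations.

Fitting is weighted Levenberg–Marquardt least squares (weights 1/σ²);
parameter uncertainties come from the covariance at the optimum scaled by
the reduced χ², flagged unavailable when the covariance is degenerate. An
independent Debye-sum oracle computes I(q) directly from coordinates
(orientation-averaged pair sum with per-sphere amplitudes, O(N²) per q) and
anchors the analytic models in tests.

Synthetic profiles use 200 log-spaced points over q = 0.004–0.2 nm⁻¹ — the
experimentally usable ultra-small-angle range for ~200 nm spheres — with
relative Gaussian counting noise (default 2 %).

# Tomogram emulation and sphere extraction

`voxelize()` rasterizes an assembly at a given pitch (default 15 nm, the
slice thickness of the emulated instrument): a voxel is occupied iff its
centre lies inside a sphere. `degrade()` then emulates the damage chain of
resin-infiltrated ion-beam tomography in three seeded, deterministic steps:

1. *Sample contraction.* The grid is resampled at the same pitch by the
   linear shrink factor (default 0.83, the middle of the reported 10–20 %
   beam-induced shrinkage). Contraction affects sizes *and* spacings — this
   is precisely what the downstream ×1.2 voxel-volume rescale compensates.
   (Per-particle erosion alone cannot stand in for sample shrinkage: it
   leaves positions at the original scale, and the rescale correction would
   then inflate spacings 1.2× relative to truth and destroy every contact.)
2. *Per-particle surface deformation.* The surface is carved where a
   correlated Gaussian random field (correlation length 30 nm, amplitude in
   nm) exceeds the local interior distance transform.
3. *Voxel noise.* Salt-and-pepper flips at a small rate.

`extract_spheres()` mirrors the segmentation chain of tomographic particle
analysis: exact Euclidean distance transform (Felzenszwalb–Huttenlocher),
Gaussian smoothing at 0.25 × expected radius, local maxima as markers
(maxima closer than 0.7 × expected diameter merged, keeping the deeper one;
fragments below 10 % of the expected sphere volume discarded as noise),
marker-controlled watershed by priority flooding, then per-label centroids
and equivalent-volume radii. Half-voxel surface offsets of the distance
transform are corrected explicitly. Particles cut by the bounded volume's
faces are recovered as caps, exactly as in a real tomogram; statistics are
therefore taken over the interior (or via truth–recovery matching in tests).

`rescale_assembly()` and `regularize_spheres()` implement the two
corrections applied to shrunken, deformed tomograms before statistics:
isotropic upscaling (default factor 1.2) and replacement of each particle by
an ideal sphere of one diameter (e.g. 252 nm), with an overlap report.

# What the synthetic data do and do not show

The generators emulate the *structural* content of the experiments:
disordered assemblies at the measured φ, diameter and polydispersity;
tomograms at the instrument pitch with realistic shrinkage/deformation;
scattering profiles over the measured q-range with counting noise. They do
not emulate segmentation errors of real backscatter contrast, anisotropic
milling artefacts, instrument smearing of the SAXS curves, or any optics.
Passing tests therefore demonstrate that the inference chain is correct and
stable under the stated degradations — not that it would survive arbitrary
real-world imaging pathologies.

# Numerical choices and limitations

* Contact criterion uses ≤ with exact arithmetic; ideal touching lattices
  are tested with a 10⁻⁹ relative numerical gap.
* Cell lists (contacts, MD, jamming) fall back to brute force for small or
  thin boxes; agreement with the all-pairs graph is exact and tested.
* The minimum-image convention requires interaction cutoffs below half the
  smallest periodic box edge.
* Sub-box packing fractions use independent per-face cap corrections and
  slightly over-correct spheres straddling region edges or corners.
* The Debye oracle treats assemblies as finite clusters (no periodic
  images); only features above the finite-size cutoff are compared.
* Jamming energy windows and FIRE tolerances are expressed in the reduced
  units of the harmonic overlap model; the just-jammed window implies
  residual overlaps of order 10⁻⁴ diameters.
* Strong gravity (about 4 kT per diameter) crushes the gel into a dense bed
  whose modal touching-neighbour count is 8, the coordination of a
  body-centred-cubic arrangement; at the run lengths used here the bed stays
  amorphous-ordered rather than developing full BCC crystallinity, so the
  dense-regime tests assert the coordination signature, not the crystal
  label.
* The simulated phi = 0.46 beds reproduce the mean touching-neighbour count
  (4.4-4.6) but their histogram is narrower (sd = 1.4) than tomographic
  histograms, whose width also carries segmentation noise and boundary
  layers.
* Sediment beds are gels of a strongly bonding model (8 kT per bond):
  they are kinetically arrested, not equilibrium fluids, and the reported
  bed density and coordination refer to the arrested state the standard
  protocol reaches, as in the experiments the model emulates.
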