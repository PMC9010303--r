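---
title: "Methods: nucleosome stacking geometry, bridging contacts, and fiber analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome stacking geometry, bridging contacts, and fiber analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucstack)
```

# Scope and model

`nucstack` treats each nucleosome as a rigid body derived from its DNA.
That choice reflects how stacking is observed experimentally: what varies
between stacked states is the relative placement of whole nucleosome
discs, not the internal DNA geometry, so all frame fitting is done on the
C1′ atoms of the two DNA strands and histones enter only through contact
roles. The package's analyses assume:

- two DNA strands of equal length per nucleosome, pairable by antiparallel
  residue order (strand-1 residue *j*, 0-based and 5′→3′, pairs with
  strand-2 residue *N*−1−*j*);
- a left-handed superhelical wrap, which fixes the sign of the frame's
  *z* axis and hence the sign of twist across structures;
- chain roles (DNA pair, histone identity, factor) supplied explicitly in
  a YAML role map. Nothing is inferred from sequence: deposited and
  synthetic files disagree on chain naming, and silent misannotation is
  worse than asking the user for a map.

# The nucleosome reference frame

The base-pair center is the midpoint of the two C1′ atoms of a pair; the
base-pair index is 0 at the dyad (for even counts, the pair holding the
5′ member of the central strand-1 dinucleotide — a deterministic,
documented tie-break). The frame is:

- origin *O*: centroid of the stably bound base-pair centers;
- *z*: unit normal of their best-fit plane (smallest principal component),
  signed so the base-pair path from −73 to +73 advances clockwise viewed
  from +*z* (left-handed wrap);
- *y*: in-plane unit vector from *O* toward the dyad pair;
- *x* = *y* × *z*, giving det[*x y z*] = +1.

Unwrapped terminal base pairs (flagged via `flexible_bp_per_end`) stay in
the series but are excluded from the fit; at least 20 bound pairs spanning
the dyad are required, and collinear centers are a hard error. The fit is
exactly equivariant under rigid motions, which is what makes the
generator/analyzer closure tests meaningful.

Superhelical locations are continuous: SHL = bp index / 10.4, one duplex
turn per SHL. The literature quotes SHLs as integers; 10.4 bp/turn is the
standard nucleosomal value (the source structures do not state a
conversion). Binned SHL labels use half-open bins, so "SHL 4–5" is
[4.0, 5.0).

**Dyad and anti-dyad sampling points.** The dyad point averages the C1′
atoms of base pairs −1..+1 (six atoms; one pair would be noise-limited).
"Opposite of the dyad" is geometrically ambiguous — it could mean the DNA
termini (SHL ±7) or the disc position across from the dyad (≈ SHL ±3.5).
The default takes the latter (base pairs ±36, ±37), and the index set is
an explicit argument of `dyad_points()`/`sampling_cloud()` so the other
reading is one keyword away.

# Step parameters and their inverse

The relative geometry of two frames is decomposed about the **mid-frame**:
the quaternion midpoint (slerp at *t* = ½) of the two rotations, with the
origin midpoint. Rise is the origin displacement along the mid-frame *z*;
shift_x/shift_y are the in-plane components; tilt is the total angle
between the *z* axes; twist is the signed angle (right-hand rule about the
mid-frame *z*) between the projections of the two dyad axes. This mirrors
the mid-frame convention of DNA base-step analysis, which is the analogy
the quantities are named after; output metadata should always carry this
definition because other conventions (e.g. sequential Euler
decompositions) give different numbers for strongly bent steps.

The generator needs the exact inverse: given frame 1 and a target step,
construct frame 2 so the decomposition returns the target. Writing the
pair symmetrically about the mid-frame as R₁ = M·S⁻¹, R₂ = M·S with S a
half-step rotation by θ about axis (ρ, 0, n_z) (bend azimuth 0), the
closed form

  sin(Γ/2) = ρ · sin θ,  tan(Ω/2) = n_z · tan θ

(Γ tilt, Ω twist) inverts the decomposition to machine precision. The
projection-defined twist is azimuth-dependent, so for a nonzero bend
azimuth the inner twist parameter is found by a bracketed 1-D root solve
(tolerance 1e−14). The default azimuth is 0; step parameters do not
constrain it, and ensembles perturb all five parameters independently.

Numerical edge cases: the rotation square root is taken on the principal
branch (total step rotation < 180°, which the half-step construction
guarantees); near-180° relative rotations extract the axis from the
symmetric part of the matrix.

# Superposition and ensembles

`superpose()` is a standard SVD Kabsch fit restricted to proper rotations
(the smallest singular direction is reflected when det < 0), erroring on
collinear point sets. Ensemble alignment superposes every frame's
reference-nucleosome C1′ atoms on those of frame 1 (configurable); the
alignment residuals are kept as metadata. Step statistics do not require
alignment — they are rigid-motion invariant — but sampling clouds do, and
`sampling_cloud()` refuses unaligned input rather than silently producing
frame-dependent dispersions.

# Contacts and bridging

A contact is a heavy-atom factor–nucleosome pair within the cutoff.
Defaults, both exposed as arguments and recorded in outputs:

- cutoff 4.5 Å — the common heavy-atom interaction threshold in
  protein–DNA interface analysis; the source data state no cutoff;
- "strong" ensemble contacts at occupancy ≥ 0.5 — occupancy (fraction of
  frames with ≥ 1 atomic contact for a residue pair) is this package's
  operationalization of "strong contact"; mean distance or interaction
  energy would be alternatives, but occupancy is robust to the placeholder
  geometry of synthetic models and is the quantity the tests can pin down.

The implementation culls candidate pairs with a cell list (cell edge =
cutoff, 27-neighborhood); its contract is bitwise agreement with the
brute-force all-pairs reference, which ships in the same function
(`method = "brute"`) and is enforced over randomized complexes in the
acceptance suite.

Bridge classification is role-based: the *specific* partner receives any
histone contacts from the factor, a *neighbor* partner receives DNA-only
contacts, and a factor is a bridge when it reaches two nucleosomes.
Histone contacts on two nucleosomes are reported as an explicit ambiguity
(both listed) instead of being resolved by a hidden priority.

# Fiber geometry

Array order comes from the annotation (repeat order), not DNA
connectivity tracing — deposited array models often have disordered
linkers. Flexible terminal nucleosomes are excluded from fits.

The helical fit has to recover the generator's rise and twist exactly on
noiseless input. A principal-component axis through ~10 origins at
~170°/step is biased by the incomplete turns (the origin centroid is off
the true axis), so the axis **direction** is instead taken from the screw
decomposition of consecutive relative frame rotations (their shared
rotation axis; the PCA direction only orients its sign), and the axis
**position** from an algebraic circle fit of the origins projected on the
transverse plane — both exact for ideal helices. Azimuths are unwrapped to
the nearest branch; rise and twist per nucleosome are mean consecutive
axial/azimuthal increments. Twist-free (ladder-like) stacks fall back to
the mean origin increment as the axis and report twist 0; origins forming
a flat closed ring (no axial advance) are a geometry error.

The "stacked-pair distance" and "stacked-pair angle" are the mean
center–center distance and inter-*z*-axis angle over (n, n+2) pairs. These
are this package's definitions — figure-based fiber descriptions elsewhere
do not pin down which distance and angle they show, so outputs are
labelled with the definition. Start-number classification compares median
center distances at offsets 1 and 2 and reports ties (within 1% relative)
as ambiguous rather than picking a side.

# Synthetic generator: what it emulates, what it does not

The generator exists so that every analysis has a knowable right answer.

- **Nucleosome**: C1′ atoms of both strands on an ideal superhelix,
  radius 41.9 Å, pitch 25.9 Å, 1.65 turns over 147 bp — canonical
  crystallographic values, overridable. Strand separation 10.5 Å across a
  pair. Histones are placeholder pseudo-atom chains (correct role labels,
  no atomic detail) inside the gyres. The CENP-A preset flags 13 bp per
  end as flexible (147 − 2·13 = 121 stably bound) and walks them off the
  superhelix along the local tangent.
- **Stacks**: nucleosome 2's frame is built from nucleosome 1's by the
  exact step inverse above, so `step_parameters()` on the built stack
  returns the ground truth to 1e−6 (observed: ~1e−12). The default preset
  step (rise 60 Å, shift (2, −3) Å, tilt 4°, twist 20°) is a
  disc-on-disc stack with mild obliquity — chosen once as a plausible
  face-to-face geometry, not fitted to any structure.
- **Factors**: placeholder chains whose bridging residues are numbered and
  named after the basic face of the CENP-N α6 helix (K102, K105, K109,
  K110, R114, K117), so interface reports on synthetic data read like
  those on real structures. Atoms sit 3 Å outside their target atoms;
  because adjacent C1′ placeholders are ~3 Å apart, each anchored residue
  also touches ±1 neighboring base pair, and preset anchors are chosen so
  the full footprint stays inside one SHL bin: base pair 47 (mono-stack
  preset, footprint SHL 4.2–4.9) and base pair 66 (fiber preset, footprint
  SHL 6.2–6.7).
- **Fibers**: nucleosome *k* at radius 50 Å, azimuth *k*·twist, height
  *k*·rise, its own axis tilted outward. Presets encode qualitative
  contrasts, not measured values: `cenpn_like` (rise 30 Å, twist 170°,
  tilt-out 18°, two factor copies per (n, n+2) pair) against `h1_like`
  (rise 12 Å, twist 155°, tilt-out 5°, no factors), giving the bridged
  fiber the larger stacked-pair distance, larger stacked-pair angle and
  steeper twist; `ladder` gives parallel columns with zero (n, n+2)
  twist. Two flexible nucleosomes per end leave 8 ordered members in the
  12-mer.
- **Ensembles**: frames perturb the mobile nucleosome's step parameters
  with independent Gaussians (tilt reflected at zero) plus optional
  isotropic per-atom jitter; a mandatory seed makes draws reproducible.
  The `bridged` preset (σ 0.5 Å / 2°) and `unbridged` preset (σ 3 Å /
  10–12°) encode the narrow vs wide sampling of stabilized vs free
  stacks; one- and two-factor stacks share the bridged dispersion, since
  a single bridge is already sufficient to stabilize stacking.

What the generator does **not** emulate: correlated or Langevin dynamics
(noise is i.i.d. per frame), sequence-dependent DNA mechanics, atomic
histone/factor detail, internal nucleosome deformation. Passing tests
therefore validate the geometry and bookkeeping of the analyses — frame
recovery, alignment, contact mapping, helical fitting — not the physics of
real trajectories; on experimental data the same code paths run, but
dispersion magnitudes and occupancies will reflect real, correlated
motion.

# Gradient profiles

Profiles are normalized per condition to I_i/I_max (the maximum maps to
exactly 1); replicates are normalized first, then averaged (the averaging
order is not fixed by the source convention; after-normalization weights
both replicates equally regardless of exposure). Interpolation uses the
Akima (1970) local cubic scheme — knot slopes are |slope-difference|-
weighted averages of neighboring secants with two extrapolated ghost
slopes per end, evaluated as piecewise cubic Hermite. It is exact at
knots, reproduces polylines on collinear data, needs ≥ 5 points, and is
implemented in the package (verified against two independent references
during development; the interior-interval agreement with `pracma` is kept
as a test). The distribution shift between conditions is summarized by
the intensity-weighted centroid fraction — a scalar operationalization of
"migrates to lower-density fractions"; the synthetic profile generator
produces Gaussian peaks at fraction 16 (compaction-competent) and 10
(compaction-deficient) over 20 fractions with log-normal replicate noise.

# Problem sizes and determinism

The shipped tests and acceptance script use sizes chosen to make the
statistics sharp while keeping the whole suite interactive: 100 random
stack ground truths for closure, 50 randomized ≤ 2,000-atom complexes ×
4 cutoffs for the contact oracle, 300 frames for step-dispersion recovery
(s.d. tolerance 25%), 500 frames for cloud dispersion (σ√3 within 10%),
and 12-mer fibers with 0.5 Å jitter for the 5% helical-recovery check.
All stochastic paths take explicit seeds; generators are deterministic
given spec + seed.

# Known limitations

- mmCIF support targets the canonical atom_site column layout (what the
  bio3d reader parses); exotic mmCIF dialects may need conversion.
- Multi-model ensembles are held in memory; very long trajectories should
  be subsampled upstream.
- The frame fit assumes a recognizably wrapped nucleosome; sub-nucleosomal
  particles (hexasomes, tetrasomes) have no defined dyad frame here.
- Base-pair-level duplex parameters (roll/slide/propeller) are out of
  scope; only nucleosome-level geometry is computed.
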