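---
title: "Building and analyzing double-stranded DNA with dnaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analyzing double-stranded DNA with dnaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaforge)
```

## The rigid-base picture

`dnaforge` treats double-stranded DNA as a chain of rigid base pairs.  Each
base pair carries a reference frame: an origin (in nm) and a right-handed
orthonormal triad, with the z axis along the helix toward the 3' end of the
reference strand and the x axis toward the major groove.  The relative
geometry of two consecutive frames is summarized by six step parameters -
three translations (shift, slide, rise, nm) and three rotations (tilt, roll,
twist, degrees) - and the internal geometry of a pair by six intra-base-pair
parameters (shear, stretch, stagger, buckle, propeller, opening).  Both sets
are defined symmetrically through the *mid-frame*: the relative rotation is
expressed as an axis-angle vector, the mid-frame is reached by half that
rotation, and translations and rotation components are resolved in the
mid-frame basis.  This axis-angle/mid-frame convention makes parameter
extraction and structure reconstruction exact mutual inverses
(`step_from_frames()` / `frames_from_step()` round-trip to 1e-8), which the
generator, the Monte Carlo engine and the analysis module all rely on.
Rotations of exactly 180 degrees have no unique mid-frame; the package
raises an error rather than silently picking an axis.

## Shape generation by spline mapping

`make()` turns a sequence and/or a shape into a structure in four stages:

1. **Spline fit** (`fit_spline()`): a componentwise cubic interpolating
   spline through at least four control points (nm), against a chord-length
   parameter.  Closed shapes use periodic end conditions, open shapes
   natural ones; the curve passes through every control point.  Arc length
   is tabulated by composite 7-point Gauss-Legendre quadrature on 2048
   subintervals, giving relative accuracy far below the 1e-6 nm spacing
   tolerance downstream.
2. **Equidistant sampling** (`sample_equidistant()`): base-pair origins are
   placed at equal arc-length spacing, 0.34 nm by default (the mean rise).
   If `n_bp` is given the spacing rescales to the fixed geometry; otherwise
   the count follows from the arc length and the residual is spread evenly
   over all gaps, with the effective spacing reported as a message.
3. **Parallel transport** (`transport_frames()`): each frame's z axis is the
   local tangent; x and y are carried along by the minimal rotation between
   consecutive tangents, so the transported field has zero intrinsic twist.
   The initial normal is the global +x axis projected perpendicular to the
   first tangent (+y when nearly parallel) - an arbitrary but deterministic
   choice.
4. **Twisting** (`apply_twist()`): open chains receive 360/10.5 degrees per
   step (10.5 bp/turn).  For closed chains the relaxed twist `Tw0` is the
   integer nearest `n_bp/10.5` (closure needs whole turns; ties round half
   to even) and the imposed total twist follows the White-Fuller theorem,
   `Tw_new = Tw0 + dLk - Wr`, spread uniformly over all steps.  The writhe
   `Wr` of the sampled backbone is computed at construction time, so the
   requested linking-number difference `dLk` is realized regardless of any
   writhe the shape already carries.  `dLk` must be an integer for closed
   topologies and is ignored (with a warning) for open ones.

Writhe is evaluated with the exact pairwise solid-angle formula for
polygonal curves (the Gauss double sum of Klenin & Langowski), skipping
segment pairs that share a vertex; at 200-500 vertices this is accurate to
well below 1e-3, which minicircle work requires.

On loading (or after generation) a structure is classified circular when the
first and last base-pair origins are closer than 1 nm *and* the chain
exceeds 20 bp - the length guard keeps short fragments with coincidentally
close ends linear - unless the caller states the topology explicitly.

## Twist, writhe and linking number

`compute_linking_number()` reports `Tw`, `Wr` and `Lk = Tw + Wr`.  Two
different twist definitions coexist in the rigid-base world and the package
keeps them deliberately separate:

* the *Curves+-style step twist* (the `twist` column of
  `compute_rigid_parameters()`), defined through the mid-frame - the right
  quantity for describing local helical geometry;
* the *ribbon twist about the base-pair origin polygon*, used by
  `compute_linking_number()`: the frame x axis is projected perpendicular
  to each polygon segment and transported across bends by the minimal
  rotation between consecutive segment directions; the per-joint residual
  rotation is the twist.

Only the second definition pairs exactly with the polygonal Gauss-sum
writhe: their sum is the linking number of the offset ribbon, an integer,
reproduced by the package to 1e-10 and conserved exactly under Monte Carlo
moves.  Summing Curves+ step twists instead leaves a residual of order
(bend)^2 x twist per step - a few 1e-3 after relaxation - which is why it is
not used for topology.

## Monte Carlo relaxation

`minimize()` runs Metropolis sampling under a quadratic rigid-base-step
energy

E = 1/2 * sum_steps (x_i - x0)' K (x_i - x0)   [kT]

with equilibrium step `x0 = (0, 0, 0.34 nm, 0, 0, 34.286 deg)`.  The default
stiffness `K` is diagonal: tilt and roll from a bending persistence length
of 50 nm and twist from a torsional persistence length of 100 nm (both
converted at the 0.34 nm rise; e.g. k_bend = (50/0.34)*(pi/180)^2 kT/deg^2),
and stiff translations corresponding to ~0.01 nm fluctuations.  These are
standard B-DNA elasticity values and are fully overridable through
`elastic_model()`.  Energies are expressed in kT at 300 K; the configured
temperature enters only through the acceptance rule
`exp(-dE * 300/T)`, so "minimization" is sampling at low-to-ambient
temperature.

Two move types are used.  *Crankshaft* rotations turn the frames strictly
between two chain points about the axis joining their origins - they leave
every origin outside the block untouched, which makes them safe for closed
chains.  *Pivots* (open chains only) redraw one step's 6-vector from a
Gaussian proposal and carry the outer segment rigidly; because the proposal
is symmetric in step coordinates, a single free step samples exactly the
Boltzmann distribution of the elastic model (the equipartition test checks
the recovered variances against kT K^-1 to 10%).  Moves touching fixed
indices are rejected outright, so constrained frames are preserved
bit-for-bit.

Excluded volume is a hard wall: base-pair origins more than
`ev_min_separation` (default 5) steps apart along the chain must stay at
least `ev_diameter` (default 2.0 nm) apart; closer-along-the-chain pairs are
exempt so helical stacking is never self-rejecting.  Violations reject the
move.  Crankshaft rotations additionally cap the per-bead displacement at
1 nm (half the hard-sphere diameter), so a moving bead can never jump across
another strand: together wall and cap forbid chain passage, and the linking
number of a closed chain is conserved *exactly* - verified to 1e-10 across
seeds and dLk values.  A 200 bp minicircle built with `dLk = 6` therefore
keeps its linking-number offset while converting twist into writhe
(|Wr| grows from ~0 to >1 within ~100 sweeps), the hallmark of plectoneme
formation.

Convergence is assessed by least-squares fitting `c + a*exp(-t/tau)` to the
per-sweep energy (or writhe) trace: a run counts as converged when it is at
least five decay times long, the fitted plateau agrees between the two
halves of the trace (within 5% or the fit's residual noise), and the last
20% of the trace is flat to a quarter of the overall range - the plateau
test covers barrier-crossing runs whose writhe must "fluctuate around a
fixed value" before they can be called equilibrated.  All randomness flows
from the single mandatory seed; identical seed, configuration and input give
bit-identical results.

Numerical hygiene: chained rigid maps accumulate floating-point drift, so
triads are re-orthonormalized (modified Gram-Schmidt) every 10 sweeps and
after the run, and the rigid map of each pivot is built from
re-orthonormalized anchor triads - without this the anchor error would
compound exponentially through successive segment transforms.

## Sequence alphabet, editing and atomic models

The code alphabet is A, T, G, C, U plus 2-aminopurine (E), tricyclic
cytosine (D), the Hachimoji quartet (B, S, Z, P) and the hydrophobic pair
d5SICS (L) / dNaM (M).  The single-valued complement map pairs B-S, P-Z,
L-M, and sends U and E to A and T, and D to G.  Because U, E and D pair
*into* the canonical alphabet, double-complementation is an involution only
on the other ten codes - an unavoidable property of any single-valued map
for this alphabet.

Atomic templates (idealized planar geometry in the standard base reference
frame, nm) are shipped for A, T, G, C, U and contain the base heavy atoms
plus the glycosidic C1' carbon; sugar and phosphate atoms are *not*
modeled, so exported PDBs are base-frame skeletons rather than
simulation-ready all-atom structures - a deliberate scope limit documented
here and in the README.  The extended codes are bookkeeping-only (sequence,
pairing, frames) unless a user registers a template with
`register_base_template()`.

* `mutate()` rewrites codes, optionally updating the partner strand from the
  pairing table (non-complementary pairings are allowed by switching that
  off).  Frames never move.
* `flip()` rotates the base atoms (not C1') about the glycosidic bond
  (C1'-N9 for purines, C1'-N1 for pyrimidines), 180 degrees by default -
  the Watson-Crick-Franklin to Hoogsteen transition.  Flip angles
  accumulate, so two 180-degree flips restore the original coordinates
  exactly.  Hydrogen-bond re-optimization of the flipped pair is left to
  the user (the protonated-cytosine chemistry of G-C Hoogsteen pairs is out
  of scope).
* `methylate()` adds the methyl carbon at C5 of cytosine (5-methylcytosine)
  or - a package decision, since no site is standard in the source
  material - at N7 of guanine, placed in the ring plane at 0.15 nm along
  the centroid-to-site direction.  `cpg_auto = TRUE` scans the reference
  strand for CG dinucleotides.  Re-methylation warns and is a no-op.
* `extend()` appends base pairs beyond a terminus, by default as an ideal
  straight B-helix continuation; `connect()` joins two duplexes with a
  straight bridge whose length, when not given, minimizes a twist-register
  penalty: a bridge of n base pairs spans n+1 steps between the fixed
  terminal frames, and candidates near gap/0.34 are scored by the squared
  deviation of the required net twist (principal twist plus whole turns)
  from (n+1) x 360/10.5, ties to the smaller n.  Both editors mark the new
  base pairs plus a `margin` of original terminal pairs as free, so a
  subsequent `minimize()` only moves the junction region.

## Analysis

`fit_base_frames()` recovers per-base frames from atomic coordinates by
least-squares rigid superposition (Kabsch) of the template onto the observed
atoms.  All template atoms are used for the fit: the wider footprint roughly
halves the noise amplification of the fitted origin relative to ring-only
fitting (with 0.01 nm coordinate noise the RMS origin error stays below
0.02 nm).  Antisense frames are flipped 180 degrees about their x axis so
both frames of a pair are co-oriented; the base-pair frame is their
mid-frame, and the intra parameters are the step-style coordinates from the
flipped Crick frame to the Watson frame.

`compute_rigid_parameters()` returns a (t, n_bp, 12) array - six intra, six
step parameters per base-pair slot, step slot i holding step i to i+1, the
last slot NA for open chains and the wrap step for closed ones.

`persistence_length()` fits the tangent correlation `<z_i . z_(i+m)>`
(averaged over positions and time frames) to `exp(-m h / l_p)` with h the
mean rise, by through-origin log-linear least squares restricted to m up to
n_bp/2 and correlations above 0.05 (the noise floor); a rigid straight chain
returns `Inf`.  Ensembles drawn from the elastic model with
`sample_ensemble()` (independent Gaussian steps chained into frames) recover
the input 50 nm to within a few percent at 300 bp x 200 samples.

`total_curvature()` sums `sqrt(tilt^2 + roll^2)` over steps - for small
per-step bends this equals the accumulated bend angle of the helical axis.

## What the synthetic data does and does not emulate

The generator and the elastic-model sampler produce idealized,
sequence-independent B-DNA: uniform rise and twist, no sequence-dependent
curvature or stiffness, no thermal intra-base-pair deformations, harmonic
(not anharmonic) step fluctuations and hard-sphere (not electrostatic)
self-avoidance.  Tests passing on these inputs validate the geometry,
topology and sampling machinery; they do not certify force-field-level
realism of any particular sequence, and exported structures are intended as
*starting* configurations for refinement, not as equilibrium ensembles.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problems chosen
to probe each property well inside its asymptotic regime: 80-500 bp
generation, a 200 bp minicircle with dLk = 6 relaxed for 100 sweeps
(writhe reaches ~1-2 of its eventual plectonemic value - topology and trend
are what is asserted), 200,000 two-base-pair sweeps for equipartition
(>= 1e5 accepted moves), and 200 x 300 bp ensembles for persistence length.
Key tolerances: 1e-8 for geometric round-trips, 1e-6 nm frame-fitting
round-trip, 1e-6 for White-Fuller closure, 1e-3 for writhe versus a
10x-refined quadrature oracle.  Spline arc-length inversion uses a table
lookup refined by Newton steps on the exact speed; degenerate inputs
(duplicate control points, 180-degree rotations, antiparallel tangents,
non-orthonormal triads beyond 1e-3) raise errors rather than guessing.

## Known limitations

* No sugar/phosphate backbone in the atomic templates; no hydrogens.
* Non-canonical codes have no atomic templates and cannot enter MC
  minimization (canonical-only, as in the modeling the package follows).
* Sequence-independent elasticity; no coupling terms in the default K
  (though any symmetric positive-semidefinite K is accepted).
* Single-stranded, branched and kilobase-scale systems are out of scope.
* The MC engine relaxes structures; it is not a calibrated thermodynamic
  sampler for observables beyond the step-parameter level checks above.
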