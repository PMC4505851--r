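---
title: "Pathways and free energies of loop wrapping/unwrapping transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathways and free energies of loop wrapping/unwrapping transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Short inter-helical loops can store a discrete piece of conformational
state: a residue *wrapped* onto the last turn of an adjacent α-helix is
held by a canonical i → i+4 H-bond, while the *unwrapped* loop is
extended and the same donor/acceptor pair sits many Ångström apart.
Switching between the two requires near-180° rotations of a few backbone
φ/ψ torsions, each crossing a steric/electrostatic barrier of several
kcal/mol. In LeuT-fold transporters the loops at the two ends of the
hash motif (EL4 and IL2 in Mhp1) do exactly this between the
outward-facing and inward-facing states, which makes their internal
conformation one of the *slow, hysteresis-generating degrees of freedom*
of the whole transporter: driving the protein by holistic coordinates
(Cα positions, domain distances) leaves the loops behind, and the
apparent free energy of the target state is then badly overestimated.

`loopstring` implements the complete desk-scale workflow for studying
such transitions: torsion-deviation maps to find the loops, targeted MD
(TMD) to generate initial transitions, string-method refinement with
Hamiltonian replica exchange to relax them into minimum free-energy
pathways with free-energy profiles, and loop-driven protocols to ask the
converse question — how much of the remainder follows when only the
loops are driven. Because the production-scale simulations behind these
methods are not reproducible on a desk, every component is exercised and
validated on two synthetic systems with independent oracles.

# Synthetic systems: what they emulate, and what they do not

## The two-well 2D potential

`make_two_well_potential()` builds a sum of Gaussian terms: two wells of
depth ≈ `barrier_height` separated along x, a positive bump displaced
along +y between them, and weak quadratic confinement. The bump forces
the minimum-energy path to bend away from the straight line joining the
wells, so a string started on that line must genuinely relax sideways.
`locate_critical_points()` is the oracle: a grid scan for local minima of
|∇V| followed by Newton refinement and Hessian classification; it
verifies construction (exactly two minima and one first-order saddle)
and supplies the exact saddle position and barrier that the string
method must recover. A seed-derived ±3 % depth asymmetry keeps the two
wells inequivalent; `asymmetry = 0` restores exact x-symmetry (used to
check that the saddle then sits on the symmetry axis).

## The toy loop chain

`build_toy_loop()` creates an n-residue chain with the five backbone
sites per residue (N, H, CA, C, O; H omitted for proline-like residues)
that carry the representative-atom description of a loop: positions and
orientations of every peptide plane. Energy terms, all with analytic
gradients in compiled code:

* harmonic bonds (k = 100 kcal/mol/Å²) and angles (40 kcal/mol/rad²)
  at ideal peptide geometry;
* stiff trans peptide-plane torsions (ω at 180°, plus impropers pinning
  O and H into the plane);
* **bistable φ/ψ torsions**: an n = 2 cosine with minima at the design
  target and 180° away (amplitude 4.0 kcal/mol), an n = 1 term
  (0.6 kcal/mol) deepening the target, and an n = 1 *direction-bias*
  term (0.75 kcal/mol) centred 90° past the target. The bias leaves
  both minima equally deep but raises one rotation direction's saddle
  by ~1.5 kcal/mol, so the designed flip pathway has a knowable,
  non-degenerate barrier ordering — without it, +180° and −180°
  rotations are exactly equivalent and any path-finding method faces an
  arbitrary binary choice at every flip;
* a **switchable helical contact**: a short-range attractive Gaussian
  well (depth 3 kcal/mol, r₀ = 2.0 Å, width 0.35 Å) between the donor
  amide H and the acceptor carbonyl O four residues earlier. A plain
  harmonic well would act at any distance and the unwrapped state would
  not be a local minimum of the full model; the localised well is the
  substance-preserving choice;
* bounded soft-core repulsion ε(1 − (r/r_c)²)³ (ε = 10 kcal/mol,
  r_c = 2.5 Å) between atoms more than three bonds apart.

The rotation barrier of ≈ 8 kcal/mol follows from a timescale argument:
over the tens-of-picosecond observation windows used here, across ~20
flippable torsions, the expected number of spontaneous flips at 300 K is
kept ≪ 1 (rate ≈ ν e^(−ΔU/kT) ≈ 2×10⁻⁵ ps⁻¹ per torsion), mirroring the
loops' stability in equilibrium runs, while driven simulations cross
easily. All site masses are 12 amu (equal masses permit the 4 fs
timestep; only configurational averages matter here), k_B =
0.0019872041 kcal/mol/K, default temperature 300 K.

`generate_endpoint_conformations()` minimises the wrapped state A from
the design geometry with the contact engaged (L-BFGS to a max per-atom
gradient below 10⁻³ kcal/mol/Å), rotates the requested torsions, and
minimises with the contact released before polishing under the full
model — so both endpoints are genuine local minima of the *same*
energy. The prescribed torsion differences are verified within 10°, and
the linear Cartesian interpolation between the endpoints crosses a
large energy barrier, which is exactly what makes string refinement
non-trivial.

What the toy does **not** capture: electrostatics and solvent (the real
loops' barriers include desolvation and H-bond competition), side
chains and chirality (the sites are achiral, so mirror conformations
are degenerate), and the coupling of a loop to a surrounding protein.
Passing tests on the toy therefore demonstrate the *methods* —
restraints, sampling, path refinement, free-energy integration — not
the energetics of any real loop.

# Dynamics and restraints

Dynamics is BAOAB-discretised Langevin (temperature default 300 K,
damping 0.1 ps⁻¹ unless a protocol states otherwise, timestep 4 fs on
the chain, 10 fs on the 2D particle). BAOAB was chosen for its
configurational sampling accuracy; all sampling statistics used here
are configurational. The noise stream comes from R's RNG, so a seed
reproduces a trajectory bitwise.

Restraint forces are exact negative gradients:

* the TMD restraint ½k(RMS − r₀)² differentiates through the optimal
  superposition; because rotation and translation are optimal, the
  envelope theorem collapses the chain rule and the gradient is the
  aligned residual rotated back, with the centring term vanishing by
  translation optimality;
* the orientation-angle restraint ½kθ² obtains the best-fit quaternion
  as the top eigenvector of the Horn matrix and its derivative by
  first-order eigenvector perturbation, with θ computed through
  atan2 so the force stays finite as θ → 0;
* quaternions use the (w, x, y, z) convention with the double cover
  fixed by w ≥ 0 and slerp along the shortest arc (an antipodal pair is
  negated first) — this is what makes "linear interpolation between
  orientation quaternions" well defined.

Every kind is checked against central finite differences at 10⁻⁴
relative tolerance in the tests and the acceptance script.

# The string method

A pathway is a `StringPath`: an ordered list of images (reference
coordinates of the representative atoms — backbone amide H, carbonyl O
and Cα of every residue, plus designated side-chain atoms), with fixed
endpoints and a per-atom spring constant. One refinement iteration:

1. **Sample.** Each image is sampled under its Cartesian-harmonic
   restraint. Two groups run independently — started from snapshots of
   the two opposite-direction TMD trajectories (the frame with the
   smallest representative-atom RMSD to each image, ties to the
   earliest frame) — but confined to the common path. Hamiltonian
   replica exchange proposes swaps between adjacent images every sweep,
   alternating odd/even pairs; the Metropolis ratio involves only the
   two images' restraint energies.
2. **Update.** The per-image means of both groups are pooled, aligned
   to the common reference frame, fitted with one cubic smoothing
   spline per Cartesian coordinate against a chordal parameter
   (per section between detected free-energy minima, so the curve may
   kink only at metastable intermediates), and re-sampled at even arc
   length with the endpoints pinned to the input conformations.
3. **Integrate.** The mean system force on image i is estimated by the
   restraint balance k(⟨x⟩ᵢ − xᵢ^ref) — unbiased for stiff springs and
   free, since the sampler already collects the means — projected on
   the unit path tangent (central differences, one-sided at the ends)
   and integrated by the trapezoidal rule over arc length, anchored at
   zero on the first image. Error bars propagate the sweep-block
   scatter of the means.

A final pass re-samples the converged path at more images with stiffer
springs (defaults mirror the production protocol: 60 images at
2 kcal/mol/Å² for refinement, 120 at 4 for the profile) and produces
one profile per group: their agreement is the convergence and
hysteresis diagnostic. The refinement warns when the per-iteration path
displacement stops decreasing over the last three iterations.

Two protocol choices deserve explanation:

* **Refinement springs are softer than profile springs.** The
  per-iteration contraction of the path toward the fixed point is
  ≈ k/(k + H⊥) where H⊥ is the transverse curvature; a stiff spring
  converges geometrically slowly. The 2D validation uses k = 8 for
  refinement and 16 for the final pass.
* **Validation temperature.** The two-well validation samples at 120 K
  (barrier/kT ≈ 20), where the free-energy barrier approximates the
  potential-energy gap the oracle provides; at 300 K transverse-entropy
  differences between well and saddle would contribute ~8 % of the
  barrier and the comparison would conflate two effects.

`run_two_well_validation()` packages the whole check: straight initial
string between the oracle's minima, 30 images, 30 iterations. At the
defaults the converged path passes within ~0.08 of the saddle, the
barrier is recovered within ~2 %, and the two groups agree well within
combined standard errors.

The harmonic exactness check (`run_harmonic_profile_check()`) exploits
that restrained means of a harmonic system are temperature-independent
(⟨x⟩ = k s/(κ + k)), so it runs in the deterministic low-temperature
limit: the recovered profile is ½κ′s² with κ′/κ = k/(κ + k) — a known
2 % stiff-spring factor at the defaults, and exactly zero for the flat
case.

## Hysteresis, and when the two groups cannot agree

With a *single* flipped torsion the transition has one well-defined
tube and the two groups' profiles coincide (the test suite demonstrates
barriers agreeing to three digits). With the canonical study condition
of **two** ±180° flips, the flip *order* is a discrete degeneracy: the
group seeded from the forward drive tends to occupy one order-tube and
the backward-seeded group the other, pooled means average two distinct
ensembles, and the profiles disagree far beyond their error bars. This
is not a failure of the machinery but the phenomenon itself — the same
situation as a loop whose forward and backward drives follow
qualitatively different pathways, where no consensus pathway exists.
The practical remedy, as in the field, is independent per-pathway
refinement: run `refine()` twice, passing the *same* group's starting
snapshots as both `states0_a` and `states0_b`, obtain one profile per
pathway, and prefer the lower barrier. The workflow reports both
groups' profiles precisely so this situation is visible rather than
averaged away.

# Targeted MD and loop driving

`run_tmd()` applies ½k(RMS − r₀)² on a selection with r₀ decreasing
linearly from the initial best-fit RMSD to zero over the run, logging
(RMS, r₀) per frame. On the toy loop (k = 500 kcal/mol/Å², tens of ps)
the final selection RMSD to the target is ≈ 0.2–0.3 Å.

`build_driving_path()` composes the loop's driving references: at
progression t, the internal conformation is the even-arc point along
the refined string, the centre is interpolated linearly, and the
orientation by slerp between the endpoint poses; frames 0 and n−1
reproduce the endpoint loop coordinates exactly (checked to 0.1 Å).
`run_loop_driven()` advances these frames stepwise (piecewise-constant
references, each held for a fixed time — the explicit frame-advance
protocol) at 2 kcal/mol/Å² per loop atom, while the whole system's
centre (1000 kcal/mol/Å²) and orientation angle (200 kcal/mol/degree²)
are pinned to a global reference, so Cartesian coordinates remain an
unambiguous internal representation. The rotation/translation-invariant
internal-restraint alternative is deliberately not implemented; the
global-pose route is simpler and the pose drift under the default
springs stays below 0.1 Å and 0.5° (measured ≈ 0.04 Å / 0.05°).

The coupled test system (`build_coupled_system()`) adds one follower
particle per residue, tethered to that residue's Cα at a fixed offset;
followers of designated residues are instead anchored to their state-A
positions. Driving the loop then carries the coupled followers to the
target while the anchored ones stay — the built-in positive and
negative controls for `follower_response()`. The negative-control
residue defaults to the contact donor, whose Cα moves ~4.4 Å between
the states; anchoring a residue that barely moves would make the
control vacuous.

# Structure handling and numerical conventions

* PDB I/O goes through bio3d; alternate locations resolve to the
  highest occupancy (ties alphabetically), only one MODEL is used, and
  malformed coordinate fields are reported by line number.
* Amide hydrogens are built at 1.00 Å from N, in the C(prev)–N–CA
  plane on the exterior-angle bisector. Crystal-structure H-bond
  distances computed with built hydrogens carry an uncertainty of
  roughly ±0.3 Å from this choice.
* Dihedrals follow the IUPAC convention (cis = 0°, trans = 180°),
  verified against bio3d's torsions; combined torsion deviation is the
  root-sum-square of the smallest periodic differences, reported in
  degrees.
* Angles are degrees in all user-facing values, coordinates Ångström,
  energies kcal/mol, times ps; selections are 1-based, as everything
  else in R.
* Cross-correlation frames are aligned to the first frame on all Cα
  before computing displacements, removing rigid-body drift that would
  otherwise inflate correlations; residues are represented by their Cα.

# Problem sizes

The default toy workflow uses an 11-residue chain (55 sites, 33
representative atoms), 60 refinement images (final pass 120), four
refinement iterations of 12 sweeps × 60 steps per image and group, 60 ps
TMD legs, and 60 driving frames held 0.6 ps each — about a minute of
computing. The 2D validation uses 30 images and 30 iterations (a few
seconds). The test suite and the acceptance script use these sizes or
smaller presets throughout; they were chosen so that statistical
tolerances (binomial bounds on acceptance rates, Bonferroni-corrected
pointwise profile agreement, 3σ bounds on restrained means) are
comfortably resolved.

# Known limitations

* The toy chain is achiral and unsolvated; its barriers are designed,
  not predicted.
* Free-energy error bars assume sweep-blocks are nearly independent;
  strongly correlated sampling underestimates them (lengthen
  `steps_per_sweep` in the final pass if in doubt).
* The mean-force estimator integrates the tangent projection; curvature
  contributions orthogonal to the path are not represented.
* Piecewise curve fitting allows kinks only at detected free-energy
  minima; a metastable state shallower than the detection threshold is
  smoothed through.
* With multiple simultaneously flipped torsions the pooled two-group
  refinement can average over distinct pathway tubes (see the
  hysteresis section); use independent per-pathway refinement there.
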