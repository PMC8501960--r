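---
title: "Elastic and thermodynamic modelling of protein-mediated DNA loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic and thermodynamic modelling of protein-mediated DNA loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmech)
```

This vignette explains the models implemented in `loopmech`, the choices
made where the design was genuinely open, and what the synthetic-data
machinery does and does not emulate.

## The elastic model

### Geometry

DNA is represented at base-pair resolution: each base pair carries an
orthonormal right-handed frame (origin plus a 3×3 rotation whose columns
are the short axis, long axis and helix normal), and successive frames
are related by six rigid-body step parameters — three angles (tilt,
roll, twist, in degrees) and three translations (shift, slide, rise, in
Å).  We use the mid-step-frame convention: the rotation from frame *i*
to *i+1* is `Rz(ω/2 − φ) Ry(Γ) Rz(ω/2 + φ)` with bend magnitude
`Γ = √(tilt² + roll²)` and bend phase `φ = atan2(tilt, roll)`, and the
translation vector is expressed in the half-way frame.  This is the
convention of the structural-parameter literature and of the `.par`
files the package reads and writes, and it makes `build_chain()` /
`extract_steps()` exact inverses (verified to 10⁻⁸ on random chains in
the test suite).  Angles are stored in degrees at the user interface and
converted to radians internally.  The decomposition used by
`extract_steps()` is two-fold degenerate — `(Γ, φ, ω)` and
`(Γ, φ + π, ω − 2π)` encode the same rotation — and is canonicalized to
|twist| ≤ 180°, the physically meaningful branch for B-DNA steps.

Strand reversal (reading a duplex in the opposite 5′→3′ direction) is
implemented by flipping every frame 180° about its short axis and
reversing the order; under this convention it negates tilt and shift and
preserves the other four parameters.  Reverse-orientation protein
footprints are generated this way, so forward and reverse footprints are
exact convention-consistent mirrors.

### Potential

Protein-free steps feel a diagonal harmonic potential about the rest
state of an ideal, naturally straight, inextensible double helix: all
parameters zero except twist (360/*n* degrees for a helical repeat of
*n* bp/turn, default 10.9) and rise (3.4 Å).  The stiffness of each
degree of freedom is set by the single deformation that raises the
energy of one step by kBT/2:

| scale | default | affected parameters |
|---|---|---|
| twist | 4.1° | twist |
| bend | 4.8° | tilt and roll, separately |
| translation | 0.02 Å | shift, slide, rise |

so `k = kBT/δ²` per degree of freedom.  Two open points were resolved as
follows.  *Bending isotropy*: a single bend scale is quoted, and a
naturally straight helix has no preferred bending direction, so the 4.8°
scale applies to tilt and roll independently (an isolated 4.8° tilt also
costs kBT/2).  *Coupling*: the potential is diagonal — no tilt–roll–twist
cross terms — which is the simplest form consistent with the stated
calibrations.  "Inextensible" is realized through the very stiff 0.02 Å
translational constants rather than hard constraints, which keeps the
optimizer unconstrained; freezing translations exactly is available by
labelling steps frozen.

These scales imply the polymer moduli of mixed-sequence DNA.  With step
variance `δ²` per bending axis (equipartition), the mean squared bend
per step is `2δ_b²` and the persistence length is `P = 2h/⟨θ²⟩ ≈ 48 nm`
(h = 3.4 Å); the torsional modulus is `C = kBT·h/δ_tw² ≈ 2.7 × 10⁻¹⁹
erg·cm` using kBT = 4.1 × 10⁻¹⁴ erg at room temperature (298 K, the
value used for every cgs conversion in the package).  `mc_moduli()`
checks both by direct Monte-Carlo sampling: the tangent–tangent
correlation of sampled free chains decays exponentially at a rate that
reproduces P, and the sampled twist variance reproduces C.

## Loop optimization

A loop is a chain whose first frame is fixed on one repressor headpiece
and whose last frame must land on the other.  Because the operators can
attach to the headpieces in either 5′→3′ direction there are four
boundary orientations (A1, A2, P1, P2, generated from one geometry by
flipping each operator frame 180° about its short axis), and each
orientation supports two topological families of solutions (F1/F2,
distinguished by the sign of a writhe-like chirality measure), giving up
to eight states per construct.

**Constraint handling.**  The end condition is enforced by quadratic
penalties — a spring on the end-origin distance and a Frobenius-norm
spring on the end-orientation mismatch — whose stiffness is raised over
a continuation ladder (10, 10³, 10⁵ kBT per Å²/rad², extended ×10 up to
two more rungs if needed).  After optimization the residuals are checked
against 0.05 Å and 0.05°; a state that cannot meet them is flagged
infeasible (zero statistical weight), not an error.  The tolerances are
far below thermal displacement scales, so the penalty formulation is
physically indistinguishable from an exact constraint while keeping the
landscape smooth.  Minimization is quasi-Newton (L-BFGS-B) over the
6×(free steps) parameters; gradients come from the compiled kernel,
which differentiates the end frame analytically through prefix/suffix
transform products (with a central difference only on the single 4×4
step transform).  The reported ψ is the elastic energy alone.

**Seeding and families.**  Initial pathways are smooth bulged curves
between the end frames: origins on a sine-bulged arc whose length
matches the chain contour, orientations from parallel-transported
tangent frames twisted at the rest rate.  The two families bulge through
opposite sides and carry opposite-signed out-of-plane excursions, so
optimization converges to the two chirality basins where they exist.
The original work obtained families by continuation from previously
solved loops, which are not available here; seeding both chiralities
recovers both basins without that history.  During spacing profiles the
two family tracks can merge at relaxed spacings where only one basin
exists; `jfactor_profile()` detects merged tracks (step-parameter RMS
below the deduplication tolerance) and re-seeds de novo at each
subsequent spacing until the second family reappears.

**Growth and protein uptake.**  `grow_loop()` adds base pairs one at a
time — each new residue copies the parameters of an existing free step
(the middle of the longest free run) — re-optimizing after every
insertion; the test suite checks that grown and de-novo optima agree to
0.1 kBT on unstrained loops.  `insert_protein()` ramps the step
parameters at the binding site linearly from their current values to the
footprint's fixed values over (by default) 5 increments, freezing the
partially deformed segment and re-optimizing the loop at every
increment; ramped and direct-frozen optimization agree to 0.1 kBT when
both converge.  Frozen steps are excluded from the energy and never
modified.

**Steric screen.**  Configurations in which two base-pair origins more
than 10 steps apart along the chain come closer than 18 Å (about one
duplex diameter) are discarded.  These two defaults are configurable;
they are deliberately coarse — base pairs are points, proteins have no
excluded volume — and serve only to reject self-intersecting pathways.

**Degenerate inputs.**  Boundaries farther apart than the chain contour
raise an infeasible-seed error; near-planar optimized loops (chirality
magnitude < 0.05) are classified `"planar"` with a warning rather than
assigned a family; extremum ties in profiles resolve to the smaller
spacing for determinism.

## Looping propensities

The relative looping propensity of a construct is the Boltzmann sum
`J = Σ exp(−ψᵢ/kBT)` over the feasible, sterically clear, deduplicated
states, and each state contributes the fraction `fᵢ = exp(−ψᵢ)/J`.
This J is relative: harmonic fluctuation corrections around the minima
are not computed, so only ratios and shapes are meaningful, and any
overlay on molar experimental J-factors requires one multiplicative
calibration constant.  Spacings may be half-integers; a spacing `sp`
maps to `floor(sp) + 1` base pairs with the residual half step absorbed
into the boundary end frame (experimental series advance in exact 1-bp
increments, so this affects only the absolute register, not the
spacing-to-spacing structure).

The twisted-wormlike-chain reference curve `wlc_jfactor()` is a
closed-form composite: a Shimada–Yamakawa-type ring-closure envelope
`1660.6 × (112.04/P³) l⁻⁵ exp(−14.055/l + 0.246 l)` mol/L (l = L/P),
multiplied by a Gaussian twist-phasing factor of period equal to the
helical repeat, with twist variance `kBT·L/C` summed over integer
linking offsets and normalized to average one over a period.  The
coefficient was validated against an independent Monte-Carlo estimate of
the same model's end-to-end closure density (a discrete Gaussian-rotation
chain, extrapolated to zero separation), which reproduces the closed
form to a few percent at l ≈ 3–4; order-one end-orientation alignment
factors are deliberately not included, consistent with use as a relative
reference.  The formula's domain is restricted to ≥100 bp, where the
approximation holds.

## The thermodynamic repression model

Reporter activity enters as the repression level
`RL = MU(no loop, −repressor) / MU(loop, +repressor)` and the normalized
level `RLn = RL(specific) / RL(nonspecific)`.  The looping J-factor
transform `J = (RL − RL_noloop)·[lacI]/(RL_noloop − 1)` (default
[lacI] = 100 nM) is exact and exactly invertible.

The fitted model treats looping as delivering extra local repressor
concentration at the proximal operator:

RL(sp) = RL_noloop + (RL_noloop − 1)·(K_NSL + K_max·e^(−ΔG_tw(sp)))

with `ΔG_tw(sp) = C_app/(2L)·(2πδ/hr)²/kBT`, where δ is the spacing
offset folded to the nearest helical register and L is the contour
carrying the twist strain.  This functional form is the unique
local-concentration model consistent with the J transform above — the
model-implied J is exactly `[lacI]·(K_NSL + K_max e^(−ΔG))`, periodic in
hr with amplitude `[lacI]·K_max` over a floor `[lacI]·K_NSL` — and with
the stated roles of the five parameters.  Alternative saturating
partition-function variants could fit comparably; conclusions drawn from
K-value comparisons should keep that in mind.  Three further
interpretive choices: `RL_noloop` is a fixed measured input (≈5 under
partial induction), not a fitted parameter, keeping exactly five
(series 1) / three (series 2) adjustable parameters; for series 1 the
twist strain is distributed over the variable loop itself (contour
= sp), while for series 2 it is distributed over the full fixed loop
(contour = 142.5 bp), which is why series-2 apparent torsional moduli
run lower; and fits are unweighted by default (inverse-variance weights
are available) since the appropriate weighting of replicate means is not
obvious.

Fitting is bounded Levenberg–Marquardt least squares (minpack.lm),
multi-started over a grid of helical repeats (10–11.5 bp/turn) crossed
with register offsets of the optimal spacing; the best-deviance solution
wins.  `sp_optimal` is identifiable only modulo hr and is reported
folded into the window `(max(sp) − hr, max(sp)]`.  Equilibrium constants
are bounded below by zero; when an estimate lands on that boundary its
confidence interval is reported one-sided.  Intervals are t-based from
the linearized covariance at the requested level (default 95%).

## The synthetic-data generator

`generate_rl_dataset()` draws replicate RL values around the model curve
with Gaussian noise on RL (default sd = 10% of the model value, the
scale of typical reporter error bars; six replicates per spacing,
matching standard colony counts) and reports per-spacing means and
standard deviations.  The default spacing grids are 131.5–146.5 bp
(series 1, operator–operator) and 85.5–100.5 bp (series 2,
protein-site–operator) in 1-bp increments.  Noise is applied on the RL
scale rather than on raw Miller units because replicate spread is
reported on that scale; the generator does not emulate colony-to-colony
covariance, day effects, or the enzymology of the assay, so parameter
recovery from these datasets demonstrates estimator correctness and
precision under idealized noise, not robustness to real-world
systematics.

The idealized footprints encode the two architectural hypotheses in
their simplest form: a 16-bp TALE footprint that is perfectly straight
with the 11.5-bp/turn repeat of TALE-bound DNA (stiffening without
deformation), and a 10-bp Nhp6A footprint with a 90° kink distributed as
roll over the three central steps — which carry zero twist, so the roll
axes stay parallel and the net inter-axis bend is exactly the nominal
kink — with net undertwisting relative to protein-free DNA.  The kink
split across three steps is a fixture choice mimicking distributed
bending in NMR ensembles, not a structural claim.  The toy repressor
boundary is a planar V: two frames 50 Å apart with helix axes tilted
30° apart, the far frame turned 180° so a smooth U-shaped loop connects
them.  It reproduces the *structure* of the real problem — four
orientation variants, two families, helical phasing of J with period
hr, J suppression by stiff footprints — but not the absolute extremal
spacings of any particular repressor geometry, which depend on the
actual crystallographic headpiece frames.

## Problem sizes and numerical settings

The shipped tests and the acceptance script use 60–90-bp loops,
23-point spacing profiles with a single boundary orientation (the
two-family structure is per-orientation, so phasing properties are
visible without the full eight-state ensemble), 400-chain Monte-Carlo
moduli estimates, a 200-replicate parameter-recovery study, and a
1.2-million-chain closure-density check — sizes chosen so the full
pipeline, including every optimization, runs in a few minutes on one
core while leaving comfortable statistical margins on every assertion.
The optimizer's continuation ladder, feasibility tolerances (0.05 Å /
0.05°), deduplication thresholds (0.5° / 0.05 Å RMS), and steric
defaults (18 Å / 10 steps) are as described above and are all
overridable through the `control` argument.  The default RNG seed used
by the generator is 20210903; all stochastic entry points take explicit
seeds.

## Known limitations

- J-factors are relative (no fluctuation determinants); absolute molar
  propensities require an external calibration constant.
- The repressor is rigid: headpiece opening/flexibility, DNA wrapping on
  the repressor, and protein–DNA binding free energies are outside the
  model.
- The elastic potential is sequence-independent, diagonal and harmonic;
  kinkable or anharmonic behaviour of strained DNA is not represented.
- The steric screen treats base pairs as points with a single cutoff.
- Classification of near-planar loops is ambiguous by construction and
  flagged rather than forced.
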