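---
title: "Modelling a special-purpose MD system-on-chip: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a special-purpose MD system-on-chip: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsoc)
```

# Scope

`mdsoc` is a software model of a dedicated molecular-dynamics machine:
512 system-on-chip nodes, each carrying 64 non-bonded force pipelines at
0.8 GHz, 64 general-purpose (GP) cores at 0.6 GHz, a shared global
memory with integer accumulate-on-write, and six network interfaces
forming an 8×8×8 torus. The package emulates the *numerics* of that
machine (what values the hardware would compute) and models its
*performance* (how long one timestep takes). It deliberately does not
model physical construction, electrical details, packet byte layouts or
cycle-accurate timing, which have no numerical consequence.

# The fixed-point arithmetic model

## Formats

Coordinates enter the pipeline as 32-bit fixed-point words. The package
maps positions box-relatively: one axis of the box spans the full word,
so the least-significant bit (lsb) is `L / 2^32` per axis. This is a
design choice — the machine documentation fixes only the word width —
and it maximises resolution while making the periodic wrap coincide
with integer wraparound (a position that rounds up to `2^32` lsb is the
box origin again). The box midpoint encodes to `2^31`, which in two's
complement is `-2^31`; decoding uses the unsigned-fraction convention
so the round trip errs by at most one lsb anywhere in the box.

Forces are accumulated as 32-bit integer words. The force lsb is
configurable; `default_force_format()` sizes it so the largest expected
pair force (Lennard-Jones at 0.9 σ plus the bare Coulomb force there)
spans about `2^20` lsb. That leaves `2^11` of integer headroom, enough
for the few hundred neighbours a particle has at liquid densities, and
makes the quantization noise of an n-term force sum at most `n·lsb/2`.

## Rounding and overflow

Quantization rounds half to even (base R's `round()`), which keeps
accumulation unbiased. Overflow wraps modulo `2^32` with a sticky flag,
hardware-adder style, rather than saturating; saturation would destroy
the order-independence that is the point of integer accumulation. The
stored word is always the exact modular sum, so any permutation of the
same terms yields a bit-identical result — the property that makes the
machine's parallel force reduction deterministic and that the package's
domain-decomposition test exploits (decomposed and flat paths must agree
bit-for-bit).

## Exact momentum conservation

Pair forces are quantized once per pair and applied as `+w` to one
particle and `-w` to the other, so pairwise contributions cancel
exactly in integer arithmetic. Bonded terms involve three or four
atoms whose double-precision forces sum to zero only to round-off; the
engine therefore quantizes all atoms of a term except the last and
assigns the last atom minus the integer sum of the others. This is the
natural hardware formulation (the third force is computed as the
negative sum) and makes the total force bank the zero word at every
step for any uncharged system. Reciprocal-space Ewald forces are
quantized independently and conserve momentum to the accuracy of the
mesh (see below), not exactly.

# The non-bonded pipeline

Each pair evaluation produces the Coulomb and van der Waals force and
both potentials in one pass. The Coulomb potential is
`k·q_i q_j·g_φ(αr)/r` with two selectable cut-off factors:

* **Gaussian kernel**: `g_φ(t) = erfc(t)`, the Ewald real-space screen;
  the force factor is then `g_c(t) = erfc(t) + (2t/√π)e^{-t²}` so that
  the force is exactly `-∇φ`.
* **Finite-support kernel**: the machine documentation names a second,
  compactly supported cut-off function without defining it. The package
  uses a quintic taper in `s = (t/t_c)²` — `1 − 10s³ + 15s⁴ − 6s⁵` —
  which is 1 at the origin and reaches 0 at the cut-off with two
  vanishing derivatives, so force and potential are continuous there.

The van der Waals term is 12-6 Lennard-Jones,
`4ε[(σ/r)¹² − (σ/r)⁶]`, the convention of the Amber-family force
fields the machine targets. Pair parameters come from a ≤64-entry
atom-type table through arithmetic or geometric means per parameter;
the default is Lorentz–Berthelot (arithmetic σ, geometric ε). The
soft-core option uses the Beutler-style shift
`r⁶ → r⁶ + α_sc(1−λ)σ⁶` scaled by λ, which reduces exactly to plain
Lennard-Jones at λ = 1 and stays finite at contact otherwise.

## ROM function tables

The hardware evaluates its fixed function forms from read-only tables.
The emulator models these as segmented quadratic fits, each segment
interpolating the function at its endpoints and midpoint. Two layout
choices matter:

* **Segment count.** 4096 segments (a few tens of kilobytes of table,
  plausible for an on-die ROM) hold the relative error of `erfc` on
  `[0, 6]` below 4.4×10⁻⁸ and of the reciprocal square root below
  10⁻⁹ — within the single-precision tolerance (1.2×10⁻⁷) the pair
  evaluation is specified to meet. Substantially fewer uniform
  segments cannot reach that tolerance at the far end of the erfc
  domain, where the function decays like `e^{-t²}` and relative
  accuracy is hardest.
* **Spacing.** Power-law kernels (`r⁻¹`, `r⁻¹²`) are tabulated on
  geometrically spaced segments with a logarithmic local variable,
  which makes their relative error flat across decades; `erfc` uses
  uniform spacing.

With tables in the path, the pipeline's force error against a
double-precision oracle is ~5×10⁻⁹ RMS over random pairs, comfortably
inside the 10⁻⁶ target that mirrors "single-precision-grade" hardware.

## Blocks and broadcast

`eval_block()` reproduces the dispatch granularity: up to 16 particles
on each side, every (i, j) pair evaluated once, partial forces reduced
inside the block before a single accumulate-on-write per particle.
Because the bank arithmetic is integer, any partition of the pair list
into blocks gives bit-identical totals — asserted in the tests.

# Gaussian-split Ewald

The Coulomb sum is split by `α`: pairs interact through
`erfc(αr)/r` inside the cut-off (the real-space correction insists on
`erfc(α r_c) < 10⁻⁷` so the discarded tail is negligible), and the
remainder is solved on a mesh. In the k-space-split variant implemented
here, charges are spread with a spherical Gaussian of width `σ_s`
(assignment), the same kernel interpolates potentials back to the
particles (the adjoint), and the factor that tops the two spreads up to
the full splitting width `1/(√2α)` is folded into the reciprocal-space
Green's function `4π/k²` together with the tinfoil `k = 0` zeroing.
This requires `σ_s² < 1/(4α²)`; the constructor enforces it.

Numerical choices, each of which was driven by a measurable failure
mode:

* **Spread width floor.** `σ_s` defaults to half the splitting width
  but never below 1.45 mesh spacings. Below that floor the Gaussian is
  under-resolved on the mesh and the aliasing error — invisible in the
  energy at the 10⁻⁴ level — shows up as a violation of momentum
  conservation in the interpolated forces at the 10⁻⁴·RMS level.
  At 1.45 h the net reciprocal-space force stays below 10⁻⁸ of the RMS
  force.
* **Smoothly truncated kernel.** The spreading Gaussian is truncated at
  `7σ_s`. A hard truncation makes node inclusion discontinuous in the
  particle position, and the resulting surface error again breaks
  momentum conservation (at ~10⁻⁴·RMS for a 5σ cut). The package
  subtracts the tangent line in `r²` at the cut radius, making the
  kernel C¹ with value and slope zero at the edge; the back
  interpolation differentiates this exact kernel, normalization
  included.
* **Per-particle renormalization.** Truncated weights are rescaled to
  sum to one, so the mesh receives exactly the total particle charge
  (conservation to 10⁻¹⁵ relative in practice).
* **Nyquist modes.** The unpaired `k = N/2` modes of even-sized axes
  have no negative partner and are dropped from the Green's function;
  their Gaussian weight is negligible by construction and keeping them
  breaks the ±k symmetry that momentum conservation rests on.

Against a direct Ewald oracle (explicit image and k-space sums) the
mesh solver agrees to ~2×10⁻⁵ relative on random neutral systems, is
invariant to a factor-2 change of α at matched mesh resolution to the
same level, and recovers the rock-salt Madelung constant
(−1.747565/a per ion pair) to a few 10⁻⁶ — all asserted at the looser
documented tolerances (10⁻⁴, 10⁻³) in the tests.

# Bonded forces and the FLOP model

Energies follow the Amber conventions without ½ factors:
`K_b(r−r₀)²`, `K_θ(θ−θ₀)²`, `Σ_n V_n(1+cos(nφ−γ))`. Forces are the
exact analytic gradients; angle and torsion terms clamp cosine
arguments to `[−1+10⁻¹², 1−10⁻¹²]` so forces stay bounded near
collinear degeneracies (an exactly collinear torsion contributes
nothing, since the dihedral is undefined there). Each term is
translation- and rotation-invariant: net force and net torque vanish to
round-off, and five-point central differences confirm the gradients to
10⁻¹⁰ relative.

The cost model weighs operations as add = mul = 1 and
rsqrt = cos = acos = 10. Per interaction: bond stretching
12 + 9 + 10 = 31 FLOP; angle bending 34 + 42 + 40 + 10 + 10 = 136 FLOP.
The torsion row of the source cost table cannot be parsed into
unambiguous per-operation tallies, so its printed per-interaction total
(183.84, an average over torsion periods) and multiplicity (3.9) enter
the model directly. Per-atom contributions are each rounded to one
decimal *before* summation — 31.0, 244.8, 717.0 — because that is the
only reading that reproduces the printed 717.0 and the 992.8 per-atom
total exactly.

# Torus network model

Nodes carry six directed links; type I packets route dimension-ordered
(X→Y→Z) along per-axis shortest wraps, so hop counts equal graph
distances (checked against BFS). Type II packets implement the 26-chip
neighbourhood scatter in three programmable forwarding stages. The
shipped forwarding table is a design choice constrained by three facts:
stages must first-reach 6, then 12, then 8 chips; all 26
Chebyshev-distance-1 neighbours must be covered; and exactly two chips
receive a redundant copy. The table that satisfies this: stage 1 sends
on all six directions; stage 2 forwards ±x arrivals to ±y, ±y to ±z
and ±z to ±x (each edge neighbour reached once); stage 3 forwards ±y
arrivals to ±z (the eight vertices) plus +z arrivals to +x (the two
redundant receptions). The table is config-overridable, as the hardware
register is programmable. Type III packets travel a line with a
decrementing hop count and reduce integer payloads into the terminal
node's memory through the same accumulate-on-write model, inheriting
its order-independence.

The link model is `lanes × rate × 0.8 (8b/10b) / 8` bytes/s — 7.2 GB/s
for the 12-lane 6 Gbps default — and the latency model is the measured
affine fit `T(ns) = 600 + 450·N_hop + 200·D/128`. Packet contention is
not modelled, matching the machine's own published estimates.

# Performance estimator

The estimator composes per-stage times for one timestep of the default
workload (50 k atoms, 100 per node, 32³ mesh, 64-node FFT
decomposition):

* pipeline stages: `count / (64 × 0.8 GHz × 30%)` — charge assignment
  and back interpolation (100×1728 particle–mesh interactions each,
  11.25 µs) and the non-bonded stage (100×100×63 half-stencil
  interactions, 41.0 µs);
* GP stages: bonded forces at `992.8 FLOP/atom / (0.6 GHz × 20%)`;
* communication: the latency model at 3 hops with 6 (particle) or 3
  (force) words per atom;
* Poisson: per 3D FFT, three 1D-FFT rounds (one 32-point transform per
  core, `2.5·N·log₂N = 400` FLOP, 3.3 µs) interleaved with two 4-hop
  64-word transposes (2.5 µs each), forward and inverse, plus a mesh
  gather and scatter — 36.4 µs in total.

The FFT FLOP convention `2.5·N·log₂N` is the real-transform count; it
is adopted because it reproduces the published 400 FLOP at N = 32,
which the complex-transform convention (5·N·log₂N) does not.

Two published figures do not follow from the machine's own stated
arithmetic, and the estimator reports rather than resolves them: the
non-bonded stage evaluates to ≈41 µs from the printed counts and 30%
efficiency against a published 30 µs estimate, and the bonded-stage
phrase "two atoms in 8.3 µs" is inconsistent with
2×992.8/0.12 GHz = 16.5 µs (8.27 µs matches *one* atom). The
`time_breakdown` carries both readings in its `notes`. The critical
path composes stages along the step schedule — distribute, then the
long-range chain (charge assignment → Poisson → back interpolation) in
parallel with non-bonded and bonded work, then gather and update —
taking maxima across parallel branches; the long-range chain dominates
and the default workload lands at ≈66 µs, consistent with the
published "hard to beat 50 µs" bound.

# The MD engine and synthetic systems

Internal units are Å, fs, amu, elementary charge and kcal/mol
(acceleration conversion 4.184×10⁻⁴, Coulomb constant 332.0637 when
requested). Integration is leap-frog, microcanonical only — the
modelled machine lists constraints and temperature/pressure coupling as
future work, so the engine omits them. Non-bonded exclusions cover 1-2
and 1-3 bonded pairs; 1-4 exclusion is a generator flag (default off)
since the source is silent on scaling policy. Cell assignment uses
half-open intervals and 0-based indices; the half stencil over the
26-cell shell enumerates every within-cutoff pair exactly once, with
deduplication handling the aliasing of very small grids.

The generators define the study conditions used throughout the tests:

* `lj_fluid` — argon-like parameters (σ = 3.4 Å, ε = 0.238 kcal/mol,
  m = 39.948 amu) on a jittered cubic lattice at a liquid-like reduced
  density (0.0125 Å⁻³ ≈ 0.49 σ⁻³ in the energy-conservation runs),
  Maxwell–Boltzmann velocities at 110 K with net momentum removed.
  The conservation benchmark uses 256 atoms for 500 steps at dt = 1 fs
  with the cut-off at 0.45 box lengths (≈3.6 σ): a plainly truncated
  potential steps by the cut-off energy whenever a pair crosses it, so
  the cut-off must be deep enough that those steps stay below the 10⁻³
  drift target.
* `salt_lattice` — ±1 charges on a rock-salt grid (even cube counts
  only, so the charge alternation is consistent across the periodic
  wrap); the Madelung benchmark.
* `toy_polymer` — a single zig-zag chain (r₀ = 1.53 Å, θ₀ = 111°,
  threefold torsions) with matching exclusions; exercises every bonded
  term and the exact-zero-sum quantization.

What these synthetic systems do *not* emulate: heterogeneous force
fields, water models, real charge distributions, or system sizes
anywhere near the machine's 50 k-atom operating point. Passing tests
therefore demonstrate the correctness of the arithmetic model and the
internal consistency of the performance model at desk scale, not the
machine's published hardware throughput, which is unreproducible in
software by design.

# Known limitations

* Network contention and multi-packet scheduling are not modelled; the
  latency model applies to isolated transfers.
* The reciprocal-space force path conserves momentum to mesh accuracy
  (≤10⁻⁸ of RMS under the defaults), not bit-exactly like the pair
  path.
* The distribute/gather stage estimates come from single evaluations of
  the latency model; the machine's own 5 µs / 4 µs figures evidently
  assume several sequential transfers whose count is not published, so
  they are not reproduced.
* Pure-R inner loops cap practical system sizes at a few hundred
  particles; the package is an emulator for studying the machine's
  numerics, not a production MD code.
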