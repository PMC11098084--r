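---
title: "The button-barcode model of homolog pairing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The button-barcode model of homolog pairing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`chrompair` simulates the recognition of homologous chromosomes by purely
nonspecific adhesion. Each chromosome arm is a bead--spring worm-like chain of
`nodes_per_arm` beads joined by Hookean springs of rest length 1 (one *length
unit*, lu, nominally 0.2 µm of chromatin). A subset of beads are *buttons*:
adhesive sites, all molecularly identical, any of which may bond reversibly to
any other button, on any chain. Chromosome identity is carried entirely by the
*spacing pattern* of the buttons — the barcode. When two chains with identical
barcodes lie side by side, every button can reach its opposite number with the
intervening chain segments at their rest lengths; aligning chains whose
barcodes differ forces one or both chains to stretch or compress, an elastic
cost of several kBT per system (computable with `discrimination_energy()`).
That energy difference, not any molecular specificity, is the source of
selective homolog pairing.

The energy of a configuration is

* stretch: ½ k_spring (d − 1)² per backbone bond of length d;
* bending: ½ k_bend |x_i − (x_{i−1}+x_{i+1})/2|² per interior bead — a
  midpoint-deviation penalty that straightens the chain. For unit bonds this
  equals (k_bend/4)(1 − cos θ) per joint to leading order, so the persistence
  length is approximately k_bend/4 lu;
* pairing: ½ k_pair d² per formed button--button bond (zero rest length);
* confinement: ½ k_confine (|x| − R)² for beads outside the nuclear sphere of
  radius R;
* tether: ½ k_tether dist(x, cap)² for each centromere (bead 0), where the cap
  is the spherical envelope patch of chord radius `rabl_patch_radius` around
  the +z pole. Clustering the centromeres in this cap creates the Rabl
  orientation: centromeres at the top of the nucleus, telomeres toward the
  bottom, so every locus acquires a characteristic vertical position.

Forces are the exact negative gradient of this energy (verified by
finite differences in the tests). Dynamics are overdamped Langevin
(Euler--Maruyama):

x ← x + (dt/γ) F + sqrt(2 kBT dt/γ) η,   η ~ N(0, I₃),

with kBT = 1 and γ = 1 defining the energy and time units.

Pairing kinetics run once per iteration, before the position update. Every
existing bond breaks independently with probability `p_unpair`; then all pairs
of free buttons closer than `capture_radius` bond greedily in order of
increasing distance (ties by chain/button index), one bond per button, with no
specificity of any kind — homologous, non-homologous and cis (same-chain)
contacts bond under identical rules. Distance-ordered capture approximates
diffusion-limited binding and keeps the update deterministic given positions;
contact formation probability is 1, so reversibility is controlled by the
single knob `p_unpair`, and cis bonds are allowed (they count as *incorrect*
pairing in all metrics).

## Parameters, units and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `nodes_per_arm` | 28 | beads | smallest arm that fits all preset layouts (see below) with contour ≈ nuclear diameter |
| `k_spring` | 50 | kBT/lu² | bond-length σ = 0.14 lu; stable under dt (see below) |
| `k_bend` | 20 | kBT/lu² | persistence length ≈ k_bend/4 = 5 lu = 1 µm, the standard chromatin stiffness used for most runs |
| `k_pair` | 25 | kBT/lu² | bond well a few kBT deep at sub-lu extension |
| `k_confine`, `k_tether` | 50 | kBT/lu² | soft-wall penalties of the same order as the backbone |
| `nucleus_radius` | 12 | lu | 2.4 µm; arm contour 27 lu spans the 24-lu diameter in Rabl orientation |
| `rabl_patch_radius` | 3 | lu | small cap → strong centromere clustering (Rabl correlation ≈ −0.9); 24 (= 2R) disables the tether |
| `capture_radius` | 1 | lu | contact distance; below the 2-lu rest separation of adjacent cis buttons |
| `p_unpair` | 0.8 | per iteration | the reversibility that maximizes fidelity in the scan |
| `dt` | 0.005 | γ·lu²/kBT | stability, see below |
| `n_steps` | 300000 | iterations | standard run length; ≈ one hour of nuclear time (`steps_per_hour`) |
| `burn_in` | 5000 | iterations | pairing disabled while the initial geometry relaxes |
| `length_unit_um` | 0.2 | µm/lu | documentation constant only |

**Time step.** The Euler--Maruyama update is stable only if dt·λ_max/γ < 2,
where λ_max is the largest eigenvalue of the energy Hessian. For a chain the
stiffest longitudinal mode approaches 4·k_spring, bending contributes up to
≈ 4·k_bend, and a pairing bond 2·k_pair, so with the defaults
dt·λ/γ ≤ 0.005·(200 + 80 + 50) = 1.65 < 2. Stiffer choices (say k_spring = 100
with dt = 0.01) put the two-bead relative mode exactly at the stability
boundary, where its variance diverges; the defaults were chosen to keep every
mode clearly inside the stable region while leaving bond-length fluctuations
(σ = sqrt(kBT/k_spring) = 0.14 lu) small against the capture radius. Blow-up
is detected and reported rather than silently clipped.

**Arm length.** The preset experiments impose hard geometric constraints:
13 randomly placed buttons at the 2-node minimum gap need ≥ 25 nodes; the
industrial 2-of-5 digit (five gaps, two wide of 6 nodes, three narrow of 2)
spans 19 nodes and should cover most of the arm; a 12-node barcode patch
(nodes 0–11) shifted distally by 12 nodes must stay in range. 28 nodes is the
smallest round geometry satisfying all of them, and it keeps the contour
(27 lu) comparable to the nuclear diameter (24 lu) so that a tethered arm
spans the nucleus — the regime in which the Rabl gradient orders loci
vertically. With much longer arms at the same nucleus the chains crumple,
genomic position decorrelates from height, and homologs frequently trap in
antiparallel registers; that regime defeats any spacing code and is
deliberately outside the defaults.

## Fidelity conventions

A button is *chromosome-correct* if bonded to any button of its homolog, and
*locus-correct* if bonded to the same-index node of its homolog. Unpaired
buttons, cis bonds and bonds to non-homologs are incorrect in both modes, and
the denominator is always the total button count. Both modes are computed for
every run; scenario summaries use chromosome mode — matching the definition
"fraction of loci paired to the correct homolog" used by the uniform-spacing,
random-code and industrial-barcode experiments — except the multi-chromosome
scan (`fig7`), whose question is specifically about same-index pairing and
which therefore uses locus mode. For nonuniform codes the two modes nearly
coincide; for uniform whole-arm codes chromosome mode is noticeably higher
because regularly spaced buttons can pair with the correct homolog shifted
out of register — a failure mode of uniform codes, not of the metric. The
chance floor with `n_pairs` homolog pairs is `1/(2·n_pairs)` (0.25 for two
pairs): each button faces one correct chromosome among homolog, non-homologs
and its own chain in cis.

`final_fidelity()` averages the last 10% of recorded frames; the run length
is the quantity that sets how close an ensemble is to its plateau.

## What the simulator emulates — and what it does not

The generator of all test and acceptance data is the simulator itself: chains
initialized with centromeres scattered on the Rabl cap and arms grown toward
the −z pole at rest length (serpentine-folded if they would exit the sphere,
then relaxed during burn-in), followed by the alternation of pairing kinetics
and Brownian steps. It emulates the features the model needs: thermal chain
motion with a tunable persistence length, nuclear confinement, centromere
clustering, and reversible nonspecific adhesion. It does **not** represent
excluded volume (chains are phantom), hydrodynamics, loop extrusion,
heterochromatin blocks, replication, or any molecular identity of the
adhesive sites; passing tests therefore show that spacing codes suffice for
selective pairing *in this physical regime*, not that real chromosomes use
them. The mapping of iterations to wall-clock time is a single documentation
constant (`steps_per_hour`, one standard run ≈ one hour of nuclear time) and
affects no computation.

## Numerical choices

* **RNG.** Chain initialization uses R's RNG (`set.seed(cfg$seed)`); the
  compiled inner loop draws from a xoshiro256++ stream seeded from R's RNG, so
  every trajectory is bit-reproducible from the single config seed. Normals
  come from Box--Muller; an inversion-method normal per coordinate per step
  would dominate the runtime at ensemble scale.
* **Greedy formation ties** are broken by (chain id, button index)
  lexicographic order, making the kinetics deterministic given positions.
* **Relaxation** in `discrimination_energy()` is plain gradient descent with
  step 1/λ_max to a maximum-force tolerance of 1e-6, from straight aligned
  chains in free space (no confinement or tether, so the result is the
  intrinsic deformation cost). Identical codes relax to exactly zero; rank
  pairing handles unequal button counts, leaving surplus buttons unbonded.
  Descent finds the local minimum reachable from the aligned start, which is
  the physically relevant branch for in-register pairing.
* **Persistence length** is fitted as log⟨cos θ(s)⟩ = −s/Lp through the origin
  over the leading separations with ⟨cos θ⟩ > 0.1. Two degenerate regimes are
  flagged: if ⟨cos θ(1)⟩ ≤ 0.1 the estimator returns the freely jointed floor
  of 0.5 lu (half the link length) with a warning; a flat decay returns a
  value at least the contour length with flag `"rigid"`.
* **Degenerate inputs.** Chains need ≥ 2 nodes; coincident bonded nodes give
  zero spring force (undefined direction); a centromere exactly at the origin
  maps to the cap pole; fidelity on a frame with no buttons is an error, and
  an empty bond set gives fidelity 0.

## Design choices that were genuinely open

* **Bending as midpoint deviation** rather than an angular cosine potential:
  it matches the "deviation of the chain shape from a straight line"
  formulation, is exactly harmonic (stable and gradient-consistent), and its
  k_bend → Lp map is established empirically by the estimator; the scan
  figures are functions of measured Lp, so the choice does not affect them.
* **One-to-one bonds.** Whether many-to-one button contacts are allowed is
  unstated in the underlying model description; exclusivity is assumed here
  and is required for the fidelity metric to be well defined.
* **Burn-in** (5000 steps without pairing) avoids initialization artifacts —
  bonds formed between chains that happen to be placed adjacently — that the
  model description does not discuss. It is configurable.
* **Heterozygous vs homozygous rearrangements**: a shifted or translocated
  code applied to one chain of a pair (heterozygous) or both (homozygous) is
  expressed by supplying per-chain barcodes; the translocation operation takes
  explicit node ranges, so both the "quarter patch" and "third of the patch"
  readings of partial swaps are expressible.
* **2-of-5 digit table**: the standard industrial symbology (digit 0 = NNWWN,
  1 = WNNNW, …), stored as explicit data. Any consistent ten-word table with
  exactly two wide bars of five preserves every qualitative claim.
* **Barcode gap floor**: constructors enforce a 2-node minimum gap so adjacent
  cis buttons rest outside the capture radius; the button/gap *inversion*
  variant deliberately violates this (consecutive-button tracts are its
  point), so editing operations validate with a 1-node floor.

## Problem sizes used by the tests and the acceptance script

Ensemble results are means over ≥ 10 independently seeded runs (the standard
figure scale is 30) of 300,000 iterations; the package runs a two-pair,
28-node-arm system at roughly 3–4 s per 300k-iteration run, so the shipped
test suite uses 10–20 runs per condition and the acceptance script 10–30 —
deliberately reduced ensembles whose SEMs are reported alongside the means.
The persistence-length run records 1,000 post-burn-in frames of a single
untethered pair. Full 30-run reproductions of every figure are available
through `run_scenario()` with default arguments.

## Known limitations

* Near the reversibility optimum the p_unpair grid points 0.4–0.8 differ by
  less than their ensemble SEMs at 10–16 runs; the argmax of a reduced scan
  is statistically soft even though p_unpair = 0 is always clearly worst.
* Uniform whole-arm codes show genuine run-to-run bistability (in-register vs
  shifted register), so their locus-mode fidelity has high variance by nature.
* The Euler--Maruyama integrator has O(k·dt) bias in stationary variances;
  distribution-level checks (Boltzmann bond lengths) are run at small k·dt
  where the bias is below statistical resolution.
* Without excluded volume, "paired" chains interpenetrate freely; pairing
  levels should be read as contact statistics, not condensed structures.
* With the centromere tether released, mean fidelity settles around 0.3-0.4
  rather than at the 0.25 chance floor: in a nucleus whose diameter is
  comparable to the arm contour, chains still meet by diffusion and the
  spacing code retains some discriminating power. A handful of no-Rabl runs
  pair well; most sit at or below chance.
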