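---
title: "Unbiased ensemble sampling of closed kinematic loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbiased ensemble sampling of closed kinematic loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(slikmc)
```

## The problem

Protein loops are flexible segments whose two ends are covalently anchored to
a structured scaffold.  Sampling loop conformations therefore means sampling
from a probability density restricted to a nonlinear implicit manifold: the
set of backbone dihedral assignments for which the terminal frames coincide
with the fixed anchors.  Standard Metropolis–Hastings moves in dihedral space
hit that manifold with probability zero, discrete search builders scale
exponentially with loop length, and plain inverse-kinematics (IK) samplers
close the loop exactly but with an uncontrolled, biased distribution.

`slikmc` implements a sub-loop inverse kinematics Monte Carlo sampler: a
blocked Gibbs sampler whose block moves close the loop exactly by analytical
IK, accepted by a Metropolis–Hastings rule whose proposal density is computed
*exactly* on the constraint manifold.  The stationary distribution is then
provably the target score, in the large-sample limit, without any tuning of
the proposal machinery.

## The model

Structural preferences are a sparse factored score over an *expanded state*
`x = (q_1..q_N, T_0..T_N, p_1..p_M)` holding the torsion angles, every link
frame and every backbone atom position:

\[ \Phi(x) \;=\; \prod_i \phi_i(S_i), \]

where each factor `phi_i` is non-negative and touches only a handful of
variables `S_i`.  Built-in factors are

* Ramachandran priors `phi(phi_r, psi_r)` per residue (piecewise-constant
  grids over the torus; bilinear interpolation optional),
* B-factor restraints: isotropic Gaussians on atom positions whose variance
  is `B_j c^2` with the crystallographic B-factor `B_j` and a user confidence
  scale `c` (the printed one-dimensional normaliser is kept even though the
  displacement is three-dimensional; as all acceptance computations use
  ratios, the constant cancels — it is flagged here rather than silently
  redefined),
* binary steric clashes with per-element van der Waals radii scaled by an
  overlap tolerance (default 0.75), evaluated through a spatial hash grid
  whose answer is identical to the exhaustive pair check,
* backbone-dependent rotamer mixtures for side-chain torsions,
* generic energies via the Gibbs measure `Phi = exp(-E/T)`.

Because frames are explicit state variables tied to their neighbours by
deterministic kinematic factors (`T_j = T_{j-1} T^{rel}_j R(a_j, q_j)`),
every factor stays local and a block move re-evaluates only the factors
whose domain intersects the block.

## Block moves on the closure manifold

A block is a window of `b` consecutive angles (default: 4 residues, `b = 8`)
with both flanking frames held fixed.  The first `b - 6` angles (`b - 3` in
the plane) are the *independent* subchain `y`, drawn from a proposal prior
`P(y)`; the remaining 6 (3) *dependent* angles `z` are solved by analytical
IK so the block's terminal frame lands exactly on its anchor.  A 6-angle
problem has a finite solution set (0 to 16 solutions); one branch is picked
uniformly at random.  Overlapping blocks at stride one residue are visited in
a configurable order (forward, backward or random — the order does not
change the stationary law).

The candidate is accepted with probability
`min(1, Phi_B(x') Q_B(x|..) / (Phi_B(x) Q_B(x'|..)))`, where the proposal
density with respect to the manifold volume measure is

\[ Q_B \;=\; \frac{P(y)}{s\,\sqrt{\det G(y)}}, \qquad
   G(y) \;=\; \Big(\tfrac{\partial f}{\partial y}\Big)^{\!T} W
              \Big(\tfrac{\partial f}{\partial y}\Big), \]

with `s` the IK solution count at `y` and `f` the chart mapping `y` to the
full block state (independent angles, dependent angles via the implicit
function theorem `dz/dy = -(dC/dz)^{-1} dC/dy`, and all intervening frames by
the chain rule).  Both the forward and the reverse move are evaluated — the
reverse solution count is recomputed at the retained state, which exact
detailed balance requires.  IK failure (no closure for the sampled `y`) and
chart singularity (`dC/dz` with reciprocal condition number below `1e-10`)
count as rejections; both leave the reverse density well defined.

Free-endpoint chains use the same closure blocks in their interior and a
standard symmetric Gaussian random walk (default 1 degree per angle) for the
terminal block.  Planar structures with several anchored branches (trees
with rings) are sampled as one block: branches are closed in topological
order, `s` is the product of the per-branch counts, and `G` comes from the
stacked multi-constraint implicit Jacobian.

### The weighting matrix W

The rows of the chart Jacobian mix radians (angles) with Angstroms (frame
origins), so the metric depends on a diagonal weighting `W`.  The default
weighs angle rows and frame-origin rows by 1 and frame-orientation rows by 0
(orientation information is already carried by the angle rows; weighting it
again would double-count rotational units).  `W` is fully configurable
through `sampler_config(w_angle=, w_frame_pos=, w_frame_rot=)`; the target
measure on the manifold is the `W`-volume measure, so changing `W` changes
the meaning of "uniform on the manifold" — all documented checks use the
default.

### The proposal prior P(y)

`P(y)` appears explicitly in `Q`, so any full-support choice leaves the
stationary distribution unchanged; it only affects mixing.  Planar studies
use the uniform prior.  For backbones the closure workspace of a 4-residue
block is narrow — redrawing `(phi, psi)` globally from a Ramachandran
marginal closes the loop only rarely — so the default protein proposal is a
mixture: with probability 0.7 a wrapped-Gaussian local step (5 degrees), else
a global redraw from the residue's Ramachandran marginal.  The mixture
density is evaluated exactly in the acceptance ratio (the local component is
conditioned on the move's starting point, so the reverse density is
evaluated at the candidate).

### Numerical choices

* Spatial 6-angle IK: damped Gauss–Newton continuation on the frame-error
  residual (rotation-vector orientation error, exact `d log` Jacobian) from
  batches of random seeds, stopping when consecutive batches stop producing
  new roots; roots deduplicated at `1e-4` rad and polished to `1e-10`.  This
  general-geometry root enumeration was chosen over closed-form polynomial
  formulations because those cover only backbone-like axis arrangements,
  while the same solver here serves arbitrary chains; completeness is
  probabilistic but in randomized audits (150-1000 problems) the generating solution
  was recovered every time with at most 12 roots observed.
* Planar 3-angle IK is closed form (two elbow branches).
* Closure tolerance `1e-8`; every emitted conformation is validated against
  it.  Chart determinants via Cholesky in log space.
* Blocks of `b <= 6` spatial angles cannot mix (the closure solution set is
  finite, and for `b <= 5` generically just the current state); the sampler
  refuses them unless `allow_small = TRUE` (used to demonstrate the
  non-mixing regime).
* One seeded random stream drives everything; a run is reproducible
  bit-for-bit from its config.

### A note on the 1/s factor in planar chains

For planar blocks the dependent subchain always has exactly 0 or 2 IK
solutions, so `s = 2` almost everywhere on the manifold for both move
directions and the `1/s` factors cancel from the acceptance ratio: omitting
them produces a bit-identical Markov chain.  The factor is *not* cosmetic in
general — spatial 6-angle problems have 0..16 solutions and the counts vary
across the manifold — but no planar experiment can detect it.  The
diagnostic switches `drop_metric` and `drop_solution_count` in
`sampler_config()` omit the corresponding terms; dropping `sqrt(det G)`
visibly biases planar stationary distributions (the package's acceptance
suite demonstrates this with an energy-distance test against rejection
sampling), while dropping `1/s` on a planar testbed provably cannot.

## Side chains

Side-chain torsions are drawn directly from backbone-dependent rotamer
priors: each `(phi, psi)` bin holds a Gaussian mixture over the chi angles;
a component is picked by weight and the chi vector sampled from it.  Because
the proposal equals the prior factor, the combined backbone + side-chain
move accepts with exactly the backbone acceptance probability when the side
chains are clash-free and zero otherwise.  B-factor restraints are not
applied to side-chain atoms (they would freeze the chain).  Non-rotameric
terminal chi angles are handled with the same mixture machinery — an
approximation, since their empirical distributions are asymmetric.

## What the synthetic fixtures emulate — and what they do not

All tests run on generated inputs: anchored equal-link planar chains
(initialised on a circular arc), free chains with Gaussian position priors,
three-anchor planar trees, and ideal-geometry poly-alanine/poly-arginine
mini-proteins written as valid PDB files with synthetic B-factors.  These
reproduce the *mathematical* structure of the application — closure
manifolds, factored priors, clashing side chains — but not real data
features: heterogeneous covalent geometry, electron-density-derived
B-factor patterns, sequence-dependent Ramachandran statistics, solvent and
crystal contacts.  Passing tests therefore certify the sampler's statistical
correctness and its interfaces, not prediction quality on real proteins.

Loop rebuilding (`cli_complete()`) discards the loop conformation found in
the input file, seeds from a random clash-free closure and perturbs it
towards the priors; the input must contain *some* coordinates for the loop
residues (any provisional model — only the covalent geometry is kept).
Rebuilding without any provisional coordinates would require modelling ideal
geometry across the gap and is out of scope.

## Problem sizes used by the checks

The test-suite runs are sized for a desk-scale machine: the planar
stationarity comparison uses a 5-angle closed chain, a `1e6`-step run for
the correct sampler, `4e5`-step runs for the negative controls and 1200
rejection-oracle samples; mixing uses a 20-link chain over 20,000 sweeps
thinned by 40; the IK audit uses 150 random 6-angle problems in the test
suite and 1000 in the acceptance script; the scaling comparison uses free
chains of 10/20/30 links with 4000 sweeps each.  The branched two-ring
comparison runs 150,000 whole-structure moves thinned to ~330 samples.

## Known limitations

* Large-scale conformational transitions that must cross low-score regions
  mix slowly — block moves are local by design.  No annealing or restart
  scheme is included.
* Multiply-closed (branched) sampling is planar only.
* The spatial IK solver's completeness is statistical, not certified; the
  solution-count term in `Q` is therefore an estimate in pathological
  geometries (never observed to miss in the audits above).
* Bond lengths and angles are rigid; only torsions move.

## A short worked example

```{r example, eval = FALSE}
fx <- make_planar_chain(20, anchor_dist = 10)       # anchored 20-link chain
cfg <- sampler_config(b = 4, n_samples = 2000, skip = 40, seed = 1)
ens <- run_sampler(fx$chain, fx$state, fx$fg, cfg)  # uniform prior
ens
mixing_report(ens)
```

For proteins, `cli_sample()` wraps loading a PDB loop, assembling
Ramachandran/B-factor/clash factors and writing a multi-MODEL ensemble; see
the README for a complete run with its printed output.
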