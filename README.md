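# slikmc

Statistically unbiased conformation ensembles of closed kinematic loops —
protein backbone loops and planar articulated chains — sampled from sparse
factored priors.

## The problem and who this is for

A loop's two ends are fixed by the surrounding structure, so its admissible
conformations form a nonlinear implicit manifold in torsion space.
Ensemble-generation tasks (loop flexibility analysis, missing-segment
completion, decoy generation) need *many* conformations drawn from a
*controlled* distribution on that manifold — not a single optimised model,
and not whatever distribution an inverse-kinematics sampler happens to emit.
`slikmc` is for structural-bioinformatics users who want exactly-closed loop
ensembles whose statistics match a declared score, and for methods people
who want the manifold-MCMC machinery (charts, metric tensors, multi-branch
closure) as reusable parts.

## The method

The target is a sparse factored score over torsions `q`, link frames `T` and
atom positions `p`:

    Phi(x) = prod_i phi_i(S_i),    x = (q_1..q_N, T_0..T_N, p_1..p_M)

with Ramachandran, B-factor (Gaussian with variance `B c^2`), steric-clash
and rotamer factors built in.  A blocked Gibbs sampler updates overlapping
windows of `b` consecutive torsions (4 residues, `b = 8`, by default): the
independent `b-6` angles `y` are drawn from a proposal prior `P(y)`, the
dependent 6 angles are closed exactly by analytical inverse kinematics (one
of the `s` solution branches picked uniformly), and the move is accepted
with the Metropolis–Hastings probability using the *exact* proposal density
on the manifold,

    Q_B = P(y) / ( s * sqrt(det G(y)) ),    G = (df/dy)' W (df/dy),

where `f` is the chart from independent angles to the full block state (the
dependent-angle sensitivity comes from the implicit function theorem) and
`W` a diagonal weighting.  The `sqrt(det G)` and `1/s` corrections are what
make the stationary distribution equal `Phi` on the manifold; the package
ships diagnostic switches that omit them and statistical tests that show the
resulting bias.  Free-endpoint chains and planar multiply-closed (branched)
structures are supported; side chains are drawn from backbone-dependent
rotamer mixtures with a clash veto that provably preserves the backbone
acceptance probability.

## Worked example

An anchored 20-link planar chain with a uniform prior (every emitted state
closes the loop to 1e-8):

```r
library(slikmc)
fx  <- make_planar_chain(20, anchor_dist = 10)
cfg <- sampler_config(b = 4, n_samples = 2000, skip = 40, seed = 1)
ens <- run_sampler(fx$chain, fx$state, fx$fg, cfg)
ens
#> <slik_ensemble> 2001 samples x 20 angles; acceptance 0.338 (34000 block moves)
#>   rejections: ik_failure 19182, singular 0, clash 0, rejected 3317
#>   thinned (skip 40): 51 samples
mixing_report(ens)
#> <slik_mixing_report> 20 series, threshold 0.20, recommended skip 2
```

About a third of the 34,000 block moves are accepted; most rejections are
closure failures of the uniformly drawn independent angles, which is the
expected cost of global proposals.  The mixing report recommends the
smallest thinning stride at which the mean absolute circular autocorrelation
of the angle series drops below 0.2.

A protein loop ensemble from a (here synthetic) PDB file, with Ramachandran,
B-factor and clash priors:

```r
mp  <- make_mini_protein(n_res = 12, loop_start = 4, loop_end = 9)
res <- cli_sample(mp$path, "A", 4, 9, n_samples = 50, skip = 5, seed = 7,
                  out_pdb = "ensemble.pdb", out_report = "report.json")
res$ensemble
#> <slik_ensemble> 51 samples x 12 angles; acceptance 0.100 (150 block moves)
#>   rejections: ik_failure 127, singular 0, clash 0, rejected 8
#>   thinned (skip 5): 11 samples
```

`ensemble.pdb` holds one MODEL per sample (model 1 is the input) with the
loop atoms replaced and everything else untouched; the run report records
the seed, configuration and acceptance statistics needed to reproduce it.
Across these 51 models the loop backbone fluctuates around the input
conformation with mean RMSD 0.20 Å (max 0.31 Å) under the default priors.
The same interface is available from a shell via the thin wrapper
`inst/exec/slikmc` (`sample`, `complete`, `planar`, `diagnose`, `fixtures`
subcommands), e.g.

```sh
Rscript inst/exec/slikmc sample --pdb in.pdb --chain A --start 4 --end 9 \
    --n-samples 200 --skip 10 --seed 1 --priors rama,bfactor,clash
```

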