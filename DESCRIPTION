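Package: slikmc
Title: Sub-Loop Inverse Kinematics Monte Carlo for Closed Kinematic Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates statistically unbiased conformation ensembles of closed
    kinematic loops -- protein backbone loops and planar articulated chains --
    from sparse factored probabilistic priors.  A blocked Gibbs sampler
    resamples short windows of consecutive torsion angles; each window is split
    into independent angles drawn from a prior and dependent angles restored by
    analytical inverse kinematics, and a Metropolis-Hastings acceptance step
    corrected by the metric tensor of the sub-loop chart keeps the stationary
    distribution equal to the specified score.  Supports Ramachandran, B-factor,
    steric-clash and backbone-dependent rotamer priors, planar branched
    structures with multiple closure constraints, mixing diagnostics, and
    missing-loop completion, with synthetic fixture generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
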