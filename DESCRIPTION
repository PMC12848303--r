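Package: neuralmd
Title: Multi-Grained SE(3)-Equivariant Neural Differential Equations for
    Protein-Ligand Binding Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns ligand trajectories around a rigid protein directly from
    snapshot data. A multi-grained SE(3)-equivariant force network (BindingNet)
    built on vector frames at the ligand-atom, protein-backbone, and
    complex-residue level predicts per-atom forces, which an augmented
    second-order neural ODE or SDE solver integrates into trajectories.
    Includes the standard machine-learned dynamics baselines (energy-head
    velocity Verlet, auto-regressive coordinate prediction, annealed Langevin
    denoising), trajectory evaluation metrics (MAE, RMSE, Matching, Stability,
    sliding-window ligand RMSF), a classical-mechanics toy binding-complex
    simulator for controlled benchmarks, and reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
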