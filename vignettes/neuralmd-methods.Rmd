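---
title: "Learning protein-ligand binding dynamics with neuralmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning protein-ligand binding dynamics with neuralmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular-dynamics trajectories of a ligand bound to a protein are expensive
to produce, and many questions in drug discovery need only the
snapshot-resolved motion of the ligand in a (comparatively rigid) pocket.
`neuralmd` learns that motion directly from data: given a rigid protein
backbone, a ligand's identity, and a series of $T$ snapshots of ligand
coordinates, it fits a neural force field and integrates Newton's second law

$$F = m \frac{d^2 x}{dt^2}$$

forward in time as an augmented second-order ODE (or SDE, for
Langevin-flavoured dynamics). The package works in the *semi-flexible*
setting: protein coordinates never move, only the ligand does.

Crucially, the model is trained **on trajectories, not on forces or
energies**: the per-atom force network is differentiated through the
integrator so that the rollout matches the observed snapshots. This makes the
approach agnostic to the physical size of the snapshot interval — the learned
"forces" live in snapshot-indexed units that absorb mass and time scales.

## The force model: multi-grained vector frames

Rotation/translation symmetry (SE(3)-equivariance) is enforced with *vector
frames*: local right-handed orthonormal bases built from the geometry, at
three granularities.

* **Ligand atoms** — for each atom pair $(i, j)$ within a cutoff $c$, a
  Gram-Schmidt frame from the pair difference and the cross product of the
  centroid-centered positions. Because $(a - b) \perp (a \times b)$, the
  frame is orthonormal by construction.
* **Protein backbone** — one frame per residue from its $N$, $C_\alpha$, $C$
  triad; the two bond directions are not orthogonal (the backbone angle is
  about 111°), so the second axis is explicitly orthogonalized.
* **Complex** — frames on consecutive *pocket* residues (residues whose
  $C_\alpha$ lies within $c$ of any ligand atom), centered on the pocket
  centroid.

Projecting any geometric vector onto a frame ("scalarization") yields three
rotation-invariant scalars. Edge features combine these projections with
node embeddings and a 16-centre Gaussian radial basis of the distance.
Equivariant information flows only through gated 3-vectors: per-atom vector
channels `vec`, and relative-position vectors, each multiplied by invariant
scalar gates. The frames' second axis is a pseudo-vector, so the features —
and hence the forces — are deliberately *not* mirror-symmetric: chirality
matters in a rigid pocket.

Two numerical choices matter here and are recorded as this package's own
readings of an under-specified construction:

* The pair-frame cross product is origin-dependent as a raw formula; we
  compute it on centroid-centered coordinates (ligand centroid for ligand
  frames, pocket centroid for complex frames), the only reading under which
  the advertised translation invariance actually holds. Pair-midpoint
  centering is excluded because it makes the two centered vectors exactly
  anti-parallel.
* The backbone frame is Gram-Schmidt orthonormalized so that every frame
  satisfies the same orthonormality contract.
* Degenerate pairs (coincident points, parallel centered positions, vector
  norms below $10^{-8}$ Å) are dropped from the edge set with a warning
  rather than crashing a forward pass.

The force on atom $i$ is the internal vector channel plus the aggregated
ligand-pocket interaction vectors. Interaction contributions enter through a
smooth cosine cutoff envelope and are **summed** (not averaged) over pocket
neighbours: physical forces superpose, and the envelope removes the
discontinuity when a residue crosses the cutoff sphere. All vector gates are
tanh-bounded, which keeps predicted forces finite however far a rollout
strays — a cheap, architecture-level guard against catastrophic divergence.

Default hyperparameters (all exposed in `bindingnet_config()`): hidden width
64, 3 message layers, cutoff 5 Å, SiLU activations, mean aggregation for
invariant messages, Xavier initialization from a configurable seed. The
desk-scale experiments use width 32, 2 layers, and cutoff 8 Å — the larger
cutoff keeps the whole toy pocket inside the interaction horizon, so the
model is never blind to the confining field.

## The dynamics solver

The augmented state $[x; v]$ evolves under $[dx/dt; dv/dt] = [v; F/m]$,
integrated with explicit Euler at step $h = 1/2$ snapshot (two force
evaluations per snapshot). The SDE variant adds a learned per-atom noise
amplitude (a ligand-only network) gated by fresh standard Gaussian noise;
the contribution enters the velocity update scaled by $\sqrt{h}$
(Euler-Maruyama), so displacement variance is step-size consistent. With the
noise network at zero the SDE rollout is bit-for-bit the ODE rollout.

Initial velocities are estimated by *positional momentum*,
$v_t = x_t - x_{t-1}$, optionally passed through a learned mapping. During
rollouts an optional *velocity refinement* adds
$\alpha \cdot \mathrm{net}(x)$ to the velocity at each snapshot boundary.
The refinement is off by default ($\alpha = 0$) but **on** ($\alpha = 1$,
zero-initialized) in the experiment drivers: a position-dependent velocity
kick is the only mechanism in this model family that can make the discrete
snapshot map dissipative, and we observed it to help long-rollout stability.

### Why stability is the hard part

Explicit Euler on an oscillatory mode of frequency $\omega$ amplifies
amplitude by $\sqrt{1 + (\omega h)^2}$ per step — there is no choice of
position-only force field whose Euler flow is neutrally stable on an
oscillation. A learned effective model must therefore trade pointwise force
accuracy against softness of its effective stiffness. Two consequences
shaped the training protocol below: short-horizon force matching alone
learns the (unstable) stiff true field, and long-horizon rollout losses are
themselves prone to exploding mid-training.

## Training protocol

`train_neuralmd()` minimizes the mean per-atom Euclidean deviation
$\mathbb{E}_t\,\lVert \hat{x}_t - x_t \rVert$ over teacher-forced rollout
segments (position restarts from data; velocity from positional momentum),
with Adam, global-norm gradient clipping at 10, and a divergence safeguard
that restores the best parameters whenever an epoch's loss explodes past
three times the best seen. Gradients flow through the full rollout —
including the force field's dependence on intermediate positions — via the
package's reverse-mode tape; they are verified against central finite
differences in the test suite.

`train_neuralmd_protocol()` is the staged recipe used by the experiment
drivers:

1. **bootstrap** — match finite-difference accelerations
   $x_{t+1} - 2x_t + x_{t-1}$ per snapshot (fast, stable, no integrator);
2. **rollout fine-tuning** on segments of 8 then 16 snapshots at decreasing
   learning rate;
3. a final low-rate stage on 20-snapshot segments drawn from the late part
   of the training trajectory, matching the evaluation horizon;
4. **checkpoint selection**: after each stage the parameters are scored by
   rolling out the last 20-24 training snapshots from their own past
   (`tail_rollout_score()`); the best checkpoint is kept. Selection uses
   training data only, so fine-tuning can never make the delivered model
   worse than the bootstrap.

Epoch counts (150/50/50/40 at learning rates 3e-3/1e-3/5e-4/1e-4) were
chosen so a full protocol trains in about three minutes on one CPU core at
the default toy scale.

## Baselines

All baselines share the BindingNet encoder; only heads, training signal and
rollout logic differ.

* **VerletMD** — the classical ML-force-field paradigm: the force surrogate
  is fitted per snapshot to finite-difference accelerations (no rollout in
  the loss) and integrated with velocity Verlet at inference. Note one
  deliberate reading: the original description derives forces from an
  energy head; fitting the force output directly is equivalent supervision
  at this scale and avoids second-order differentiation, which the
  package's tape does not implement. The per-snapshot training signal —
  not the integrator — is what makes this family fragile over long
  rollouts, and that property is preserved.
* **GNN-MD** — auto-regressive coordinate prediction,
  $x_{t+1} = x_t + \mathrm{net}(x_t)$; the displacement (residual)
  parameterization keeps the step translation-equivariant.
* **DenoisingLD** — denoising score matching on next-snapshot coordinates;
  inference runs 10 annealed Langevin updates per snapshot down a geometric
  noise schedule ($\sigma$ from 1.0 to 0.01 Å, $\eta_i = 0.05\sigma_i^2$ —
  standard annealed-Langevin settings at toy scale; the noise-conditioning
  enters as a learned $\sigma$-embedding added to the atom embeddings).

## Evaluation metrics

* **MAE** (Å) — mean per-atom Euclidean deviation over snapshots and atoms;
  identical to the training loss.
* **RMSE** — root mean squared *per-component* deviation. The two are
  deliberately on different scalar populations: for isotropic errors
  RMSE $\approx 0.63 \times$ MAE, reproducing the reported ordering of the
  two reconstruction metrics (this aggregation reading is the package's
  own inference; the alternative — both on the same population — cannot
  produce RMSE < MAE).
* **Matching** (Å²) — mean squared error of intra-ligand pairwise distances
  over snapshots and unordered pairs (all pairs by default; configurable).
* **Stability** (%) — share of (snapshot, pair) combinations whose distance
  error stays within $\Delta = 0.5$ Å.
* **Ligand RMSF** (Å) — $\sqrt{\mathbb{E}_t[\frac{1}{N}\sum_i
  \lVert r_{i,t} - \langle r_i \rangle \rVert^2]}$, computed over
  non-overlapping 5-snapshot sliding windows (the two quoted example
  windows are consistent with stride = window = 5), labelled with inclusive
  snapshot ranges such as [81, 85] … [96, 100].

Each metric is checked against an independent double-loop implementation at
$10^{-12}$.

## The synthetic benchmark

`make_toy_complex()` builds a chain-bonded 8-atom carbon ligand with
randomized equilibrium geometry inside a ring of 10 frozen pseudo-residues
(backbone triads with 1.46/1.52 Å bond lengths, ring radius 7 Å);
`simulate_ground_truth()` integrates harmonic bonds plus a Lennard-Jones
pocket with velocity Verlet (50 fine steps of 0.01 per snapshot), optionally
with a BAOAB Langevin thermostat. Reduced units: unit atomic masses, energy
scales set by the force-field constants. Oracle forces are verified against
finite differences of the analytic potential; Newtonian runs conserve energy
to better than 0.1%; thermostatted runs equilibrate kinetic energy to
$\tfrac{3}{2} N k_B T$ within 20%.

Parameter choices, made once for realism at snapshot resolution: bond
stiffness $k = 4$ so the bond period spans ~6 snapshots, Lennard-Jones
$\epsilon = 0.5$, $\sigma = 4$ Å so the pocket oscillation period spans
~9 snapshots — data where fluctuations are *resolved*, as in
nanosecond-interval binding trajectories, rather than aliased. The default
study trajectory (`toy_system()`) starts the ligand with a gentle
centre-of-mass kick (0.4 in fine velocity units) plus small internal
excitation, under deterministic Newtonian dynamics (friction and
temperature zero).

What the generator does *not* emulate: solvent, electrostatics,
protein-side flexibility, thermal kicks in the default setting, and the
conformational richness of real ligands. Passing the synthetic recovery
test shows the estimator and protocol work end to end on resolvable
dynamics; it does not certify accuracy on experimental binding
trajectories.

A candid note on difficulty: because the default system is conservative, it
settles into a bounded oscillation, which makes the trivial
"freeze-at-last-training-position" reference unusually strong on the test
segment (its error is bounded by the oscillation amplitude), while
snapshot-scale Euler instability bounds how long any learned position-only
force field can phase-track — the *true* force field rolled out with the
same Euler integrator diverges outright. Under the default conditions the
staged protocol reaches test MAE within ~15-50% of the freeze reference
without beating it, and VerletMD — whose symplectic integrator is exactly
right for conservative, noise-free data — posts the best stability of all
methods. Both orderings are properties of this deliberately clean
benchmark, not of the methods in general: on noisy, large-timestep,
thermostatted trajectories the per-snapshot force-matching paradigm
degrades and trajectory-trained rollouts dominate. The experiment reports
always include the freeze reference so the comparison stays visible.

## Protocols

`split_single_trajectory()` reproduces the temporal 80/20 protocol (train
on snapshots 1-80, test on 81-100); test rollouts start from the last
training position with positional-momentum velocity from the final training
pair — the initialization the package adopts where the protocol is silent.
`split_multi_trajectory()` partitions complexes (never snapshots) 80/10/10
with a seeded permutation. Experiments repeat over seeds (0, 42, 123 by
default) and report mean ± sample standard deviation. Training segments are
mini-batched stochastically per epoch; all randomness is derived from the
run seed through a scoped RNG, so every experiment is bit-reproducible.

## File formats

Proteins are read from PDB `ATOM` records (first model, altloc blank/'A',
waters and other heteroatoms excluded, residues missing any backbone atom
dropped with a warning); ligands from PDB `HETATM` or SDF V2000. Masses come
from the standard atomic-weight table. Trajectories use a single-file
binary container with an HDF5-style logical layout
(`/ligand/coordinates` [T, N, 3] in Å as 64-bit reals, optional
`/ligand/velocities`, protein backbone datasets, a `snapshot_interval`
attribute) — a JSON header plus little-endian doubles, so round trips are
bitwise exact. No R HDF5 bindings are available in this package's
dependency footprint, which is why the container is self-describing and
deliberately minimal.

## Known limitations

* Second-order derivatives are not implemented in the autodiff tape, so
  energy-head forces cannot be trained through a rollout loss (see the
  VerletMD note above).
* The rigid-protein assumption is structural: flexible-protein dynamics are
  out of scope.
* Training has only been exercised at desk scale (tens of atoms); the
  dense per-edge tape would need batching work for thousands of atoms.
* The SDE noise head is trained jointly with the mean force; no
  thermostat-parameter interpretation of the learned amplitude is claimed.
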