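---
title: "Sampling protein conformational transitions with elastic-network Brownian dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling protein conformational transitions with elastic-network Brownian dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdpath)
```

## The problem

Experimental structural biology captures proteins in discrete metastable
states -- open and closed, active and inactive, rotary steps of a motor --
but rarely the pathway connecting them. `bdpath` generates such pathways at
the coarse-grained level: each residue is reduced to its C-alpha bead, the
protein becomes an elastic network of harmonic springs, and overdamped
(Brownian) dynamics is driven from the start conformation toward the target
by importance sampling on a pairwise-distance progress variable. The same
package provides the analysis toolkit used to judge the result: ensemble
principal component analysis (PCA) with Kabsch superposition, RMSD and
collectivity of the conformational change, consecutive C-alpha
stereochemistry, subspace overlaps and RMSIP, and three-point angles.

## The model

**Elastic network.** Springs connect three kinds of bead pairs:

* *bonded* pairs, with residue-number separation $s \le$ `sequence_span`
  within a chain, with stiffness $k = C_\text{seq}/s^{\,p_\text{seq}}$;
* *Cartesian* pairs, any two beads closer than the cutoff $r_c$ in the
  conformation the network was built from, with stiffness
  $k = C_\text{cart}\,(d_\text{ref}/d_0)^{\,p_\text{cart}}$, non-increasing
  in the rest length $d_0$;
* *rigid-block* pairs: inside a user-declared block every pair is connected
  regardless of distance, at a fixed stiffness (1 kcal/mol/A^2 by default),
  which preserves quasi-rigid units (e.g. a rotor ring) through large
  rotations.

The force on each bead sums harmonic pair forces over a neighbour list
rather than all $\binom{N}{2}$ pairs, which is what makes the cost per step
quasi-linear in $N$ at fixed packing density.

**Dynamics.** The integrator is the overdamped (position-Langevin) limit,

$$\Delta r_i = \frac{\Delta t}{\gamma} F_i +
  \sqrt{\tfrac{2 k_B T \Delta t}{\gamma}}\,\eta_i ,$$

with independent standard-normal noise per coordinate. Inertia is dropped
deliberately: at the friction scales relevant for residue-level beads in
solvent the momentum autocorrelation is far shorter than any conformational
timescale, so masses are not parameters of the method.

**Importance sampling.** Progress toward the target is measured by
$\Gamma = \sum_{(i,j)} (d^{s}_{ij} - d^{t}_{ij})^2$ over pairs of matched
residues -- by default *all* matched pairs, exactly the printed double sum; a
cutoff-restricted variant is available for very large systems
(`gamma_scope = "cutoff"`). Because $\Gamma$ depends only on internal
distances it is invariant under rigid-body motion of either conformation.
Every `bias_frequency` (default 10) BD steps, $\Gamma$ is compared with the
last accepted value; the segment is kept only if it *strictly* decreased
$\Gamma$ (ties reject), otherwise all coordinates roll back and the next
segment starts from fresh noise. The run terminates when the matched-residue
RMSD to the target (after Kabsch superposition) reaches
`convergence_rmsd` (1 A, the scale of thermal fluctuation), when $\Gamma$
reaches `gamma_epsilon`, or when the checkpoint budget is exhausted.
Residues present in only one end state carry no bias terms: they fluctuate
freely under the network and the thermostat, which is what lets end states
of different residue or chain composition be connected.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` ($r_c$) | 8 | A | Cartesian pair-list radius |
| `bias_frequency` ($k$) | 10 | steps | BD steps per accept/reject test |
| `convergence_rmsd` | 1 | A | stop at thermal-oscillation distance |
| `sequence_span` | 3 | -- | separations treated as bonded |
| `sequence_constant` | 60 | kcal/mol/A^2 | bonded stiffness scale |
| `sequence_exponent` | 2 | -- | bonded decay with separation |
| `cartesian_constant` | 6 | kcal/mol/A^2 | Cartesian stiffness scale |
| `cartesian_exponent` | 6 | -- | Cartesian decay with distance |
| `reference_length` | 3.8 | A | ideal consecutive C-alpha spacing |
| `rigid_spring_constant` | 1 | kcal/mol/A^2 | intra-block stiffness |
| `temperature` | 300 | K | thermostat |
| `timestep` | 0.015 | ps | nominal integration step |
| `friction` | 20 | 1/ps | per-bead friction |

The cutoff and biasing frequency follow the values found optimal for this
family of samplers; the spring-rule constants are *placeholders in a
documented functional form* -- the upstream force field delegates its exact
MD-derived constants to its own reference, so every constant here is
exposed in `enm_params()` and can be overridden from the CLI config file.
Temperature, timestep and friction are chosen so the per-step free-diffusion
RMS displacement is about 0.03 A per coordinate, comfortably inside the
0.01-0.05 A band where the overdamped discretization is stable for the
stiffest default spring ($\mu k_\text{max} \approx 0.05 \ll 1$).

## Numerical design choices

**Adaptive integration step.** A strict-decrease acceptance rule starves
when the remaining distance mismatch becomes comparable to the diffusion
accumulated over one segment: the convexity of $\Gamma$ means random motion
*increases* it in expectation, and at a fixed step size the acceptance
probability collapses before the convergence threshold is reached (we
observed stalls at 2-2.5 A RMSD on the benchmark hinge at any fixed step in
the stable range, while direct gradient descent on $\Gamma$ from the stalled
structures continued to the target -- demonstrating a proposal-scale
artifact, not a landscape minimum). `run_transition()` therefore runs a
step-size controller: after `adapt_after` (50) consecutive rejections the
timestep is multiplied by `adapt_factor` (0.6) -- with the noise scaled by
its square root, so each stage is still proper Brownian dynamics at fixed
temperature -- and each acceptance multiplies it back by `recover_factor`
(1.05), never above the nominal timestep nor below `min_step_scale`
(1/1024) of it. The schedule is part of the trajectory and fully
reproducible from the seed.

**Adaptive pair list and rest lengths.** The neighbour list is rebuilt
every `rebuild_every` (25) accepted checkpoints, and immediately whenever
any bead has moved more than $r_c/4$ since the last build. At a rebuild,
Cartesian springs re-derive rest length and stiffness from the *current*
structure, so the network minimum tracks the deformation instead of pulling
back toward the start; bonded nearest-neighbour springs keep their original
rest lengths (they anchor the chain's local scale -- making them adaptive
lets thermal ratcheting inflate the backbone), and rigid-block springs keep
theirs (block-geometry memory). Springs at separations 2-3 re-derive like
Cartesian ones: they encode soft pseudo-angles that must change during a
transition.

**Superposition.** Kabsch superposition uses the SVD of the 3x3 covariance
with the determinant correction, so reflections are never returned; fewer
than 3 masked beads or exact collinearity is an error rather than a silent
degenerate fit.

**PCA conventions.** The covariance is taken about the ensemble *mean*,
while projections are anchored at the *reference* structure,
$p_{l,m} = (X_l - X_\text{ref})\cdot PC_m/|PC_m|$. These two printed
conventions differ, and both are implemented exactly as stated; reference
anchoring means the reference projects to the origin, not the ensemble
centroid. Eigenvector signs are fixed (largest-magnitude component
positive) and degenerate eigenvalue blocks are ordered by the index of that
component, so bases are reproducible across platforms. Eigenvalues
numerically indistinguishable from zero are clamped to zero; a
two-conformation ensemble has exactly one positive eigenvalue.

**Altlocs and residue identity.** Residues are identified by (chain,
residue number, insertion code) exactly as found in the file -- no silent
renumbering -- and matched across end states by key equality, never by
sequence alignment. Alternate locations keep the highest-occupancy copy,
ties broken alphabetically. The first MODEL block is read for input
structures; all blocks for trajectories.

**Degenerate inputs.** Coincident beads are an error (corrupt input, not a
case to smooth over); zero matched residues is an error; an empty residue
intersection across an ensemble is an error; all-zero displacement fields
make the collectivity undefined and raise rather than returning a
conventional value.

## The synthetic two-state generator

`make_two_state()` builds idealized C-alpha systems with known ground
truth: chains have exactly 3.8 A consecutive spacing, and the motions --
hinge rotation of the distal half, rigid rotor rotation of a chain, radial
breathing of a multi-chain ring, uniform translation, single-residue
displacement -- are exact rigid transformations, so reference RMSD and
collectivity values are closed-form. The default chain geometry is a
compact alpha-helix-like coil (~95 deg twist per residue with a constant
rise). That choice is deliberate and load-bearing: a near-planar extended
strand admits spurious solutions of the pairwise-distance constraints --
including the enantiomer of the target, which satisfies *every* pair
distance -- and a monotone distance-descent sampler that enters such a basin
can never leave it (we observed exactly this with a low-pitch variant of
the generator: descent to near-zero $\Gamma$ at 6 A RMSD from the target).
Densely connected, strongly chiral helical geometry keeps those basins
remote, as the packed tertiary structure of real folds does. An extended
open-strand geometry remains available (`geometry = "extended"`) for
exercises where sparse connectivity is the point.

The canonical benchmark (`hinge_study_fixture()`) is a 60-residue helical
chain whose distal half rotates by 61 degrees, putting the superposed
end-state RMSD at 8.0 A. The validation suite runs it at the default
parameters over ten seeds (a few seconds per run; problem sizes throughout
the tests range from 2-bead closed forms to 4000-residue chains for the
scaling checks, and a 500-member ensemble for PCA recovery).

What passing these tests does *not* show about real data: the fixtures have
ideal geometry, a single uniform bead type, no missing-density noise, and
motions that are exactly rigid; real cryo-EM ensembles have heterogeneous
resolution, gaps, and motions that mix rigid and plastic components. The
fixture results validate the machinery -- bias, acceptance, network
adaptation, analysis -- not the biological accuracy of any particular
pathway.

## Known limitations

* No excluded volume: beads interact only through springs and the bias, so
  chains can pass through each other in principle; stereochemistry is kept
  by the bonded terms and verified a posteriori with
  `consecutive_ca_distances()`.
* The method gives no energetics or kinetics: frames are ordered by the
  monotone progress variable, not by time in any physical ensemble.
* Forward and reverse runs are independent simulations; no path symmetry is
  assumed, and none should be expected.
* Coarse-grained intermediates need atomistic reconstruction and refinement
  before all-atom applications; that pipeline is out of scope here.
* With `gamma_scope = "all"` the progress variable itself is quadratic in
  the number of matched residues; the cutoff-restricted scope trades some
  bias fidelity for scalability on very large systems.

## A worked sketch

```{r example, eval = FALSE}
fx <- hinge_study_fixture()
path <- run_transition(fx$start, fx$target, seed = 1)
path

# stereochemistry of the midpoint intermediate
mid <- path$frames[[which.min(abs(path$rmsd_to_target -
                                  path$rmsd_to_target[1] / 2))]]
ca_distance_stats(mid)

# project the path onto the two-end-state PC basis
ens <- superpose_ensemble(reduce_to_common(list(fx$start, fx$target)))
basis <- ensemble_pca(ens)
head(project_path(path, basis, m = 1))
```
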