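---
title: "Physics-guided residual corrections for hydration free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-guided residual corrections for hydration free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Every practical physics-based estimate of a small molecule's hydration free
energy (HFE) carries a residual error relative to experiment. `solvcorr`
implements the residual-learning (delta-ML) strategy: keep the physics
prediction as the backbone of the estimate and train a graph neural network
to predict only its error, so that

$$\hat{y}_i = y_{\mathrm{phys},i} + y_{\mathrm{nn},i}.$$

Training minimizes the mean squared error of the *combined* prediction over a
minibatch of $N$ molecules,

$$L = \frac{1}{N}\sum_{i=1}^{N}
  \bigl(y_{\mathrm{expt},i} - (y_{\mathrm{phys},i} + y_{\mathrm{nn},i})\bigr)^2
  = \mathrm{RMSE}^2,$$

which is `residual_loss()`. The physics model and the network never interact
except through this loss: the physics prediction is an input column, and any
model (an explicit-solvent calculation, a generalized Born variant, or the
package's own GB calculator) can supply it. A `dnn_alone` training mode drops
the physics term and regresses the experimental HFE directly; it exists to
demonstrate why the hybrid is preferable on out-of-distribution data.

### Why residual learning

The physics model supplies the part of the prediction governed by known
physics, leaving a smaller, smoother function for the network to learn. Two
practical consequences drive the package design:

* the correction is small relative to the physics term, so even a poor
  network extrapolation degrades the final prediction gracefully; and
* the approach composes with *any* predictor of the target quantity, with no
  integration effort beyond aligning prediction columns.

## Architectures

Two standard graph regressors are implemented directly in matrix code with
hand-derived backpropagation (no deep-learning runtime is required):

* **GraphConv** — two Duvenaud-style graph convolutions of widths 53 and 38,
  each followed by a per-atom max pooling over the closed neighbourhood, an
  atom-level dense layer of width 27 with rectifier activation, a graph
  gather (concatenated sum and max over atoms), and a final linear layer.
  Dropout 0.4 is applied after every learned layer during training. Edge
  features are not consumed by this architecture.
* **MPNN** — node features are embedded to width 64, followed by three
  edge-conditioned message-passing steps: a two-layer edge network (hidden
  width 128) maps each edge feature vector to a 64 x 64 operator, messages
  are sum-aggregated, passed through a rectifier and a gated recurrent unit
  whose parameters are shared across steps. Readout is Set2Set with six
  attention steps (or a plain sum of node states), followed by a two-layer
  head. Single-node graphs are rejected: one node supplies no edges to
  condition messages on, which is also why single-heavy-atom molecules are
  filtered from the modeled dataset.

Design points the underlying descriptions leave open, fixed here: the
GraphConv pool operator is the per-atom maximum over the closed
neighbourhood and the gather concatenates sum and max (the conventions of
the reference implementations); the GRU shares parameters across the three
steps; the sum-readout variant keeps the same head with its input width
adapted (64 instead of 128); weights use uniform fan-in initialization. Only
reproducibility-per-seed is contracted, not a specific initialization law.

Gradient correctness is not assumed: the test suite checks every parameter
block of both architectures against central finite differences on small
configurations, and checks permutation invariance of the outputs at 1e-5.

## Featurization

Molecules are heavy-atom graphs: every non-hydrogen atom is a node, every
covalent bond an edge, and hydrogens appear only as a node feature.
Chemistry node features (24 columns) are one-hot blocks — element identity
over {C, N, O, F, P, S, Cl, Br, I}, heavy-atom degree 0-5, attached
hydrogens 0-4, hybridization (sp, sp2, sp3), and an aromaticity bit.
Physics node features (2 columns) are the partial charge and the inverse
effective Born radius; the physics edge feature is the inverse bonded
distance. Numeric features are min-max normalized to [0, 1].

Choices worth knowing:

* Hybridization states outside {sp, sp2, sp3} (halogens, some S/P states)
  encode as an all-zero block rather than an error, since such atoms occur
  in real HFE databases.
* The normalizer is fitted on the training partition only and reused for
  validation/test with clamping into [0, 1]; fitting scope is not dictated
  by the original description, and train-only fitting avoids leakage. A
  constant feature maps to 0 by convention.
* Node ordering is the package's canonical atom ranking, so featurization is
  deterministic and independent of SMILES atom order.
* 3D geometry (for inverse distances and GB features) comes from an attached
  structure file when present, otherwise from a deterministic
  distance-geometry-style conformer seeded per molecule id. The embedding
  targets bond lengths, ideal-angle 1-3 distances and a nonbonded lower
  bound; it provides plausible, reproducible geometry, not a force-field
  minimum — a real application with real structures should attach them.

No cheminformatics toolkit exists for R in the supported environment, so the
package carries its own SMILES parser, implicit-hydrogen assignment, ring
perception, canonical ranking, and Bemis-Murcko framework extraction for
the restricted 9-element vocabulary. An independent toolkit (RDKit) was used
only to freeze expected values into the test suite.

## The generalized Born module

The polar solvation energy is evaluated as

$$\Delta G^{\mathrm{pol}} \approx -\frac{1}{2}
  \Bigl(\frac{1}{\epsilon_{\mathrm{in}}}-\frac{1}{\epsilon_{\mathrm{out}}}\Bigr)
  \frac{1}{1+\beta\alpha} \sum_{ij} q_i q_j
  \Bigl(\frac{1}{f_{ij}} + \frac{\alpha\beta}{A}\Bigr),
  \qquad \beta = \epsilon_{\mathrm{in}}/\epsilon_{\mathrm{out}},$$

with the canonical pair function
$f_{ij} = \sqrt{r_{ij}^2 + R_i R_j \exp(-r_{ij}^2/4R_iR_j)}$. Defaults:
$\epsilon_{\mathrm{in}} = 1$, $\epsilon_{\mathrm{out}} = 78.5$,
$\alpha = 0.571412$, electrostatic constant 332.06 kcal A / (mol e$^2$); all
configurable. The diagonal terms of the pair decomposition are the per-atom
self energies offered as a diagnostic; they are excluded from the default
feature sets because they are functions of the included features.

* **Effective Born radii** use pairwise descreening in the Coulomb-field
  approximation: the inverse intrinsic radius minus a closed-form integral
  of the $1/r^4$ kernel over each neighbouring sphere, clamped from below by
  the intrinsic radius. The closed form is validated in the tests against a
  numerical volume-integration oracle (agreement well within the 5%
  contract for non-overlapping configurations). No bit-compatibility with
  any external GB program is claimed.
* **Electrostatic size $A$** is the capacitance of the atom-sphere assembly
  from a method-of-moments solve, using the GB pair kernel as the potential
  coefficient matrix. A moments-of-inertia (ellipsoid) estimate was
  considered and rejected: it cannot satisfy the two-sphere capacitance
  check (for two unit spheres 10 A apart it gives ~6.5 A against a
  boundary-element value of ~1.8 A), whereas the capacitance definition is
  exact in the single-atom limit — which is also what makes the whole
  expression reduce to the Born formula for one atom, the invariant the
  tests enforce at 1e-9 relative tolerance.
* **Partial charges** default to an electronegativity-equalization solve
  over the full molecule (explicit hydrogens included) followed by
  condensation of hydrogen charges onto their heavy atoms; the condensed
  charges sum exactly to the formal charge. Structure-file charges take
  precedence when present. The charge model behind the published features is
  unstated, so this is a package decision, not a reproduction.
* Intrinsic radii are a bundled Bondi-style per-element table.

## Dataset handling and splits

`parse_freesolv()` reads the semicolon-delimited FreeSolv v0.52 text dialect
(comments on `#` lines; seven parsed fields; trailing references ignored)
and validates every SMILES against the element vocabulary at read time. Two
record-level filters implement the low-uncertainty protocol: molecules with
|HFE| < 6 kcal/mol are removed when their uncertainty exceeds 0.6 kcal/mol,
molecules with |HFE| >= 6 kcal/mol when their relative uncertainty exceeds
10% — both thresholds strict, so boundary records survive — and
single-heavy-atom molecules are removed. Splits are computed on the
*pre-filter* dataset and the filters are then applied per partition
(`filter_split()`), so filtered and unfiltered evaluations share membership.

Three 6:1:1 split policies:

* **stratified** — quantile bins on the experimental HFE (8 by default; the
  bin count and shape are not published, and quantile bins guarantee
  nonempty strata), seeded shuffling within bins, proportional allocation
  with round-robin leftovers. Partition sizes match the exact targets to
  within the bin count; no attempt is made to reproduce the original split
  membership, whose seed is not public.
* **hfe_extreme** — the molecules of largest |HFE| form the test set (ties
  at the cutoff broken by ascending id), remainder split 6:1; the test set
  is out-of-distribution by construction.
* **scaffold** — Bemis-Murcko frameworks (ring systems plus linkers, with
  multiply-bonded substituents retained); acyclic molecules are distributed
  randomly, scaffold groups assigned whole, largest first, to the partition
  furthest below its target. Frameworks are kept structure-preserving (not
  collapsed to generic carbon skeletons), since scaffold identity is
  compared as a literal canonical structure.

## Training protocol

Minibatch Adam (the learning-rate value 0.001 is prescribed; the optimizer
itself is not, and adaptive-moment descent is this package's choice), batch
size 100, reshuffled each epoch with the member's seed; the last partial
batch is kept. After each epoch the validation RMSE of the combined
prediction is recorded. Early stopping: training stops when no improvement
of at least 0.01 kcal/mol has occurred within the patience window (20
epochs for the MPNN, 100 for GraphConv), and the returned weights are those
of the best validation epoch. Safety caps of 500 (MPNN) and 2000
(GraphConv) epochs exist because no cap is prescribed; they are far above
the patience window. An ensemble trains 20 members (`base_seed + k`) on
identical data; the final correction is the arithmetic mean of member
outputs. Reported metrics are the RMSE to experiment and the relative
improvement (RMSE_phys - RMSE) / RMSE_phys.

## The synthetic world

`generate_synthetic_dataset()` builds a fully self-contained benchmark with
the statistical shape of a real HFE database, so that every pipeline stage
is testable without any download:

* molecules are assembled from a weighted fragment grammar over
  {C, N, O, F, S, Cl} (alkyl carbons, ethers, amines, carbonyls, nitriles,
  halogens, benzene/pyridine/furan/thiophene rings), valence-correct by
  construction, 2-24 heavy atoms; with the default weights the sample has a
  mean of ~9 heavy atoms and a roughly even acyclic/aromatic split,
  matching the target database's shape (mean 8.7 +/- 4.2, 320/322);
* the ground-truth HFE is a linear function of descriptor counts (heavy
  atoms, O, N, aromatic rings) whose default coefficients were calibrated
  once against the target distribution (-3.8 +/- ~4 kcal/mol) and then
  frozen;
* the synthetic "physics model" predicts truth plus a structured residual
  proportional to a standardized combination of aromatic-atom and oxygen
  counts, amplitude 1.5 kcal/mol RMS by default. The residual depends only
  on information expressible from the node features, which is what makes
  the residual-recovery acceptance test fair: a correctly implemented
  network *can* learn it;
* "experimental" values add Gaussian noise with sigma 0.3 kcal/mol, and a
  10% minority of records get sigma inflated threefold with the inflated
  value as their uncertainty label, enabling a miniature
  filtered-vs-unfiltered comparison.

What a green synthetic test does establish: the loss, featurization,
training loop, early stopping, ensembling and evaluation machinery are
correctly wired, and the networks can recover a learnable residual through
them. What it does not establish: accuracy on real chemistry — the grammar
does not emulate conformational flexibility, tautomerism, long-range
electrostatics, or measurement idiosyncrasies of real HFE data.

## Numerical choices and degenerate inputs

* Filter boundaries are non-strict survivals (exactly 0.6 kcal/mol and
  exactly 10% are kept).
* Tie-breaks are by ascending compound id everywhere after the primary key,
  making every split a pure function of (data, seed).
* A constant numeric feature normalizes to 0; out-of-range inference values
  clamp to [0, 1].
* Born radii are clamped from below by intrinsic radii; coincident atoms are
  an error, not a NaN.
* The GB module's charge-inversion symmetry is a property of the plain GB
  quadratic form; models that deliberately break it (charge-hydration
  asymmetry) are out of scope and their predictions enter only as input
  columns.
* Ensembles with one member degrade to that member; the mean-correction
  convexity property (ensemble RMSE <= mean member RMSE) is tested.

## Known limitations

* Conformers are synthetic embeddings unless structures are attached; GB
  features computed from them are self-consistent but not comparable to
  values from optimized 3D structures.
* The canonical ranking resolves ties by refinement and class promotion;
  atoms still tied are treated as symmetry-equivalent. This is exact for
  the molecule sizes targeted here but is not a certified graph-canonization
  algorithm.
* The FreeSolv v0.52 file itself is not bundled (size and redistribution);
  statistics over the real database require pointing `SOLVCORR_FREESOLV` at
  a local copy, and the corresponding acceptance checks fail (honestly)
  without it.
* Training runs at desk scale: the reference ensembles in the tests use 5
  members, not 20, and tightened epoch caps (120 GraphConv / 40 MPNN for
  the in-distribution benchmark, 30 for the out-of-distribution
  comparison), to stay inside a CPU-only time budget. The full 20-member
  protocol is the library default.
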