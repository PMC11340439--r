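---
title: "Equivariant prediction of carbohydrate NMR chemical shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant prediction of carbohydrate NMR chemical shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The isotropic chemical shift observed in solution NMR is a scalar: it
does not change when a molecule is translated, rotated or mirrored.
Carbohydrates are a hard case for empirical shift prediction because
their spectra are dominated by stereochemistry — diastereomers such as
the alpha and beta anomers of a pyranose differ only in the spatial
arrangement of the same bond graph, yet every carbon's shift moves.
A predictive model therefore has to see 3D geometry, and it has to
respect the symmetry of the observable: predictions must be exactly
invariant under the Euclidean group E(3) while internal representations
transform covariantly.

`eqshift` implements an E(3)-equivariant graph self-attention network
for per-atom prediction of carbon-13 and proton shifts, together with
the surrounding pipeline: SMILES parsing, conformer-ensemble
generation, featurisation, masked-MAE training with ensemble
augmentation, stratified cross-validation, and ensemble prediction with
an uncertainty estimate.

## Molecular representation

Hydrogens are excluded from the graph; each heavy atom carries its
element and the number of attached hydrogens as categorical embedding
indices. Directed edges connect every bonded pair (keeping the bond
category regardless of distance) and every pair of atoms closer than
`r_cut = 6` angstrom (category "none"). Each edge carries an invariant
scalar embedding — a learned bond-category vector with the raw
euclidean distance appended — and the real spherical harmonics (orders
0..2) of its unit direction vector. Feeding the raw distance rather
than a radial basis expansion is the default; `radial_n` in
`eqshift_config()` switches to Gaussian radial bases as an extension.

Bond categories are `single`, `double` and `other`; `other` absorbs
aromatic and triple bonds so arbitrary organic molecules can pass
through the pipeline without changing the embedding table size. The
element vocabulary is C, N, O, S, P, F, Cl plus a shared "other" row,
and attached-hydrogen counts are capped at 4 (the organic valence
bound).

One deliberate convention: a dataset stores a single H1 record per
heavy atom. Where a source lists two diastereotopic proton values
(e.g. H6a/H6b of an exocyclic CH2), they must be averaged before
loading — the network emits one invariant scalar per node per nucleus,
so there is nothing for a second value to supervise.

## Network

Node features are geometric tensors: concatenations of
irreducible-representation (irrep) blocks labelled by order l and
parity, stored column-wise per multiplicity. The default architecture
uses seven attention layers with hidden layout
`64x0e + 32x1o + 8x2e`, a 128-dimensional invariant input embedding,
32-dimensional edge scalars, and a readout that maps the final scalar
block to 128 invariants followed by one two-layer MLP (hidden width
384, SiLU) per nucleus.

Each layer computes, per directed edge from sender j to receiver i:

- a query `q_i` by an irreps-wise linear map of the receiver's tensor;
- a key `k_ij` and value `v_ij` as weighted tensor products of the
  sender's tensor with the edge harmonics, where the tensor-product
  weights are produced per edge by small scalar networks of the
  invariant edge embedding (`NN_k`, `NN_v`);
- an attention logit as the invariant channel of `q (x) k` — summed
  over multiplicities this is a scaled dot product — followed by a
  numerically stabilised softmax over the incoming edges of each node;
- an aggregation `sum_j alpha_ij v_ij`, passed through a gated
  equivariant feed-forward block, a residual connection, and an
  equivariant layer normalisation (scalars standardised with learned
  gain and bias; each l>0 block rescaled by the root mean square of its
  per-copy norms, preserving directions).

Attention neighbourhoods exclude the self node; self information flows
through the residual. A node with no neighbours (possible only for
degenerate inputs) aggregates the zero tensor by contract rather than
producing NaN from an empty softmax.

The tensor-product coupling coefficients are computed at load time by
Gauss-Legendre quadrature of triple products of the package's own real
spherical harmonics. Every path used by the architecture has even
l1+l2+l3, where this Gaunt-type tensor spans the unique equivariant
coupling; paths whose output parity is not the natural parity of the
output order (for example the pseudovector from `1o x 1o`) are dropped
because no hidden block could consume them. The Wigner rotation blocks
used by the test suite are recovered numerically from the harmonics by
least squares, deliberately independent of the tensor-product code
path they verify.

All of this runs on a small reverse-mode tape written for this package
(matrix primitives, gather/scatter, segment softmax, the equivariant
custom operations with analytic vector-Jacobian products); every
primitive's gradient is checked against central finite differences in
the test suite.

## Conformers and ensemble training

A single conformer is an arbitrary choice for a flexible molecule, so
both training and prediction use an ensemble. Candidates are embedded
with the ETKDGv3 distance-geometry method and scored with the MMFF94
force field (hydrogens present for the force field, stripped for the
graph) through a small subprocess bridge to RDKit; the pipeline then
visits candidates in energy-ascending order, keeps one only if its
aligned heavy-atom RMSD to every kept candidate exceeds 0.01 angstrom,
and retains the lowest-energy 100 of 200 generated. Alignment uses
Kabsch superposition restricted to proper rotations so that mirror
image conformers of a chiral molecule are not collapsed as duplicates;
processing in energy order biases retention toward low-energy basins.
Both choices are this package's resolutions of genuinely open design
points, recorded here because the frame-independence of a 0.01
angstrom threshold depends on them. If fewer diverse candidates
survive than requested, the ensemble is returned short with a warning:
small rigid molecules legitimately have few conformers.

Training expands the dataset to one graph per (molecule, conformer)
pair, each carrying the molecule's full shift targets. The triangle
inequality guarantees that the error of the ensemble-mean prediction
is bounded by the mean per-conformer error, which licenses treating
conformers as independent training points; the package asserts this
inequality on evaluation runs. Prediction averages one forward pass
per conformer and reports the population standard deviation across
the ensemble as an uncertainty estimate (population 1/N conventions
are used for every standard deviation in the package).

Two heads are trained jointly on a masked mean-absolute-error, with
targets z-scored per nucleus using training statistics stored inside
the model artifact — carbon shifts span roughly 0-200 ppm and proton
shifts 0-10 ppm, so joint training needs comparable scales. Two
learning-rate schedules are provided, matching the two training
regimes: `single_conformer` holds out 5 percent of molecules
(molecule-level, to prevent conformer leakage) and multiplies the rate
by 0.1 when the validation MAE has not improved for 20 epochs;
`ensemble` runs exactly three epochs over the expanded set with the
rate divided by 10 each new epoch. An "epoch" in ensemble mode is one
pass over the expanded conformer-sample list. Batches group graph
samples, not molecules, so a molecule's conformers may land in
different gradient steps.

Cross-validation is stratified by saccharide class (mono/di/tri):
within each class molecules are dealt into k folds with remainders
assigned to the currently smallest folds, so a 375-molecule collection
with 107/153/115 classes yields test folds of 37-38 molecules. Fold
metrics are aggregated as "mean (sd)" with no further correction.
Structure-exclusion splits take an arbitrary predicate over molecules
for extrapolation stress tests.

## The synthetic oracle

Real training data for this model is an external download, so the
package carries a synthetic supervision signal with the same
statistical shape: a fixed catalogue of 17 small polyol/ether/acetyl
molecules (5-20 heavy atoms, stereocentres, pseudo-classes by size in
roughly the 29/41/29 percent proportions of a mono/di/tri collection),
and a shift oracle

    delta(i) = a(element) + b * sum_j exp(-d_ij^2 / sigma^2)
             + c * sum_(j,k) cos(theta_jik) + eps

with the pair sum over atoms within 6 angstrom and the angle sum over
bonded-neighbour pairs. Defaults: a = (C 85, O 55, N 35, other 25),
b = 15, sigma = 1.5 angstrom, c = 8, noise sd 0.3 — chosen once so
carbon-like targets land around 65-110 ppm (inside the 0-200 ppm
window) and the proton mimic (the same value divided by 10) lands
roughly in the 0-10 window. The noise is drawn once per (molecule,
atom) — not per conformer — so the oracle behaves like a single
experimental value observed across many geometries, exactly as
ensemble training assumes. The oracle depends on coordinates only
through distances and angles and is therefore exactly E(3)-invariant,
making it a valid target for invariance-preserving recovery tests;
with c != 0 it carries angular information that pairwise distances of
a single message pass cannot see, which is what separates the l=2
model from its scalars-only ablation.

What the synthetic data does not emulate: real shift physics (no
electronegativity, anisotropy or solvent effects), experimental error
structure, and the size and diversity of a real carbohydrate
collection. Passing the recovery tests demonstrates that the
architecture, gradients, training loop and ensemble machinery work end
to end — not that the package reproduces experimental accuracy, which
requires training on real data at full scale.

## Numerical choices and problem sizes

- Tolerances for E(3) invariance are quoted at 1e-4 in normalised
  units, a level chosen with 32-bit GPU arithmetic in mind; this
  implementation is 64-bit and typically lands near 1e-13.
- Softmax uses per-neighbourhood max subtraction; layer-norm guards
  use eps 1e-6 (scalars) and 1e-12 (rms of l>0 norms), so all-zero
  blocks stay zero.
- Weight initialisation: standard normal for irreps-linear weights
  with 1/sqrt(fan_in) folded into the operation, 1/sqrt(fan_in)-scaled
  normals for the scalar MLPs, zeros for biases, ones for gains.
- The test suite and the acceptance script train 2-layer reduced
  models (hidden `16x0e+8x1o+4x2e`, about 22k parameters) on 50
  catalogue molecules with 5 conformers each for 25 epochs — the
  package's chosen verification scale, at which the held-out
  ensemble-mean MAE lands well inside the 0.25 acceptance ratio (the
  acceptance script reports about 0.17 of the carbon target spread and
  0.03 of the proton spread). The scalars-only ablation is matched in parameter
  count (`24x0e`, within 2 percent) so the comparison isolates the
  geometric representation rather than capacity.
- Deterministic behaviour: every stochastic step (catalogue sampling,
  embedding, validation split, batch order, initialisation) is seeded;
  two runs with the same seed produce identical loss traces, and
  generated ensembles are bit-identical.

## Limitations

- Only the isotropic scalar shift is predicted, not the full
  second-rank shift tensor.
- Conformers are sampled by force-field energy ranking, not by free
  energy; no solvent model and no temperature covariate.
- IUPAC glycan name conversion is out of scope; the package consumes
  SMILES.
- The RDKit bridge requires a `python` interpreter with RDKit on the
  PATH (override with the `EQSHIFT_PYTHON` environment variable);
  everything downstream of parsing and embedding is pure R.
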