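---
title: "Hybrid quantum-classical drug response prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid quantum-classical drug response prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

`hqdr` predicts the half-maximal inhibitory concentration (IC50) of an
anticancer drug on a tumour cell line. A drug is supplied as a SMILES string;
a cell line as a 735-dimensional binary vector of genomic-mutation
indicators (1 = mutation present). The supervised example is the triple
(drug, cell line, raw IC50 > 0). Raw IC50 values span many orders of
magnitude, so targets are squashed into (0, 1) with the logistic-like map

$$\mathrm{norm}(y) = \frac{1}{1 + y^{0.1}}, \qquad y > 0,$$

which is strictly decreasing (potent drugs map high) and has the exact
inverse $y = (1/v - 1)^{10}$, both implemented as `normalize_ic50()` /
`denormalize_ic50()`. The loss is the plain MSE over normalized targets.

## Architecture

Two classical encoder branches produce 128-dimensional embeddings each:

* **Cell branch** — three blocks of (1-D convolution → ReLU → max-pool) over
  the 735-long binary vector, then one dense layer to 128. The reference
  description fixes "three repetitions" and the final 128 but not the channel
  counts, kernel or pool widths; we use channels 32/64/96, kernel 8,
  non-overlapping pool width 3 (all arguments of `cell_encoder_init()`).
  ReLU is applied after every convolution; the reference text does not say
  whether each repetition includes one, and this is our choice.
* **Drug branch** — the SMILES is parsed into a molecular graph
  (`smiles_to_graph()`): one node per heavy atom, symmetric binary adjacency,
  and a 78-dimensional binary feature row per atom (44-slot element one-hot
  ending in an "other" slot, 11-slot one-hots for degree, total hydrogens and
  implicit valence, plus an aromatic flag). Three graph convolutions
  $\mathrm{ReLU}(\hat D^{-1/2}(A+I)\hat D^{-1/2} X W)$ widen the channels
  78 → 78 → 156 → 312 — the only widening consistent with the published
  dense-layer plan 312, 1024, 128 — followed by global max pooling over
  nodes and the two dense layers. Max pooling plus symmetric normalization
  make the embedding invariant under node reordering, which the tests verify
  numerically.

The embeddings are concatenated drug-block-first into a 256-vector
(`fuse()`); the order is arbitrary in the source description and frozen here
for reproducibility.

### The quantum depth-infused head

The 256 fused values are the features $\phi_1,\dots,\phi_{256}$ of an
8-qubit data re-uploading circuit with a lattice of 32 encoding blocks:

1. five initial variational layers;
2. for each block $b = 1..32$: an angle embedding that applies
   $R_Z(\phi_{8(b-1)+j})$ to qubit $j$, then five variational layers with
   their own parameters;
3. measurement propagation: $\mathrm{CNOT}(k \to 1)$ for $k = 2..8$;
4. readout of $\langle Z_1 \rangle \in [-1, 1]$, rescaled by two trainable
   scalars: $\hat y = s\,\langle Z_1\rangle + t$.

A variational layer is one trainable rotation per qubit followed by the
entangling chain $\mathrm{CNOT}(1\to2), \dots, \mathrm{CNOT}(7\to8)$. The
trainable-angle count is $8\times5 + 8\times5\times32 = 1320$, checked
exactly by `count_parameters()`. Design points that the source leaves open,
fixed here:

* **Rotation axis.** The description says only "rotations with trainable
  parameters" while listing X, Y and Z rotations among its gates. We use
  $R_Y$: any single-axis choice yields the printed count of 8 angles per
  layer, and $R_Y$ moves population off the Z axis so that the diagonal
  $R_Z$ encodings become observable. Had the variational rotations also been
  $R_Z$, the circuit would be diagonal and the readout constant.
* **Entangler topology.** "Subsequent CNOT operations" is read as the open
  chain $1\to2\to\dots\to8$, not a ring.
* **Encoding scale.** The feature enters its $R_Z$ with proportionality
  constant 1 (configurable via `encoding_scale`).
* **Propagation order.** The $\mathrm{CNOT}(k\to1)$ chain is applied in
  ascending $k$; the order cannot affect $\langle Z_1\rangle$ (all gates are
  diagonal in the target's computational basis after the final layer) but is
  fixed for reproducibility.
* **Uniform layers.** The five initial layers each end with the entangling
  chain, exactly like the per-block layers.

Basis labelling is little-endian: bit $k$ of a basis-state index is the
state of qubit $k+1$, and qubit 1 is the measured "first" qubit.

Because every feature enters the circuit through exactly one $R_Z$ gate, the
readout is a degree-1 trigonometric polynomial
$a + b\cos\phi_i + c\sin\phi_i$ in any single feature — the data
re-uploading lattice gains expressivity across blocks, not within one gate.
The test suite fits the three coefficients from three probe angles and
checks ten held-out angles to $10^{-9}$.

### The classical twin

For controlled comparisons, `hqdr_model("classical", ...)` replaces the
quantum head with two dense layers of 8 and 1 neurons (ReLU between them —
the activation is unstated in the source and chosen to match every other
junction). Its first layer has $256\times8+8 = 2056$ parameters. Note the
published parameter comparison (1320 vs 2056) counts only that first dense
layer; the classical head's two-layer total is 2065, and
`count_head_parameters()` therefore reports per-layer counts. Both variants
built from one seed share bit-identical trunks.

## Simulation and gradients

The quantum layer runs on an exact dense statevector engine written in C++
(Rcpp): $2^8 = 256$ complex amplitudes, specialized in-place loops for
$R_X$, $R_Y$, $R_Z$ and CNOT. Unitarity holds to machine precision; the
tests bound the norm drift after 10,000 random gates by $10^{-12}$ and check
every gate against dense Kronecker-product oracles.

Gradients use adjoint differentiation: one forward pass, then a single
backward sweep that un-applies each gate and accumulates
$\partial\langle Z_1\rangle/\partial\theta = \mathrm{Im}\,\langle\lambda|P|\psi\rangle$
for each rotation $R_P(\theta)$. This is exact — every angle derivative
equals its parameter-shift value $[f(\theta+\pi/2)-f(\theta-\pi/2)]/2$, which
the tests verify together with central finite differences — and costs about
three circuit evaluations regardless of the 1320-parameter count, where
naive parameter-shift would cost 2640. The same sweep yields the gradient
with respect to the 256 encoded features, which is what backpropagates into
the classical trunk.

The classical trunk's backpropagation is written out explicitly (im2col
convolutions, argmax-routed pooling, dense GCN algebra); finite-difference
checks in the test suite cover every layer type. The optimizer is Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) at the protocol
learning rate $1.8\times10^{-3}$.

## Training protocol

`split_dataset()` applies one seeded shuffle and cuts disjoint train/test
subsets (defaults 5000/1000, or an 80/20 fraction). The training order is
re-shuffled each epoch from a seed derived from (config seed, epoch index);
the test order is frozen. Deriving the shuffle from the global epoch index
makes a run resumable: training 2 + 2 epochs in two calls is bit-identical
to one 4-epoch call, which the tests assert. There is no early stopping.
Batch size (64) and epoch count (100) are defaults, not protocol constants.

Mini-batch gradients reuse embeddings: each unique drug and cell line in a
batch is encoded once and its embedding gradient is the sum over the pairs
that share it. Losses must stay finite; a non-finite batch loss aborts with
the epoch and batch named.

`size_sweep()` trains both variants with identical hyperparameters and trunk
initializations across training sizes and reports final test MSEs and their
signed difference (classical − hybrid, positive = hybrid better). The
published size→test-size triples (50→10, 200→50, 5000→1000) do not follow a
single ratio; the sweep uses that lookup for these three sizes and size/5
otherwise. The sweep is a report, not a test: on small stochastic runs the
sign of the difference varies with the seed, so no monotone trend is
asserted anywhere.

## Synthetic data

`generate_fixtures()` makes the package runnable and testable offline. It
draws drugs from a curated pool of 60 small molecules, samples cell-line
mutation vectors i.i.d. Bernoulli(0.1), and plants the response

$$\log(\mathrm{IC50}) = 1.5\,z_{\mathrm{cell}} + 1.0\,z_{\mathrm{drug}} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

over the full drug × cell cross product, where $z_{\mathrm{cell}}$ is the
standardized count of ones among mutation slots 1–20 and $z_{\mathrm{drug}}$
the standardized heavy-atom count. Both signals are recoverable from the
model's inputs by construction, so the task is solvable; $\sigma = 0.1$ by
default. What the generator does **not** emulate: correlated mutation
patterns, drug-class structure, censored or thresholded IC50 measurements,
and missing pairs (real panels are incomplete — the published panel of 223
drugs × 948 cell lines reports 172,114 measured pairs, far fewer than the
211,404-pair cross product). Passing tests therefore demonstrate the
correctness and trainability of the machinery, not clinical performance.

A note on scale: after normalization the planted targets concentrate near
0.5 (the transform is flat around $y = 1$), so their variance is small. The
learnability tests consequently require the trained model to beat the
*variance of the targets* on held-out pairs — predicting the mean is not
enough — and additionally to drive training MSE below 0.01 under the study
conditions (5 drugs × 40 cell lines, noise 0.1, learning rate
$1.8\times10^{-3}$, at most 300 epochs).

## Problem sizes and tolerances used by the tests

Gate-versus-oracle comparisons run on 2–3 qubits at $10^{-12}$; norm
preservation over 10,000 random gates at $10^{-12}$; gradient checks at 20
random points of the full 8-qubit, 32-block circuit against parameter shift
($10^{-9}$) and central differences ($10^{-5}$ relative, $h = 10^{-6}$);
the single-feature sinusoid fit at $10^{-9}$ on 10 held-out angles.
Training-based tests use 200-pair bundles (5 drugs × 40 cells) with batch
64, and the sweep smoke tests use short runs (15 epochs or fewer); these
sizes were chosen as the smallest at which the planted signal is cleanly
learnable, and they are stated here as the package's reference conditions.

Degenerate inputs are handled explicitly: single-atom molecules (pooling
over one node), empty or unparseable SMILES (named errors), profiles of the
wrong length, IC50 ≤ 0, dangling drug/cell references and duplicate pairs
(named validation errors with row numbers). Global max pooling breaks ties
toward the first node; max-pool remainders at the end of a feature map are
dropped.

## Known limitations

* The SMILES backend is OpenBabel (via ChemmineR/ChemmineOB); node order is
  OpenBabel's atom order and aromaticity is OpenBabel's perception model.
  For atoms whose hydrogens are written explicitly in brackets (e.g.
  pyrrole's `[nH]`), the implicit-valence feature counts those hydrogens,
  which toolkits that track "explicit" hydrogen separately would not.
* Formal-charge handling adds the charge to the default valence, which is
  correct for the common N⁺/O⁻/S⁺ cases but approximate for exotic charged
  carbons.
* The quantum layer is simulated exactly; shot noise, hardware noise and
  shallow-wide circuit reformulations are out of scope.
* Predictions are not clamped to (0, 1): the affine readout can transiently
  leave the target range during training.
* Dropout is available on the fused representation (`dropout` in
  `train_config()`) but defaults to 0, matching the reference protocol,
  which never mentions it.
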