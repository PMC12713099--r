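---
title: "Modeling PROTAC degradation with ternary attention: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PROTAC degradation with ternary attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

A PROTAC (proteolysis targeting chimera) is a heterobifunctional molecule: a
warhead that binds a protein of interest (POI), an E3-ligand that recruits an
E3 ubiquitin ligase, and a linker joining the two. Degradation happens only
when the full POI–PROTAC–E3 ternary complex forms and presents the POI for
ubiquitination, so activity is a property of the *triplet*, not of the
molecule alone. `protactan` frames this as binary classification: given a
PROTAC SMILES and the two protein sequences, predict high (1) versus low (0)
degradation activity, where activity labels are derived from DC50 (the
half-maximal degradation concentration, in nM) and Dmax (the maximal percent
degradation).

## Model

### Hierarchical PROTAC encoder

Each molecule is a 2D heavy-atom graph. Every atom carries nine integer-coded
descriptors (atomic number, chirality code, degree, formal charge, implicit
hydrogen count, radical electrons, hybridization, aromaticity, ring
membership) and every directed edge three (bond type, stereo code,
conjugation). On top of the atom-level view, a molecule-level *global
feature* is appended to every node row: the SMILES string encoded
character-by-character against a fixed 39-symbol vocabulary (length
$|S| = 128$, 0-padded, unknown characters map to 0) concatenated with nine
standardized physicochemical properties. The node width is therefore
$9 + |S| + 9 = 146$ at the defaults. The global feature is computed from the
canonical SMILES so that two writings of the same molecule featurize
identically; together with the permutation-equivariant graph layers this
makes predictions invariant to atom indexing, which the tests assert.

The encoder applies one dense layer (146 to 64) and two edge-aware graph
convolutions (64 to 128 to 128). Each convolution aggregates neighbor
messages under symmetric degree normalization with self-loops; the three
integer bond attributes pass through a learned linear embedding that is
added to the aggregated messages. This is the minimal standard realization
of an edge-conditioned GCN and is isolated behind `encode_protac()` so a
different message function can be substituted without touching the rest of
the model.

### Protein encoders

POI and E3 sequences are embedded by a pluggable protein language model
(PLM) interface: any object with `dim()` and `tokens(sequence)`. Sequences
are truncated at 1022 residues; the embedding width is 1280. A learned
two-layer adapter (1280 to 128 to 64, separate weights for POI and E3) maps
embeddings into the model space. Two modes exist:

* **pooled** — the per-residue matrix is averaged into one 1280-vector
  before the adapter, giving a single substructure column per protein
  ($\alpha = 1$). This matches the averaged sequence representation of the
  encoder design and is the training default because it is fast on CPU.
* **token** — the adapter is applied per residue, keeping one column per
  residue so attention maps resolve to residues. Because the adapter acts
  column-wise, a model trained in pooled mode can run in token mode at
  explanation time with the same weights; only the substructure axis length
  changes, never a tensor width.

The packaged embedder is a deterministic stub that maps each residue letter
to a fixed pseudo-random 1280-vector derived from (seed, letter). It has the
exact interface and shapes of a real PLM, is identical across platforms, and
needs no downloads; all tests run on it. A real PLM can be plugged in by
implementing the same two functions. What the stub does *not* emulate is
context dependence: real PLM embeddings of a residue depend on its
neighbors, the stub's do not. Passing tests therefore demonstrate the
plumbing, optimization, and attention algebra, not biological transfer.

### Ternary attention network (TAN)

Given hidden representations $X_p \in \mathbb{R}^{D_p\times\alpha}$ (POI),
$X_t \in \mathbb{R}^{D_t\times\beta}$ (PROTAC atoms),
$X_e \in \mathbb{R}^{D_e\times\gamma}$ (E3), the attention map is

$$A_{ijl} \;=\; q^{\top}\bigl(\sigma(U^{\top}x_{p_i}) \odot
\sigma(W^{\top}x_{t_j}) \odot \sigma(V^{\top}x_{e_l})\bigr),$$

a 3D tensor scoring every (POI substructure, atom, E3 substructure) triplet.
$U, W, V$ project each entity to a shared latent width $\kappa$; $q$ is a
per-head weight vector. The fusion layer reuses the same projections —
introducing no new parameters — and contracts the map against the three
projected representations:

$$f_k \;=\; \sum_{i,j,l} A_{ijl}\,
\sigma(U^{\top}x_{p_i})_k\,\sigma(W^{\top}x_{t_j})_k\,
\sigma(V^{\top}x_{e_l})_k.$$

This specific contraction is pinned down by two properties that the layer
must satisfy and that the tests check: (i) it introduces no parameters
beyond $U, W, V, q$, and (ii) when the third axis is collapsed
($\gamma = 1$ with its projected factor forced to ones) the whole network
reduces exactly to a bilinear attention network over the remaining two
entities. Substituting the definition of $A$ gives a Gram-matrix form

$$f = (G_p \odot G_t \odot G_e)^{\top} q, \qquad
G_\bullet = Z_\bullet^{\top} Z_\bullet,$$

which the training path uses ($O(\kappa^2)$ instead of
$O(\alpha\beta\gamma\kappa)$, never materializing $A$); when both protein
axes are pooled the POI/E3 Grams are rank one and the fusion further reduces
to vector Hadamards around the single PROTAC Gram. All three routes — loop
definition, materialized tensor algebra, and Gram shortcut — are held
together by oracle-equivalence tests at $10^{-6}$ absolute on double
precision.

Multiple heads share $U, W, V$; each head adds exactly $\kappa$ parameters
(its $q$). Head fusions are summed. The joint vector is average-pooled with
stride $s$ and classified by a two-layer MLP with log-softmax.

There is no softmax normalization of $A$ anywhere: the attention map is used
raw, so exported weights are interaction magnitudes, not distributions.

### Defaults and their provenance

| parameter | default | note |
|---|---|---|
| SMILES code length $|S|$ | 128 | fixes node width 146 |
| protein cap | 1022 residues | PLM context limit |
| PLM width | 1280 | adapter input |
| adapter | [128, 64] | separate POI / E3 instances |
| GCN | [128, 128], edge dim 3 | after the 146 to 64 linear layer |
| heads | 2 | |
| $\kappa$ | 256 | latent width; our choice, unconstrained by the design |
| stride $s$ | 2 | pooling; our choice |
| MLP hidden | 64 | |
| optimizer | Adam, lr 5e-4, batch 4 | |
| epochs | at most 100, patience 30 on val AUROC | best-AUROC checkpoint kept |
| activation $\sigma$ | ReLU everywhere | configurable |

When a train/test split has no validation set, 10% of the training split
(stratified) is carved out as the early-stopping monitor, so the test set
never influences epoch selection.

## Training without a deep-learning framework

No neural-network library is part of this package's dependency set, so
training runs on a small reverse-mode autodiff tape (`R/autodiff.R`)
covering exactly the operations the model needs: matrix product, broadcast
bias addition, Hadamard product, ReLU, transpose, Gram matrix, a fused
transpose-times-vector, scaling, and log-softmax NLL. Every op's gradient,
and the end-to-end gradient of the full model, is verified against central
finite differences (tolerance 1e-3 relative on the composite). Prediction
uses a plain-matrix forward pass that also materializes attention maps; a
dedicated test pins the two forwards to each other at 1e-10.

## Data curation

PROTAC-DB-style tables are parsed with tolerant column-name matching
(`Smiles`, `Uniprot`, `E3 ligase Uniprot`, `DC50 (nM)`, `Dmax (%)`, and any
column containing "assay" or "degradation" as free text). Labeling is
tiered: explicit DC50/Dmax first; if both are absent, values extracted from
assay text by rule (DC50 with pM/nM/µM/mM/M units in either phrase order,
Dmax or "X% degradation" percentages, and qualitative "no degradation"
statements as low-activity evidence). The default cutoffs — DC50 at most
100 nM and Dmax at least 80% for high activity, DC50 above 100 nM or Dmax
below 50% for low, gray zone excluded — follow the established labeling
protocol of prior degradation predictors and are fully configurable; a
missing value never blocks the other criterion.

Two leakage-safe splits are provided. The SMILES-based split canonicalizes
molecules and removes from the test set any record whose molecule also
occurs in training. The similarity-based split removes an evaluation record
only when *all three* similarities to some training record reach the
threshold (default 0.9): molecular Tanimoto on path fingerprints (OpenBabel
FP2, 1024 bits — the configurable default here, as circular fingerprints
are not available in this toolchain), and Needleman–Wunsch global-alignment
identity for POI and E3 (identity matrix +1/0, gap 1, so 0.9 reads as
near-identity; BLOSUM62 selectable). The conjunction is deliberate: a
triplet is only a leak if the molecule *and* both proteins are
near-duplicates.

## Interpretability conventions

Pairwise maps are means of the 3D tensor over the dropped axis; per-atom
weights are means over both protein axes; per-residue weights means over the
other two axes. Heads are combined by mean by default (sum available) —
the two differ only by a constant factor, so rankings are identical either
way. Weights are exported raw, without normalization, so users can
re-normalize as needed. Atom indices are 0-based in canonical atom order;
residue indices are 1-based (UniProt/PDB convention). Selecting the "top
60%" of atoms takes the ceiling of 0.6 times the atom count, ties broken by
ascending index; residue top-k uses the same stable tie-break. Residue-level
attribution requires token-mode maps and raises an explicit error on pooled
maps.

## The synthetic benchmark

`generate_dataset(n, seed)` emulates the three input artifacts offline:

* **Molecules** — warhead + linker + E3-ligand concatenations from a
  packaged library (10 warheads, 10 linkers from rigid alkyl to flexible
  PEG-like, 5 E3-ligand mimics); every product is valid SMILES. Chemical
  realism is not attempted.
* **Proteins** — 12 POIs and 4 E3 ligases, uniform random sequences of
  length 50–300; six POIs carry a planted `WYWYWYWYWY` motif.
* **Signal** — the planted label is 1 iff the warhead is one of the five
  "active" fragments AND the POI carries the motif; classes are balanced by
  drawing the planted label fair-coin and sampling a consistent
  (warhead, POI) combination. Because negatives include active-warhead and
  motif-POI records, neither entity alone separates the classes (either
  alone gives roughly 0.75 AUROC), so clearing the 0.9 AUROC bar requires
  the model to combine molecule and protein information — exercising the
  ternary fusion, not just one encoder. A `molecule_only` rule is available
  for encoder unit tests.
* **Noise** — labels flip with probability 0.05 (our choice of a realistic
  assay-noise level, fixed before any acceptance run); DC50/Dmax values are
  generated consistently with the flipped label, positives in 1–100 nM with
  Dmax 85–100%, negatives in 316–10000 nM with Dmax 5–45%, so curation
  reproduces the generator's labels exactly.
* **Assay text** — 30% of records carry their values only as rendered text
  (nM and µM templates in both phrase orders, percent-degradation phrasing,
  and qualitative negatives), written at full precision so extraction can
  be scored for exact recovery.

The standard study size is n = 400 with an 80/20 SMILES-based split; at that
size the full generate–curate–split–train–evaluate pipeline runs in roughly
seven minutes on one CPU core, and training typically reaches validation
AUROC above 0.95 within the first ten epochs. Unit tests use n = 24–150.

What passing on this benchmark shows: correct featurization, optimization,
attention algebra, leakage control, and that the architecture can learn a
joint molecule–protein rule. What it does not show: performance on real
degradation data, which has correlated chemistry, unbalanced protein usage,
assay heterogeneity, and PLM embeddings with real structural content.

## Numerical choices and degenerate inputs

* Oracle equivalence tolerance 1e-6 absolute (double precision throughout).
* Zero-variance property columns standardize to zero with std set to 1 and
  a warning; property scalers are fit on the training split only and stored
  with the model.
* Single-atom molecules: the graph has no edges; GCN layers reduce to their
  self-loop terms. Zero-bond molecules carry empty edge arrays, and the
  V2000 atom/bond blocks are read directly because the higher-level SDF
  container in the chemistry toolchain cannot represent bond-free
  molecules.
* SMILES syntax is validated (branch/bracket/ring-label balance) before
  conversion because the underlying toolkit silently repairs some malformed
  strings; malformed input raises an error naming the offending SMILES.
* Atom perception (hybridization, implicit hydrogens, conjugation,
  rotatable bonds) is computed from the kekulized structure with simple
  valence rules; chirality and bond-stereo codes are taken from the SDF
  parity/stereo fields and are 0 for the 2D inputs this package targets.
* The 39-symbol SMILES vocabulary is derived at first use from a packaged
  sample of lead-like SMILES by token frequency (Cl/Br as single tokens),
  ties broken lexicographically. The encoding only needs to be fixed and
  documented, not identical to any external table, for the method to work.
* AUROC is trapezoidal (via pROC) and is cross-checked in tests against a
  rank-based Mann–Whitney computation; accuracy and F1 follow the standard
  confusion-matrix formulas at probability threshold 0.5.

## Known limitations

* The stub embedder carries no evolutionary or structural signal; results
  on synthetic data do not transfer to claims about real PROTACs.
* Training is CPU-bound R; it is sized for datasets of order 10^3 samples,
  not 10^5.
* Warhead/linker/E3-ligand decomposition, 3D conformers, and docking-style
  analyses are out of scope; attention maps are exported as data files
  rather than rendered onto structures.
* OpenBabel FP2 path fingerprints stand in for circular fingerprints in the
  similarity split; at a 0.9 threshold both behave as near-duplicate
  detectors, but absolute similarity values are not comparable between the
  two families.
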